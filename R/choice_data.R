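#' Trial-level choice data and per-participant count tables
#'
#' Two-triplet context-effect experiments present the same core pair
#' (target/competitor) inside two three-option sets ("contexts") that differ
#' only in the third option (the decoy).  The raw data are trial records:
#' which role the chosen option played, in which context, for which
#' participant and effect type.  All measures and models in this package
#' consume the per-participant choice frequencies of the three roles in the
#' two contexts, held in a counts table with one row per participant
#' \eqn{\times} effect and columns `n_t_C1, n_c_C1, n_d_C1, n_t_C2, n_c_C2,
#' n_d_C2`.
#'
#' @name choice-data
NULL

.cfx_roles <- c("target", "competitor", "decoy")
.cfx_contexts <- c("C1", "C2")
.cfx_effects <- c("attraction", "similarity", "compromise", "other")
.cfx_trial_cols <- c("participant_id", "effect", "context", "chosen_role")
.cfx_count_cols <- c("n_t_C1", "n_c_C1", "n_d_C1", "n_t_C2", "n_c_C2", "n_d_C2")

#' Construct a per-participant count table
#'
#' @param n_t_C1,n_c_C1,n_d_C1 choice frequencies of target, competitor and
#'   decoy in context 1 (vectors recycle to a common length).
#' @param n_t_C2,n_c_C2,n_d_C2 the same frequencies in context 2.
#' @param participant_id,effect optional labels; defaults are `p1, p2, ...`
#'   and `"other"`.
#' @return A `cfx_counts` data frame with one row per participant
#'   \eqn{\times} effect.
#' @examples
#' context_counts(30, 20, 0, 10, 15, 0)
#' @export
context_counts <- function(n_t_C1, n_c_C1, n_d_C1 = 0,
                           n_t_C2, n_c_C2, n_d_C2 = 0,
                           participant_id = NULL, effect = "other") {
  counts <- data.frame(n_t_C1 = n_t_C1, n_c_C1 = n_c_C1, n_d_C1 = n_d_C1,
                       n_t_C2 = n_t_C2, n_c_C2 = n_c_C2, n_d_C2 = n_d_C2)
  n <- nrow(counts)
  counts <- cbind(
    data.frame(participant_id = as.character(participant_id %||% paste0("p", seq_len(n))),
               effect = rep_len(as.character(effect), n),
               stringsAsFactors = FALSE),
    counts)
  validate_counts(counts)
}

#' Validate a count table or a trial table built in code
#'
#' `validate_counts()` checks the six-frequency schema (nonnegative integer
#' counts, required columns) and stamps the `cfx_counts` class;
#' `validate_trials()` checks the categorical labels of a trial-level data
#' frame and stamps `cfx_trials`.  Both are applied automatically by the
#' readers; call them directly when assembling tables programmatically.
#'
#' @param counts,trials a data frame in the respective format.
#' @return The validated, classed data frame.
#' @export
validate_counts <- function(counts) {
  missing <- setdiff(c(.cfx_trial_cols[1:2], .cfx_count_cols), names(counts))
  if (length(missing))
    cfx_abort(sprintf("count table lacks column(s): %s",
                      paste(missing, collapse = ", ")), "cfx_schema_error")
  m <- as.matrix(counts[.cfx_count_cols])
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    cfx_abort("choice frequencies must be nonnegative integers",
              "cfx_validation_error")
  counts <- counts[c(.cfx_trial_cols[1:2], .cfx_count_cols)]
  class(counts) <- c("cfx_counts", "data.frame")
  counts
}

read_mapping <- function(col_map) {
  if (is.null(col_map)) return(NULL)
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    col_map <- if (grepl("\\.ya?ml$", col_map) &&
                   requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(col_map)
    } else {
      jsonlite::read_json(col_map, simplifyVector = TRUE)
    }
  }
  unlist(col_map)
}

#' Read trial-level choice data from a delimited file
#'
#' Expects a header with the columns `participant_id`, `effect`, `context`
#' and `chosen_role`; other columns are ignored.  `col_map` renames
#' nonstandard headers, either as a named character vector
#' (`c(chosen_role = "choice")`) or as a path to a small YAML/JSON file with
#' the same mapping.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma; use `"\t"` for TSV).
#' @param col_map optional mapping from standard to file column names.
#' @return A `cfx_trials` data frame with validated categorical labels:
#'   `context` in `C1`/`C2`, `chosen_role` in `target`/`competitor`/`decoy`.
#' @export
read_choice_trials <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path))
    cfx_abort(sprintf("file not found: %s", path), "cfx_schema_error")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  map <- read_mapping(col_map)
  for (std in names(map)) {
    if (map[[std]] %in% names(raw))
      names(raw)[names(raw) == map[[std]]] <- std
  }
  missing <- setdiff(.cfx_trial_cols, names(raw))
  if (length(missing))
    cfx_abort(sprintf("input lacks required column(s): %s",
                      paste(missing, collapse = ", ")), "cfx_schema_error")
  trials <- raw[.cfx_trial_cols]
  validate_trials(trials)
}

#' @rdname validate_counts
#' @export
validate_trials <- function(trials) {
  bad_role <- which(!trials$chosen_role %in% .cfx_roles)
  if (length(bad_role))
    cfx_abort(sprintf("unknown chosen_role '%s' at row %d (allowed: %s)",
                      trials$chosen_role[bad_role[1]], bad_role[1],
                      paste(.cfx_roles, collapse = ", ")),
              "cfx_validation_error")
  bad_ctx <- which(!trials$context %in% .cfx_contexts)
  if (length(bad_ctx))
    cfx_abort(sprintf("unknown context '%s' at row %d (allowed: %s)",
                      trials$context[bad_ctx[1]], bad_ctx[1],
                      paste(.cfx_contexts, collapse = ", ")),
              "cfx_validation_error")
  bad_eff <- which(!trials$effect %in% .cfx_effects)
  if (length(bad_eff))
    cfx_abort(sprintf("unknown effect '%s' at row %d (allowed: %s)",
                      trials$effect[bad_eff[1]], bad_eff[1],
                      paste(.cfx_effects, collapse = ", ")),
              "cfx_validation_error")
  class(trials) <- c("cfx_trials", "data.frame")
  trials
}

#' Write trial-level data or a count table to a delimited file
#'
#' @param x a `cfx_trials` or `cfx_counts` data frame.
#' @param path destination file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate trials into per-participant choice frequencies
#'
#' Tallies, for every participant \eqn{\times} effect cell, how often each
#' role (target, competitor, decoy) was chosen in each context.  Cells with
#' no trials at all are absent from the result; the six counts of every
#' returned row sum to that cell's number of trials.
#'
#' @param trials a `cfx_trials` data frame (see [read_choice_trials()]).
#' @return A `cfx_counts` data frame.
#' @export
aggregate_counts <- function(trials) {
  if (nrow(trials) == 0) {
    warning("no trials supplied; returning an empty count table")
    return(context_counts(integer(0), integer(0), integer(0),
                          integer(0), integer(0), integer(0),
                          participant_id = character(0), effect = character(0)))
  }
  trials <- validate_trials(as.data.frame(trials))
  tab <- table(cell = paste(trials$participant_id, trials$effect, sep = "\r"),
               role = factor(trials$chosen_role, .cfx_roles),
               context = factor(trials$context, .cfx_contexts))
  cells <- do.call(rbind, strsplit(dimnames(tab)$cell, "\r", fixed = TRUE))
  counts <- data.frame(
    participant_id = cells[, 1], effect = cells[, 2],
    n_t_C1 = as.integer(tab[, "target", "C1"]),
    n_c_C1 = as.integer(tab[, "competitor", "C1"]),
    n_d_C1 = as.integer(tab[, "decoy", "C1"]),
    n_t_C2 = as.integer(tab[, "target", "C2"]),
    n_c_C2 = as.integer(tab[, "competitor", "C2"]),
    n_d_C2 = as.integer(tab[, "decoy", "C2"]),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  validate_counts(counts)
}

#' Read a pre-aggregated count table
#'
#' Accepts the six-frequency format in which reanalysis datasets are
#' distributed: one row per participant (optionally per effect) with columns
#' `n_t_C1, n_c_C1, n_d_C1, n_t_C2, n_c_C2, n_d_C2`.  Missing decoy columns
#' default to zero (binary-choice data carry no decoy counts).
#'
#' @inheritParams read_choice_trials
#' @return A `cfx_counts` data frame.
#' @export
read_context_counts <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path))
    cfx_abort(sprintf("file not found: %s", path), "cfx_schema_error")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  map <- read_mapping(col_map)
  for (std in names(map)) {
    if (map[[std]] %in% names(raw))
      names(raw)[names(raw) == map[[std]]] <- std
  }
  if (!"participant_id" %in% names(raw))
    raw$participant_id <- paste0("p", seq_len(nrow(raw)))
  if (!"effect" %in% names(raw)) raw$effect <- "other"
  for (d in c("n_d_C1", "n_d_C2")) if (!d %in% names(raw)) raw[[d]] <- 0L
  validate_counts(raw)
}

#' Keep only cells on which relative choice shares are defined
#'
#' A within-context share is undefined (0/0) for a participant who never
#' chose the target or competitor in that context; such cells cannot enter
#' the hierarchical fits and are dropped with a message.
#'
#' @param counts a `cfx_counts` data frame.
#' @return The filtered `cfx_counts`.
#' @export
model_ready_counts <- function(counts) {
  ok <- (counts$n_t_C1 + counts$n_c_C1 >= 1) & (counts$n_t_C2 + counts$n_c_C2 >= 1)
  if (any(!ok))
    message(sprintf(
      "dropping %d cell(s) with no target/competitor choices in a context", sum(!ok)))
  out <- counts[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cfx_counts", "data.frame")
  out
}
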