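#' Choice-share measures for two-triplet context-effect designs
#'
#' Let \eqn{n_{t,Cs}}, \eqn{n_{c,Cs}}, \eqn{n_{d,Cs}} be how often a
#' participant chose the target, competitor and decoy in context
#' \eqn{s \in \{1, 2\}}.  The *relative choice share of the target* comes in
#' two forms:
#'
#' \deqn{RST_{UW} = \frac{n_{t,C1} + n_{t,C2}}
#'                       {n_{t,C1} + n_{t,C2} + n_{c,C1} + n_{c,C2}},}
#' \deqn{RST_{EW} = \tfrac12\left(\frac{n_{t,C1}}{n_{t,C1} + n_{c,C1}} +
#'                          \frac{n_{t,C2}}{n_{t,C2} + n_{c,C2}}\right).}
#'
#' `UW` collapses counts across contexts, which weights the two within-set
#' shares by their sample sizes ("unequal weights"); `EW` averages the two
#' shares with equal weights and is unbiased under unequal sample sizes.
#' The two coincide exactly when both contexts have the same number of
#' target + competitor choices.  Values above 0.5 indicate a violation of
#' independence from irrelevant alternatives in the direction of the effect.
#'
#' The *absolute choice shares* divide by all three roles and test the
#' regularity principle instead:
#' \deqn{AST = \tfrac12\sum_s \frac{n_{t,Cs}}{n_{t,Cs} + n_{c,Cs} + n_{d,Cs}},
#'  \quad
#'  ASC = \tfrac12\sum_s \frac{n_{c,Cs}}{n_{t,Cs} + n_{c,Cs} + n_{d,Cs}}.}
#' Regularity is satisfied when both are at or below 0.5; AST > 0.5 signals
#' an attraction effect, ASC > 0.5 its reversal (repulsion).
#'
#' All three functions are vectorised over the rows of a [context_counts()]
#' table and return full-precision values; rounding is left to reporting.
#'
#' @param counts a `cfx_counts` data frame (or anything [validate_counts()]
#'   accepts).
#' @return A data frame with one row per input row: the participant/effect
#'   labels, the within-context shares (`share_C1`, `share_C2`) and the
#'   measure `value` (for [absolute_shares()]: `ast` and `asc` with their
#'   per-context shares).
#' @examples
#' cc <- context_counts(30, 20, 0, 10, 15, 0)
#' rst_uw(cc)$value   # 40/75 = 0.533...
#' rst_ew(cc)$value   # (0.6 + 0.4)/2 = 0.5
#' @name rst
NULL

#' @rdname rst
#' @export
rst_uw <- function(counts) {
  counts <- validate_counts(as.data.frame(counts))
  denom <- counts$n_t_C1 + counts$n_c_C1 + counts$n_t_C2 + counts$n_c_C2
  if (any(denom < 1))
    cfx_abort("RST_UW undefined: no target or competitor choices in either context",
              "cfx_measure_error")
  data.frame(participant_id = counts$participant_id, effect = counts$effect,
             share_C1 = counts$n_t_C1 / (counts$n_t_C1 + counts$n_c_C1),
             share_C2 = counts$n_t_C2 / (counts$n_t_C2 + counts$n_c_C2),
             value = (counts$n_t_C1 + counts$n_t_C2) / denom,
             measure = "rst_uw", stringsAsFactors = FALSE)
}

#' @rdname rst
#' @export
rst_ew <- function(counts) {
  counts <- validate_counts(as.data.frame(counts))
  d1 <- counts$n_t_C1 + counts$n_c_C1
  d2 <- counts$n_t_C2 + counts$n_c_C2
  if (any(d1 < 1) || any(d2 < 1))
    cfx_abort("RST_EW undefined: a context has no target or competitor choices",
              "cfx_measure_error")
  s1 <- counts$n_t_C1 / d1
  s2 <- counts$n_t_C2 / d2
  data.frame(participant_id = counts$participant_id, effect = counts$effect,
             share_C1 = s1, share_C2 = s2, value = 0.5 * (s1 + s2),
             measure = "rst_ew", stringsAsFactors = FALSE)
}

#' @rdname rst
#' @export
absolute_shares <- function(counts) {
  counts <- validate_counts(as.data.frame(counts))
  d1 <- counts$n_t_C1 + counts$n_c_C1 + counts$n_d_C1
  d2 <- counts$n_t_C2 + counts$n_c_C2 + counts$n_d_C2
  if (any(d1 < 1) || any(d2 < 1))
    cfx_abort("absolute shares undefined: a context has no choices at all",
              "cfx_measure_error")
  data.frame(participant_id = counts$participant_id, effect = counts$effect,
             ast_C1 = counts$n_t_C1 / d1, ast_C2 = counts$n_t_C2 / d2,
             asc_C1 = counts$n_c_C1 / d1, asc_C2 = counts$n_c_C2 / d2,
             ast = 0.5 * (counts$n_t_C1 / d1 + counts$n_t_C2 / d2),
             asc = 0.5 * (counts$n_c_C1 / d1 + counts$n_c_C2 / d2),
             stringsAsFactors = FALSE)
}

#' Compute a choice-share measure by name
#'
#' @inheritParams rst
#' @param measure one of `"rst_uw"`, `"rst_ew"`, `"ast"`, `"asc"`.
#' @return A data frame as in [rst_uw()], with a `value` column.
#' @export
choice_share <- function(counts, measure = c("rst_uw", "rst_ew", "ast", "asc")) {
  measure <- match.arg(measure)
  switch(measure,
    rst_uw = rst_uw(counts),
    rst_ew = rst_ew(counts),
    ast = {
      a <- absolute_shares(counts)
      data.frame(participant_id = a$participant_id, effect = a$effect,
                 share_C1 = a$ast_C1, share_C2 = a$ast_C2, value = a$ast,
                 measure = "ast", stringsAsFactors = FALSE)
    },
    asc = {
      a <- absolute_shares(counts)
      data.frame(participant_id = a$participant_id, effect = a$effect,
                 share_C1 = a$asc_C1, share_C2 = a$asc_C2, value = a$asc,
                 measure = "asc", stringsAsFactors = FALSE)
    })
}

#' One-sample t test on per-participant choice shares
#'
#' The frequentist companion test: does the mean share across participants
#' differ from the no-effect value 0.5 (or another null)?  A thin wrapper
#' around [stats::t.test()] that enforces the degenerate-sample guard.
#'
#' @param values numeric vector of per-participant shares.
#' @param null_value the null mean (default 0.5).
#' @param sidedness `"two_sided"` or `"greater"` (one-sided, effect above the
#'   null, as used for AST-style directional hypotheses).
#' @return A `cfx_ttest` list: `statistic`, `df`, `p_value`, `sidedness`,
#'   `estimate`.
#' @export
rst_t_test <- function(values, null_value = 0.5,
                       sidedness = c("two_sided", "greater")) {
  sidedness <- match.arg(sidedness)
  values <- as.numeric(values)
  if (length(values) < 2)
    cfx_abort("t test needs at least two values", "cfx_degenerate_error")
  if (stats::var(values) == 0)
    cfx_abort("t test undefined: sample variance is zero", "cfx_degenerate_error")
  ht <- stats::t.test(values, mu = null_value,
                      alternative = if (sidedness == "greater") "greater" else "two.sided")
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, sidedness = sidedness,
                 estimate = unname(ht$estimate), null_value = null_value),
            class = "cfx_ttest")
}

#' @export
print.cfx_ttest <- function(x, ...) {
  cat(sprintf("One-sample t test (%s): t(%g) = %.3f, p = %.4g, mean = %.4f vs %.2f\n",
              x$sidedness, x$df, x$statistic, x$p_value, x$estimate, x$null_value))
  invisible(x)
}
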