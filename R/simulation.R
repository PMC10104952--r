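#' Configuration of the synthetic two-triplet data generator
#'
#' The generator emulates the reference simulation design: a population of
#' participants whose per-context target rates are drawn from beta
#' distributions with means \eqn{\mu_1, \mu_2} and common concentration
#' \eqn{\kappa}; context 1 always has `n_max` target/competitor trials;
#' context 2 loses a per-participant number of trials drawn from a normal
#' distribution centred on the intended sample-size difference
#' (`delta_mean`) with spread `delta_sd`, truncated to `[0, n_max - 1]` and
#' rounded, so at least one observation always remains.  Defaults are the
#' study conditions: 55 participants, \eqn{\kappa = 5}, 60 trials per
#' context, difference spread 5.
#'
#' @param n_participants number of simulated participants.
#' @param mu_1,mu_2 generating group mean rates per context.
#' @param kappa generating concentration of the parent beta distribution.
#' @param n_max trials per context before any imbalance.
#' @param delta_mean intended sample-size difference (0 to `n_max - 1`).
#' @param delta_sd spread of per-participant differences.
#' @param deplete which context loses trials (default `"C2"`).
#' @param effect effect label written into the counts.
#' @param seed default seed used by [generate_dataset()].
#' @return A `cfx_generator_config` list.
#' @export
generator_config <- function(n_participants = 55, mu_1 = 0.5, mu_2 = 0.5,
                             kappa = 5, n_max = 60, delta_mean = 0,
                             delta_sd = 5, deplete = c("C2", "C1"),
                             effect = "other", seed = 1) {
  deplete <- match.arg(deplete)
  stopifnot(n_participants >= 1, mu_1 > 0, mu_1 < 1, mu_2 > 0, mu_2 < 1,
            kappa > 0, n_max >= 1, delta_mean >= 0, delta_mean <= n_max - 1,
            delta_sd >= 0)
  structure(list(n_participants = as.integer(n_participants),
                 mu_1 = mu_1, mu_2 = mu_2, kappa = kappa,
                 n_max = as.integer(n_max), delta_mean = delta_mean,
                 delta_sd = delta_sd, deplete = deplete, effect = effect,
                 seed = seed),
            class = "cfx_generator_config")
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(round(rep(mean, n)), lo), hi))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(round(stats::qnorm(p, mean, sd)), lo), hi)
}

#' Generate a synthetic two-triplet dataset
#'
#' @param config a [generator_config()].
#' @param seed integer seed (defaults to the config's).
#' @return A `cfx_counts` table with one row per participant; decoy counts
#'   are zero (the generator models target/competitor choices only, as the
#'   relative-share models require).
#' @examples
#' cc <- generate_dataset(generator_config(n_participants = 5, seed = 42))
#' @export
generate_dataset <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_participants
  th1 <- clamp_unit(stats::rbeta(n, config$mu_1 * config$kappa,
                                 (1 - config$mu_1) * config$kappa))
  th2 <- clamp_unit(stats::rbeta(n, config$mu_2 * config$kappa,
                                 (1 - config$mu_2) * config$kappa))
  d <- rtruncnorm_int(n, config$delta_mean, config$delta_sd, 0, config$n_max - 1)
  N_dep <- config$n_max - d
  if (config$deplete == "C2") { N1 <- rep(config$n_max, n); N2 <- N_dep }
  else { N1 <- N_dep; N2 <- rep(config$n_max, n) }
  y1 <- stats::rbinom(n, N1, th1)
  y2 <- stats::rbinom(n, N2, th2)
  context_counts(y1, N1 - y1, 0, y2, N2 - y2, 0,
                 participant_id = sprintf("p%02d", seq_len(n)),
                 effect = config$effect)
}

#' Simulation study of sample-size-imbalance bias in RST inference
#'
#' For every imbalance level and replicate, a dataset is generated, both RST
#' measures' alternative and null hierarchical models are fitted to the
#' *same* data, marginal likelihoods are estimated by bridge sampling, and
#' the log Bayes factor and categorical decision are recorded (plus the
#' frequentist one-sample t tests on the per-participant shares).  Under
#' `scenario = "null_true"` the generating means mirror about 0.5
#' (\eqn{\mu_1 = p}, \eqn{\mu_2 = 1 - p}: no IIA violation, average share
#' 0.5); under `"alternative_true"` both contexts share the same mean
#' \eqn{p \ne 0.5}.
#'
#' At the reference scale (59 levels \eqn{\times} 100 replicates) this is a
#' compute-day job; the defaults here are a reduced grid that preserves the
#' qualitative contrast.  Individual fit failures are recorded per cell and
#' the study continues.
#'
#' @param levels integer vector of intended sample-size differences.
#' @param reps replicates per level.
#' @param scenario `"null_true"` or `"alternative_true"`.
#' @param effect_level the generating rate level \eqn{p} (0.50, 0.55, 0.60
#'   in the reference design).
#' @param config base [generator_config()] supplying participants,
#'   concentration, trial counts and difference spread.
#' @param control [mcmc_control()] for every fit.
#' @param seed integer master seed; each (level, rep) cell derives its own.
#' @param t_tests also run the frequentist arm.
#' @return A `cfx_study` object with `$records` (one row per level
#'   \eqn{\times} rep \eqn{\times} measure) and `$summary` (per-level mean
#'   log BF10 with a 95% confidence interval).
#' @export
run_study <- function(levels = c(0, 20, 40), reps = 10,
                      scenario = c("null_true", "alternative_true"),
                      effect_level = 0.55,
                      config = generator_config(),
                      control = mcmc_control(iter = 800, warmup = 300,
                                             quiet = TRUE),
                      seed = 1, t_tests = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(effect_level > 0, effect_level < 1)
  if (scenario == "null_true") {
    config$mu_1 <- effect_level; config$mu_2 <- 1 - effect_level
  } else {
    config$mu_1 <- effect_level; config$mu_2 <- effect_level
  }
  rows <- list()
  for (li in seq_along(levels)) {
    config$delta_mean <- levels[li]
    for (r in seq_len(reps)) {
      cell_seed <- ((seed %% 20000) * 100000 + li * 1000 + r) %% 2147483647
      cc <- generate_dataset(config, seed = cell_seed)
      for (measure in c("rst_uw", "rst_ew")) {
        rec <- data.frame(delta_mean = levels[li], dataset_index = r,
                          measure = measure, log_bf10 = NA_real_,
                          decision = NA_character_, max_rhat = NA_real_,
                          t_p_value = NA_real_, error = NA_character_,
                          stringsAsFactors = FALSE)
        res <- tryCatch(
          context_test(cc, measure, control = control, seed = cell_seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          rec$error <- conditionMessage(res)
        } else {
          rec$log_bf10 <- res$log_bf10
          rec$decision <- res$decision_bf
          rec$max_rhat <- res$diagnostics$max_rhat
        }
        if (t_tests) {
          vals <- choice_share(cc, measure)$value
          rec$t_p_value <- tryCatch(rst_t_test(vals)$p_value,
                                    error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, rows)
  ok <- records[!is.na(records$log_bf10), ]
  if (nrow(ok) == 0) {
    summary <- data.frame(delta_mean = numeric(0), measure = character(0),
                          n = integer(0), mean_log_bf10 = numeric(0),
                          ci_lower = numeric(0), ci_upper = numeric(0),
                          prop_supports_alt = numeric(0))
    return(structure(list(records = records, summary = summary,
                          levels = levels, reps = reps, scenario = scenario,
                          effect_level = effect_level, config = config,
                          control = control, seed = seed),
                     class = "cfx_study"))
  }
  summary <- do.call(rbind, lapply(split(ok, list(ok$delta_mean, ok$measure),
                                         drop = TRUE), function(g) {
    m <- mean(g$log_bf10); s <- stats::sd(g$log_bf10); k <- nrow(g)
    ci <- if (k > 1) stats::qt(0.975, k - 1) * s / sqrt(k) else NA_real_
    data.frame(delta_mean = g$delta_mean[1], measure = g$measure[1],
               n = k, mean_log_bf10 = m, ci_lower = m - ci, ci_upper = m + ci,
               prop_supports_alt = mean(g$decision == "supports_alternative"),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[order(summary$measure, summary$delta_mean), ]
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, levels = levels,
                 reps = reps, scenario = scenario,
                 effect_level = effect_level, config = config,
                 control = control, seed = seed),
            class = "cfx_study")
}

#' @export
print.cfx_study <- function(x, ...) {
  cat(sprintf("Imbalance-bias study: scenario %s, level p = %.2f, %d reps x levels {%s}\n",
              x$scenario, x$effect_level, x$reps,
              paste(x$levels, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
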