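#' Per-participant shares for pairs of context effects
#'
#' Computes one choice-share value per participant for each of two effects,
#' keeping only participants present for both (a complete-pairs design is
#' required for a correlation).
#'
#' @param counts a `cfx_counts` table with an `effect` column.
#' @param effects character vector of two effect labels.
#' @param measure which share to compute (see [choice_share()]).
#' @return A data frame `participant_id`, `x`, `y` (shares for the first
#'   and second effect).
#' @export
participant_effect_values <- function(counts,
                                      effects = c("attraction", "compromise"),
                                      measure = c("rst_uw", "rst_ew", "ast", "asc")) {
  measure <- match.arg(measure)
  stopifnot(length(effects) == 2)
  counts <- validate_counts(as.data.frame(counts))
  counts <- model_ready_counts(counts)
  vals <- choice_share(counts, measure)
  a <- vals[vals$effect == effects[1], c("participant_id", "value")]
  b <- vals[vals$effect == effects[2], c("participant_id", "value")]
  pairs <- merge(a, b, by = "participant_id", suffixes = c("_x", "_y"))
  dropped <- length(union(a$participant_id, b$participant_id)) - nrow(pairs)
  if (dropped > 0)
    message(sprintf("dropping %d participant(s) missing one of the effects",
                    dropped))
  if (nrow(pairs) == 0)
    cfx_abort("no participant has values for both effects",
              "cfx_insufficient_error")
  data.frame(participant_id = pairs$participant_id,
             x = pairs$value_x, y = pairs$value_y, stringsAsFactors = FALSE)
}

# Bivariate-normal log posterior on the unconstrained scale
# (m1, m2, log s1, log s2, atanh r), with flat-normal priors on the means,
# half-normal priors on the scales, uniform prior on the correlation.
bvn_log_post <- function(p, x, y) {
  m1 <- p[1]; m2 <- p[2]; s1 <- exp(p[3]); s2 <- exp(p[4]); r <- tanh(p[5])
  n <- length(x)
  u <- (x - m1) / s1; v <- (y - m2) / s2
  om <- 1 - r^2
  ll <- -n * (log(2 * pi) + log(s1) + log(s2) + 0.5 * log(om)) -
    sum(u^2 - 2 * r * u * v + v^2) / (2 * om)
  lp <- stats::dnorm(m1, 0.5, 10, log = TRUE) + stats::dnorm(m2, 0.5, 10, log = TRUE) +
    stats::dnorm(s1, 0, 1, log = TRUE) + stats::dnorm(s2, 0, 1, log = TRUE) +
    p[3] + p[4] +              # Jacobians of log scales
    log(om)                    # uniform prior on r + Jacobian of atanh
  out <- ll + lp
  if (is.nan(out)) -Inf else out
}

#' Bayesian correlation between two context effects
#'
#' Models the paired per-participant shares as bivariate normal and reports
#' the posterior of the correlation parameter under a uniform prior on
#' \eqn{(-1, 1)} (flat-normal priors on the means, half-normal on the
#' scales).  Sampling is by adaptive random-walk Metropolis on the
#' unconstrained scale.
#'
#' @param x,y paired numeric vectors, or `x` a data frame with `x` and `y`
#'   columns (as from [participant_effect_values()]).
#' @param control an [mcmc_control()] object.
#' @param seed integer seed.
#' @param mass HDI probability mass.
#' @return A `cfx_corr` object: posterior `mean_r`, `hdi`, draws of `r`,
#'   split R-hat.
#' @export
correlate_effects <- function(x, y = NULL,
                              control = mcmc_control(iter = 2000, warmup = 500),
                              seed = 1, mass = 0.95) {
  if (is.null(y)) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    cfx_abort("need at least 3 pairs", "cfx_insufficient_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    cfx_abort("a margin has zero variance; correlation undefined",
              "cfx_degenerate_error")
  n_kept <- control$iter - control$warmup
  draws_r <- matrix(NA_real_, n_kept, control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(((seed %% 2100000) * 1000 + ch * 13) %% 2147483647)
    p <- c(mean(x), mean(y), log(stats::sd(x)), log(stats::sd(y)),
           atanh(min(max(stats::cor(x, y), -0.99), 0.99))) +
      stats::rnorm(5, 0, 0.1)
    ls <- rep(log(0.2), 5)
    lp <- bvn_log_post(p, x, y)
    for (it in seq_len(control$iter)) {
      for (j in 1:5) {
        pp <- p; pp[j] <- p[j] + exp(ls[j]) * stats::rnorm(1)
        lpp <- bvn_log_post(pp, x, y)
        d <- lpp - lp
        a <- if (is.nan(d)) 0 else exp(min(0, d))
        if (stats::runif(1) < a) { p <- pp; lp <- lpp }
        if (it <= control$warmup)
          ls[j] <- ls[j] + (a - control$adapt_target) / sqrt(it)
      }
      if (it > control$warmup) draws_r[it - control$warmup, ch] <- tanh(p[5])
    }
  }
  rh <- split_rhat(draws_r)
  r <- as.vector(draws_r)
  structure(list(mean_r = mean(r), hdi = hdi(r, mass), mass = mass,
                 draws = r, rhat = rh, n = length(x), seed = seed),
            class = "cfx_corr")
}

#' @export
print.cfx_corr <- function(x, ...) {
  cat(sprintf("Bayesian correlation (n = %d): r = %.3f, %g%% HDI [%.3f, %.3f] (R-hat %.3f)\n",
              x$n, x$mean_r, 100 * x$mass, x$hdi[1], x$hdi[2], x$rhat))
  invisible(x)
}
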