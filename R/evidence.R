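#' Bridge-sampling estimate of the log marginal likelihood
#'
#' Implements the iterative optimal-bridge estimator (Meng & Wong fixed
#' point) with a multivariate-normal proposal on the unconstrained
#' parameter scale.  The first half of the posterior draws fits the proposal
#' (moment matching); the second half enters the bridge iteration together
#' with an equal number of fresh proposal draws.  The fixed point is
#' iterated until the relative change falls below `tol`.
#'
#' @param samples a `cfx_samples` object, or a plain matrix of posterior
#'   draws (rows = draws) on the scale on which `log_density` is written.
#' @param log_density joint log-density (posterior kernel) taking a matrix
#'   of draws and returning a vector; defaults to the model's own
#'   unconstrained-scale density when `samples` is a `cfx_samples`.
#' @param seed integer seed for the proposal draws.
#' @param tol relative-change convergence tolerance of the fixed point.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @return A `cfx_bridge` list: `logml` (nats), `error` (approximate
#'   relative root-mean-squared error of the estimate, also its standard
#'   error in nats), `n_iter`, `n_draws`.
#' @examples
#' # 1-d standard-normal "posterior" with unnormalised kernel exp(-x^2/2):
#' # bridge recovers the normalising constant log(sqrt(2*pi))
#' x <- matrix(rnorm(4000))
#' b <- bridge_logml(x, function(m) -m[, 1]^2 / 2, seed = 1)
#' b$logml - log(sqrt(2 * pi))
#' @export
bridge_logml <- function(samples, log_density = NULL, seed = 1,
                         tol = 1e-10, max_iter = 1000) {
  if (inherits(samples, "cfx_samples")) {
    model <- samples$model
    if (is.null(log_density))
      log_density <- function(m) cfx_log_density(model, m)
    U <- samples$unconstrained
  } else U <- as.matrix(samples)
  if (is.null(log_density))
    cfx_abort("log_density must be supplied for plain draw matrices",
              "cfx_schema_error")
  ntot <- nrow(U)
  if (ntot < 4) cfx_abort("too few posterior draws", "cfx_validation_error")
  half <- ntot %/% 2L
  # Interleave so both halves cover all chains evenly.
  fit_idx <- seq(1L, ntot, by = 2L)[seq_len(half)]
  U_fit <- U[fit_idx, , drop = FALSE]
  U_est <- U[-fit_idx, , drop = FALSE]
  m <- colMeans(U_fit)
  S <- stats::cov(U_fit)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    warning("proposal covariance singular; ridge regularization applied",
            call. = FALSE)
    S <- S + diag(1e-8 + 1e-6 * mean(diag(S)), ncol(S))
    R <- chol(S)
  }
  n1 <- nrow(U_est)                       # posterior draws in the estimator
  n2 <- n1                                # proposal draws
  set.seed(seed)
  Q <- matrix(stats::rnorm(n2 * ncol(U)), n2) %*% R +
    rep(m, each = n2)
  ldet <- sum(log(diag(R)))
  lq <- function(X) {
    Z <- forwardsolve(t(R), t(X) - m)
    -0.5 * colSums(Z^2) - ldet - 0.5 * ncol(U) * log(2 * pi)
  }
  l1 <- log_density(Q) - lq(Q)            # proposal draws
  l2 <- log_density(U_est) - lq(U_est)    # posterior draws
  lstar <- stats::median(l1[is.finite(l1)])
  e1 <- exp(l1 - lstar); e1[!is.finite(l1)] <- 0
  e2 <- exp(l2 - lstar)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  r <- exp(stats::median(l2) - lstar)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    num <- mean(e1 / (s1 * e1 + s2 * r))
    den <- mean(1 / (s1 * e2 + s2 * r))
    r_new <- num / den
    trace <- c(trace, log(r_new) + lstar)
    if (is.finite(r_new) && abs(r_new - r) / r < tol) { r <- r_new; break }
    r <- r_new
    if (it == max_iter) {
      e <- simpleError("bridge-sampling fixed point did not converge")
      e$trace <- trace
      class(e) <- c("cfx_bridge_error", class(e))
      stop(e)
    }
  }
  f1 <- e1 / (s1 * e1 + s2 * r)
  f2 <- 1 / (s1 * e2 + s2 * r)
  re2 <- stats::var(f1) / (n2 * mean(f1)^2) + stats::var(f2) / (n1 * mean(f2)^2)
  structure(list(logml = log(r) + lstar, error = sqrt(re2), n_iter = it,
                 n_draws = n1 + n2),
            class = "cfx_bridge")
}

#' @export
print.cfx_bridge <- function(x, ...) {
  cat(sprintf("log marginal likelihood: %.4f (approx. error %.2e, %d bridge iterations)\n",
              x$logml, x$error, x$n_iter))
  invisible(x)
}

#' Bayes factor from two log marginal likelihoods
#'
#' @param logml_alt,logml_null log marginal likelihoods (numbers or
#'   `cfx_bridge` results) of the alternative and null models.
#' @return A `cfx_bf` list: `bf10`, `log_bf10`, `log10_bf10`.
#' @export
bayes_factor <- function(logml_alt, logml_null) {
  la <- if (inherits(logml_alt, "cfx_bridge")) logml_alt$logml else logml_alt
  ln <- if (inherits(logml_null, "cfx_bridge")) logml_null$logml else logml_null
  if (!is.finite(la) || !is.finite(ln))
    cfx_abort("non-finite log marginal likelihood", "cfx_validation_error")
  structure(list(bf10 = exp(la - ln), log_bf10 = la - ln,
                 log10_bf10 = (la - ln) / log(10)),
            class = "cfx_bf")
}

#' @export
print.cfx_bf <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (log BF10 = %.3f)\n", x$bf10, x$log_bf10))
  invisible(x)
}

#' Highest density interval
#'
#' The shortest contiguous interval containing `mass` of the draws
#' (sorted-window method; assumes a unimodal posterior, which all group-level
#' posteriors in this package are by construction).
#'
#' @param x numeric draws, or a `cfx_fit`/`cfx_samples` object (then the
#'   interval is for the group-level share).
#' @param mass probability mass, strictly between 0 and 1.
#' @param ... passed to methods.
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95, ...) UseMethod("hdi")

#' @rdname hdi
#' @export
hdi.default <- function(x, mass = 0.95, ...) {
  stopifnot(mass > 0, mass < 1)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100)
    cfx_abort("need at least 100 draws for an HDI", "cfx_insufficient_error")
  w <- ceiling(mass * n)
  xs <- sort(x)
  lo <- seq_len(n - w + 1L)
  widths <- xs[lo + w - 1L] - xs[lo]
  i <- which.min(widths)
  c(xs[i], xs[i + w - 1L])
}

#' @rdname hdi
#' @export
hdi.cfx_fit <- function(x, mass = 0.95, ...) hdi(group_share_draws(x), mass)

#' @rdname hdi
#' @export
hdi.cfx_samples <- function(x, mass = 0.95, ...) hdi(group_share_draws(x), mass)

#' Categorical decision from Bayes factor or HDI
#'
#' The Bayes-factor rule classifies `bf10 >= threshold` as support for the
#' alternative, `bf10 <= 1/threshold` as support for the null (default
#' threshold 3), anything between as inconclusive.  The HDI rule asks
#' whether the null value (0.5, no context effect) lies outside the interval
#' — for directional hypotheses (`"greater"`, used with absolute shares)
#' only an interval entirely above the null counts as exclusion.
#'
#' @param evidence a `cfx_evidence` object, or any list with `bf10` and/or
#'   `hdi` entries.
#' @param rule `"bf"` or `"hdi"`.
#' @param direction `"two_sided"` or `"greater"`.
#' @param bf_threshold Bayes-factor decision threshold (default 3).
#' @param null_value the no-effect share (default 0.5).
#' @return One of `"supports_alternative"`, `"supports_null"`,
#'   `"inconclusive"`, `"hdi_excludes_null"`, `"hdi_includes_null"`.
#' @export
decide <- function(evidence, rule = c("bf", "hdi"),
                   direction = c("two_sided", "greater"),
                   bf_threshold = 3, null_value = 0.5) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  if (rule == "bf") {
    bf10 <- if (inherits(evidence$bf10, "cfx_bf")) evidence$bf10$bf10 else evidence$bf10
    if (is.null(bf10)) cfx_abort("no bf10 in evidence", "cfx_schema_error")
    if (bf10 >= bf_threshold) "supports_alternative"
    else if (bf10 <= 1 / bf_threshold) "supports_null"
    else "inconclusive"
  } else {
    h <- evidence$hdi
    if (is.null(h)) cfx_abort("no hdi in evidence", "cfx_schema_error")
    excl <- if (direction == "greater") h[1] > null_value
            else (null_value < h[1] || null_value > h[2])
    if (excl) "hdi_excludes_null" else "hdi_includes_null"
  }
}

#' Bayesian test for a context effect
#'
#' Fits the alternative and (for RST measures) null hierarchical models to
#' the same counts, estimates both marginal likelihoods by bridge sampling,
#' and reports the Bayes factor, the 95% HDI of the group-level share, and
#' categorical decisions under both rules.  For absolute shares
#' (`"ast"`/`"asc"`) inference is HDI-based and one-sided (share > 0.5).
#'
#' @inheritParams fit_context_model
#' @param measure `"rst_uw"`, `"rst_ew"`, `"ast"` or `"asc"`.
#' @param mass HDI probability mass.
#' @param bf_threshold Bayes-factor decision threshold.
#' @return A `cfx_evidence` object: `logml_alt`, `logml_null`, `bf10`,
#'   `log_bf10`, `hdi`, `decision_bf`, `decision_hdi`, `fits`,
#'   `diagnostics`.
#' @export
context_test <- function(counts, measure = c("rst_uw", "rst_ew", "ast", "asc"),
                         priors = cfx_priors(), control = mcmc_control(),
                         seed = 1, mass = 0.95, bf_threshold = 3) {
  measure <- match.arg(measure)
  fit_measure <- if (measure %in% c("ast", "asc")) "ast" else measure
  alt <- fit_context_model(counts, fit_measure, "alternative",
                           priors = priors, control = control, seed = seed)
  out <- list(measure = measure, mass = mass)
  draws <- group_share_draws(alt, measure_kind = measure)
  out$hdi <- hdi(draws, mass)
  out$posterior_mean <- mean(draws)
  if (fit_measure == "ast") {
    out$fits <- list(alternative = alt)
    out$decision_hdi <- decide(out, rule = "hdi", direction = "greater")
    out$diagnostics <- list(max_rhat = max(alt$samples$rhat, na.rm = TRUE),
                            warnings = alt$samples$warnings)
  } else {
    null <- fit_context_model(counts, fit_measure, "null",
                              priors = priors, control = control,
                              seed = seed + 1)
    out$logml_alt <- bridge_logml(alt$samples, seed = seed + 2)
    out$logml_null <- bridge_logml(null$samples, seed = seed + 3)
    bf <- bayes_factor(out$logml_alt, out$logml_null)
    out$bf10 <- bf$bf10
    out$log_bf10 <- bf$log_bf10
    out$fits <- list(alternative = alt, null = null)
    out$decision_bf <- decide(out, rule = "bf", bf_threshold = bf_threshold)
    out$decision_hdi <- decide(out, rule = "hdi")
    out$diagnostics <- list(
      max_rhat = max(c(alt$samples$rhat, null$samples$rhat), na.rm = TRUE),
      warnings = c(alt$samples$warnings, null$samples$warnings))
  }
  class(out) <- "cfx_evidence"
  out
}

#' @export
print.cfx_evidence <- function(x, ...) {
  cat(sprintf("Context-effect test, measure %s\n", x$measure))
  cat(sprintf("group share: mean %.3f, %g%% HDI [%.3f, %.3f] -> %s\n",
              x$posterior_mean, 100 * x$mass, x$hdi[1], x$hdi[2],
              x$decision_hdi))
  if (!is.null(x$bf10))
    cat(sprintf("BF10 = %.4g (log %.3f) -> %s\n",
                x$bf10, x$log_bf10, x$decision_bf))
  if (!is.null(x$diagnostics$max_rhat))
    cat(sprintf("max split R-hat %.4f\n", x$diagnostics$max_rhat))
  invisible(x)
}

#' Export an evidence result as a JSON report
#'
#' @param x a `cfx_evidence` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_evidence_json <- function(x, path) {
  rep <- list(measure = x$measure, posterior_mean = x$posterior_mean,
              hdi = as.numeric(x$hdi), mass = x$mass,
              decision_hdi = x$decision_hdi)
  if (!is.null(x$bf10))
    rep <- c(rep, list(
      bf10 = x$bf10, log_bf10 = x$log_bf10,
      logml_alt = x$logml_alt$logml, logml_alt_error = x$logml_alt$error,
      logml_null = x$logml_null$logml, logml_null_error = x$logml_null$error,
      decision_bf = x$decision_bf))
  rep$max_rhat <- x$diagnostics$max_rhat
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
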