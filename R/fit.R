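#' Fit a hierarchical Bayesian choice-share model
#'
#' The main modelling entry point.  For the relative choice share of the
#' target it fits a hierarchical beta-binomial: each participant's target
#' rate \eqn{\theta_i \sim \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)} with the
#' pooled (`rst_uw`) or per-context (`rst_ew`) counts binomial given the
#' rate.  For absolute shares (`ast`) it fits a hierarchical
#' Dirichlet-multinomial over the three roles, per context.  The null
#' variants encode "no context effect": \eqn{\mu = 0.5} fixed for `rst_uw`,
#' \eqn{\mu_2 = 1 - \mu_1} for `rst_ew` (their average is 0.5).
#'
#' @param counts a `cfx_counts` table (see [context_counts()],
#'   [aggregate_counts()], [read_context_counts()]).  Cells on which the
#'   measure is undefined are dropped with a message.
#' @param measure `"rst_uw"`, `"rst_ew"` or `"ast"`.
#' @param hypothesis `"alternative"` (free group mean) or `"null"`.
#' @param priors a [cfx_priors()] object.
#' @param control an [mcmc_control()] object.
#' @param seed integer master seed.
#' @param fixed optional list fixing `mu` and/or `kappa` (non-hierarchical
#'   reductions used mainly for validation).
#' @return A `cfx_fit` object with `print`, `summary`, `coef`, `plot` and
#'   [hdi()] methods; `$samples` holds the [sample_posterior()] result.
#' @examples
#' cc <- generate_dataset(generator_config(n_participants = 8, n_max = 12,
#'                                         seed = 1))
#' fit <- fit_context_model(cc, "rst_ew",
#'                          control = mcmc_control(iter = 300, warmup = 100),
#'                          seed = 1)
#' coef(fit)
#' @export
fit_context_model <- function(counts,
                              measure = c("rst_uw", "rst_ew", "ast"),
                              hypothesis = c("alternative", "null"),
                              priors = cfx_priors(),
                              control = mcmc_control(), seed = 1,
                              fixed = list()) {
  measure <- match.arg(measure)
  hypothesis <- match.arg(hypothesis)
  counts <- validate_counts(as.data.frame(counts))
  if (measure != "ast" && nrow(counts)) counts <- model_ready_counts(counts)
  model <- cfx_model(counts, measure, hypothesis, priors, fixed)
  samples <- sample_posterior(model, control, seed)
  structure(list(samples = samples, model = model, measure = measure,
                 hypothesis = hypothesis, counts = counts, seed = seed,
                 control = control, call = match.call()),
            class = "cfx_fit")
}

#' Posterior draws of the group-level choice share
#'
#' Maps posterior draws onto the group-level share the measure reports:
#' `rst_uw` uses \eqn{\mu} directly; `rst_ew` averages the two context means
#' \eqn{(\mu_1 + \mu_2)/2}; `ast`/`asc` average the target (competitor)
#' components of the two context simplex means.
#'
#' @param samples a `cfx_samples` or `cfx_fit` object.
#' @param measure_kind which share to derive; defaults to the fitted
#'   measure (for fits of the Dirichlet-multinomial model, `"ast"` or
#'   `"asc"`).
#' @return Numeric vector of draws pooled across chains.
#' @export
group_share_draws <- function(samples, measure_kind = NULL) {
  if (inherits(samples, "cfx_fit")) {
    measure_kind <- measure_kind %||% samples$measure
    samples <- samples$samples
  }
  measure_kind <- measure_kind %||% samples$model$measure
  switch(measure_kind,
    rst_uw = posterior_draws(samples, "mu"),
    rst_ew = 0.5 * (posterior_draws(samples, "mu[1]") +
                    posterior_draws(samples, "mu[2]")),
    ast = 0.5 * (posterior_draws(samples, "mu[t,1]") +
                 posterior_draws(samples, "mu[t,2]")),
    asc = 0.5 * (posterior_draws(samples, "mu[c,1]") +
                 posterior_draws(samples, "mu[c,2]")),
    cfx_abort(sprintf("unknown measure kind '%s'", measure_kind),
              "cfx_schema_error"))
}

group_par_names <- function(fit) {
  grep("^(mu|kappa|alr)", fit$samples$par_names, value = TRUE)
}

#' @export
coef.cfx_fit <- function(object, ...) {
  pars <- group_par_names(object)
  vapply(pars, function(p) mean(posterior_draws(object$samples, p)), 0)
}

#' @export
print.cfx_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s model (%s hypothesis), %d participants\n",
              toupper(sub("_", "-", x$measure)), x$hypothesis, x$model$n))
  g <- group_share_draws(x)
  h <- hdi(g)
  cat(sprintf("group share: mean %.3f, 95%% HDI [%.3f, %.3f]\n",
              mean(g), h[1], h[2]))
  cat(sprintf("%d chains x %d draws; max split R-hat %.4f\n",
              x$samples$n_chains, x$samples$n_kept,
              max(x$samples$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cfx_fit <- function(object, mass = 0.95, ...) {
  pars <- group_par_names(object)
  tab <- t(vapply(pars, function(p) {
    d <- posterior_draws(object$samples, p)
    h <- if (length(unique(d)) > 1) hdi(d, mass) else c(d[1], d[1])
    c(mean = mean(d), sd = stats::sd(d), lower = h[1], upper = h[2],
      rhat = object$samples$rhat[[p]])
  }, numeric(5)))
  out <- list(measure = object$measure, hypothesis = object$hypothesis,
              n = object$model$n, group = tab,
              share = c(mean = mean(group_share_draws(object)),
                        hdi(group_share_draws(object), mass)),
              warnings = object$samples$warnings)
  class(out) <- "summary.cfx_fit"
  out
}

#' @export
print.summary.cfx_fit <- function(x, ...) {
  cat(sprintf("%s model, %s hypothesis, n = %d\n", x$measure, x$hypothesis, x$n))
  print(round(x$group, 4))
  cat(sprintf("group share: mean %.3f, HDI [%.3f, %.3f]\n",
              x$share[1], x$share[2], x$share[3]))
  if (length(x$warnings)) cat(x$warnings, sep = "\n")
  invisible(x)
}

#' @export
plot.cfx_fit <- function(x, ...) {
  g <- group_share_draws(x)
  d <- stats::density(g)
  plot(d, main = sprintf("Posterior of the group %s", x$measure),
       xlab = "group-level choice share", ...)
  graphics::abline(v = 0.5, lty = 2)
  h <- hdi(g)
  graphics::segments(h[1], 0, h[2], 0, lwd = 3)
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws replicate count tables: for each requested replicate one posterior
#' draw of the individual rates is taken and new counts are generated with
#' the observed per-cell trial totals.
#'
#' @param object a `cfx_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `cfx_counts` tables.
#' @export
simulate.cfx_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  s <- object$samples
  total <- s$n_kept * s$n_chains
  idx <- sample.int(total, nsim, replace = nsim > total)
  cc <- object$counts
  n <- nrow(cc)
  lapply(idx, function(i) {
    if (object$measure == "rst_uw") {
      th <- vapply(seq_len(n), function(j)
        posterior_draws(s, sprintf("theta[%d]", j))[i], 0)
      N1 <- cc$n_t_C1 + cc$n_c_C1; N2 <- cc$n_t_C2 + cc$n_c_C2
      y1 <- stats::rbinom(n, N1, th); y2 <- stats::rbinom(n, N2, th)
      context_counts(y1, N1 - y1, 0, y2, N2 - y2, 0,
                     participant_id = cc$participant_id, effect = cc$effect)
    } else if (object$measure == "rst_ew") {
      t1 <- vapply(seq_len(n), function(j)
        posterior_draws(s, sprintf("theta[%d,1]", j))[i], 0)
      t2 <- vapply(seq_len(n), function(j)
        posterior_draws(s, sprintf("theta[%d,2]", j))[i], 0)
      N1 <- cc$n_t_C1 + cc$n_c_C1; N2 <- cc$n_t_C2 + cc$n_c_C2
      y1 <- stats::rbinom(n, N1, t1); y2 <- stats::rbinom(n, N2, t2)
      context_counts(y1, N1 - y1, 0, y2, N2 - y2, 0,
                     participant_id = cc$participant_id, effect = cc$effect)
    } else {
      draw_ctx <- function(ctx, Ntot) {
        t(vapply(seq_len(n), function(j) {
          p <- vapply(c("t", "c", "d"), function(k)
            posterior_draws(s, sprintf("theta[%d,%s,%d]", j, k, ctx))[i], 0)
          stats::rmultinom(1, Ntot[j], p)[, 1]
        }, numeric(3)))
      }
      X1 <- draw_ctx(1, cc$n_t_C1 + cc$n_c_C1 + cc$n_d_C1)
      X2 <- draw_ctx(2, cc$n_t_C2 + cc$n_c_C2 + cc$n_d_C2)
      context_counts(X1[, 1], X1[, 2], X1[, 3], X2[, 1], X2[, 2], X2[, 3],
                     participant_id = cc$participant_id, effect = cc$effect)
    }
  })
}
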