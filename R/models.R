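#' Prior settings for the hierarchical models
#'
#' The group-level mean of each beta-binomial hierarchy has a Beta prior
#' (default Beta(2, 2), the two-alternative equivalent of the Dirichlet(2,2,2)
#' used for three-alternative simplex means), each concentration a
#' Gamma(shape, rate) prior (default Gamma(0.001, 0.001)), and the
#' three-component simplex mean a Dirichlet prior (default (2, 2, 2)).
#'
#' @param mu length-2 Beta shape pair for group means.
#' @param kappa length-2 Gamma shape–rate pair for concentrations.
#' @param dirichlet length-3 Dirichlet pseudo-count vector for simplex means.
#' @return A `cfx_priors` list.
#' @export
cfx_priors <- function(mu = c(2, 2), kappa = c(0.001, 0.001),
                       dirichlet = c(2, 2, 2)) {
  stopifnot(length(mu) == 2, length(kappa) == 2, length(dirichlet) == 3,
            all(mu > 0), all(kappa > 0), all(dirichlet > 0))
  structure(list(mu = mu, kappa = kappa, dirichlet = dirichlet),
            class = "cfx_priors")
}

#' Sampler settings
#'
#' Defaults mirror the reference analysis: three independent chains of 1500
#' iterations each, the first 500 discarded as warm-up.
#'
#' @param chains number of independent chains.
#' @param iter iterations per chain (including warm-up).
#' @param warmup warm-up iterations discarded from each chain.
#' @param kappa_min lower bound on concentrations during sampling; keeps the
#'   beta/Dirichlet shapes away from the degenerate spike at zero.
#' @param adapt_target target acceptance rate of the adaptive random-walk
#'   updates for the group-level parameters.
#' @param scans random-walk scans of the group-level block per iteration;
#'   the marginal-likelihood evaluations are cheap next to the conditional
#'   draws of the individual rates, so several scans per iteration buy a
#'   large drop in autocorrelation of the group-level chains.
#' @param quiet suppress convergence warnings (they are still recorded on the
#'   result).
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(chains = 3, iter = 1500, warmup = 500,
                         kappa_min = 1e-6, adapt_target = 0.44, scans = 5,
                         quiet = FALSE) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0, scans >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), kappa_min = kappa_min,
                 adapt_target = adapt_target, scans = as.integer(scans),
                 quiet = isTRUE(quiet)),
            class = "mcmc_control")
}

# ---------------------------------------------------------------------------
# Model objects.  A cfx_model bundles the data in model-ready form, the
# hypothesis variant, the priors, any fixed hyperparameters, and the layout
# of the unconstrained parameter vector used by the sampler and by bridge
# sampling.

cfx_model <- function(counts, measure = c("rst_uw", "rst_ew", "ast"),
                      hypothesis = c("alternative", "null"),
                      priors = cfx_priors(), fixed = list()) {
  measure <- match.arg(measure)
  hypothesis <- match.arg(hypothesis)
  counts <- validate_counts(as.data.frame(counts))
  n <- nrow(counts)
  m <- list(measure = measure, hypothesis = hypothesis, priors = priors,
            fixed = fixed, n = n)
  if (measure == "rst_uw") {
    y <- counts$n_t_C1 + counts$n_t_C2
    N <- y + counts$n_c_C1 + counts$n_c_C2
    if (any(N < 1))
      cfx_abort("RST model needs >= 1 target/competitor choice per participant",
                "cfx_validation_error")
    m$data <- list(y = y, N = N)
    mu_free <- hypothesis == "alternative" && is.null(fixed$mu)
    kappa_free <- is.null(fixed$kappa)
    m$mu_fixed <- if (!mu_free) (fixed$mu %||% 0.5)
    m$hyper_names <- c(if (mu_free) "mu", if (kappa_free) "kappa")
    m$dim <- length(m$hyper_names) + n
    m$par_names <- c("mu", "kappa",
                     paste0("theta[", seq_len(n), "]", recycle0 = TRUE))
    m$free <- c(mu_free, kappa_free, rep(TRUE, n))
  } else if (measure == "rst_ew") {
    d <- list(y1 = counts$n_t_C1, N1 = counts$n_t_C1 + counts$n_c_C1,
              y2 = counts$n_t_C2, N2 = counts$n_t_C2 + counts$n_c_C2)
    if (any(d$N1 < 1) || any(d$N2 < 1))
      cfx_abort("RST_EW model needs >= 1 target/competitor choice per context",
                "cfx_validation_error")
    m$data <- d
    # Null variant: mu_2 = 1 - mu_1 (average fixed at 0.5); both kappas free.
    m$hyper_names <- c("mu[1]", if (hypothesis == "alternative") "mu[2]",
                       "kappa[1]", "kappa[2]")
    m$dim <- length(m$hyper_names) + 2 * n
    m$par_names <- c("mu[1]", "mu[2]", "kappa[1]", "kappa[2]",
                     paste0("theta[", rep(seq_len(n), 2), ",",
                            rep(1:2, each = n), "]", recycle0 = TRUE))
    m$free <- c(TRUE, hypothesis == "alternative", TRUE, TRUE, rep(TRUE, 2 * n))
  } else {
    X1 <- as.matrix(counts[c("n_t_C1", "n_c_C1", "n_d_C1")])
    X2 <- as.matrix(counts[c("n_t_C2", "n_c_C2", "n_d_C2")])
    if (any(rowSums(X1) < 1) || any(rowSums(X2) < 1))
      cfx_abort("AST model needs >= 1 choice per context per participant",
                "cfx_validation_error")
    if (hypothesis != "alternative")
      cfx_abort("the Dirichlet-multinomial model has no null variant; absolute-share inference is HDI-based",
                "cfx_validation_error")
    m$data <- list(X1 = unname(X1), X2 = unname(X2))
    m$hyper_names <- c("alr_mu[1,1]", "alr_mu[2,1]", "kappa[1]",
                       "alr_mu[1,2]", "alr_mu[2,2]", "kappa[2]")
    m$dim <- 6 + 4 * n
    comp <- c("t", "c", "d")
    m$par_names <- c(paste0("mu[", rep(comp, 2), ",", rep(1:2, each = 3), "]"),
                     "kappa[1]", "kappa[2]",
                     paste0("theta[", rep(seq_len(n), each = 3), ",", comp, ",",
                            rep(1:2, each = 3 * n), "]", recycle0 = TRUE))
    m$free <- rep(TRUE, length(m$par_names))
  }
  class(m) <- "cfx_model"
  m
}

# Beta log-density written out so invalid shapes give -Inf, never NaN.
lbeta_dens <- function(x, a, b) {
  out <- (a - 1) * log(x) + (b - 1) * log1p(-x) +
    lgamma(a + b) - lgamma(a) - lgamma(b)
  out[a <= 0 | b <= 0] <- -Inf
  out
}

ldirichlet_dens <- function(x, alpha) {
  # x, alpha: vectors of equal length (single simplex point)
  if (any(alpha <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Joint log-density of the collapsed-counts (unequal-weights) RST model
#'
#' Each participant's pooled target count is binomial with rate
#' \eqn{\theta_i}; the rates are drawn from Beta(\eqn{\mu\kappa},
#' \eqn{(1-\mu)\kappa}).  Under the null hypothesis \eqn{\mu} is fixed at
#' 0.5 and carries no prior term; under the alternative it has the Beta
#' prior from `priors`.  \eqn{\kappa} always has its Gamma prior.  Returns
#' `-Inf` (never `NaN`) outside the support.
#'
#' @param theta per-participant rates in (0, 1).
#' @param y,N per-participant target counts and totals.
#' @param mu group mean rate; ignored (fixed at 0.5) under the null.
#' @param kappa group concentration (> 0).
#' @param hypothesis `"alternative"` or `"null"`.
#' @param priors a [cfx_priors()] object.
#' @return The log joint density in nats (natural-parameter scale, no
#'   change-of-variable terms).
#' @export
log_density_rst_uw <- function(theta, y, N, mu = 0.5, kappa,
                               hypothesis = c("alternative", "null"),
                               priors = cfx_priors()) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "null") mu <- 0.5
  if (any(theta <= 0) || any(theta >= 1) || kappa <= 0 || mu <= 0 || mu >= 1)
    return(-Inf)
  ld <- sum(stats::dbinom(y, N, theta, log = TRUE)) +
    sum(lbeta_dens(theta, mu * kappa, (1 - mu) * kappa)) +
    stats::dgamma(kappa, priors$kappa[1], rate = priors$kappa[2], log = TRUE)
  if (hypothesis == "alternative")
    ld <- ld + lbeta_dens(mu, priors$mu[1], priors$mu[2])
  if (is.nan(ld)) -Inf else ld
}

#' Joint log-density of the equal-weights RST model
#'
#' Two beta-binomial hierarchies, one per context, with their own means and
#' concentrations.  The null variant constrains \eqn{\mu_2 = 1 - \mu_1}
#' (equivalently, the average of the two means is 0.5) with a single prior
#' term on \eqn{\mu_1}; both concentrations stay free.
#'
#' @param theta1,theta2 per-participant rates in contexts 1 and 2.
#' @param y1,N1,y2,N2 per-context target counts and totals.
#' @param mu1,mu2 group means; `mu2` is ignored under the null.
#' @param kappa1,kappa2 group concentrations.
#' @inheritParams log_density_rst_uw
#' @export
log_density_rst_ew <- function(theta1, theta2, y1, N1, y2, N2,
                               mu1, mu2 = NULL, kappa1, kappa2,
                               hypothesis = c("alternative", "null"),
                               priors = cfx_priors()) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "null") mu2 <- 1 - mu1
  if (any(c(theta1, theta2) <= 0) || any(c(theta1, theta2) >= 1) ||
      kappa1 <= 0 || kappa2 <= 0 ||
      mu1 <= 0 || mu1 >= 1 || mu2 <= 0 || mu2 >= 1)
    return(-Inf)
  ld <- sum(stats::dbinom(y1, N1, theta1, log = TRUE)) +
    sum(lbeta_dens(theta1, mu1 * kappa1, (1 - mu1) * kappa1)) +
    sum(stats::dbinom(y2, N2, theta2, log = TRUE)) +
    sum(lbeta_dens(theta2, mu2 * kappa2, (1 - mu2) * kappa2)) +
    stats::dgamma(kappa1, priors$kappa[1], rate = priors$kappa[2], log = TRUE) +
    stats::dgamma(kappa2, priors$kappa[1], rate = priors$kappa[2], log = TRUE) +
    lbeta_dens(mu1, priors$mu[1], priors$mu[2])
  if (hypothesis == "alternative")
    ld <- ld + lbeta_dens(mu2, priors$mu[1], priors$mu[2])
  if (is.nan(ld)) -Inf else ld
}

#' Joint log-density of the Dirichlet-multinomial absolute-share model
#'
#' Per context, each participant's three choice probabilities form a simplex
#' vector drawn from a group Dirichlet with mean simplex \eqn{\vec\mu} and
#' concentration \eqn{\kappa}; counts are multinomial.  \eqn{\vec\mu} has a
#' Dirichlet(2,2,2) prior and \eqn{\kappa} a Gamma(0.001, 0.001) prior, per
#' context.
#'
#' @param theta1,theta2 `n x 3` matrices of per-participant simplex rows.
#' @param X1,X2 `n x 3` count matrices (target, competitor, decoy).
#' @param mu1,mu2 group simplex means (length 3).
#' @param kappa1,kappa2 group concentrations.
#' @inheritParams log_density_rst_uw
#' @export
log_density_ast <- function(theta1, theta2, X1, X2, mu1, mu2, kappa1, kappa2,
                            priors = cfx_priors()) {
  theta1 <- rbind(theta1); theta2 <- rbind(theta2)
  X1 <- rbind(X1); X2 <- rbind(X2)
  ok_simplex <- function(th) all(th > 0) && all(th < 1) &&
    all(abs(rowSums(th) - 1) < 1e-8)
  if (!ok_simplex(theta1) || !ok_simplex(theta2) ||
      kappa1 <= 0 || kappa2 <= 0 ||
      !ok_simplex(rbind(mu1)) || !ok_simplex(rbind(mu2)))
    return(-Inf)
  one_context <- function(theta, X, mu, kappa) {
    alpha <- mu * kappa
    lmult <- sum(lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1)) +
                   rowSums(X * log(theta)))
    lhier <- sum(apply(theta, 1, ldirichlet_dens, alpha = alpha))
    lmult + lhier +
      ldirichlet_dens(mu, priors$dirichlet) +
      stats::dgamma(kappa, priors$kappa[1], rate = priors$kappa[2], log = TRUE)
  }
  ld <- one_context(theta1, X1, mu1, kappa1) +
    one_context(theta2, X2, mu2, kappa2)
  if (is.nan(ld)) -Inf else ld
}

# ---------------------------------------------------------------------------
# Vectorised unconstrained-scale joint log-density (log posterior kernel
# including change-of-variable terms), evaluated at a matrix of draws (one
# row per draw).  This is the density bridge sampling integrates.

cfx_log_density <- function(model, pmat) {
  pmat <- rbind(pmat)
  stopifnot(ncol(pmat) == model$dim)
  pr <- model$priors
  nh <- length(model$hyper_names)
  n <- model$n
  lmu_prior <- function(eta) {  # Beta prior on inv_logit(eta) + Jacobian
    lm <- log_inv_logit(eta); l1m <- log1m_inv_logit(eta)
    (pr$mu[1] - 1) * lm + (pr$mu[2] - 1) * l1m - lbeta(pr$mu[1], pr$mu[2]) +
      lm + l1m
  }
  lkappa_prior <- function(eta)  # Gamma prior on exp(eta) + Jacobian
    stats::dgamma(exp(eta), pr$kappa[1], rate = pr$kappa[2], log = TRUE) + eta

  if (model$measure == "rst_uw") {
    i <- 1L
    if (is.null(model$mu_fixed)) { eta_mu <- pmat[, i]; i <- i + 1L }
    if (is.null(model$fixed$kappa)) { eta_k <- pmat[, i]; i <- i + 1L }
    zeta <- pmat[, i:(i + n - 1L), drop = FALSE]
    mu <- if (is.null(model$mu_fixed)) inv_logit(eta_mu) else model$mu_fixed
    kappa <- if (is.null(model$fixed$kappa)) exp(eta_k) else model$fixed$kappa
    lth <- log_inv_logit(zeta); l1th <- log1m_inv_logit(zeta)
    a <- mu * kappa; b <- (1 - mu) * kappa
    ld <- rowSums(rep(model$data$y, each = nrow(pmat)) * lth +
                    rep(model$data$N - model$data$y, each = nrow(pmat)) * l1th) +
      sum(lchoose(model$data$N, model$data$y)) +
      (a - 1) * rowSums(lth) + (b - 1) * rowSums(l1th) +
      n * (lgamma(kappa) - lgamma(a) - lgamma(b)) +
      rowSums(lth + l1th)                                   # theta Jacobians
    if (is.null(model$mu_fixed)) ld <- ld + lmu_prior(eta_mu)
    if (is.null(model$fixed$kappa)) ld <- ld + lkappa_prior(eta_k)
  } else if (model$measure == "rst_ew") {
    alt <- model$hypothesis == "alternative"
    eta_mu1 <- pmat[, 1L]
    eta_mu2 <- if (alt) pmat[, 2L]
    eta_k1 <- pmat[, nh - 1L]; eta_k2 <- pmat[, nh]
    z1 <- pmat[, nh + seq_len(n), drop = FALSE]
    z2 <- pmat[, nh + n + seq_len(n), drop = FALSE]
    mu1 <- inv_logit(eta_mu1)
    mu2 <- if (alt) inv_logit(eta_mu2) else 1 - mu1
    k1 <- exp(eta_k1); k2 <- exp(eta_k2)
    ctx <- function(z, y, N, mu, kappa) {
      lth <- log_inv_logit(z); l1th <- log1m_inv_logit(z)
      a <- mu * kappa; b <- (1 - mu) * kappa
      rowSums(rep(y, each = nrow(pmat)) * lth +
                rep(N - y, each = nrow(pmat)) * l1th) +
        sum(lchoose(N, y)) +
        (a - 1) * rowSums(lth) + (b - 1) * rowSums(l1th) +
        n * (lgamma(kappa) - lgamma(a) - lgamma(b)) +
        rowSums(lth + l1th)
    }
    ld <- ctx(z1, model$data$y1, model$data$N1, mu1, k1) +
      ctx(z2, model$data$y2, model$data$N2, mu2, k2) +
      lkappa_prior(eta_k1) + lkappa_prior(eta_k2) + lmu_prior(eta_mu1)
    if (alt) ld <- ld + lmu_prior(eta_mu2)
  } else {
    ld <- 0
    for (s in 1:2) {
      off <- (s - 1L) * 3L
      A <- pmat[, off + 1:2, drop = FALSE]
      eta_k <- pmat[, off + 3L]
      kappa <- exp(eta_k)
      lden_mu <- log1p(exp(A[, 1]) + exp(A[, 2]))
      lmu <- cbind(A[, 1] - lden_mu, A[, 2] - lden_mu, -lden_mu)
      X <- model$data[[paste0("X", s)]]
      tcols <- 6L + (s - 1L) * 2L * n + seq_len(2L * n)
      Z <- pmat[, tcols, drop = FALSE]
      A1 <- Z[, seq(1, 2 * n, 2), drop = FALSE]
      A2 <- Z[, seq(2, 2 * n, 2), drop = FALSE]
      lden <- log1p(exp(A1) + exp(A2))
      lth1 <- A1 - lden; lth2 <- A2 - lden; lth3 <- -lden
      alpha <- exp(lmu) * kappa                      # ndraws x 3
      ld <- ld +
        drop(lth1 %*% X[, 1] + lth2 %*% X[, 2] + lth3 %*% X[, 3]) +
        sum(lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))) +
        (alpha[, 1] - 1) * rowSums(lth1) + (alpha[, 2] - 1) * rowSums(lth2) +
        (alpha[, 3] - 1) * rowSums(lth3) +
        n * (lgamma(kappa) - lgamma(alpha[, 1]) - lgamma(alpha[, 2]) -
               lgamma(alpha[, 3])) +
        rowSums(lth1 + lth2 + lth3) +                # theta Jacobians
        drop(lmu %*% (pr$dirichlet - 1)) +
        lgamma(sum(pr$dirichlet)) - sum(lgamma(pr$dirichlet)) +
        rowSums(lmu) +                               # mu Jacobian
        stats::dgamma(kappa, pr$kappa[1], rate = pr$kappa[2], log = TRUE) + eta_k
    }
  }
  ld[is.nan(ld)] <- -Inf
  unname(ld)
}
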