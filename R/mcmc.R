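# Posterior sampling for the hierarchical models.
#
# The individual-level rates are conjugate given the group-level parameters
# (beta within binomial, Dirichlet within multinomial), so the sampler
# collapses them out: the group-level block (mu, kappa per hierarchy) moves
# by adaptive random-walk Metropolis on the *marginal* posterior
# (beta-binomial / Dirichlet-multinomial likelihood), and the rates are then
# drawn exactly from their conditional posteriors.  This is an exact sampler
# for the full joint posterior with far better mixing than a joint random
# walk, which the R-hat < 1.01 contract relies on.

# Builds a specialised marginal log-posterior closure for the group-level
# block (data unpacked into locals; called tens of thousands of times per
# fit, so the hot path avoids per-call allocation).  Additive constants in
# the counts are dropped: only differences matter to Metropolis.
make_marg_log_post <- function(model, kappa_min = 1e-6) {
  pr <- model$priors
  a_mu <- pr$mu[1]; b_mu <- pr$mu[2]
  a_k <- pr$kappa[1]; r_k <- pr$kappa[2]
  # Beta prior on inv_logit(eta) + Jacobian, up to a constant
  lmu_pr <- function(eta)
    a_mu * stats::plogis(eta, log.p = TRUE) + b_mu * stats::plogis(-eta, log.p = TRUE)
  # Gamma prior on exp(eta) + Jacobian
  lk_pr <- function(eta, kappa) a_k * eta - r_k * kappa
  if (model$measure == "rst_uw") {
    y <- model$data$y; N <- model$data$N; n <- model$n
    mu_free <- is.null(model$mu_fixed)
    kappa_free <- is.null(model$fixed$kappa)
    mu0 <- model$mu_fixed; kappa0 <- model$fixed$kappa
    function(h) {
      i <- 1L
      if (mu_free) { mu <- stats::plogis(h[i]); i <- i + 1L } else mu <- mu0
      kappa <- if (kappa_free) exp(h[i]) else kappa0
      if (kappa < kappa_min || kappa > 1e12) return(-Inf)
      a <- mu * kappa; b <- kappa - a
      ld <- sum(lgamma(a + y)) + sum(lgamma(b + N - y)) -
        sum(lgamma(kappa + N)) + n * (lgamma(kappa) - lgamma(a) - lgamma(b))
      if (mu_free) ld <- ld + lmu_pr(h[1L])
      if (kappa_free) ld <- ld + lk_pr(h[i], kappa)
      if (is.nan(ld)) -Inf else ld
    }
  } else if (model$measure == "rst_ew") {
    y1 <- model$data$y1; N1 <- model$data$N1
    y2 <- model$data$y2; N2 <- model$data$N2; n <- model$n
    alt <- model$hypothesis == "alternative"
    function(h) {
      mu1 <- stats::plogis(h[1L])
      mu2 <- if (alt) stats::plogis(h[2L]) else 1 - mu1
      nh <- length(h)
      k1 <- exp(h[nh - 1L]); k2 <- exp(h[nh])
      if (k1 < kappa_min || k2 < kappa_min || k1 > 1e12 || k2 > 1e12)
        return(-Inf)
      a1 <- mu1 * k1; b1 <- k1 - a1
      a2 <- mu2 * k2; b2 <- k2 - a2
      ld <- sum(lgamma(a1 + y1)) + sum(lgamma(b1 + N1 - y1)) -
        sum(lgamma(k1 + N1)) + n * (lgamma(k1) - lgamma(a1) - lgamma(b1)) +
        sum(lgamma(a2 + y2)) + sum(lgamma(b2 + N2 - y2)) -
        sum(lgamma(k2 + N2)) + n * (lgamma(k2) - lgamma(a2) - lgamma(b2)) +
        lmu_pr(h[1L]) + lk_pr(h[nh - 1L], k1) + lk_pr(h[nh], k2)
      if (alt) ld <- ld + lmu_pr(h[2L])
      if (is.nan(ld)) -Inf else ld
    }
  } else {
    X1 <- model$data$X1; X2 <- model$data$X2; n <- model$n
    Nt1 <- rowSums(X1); Nt2 <- rowSums(X2)
    dir_pr <- pr$dirichlet
    ctx <- function(X, Ntot, hs) {
      kappa <- exp(hs[3L])
      if (kappa < kappa_min || kappa > 1e12) return(-Inf)
      e1 <- exp(hs[1L]); e2 <- exp(hs[2L])
      mu <- c(e1, e2, 1) / (1 + e1 + e2)
      alpha <- mu * kappa
      sum(lgamma(sweep(X, 2, alpha, "+"))) - n * sum(lgamma(alpha)) +
        n * lgamma(kappa) - sum(lgamma(Ntot + kappa)) +
        sum(dir_pr * log(mu)) +                      # Dirichlet prior + alr Jacobian
        a_k * hs[3L] - r_k * kappa
    }
    function(h) {
      ld <- ctx(X1, Nt1, h[1:3]) + ctx(X2, Nt2, h[4:6])
      if (is.nan(ld)) -Inf else ld
    }
  }
}

# Marginal (rates integrated out) log-posterior of the group-level block on
# the unconstrained scale, including priors and Jacobians (reference
# implementation; the sampler uses the specialised closure above, which this
# must agree with up to a constant).
marg_log_post <- function(model, h, kappa_min = 1e-6) {
  pr <- model$priors
  lmu_pr <- function(eta) {
    lm <- log_inv_logit(eta); l1m <- log1m_inv_logit(eta)
    (pr$mu[1] - 1) * lm + (pr$mu[2] - 1) * l1m - lbeta(pr$mu[1], pr$mu[2]) +
      lm + l1m
  }
  lk_pr <- function(eta)
    stats::dgamma(exp(eta), pr$kappa[1], rate = pr$kappa[2], log = TRUE) + eta
  bb_lik <- function(y, N, mu, kappa) {
    a <- mu * kappa; b <- (1 - mu) * kappa
    sum(lchoose(N, y) + lbeta(a + y, b + N - y) - lbeta(a, b))
  }
  if (model$measure == "rst_uw") {
    i <- 1L; ld <- 0
    if (is.null(model$mu_fixed)) {
      mu <- inv_logit(h[i]); ld <- ld + lmu_pr(h[i]); i <- i + 1L
    } else mu <- model$mu_fixed
    if (is.null(model$fixed$kappa)) {
      kappa <- exp(h[i])
      if (kappa < kappa_min) return(-Inf)
      ld <- ld + lk_pr(h[i])
    } else kappa <- model$fixed$kappa
    ld <- ld + bb_lik(model$data$y, model$data$N, mu, kappa)
  } else if (model$measure == "rst_ew") {
    alt <- model$hypothesis == "alternative"
    mu1 <- inv_logit(h[1L])
    mu2 <- if (alt) inv_logit(h[2L]) else 1 - mu1
    k1 <- exp(h[length(h) - 1L]); k2 <- exp(h[length(h)])
    if (k1 < kappa_min || k2 < kappa_min) return(-Inf)
    ld <- bb_lik(model$data$y1, model$data$N1, mu1, k1) +
      bb_lik(model$data$y2, model$data$N2, mu2, k2) +
      lmu_pr(h[1L]) + lk_pr(h[length(h) - 1L]) + lk_pr(h[length(h)])
    if (alt) ld <- ld + lmu_pr(h[2L])
  } else {
    dm_lik <- function(X, alpha) {
      kappa <- sum(alpha)
      Ntot <- rowSums(X)
      sum(lgamma(Ntot + 1) - rowSums(lgamma(X + 1)) +
            lgamma(kappa) - lgamma(Ntot + kappa) +
            rowSums(lgamma(sweep(X, 2, alpha, "+")) -
                      rep(lgamma(alpha), each = nrow(X))))
    }
    ld <- 0
    for (s in 1:2) {
      hs <- h[(s - 1L) * 3L + 1:3]
      mu <- drop(alr_inv(rbind(hs[1:2])))
      kappa <- exp(hs[3L])
      if (kappa < kappa_min) return(-Inf)
      ld <- ld + dm_lik(model$data[[paste0("X", s)]], mu * kappa) +
        ldirichlet_dens(mu, pr$dirichlet) + sum(log(mu)) + lk_pr(hs[3L])
    }
  }
  if (is.nan(ld)) -Inf else ld
}

# Exact conditional draw of the individual rates given the group block;
# returns both the constrained values (in par_names order, after the group
# parameters) and their unconstrained counterparts (in cfx_log_density's
# column order).
conditional_rates <- function(model, h) {
  n <- model$n
  if (model$measure == "rst_uw") {
    i <- 1L
    if (is.null(model$mu_fixed)) { mu <- inv_logit(h[i]); i <- i + 1L }
    else mu <- model$mu_fixed
    kappa <- if (is.null(model$fixed$kappa)) exp(h[i]) else model$fixed$kappa
    th <- clamp_unit(stats::rbeta(n, mu * kappa + model$data$y,
                                  (1 - mu) * kappa + model$data$N - model$data$y))
    list(constrained = c(mu, kappa, th), unconstrained = logit(th))
  } else if (model$measure == "rst_ew") {
    alt <- model$hypothesis == "alternative"
    mu1 <- inv_logit(h[1L])
    mu2 <- if (alt) inv_logit(h[2L]) else 1 - mu1
    k1 <- exp(h[length(h) - 1L]); k2 <- exp(h[length(h)])
    t1 <- clamp_unit(stats::rbeta(n, mu1 * k1 + model$data$y1,
                                  (1 - mu1) * k1 + model$data$N1 - model$data$y1))
    t2 <- clamp_unit(stats::rbeta(n, mu2 * k2 + model$data$y2,
                                  (1 - mu2) * k2 + model$data$N2 - model$data$y2))
    list(constrained = c(mu1, mu2, k1, k2, t1, t2),
         unconstrained = c(logit(t1), logit(t2)))
  } else {
    cons <- c(); unc <- c(); mus <- c(); kappas <- c()
    for (s in 1:2) {
      hs <- h[(s - 1L) * 3L + 1:3]
      mu <- drop(alr_inv(rbind(hs[1:2]))); kappa <- exp(hs[3L])
      X <- model$data[[paste0("X", s)]]
      shape <- sweep(X, 2, mu * kappa, "+")
      G <- matrix(stats::rgamma(n * 3L, shape = shape), nrow = n)
      G <- pmax(G, 1e-300)
      th <- clamp_unit(G / rowSums(G))
      th <- th / rowSums(th)
      mus <- c(mus, mu); kappas <- c(kappas, kappa)
      cons <- c(cons, as.vector(t(th)))
      unc <- c(unc, as.vector(t(alr(th))))
    }
    list(constrained = c(mus, kappas, cons), unconstrained = unc)
  }
}

init_hyper <- function(model) {
  if (model$measure == "rst_uw") {
    p <- clamp_unit(sum(model$data$y) / max(sum(model$data$N), 1), 1e-3)
    c(if (is.null(model$mu_fixed)) logit(p),
      if (is.null(model$fixed$kappa)) log(5))
  } else if (model$measure == "rst_ew") {
    p1 <- clamp_unit(sum(model$data$y1) / max(sum(model$data$N1), 1), 1e-3)
    p2 <- clamp_unit(sum(model$data$y2) / max(sum(model$data$N2), 1), 1e-3)
    c(logit(p1), if (model$hypothesis == "alternative") logit(p2),
      log(5), log(5))
  } else {
    unlist(lapply(1:2, function(s) {
      X <- model$data[[paste0("X", s)]]
      p <- clamp_unit(colSums(X) / sum(X), 1e-3); p <- p / sum(p)
      c(drop(alr(rbind(p))), log(5))
    }))
  }
}

#' Draw from the posterior of a hierarchical choice-share model
#'
#' Runs independent Markov chains (collapsed Metropolis-within-Gibbs; see
#' the package vignette) and returns draws on the constrained scale together
#' with the unconstrained draws that bridge sampling consumes, rank-normalised
#' split-\eqn{\hat R} per free parameter, and acceptance diagnostics.  A
#' \eqn{\hat R \ge 1.01} attaches a convergence warning to the result rather
#' than failing.
#'
#' @param model a model built by [cfx_model()] (done for you by
#'   [fit_context_model()]).
#' @param control an [mcmc_control()] list.
#' @param seed integer master seed; per-chain seeds are derived
#'   deterministically from it.
#' @return A `cfx_samples` object.
#' @export
sample_posterior <- function(model, control = mcmc_control(), seed = 1) {
  n_kept <- control$iter - control$warmup
  nh <- length(model$hyper_names)
  npar <- length(model$par_names)
  draws <- array(NA_real_, c(n_kept, control$chains, npar),
                 dimnames = list(NULL, NULL, model$par_names))
  unc <- array(NA_real_, c(n_kept, control$chains, model$dim))
  accept <- matrix(0, control$chains, max(nh, 1L))
  lp_fun <- make_marg_log_post(model, control$kappa_min)
  for (ch in seq_len(control$chains)) {
    set.seed(((seed %% 2100000) * 1000 + ch * 7) %% 2147483647)
    h <- init_hyper(model) + if (nh) stats::rnorm(nh, 0, 0.3) else numeric(0)
    ls <- rep(log(0.5), nh)
    lp <- if (nh) lp_fun(h) else 0
    if (!is.finite(lp)) { h <- init_hyper(model); lp <- lp_fun(h) }
    n_acc <- rep(0, max(nh, 1L))
    for (it in seq_len(control$iter)) {
      if (nh) for (sc in seq_len(control$scans)) for (j in seq_len(nh)) {
        hp <- h; hp[j] <- h[j] + exp(ls[j]) * stats::rnorm(1)
        lpp <- lp_fun(hp)
        d <- lpp - lp
        a <- if (is.nan(d)) 0 else exp(min(0, d))
        if (stats::runif(1) < a) { h <- hp; lp <- lpp }
        if (it <= control$warmup) {
          ls[j] <- ls[j] + (a - control$adapt_target) / sqrt(it)
        } else n_acc[j] <- n_acc[j] + a / control$scans
      }
      rates <- conditional_rates(model, h)
      if (it > control$warmup) {
        k <- it - control$warmup
        draws[k, ch, ] <- rates$constrained
        unc[k, ch, ] <- c(h, rates$unconstrained)
      }
    }
    accept[ch, ] <- n_acc / n_kept
  }
  rh <- rep(NA_real_, npar); names(rh) <- model$par_names
  for (p in which(model$free))
    rh[p] <- split_rhat(draws[, , p, drop = FALSE][, , 1, drop = TRUE])
  warn <- character(0)
  if (any(rh >= 1.01, na.rm = TRUE))
    warn <- sprintf("convergence warning: %d parameter(s) with split R-hat >= 1.01 (max %.3f)",
                    sum(rh >= 1.01, na.rm = TRUE), max(rh, na.rm = TRUE))
  if (length(warn) && !control$quiet) warning(warn, call. = FALSE)
  structure(list(draws = draws,
                 unconstrained = matrix(aperm(unc, c(1, 2, 3)),
                                        nrow = n_kept * control$chains,
                                        ncol = model$dim),
                 par_names = model$par_names, free = model$free,
                 n_chains = control$chains, n_warmup = control$warmup,
                 n_kept = n_kept, rhat = rh, accept = accept,
                 model = model, seed = seed, warnings = warn),
            class = "cfx_samples")
}

#' @export
print.cfx_samples <- function(x, ...) {
  cat(sprintf("Posterior draws: %d chains x %d kept iterations (%d warm-up), %d parameters\n",
              x$n_chains, x$n_kept, x$n_warmup, length(x$par_names)))
  cat(sprintf("max split R-hat: %.4f\n", max(x$rhat, na.rm = TRUE)))
  if (length(x$warnings)) cat(x$warnings, sep = "\n")
  invisible(x)
}

#' Extract a parameter's pooled posterior draws
#'
#' @param samples a `cfx_samples` object.
#' @param par parameter name as in `samples$par_names`.
#' @return Numeric vector of draws pooled across chains.
#' @export
posterior_draws <- function(samples, par) {
  if (!par %in% samples$par_names)
    cfx_abort(sprintf("no parameter named '%s'", par), "cfx_schema_error")
  as.vector(samples$draws[, , par])
}

#' Export posterior draws as CSV with a JSON diagnostics summary
#'
#' Writes the pooled constrained-scale draws (one column per parameter, one
#' row per kept draw across chains) and, optionally, a JSON file with the
#' sampler configuration, per-parameter split R-hat and any convergence
#' warnings.
#'
#' @param samples a `cfx_samples` object (or the `$samples` of a `cfx_fit`).
#' @param path destination CSV file.
#' @param diagnostics_path optional destination for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(samples, path, diagnostics_path = NULL) {
  if (inherits(samples, "cfx_fit")) samples <- samples$samples
  flat <- apply(samples$draws, 3, as.vector)
  utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(list(
      n_chains = samples$n_chains, n_warmup = samples$n_warmup,
      n_kept = samples$n_kept, seed = samples$seed,
      rhat = as.list(samples$rhat[samples$free]),
      max_rhat = max(samples$rhat, na.rm = TRUE),
      mean_accept = mean(samples$accept),
      warnings = samples$warnings),
      diagnostics_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Rank-normalised split R-hat
#'
#' The convergence diagnostic of Vehtari et al. (2021): chains are split in
#' half, draws are rank-normalised (and, for the tail version, folded about
#' the median), and the classic potential-scale-reduction factor is taken;
#' the reported value is the worse of the bulk and tail versions.
#'
#' @param x matrix of draws, iterations in rows, chains in columns.
#' @return A scalar; `NA` when the draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4) return(NA_real_)
  basic <- function(z) {
    n <- nrow(z)
    half <- n %/% 2L
    zs <- cbind(z[seq_len(half), , drop = FALSE],
                z[seq.int(n - half + 1L, n), , drop = FALSE])
    W <- mean(apply(zs, 2, stats::var))
    B <- half * stats::var(colMeans(zs))
    if (!is.finite(W) || W == 0) return(NA_real_)
    sqrt(((half - 1) / half * W + B / half) / W)
  }
  rank_norm <- function(v) {
    z <- stats::qnorm((rank(v) - 3 / 8) / (length(v) + 1 / 4))
    matrix(z, nrow(x), ncol(x))
  }
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  max(basic(rank_norm(as.vector(x))),
      basic(rank_norm(abs(as.vector(x) - stats::median(x)))))
}
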