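test_that("the collapsed-model joint density matches a hand-assembled sum", {
  pr <- cfx_priors()
  got <- log_density_rst_uw(theta = 0.5, y = 1, N = 2, mu = 0.5, kappa = 2,
                            priors = pr)
  # term-by-term oracle from base distribution functions
  want <- dbinom(1, 2, 0.5, log = TRUE) +
    dbeta(0.5, 0.5 * 2, 0.5 * 2, log = TRUE) +
    dgamma(2, 0.001, rate = 0.001, log = TRUE) +
    dbeta(0.5, 2, 2, log = TRUE)
  expect_equal(got, want, tolerance = 1e-12)

  # the alternative at mu = 0.5 is the null plus the mu-prior density there
  null <- log_density_rst_uw(0.5, 1, 2, kappa = 2, hypothesis = "null",
                             priors = pr)
  expect_equal(got, null + dbeta(0.5, 2, 2, log = TRUE), tolerance = 1e-12)
})

test_that("densities are -Inf outside the support and never NaN", {
  for (th in c(0, 1, -0.1, 1.1))
    expect_identical(log_density_rst_uw(th, 1, 2, 0.5, 2), -Inf)
  expect_identical(log_density_rst_uw(0.5, 1, 2, mu = 0, kappa = 2), -Inf)
  expect_identical(log_density_rst_uw(0.5, 1, 2, mu = 0.5, kappa = 0), -Inf)
  expect_identical(log_density_rst_ew(0.5, 1, 3, 4, 2, 4, mu1 = 0.5,
                                      mu2 = 0.5, kappa1 = 0, kappa2 = 1), -Inf)
  # Dirichlet-multinomial with kappa -> 0: finite or -Inf, never NaN
  th <- rbind(c(1, 1, 1) / 3)
  for (k in c(1e-8, 1e-300, 0)) {
    v <- log_density_ast(th, th, rbind(c(1, 0, 0)), rbind(c(1, 0, 0)),
                         mu1 = c(1, 1, 1) / 3, mu2 = c(1, 1, 1) / 3,
                         kappa1 = k, kappa2 = 1)
    expect_false(is.nan(v))
  }
  expect_identical(log_density_ast(rbind(c(0.5, 0.5, 0.1)), th,
                                   rbind(c(1, 0, 0)), rbind(c(1, 0, 0)),
                                   c(1, 1, 1) / 3, c(1, 1, 1) / 3, 1, 1), -Inf)
})

test_that("the equal-weights density decomposes into two independent hierarchies", {
  pr <- cfx_priors()
  y1 <- c(3, 5); N1 <- c(8, 9); y2 <- c(2, 6); N2 <- c(7, 10)
  th1 <- c(0.4, 0.6); th2 <- c(0.3, 0.55)
  # single-hierarchy oracle assembled from base densities
  one <- function(th, y, N, mu, kappa)
    sum(dbinom(y, N, th, log = TRUE)) +
      sum(dbeta(th, mu * kappa, (1 - mu) * kappa, log = TRUE)) +
      dgamma(kappa, 0.001, rate = 0.001, log = TRUE)
  got <- log_density_rst_ew(th1, th2, y1, N1, y2, N2,
                            mu1 = 0.45, mu2 = 0.6, kappa1 = 4, kappa2 = 6)
  want <- one(th1, y1, N1, 0.45, 4) + one(th2, y2, N2, 0.6, 6) +
    dbeta(0.45, 2, 2, log = TRUE) + dbeta(0.6, 2, 2, log = TRUE)
  expect_equal(got, want, tolerance = 1e-12)

  # setting mu2 = 1 - mu1 in the alternative reproduces the null's terms
  alt_c <- log_density_rst_ew(th1, th2, y1, N1, y2, N2,
                              mu1 = 0.45, mu2 = 0.55, kappa1 = 4, kappa2 = 6)
  nul <- log_density_rst_ew(th1, th2, y1, N1, y2, N2,
                            mu1 = 0.45, kappa1 = 4, kappa2 = 6,
                            hypothesis = "null")
  expect_equal(alt_c, nul + dbeta(0.55, 2, 2, log = TRUE), tolerance = 1e-12)

  # mirror symmetry: swapping contexts and mirroring rates leaves it unchanged
  m1 <- log_density_rst_ew(th1, th2, y1, N1, y2, N2,
                           mu1 = 0.45, mu2 = 0.55, kappa1 = 4, kappa2 = 4)
  m2 <- log_density_rst_ew(th2, th1, y2, N2, y1, N1,
                           mu1 = 0.55, mu2 = 0.45, kappa1 = 4, kappa2 = 4)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("the Dirichlet-multinomial density matches hand terms and is additive over contexts", {
  th <- rbind(c(1, 1, 1) / 3)
  X <- rbind(c(1, 0, 0))
  mu <- c(1, 1, 1) / 3
  got <- log_density_ast(th, th, X, X, mu, mu, 3, 3)
  one_ctx <- log(1 / 3) +                               # multinomial term
    lgamma(3) - sum(lgamma(mu * 3)) + sum((mu * 3 - 1) * log(1 / 3)) +
    lgamma(6) - 3 * lgamma(2) + sum((2 - 1) * log(mu)) +
    dgamma(3, 0.001, rate = 0.001, log = TRUE)
  expect_equal(got, 2 * one_ctx, tolerance = 1e-10)
})

test_that("the unconstrained-scale density equals the constrained density plus Jacobians", {
  cc <- context_counts(c(6, 3), c(4, 7), 0, c(5, 8), c(5, 2), 0)
  pr <- cfx_priors()
  m <- contextfx:::cfx_model(cc, "rst_uw", "alternative", pr)
  eta_mu <- 0.3; eta_k <- log(4); zeta <- c(-0.2, 0.5)
  u <- c(eta_mu, eta_k, zeta)
  mu <- plogis(eta_mu); th <- plogis(zeta)
  jac <- log(mu * (1 - mu)) + eta_k + sum(log(th * (1 - th)))
  expect_equal(contextfx:::cfx_log_density(m, u),
               log_density_rst_uw(th, m$data$y, m$data$N, mu, 4, priors = pr) + jac,
               tolerance = 1e-10)

  m2 <- contextfx:::cfx_model(cc, "rst_ew", "null", pr)
  u2 <- c(0.3, log(4), log(6), -0.2, 0.5, 0.1, -0.4)
  th1 <- plogis(u2[4:5]); th2 <- plogis(u2[6:7])
  jac2 <- log(plogis(0.3) * (1 - plogis(0.3))) + log(4) + log(6) +
    sum(log(th1 * (1 - th1))) + sum(log(th2 * (1 - th2)))
  expect_equal(contextfx:::cfx_log_density(m2, u2),
               log_density_rst_ew(th1, th2, m2$data$y1, m2$data$N1,
                                  m2$data$y2, m2$data$N2, mu1 = plogis(0.3),
                                  kappa1 = 4, kappa2 = 6,
                                  hypothesis = "null", priors = pr) + jac2,
               tolerance = 1e-10)

  # matrix evaluation agrees with row-by-row evaluation
  set.seed(5)
  U <- matrix(rnorm(10 * m$dim), 10)
  expect_equal(contextfx:::cfx_log_density(m, U),
               vapply(seq_len(10), function(i)
                 contextfx:::cfx_log_density(m, U[i, , drop = FALSE]), 0),
               tolerance = 1e-10)
})

test_that("the alternative model's maximum joint density dominates the null's", {
  y <- c(9, 7); N <- c(12, 12); y2 <- c(4, 6); N2 <- c(12, 11)
  # collapsed model: null optimises (kappa, theta), alternative adds mu
  f0 <- function(u) -log_density_rst_uw(plogis(u[-1]), y, N, kappa = exp(u[1]),
                                        hypothesis = "null")
  f1 <- function(u) -log_density_rst_uw(plogis(u[-(1:2)]), y, N,
                                        mu = plogis(u[1]), kappa = exp(u[2]))
  o0 <- optim(c(log(4), qlogis(y / N)), f0, method = "BFGS")
  o1 <- optim(c(0, o0$par), f1, method = "BFGS")
  expect_gte(-o1$value, -o0$value)
  # the embedding alone already guarantees it: alt at mu = 0.5 is the null
  # plus a positive prior log-density log(1.5)
  expect_equal(-f1(c(0, o0$par)), -o0$value + dbeta(0.5, 2, 2, log = TRUE),
               tolerance = 1e-10)

  # equal-weights model: null ties mu2 = 1 - mu1
  g0 <- function(u) -log_density_rst_ew(plogis(u[4:5]), plogis(u[6:7]),
                                        y, N, y2, N2, mu1 = plogis(u[1]),
                                        kappa1 = exp(u[2]), kappa2 = exp(u[3]),
                                        hypothesis = "null")
  g1 <- function(u) -log_density_rst_ew(plogis(u[5:6]), plogis(u[7:8]),
                                        y, N, y2, N2, mu1 = plogis(u[1]),
                                        mu2 = plogis(u[2]),
                                        kappa1 = exp(u[3]), kappa2 = exp(u[4]))
  p0 <- optim(c(0, log(4), log(4), qlogis(y / N), qlogis(y2 / N2)), g0,
              method = "BFGS")
  p1 <- optim(c(p0$par[1], -p0$par[1], p0$par[-1]), g1, method = "BFGS")
  expect_gte(-p1$value, -p0$value)
})
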