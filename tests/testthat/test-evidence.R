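test_that("bridge sampling recovers a two-parameter Gaussian conjugate marginal", {
  # y_j ~ N(theta_j, s2) with theta_j ~ N(0, t2): marginal y_j ~ N(0, s2 + t2)
  s2 <- 1; t2 <- 4
  yobs <- c(1.3, -0.7)
  post_var <- 1 / (1 / s2 + 1 / t2)
  post_mean <- post_var * yobs / s2
  set.seed(31)
  draws <- cbind(rnorm(10000, post_mean[1], sqrt(post_var)),
                 rnorm(10000, post_mean[2], sqrt(post_var)))
  logp <- function(m)
    dnorm(yobs[1], m[, 1], sqrt(s2), log = TRUE) +
    dnorm(yobs[2], m[, 2], sqrt(s2), log = TRUE) +
    dnorm(m[, 1], 0, sqrt(t2), log = TRUE) +
    dnorm(m[, 2], 0, sqrt(t2), log = TRUE)
  b <- bridge_logml(draws, logp, seed = 32)
  analytic <- sum(dnorm(yobs, 0, sqrt(s2 + t2), log = TRUE))
  expect_lt(abs(b$logml - analytic), 0.01)
  expect_lt(b$error, 0.01)

  # doubling the draws moves the estimate by less than the stated error
  set.seed(33)
  draws2 <- cbind(rnorm(20000, post_mean[1], sqrt(post_var)),
                  rnorm(20000, post_mean[2], sqrt(post_var)))
  b2 <- bridge_logml(draws2, logp, seed = 34)
  expect_lt(abs(b2$logml - b$logml), 3 * (b$error + b2$error) + 1e-3)
})

test_that("a model bridged against itself gives a unit Bayes factor", {
  set.seed(41)
  draws <- matrix(rnorm(6000), ncol = 1)
  logp <- function(m) dnorm(m[, 1], log = TRUE)
  b1 <- bridge_logml(draws, logp, seed = 1)
  b2 <- bridge_logml(draws, logp, seed = 2)
  bf <- bayes_factor(b1, b2)
  expect_equal(bf$bf10, 1, tolerance = 0.02)
})

test_that("Bayes factors follow the log-marginal difference and reject non-finite input", {
  expect_equal(bayes_factor(-10, -10)$bf10, 1)
  bf3 <- bayes_factor(-7 + log(3), -7)
  expect_equal(bf3$bf10, 3, tolerance = 1e-12)
  expect_equal(bayes_factor(-9, -7)$bf10, exp(-2))
  expect_equal(bayes_factor(-9, -7)$log10_bf10, -2 / log(10))
  expect_error(bayes_factor(NaN, -1), class = "cfx_validation_error")
  expect_error(bayes_factor(-Inf, -1), class = "cfx_validation_error")
})

test_that("highest density intervals are shortest windows with nesting and guards", {
  expect_equal(hdi(rep(1.7, 200)), c(1.7, 1.7))
  expect_error(hdi(rnorm(50)), class = "cfx_insufficient_error")
  expect_error(hdi(rnorm(200), mass = 1.2))
  set.seed(51)
  x <- rnorm(200000)
  h95 <- hdi(x, 0.95)
  h90 <- hdi(x, 0.90)
  expect_gte(h90[1], h95[1])
  expect_lte(h90[2], h95[2])
  expect_equal(h95, c(-1.96, 1.96), tolerance = 0.03)
  # a skewed distribution: the interval hugs the density peak at zero
  e <- rexp(200000)
  he <- hdi(e, 0.95)
  expect_lt(he[1], 0.02)
  expect_lt(he[2], qexp(0.975) + 0.1)
})

test_that("decision rules classify Bayes factors and HDIs, including boundaries", {
  expect_equal(decide(list(bf10 = 5)), "supports_alternative")
  expect_equal(decide(list(bf10 = 3)), "supports_alternative")
  expect_equal(decide(list(bf10 = 1)), "inconclusive")
  expect_equal(decide(list(bf10 = 1 / 3)), "supports_null")
  expect_equal(decide(list(bf10 = 0.1)), "supports_null")
  expect_equal(decide(list(bf10 = 2.9)), "inconclusive")

  expect_equal(decide(list(hdi = c(0.506, 0.556)), rule = "hdi"),
               "hdi_excludes_null")
  expect_equal(decide(list(hdi = c(0.48, 0.56)), rule = "hdi"),
               "hdi_includes_null")
  expect_equal(decide(list(hdi = c(0.5, 0.55)), rule = "hdi"),
               "hdi_includes_null")
  # one-sided (regularity-violation direction): only intervals above count
  expect_equal(decide(list(hdi = c(0.506, 0.556)), rule = "hdi",
                      direction = "greater"), "hdi_excludes_null")
  expect_equal(decide(list(hdi = c(0.4, 0.45)), rule = "hdi",
                      direction = "greater"), "hdi_includes_null")
  expect_error(decide(list(), rule = "bf"), class = "cfx_schema_error")
})

test_that("group-level share draws honour each measure's definition", {
  cc <- random_counts(10, seed = 6)
  fit <- fit_context_model(cc, "rst_ew", control = fast_ctrl(), seed = 2)
  mu1 <- posterior_draws(fit$samples, "mu[1]")
  mu2 <- posterior_draws(fit$samples, "mu[2]")
  expect_equal(group_share_draws(fit), (mu1 + mu2) / 2)
  # the null model's derived share is identically 0.5
  fit0 <- fit_context_model(cc, "rst_ew", "null", control = fast_ctrl(),
                            seed = 2)
  expect_equal(unique(group_share_draws(fit0)), 0.5)
  expect_error(group_share_draws(fit$samples, "ast"),
               class = "cfx_schema_error")
})

test_that("context_test combines fits, bridge and decisions coherently", {
  cfg <- generator_config(n_participants = 20, mu_1 = 0.8, mu_2 = 0.8,
                          kappa = 12, n_max = 40, delta_sd = 0)
  cc <- generate_dataset(cfg, seed = 21)
  res <- context_test(cc, "rst_ew", control = fast_ctrl(iter = 600,
                                                        warmup = 200),
                      seed = 5)
  expect_s3_class(res, "cfx_evidence")
  expect_equal(res$bf10, exp(res$logml_alt$logml - res$logml_null$logml))
  # a strong simulated effect must be detected by both rules
  expect_equal(res$decision_bf, "supports_alternative")
  expect_equal(res$decision_hdi, "hdi_excludes_null")
  expect_gt(res$hdi[1], 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_evidence_json(res, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$bf10, res$bf10, tolerance = 1e-8)
})
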