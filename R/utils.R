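# Internal numerical helpers shared across the package.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# log(theta) and log(1 - theta) computed stably from the logit.
log_inv_logit <- function(x) stats::plogis(x, log.p = TRUE)
log1m_inv_logit <- function(x) stats::plogis(-x, log.p = TRUE)

# Additive log-ratio transform for K-simplexes (last component is the
# reference).  `a` has K - 1 columns; returns K columns summing to 1.
alr_inv <- function(a) {
  a <- as.matrix(a)
  e <- exp(cbind(a, 0))
  e / rowSums(e)
}

alr <- function(p) {
  p <- as.matrix(p)
  k <- ncol(p)
  log(p[, -k, drop = FALSE]) - log(p[, k])
}

# Draws from a Dirichlet distribution, one row per draw.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Keep rates strictly inside (0, 1) so their logit stays finite.
clamp_unit <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

cfx_abort <- function(msg, class) {
  stop(structure(class = c(class, "cfx_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
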