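# Fixtures built in code: tiny trial tables and random count tables.

worked_example_counts <- function() {
  # the car-scenario participant: 30/20 target/competitor in context 1,
  # 10/15 in context 2
  context_counts(30, 20, 0, 10, 15, 0, participant_id = "p1",
                 effect = "compromise")
}

make_trials <- function(participant_id, effect, context, chosen_role) {
  data.frame(participant_id = participant_id, effect = effect,
             context = context, chosen_role = chosen_role,
             stringsAsFactors = FALSE)
}

# counts table drawn uniformly over 0..max_count (ensuring defined shares)
random_counts <- function(n, max_count = 40, equal_totals = FALSE, seed = 1) {
  set.seed(seed)
  draw <- function() sample.int(max_count, n, replace = TRUE)
  t1 <- draw(); c1 <- draw()
  if (equal_totals) {
    tot <- t1 + c1
    t2 <- vapply(tot, function(m) sample.int(m + 1, 1) - 1L, 1L)
    c2 <- tot - t2
    keep <- (t2 + c2) >= 1
    t1 <- t1[keep]; c1 <- c1[keep]; t2 <- t2[keep]; c2 <- c2[keep]
  } else {
    t2 <- draw(); c2 <- draw()
  }
  context_counts(t1, c1, 0, t2, c2, 0)
}

fast_ctrl <- function(iter = 400, warmup = 150, chains = 2, ...)
  mcmc_control(iter = iter, warmup = warmup, chains = chains, quiet = TRUE, ...)
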