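test_that("trial files parse, with unknown labels and missing columns rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,effect,context,chosen_role",
               "p1,attraction,C1,target",
               "p1,attraction,C1,competitor",
               "p1,attraction,C2,decoy",
               "p2,similarity,C2,target"), f)
  tr <- read_choice_trials(f)
  expect_s3_class(tr, "cfx_trials")
  expect_equal(nrow(tr), 4)
  expect_setequal(unique(tr$chosen_role), c("target", "competitor", "decoy"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,effect,context,chosen_role",
               "p1,attraction,C1,target",
               "p1,attraction,C1,foil"), bad)
  err <- tryCatch(read_choice_trials(bad), error = identity)
  expect_s3_class(err, "cfx_validation_error")
  expect_match(conditionMessage(err), "foil")
  expect_match(conditionMessage(err), "row 2")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,effect,context", "p1,attraction,C1"), miss)
  err2 <- tryCatch(read_choice_trials(miss), error = identity)
  expect_s3_class(err2, "cfx_schema_error")
  expect_match(conditionMessage(err2), "chosen_role")
})

test_that("column remapping via a config file works", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,cond,set,choice",
               "p1,attraction,C1,target",
               "p1,attraction,C2,competitor"), f)
  map <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(participant_id = "subject", effect = "cond",
                            context = "set", chosen_role = "choice"),
                       map, auto_unbox = TRUE)
  tr <- read_choice_trials(f, col_map = map)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$participant_id, c("p1", "p1"))
})

test_that("aggregation reproduces the worked-example counts and conserves totals", {
  tr <- make_trials("p1", "compromise",
                    rep(c("C1", "C1", "C2", "C2"), c(30, 20, 10, 15)),
                    rep(c("target", "competitor", "target", "competitor"),
                        c(30, 20, 10, 15)))
  cc <- aggregate_counts(validate_trials(tr))
  expect_equal(unname(unlist(cc[1, c("n_t_C1", "n_c_C1", "n_d_C1",
                                     "n_t_C2", "n_c_C2", "n_d_C2")])),
               c(30, 20, 0, 10, 15, 0))

  # conservation on a random 1000-trial dataset, against an independent tally
  set.seed(42)
  tr2 <- make_trials(sample(paste0("p", 1:8), 1000, TRUE),
                     sample(c("attraction", "similarity"), 1000, TRUE),
                     sample(c("C1", "C2"), 1000, TRUE),
                     sample(c("target", "competitor", "decoy"), 1000, TRUE))
  cc2 <- aggregate_counts(validate_trials(tr2))
  count_cols <- c("n_t_C1", "n_c_C1", "n_d_C1", "n_t_C2", "n_c_C2", "n_d_C2")
  expect_equal(sum(cc2[count_cols]), 1000)
  for (k in sample(nrow(cc2), 5)) {
    cell <- tr2[tr2$participant_id == cc2$participant_id[k] &
                  tr2$effect == cc2$effect[k], ]
    expect_equal(sum(cc2[k, count_cols]), nrow(cell))
    expect_equal(cc2$n_t_C1[k],
                 sum(cell$context == "C1" & cell$chosen_role == "target"))
  }
  # zero-trial cells are absent
  expect_false(any(rowSums(cc2[count_cols]) == 0))
})

test_that("empty trial input warns and yields an empty table", {
  expect_warning(cc <- aggregate_counts(validate_trials(
    make_trials(character(0), character(0), character(0), character(0)))),
    "no trials")
  expect_equal(nrow(cc), 0)
})

test_that("write-then-read round-trips trials and counts exactly", {
  set.seed(7)
  tr <- validate_trials(make_trials(
    sample(paste0("p", 1:4), 200, TRUE), "compromise",
    sample(c("C1", "C2"), 200, TRUE),
    sample(c("target", "competitor", "decoy"), 200, TRUE)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(tr, f)
  expect_equal(as.data.frame(read_choice_trials(f)), as.data.frame(tr))

  cc <- aggregate_counts(tr)
  g <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(cc, g)
  back <- read_context_counts(g)
  expect_equal(as.data.frame(back), as.data.frame(cc))
})

test_that("pre-aggregated count tables load with default decoys and remapped names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,n_t_C1,n_c_C1,n_t_C2,n_c_C2",
               "s1,30,20,10,15", "s2,12,8,9,11"), f)
  cc <- read_context_counts(f)
  expect_equal(cc$n_d_C1, c(0, 0))
  expect_equal(rst_uw(cc)$value[1], 40 / 75)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,T1,C1,D1,T2,C2,D2", "s1,5,3,1,4,4,2"), g)
  cc2 <- read_context_counts(g, col_map = c(
    participant_id = "id", n_t_C1 = "T1", n_c_C1 = "C1", n_d_C1 = "D1",
    n_t_C2 = "T2", n_c_C2 = "C2", n_d_C2 = "D2"))
  expect_equal(cc2$n_d_C2, 2)
})

test_that("undefined cells are excluded from model-ready counts", {
  cc <- context_counts(c(5, 0), c(5, 0), 0, c(5, 3), c(5, 2), 0)
  expect_message(ok <- model_ready_counts(cc), "dropping 1")
  expect_equal(nrow(ok), 1)
  expect_error(context_counts(-1, 1, 0, 1, 1, 0), class = "cfx_validation_error")
  expect_error(context_counts(0.5, 1, 0, 1, 1, 0), class = "cfx_validation_error")
})
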