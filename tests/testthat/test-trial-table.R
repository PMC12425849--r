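test_that("a generated fixture round-trips through a delimited file", {
  tt <- simulate_scenario(15, 30, n_participants = 15, n_trials = 100,
                          seed = 42)
  raw <- data.frame(subj = tt$participant, cond = tt$condition,
                    rt = tt$outcome)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)

  back <- read_trial_table(path, participant = "subj", condition = "cond",
                           outcome = "rt",
                           condition_levels = c("congruent", "incongruent"))
  expect_s3_class(back, "trial_table")
  expect_equal(nrow(back), 3000)
  expect_equal(length(unique(back$participant)), 15)
  expect_equal(levels(back$condition), c("congruent", "incongruent"))
  expect_equal(back$outcome, tt$outcome)
})

test_that("schema and validation errors are specific", {
  d <- data.frame(participant = rep("p1", 4),
                  condition = c("a", "a", "b", "b"), outcome = 1:4)
  expect_error(trial_table(d, outcome = "rt"), "rt")

  d3 <- d
  d3$condition <- c("a", "b", "c", "a")
  expect_error(
    suppressMessages(trial_table(d3)),
    "exactly 2 levels.*a, b, c")

  dbad <- d
  dbad$outcome <- c("1", "2", "oops", "4")
  expect_error(suppressMessages(trial_table(dbad)), "row\\(s\\) 3")

  dna <- d
  dna$outcome[2] <- NA
  expect_error(suppressMessages(trial_table(dna)), "row\\(s\\) 2")
})

test_that("declared condition-level order sets the sign convention", {
  d <- data.frame(participant = "p1",
                  condition = c("cong", "cong", "incong", "incong"),
                  outcome = c(1, 2, 5, 6))
  t1 <- trial_table(d, condition_levels = c("cong", "incong"))
  t2 <- trial_table(d, condition_levels = c("incong", "cong"))
  expect_equal(mean_difference(t1), 4)
  expect_equal(mean_difference(t2), -4)
})

test_that("exclusion rules drop low-trial and zero-variance participants", {
  set.seed(7)
  cells <- lapply(1:10, function(i) {
    list(neg = rnorm(6), pos = rnorm(6))
  })
  names(cells) <- sprintf("s%02d", 1:10)
  cells$s03$pos <- rnorm(4)                     # 4 trials in one condition
  cells$s08 <- list(neg = rep(1, 6), pos = rep(1, 6))  # constant outcome
  tt <- make_tt(cells)

  res <- apply_exclusions(tt, min_trials = 5)
  expect_s3_class(res, "exclusion_result")
  expect_equal(sum(res$report$excluded), 2)
  expect_equal(length(unique(res$table$participant)), 8)
  expect_equal(res$report$reason[res$report$participant == "s03"],
               "min_trials")
  expect_equal(res$report$reason[res$report$participant == "s08"],
               "zero_variance")

  # retained + excluded rows account for every input row
  n_excluded_rows <- sum(tt$participant %in%
                           res$report$participant[res$report$excluded])
  expect_equal(nrow(res$table) + n_excluded_rows, nrow(tt))

  # idempotence
  res2 <- apply_exclusions(res$table, min_trials = 5)
  expect_equal(res2$table, res$table)
  expect_false(any(res2$report$excluded))
})

test_that("a fully excluded table raises an empty-analysis-set error", {
  tt <- make_tt(list(p1 = list(neg = 1:2, pos = 1:2)))
  expect_error(apply_exclusions(tt, min_trials = 5), "empty analysis set")
})

test_that("min_trials applies per condition cell of a two-factor design", {
  d <- expand.grid(trial = 1:5, condition = c("a", "b"),
                   condition2 = c("x", "y"))
  d$participant <- "p1"
  d$outcome <- rnorm(nrow(d))
  # 5 trials in every cell of one participant; a second participant with
  # only 3 trials in cell (b, y)
  d2 <- d[!(d$condition == "b" & d$condition2 == "y" & d$trial > 3), ]
  d2$participant <- "p2"
  d2$outcome <- rnorm(nrow(d2))
  tt <- suppressMessages(
    trial_table(rbind(d, d2), condition2 = "condition2"))
  res <- apply_exclusions(tt, min_trials = 5)
  expect_equal(res$report$excluded,
               res$report$participant == "p2")
  expect_equal(res$report$reason[res$report$participant == "p2"],
               "min_trials")
})
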