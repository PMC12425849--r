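test_that("mean difference follows the declared sign convention", {
  tt <- one_participant(neg = c(1, 2, 3), pos = c(3, 4, 5))
  expect_equal(mean_difference(tt), 2)
  expect_equal(stat_function(statistic_spec("mean_diff",
                                            swap_sign = TRUE))(tt), -2)
  same <- one_participant(neg = c(1, 2, 3), pos = c(1, 2, 3))
  expect_equal(mean_difference(same), 0)
  expect_error(mean_difference(one_participant(neg = numeric(0), pos = 1:3)),
               "1 trial per condition")
})

test_that("Cohen's d matches the hand-computed pooled formula", {
  tt <- one_participant(neg = c(0, 0, 1, 1), pos = c(1, 1, 2, 2))
  # cell means 0.5 and 1.5, both cell variances 1/3, pooled sd sqrt(1/3)
  expect_equal(cohens_d(tt), 1 / sqrt(1 / 3))

  # scale invariance, shift invariance, antisymmetry
  tt10 <- one_participant(neg = 10 * c(0, 0, 1, 1), pos = 10 * c(1, 1, 2, 2))
  expect_equal(cohens_d(tt10), cohens_d(tt))
  tt_shift <- one_participant(neg = c(0, 0, 1, 1) + 7,
                              pos = c(1, 1, 2, 2) + 7)
  expect_equal(cohens_d(tt_shift), cohens_d(tt))
  expect_equal(stat_function(statistic_spec("cohen_d",
                                            swap_sign = TRUE))(tt),
               -cohens_d(tt))

  expect_equal(cohens_d(one_participant(neg = c(1, 2), pos = c(1, 2))), 0)
  expect_error(cohens_d(one_participant(neg = c(1, 1), pos = c(1, 1))),
               "zero pooled SD")
})

test_that("d-prime matches the closed form with extreme-rate correction", {
  expect_equal(dprime(responses = rep(c(1, 0), each = 10),
                      signal = rep(c(1, 0), c(10, 10)),
                      correct = TRUE),
               qnorm(0.95) - qnorm(0.05))
  resp <- c(rep(1, 9), 0, rep(1, 2), rep(0, 8))
  sig <- rep(c(1, 0), each = 10)
  expect_equal(dprime(resp, sig), qnorm(0.9) - qnorm(0.2))
  expect_equal(dprime(responses = c(1, 0, 1, 0), signal = c(1, 1, 0, 0)), 0)
  expect_error(dprime(c(1, 0), c(1, 1)), "both stimulus classes")
})

test_that("phi coefficient matches direct arithmetic and bounds", {
  expect_equal(phi_coefficient(10, 10, 10, 10), 0)
  expect_equal(phi_coefficient(10, 0, 0, 10), 1)
  expect_equal(phi_coefficient(8, 2, 3, 7),
               (8 * 7 - 2 * 3) / sqrt(10 * 10 * 11 * 9))
  expect_error(phi_coefficient(5, 5, 0, 0), "zero margin")
})

test_that("type-2 AUROC hits its anchor points and the pairwise oracle", {
  # confidence independent of accuracy
  expect_equal(type2_auroc(correct = c(1, 1, 0, 0),
                           confidence = c(1, 2, 1, 2)), 0.5)
  # perfect separation
  expect_equal(type2_auroc(correct = c(1, 1, 1, 0, 0),
                           confidence = c(3, 3, 2, 1, 1)), 1)
  # tied 6-trial instance from the pairwise oracle
  expect_equal(type2_auroc(correct = c(1, 1, 1, 0, 0, 0),
                           confidence = c(3, 2, 2, 2, 1, 1)),
               oracle_auroc_pairwise(c(1, 1, 1, 0, 0, 0),
                                     c(3, 2, 2, 2, 1, 1)))
  expect_error(type2_auroc(correct = c(1, 1), confidence = c(1, 2)),
               "undefined")
})

test_that("type-2 AUROC equals the pairwise oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    correct <- c(1, 0, rbinom(n - 2, 1, 0.6))  # both classes present
    conf <- sample(1:4, n, replace = TRUE)
    expect_equal(type2_auroc(correct, conf),
                 oracle_auroc_pairwise(correct, conf))
  }
})

test_that("interaction contrast is cell-mean arithmetic", {
  build <- function(m) {
    # m: 2x2 matrix of cell means, rows condition (ref, pos),
    # cols condition2 (ref, pos); two identical trials per cell
    g <- expand.grid(condition = c("a", "b"), condition2 = c("x", "y"),
                     rep = 1:2)
    g$participant <- "p1"
    g$outcome <- m[cbind(as.integer(g$condition == "b") + 1,
                         as.integer(g$condition2 == "y") + 1)]
    suppressMessages(trial_table(g, condition2 = "condition2"))
  }
  additive <- build(matrix(c(1, 3, 2, 4), 2))  # no interaction
  expect_equal(interaction_contrast(additive), 0)
  single <- build(matrix(c(0, 0, 0, 10), 2))   # only (pos, pos) cell high
  expect_equal(interaction_contrast(single), 10)
  set.seed(4)
  m <- matrix(rnorm(4), 2)
  expect_equal(interaction_contrast(build(m)),
               (m[2, 2] - m[1, 2]) - (m[2, 1] - m[1, 1]))
})

test_that("every statistic is antisymmetric under a condition swap", {
  set.seed(21)
  n <- 12
  base <- data.frame(
    participant = "p1",
    condition = rep(c("a", "b"), each = n),
    outcome = rbinom(2 * n, 1, 0.5),
    accuracy = rbinom(2 * n, 1, 0.7),
    confidence = sample(1:4, 2 * n, replace = TRUE),
    signal = rep(c(0, 1), n))
  fwd <- trial_table(base, accuracy = "accuracy", confidence = "confidence",
                     signal = "signal", condition_levels = c("a", "b"))
  rev <- trial_table(base, accuracy = "accuracy", confidence = "confidence",
                     signal = "signal", condition_levels = c("b", "a"))
  cont <- base
  cont$outcome <- rnorm(2 * n)
  fwd_c <- trial_table(cont, condition_levels = c("a", "b"))
  rev_c <- trial_table(cont, condition_levels = c("b", "a"))

  expect_equal(mean_difference(rev_c), -mean_difference(fwd_c))
  expect_equal(cohens_d(rev_c), -cohens_d(fwd_c))
  expect_equal(dprime_difference(rev), -dprime_difference(fwd))
  expect_equal(phi_from_trials(rev), -phi_from_trials(fwd))
  expect_equal(auroc2_difference(rev), -auroc2_difference(fwd))
})

test_that("participant_effects computes one value per retained participant", {
  tt <- simulate_scenario(15, 30, n_participants = 6, n_trials = 10,
                          seed = 9)
  eff <- participant_effects(tt, statistic_spec("mean_diff"))
  expect_equal(nrow(eff), 6)
  expect_true(all(is.finite(eff$value)))
  for (id in eff$participant) {
    tr <- tt[tt$participant == id, ]
    expect_equal(eff$value[eff$participant == id],
                 mean(tr$outcome[tr$condition == "incongruent"]) -
                   mean(tr$outcome[tr$condition == "congruent"]))
  }
})

test_that("participants with undefined type-2 AUROC are dropped, with reason", {
  set.seed(3)
  d <- data.frame(
    participant = rep(c("ok", "allcorrect"), each = 16),
    condition = rep(rep(c("a", "b"), each = 8), 2),
    outcome = 0,
    accuracy = c(rbinom(16, 1, 0.6), rep(1, 16)),
    confidence = sample(1:4, 32, replace = TRUE))
  d$accuracy[1:2] <- c(1, 0); d$accuracy[9:10] <- c(1, 0)
  tt <- trial_table(d, accuracy = "accuracy", confidence = "confidence",
                    condition_levels = c("a", "b"))
  eff <- suppressMessages(
    participant_effects(tt, statistic_spec("auroc2_diff")))
  expect_equal(eff$participant, "ok")
  expect_equal(attr(eff, "dropped")$participant, "allcorrect")
})

test_that("sign-flip test matches exhaustive enumeration and edge cases", {
  expect_equal(sign_flip_test(rep(0, 5))$p.value, 1)

  set.seed(14)
  for (rep in 1:10) {
    e <- rnorm(3)
    r <- sign_flip_test(e)
    expect_true(r$exhaustive)
    expect_equal(r$p.value, oracle_flip_p(e))
  }

  strong <- sign_flip_test(rnorm(15, mean = 10, sd = 1))
  expect_lt(strong$p.value, 0.01)

  # Monte-Carlo path: deterministic under a seed, add-one bounded below
  e <- rnorm(20)
  r1 <- sign_flip_test(e, n_flips = 500, seed = 8)
  r2 <- sign_flip_test(e, n_flips = 500, seed = 8)
  expect_false(r1$exhaustive)
  expect_identical(r1$p.value, r2$p.value)
  expect_gte(r1$p.value, 1 / 501)
  expect_error(sign_flip_test(e, n_flips = 0), "n_flips")
  expect_error(sign_flip_test(1), "2 participants")
})
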