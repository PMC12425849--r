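# Prevalence global-null test (GNT): test each participant individually,
# then ask whether the count of significant participants exceeds what the
# individual-level false-positive rate alone would produce.

#' Individual-level condition test for one participant
#'
#' Two-sided test of the condition effect within a single participant's
#' trials: either a pooled-variance two-sample t-test on the outcome
#' between conditions (`"t"`, the default for continuous outcomes), or a
#' within-participant label-permutation test on the mean difference
#' (`"permutation"`, exact by enumeration when the number of distinct
#' label assignments is at most 50000, Monte-Carlo with the add-one
#' estimator otherwise).
#'
#' @param trials One participant's rows of a [trial_table()].
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible
#'   (default 2000).
#' @param seed Optional integer seed (permutation method only).
#' @return A list with `p.value`, `statistic` (t value or mean difference)
#'   and `method`.
#' @export
individual_test <- function(trials, method = c("t", "permutation"),
                            n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  cc <- split_conditions(trials)
  if (method == "t") {
    if (nrow(cc$pos) < 2 || nrow(cc$neg) < 2) {
      stop("t-test requires >= 2 trials per condition", call. = FALSE)
    }
    if (stats::var(cc$pos$outcome) == 0 && stats::var(cc$neg$outcome) == 0) {
      stop("degenerate variance: use method = \"permutation\"",
           call. = FALSE)
    }
    ht <- stats::t.test(cc$pos$outcome, cc$neg$outcome, var.equal = TRUE)
    list(p.value = ht$p.value, statistic = unname(ht$statistic),
         method = "t")
  } else {
    y <- trials$outcome
    n <- length(y); n_pos <- nrow(cc$pos)
    obs <- mean(cc$pos$outcome) - mean(cc$neg$outcome)
    tol <- 1e-12 * max(1, abs(obs))
    n_assign <- choose(n, n_pos)
    if (n_assign <= 5e4) {
      sel <- utils::combn(n, n_pos)
      stats_ <- apply(sel, 2, function(ix) mean(y[ix]) - mean(y[-ix]))
      p <- mean(abs(stats_) >= abs(obs) - tol)
    } else {
      p <- with_seed(seed, {
        hits <- 0L
        for (b in seq_len(n_perm)) {
          ix <- sample.int(n, n_pos)
          if (abs(mean(y[ix]) - mean(y[-ix])) >= abs(obs) - tol) {
            hits <- hits + 1L
          }
        }
        (1 + hits) / (n_perm + 1)
      })
    }
    list(p.value = p, statistic = obs, method = "permutation")
  }
}

#' One-sided binomial test of effect prevalence against the global null
#'
#' Given `k` of `n` participants individually significant at
#' `alpha_individual`, tests whether the observed prevalence `k/n` exceeds
#' the rate expected under the global null (no participant has any true
#' effect), where individually significant results arise at rate
#' `alpha_individual` by construction: `p = P(X >= k | n,
#' alpha_individual)`. The one-sided `1 - alpha_prevalence` confidence
#' interval on prevalence is the Clopper-Pearson inversion
#' `[qbeta(alpha_prevalence, k, n - k + 1), 1]`; its upper bound is always
#' 100%, and the global null is rejected exactly when the lower bound
#' exceeds `alpha_individual`.
#'
#' @param k Number of individually significant participants, or a logical
#'   vector of significance flags (in which case `n` is taken from its
#'   length).
#' @param n Number of participants tested.
#' @param alpha_individual Significance level of the individual-level tests
#'   (default 0.05).
#' @param alpha_prevalence Level of the group-level binomial test (default
#'   0.05).
#' @return An object of class `prevalence_result`.
#' @examples
#' prevalence_test(k = 12, n = 15)  # CI lower bound 0.56, p < .001
#' prevalence_test(k = 1, n = 15)   # p = .537
#' @export
prevalence_test <- function(k, n = length(k), alpha_individual = 0.05,
                            alpha_prevalence = 0.05) {
  if (is.logical(k)) k <- sum(k)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k > n || k < 0) stop("k must lie in [0, n]", call. = FALSE)
  p <- stats::pbinom(k - 1, n, alpha_individual, lower.tail = FALSE)
  ci_lower <- if (k == 0) 0 else stats::qbeta(alpha_prevalence, k, n - k + 1)
  structure(list(n = n, k = k, prevalence = k / n,
                 alpha_individual = alpha_individual,
                 alpha_prevalence = alpha_prevalence,
                 p.value = p, ci_lower = ci_lower,
                 reject = p < alpha_prevalence),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat("Prevalence global-null test (one-sided binomial)\n")
  cat(sprintf("  %d of %d participants significant at alpha_individual = %g (%.0f%%)\n",
              x$k, x$n, x$alpha_individual, 100 * x$prevalence))
  cat(sprintf("  one-sided %g%% CI on prevalence = [%.0f%%, 100%%], p = %.4g\n",
              100 * (1 - x$alpha_prevalence), 100 * x$ci_lower, x$p.value))
  cat(if (x$reject) "  global null rejected\n" else "  global null retained\n")
  invisible(x)
}

#' Prevalence global-null test on a trial table
#'
#' Runs [individual_test()] on every participant and feeds the count of
#' significant results into [prevalence_test()].
#'
#' @inheritParams sign_consistency_test
#' @param method Individual-level test, `"t"` (default; continuous
#'   outcomes) or `"permutation"`.
#' @inheritParams prevalence_test
#' @param seed Optional integer master seed (Monte-Carlo permutation path).
#' @return A `prevalence_result` with the per-participant p-values attached
#'   as `$individual` (data.frame).
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 10, n_trials = 30,
#'                         seed = 4)
#' gnt_test(tt)
#' @export
gnt_test <- function(x, method = c("t", "permutation"),
                     alpha_individual = 0.05, alpha_prevalence = 0.05,
                     seed = NULL) {
  stopifnot(inherits(x, "trial_table"))
  method <- match.arg(method)
  check_cells(x, min_per_cell = if (method == "t") 2 else 1)
  parts <- split_participants(x)
  seeds <- spawn_seeds(seed, length(parts))
  res <- lapply(seq_along(parts), function(i) {
    individual_test(parts[[i]], method = method, seed = seeds[i])
  })
  pvals <- vapply(res, `[[`, numeric(1), "p.value")
  out <- prevalence_test(k = sum(pvals < alpha_individual),
                         n = length(parts),
                         alpha_individual = alpha_individual,
                         alpha_prevalence = alpha_prevalence)
  out$individual <- data.frame(
    participant = names(parts), p.value = pvals,
    significant = pvals < alpha_individual,
    stringsAsFactors = FALSE)
  out$method <- method
  out
}
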