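#' Shuffle condition labels within a participant
#'
#' Randomly reassigns the condition labels to a participant's trials,
#' keeping the per-condition trial counts and the outcome values untouched.
#' This breaks any correlation between condition and outcome and is the
#' elementary move behind every permutation null in the package.
#'
#' @param trials One participant's rows of a [trial_table()].
#' @param seed Optional integer seed.
#' @return `trials` with a permuted `condition` column.
#' @export
permute_labels <- function(trials, seed = NULL) {
  with_seed(seed, {
    trials$condition <- sample(trials$condition)
    trials
  })
}

# M permuted assignments for a participant with n trials of which n_pos are
# in the positive condition: an n_pos x M matrix of trial indices assigned
# to the positive condition. Consumes the current RNG stream.
draw_permutations <- function(n, n_pos, M) {
  vapply(seq_len(M), function(m) sample.int(n, n_pos), integer(n_pos))
}

#' Build the within-participant permutation null distribution
#'
#' For each participant, `M` label permutations are drawn and the statistic
#' recomputed on each, giving a per-participant bank of permuted values.
#' `B` group-level null samples are then formed, each the mean over
#' participants of one value drawn uniformly (with replacement) from each
#' participant's bank. Sampling from pre-computed banks instead of
#' repermuting for every group sample is the standard two-stage shortcut
#' for group-level permutation nulls.
#'
#' One master `seed` deterministically spawns an independent stream per
#' participant (in sorted participant order), so results do not depend on
#' how many random draws other participants consumed.
#'
#' @param x A [trial_table()] (exclusion-filtered).
#' @param stat_fn Function mapping one participant's trials to a single
#'   number; typically built from a [statistic_spec()] or a per-participant
#'   resampling score such as [participant_sign_consistency()].
#' @param M Permutations per participant (default 100).
#' @param B Group-level null samples (default 10000).
#' @param seed Optional integer master seed.
#' @return An object of class `perm_null`: `samples` (length `B`), `banks`
#'   (`M` x participants matrix), `M`, `B`, `seed`.
#' @export
build_null <- function(x, stat_fn, M = 100, B = 10000, seed = NULL) {
  stopifnot(inherits(x, "trial_table"))
  if (M < 1 || B < 1) stop("M and B must be >= 1", call. = FALSE)
  parts <- split_participants(x)
  seeds <- spawn_seeds(seed, length(parts) + 1L)
  banks <- vapply(seq_along(parts), function(i) {
    tr <- parts[[i]]
    with_seed(seeds[i], {
      vapply(seq_len(M), function(m) {
        tr$condition <- sample(tr$condition)
        stat_fn(tr)
      }, numeric(1))
    })
  }, numeric(M))
  banks <- matrix(banks, nrow = M,
                  dimnames = list(NULL, names(parts)))
  samples <- aggregate_banks(banks, B, seeds[length(seeds)])
  structure(list(samples = samples, banks = banks, M = M, B = B,
                 seed = seed, participants = names(parts)),
            class = "perm_null")
}

# Second stage: B group samples, each a mean of one uniformly drawn bank
# value per participant.
aggregate_banks <- function(banks, B, seed = NULL) {
  M <- nrow(banks)
  P <- ncol(banks)
  with_seed(seed, {
    acc <- numeric(B)
    for (p in seq_len(P)) {
      acc <- acc + banks[sample.int(M, B, replace = TRUE), p]
    }
    acc / P
  })
}

#' Permutation p-value
#'
#' `(1 + #(null >= observed)) / (B + 1)` for `direction = "greater"` (the
#' add-one estimator, which never returns 0 and is valid for permutation
#' tests); analogously for `"less"`.
#'
#' @param observed Observed group-level statistic.
#' @param null A `perm_null` from [build_null()], or a numeric vector of
#'   null samples.
#' @param direction `"greater"` (default) or `"less"`.
#' @return A p-value in `(0, 1]`.
#' @export
perm_p_value <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  samples <- if (inherits(null, "perm_null")) null$samples else null
  if (length(samples) == 0) stop("empty null distribution", call. = FALSE)
  tol <- 1e-12 * max(1, abs(observed))
  hits <- if (direction == "greater") {
    sum(samples >= observed - tol)
  } else {
    sum(samples <= observed + tol)
  }
  (1 + hits) / (length(samples) + 1)
}

#' @export
print.perm_null <- function(x, ...) {
  cat("Permutation null distribution\n")
  cat(sprintf("  %d group samples from %d-permutation banks of %d participants\n",
              x$B, x$M, length(x$participants)))
  cat(sprintf("  mean = %.4g, 95%% quantiles [%.4g, %.4g]\n",
              mean(x$samples),
              stats::quantile(x$samples, 0.025),
              stats::quantile(x$samples, 0.975)))
  invisible(x)
}
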