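# Absolute Effect Size test: does the average magnitude of standardised
# within-participant effects exceed what label shuffling alone produces?

#' Absolute standardised effect of one participant
#'
#' `|stat_fn(trials)|` for the statistic named by `spec` — by default
#' Cohen's d, the conventional choice for continuous (RT) outcomes;
#' `dprime_diff` and `phi` serve binary accuracy and response-category
#' outcomes.
#'
#' @inheritParams participant_sign_consistency
#' @param spec A [statistic_spec()] (default `cohen_d`).
#' @return A non-negative number.
#' @export
participant_abs_effect <- function(trials,
                                   spec = statistic_spec("cohen_d")) {
  abs(stat_function(spec)(trials))
}

# |d| for K condition assignments at once (vectorised Cohen's d).
abs_d_scores_fast <- function(y, pos_mat) {
  X <- matrix(apply(pos_mat, 2, function(ix) y[ix]), ncol = ncol(pos_mat))
  Z <- matrix(apply(pos_mat, 2, function(ix) y[-ix]), ncol = ncol(pos_mat))
  n1 <- nrow(X); n0 <- nrow(Z)
  m1 <- colMeans(X); m0 <- colMeans(Z)
  v1 <- (colSums(X^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(Z^2) - n0 * m0^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  abs(m1 - m0) / sqrt(sp2)
}

#' Group-level absolute effect size test
#'
#' Averages `|ES|` (by default `|Cohen's d|`) over participants and
#' compares the group mean against the same within-participant
#' label-permutation null construction as [sign_consistency_test()]: `M`
#' permutations per participant, recomputing `|ES|` on each shuffled set
#' of labels, aggregated into `B` group-level null samples. One-sided
#' (greater) p-value: the alternative is larger effect magnitudes than
#' label shuffling alone produces.
#'
#' @inheritParams sign_consistency_test
#' @param spec A [statistic_spec()] naming the standardised statistic
#'   (default `cohen_d`).
#' @return A `nondir_result`.
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 8, n_trials = 20,
#'                         seed = 3)
#' absolute_es_test(tt, M = 50, B = 1000, seed = 1)
#' @export
absolute_es_test <- function(x, spec = statistic_spec("cohen_d"),
                             M = 100, B = 10000, seed = NULL) {
  stopifnot(inherits(x, "trial_table"))
  if (M < 1 || B < 1) stop("M and B must be >= 1", call. = FALSE)
  check_cells(x, min_per_cell = 2)
  parts <- split_participants(x)
  if (length(parts) < 2) stop("need at least 2 participants", call. = FALSE)
  seeds <- spawn_seeds(seed, length(parts) + 1L)

  fast <- spec$name == "cohen_d" && is.null(x$condition2)
  stat_fn <- if (!fast) stat_function(spec)

  scores <- numeric(length(parts))
  banks <- matrix(NA_real_, M, length(parts),
                  dimnames = list(NULL, names(parts)))
  for (i in seq_along(parts)) {
    tr <- parts[[i]]
    lv <- levels(tr$condition)
    pos_idx <- which(tr$condition == lv[2])
    n <- nrow(tr); n_pos <- length(pos_idx)
    res <- with_seed(seeds[i], {
      perms <- draw_permutations(n, n_pos, M)
      if (fast) {
        list(obs = abs_d_scores_fast(tr$outcome, matrix(pos_idx, ncol = 1)),
             bank = abs_d_scores_fast(tr$outcome, perms))
      } else {
        obs <- abs(stat_fn(tr))
        bank <- vapply(seq_len(M), function(m) {
          ptr <- tr
          ptr$condition <- factor(
            ifelse(seq_len(n) %in% perms[, m], lv[2], lv[1]), levels = lv)
          abs(stat_fn(ptr))
        }, numeric(1))
        list(obs = obs, bank = bank)
      }
    })
    scores[i] <- res$obs
    banks[, i] <- res$bank
  }

  samples <- aggregate_banks(banks, B, seeds[length(seeds)])
  observed <- mean(scores)
  p <- perm_p_value(observed, samples, "greater")
  new_nondir_result(
    method = "Absolute effect size test",
    score_name = "|effect size|",
    statistic = observed,
    per_participant = data.frame(participant = names(parts), score = scores,
                                 stringsAsFactors = FALSE),
    null_samples = samples, banks = banks, p.value = p,
    params = list(statistic = spec$name, n_splits = NA_integer_, M = M,
                  B = B, seed = seed))
}
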