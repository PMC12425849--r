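# Sign Consistency test: split-half agreement of within-participant effect
# signs, compared against a within-participant label-permutation null.
#
# Per participant the trials are repeatedly split into two stratified
# halves (each half gets half of each condition's trials; odd cell counts
# split floor/ceil) and the summary statistic is computed on each half.
# The consistency score SC is the proportion of splits in which both
# halves' statistics share a (non-zero) sign. A split in which either
# half's statistic is exactly 0 counts as inconsistent: zero carries no
# sign. The same split schedule is reused for the observed labels and for
# every permutation of a participant (variance reduction + determinism).

# -- split schedules -------------------------------------------------------

# Random stratified half-splits of one cell of size n: half 1 gets
# floor(n/2) trials. Returned as mean-weight matrices so that
# A1 %*% x = half-1 cell mean for each split. Consumes the RNG stream.
split_matrices <- function(n, n_splits) {
  h <- floor(n / 2)
  H <- matrix(FALSE, n_splits, n)
  for (i in seq_len(n_splits)) H[i, sample.int(n, h)] <- TRUE
  list(A1 = H / h, A2 = (!H) / (n - h), H = H, h = h)
}

# All distinct stratified splits of a cell of size n.
exhaustive_cell_splits <- function(n) {
  h <- floor(n / 2)
  sel <- utils::combn(n, h)
  H <- matrix(FALSE, ncol(sel), n)
  for (i in seq_len(ncol(sel))) H[i, sel[, i]] <- TRUE
  list(A1 = H / h, A2 = (!H) / (n - h), H = H, h = h)
}

expand_pair <- function(Sp, Sn) {
  kp <- nrow(Sp$H); kn <- nrow(Sn$H)
  ip <- rep(seq_len(kp), each = kn)
  in_ <- rep(seq_len(kn), times = kp)
  list(p = lapply(Sp, function(m) if (is.matrix(m)) m[ip, , drop = FALSE] else m),
       n = lapply(Sn, function(m) if (is.matrix(m)) m[in_, , drop = FALSE] else m))
}

# -- fast mean-difference path --------------------------------------------

# SC scores for K condition assignments at once. y: the participant's
# outcomes; pos_mat: n_pos x K matrix of indices assigned to the positive
# condition; Sp, Sn: split weight matrices for the two cells.
sc_scores_fast <- function(y, pos_mat, Sp, Sn) {
  X <- apply(pos_mat, 2, function(ix) y[ix])
  Z <- apply(pos_mat, 2, function(ix) y[-ix])
  X <- matrix(X, ncol = ncol(pos_mat))
  Z <- matrix(Z, ncol = ncol(pos_mat))
  D1 <- Sp$A1 %*% X - Sn$A1 %*% Z
  D2 <- Sp$A2 %*% X - Sn$A2 %*% Z
  colMeans(D1 * D2 > 0)
}

# -- generic statistic path ------------------------------------------------

# Build the two halves of one split as trial data.frames with the assigned
# condition labels, and return sign agreement.
split_agreement <- function(trials, pos_idx, sp, sn, stat_fn) {
  n <- nrow(trials)
  neg_idx <- setdiff(seq_len(n), pos_idx)
  lv <- levels(trials$condition)
  make_half <- function(selp, seln) {
    half <- trials[c(pos_idx[selp], neg_idx[seln]), , drop = FALSE]
    half$condition <- factor(rep(lv[2:1], c(length(selp), length(seln))),
                             levels = lv)
    half
  }
  v1 <- stat_fn(make_half(sp$sel, sn$sel))
  v2 <- stat_fn(make_half(sp$rest, sn$rest))
  (v1 > 0 && v2 > 0) || (v1 < 0 && v2 < 0)
}

sc_score_generic <- function(trials, pos_idx, schedule, stat_fn) {
  mean(vapply(schedule,
              function(s) split_agreement(trials, pos_idx, s$p, s$n, stat_fn),
              logical(1)))
}

random_schedule <- function(n_pos, n_neg, n_splits) {
  hp <- floor(n_pos / 2); hn <- floor(n_neg / 2)
  lapply(seq_len(n_splits), function(i) {
    sp <- sample.int(n_pos, hp)
    sn <- sample.int(n_neg, hn)
    list(p = list(sel = sp, rest = setdiff(seq_len(n_pos), sp)),
         n = list(sel = sn, rest = setdiff(seq_len(n_neg), sn)))
  })
}

# -- user-facing functions -------------------------------------------------

#' Split-half sign consistency of one participant
#'
#' Estimates the probability that two random stratified halves of a
#' participant's trials show the same qualitative effect: the proportion
#' of `n_splits` random splits in which both halves' summary statistics
#' share a non-zero sign. 0.5 is chance for a continuous outcome with no
#' true effect; values near 1 indicate a stable within-participant effect
#' of either sign.
#'
#' @param trials One participant's rows of a [trial_table()], with at least
#'   2 trials per condition (each half needs one).
#' @param spec A [statistic_spec()]; the score only uses the statistic's
#'   sign, so it is invariant to the sign convention.
#' @param n_splits Number of random splits (default 500).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all distinct stratified splits instead of
#'   sampling (exact; only feasible for small trial counts, capped at
#'   100000 splits).
#' @return The sign-consistency score, in `[0, 1]`.
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 1, n_trials = 20,
#'                         seed = 2)
#' participant_sign_consistency(tt, seed = 1)
#' @export
participant_sign_consistency <- function(trials,
                                         spec = statistic_spec("mean_diff"),
                                         n_splits = 500, seed = NULL,
                                         exhaustive = FALSE) {
  cc <- split_conditions(trials)
  n_pos <- nrow(cc$pos); n_neg <- nrow(cc$neg)
  if (n_pos < 2 || n_neg < 2) {
    stop("sign consistency requires >= 2 trials per condition",
         " (participant ", trials$participant[1], ")", call. = FALSE)
  }
  if (exhaustive) {
    total <- choose(n_pos, floor(n_pos / 2)) * choose(n_neg, floor(n_neg / 2))
    if (total > 1e5) {
      stop("too many stratified splits to enumerate (", total, ")",
           call. = FALSE)
    }
  }
  pos_idx <- which(trials$condition == levels(trials$condition)[2])
  if (spec$name == "mean_diff" && is.null(trials$condition2)) {
    with_seed(seed, {
      S <- if (exhaustive) {
        expand_pair(exhaustive_cell_splits(n_pos),
                    exhaustive_cell_splits(n_neg))
      } else {
        list(p = split_matrices(n_pos, n_splits),
             n = split_matrices(n_neg, n_splits))
      }
      sc_scores_fast(trials$outcome, matrix(pos_idx, ncol = 1), S$p, S$n)
    })
  } else {
    stat_fn <- stat_function(spec)
    with_seed(seed, {
      schedule <- if (exhaustive) {
        exhaustive_schedule(n_pos, n_neg)
      } else {
        random_schedule(n_pos, n_neg, n_splits)
      }
      sc_score_generic(trials, pos_idx, schedule, stat_fn)
    })
  }
}

exhaustive_schedule <- function(n_pos, n_neg) {
  hp <- floor(n_pos / 2); hn <- floor(n_neg / 2)
  selp <- utils::combn(n_pos, hp)
  seln <- utils::combn(n_neg, hn)
  out <- vector("list", ncol(selp) * ncol(seln))
  k <- 1L
  for (i in seq_len(ncol(selp))) {
    for (j in seq_len(ncol(seln))) {
      out[[k]] <- list(
        p = list(sel = selp[, i], rest = setdiff(seq_len(n_pos), selp[, i])),
        n = list(sel = seln[, j], rest = setdiff(seq_len(n_neg), seln[, j])))
      k <- k + 1L
    }
  }
  out
}

#' Group-level sign consistency test
#'
#' Averages the per-participant split-half sign-consistency scores
#' ([participant_sign_consistency()]) and compares the group mean against a
#' permutation null built by reshuffling condition labels within
#' participants: `M` label permutations per participant, each rescored
#' with the *same* split schedule, aggregated into `B` group-level null
#' samples (see [build_null()]). The p-value is one-sided (greater): the
#' alternative is more sign consistency than expected when no participant's
#' outcome is sensitive to the condition.
#'
#' @param x A validated, exclusion-filtered [trial_table()] with at least 2
#'   participants and 2 trials per condition cell.
#' @param spec A [statistic_spec()] (default `mean_diff`; only its sign is
#'   used).
#' @param n_splits Random stratified splits per participant (default 500).
#' @param M Label permutations per participant (default 100).
#' @param B Group-level null samples (default 10000).
#' @param seed Optional integer master seed.
#' @return A `nondir_result`: group statistic, per-participant scores, null
#'   samples, p-value and parameters.
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 8, n_trials = 20,
#'                         seed = 3)
#' sign_consistency_test(tt, n_splits = 100, M = 50, B = 1000, seed = 1)
#' @export
sign_consistency_test <- function(x, spec = statistic_spec("mean_diff"),
                                  n_splits = 500, M = 100, B = 10000,
                                  seed = NULL) {
  stopifnot(inherits(x, "trial_table"))
  if (M < 1 || B < 1 || n_splits < 1) {
    stop("n_splits, M and B must be >= 1", call. = FALSE)
  }
  check_cells(x, min_per_cell = 2)
  parts <- split_participants(x)
  if (length(parts) < 2) stop("need at least 2 participants", call. = FALSE)
  seeds <- spawn_seeds(seed, length(parts) + 1L)

  fast <- spec$name == "mean_diff" && is.null(x$condition2)
  stat_fn <- if (!fast) stat_function(spec)

  scores <- numeric(length(parts))
  banks <- matrix(NA_real_, M, length(parts),
                  dimnames = list(NULL, names(parts)))
  for (i in seq_along(parts)) {
    tr <- parts[[i]]
    lv2 <- levels(tr$condition)[2]
    pos_idx <- which(tr$condition == lv2)
    n <- nrow(tr); n_pos <- length(pos_idx); n_neg <- n - n_pos
    if (n_pos < 2 || n_neg < 2) {
      stop("participant ", tr$participant[1],
           " has fewer than 2 trials in a condition", call. = FALSE)
    }
    # per-participant stream: splits first, then permutations
    res <- with_seed(seeds[i], {
      if (fast) {
        S <- list(p = split_matrices(n_pos, n_splits),
                  n = split_matrices(n_neg, n_splits))
        perms <- draw_permutations(n, n_pos, M)
        list(obs = sc_scores_fast(tr$outcome, matrix(pos_idx, ncol = 1),
                                  S$p, S$n),
             bank = sc_scores_fast(tr$outcome, perms, S$p, S$n))
      } else {
        schedule <- random_schedule(n_pos, n_neg, n_splits)
        perms <- draw_permutations(n, n_pos, M)
        obs <- sc_score_generic(tr, pos_idx, schedule, stat_fn)
        bank <- vapply(seq_len(M), function(m) {
          sc_score_generic(tr, perms[, m], schedule, stat_fn)
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
    method = "Sign consistency test",
    score_name = "sign consistency",
    statistic = observed,
    per_participant = data.frame(participant = names(parts), score = scores,
                                 stringsAsFactors = FALSE),
    null_samples = samples, banks = banks, p.value = p,
    params = list(statistic = spec$name, n_splits = n_splits, M = M, B = B,
                  seed = seed))
}

new_nondir_result <- function(method, score_name, statistic, per_participant,
                              null_samples, banks, p.value, params) {
  structure(list(method = method, score_name = score_name,
                 statistic = statistic, per_participant = per_participant,
                 null_samples = null_samples, banks = banks,
                 p.value = p.value, params = params),
            class = "nondir_result")
}

#' @export
print.nondir_result <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("  statistic: %s over %d participants\n",
              x$params$statistic, nrow(x$per_participant)))
  cat(sprintf("  group mean %s = %.4g\n", x$score_name, x$statistic))
  cat(sprintf("  permutation null: M = %d per participant, B = %d group samples\n",
              x$params$M, x$params$B))
  cat(sprintf("  p (one-sided, greater) = %.4g\n", x$p.value))
  invisible(x)
}
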