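# Fixture builders and independent oracles. Oracles are deliberately
# written as brute-force enumerations, sharing no code with the package
# internals they check.

# Quick trial table for one or more participants from outcome vectors.
# `cells` is a named list: participant id -> list(neg = ..., pos = ...).
make_tt <- function(cells, levels = c("a", "b"), ...) {
  rows <- do.call(rbind, lapply(names(cells), function(id) {
    data.frame(
      participant = id,
      condition = rep(levels, c(length(cells[[id]]$neg),
                                length(cells[[id]]$pos))),
      outcome = c(cells[[id]]$neg, cells[[id]]$pos),
      stringsAsFactors = FALSE)
  }))
  suppressMessages(trial_table(rows, condition_levels = levels, ...))
}

one_participant <- function(neg, pos, levels = c("a", "b")) {
  make_tt(list(p1 = list(neg = neg, pos = pos)), levels = levels)
}

# Exhaustive stratified split-half sign-consistency of mean differences:
# enumerate every way of giving floor(n/2) trials of each condition to
# half 1, and count splits where both halves' mean differences share a
# non-zero sign.
oracle_sc_exhaustive <- function(neg, pos) {
  hp <- floor(length(pos) / 2)
  hn <- floor(length(neg) / 2)
  sel_p <- utils::combn(length(pos), hp)
  sel_n <- utils::combn(length(neg), hn)
  agree <- 0L
  total <- 0L
  for (i in seq_len(ncol(sel_p))) {
    for (j in seq_len(ncol(sel_n))) {
      d1 <- mean(pos[sel_p[, i]]) - mean(neg[sel_n[, j]])
      d2 <- mean(pos[-sel_p[, i]]) - mean(neg[-sel_n[, j]])
      agree <- agree + as.integer(d1 * d2 > 0)
      total <- total + 1L
    }
  }
  agree / total
}

# Pairwise-comparison (Mann-Whitney with tie correction) type-2 AUROC.
oracle_auroc_pairwise <- function(correct, confidence) {
  hit <- confidence[correct == 1]
  miss <- confidence[correct == 0]
  wins <- 0
  for (h in hit) for (m in miss) {
    wins <- wins + (h > m) + 0.5 * (h == m)
  }
  wins / (length(hit) * length(miss))
}

# Exhaustive two-sided sign-flip p for the population mean.
oracle_flip_p <- function(effects) {
  n <- length(effects)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- abs(signs %*% effects / n)
  mean(means >= abs(mean(effects)) - 1e-12)
}

# Exhaustive two-sided within-participant permutation p for the mean
# difference: enumerate all assignments of n_pos trials to the positive
# condition.
oracle_perm_p <- function(y, n_pos) {
  obs <- mean(y[seq_len(n_pos)]) - mean(y[-seq_len(n_pos)])
  sel <- utils::combn(length(y), n_pos)
  stats_ <- apply(sel, 2, function(ix) mean(y[ix]) - mean(y[-ix]))
  mean(abs(stats_) >= abs(obs) - 1e-12)
}
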