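#' Omnibus trial-level ANOVA with participants as fixed effects
#'
#' Tests the joint null that no participant shows any condition effect, by
#' comparing two least-squares fits of the trial-level outcome: a full
#' model with one intercept and one condition effect per participant
#' (participant, condition and their interaction), and a reduced model
#' with participant intercepts only. With `P` participants, `C = 2`
#' conditions and `N` trials in total,
#' `F = [(SSE_reduced - SSE_full) / P] / [SSE_full / (N - 2P)]` on
#' `(P, N - 2P)` degrees of freedom. Implemented as a direct residual
#' sum-of-squares decomposition over cell and participant means, which is
#' exact, leaves no sum-of-squares-type ambiguity, and handles unbalanced
#' cell counts naturally.
#'
#' The test assumes normal errors with equal variance across participants
#' and conditions; violations of the equal-variance assumption can
#' seriously distort its error rates, and no robust variant is offered.
#'
#' @param x A [trial_table()] with two conditions and at least 2 trials per
#'   participant-by-condition cell.
#' @return An object of class `oanova_result`: `statistic` (F), `df1`,
#'   `df2`, `p.value`, `sse_full`, `sse_reduced`, `n_participants`,
#'   `n_trials`.
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 15, n_trials = 100,
#'                         seed = 5)
#' oanova_test(tt)  # df = (15, 2970)
#' @export
oanova_test <- function(x) {
  stopifnot(inherits(x, "trial_table"))
  check_cells(x, min_per_cell = 2)
  y <- x$outcome
  part <- factor(x$participant)
  cell <- interaction(part, x$condition, drop = FALSE)

  ss_within <- function(g) {
    means <- tapply(y, g, mean)
    sum((y - means[g])^2)
  }
  sse_full <- ss_within(cell)          # participant x condition cell means
  sse_reduced <- ss_within(part)       # participant intercepts only

  P <- nlevels(part)
  N <- length(y)
  df1 <- P                              # P * (C - 1), C = 2
  df2 <- N - 2L * P
  if (df2 < 1) stop("not enough trials for the full model", call. = FALSE)
  f <- ((sse_reduced - sse_full) / df1) / (sse_full / df2)
  structure(list(statistic = f, df1 = df1, df2 = df2,
                 p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 sse_full = sse_full, sse_reduced = sse_reduced,
                 n_participants = P, n_trials = N),
            class = "oanova_result")
}

#' @export
print.oanova_result <- function(x, ...) {
  cat("Omnibus ANOVA test (participants as fixed effects)\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p.value))
  cat(sprintf("  SSE full = %.6g, SSE reduced = %.6g (%d trials, %d participants)\n",
              x$sse_full, x$sse_reduced, x$n_trials, x$n_participants))
  invisible(x)
}
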