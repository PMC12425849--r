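#' Declare a per-participant summary statistic
#'
#' A `statistic_spec` names the signed within-participant summary statistic
#' that all group-level tests are built on, together with its sign
#' convention and options. Available statistics:
#'
#' * `mean_diff` — mean outcome difference between conditions (outcome
#'   units); the canonical RT congruency effect.
#' * `cohen_d` — mean difference standardised by the pooled SD
#'   (dimensionless).
#' * `dprime_diff` — difference in signal-detection sensitivity d' between
#'   conditions; needs a binary `outcome` (the response) and a 0/1 `signal`
#'   column.
#' * `phi` — phi coefficient of the 2x2 condition-by-response table; needs
#'   a binary outcome.
#' * `auroc2_diff` — difference in response-conditional type-2 AUROC
#'   (metacognitive sensitivity) between the two conditions (= the two
#'   response categories); needs `accuracy` and `confidence` columns.
#' * `interaction_contrast` — difference of condition differences across
#'   the levels of `condition2` (outcome units).
#'
#' The positive direction is taken from the trial table's declared
#' condition-level order (second level positive); `swap_sign = TRUE` flips
#' it. Every statistic is antisymmetric under swapping the convention.
#'
#' @param name One of `"mean_diff"`, `"cohen_d"`, `"dprime_diff"`, `"phi"`,
#'   `"auroc2_diff"`, `"interaction_contrast"`.
#' @param swap_sign Flip the sign convention declared by the trial table.
#' @param extreme_rate_correction For `dprime_diff`: extreme hit/false-alarm
#'   rates of 0 or 1 are replaced by `1/(2N)` and `1 - 1/(2N)` (standard
#'   signal-detection practice). Set to `FALSE` to error on extreme rates
#'   instead.
#' @return An object of class `statistic_spec`.
#' @examples
#' spec <- statistic_spec("mean_diff")
#' @export
statistic_spec <- function(name = c("mean_diff", "cohen_d", "dprime_diff",
                                    "phi", "auroc2_diff",
                                    "interaction_contrast"),
                           swap_sign = FALSE,
                           extreme_rate_correction = TRUE) {
  name <- match.arg(name)
  structure(list(name = name, swap_sign = swap_sign,
                 extreme_rate_correction = extreme_rate_correction),
            class = "statistic_spec")
}

#' @export
print.statistic_spec <- function(x, ...) {
  cat("Statistic spec: ", x$name,
      if (x$swap_sign) " (sign convention swapped)", "\n", sep = "")
  invisible(x)
}

# Resolve a spec to a function(trials) -> one finite real, where `trials`
# is one participant's rows of a trial_table.
stat_function <- function(spec) {
  stopifnot(inherits(spec, "statistic_spec"))
  fn <- switch(spec$name,
    mean_diff = function(tr) mean_difference(tr),
    cohen_d = function(tr) cohens_d(tr),
    dprime_diff = function(tr)
      dprime_difference(tr, correct = spec$extreme_rate_correction),
    phi = function(tr) phi_from_trials(tr),
    auroc2_diff = function(tr) auroc2_difference(tr),
    interaction_contrast = function(tr) interaction_contrast(tr))
  if (spec$swap_sign) function(tr) -fn(tr) else fn
}

split_conditions <- function(trials) {
  lv <- levels(trials$condition)
  list(neg = trials[trials$condition == lv[1], , drop = FALSE],
       pos = trials[trials$condition == lv[2], , drop = FALSE])
}

#' Per-participant signed summary statistics
#'
#' Low-level statistic functions operating on one participant's trials (the
#' rows of a [trial_table()] belonging to a single participant). Most users
#' go through [participant_effects()] or the test functions instead.
#'
#' @param trials One participant's rows of a [trial_table()].
#' @return A single finite number; its sign follows the table's declared
#'   condition order (positive = second level higher).
#' @name participant_statistics
NULL

#' @describeIn participant_statistics Mean outcome in the positive condition
#'   minus mean outcome in the reference condition (outcome units).
#' @export
mean_difference <- function(trials) {
  cc <- split_conditions(trials)
  if (nrow(cc$pos) < 1 || nrow(cc$neg) < 1) {
    stop("mean_difference requires at least 1 trial per condition",
         call. = FALSE)
  }
  mean(cc$pos$outcome) - mean(cc$neg$outcome)
}

#' @describeIn participant_statistics Two-sample Cohen's d: the mean
#'   difference divided by the pooled SD (per-cell Bessel-corrected
#'   variances weighted by their degrees of freedom).
#' @export
cohens_d <- function(trials) {
  cc <- split_conditions(trials)
  n1 <- nrow(cc$pos); n0 <- nrow(cc$neg)
  if (n1 < 2 || n0 < 2) {
    stop("cohens_d requires at least 2 trials per condition", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(cc$pos$outcome) +
          (n0 - 1) * stats::var(cc$neg$outcome)) / (n1 + n0 - 2)
  if (sp2 <= 0) {
    stop("zero pooled SD: participant should have been excluded",
         call. = FALSE)
  }
  (mean(cc$pos$outcome) - mean(cc$neg$outcome)) / sqrt(sp2)
}

#' Signal-detection sensitivity d'
#'
#' `z(hit rate) - z(false-alarm rate)` from binary responses under two
#' stimulus classes. Extreme rates of 0 or 1 are replaced by `1/(2N)` and
#' `1 - 1/(2N)` respectively (N = the number of trials in that class)
#' unless `correct = FALSE`.
#'
#' @param responses 0/1 vector of "signal present" responses.
#' @param signal 0/1 vector of true stimulus class, same length.
#' @param correct Apply the extreme-rate correction (default TRUE).
#' @return d' in z-units.
#' @examples
#' dprime(responses = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 1),
#'        signal    = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
#' @export
dprime <- function(responses, signal, correct = TRUE) {
  stopifnot(length(responses) == length(signal))
  n_sig <- sum(signal == 1); n_noise <- sum(signal == 0)
  if (n_sig == 0 || n_noise == 0) {
    stop("d' requires trials in both stimulus classes", call. = FALSE)
  }
  hr <- mean(responses[signal == 1])
  fa <- mean(responses[signal == 0])
  if (correct) {
    hr <- clamp_rate(hr, n_sig)
    fa <- clamp_rate(fa, n_noise)
  } else if (hr %in% c(0, 1) || fa %in% c(0, 1)) {
    stop("extreme hit/false-alarm rate with correction disabled",
         call. = FALSE)
  }
  stats::qnorm(hr) - stats::qnorm(fa)
}

clamp_rate <- function(p, n) {
  if (p == 0) 1 / (2 * n) else if (p == 1) 1 - 1 / (2 * n) else p
}

#' @describeIn participant_statistics d' in the positive condition minus d'
#'   in the reference condition; needs binary `outcome` (the response) and
#'   a `signal` column.
#' @param correct Apply the d' extreme-rate correction.
#' @export
dprime_difference <- function(trials, correct = TRUE) {
  if (is.null(trials$signal)) {
    stop("dprime_diff requires a `signal` column in the trial table",
         call. = FALSE)
  }
  cc <- split_conditions(trials)
  dprime(cc$pos$outcome, cc$pos$signal, correct = correct) -
    dprime(cc$neg$outcome, cc$neg$signal, correct = correct)
}

#' Phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` for cell counts
#' `a, b, c, d` laid out row-wise. Errors when any margin is zero (the
#' coefficient is undefined).
#'
#' @param a,b,c,d Non-negative cell counts: rows are condition
#'   (positive, reference), columns response (1, 0).
#' @return phi in `[-1, 1]`.
#' @examples
#' phi_coefficient(8, 2, 3, 7)
#' @export
phi_coefficient <- function(a, b, c, d) {
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("phi undefined: zero margin in the 2x2 table",
                        call. = FALSE)
  (a * d - b * c) / sqrt(prod(m))
}

phi_from_trials <- function(trials) {
  if (!all(trials$outcome %in% c(0, 1))) {
    stop("phi requires a binary (0/1) outcome", call. = FALSE)
  }
  cc <- split_conditions(trials)
  phi_coefficient(a = sum(cc$pos$outcome == 1),
                  b = sum(cc$pos$outcome == 0),
                  c = sum(cc$neg$outcome == 1),
                  d = sum(cc$neg$outcome == 0))
}

#' Response-conditional type-2 AUROC
#'
#' Area under the type-2 ROC curve: how well confidence ratings
#' discriminate correct from incorrect trials, computed by the trapezoidal
#' rule over the observed confidence levels used as criteria. Ties receive
#' half credit, so the value equals the pairwise (Mann-Whitney) probability
#' `P(conf_correct > conf_incorrect) + 0.5 P(equal)`. 0.5 means no
#' metacognitive sensitivity; 1 means perfect.
#'
#' @param correct 0/1 vector of objective accuracy.
#' @param confidence Numeric/ordinal confidence ratings, same length.
#' @return Area in `[0, 1]`, or an error when either all trials are correct
#'   or all are incorrect (the curve is undefined).
#' @examples
#' type2_auroc(correct = c(1, 1, 1, 0, 0, 0),
#'             confidence = c(3, 3, 2, 2, 1, 1))
#' @export
type2_auroc <- function(correct, confidence) {
  stopifnot(length(correct) == length(confidence))
  n_hit <- sum(correct == 1); n_miss <- sum(correct == 0)
  if (n_hit == 0 || n_miss == 0) {
    stop("type-2 AUROC undefined: need both correct and incorrect trials",
         call. = FALSE)
  }
  # criteria sweep from the most conservative (highest confidence) down;
  # cumulative type-2 hit rate vs type-2 false-alarm rate
  crit <- sort(unique(confidence), decreasing = TRUE)
  h2 <- c(0, vapply(crit, function(k) mean(confidence[correct == 1] >= k),
                    numeric(1)))
  f2 <- c(0, vapply(crit, function(k) mean(confidence[correct == 0] >= k),
                    numeric(1)))
  sum(diff(f2) * (h2[-1] + h2[-length(h2)]) / 2)
}

auroc2_difference <- function(trials) {
  if (is.null(trials$accuracy) || is.null(trials$confidence)) {
    stop("auroc2_diff requires `accuracy` and `confidence` columns",
         call. = FALSE)
  }
  cc <- split_conditions(trials)
  type2_auroc(cc$pos$accuracy, cc$pos$confidence) -
    type2_auroc(cc$neg$accuracy, cc$neg$confidence)
}

#' @describeIn participant_statistics Interaction contrast on cell means for
#'   two 2-level factors: the condition difference at the positive level of
#'   `condition2` minus the condition difference at its reference level.
#' @export
interaction_contrast <- function(trials) {
  if (is.null(trials$condition2)) {
    stop("interaction_contrast requires a `condition2` column",
         call. = FALSE)
  }
  m <- tapply(trials$outcome, list(trials$condition, trials$condition2),
              mean)
  if (any(is.na(m))) stop("empty condition x condition2 cell", call. = FALSE)
  # rows: condition (ref, pos); cols: condition2 (ref, pos)
  (m[2, 2] - m[1, 2]) - (m[2, 1] - m[1, 1])
}

#' Compute the summary statistic for every participant
#'
#' Applies a [statistic_spec()] to each participant's trials. Participants
#' for whom the statistic is undefined in a recoverable way (type-2 AUROC
#' with a response cell lacking correct or incorrect trials) are dropped
#' with their reason recorded in the `dropped` attribute; structural errors
#' (zero pooled SD, empty cells) propagate, since those participants should
#' have been excluded upstream.
#'
#' @param x A [trial_table()].
#' @param spec A [statistic_spec()].
#' @return A data.frame with columns `participant`, `value`, `n_trials`,
#'   plus attribute `dropped` (possibly empty data.frame of participant /
#'   reason).
#' @examples
#' tt <- simulate_scenario(15, 30, n_participants = 5, n_trials = 20,
#'                         seed = 1)
#' participant_effects(tt, statistic_spec("mean_diff"))
#' @export
participant_effects <- function(x, spec = statistic_spec("mean_diff")) {
  stopifnot(inherits(x, "trial_table"))
  fn <- stat_function(spec)
  parts <- split_participants(x)
  droppable <- spec$name == "auroc2_diff"
  vals <- lapply(names(parts), function(id) {
    v <- if (droppable) {
      tryCatch(fn(parts[[id]]), error = function(e) {
        structure(NA_real_, reason = conditionMessage(e))
      })
    } else fn(parts[[id]])
    v
  })
  dropped_idx <- vapply(vals, function(v) is.na(v), logical(1))
  dropped <- data.frame(
    participant = names(parts)[dropped_idx],
    reason = vapply(vals[dropped_idx],
                    function(v) attr(v, "reason") %||% "undefined",
                    character(1)),
    stringsAsFactors = FALSE)
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " participant(s) dropped for statistic ",
            spec$name, ": ", paste(dropped$participant, collapse = ", "))
  }
  out <- data.frame(
    participant = names(parts)[!dropped_idx],
    value = unlist(vals[!dropped_idx]),
    n_trials = vapply(parts[!dropped_idx], nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Directional group-level sign-flipping test
#'
#' Two-sided non-parametric test of a zero population mean for a vector of
#' per-participant effects, used to filter out experiments that already show
#' a significant directional effect. Signs of the per-participant effects
#' are flipped at random and the proportion of flip patterns with
#' `|mean| >= |observed mean|` is the p-value. With `2^n <= 32768` the flip
#' patterns are enumerated exhaustively (exact p); otherwise `n_flips`
#' Monte-Carlo patterns are drawn and the add-one estimator is used.
#'
#' @param effects Numeric vector of per-participant signed effects, or the
#'   data.frame returned by [participant_effects()].
#' @param n_flips Number of Monte-Carlo sign-flip resamples (default
#'   10000); ignored when exhaustive enumeration is feasible.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @return A list of class `sign_flip_test` with `statistic` (the observed
#'   mean), `p.value`, `n` and `exhaustive`.
#' @examples
#' sign_flip_test(c(10, 12, -2, 8, 14, 9), seed = 1)
#' @export
sign_flip_test <- function(effects, n_flips = 10000, seed = NULL) {
  if (is.data.frame(effects)) effects <- effects$value
  n <- length(effects)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (n_flips < 1) stop("n_flips must be >= 1", call. = FALSE)
  obs <- mean(effects)
  tol <- 1e-12 * max(1, abs(obs))
  exhaustive <- 2^n <= 2^15
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    flip_means <- as.vector(signs %*% effects) / n
    p <- mean(abs(flip_means) >= abs(obs) - tol)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_flips)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        if (abs(mean(s * effects)) >= abs(obs) - tol) hits <- hits + 1L
      }
      (1 + hits) / (n_flips + 1)
    })
  }
  structure(list(statistic = obs, p.value = p, n = n,
                 exhaustive = exhaustive,
                 n_flips = if (exhaustive) 2L^n else n_flips),
            class = "sign_flip_test")
}

#' @export
print.sign_flip_test <- function(x, ...) {
  cat("Directional sign-flipping test (two-sided)\n")
  cat(sprintf("  group mean = %.4g, p = %.4g (%s, %d flip patterns, n = %d)\n",
              x$statistic, x$p.value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_flips, x$n))
  invisible(x)
}
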