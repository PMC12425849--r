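# Generative simulator for within-participant congruency-style
# experiments, and Monte-Carlo operating characteristics of the tests.

#' Simulate a within-participant two-condition experiment
#'
#' Generates trial-level data from the two-scenario generative model used
#' to validate the tests. Each participant `i` has a latent true effect
#' `e_i ~ N(0, sigma_b)`; each trial's outcome is
#' `c * e_i + N(0, sigma_w)`, where `c = 1` for the positive (incongruent)
#' condition and `c = 0` for the reference (congruent) condition. Two named
#' scenarios are built in:
#'
#' * **non-directional differences** — `sigma_b = 15`, `sigma_w = 30`:
#'   every participant has a true effect, but signs and magnitudes vary,
#'   so directional group tests cancel out.
#' * **global null** — `sigma_b = 0`, `sigma_w = 100`: no participant has
#'   any effect.
#'
#' Both scenarios default to 15 participants and 100 trials per condition.
#' Units are arbitrary outcome units (milliseconds in the RT reading); no
#' baseline constant is added, since every test in the package is
#' location-invariant.
#'
#' @param sigma_b Between-participant SD of true effects (>= 0).
#' @param sigma_w Within-participant trial SD (> 0).
#' @param n_participants Number of participants (default 15).
#' @param n_trials Trials per condition per participant (default 100).
#' @param seed Optional integer seed; identical arguments and seed give an
#'   identical dataset.
#' @param scenario Instead of `sigma_b`/`sigma_w`, name a built-in
#'   scenario: `"non_directional"` or `"global_null"`.
#' @return A [trial_table()] with condition levels
#'   `c("congruent", "incongruent")` and an attribute `true_effects`
#'   (data.frame of participant and latent `e_i`).
#' @examples
#' tt <- simulate_scenario(scenario = "global_null", seed = 1)
#' head(attr(tt, "true_effects"))
#' @export
simulate_scenario <- function(sigma_b, sigma_w, n_participants = 15,
                              n_trials = 100, seed = NULL,
                              scenario = NULL) {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("non_directional", "global_null"))
    pars <- switch(scenario,
                   non_directional = c(sigma_b = 15, sigma_w = 30),
                   global_null = c(sigma_b = 0, sigma_w = 100))
    sigma_b <- pars[["sigma_b"]]
    sigma_w <- pars[["sigma_w"]]
  }
  if (sigma_b < 0 || sigma_w <= 0 || n_participants < 1 || n_trials < 1) {
    stop("invalid scenario parameters: need sigma_b >= 0, sigma_w > 0, ",
         "n_participants >= 1, n_trials >= 1", call. = FALSE)
  }
  with_seed(seed, {
    e <- stats::rnorm(n_participants, 0, sigma_b)
    ids <- sprintf(paste0("p%0", max(2L, nchar(n_participants)), "d"),
                   seq_len(n_participants))
    n_row <- 2L * n_trials
    d <- data.frame(
      participant = rep(ids, each = n_row),
      condition = rep(rep(c("congruent", "incongruent"), each = n_trials),
                      times = n_participants),
      stringsAsFactors = FALSE)
    cvec <- as.integer(d$condition == "incongruent")
    d$outcome <- cvec * rep(e, each = n_row) +
      stats::rnorm(nrow(d), 0, sigma_w)
    tt <- trial_table(d, condition_levels = c("congruent", "incongruent"))
    attr(tt, "true_effects") <- data.frame(participant = ids, effect = e,
                                           stringsAsFactors = FALSE)
    attr(tt, "params") <- list(sigma_b = sigma_b, sigma_w = sigma_w,
                               n_participants = n_participants,
                               n_trials = n_trials, seed = seed)
    tt
  })
}

#' Monte-Carlo rejection rate of a test
#'
#' Simulates `n_sims` fresh datasets from [simulate_scenario()] (new latent
#' effects every replicate) and reports the fraction on which the named
#' test rejects at level `alpha`, with an exact (Clopper-Pearson) 95%
#' binomial confidence interval. With `sigma_b = 0` the rate estimates the
#' test's type-I error; otherwise its power.
#'
#' @param test One of `"sign_consistency"`, `"absolute_es"`, `"gnt"`,
#'   `"oanova"`, `"sign_flip"`.
#' @inheritParams simulate_scenario
#' @param n_sims Number of simulated datasets (>= 1).
#' @param alpha Rejection level (default 0.05).
#' @param seed Optional integer master seed.
#' @param ... Tuning parameters forwarded to the test (`n_splits`, `M`,
#'   `B`, `spec`, `method`, ...).
#' @return A list of class `rejection_rate`: `rate`, `ci` (95% exact),
#'   `rejections`, `n_sims`, `p.values`, plus the scenario parameters.
#' @examples
#' estimate_rejection_rate("oanova", sigma_b = 0, sigma_w = 100,
#'                         n_participants = 10, n_trials = 20,
#'                         n_sims = 50, seed = 1)
#' @export
estimate_rejection_rate <- function(test = c("sign_consistency",
                                             "absolute_es", "gnt",
                                             "oanova", "sign_flip"),
                                    sigma_b, sigma_w, n_participants = 15,
                                    n_trials = 100, n_sims = 100,
                                    alpha = 0.05, seed = NULL, ...) {
  test <- match.arg(test)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  seeds <- spawn_seeds(seed, 2L * n_sims)
  extra <- list(...)

  pvals <- vapply(seq_len(n_sims), function(s) {
    tt <- simulate_scenario(sigma_b, sigma_w, n_participants, n_trials,
                            seed = seeds[s])
    run_test_p(test, tt, seed = seeds[n_sims + s], extra)
  }, numeric(1))

  k <- sum(pvals < alpha)
  ci <- stats::binom.test(k, n_sims)$conf.int
  structure(list(test = test, rate = k / n_sims, rejections = k,
                 n_sims = n_sims, ci = as.numeric(ci), alpha = alpha,
                 p.values = pvals,
                 params = list(sigma_b = sigma_b, sigma_w = sigma_w,
                               n_participants = n_participants,
                               n_trials = n_trials, seed = seed)),
            class = "rejection_rate")
}

# Dispatch a named test on a simulated table and return its p-value.
run_test_p <- function(test, tt, seed, extra) {
  arg <- function(name, default) extra[[name]] %||% default
  switch(test,
    sign_consistency = sign_consistency_test(
      tt, spec = arg("spec", statistic_spec("mean_diff")),
      n_splits = arg("n_splits", 500), M = arg("M", 100),
      B = arg("B", 10000), seed = seed)$p.value,
    absolute_es = absolute_es_test(
      tt, spec = arg("spec", statistic_spec("cohen_d")),
      M = arg("M", 100), B = arg("B", 10000), seed = seed)$p.value,
    gnt = gnt_test(tt, method = arg("method", "t"),
                   alpha_individual = arg("alpha_individual", 0.05),
                   seed = seed)$p.value,
    oanova = oanova_test(tt)$p.value,
    sign_flip = sign_flip_test(
      participant_effects(tt, arg("spec", statistic_spec("mean_diff"))),
      n_flips = arg("n_flips", 10000), seed = seed)$p.value)
}

#' @export
print.rejection_rate <- function(x, ...) {
  kind <- if (x$params$sigma_b == 0) "type-I error" else "power"
  cat(sprintf("Monte-Carlo %s of the %s test\n", kind, x$test))
  cat(sprintf("  scenario: sigma_b = %g, sigma_w = %g, %d participants x %d trials/condition\n",
              x$params$sigma_b, x$params$sigma_w,
              x$params$n_participants, x$params$n_trials))
  cat(sprintf("  rejection rate at alpha = %g: %.3f (%d / %d), 95%% CI [%.3f, %.3f]\n",
              x$alpha, x$rate, x$rejections, x$n_sims, x$ci[1], x$ci[2]))
  invisible(x)
}
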