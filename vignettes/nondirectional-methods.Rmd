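---
title: "Detecting non-directional within-participant effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-directional within-participant effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nondirtest)
```

## The inferential problem

A within-participant manipulation (congruent vs incongruent primes, two
response categories, two attention conditions) may affect every
participant while leaving the *population mean* of the signed effects at
zero, because effect signs differ across individuals. Directional
group-level tests — the paired t-test, the sign-flipping permutation test
on the population mean — operate on one signed summary number per
participant and cannot distinguish this situation from the *global null*,
under which no participant has any effect. The tests in this package
target the global null directly: rejecting it licenses the claim that the
manipulation causally affected at least some individuals, without any
commitment about the direction or group-average size of those effects.

Interpretation still requires care. A non-directional effect can be
produced by any variable that is confounded with condition *within*
participants — condition order, stimulus–response mapping — even when such
nuisance variables are perfectly counterbalanced *between* participants.
Between-participant counterbalancing protects the mean, not the
individual-level contrast; only within-participant randomisation of the
nuisance variable makes a non-directional finding attributable to the
manipulation itself.

## Data model and eligibility rules

Input is a long-format trial table: participant identifier, a two-level
condition factor, a numeric outcome, and optional `accuracy`,
`confidence`, `signal` and `condition2` columns for the specialised
statistics. The order in which the user declares the condition levels
fixes the sign convention (second level positive) for every signed
statistic; it is never inferred from file order, so results are
reproducible across differently sorted files.

`apply_exclusions()` drops participants with fewer than `min_trials`
(default 5) trials in any condition cell, and participants with zero
outcome variance. Two readings of the zero-variance rule are possible:
per condition cell, or globally over the participant's trials. The global
reading is used here, as a participant whose outcome is constant within
one condition but not the other still carries sign information; the
per-cell degenerate cases that actually break a statistic (zero pooled
SD) are caught by that statistic's own preconditions. The exclusion
report records every participant with the triggering rule, and the
operation is idempotent.

## Per-participant statistics

All group tests are built over a pluggable signed summary statistic
(`statistic_spec()`):

* `mean_diff` — difference of condition means (outcome units);
* `cohen_d` — `mean_diff` standardised by the pooled SD with per-cell
  Bessel correction, the conventional two-sample *d*. No small-sample
  (Hedges) bias correction is applied by default: the permutation null
  is subject to the same bias, so it cancels in the comparison;
* `dprime_diff` — difference between conditions in signal-detection
  sensitivity `d' = z(HR) − z(FAR)`. Extreme rates (0 or 1) are replaced
  by `1/(2N)` and `1 − 1/(2N)`, the standard correction; it is
  configurable because analyses differ in this choice;
* `phi` — the 2×2 condition-by-response correlation;
* `auroc2_diff` — difference between the two response categories in
  response-conditional type-2 AUROC (metacognitive sensitivity),
  computed by the trapezoidal rule over the observed confidence criteria,
  which is identical to the pairwise Mann–Whitney probability with half
  credit for ties. Participants for whom a response cell contains only
  correct or only incorrect trials have no defined curve and are dropped
  for this statistic, with the reason logged;
* `interaction_contrast` — difference of condition differences across a
  second two-level factor, on cell means.

Each statistic flips sign when the declared condition order is swapped,
and the location-scale invariances one expects (shift invariance for
`mean_diff`, full scale invariance for `cohen_d`) hold exactly.

## The permutation engine

Both novel tests share one null construction. For each participant, `M`
permutations of the condition labels are drawn (counts per condition
preserved, outcomes untouched) and the participant's score is recomputed
on each, giving a bank of `M` null scores. A group-level null sample is
the mean of one bank value per participant, drawn uniformly with
replacement; `B` such samples form the null distribution. This two-stage
scheme (banks of `M = 100`, `B = 10,000` group samples, the defaults)
approximates the full permutation null at a fraction of its cost, at the
price of reusing bank entries across group samples — with `M = 100` per
participant the approximation error is negligible relative to the
Monte-Carlo error of `B` itself. Duplicate permutations within a bank are
permitted; for participants with few trials the duplicates simply mirror
the discreteness of the exact null.

P-values use the add-one estimator `p = (1 + #{null ≥ observed})/(B + 1)`,
which can never return zero and keeps the test valid at any `B`. The
smallest attainable p-value at the default `B` is therefore
`1/10001 ≈ 1e-4`.

Reproducibility: one master seed deterministically spawns an independent
sub-seed per participant (in sorted participant order) plus one for the
aggregation stage, so identical seeds give bit-identical nulls regardless
of how many random draws any one participant consumes.

## Sign consistency

`participant_sign_consistency()` estimates the probability that two
random halves of a participant's trials agree on the sign of the effect.
Three choices are deliberate:

* **Stratified splits.** Halves receive `floor(n_c/2)` and `ceil(n_c/2)`
  trials of each condition cell `c`. Unstratified splitting could leave a
  half without one condition, where the statistic is undefined.
* **Zero counts as inconsistent.** A split in which either half's
  statistic is exactly zero contributes disagreement: zero carries no
  sign, and crediting it would anti-conservatively inflate SC for
  discrete outcomes. For continuous outcomes ties are measure-zero and
  the rule is inert.
* **One split schedule per participant.** The schedule drawn for the
  observed labels is reused for all `M` permutations, so observed and
  null scores differ only in the labels (variance reduction), and the
  test is deterministic under a seed.

The default `n_splits = 500` estimates each `SC_i` with binomial SE at
most `0.5/sqrt(500) ≈ 0.022`, small against the participant-to-participant
spread. For small trial counts the splits can instead be enumerated
exhaustively (`exhaustive = TRUE`); the test suite checks the Monte-Carlo
and exhaustive estimates against an independent enumeration oracle.

Under the global null with a continuous outcome the two halves are
independent and symmetric, so `E[SC_i] = 0.5`; the calibration tests
verify the group mean sits at 0.5 across simulated null datasets. With
`mean_diff` (and `cohen_d`, which shares its sign) the half-statistics
are linear in cell means, and the implementation evaluates all splits and
permutations by matrix products; other statistics take a generic
(slower) path through the same schedule.

## Absolute effect size

`absolute_es_test()` replaces the consistency score with `|ES_i|`
(default `|Cohen's d|`) and reuses the identical null construction,
recomputing `|ES|` on each label permutation rather than deriving it
analytically — the observed and null statistics must be the same
functional of the data for the comparison to be exchangeable. Because a
stable effect of either sign moves `|ES_i|` directly rather than through
a sign-agreement probability, this test tends to be at least as sensitive
as sign consistency (the suite checks the ordering on matched
simulations). Under the global null `d_i` is approximately
`N(0, 2/N_t)`, so the group mean `|d|` concentrates near the folded-normal
value `sqrt(2/N_t)·sqrt(2/π)` — `0.113` at `N_t = 100` — which the tests
use as an anchor.

## The comparison tests

**GNT.** Stage one tests each participant at `alpha_individual`
(default .05) with a two-sided pooled-variance t-test — the pooled
variant matching the equal-variance data model; an exact
label-permutation test is available for outcomes where the t model is
inappropriate, enumerating all assignments when there are at most 50,000
of them. Stage two compares the significant count `k` against
`Binomial(n, alpha_individual)` one-sidedly:
`p = P(X ≥ k)`, with the one-sided Clopper–Pearson lower prevalence bound
`qbeta(alpha_prevalence, k, n − k + 1)`. The rejection rule and the CI are
exactly dual (`p < alpha_prevalence ⇔ lower bound > alpha_individual`),
which the suite checks over a grid. Note the second stage is discrete: at
`n = 15` the largest attainable size below .05 is `P(X ≥ 3) = .0362`, so
GNT is inherently conservative at this sample size — visible in its
calibrated type-I error.

**OANOVA.** The residual sum of squares of a per-participant
cell-means fit (`2P` parameters) is compared with that of a
participant-intercepts fit (`P` parameters):
`F = [(SSE_red − SSE_full)/P]/[SSE_full/(N − 2P)]` on `(P, N − 2P)` df.
Computing the SSEs directly from group means avoids any ambiguity about
sums-of-squares types and handles unbalanced cells naturally
(`df2 = N − 2P` regardless of balance); the suite cross-checks against an
independent nested `lm()` comparison. The test assumes normal errors with
equal variance across participants and conditions; violations of the
equal-variance assumption can seriously distort it, and no robust variant
is provided — the permutation tests are the recommended alternative when
the error model is in doubt.

## The generative simulator

`simulate_scenario()` draws a latent effect `e_i ~ N(0, sigma_b)` per
participant and trial outcomes `c·e_i + N(0, sigma_w)` with `c = 1` in
the positive (incongruent) condition. Two named parameterisations are the
validation scenarios used throughout: *non-directional differences*
(`sigma_b = 15`, `sigma_w = 30`) and *global null* (`sigma_b = 0`,
`sigma_w = 100`), both at 15 participants × 100 trials per condition. No
baseline RT constant is added: every test in the package is
location-invariant, so a baseline would be presentational only.

The simulator emulates the variance structure that makes directional
tests fail — between-participant sign heterogeneity against
within-participant noise — and nothing else. Real RT data are
right-skewed, sometimes heteroscedastic across participants and
conditions, and serially dependent within blocks; none of this is
generated. Passing calibration under the simulator therefore shows the
machinery is correct under exchangeability with i.i.d. normal noise, not
that the parametric comparison tests are robust to real-data pathologies
(the permutation tests remain valid under within-participant
exchangeability regardless of the outcome distribution). Lognormal or
ex-Gaussian trial noise and unequal per-participant variances would be
the natural extensions.

`estimate_rejection_rate()` wraps the loop "simulate fresh dataset → run
test → reject at alpha?", drawing new latent effects each replicate
(the scenarios define distributions, not fixed effect vectors), and
reports the rejection fraction with an exact binomial CI.

## Numerical and scale choices

* Ties in permutation and sign-flip tests are resolved with a relative
  tolerance of `1e-12` when comparing against the observed statistic, so
  exact ties count as at least as extreme (conservative).
* The directional sign-flip filter enumerates all `2^n` flip patterns
  when `n ≤ 15` (exact p); beyond that it uses 10,000 Monte-Carlo flips
  with the add-one estimator.
* Test-suite problem sizes: the type-I calibration runs 1,000 global-null
  simulations at 15 participants × 20 trials per condition with
  `n_splits = 100`, `M = 50`, `B = 1000`. Calibration of a permutation
  test does not depend on the problem size, and the reduced null keeps
  the estimate's binomial error (±1.4 percentage points at 95%) the
  dominant uncertainty. The scenario-level checks run at the full
  15 × 100 defaults.
* `B = 1000` is a sensible floor for exploratory runs; published
  p-values should use the default `B = 10,000`, below which the add-one
  floor (`1e-3`) starts to matter.

## Known limitations

* Only two-level factors (at most two of them) are supported; no
  continuous covariates or >2-level designs.
* The sign-consistency score is a probability of agreement, not an
  effect-size estimate; participants with few trials have noisy `SC_i`,
  and `n_splits` cannot reduce the half-sampling noise floor.
* GNT dichotomises individual evidence and inherits binomial
  discreteness; with 15 participants its effective size is .0362, not
  .05.
* The |ES| test's null mean is positive (a folded distribution), so its
  group statistic is not comparable across datasets with different trial
  counts without reference to its own null.
* P-values below `1/(B+1)` are unattainable by construction.
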