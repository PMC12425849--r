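# nondirtest

Non-directional tests for within-participant effects in trial-level
behavioural data.

## The problem

Standard group-level analyses of within-participant experiments — a paired
t-test on per-participant condition differences, say — are *directional*:
they test whether the population mean of the signed individual effects
differs from zero. When a manipulation genuinely affects every participant
but the *sign* of the effect varies across individuals (some respond
faster in the incongruent condition, some slower), positive and negative
effects cancel and the directional test sees nothing. A null result then
says little about whether the manipulation had any causal effect at the
individual level.

`nondirtest` tests the *global null* instead — the hypothesis that no
single participant has any true effect of the manipulation — using methods
that are agnostic to effect signs. It is aimed at experimental
psychologists and cognitive neuroscientists analysing long-format
trial-level data (participant, two-level condition, outcome), for example
masked-priming RT experiments or confidence-rating tasks.

## The tests

Two non-parametric permutation tests form the core. Both summarise each
participant `i` with a score, average the scores, and compare the group
mean against a null distribution built by shuffling condition labels
*within* participants (which destroys any condition–outcome association
without touching individual outcome distributions):

* **Sign consistency (SC).** For each participant, split the trials into
  two random stratified halves many times (default 500) and record how
  often both halves' condition effects share a sign:
  `SC_i = Pr[ sign(d_half1) = sign(d_half2) != 0 ]`.
  Under no effect, halves are independent and `E[SC_i] = 0.5` for a
  continuous outcome; a stable effect of *either* sign pushes `SC_i`
  toward 1.

* **Absolute effect size (|ES|).** The group mean of `|d_i|`, the absolute
  standardised within-participant effect (Cohen's *d* for continuous
  outcomes; *d′* differences or φ for binary ones). True effects of any
  sign inflate `mean |d_i|` above its label-shuffled expectation.

The permutation null is built in two stages (per-participant banks of
`M = 100` label permutations, resampled into `B = 10,000` group-level
null means), and `p = (1 + #{null >= observed}) / (B + 1)`, one-sided.

Two established non-directional tests are included for comparison:

* **GNT** (prevalence global-null test): test each participant at
  `alpha_individual` (two-sided t or exact permutation), then test the
  count of significant participants against a Binomial(n,
  `alpha_individual`) with a one-sided binomial test; the one-sided
  Clopper–Pearson interval on prevalence always includes 100%, and the
  global null is rejected when its lower bound exceeds `alpha_individual`.

* **OANOVA** (omnibus trial-level ANOVA, participants as fixed effects):
  `F = [(SSE_reduced − SSE_full)/P] / [SSE_full/(N − 2P)]` comparing
  participant-intercept-only and participant-by-condition least-squares
  fits, on `(P, N − 2P)` df.

A generative simulator (`simulate_scenario()`) produces the two validation
scenarios — *non-directional differences* (`e_i ~ N(0, 15)` effects, trial
noise SD 30) and *global null* (no effects, noise SD 100), 15 participants
× 100 trials per condition — and `estimate_rejection_rate()` measures
power and type-I error by Monte Carlo.

## Worked example

```r
library(nondirtest)

# a simulated experiment where every participant has a true effect,
# but signs vary (true effects here span -35 to +29 ms)
tt <- simulate_scenario(scenario = "non_directional", seed = 1)

# the directional test misses it
eff <- participant_effects(tt, statistic_spec("mean_diff"))
sign_flip_test(eff, seed = 2)
#> Directional sign-flipping test (two-sided)
#>   group mean = 0.1303, p = 0.9786 (exhaustive, 32768 flip patterns, n = 15)

# the non-directional tests do not
sign_consistency_test(tt, seed = 2)
#> Sign consistency test
#>   statistic: mean_diff over 15 participants
#>   group mean sign consistency = 0.8947
#>   permutation null: M = 100 per participant, B = 10000 group samples
#>   p (one-sided, greater) = 9.999e-05

absolute_es_test(tt, seed = 2)
#> Absolute effect size test
#>   statistic: cohen_d over 15 participants
#>   group mean |effect size| = 0.4324
#>   permutation null: M = 100 per participant, B = 10000 group samples
#>   p (one-sided, greater) = 9.999e-05

gnt_test(tt)
#> Prevalence global-null test (one-sided binomial)
#>   8 of 15 participants significant at alpha_individual = 0.05 (53%)
#>   one-sided 95% CI on prevalence = [30%, 100%], p = 1.83e-07
#>   global null rejected

oanova_test(tt)
#> Omnibus ANOVA test (participants as fixed effects)
#>   F(15, 2970) = 13.95, p = 6.185e-35
```

The group mean of the signed effects is 0.13 ms — invisible to any
directional test — yet 89% of random split-halves agree on each
participant's effect sign, and the mean |d| of 0.43 is far beyond the
label-shuffled null: the manipulation affected essentially everyone,
just not in the same direction.

Real datasets enter through `read_trial_table()` (CSV/TSV, column mapping,
declared condition-level order fixing the sign convention) and
`apply_exclusions()` (participants need at least 5 trials per condition
cell and non-zero outcome variance). `run_nondir()` executes the whole
pipeline from a YAML/JSON config and serialises results;
`run_nondir_batch()` maps it over a directory of datasets.

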