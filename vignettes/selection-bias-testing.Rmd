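---
title: "Testing single trials for selection-bias risk with the I² point estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing single trials for selection-bias risk with the I² point estimate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sctbias)
```

## The model

True randomisation balances baseline characteristics between trial arms in
expectation, and — crucially for this method — it leaves *no heterogeneity*
for a baseline-data meta-analysis to detect: unlike outcome variables,
baseline variables measured before treatment cannot differ systematically
between comparable trials for any reason other than poor (or subverted)
allocation. The I² point estimate of a fixed-effect meta-analysis,

$$ I^2 = \max\!\left(0,\; 100\cdot\frac{Q - \mathrm{df}}{Q}\right), \qquad
   Q = \sum_i w_i\,(\mathrm{MD}_i - \widehat{\mathrm{MD}})^2, \quad
   w_i = 1/v_i, $$

is therefore expected to be exactly 0% when the pooled studies are all
genuinely randomised, and to move above 0% when at least one of them is
not.

The test exploits this with a three-study design. Two *simulated comparator
trials* (SCTs) are built to be ideally randomised by construction and are
first pooled alone; their zero I² is confirmed. The trial under test — known
only through its published per-arm baseline mean, SD and patient count — is
then added as a third study and the meta-analysis repeated. Because the two
comparators contribute no heterogeneity, any I² above zero in the three-study
analysis is attributable to the tested trial, and the trial is classified as
at risk of selection bias. Effects are raw mean differences of the baseline
variable with variance $s_1^2/n_1 + s_2^2/n_2$; each comparator enters as
group A minus group B, the trial as test arm minus control arm, trial last.

The assumptions worth keeping in view:

* the baseline variable is reported per arm as mean, SD and n (conversions
  from median/range and from standard errors are provided for when it is
  not, see below);
* the variable's plausible range over both arms is known or can be estimated
  by the reviewer — the comparators sample uniformly from it;
* a two-sided comparison of one trial against an idealised null: the test
  says nothing about the direction, magnitude, or outcome-relevance of any
  bias it flags.

## The simulated comparator trial

`build_sct()` constructs an SCT exactly as three parallel columns: an
ascending patient ID `1..n_total`, a block-randomised allocation over
groups A and B, and `n_total` integer values drawn uniformly (with
replacement) from the trial's baseline range and sorted ascending, paired
with the allocation row by row. Arm summaries use the sample SD
(n − 1 denominator), the standard for trial summary tables.

Two construction details deserve explanation because the method's behaviour
depends on them:

* **Truncated final block.** With block size 4 and `n_total` not a multiple
  of 4, one further full block is permuted and its first `n_total mod 4`
  entries are used. Group sizes can then differ by up to 2 (e.g. a 14/12
  split at N_T = 26), which is consistent with the worked examples the
  package bundles; overall imbalance never exceeds half a block.
* **Sorted values paired with blocked allocation.** Because the value column
  is ascending and every block of 4 consecutive (hence similar) values sends
  two patients to each arm, the two arms are close to stratified samples of
  the same values. The mean difference of an SCT is therefore much *less*
  variable than its inverse-variance weight suggests, and a generated SCT
  pair shows rounded I² > 0 only rarely (a few percent of pairs, versus the
  roughly one-third a naive two-study chi-square argument would give). This
  is a feature: the null reference is very stable. The test suite's
  chi-square calibration property is accordingly checked on effects
  simulated as independent normals with their stated variances — the
  textbook null for Q — not on SCT-generated effects.

`make_null_pair()` makes the "confirm the zero" step explicit: pairs are
generated with seeds derived successively from the configuration seed until
one pools at rounded I² = 0, capped at `max_null_attempts` (default 100,
far more than ever needed given the rarity of failures), and the number of
attempts is recorded in the result for auditability. A failure reports every
attempted I² value.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `block_size` | 4 | patients | the block length used in the worked examples; small enough to bound imbalance at ±2 |
| `max_null_attempts` | 100 | pairs | regeneration cap for the null pair; failures are rare so this is generous |
| `classification_basis` | `"rounded"` | — | classify from the integer-displayed I², as meta-analysis software reports it; `"raw"` would flag microscopic heterogeneity (e.g. I² = 0.2%) that any reader would call 0% |
| `seed` | `NULL` | — | every random step (comparator generation, simulation) derives its stream from this one integer |
| `bias_fraction` (simulation) | — | proportion | fraction of discordant patient pairs whose allocation is overridden; 0 = ideal randomisation |

Units of the baseline variable are carried as opaque labels (years, months);
the method is unit-invariant because I² is scale-free — multiplying all
means and SDs by a constant leaves it unchanged (a property the test suite
checks).

## Numerical choices

* **Rounding.** I² is computed at full precision throughout; only the
  displayed/classified value is rounded to an integer percent, half away
  from zero (base R's `round()` rounds half to even, which would turn e.g.
  70.5 into 70). No intermediate rounding is applied anywhere — the bundled
  worked examples reproduce exactly under this policy.
* **Truncation.** I² is set to 0 whenever Q ≤ df, including Q = 0, so it
  always lies in [0, 100).
* **Degenerate studies.** An effect with zero variance (both arm SDs zero)
  cannot be inverse-variance weighted and is rejected with a specific error
  rather than given infinite weight. One deliberate exception: a comparator
  pair generated over a *constant* baseline range (low = high) has identical
  arm means by construction and is accepted as a trivially perfect null by
  `make_null_pair()`, though any trial tested over such a range still fails
  as degenerate.
* **Direction convention.** Every study enters as first-listed arm minus
  second-listed arm (A − B, test − control). A consistent convention matters
  because flipping one study's sign changes Q; the chosen one matches the
  column order of the bundled tables.
* **Seeding.** Derived seeds are drawn with replacement from one stream per
  configuration seed, so extending a simulation (more replicates) reproduces
  the original replicates as a prefix.

## Practical conversions

Reports that give a median and range instead of mean and SD are handled by
`median_range_to_mean_sd()`: mean ≈ (low + 2·median + high)/4, and SD by the
group-size-dependent approximation — the small-sample formula up to n = 15,
range/4 up to n = 70, range/6 above (branch boundaries closed on the left,
following the approximation's published form). `se_to_sd()` rescales a
reported standard error by √n. Both are conveniences for applying the test
in practice; the bundled worked examples all reported means and SDs
directly.

## The accuracy simulation

The simulation study estimates the operating characteristics the test's
design motivates but which cannot be measured from 16 studies alone.
`simulate_trial()` emulates a biased trial with a *directional
misallocation* mechanism: starting from an ideal SCT-style trial, discordant
patient pairs (one A, one B) are formed at random and, in a `bias_fraction`
share of them, the patient with the higher baseline value is forced into the
test arm. This is the canonical picture of selection bias at baseline — a
value-linked allocation override — and gives a smoothly tunable effect size
that reduces exactly to ideal randomisation at fraction 0.
`estimate_accuracy()` runs the full test on every replicate and tabulates
positives against the ground truth; sensitivity and specificity get 95%
Wilson score intervals (stable near 0 and 1, where this test operates —
computed via `prop.test(correct = FALSE)`).

What the generator emulates — and what it does not: simulated trials have
uniform integer baseline values, exactly two arms, block-4 allocation, and a
bias mechanism acting only through the baseline variable. Real trials have
non-uniform age distributions, unequal arm sizes from other causes, baseline
variables measured with error, and biases that may be weaker, non-monotone
in the baseline value, or confined to subgroups. Passing simulations
therefore demonstrate that the test detects value-linked misallocation of
the modelled kind at the modelled sizes; they do not establish its
sensitivity against every form of real-world allocation subversion, nor the
false-positive rate under non-uniform baseline distributions.

```{r, eval = FALSE}
sc  <- simulation_scenarios(200, 18, 80, bias_fractions = c(0, 0.25, 0.5),
                            n_replicates = 200, seed = 1)
acc <- estimate_accuracy(sc)
glance(acc)
autoplot(acc)
```

The test suite exercises this machinery at moderate sizes chosen to probe
each property sharply while keeping the full suite quick: the monotonicity
of the positive rate in the bias fraction is checked at N_T = 200 with 500
replicates per scenario, the chi-square calibration of Q at 10,000
replicates of five-study nulls, and the remaining distributional properties
at a few hundred seeds each.

## Known limitations

* The test is one-sided in information: it can flag heterogeneity, but a
  negative result does not certify sound randomisation — a biased trial can
  balance any single baseline variable by chance (two of the bundled cohort
  studies test negative, one plausibly because its groups were age-matched).
  Testing additional reported baseline variables raises precision; this
  package runs one variable per call, and combining calls across variables
  is left to the analyst.
* The reviewer-supplied baseline range matters: the comparators' effect
  variances scale with it. An over-wide range inflates comparator variance
  and down-weights the comparators relative to the trial.
* I² from three studies is a point estimate with wide sampling uncertainty;
  the method deliberately uses the point estimate and an exact-zero
  threshold rather than an interval, so it should be read as a screening
  classification, not an effect size.
* No bias magnitude or direction on *outcomes* is estimated, and no
  appraisal-tool scoring is automated; a positive result is an empirical
  input to appraisal, nothing more.
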