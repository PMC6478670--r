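---
title: "Polyrisk scoring: model, construction and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyrisk scoring: model, construction and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

## The scoring model

The package builds additive polyrisk scores over non-genetic risk and
protective factors for psychosis, in direct analogy with polygenic risk
scores: a weighted sum of exposures, with weights on the log scale so
that independent risks combine additively.

For a factor level with relative risk $RR$ (odds ratios from the
epidemiological literature are used in this role, as is conventional
when the outcome is rare) the construction is:

1. **Raw score** $r = \log_{10} RR$. The baseline (unexposed) level has
   $RR = 1$ and hence $r = 0$.
2. **Centering.** Subtract the prevalence-weighted population mean of
   the factor's raw scores, $\bar r = \sum_i p_i r_i$, where $p_i$ is
   the population prevalence of level $i$. After centering, every factor
   — and therefore the total score — has population mean zero, so a
   positive score means above-average risk.
3. **Scaling and rounding.** Multiply by 10 and round to the nearest
   half integer for ease of use.

A total score $S$ then corresponds to an *equivalent relative risk* of
$10^{S/10}$ against the population average, which is what
`pps_to_rr()` computes; `rr_to_pps()` is its exact inverse. Worked
through for urbanicity ($RR = 2.2$, urban prevalence $73.6\%$):
$r = \log_{10} 2.2 = 0.34$, $\bar r = 0.736 \times 0.34 = 0.25$, giving
final scores $+1$ (urban) and $-2.5$ (rural).

```{r urbanicity}
fit <- pps(factor_table(data.frame(
  factor = "Urbanicity", level = c("Yes", "No"),
  relative_risk = c(2.2, 1), prevalence = c(0.736, 0.264),
  baseline = c(FALSE, TRUE))))
fit$scores[, c("level", "raw_score", "centered_score", "final_score")]
```

The scale (10) and grid (0.5) are exposed as construction parameters of
`pps()` for sensitivity analysis, but all shipped defaults use these
values.

### Composite factors

Exposures with logical dependencies are combined into one composite
factor before scoring: an immigrant cannot be both first- and
second-generation, and ethnic-density strata apply only to minority
ethnicity. `build_composite_factor()` crosses the component levels,
drops inadmissible combinations, collapses combinations where a
component is not applicable (the majority-ethnicity reference level is
a single row, not stratified by density), and gives each remaining
level the *product* of its component relative risks — equivalently, the
sum of component log relative risks — together with a supplied joint
prevalence. The shipped defaults assume the proportion and the extra
risk of the higher-risk origin/ethnicity subgroup are the same across
generations and density strata respectively, which is what makes the
joint prevalences factorise.

### Protective factors

Protective associations (olfactory identification, premorbid IQ) are
re-oriented so the *scored* level is the risk-increasing direction:
impairment is scored with $RR = 1/OR$. This matches the published
orientation of the scoring table (positive score for the impaired
level) and keeps every factor's exposed score above its baseline score.

## Prevalence provenance and what "approximate" means here

Only the urbanicity prevalence (73.6% urban) is an externally reported
population value. The source prevalence file behind the published
scoring table is not public, so the remaining shipped prevalences are
**reverse-engineered from the published half-integer scores**: for a
two-level factor with exposed score $s^+$ and baseline score $s^-$,
the construction implies $RR = 10^{(s^+ - s^-)/10}$ and
$p \approx -s^-/(10 \log_{10} RR)$, each up to $\pm 0.25$ of rounding
slack per score (`invert_published_scores()` returns the admissible
interval). Where the interval left slack we fixed the value once on
plausibility grounds — e.g. the low-IQ prevalence 0.335 is
$\Phi(-0.427)$, the mass below an IQ of 93.6 under a mean-100, sd-15
normal — and the composite component risks were chosen so the forward
construction lands every published score exactly with zero rounding
error. The provenance string of `pps_factors()` flags all of this;
supplying measured prevalences through `factor_table()` replaces the
defaults wholesale and everything downstream recomputes.

Two published summary quantities are therefore reproduced only
approximately by the defaults: the fraction of the population with a
negative score (computed 52.8% vs the published 53.6%) and with
equivalent RR above 30 (1.6% vs 1.8%). The package's tests treat these
as soft checks with a ±5 percentage-point band; the structural
invariants below are exact and hold for *any* valid configuration.

### The score floor

The published prose quotes a minimum possible total of −7.5, but the
published per-level scores sum to −9.5 at their per-factor minima, and
no combination-exclusion rule in the source reconciles the two. The
package reports the configured sum (−9.5) everywhere and does not
hard-code −7.5.

## Scoring individuals and missing data

`predict()` on a `pps` object sums the assigned levels' final scores.
Missing factors are routine in sequential assessment (self-reported
factors first, clinical factors later), so partial profiles are
accepted by design and handled by policy:

* `"population_average"` (default) substitutes the factor's
  prevalence-weighted mean *final* score — the zero-information value
  under the centering construction, which is within half a grid step of
  0; totals remain comparable across individuals with different
  missingness patterns.
* `"omit"` contributes 0 and counts the factor in `n_missing`; totals
  are then sums over observed factors only.
* `"error"` aborts, for pipelines where completeness is a contract.

Per-factor contributions (`per_factor = TRUE`) support the sequential
workflow: score the self-administered block first, escalate to clinical
assessment when the partial score crosses a threshold.

## The population score distribution

`pps_distribution()` characterises the total score in a hypothetical
general population under **independence across factors** (the
within-group dependencies are already encoded as composite levels).
Independence is an assumption, not a finding: the source association
measures are univariate and possibly mutually confounded, and no
dependence structure is published. Two methods are provided:

* **Exact enumeration** (default): sequential convolution of the
  per-factor score distributions on the half-integer grid. With the
  shipped configuration this is a product over
  $2\times7\times5\times2^5 = 2240$ combinations, done in grid units
  (integers, score/0.5) so no floating-point keys are compared. This is
  the authoritative oracle.
* **Monte Carlo**: draws individuals per-factor from the prevalences
  and tabulates scores — an emulation of the published
  ten-million-permutation procedure, retained because it generalises to
  dependence extensions and for cross-validation of the enumeration.
  One seeded generator per call, per-factor draws in declared factor
  order, and the caller's RNG state is restored, so runs are
  reproducible bit-for-bit for a fixed seed.

`summary()` reports the histogram bins used to read the distribution:
$P(S<0)$ (equivalent RR below 1), $P(0 \le S \le 5)$, $P(S>5)$ and
$P(S>15)$. The RR thresholds 3 and 30 map to $10\log_{10}3 = 4.77$ and
$10\log_{10}30 = 14.77$ on the score axis, which fall between grid
points; the bins are aligned to the enclosing published grid edges 5
and 15.

```{r distribution}
full <- pps()
summary(pps_distribution(full))
```

## Risk updating for sequential detection

Detection is a funnel: recruitment into an assessment enriches risk
(e.g. a 3-year outcome probability of 0.43% in the general population
vs 15% in help-seeking samples, about 35-fold on the probability
scale), and the assessment itself then moves the pre-test probability
to a post-test probability through its likelihood ratio on the *odds*
scale: $\text{odds}_{post} = \text{odds}_{pre} \times LR$.
`update_risk()` applies an LR, `derive_lr()` recovers the LR implied by
an observed pre/post pair (exact inverse, to machine precision), and
`chain_tests()` applies a sequence of LRs — under conditional
independence of the test results this equals one update with the
product of the LRs, which the package documents as a contract rather
than a fact about real assessments. Fold changes are reported on the
probability scale because that is how risk-enrichment multiples are
conventionally quoted; the odds-scale LR is reported alongside and the
two are deliberately distinct numbers.

`absolute_risk()` bridges a score's equivalent relative risk to an
absolute probability either as `baseline * RR` capped at 1 (simple,
approximate) or on the odds scale (exact when the RR is an odds
ratio). No published link function exists for this step; both options
are flagged exploratory.

## Numerical choices

* **Tie rule.** Half-integer rounding uses round-half-away-from-zero
  (0.25 → 0.5, −1.25 → −1.5); the construction's source is silent and
  this rule reproduces the published table under the inverted
  prevalences. Midpoints are detected with a $10^{-9}$ tolerance so
  values like $10 \times 0.025$ that are midpoints only up to floating
  error still take the tie branch.
* **Grid arithmetic.** Convolution and binning key scores by the
  integer `score/grid`, never by floating-point equality.
* **Degenerate inputs.** A factor with $RR = 1$ everywhere scores 0
  everywhere; a one-level factor is its own baseline with prevalence 1;
  `invert_published_scores()` rejects equal published scores as
  degenerate; probabilities at the boundary of (0, 1) are rejected in
  the odds arithmetic.
* **Validation.** Prevalences must sum to 1 within $10^{-6}$ per
  factor; composite levels must equal the product of their components
  within $10^{-9}$; errors name the factor and the violated rule.

## The synthetic cohort generator

`generate_cohort()` draws factor levels independently from the
configured prevalences and masks assignments missing completely at
random at a requested rate. It emulates the *marginal* structure of
self-administered or record-extracted factor data in a general
population. It does **not** emulate correlated exposures, help-seeking
selection (risk-enriched sampling), measurement error in the
instruments, or informative missingness — so tests that pass on
synthetic cohorts validate the scoring arithmetic and the pipeline
plumbing, not the epidemiological adequacy of the score in real
populations, which requires external longitudinal validation.

## Problem sizes used in the tests

Unit tests run the Monte-Carlo cross-checks at $n = 2\times10^4$ and
the full-configuration agreement check at $n = 10^6$ (3-standard-error
pointwise bands against the exact enumeration); the reproduction script
uses $n = 10^7$, the scale of the published permutation analysis. The
enumeration itself is exact and instantaneous at the shipped size
(2240 combinations, 81 support points).

## Known limitations

* The shipped prevalences and composite component risks are
  approximate reconstructions; headline population fractions shift
  within a few percentage points if the true prevalence file is
  supplied.
* Factor independence in the distribution engine and conditional
  independence in chained likelihood ratios are modelling assumptions.
* No genotype integration: combining with a polygenic score is additive
  on the log scale by construction, and `rr_to_pps()` is the hook for
  callers, but no combination is implemented or validated here.
* The score is a prototype instrument; nothing in this package
  constitutes clinical validation.
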