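# polyrisk

Additive polyrisk scores for psychosis risk detection: build a scoring
system from relative risks and population prevalences, score
individuals, characterise the score distribution in a hypothetical
general population, and update pre-/post-test probabilities for
sequential detection strategies.

## Who this is for

Researchers in psychiatric epidemiology and early-detection services
who want to work with Psychosis Polyrisk Score (PPS)-style instruments:
prototype a scoring table from published association measures, audit a
published table by inverting it back to implied risks and prevalences,
simulate what the score looks like in a general population, and reason
quantitatively about risk enrichment along a detection pathway.

## The model

For each level of a risk factor with relative risk *RR* (odds ratios
are accepted in this role) and population prevalence *p*:

- raw score: *r* = log₁₀ *RR*  (baseline level: *r* = 0)
- centered score: *c* = *r* − Σᵢ *pᵢ rᵢ*  (population mean zero per factor)
- final score: 10 · *c*, rounded to the nearest half integer
  (ties away from zero)

Scores add across factors; a total score *S* is interpretable as an
equivalent relative risk 10^(S/10) against the population average.
Logically dependent exposures (immigration generation × origin,
ethnicity × ethnic density) are combined into composite factors whose
level risks are products of component risks. Pre-/post-test updating
uses post-test odds = pre-test odds × likelihood ratio.

The shipped default configuration reproduces the published PPS
prototype scoring table (8 factor groups, 24 levels, totals from −9.5
to 32). Only the urbanicity prevalence is an externally reported value;
the remaining prevalences are approximate inversions of the published
scores — see the methods vignette (`vignettes/polyrisk-methods.Rmd`)
for the construction and its limits.

## Worked example

```r
library(polyrisk)

fit <- pps()          # scoring system from the shipped configuration
summary(fit)
#> Polyrisk scoring system: 8 factors
#> ...
#> Total score range: -9.5 to 32.0 (equivalent RR 0.112 to 1.58e+03)

# score one partially observed individual
predict(fit, c(Urbanicity = "Yes", `Childhood trauma` = "Yes",
               `Clinical high risk state for psychosis` = ">9"),
        missing = "omit")
#>   id total_pps equivalent_rr n_missing
#> 1  1      13.5      22.38721         5
```

The individual scores 1 (urban) + 4 (childhood trauma) + 8.5 (positive
prodromal screen) = 13.5 points, an equivalent relative risk of
10^1.35 ≈ 22.4 versus the population average; five factors were
unobserved and contributed nothing under the `"omit"` policy.

```r
summary(pps_distribution(fit))     # exact enumeration, 2240 combinations
#> Score distribution summary (enumeration)
#>   negative score (RR < 1):    52.8%
#>   score in [0, 5] (RR 1-3):   27.7%
#>   score > 5  (RR > 3):        19.5%
#>   score > 15 (RR > 30):        1.6%
#>   observed support: -9.5 to 32.0

# an assessment that moves a 15% pre-test risk to 26% has LR ~1.99
update_risk(0.15, derive_lr(0.15, 0.26), horizon = "3-year")
#> Risk update (3-year horizon)
#>   pre-test probability:  0.15
#>   likelihood ratio:      1.991
#>   post-test probability: 0.26
#>   fold change (risk scale): 1.733
```

So just over half of a hypothetical general population sits below
average risk, and under 2% carries an equivalent relative risk above
30; the risk-updating arithmetic separates the large enrichment
achieved by recruitment from the modest one achieved by the assessment
itself.

A command-line interface wrapping the same functions is installed at
`inst/exec/polyrisk` (subcommands `build-table`, `score`, `enumerate`,
`simulate`, `update-risk`, `gen-cohort`); see `?polyrisk_cli`.

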