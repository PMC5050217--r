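# burncohort

Severely burned patients are at high risk of repeated infections during
recovery, and identifying — at triage — the subgroup that will go on to
suffer many independent infection episodes is an open clinical problem.
`burncohort` implements a complete, tested analysis pipeline for studying
one candidate early biomarker of that risk: the plasma **TNF-α/IL-10
cytokine ratio**, a dimensionless measure of the pro- versus
anti-inflammatory balance measured within 48 h of injury. The package is
aimed at biostatisticians and trauma-immunology researchers who want to
reproduce, stress-test or re-apply this style of analysis to their own
burn or trauma cohorts.

## What the package does

Starting from two patient-level tables — `patients.csv` (demographics,
burn characteristics, timing, plasma TNF-α and IL-10 in pg/mL, recorded
APACHEII, outcomes) and `infections.csv` (one row per recorded infection
with day since injury, infection type, mode, and pathogen) — the pipeline:

1. **Screens eligibility**: adults (age ≥ 16), non-electrical burns, blood
   draw ≤ 48 h since injury, first infection no sooner than 24 h after the
   draw, at least one ICU day; exclusion reasons are enumerated per
   patient.
2. **Tabulates independent infection episodes** with a waiting-list
   decision tree: each record keeps its episode open for **6 days** for a
   similar follow-up record (same infection type, mode and pathogen) or
   **2 days** for a dissimilar one; patients with **≥ 3 episodes** form the
   hypersusceptible case group.
3. **Computes burn severity scores**: Baux (TBSA % + age), revised Baux
   (Baux + 17 for inhalation injury), ABSI, and the Ryan score
   (count of TBSA > 40 %, age > 60, inhalation injury), with the recorded
   APACHEII passed through.
4. **Derives the TNF-α/IL-10 ratio**, standardizes it, and compares it
   across severity strata (mean splits, quartiles, score categories) with
   equal-variance t-tests, Mann–Whitney tests, Fisher's exact test, and
   one-way ANOVA with Dunnett's many-to-one adjustment.
5. **Evaluates prediction**: Firth-penalized logistic regression (the
   Jeffreys-prior penalty keeps estimates finite in small, separable
   samples), in-sample AUROC by the Mann–Whitney estimator
   (AUROC = P(random case outscores random non-case, ties ½)),
   stratified-bootstrap percentile confidence intervals, and
   Youden-optimal operating points whose sensitivity/specificity carry
   Wilson score intervals with continuity correction.
6. **Generates synthetic cohorts** whose group-wise distributions are
   moment-matched to the published baseline table of a 34-patient cohort
   (17 cases / 17 non-cases), so every stage can be exercised and tested
   without access to the study's non-public patient data.

## Worked example

```r
library(burncohort)

sim    <- generate_cohort(seed = 42)       # synthetic 17 + 17 cohort
report <- run_analysis(sim$patients, sim$infections,
                       n_boot = 2000, seed = 42)
print(report)
#> burncohort analysis report
#>   eligible patients: 34 of 34
#>   cases (>=3 episodes): 17
#>   models fitted: 9

round(report$models[, c("auroc", "ci_lo", "ci_hi",
                        "sensitivity", "specificity")], 2)
#>           model auroc ci_lo ci_hi sensitivity specificity
#>           ratio  0.92  0.82  0.99        0.82        0.88
#>            tbsa  0.73  0.54  0.89        0.53        0.94
#>        apacheii  0.89  0.76  0.99        0.94        0.76
#>            baux  0.56  0.36  0.75        0.35        0.88
#>           rbaux  0.64  0.44  0.82        0.59        0.71
#>      ratio+tbsa  0.99  0.95  1.00        0.94        1.00
#>  ratio+apacheii  0.95  0.85  1.00        0.94        0.94
#>      ratio+baux  0.95  0.88  1.00        0.88        0.94
#>     ratio+rbaux  0.95  0.88  1.00        0.94        0.88
```

Each row is one Firth-penalized logistic model for the ≥ 3-episode
outcome: the apparent AUROC with its stratified-bootstrap 95% CI, and the
Youden operating point's sensitivity and specificity. On this synthetic
draw the ratio alone discriminates cases well (AUROC 0.92) and combining
it with a clinical score improves the apparent fit, as expected when both
carry planted signal. Baseline comparisons come in a Table-1-style frame:

```r
report$baseline[report$baseline$variable == "tnf_il10_ratio", ]
#>  variable       overall        noncase         case            test  p
#>  tnf_il10_ratio 0.165 ± 0.176  0.267 ± 0.194  0.0633 ± 0.0633 t-test 0.0098
```

i.e. the case group's early ratio is markedly lower — the inverse
relation between injury severity / infection hypersusceptibility and the
pro- to anti-inflammatory balance that motivates the biomarker. Interval
estimates for proportions use the continuity-corrected Wilson score
method:

```r
wilson_ci_cc(14, 17)
#> 14/17 = 0.824, 95% Wilson CC CI (0.558, 0.953)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/burncohort.R` (subcommands `simulate`, `run`, `episodes`,
`scores`, `biomarker`).

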