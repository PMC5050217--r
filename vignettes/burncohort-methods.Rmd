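---
title: "Methods: infection hypersusceptibility analysis for burn cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infection hypersusceptibility analysis for burn cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burncohort)
```

## The scientific problem

Severe burn injury (here, ≥ 20% total body surface area, TBSA) destroys
the dermal barrier and profoundly perturbs systemic immunity, leaving
patients exposed to repeated bacterial and fungal infections during a
recovery that lasts weeks to months. Clinical severity scores — Baux,
revised Baux (R-Baux), ABSI, Ryan, APACHEII — were designed for mortality
risk, not infection risk, and require multiple measurements. The analysis
this package implements asks whether a single early blood draw, summarized
as the ratio of plasma TNF-α (pro-inflammatory) to IL-10
(anti-inflammatory) concentration, predicts which patients will become
*hypersusceptible*, defined as accumulating **three or more independent
infection episodes** over the whole course of recovery. The working
hypothesis is that a *low* early ratio reflects a state of relative
immunosuppression and therefore predicts the case group.

## Episode tabulation: the waiting-list decision tree

Raw infection surveillance data over-counts: a single clinical infection
generates several records (repeat cultures, the same pneumonia charted on
consecutive days). Records are merged into independent episodes with a
waiting-list rule. Each processed record "waits" for follow-up records:

* a record within `similar_window` days (default **6**) whose infection
  type, mode and pathogen all match joins the same episode;
* a record within `dissimilar_window` days (default **2**) joins even if
  the fields differ (it is read as a continuation of the same clinical
  event);
* otherwise the record opens a new episode.

Three conventions are underdetermined by the verbal rule; the package
fixes them as follows and exposes the windows and similarity fields in
`waiting_list_policy()` for sensitivity analysis:

* **Anchor renewal.** Every joining record re-arms its episode's window
  (its own day becomes a fresh anchor), because the waiting-list phrasing
  implies every record waits, not only episode openers. A chain of
  records each ≤ 6 days apart therefore forms one episode regardless of
  total span.
* **Boundary inclusivity.** A gap exactly equal to the window still
  merges ("for 6 days" is read as through day +6).
* **Unknown pathogens.** The literal label `"unknown"` never matches
  anything — including another `"unknown"` — so unidentified organisms
  conservatively force the short window rather than gluing unrelated
  events together.

When several records are simultaneously waiting for a candidate, it joins
the episode of the most recent one (ties: lowest episode index). Ordering
is by day, then input order, then infection type, making the tabulation
invariant to row shuffling. The implementation is checked against an
independently coded brute-force transcription of the rule on random
histories of up to 8 records, and against round-trip recovery of planted
episode counts.

## Severity scores

* **Baux** = TBSA % + age (years); **R-Baux** = Baux + 17 if inhalation
  injury. Both are exact arithmetic; `rbaux − baux ∈ {0, 17}` always.
* **Ryan** = number of risk factors among TBSA > 40 %, age > 60,
  inhalation injury (strict inequalities, so TBSA 40 / age 60 score 0).
* **ABSI** = 1 (male) + 1 (inhalation) + 1 (full-thickness burn)
  + age-category points (1 for 0–20 y, 2 for 21–40, … in 20-year steps)
  + TBSA-category points (1 for 1–10 %, 2 for 11–20 %, … in 10 % steps).
  The published tables assume integer inputs; fractional values bucket by
  half-open intervals matching the integer labels (age 20 → 1 point,
  age 20.5 → 2 points; TBSA < 1 % → 0 points, an extension that never
  triggers in this severely burned population whose minimum TBSA is
  20 %). Categories continue unbounded in the same steps rather than
  capping, which again cannot matter on the physiological range.
  Reporting categories are moderately severe (6–7), serious (8–9),
  severe (10–11), maximum (≥ 12).
* **APACHEII** is never computed: it is recorded at the treating
  institution and enters as a required input column.

The ABSI calculator is verified against a table-driven oracle over the
full integer grid age 0–100 × TBSA 1–100 × all flag combinations.

## The biomarker and its stratified comparisons

The ratio is TNF-α ÷ IL-10, both in pg/mL, so it is dimensionless and
scale-equivariant (a common assay calibration factor cancels). IL-10
values of zero make the ratio undefined; by default this is an error, and
callers who know the assay's detection limit may opt into the common
LOD/2 substitution (`ratio_series(..., il10_lod = )`). Z-scores use the
sample mean and SD (denominator n − 1).

Stratified comparisons mirror the figure panels of a baseline-table
analysis: two-level mean splits for TBSA, APACHEII, Baux and R-Baux,
binary splits for inhalation and full-thickness burn, and category panels
for Ryan (0–3) and ABSI severity with one-way ANOVA plus Dunnett's
many-to-one comparisons against the first category. The mean split uses
the *floor* of the sample mean as an integer cutpoint (a mean TBSA of
41.6 % splits ≤ 41 vs ≥ 42), reproducing how such tables print their
thresholds. Quartile panels use the linear-interpolation quantile
convention (R type 7) with ties assigned to the lower bin. Per-stratum
summaries report mean, SD and SE (SD/√n); plots of such panels
conventionally use the SE.

## Hypothesis tests

Group comparisons delegate to the standard implementations: pooled
two-sample t-test (`stats::t.test`, `var.equal = TRUE`), Mann–Whitney
(`stats::wilcox.test`; exact permutation p below 9 per group without
ties, otherwise the tie-corrected continuity-corrected normal
approximation), Fisher's exact test (`stats::fisher.test`; a zero margin
is degenerate with p = 1), and one-way ANOVA (`stats::aov`) with
Dunnett's single-step adjustment from the equicorrelated multivariate-t
distribution (`multcomp`). The quasi-Monte-Carlo integration inside the
Dunnett adjustment runs under a fixed internal seed so adjusted p-values
are reproducible to well below 10⁻³. A summary-statistic variant of the
pooled t-test allows re-testing printed group means/SDs without raw data
and agrees with the raw-sample version to 10⁻¹² when the summaries come
from the samples.

Binomial proportions (sensitivity, specificity) carry Wilson score
intervals with Newcombe's continuity correction, clamped to [0, 1], with
exact 0/1 endpoints at the boundary counts. The continuity-corrected
interval strictly contains the uncorrected Wilson interval for interior
counts.

## Prediction models

Nine Firth-penalized logistic models are fitted for the ≥ 3-episode
outcome: five single predictors (ratio, TBSA, APACHEII, Baux, R-Baux) and
the ratio combined with each clinical score. Firth's penalty — adding
½ log det I(β) to the log-likelihood — is the standard remedy for
17 + 17-sized case-control data, where ordinary maximum likelihood is
biased and diverges under separation; the intercept-only fit has the
closed form logit((k + ½)/(n + 1)).

Numerically, the fitter standardizes non-constant design columns
(back-transforming the coefficients afterwards) so that the stopping rule
max |modified score| < 10⁻⁶ is scale-free, and uses damped Newton steps
on the hat-value-adjusted score with step-halving. On very small or
ill-conditioned problems the unpenalized information is a poor curvature
estimate for the *penalized* objective and Newton can stall; the fitter
then finishes with a BFGS ascent of the penalized likelihood using the
exact modified score as gradient. Converged fits always satisfy the score
tolerance, and fits are verified against derivative-free maximization of
an independently coded penalized likelihood.

The AUROC is the Mann–Whitney estimator computed from midranks (exactly
the fraction of case/non-case pairs ordered correctly, ties ½). Because
the AUROC of a monotone transform equals that of the raw predictor, the
single-predictor model AUROCs equal the raw score AUROCs — the logistic
fit matters only for combining predictors and for orientation (the ratio
enters on its raw scale; its fitted slope is negative, and scoring by
predicted probability removes any need for manual sign flips). All
AUROCs are *apparent* (in-sample): no cross-validation is attempted,
matching the descriptive intent of the model panel.

Confidence intervals for the AUROC use the stratified bootstrap — cases
and non-cases resampled independently, so every replicate keeps both
classes — with percentile endpoints (the resampling scheme is prescribed;
the percentile interval is this package's choice of interval type) and a
recorded seed for bit-reproducibility. The default is 10,000 replicates.
Operating points default to the Youden rule (maximize sens + spec − 1,
ties toward sensitivity); closest-to-top-left and maximum-sensitivity
rules are available, since published operating points rarely state their
rule.

## The synthetic cohort generator

The generator exists because the underlying patient-level data are not
public. It emulates the *published group-level structure* of the study
cohort — 17 hypersusceptible cases and 17 non-cases — so that the full
pipeline is exercisable and testable:

* **Ratio**: per-group log-normals moment-matched (μ = ln m − σ²/2,
  σ² = ln(1 + (s/m)²)) to non-case 0.200 ± 0.154 and case 0.067 ± 0.072.
  The log-normal family is a modelling choice: the ratio is positive and
  right-skewed (group SDs comparable to means). Under it, the theoretical
  case/non-case AUROC is Φ(1.12) ≈ 0.87.
* **TBSA** (per group 31.9 ± 11.2 / 51.2 ± 20.0 on [20, 100]), **age**
  (40.6 ± 17.2 on [16, 90]), **APACHEII**, admission and blood-draw times,
  BMI, and stay lengths: truncated normals whose *post-truncation* mean
  and SD match the published values — the underlying parameters are
  solved from the closed-form truncated-normal moments, since plugging
  printed values in naively shifts means (e.g. case TBSA would inflate
  from 51.2 to ≈ 53).
* **Binary fields** (sex, inhalation 5/17 vs 10/17, burn depth, death)
  are Bernoulli at the published per-group frequencies; etiology is
  categorical at the published counts.
* **Episode counts** define the groups by construction: non-cases draw
  from {0, 1, 2} with probabilities (0.30, 0.40, 0.30) (median 1,
  quartiles [0, 2]); cases draw 3 + NegBin(size 2.5, mean 4), giving
  median 6 with quartiles near [5, 10]. These shapes were calibrated once
  to the published medians/IQRs and verified by simulation.
* **Infection histories** are planted so episode tabulation recovers each
  patient's count exactly: within-cluster gaps stay at or below the
  dissimilar window (merging regardless of similarity), between-cluster
  gaps strictly exceed the similar window. Pathogen labels are sampled
  from the published prevalence list independently per episode, and the
  first infection is placed later than both day 1 and 24 h after the
  blood draw, so every generated patient passes the eligibility filter.
* TNF-α and IL-10 are emitted *separately* — IL-10 log-normal
  (median 20 pg/mL, σ_log 0.9, a typical early post-burn magnitude; no
  group-level IL-10 summaries are published) and TNF-α = ratio × IL-10 —
  so the biomarker stage computes the ratio rather than receiving it.

What the generator deliberately does **not** model: within-group
correlation between the ratio and severity (the inverse ratio-severity
association arises only from the case/non-case mixture), correlations
among severity components beyond their arithmetic definitions, repeat
polymicrobial cultures, and within-patient pathogen persistence
(independent sampling per episode). Passing tests on synthetic cohorts
therefore demonstrate the *machinery* — episode logic, score arithmetic,
estimator correctness, interval calibration — not clinical effect sizes
beyond the planted ones.

## Numerical choices and degenerate inputs

* Time units: hours since injury for admission/draw, fractional days
  since injury for infections; the conversion lives in one internal
  helper. Eligibility's "first infection at least 24 h after draw" is a
  non-strict inequality (boundary equality is eligible), and the 48-h
  draw window is injury-relative, not admission-relative.
* The age criterion is age ≥ 16 (the inclusion wording; published
  inclusion and exclusion sentences disagree at exactly 16).
* Zero pooled variance: t-tests return p = 1 at equal means and error at
  unequal means. Constant ratio series cannot be z-scored (error). Empty
  strata are reported with n = 0 and no summary; strata with fewer than
  2 patients are excluded from testing with the panel retained.
* Episode indices are 1-based in R convention; the audit map preserves
  input row order.
* The patient-by-pathogen matrix is produced by *sorting* on the ratio
  z-score; any visual clustering of pathogens with case status in such
  displays is a by-product of that ordering, not an algorithmic
  clustering.

## Problem sizes used by the test suite

Stochastic properties run at fixed seeds with sizes chosen to make Monte
Carlo error small against the tested margins: moment recovery at 4,000
per group; bootstrap-coverage calibration with 4,000 simulated 17 + 17
cohorts × 2,000 replicates (coverage of the percentile interval at a true
AUROC of 0.80 measures ≈ 92.6 ± 0.4 %, at the permissive edge of the
nominal 95 % — a known small-sample property of percentile intervals);
episode-oracle equivalence over hundreds of random histories; and the
ratio-model AUROC distribution over 120 generated cohorts. The published
interval (0.63–0.93) contains the apparent ratio-model AUROC in ≈ 85 % of
generated cohorts under this calibration.

## Known limitations

* All model performance is apparent (in-sample); with 34 patients any
  cross-validated estimate would be extremely noisy, but users should not
  read the panel's AUROCs as out-of-sample performance.
* The waiting-list conventions (anchor renewal, inclusive boundaries)
  are interpretations of a verbal rule; both are configurable, and
  sensitivity to them should be reported when applying the pipeline to
  new data.
* The generator reproduces first and second moments and group
  frequencies, not the full joint distribution of a real burn cohort.
* Detection-limit handling for cytokines is a policy, not a model; the
  LOD/2 substitution is crude and flagged as such.

## A minimal end-to-end run

```{r example, eval = FALSE}
sim <- generate_cohort(seed = 1)
report <- run_analysis(sim$patients, sim$infections,
                       n_boot = 2000, seed = 1, out_dir = "burncohort_out")
report$models[, c("model", "auroc", "ci_lo", "ci_hi")]
```
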