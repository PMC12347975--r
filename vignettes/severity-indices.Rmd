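---
title: "Metabolic-inflammatory indices for appendicitis severity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic-inflammatory indices for appendicitis severity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metinflam)
```

## The problem

Acute appendicitis spans a severity spectrum — edematous, suppurative,
gangrenous, perforated by histopathology; surgical stages I-IV
intraoperatively — and the clinically urgent distinction is between the
benign end (non-perforated, uncomplicated) and the dangerous one
(perforated; complicated = stages III-IV). All the raw material for a
risk score is already in the admission bloodwork: the stress response
raises glucose, pre-renal hypoperfusion raises creatinine and urea,
endothelial activation moves the coagulation times, and the
inflammatory response shifts the differential toward neutrophils and
away from lymphocytes.

This package implements a complete severity-stratification pipeline
built on nine indices that combine those signals, with every stage
testable on synthetic cohorts. It is aimed at biostatisticians and
clinical researchers who want to evaluate such indices on their own
cohorts, or probe the statistical behaviour of the published ones.

## The indices

With G = glucose (mg/dL), Cr = serum creatinine (mg/dL) and N, L, P the
neutrophil, lymphocyte and platelet values:

| index | formula | index | formula |
|---|---|---|---|
| NLR | N/L | NLCR | Cr·N/L |
| PLR | P/L | CLR | Cr/L |
| SII | P·N/L | GCNLI | (G/Cr)·(N/L) |
| IMI | G·N/L | MISI | G·Cr/L |
| GLR | G/L | | |

`compute_indices()` evaluates all nine per patient and never imputes: a
missing input yields a missing index, mirroring a complete-case design.
Five algebraic identities (SII = NLR·P, IMI = GLR·N, NLCR = NLR·Cr,
GCNLI = IMI/Cr, MISI = GLR·Cr) are enforced as test invariants.

### The units question

Source tables label the differential inputs inconsistently: the rows
named "Lymphocytes (%)" carry values (1.52 ± 0.80) that are only
plausible as absolute counts in 10^3/µL, while the rows labelled as
counts carry percentage-sized values. The package therefore computes
indices from **absolute counts by default**, with `units = "percent"`
as an explicit alternative, and every report records the policy used.
The published fixed cutoffs (e.g. IMI 658.71 histopathological) are
shipped as presets labelled *as published, units convention
unverified*: they are only meaningful under whatever convention
produced them, which the source does not state.

A tie at the cutoff is classified negative (positivity is strict
`score > cutoff`), configurable via `classify_at_cutoff(strict =)`.
This matches the phrasing "values above the fixed cutoff"; the
alternative convention would shift every 2×2 cell containing ties.

## The synthetic cohort generator

No patient-level data are distributed with the study, so
`cohort_config()` + `generate_cohort()` emulate its conditions:

* **n = 246**, perforated/non-perforated 21/225, severity-class
  prevalences 17.48/63.82/10.16/8.54% (histopathological) and
  1.63/29.27/36.18/32.92% (stages I-IV), allocated by largest
  remainder so that counts at n = 246 are exactly 43/157/25/21 and
  4/72/89/81.
* **Group-conditional marginals**: each lab field is (truncated) normal
  with the printed group mean ± SD; truncation at physiological bounds
  (positive concentrations and counts, percentages in 0-100) is exact,
  via inverse-CDF sampling of the idiosyncratic noise.
* **Latent structure**: three independent standard-normal factors —
  coagulation (PT, INR, aPTT), renal-metabolic (urea, creatinine,
  glucose) and immune (neutrophils +, lymphocytes −) — each loaded
  field gets loading 0.85, the rest unique noise. The magnitude 0.85 is
  a design choice: strong enough that the three-block structure is
  genuinely recoverable and the candidate variable set passes the
  KMO adequacy gate (both of which the generator is required to
  deliver), while leaving ~28% unique variance per field.
* **Both classifications from one severity scale**: a single latent
  severity score is thresholded for the histopathological class and the
  surgical stage, so perforated patients are automatically a subset of
  stage IV, as anatomy dictates.
* **Missingness** is MCAR per lab field at a configurable rate
  (default 0), keeping complete-case analyses unbiased.
* One documented `seed`; the global RNG state is never touched.

### What the generator does not pretend to do

The printed parameter table contains internally implausible entries —
a perforated-group aPTT mean of 17.57 s against 33.45 s non-perforated
(and equal to the PT mean), "Segmented 8 ± 79.07", a perforated
lymphocyte mean of 0.1 with SD 0.57, calcium 14.54 ± 21.8. The
generator uses them **as printed** and lists every one in
`cohort_config()$flags` rather than silently correcting; the
lymphocyte truncation in particular raises the realized perforated
mean to about 0.34. A further inconsistency is irreducible: the
printed stage prevalences put 69.1% of patients in stages III-IV,
the complement of the reported complicated/uncomplicated 76/170
split. The config stores the reported binary sizes as metadata and
the generator follows the printed stage prevalences, so a default
cohort has 170 complicated patients; the discrepancy is flagged, not
resolved.

Consequences worth knowing before generalizing from passing tests:
the synthetic separation is *stronger* than clinical reality (default
cohorts give index AUCs of 0.83-0.94 against the published 0.6-0.74),
lab physiology is not age- or sex-conditional, inter-electrolyte
correlations are not modelled, and sub-stages within the non-perforated
group share one lab distribution. Passing tests demonstrate the
machinery is correct and calibrated, not that real-world performance
matches.

## Univariate screening

`compare_continuous()` gates on Shapiro-Wilk normality at α = 0.05 per
group (Anderson-Darling beyond n = 5000, Shapiro-Wilk's hard limit) and
runs Student's t or Mann-Whitney accordingly, recording the branch —
the source states only "as appropriate", so the gate had to be pinned
somewhere and per-group Shapiro at 0.05 is the common convention of the
point-and-click packages of that era. `compare_categorical()` switches
to Fisher's exact test when any expected cell is below 5 (Yates
correction on 2×2 chi-square); `compare_across_stages()` does
ANOVA/Kruskal-Wallis with the same gate. `screen_cohort()` applies
these across a cohort with **no multiple-testing correction** —
deliberately mirroring the original screening — but reports the number
of tests run so readers can Bonferroni mentally.

The two-stage normality-gated test has a mildly inflated conditional
size on the rank branch (samples that fail a normality pretest are
selected for unusualness), a known property of pretesting; the overall
type-I error stays within binomial bounds of the nominal 0.05, which
the acceptance suite checks by simulation.

## Factor analysis and the KMO gate

`kmo()` computes the Kaiser-Meyer-Olkin sampling adequacy from the
anti-image partial correlations p_ij = −s_ij/√(s_ii·s_jj) of the
correlation-matrix inverse: overall KMO = Σr²/(Σr² + Σp²) over
off-diagonal pairs, per-variable analogues restricted to a row. The
test suite pins it to a hand-derived closed form on a two-block 4×4
matrix (within-block r = 0.8 gives exactly 0.5).

`extract_factors()` is principal-component extraction with Kaiser
(eigenvalue ≥ 1) retention, optional varimax rotation (default off —
the source names neither extraction nor rotation, and unrotated PCA is
the minimal choice), sign-fixed loadings, and membership by largest
absolute loading. `select_model()` fits candidate variable sets per
subgroup, ranks by KMO, applies the > 0.6 adequacy gate, and returns
the argmax with a deterministic first-listed tie-break; an explicit
"no adequate model" outcome replaces silent failure. Component counts
are treated as data-dependent outcomes, never constraints.

Two practical notes. First, on *full* default cohorts the mixture of
the two histopathological groups adds severity-driven cross-block
correlations (the implausible printed aPTT/INR shifts are large), which
drags full-cohort KMO below 0.6; fitting per severity subgroup — the
same stratified procedure the source reports, which selected its best
model by the optimal per-stage KMO — recovers clean structure, with
best-subgroup KMO around 0.69 and the three planted memberships
recovered essentially always. The structure-recovery acceptance check
therefore follows the stratified procedure. Second, membership is only
cleanly interpretable after rotation, so recovery checks request
varimax explicitly.

## ROC, cutoffs and 2×2 performance

`roc_curve()` builds the empirical ROC over all distinct thresholds
with strict-`>` positivity; the trapezoidal AUC is numerically the
Mann-Whitney U/(n₁n₂) with ties counted ½ (pinned to a brute-force
pair-counting oracle at 1e-12, and cross-checked against pROC).
Orientation is fixed as higher score = disease; an index running the
other way must be inverted explicitly — no silent auto-flip.

AUC inference is Hanley-McNeil: SE from Q₁ = A/(2−A), Q₂ = 2A²/(1+A),
Wald 95% CI clipped to [0,1], two-sided normal p against 0.5 using the
same SE. The choice matches the SPSS/SigmaPlot-era default and needs no
resampling; a DeLong variant was considered and dropped because it
requires the raw score vectors rather than (AUC, n₁, n₂), changing the
interface for no gain at these sample sizes.

`youden_optimal_cutoff()` maximizes J = Se + Sp − 100 over observed
score values (never midpoints), ties broken toward higher sensitivity
then lower threshold. `performance_at_cutoff()` derives Se, Sp, PPV,
NPV, J (full precision; rounding only at the report layer), the odds
ratio with Woolf logit CI, and a Fisher exact p. A zero discordant cell
reports OR = +∞ with a one-sided interval, as the published tables do,
unless the Haldane-Anscombe 0.5 correction is requested. Degenerate
dichotomizations (an empty predicted class) are flagged, with undefined
metrics left missing.

## Post-hoc power

`or_to_cohens_d()` applies d = ln(OR)·√3/π — the variance matching of
the logistic and normal latent scales — and `power_two_group()` the
two-group normal-approximation power
Φ(|d|/√(1/n₁+1/n₂) − z₀.₉₇₅) + Φ(−|d|/√(1/n₁+1/n₂) − z₀.₉₇₅).
The second term is negligible at the published magnitudes but is kept
so d = 0 returns exactly α. `power_table()` maps rows of
(index, OR, n₁, n₂); fed with `published_power_inputs()` (printed,
rounded ORs — which is why reported effect sizes can differ in the
fifth decimal from full-precision runs, a distinction the `or_source`
attribute records) it reproduces all twelve published rows to ±0.0005.
The closed form is pinned to a 200,000-replicate Monte-Carlo of the
two-group normal model within 0.002.

## Numerical and edge-case choices

* Truncated sampling is inverse-CDF exact; a configuration whose bounds
  exclude essentially all mass raises a config error instead of looping.
* Singular correlation matrices abort with the collinear variables
  named (smallest-eigenvector loadings above 0.3).
* p-values below 5e-4 render as "<=0.0005" in `format_p()` display
  output only; machine columns keep full precision.
* Stage errors in `run_pipeline()` abort with the stage named, after
  preserving any reports already written.

## Problem sizes used in the test suite

The suite runs the oracle equivalences at 500 random ROC instances,
type-I calibration at 1,000 replicates (n = 30/group), AUC CI coverage
over 100 zero-separation cohorts of n = 246, structure recovery over
100 seeds at n = 246, and the Monte-Carlo power oracle at 200,000
replicates — sizes chosen so each empirical rate has tight enough
binomial error to be meaningful while the whole suite stays quick on a
laptop.

## Known limitations

Beyond the generator caveats above: no ROC comparison tests between
correlated curves, no smoothing or binormal fits, no a-priori sample
size planning (only achieved power), no reference-interval flagging,
and no unit auto-detection — by design, since silent unit guessing is
exactly how fixed cutoffs get misapplied.
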