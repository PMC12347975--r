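# metinflam

Severity stratification for acute appendicitis from routine admission
labs. The package computes nine metabolic-inflammatory indices and
implements the full analysis pipeline around them: univariate screening
between severity groups, Kaiser-Meyer-Olkin-guided factor analysis of
candidate lab panels, ROC/cutoff/odds-ratio evaluation, and post-hoc
power analysis — plus a synthetic cohort generator so every stage runs
and is testable without patient data.

It is written for biostatisticians and clinical researchers evaluating
laboratory-based severity markers: the perforated vs non-perforated
(histopathological) and complicated vs uncomplicated (surgical stages
III-IV vs I-II) distinctions drive antibiotic and operative urgency, and
all inputs are routine emergency-department bloodwork.

## The indices

With G = glucose (mg/dL), Cr = serum creatinine (mg/dL), and N, L, P the
neutrophil, lymphocyte and platelet values (absolute counts in 10^3/µL
by default):

    NLR  = N/L          PLR  = P/L          SII   = P·N/L
    IMI  = G·N/L        GLR  = G/L          NLCR  = Cr·N/L
    CLR  = Cr/L         GCNLI = (G/Cr)·(N/L)  MISI = G·Cr/L

Downstream, an index is evaluated by its empirical ROC (trapezoidal
AUC = Mann-Whitney U/(n₁n₂), Hanley-McNeil CI and p against chance),
dichotomized at a Youden-optimal or published fixed cutoff
(positive iff score > cutoff), summarized as Se/Sp/PPV/NPV/Youden
J = Se + Sp − 100 and odds ratio with Woolf CI, and its post-hoc power
computed from the odds ratio via d = ln(OR)·√3/π and the two-group
normal approximation.

## Worked example

```r
library(metinflam)

cohort <- generate_cohort(cohort_config(seed = 42))   # synthetic, n = 246
scored <- compute_indices(cohort)

evaluate_indices(scored, "histopathological",
                 indices = c("imi", "glr", "misi"))
#>   index    auc auc_lo auc_hi cutoff sensitivity specificity youden odds_ratio
#> 1   imi 0.8470 0.7411 0.9529 2054.7       76.19       80.00  56.19      12.80
#> 2   glr 0.8840 0.7891 0.9790  174.9       76.19       86.22  62.41      20.03
#> 3  misi 0.8317 0.7221 0.9414  244.9       61.90       92.00  53.90      18.69
```

Each row is one index against the perforated/non-perforated outcome:
its AUC with 95% CI, the Youden-optimal cutoff on this cohort, and the
2×2 performance at that cutoff — e.g. GLR separates best here
(AUC 0.88), and patients above its cutoff have ~20-fold higher odds of
perforation *in this synthetic cohort*, whose separation is stronger
than clinical reality (see the vignette's caveats).

The published power table is reproduced from the printed odds ratios
and group sizes (21 perforated / 225 non-perforated):

```r
power_table(published_power_inputs())[1:3, c(1:4, 8:10)]
#>             outcome index odds_ratio n1 cohens_d    power power_rounded
#> 1 histopathological   imi      10.45 21 1.293749 0.999896         1.000
#> 2 histopathological   glr       6.01 21 0.988767 0.991188         0.991
#> 3 histopathological  nlcr       4.20 21 0.791204 0.934169         0.934
```

An IMI odds ratio of 10.45 maps to a standardized effect of d = 1.294;
at group sizes 21/225 and two-tailed α = 0.05 the achieved power is
0.9999 — the sample was ample for effects of that size.

Other entry points: `screen_cohort()` (gated t/Mann-Whitney and
chi-square/Fisher screening), `kmo()` / `fit_factor_model()` /
`select_model()` (adequacy-gated factor analysis), `roc_curve()` with
`autoplot()`, and `run_pipeline()` for the end-to-end run with CSV
reports and a reproducibility manifest. A thin CLI with
`simulate|calc|screen|factors|evaluate|power|run` subcommands lives at
`inst/cli/metinflam.R`.

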