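#' Published fixed cutoffs for the nine indices
#'
#' The fixed cutoffs reported by the source study for each index under the
#' two severity classifications: histopathological (perforated vs
#' non-perforated) and surgical (complicated, stages III-IV, vs
#' uncomplicated, stages I-II). They are shipped as published; the units
#' convention under which they were derived (absolute counts vs
#' differential percentages) is not stated in the source, so they carry the
#' caveat "units convention unverified" and should be applied under a
#' consciously chosen policy (see [compute_indices()]).
#'
#' @param outcome Which classification the cutoffs dichotomize.
#' @return Tibble with columns `index` and `cutoff`.
#' @export
published_cutoffs <- function(outcome = c("histopathological", "surgical")) {
  outcome <- match.arg(outcome)
  cuts <- switch(outcome,
    histopathological = c(nlr = 5.015, plr = 147.42, sii = 1463.02,
                          imi = 658.71, glr = 117.46, nlcr = 9.66,
                          clr = 0.64, gcnli = 905.51, misi = 83.82),
    surgical = c(nlr = 10.76, plr = 235.355, sii = 3718.42,
                 imi = 987.83, glr = 71.74, nlcr = 8.04,
                 clr = 0.47, gcnli = 1267.7, misi = 54.81)
  )
  tibble(index = names(cuts), cutoff = unname(cuts))
}

#' Published diagnostic performance of the indices at their fixed cutoffs
#'
#' The reported AUC, cutoff, sensitivity, specificity, predictive values,
#' Youden index and odds ratio (with 95% CI) for each index under each
#' classification, as printed by the source study. Useful as presets and
#' for internal-consistency checks (e.g. the Youden identity
#' J = Se + Sp - 100). Percent-scale columns are on the 0-100 scale.
#'
#' `odds_ratio` is `Inf` for the one row reported as unbounded (SII,
#' histopathological, zero discordant cell).
#'
#' @return Tibble with one row per index x classification.
#' @export
published_performance <- function() {
  bind_rows(
    tibble(
      outcome = "histopathological",
      index = c("nlr", "plr", "sii", "imi", "glr", "nlcr", "clr", "gcnli", "misi"),
      auc = c(0.662, 0.648, 0.600, 0.688, 0.721, 0.699, 0.720, 0.597, 0.742),
      cutoff = c(5.015, 147.42, 1463.02, 658.71, 117.46, 9.66, 0.64, 905.51, 83.82),
      sensitivity = c(95.45, 95.24, 100, 94.74, 68.42, 57.89, 73.68, 89.47, 68.42),
      specificity = c(26.76, 32.26, 31.13, 36.72, 73.48, 75.14, 62.98, 33.9, 72.38),
      ppv = c(11.86, 11.98, 12.57, 13.84, 21.31, 20, 17.28, 12.69, 20.63),
      npv = c(98.28, 98.59, 100, 98.48, 95.68, 94.3, 95.8, 96.77, 95.62),
      youden = c(22.21, 27.5, 31.13, 31.46, 41.9, 33.04, 36.67, 23.37, 40.8),
      odds_ratio = c(7.7, 9.5, Inf, 10.45, 6.01, 4.2, 4.76, 4.36, 5.68),
      or_lo = c(1.0, 1.3, NA, 1.36, 2.16, 1.57, 1.64, 0.97, 2.04),
      or_hi = c(58.4, 72.4, NA, 80.08, 16.68, 10.99, 13.82, 19.5, 15.75)
    ),
    tibble(
      outcome = "surgical",
      index = c("nlr", "plr", "sii", "imi", "glr", "nlcr", "clr", "gcnli", "misi"),
      auc = c(0.679, 0.677, 0.667, 0.753, 0.743, 0.677, 0.632, 0.762, 0.676),
      cutoff = c(10.76, 235.355, 3718.42, 987.83, 71.74, 8.04, 0.47, 1267.7, 54.81),
      sensitivity = c(45.96, 46.34, 33.75, 58.52, 65.94, 46.67, 64.49, 68.15, 60.15),
      specificity = c(82.19, 83.78, 91.78, 78.69, 75.81, 83.61, 64.52, 73.77, 72.58),
      ppv = c(85.06, 86.36, 90, 85.87, 85.85, 86.3, 80.18, 85.18, 83),
      npv = c(40.82, 41.33, 38.73, 46.15, 50, 41.46, 44.94, 51.14, 45),
      youden = c(28.15, 30.12, 25.53, 37.21, 41.75, 30.27, 29.01, 41.92, 32.73),
      odds_ratio = c(3.9, 4.5, 5.7, 5.21, 6.1, 4.46, 3.3, 6.02, 3.99),
      or_lo = c(1.99, 2.2, 2.3, 2.58, 3.07, 2.09, 1.76, 3.06, 2.08),
      or_hi = c(7.7, 8.0, 13.9, 10.51, 11.97, 9.52, 6.18, 11.83, 7.68)
    )
  )
}

#' Published odds ratios and group sizes for the post-hoc power analysis
#'
#' The inputs of the reported power table: odds ratio, group sizes (cases,
#' controls) and classification for the six proposed metabolic-inflammatory
#' indices, together with the printed effect-size and power columns for
#' reference. The printed (rounded) odds ratios are the intended inputs
#' when reproducing the table.
#'
#' @return Tibble with columns `outcome`, `index`, `odds_ratio`, `n1`,
#'   `n2`, and the printed reference columns `effect_size_printed`,
#'   `power_printed`, `power_rounded_printed`.
#' @seealso [power_table()]
#' @export
published_power_inputs <- function() {
  bind_rows(
    tibble(
      outcome = "histopathological",
      index = c("imi", "glr", "nlcr", "clr", "gcnli", "misi"),
      odds_ratio = c(10.45, 6.01, 4.2, 4.76, 4.36, 5.68),
      n1 = 21, n2 = 225,
      effect_size_printed = c(1.29375, 0.98877, 0.79120, 0.86021, 0.81182, 0.95763),
      power_printed = c(0.99990, 0.99119, 0.93416, 0.96485, 0.94497, 0.98735),
      power_rounded_printed = c(1.000, 0.991, 0.934, 0.965, 0.945, 0.987)
    ),
    tibble(
      outcome = "surgical",
      index = c("imi", "glr", "nlcr", "clr", "gcnli", "misi"),
      odds_ratio = c(5.21, 6.1, 4.46, 3.3, 6.02, 3.99),
      n1 = 76, n2 = 170,
      effect_size_printed = c(0.91001, 0.99696, 0.82432, 0.65824, 0.98968, 0.76292),
      power_printed = c(1.00000, 1.00000, 0.99997, 0.99753, 1.00000, 0.99982),
      power_rounded_printed = c(1.000, 1.000, 1.000, 0.998, 1.000, 1.000)
    )
  )
}
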