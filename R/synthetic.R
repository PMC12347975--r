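# Group-conditional parameter table for the default generator. Histopathological
# columns (perforated vs non-perforated) drive generation; surgical columns
# (complicated vs uncomplicated) are carried for reference and reporting.
# Several printed entries are internally implausible (see cohort_config()$flags)
# and are used as printed, never silently corrected.
default_lab_params <- function() {
  tribble_cols <- c("field", "m_perf", "s_perf", "m_non", "s_non",
                    "m_comp", "s_comp", "m_unc", "s_unc", "lo", "hi",
                    "factor", "loading_sign")
  p <- rbind(
    c("age",              36.67, 24.58, 23.68, 18.43, 24.75, 20.23, 24.90, 17.23, 0, Inf, NA, 0),
    c("hospital_days",     4.71,  3.64,  3.10,  2.75,  3.46,  2.74,  2.45,  2.96, 0, Inf, NA, 0),
    c("platelets",       245.52, 81.02, 273.91, 80.15, 274.15, 84.18, 265.43, 71.5, 0, Inf, NA, 0),
    c("leukocytes",       13.34,  4.63, 14.77,  5.10, 15.26,  5.3, 13.25,  4.21, 0, Inf, NA, 0),
    c("lymphocyte_count",  0.1,   0.57,  1.52,  0.80,  1.35,  0.79,  1.77,  0.75, 0, Inf, 3, -1),
    c("neutrophil_count", 11.55,  4.21, 11.85,  4.97, 12.45,  5.12, 10.43,  4.09, 0, Inf, 3, 1),
    c("lymphocyte_pct",    9.64,  5.2,  12.8,   9.17, 11.34,  7.98, 15.54, 10.47, 0, 100, NA, 0),
    c("neutrophil_pct",    8,    79.07, 75.66, 12.29, 76.51, 12.06, 74.51, 12.79, 0, 100, NA, 0),
    c("prothrombin_time", 15.62,  2.23, 17.57,  5.47, 16.22,  2.95, 14.89,  1.84, 0, Inf, 1, 1),
    c("inr",               1.9,   0.47,  1.21,  0.2,   1.27,  0.26,  1.15,  0.16, 0, Inf, 1, 1),
    c("aptt",             17.57,  5.5,  33.45,  5.53, 34.74,  6.17, 31.82,  3.84, 0, Inf, 1, 1),
    c("glucose",         125.73, 30.49, 109.27, 39.66, 117.01, 43.58, 96.65, 20.61, 0, Inf, 2, 1),
    c("urea",             40,    46.48, 26.82, 17.66, 28.63, 23.28, 26.69, 19.25, 0, Inf, 2, 1),
    c("serum_creatinine",  0.96,  0.41,  0.77,  0.57,  0.77,  0.46,  0.84,  0.74, 0, Inf, 2, 1),
    c("phosphorus",        3.47,  1.74,  4.53,  9.28,  4.68, 10.51,  3.86,  2.31, 0, Inf, NA, 0),
    c("calcium",          14.54, 21.8,   9.11,  1.29,  9.8,   8.42,  9.35,  0.61, 0, Inf, NA, 0),
    c("chloride",         98.78,  6.16, 101.3,  9.37, 100.23, 10.56, 102.95, 3.9, 0, Inf, NA, 0),
    c("potassium",         3.82,  0.55,  3.9,   0.43,  3.94,  0.48,  3.77,  0.33, 0, Inf, NA, 0),
    c("sodium",          133.84,  5.33, 135.41, 10.98, 135.37, 5.44, 135.04, 17.3, 0, Inf, NA, 0),
    c("magnesium",         2.08,  0.37,  1.98,  0.4,   2.01,  0.33,  1.97,  0.52, 0, Inf, NA, 0),
    c("bun",              18.66, 21.77, 12.49,  7.48, 13.59, 11.17, 11.94,  5.93, 0, Inf, NA, 0)
  )
  out <- as_tibble(as.data.frame(p, stringsAsFactors = FALSE))
  names(out) <- tribble_cols
  out[-1] <- lapply(out[-1], as.numeric)
  out
}

#' Default synthetic-cohort configuration
#'
#' Builds the generating configuration for [generate_cohort()]. The
#' defaults encode the source study's conditions: 246 patients; reported
#' binary group sizes 21/225 (perforated vs non-perforated, by
#' histopathology) and 76/170 (complicated vs uncomplicated, by surgical
#' stage); group-conditional lab means and SDs as printed; severity-class
#' prevalences of 17.48/63.82/10.16/8.54% (edematous/suppurative/
#' gangrenous/perforated) and 1.63/29.27/36.18/32.92% (surgical stages
#' I-IV); and a latent three-factor correlation structure — coagulation
#' (prothrombin time, INR, aPTT), renal-metabolic (urea, creatinine,
#' glucose) and immune (neutrophils loading positively, lymphocytes
#' negatively).
#'
#' Note the printed surgical-stage prevalences put 69.1% of patients in
#' stages III-IV, the complement of the reported 76/170 complicated/
#' uncomplicated split; both are kept as printed and the discrepancy is
#' recorded in `$flags`, together with the other internally implausible
#' printed parameters (e.g. a perforated-group aPTT mean far below the
#' non-perforated one). Nothing is silently corrected.
#'
#' @param n Cohort size; default 246.
#' @param seed Default seed used by [generate_cohort()]; integer.
#' @param missing_rate MCAR missingness probability applied per lab field,
#'   in `[0, 1)`; default 0.
#' @param separation Scales the perforated-group shift: 1 reproduces the
#'   printed group difference, 0 makes both groups share the
#'   non-perforated parameters (a null cohort for calibration checks).
#' @param loading Magnitude of the latent-factor loadings for the loaded
#'   fields, in `[0, 1)`; default 0.85 (strong but leaving substantial
#'   unique variance, so the three-block structure is recoverable).
#' @param params Optional replacement parameter table with the columns of
#'   the default one (advanced use; see `cohort_config()$params`).
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$group_n$histopathological
#' @export
cohort_config <- function(n = 246, seed = 1, missing_rate = 0,
                          separation = 1, loading = 0.85, params = NULL) {
  params <- params %||% default_lab_params()
  stopifnot(is.data.frame(params),
            all(c("field", "m_perf", "s_perf", "m_non", "s_non",
                  "lo", "hi", "factor", "loading_sign") %in% names(params)))
  if (n < 4) abort("cohort size must be at least 4", class = "metinflam_config_error")
  if (any(params$s_perf <= 0) || any(params$s_non <= 0)) {
    abort("all SDs must be positive", class = "metinflam_config_error")
  }
  if (loading < 0 || loading >= 1) {
    abort("loading magnitude must be in [0, 1)", class = "metinflam_config_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)", class = "metinflam_config_error")
  }
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    group_n = list(
      histopathological = c(perforated = 21L, non_perforated = 225L),
      surgical = c(complicated = 76L, uncomplicated = 170L)
    ),
    histopath_prevalence = c(edematous = 0.1748, suppurative = 0.6382,
                             gangrenous = 0.1016, perforated = 0.0854),
    stage_prevalence = c(I = 0.0163, II = 0.2927, III = 0.3618, IV = 0.3292),
    p_male = 0.516,
    params = as_tibble(params),
    loading = loading,
    separation = separation,
    missing_rate = missing_rate,
    flags = c(
      "stage prevalences put stages III-IV at 69.1% of patients, the complement of the reported complicated/uncomplicated 76/170 split; both kept as printed",
      "perforated-group aPTT mean (17.57) is far below the non-perforated mean (33.45) and equals the non-perforated PT mean",
      "perforated-group neutrophil_pct parameters (8 +/- 79.07) are implausible as printed",
      "perforated-group lymphocyte_count mean 0.1 with SD 0.57 is heavily truncated at zero; realized mean is higher",
      "perforated-group calcium parameters (14.54 +/- 21.8) are implausible as printed",
      "lab generation conditions on the histopathological binary group; surgical-column parameters are carried for reference only"
    )
  )
  class(cfg) <- "cohort_config"
  cfg
}

# largest-remainder allocation of n across prevalence classes
allocate_counts <- function(n, prev) {
  raw <- prev / sum(prev) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(prev))
}

# truncated-normal draw of the idiosyncratic noise so that
# mu + sd * (lambda * f + sqrt(1 - lambda^2) * eps) lies in (lo, hi)
rtrunc_eps <- function(n, base, mu, sd, lo, hi, c_uniq) {
  elo <- ((lo - mu) / sd - base) / c_uniq
  ehi <- ((hi - mu) / sd - base) / c_uniq
  plo <- pnorm(elo); phi <- pnorm(ehi)
  if (any(phi - plo < 1e-12)) {
    abort("infeasible config: truncation bounds leave no probability mass",
          class = "metinflam_config_error")
  }
  qnorm(runif(n, plo, phi))
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort with the statistical structure the severity analysis
#' assumes. Each patient gets a latent severity score; histopathological
#' classes and surgical stages are assigned by thresholding that score at
#' the configured prevalences, so perforated patients are a subset of the
#' highest surgical stages. Lab fields are built from three independent
#' latent factors (coagulation, renal-metabolic, immune) via the configured
#' loadings plus independent noise, rescaled to the histopathological
#' group's target mean/SD, and truncated at physiological bounds (all
#' concentrations and counts positive, percentages within 0-100) by
#' truncated-normal sampling of the idiosyncratic noise. Missingness, when
#' configured, is injected completely at random per lab field. Generation
#' is fully reproducible given the seed; the global random state is left
#' untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return Tibble with one row per patient: `id`, `sex`, `age`,
#'   `hospital_days`, the lab fields, `histopath`, `surgical_stage`, and
#'   the derived binary outcomes `perforated` (histopath == perforated) and
#'   `complicated` (stage III or IV). The generating config is attached as
#'   attribute `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' table(cohort$histopath)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n
  hist_counts <- allocate_counts(n, config$histopath_prevalence)
  stage_counts <- allocate_counts(n, config$stage_prevalence)

  severity <- rnorm(n)
  rk <- rank(severity, ties.method = "first")  # 1 = least severe
  hist_breaks <- cumsum(hist_counts)
  histopath <- names(hist_counts)[findInterval(rk, c(0, hist_breaks), left.open = TRUE)]
  stage_breaks <- cumsum(stage_counts)
  surgical_stage <- names(stage_counts)[findInterval(rk, c(0, stage_breaks), left.open = TRUE)]

  perforated <- histopath == "perforated"
  complicated <- surgical_stage %in% c("III", "IV")

  fac <- matrix(rnorm(n * 3), nrow = n)  # coagulation, renal-metabolic, immune
  pars <- config$params
  sep <- config$separation
  lab <- vector("list", nrow(pars))
  names(lab) <- pars$field
  for (j in seq_len(nrow(pars))) {
    pj <- pars[j, ]
    mu_perf <- pj$m_non + sep * (pj$m_perf - pj$m_non)
    sd_perf <- pj$s_non + sep * (pj$s_perf - pj$s_non)
    mu <- ifelse(perforated, mu_perf, pj$m_non)
    sd <- ifelse(perforated, sd_perf, pj$s_non)
    lam <- if (!is.na(pj$factor)) config$loading * pj$loading_sign else 0
    base <- if (lam != 0) lam * fac[, pj$factor] else rep(0, n)
    c_uniq <- sqrt(1 - lam^2)
    eps <- rtrunc_eps(n, base, mu, sd, pj$lo, pj$hi, c_uniq)
    lab[[j]] <- mu + sd * (base + c_uniq * eps)
  }

  lab_fields <- setdiff(pars$field, c("age", "hospital_days"))
  if (config$missing_rate > 0) {
    for (f in lab_fields) {
      drop <- runif(n) < config$missing_rate
      lab[[f]][drop] <- NA_real_
    }
  }

  out <- tibble(
    id = sprintf("P%04d", seq_len(n)),
    sex = ifelse(runif(n) < config$p_male, "male", "female"),
    age = lab$age,
    hospital_days = lab$hospital_days
  )
  for (f in lab_fields) out[[f]] <- lab[[f]]
  out$histopath <- factor(histopath,
                          levels = c("edematous", "suppurative", "gangrenous", "perforated"))
  out$surgical_stage <- factor(surgical_stage, levels = c("I", "II", "III", "IV"))
  out$perforated <- perforated
  out$complicated <- complicated
  attr(out, "config") <- config
  out
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, seed = %d, separation = %g, loading = %g, missing_rate = %g\n",
              x$n, x$seed, x$separation, x$loading, x$missing_rate))
  cat(sprintf("  histopathological groups: %s\n",
              paste(names(x$group_n$histopathological), x$group_n$histopathological,
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  surgical groups (reported): %s\n",
              paste(names(x$group_n$surgical), x$group_n$surgical,
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  flags: %d printed-parameter caveats (see $flags)\n", length(x$flags)))
  invisible(x)
}
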