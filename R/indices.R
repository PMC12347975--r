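#' Names of the nine metabolic-inflammatory indices
#'
#' @return Character vector: `nlr`, `plr`, `sii`, `imi`, `glr`, `nlcr`,
#'   `clr`, `gcnli`, `misi`.
#' @export
index_names <- function() {
  c("nlr", "plr", "sii", "imi", "glr", "nlcr", "clr", "gcnli", "misi")
}

# lab columns each index needs, under the absolute-count units policy
index_inputs <- function(units = c("count", "percent")) {
  units <- match.arg(units)
  neut <- if (units == "count") "neutrophil_count" else "neutrophil_pct"
  lymph <- if (units == "count") "lymphocyte_count" else "lymphocyte_pct"
  list(
    nlr   = c(neut, lymph),
    plr   = c("platelets", lymph),
    sii   = c("platelets", neut, lymph),
    imi   = c("glucose", neut, lymph),
    glr   = c("glucose", lymph),
    nlcr  = c("serum_creatinine", neut, lymph),
    clr   = c("serum_creatinine", lymph),
    gcnli = c("glucose", "serum_creatinine", neut, lymph),
    misi  = c("glucose", "serum_creatinine", lymph)
  )
}

#' Compute the nine metabolic-inflammatory indices
#'
#' Adds the index columns `nlr`, `plr`, `sii`, `imi`, `glr`, `nlcr`, `clr`,
#' `gcnli` and `misi` to a patient-level data frame. Writing G for glucose
#' (mg/dL), Cr for serum creatinine (mg/dL) and N, L, P for the neutrophil,
#' lymphocyte and platelet values under the configured units policy:
#'
#' \deqn{NLR = N/L,\quad PLR = P/L,\quad SII = P \cdot N / L,}
#' \deqn{IMI = G \cdot N / L,\quad GLR = G/L,\quad NLCR = Cr \cdot N / L,}
#' \deqn{CLR = Cr/L,\quad GCNLI = (G/Cr)(N/L),\quad MISI = G \cdot Cr / L.}
#'
#' Rows with a missing input yield a missing index value — nothing is
#' imputed. A zero or negative lymphocyte value, or any negative input, is a
#' domain error naming the offending column (ratios against a non-positive
#' denominator have no clinical meaning).
#'
#' @param data Data frame with one row per patient. Under
#'   `units = "count"` the neutrophil/lymphocyte inputs are the absolute
#'   counts in 10^3/uL (`neutrophil_count`, `lymphocyte_count`); under
#'   `units = "percent"` they are the differential percentages
#'   (`neutrophil_pct`, `lymphocyte_pct`). `platelets` (10^3/uL), `glucose`
#'   (mg/dL) and `serum_creatinine` (mg/dL) are used by the metabolic
#'   indices. Columns that are absent are treated as all-missing, with a
#'   warning.
#' @param units Units policy for the differential inputs; default
#'   `"count"`. The published fixed cutoffs (see [published_cutoffs()]) are
#'   only meaningful under a fixed convention, so results carry the policy
#'   used in the `"units"` attribute.
#' @return The input as a tibble with the nine index columns appended and an
#'   attribute `units` recording the policy.
#' @examples
#' labs <- tibble::tibble(glucose = 100, neutrophil_count = 8,
#'                        lymphocyte_count = 2, serum_creatinine = 1,
#'                        platelets = 200)
#' compute_indices(labs)
#' @export
compute_indices <- function(data, units = c("count", "percent")) {
  units <- match.arg(units)
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)

  needs <- unique(unlist(index_inputs(units)))
  absent <- setdiff(needs, names(data))
  if (length(absent) > 0) {
    warn(paste0("column(s) not found, treated as missing: ",
                paste(absent, collapse = ", ")))
  }
  col <- function(nm) {
    if (nm %in% names(data)) as.numeric(data[[nm]]) else rep(NA_real_, nrow(data))
  }

  for (nm in needs) {
    x <- col(nm)
    bad <- which(!is.na(x) & x < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative value in '%s' (row %d)", nm, bad[1]),
            class = "metinflam_domain_error")
    }
  }
  lymph_nm <- if (units == "count") "lymphocyte_count" else "lymphocyte_pct"
  L <- col(lymph_nm)
  zero <- which(!is.na(L) & L <= 0)
  if (length(zero) > 0) {
    abort(sprintf("zero or negative lymphocyte value in '%s' (row %d): cannot form ratios",
                  lymph_nm, zero[1]),
          class = "metinflam_domain_error")
  }

  neut_nm <- if (units == "count") "neutrophil_count" else "neutrophil_pct"
  N <- col(neut_nm); P <- col("platelets")
  G <- col("glucose"); Cr <- col("serum_creatinine")

  out <- mutate(data,
    nlr   = N / L,
    plr   = P / L,
    sii   = P * N / L,
    imi   = G * N / L,
    glr   = G / L,
    nlcr  = Cr * N / L,
    clr   = Cr / L,
    gcnli = (G / Cr) * (N / L),
    misi  = G * Cr / L
  )
  attr(out, "units") <- units
  out
}

#' Classify index scores against a cutoff
#'
#' A score is test-positive when it lies strictly above the cutoff (higher
#' score = disease-positive orientation); a score exactly equal to the
#' cutoff is negative under the default strict rule. Missing scores are
#' `"indeterminate"`, never silently positive or negative.
#'
#' @param scores Numeric vector of index scores.
#' @param cutoff Single finite cutoff, e.g. one from [published_cutoffs()].
#' @param strict If `TRUE` (default) positivity requires `score > cutoff`;
#'   if `FALSE`, `score >= cutoff`.
#' @return Factor with levels `negative`, `positive`, `indeterminate`.
#' @examples
#' cut <- published_cutoffs("histopathological")$cutoff[
#'   published_cutoffs("histopathological")$index == "imi"]
#' classify_at_cutoff(c(658.72, 658.71, NA), cut)
#' @export
classify_at_cutoff <- function(scores, cutoff, strict = TRUE) {
  stopifnot(is.numeric(scores), length(cutoff) == 1, is.finite(cutoff))
  pos <- if (strict) scores > cutoff else scores >= cutoff
  out <- ifelse(is.na(scores), "indeterminate",
                ifelse(pos, "positive", "negative"))
  factor(out, levels = c("negative", "positive", "indeterminate"))
}
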