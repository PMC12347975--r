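# recognized cohort columns (case-insensitive on read)
cohort_columns <- function() {
  c("id", "sex", "age", "hospital_days",
    default_lab_params()$field[-(1:2)],
    "histopath", "surgical_stage")
}

canonical_histopath <- c("edematous", "suppurative", "gangrenous", "perforated")
canonical_stages <- c("I", "II", "III", "IV")

#' Read a patient cohort from CSV
#'
#' Reads a cohort with the documented column dictionary (the lab fields of
#' [cohort_config()]'s parameter table plus `id`, `sex`, `age`,
#' `hospital_days`, `histopath`, `surgical_stage`), matched
#' case-insensitively. Unparseable numeric cells become missing with a
#' warning naming the row (1-based, header excluded) and column;
#' categorical labels are normalized (any case accepted; surgical stages
#' also accepted as 1-4) and unknown labels become missing with a warning.
#' Duplicate patient ids are an error.
#'
#' @param path CSV file with a header row.
#' @return Tibble with canonical column names and types, and derived
#'   `perforated` / `complicated` flags when the outcome columns are
#'   present.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  known <- cohort_columns()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unrecognized column(s): ", paste(unknown, collapse = ", ")))
    raw <- raw[, intersect(names(raw), known), drop = FALSE]
  }
  out <- as_tibble(raw)

  numeric_cols <- setdiff(intersect(known, names(out)),
                          c("id", "sex", "histopath", "surgical_stage"))
  for (col in numeric_cols) {
    x <- out[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad) > 0) {
      warn(sprintf("column '%s': %d unparseable cell(s) set to missing (first at row %d: \"%s\")",
                   col, length(bad), bad[1], x[bad[1]]))
    }
    out[[col]] <- num
  }

  if ("histopath" %in% names(out)) {
    lab <- tolower(trimws(out$histopath))
    bad <- which(!is.na(lab) & !(lab %in% canonical_histopath))
    if (length(bad) > 0) {
      warn(sprintf("column 'histopath': %d unknown label(s) set to missing (first at row %d: \"%s\")",
                   length(bad), bad[1], out$histopath[bad[1]]))
      lab[bad] <- NA_character_
    }
    out$histopath <- factor(lab, levels = canonical_histopath)
    out$perforated <- !is.na(lab) & lab == "perforated"
  }
  if ("surgical_stage" %in% names(out)) {
    lab <- toupper(trimws(out$surgical_stage))
    lab[lab %in% as.character(1:4)] <- canonical_stages[match(
      lab[lab %in% as.character(1:4)], as.character(1:4))]
    bad <- which(!is.na(lab) & !(lab %in% canonical_stages))
    if (length(bad) > 0) {
      warn(sprintf("column 'surgical_stage': %d unknown label(s) set to missing (first at row %d: \"%s\")",
                   length(bad), bad[1], out$surgical_stage[bad[1]]))
      lab[bad] <- NA_character_
    }
    out$surgical_stage <- factor(lab, levels = canonical_stages)
    out$complicated <- !is.na(lab) & lab %in% c("III", "IV")
  }
  if ("sex" %in% names(out)) {
    out$sex <- tolower(trimws(out$sex))
  }
  if ("id" %in% names(out)) {
    dup <- out$id[duplicated(out$id) & !is.na(out$id)]
    if (length(dup) > 0) {
      abort(paste0("duplicate patient id(s): ", paste(unique(dup), collapse = ", ")),
            class = "metinflam_validation_error")
    }
  }
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the canonical columns so that a
#' round-trip is field-identical for valid cohorts. Derived flags
#' (`perforated`, `complicated`) are not written — they are recomputed on
#' read.
#'
#' @param data Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  keep <- intersect(cohort_columns(), names(data))
  readr::write_csv(as_tibble(data)[, keep, drop = FALSE], path, progress = FALSE)
  invisible(path)
}
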