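# normality gate used before choosing parametric vs rank tests.
# shapiro.test caps at n = 5000; beyond that the Anderson-Darling test is
# an equivalent deterministic gate.
is_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
  p <- if (length(x) <= 5000) shapiro.test(x)$p.value else nortest::ad.test(x)$p.value
  p > alpha
}

sig_stars <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**", p <= 0.05 ~ "*",
                   is.na(p) ~ "", TRUE ~ "")
}

#' Compare a continuous variable between two groups
#'
#' Applies Student's t test when both groups pass the normality gate
#' (Shapiro-Wilk at `normality_alpha` per group), otherwise the
#' Mann-Whitney rank-sum test; the branch taken is recorded. Missing values
#' are dropped per group (complete cases), and the complete-case counts are
#' reported.
#'
#' @param values_a,values_b Numeric vectors for the two groups; at least 2
#'   non-missing values each.
#' @param normality_alpha Per-group significance level of the normality
#'   gate; default 0.05.
#' @param var_equal Passed to [stats::t.test()] when the parametric branch
#'   runs; default `TRUE` (the classical two-sample t test).
#' @return One-row tibble: `test`, `statistic`, `p_value`, per-group
#'   `n_used`, means and SDs, and `normal_a`/`normal_b` gate outcomes.
#' @export
compare_continuous <- function(values_a, values_b, normality_alpha = 0.05,
                               var_equal = TRUE) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 non-missing values per group",
          class = "metinflam_degenerate_error")
  }
  if (length(unique(c(a, b))) == 1) {
    abort("all values identical in both groups: no test is defined",
          class = "metinflam_degenerate_error")
  }
  na <- is_normal(a, normality_alpha)
  nb <- is_normal(b, normality_alpha)
  if (na && nb) {
    ht <- t.test(a, b, var.equal = var_equal)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    test <- "mann_whitney"
  }
  tibble(
    test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
    normal_a = na, normal_b = nb
  )
}

#' Compare a categorical variable between groups
#'
#' Pearson chi-square test of homogeneity on a contingency table, switching
#' to Fisher's exact test when any expected cell count is below 5. For 2x2
#' tables the chi-square branch applies the Yates continuity correction.
#'
#' @param counts Matrix (or table) of non-negative integer counts, groups
#'   in rows; every row and column must have a nonzero margin.
#' @return One-row tibble: `test`, `statistic` (NA for the exact test),
#'   `p_value`, `n_used`, `min_expected`.
#' @examples
#' compare_categorical(matrix(c(11, 116, 10, 109), nrow = 2))
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || sum(counts) == 0) {
    abort("empty contingency table", class = "metinflam_degenerate_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "metinflam_domain_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("every margin must have at least one nonzero count",
          class = "metinflam_degenerate_error")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    ht <- fisher.test(counts)
    tibble(test = "fisher", statistic = NA_real_, p_value = ht$p.value,
           n_used = sum(counts), min_expected = min(expected))
  } else {
    ht <- suppressWarnings(chisq.test(counts, correct = TRUE))
    tibble(test = "chi_square", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_used = sum(counts),
           min_expected = min(expected))
  }
}

#' Omnibus comparison across severity stages
#'
#' One-way ANOVA across the histopathological classes or surgical stages
#' when every group passes the normality gate, otherwise the
#' Kruskal-Wallis rank test; the branch taken is recorded.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length, e.g.
#'   `surgical_stage`.
#' @param normality_alpha Per-group normality gate level; default 0.05.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_used`,
#'   `n_groups`.
#' @export
compare_across_stages <- function(values, groups, normality_alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  x <- values[keep]
  g <- droplevels(as.factor(groups[keep]))
  sizes <- table(g)
  if (sum(sizes >= 2) < 2) {
    abort("need at least two groups with at least 2 values each",
          class = "metinflam_degenerate_error")
  }
  if (length(unique(x)) == 1) {
    abort("all values identical across groups: no test is defined",
          class = "metinflam_degenerate_error")
  }
  normal <- all(vapply(split(x, g), is_normal, logical(1), alpha = normality_alpha))
  if (normal) {
    fit <- aov(x ~ g)
    tab <- anova(fit)
    tibble(test = "anova", statistic = tab$`F value`[1],
           p_value = tab$`Pr(>F)`[1], n_used = length(x),
           n_groups = nlevels(g))
  } else {
    ht <- kruskal.test(x, g)
    tibble(test = "kruskal_wallis", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_used = length(x), n_groups = nlevels(g))
  }
}

# binary outcome labels for a cohort
outcome_labels <- function(data, outcome = c("histopathological", "surgical")) {
  outcome <- match.arg(outcome)
  if (outcome == "histopathological") {
    if (!"histopath" %in% names(data)) {
      abort("column 'histopath' required for the histopathological outcome",
            class = "metinflam_validation_error")
    }
    as.character(data$histopath) == "perforated"
  } else {
    if (!"surgical_stage" %in% names(data)) {
      abort("column 'surgical_stage' required for the surgical outcome",
            class = "metinflam_validation_error")
    }
    as.character(data$surgical_stage) %in% c("III", "IV")
  }
}

#' Univariate screening of a cohort against a severity outcome
#'
#' Reproduces the descriptive screening stage: every continuous variable is
#' compared between the positive (perforated, or complicated) and negative
#' groups with [compare_continuous()], and `sex` (when present) with
#' [compare_categorical()]. No multiple-testing correction is applied; the
#' number of tests run is recorded in the `n_tests` attribute so readers
#' can judge the screening burden.
#'
#' @param data Cohort data frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]) with the outcome column the chosen classification
#'   needs (`histopath` or `surgical_stage`).
#' @param outcome `"histopathological"` (perforated vs non-perforated) or
#'   `"surgical"` (complicated, stages III-IV, vs uncomplicated).
#' @param variables Which columns to screen; defaults to all numeric
#'   columns except identifiers and derived outcome flags.
#' @param normality_alpha Normality gate level; default 0.05.
#' @return Tibble with one row per variable: test used, statistic,
#'   p-value, significance stars, per-group complete-case counts and
#'   summaries.
#' @export
screen_cohort <- function(data, outcome = c("histopathological", "surgical"),
                          variables = NULL, normality_alpha = 0.05) {
  outcome <- match.arg(outcome)
  pos <- outcome_labels(data, outcome)
  if (is.null(variables)) {
    skip <- c("id", "perforated", "complicated")
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, skip)
  }
  rows <- purrr::map(variables, function(v) {
    res <- tryCatch(
      compare_continuous(data[[v]][pos], data[[v]][!pos],
                         normality_alpha = normality_alpha),
      metinflam_degenerate_error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    mutate(res, variable = v, .before = 1)
  })
  out <- bind_rows(rows)
  if ("sex" %in% names(data)) {
    tab <- table(factor(pos, levels = c(TRUE, FALSE)), data$sex)
    if (all(dim(tab) == c(2, 2)) && sum(tab) > 0) {
      sx <- compare_categorical(tab)
      out <- bind_rows(out, tibble(
        variable = "sex", test = sx$test, statistic = sx$statistic,
        p_value = sx$p_value, n_a = sum(pos & !is.na(data$sex)),
        n_b = sum(!pos & !is.na(data$sex)),
        mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_, sd_b = NA_real_,
        normal_a = NA, normal_b = NA
      ))
    }
  }
  out <- mutate(out, significance = sig_stars(.data$p_value), outcome = outcome)
  attr(out, "n_tests") <- nrow(out)
  out
}
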