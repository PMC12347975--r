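coerce_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1), na.rm = TRUE)) {
    return(labels == 1)
  }
  abort("labels must be logical or 0/1, positives oriented as higher-score",
        class = "metinflam_validation_error")
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC over all distinct score thresholds with the
#' higher-score = disease-positive orientation, computes the AUC by the
#' trapezoidal rule (numerically identical to the Mann-Whitney statistic
#' U/(n_pos * n_neg) with ties counted one half), and attaches
#' Hanley-McNeil inference against chance via [auc_inference()].
#'
#' @param scores Numeric index scores; missing pairs are dropped.
#' @param labels Logical (or 0/1) outcome, `TRUE` = disease-positive.
#' @return Object of class `roc_result`: `thresholds` (descending, with a
#'   leading `Inf` sentinel), `tpr`, `fpr`, per-threshold `sensitivity` and
#'   `specificity` (percent), `auc`, `auc_se`, `auc_ci`, `p_vs_chance`,
#'   `n_pos`, `n_neg`.
#' @examples
#' r <- roc_curve(c(1, 2, 3, -1, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' r$auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- coerce_labels(labels)
  keep <- !is.na(scores) & !is.na(labels)
  s <- scores[keep]; y <- labels[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("need at least one positive and one negative with non-missing scores",
          class = "metinflam_degenerate_error")
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(s > t & y), numeric(1))
  fp <- vapply(thr, function(t) sum(s > t & !y), numeric(1))
  # at the lowest observed score everything is non-positive under strict ">";
  # close the curve at (1, 1) by including the all-positive rule
  tpr <- c(tp / n_pos, 1)
  fpr <- c(fp / n_neg, 1)
  thr <- c(thr, -Inf)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  inf <- auc_inference(auc, n_pos, n_neg)
  structure(list(
    thresholds = thr, tpr = tpr, fpr = fpr,
    sensitivity = 100 * tpr, specificity = 100 * (1 - fpr),
    auc = auc, auc_se = inf$se, auc_ci = inf$ci,
    p_vs_chance = inf$p_vs_chance, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' Hanley-McNeil inference for an AUC
#'
#' Standard error of a trapezoidal AUC by the Hanley-McNeil formula with
#' \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, a Wald 95% confidence
#' interval clipped to `[0, 1]`, and a two-sided normal p-value against
#' chance (AUC = 0.5) using the same standard error.
#'
#' @param auc Observed AUC in `[0, 1]`.
#' @param n_pos,n_neg Group sizes (at least 1 each).
#' @return List: `se`, `ci` (length-2), `p_vs_chance`.
#' @examples
#' auc_inference(0.742, 19, 177)
#' @export
auc_inference <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  hm_se <- function(A) {
    Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
    sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
           (n_pos * n_neg))
  }
  se <- hm_se(auc)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  p <- if (se == 0) 0 else 2 * pnorm(-abs(auc - 0.5) / se)
  if (auc == 0.5) p <- 1
  list(se = se, ci = ci, p_vs_chance = p)
}

#' Youden-optimal cutoff
#'
#' Returns the observed score value maximizing the Youden index
#' J = sensitivity + specificity - 100 over all thresholds of an empirical
#' ROC. Ties are broken toward higher sensitivity, then toward the lower
#' threshold; the sentinel thresholds are never returned.
#'
#' @param roc A [roc_curve()] result.
#' @return List: `cutoff` (an observed score), `youden`, `sensitivity`,
#'   `specificity` at the cutoff (percent scale).
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  ok <- is.finite(roc$thresholds)
  thr <- roc$thresholds[ok]
  se <- roc$sensitivity[ok]
  sp <- roc$specificity[ok]
  j <- se + sp - 100
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[se[best] == max(se[best])]
  if (length(best) > 1) best <- best[which.min(thr[best])]
  list(cutoff = thr[best], youden = j[best],
       sensitivity = se[best], specificity = sp[best])
}

#' Diagnostic performance at a fixed cutoff
#'
#' Dichotomizes scores at the cutoff (positive iff score strictly above),
#' builds the 2x2 table against the outcome and derives sensitivity,
#' specificity, predictive values, the Youden index (all percent scale),
#' and the odds ratio with its Woolf logit 95% confidence interval
#' \eqn{\exp(\ln OR \pm 1.96\sqrt{1/tp + 1/fp + 1/fn + 1/tn})} and a
#' Fisher exact p-value. With a zero discordant cell the odds ratio is
#' reported as `+Inf` with a one-sided interval, unless the
#' Haldane-Anscombe 0.5 correction is enabled. Percentages are kept at
#' full precision; round only at the report layer.
#'
#' @inheritParams roc_curve
#' @param cutoff Finite cutoff.
#' @param haldane Apply the 0.5-cell correction for zero cells instead of
#'   reporting an unbounded odds ratio; default `FALSE`.
#' @return One-row tibble: `cutoff`, the cells `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, `odds_ratio`,
#'   `or_lo`, `or_hi`, `or_p`, `n_used`, `degenerate`.
#' @export
performance_at_cutoff <- function(scores, labels, cutoff, haldane = FALSE) {
  stopifnot(length(cutoff) == 1, is.finite(cutoff))
  labels <- coerce_labels(labels)
  keep <- !is.na(scores) & !is.na(labels)
  s <- scores[keep]; y <- labels[keep]
  if (sum(y) == 0 || sum(!y) == 0) {
    abort("need at least one positive and one negative with non-missing scores",
          class = "metinflam_degenerate_error")
  }
  pred <- s > cutoff
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  perf <- performance_from_table(tp, fp, fn, tn, haldane = haldane)
  mutate(perf, cutoff = cutoff, .before = 1)
}

# metrics from an explicit 2x2 table; shared by performance_at_cutoff and
# the report layer
performance_from_table <- function(tp, fp, fn, tn, haldane = FALSE) {
  n <- tp + fp + fn + tn
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  se <- div(tp, tp + fn); sp <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp); npv <- div(tn, tn + fn)
  youden <- se + sp - 100
  degenerate <- (tp + fp == 0) || (fn + tn == 0)

  cells <- c(tp, fp, fn, tn)
  if (any(cells == 0) && haldane) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
  if (a * d == 0 && b * c_ == 0) {
    or <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else if (b * c_ == 0) {
    or <- Inf
    lse <- sqrt(1 / (tp + 0.5) + 1 / (fp + 0.5) + 1 / (fn + 0.5) + 1 / (tn + 0.5))
    lo <- exp(log((tp + 0.5) * (tn + 0.5) / ((fp + 0.5) * (fn + 0.5))) -
                qnorm(0.975) * lse)
    hi <- Inf
  } else if (a * d == 0) {
    or <- 0
    lse <- sqrt(1 / (tp + 0.5) + 1 / (fp + 0.5) + 1 / (fn + 0.5) + 1 / (tn + 0.5))
    lo <- 0
    hi <- exp(log((tp + 0.5) * (tn + 0.5) / ((fp + 0.5) * (fn + 0.5))) +
                qnorm(0.975) * lse)
  } else {
    or <- (a * d) / (b * c_)
    lse <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    lo <- exp(log(or) - qnorm(0.975) * lse)
    hi <- exp(log(or) + qnorm(0.975) * lse)
  }
  or_p <- if (degenerate) NA_real_ else
    fisher.test(matrix(c(tp, fn, fp, tn), nrow = 2))$p.value

  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
         youden = youden, odds_ratio = or, or_lo = lo, or_hi = hi,
         or_p = or_p, n_used = n, degenerate = degenerate)
}

#' Evaluate indices against a severity outcome
#'
#' The report behind the diagnostic-performance tables: for each requested
#' index it builds the ROC against the chosen outcome, reports the AUC
#' with Hanley-McNeil 95% CI and p-value against chance, selects a cutoff
#' (Youden-optimal, the published preset, or user-supplied), and derives
#' the full 2x2 performance at that cutoff. Every row carries the
#' complete-case `n_used` and the units policy in the `units` attribute.
#'
#' @param data Cohort data frame; index columns are computed on the fly
#'   via [compute_indices()] when absent.
#' @param outcome `"histopathological"` or `"surgical"`.
#' @param indices Which indices to evaluate; default all nine.
#' @param cutoff_mode `"youden"` (default), `"published"` (the fixed
#'   published cutoffs for this outcome), or `"user"`.
#' @param user_cutoffs Named numeric vector of cutoffs (required when
#'   `cutoff_mode = "user"`).
#' @param units Units policy forwarded to [compute_indices()].
#' @param haldane Passed to [performance_at_cutoff()].
#' @return Tibble with one row per index: `auc`, `auc_lo`, `auc_hi`,
#'   `auc_p`, `cutoff`, `cutoff_mode`, the 2x2 cells and derived metrics,
#'   `n_pos`, `n_neg`, `n_used`.
#' @export
evaluate_indices <- function(data, outcome = c("histopathological", "surgical"),
                             indices = index_names(),
                             cutoff_mode = c("youden", "published", "user"),
                             user_cutoffs = NULL,
                             units = c("count", "percent"), haldane = FALSE) {
  outcome <- match.arg(outcome)
  cutoff_mode <- match.arg(cutoff_mode)
  units <- match.arg(units)
  bad <- setdiff(indices, index_names())
  if (length(bad) > 0) {
    abort(paste0("unknown index name(s): ", paste(bad, collapse = ", ")),
          class = "metinflam_validation_error")
  }
  if (cutoff_mode == "user" &&
      (is.null(user_cutoffs) || !all(indices %in% names(user_cutoffs)))) {
    abort("cutoff_mode = 'user' needs a named cutoff for every index",
          class = "metinflam_validation_error")
  }
  if (!all(indices %in% names(data))) data <- compute_indices(data, units)
  pos <- outcome_labels(data, outcome)
  preset <- published_cutoffs(outcome)

  rows <- purrr::map(indices, function(ix) {
    sc <- data[[ix]]
    roc <- roc_curve(sc, pos)
    cut <- switch(cutoff_mode,
      youden = youden_optimal_cutoff(roc)$cutoff,
      published = preset$cutoff[preset$index == ix],
      user = unname(user_cutoffs[ix])
    )
    perf <- performance_at_cutoff(sc, pos, cut, haldane = haldane)
    mutate(perf,
           index = ix, outcome = outcome, cutoff_mode = cutoff_mode,
           auc = roc$auc, auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
           auc_p = roc$p_vs_chance, n_pos = roc$n_pos, n_neg = roc$n_neg,
           .before = 1)
  })
  out <- bind_rows(rows)
  attr(out, "units") <- units
  out
}

#' Render p-values the way the source tables print them
#'
#' Values below 5e-4 are shown as `"<=0.0005"`; others are rounded to the
#' given number of digits. Machine output keeps full precision — this is a
#' display helper only.
#'
#' @param p Numeric p-values.
#' @param digits Rounding for displayable values; default 3.
#' @return Character vector.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 5e-4, "<=0.0005", formatC(round(p, digits), format = "g")))
}

#' @describeIn roc_curve Per-threshold tibble (threshold, tpr, fpr,
#'   sensitivity, specificity).
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr,
         sensitivity = x$sensitivity, specificity = x$specificity)
}

#' @describeIn roc_curve One-row summary (auc, se, ci, p, group sizes).
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se, auc_lo = x$auc_ci[1],
         auc_hi = x$auc_ci[2], p_vs_chance = x$p_vs_chance,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn roc_curve ROC curve plot with the chance diagonal.
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$auc_ci[1], object$auc_ci[2]))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (95%% CI %.4f-%.4f), p vs chance = %s; n_pos = %d, n_neg = %d\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], format_p(x$p_vs_chance), x$n_pos, x$n_neg))
  invisible(x)
}
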