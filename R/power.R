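#' Convert an odds ratio to Cohen's d
#'
#' The logistic-to-normal scaling \eqn{d = \ln(OR)\,\sqrt{3}/\pi}: a
#' logistic effect expressed as the standardized mean difference of the
#' latent normal model with matching variance. Negative for OR < 1.
#'
#' @param odds_ratio Positive odds ratio(s).
#' @return Cohen's d, same length as the input.
#' @examples
#' or_to_cohens_d(4.2)
#' @export
or_to_cohens_d <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    abort("odds ratios must be positive and finite",
          class = "metinflam_domain_error")
  }
  log(odds_ratio) * sqrt(3) / pi
}

#' Post-hoc power for a two-group normal-approximation model
#'
#' Achieved power for detecting a standardized effect d between two
#' independent groups at a two-tailed level alpha:
#' \deqn{power = \Phi\!\big(|d|/\sqrt{1/n_1 + 1/n_2} - z_{1-\alpha/2}\big)
#'   + \Phi\!\big(-|d|/\sqrt{1/n_1 + 1/n_2} - z_{1-\alpha/2}\big).}
#' The second (opposite-tail) term is negligible for moderate effects but
#' is included so that d = 0 returns exactly alpha.
#'
#' @param d Cohen's d (vectorized).
#' @param n1,n2 Group sizes, at least 2 each.
#' @param alpha Two-tailed significance level in (0, 1); default 0.05.
#' @return Power in `[alpha, 1]`, same length as `d`.
#' @examples
#' power_two_group(or_to_cohens_d(10.45), 21, 225)
#' @export
power_two_group <- function(d, n1, n2, alpha = 0.05) {
  if (any(n1 < 2) || any(n2 < 2)) {
    abort("group sizes must be at least 2", class = "metinflam_domain_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("alpha must be in (0, 1)", class = "metinflam_domain_error")
  }
  se <- sqrt(1 / n1 + 1 / n2)
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(d) / se - z) + pnorm(-abs(d) / se - z)
}

#' Post-hoc power table from odds ratios and group sizes
#'
#' For each row (index label, odds ratio, group sizes) converts the odds
#' ratio to Cohen's d via [or_to_cohens_d()] and computes the achieved
#' two-tailed power via [power_two_group()]. With the published inputs
#' ([published_power_inputs()]) this reproduces the reported power table;
#' note the printed (rounded) odds ratios are then the inputs, which can
#' move the fifth decimal relative to full-precision ones — `or_source`
#' records which mode produced a report.
#'
#' @param rows Data frame with columns `odds_ratio`, `n1`, `n2` and any
#'   identifier columns (e.g. `index`, `outcome`), such as
#'   [published_power_inputs()] or the output of [evaluate_indices()]
#'   (whose `n_pos`/`n_neg` are taken as `n1`/`n2`).
#' @param alpha Two-tailed level; default 0.05.
#' @param or_source Label recorded in the output: `"as_published"`
#'   (rounded printed ORs) or `"full_precision"` (ORs computed from data).
#' @return The input tibble with `cohens_d`, `power` and `power_rounded`
#'   (3 decimals) appended; empty input gives an empty report.
#' @examples
#' power_table(published_power_inputs())
#' @export
power_table <- function(rows, alpha = 0.05,
                        or_source = c("as_published", "full_precision")) {
  or_source <- match.arg(or_source)
  rows <- as_tibble(rows)
  if (!"n1" %in% names(rows) && "n_pos" %in% names(rows)) {
    rows <- rename(rows, n1 = "n_pos", n2 = "n_neg")
  }
  if (nrow(rows) == 0) {
    return(mutate(rows, cohens_d = numeric(0), power = numeric(0),
                  power_rounded = numeric(0)))
  }
  stopifnot(all(c("odds_ratio", "n1", "n2") %in% names(rows)))
  bad <- which(!is.finite(rows$odds_ratio) | rows$odds_ratio <= 0)
  if (length(bad) > 0) {
    lab <- if ("index" %in% names(rows)) rows$index[bad] else as.character(bad)
    abort(paste0("invalid odds ratio in row(s): ", paste(lab, collapse = ", ")),
          class = "metinflam_domain_error")
  }
  out <- mutate(rows,
    cohens_d = or_to_cohens_d(.data$odds_ratio),
    power = power_two_group(.data$cohens_d, .data$n1, .data$n2, alpha = alpha),
    power_rounded = round(.data$power, 3)
  )
  attr(out, "or_source") <- or_source
  attr(out, "alpha") <- alpha
  out
}
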