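#' Variables of the published best candidate model
#'
#' The eight routine labs of the best-performing candidate variable set for
#' factor analysis: coagulation times (prothrombin time, INR, aPTT),
#' renal-metabolic chemistry (urea, serum creatinine, glucose) and the
#' differential (neutrophils, lymphocytes). Under the package's default
#' absolute-count units policy the differential enters as
#' `neutrophil_count` / `lymphocyte_count`.
#'
#' @return Character vector of eight column names.
#' @export
model3_variables <- function() {
  c("prothrombin_time", "inr", "aptt", "urea", "serum_creatinine",
    "neutrophil_count", "lymphocyte_count", "glucose")
}

check_correlation <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || nrow(R) < 3) {
    abort("correlation matrix must be square with at least 3 variables",
          class = "metinflam_validation_error")
  }
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8 ||
      max(abs(R)) > 1 + 1e-8) {
    abort("not a correlation matrix (symmetric, unit diagonal, entries in [-1, 1])",
          class = "metinflam_validation_error")
  }
  if (is.null(rownames(R))) {
    rownames(R) <- colnames(R) <- paste0("V", seq_len(nrow(R)))
  }
  (R + t(R)) / 2
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Computes the KMO statistic from a correlation matrix: the anti-image
#' partial correlations are obtained from the matrix inverse as
#' \eqn{p_{ij} = -s_{ij} / \sqrt{s_{ii} s_{jj}}} (with \eqn{S = R^{-1}}),
#' and the overall measure is the ratio of summed squared correlations to
#' summed squared correlations plus summed squared partials over all
#' off-diagonal pairs. The per-variable measure restricts both sums to row
#' i. Values above 0.6 are conventionally deemed adequate for factor
#' analysis.
#'
#' @param correlation Positive-definite correlation matrix of at least 3
#'   variables.
#' @return List with `overall` (scalar in (0, 1]) and `per_variable`
#'   (named vector).
#' @examples
#' R <- matrix(0.7, 4, 4); diag(R) <- 1
#' kmo(R)$overall
#' @export
kmo <- function(correlation) {
  R <- check_correlation(correlation)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    # name the (near-)collinear variables via the smallest eigenvector
    v <- eigen(R, symmetric = TRUE)$vectors[, nrow(R)]
    culprits <- rownames(R)[abs(v) > 0.3]
    abort(paste0("correlation matrix is singular or nearly so; collinear variables: ",
                 paste(culprits, collapse = ", ")),
          class = "metinflam_rank_error")
  }
  S <- solve(R)
  P <- -S / sqrt(outer(diag(S), diag(S)))
  diag(P) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; p2 <- P^2
  overall <- sum(r2) / (sum(r2) + sum(p2))
  per_var <- rowSums(r2) / (rowSums(r2) + rowSums(p2))
  list(overall = overall, per_variable = stats::setNames(per_var, rownames(R)))
}

#' Principal-component factor extraction
#'
#' Extracts components from a correlation matrix by eigendecomposition.
#' Components are retained by the Kaiser rule (eigenvalue >= 1) unless a
#' fixed number is requested; loadings are the eigenvectors scaled by the
#' square root of their eigenvalues, optionally varimax-rotated, and each
#' component is signed so its largest-magnitude loading is positive.
#' Component membership assigns each variable to the component on which it
#' has the largest absolute loading.
#'
#' @param correlation Correlation matrix (see [kmo()] for requirements), or
#'   use [fit_factor_model()] to go straight from data.
#' @param n_components Fixed number of components; default `NULL` applies
#'   the eigenvalue >= 1 rule.
#' @param rotate `"none"` (default) or `"varimax"`.
#' @return Object of class `factor_model`: variables, correlation, KMO
#'   measures, eigenvalues, loadings, per-component and cumulative %
#'   variance explained, and `membership`.
#' @export
extract_factors <- function(correlation, n_components = NULL,
                            rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  R <- check_correlation(correlation)
  p <- nrow(R)
  km <- kmo(R)
  eg <- eigen(R, symmetric = TRUE)
  if (is.null(n_components)) n_components <- sum(eg$values >= 1)
  if (n_components < 1) {
    abort("retention policy keeps 0 components", class = "metinflam_validation_error")
  }
  k <- min(n_components, p)
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  if (rotate == "varimax" && k > 1) {
    L <- unclass(stats::varimax(L, normalize = TRUE)$loadings)
    # keep components ordered by explained variance after rotation
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
  }
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, flip, `*`)
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("C", seq_len(k))
  var_expl <- colSums(L^2) / p * 100
  membership <- stats::setNames(colnames(L)[apply(abs(L), 1, which.max)], rownames(R))
  structure(list(
    variables = rownames(R), correlation = R,
    kmo_overall = km$overall, kmo_per_variable = km$per_variable,
    eigenvalues = eg$values, loadings = L, rotation = rotate,
    n_components = k, variance_explained = var_expl,
    cumulative_variance = cumsum(var_expl), membership = membership
  ), class = "factor_model")
}

#' Fit a factor model on cohort data
#'
#' Convenience wrapper: Pearson correlation on the complete cases of the
#' chosen variables (listwise deletion), then [extract_factors()].
#'
#' @param data Cohort data frame.
#' @param variables Columns to analyse; default [model3_variables()].
#' @inheritParams extract_factors
#' @return A `factor_model`; the complete-case count is stored as `n_used`.
#' @export
fit_factor_model <- function(data, variables = model3_variables(),
                             n_components = NULL,
                             rotate = c("none", "varimax")) {
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("variables not in data: ", paste(missing_vars, collapse = ", ")),
          class = "metinflam_validation_error")
  }
  X <- as.data.frame(data)[, variables, drop = FALSE]
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < length(variables) + 2) {
    abort("too few complete cases for the candidate variable set",
          class = "metinflam_degenerate_error")
  }
  R <- cor(as.matrix(X))
  fm <- extract_factors(R, n_components = n_components, rotate = rotate)
  fm$n_used <- nrow(X)
  fm
}

#' Select the best candidate variable set by KMO
#'
#' Fits each candidate variable set on each subgroup's complete cases,
#' ranks candidates by overall KMO, discards those at or below the
#' adequacy threshold, and returns the argmax per subgroup (ties broken by
#' first-listed candidate). Subgroups with no adequate candidate get an
#' explicit "no adequate model" outcome rather than a silent drop.
#'
#' @param data Cohort data frame.
#' @param candidates Named list of character vectors (candidate variable
#'   sets); a single unnamed vector is also accepted.
#' @param subgroup Optional column name to stratify by (e.g.
#'   `"surgical_stage"`); `NULL` fits on the whole cohort.
#' @param threshold KMO adequacy threshold; default 0.6.
#' @param rotate Passed to [extract_factors()].
#' @return List with `summary` (tibble: subgroup, candidate, kmo, adequate,
#'   selected) and `best` (named list of `factor_model` or `NULL` per
#'   subgroup).
#' @export
select_model <- function(data, candidates, subgroup = NULL, threshold = 0.6,
                         rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  if (!is.list(candidates)) candidates <- list(candidates)
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  groups <- if (is.null(subgroup)) {
    list(all = data)
  } else {
    split(data, as.factor(data[[subgroup]]))
  }
  summary_rows <- list()
  best <- stats::setNames(vector("list", length(groups)), names(groups))
  for (gname in names(groups)) {
    fits <- purrr::map(candidates, function(vars) {
      tryCatch(fit_factor_model(groups[[gname]], vars, rotate = rotate),
               error = function(e) NULL)
    })
    kmos <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$kmo_overall,
                   numeric(1))
    adequate <- !is.na(kmos) & kmos > threshold
    sel <- if (any(adequate)) which(adequate)[which.max(kmos[adequate])] else NA_integer_
    summary_rows[[gname]] <- tibble(
      subgroup = gname, candidate = names(candidates), kmo = unname(kmos),
      adequate = unname(adequate),
      selected = if (is.na(sel)) rep(FALSE, length(candidates))
                 else seq_along(candidates) == sel
    )
    if (!is.na(sel)) best[[gname]] <- fits[[sel]]
  }
  out <- list(summary = bind_rows(summary_rows), best = best,
              threshold = threshold)
  class(out) <- "model_selection"
  out
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d variables, %d component(s), rotation = %s\n",
              length(x$variables), x$n_components, x$rotation))
  cat(sprintf("  overall KMO %.3f; cumulative variance %.1f%%\n",
              x$kmo_overall, x$cumulative_variance[x$n_components]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' @describeIn extract_factors Loadings in long form (one row per variable
#'   x component) with the membership flag.
#' @param x A `factor_model`.
#' @param ... Unused.
#' @export
tidy.factor_model <- function(x, ...) {
  L <- x$loadings
  out <- as_tibble(as.data.frame.table(L, stringsAsFactors = FALSE))
  names(out) <- c("variable", "component", "loading")
  out$member <- x$membership[out$variable] == out$component
  out
}

#' @describeIn extract_factors One-row model summary (KMO, components,
#'   cumulative variance explained).
#' @export
glance.factor_model <- function(x, ...) {
  tibble(
    kmo = x$kmo_overall, n_components = x$n_components,
    cumulative_variance = x$cumulative_variance[x$n_components],
    n_variables = length(x$variables),
    n_used = x$n_used %||% NA_integer_, rotation = x$rotation
  )
}

#' @describeIn extract_factors Loading heatmap (variables x components).
#' @param object A `factor_model`.
#' @export
autoplot.factor_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "component", y = NULL, fill = "loading",
                  title = sprintf("Loadings (KMO = %.3f)", object$kmo_overall))
}
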