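# hand-derived KMO for a two-block 4x4 correlation matrix (within-block
# r = 0.8, across-block 0): the inverse is block-diagonal with 2x2 blocks
# (1/(1-r^2)) * [[1, -r], [-r, 1]], so every within-pair partial equals r
# and the squared sums cancel to give KMO = 0.5 overall and per variable.
two_block_r <- function(r = 0.8) {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- r
  R[3, 4] <- R[4, 3] <- r
  dimnames(R) <- list(letters[1:4], letters[1:4])
  R
}

test_that("KMO matches the hand-computed value on the 4x4 block matrix", {
  km <- kmo(two_block_r())
  expect_equal(km$overall, 0.5, tolerance = 1e-12)
  expect_equal(unname(km$per_variable), rep(0.5, 4), tolerance = 1e-12)
})

test_that("KMO approaches 0.5 in the small-correlation limit", {
  withr::with_seed(3, {
    E <- matrix(rnorm(7 * 7, sd = 0.01), 7, 7)
  })
  R <- diag(7) + (E + t(E)) / 2
  diag(R) <- 1
  km <- kmo(R)
  # with vanishing correlations, partials converge to the raw correlations
  S <- solve(R)
  P <- -S / sqrt(outer(diag(S), diag(S)))
  diag(P) <- 0
  off <- upper.tri(R)
  expect_lt(max(abs(P[off] - R[off])), 0.002)
  expect_equal(km$overall, 0.5, tolerance = 0.01)
})

test_that("strong single-factor data has KMO above the adequacy gate", {
  R <- matrix(0.7, 6, 6); diag(R) <- 1
  expect_gt(kmo(R)$overall, 0.6)
})

test_that("KMO is invariant to variable reordering and sign flips", {
  co <- generate_cohort(cohort_config(seed = 2))
  R <- cor(as.matrix(co[, model3_variables()]))
  base <- kmo(R)$overall
  perm <- sample(nrow(R))
  expect_equal(kmo(R[perm, perm])$overall, base, tolerance = 1e-12)
  s <- diag(c(-1, 1, -1, 1, 1, -1, 1, 1))
  Rs <- s %*% R %*% s
  dimnames(Rs) <- dimnames(R)
  expect_equal(kmo(Rs)$overall, base, tolerance = 1e-12)
})

test_that("singular correlation matrices name the collinear variables", {
  R <- matrix(0.5, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- 1  # variable 'b' duplicates 'a'
  dimnames(R) <- list(letters[1:4], letters[1:4])
  expect_error(kmo(R), "a, b", class = "metinflam_rank_error")
})

test_that("identity correlation yields unit eigenvalues and equal shares", {
  fm <- extract_factors(diag(8))
  expect_equal(fm$eigenvalues, rep(1, 8))
  expect_equal(fm$n_components, 8)
  expect_equal(fm$variance_explained, rep(100 / 8, 8),
               ignore_attr = TRUE)
  expect_equal(max(fm$cumulative_variance), 100, tolerance = 1e-9)
})

test_that("eigenvalues conserve the trace and cumulative variance is monotone", {
  co <- generate_cohort(cohort_config(seed = 19))
  fm <- fit_factor_model(co)
  expect_equal(sum(fm$eigenvalues), length(fm$variables), tolerance = 1e-9)
  expect_true(all(diff(fm$cumulative_variance) >= -1e-12))
  expect_lte(max(fm$cumulative_variance), 100 + 1e-9)
  # each component's largest-magnitude loading is signed positive
  for (k in seq_len(fm$n_components)) {
    col <- fm$loadings[, k]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("a dominant single factor absorbs the variance as noise vanishes", {
  shares <- sapply(c(0.5, 0.1, 0.01), function(noise) {
    # rank-1 all-ones structure plus isotropic noise
    R <- (1 - noise) * matrix(1, 6, 6)
    diag(R) <- 1
    fm <- extract_factors(R, n_components = 1)
    fm$variance_explained[1]
  })
  expect_true(all(diff(shares) > 0))
  expect_gt(shares[3], 99)
})

test_that("varimax rotation recovers planted block structure", {
  co <- generate_cohort(cohort_config(n = 1000, separation = 0), seed = 77)
  fm <- fit_factor_model(co, rotate = "varimax")
  expect_equal(fm$n_components, 3)
  expect_true(memberships_match_blocks(fm$membership))
  expect_gt(fm$kmo_overall, 0.6)
})

test_that("model selection picks the structured candidate and honors the gate", {
  co <- generate_cohort(cohort_config(seed = 23, separation = 0))
  noise_vars <- c("sodium", "potassium", "magnesium", "calcium")
  sel <- select_model(co, list(structured = model3_variables(),
                               noise = noise_vars))
  expect_true(sel$summary$selected[sel$summary$candidate == "structured"])
  expect_gt(sel$summary$kmo[sel$summary$candidate == "structured"],
            sel$summary$kmo[sel$summary$candidate == "noise"])
  # impossible threshold leaves an explicit no-adequate-model outcome
  sel2 <- select_model(co, list(structured = model3_variables()),
                       threshold = 1.1)
  expect_false(any(sel2$summary$selected))
  expect_null(sel2$best$all)
  # single adequate candidate is selected
  sel3 <- select_model(co, list(only = model3_variables()), threshold = 0.3)
  expect_true(sel3$summary$selected)
  expect_s3_class(sel3$best$all, "factor_model")
})

test_that("stratified fitting reports one candidate row per subgroup", {
  co <- generate_cohort(cohort_config(seed = 29))
  sel <- select_model(co, list(m3 = model3_variables()),
                      subgroup = "surgical_stage", rotate = "varimax")
  expect_setequal(unique(sel$summary$subgroup), c("I", "II", "III", "IV"))
  # stage I has only 4 patients: too few complete cases, KMO must be NA
  expect_true(is.na(sel$summary$kmo[sel$summary$subgroup == "I"]))
  expect_gt(max(sel$summary$kmo, na.rm = TRUE), 0.6)
})

test_that("factor model tidiers expose loadings and fit summary", {
  co <- generate_cohort(cohort_config(seed = 41))
  fm <- fit_factor_model(co, rotate = "varimax")
  td <- generics::tidy(fm)
  expect_equal(nrow(td), length(fm$variables) * fm$n_components)
  expect_true(all(c("variable", "component", "loading", "member") %in% names(td)))
  gl <- generics::glance(fm)
  expect_equal(gl$kmo, fm$kmo_overall)
  expect_equal(gl$n_used, fm$n_used)
  p <- ggplot2::autoplot(fm)
  expect_s3_class(p, "ggplot")
})
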