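test_that("perfect separation gives AUC 1 and chance labels give AUC near 0.5", {
  r <- roc_curve(c(1, 2, 3, -1, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  withr::with_seed(8, {
    s <- rnorm(4000)
    y <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  })
  expect_lt(abs(roc_curve(s, y)$auc - 0.5), 0.03)
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  withr::with_seed(17, {
    for (i in 1:500) {
      n <- sample(6:64, 1)
      s <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
      y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      r <- roc_curve(s, y)
      expect_equal(r$auc, pairwise_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(23, {
    s <- rnorm(300)
    y <- runif(300) < plogis(s)
  })
  if (sum(y) == 0 || sum(!y) == 0) skip("degenerate draw")
  base <- roc_curve(s, y)$auc
  expect_equal(roc_curve(exp(s), y)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(atan(s), y)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(5 * s + 2, y)$auc, base, tolerance = 1e-12)
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- round(rnorm(60), 1)
      y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
      if (sum(y) == 0 || sum(!y) == 0) next
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-10)
    }
  })
})

test_that("single-class input is rejected", {
  expect_error(roc_curve(1:5, rep(TRUE, 5)),
               class = "metinflam_degenerate_error")
  expect_error(roc_curve(c(1, 2, NA), c(TRUE, TRUE, FALSE)),
               class = "metinflam_degenerate_error")
})

test_that("Hanley-McNeil inference behaves at the null and the reported case", {
  null <- auc_inference(0.5, 20, 20)
  expect_equal(null$p_vs_chance, 1)
  # the reported strongest index: AUC 0.742 with 19 perforated complete cases
  rep_case <- auc_inference(0.742, 19, 177)
  expect_lte(rep_case$p_vs_chance, 0.0005)
  expect_true(rep_case$ci[1] > 0.5)
  ci_clip <- auc_inference(0.99, 3, 5)
  expect_lte(ci_clip$ci[2], 1)
})

test_that("Hanley-McNeil SE tracks a bootstrap SE on a simulated instance", {
  withr::with_seed(47, {
    s <- c(rnorm(25, 1), rnorm(40))
    y <- rep(c(TRUE, FALSE), c(25, 40))
    r <- roc_curve(s, y)
    boots <- replicate(10000, {
      sp <- sample(s[y], replace = TRUE)
      sn <- sample(s[!y], replace = TRUE)
      r1 <- rank(c(sp, sn))
      (sum(r1[1:25]) - 25 * 26 / 2) / (25 * 40)
    })
  })
  expect_lt(abs(r$auc_se - sd(boots)) / sd(boots), 0.15)
})

test_that("Youden-optimal cutoff matches an exhaustive scan", {
  withr::with_seed(59, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      s <- round(rnorm(n, mean = ifelse(runif(n) < 0.4, 0.8, 0)), 1)
      y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      r <- roc_curve(s, y)
      opt <- youden_optimal_cutoff(r)
      # independent scan over every observed score value
      scan <- sapply(sort(unique(s)), function(t) {
        se <- 100 * sum(s > t & y) / sum(y)
        sp <- 100 * sum(s <= t & !y) / sum(!y)
        se + sp - 100
      })
      expect_equal(opt$youden, max(scan), tolerance = 1e-12)
      expect_gte(opt$youden,
                 100 * sum(s > opt$cutoff & y) / sum(y) +
                   100 * sum(s <= opt$cutoff & !y) / sum(!y) - 100 - 1e-12)
    }
  })
})

test_that("perfectly separated groups reach J = 100 at an observed score", {
  r <- roc_curve(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  opt <- youden_optimal_cutoff(r)
  expect_equal(opt$youden, 100)
  expect_true(opt$cutoff %in% c(5, 6, 7, 1, 2))
  expect_equal(opt$cutoff, 2)  # lower-threshold tie-break at max sensitivity
})

test_that("label inversion with score negation preserves the optimal J", {
  withr::with_seed(61, {
    s <- round(rnorm(80), 1)
    y <- runif(80) < plogis(2 * s)
  })
  if (sum(y) == 0 || sum(!y) == 0) skip("degenerate draw")
  j1 <- youden_optimal_cutoff(roc_curve(s, y))$youden
  j2 <- youden_optimal_cutoff(roc_curve(-s, !y))$youden
  expect_equal(j1, j2, tolerance = 1e-9)
})

test_that("cutoff performance reproduces the 2x2 arithmetic exactly", {
  # constructed table: 18/19 sensitivity matches the printed granularity
  s <- c(rep(1, 18), 0, rep(1, 120), rep(0, 57))
  y <- rep(c(TRUE, FALSE), c(19, 177))
  perf <- performance_at_cutoff(s, y, 0.5)
  expect_equal(perf$tp, 18); expect_equal(perf$fn, 1)
  expect_equal(perf$fp, 120); expect_equal(perf$tn, 57)
  expect_equal(perf$sensitivity, 100 * 18 / 19)
  expect_equal(round(perf$sensitivity, 2), 94.74)
  expect_equal(perf$specificity, 100 * 57 / 177)
  expect_equal(perf$ppv, 100 * 18 / 138)
  expect_equal(perf$npv, 100 * 57 / 58)
  expect_equal(perf$youden, perf$sensitivity + perf$specificity - 100)
  expect_equal(perf$odds_ratio, (18 * 57) / (120 * 1))
  expect_equal(perf$n_used, 196)
})

test_that("published Youden rows are consistent with printed Se and Sp", {
  expect_equal(68.42 + 72.38 - 100, 40.8, tolerance = 1e-9)
})

test_that("degenerate dichotomization is flagged, not silently scored", {
  s <- rep(0, 10)
  y <- rep(c(TRUE, FALSE), 5)
  perf <- performance_at_cutoff(s, y, 1)  # everything classified negative
  expect_equal(perf$sensitivity, 0)
  expect_equal(perf$specificity, 100)
  expect_true(is.na(perf$odds_ratio))
  expect_true(perf$degenerate)
})

test_that("zero discordant cells give an unbounded OR unless corrected", {
  s <- c(rep(2, 10), rep(0, 10))
  y <- rep(c(TRUE, FALSE), c(10, 10))
  perf <- performance_at_cutoff(s, y, 1)
  expect_equal(perf$odds_ratio, Inf)
  expect_true(is.finite(perf$or_lo) && perf$or_lo > 0)
  expect_equal(perf$or_hi, Inf)
  corrected <- performance_at_cutoff(s, y, 1, haldane = TRUE)
  expect_true(is.finite(corrected$odds_ratio))
  expect_equal(corrected$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("OR exceeds 1 exactly when tp*tn exceeds fp*fn", {
  withr::with_seed(71, {
    for (i in 1:60) {
      cells <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))
      perf <- metinflam:::performance_from_table(cells[1], cells[2],
                                                 cells[3], cells[4])
      if (is.na(perf$odds_ratio) || !is.finite(perf$odds_ratio)) next
      expect_equal(perf$odds_ratio > 1,
                   cells[1] * cells[4] > cells[2] * cells[3])
    }
  })
})

test_that("Woolf CI and Fisher p agree with the standard implementations", {
  perf <- metinflam:::performance_from_table(20, 15, 10, 40)
  lse <- sqrt(1 / 20 + 1 / 15 + 1 / 10 + 1 / 40)
  expect_equal(perf$or_lo, exp(log(perf$odds_ratio) - qnorm(0.975) * lse))
  expect_equal(perf$or_hi, exp(log(perf$odds_ratio) + qnorm(0.975) * lse))
  ref <- fisher.test(matrix(c(20, 10, 15, 40), 2))$p.value
  expect_equal(perf$or_p, ref)
})

test_that("index evaluation reports a full table row per index", {
  co <- generate_cohort(cohort_config(seed = 3))
  ev <- evaluate_indices(co, "histopathological")
  expect_equal(nrow(ev), 9)
  expect_setequal(ev$index, index_names())
  expect_true(all(ev$n_used <= nrow(co)))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(ev$youden, ev$sensitivity + ev$specificity - 100)
  expect_identical(attr(ev, "units"), "count")
  # published-cutoff mode uses exactly the preset values
  ev2 <- evaluate_indices(co, "surgical", indices = c("imi", "misi"),
                          cutoff_mode = "published")
  expect_equal(ev2$cutoff, c(987.83, 54.81))
  expect_error(evaluate_indices(co, "histopathological", indices = "nope"),
               class = "metinflam_validation_error")
  expect_error(evaluate_indices(co, "histopathological", cutoff_mode = "user"),
               class = "metinflam_validation_error")
})

test_that("roc tidiers and plots expose the stored curve", {
  co <- generate_cohort(cohort_config(seed = 3))
  sc <- compute_indices(co)
  r <- roc_curve(sc$misi, co$perforated)
  td <- generics::tidy(r)
  expect_equal(nrow(td), length(r$thresholds))
  # stored curve integrates back to the stored AUC
  auc <- sum(diff(td$fpr) * (head(td$tpr, -1) + td$tpr[-1]) / 2)
  expect_equal(auc, r$auc, tolerance = 1e-12)
  expect_true(all(diff(td$tpr) >= 0) && all(diff(td$fpr) >= 0))
  gl <- generics::glance(r)
  expect_equal(gl$auc, r$auc)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})

test_that("p-value formatting mirrors the report style", {
  expect_equal(format_p(c(0.0001, 0.012, NA)),
               c("<=0.0005", "0.012", NA))
})
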