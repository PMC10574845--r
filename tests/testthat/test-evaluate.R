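test_that("regression metrics match hand-computed values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$rmse, m$mae, m$me), c(0, 0, 0))
  expect_equal(m$r, 1)
  m2 <- regression_metrics(c(1, 2, 3) + 2, c(1, 2, 3))
  expect_equal(c(m2$rmse, m2$mae, m2$me), c(2, 2, 2))
  m3 <- regression_metrics(c(1, 2, 4), c(1, 2, 3))
  expect_equal(m3$me, 1 / 3)
  expect_equal(m3$mae, 1 / 3)
  expect_equal(m3$rmse, 1 / sqrt(3))
  # identity rmse^2 = me^2 + std^2 (n-1)/n
  set.seed(1)
  m4 <- regression_metrics(rnorm(100, 1), rnorm(100))
  expect_equal(m4$rmse^2, m4$me^2 + m4$std^2 * 99 / 100, tolerance = 1e-9)
  expect_error(regression_metrics(rep(1, 5), 1:5), "zero-variance")
  expect_error(regression_metrics(1, 1), "at least 2")
})

test_that("mean arterial pressure follows (SBP + 2 DBP)/3", {
  expect_equal(mean_arterial_pressure(120, 60), 80)
  expect_equal(mean_arterial_pressure(180, 110), 400 / 3, tolerance = 1e-9)
  expect_equal(mean_arterial_pressure(100, 100 - 1e-9), 100, tolerance = 1e-6)
  expect_error(mean_arterial_pressure(80, 90), "exceed")
})

test_that("the AAMI verdict uses inclusive 5/8 mmHg bounds", {
  expect_true(aami_check(0.020, 5.67)$pass)
  r <- aami_check(5.01, 7)
  expect_false(r$pass)
  expect_false(r$me_ok)
  expect_true(r$std_ok)
  expect_true(aami_check(0, 8.0)$pass)
  expect_true(aami_check(-5, 8)$pass)
})

test_that("BHS grading follows the cumulative-percentage table", {
  expect_identical(bhs_grade(percentages = c(80.96, 92.91, 96.73))$grade, "A")
  expect_identical(bhs_grade(percentages = c(59.9, 99, 99))$grade, "B")
  expect_identical(bhs_grade(percentages = c(10, 20, 30))$grade, "D")
  # exact boundary: all three thresholds met
  expect_identical(bhs_grade(percentages = c(60, 85, 95))$grade, "A")
  expect_identical(bhs_grade(percentages = c(60, 84.9, 95))$grade, "B")
})

test_that("BHS and AAMI agree with brute-force recomputation", {
  set.seed(2)
  for (trial in 1:100) {
    err <- rnorm(200, sd = runif(1, 2, 12))
    g <- bhs_grade(err)
    pct <- 100 * c(mean(abs(err) <= 5), mean(abs(err) <= 10),
                   mean(abs(err) <= 15))
    expect_equal(c(g$pct_le_5, g$pct_le_10, g$pct_le_15), pct)
    grade_bf <- if (pct[1] >= 60 && pct[2] >= 85 && pct[3] >= 95) "A"
      else if (pct[1] >= 50 && pct[2] >= 75 && pct[3] >= 90) "B"
      else if (pct[1] >= 40 && pct[2] >= 65 && pct[3] >= 85) "C" else "D"
    expect_identical(g$grade, grade_bf)
    a <- aami_check(mean(err), stats::sd(err))
    expect_identical(a$pass, abs(mean(err)) <= 5 && stats::sd(err) <= 8)
  }
})

test_that("shrinking all errors never worsens the BHS grade", {
  set.seed(3)
  ord <- c(D = 0, C = 1, B = 2, A = 3)
  for (trial in 1:20) {
    err <- rnorm(100, sd = runif(1, 3, 14))
    g1 <- ord[bhs_grade(err)$grade]
    g2 <- ord[bhs_grade(err * 0.6)$grade]
    expect_gte(g2, g1)
  }
})

test_that("guideline classification handles the printed examples", {
  expect_identical(as.character(classify_esh_esc(118, 78)), "Optimal")
  expect_identical(as.character(classify_esh_esc(150, 85)),
                   "Isolated Systolic Hypertension")
  expect_identical(as.character(classify_esh_esc(135, 95)),
                   "Grade 1 Hypertension")
  expect_identical(as.character(classify_esh_esc(125, 82)), "Normal")
  expect_identical(as.character(classify_esh_esc(132, 70)), "High Normal")
  expect_identical(as.character(classify_esh_esc(165, 102)),
                   "Grade 2 Hypertension")
  expect_identical(as.character(classify_esh_esc(120, 115)),
                   "Grade 3 Hypertension")
  expect_error(classify_esh_esc(-1, 80), "positive")
})

test_that("confusion summaries reduce to hand-computed one-vs-rest values", {
  truth <- classify_esh_esc(c(118, 118, 150, 150), c(78, 78, 85, 85))
  pred <- classify_esh_esc(c(118, 150, 150, 118), c(78, 85, 85, 78))
  cs <- confusion_summary(truth, pred)
  opt <- cs$per_class[cs$per_class$class == "Optimal", ]
  # TP=1 FN=1 FP=1 TN=1 on the 2x2 degenerate table
  expect_equal(opt$accuracy, 50)
  expect_equal(opt$sensitivity, 50)
  expect_equal(opt$specificity, 50)
  expect_equal(opt$f1, 50)
  expect_equal(opt$prevalence, 50)
  expect_true(all(is.na(
    cs$per_class$sensitivity[cs$per_class$class == "Normal"])))
  perfect <- confusion_summary(truth, truth)
  pc <- perfect$per_class[perfect$per_class$prevalence > 0, ]
  expect_true(all(pc$accuracy == 100 & pc$sensitivity == 100 &
                    pc$specificity == 100 & pc$f1 == 100))
})

test_that("weighted averages equal direct prevalence-weighted sums", {
  set.seed(4)
  sbp_t <- runif(300, 90, 190)
  dbp_t <- pmin(runif(300, 55, 115), sbp_t - 10)
  sbp_p <- sbp_t + rnorm(300, 0, 8)
  dbp_p <- pmin(dbp_t + rnorm(300, 0, 5), sbp_p - 1)
  cs <- confusion_summary(classify_esh_esc(sbp_t, dbp_t),
                          classify_esh_esc(pmax(sbp_p, 1), pmax(dbp_p, 1)))
  pc <- cs$per_class
  for (mname in c("accuracy", "sensitivity", "specificity", "f1")) {
    ok <- is.finite(pc[[mname]])
    expect_equal(unname(cs$weighted[[mname]]),
                 sum(pc[[mname]][ok] * pc$prevalence[ok] / 100),
                 tolerance = 1e-9)
  }
})

test_that("Bland-Altman limits follow bias +/- 1.96 SD", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high, ba$pct_outside),
               c(0, 0, 0, 0))
  set.seed(5)
  d <- rnorm(5000, 1, 4)
  ba2 <- bland_altman(d, rep(0, 5000))
  expect_equal(ba2$loa_low, ba2$bias - 1.96 * ba2$sd_diff)
  expect_equal(ba2$loa_high, ba2$bias + 1.96 * ba2$sd_diff)
})

test_that("the composite evaluation report is internally consistent", {
  set.seed(6)
  n <- 400
  sbp_t <- runif(n, 90, 175)
  dbp_t <- pmin(runif(n, 60, 105), sbp_t - 15)
  sbp_p <- sbp_t + rnorm(n, 0, 4)
  dbp_p <- pmin(dbp_t + rnorm(n, 0, 3), sbp_p - 1)
  rep <- bp_evaluation_report(sbp_p, sbp_t, dbp_p, dbp_t)
  expect_equal(rep$sbp$metrics$me, mean(sbp_p - sbp_t), tolerance = 1e-9)
  expect_identical(rep$sbp$aami$pass,
                   abs(rep$sbp$metrics$me) <= 5 && rep$sbp$metrics$std <= 8)
  expect_equal(sum(rep$esh_esc$confusion), n)
})
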