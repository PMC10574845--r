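# Clinical evaluation of blood-pressure estimators: regression metrics,
# AAMI and BHS protocol checks, ESH/ESC seven-class hypertension
# classification with confusion summaries, and Bland-Altman agreement.

#' Regression error metrics for blood-pressure prediction
#'
#' Errors are defined as `pred - true`. `std` is the sample standard
#' deviation of the errors (n-1 denominator), so
#' `rmse^2 = me^2 + std^2 * (n-1)/n`.
#'
#' @param pred,true Equal-length finite numeric vectors, `n >= 2`.
#' @return Object of class `bp_metrics`: list with `rmse`, `mae`, `r`
#'   (Pearson correlation of `pred` and `true`), `me`, `std`, `n`.
#' @export
regression_metrics <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true must have equal length")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (!all(is.finite(pred)) || !all(is.finite(true))) stop("inputs must be finite")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  err <- pred - true
  structure(
    list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
         r = stats::cor(pred, true), me = mean(err), std = stats::sd(err),
         n = length(err)),
    class = "bp_metrics"
  )
}

#' @export
print.bp_metrics <- function(x, ...) {
  cat(sprintf("BP regression metrics (n = %d)\n", x$n))
  cat(sprintf("  RMSE %.3f  MAE %.3f  R %.3f  ME %+.3f  SD %.3f (mmHg)\n",
              x$rmse, x$mae, x$r, x$me, x$std))
  invisible(x)
}

#' Mean arterial pressure
#'
#' `MAP = (SBP + 2 DBP) / 3`, the standard single-cycle average pressure.
#'
#' @param sbp,dbp Systolic and diastolic pressures in mmHg (vectorized).
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) stop("pressures must be finite")
  if (any(sbp <= dbp)) stop("SBP must exceed DBP")
  (sbp + 2 * dbp) / 3
}

#' AAMI protocol verdict
#'
#' A device passes when the mean error does not exceed 5 mmHg in magnitude
#' and the error standard deviation does not exceed 8 mmHg (bounds
#' inclusive).
#'
#' @param me Mean error in mmHg, or a `bp_metrics` object (then `std` is
#'   taken from it).
#' @param std Error standard deviation in mmHg.
#' @return List with `me_ok`, `std_ok`, `pass`.
#' @export
aami_check <- function(me, std = NULL) {
  if (inherits(me, "bp_metrics")) {
    std <- me$std
    me <- me$me
  }
  me_ok <- abs(me) <= 5
  std_ok <- std <= 8
  list(me_ok = me_ok, std_ok = std_ok, pass = me_ok && std_ok)
}

.bhs_rows <- data.frame(
  grade = c("A", "B", "C"),
  p5 = c(60, 50, 40), p10 = c(85, 75, 65), p15 = c(95, 90, 85)
)

#' BHS grading of absolute errors
#'
#' Grades by the cumulative percentages of absolute errors within 5, 10 and
#' 15 mmHg. A grade is awarded only when all three of its thresholds are
#' met (A: 60/85/95, B: 50/75/90, C: 40/65/85, otherwise D).
#'
#' @param errors Numeric vector of signed errors in mmHg, or `NULL` when
#'   `percentages` is given directly.
#' @param percentages Optional length-3 vector of cumulative percentages
#'   (within 5/10/15 mmHg), e.g. from a published table.
#' @return List with `pct_le_5`, `pct_le_10`, `pct_le_15`, `grade`.
#' @export
bhs_grade <- function(errors = NULL, percentages = NULL) {
  if (is.null(percentages)) {
    if (is.null(errors) || length(errors) < 1) stop("need errors or percentages")
    a <- abs(errors)
    percentages <- 100 * c(mean(a <= 5), mean(a <= 10), mean(a <= 15))
  }
  stopifnot(length(percentages) == 3)
  grade <- "D"
  for (i in seq_len(nrow(.bhs_rows))) {
    row <- .bhs_rows[i, ]
    if (percentages[1] >= row$p5 && percentages[2] >= row$p10 &&
        percentages[3] >= row$p15) {
      grade <- row$grade
      break
    }
  }
  list(pct_le_5 = percentages[1], pct_le_10 = percentages[2],
       pct_le_15 = percentages[3], grade = grade)
}

#' ESH/ESC blood-pressure classes
#'
#' The seven hypertension categories in the fixed order used throughout
#' the package.
#' @return Character vector of the seven class labels.
#' @export
esh_esc_classes <- function() {
  c("Optimal", "Normal", "High Normal", "Grade 1 Hypertension",
    "Grade 2 Hypertension", "Grade 3 Hypertension",
    "Isolated Systolic Hypertension")
}

#' Classify (SBP, DBP) pairs per the ESH/ESC guideline
#'
#' Seven-class categorization. The guideline's "and/or" rules overlap
#' (e.g. SBP 150 / DBP 85 is Grade 1 by the systolic arm and isolated
#' systolic hypertension by definition); the implemented decision cascade
#' resolves them into a partition: isolated systolic hypertension first
#' (SBP >= 140 and DBP < 90), then the hypertension grades by the maximum
#' of the systolic and diastolic component grades (Grade 3: SBP >= 180 or
#' DBP >= 110; Grade 2: SBP >= 160 or DBP >= 100; Grade 1: SBP >= 140 or
#' DBP >= 90), then High Normal (SBP >= 130 or DBP >= 85), Normal
#' (SBP >= 120 or DBP >= 80), else Optimal.
#'
#' @param sbp,dbp Finite positive pressures in mmHg (vectorized).
#' @return Factor with levels [esh_esc_classes()].
#' @export
classify_esh_esc <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0)) {
    stop("pressures must be finite and positive")
  }
  lab <- ifelse(sbp >= 140 & dbp < 90, "Isolated Systolic Hypertension",
         ifelse(sbp >= 180 | dbp >= 110, "Grade 3 Hypertension",
         ifelse(sbp >= 160 | dbp >= 100, "Grade 2 Hypertension",
         ifelse(sbp >= 140 | dbp >= 90,  "Grade 1 Hypertension",
         ifelse(sbp >= 130 | dbp >= 85,  "High Normal",
         ifelse(sbp >= 120 | dbp >= 80,  "Normal", "Optimal"))))))
  factor(lab, levels = esh_esc_classes())
}

#' One-vs-rest confusion summary over the ESH/ESC classes
#'
#' Builds the 7x7 confusion matrix and per-class accuracy, sensitivity,
#' specificity and F1 (one-vs-rest), plus prevalence-weighted averages
#' where the weights are the per-class fractions of true labels (no
#' renormalization; classes absent from both truth and prediction are
#' excluded as undefined).
#'
#' @param true_labels,pred_labels Factors or characters over the seven
#'   ESH/ESC labels.
#' @return List with `confusion` (7x7 counts, truth in rows), `per_class`
#'   data frame (percentages), and `weighted` averages (percentages).
#' @export
confusion_summary <- function(true_labels, pred_labels) {
  lev <- esh_esc_classes()
  tl <- factor(as.character(true_labels), levels = lev)
  pl <- factor(as.character(pred_labels), levels = lev)
  if (anyNA(tl) || anyNA(pl)) stop("labels outside the seven-class set")
  n <- length(tl)
  cm <- table(true = tl, pred = pl)
  per <- lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    present <- (tp + fn + fp) > 0
    data.frame(
      class = cl,
      accuracy = 100 * (tp + tn) / n,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else NA_real_,
      prevalence = 100 * (tp + fn) / n,
      present = present
    )
  })
  per <- do.call(rbind, per)
  use <- per$present
  weighted <- vapply(c("accuracy", "sensitivity", "specificity", "f1"),
                     function(m) weighted_metric_average(per[[m]][use],
                                                        per$prevalence[use]),
                     numeric(1))
  list(confusion = cm, per_class = per[, setdiff(names(per), "present")],
       weighted = weighted)
}

#' Prevalence-weighted average of per-class metrics
#'
#' `sum(metric * prevalence / 100)` with prevalences in percent and no
#' renormalization, the scheme that reproduces a published class table's
#' averages from its printed rows.
#'
#' @param metric_pct Per-class metric values in percent (NA dropped
#'   together with their weights).
#' @param prevalence_pct Per-class prevalences in percent.
#' @return Weighted average in percent.
#' @export
weighted_metric_average <- function(metric_pct, prevalence_pct) {
  ok <- is.finite(metric_pct)
  sum(metric_pct[ok] * prevalence_pct[ok] / 100)
}

#' Full clinical evaluation report for paired SBP/DBP predictions
#'
#' Bundles, per pressure (SBP, DBP, and MAP derived via
#' [mean_arterial_pressure()]): regression metrics, the AAMI verdict, BHS
#' grading and Bland-Altman agreement; plus the ESH/ESC seven-class
#' confusion summary of (SBP, DBP) pairs.
#'
#' @param pred_sbp,true_sbp,pred_dbp,true_dbp Numeric vectors (equal
#'   length).
#' @return Nested list of class `bp_report`.
#' @export
bp_evaluation_report <- function(pred_sbp, true_sbp, pred_dbp, true_dbp) {
  one <- function(pred, true) {
    m <- regression_metrics(pred, true)
    list(metrics = m, aami = aami_check(m), bhs = bhs_grade(pred - true),
         bland_altman = bland_altman(pred, true))
  }
  ok <- pred_sbp > pred_dbp             # MAP defined only when SBP > DBP
  out <- list(
    sbp = one(pred_sbp, true_sbp),
    dbp = one(pred_dbp, true_dbp),
    map = one(mean_arterial_pressure(pred_sbp[ok], pred_dbp[ok]),
              mean_arterial_pressure(true_sbp[ok], true_dbp[ok])),
    esh_esc = confusion_summary(classify_esh_esc(true_sbp, true_dbp),
                                classify_esh_esc(pred_sbp, pred_dbp)),
    n = length(pred_sbp)
  )
  class(out) <- "bp_report"
  out
}

#' @export
print.bp_report <- function(x, ...) {
  for (nm in c("sbp", "dbp", "map")) {
    m <- x[[nm]]$metrics
    cat(sprintf(
      "%s: RMSE %.2f MAE %.2f R %.3f ME %+.3f SD %.2f | AAMI %s | BHS %s\n",
      toupper(nm), m$rmse, m$mae, m$r, m$me, m$std,
      if (x[[nm]]$aami$pass) "pass" else "fail", x[[nm]]$bhs$grade))
    ba <- x[[nm]]$bland_altman
    cat(sprintf("     LOA [%.2f, %.2f] mmHg, %.2f%% outside\n",
                ba$loa_low, ba$loa_high, ba$pct_outside))
  }
  w <- x$esh_esc$weighted
  cat(sprintf(
    "ESH/ESC weighted: acc %.1f%% sens %.1f%% spec %.1f%% F1 %.1f%%\n",
    w[["accuracy"]], w[["sensitivity"]], w[["specificity"]], w[["f1"]]))
  invisible(x)
}

#' Limits of agreement from bias and SD of differences
#'
#' @param bias Mean difference in mmHg.
#' @param std SD of the differences in mmHg.
#' @return Numeric `c(low, high)` = `bias -/+ 1.96 * std`.
#' @export
loa_limits <- function(bias, std) c(bias - 1.96 * std, bias + 1.96 * std)

#' Bland-Altman agreement analysis
#'
#' Differences are `pred - true`; the x-axis pairing value is the mean of
#' the two measurements. Limits of agreement are `bias +/- 1.96 * SD` of
#' the differences.
#'
#' @param pred,true Equal-length numeric vectors, `n >= 3`.
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pct_outside` (percent of differences strictly outside the limits),
#'   `means` and `diffs` for plotting.
#' @export
bland_altman <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true must have equal length")
  if (length(pred) < 3) stop("need at least 3 observations")
  d <- pred - true
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- loa_limits(bias, s)
  list(bias = bias, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
       pct_outside = 100 * mean(d < loa[1] | d > loa[2]),
       means = (pred + true) / 2, diffs = d)
}
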