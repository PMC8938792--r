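#' @title Segmentation metrics and cohort statistics
#' @description Overlap metrics (pixel accuracy, per-class Dice and IoU and
#'   their means), observer-style per-region agreement tables, ROC analysis
#'   with Youden cut-points, the symptom-questionnaire responder rule, and
#'   the cohort statistical battery (Welch/Student t-test, one-way ANOVA,
#'   multiple linear regression).
#' @name evalstats
NULL

#' Confusion matrix between two label grids
#'
#' @param pred,ref integer arrays/vectors of equal length.
#' @param classes class vocabulary (default: union of observed labels).
#' @return K x K integer matrix, rows = prediction, columns = reference.
#' @export
confusion_matrix <- function(pred, ref, classes = NULL) {
  if (length(pred) != length(ref)) stop("shape mismatch")
  if (is.null(classes)) classes <- sort(unique(c(pred, ref)))
  p <- factor(as.vector(pred), levels = classes)
  r <- factor(as.vector(ref), levels = classes)
  table(prediction = p, reference = r)
}

#' Segmentation accuracy metrics
#'
#' Pixel accuracy, per-class Dice `2|P&R| / (|P|+|R|)`, per-class IoU
#' `|P&R| / |P|R|union`, and their means. Classes absent from both
#' prediction and reference are excluded from the means; a class present in
#' the reference but entirely missed scores 0. The background class is
#' excluded from the means by default (the metrics of interest concern the
#' regions).
#'
#' @param pred,ref label grids (any shape, compared elementwise).
#' @param classes classes to evaluate; default: all non-background classes
#'   observed in either grid.
#' @param include_background include class 0 in the means.
#' @return List: `pixel_accuracy`, `dice` (named per class), `mean_dice`,
#'   `iou`, `miou`, `n_pixels`.
#' @export
seg_metrics <- function(pred, ref, classes = NULL,
                        include_background = FALSE) {
  if (length(pred) != length(ref)) stop("shape mismatch")
  pred <- as.vector(pred); ref <- as.vector(ref)
  if (is.null(classes)) {
    classes <- sort(unique(c(pred, ref)))
    if (!include_background) classes <- setdiff(classes, 0)
  }
  pa <- mean(pred == ref)
  dice <- iou <- setNames(numeric(length(classes)), classes)
  present <- logical(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    np <- sum(pred == k); nr <- sum(ref == k)
    ni <- sum(pred == k & ref == k)
    present[i] <- (np + nr) > 0
    dice[i] <- if (np + nr > 0) 2 * ni / (np + nr) else NA_real_
    iou[i] <- if (np + nr - ni > 0) ni / (np + nr - ni) else NA_real_
  }
  list(pixel_accuracy = pa,
       dice = dice, mean_dice = mean(dice[present]),
       iou = iou, miou = mean(iou[present]),
       n_pixels = length(pred))
}

#' Per-region agreement table
#'
#' Fraction of subjects whose per-region result agrees with the reference
#' within a tolerance, shaped like an observer-agreement table
#' (sinus x side). Agreement for a subject/region means the absolute
#' difference in opacification ratio is at most `tolerance` (and both agree
#' on whether the region is present).
#'
#' @param pred_reports,ref_reports lists of per-region report data frames
#'   (one per subject, as from [region_volumes()]), with matching names or
#'   order.
#' @param tolerance maximum absolute difference in `ratio` still counted as
#'   agreement.
#' @return Data frame: region_id, n, agree, agreement (fraction).
#' @export
region_agreement <- function(pred_reports, ref_reports, tolerance = 0.1) {
  if (length(pred_reports) != length(ref_reports)) stop("unmatched subjects")
  if (!is.null(names(pred_reports)) && !is.null(names(ref_reports))) {
    if (!setequal(names(pred_reports), names(ref_reports)))
      stop("unmatched subject ids")
    ref_reports <- ref_reports[names(pred_reports)]
  }
  regs <- pred_reports[[1]]$region_id
  agree <- setNames(integer(length(regs)), regs)
  for (s in seq_along(pred_reports)) {
    p <- pred_reports[[s]]; r <- ref_reports[[s]]
    stopifnot(identical(p$region_id, r$region_id))
    ok <- abs(p$ratio - r$ratio) <= tolerance &
      ((p$total_vox > 0) == (r$total_vox > 0))
    agree <- agree + as.integer(ok)
  }
  data.frame(region_id = regs, n = length(pred_reports),
             agree = as.integer(agree),
             agreement = as.numeric(agree) / length(pred_reports),
             stringsAsFactors = FALSE)
}

#' ROC curve, AUC and Youden cut-point
#'
#' Threshold sweep over the unique scores; AUC by the trapezoidal rule,
#' which for a finite sample equals the rank statistic
#' `P(score+ > score-) + 0.5 P(tie)`. The Youden cut-point maximises
#' `sensitivity + specificity - 1`; ties are broken toward the higher
#' threshold (higher specificity).
#'
#' @param scores numeric marker values (higher = more positive).
#' @param labels 0/1 or logical class labels; both classes must be present.
#' @return List of class `roc_result`: `curve` (threshold, fpr, tpr),
#'   `auc`, `youden_cutpoint`, `sensitivity`, `specificity`.
#' @export
roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  # predict positive when score >= threshold; add sentinel ends
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  youden <- curve$tpr - curve$fpr
  best <- which(youden == max(youden))
  best <- best[which.max(curve$threshold[best])]  # higher specificity
  structure(list(curve = curve, auc = auc,
                 youden_cutpoint = curve$threshold[best],
                 sensitivity = curve$tpr[best],
                 specificity = 1 - curve$fpr[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, Youden cut %.3g (sens %.2f, spec %.2f)\n",
              x$auc, x$youden_cutpoint, x$sensitivity, x$specificity))
  invisible(x)
}

#' Symptom-score responder rule
#'
#' A subject is a responder when the post-treatment symptom score dropped by
#' at least 25% of the pre-treatment score.
#'
#' @param snot_pre,snot_post pre/post questionnaire totals (0-110 scale);
#'   `snot_pre` must be positive.
#' @param reduction required relative reduction (default 0.25).
#' @return Logical vector.
#' @export
responder <- function(snot_pre, snot_post, reduction = 0.25) {
  if (any(snot_pre <= 0)) stop("snot_pre must be positive")
  (snot_pre - snot_post) / snot_pre >= reduction
}

#' Cohort statistical battery
#'
#' The standard battery applied to cohort tables: two-sample t-tests
#' (Welch by default, pooled-variance Student optionally), one-way ANOVA,
#' and ordinary-least-squares multiple regression, with significance
#' flagged at `alpha`.
#'
#' @param data cohort data frame.
#' @param t_tests named list of formulas `outcome ~ group` for two-sample
#'   tests.
#' @param anovas named list of formulas for one-way ANOVA.
#' @param regressions named list of formulas for OLS regression.
#' @param welch use Welch's unequal-variance t-test (default TRUE).
#' @param alpha significance level (default 0.05).
#' @return List with tidy data frames `t_tests`, `anovas`, `regressions`
#'   (term-level coefficient table) and the fitted `lm` objects in
#'   `fits`.
#' @export
stat_battery <- function(data, t_tests = list(), anovas = list(),
                         regressions = list(), welch = TRUE, alpha = 0.05) {
  tt <- lapply(names(t_tests), function(nm) {
    f <- t_tests[[nm]]
    mf <- stats::model.frame(f, data)
    groups <- split(mf[[1]], mf[[2]])
    if (length(groups) != 2 || any(vapply(groups, length, 1L) < 2))
      stop("t-test needs exactly two groups with n >= 2: ", nm)
    ht <- t.test(mf[[1]] ~ mf[[2]], var.equal = !welch)
    data.frame(test = nm, statistic = unname(ht$statistic),
               df = unname(ht$parameter), p_value = ht$p.value,
               mean_1 = unname(ht$estimate[1]), mean_2 = unname(ht$estimate[2]),
               significant = ht$p.value < alpha, stringsAsFactors = FALSE)
  })
  av <- lapply(names(anovas), function(nm) {
    fit <- aov(anovas[[nm]], data)
    s <- summary(fit)[[1]]
    data.frame(test = nm, statistic = s$`F value`[1], df1 = s$Df[1],
               df2 = s$Df[2], p_value = s$`Pr(>F)`[1],
               significant = s$`Pr(>F)`[1] < alpha, stringsAsFactors = FALSE)
  })
  fits <- lapply(regressions, function(f) lm(f, data))
  rg <- lapply(names(regressions), function(nm) {
    fit <- fits[[nm]]
    cf <- summary(fit)$coefficients
    ci <- confint(fit)
    data.frame(model = nm, term = rownames(cf), estimate = cf[, 1],
               std_error = cf[, 2], p_value = cf[, 4],
               ci_lo = ci[, 1], ci_hi = ci[, 2],
               significant = cf[, 4] < alpha, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  list(t_tests = if (length(tt)) do.call(rbind, tt) else NULL,
       anovas = if (length(av)) do.call(rbind, av) else NULL,
       regressions = if (length(rg)) do.call(rbind, rg) else NULL,
       fits = fits)
}
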