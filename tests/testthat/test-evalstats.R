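# Metrics, ROC, responder rule, statistical battery.

test_that("confusion matrix counts every pair once", {
  pred <- c(0, 0, 1, 1, 2)
  ref <- c(0, 1, 1, 2, 2)
  cm <- confusion_matrix(pred, ref)
  expect_equal(sum(cm), 5)
  expect_equal(unname(cm["1", "1"]), 1L)
  expect_equal(unname(cm["0", "1"]), 1L)
  expect_error(confusion_matrix(1:3, 1:4), "mismatch")
})

test_that("worked 2x2 example: Dice 0.5, IoU 1/3", {
  # class 1: |P|=2, |R|=2, intersection 1
  pred <- c(1, 1, 0, 0)
  ref <- c(1, 0, 1, 0)
  m <- seg_metrics(pred, ref)
  expect_equal(unname(m$dice["1"]), 0.5)
  expect_equal(unname(m$iou["1"]), 1 / 3)
  expect_equal(m$pixel_accuracy, 0.5)
})

test_that("Dice-IoU identity d = 2j/(1+j) holds per class (property)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 200
    pred <- sample(0:4, n, replace = TRUE)
    ref <- sample(0:4, n, replace = TRUE)
    m <- seg_metrics(pred, ref, include_background = TRUE)
    ok <- !is.na(m$iou)
    expect_equal(m$dice[ok], 2 * m$iou[ok] / (1 + m$iou[ok]),
                 tolerance = 1e-12)
  }
})

test_that("perfect and disjoint segmentations hit the metric extremes", {
  ref <- c(rep(0, 10), rep(1, 5), rep(2, 5))
  m1 <- seg_metrics(ref, ref)
  expect_equal(m1$mean_dice, 1)
  expect_equal(m1$miou, 1)
  expect_equal(m1$pixel_accuracy, 1)
  pred <- ifelse(ref == 1, 2, ifelse(ref == 2, 1, 0))
  m0 <- seg_metrics(pred, ref)
  expect_equal(m0$mean_dice, 0)
})

test_that("classes absent from both grids are excluded from the means", {
  pred <- c(1, 1, 0); ref <- c(1, 0, 0)
  m <- seg_metrics(pred, ref, classes = c(1, 2, 3))
  expect_true(is.na(m$dice["2"]))
  expect_equal(m$mean_dice, unname(m$dice["1"]))
})

test_that("trapezoid AUC equals the all-pairs rank statistic (property)", {
  set.seed(77)
  for (rep in 1:25) {
    n <- 40
    lab <- c(rep(1, 15), rep(0, 25))
    sc <- round(rnorm(n), 1)  # induces ties
    r <- roc(sc, lab)
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    pairs <- outer(pos, neg, `-`)
    auc_rank <- (sum(pairs > 0) + 0.5 * sum(pairs == 0)) / length(pairs)
    expect_equal(r$auc, auc_rank, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms of the marker", {
  set.seed(5)
  sc <- rnorm(60); lab <- rbinom(60, 1, plogis(sc))
  if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
  a1 <- roc(sc, lab)$auc
  a2 <- roc(exp(sc), lab)$auc
  a3 <- roc(2 * sc + 7, lab)$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("roc agrees with pROC on AUC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(80); lab <- rbinom(80, 1, plogis(2 * sc))
  if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
  ours <- roc(sc, lab)$auc
  theirs <- as.numeric(suppressMessages(pROC::auc(lab, sc)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("Youden cut-point separates a cleanly separable marker", {
  sc <- c(1, 2, 3, 10, 11, 12)
  lab <- c(0, 0, 0, 1, 1, 1)
  r <- roc(sc, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_cutpoint, 10)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc(sc, rep(1, 6)), "both classes")
})

test_that("responder rule: 25% reduction is the closed boundary", {
  expect_true(responder(40, 30))    # exactly 25%
  expect_false(responder(40, 31))   # 22.5%
  expect_equal(responder(c(40, 40, 80), c(10, 35, 60)),
               c(TRUE, FALSE, TRUE))
  expect_error(responder(0, 0), "positive")
})

test_that("stat battery matches direct t.test/aov/lm to near machine precision", {
  set.seed(99)
  d <- data.frame(y = rnorm(60), g = rep(c("a", "b"), 30),
                  x1 = rnorm(60), x2 = rnorm(60),
                  f3 = rep(c("u", "v", "w"), 20))
  d$y <- d$y + 0.8 * d$x1 + ifelse(d$g == "b", 0.5, 0)
  b <- stat_battery(d,
                    t_tests = list(y_by_g = y ~ g),
                    anovas = list(y_by_f3 = y ~ f3),
                    regressions = list(m = y ~ x1 + x2))
  ht <- t.test(y ~ g, data = d)
  expect_equal(b$t_tests$statistic, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(b$t_tests$p_value, ht$p.value, tolerance = 1e-10)
  sa <- summary(aov(y ~ f3, d))[[1]]
  expect_equal(b$anovas$statistic, sa$`F value`[1], tolerance = 1e-10)
  fit <- lm(y ~ x1 + x2, d)
  expect_equal(b$regressions$estimate, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(b$regressions$ci_lo, unname(confint(fit)[, 1]),
               tolerance = 1e-10)
  # Student (pooled) variant
  bs <- stat_battery(d, t_tests = list(y_by_g = y ~ g), welch = FALSE)
  hts <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(bs$t_tests$statistic, unname(hts$statistic), tolerance = 1e-10)
  expect_error(stat_battery(d, t_tests = list(bad = y ~ f3)), "two groups")
})

test_that("region agreement detects injected disagreements", {
  mk <- function(rat) data.frame(region_id = sinus_regions(),
                                 total_vox = 100L, ratio = rat)
  base <- lapply(1:5, function(i) mk(rep(0.3, 12)))
  pred <- base
  # subject 2: Max-L ratio off by 0.5; subject 4: Sph-R off by 0.2
  pred[[2]]$ratio[1] <- 0.8
  pred[[4]]$ratio[10] <- 0.5
  ag <- region_agreement(pred, base, tolerance = 0.1)
  expect_equal(ag$agreement[ag$region_id == "Max-L"], 4 / 5)
  expect_equal(ag$agreement[ag$region_id == "Sph-R"], 4 / 5)
  expect_true(all(ag$agreement[!ag$region_id %in% c("Max-L", "Sph-R")] == 1))
  # presence disagreement also counts
  pred2 <- base
  pred2[[1]]$total_vox[3] <- 0L
  ag2 <- region_agreement(pred2, base)
  expect_equal(ag2$agreement[3], 4 / 5)
})
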