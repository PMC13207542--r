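test_that("classification metrics follow the confusion-count formulas", {
  perfect <- clsMetrics(c(tp = 5, fp = 0, tn = 7, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))
  m <- clsMetrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m[["pre"]], 0.75)
  expect_equal(m[["rec"]], 0.6)
  expect_equal(m[["f1"]], 2 / 3, tolerance = 1e-9)
  expect_equal(m[["acc"]], 0.7)
  # accuracy is symmetric under swapping tp<->tn and fp<->fn
  sw <- clsMetrics(c(tp = 4, fp = 2, tn = 3, fn = 1))
  expect_equal(sw[["acc"]], m[["acc"]])
  expect_error(clsMetrics(c(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
  # undefined ratios are absent, not 0
  none <- clsMetrics(c(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(none[["pre"]]))
})

test_that("trapezoidal AUC matches intuition and handles ties", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(rocAUC(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("trapezoidal AUC equals the pairwise statistic on random vectors", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)  # rounded so ties actually occur
    expect_equal(rocAUC(scores, labels), brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("per-image segmentation metrics substitute pixel counts", {
  gt <- matrix(0, 4, 4); gt[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:2] <- 1
  m <- segMetricsPerImage(pred, gt)
  expect_equal(m[["iou"]], 0.5)
  expect_equal(m[["dc"]], 2 / 3, tolerance = 1e-9)
  expect_equal(m[["se"]], 0.5)
  expect_equal(m[["pc"]], 1)
  expect_equal(m[["acc"]], 14 / 16)
  same <- segMetricsPerImage(gt, gt)
  expect_equal(unname(same), rep(1, 5))
  expect_error(segMetricsPerImage(matrix(0, 2, 2), gt), "shapes")
})

test_that("empty ground truth is excluded regardless of the prediction", {
  empty <- matrix(0, 4, 4)
  full <- matrix(1, 4, 4)
  expect_true(segMetricsPerImage(full, empty)$excluded)
  expect_true(segMetricsPerImage(empty, empty)$excluded)
  # empty prediction on a non-empty truth: PC is absent, not 0
  gt <- matrix(0, 4, 4); gt[2, 2] <- 1
  m <- segMetricsPerImage(empty, gt)
  expect_true(is.na(m[["pc"]]))
  expect_equal(m[["iou"]], 0)
})

test_that("DC = 2 IOU / (1 + IOU) holds per image, and F1 equals DC on counts", {
  set.seed(7)
  for (i in 1:15) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    gt <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(gt) == 0) next
    m <- segMetricsPerImage(pred, gt)
    expect_equal(m[["dc"]], 2 * m[["iou"]] / (1 + m[["iou"]]),
                 tolerance = 1e-12)
    # classification F1 on the same pixel counts equals the Dice coefficient
    cm <- clsMetrics(c(tp = sum(pred & gt), fp = sum(pred & !gt),
                       tn = sum(!pred & !gt), fn = sum(!pred & gt)))
    if (!is.na(cm[["f1"]])) expect_equal(cm[["f1"]], m[["dc"]],
                                         tolerance = 1e-12)
  }
})

test_that("an always-normal classifier scores zero recall and zero overlap", {
  co <- generateCohort(8, classMix = c(benign = 0.5, malignant = 0.25,
                                       normal = 0.25),
                       areaRange = c(150, 900), size = 64, seed = 12L)
  samples <- lapply(co$samples, preprocessEval, targetSize = 32L)
  cfg <- modelConfig(encoderChannels = c(4L, 8L), inputSize = 32L)
  model <- buildNUnet(cfg, seed = 3L)
  # pin the head to a constant "normal" decision
  fillParams(model$root$children$clsHead, 0)
  model$root$children$clsHead$children$fc2$params$b <- c(-1, 1)
  rep <- evaluateFold(model, samples)
  expect_equal(rep@classification[["rec"]], 0)
  expect_equal(rep@confusion[["tp"]], 0)
  # every lesion image is suppressed by CSB, so IOU and SE collapse to 0
  expect_equal(rep@segmentation[["iou"]], 0)
  expect_equal(rep@segmentation[["se"]], 0)
  # excluded count equals the number of normal images in the test list
  expect_equal(rep@excludedCount,
               sum(co$manifest$category == "normal"))
  expect_equal(rep@nImages, 8L)
})

test_that("fold aggregation reports sample mean and SD per metric", {
  mk <- function(acc) methods::new("MetricsReport",
    classification = c(acc = acc, pre = 1, rec = 1, f1 = 1, auc = 1),
    segmentation = c(iou = acc, dc = acc, acc = acc, se = acc, pc = acc),
    confusion = c(tp = 1, fp = 0, tn = 1, fn = 0),
    excludedCount = 0L, nImages = 2L)
  same <- aggregateFolds(list(mk(0.8), mk(0.8), mk(0.8)))
  expect_true(all(same$sd == 0))
  two <- aggregateFolds(list(mk(0.8), mk(0.9)))
  expect_equal(two$mean[two$metric == "cls_acc"], 0.85)
  expect_equal(two$sd[two$metric == "cls_acc"], 0.0707, tolerance = 1e-3)
  # permutation invariance of the mean
  rev2 <- aggregateFolds(list(mk(0.9), mk(0.8)))
  expect_equal(two$mean, rev2$mean)
  expect_error(aggregateFolds(list(mk(0.8))), "at least 2")
})
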