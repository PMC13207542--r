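# Metric suite: classification accuracy / precision / recall / F1 with the
# lesion class as positive, trapezoidal ROC-AUC on the pre-gate lesion
# probability, per-image segmentation overlap metrics with the empty-mask
# exclusion policy, and mean +/- SD aggregation across folds. Ratios with
# a zero denominator are reported as absent (NA), never as 0 or 1.

#' Classification metrics from confusion counts
#'
#' acc = (tp+tn)/all, pre = tp/(tp+fp), rec = tp/(tp+fn),
#' f1 = 2 pre rec / (pre + rec). Undefined ratios are returned as NA.
#'
#' @param counts named numeric with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn} (lesion = positive class)
#' @return named numeric: acc, pre, rec, f1
#' @export
clsMetrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be >= 0")
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  pre <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0) {
    2 * pre * rec / (pre + rec)
  } else NA_real_
  c(acc = (tp + tn) / total, pre = pre, rec = rec, f1 = f1)
}

#' Trapezoidal ROC-AUC
#'
#' Sweeps the decision threshold over the score values (ties grouped),
#' integrates TPR over FPR with the trapezoid rule, and therefore equals
#' the pairwise rank statistic with half-credit for tied pairs.
#'
#' @param scores continuous lesion scores
#' @param labels 0/1 labels (1 = lesion)
#' @return the AUC in [0, 1]
#' @export
rocAUC <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC is undefined with a single class present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1),
                     numeric(1)) / npos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0),
                     numeric(1)) / nneg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Per-image segmentation metrics with empty-mask exclusion
#'
#' Images with an empty ground-truth mask are excluded (the overlap ratios
#' are undefined or convention-dependent there); otherwise pixel-level
#' IOU = TP/(TP+FP+FN), DC = 2TP/(2TP+FP+FN), Acc = (TP+TN)/all,
#' SE = TP/(TP+FN) and PC = TP/(TP+FP) are returned, with PC absent (NA)
#' when the prediction is empty.
#'
#' @param pred,gt binary masks of identical shape
#' @return \code{list(excluded = TRUE)} for an empty ground truth, else a
#'   named numeric (iou, dc, acc, se, pc)
#' @export
segMetricsPerImage <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  if (!is_binary_mask(pred) || !is_binary_mask(gt)) {
    stop("masks must be {0,1}-valued")
  }
  if (sum(gt) == 0) return(list(excluded = TRUE))
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  c(iou = tp / (tp + fp + fn),
    dc = 2 * tp / (2 * tp + fp + fn),
    acc = (tp + tn) / (tp + fp + tn + fn),
    se = tp / (tp + fn),
    pc = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Evaluate a model on one test fold
#'
#' Runs the full gated prediction (\code{\link{predictSample}}, i.e. with
#' CSB applied) on every test image, accumulates the classification
#' confusion counts and ROC-AUC from the pre-gate lesion probabilities,
#' and averages the per-image segmentation metrics over the non-excluded
#' (lesion-containing) images.
#'
#' @param model a trained \code{NUnetModel}
#' @param samples list of test \linkS4class{ImageSample} at the model
#'   input size
#' @param threshold segmentation binarization threshold
#' @return a \linkS4class{MetricsReport}
#' @export
evaluateFold <- function(model, samples, threshold = 0.5) {
  if (length(samples) == 0) stop("empty test list")
  n <- length(samples)
  truth <- vapply(samples, presenceLabel, character(1)) == "lesion"
  probs <- numeric(n)
  predPos <- logical(n)
  seg_rows <- list()
  excluded <- 0L
  for (i in seq_len(n)) {
    pr <- predictSample(model, samples[[i]], threshold)
    probs[i] <- pr$lesionProbability
    predPos[i] <- pr$sigma == 0
    m <- segMetricsPerImage(pr$mask, maskData(samples[[i]]))
    if (is.list(m) && isTRUE(m$excluded)) excluded <- excluded + 1L
    else seg_rows[[length(seg_rows) + 1L]] <- m
  }
  counts <- c(tp = sum(predPos & truth), fp = sum(predPos & !truth),
              tn = sum(!predPos & !truth), fn = sum(!predPos & truth))
  cl <- clsMetrics(counts)
  auc <- if (any(truth) && any(!truth)) rocAUC(probs, as.numeric(truth))
         else NA_real_
  seg <- if (length(seg_rows)) {
    mat <- do.call(rbind, seg_rows)
    colMeans(mat, na.rm = TRUE)
  } else c(iou = NA_real_, dc = NA_real_, acc = NA_real_, se = NA_real_,
           pc = NA_real_)
  methods::new("MetricsReport",
               classification = c(cl, auc = auc), segmentation = seg,
               confusion = counts, excludedCount = excluded,
               nImages = as.integer(n))
}

#' Aggregate per-fold reports into a mean +/- SD table
#'
#' @param reports list of at least two \linkS4class{MetricsReport} objects
#'   with identical metric sets
#' @return data.frame with columns metric, mean, sd (sample SD, k-1
#'   denominator)
#' @export
aggregateFolds <- function(reports) {
  if (length(reports) < 2) stop("fold aggregation needs at least 2 reports")
  rows <- lapply(reports, function(r) {
    c(stats::setNames(r@classification,
                      paste0("cls_", names(r@classification))),
      stats::setNames(r@segmentation,
                      paste0("seg_", names(r@segmentation))))
  })
  nm <- names(rows[[1]])
  for (r in rows) {
    if (!identical(names(r), nm)) stop("inconsistent metric sets across folds")
  }
  mat <- do.call(rbind, rows)
  data.frame(metric = nm, mean = colMeans(mat),
             sd = apply(mat, 2, stats::sd), row.names = NULL)
}
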