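#' @import methods
NULL

#' Specification of one synthetic breast-ultrasound phantom
#'
#' Describes a single speckle phantom: canvas size, whether a hypoechoic
#' lesion is present and how many foreground pixels it should occupy, the
#' lesion geometry, the echogenicity contrast between lesion and surrounding
#' tissue, the speckle strength, and how the paired mask is encoded
#' (white-on-black grayscale, or RGB with green = benign / red = malignant).
#'
#' @slot height,width canvas size in pixels (at least 64)
#' @slot lesionPresent logical; normal phantoms carry an all-zero mask
#' @slot targetArea requested lesion foreground pixel count (0 when normal)
#' @slot lesionShape \code{"ellipse"} or \code{"perturbed-ellipse"}
#' @slot contrast echogenicity contrast in (0, 1]; lesion pixels are darker
#'   than surrounding tissue by roughly this relative amount
#' @slot speckleScale multiplicative speckle strength (> 0; 1 = full
#'   unit-mean Rayleigh speckle)
#' @slot maskEncoding \code{"grayscale-binary"} or \code{"rgb-coded"}
#' @slot rgbClass \code{"benign-green"} or \code{"malignant-red"} (used only
#'   for rgb-coded masks)
#' @slot seed integer seed making the phantom fully reproducible
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  height = "integer", width = "integer", lesionPresent = "logical",
  targetArea = "numeric", lesionShape = "character", contrast = "numeric",
  speckleScale = "numeric", maskEncoding = "character", rgbClass = "character",
  seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@height < 64L || object@width < 64L)
    return("height and width must both be at least 64 pixels")
  if (object@lesionPresent && object@targetArea <= 0)
    return("targetArea must be positive when lesionPresent is TRUE")
  if (!object@lesionPresent && object@targetArea != 0)
    return("targetArea must be 0 when lesionPresent is FALSE")
  if (!object@lesionShape %in% c("ellipse", "perturbed-ellipse"))
    return("lesionShape must be 'ellipse' or 'perturbed-ellipse'")
  if (object@contrast <= 0 || object@contrast > 1)
    return("contrast must lie in (0, 1]")
  if (object@speckleScale <= 0)
    return("speckleScale must be positive")
  if (!object@maskEncoding %in% c("grayscale-binary", "rgb-coded"))
    return("maskEncoding must be 'grayscale-binary' or 'rgb-coded'")
  if (!object@rgbClass %in% c("benign-green", "malignant-red"))
    return("rgbClass must be 'benign-green' or 'malignant-red'")
  TRUE
})

#' One image with its paired lesion mask and labels
#'
#' The central data container: a 3-channel intensity image in [0, 1], a
#' binary lesion mask, the diagnostic category, the derived lesion-presence
#' label, the lesion area A (foreground pixel count), and the lesion-size
#' stratum used by the stratified splitting protocol.
#'
#' @slot image H x W x 3 numeric array with values in [0, 1]
#' @slot mask H x W matrix with values in {0, 1}
#' @slot category \code{"benign"}, \code{"malignant"} or \code{"normal"}
#' @slot presenceLabel \code{"lesion"} or \code{"normal"}
#' @slot areaA foreground pixel count of \code{mask}
#' @slot stratum \code{"small"}, \code{"medium"}, \code{"large"} or
#'   \code{"none"} (normal samples never enter a size tier)
#' @slot sampleId unique sample identifier
#' @slot role split membership tag (\code{"train"}, \code{"val"},
#'   \code{"test"} or \code{""}); the augmentation leakage guard checks it
#' @exportClass ImageSample
setClass("ImageSample", representation(
  image = "array", mask = "matrix", category = "character",
  presenceLabel = "character", areaA = "numeric", stratum = "character",
  sampleId = "character", role = "character"))

setValidity("ImageSample", function(object) {
  if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
    return("image must be an H x W x 3 array")
  if (!all(object@mask %in% c(0, 1)))
    return("mask must be {0,1}-valued")
  if (!object@category %in% c("benign", "malignant", "normal"))
    return("category must be benign, malignant or normal")
  allzero <- sum(object@mask) == 0
  if ((object@presenceLabel == "normal") != allzero)
    return("presenceLabel 'normal' must coincide with an all-zero mask")
  if ((object@category == "normal") != allzero)
    return("category 'normal' must coincide with an all-zero mask")
  if (object@areaA != sum(object@mask))
    return("areaA must equal the mask foreground pixel count")
  TRUE
})

#' Lesion-size stratification thresholds
#'
#' The empirical 33\% and 66\% quantiles (alpha, beta) of lesion area among
#' lesion-positive samples, delimiting the small / medium / large tiers.
#'
#' @slot alpha,beta area thresholds in pixels, 0 < alpha <= beta
#' @exportClass StratificationThresholds
setClass("StratificationThresholds",
         representation(alpha = "numeric", beta = "numeric"))

setValidity("StratificationThresholds", function(object) {
  if (object@alpha <= 0 || object@alpha > object@beta)
    return("thresholds must satisfy 0 < alpha <= beta")
  TRUE
})

#' Five-fold train/validation/test assignment
#'
#' Per-fold id lists under the rotating 6:2:2 scheme: fold f tests on block
#' f, validates on block f+1 (mod k), trains on the rest.
#'
#' @slot k number of folds
#' @slot folds list of k lists, each with \code{train}, \code{val},
#'   \code{test} character id vectors
#' @slot seed integer seed the assignment was drawn with
#' @exportClass SplitAssignment
setClass("SplitAssignment",
         representation(k = "integer", folds = "list", seed = "integer"))

setValidity("SplitAssignment", function(object) {
  if (length(object@folds) != object@k) return("folds list must have k entries")
  all_ids <- sort(unique(unlist(object@folds[[1]])))
  for (f in object@folds) {
    if (length(intersect(f$train, f$val)) || length(intersect(f$train, f$test)) ||
        length(intersect(f$val, f$test)))
      return("train/val/test lists must be pairwise disjoint within a fold")
    if (!identical(sort(unique(c(f$train, f$val, f$test))), all_ids))
      return("each fold must cover the full cohort")
  }
  test_all <- unlist(lapply(object@folds, `[[`, "test"))
  if (any(duplicated(test_all)) || !identical(sort(test_all), all_ids))
    return("every id must appear in exactly one test list")
  TRUE
})

#' Training-time geometric augmentation policy
#'
#' @slot resizeScaleRange random resize scale interval (bicubic for images,
#'   nearest-neighbor for masks)
#' @slot coarseRotations right-angle rotation choices in degrees
#' @slot coarseProb probability of applying a coarse rotation
#' @slot fineRotationRange small-angle rotation interval in degrees,
#'   within [-10, 10]
#' @slot cropFraction center-crop fraction in (0, 1]
#' @slot flipProbabilities horizontal/vertical flip probabilities
#' @slot targetSize output resolution in pixels
#' @exportClass AugmentationPolicy
setClass("AugmentationPolicy", representation(
  resizeScaleRange = "numeric", coarseRotations = "numeric",
  coarseProb = "numeric", fineRotationRange = "numeric",
  cropFraction = "numeric", flipProbabilities = "numeric",
  targetSize = "integer"))

setValidity("AugmentationPolicy", function(object) {
  if (object@fineRotationRange[1] < -10 || object@fineRotationRange[2] > 10)
    return("fineRotationRange must lie within [-10, 10] degrees")
  if (object@cropFraction <= 0 || object@cropFraction > 1)
    return("cropFraction must lie in (0, 1]")
  if (any(object@flipProbabilities < 0) || any(object@flipProbabilities > 1))
    return("flipProbabilities must lie in [0, 1]")
  TRUE
})

#' N-Unet architecture configuration
#'
#' Channel schedule and block hyperparameters of the multi-task network.
#' The defaults are the calibrated full-size model: encoder channels
#' 16-32-64-128-256 on a 256x256 input, a 512-channel bottleneck at 8x8,
#' AFF side-branch widths (25, 32, 64, 128, 96) and attention-gate widths
#' (16, 16, 32, 64, 128), which together land the complexity audit on the
#' published 8.95 M parameter / 14.74 G budget.
#'
#' @slot inputChannels number of image channels (3)
#' @slot inputSize square input resolution in pixels
#' @slot encoderChannels strictly increasing encoder channel schedule
#' @slot bottleneckChannels bottleneck width (twice the last encoder level)
#' @slot seReduction,cbamReduction bottleneck ratios of the SE and CBAM MLPs
#' @slot cbamSpatialKernel CBAM spatial-attention kernel size
#' @slot affDropout dropout rate on the AFF side branch
#' @slot affSideWidths pointwise output width of each AFF side branch
#' @slot gateWidths intermediate channel count F of each attention gate
#' @slot headDims classification head dimensions (bottleneck, hidden, 2)
#' @slot segOutChannels segmentation head output channels (1)
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  inputChannels = "integer", inputSize = "integer",
  encoderChannels = "integer", bottleneckChannels = "integer",
  seReduction = "integer", cbamReduction = "integer",
  cbamSpatialKernel = "integer", affDropout = "numeric",
  affSideWidths = "integer", gateWidths = "integer", headDims = "integer",
  segOutChannels = "integer"))

setValidity("ModelConfig", function(object) {
  ch <- object@encoderChannels
  L <- length(ch)
  if (L < 1L || any(diff(ch) <= 0))
    return("encoderChannels must be strictly increasing")
  if (object@bottleneckChannels != 2L * ch[L])
    return("bottleneckChannels must be twice the last encoder channel count")
  if (object@inputSize %% 2L^L != 0L || object@inputSize %/% 2L^L < 4L)
    return("inputSize must leave a bottleneck of at least 4x4 after L halvings")
  if (length(object@affSideWidths) != L || length(object@gateWidths) != L)
    return("affSideWidths and gateWidths must have one entry per encoder level")
  if (length(object@headDims) != 3L || object@headDims[1] != object@bottleneckChannels ||
      object@headDims[3] != 2L)
    return("headDims must be (bottleneck, hidden, 2)")
  TRUE
})

#' Adaptive multi-task loss state
#'
#' Hyperparameters and learnable uncertainty variables of the AMTL loss:
#' the focal focusing parameter gamma, the lesion-class weight omega, the
#' Dice smoothing constant epsilon, and the two log-variance variables
#' s_i = log(sigma_i^2) encoding the per-task homoscedastic uncertainties.
#'
#' @slot gamma focal focusing parameter (>= 0, default 2)
#' @slot omega lesion-class weight N_neg / N_pos (> 0)
#' @slot epsilon Dice smoothing constant (default 1e-5)
#' @slot logVar two learnable log-variances; sigma_i = exp(logVar_i / 2)
#'   so both start at sigma = 1 when logVar = c(0, 0)
#' @slot taskCount number of tasks D_s (2)
#' @exportClass LossState
setClass("LossState", representation(
  gamma = "numeric", omega = "numeric", epsilon = "numeric",
  logVar = "numeric", taskCount = "integer"))

setValidity("LossState", function(object) {
  if (object@gamma < 0) return("gamma must be non-negative")
  if (object@omega <= 0) return("omega must be positive")
  if (object@epsilon <= 0) return("epsilon must be positive")
  if (length(object@logVar) != object@taskCount)
    return("logVar must have one entry per task")
  TRUE
})

#' Training configuration
#'
#' @slot batchSize minibatch size (published setting: 6)
#' @slot epochs training epochs (published setting: 800)
#' @slot optimizer optimizer name (\code{"adam"})
#' @slot initialLr initial learning rate (published setting: 1e-5)
#' @slot lrSchedule \code{"cosine"} (annealed to 0 over the run) or
#'   \code{"constant"}
#' @slot seed integer seed for batching, initialization and augmentation
#' @slot checkpointDir directory checkpoints are written to
#' @slot selectMetric validation criterion for best-checkpoint selection
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  batchSize = "integer", epochs = "integer", optimizer = "character",
  initialLr = "numeric", lrSchedule = "character", seed = "integer",
  checkpointDir = "character", selectMetric = "character"))

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L) return("batchSize must be at least 1")
  if (object@epochs < 1L) return("epochs must be at least 1")
  if (object@initialLr <= 0) return("initialLr must be positive")
  TRUE
})

#' Per-fold evaluation report
#'
#' Classification metrics over all test images and per-image-averaged
#' segmentation metrics over the non-excluded (lesion-containing) images.
#'
#' @slot classification named numeric: acc, pre, rec, f1, auc (NA when a
#'   ratio is undefined)
#' @slot segmentation named numeric: iou, dc, acc, se, pc per-image means
#' @slot confusion named numeric: tp, fp, tn, fn sample counts
#' @slot excludedCount number of evaluated images excluded by the
#'   empty-mask rule
#' @slot nImages number of evaluated images
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  classification = "numeric", segmentation = "numeric", confusion = "numeric",
  excludedCount = "integer", nImages = "integer"))

setValidity("MetricsReport", function(object) {
  vals <- c(object@classification, object@segmentation)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (any(vals < 0) || any(vals > 1)))
    return("all metrics must lie in [0, 1]")
  if (object@excludedCount < 0L) return("excludedCount must be non-negative")
  TRUE
})

#' Model complexity report
#'
#' Trainable parameter and multiply-accumulate counts, per named block and
#' in total. FLOPs are reported as 2 x MACs (one multiply and one add per
#' accumulate), the convention behind the published per-model figures.
#'
#' @slot totalParams total trainable parameter count
#' @slot paramsByBlock named per-block parameter counts
#' @slot totalMacs multiply-accumulate count at \code{inputSize}
#' @slot macsByBlock named per-block MAC counts
#' @slot totalFlops 2 x totalMacs
#' @slot inputSize input resolution the MACs were counted at
#' @exportClass ComplexityReport
setClass("ComplexityReport", representation(
  totalParams = "numeric", paramsByBlock = "numeric", totalMacs = "numeric",
  macsByBlock = "numeric", totalFlops = "numeric", inputSize = "integer"))

setValidity("ComplexityReport", function(object) {
  if (abs(object@totalParams - sum(object@paramsByBlock)) > 1e-6)
    return("totalParams must equal the sum of paramsByBlock")
  if (abs(object@totalMacs - sum(object@macsByBlock)) > 1e-6)
    return("totalMacs must equal the sum of macsByBlock")
  TRUE
})
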