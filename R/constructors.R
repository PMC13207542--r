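#' Create a phantom specification
#'
#' @param height,width canvas size in pixels (at least 64)
#' @param lesionPresent whether the phantom carries a lesion
#' @param targetArea requested lesion foreground pixel count; must be
#'   positive exactly when \code{lesionPresent} is \code{TRUE}
#' @param lesionShape \code{"ellipse"} or \code{"perturbed-ellipse"}
#' @param contrast echogenicity contrast in (0, 1]
#' @param speckleScale multiplicative speckle strength (> 0)
#' @param maskEncoding \code{"grayscale-binary"} or \code{"rgb-coded"}
#' @param rgbClass \code{"benign-green"} or \code{"malignant-red"}
#' @param seed integer seed
#' @return a validated \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(height = 256L, width = 256L, lesionPresent = TRUE,
                        targetArea = if (lesionPresent) 2000 else 0,
                        lesionShape = "perturbed-ellipse", contrast = 0.55,
                        speckleScale = 1, maskEncoding = "grayscale-binary",
                        rgbClass = "benign-green", seed = 1L) {
  methods::new("PhantomSpec", height = as.integer(height),
               width = as.integer(width), lesionPresent = lesionPresent,
               targetArea = as.numeric(targetArea), lesionShape = lesionShape,
               contrast = contrast, speckleScale = speckleScale,
               maskEncoding = maskEncoding, rgbClass = rgbClass,
               seed = as.integer(seed))
}

# internal ImageSample builder; derives presence label, area and default
# stratum from the mask so the class invariants hold by construction
image_sample <- function(image, mask, category, sampleId,
                         stratum = NULL, role = "") {
  area <- sum(mask)
  methods::new("ImageSample", image = image, mask = mask, category = category,
               presenceLabel = if (area > 0) "lesion" else "normal",
               areaA = area,
               stratum = if (is.null(stratum)) {
                 if (area > 0) "unassigned" else "none"
               } else stratum,
               sampleId = sampleId, role = role)
}

#' Create a training augmentation policy
#'
#' Defaults follow the standard geometric-augmentation recipe: random
#' bicubic resize in [0.8, 1.25], a right-angle rotation (90/180/270
#' degrees) with probability 0.75, a small rotation in [-10, 10] degrees,
#' center cropping to 90\% and independent horizontal/vertical flips with
#' probability 0.5, resampled to \code{targetSize} at the end.
#'
#' @param resizeScaleRange,coarseRotations,coarseProb,fineRotationRange
#'   see \linkS4class{AugmentationPolicy}
#' @param cropFraction,flipProbabilities,targetSize
#'   see \linkS4class{AugmentationPolicy}
#' @return a validated \linkS4class{AugmentationPolicy}
#' @export
augmentationPolicy <- function(resizeScaleRange = c(0.8, 1.25),
                               coarseRotations = c(90, 180, 270),
                               coarseProb = 0.75,
                               fineRotationRange = c(-10, 10),
                               cropFraction = 0.9,
                               flipProbabilities = c(0.5, 0.5),
                               targetSize = 256L) {
  methods::new("AugmentationPolicy", resizeScaleRange = resizeScaleRange,
               coarseRotations = coarseRotations, coarseProb = coarseProb,
               fineRotationRange = fineRotationRange,
               cropFraction = cropFraction,
               flipProbabilities = flipProbabilities,
               targetSize = as.integer(targetSize))
}

#' Create a model configuration
#'
#' With no arguments this returns the calibrated full-size N-Unet
#' configuration (8.95 M parameters, 14.74 G at 256x256; see
#' \code{\link{countParams}}). Passing a shorter \code{encoderChannels}
#' schedule yields a reduced model for experimentation; side and gate
#' widths then default to the schedule itself and half of it.
#'
#' @param encoderChannels strictly increasing channel schedule
#' @param inputSize square input resolution
#' @param affSideWidths,gateWidths per-level AFF side-branch and
#'   attention-gate widths; defaulted as described above
#' @param seReduction,cbamReduction,cbamSpatialKernel,affDropout block
#'   hyperparameters (defaults 16, 16, 7, 0.2)
#' @param headHidden hidden width of the classification head (default
#'   twice the bottleneck width)
#' @return a validated \linkS4class{ModelConfig}
#' @export
modelConfig <- function(encoderChannels = c(16L, 32L, 64L, 128L, 256L),
                        inputSize = 256L,
                        affSideWidths = NULL, gateWidths = NULL,
                        seReduction = 16L, cbamReduction = 16L,
                        cbamSpatialKernel = 7L, affDropout = 0.2,
                        headHidden = NULL) {
  ch <- as.integer(encoderChannels)
  default_full <- identical(ch, c(16L, 32L, 64L, 128L, 256L))
  if (is.null(affSideWidths)) {
    affSideWidths <- if (default_full) c(25L, 32L, 64L, 128L, 96L) else ch
  }
  if (is.null(gateWidths)) {
    gateWidths <- if (default_full) c(16L, 16L, 32L, 64L, 128L)
                  else pmax(1L, ch %/% 2L)
  }
  bott <- 2L * ch[length(ch)]
  if (is.null(headHidden)) headHidden <- 2L * bott
  methods::new("ModelConfig", inputChannels = 3L,
               inputSize = as.integer(inputSize), encoderChannels = ch,
               bottleneckChannels = bott, seReduction = as.integer(seReduction),
               cbamReduction = as.integer(cbamReduction),
               cbamSpatialKernel = as.integer(cbamSpatialKernel),
               affDropout = affDropout,
               affSideWidths = as.integer(affSideWidths),
               gateWidths = as.integer(gateWidths),
               headDims = c(bott, as.integer(headHidden), 2L),
               segOutChannels = 1L)
}

#' Create an adaptive multi-task loss state
#'
#' @param gamma focal focusing parameter (default 2)
#' @param omega lesion-class weight N_neg / N_pos (default 1; computed from
#'   the training fold via \code{\link{computeClassWeight}} in practice)
#' @param epsilon Dice smoothing constant (default 1e-5)
#' @param logVar initial log-variances; the default c(0, 0) corresponds to
#'   sigma_1 = sigma_2 = 1
#' @return a validated \linkS4class{LossState}
#' @export
lossState <- function(gamma = 2, omega = 1, epsilon = 1e-5,
                      logVar = c(0, 0)) {
  methods::new("LossState", gamma = gamma, omega = omega, epsilon = epsilon,
               logVar = logVar, taskCount = length(logVar))
}

#' Create a training configuration
#'
#' Defaults are the published settings (batch size 6, 800 epochs, Adam at
#' 1e-5 with cosine annealing); tests and the end-to-end smoke pipeline
#' pass far smaller \code{epochs}.
#'
#' @param batchSize,epochs,initialLr,lrSchedule,seed,checkpointDir,selectMetric
#'   see \linkS4class{TrainConfig}
#' @return a validated \linkS4class{TrainConfig}
#' @export
trainConfig <- function(batchSize = 6L, epochs = 800L, initialLr = 1e-5,
                        lrSchedule = "cosine", seed = 1L,
                        checkpointDir = tempdir(),
                        selectMetric = "val_loss") {
  methods::new("TrainConfig", batchSize = as.integer(batchSize),
               epochs = as.integer(epochs), optimizer = "adam",
               initialLr = initialLr, lrSchedule = lrSchedule,
               seed = as.integer(seed), checkpointDir = checkpointDir,
               selectMetric = selectMetric)
}

## ---- accessors and show methods ------------------------------------------

#' @describeIn imageData-accessors image array of a sample
#' @export
imageData <- function(x) x@image

#' Accessors for ImageSample slots
#'
#' @param x an \linkS4class{ImageSample}
#' @return the corresponding slot value
#' @name imageData-accessors
NULL

#' @describeIn imageData-accessors binary mask matrix
#' @export
maskData <- function(x) x@mask

#' @describeIn imageData-accessors diagnostic category
#' @export
category <- function(x) x@category

#' @describeIn imageData-accessors lesion-presence label
#' @export
presenceLabel <- function(x) x@presenceLabel

#' @describeIn imageData-accessors lesion area A in pixels
#' @export
lesionAreaA <- function(x) x@areaA

#' @describeIn imageData-accessors sample identifier
#' @export
sampleId <- function(x) x@sampleId

setMethod("show", "ImageSample", function(object) {
  d <- dim(object@image)
  cat("ImageSample", object@sampleId, sprintf("(%dx%d)", d[1], d[2]),
      "category:", object@category,
      "| A =", object@areaA, "px | stratum:", object@stratum, "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d %s targetArea=%g encoding=%s seed=%d\n",
              object@height, object@width,
              if (object@lesionPresent) object@lesionShape else "normal",
              object@targetArea, object@maskEncoding, object@seed))
})

setMethod("show", "SplitAssignment", function(object) {
  sizes <- vapply(object@folds, function(f)
    sprintf("%d/%d/%d", length(f$train), length(f$val), length(f$test)),
    character(1))
  cat(sprintf("SplitAssignment with %d folds (train/val/test): %s\n",
              object@k, paste(sizes, collapse = ", ")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %dx%d input, encoder %s, bottleneck %d, head %s\n",
    object@inputSize, object@inputSize,
    paste(object@encoderChannels, collapse = "-"),
    object@bottleneckChannels, paste(object@headDims, collapse = "->")))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", object@nImages, "images",
      sprintf("(%d excluded from segmentation by the empty-mask rule)\n",
              object@excludedCount))
  cl <- object@classification
  cat("  classification:",
      paste(sprintf("%s=%.4f", names(cl), cl), collapse = " "), "\n")
  sg <- object@segmentation
  cat("  segmentation:  ",
      paste(sprintf("%s=%.4f", names(sg), sg), collapse = " "), "\n")
})

setMethod("show", "ComplexityReport", function(object) {
  cat(sprintf(
    "ComplexityReport: %.2f M parameters, %.2f G (%.4f GMACs) at %dx%d\n",
    object@totalParams / 1e6, object@totalFlops / 1e9, object@totalMacs / 1e9,
    object@inputSize, object@inputSize))
})
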