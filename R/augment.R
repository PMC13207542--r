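# Training-only geometric augmentation and deterministic evaluation
# preprocessing. Dataset splitting strictly precedes augmentation: the
# augmenter refuses any sample whose role is not "train", so no derivative
# of a validation or test image can enter the training stream. Images are
# interpolated bicubically, masks with nearest-neighbor, and one geometric
# draw is applied jointly to both, keeping masks {0, 1}-valued throughout.

#' Random training augmentation
#'
#' Applies, in order: random resize (scale drawn from
#' \code{resizeScaleRange}), a right-angle rotation (90/180/270 degrees)
#' with probability \code{coarseProb}, a small random rotation from
#' \code{fineRotationRange}, center cropping to \code{cropFraction}, random
#' horizontal/vertical flips, and a final resize to \code{targetSize}.
#' Consumes the global RNG stream (seed it for reproducibility).
#'
#' @param sample an \linkS4class{ImageSample} whose \code{role} is
#'   \code{"train"}; anything else is rejected (leakage guard)
#' @param policy an \linkS4class{AugmentationPolicy}
#' @return the augmented \linkS4class{ImageSample}
#' @export
augmentTrain <- function(sample, policy = augmentationPolicy()) {
  if (sample@role != "train") {
    stop("augmentation refused: sample ", sampleId(sample),
         " is not flagged as training (role = '", sample@role,
         "'); augmenting validation or test images would leak")
  }
  img <- imageData(sample)
  mask <- maskData(sample)
  s <- stats::runif(1, policy@resizeScaleRange[1], policy@resizeScaleRange[2])
  nh <- max(8L, round(nrow(mask) * s))
  nw <- max(8L, round(ncol(mask) * s))
  img <- clamp01(resizeImage(img, nh, nw, "bicubic"))
  mask <- resizeImage(mask, nh, nw, "nearest")
  if (stats::runif(1) < policy@coarseProb) {
    kturn <- base::sample(seq_along(policy@coarseRotations), 1)
    quarters <- policy@coarseRotations[kturn] / 90
    img <- rot90k(img, quarters)
    mask <- rot90k(mask, quarters)
  }
  ang <- stats::runif(1, policy@fineRotationRange[1],
                      policy@fineRotationRange[2])
  if (ang != 0) {
    img <- clamp01(rotateImage(img, ang, "bicubic"))
    mask <- rotateImage(mask, ang, "nearest")
  }
  if (policy@cropFraction < 1) {
    img <- centerCrop(img, policy@cropFraction)
    mask <- centerCrop(mask, policy@cropFraction)
  }
  if (stats::runif(1) < policy@flipProbabilities[1]) {
    img <- flipH(img); mask <- flipH(mask)
  }
  if (stats::runif(1) < policy@flipProbabilities[2]) {
    img <- flipV(img); mask <- flipV(mask)
  }
  tg <- policy@targetSize
  img <- clamp01(resizeImage(img, tg, tg, "bicubic"))
  mask <- resizeImage(mask, tg, tg, "nearest")
  image_sample(img, mask, category(sample), sampleId(sample),
               role = sample@role)
}

#' Deterministic evaluation preprocessing
#'
#' Resize to the target resolution (bicubic image, nearest-neighbor mask)
#' and per-image min-max intensity normalization to [0, 1]. Consumes no
#' randomness; calling it twice gives identical output.
#'
#' @param sample an \linkS4class{ImageSample}
#' @param targetSize output resolution in pixels (default 256)
#' @return the preprocessed \linkS4class{ImageSample}
#' @export
preprocessEval <- function(sample, targetSize = 256L) {
  img <- imageData(sample)
  mask <- maskData(sample)
  if (nrow(mask) != targetSize || ncol(mask) != targetSize) {
    img <- resizeImage(img, targetSize, targetSize, "bicubic")
    mask <- resizeImage(mask, targetSize, targetSize, "nearest")
  }
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
         else img * 0
  image_sample(img, mask, category(sample), sampleId(sample),
               stratum = sample@stratum, role = sample@role)
}
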