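# Classification-gated inference: the conditional segmentation boosting
# (CSB) rule. The classifier's discrete decision sigma (0 = nodule-
# containing, 1 = normal) scalar-gates the whole segmentation map,
# S_hat = (1 - sigma) * S: predictions on images classified normal are
# fully suppressed, everything else passes through unchanged. Information
# flows strictly one way -- the decision never reads the segmentation map
# -- and the gate adds no parameters. The flip side is an asymmetric risk:
# a false-negative classification deterministically zeroes a true lesion.

#' Classification decision from logits
#'
#' Column/index 1 is the lesion class, so sigma equals 0 exactly when the
#' lesion logit wins the argmax; ties break toward the lesion class
#' (sigma = 0).
#'
#' @param logits length-2 numeric vector (lesion, normal); must be finite
#' @return a list with \code{sigma} (0 = nodule-containing, 1 = normal) and
#'   \code{lesionProbability} (the softmax probability of the lesion class)
#' @export
decideClass <- function(logits) {
  if (length(logits) != 2L || !all(is.finite(logits))) {
    stop("decideClass expects two finite logits")
  }
  z <- logits - max(logits)
  p <- exp(z[1]) / sum(exp(z))
  list(sigma = if (logits[1] >= logits[2]) 0 else 1, lesionProbability = p)
}

#' Conditional segmentation boosting gate
#'
#' @param S segmentation map (any numeric array)
#' @param sigma discrete decision, exactly 0 or 1
#' @return (1 - sigma) * S: S unchanged when sigma = 0, all-zero when
#'   sigma = 1
#' @export
csbGate <- function(S, sigma) {
  if (!sigma %in% c(0, 1)) stop("sigma must be exactly 0 or 1")
  (1 - sigma) * S
}

#' Full gated prediction for one image
#'
#' Forward pass, classification decision, CSB gating of the probability
#' map, and thresholding into a binary mask. Because the gate is a binary
#' scalar, gate-then-threshold and threshold-then-gate give identical
#' masks.
#'
#' @param model a trained \code{NUnetModel}
#' @param image H x W x 3 array or an \linkS4class{ImageSample}
#' @param threshold binarization threshold on the probability map
#'   (default 0.5, the sigmoid midpoint)
#' @return a list with \code{presenceLabel}, \code{mask} (binary matrix
#'   after gating), \code{lesionProbability}, \code{sigma} and
#'   \code{probMap} (the raw pre-gate probability map)
#' @export
predictSample <- function(model, image, threshold = 0.5) {
  if (methods::is(image, "ImageSample")) image <- imageData(image)
  out <- nunetForward(model, image, training = FALSE)
  dec <- decideClass(out$logits[1, ])
  raw <- matrix(out$seg[, , 1], dim(out$seg)[1], dim(out$seg)[2])
  gated <- csbGate(raw, dec$sigma)
  list(presenceLabel = if (dec$sigma == 0) "lesion" else "normal",
       mask = (gated >= threshold) + 0,
       lesionProbability = dec$lesionProbability,
       sigma = dec$sigma, probMap = raw)
}
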