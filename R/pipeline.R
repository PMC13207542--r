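# Mask decoding, lesion-area stratification and the leakage-free stratified
# five-fold 6:2:2 splitting protocol. Lesion-positive samples are tiered
# into small / medium / large by the empirical 33% and 66% quantiles of
# their foreground area; normal (zero-area) samples take part in
# category-level stratification only, which keeps the tiers undistorted.

#' Decode an RGB-coded lesion mask to binary
#'
#' Green (benign) and red (malignant) regions merge into a single
#' foreground class; black pixels are background. Pixels matching no known
#' code are treated as background and counted in a one-shot warning.
#'
#' @param rgbMask H x W x 3 array with values in [0, 1]
#' @return H x W matrix with values in {0, 1}
#' @export
binarizeMask <- function(rgbMask) {
  if (length(dim(rgbMask)) != 3L || dim(rgbMask)[3] < 3L) {
    stop("binarizeMask expects an H x W x 3 color mask")
  }
  R <- rgbMask[, , 1]; G <- rgbMask[, , 2]; B <- rgbMask[, , 3]
  green <- G >= 0.5 & R < 0.5 & B < 0.5
  red <- R >= 0.5 & G < 0.5 & B < 0.5
  black <- R < 0.25 & G < 0.25 & B < 0.25
  unknown <- sum(!(green | red | black))
  if (unknown > 0) {
    warning(unknown, " mask pixel(s) matched no known color code; ",
            "treated as background")
  }
  (green | red) + 0
}

#' Lesion area: foreground pixel count of a binary mask
#'
#' @param mask a {0, 1}-valued matrix (conventionally at the standardized
#'   256 x 256 resolution)
#' @return the number of foreground pixels A
#' @export
lesionArea <- function(mask) {
  if (!is_binary_mask(mask)) stop("lesionArea requires a {0,1}-valued mask")
  sum(mask)
}

#' Size-stratification thresholds from lesion areas
#'
#' Zero areas (normal samples) are excluded, then alpha and beta are the
#' empirical 33\% and 66\% quantiles of the remaining areas under the
#' linear-interpolation rule (order-statistic index 1 + (n-1)p, R type 7).
#'
#' @param areas numeric vector of lesion areas in pixels
#' @return a \linkS4class{StratificationThresholds}
#' @export
computeThresholds <- function(areas) {
  pos <- areas[areas > 0]
  if (length(pos) == 0) {
    stop("cannot stratify: no lesion-positive samples (all areas zero)")
  }
  q <- stats::quantile(pos, c(0.33, 0.66), names = FALSE, type = 7)
  methods::new("StratificationThresholds", alpha = q[1], beta = q[2])
}

#' Assign a lesion-size stratum
#'
#' A = 0 maps to \code{"none"} (normal sample, outside the size tiers);
#' otherwise A < alpha is small, alpha <= A < beta is medium and
#' A >= beta is large (left-closed boundaries).
#'
#' @param areaA lesion area in pixels (>= 0)
#' @param thresholds a \linkS4class{StratificationThresholds}
#' @return one of \code{"none"}, \code{"small"}, \code{"medium"},
#'   \code{"large"}
#' @export
stratifyArea <- function(areaA, thresholds) {
  if (any(areaA < 0)) stop("lesion area must be non-negative")
  out <- character(length(areaA))
  out[areaA == 0] <- "none"
  out[areaA > 0 & areaA < thresholds@alpha] <- "small"
  out[areaA >= thresholds@alpha & areaA < thresholds@beta] <- "medium"
  out[areaA >= thresholds@beta] <- "large"
  out
}

#' Stratified five-fold 6:2:2 split
#'
#' Samples are grouped into strata (category x size tier), each stratum is
#' shuffled once and partitioned into k near-equal blocks, and fold f then
#' uses block f as test, block f+1 (mod k) as validation and the remaining
#' k-2 blocks as training -- the rotation that realizes an approximate
#' 6:2:2 ratio inside five-fold cross-validation. Per-stratum proportions
#' are preserved within one sample per block; a stratum with fewer members
#' than folds is still distributed (never duplicated) with a warning.
#'
#' @param manifest data.frame with \code{sample_id} and \code{category}
#'   columns and either a \code{stratum} or an \code{area} column (areas
#'   are converted using \code{thresholds})
#' @param k number of folds (default 5)
#' @param thresholds optional \linkS4class{StratificationThresholds},
#'   required when only areas are given
#' @param seed integer seed for the single shuffle
#' @return a validated \linkS4class{SplitAssignment}
#' @export
makeFolds <- function(manifest, k = 5L, thresholds = NULL, seed = 1L) {
  if (is.null(manifest$stratum)) {
    if (is.null(manifest$area)) {
      stop("manifest needs a 'stratum' or an 'area' column")
    }
    if (is.null(thresholds)) thresholds <- computeThresholds(manifest$area)
    manifest$stratum <- stratifyArea(manifest$area, thresholds)
  }
  k <- as.integer(k)
  strata <- split(manifest$sample_id,
                  paste(manifest$category, manifest$stratum))
  small <- names(strata)[vapply(strata, length, integer(1)) < k]
  if (length(small)) {
    warning("stratum ", paste(small, collapse = ", "),
            " has fewer samples than folds; ",
            "its members are spread without duplication")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  blocks <- rep(list(character(0)), k)
  offset <- 0L
  for (ids in strata) {
    ids <- sample(ids)
    # rotate the starting block between strata so remainders spread evenly
    asg <- (seq_along(ids) - 1L + offset) %% k + 1L
    for (b in seq_len(k)) blocks[[b]] <- c(blocks[[b]], ids[asg == b])
    offset <- (offset + length(ids)) %% k
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- f
    val <- f %% k + 1L
    train <- setdiff(seq_len(k), c(test, val))
    list(train = sort(unlist(blocks[train])),
         val = sort(blocks[[val]]),
         test = sort(blocks[[test]]))
  })
  methods::new("SplitAssignment", k = k, folds = folds,
               seed = as.integer(seed))
}

#' Write / read a split assignment as JSON
#'
#' @param split a \linkS4class{SplitAssignment}
#' @param path output JSON path
#' @return \code{path} (write) or a \linkS4class{SplitAssignment} (read)
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(list(k = split@k, seed = split@seed,
                            folds = split@folds),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(x$folds, function(f) list(
    train = vapply(f$train, as.character, character(1), USE.NAMES = FALSE),
    val = vapply(f$val, as.character, character(1), USE.NAMES = FALSE),
    test = vapply(f$test, as.character, character(1), USE.NAMES = FALSE)))
  methods::new("SplitAssignment", k = as.integer(x$k), folds = folds,
               seed = as.integer(x$seed))
}

# tag each sample with its role in the given fold (leakage bookkeeping)
assign_roles <- function(samples, split, fold) {
  f <- split@folds[[fold]]
  lapply(samples, function(s) {
    s@role <- if (sampleId(s) %in% f$train) "train"
              else if (sampleId(s) %in% f$val) "val"
              else if (sampleId(s) %in% f$test) "test"
              else ""
    s
  })
}
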