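# Synthetic breast-ultrasound phantoms: a smooth low-frequency tissue field
# multiplied by unit-mean Rayleigh speckle (the first-order model of
# coherent ultrasound texture), with an optional hypoechoic lesion of
# controlled pixel area -- an ellipse whose boundary can carry a radial
# sinusoidal perturbation to emulate irregular lesion morphology. The
# lesion scale is found by bisection so the mask foreground count hits the
# requested area. Phantoms stand in for clinical data in every test; they
# emulate speckle, low contrast and the two-orders-of-magnitude lesion-size
# range, not acoustic shadowing or beam physics.

# unit-mean Rayleigh draws (scale sqrt(2/pi) makes E[X] = 1)
rayleigh_unit <- function(n) sqrt(2 / pi) * sqrt(-2 * log(stats::runif(n)))

# smooth tissue background: coarse Gaussian grid, bicubically upsampled
tissue_field <- function(H, W) {
  gh <- max(4L, ceiling(H / 32L))
  gw <- max(4L, ceiling(W / 32L))
  coarse <- matrix(stats::rnorm(gh * gw, 0.62, 0.07), gh, gw)
  resizeImage(coarse, H, W, "bicubic")
}

# binary lesion mask for a given scale t; geometry fixed by `geo`
lesion_mask_at <- function(H, W, geo, t) {
  a <- t
  b <- t * geo$aspect
  r <- rep(seq_len(H), W) - geo$cy
  c <- rep(seq_len(W), each = H) - geo$cx
  u <- cos(geo$theta) * r + sin(geo$theta) * c
  v <- -sin(geo$theta) * r + cos(geo$theta) * c
  rho <- sqrt((u / a)^2 + (v / b)^2)
  lim <- 1 + geo$amp * sin(geo$freq * atan2(v / b, u / a) + geo$phase)
  matrix(as.numeric(rho <= lim), H, W)
}

#' Generate one synthetic phantom
#'
#' Deterministic for a fixed \code{seed}: the same \linkS4class{PhantomSpec}
#' always yields bit-identical image and mask. The lesion is hypoechoic
#' (interior intensity reduced by the spec's contrast) and its foreground
#' pixel count is driven to within 15\% of \code{targetArea} (closely for
#' all but the tiniest lesions, where pixel quantization dominates).
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return an \linkS4class{ImageSample}; the category is \code{"normal"}
#'   for lesion-free phantoms, otherwise taken from the spec's
#'   \code{rgbClass} (benign or malignant)
#' @export
generatePhantom <- function(spec) {
  methods::validObject(spec)
  old <- local_seed(spec@seed)
  on.exit(restore_seed(old))
  H <- spec@height; W <- spec@width
  tissue <- tissue_field(H, W)
  mask <- matrix(0, H, W)
  if (spec@lesionPresent) {
    geo <- list(
      cy = H * stats::runif(1, 0.4, 0.6),
      cx = W * stats::runif(1, 0.4, 0.6),
      theta = stats::runif(1, 0, pi),
      aspect = stats::runif(1, 0.55, 0.95),
      amp = if (spec@lesionShape == "perturbed-ellipse") 0.18 else 0,
      freq = sample(3:6, 1),
      phase = stats::runif(1, 0, 2 * pi))
    lo <- 0.5
    hi <- max(H, W)
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      area <- sum(lesion_mask_at(H, W, geo, mid))
      if (area < spec@targetArea) lo <- mid else hi <- mid
    }
    mask <- lesion_mask_at(H, W, geo, hi)
    tissue <- tissue * (1 - spec@contrast * mask)
  }
  speckle <- matrix(rayleigh_unit(H * W), H, W)
  intensity <- clamp01(tissue * (1 + spec@speckleScale * (speckle - 1)))
  img <- array(rep(intensity, 3L), c(H, W, 3L))
  cat <- if (!spec@lesionPresent) "normal"
         else if (spec@rgbClass == "malignant-red") "malignant" else "benign"
  image_sample(img, mask, cat, sprintf("phantom-seed%d", spec@seed))
}

#' Generate a phantom cohort with a controlled class mix
#'
#' Class counts are the rounded \code{n * classMix} proportions (largest
#' remainder completion), lesion areas are drawn log-uniformly between
#' \code{areaRange[1]} and \code{areaRange[2]} pixels (spanning the roughly
#' two orders of magnitude seen in clinical lesion sizes), and every
#' per-sample phantom seed derives from \code{seed}, so the whole cohort is
#' reproducible.
#'
#' @param n cohort size
#' @param classMix named proportions over benign/malignant/normal, summing
#'   to 1 (within 1e-9)
#' @param areaRange lesion-area law bounds in pixels (log-uniform)
#' @param size canvas side in pixels
#' @param maskEncoding encoding used when the cohort is written to disk
#' @param contrast,speckleScale,lesionShape forwarded to each phantom spec
#' @param seed integer master seed
#' @return a list with \code{samples} (list of \linkS4class{ImageSample})
#'   and \code{manifest} (data.frame: sample_id, image_path, mask_path,
#'   category)
#' @export
generateCohort <- function(n,
                           classMix = c(benign = 0.56, malignant = 0.27,
                                        normal = 0.17),
                           areaRange = c(500, 8000), size = 256L,
                           maskEncoding = "grayscale-binary",
                           contrast = 0.55, speckleScale = 1,
                           lesionShape = "perturbed-ellipse", seed = 1L) {
  if (n < 1) stop("cohort size must be at least 1")
  if (abs(sum(classMix) - 1) > 1e-9) {
    stop("class proportions must sum to 1 (got ", sum(classMix), ")")
  }
  cls <- c("benign", "malignant", "normal")
  mix <- classMix[cls]
  mix[is.na(mix)] <- 0
  counts <- floor(n * mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * mix - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  categories <- rep(cls, counts)
  old <- local_seed(seed)
  areas <- exp(stats::runif(n, log(areaRange[1]), log(areaRange[2])))
  restore_seed(old)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    lesion <- categories[i] != "normal"
    sp <- phantomSpec(height = size, width = size, lesionPresent = lesion,
                      targetArea = if (lesion) round(areas[i]) else 0,
                      lesionShape = lesionShape, contrast = contrast,
                      speckleScale = speckleScale,
                      maskEncoding = maskEncoding,
                      rgbClass = if (categories[i] == "malignant")
                        "malignant-red" else "benign-green",
                      seed = derive_seed(seed, i))
    s <- generatePhantom(sp)
    s@sampleId <- sprintf("S%04d", i)
    samples[[i]] <- s
  }
  manifest <- data.frame(
    sample_id = vapply(samples, sampleId, character(1)),
    image_path = NA_character_, mask_path = NA_character_,
    category = categories, stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest,
       maskEncoding = maskEncoding, seed = seed)
}

#' Write a cohort to disk
#'
#' Writes one image PNG and one mask PNG per sample plus a manifest CSV.
#' PNG storage is lossless at these value sets, so a round trip through
#' \code{\link{readCohort}} reproduces every mask bit-exactly.
#'
#' @param cohort a list from \code{\link{generateCohort}}, or a bare list
#'   of \linkS4class{ImageSample} objects
#' @param directory output directory (created if needed)
#' @param maskEncoding \code{"grayscale-binary"} (white-on-black) or
#'   \code{"rgb-coded"} (green = benign, red = malignant, black background)
#' @return the manifest file path, invisibly
#' @export
writeCohort <- function(cohort, directory,
                        maskEncoding = NULL) {
  samples <- if (!is.null(cohort$samples)) cohort$samples else cohort
  if (is.null(maskEncoding)) {
    maskEncoding <- if (!is.null(cohort$maskEncoding)) cohort$maskEncoding
                    else "grayscale-binary"
  }
  dir.create(file.path(directory, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ipath <- file.path(directory, "images", paste0(sampleId(s), ".png"))
    mpath <- file.path(directory, "masks", paste0(sampleId(s), "_mask.png"))
    ok <- try(png::writePNG(imageData(s), ipath), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write image: ", ipath)
    m <- maskData(s)
    mi <- if (maskEncoding == "rgb-coded") {
      enc <- array(0, c(nrow(m), ncol(m), 3L))
      chan <- if (category(s) == "malignant") 1L else 2L  # red / green
      enc[, , chan] <- m
      enc
    } else m
    ok <- try(png::writePNG(mi, mpath), silent = TRUE)
    if (inherits(ok, "try-error")) stop("failed to write mask: ", mpath)
    rows[[i]] <- data.frame(sample_id = sampleId(s), image_path = ipath,
                            mask_path = mpath, category = category(s),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' Masks are decoded according to their stored convention: grayscale masks
#' threshold white-on-black, RGB-coded masks go through
#' \code{\link{binarizeMask}} (green and red merge into one foreground
#' class).
#'
#' @param manifestPath path to a manifest CSV written by
#'   \code{\link{writeCohort}}
#' @return a list with \code{samples} and \code{manifest}
#' @export
readCohort <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- png::readPNG(manifest$image_path[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    mraw <- png::readPNG(manifest$mask_path[i])
    mask <- if (length(dim(mraw)) == 3L) binarizeMask(mraw)
            else (mraw > 0.5) + 0
    samples[[i]] <- image_sample(img, mask, manifest$category[i],
                                 manifest$sample_id[i])
  }
  list(samples = samples, manifest = manifest)
}
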