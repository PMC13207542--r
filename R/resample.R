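# Image resampling: separable resize and in-plane rotation with bicubic
# (Keys, a = -0.5) interpolation for intensity images and nearest-neighbor
# for label masks. No installed package provides bicubic resampling, so the
# kernels are implemented here; masks always go through nearest-neighbor so
# they stay exactly {0, 1}-valued.

keys_kernel <- function(d) {
  a <- -0.5
  d <- abs(d)
  ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
         ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
}

# interpolation matrix mapping n_in samples to n_out (half-pixel centers,
# edge replication via index clamping)
resample_matrix <- function(n_in, n_out, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out + 0.5  # 1-based source coordinate
    if (method == "nearest") {
      j <- min(max(round(src), 1L), n_in)
      A[i, j] <- 1
    } else {
      base <- floor(src)
      for (t in -1:2) {
        j <- base + t
        w <- keys_kernel(src - j)
        jc <- min(max(j, 1), n_in)
        A[i, jc] <- A[i, jc] + w
      }
    }
  }
  A
}

# resize a matrix or H x W x C array to height x width
resizeImage <- function(x, height, width, method = "bicubic") {
  d <- dim(x)
  Ar <- resample_matrix(d[1], height, method)
  Ac <- resample_matrix(d[2], width, method)
  res1 <- function(m) Ar %*% m %*% t(Ac)
  if (length(d) == 2L) {
    res1(x)
  } else {
    out <- array(0, c(height, width, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- res1(x[, , k])
    out
  }
}

# exact right-angle rotation (counter-clockwise by 90 * k degrees)
rot90k <- function(x, k) {
  k <- ((k %% 4) + 4) %% 4
  one <- function(m) switch(as.character(k),
    "0" = m,
    "1" = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
    "2" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    "3" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
  d <- dim(x)
  if (length(d) == 2L) return(one(x))
  slices <- lapply(seq_len(d[3]), function(kk) one(x[, , kk]))
  out <- array(0, c(dim(slices[[1]]), d[3]))
  for (kk in seq_len(d[3])) out[, , kk] <- slices[[kk]]
  out
}

# arbitrary-angle rotation about the image center (degrees,
# counter-clockwise); out-of-canvas samples are filled with 0
rotateImage <- function(x, angle, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep(seq_len(H), W) - cy
  c <- rep(seq_len(W), each = H) - cx
  # inverse map: rotate output coords by -theta into the source frame
  sy <- cos(th) * r + sin(th) * c + cy
  sx <- -sin(th) * r + cos(th) * c + cx
  one <- if (method == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    iy <- pmin(pmax(iy, 1L), H); ix <- pmin(pmax(ix, 1L), W)
    function(m) {
      v <- m[cbind(iy, ix)]
      v[!ok] <- 0
      matrix(v, H, W)
    }
  } else {
    by <- floor(sy); bx <- floor(sx)
    inside <- sy >= 0.5 & sy <= H + 0.5 & sx >= 0.5 & sx <= W + 0.5
    taps <- list()
    for (ty in -1:2) for (tx in -1:2) {
      jy <- by + ty; jx <- bx + tx
      w <- keys_kernel(sy - jy) * keys_kernel(sx - jx)
      taps[[length(taps) + 1L]] <- list(
        iy = pmin(pmax(jy, 1L), H), ix = pmin(pmax(jx, 1L), W), w = w)
    }
    function(m) {
      v <- numeric(H * W)
      for (tp in taps) v <- v + tp$w * m[cbind(tp$iy, tp$ix)]
      v[!inside] <- 0
      matrix(v, H, W)
    }
  }
  if (length(d) == 2L) return(one(x))
  out <- array(0, d)
  for (k in seq_len(d[3])) out[, , k] <- one(x[, , k])
  out
}

# center crop to a fraction of each side
centerCrop <- function(x, fraction) {
  d <- dim(x)
  nh <- max(1L, round(d[1] * fraction))
  nw <- max(1L, round(d[2] * fraction))
  r0 <- (d[1] - nh) %/% 2L
  c0 <- (d[2] - nw) %/% 2L
  if (length(d) == 2L) x[r0 + seq_len(nh), c0 + seq_len(nw), drop = FALSE]
  else x[r0 + seq_len(nh), c0 + seq_len(nw), , drop = FALSE]
}

flipH <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) x[, rev(seq_len(d[2])), drop = FALSE]
  else x[, rev(seq_len(d[2])), , drop = FALSE]
}

flipV <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) x[rev(seq_len(d[1])), , drop = FALSE]
  else x[rev(seq_len(d[1])), , , drop = FALSE]
}
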