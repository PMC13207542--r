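# Independent brute-force oracles (plain nested loops, no shared code with
# the package's convolution/attention machinery) and small fixture builders.

# standard convolution, stride 1, same padding: x H x W x C, w k x k x C x Cout
brute_conv <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)[1]; pad <- (k - 1) / 2; cout <- dim(w)[4]
  out <- array(0, c(d[1], d[2], cout))
  for (o in seq_len(cout)) {
    for (h in seq_len(d[1])) {
      for (v in seq_len(d[2])) {
        acc <- if (is.null(b)) 0 else b[o]
        for (c in seq_len(d[3])) {
          for (di in seq_len(k)) {
            for (dj in seq_len(k)) {
              hh <- h + di - 1 - pad
              ww <- v + dj - 1 - pad
              if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2]) {
                acc <- acc + x[hh, ww, c] * w[di, dj, c, o]
              }
            }
          }
        }
        out[h, v, o] <- acc
      }
    }
  }
  out
}

# depthwise stage: one kernel per channel
brute_dwconv <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)[1]; pad <- (k - 1) / 2
  out <- array(0, d)
  for (c in seq_len(d[3])) {
    for (h in seq_len(d[1])) {
      for (v in seq_len(d[2])) {
        acc <- if (is.null(b)) 0 else b[c]
        for (di in seq_len(k)) {
          for (dj in seq_len(k)) {
            hh <- h + di - 1 - pad
            ww <- v + dj - 1 - pad
            if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2]) {
              acc <- acc + x[hh, ww, c] * w[di, dj, c]
            }
          }
        }
        out[h, v, c] <- acc
      }
    }
  }
  out
}

# explicit SE evaluation: two-layer perceptron on the GAP descriptor
brute_se <- function(x, w1, b1, w2, b2) {
  C <- dim(x)[3]
  z <- vapply(seq_len(C), function(c) mean(x[, , c]), numeric(1))
  h <- pmax(as.vector(z %*% w1) + b1, 0)
  s <- 1 / (1 + exp(-(as.vector(h %*% w2) + b2)))
  out <- x
  for (c in seq_len(C)) out[, , c] <- s[c] * x[, , c]
  list(out = out, s = s)
}

# explicit CBAM evaluation (channel then spatial attention)
brute_cbam <- function(x, w1, b1, w2, b2, spw, spb) {
  C <- dim(x)[3]
  mlp <- function(z) as.vector(pmax(as.vector(z %*% w1) + b1, 0) %*% w2) + b2
  zavg <- vapply(seq_len(C), function(c) mean(x[, , c]), numeric(1))
  zmax <- vapply(seq_len(C), function(c) max(x[, , c]), numeric(1))
  s <- 1 / (1 + exp(-(mlp(zavg) + mlp(zmax))))
  xc <- x
  for (c in seq_len(C)) xc[, , c] <- s[c] * x[, , c]
  pooled <- array(0, c(dim(x)[1], dim(x)[2], 2))
  for (h in seq_len(dim(x)[1])) {
    for (v in seq_len(dim(x)[2])) {
      pooled[h, v, 1] <- mean(xc[h, v, ])
      pooled[h, v, 2] <- max(xc[h, v, ])
    }
  }
  ms <- 1 / (1 + exp(-brute_conv(pooled, spw, spb)[, , 1]))
  out <- xc
  for (c in seq_len(C)) out[, , c] <- ms * xc[, , c]
  list(out = out, s = s, ms = ms)
}

# pairwise-comparison AUC (half credit for ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# small all-lesion phantom set at a given evaluation size, tagged as training
make_training_phantoms <- function(n = 8, canvas = 64L, evalSize = 32L,
                                   seed = 5L) {
  co <- generateCohort(n, classMix = c(benign = 0.5, malignant = 0.5,
                                       normal = 0),
                       areaRange = c(200, 1200), size = canvas, seed = seed)
  lapply(co$samples, function(s) {
    s@role <- "train"
    preprocessEval(s, evalSize)
  })
}
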