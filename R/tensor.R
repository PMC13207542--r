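# Reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are 4-D arrays with dim = c(H, W, N, C): the batch axis sits
# before channels so that matrix(x, H*W*N, C) exposes channels as columns,
# which lets every convolution run as k*k BLAS matrix products (shift-and-
# multiply form). Pooled descriptors are [N, C] matrices, per-sample vectors
# are length-N numerics, losses are length-1 scalars.
#
# A tape records nodes in creation order; backward() walks it in reverse,
# so any DAG built by the ops below differentiates correctly.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

node_new <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

tp_leaf <- function(tape, value) node_new(tape, value)

acc_grad <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

tp_backward <- function(tape, nd) {
  if (length(nd$v) != 1L) stop("backward() expects a scalar loss node")
  nd$g <- 1
  for (i in seq(tape$n, 1L)) {
    cur <- tape$nodes[[i]]
    if (!is.null(cur$g) && !is.null(cur$bw)) cur$bw(cur)
  }
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

op_relu <- function(tape, x) {
  node_new(tape, x$v * (x$v > 0), function(nd) acc_grad(x, nd$g * (x$v > 0)))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$v))
  node_new(tape, s, function(nd) acc_grad(x, nd$g * s * (1 - s)))
}

op_exp <- function(tape, x) {
  e <- exp(x$v)
  node_new(tape, e, function(nd) acc_grad(x, nd$g * e))
}

op_log <- function(tape, x) {
  node_new(tape, log(x$v), function(nd) acc_grad(x, nd$g / x$v))
}

op_pow <- function(tape, x, p) {
  node_new(tape, x$v^p, function(nd) acc_grad(x, nd$g * p * x$v^(p - 1)))
}

op_neg <- function(tape, x) {
  node_new(tape, -x$v, function(nd) acc_grad(x, -nd$g))
}

op_clamp <- function(tape, x, lo, hi) {
  keep <- x$v >= lo & x$v <= hi
  node_new(tape, pmin(pmax(x$v, lo), hi),
           function(nd) acc_grad(x, nd$g * keep))
}

# a and b must have identical shape, or one of them is a length-1 scalar node
op_add <- function(tape, a, b) {
  node_new(tape, a$v + b$v, function(nd) {
    acc_grad(a, if (length(a$v) == 1L && length(nd$g) > 1L) sum(nd$g) else nd$g)
    acc_grad(b, if (length(b$v) == 1L && length(nd$g) > 1L) sum(nd$g) else nd$g)
  })
}

op_sub <- function(tape, a, b) op_add(tape, a, op_neg(tape, b))

op_mul <- function(tape, a, b) {
  node_new(tape, a$v * b$v, function(nd) {
    ga <- nd$g * b$v
    gb <- nd$g * a$v
    acc_grad(a, if (length(a$v) == 1L && length(ga) > 1L) sum(ga) else ga)
    acc_grad(b, if (length(b$v) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

op_div <- function(tape, a, b) {
  node_new(tape, a$v / b$v, function(nd) {
    ga <- nd$g / b$v
    gb <- -nd$g * a$v / b$v^2
    acc_grad(a, if (length(a$v) == 1L && length(ga) > 1L) sum(ga) else ga)
    acc_grad(b, if (length(b$v) == 1L && length(gb) > 1L) sum(gb) else gb)
  })
}

# multiply / add with a constant (no gradient through k)
op_mulc <- function(tape, x, k) {
  node_new(tape, x$v * k, function(nd) acc_grad(x, nd$g * k))
}

op_addc <- function(tape, x, k) {
  node_new(tape, x$v + k, function(nd) acc_grad(x, nd$g))
}

op_sum <- function(tape, x) {
  d <- dim(x$v)
  node_new(tape, sum(x$v), function(nd) {
    g <- rep(nd$g, length(x$v))
    if (!is.null(d)) dim(g) <- d
    acc_grad(x, g)
  })
}

op_mean <- function(tape, x) {
  n <- length(x$v)
  d <- dim(x$v)
  node_new(tape, sum(x$v) / n, function(nd) {
    g <- rep(nd$g / n, n)
    if (!is.null(d)) dim(g) <- d
    acc_grad(x, g)
  })
}

## ---- linear algebra -------------------------------------------------------

# x: [N, Cin] node; w: [Cin, Cout] node; b: [Cout] node or NULL
op_linear <- function(tape, x, w, b = NULL) {
  y <- x$v %*% w$v
  if (!is.null(b)) y <- y + rep(b$v, each = nrow(y))
  node_new(tape, y, function(nd) {
    g <- nd$g
    acc_grad(x, g %*% t(w$v))
    acc_grad(w, t(x$v) %*% g)
    if (!is.null(b)) acc_grad(b, colSums(g))
  })
}

# select element i of a plain vector node
op_index <- function(tape, x, i) {
  node_new(tape, x$v[i], function(nd) {
    g <- numeric(length(x$v))
    g[i] <- nd$g
    acc_grad(x, g)
  })
}

# select column j of an [N, K] matrix as a length-N vector
op_col <- function(tape, x, j) {
  node_new(tape, x$v[, j], function(nd) {
    g <- matrix(0, nrow(x$v), ncol(x$v))
    g[, j] <- nd$g
    acc_grad(x, g)
  })
}

## ---- convolution ----------------------------------------------------------

# Convolutions run as one BLAS product on the im2col patch matrix; the
# patch gather/scatter and the depthwise loops live in src/conv_ops.cpp.

# standard convolution, stride 1, same padding, odd kernel.
# x: [H, W, N, Cin]; w: [k, k, Cin, Cout]; b: [Cout] node or NULL
op_conv2d <- function(tape, x, w, b = NULL) {
  dw <- dim(w$v)
  k <- dw[1]; cin <- dw[3]; cout <- dw[4]
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; N <- d[3]
  if (d[4] != cin) stop("conv2d: input has ", d[4], " channels, kernel expects ", cin)
  HWN <- H * W * N
  # weight as [k*k*cin, cout] with rows matching the im2col column order
  # (channel fastest, then di, then dj)
  W9 <- if (k == 1L) matrix(w$v, cin, cout)
        else matrix(aperm(w$v, c(3, 1, 2, 4)), k * k * cin, cout)
  xm <- x$v
  dim(xm) <- c(HWN, cin)
  P <- if (k == 1L) xm else cpp_im2col(x$v, H, W, N, cin, k)
  out <- P %*% W9
  if (!is.null(b)) out <- out + rep(b$v, each = HWN)
  dim(out) <- c(H, W, N, cout)
  node_new(tape, out, function(nd) {
    gm <- nd$g
    dim(gm) <- c(HWN, cout)
    dW9 <- crossprod(P, gm)
    dwv <- if (k == 1L) array(dW9, dw)
           else aperm(array(dW9, c(cin, k, k, cout)), c(2, 3, 1, 4))
    dP <- gm %*% t(W9)
    dx <- if (k == 1L) dP else cpp_col2im(dP, H, W, N, cin, k)
    dim(dx) <- d
    acc_grad(x, dx)
    acc_grad(w, dwv)
    if (!is.null(b)) acc_grad(b, colSums(gm))
  })
}

# depthwise convolution: one k x k kernel per channel.
# x: [H, W, N, C]; w: [k, k, C]; b: [C] node or NULL
op_dwconv2d <- function(tape, x, w, b = NULL) {
  dw <- dim(w$v)
  k <- dw[1]; C <- dw[3]
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; N <- d[3]
  if (d[4] != C) stop("dwconv2d: channel mismatch (", d[4], " vs ", C, ")")
  HWN <- H * W * N
  out <- cpp_dwconv(x$v, w$v, H, W, N, C, k)
  if (!is.null(b)) out <- out + rep(b$v, each = HWN)
  dim(out) <- d
  node_new(tape, out, function(nd) {
    bw <- cpp_dwconv_bwd(x$v, w$v, nd$g, H, W, N, C, k)
    dx <- bw$dx
    dim(dx) <- d
    dwv <- bw$dw
    dim(dwv) <- dw
    acc_grad(x, dx)
    acc_grad(w, dwv)
    if (!is.null(b)) {
      gm <- nd$g
      dim(gm) <- c(HWN, C)
      acc_grad(b, colSums(gm))
    }
  })
}

## ---- pooling and resampling ----------------------------------------------

op_maxpool2 <- function(tape, x) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]
  if (H %% 2L || W %% 2L) stop("maxpool2 requires even spatial dims")
  mp <- cpp_maxpool2(x$v, H, W, d[3], d[4])
  out <- mp$y
  dim(out) <- c(H %/% 2L, W %/% 2L, d[3], d[4])
  node_new(tape, out, function(nd) {
    dx <- numeric(length(x$v))
    # ties within a window resolve to the first candidate (top-left order)
    dx[mp$idx] <- dx[mp$idx] + as.vector(nd$g)
    dim(dx) <- d
    acc_grad(x, dx)
  })
}

# interpolation matrix for 2x bilinear upsampling (half-pixel centers)
upsample2_matrix <- function(H) {
  A <- matrix(0, 2L * H, H)
  for (i in seq_len(2L * H)) {
    src <- (i - 0.5) / 2 - 0.5
    i0 <- floor(src)
    fr <- src - i0
    lo <- min(max(i0 + 1, 1), H)
    hi <- min(max(i0 + 2, 1), H)
    A[i, lo] <- A[i, lo] + (1 - fr)
    A[i, hi] <- A[i, hi] + fr
  }
  A
}

.mat_cache <- new.env(parent = emptyenv())

upsample2_cached <- function(H) {
  key <- as.character(H)
  if (is.null(.mat_cache[[key]])) .mat_cache[[key]] <- upsample2_matrix(H)
  .mat_cache[[key]]
}

# apply matrix A to the H axis of a [H, W, N, C] array
apply_rows <- function(x, A) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])
  array(y, c(nrow(A), d[2], d[3], d[4]))
}

# apply matrix A to the W axis
apply_cols <- function(x, A) {
  xp <- aperm(x, c(2, 1, 3, 4))
  yp <- apply_rows(xp, A)
  aperm(yp, c(2, 1, 3, 4))
}

op_upsample2 <- function(tape, x) {
  d <- dim(x$v)
  AH <- upsample2_cached(d[1])
  AW <- upsample2_cached(d[2])
  y <- apply_cols(apply_rows(x$v, AH), AW)
  node_new(tape, y, function(nd) {
    acc_grad(x, apply_cols(apply_rows(nd$g, t(AH)), t(AW)))
  })
}

# global average pool: [H, W, N, C] -> [N, C]
op_gap <- function(tape, x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  cm <- colMeans(matrix(x$v, HW, d[3] * d[4]))
  node_new(tape, matrix(cm, d[3], d[4]), function(nd) {
    acc_grad(x, array(rep(as.vector(nd$g), each = HW) / HW, d))
  })
}

# global max pool over space: [H, W, N, C] -> [N, C]
op_gmaxpool <- function(tape, x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  m <- matrix(x$v, HW, d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  val <- m[idx + (seq_along(idx) - 1L) * HW]
  node_new(tape, matrix(val, d[3], d[4]), function(nd) {
    g <- matrix(0, HW, d[3] * d[4])
    g[idx + (seq_along(idx) - 1L) * HW] <- as.vector(nd$g)
    acc_grad(x, array(g, d))
  })
}

# channel-axis average and max pooling: [H, W, N, C] -> [H, W, N, 2]
op_chanpool <- function(tape, x) {
  d <- dim(x$v)
  HWN <- d[1] * d[2] * d[3]
  C <- d[4]
  m <- matrix(x$v, HWN, C)
  avg <- rowMeans(m)
  mx <- m[, 1]
  idx <- rep(1L, HWN)
  if (C > 1) for (cc in 2:C) {
    upd <- m[, cc] > mx
    mx[upd] <- m[upd, cc]
    idx[upd] <- cc
  }
  node_new(tape, array(c(avg, mx), c(d[1], d[2], d[3], 2L)), function(nd) {
    gm <- matrix(nd$g, HWN, 2L)
    dx <- matrix(rep(gm[, 1] / C, C), HWN, C)
    dx[cbind(seq_len(HWN), idx)] <- dx[cbind(seq_len(HWN), idx)] + gm[, 2]
    acc_grad(x, array(dx, d))
  })
}

# concatenate along channels
op_concat_c <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  if (!all(da[1:3] == db[1:3])) stop("concat: spatial/batch dims differ")
  HWN <- da[1] * da[2] * da[3]
  y <- array(cbind(matrix(a$v, HWN, da[4]), matrix(b$v, HWN, db[4])),
             c(da[1], da[2], da[3], da[4] + db[4]))
  node_new(tape, y, function(nd) {
    gm <- matrix(nd$g, HWN, da[4] + db[4])
    acc_grad(a, array(gm[, seq_len(da[4])], da))
    acc_grad(b, array(gm[, da[4] + seq_len(db[4])], db))
  })
}

# multiply map by per-channel, per-sample weights s: [N, C]
op_scale_channels <- function(tape, x, s) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  S <- array(rep(as.vector(s$v), each = HW), d)
  node_new(tape, x$v * S, function(nd) {
    acc_grad(x, nd$g * S)
    acc_grad(s, matrix(colSums(matrix(nd$g * x$v, HW, d[3] * d[4])), d[3], d[4]))
  })
}

# multiply map by a one-channel spatial map m: [H, W, N, 1]
op_scale_spatial <- function(tape, x, m) {
  d <- dim(x$v)
  M <- array(rep(as.vector(m$v), d[4]), d)
  node_new(tape, x$v * M, function(nd) {
    acc_grad(x, nd$g * M)
    acc_grad(m, array(rowSums(matrix(nd$g * x$v, d[1] * d[2] * d[3], d[4])),
                      c(d[1], d[2], d[3], 1L)))
  })
}

# per-sample spatial sum of a single-channel map: [H, W, N, 1] -> length-N
op_spatsum <- function(tape, x) {
  d <- dim(x$v)
  if (d[4] != 1L) stop("spatsum expects a single-channel map")
  HW <- d[1] * d[2]
  node_new(tape, colSums(matrix(x$v, HW, d[3])), function(nd) {
    acc_grad(x, array(rep(nd$g, each = HW), d))
  })
}

## ---- batch normalization --------------------------------------------------

# gamma, beta: [C] nodes; mod: environment holding running_mean / running_var
op_bn <- function(tape, x, gamma, beta, mod, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x$v)
  HWN <- d[1] * d[2] * d[3]
  C <- d[4]
  m <- x$v
  dim(m) <- c(HWN, C)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m * m) - mu * mu
    va[va < 0] <- 0
    if (HWN > 1) {
      mod$running_mean <- (1 - momentum) * mod$running_mean + momentum * mu
      mod$running_var <- (1 - momentum) * mod$running_var +
        momentum * va * HWN / (HWN - 1)
    }
  } else {
    mu <- mod$running_mean
    va <- mod$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  scale <- gamma$v * invstd
  y <- m * rep(scale, each = HWN) + rep(beta$v - mu * scale, each = HWN)
  dim(y) <- d
  node_new(tape, y, function(nd) {
    gm <- nd$g
    dim(gm) <- c(HWN, C)
    xhat <- m * rep(invstd, each = HWN) - rep(mu * invstd, each = HWN)
    acc_grad(gamma, colSums(gm * xhat))
    acc_grad(beta, colSums(gm))
    if (training) {
      s1 <- colSums(gm)
      s2 <- colSums(gm * xhat)
      dx <- (gm - rep(s1 / HWN, each = HWN) -
               xhat * rep(s2 / HWN, each = HWN)) * rep(scale, each = HWN)
    } else {
      dx <- gm * rep(scale, each = HWN)
    }
    dim(dx) <- d
    acc_grad(x, dx)
  })
}

op_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- (stats::runif(length(x$v)) >= p) / (1 - p)
  dim(keep) <- dim(x$v)
  node_new(tape, x$v * keep, function(nd) acc_grad(x, nd$g * keep))
}
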