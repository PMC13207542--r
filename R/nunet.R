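# N-Unet assembly: AFF-enhanced encoder, CLAE-refined decoder, single-channel
# sigmoid segmentation head and a two-layer classification head reading the
# bottleneck. The encoder keeps two coupled streams: the main downsampling
# path X_l (Double Conv per level) and the AFF side chain A_l, where each AFF
# fuses the previous AFF output (2x2 max-pooled into alignment) with the
# current main-path feature. The final AFF output feeds the bottleneck, and
# the per-level AFF outputs are the skip features the decoder refines.

# convert user-facing arrays to the internal [H, W, N, C] layout
as_feature <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array input")
  if (length(d) == 2L) array(x, c(d[1], d[2], 1L, 1L))
  else if (length(d) == 3L) array(x, c(d[1], d[2], 1L, d[3]))
  else stop("expected an H x W or H x W x C array")
}

from_feature <- function(v) {
  d <- dim(v)
  if (d[4] == 1L) matrix(v, d[1], d[2]) else array(v, c(d[1], d[2], d[4]))
}

# stack a list of H x W x C arrays into one [H, W, N, C] batch
stack_batch <- function(images) {
  d <- dim(images[[1]])
  N <- length(images)
  out <- array(0, c(d[1], d[2], N, d[3]))
  for (i in seq_len(N)) out[, , i, ] <- images[[i]]
  out
}

#' Build an N-Unet model
#'
#' Instantiates the full module tree described by a
#' \linkS4class{ModelConfig}: per-level Double Conv encoder blocks with AFF
#' fusion, a single-conv 512-channel bottleneck, bilinear-upsampling decoder
#' blocks with CLAE refinement, the 1x1 sigmoid segmentation head, the
#' GAP + two-layer classification head, and the two AMTL log-variance
#' parameters.
#'
#' @param config a \linkS4class{ModelConfig}
#' @param seed integer seed for weight initialization
#' @return an object of class \code{NUnetModel} (an environment holding the
#'   module tree and the configuration)
#' @export
buildNUnet <- function(config = modelConfig(), seed = 1L) {
  methods::validObject(config)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ch <- config@encoderChannels
  L <- length(ch)
  bott <- config@bottleneckChannels
  red <- config@seReduction
  root <- new_module("nunet")
  root$children$stem <- mod_double_conv(config@inputChannels, ch[1], 0L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      root$children[[paste0("enc", i)]] <-
        mod_double_conv(ch[i - 1L], ch[i], i - 1L)
    }
    root$children[[paste0("aff", i)]] <-
      mod_aff(if (i == 1L) ch[1] else ch[i - 1L], ch[i],
              config@affSideWidths[i], i - 1L,
              dropout = config@affDropout, reduction = red)
  }
  root$children$bottleneck <- mod_cbr(ch[L], bott, 3L, L)
  prev <- bott
  for (i in seq(L, 1L)) {
    root$children[[paste0("up", i)]] <- mod_conv(prev, ch[i], 3L, i - 1L)
    root$children[[paste0("clae", i)]] <-
      mod_clae(ch[i], config@gateWidths[i], i - 1L,
               reduction = config@cbamReduction)
    prev <- ch[i]
  }
  root$children$segHead <- mod_conv(ch[1], config@segOutChannels, 1L, 0L)
  head <- new_module("cls_head")
  head$children$fc1 <- mod_linear(config@headDims[1], config@headDims[2])
  head$children$fc2 <- mod_linear(config@headDims[2], config@headDims[3])
  root$children$clsHead <- head
  amtl <- new_module("amtl")
  amtl$params$logVar <- c(0, 0)
  root$children$amtl <- amtl
  model <- new.env(parent = emptyenv())
  model$root <- root
  model$config <- config
  class(model) <- "NUnetModel"
  model
}

# internal graph-building forward; returns tape nodes
nunet_graph <- function(model, ctx, x) {
  cfg <- model$config
  ch <- cfg@encoderChannels
  L <- length(ch)
  blk <- model$root$children
  X <- fwd_double_conv(blk$stem, ctx, x)
  A <- fwd_aff(blk$aff1, ctx, X, X)
  skips <- vector("list", L)
  skips[[1]] <- A
  for (i in seq_len(L)[-1]) {
    X <- fwd_double_conv(blk[[paste0("enc", i)]], ctx,
                         op_maxpool2(ctx$tape, X))
    A <- fwd_aff(blk[[paste0("aff", i)]], ctx, op_maxpool2(ctx$tape, A), X)
    skips[[i]] <- A
  }
  B <- fwd_cbr(blk$bottleneck, ctx, op_maxpool2(ctx$tape, A))
  D <- B
  for (i in seq(L, 1L)) {
    D <- fwd_conv(blk[[paste0("up", i)]], ctx, op_upsample2(ctx$tape, D))
    D <- fwd_clae(blk[[paste0("clae", i)]], ctx, skips[[i]], D)
  }
  seg <- op_sigmoid(ctx$tape, fwd_conv(blk$segHead, ctx, D))
  z <- op_gap(ctx$tape, B)
  h <- op_relu(ctx$tape, fwd_linear(blk$clsHead$children$fc1, ctx, z))
  logits <- fwd_linear(blk$clsHead$children$fc2, ctx, h)
  list(seg = seg, logits = logits)
}

#' Forward pass of an N-Unet model
#'
#' @param model an \code{NUnetModel} from \code{\link{buildNUnet}}
#' @param images one H x W x 3 array or a list of them (a batch)
#' @param training logical; \code{TRUE} enables dropout and batch-statistics
#'   normalization, \code{FALSE} gives the deterministic evaluation mode
#' @return a list with \code{seg}, an H x W x N array of per-pixel lesion
#'   probabilities in (0, 1), and \code{logits}, an N x 2 matrix of
#'   classification logits (column 1 = lesion class, column 2 = normal)
#' @export
nunetForward <- function(model, images, training = FALSE) {
  if (!is.list(images)) images <- list(images)
  sz <- model$config@inputSize
  for (im in images) {
    d <- dim(im)
    if (length(d) != 3L || d[1] != sz || d[2] != sz || d[3] != 3L) {
      stop("input image must be ", sz, "x", sz, "x3, got ",
           paste(dim(im), collapse = "x"))
    }
  }
  ctx <- list(tape = tape_new(), training = training)
  module_clear_leaves(model$root)
  out <- nunet_graph(model, ctx, tp_leaf(ctx$tape, stack_batch(images)))
  d <- dim(out$seg$v)
  list(seg = array(out$seg$v, c(d[1], d[2], d[3])), logits = out$logits$v)
}

## ---- functional block surfaces -------------------------------------------

run_block <- function(fun) {
  ctx <- list(tape = tape_new(), training = FALSE)
  fun(ctx)
}

#' Depthwise separable convolution
#'
#' Applies one spatial kernel per channel (depthwise stage) followed by a
#' 1x1 pointwise convolution mixing channels, with stride 1 and same
#' padding.
#'
#' @param x H x W x C input array
#' @param depthwise k x k x C array of per-channel kernels
#' @param pointwise C x Cout matrix of 1x1 mixing weights
#' @param dwBias,pwBias optional bias vectors (length C and Cout)
#' @return H x W x Cout array
#' @export
dsConv <- function(x, depthwise, pointwise, dwBias = NULL, pwBias = NULL) {
  C <- dim(depthwise)[3]
  if (dim(as_feature(x))[4] != C) {
    stop("dsConv: one depthwise kernel is required per input channel")
  }
  if (nrow(pointwise) != C) {
    stop("dsConv: pointwise kernel rows must match the channel count")
  }
  run_block(function(ctx) {
    xt <- tp_leaf(ctx$tape, as_feature(x))
    y <- op_dwconv2d(ctx$tape, xt, tp_leaf(ctx$tape, depthwise),
                     if (is.null(dwBias)) NULL else tp_leaf(ctx$tape, dwBias))
    pw <- array(pointwise, c(1L, 1L, dim(pointwise)))
    y <- op_conv2d(ctx$tape, y, tp_leaf(ctx$tape, pw),
                   if (is.null(pwBias)) NULL else tp_leaf(ctx$tape, pwBias))
    from_feature(y$v)
  })
}

#' Squeeze-and-excitation channel recalibration
#'
#' Global average pooling, a two-layer bottleneck perceptron
#' (C -> C/reduction -> C) with ReLU then sigmoid, and per-channel
#' rescaling of the input.
#'
#' @param x H x W x C input array
#' @param fc1w,fc1b,fc2w,fc2b perceptron weights: C x Cr matrix, length-Cr
#'   bias, Cr x C matrix, length-C bias
#' @return H x W x C array; the per-channel weights s are attached as
#'   attribute \code{"channelWeights"}
#' @export
seRecalibrate <- function(x, fc1w, fc1b, fc2w, fc2b) {
  run_block(function(ctx) {
    xt <- tp_leaf(ctx$tape, as_feature(x))
    z <- op_gap(ctx$tape, xt)
    s <- op_sigmoid(ctx$tape, op_linear(ctx$tape,
           op_relu(ctx$tape, op_linear(ctx$tape, z,
             tp_leaf(ctx$tape, fc1w), tp_leaf(ctx$tape, fc1b))),
           tp_leaf(ctx$tape, fc2w), tp_leaf(ctx$tape, fc2b)))
    out <- from_feature(op_scale_channels(ctx$tape, xt, s)$v)
    attr(out, "channelWeights") <- as.vector(s$v)
    out
  })
}

#' CBAM channel-then-spatial attention
#'
#' Channel attention from average- and max-pooled descriptors through one
#' shared MLP, then spatial attention from channel-wise average/max planes
#' through a 7x7 (or \code{k}x\code{k}) convolution.
#'
#' @param x H x W x C input array
#' @param fc1w,fc1b,fc2w,fc2b shared MLP weights (C -> Cr -> C)
#' @param spatialW k x k x 2 x 1 convolution kernel
#' @param spatialB length-1 bias
#' @return H x W x C array with attributes \code{"channelWeights"} and
#'   \code{"spatialMap"}
#' @export
cbamAttention <- function(x, fc1w, fc1b, fc2w, fc2b, spatialW, spatialB) {
  run_block(function(ctx) {
    xt <- tp_leaf(ctx$tape, as_feature(x))
    mlp <- function(z) op_linear(ctx$tape,
      op_relu(ctx$tape, op_linear(ctx$tape, z,
        tp_leaf(ctx$tape, fc1w), tp_leaf(ctx$tape, fc1b))),
      tp_leaf(ctx$tape, fc2w), tp_leaf(ctx$tape, fc2b))
    s <- op_sigmoid(ctx$tape, op_add(ctx$tape,
           mlp(op_gap(ctx$tape, xt)), mlp(op_gmaxpool(ctx$tape, xt))))
    xc <- op_scale_channels(ctx$tape, xt, s)
    ms <- op_sigmoid(ctx$tape, op_conv2d(ctx$tape,
            op_chanpool(ctx$tape, xc),
            tp_leaf(ctx$tape, spatialW), tp_leaf(ctx$tape, spatialB)))
    out <- from_feature(op_scale_spatial(ctx$tape, xc, ms)$v)
    attr(out, "channelWeights") <- as.vector(s$v)
    attr(out, "spatialMap") <- matrix(ms$v, dim(ms$v)[1], dim(ms$v)[2])
    out
  })
}

#' Additive attention gate
#'
#' Computes per-pixel gating coefficients
#' alpha = sigmoid(Wa . ReLU(W1 Xs + W2 Xu)) through 1x1 projections into F
#' intermediate channels, and returns alpha * Xs.
#'
#' @param xs H x W x C skip feature (gated)
#' @param xu H x W x Cu coarser decoder feature (must be spatially aligned)
#' @param w1,b1 1x1 projection of \code{xs}: C x F matrix and length-F bias
#' @param w2,b2 1x1 projection of \code{xu}: Cu x F matrix and length-F bias
#' @param wa,ba 1x1 projection to one channel: F x 1 matrix, length-1 bias
#' @return H x W x C array with attribute \code{"alpha"} (the gate map)
#' @export
attentionGate <- function(xs, xu, w1, b1, w2, b2, wa, ba) {
  fs <- as_feature(xs); fu <- as_feature(xu)
  if (!all(dim(fs)[1:2] == dim(fu)[1:2])) {
    stop("attentionGate: inputs are not spatially aligned")
  }
  as_k1 <- function(m) array(m, c(1L, 1L, dim(m)))
  run_block(function(ctx) {
    xst <- tp_leaf(ctx$tape, fs)
    xut <- tp_leaf(ctx$tape, fu)
    pre <- op_relu(ctx$tape, op_add(ctx$tape,
      op_conv2d(ctx$tape, xst, tp_leaf(ctx$tape, as_k1(w1)),
                tp_leaf(ctx$tape, b1)),
      op_conv2d(ctx$tape, xut, tp_leaf(ctx$tape, as_k1(w2)),
                tp_leaf(ctx$tape, b2))))
    alpha <- op_sigmoid(ctx$tape, op_conv2d(ctx$tape, pre,
               tp_leaf(ctx$tape, as_k1(wa)), tp_leaf(ctx$tape, ba)))
    out <- from_feature(op_scale_spatial(ctx$tape, xst, alpha)$v)
    attr(out, "alpha") <- matrix(alpha$v, dim(alpha$v)[1], dim(alpha$v)[2])
    out
  })
}

#' Classification head
#'
#' Global average pooling of the bottleneck feature followed by a two-layer
#' fully connected head (bottleneck -> hidden -> 2) with ReLU in between.
#'
#' @param x H x W x C bottleneck feature
#' @param w1,b1,w2,b2 head weights (C x hidden, hidden, hidden x 2, 2)
#' @return length-2 numeric vector of logits (lesion, normal)
#' @export
classificationHead <- function(x, w1, b1, w2, b2) {
  xt <- as_feature(x)
  if (dim(xt)[4] != nrow(w1)) {
    stop("classificationHead: bottleneck has ", dim(xt)[4],
         " channels, head expects ", nrow(w1))
  }
  run_block(function(ctx) {
    z <- op_gap(ctx$tape, tp_leaf(ctx$tape, xt))
    h <- op_relu(ctx$tape, op_linear(ctx$tape, z,
           tp_leaf(ctx$tape, w1), tp_leaf(ctx$tape, b1)))
    as.vector(op_linear(ctx$tape, h,
           tp_leaf(ctx$tape, w2), tp_leaf(ctx$tape, b2))$v)
  })
}

#' Stand-alone AFF and CLAE blocks
#'
#' Constructors for individually testable encoder/decoder blocks with
#' randomly initialized weights; \code{\link{fillParams}} can overwrite
#' them with a constant.
#'
#' @param cSideIn,c,sideWidth AFF side-branch input width, level width, and
#'   side-branch pointwise width
#' @param f attention-gate intermediate width of the CLAE block
#' @param seed integer seed for weight initialization
#' @return a module environment accepted by \code{\link{affForward}} /
#'   \code{\link{claeForward}}
#' @name standalone-blocks
NULL

#' @rdname standalone-blocks
#' @export
newAFFBlock <- function(cSideIn, c, sideWidth = c, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  mod_aff(cSideIn, c, sideWidth, 0L)
}

#' @rdname standalone-blocks
#' @export
newCLAEBlock <- function(c, f = max(1L, c %/% 2L), seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  mod_clae(c, f, 0L)
}

#' @describeIn standalone-blocks run an AFF block on side/main H x W x C
#'   arrays
#' @param block a module environment
#' @param side,main,skip,up input feature arrays
#' @param training logical
#' @export
affForward <- function(block, side, main, training = FALSE) {
  ctx <- list(tape = tape_new(), training = training)
  module_clear_leaves(block)
  from_feature(fwd_aff(block, ctx, tp_leaf(ctx$tape, as_feature(side)),
                       tp_leaf(ctx$tape, as_feature(main)))$v)
}

#' @describeIn standalone-blocks run a CLAE block on skip/upsampled
#'   H x W x C arrays
#' @export
claeForward <- function(block, skip, up, training = FALSE) {
  ctx <- list(tape = tape_new(), training = training)
  module_clear_leaves(block)
  from_feature(fwd_clae(block, ctx, tp_leaf(ctx$tape, as_feature(skip)),
                        tp_leaf(ctx$tape, as_feature(up)))$v)
}

#' Overwrite every parameter of a block with a constant
#'
#' Mainly used to exercise the analytic zero-weight collapses of the
#' attention blocks (every sigmoid gate becomes exactly 0.5).
#'
#' @param block a module environment
#' @param value the constant to fill with (default 0)
#' @return the block, invisibly
#' @export
fillParams <- function(block, value = 0) {
  for (ref in module_param_refs(block)) {
    p <- ref$mod$params[[ref$name]]
    p[] <- value
    ref$mod$params[[ref$name]] <- p
  }
  invisible(block)
}
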