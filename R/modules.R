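# Layer and block constructors. A module is an environment carrying
# parameter arrays (mutated in place by the optimizer), buffers (batch-norm
# running statistics), child modules, and the static metadata the complexity
# audit needs (kernel size, fan-in/out, dyadic resolution level).
#
# `lvl` is the number of 2x downsamplings between the network input and the
# tensor this layer operates on; the audit turns it into an output
# resolution for any stated input size.

new_module <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$children <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(.kind, "nn_module")
  e
}

init_norm <- function(dims, sd) array(stats::rnorm(prod(dims), 0, sd), dims)

mod_conv <- function(cin, cout, k, lvl, bias = TRUE) {
  m <- new_module("conv", k = k, cin = cin, cout = cout, groups = 1L, lvl = lvl)
  m$params$w <- init_norm(c(k, k, cin, cout), sqrt(2 / (k * k * cin)))
  if (bias) m$params$b <- numeric(cout)
  m
}

mod_dwconv <- function(c, k, lvl, bias = TRUE) {
  m <- new_module("dwconv", k = k, cin = c, cout = c, groups = c, lvl = lvl)
  m$params$w <- init_norm(c(k, k, c), sqrt(2 / (k * k)))
  if (bias) m$params$b <- numeric(c)
  m
}

mod_linear <- function(cin, cout, bias = TRUE) {
  m <- new_module("linear", cin = cin, cout = cout)
  m$params$w <- init_norm(c(cin, cout), sqrt(2 / cin))
  if (bias) m$params$b <- numeric(cout)
  m
}

mod_bn <- function(c) {
  m <- new_module("bn", c = c)
  m$params$gamma <- rep(1, c)
  m$params$beta <- numeric(c)
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m
}

# forward helpers -----------------------------------------------------------

param_leaf <- function(ctx, mod, name) {
  nd <- tp_leaf(ctx$tape, mod$params[[name]])
  mod$.leaves[[name]] <- nd
  nd
}

fwd_conv <- function(mod, ctx, x) {
  w <- param_leaf(ctx, mod, "w")
  b <- if (!is.null(mod$params$b)) param_leaf(ctx, mod, "b") else NULL
  if (mod$kind == "dwconv") op_dwconv2d(ctx$tape, x, w, b)
  else op_conv2d(ctx$tape, x, w, b)
}

fwd_linear <- function(mod, ctx, x) {
  w <- param_leaf(ctx, mod, "w")
  b <- if (!is.null(mod$params$b)) param_leaf(ctx, mod, "b") else NULL
  op_linear(ctx$tape, x, w, b)
}

fwd_bn <- function(mod, ctx, x) {
  op_bn(ctx$tape, x, param_leaf(ctx, mod, "gamma"), param_leaf(ctx, mod, "beta"),
        mod, ctx$training)
}

# conv (no bias) + BN + ReLU
mod_cbr <- function(cin, cout, k, lvl) {
  m <- new_module("cbr")
  m$children$conv <- mod_conv(cin, cout, k, lvl, bias = FALSE)
  m$children$bn <- mod_bn(cout)
  m
}

fwd_cbr <- function(mod, ctx, x) {
  op_relu(ctx$tape, fwd_bn(mod$children$bn, ctx,
                           fwd_conv(mod$children$conv, ctx, x)))
}

# the Double Conv (3x3) block of the topology diagrams
mod_double_conv <- function(cin, cout, lvl) {
  m <- new_module("double_conv")
  m$children$c1 <- mod_cbr(cin, cout, 3L, lvl)
  m$children$c2 <- mod_cbr(cout, cout, 3L, lvl)
  m
}

fwd_double_conv <- function(mod, ctx, x) {
  fwd_cbr(mod$children$c2, ctx, fwd_cbr(mod$children$c1, ctx, x))
}

# squeeze-and-excitation: GAP -> FC C/r -> ReLU -> FC C -> sigmoid -> rescale
mod_se <- function(c, reduction = 16L) {
  cr <- max(1L, c %/% reduction)
  m <- new_module("se", c = c, cr = cr)
  m$children$fc1 <- mod_linear(c, cr)
  m$children$fc2 <- mod_linear(cr, c)
  m
}

fwd_se <- function(mod, ctx, x) {
  z <- op_gap(ctx$tape, x)
  s <- op_sigmoid(ctx$tape, fwd_linear(mod$children$fc2, ctx,
        op_relu(ctx$tape, fwd_linear(mod$children$fc1, ctx, z))))
  op_scale_channels(ctx$tape, x, s)
}

# depthwise separable convolution: 3x3 depthwise + 1x1 pointwise
mod_dsconv <- function(cin, cout, lvl) {
  m <- new_module("dsconv")
  m$children$dw <- mod_dwconv(cin, 3L, lvl)
  m$children$pw <- mod_conv(cin, cout, 1L, lvl)
  m
}

fwd_dsconv <- function(mod, ctx, x) {
  fwd_conv(mod$children$pw, ctx, fwd_conv(mod$children$dw, ctx, x))
}

# adaptive feature fusion: DS side branch -> SE -> dropout, concatenated with
# the main-path feature, then two conv+BN+ReLU fusions with an SE in between
mod_aff <- function(c_side_in, c, side_width, lvl, dropout = 0.2,
                    reduction = 16L) {
  m <- new_module("aff", dropout = dropout)
  m$children$ds <- mod_dsconv(c_side_in, side_width, lvl)
  m$children$se_side <- mod_se(side_width, reduction)
  m$children$fuse1 <- mod_cbr(side_width + c, c, 3L, lvl)
  m$children$se_fused <- mod_se(c, reduction)
  m$children$fuse2 <- mod_cbr(c, c, 3L, lvl)
  m
}

fwd_aff <- function(mod, ctx, side, main) {
  ds <- dim(side$v); dm <- dim(main$v)
  if (!all(ds[1:2] == dm[1:2])) {
    stop("aff: side and main features are not spatially aligned (",
         ds[1], "x", ds[2], " vs ", dm[1], "x", dm[2], ")")
  }
  s <- fwd_se(mod$children$se_side, ctx, fwd_dsconv(mod$children$ds, ctx, side))
  s <- op_dropout(ctx$tape, s, mod$dropout, ctx$training)
  fused <- fwd_cbr(mod$children$fuse1, ctx, op_concat_c(ctx$tape, s, main))
  fwd_cbr(mod$children$fuse2, ctx, fwd_se(mod$children$se_fused, ctx, fused))
}

# CBAM: channel attention (shared MLP on avg+max descriptors), then spatial
# attention (7x7 conv over channel-pooled avg/max planes)
mod_cbam <- function(c, lvl, reduction = 16L, spatial_kernel = 7L) {
  cr <- max(1L, c %/% reduction)
  m <- new_module("cbam", c = c)
  m$children$fc1 <- mod_linear(c, cr)
  m$children$fc2 <- mod_linear(cr, c)
  m$children$spatial <- mod_conv(2L, 1L, spatial_kernel, lvl)
  m
}

fwd_cbam_mlp <- function(mod, ctx, z) {
  fwd_linear(mod$children$fc2, ctx,
             op_relu(ctx$tape, fwd_linear(mod$children$fc1, ctx, z)))
}

fwd_cbam <- function(mod, ctx, x) {
  za <- op_gap(ctx$tape, x)
  zm <- op_gmaxpool(ctx$tape, x)
  s <- op_sigmoid(ctx$tape, op_add(ctx$tape,
        fwd_cbam_mlp(mod, ctx, za), fwd_cbam_mlp(mod, ctx, zm)))
  xc <- op_scale_channels(ctx$tape, x, s)
  ms <- op_sigmoid(ctx$tape,
        fwd_conv(mod$children$spatial, ctx, op_chanpool(ctx$tape, xc)))
  op_scale_spatial(ctx$tape, xc, ms)
}

# attention gate: alpha = sigmoid(Wa . ReLU(W1 Xs + W2 Xu)), output alpha * Xs
mod_ag <- function(c, cu, f, lvl) {
  m <- new_module("ag", f = f)
  m$children$w1 <- mod_conv(c, f, 1L, lvl)
  m$children$w2 <- mod_conv(cu, f, 1L, lvl)
  m$children$wa <- mod_conv(f, 1L, 1L, lvl)
  m
}

fwd_ag <- function(mod, ctx, xs, xu) {
  ds <- dim(xs$v); du <- dim(xu$v)
  if (!all(ds[1:2] == du[1:2])) {
    stop("attention gate: features not spatially aligned after upsampling")
  }
  pre <- op_relu(ctx$tape, op_add(ctx$tape,
           fwd_conv(mod$children$w1, ctx, xs),
           fwd_conv(mod$children$w2, ctx, xu)))
  alpha <- op_sigmoid(ctx$tape, fwd_conv(mod$children$wa, ctx, pre))
  op_scale_spatial(ctx$tape, xs, alpha)
}

# cross-level attention enhancement: CBAM on the skip feature, attention-gate
# it against the upsampled decoder feature, then concatenate and fuse
mod_clae <- function(c, f, lvl, reduction = 16L) {
  m <- new_module("clae")
  m$children$cbam <- mod_cbam(c, lvl, reduction)
  m$children$ag <- mod_ag(c, c, f, lvl)
  m$children$fuse <- mod_double_conv(2L * c, c, lvl)
  m
}

fwd_clae <- function(mod, ctx, skip, up) {
  xs <- fwd_cbam(mod$children$cbam, ctx, skip)
  xg <- fwd_ag(mod$children$ag, ctx, xs, up)
  fwd_double_conv(mod$children$fuse, ctx, op_concat_c(ctx$tape, xg, up))
}

# parameter walking ---------------------------------------------------------

# flat list of list(mod, name, path) over every trainable array
module_param_refs <- function(mod, path = character()) {
  out <- list()
  for (nm in names(mod$params)) {
    out[[length(out) + 1L]] <- list(mod = mod, name = nm,
                                    path = paste(c(path, nm), collapse = "."))
  }
  for (nm in names(mod$children)) {
    out <- c(out, module_param_refs(mod$children[[nm]], c(path, nm)))
  }
  out
}

module_n_params <- function(mod) {
  sum(vapply(module_param_refs(mod),
             function(r) length(r$mod$params[[r$name]]), numeric(1)))
}

# conv / linear leaf modules in traversal order (for the MAC audit)
module_compute_leaves <- function(mod) {
  out <- list()
  if (mod$kind %in% c("conv", "dwconv", "linear")) out <- list(mod)
  for (ch in mod$children) out <- c(out, module_compute_leaves(ch))
  out
}

# multiply-accumulate count of one forward pass at the given input size
module_macs <- function(mod, input_size) {
  leaves <- module_compute_leaves(mod)
  total <- 0
  for (lf in leaves) {
    if (lf$kind == "linear") {
      total <- total + lf$cin * lf$cout
    } else {
      hw <- (input_size / 2^lf$lvl)^2
      total <- total + lf$k^2 * lf$cin * lf$cout / lf$groups * hw
    }
  }
  total
}

# reset transient leaf registries before a training step
module_clear_leaves <- function(mod) {
  mod$.leaves <- list()
  for (ch in mod$children) module_clear_leaves(ch)
  invisible(NULL)
}

# read gradients accumulated during backward; NULL for untouched params
module_grad <- function(ref) {
  lv <- ref$mod$.leaves[[ref$name]]
  if (is.null(lv)) NULL else lv$g
}

# deep copy of parameter and buffer state (for checkpointing)
module_state <- function(mod) {
  st <- list(params = mod$params)
  if (mod$kind == "bn") {
    st$running_mean <- mod$running_mean
    st$running_var <- mod$running_var
  }
  st$children <- lapply(mod$children, module_state)
  st
}

module_load_state <- function(mod, st) {
  mod$params <- st$params
  if (mod$kind == "bn") {
    mod$running_mean <- st$running_mean
    mod$running_var <- st$running_var
  }
  for (nm in names(mod$children)) {
    module_load_state(mod$children[[nm]], st$children[[nm]])
  }
  invisible(NULL)
}
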