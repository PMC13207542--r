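# Finite-difference validation of the reverse-mode engine on the operators
# the network composes. Each check perturbs a handful of entries.

check_grads <- function(build, arrs, n_probe = 4, tol = 1e-4, eps = 1e-6) {
  g <- build(arrs)
  nunet:::tp_backward(g$tape, g$loss)
  for (nm in names(arrs)) {
    grad <- g$leaves[[nm]]$g
    set.seed(17)
    for (i in sample(length(arrs[[nm]]), min(n_probe, length(arrs[[nm]])))) {
      up <- arrs; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- arrs; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (build(up)$loss$v - build(dn)$loss$v) / (2 * eps)
      expect_equal(grad[i], num, tolerance = tol)
    }
  }
}

test_that("conv + pooling + upsampling gradients match finite differences", {
  set.seed(7)
  arrs <- list(x = array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)),
               w = array(rnorm(3 * 3 * 2 * 3) / 3, c(3, 3, 2, 3)),
               b = rnorm(3))
  check_grads(function(a) {
    tp <- nunet:::tape_new()
    lx <- nunet:::tp_leaf(tp, a$x)
    lw <- nunet:::tp_leaf(tp, a$w)
    lb <- nunet:::tp_leaf(tp, a$b)
    y <- nunet:::op_conv2d(tp, lx, lw, lb)
    y <- nunet:::op_sigmoid(tp, y)
    y <- nunet:::op_maxpool2(tp, y)
    y <- nunet:::op_upsample2(tp, y)
    list(tape = tp, loss = nunet:::op_mean(tp, nunet:::op_pow(tp, y, 2)),
         leaves = list(x = lx, w = lw, b = lb))
  }, arrs)
})

test_that("depthwise conv and channel pooling gradients are exact", {
  set.seed(8)
  arrs <- list(x = array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3)),
               w = array(rnorm(3 * 3 * 3) / 3, c(3, 3, 3)))
  check_grads(function(a) {
    tp <- nunet:::tape_new()
    lx <- nunet:::tp_leaf(tp, a$x)
    lw <- nunet:::tp_leaf(tp, a$w)
    y <- nunet:::op_dwconv2d(tp, lx, lw)
    y <- nunet:::op_chanpool(tp, y)
    y <- nunet:::op_relu(tp, y)
    list(tape = tp, loss = nunet:::op_mean(tp, nunet:::op_pow(tp, y, 2)),
         leaves = list(x = lx, w = lw))
  }, arrs)
})

test_that("batch-norm (training mode) gradients match finite differences", {
  set.seed(9)
  arrs <- list(x = array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)),
               gamma = runif(2, 0.5, 1.5), beta = rnorm(2))
  check_grads(function(a) {
    tp <- nunet:::tape_new()
    lx <- nunet:::tp_leaf(tp, a$x)
    lg <- nunet:::tp_leaf(tp, a$gamma)
    lb <- nunet:::tp_leaf(tp, a$beta)
    mod <- nunet:::mod_bn(2L)  # fresh buffers each call
    y <- nunet:::op_bn(tp, lx, lg, lb, mod, training = TRUE)
    list(tape = tp, loss = nunet:::op_mean(tp, nunet:::op_pow(tp, y, 2)),
         leaves = list(x = lx, gamma = lg, beta = lb))
  }, arrs, tol = 1e-3)
})

test_that("attention rescaling and loss-graph gradients are exact", {
  set.seed(10)
  arrs <- list(x = array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)),
               s = matrix(runif(6, 0.2, 0.8), 2, 3),
               logits = matrix(rnorm(4), 2, 2), lv = c(0.2, -0.3))
  gm <- array(rbinom(8, 1, 0.5), c(2, 2, 2, 1))
  xi <- c(1, 0)
  check_grads(function(a) {
    tp <- nunet:::tape_new()
    ctx <- list(tape = tp, training = FALSE)
    lx <- nunet:::tp_leaf(tp, a$x)
    ls <- nunet:::tp_leaf(tp, a$s)
    ll <- nunet:::tp_leaf(tp, a$logits)
    lv <- nunet:::tp_leaf(tp, a$lv)
    y <- nunet:::op_scale_channels(tp, lx, ls)
    y <- nunet:::op_gmaxpool(tp, y)
    lcls <- nunet:::graph_focal_bce(ctx, ll, xi, omega = 0.5, gamma = 2)
    # segmentation probabilities derived from x through a 1x1 conv so the
    # Dice gradient flows back into the input
    seg <- nunet:::op_sigmoid(tp, nunet:::op_conv2d(tp, lx,
      nunet:::tp_leaf(tp, array(c(0.3, -0.2, 0.5), c(1, 1, 3, 1)))))
    lseg <- nunet:::graph_dice(ctx, seg, gm, 1e-5)
    reg <- nunet:::op_mean(tp, y)
    s1 <- nunet:::op_index(tp, lv, 1L)
    s2 <- nunet:::op_index(tp, lv, 2L)
    amtl <- nunet:::op_mulc(tp, nunet:::op_add(tp,
      nunet:::op_add(tp,
        nunet:::op_mulc(tp, nunet:::op_mul(tp, lcls,
          nunet:::op_exp(tp, nunet:::op_neg(tp, s1))), 0.5),
        nunet:::op_mulc(tp, s1, 0.5)),
      nunet:::op_add(tp,
        nunet:::op_mulc(tp, nunet:::op_mul(tp, lseg,
          nunet:::op_exp(tp, nunet:::op_neg(tp, s2))), 0.5),
        nunet:::op_mulc(tp, s2, 0.5))), 0.5)
    list(tape = tp, loss = nunet:::op_add(tp, amtl, reg),
         leaves = list(x = lx, s = ls, logits = ll, lv = lv))
  }, arrs, tol = 1e-4)
})

test_that("a whole tiny N-Unet training step agrees with finite differences", {
  cfg <- modelConfig(encoderChannels = c(2L, 4L), inputSize = 16L)
  model <- buildNUnet(cfg, seed = 13L)
  set.seed(14)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  xb <- aperm(array(x, c(16, 16, 3, 2)), c(1, 2, 4, 3))
  gm <- array(0, c(16, 16, 2, 1)); gm[5:9, 5:9, 1, 1] <- 1
  xi <- c(1, 0)
  loss_of <- function() {
    ctx <- list(tape = nunet:::tape_new(), training = FALSE)
    nunet:::module_clear_leaves(model$root)
    out <- nunet:::nunet_graph(model, ctx, nunet:::tp_leaf(ctx$tape, xb))
    lcls <- nunet:::graph_focal_bce(ctx, out$logits, xi, 1, 2)
    lseg <- nunet:::graph_dice(ctx, out$seg, gm, 1e-5)
    list(ctx = ctx,
         total = nunet:::graph_amtl(ctx, lcls, lseg,
                                    model$root$children$amtl))
  }
  g <- loss_of()
  nunet:::tp_backward(g$ctx$tape, g$total)
  refs <- nunet:::module_param_refs(model$root)
  # snapshot the gradients before the probing forwards overwrite the leaves
  grads <- lapply(refs, nunet:::module_grad)
  set.seed(15)
  probes <- sample(length(refs), 6)
  eps <- 1e-5
  for (ri in probes) {
    ref <- refs[[ri]]
    grad <- grads[[ri]]
    i <- sample(length(ref$mod$params[[ref$name]]), 1)
    orig <- ref$mod$params[[ref$name]][i]
    ref$mod$params[[ref$name]][i] <- orig + eps
    up <- loss_of()$total$v
    ref$mod$params[[ref$name]][i] <- orig - eps
    dn <- loss_of()$total$v
    ref$mod$params[[ref$name]][i] <- orig
    expect_equal(grad[i], (up - dn) / (2 * eps), tolerance = 1e-3)
  }
})
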