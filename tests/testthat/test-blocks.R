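set.seed(42)

test_that("depthwise separable conv matches the nested-loop oracle", {
  for (rep in 1:3) {
    x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    dw <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
    pw <- matrix(rnorm(2 * 3), 2, 3)
    dwb <- rnorm(2); pwb <- rnorm(3)
    got <- dsConv(x, dw, pw, dwb, pwb)
    mid <- brute_dwconv(x, dw, dwb)
    want <- brute_conv(mid, array(pw, c(1, 1, 2, 3)), pwb)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("identity pointwise mixing keeps channels separated", {
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  dw <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  base <- dsConv(x, dw, diag(2))
  x2 <- x
  x2[, , 2] <- x2[, , 2] + 1  # perturb channel 2 only
  pert <- dsConv(x2, dw, diag(2))
  expect_equal(pert[, , 1], base[, , 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pert[, , 2], base[, , 2])))
})

test_that("DS convolution parameter count follows k*k*M + M*N (+ biases)", {
  m <- 6L; n <- 10L
  mod <- nunet:::mod_dsconv(m, n, 0L)
  expect_equal(nunet:::module_n_params(mod), 9 * m + m + m * n + n)
})

test_that("SE with zero weights halves every channel", {
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  out <- seRecalibrate(x, matrix(0, 4, 1), 0, matrix(0, 1, 4), rep(0, 4))
  expect_equal(attr(out, "channelWeights"), rep(0.5, 4))
  attr(out, "channelWeights") <- NULL
  expect_equal(out, 0.5 * x, tolerance = 1e-12)
})

test_that("SE with hand-set weights matches the two-layer perceptron", {
  for (rep in 1:3) {
    x <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
    w1 <- matrix(rnorm(4 * 2), 4, 2); b1 <- rnorm(2)
    w2 <- matrix(rnorm(2 * 4), 2, 4); b2 <- rnorm(4)
    got <- seRecalibrate(x, w1, b1, w2, b2)
    want <- brute_se(x, w1, b1, w2, b2)
    expect_equal(attr(got, "channelWeights"), want$s, tolerance = 1e-6)
    attr(got, "channelWeights") <- NULL
    expect_equal(got, want$out, tolerance = 1e-6)
    expect_true(all(want$s > 0 & want$s < 1))  # sigmoid range
  }
})

test_that("CBAM with zero weights scales the input by exactly 0.25", {
  x <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  out <- cbamAttention(x, matrix(0, 2, 1), 0, matrix(0, 1, 2), c(0, 0),
                       array(0, c(7, 7, 2, 1)), 0)
  expect_equal(attr(out, "channelWeights"), rep(0.5, 2))
  expect_true(all(attr(out, "spatialMap") == 0.5))
  attributes(out) <- list(dim = dim(x))
  expect_equal(out, 0.25 * x, tolerance = 1e-12)
})

test_that("CBAM matches the brute-force oracle on random inputs", {
  for (rep in 1:3) {
    x <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
    w1 <- matrix(rnorm(2), 2, 1); b1 <- 0.1
    w2 <- matrix(rnorm(2), 1, 2); b2 <- rnorm(2)
    spw <- array(rnorm(7 * 7 * 2) / 7, c(7, 7, 2, 1)); spb <- 0.05
    got <- cbamAttention(x, w1, b1, w2, b2, spw, spb)
    want <- brute_cbam(x, w1, b1, w2, b2, spw, spb)
    expect_equal(attr(got, "channelWeights"), want$s, tolerance = 1e-6)
    expect_equal(attr(got, "spatialMap"), want$ms, tolerance = 1e-6)
    attributes(got) <- list(dim = dim(x))
    expect_equal(got, want$out, tolerance = 1e-6)
  }
})

test_that("a spatially constant input gives identical avg and max descriptors", {
  x <- array(rep(c(1.3, -0.4), each = 9), c(3, 3, 2))
  # with the shared MLP, s = sigmoid(2 MLP(z)) when z_avg = z_max
  w1 <- matrix(rnorm(2), 2, 1); b1 <- 0; w2 <- matrix(rnorm(2), 1, 2)
  got <- cbamAttention(x, w1, b1, w2, c(0, 0), array(0, c(7, 7, 2, 1)), 0)
  z <- c(1.3, -0.4)
  mlp <- as.vector(pmax(z %*% w1, 0) %*% w2)
  expect_equal(attr(got, "channelWeights"), 1 / (1 + exp(-2 * mlp)),
               tolerance = 1e-9)
})

test_that("attention gate collapses to a 0.5 gate at zero weights", {
  xs <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  xu <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  out <- attentionGate(xs, xu, matrix(0, 3, 2), c(0, 0), matrix(0, 3, 2),
                       c(0, 0), matrix(0, 2, 1), 0)
  expect_true(all(attr(out, "alpha") == 0.5))
  expect_equal(dim(out), dim(xs))
  attributes(out) <- list(dim = dim(xs))
  expect_equal(out, 0.5 * xs, tolerance = 1e-12)
})

test_that("attention gate matches scalar hand evaluation on 1x1 input", {
  xs <- array(0.7, c(1, 1, 1)); xu <- array(-0.2, c(1, 1, 1))
  w1 <- matrix(1.5); b1 <- 0.1; w2 <- matrix(-0.8); b2 <- -0.05
  wa <- matrix(2); ba <- 0.3
  got <- attentionGate(xs, xu, w1, b1, w2, b2, wa, ba)
  pre <- max(1.5 * 0.7 + 0.1 + (-0.8) * (-0.2) - 0.05, 0)
  alpha <- 1 / (1 + exp(-(2 * pre + 0.3)))
  expect_equal(as.vector(got), alpha * 0.7, tolerance = 1e-9)
  expect_error(attentionGate(xs, array(0, c(2, 2, 1)), w1, b1, w2, b2,
                             wa, ba), "aligned")
})

test_that("AFF fuses side and main features with the right shapes", {
  blk <- newAFFBlock(cSideIn = 3L, c = 4L, sideWidth = 4L, seed = 2L)
  side <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  main <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  out <- affForward(blk, side, main)
  expect_equal(dim(out), c(6L, 6L, 4L))
  # evaluation mode is deterministic (dropout inactive)
  expect_identical(out, affForward(blk, side, main))
  expect_error(affForward(blk, side, array(0, c(4, 4, 4))), "aligned")
})

test_that("zero-weight CLAE attention reduces to fusing 0.125 x skip", {
  blk <- newCLAEBlock(c = 4L, f = 2L, seed = 3L)
  fillParams(blk$children$cbam, 0)
  fillParams(blk$children$ag, 0)
  skip <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  up <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  got <- claeForward(blk, skip, up)
  expect_equal(dim(got), c(4L, 4L, 4L))
  # CBAM gates 0.5 x 0.5, attention gate 0.5: X^G = 0.125 * skip,
  # then the ordinary Double Conv fusion of [X^G ; up]
  ctx <- list(tape = nunet:::tape_new(), training = FALSE)
  cat_in <- nunet:::op_concat_c(ctx$tape,
    nunet:::tp_leaf(ctx$tape, nunet:::as_feature(0.125 * skip)),
    nunet:::tp_leaf(ctx$tape, nunet:::as_feature(up)))
  want <- nunet:::from_feature(
    nunet:::fwd_double_conv(blk$children$fuse, ctx, cat_in)$v)
  expect_equal(got, want, tolerance = 1e-9)
  # evaluation-mode determinism of the full block
  expect_identical(claeForward(blk, skip, up), claeForward(blk, skip, up))
})

test_that("the classification head reads a 512-vector through two layers", {
  x <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  w1 <- matrix(0, 8, 16); w2 <- matrix(0, 16, 2)
  expect_equal(classificationHead(x, w1, rep(0, 16), w2, c(0, 0)), c(0, 0))
  # constant bottleneck: GAP equals that constant per channel
  xc <- array(rep(seq_len(8), each = 4), c(2, 2, 8))
  w1 <- matrix(rnorm(8 * 16), 8, 16); b1 <- rnorm(16)
  w2 <- matrix(rnorm(16 * 2), 16, 2); b2 <- rnorm(2)
  want <- as.vector(pmax(seq_len(8) %*% w1 + rep(b1, each = 1), 0) %*% w2) + b2
  expect_equal(classificationHead(xc, w1, b1, w2, b2), want,
               tolerance = 1e-9)
  expect_error(classificationHead(x, matrix(0, 4, 16), rep(0, 16), w2, b2),
               "channels")
})

test_that("the default two-layer head carries 527362 parameters", {
  head <- nunet:::new_module("cls_head")
  head$children$fc1 <- nunet:::mod_linear(512L, 1024L)
  head$children$fc2 <- nunet:::mod_linear(1024L, 2L)
  expect_equal(nunet:::module_n_params(head),
               512 * 1024 + 1024 + 1024 * 2 + 2)
})

test_that("the assembled model honors its shape and range contracts", {
  cfg <- modelConfig(encoderChannels = c(4L, 8L, 16L), inputSize = 64L)
  model <- buildNUnet(cfg, seed = 5L)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- nunetForward(model, img)
  expect_equal(dim(out$seg), c(64L, 64L, 1L))
  expect_equal(dim(out$logits), c(1L, 2L))
  expect_true(all(out$seg > 0 & out$seg < 1))
  # evaluation-mode determinism
  out2 <- nunetForward(model, img)
  expect_identical(out$seg, out2$seg)
  expect_identical(out$logits, out2$logits)
  expect_error(nunetForward(model, array(0, c(32, 32, 3))), "64x64x3")
})

test_that("model configs reject inconsistent channel schedules", {
  expect_error(modelConfig(encoderChannels = c(16L, 8L)), "increasing")
  expect_error(methods::new("ModelConfig", inputChannels = 3L,
                            inputSize = 256L,
                            encoderChannels = c(16L, 32L),
                            bottleneckChannels = 128L,
                            seReduction = 16L, cbamReduction = 16L,
                            cbamSpatialKernel = 7L, affDropout = 0.2,
                            affSideWidths = c(16L, 32L),
                            gateWidths = c(8L, 16L),
                            headDims = c(128L, 256L, 2L),
                            segOutChannels = 1L),
               "twice")
})
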