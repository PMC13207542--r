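test_that("focal loss collapses to plain BCE at gamma = 0, omega = 1", {
  set.seed(1)
  z <- runif(20, 0.05, 0.95)
  xi <- rbinom(20, 1, 0.5)
  bce <- -mean(xi * log(z) + (1 - xi) * log(1 - z))
  expect_equal(focalBCE(z, xi, omega = 1, gamma = 0), bce, tolerance = 1e-9)
})

test_that("the focal hand value 0.25 ln 2 holds at (0.5, 1, 2)", {
  expect_equal(focalBCE(0.5, 1, omega = 1, gamma = 2), 0.25 * log(2),
               tolerance = 1e-9)
})

test_that("focal loss decreases monotonically toward perfect prediction", {
  for (gamma in c(0, 0.5, 2, 5)) {
    z <- seq(0.05, 0.999, length.out = 60)
    losses <- vapply(z, function(p) focalBCE(p, 1, gamma = gamma), numeric(1))
    expect_true(all(diff(losses) < 0))
    expect_lt(losses[length(losses)], 1e-2)
  }
  expect_error(focalBCE(1.2, 1), "\\[0, 1\\]")
})

test_that("the class weight is N_neg / N_pos on merged lesion classes", {
  cats <- rep(c("benign", "malignant", "normal"), c(437, 210, 133))
  expect_equal(computeClassWeight(cats), 133 / 647, tolerance = 1e-9)
  expect_equal(round(computeClassWeight(cats), 4), 0.2056)
  # balance and scale invariance
  expect_equal(computeClassWeight(rep(c("benign", "normal"), c(5, 5))), 1)
  expect_equal(computeClassWeight(rep(cats, 2)), 133 / 647, tolerance = 1e-12)
  expect_error(computeClassWeight(rep("normal", 4)), "no lesion")
})

test_that("Dice loss is exactly zero on perfect and empty-empty agreement", {
  ones <- matrix(1, 10, 10)
  zeros <- matrix(0, 10, 10)
  expect_identical(diceLoss(ones, ones), 0)
  expect_identical(diceLoss(zeros, zeros), 0)
  # all-ones prediction against an empty 100-pixel truth
  expect_equal(diceLoss(matrix(1, 10, 10), zeros, epsilon = 1e-5),
               1 - 1e-5 / (100 + 1e-5), tolerance = 1e-12)
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("Dice loss stays in [0,1] and is symmetric for binary inputs", {
  set.seed(2)
  for (i in 1:10) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    a <- diceLoss(p, g)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(a, diceLoss(g, p), tolerance = 1e-12)
  }
})

test_that("AMTL at unit sigmas is the equal-weight quarter sum", {
  st <- lossState()  # logVar = c(0,0): sigma_1 = sigma_2 = 1
  expect_equal(amtlCombine(0.8, 0.3, st), (0.8 + 0.3) / 4, tolerance = 1e-12)
  expect_error(amtlCombine(NaN, 0.3, st), "classification")
  expect_error(amtlCombine(0.1, Inf, st), "segmentation")
})

test_that("the minimizing sigma of L/(2 sigma^2) + log sigma is sqrt(L)", {
  for (L in c(0.2, 1, 3.7)) {
    sig <- seq(0.05, 5, by = 1e-3)
    obj <- L / (2 * sig^2) + log(sig)
    expect_equal(sig[which.min(obj)], sqrt(L), tolerance = 2e-3)
    # the same through the combined loss, holding the other task at sqrt(L2)
    f <- function(s1) amtlCombine(L, 1, lossState(logVar = c(2 * log(s1), 0)))
    grid <- vapply(sig, f, numeric(1))
    expect_equal(sig[which.min(grid)], sqrt(L), tolerance = 2e-3)
  }
})

test_that("graph losses agree with their numeric counterparts", {
  set.seed(3)
  # focal via the two-logit graph path
  logits <- matrix(rnorm(12), 6, 2)
  xi <- rbinom(6, 1, 0.5)
  ctx <- list(tape = nunet:::tape_new(), training = FALSE)
  ln <- nunet:::tp_leaf(ctx$tape, logits)
  g <- nunet:::graph_focal_bce(ctx, ln, xi, omega = 0.7, gamma = 2)
  p <- 1 / (1 + exp(-(logits[, 1] - logits[, 2])))
  expect_equal(g$v, focalBCE(p, xi, omega = 0.7, gamma = 2),
               tolerance = 1e-9)
  # dice via the graph path
  seg <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  gm <- array(rbinom(128, 1, 0.3), c(8, 8, 2, 1))
  ctx <- list(tape = nunet:::tape_new(), training = FALSE)
  sn <- nunet:::tp_leaf(ctx$tape, seg)
  d <- nunet:::graph_dice(ctx, sn, gm, 1e-5)
  expect_equal(d$v, diceLoss(array(seg, c(8, 8, 2)), array(gm, c(8, 8, 2))),
               tolerance = 1e-9)
})
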