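small_setup <- function(n = 4, seed = 5L) {
  samples <- make_training_phantoms(n = n, canvas = 64L, evalSize = 32L,
                                    seed = seed)
  cfg <- modelConfig(encoderChannels = c(4L, 8L), inputSize = 32L)
  list(samples = samples, cfg = cfg)
}

test_that("a zero learning rate leaves every parameter unchanged", {
  su <- small_setup()
  model <- buildNUnet(su$cfg, seed = 1L)
  all_params <- function(m) lapply(nunet:::module_param_refs(m$root),
                                   function(r) r$mod$params[[r$name]])
  before <- all_params(model)
  set.seed(2)
  v <- trainStep(model, su$samples, omega = 1, lr = 0)
  expect_true(all(is.finite(v)))
  expect_identical(all_params(model), before)
})

test_that("two fresh seeded runs produce identical post-step losses", {
  su <- small_setup()
  run <- function() {
    model <- buildNUnet(su$cfg, seed = 1L)
    set.seed(7)
    losses <- replicate(3, trainStep(model, su$samples, omega = 1,
                                     lr = 1e-3)["total"])
    losses
  }
  expect_identical(run(), run())
})

test_that("one step with unequal task losses moves both uncertainty variables", {
  su <- small_setup()
  model <- buildNUnet(su$cfg, seed = 1L)
  expect_equal(model$root$children$amtl$params$logVar, c(0, 0))
  set.seed(3)
  v <- trainStep(model, su$samples, omega = 1, lr = 1e-2)
  expect_false(isTRUE(all.equal(v["cls"], v["seg"])))
  lv <- model$root$children$amtl$params$logVar
  expect_true(all(lv != 0))
})

test_that("cosine annealing starts at the initial rate and ends near zero", {
  lr0 <- 1e-5
  expect_equal(nunet:::cosine_lr(lr0, 1, 800), lr0)
  expect_equal(nunet:::cosine_lr(lr0, 800, 800), 0, tolerance = 1e-20)
  mid <- nunet:::cosine_lr(lr0, 400, 800)
  expect_gt(mid, 0.4 * lr0); expect_lt(mid, 0.6 * lr0)
  expect_equal(nunet:::cosine_lr(lr0, 1, 1), lr0)
})

test_that("fit logs one row per epoch and refuses leaky inputs", {
  su <- small_setup(n = 6)
  ids <- vapply(su$samples, sampleId, character(1))
  tc <- trainConfig(batchSize = 3L, epochs = 2L, initialLr = 1e-3,
                    seed = 1L, checkpointDir = withr::local_tempdir())
  fit <- fitNUnet(su$samples, ids[1:4], ids[5:6], su$cfg, tc)
  expect_equal(nrow(fit$log), 2L)
  expect_equal(fit$log$epoch, 1:2)
  expect_equal(fit$log$lr[1], 1e-3)
  expect_true(file.exists(fit$bestCheckpoint))
  expect_error(fitNUnet(su$samples, character(0), ids[5:6], su$cfg, tc),
               "empty training list")
  expect_error(fitNUnet(su$samples, ids[1:4], ids[4:5], su$cfg, tc),
               "overlap")
})

test_that("training resumes from a checkpoint with identical losses", {
  su <- small_setup(n = 4)
  ids <- vapply(su$samples, sampleId, character(1))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tc4 <- trainConfig(batchSize = 2L, epochs = 4L, initialLr = 1e-3,
                     seed = 9L, checkpointDir = dir1)
  full <- fitNUnet(su$samples, ids[1:3], ids[4], su$cfg, tc4)
  tc4b <- trainConfig(batchSize = 2L, epochs = 4L, initialLr = 1e-3,
                      seed = 9L, checkpointDir = dir2)
  part <- fitNUnet(su$samples, ids[1:3], ids[4], su$cfg, tc4b,
                   stopAfterEpoch = 2L)
  resumed <- fitNUnet(su$samples, ids[1:3], ids[4], su$cfg, tc4b,
                      resumeFrom = part$finalCheckpoint)
  expect_equal(resumed$log$train_total, full$log$train_total,
               tolerance = 1e-10)
  expect_equal(resumed$log$val_total, full$log$val_total, tolerance = 1e-10)
})

test_that("checkpoints round-trip the full model state", {
  su <- small_setup()
  model <- buildNUnet(su$cfg, seed = 4L)
  set.seed(5)
  trainStep(model, su$samples, omega = 1, lr = 1e-3)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(model, path, extra = list(epoch = 1L))
  back <- loadCheckpoint(path)
  img <- imageData(su$samples[[1]])
  expect_identical(nunetForward(back$model, img)$logits,
                   nunetForward(model, img)$logits)
  expect_equal(back$extra$epoch, 1L)
})

test_that("a non-finite loss aborts the step without touching state", {
  su <- small_setup()
  model <- buildNUnet(su$cfg, seed = 1L)
  # poison a weight so the forward pass overflows to NaN
  model$root$children$segHead$params$w[] <- NaN
  stem_before <- model$root$children$stem$children$c1$children$conv$params$w
  expect_warning(trainStep(model, su$samples, omega = 1, lr = 1e-3),
                 "non-finite")
  expect_identical(
    model$root$children$stem$children$c1$children$conv$params$w,
    stem_before)
})
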