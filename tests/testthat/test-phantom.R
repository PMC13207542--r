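test_that("a fixed seed reproduces a phantom bit-identically", {
  sp <- phantomSpec(height = 64, width = 64, targetArea = 400, seed = 7L)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(imageData(a), imageData(b))
  expect_identical(maskData(a), maskData(b))
})

test_that("lesion-free phantoms are normal with an all-zero mask", {
  s <- generatePhantom(phantomSpec(height = 64, width = 64,
                                   lesionPresent = FALSE, seed = 3L))
  expect_equal(sum(maskData(s)), 0)
  expect_equal(presenceLabel(s), "normal")
  expect_equal(category(s), "normal")
  expect_equal(lesionAreaA(s), 0)
})

test_that("the mask foreground count hits the requested area within 15%", {
  s <- generatePhantom(phantomSpec(height = 256, width = 256,
                                   targetArea = 2000, seed = 1L))
  expect_gte(sum(maskData(s)), 1700)
  expect_lte(sum(maskData(s)), 2300)
  for (seed in 2:5) {
    for (target in c(500, 4000)) {
      s <- generatePhantom(phantomSpec(height = 128, width = 128,
                                       targetArea = target, seed = seed))
      expect_lt(abs(sum(maskData(s)) - target) / target, 0.15)
    }
  }
})

test_that("lesions are hypoechoic: darker inside than outside", {
  for (seed in 1:6) {
    s <- generatePhantom(phantomSpec(height = 64, width = 64,
                                     targetArea = 500, contrast = 0.55,
                                     seed = seed))
    img <- imageData(s)[, , 1]
    m <- maskData(s) == 1
    expect_lt(mean(img[m]), mean(img[!m]))
  }
})

test_that("phantom specs reject invalid fields by name", {
  expect_error(phantomSpec(height = 32, width = 64), "height")
  expect_error(phantomSpec(lesionPresent = TRUE, targetArea = 0),
               "targetArea")
  expect_error(phantomSpec(contrast = 1.5), "contrast")
  expect_error(phantomSpec(lesionShape = "square"), "lesionShape")
})

test_that("cohort class counts follow the rounded mix exactly", {
  co <- generateCohort(100, classMix = c(benign = 0.5, malignant = 0.3,
                                         normal = 0.2),
                       areaRange = c(100, 800), size = 64, seed = 2L)
  tab <- table(co$manifest$category)
  expect_equal(as.integer(tab[c("benign", "malignant", "normal")]),
               c(50L, 30L, 20L))
  expect_false(any(duplicated(co$manifest$sample_id)))
})

test_that("cohort generation is deterministic and area law respects bounds", {
  co1 <- generateCohort(30, areaRange = c(100, 900), size = 64, seed = 11L)
  co2 <- generateCohort(30, areaRange = c(100, 900), size = 64, seed = 11L)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(lapply(co1$samples, maskData),
                   lapply(co2$samples, maskData))
  areas <- vapply(co1$samples, lesionAreaA, numeric(1))
  pos <- areas[areas > 0]
  q <- stats::quantile(pos, c(0.33, 0.66))
  expect_true(all(q >= 100 * 0.8 & q <= 900 * 1.2))
  # per-sample invariant: normal label iff zero area
  lbl <- vapply(co1$samples, presenceLabel, character(1))
  expect_identical(lbl == "normal", areas == 0)
})

test_that("mis-specified class proportions are rejected", {
  expect_error(generateCohort(10, classMix = c(benign = 0.6, malignant = 0.3,
                                               normal = 0.2)),
               "sum to 1")
})
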