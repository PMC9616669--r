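test_that("an image exactly patch-sized yields only the full-image window", {
  samples <- tinySamples(1, size = 64, seed = 51)
  ps <- extractRandomPatches(samples, 5, patchSize = 64, seed = 1,
                             normalize = FALSE)
  expect_true(all(ps@coords$top == 1L))
  expect_true(all(ps@coords$left == 1L))
  expect_equal(ps@patches[1, 1, , ], sampleImage(samples[[1]])[, ])
  expect_error(extractRandomPatches(samples, 2, patchSize = 96), "smaller")
})

test_that("stored patches re-cut bitwise from their source windows", {
  samples <- tinySamples(3, size = 64, seed = 52)
  ps <- extractRandomPatches(samples, 40, patchSize = 32, seed = 7,
                             normalize = FALSE)
  byId <- setNames(samples, sapply(samples, sampleId))
  for (i in seq_len(40)) {                      # re-cut oracle, all patches
    src <- byId[[ps@coords$sampleId[i]]]
    top <- ps@coords$top[i]; left <- ps@coords$left[i]
    expect_identical(ps@patches[i, 1, , ],
                     sampleImage(src)[top:(top + 31), left:(left + 31)])
    expect_identical(ps@labels[i, 1, , ],
                     vesselMask(src)[top:(top + 31), left:(left + 31)])
  }
  # determinism of the draw
  ps2 <- extractRandomPatches(samples, 40, patchSize = 32, seed = 7,
                              normalize = FALSE)
  expect_identical(ps@patches, ps2@patches)
  expect_identical(ps@coords, ps2@coords)
})

test_that("split arithmetic reproduces the published 152,000/38,000 protocol", {
  idx <- splitIndices(190000, 0.8, seed = 1)
  expect_equal(length(idx$train), 152000L)
  expect_equal(length(idx$val), 38000L)
  # partition property
  expect_identical(sort(c(idx$train, idx$val)), 1:190000)
  expect_length(intersect(idx$train, idx$val), 0)
  # counting oracle at small n
  for (s in 1:5) {
    sm <- splitIndices(10, 0.8, seed = s)
    expect_equal(c(length(sm$train), length(sm$val)), c(8L, 2L))
  }
  expect_error(splitIndices(5, 0.05), "empty")
})

test_that("patch-set splitting partitions patches deterministically", {
  samples <- tinySamples(2, size = 64, seed = 53)
  ps <- extractRandomPatches(samples, 20, patchSize = 32, seed = 3)
  sp <- splitPatches(ps, 0.8, seed = 9)
  expect_equal(dim(sp$train@patches)[1], 16L)
  expect_equal(dim(sp$val@patches)[1], 4L)
  sp2 <- splitPatches(ps, 0.8, seed = 9)
  expect_identical(sp$train@coords, sp2$train@coords)
})

test_that("tiling covers every pixel, with clamped edge windows", {
  cover <- function(H, W, P, stride) {
    img <- matrix(rnorm(H * W), H, W)
    tl <- tileImage(img, P, stride)
    bitmap <- matrix(0, H, W)
    for (i in seq_len(nrow(tl$coords))) {
      rs <- tl$coords$top[i]:(tl$coords$top[i] + P - 1)
      cs <- tl$coords$left[i]:(tl$coords$left[i] + P - 1)
      bitmap[rs, cs] <- bitmap[rs, cs] + 1
    }
    bitmap
  }
  expect_equal(nrow(tileImage(matrix(0, 96, 96), 96, 96)$coords), 1L)
  expect_true(all(cover(100, 100, 96, 48) >= 1))       # coverage bitmap
  bm <- cover(128, 96, 32, 32)                         # exact tiling
  expect_true(all(bm == 1))
  expect_error(tileImage(matrix(0, 64, 64), 32, 0), "positive")
  expect_error(tileImage(matrix(0, 64, 64), 32, 40), "exceed")
  expect_error(tileImage(matrix(0, 16, 16), 32), "smaller")
})

test_that("reconstruction averages overlapping predictions exactly", {
  set.seed(54)
  # constant predictions reconstruct to the constant
  tl <- tileImage(matrix(0, 80, 70), 32, 16)
  n <- nrow(tl$coords)
  preds <- array(0.37, c(n, 32, 32))
  expect_equal(reconstructFromPatches(preds, tl$coords, 80, 70),
               matrix(0.37, 80, 70))

  # stride = P round-trip is the identity
  img <- matrix(runif(96 * 64), 96, 64)
  tl <- tileImage(img, 32, 32)
  rec <- reconstructFromPatches(tl$patches[, 1, , ], tl$coords, 96, 64)
  expect_identical(rec, img)

  # overlapping case against a brute-force accumulation oracle
  img <- matrix(runif(50 * 40), 50, 40)
  tl <- tileImage(img, 16, 7)
  n <- nrow(tl$coords)
  preds <- array(runif(n * 16 * 16), c(n, 16, 16))
  acc <- matrix(0, 50, 40); cnt <- matrix(0, 50, 40)
  for (i in seq_len(n)) {
    rs <- tl$coords$top[i]:(tl$coords$top[i] + 15)
    cs <- tl$coords$left[i]:(tl$coords$left[i] + 15)
    acc[rs, cs] <- acc[rs, cs] + preds[i, , ]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  expect_equal(reconstructFromPatches(preds, tl$coords, 50, 40), acc / cnt,
               tolerance = 1e-15)
})

test_that("round-trip with consistent overlapping predictions is the identity", {
  set.seed(55)
  for (rep in 1:5) {
    H <- sample(48:96, 1); W <- sample(48:96, 1)
    img <- matrix(runif(H * W), H, W)
    tl <- tileImage(img, 32, 16)
    rec <- reconstructFromPatches(tl$patches[, 1, , ], tl$coords, H, W)
    expect_equal(rec, img, tolerance = 1e-12)
  }
})
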