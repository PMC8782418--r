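test_that("patch grids follow the stride arithmetic", {
  m <- matrix(rnorm(512 * 512), 512, 512)
  g <- extractPatches(m, 128, 32)
  expect_length(patches(g), 169)   # (512-128)/32 + 1 = 13 per axis

  # p = dim: a single patch at (0, 0)
  g1 <- extractPatches(matrix(1:64, 8, 8), 8, 4)
  expect_length(patches(g1), 1)
  expect_identical(patchOffsets(g1), cbind(0L, 0L))

  # offsets enumeration oracle: 256/128/64 -> {0, 64, 128}^2
  g9 <- extractPatches(matrix(0, 256, 256), 128, 64)
  expect_length(patches(g9), 9)
  expect_setequal(unique(patchOffsets(g9)[, 1]), c(0L, 64L, 128L))
  expect_setequal(unique(patchOffsets(g9)[, 2]), c(0L, 64L, 128L))

  # flush-to-edge rule for non-divisible remainders
  gf <- extractPatches(matrix(0, 100, 100), 64, 32)
  expect_setequal(unique(patchOffsets(gf)[, 1]), c(0L, 32L, 36L))

  expect_error(extractPatches(matrix(0, 64, 64), 128, 32), "exceeds")
})

test_that("extract -> reassemble is the bit-level identity", {
  set.seed(3)
  for (dims in list(c(512L, 512L), c(256L, 192L), c(100L, 100L))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    p <- if (dims[1] >= 512) 128L else 64L
    expect_identical(reassemblePatches(extractPatches(x, p, 32L)), x)
  }
})

test_that("coverage counts match the brute-force offset enumeration", {
  g <- extractPatches(matrix(0, 512, 512), 128, 32)
  cov <- patchCoverage(g)
  expect_identical(cov[1, 1], 1L)            # corner: only offset 0 covers it
  expect_identical(cov[256, 256], 16L)       # interior: 4 starts per axis
  # oracle: count offsets covering each probe pixel directly
  off <- patchOffsets(g)
  for (px in list(c(1, 1), c(256, 256), c(64, 400), c(512, 512))) {
    n <- sum(off[, 1] <= px[1] - 1 & px[1] - 1 < off[, 1] + 128 &
             off[, 2] <= px[2] - 1 & px[2] - 1 < off[, 2] + 128)
    expect_identical(cov[px[1], px[2]], as.integer(n))
  }
  # mass conservation: total coverage = patches * p^2
  expect_identical(sum(cov), length(patches(g)) * 128L * 128L)
})

test_that("overlap averaging averages exactly", {
  # two patches overlapping in one column; overlapped pixels = (a + b) / 2
  g <- extractPatches(matrix(0, 4, 7), 4, 3)
  expect_identical(nrow(patchOffsets(g)), 2L)
  g@patches[[1]][] <- 2   # covers cols 1:4
  g@patches[[2]][] <- 8   # covers cols 4:7
  out <- reassemblePatches(g)
  expect_true(all(out[, c(1, 2, 3)] == 2))
  expect_true(all(out[, 4] == 5))
  expect_true(all(out[, c(5, 6, 7)] == 8))
})

test_that("reassembly is invariant to patch order and rejects gaps", {
  set.seed(8)
  x <- matrix(rnorm(96 * 96), 96, 96)
  g <- extractPatches(x, 32, 16)
  perm <- sample(length(patches(g)))
  g2 <- g
  g2@patches <- g@patches[perm]
  g2@offsets <- g@offsets[perm, ]
  expect_identical(reassemblePatches(g2), reassemblePatches(g))

  # dropping the corner patch leaves uncovered pixels -> error with coords
  keep <- -1L
  g3 <- g
  g3@patches <- g@patches[keep]
  g3@offsets <- g@offsets[keep, ]
  expect_error(reassemblePatches(g3), "covered by no patch")
})

test_that("identity generator makes denoiseImage a lossless round trip", {
  spec <- smallLDSpec(128L)
  img <- makePhantom(spec, seed = 6, doseLabel = "low")$image
  vi <- denoiseImage(img, identityGenerator(), p = 64, s = 32)
  expect_lt(max(abs(pixels(vi) - pixels(img))), 1e-6)
  expect_identical(doseLabel(vi), "virtual")
  expect_identical(dim(pixels(vi)), dim(pixels(img)))
})

test_that("constant input maps to the replicated single-patch response", {
  # with a constant slice every extracted patch is identical, so the
  # reassembled output must equal the overlap average of one generator
  # response placed at every offset (computed here independently)
  cfg <- tinyNet(base = 2L)
  g <- buildGenerator(cfg, seed = 19)
  img <- CTImage(matrix(150, 96, 96))
  p <- 32L; s <- 16L
  vi <- denoiseImage(img, g, p = p, s = s)

  norm <- asNamespace("waveganCT")$huNormalization()
  xin <- array((150 - norm$center) / norm$scale, c(p, p, 1, 1))
  resp <- matrix(generatorApply(g, xin)[, , 1, 1], p, p)
  acc <- matrix(0, 96, 96); cov <- matrix(0, 96, 96)
  for (r0 in seq(0, 64, by = 16)) for (c0 in seq(0, 64, by = 16)) {
    acc[(r0 + 1):(r0 + p), (c0 + 1):(c0 + p)] <-
      acc[(r0 + 1):(r0 + p), (c0 + 1):(c0 + p)] + resp
    cov[(r0 + 1):(r0 + p), (c0 + 1):(c0 + p)] <-
      cov[(r0 + 1):(r0 + p), (c0 + 1):(c0 + p)] + 1
  }
  expected <- (acc / cov) * norm$scale + norm$center
  expect_equal(pixels(vi), expected, tolerance = 1e-12)
})
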