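test_that("roiStats computes pixel-center statistics", {
  # constant image: mean c, sd 0
  img <- CTImage(matrix(42, 16, 16))
  s <- roiStats(img, ROISpec("r", c(8, 8), 3))
  expect_equal(s$mean, 42)
  expect_equal(s$sd, 0)
  expect_gt(s$n, 20)

  # 2-pixel ROI with values {10, 14}: mean 12, sample sd = sqrt(8)
  m <- matrix(0, 4, 4)
  m[2, 2] <- 10; m[2, 3] <- 14
  roi2 <- ROISpec("pair", c(1, 1.5), 0.6)   # pixel centers (1,1) and (1,2)
  s2 <- roiStats(CTImage(m), roi2)
  expect_identical(s2$n, 2L)
  expect_equal(s2$mean, 12)
  expect_equal(s2$sd, sqrt(8))

  expect_error(roiStats(img, ROISpec("out", c(2, 2), 8)), "outside")
})

test_that("synthetic liver ROI recovers the generation target", {
  spec <- smallSDSpec(256L)
  ph <- makePhantom(spec, seed = 21)
  rois <- defaultROIs(spec)
  means <- vapply(paste0("liver_", 1:4), function(k)
    roiStats(ph$image, rois[[k]])$mean, numeric(1))
  expect_lt(abs(mean(means) - 120.7), 2)
})

test_that("image noise is the mean of the two muscle ROI SDs", {
  img <- CTImage(matrix(5, 8, 8))
  rois <- list(ROISpec("muscle_left", c(2, 2), 1.2),
               ROISpec("muscle_right", c(5, 5), 1.2))
  expect_equal(imageNoise(img, rois), 0)

  # two 2-pixel ROIs engineered to SDs 10 and 14 -> SDn = 12
  m <- matrix(0, 6, 6)
  m[2, 2] <- 0; m[2, 3] <- 10 * sqrt(2)
  m[5, 2] <- 0; m[5, 3] <- 14 * sqrt(2)
  rois2 <- list(ROISpec("l", c(1, 1.5), 0.6), ROISpec("r", c(4, 1.5), 0.6))
  expect_equal(imageNoise(CTImage(m), rois2), 12)

  expect_error(imageNoise(img, rois[1]), "two")
})

test_that("configured dose noise is recovered as SDn over seeds", {
  spec <- phantomSpec(imageSize = c(128, 128),
                      tissueTable = lowDoseTissueTable(), noiseSD = 14.2)
  rois <- defaultROIs(spec)
  muscles <- rois[c("muscle_left", "muscle_right")]
  sdns <- vapply(1:20, function(s)
    imageNoise(makePhantom(spec, seed = s)$image, muscles), numeric(1))
  expect_lt(abs(mean(sdns) - 14.2), 0.7)
})

test_that("CNR and SNR are the exact closed forms", {
  expect_equal(computeCNR(100, 100, 7), 0)
  expect_equal(computeCNR(200, 100, 50), 2)
  # group means of the two domains give the ratio-of-means values
  expect_equal(computeCNR(247.3, 75.8, 14.2), (247.3 - 75.8) / 14.2)
  expect_equal(computeSNR(247.3, 14.2), 247.3 / 14.2)
  expect_equal(computeSNR(0, 5), 0)
  expect_equal(computeSNR(100, 10), 10)
  set.seed(5)
  for (i in 1:25) {
    o <- rnorm(1, 150, 50); mm <- rnorm(1, 70, 10); s <- runif(1, 1, 30)
    expect_equal(computeCNR(o, mm, s), (o - mm) / s)
    expect_equal(computeSNR(o, s), o / s)
  }
  expect_error(computeCNR(100, 50, 0), "undefined")
  expect_error(computeSNR(100, 0), "undefined")
})

test_that("qualityReport applies the organ ROI protocol", {
  spec <- smallSDSpec(256L)
  ph <- makePhantom(spec, seed = 31)
  q <- qualityReport(ph$image, defaultROIs(spec))
  expect_lt(abs(roiMeans(q)[["portal_vein"]] - 187.6), 3)
  expect_lt(abs(roiMeans(q)[["liver"]] - 120.7), 2)
  expect_lt(abs(roiMeans(q)[["muscle"]] - 70.7), 2)
  expect_lt(abs(sdn(q) - 10.6), 2)
  expect_equal(cnr(q)[["portal_vein"]],
               (roiMeans(q)[["portal_vein"]] - roiMeans(q)[["muscle"]]) /
                 sdn(q))
  expect_equal(snr(q)[["liver"]], roiMeans(q)[["liver"]] / sdn(q))
})

test_that("NPS of a constant region is identically zero", {
  lab <- matrix(2L, 64, 64)
  mask <- LabelMask(lab, c(`2` = "liver"))
  img <- CTImage(matrix(100, 64, 64))
  r <- computeNPS(img, mask, "liver")
  expect_true(all(npsMagnitudes(r) == 0))
  expect_equal(npsAUC(r), 0)
})

test_that("white-noise NPS satisfies Parseval and is flat at mid frequencies", {
  set.seed(77)
  mu <- 100; sigma <- 10
  m <- matrix(mu + rnorm(256 * 256, 0, sigma), 256, 256)
  mask <- LabelMask(matrix(2L, 256, 256), c(`2` = "liver"))
  r <- computeNPS(CTImage(m), mask, "liver")
  # 2-D spectral mass = relative variance of the fluctuation field
  expect_lt(abs(npsSpectralMass(r) - (sigma / mu)^2) / (sigma / mu)^2, 0.05)
  # radially averaged curve flat within 10% over mid frequencies
  mid <- npsMagnitudes(r)[4:13]
  expect_true(all(abs(mid - mean(mid)) / mean(mid) < 0.10))
})

test_that("low-pass filtering strictly lowers the NPS peak frequency", {
  set.seed(41)
  mu <- 100; sigma <- 8
  raw <- matrix(mu + rnorm(256 * 256, 0, sigma), 256, 256)
  sm <- blurMatrix(raw - mu, sigma = 1.5) + mu
  mask <- LabelMask(matrix(2L, 256, 256), c(`2` = "liver"))
  rRaw <- computeNPS(CTImage(raw), mask, "liver")
  rSm <- computeNPS(CTImage(sm), mask, "liver")
  expect_lt(peakFrequency(rSm), peakFrequency(rRaw))
  expect_lt(npsAUC(rSm), npsAUC(rRaw))
})

test_that("mean normalization removes DC and rescales predictably", {
  set.seed(13)
  m <- matrix(200 + rnorm(96 * 96, 0, 10), 96, 96)
  mask <- LabelMask(matrix(2L, 96, 96), c(`2` = "liver"))
  r1 <- computeNPS(CTImage(m), mask, "liver")
  r2 <- computeNPS(CTImage(m + 100), mask, "liver")
  # the same fluctuation field measured against a higher mean: the peak
  # location is unchanged and the relative spectrum scales by (mu1/mu2)^2
  expect_equal(peakFrequency(r2), peakFrequency(r1))
  scale <- (mean(m) / mean(m + 100))^2
  expect_equal(npsMagnitudes(r2)[-1], npsMagnitudes(r1)[-1] * scale,
               tolerance = 0.02)
  expect_error(computeNPS(CTImage(matrix(1, 16, 16)),
                          LabelMask(matrix(2L, 16, 16), c(`2` = "liver")),
                          "liver"), "tile")
})

test_that("dose report reproduces reduction arithmetic and its invariances", {
  sdRec <- doseRecord(4.1, 156.2, ed = 4.4)
  ldRec <- doseRecord(2.6, 105.4, ed = 3.0)
  rep <- doseReport(sdRec, ldRec)
  expect_equal(rep$reduction_pct, c(36.6, 32.5, 31.8))

  # equal means -> 0%
  expect_equal(doseReport(sdRec, sdRec)$reduction_pct, c(0, 0, 0))

  # scale invariance: multiplying all records by c > 0 changes nothing
  set.seed(23)
  for (i in 1:5) {
    cst <- runif(1, 0.1, 10)
    sc <- function(df) { df[] <- lapply(df, function(v) v * cst); df }
    expect_equal(doseReport(sc(sdRec), sc(ldRec))$reduction_pct,
                 rep$reduction_pct)
  }

  # ED = DLP x K
  r <- doseRecord(4, 150, kFactor = 0.02)
  expect_equal(r$ed, 3)
  expect_error(doseRecord(4, 150, kFactor = 0.02, ed = 5), "inconsistent")
  expect_error(doseReport(doseRecord(0, 0, ed = 0), ldRec), "undefined")
})

test_that("evaluateImages yields one complete row per image", {
  spec <- smallSDSpec(128L)
  imgs <- list(makePhantom(spec, seed = 1)$image,
               makePhantom(spec, seed = 2)$image)
  df <- evaluateImages(imgs, defaultROIs(spec))
  expect_identical(nrow(df), 2L)
  expect_true(all(is.finite(df$sdn)))
  expect_true(all(c("cnr_portal_vein", "snr_liver") %in% names(df)))
})
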