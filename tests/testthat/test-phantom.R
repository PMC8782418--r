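test_that("phantom regions hit their target means and noise", {
  # standard-dose profile: every organ mean within 2 HU of its target
  spec <- smallSDSpec(256L)
  ph <- makePhantom(spec, seed = 4)
  lab <- labelMatrix(ph$mask)
  px <- pixels(ph$image)
  targets <- c(liver = 120.7, portal_vein = 187.6, muscle_left = 70.7,
               muscle_right = 70.7, body = 50)
  legend <- maskLegend(ph$mask)
  for (region in names(targets)) {
    k <- as.integer(names(legend)[legend == region])
    expect_lt(abs(mean(px[lab == k]) - targets[[region]]), 2,
              label = paste("mean of", region))
  }
  # air background exact
  expect_true(all(px[lab == 0] == -1000))

  # zero noise, zero texture: within-region SD exactly 0
  spec0 <- phantomSpec(imageSize = c(64, 64), noiseSD = 0)
  ph0 <- makePhantom(spec0, seed = 1)
  lab0 <- labelMatrix(ph0$mask)
  expect_identical(sd(pixels(ph0$image)[lab0 == 2]), 0)

  # texture + dose noise combine in quadrature
  specT <- phantomSpec(imageSize = c(256, 256),
                       tissueTable = modifyList(standardDoseTissueTable(),
                         list(liver = tissueSpec("liver", 120.7, 8))),
                       noiseSD = 6)
  phT <- makePhantom(specT, seed = 9)
  sdLiver <- sd(pixels(phT$image)[labelMatrix(phT$mask) == 2])
  expect_lt(abs(sdLiver - sqrt(8^2 + 6^2)), 0.5)
})

test_that("configured noise SD is recovered empirically over seeds", {
  spec <- phantomSpec(imageSize = c(256, 256),
                      tissueTable = lowDoseTissueTable(), noiseSD = 14.2)
  sds <- vapply(1:20, function(s) {
    ph <- makePhantom(spec, seed = s)
    sd(pixels(ph$image)[labelMatrix(ph$mask) == 2])
  }, numeric(1))
  expect_lt(abs(mean(sds) - 14.2), 0.5)
})

test_that("phantom generation is deterministic given the seed", {
  spec <- smallLDSpec(64L)
  a <- makePhantom(spec, seed = 33)
  b <- makePhantom(spec, seed = 33)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(labelMatrix(a$mask), labelMatrix(b$mask))
  c <- makePhantom(spec, seed = 34)
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("unpaired corpus: distinct jittered images, reproducible, unpaired", {
  ld <- smallLDSpec(64L); sd <- smallSDSpec(64L)
  c1 <- makeUnpairedCorpus(ld, sd, 4, 4, seed = 5)
  expect_length(c1$ld, 4); expect_length(c1$sd, 4)
  all8 <- c(c1$ld, c1$sd)
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(pixels(all8[[i]]), pixels(all8[[j]])))
  c2 <- makeUnpairedCorpus(ld, sd, 4, 4, seed = 5)
  for (i in 1:4) expect_identical(pixels(c1$ld[[i]]), pixels(c2$ld[[i]]))
  # minimal corpus is valid
  expect_silent(cmin <- makeUnpairedCorpus(ld, sd, 1, 1, seed = 1))
  expect_error(makeUnpairedCorpus(ld, sd, 0, 1, seed = 1), ">= 1")
})

test_that("corpus-level contrast difference matches the two dose domains", {
  ld <- smallLDSpec(128L); sd <- smallSDSpec(128L)
  corp <- makeUnpairedCorpus(ld, sd, 6, 6, seed = 8)
  pvMean <- function(imgs, masks) mean(vapply(seq_along(imgs), function(i)
    mean(pixels(imgs[[i]])[labelMatrix(masks[[i]]) == 3]), numeric(1)))
  dPV <- pvMean(corp$ld, corp$ldMasks) - pvMean(corp$sd, corp$sdMasks)
  # portal vein 247.3 vs 187.6 -> ~59.7 HU apart
  expect_lt(abs(dPV - 59.7), 5)
})

test_that("invalid geometry is rejected and names the offending primitive", {
  spec <- smallSDSpec(64L)
  bad <- spec
  bad$geometry$portalVeinDisc$center <- c(10, 10)  # outside the liver
  expect_error(makePhantom(bad, 1), "portalVeinDisc")
  bad2 <- spec
  bad2$geometry$muscleDiscLeft$center <- spec$geometry$liverEllipse$center
  expect_error(makePhantom(bad2, 1), "muscleDiscLeft")
  bad3 <- spec
  bad3$geometry$bodyEllipse$axes <- c(60, 60)  # overflows the canvas
  expect_error(makePhantom(bad3, 1), "bodyEllipse")
})

test_that("every labeled pixel is drawn from its region's tissue", {
  # give each tissue a wildly different mean and zero noise: pixel value
  # then identifies its source tissue exactly
  tt <- list(body = tissueSpec("body", 0),
             liver = tissueSpec("liver", 500),
             portal_vein = tissueSpec("portal_vein", 1000),
             muscle_left = tissueSpec("muscle_left", 1500),
             muscle_right = tissueSpec("muscle_right", 2000))
  spec <- phantomSpec(imageSize = c(96, 96), tissueTable = tt, noiseSD = 0)
  ph <- makePhantom(spec, seed = 2)
  lab <- labelMatrix(ph$mask)
  px <- pixels(ph$image)
  expected <- c(0, 500, 1000, 1500, 2000)
  for (k in 1:5)
    expect_true(all(px[lab == k] == expected[k]))
})
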