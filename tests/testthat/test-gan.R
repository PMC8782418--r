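test_that("generator preserves shape and is deterministic in its build", {
  cfg <- tinyNet()
  g1 <- buildGenerator(cfg, seed = 7)
  g2 <- buildGenerator(cfg, seed = 7)
  expect_identical(modelParameters(g1), modelParameters(g2))
  g3 <- buildGenerator(cfg, seed = 8)
  expect_false(identical(modelParameters(g3), modelParameters(g1)))

  x <- array(0, dim = c(128, 128, 1, 1))
  y <- generatorApply(g1, x)
  expect_identical(dim(y), c(128L, 128L, 1L, 1L))
  expect_true(all(is.finite(y)))
  # arbitrary even sizes divisible by 2^depth
  y2 <- generatorApply(g1, array(rnorm(32 * 64 * 2), dim = c(32, 64, 1, 2)))
  expect_identical(dim(y2), c(32L, 64L, 1L, 2L))
  expect_true(all(is.finite(y2)))
  # incompatible size -> configuration error
  expect_error(generatorApply(g1, array(0, dim = c(30, 30, 1, 1))),
               "divisible")
})

test_that("weights are initialized from N(0, 0.01)", {
  cfg <- networkConfig(depth = 2, baseFeatures = 24, discBaseFeatures = 24)
  g <- buildGenerator(cfg, seed = 123)
  w <- unlist(modelParameters(g)[grep("\\.w$", names(modelParameters(g)))])
  expect_lt(abs(mean(w)), 5e-4)
  expect_lt(abs(sd(w) - 0.01), 5e-4)
})

test_that("discriminator score-map size follows the stride-2 arithmetic", {
  cfg <- tinyNet()
  d <- buildDiscriminator(cfg, seed = 3)
  s128 <- discriminatorApply(d, array(rnorm(128 * 128), c(128, 128, 1, 1)))
  expect_identical(dim(s128), c(8L, 8L, 1L, 1L))   # 128 / 2^4
  s64 <- discriminatorApply(d, array(rnorm(64 * 64 * 3), c(64, 64, 1, 3)))
  expect_identical(dim(s64), c(4L, 4L, 1L, 3L))
  expect_identical(modelParameters(buildDiscriminator(cfg, seed = 3)),
                   modelParameters(d))
  expect_error(discriminatorApply(d, array(0, c(8, 8, 1, 1))), "small")
})

test_that("parameter count matches the layer-by-layer counting formula", {
  f <- c(3L, 5L); fb <- 2L * f[2]
  cfg <- networkConfig(depth = 2, featureSchedule = f, baseFeatures = 3,
                       discBaseFeatures = 2, discLayers = 3)
  g <- buildGenerator(cfg, seed = 1)
  convBN <- function(k, cin, cout) (k^2 * cin + 1) * cout + 2 * cout
  expected <-
    convBN(3, 1, f[1]) + convBN(3, f[1], f[1]) +          # enc1
    convBN(3, f[1], f[2]) + convBN(3, f[2], f[2]) +       # enc2
    convBN(3, f[2], fb) + convBN(3, fb, fb) +             # bottleneck
    convBN(3, fb, f[2]) + convBN(3, 2 * f[2], f[2]) +     # dec2
      convBN(3, f[2], f[2]) +
    convBN(3, f[2], f[1]) + convBN(3, 2 * f[1], f[1]) +   # dec1
      convBN(3, f[1], f[1]) +
    (1 * f[1] + 1) * 1                                    # 1x1 output
  expect_identical(sum(vapply(modelParameters(g), length, 1L)),
                   as.integer(expected))

  d <- buildDiscriminator(cfg, seed = 1)
  gch <- 2L * 2^(0:2)
  expectedD <- convBN(4, 1, gch[1]) + convBN(4, gch[1], gch[2]) +
    convBN(4, gch[2], gch[3]) + (1 * gch[3] + 1) * 1
  expect_identical(sum(vapply(modelParameters(d), length, 1L)),
                   as.integer(expectedD))
})

test_that("least-squares losses match their closed forms", {
  ones <- array(1, c(4, 4, 1, 2)); zeros <- array(0, c(4, 4, 1, 2))
  # ideal discriminator
  expect_equal(discriminatorLoss(ones, zeros), 0)
  # maximally fooled
  expect_equal(discriminatorLoss(zeros, ones), 1)
  expect_equal(discriminatorLoss(matrix(0.5), matrix(0.5)), 0.25)

  p <- array(rnorm(64), c(8, 8, 1, 1))
  # both generator terms vanish at the ideal point
  expect_equal(generatorLoss(ones, p, p, lambdaPix = 10), 0)
  # adversarial term alone
  expect_equal(generatorLoss(zeros, p, p, lambdaPix = 5), 0.5)
  # pixel term alone: constant offset 2, lambda 1, L2 -> mean(2^2) = 4
  expect_equal(generatorLoss(ones, p + 2, p, lambdaPix = 1), 4)
  # L1 variant
  expect_equal(generatorLoss(ones, p + 2, p, lambdaPix = 1, norm = "l1"), 2)

  # random score maps against direct arithmetic
  set.seed(11)
  for (rep in 1:10) {
    r <- array(rnorm(32), c(4, 8, 1, 1)); fk <- array(rnorm(32), c(4, 8, 1, 1))
    expect_equal(discriminatorLoss(r, fk),
                 0.5 * mean((r - 1)^2) + 0.5 * mean(fk^2))
    a <- array(rnorm(16), c(4, 4, 1, 1)); b <- array(rnorm(16), c(4, 4, 1, 1))
    lam <- runif(1, 0, 20)
    expect_equal(generatorLoss(fk, a, b, lam),
                 0.5 * mean((fk - 1)^2) + lam * mean((a - b)^2))
  }

  expect_error(discriminatorLoss(numeric(0), ones), "non-empty")
  expect_error(generatorLoss(ones, p, array(0, c(4, 4, 1, 1)), 1), "shape")
})

test_that("gradients reach every parameter and match finite differences", {
  ns <- asNamespace("waveganCT")
  cfg <- networkConfig(depth = 2, baseFeatures = 2, discBaseFeatures = 2,
                       discLayers = 2)
  set.seed(42)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  tgt <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  g <- buildGenerator(cfg, seed = 5)
  par <- g@parameters; st <- g@state
  fw <- ns$generatorForwardCore(par, st, cfg, x, training = TRUE)
  dy <- 2 * (fw$y - tgt) / length(fw$y)
  gr <- ns$generatorBackwardCore(dy, fw$cache, par, cfg)

  # no dead branches: every parameter tensor receives gradient mass
  expect_setequal(names(gr), names(par))
  expect_true(all(vapply(gr, function(a) sum(abs(a)) > 0, logical(1))))

  # finite-difference spot check (epsilon small enough to avoid the
  # leaky-ReLU kinks)
  lossFn <- function(p) {
    y <- ns$generatorForwardCore(p, st, cfg, x, training = TRUE,
                                 keepCache = FALSE)$y
    mean((y - tgt)^2)
  }
  set.seed(9)
  for (nm in sample(names(par), 6)) {
    i <- sample(length(par[[nm]]), 1)
    eps <- 1e-6
    p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (lossFn(p1) - lossFn(p2)) / (2 * eps)
    expect_lt(abs(num - gr[[nm]][i]) / max(1e-7, abs(num) + abs(gr[[nm]][i])),
              1e-3, label = paste("gradient of", nm))
  }

  # discriminator gradients likewise
  d <- buildDiscriminator(cfg, seed = 6)
  fd <- ns$discriminatorForwardCore(d@parameters, d@state, cfg, x,
                                    training = TRUE)
  db <- ns$discriminatorBackwardCore((fd$y - 1) / length(fd$y), fd$cache,
                                     d@parameters, cfg, needDx = TRUE)
  expect_setequal(names(db$grads), names(d@parameters))
  expect_true(all(vapply(db$grads, function(a) sum(abs(a)) > 0, logical(1))))
})

test_that("checkpoints round-trip the full model", {
  cfg <- tinyNet(base = 2L, discLayers = 2L)
  g <- buildGenerator(cfg, seed = 77)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(g, path, seed = 77L)
  g2 <- loadCheckpoint(path)
  expect_identical(modelParameters(g2), modelParameters(g))
  expect_identical(modelConfig(g2), modelConfig(g))
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  expect_identical(generatorApply(g2, x), generatorApply(g, x))
  expect_error(loadCheckpoint(tempfile()), "not found")
})
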