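# Shared fixtures: small phantom specifications matching the two dose
# domains, and a desk-scale network configuration.

smallLDSpec <- function(size = 128L)
  phantomSpec(imageSize = c(size, size), tissueTable = lowDoseTissueTable(),
              noiseSD = 14.2)

smallSDSpec <- function(size = 128L)
  phantomSpec(imageSize = c(size, size),
              tissueTable = standardDoseTissueTable(), noiseSD = 10.6)

tinyNet <- function(depth = 2L, base = 4L, discLayers = 4L)
  networkConfig(depth = depth, baseFeatures = base,
                discBaseFeatures = base, discLayers = discLayers)

# Gaussian blur with a small separable kernel (test-side oracle for
# low-pass filtering; independent of any package code).
blurMatrix <- function(m, sigma = 1.5) {
  half <- ceiling(3 * sigma)
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad <- function(x, n) x[c(rep(1, n), seq_len(nrow(x)), rep(nrow(x), n)), ]
  convRows <- function(x) {
    xp <- pad(x, half)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(nrow(x)))
      out[i, ] <- colSums(xp[i:(i + 2 * half), , drop = FALSE] * k)
    out
  }
  t(convRows(t(convRows(m))))
}
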