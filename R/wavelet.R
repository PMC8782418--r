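## Single-level orthonormal 2-D Haar analysis/synthesis. These are the
## down- and up-sampling operators of the framelet generator; exposed
## publicly because their perfect-reconstruction and energy-conservation
## properties are contracts the network relies on.

#' Single-level 2-D Haar wavelet analysis
#'
#' Decomposes an even-sized matrix into the four half-resolution subbands
#' LL, LH, HL, HH using the orthonormal Haar filter bank (every 2-D filter
#' tap is +/- 1/2). For each 2x2 block `[a b; c d]` (rows down, columns
#' right):
#' \deqn{LL = (a+b+c+d)/2,\; LH = (a-b+c-d)/2,\; HL = (a+b-c-d)/2,\; HH = (a-b-c+d)/2}
#' so LH carries detail along the width, HL along the height. The map is
#' orthogonal: `sum(x^2)` equals the summed squared energy of the four
#' subbands, and [haarRecompose()] inverts it exactly. A constant matrix
#' `c` yields `ll == 2*c` and zero details.
#'
#' Odd dimensions are a hard error; the network guarantees even sizes by
#' construction and silent padding would break perfect reconstruction.
#'
#' @param x numeric matrix with even numbers of rows and columns.
#' @return A [SubbandSet-class] with subbands of half the size.
#' @seealso [haarRecompose()]
#' @examples
#' s <- haarDecompose(rbind(c(1, 2), c(3, 4)))
#' subband(s, "ll")  # 5
#' @export
haarDecompose <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix")
  if (nrow(x) %% 2L || ncol(x) %% 2L)
    stop(sprintf("Haar analysis requires even dimensions, got %d x %d",
                 nrow(x), ncol(x)))
  a <- array(x, dim = c(nrow(x), ncol(x), 1L, 1L))
  s <- .haarForward(a)
  h2 <- nrow(x) %/% 2L; w2 <- ncol(x) %/% 2L
  band <- function(i) matrix(s[, , i, 1L], h2, w2)
  new("SubbandSet", ll = band(1L), lh = band(2L), hl = band(3L),
      hh = band(4L), orthonormal = TRUE)
}

#' Single-level 2-D Haar wavelet synthesis
#'
#' Exact inverse of [haarDecompose()]: reconstructs the `2n x 2m` matrix
#' from a [SubbandSet-class]. Because the analysis is orthogonal the round
#' trip is exact to floating-point precision.
#'
#' @param s a [SubbandSet-class] whose four subbands share one shape.
#' @return Numeric matrix of twice the subband size in each dimension.
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' max(abs(haarRecompose(haarDecompose(x)) - x)) < 1e-12
#' @export
haarRecompose <- function(s) {
  stopifnot(is(s, "SubbandSet"))
  validObject(s)
  d <- dim(s@ll)
  a <- array(c(s@ll, s@lh, s@hl, s@hh), dim = c(d[1], d[2], 4L, 1L))
  matrix(.haarInverse(a)[, , 1L, 1L], 2L * d[1], 2L * d[2])
}

## Batched forms used inside the network (arrays (H, W, C, N)).
## The transform is orthogonal, so the gradient of the analysis is the
## synthesis applied to the upstream gradient, and vice versa.
haarForwardBatch <- function(x) .haarForward(x)
haarInverseBatch <- function(s) .haarInverse(s)
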