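# Signed distance-correlation association measures and their bootstrap
# aggregation into a per-group association matrix.

#' Sign of Kendall's tau
#'
#' Direction of monotone association via tie-corrected Kendall tau-b.
#' Exact zero tau, or a constant input vector (tau undefined), returns 0.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return -1, 0 or +1.
#' @export
kendallSign <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  tau <- suppressWarnings(cor(x, y, method = "kendall"))
  if (is.na(tau)) return(0)
  sign(tau)
}

# Double-centered pairwise-distance matrix of one variable (V-statistic
# centering).
.centeredDist <- function(x) {
  a <- as.matrix(dist(x))
  rm <- rowMeans(a)
  a - outer(rm, rm, "+") + mean(a)
}

#' Distance correlation (sample V-statistic)
#'
#' Strength of (possibly nonlinear) dependence in [0, 1], computed from
#' double-centered pairwise-distance matrices.  Returns 0 when either
#' distance variance is 0 (degenerate guard, e.g. a constant vector).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Distance correlation in [0, 1].
#' @export
distanceCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  A <- .centeredDist(x)
  B <- .centeredDist(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- max(0, mean(A * B))
  sqrt(dcov2 / sqrt(dvx * dvy))
}

#' Signed distance correlation
#'
#' Product of the distance correlation and the sign of Kendall's tau,
#' representing both magnitude and monotone direction of association.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Value in [-1, 1]; its magnitude equals [distanceCorrelation()].
#' @export
signedDistanceCorrelation <- function(x, y) {
  distanceCorrelation(x, y) * kendallSign(x, y)
}

# All-pairs signed distance correlation of the columns of a matrix,
# vectorized over pairs: the double-centered distance matrices are
# flattened into columns of M so that crossprod(M)/n^2 yields every
# pairwise distance covariance at once.
.signedMatrix <- function(block) {
  p <- ncol(block)
  n <- nrow(block)
  if (n < 3L) {
    # size-2 subsamples are degenerate for distance correlation (always 1
    # for non-constant pairs); they contribute no information
    return(matrix(0, p, p, dimnames = list(colnames(block), colnames(block))))
  }
  M <- vapply(seq_len(p), function(j) as.vector(.centeredDist(block[, j])),
              numeric(n * n))
  dcov2 <- crossprod(M) / (n * n)
  dvar <- diag(dcov2)
  denom <- sqrt(outer(dvar, dvar))
  r <- matrix(0, p, p)
  ok <- denom > 0
  r[ok] <- sqrt(pmax(0, dcov2[ok]) / denom[ok])
  ks <- suppressWarnings(cor(block, method = "kendall"))
  ks[is.na(ks)] <- 0
  r <- r * sign(ks)
  diag(r) <- 0
  dimnames(r) <- list(colnames(block), colnames(block))
  r
}

#' Bootstrap-aggregated signed association matrix of one group
#'
#' Draws `nBoot` subsamples without replacement, each of size
#' `max(2, floor(n / 3))`, computes the full pairwise signed
#' distance-correlation matrix on each, and aggregates entrywise by the
#' median.  Size-2 subsamples are degenerate for distance correlation and
#' contribute zeros.
#'
#' @param block Numeric matrix (samples x features) of one diagnosis
#'   group, or a [BreathomicsExperiment-class] (all its samples are used).
#' @param nBoot Number of subsamples (default 500).
#' @param seed Integer seed.
#' @return A [SignedCorrelationMatrix-class].
#' @export
bootstrapAssociationMatrix <- function(block, nBoot = 500L, seed) {
  if (is(block, "BreathomicsExperiment")) block <- intensityMatrix(block)
  block <- as.matrix(block)
  n <- nrow(block)
  if (n < 3L) stop("group size must be >= 3")
  nBoot <- as.integer(nBoot)
  m <- max(2L, floor(n / 3))
  p <- ncol(block)
  acc <- array(NA_real_, c(p, p, nBoot))
  .withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, m)
      acc[, , b] <- .signedMatrix(block[idx, , drop = FALSE])
    }
  })
  med <- apply(acc, c(1L, 2L), median)
  med <- (med + t(med)) / 2
  diag(med) <- 0
  dimnames(med) <- list(colnames(block), colnames(block))
  new("SignedCorrelationMatrix", matrix = med, nBoot = nBoot,
      subsampleSize = as.integer(m), seed = as.integer(seed))
}
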