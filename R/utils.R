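#' @keywords internal
"_PACKAGE"

## Numerically stable log(sum(exp(x))) for a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log(sum(exp())) for a matrix, vectorized.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

#' Solve a small assignment problem exactly
#'
#' Finds the permutation `p` minimizing `sum(cost[i, p[i]])` by dynamic
#' programming over column subsets. Rectangular matrices are padded with
#' zero-cost dummy rows/columns; entries of `p` mapped to a dummy column are
#' returned as `NA`. Ties are broken toward the lowest column index for the
#' lowest row index, so an all-constant cost matrix yields the identity.
#'
#' Exact and exponential in `min(dim(cost))`; intended for cluster-label
#' matching where the number of clusters is small (hard limit 15).
#'
#' @param cost numeric matrix of assignment costs.
#' @return integer vector `p` of length `nrow(cost)`.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost) || anyNA(cost)) {
    stop("'cost' must be a numeric matrix without missing values")
  }
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  if (n > 15L) stop("assignment solver limited to 15 rows/columns")
  if (n == 0L) return(integer(0))
  C <- matrix(0, n, n)
  C[seq_len(nr), seq_len(nc)] <- cost
  nmask <- bitwShiftL(1L, n)
  popcount <- integer(nmask)
  for (m in seq_len(nmask - 1L)) {
    popcount[m + 1L] <- popcount[bitwShiftR(m, 1) + 1L] + bitwAnd(m, 1L)
  }
  ## dp[mask+1]: min cost of assigning the LAST popcount(mask) rows to the
  ## columns in mask. Filled in increasing popcount so row indices line up.
  dp <- rep(Inf, nmask)
  dp[1L] <- 0
  ord <- order(popcount[-1L])
  masks <- (seq_len(nmask - 1L))[ord]
  for (m in masks) {
    r <- n - popcount[m + 1L] + 1L  # row assigned at this level
    best <- Inf
    for (c in seq_len(n)) {
      bit <- bitwShiftL(1L, c - 1L)
      if (bitwAnd(m, bit) == 0L) next
      v <- C[r, c] + dp[bitwXor(m, bit) + 1L]
      if (v < best) best <- v
    }
    dp[m + 1L] <- best
  }
  ## Reconstruct from row 1 downward; first-index tie-break.
  p <- integer(n)
  mask <- nmask - 1L
  for (r in seq_len(n)) {
    best <- Inf
    pick <- 0L
    for (c in seq_len(n)) {
      bit <- bitwShiftL(1L, c - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      v <- C[r, c] + dp[bitwXor(mask, bit) + 1L]
      if (v < best - 1e-12) {
        best <- v
        pick <- c
      }
    }
    p[r] <- pick
    mask <- bitwXor(mask, bitwShiftL(1L, pick - 1L))
  }
  p <- p[seq_len(nr)]
  p[p > nc] <- NA_integer_
  p
}

## k-means++ style seeding: returns K rows of X chosen with the usual
## squared-distance weighting. Uses the current RNG state.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of points available for seeding")
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1L], ])^2)
    for (k in 2L:K) {
      prob <- d2
      if (all(prob <= 0)) prob <- rep(1, n)
      idx[k] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[k], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

## Nearest-centroid labels (Euclidean); ties go to the lowest centroid index.
nearest_centroid <- function(X, centers) {
  D <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-D, ties.method = "first")
}
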