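## Real solid-harmonic basis evaluation and probing-matrix construction.
##
## Convention used throughout the package: real regular solid harmonics
## R_l^m in Racah-style normalisation,
##   R_l^m = sqrt((2 - d_m0) (l-|m|)!/(l+|m|)!) * Pi_l^{|m|}(z, r^2) * A/B_|m|(x,y)
## with A_m = Re[(x+iy)^m], B_m = Im[(x+iy)^m].  These are homogeneous
## harmonic polynomials of degree l (so they scale as r^l and carry units
## m^l), and the low orders come out as {1; y, z, x; ...}.  Ordering of the
## basis: ascending order l, and within each order m = -l..+l, so index
## (1-based) of (l, m) is l^2 + l + m + 1.

#' Number of solid-harmonic basis functions up to a given order
#'
#' @param maxOrder highest harmonic order, a single nonnegative integer.
#' @return `(maxOrder + 1)^2`, e.g. 16 for a third-order expansion.
#' @examples
#' countBasis(3)  # 16
#' @export
countBasis <- function(maxOrder) {
  if (length(maxOrder) != 1L || !is.finite(maxOrder) || maxOrder < 0 ||
      maxOrder %% 1 != 0)
    invalidArgument("maxOrder must be a single nonnegative integer")
  n <- as.integer(maxOrder) + 1L
  n * n
}

#' Harmonic (l, m) index table
#'
#' The fixed basis ordering used by every function in the package: ascending
#' order l, and m = -l..+l within each order. Row 1 is (0, 0); rows 2-4 are
#' the three first-order terms (y, z, x under the package's convention).
#'
#' @param maxOrder highest harmonic order.
#' @return data.frame with columns `index`, `l`, `m`.
#' @examples
#' harmonicIndices(1)
#' @export
harmonicIndices <- function(maxOrder) {
  nb <- countBasis(maxOrder)
  l <- rep.int(0:maxOrder, 2L * (0:maxOrder) + 1L)
  m <- unlist(lapply(0:maxOrder, function(ll) seq(-ll, ll)), use.names = FALSE)
  data.frame(index = seq_len(nb), l = l, m = m)
}

#' Basis rows carrying the linear (first-order) gradient terms
#'
#' Under the package's harmonic convention the first-order basis functions
#' are y (m = -1), z (m = 0) and x (m = +1). This helper returns the 1-based
#' row indices of the x, y and z terms in that basis.
#'
#' @return named integer vector `c(x = 4, y = 2, z = 3)`.
#' @export
axisRows <- function() c(x = 4L, y = 2L, z = 3L)

## Evaluate one real solid harmonic at a set of points. Exact polynomial
## evaluation; well-behaved at the origin (all l > 0 terms vanish there).
.solidHarmonic <- function(x, y, z, l, m) {
  am <- abs(m)
  r2 <- x * x + y * y + z * z
  kmax <- (l - am) %/% 2
  pival <- 0
  for (kk in 0:kmax) {
    coef <- (-1)^kk * 2^(-l) * choose(l, kk) * choose(2 * (l - kk), l) *
      factorial(l - 2 * kk) / factorial(l - 2 * kk - am)
    zp <- if (l - 2 * kk - am == 0L) 1 else z^(l - 2 * kk - am)
    rp <- if (kk == 0L) 1 else r2^kk
    pival <- pival + coef * rp * zp
  }
  if (am == 0L) {
    ang <- 1
  } else {
    w <- complex(real = x, imaginary = y)^am
    ang <- if (m > 0) Re(w) else Im(w)
  }
  norm <- sqrt((2 - (m == 0)) * factorial(l - am) / factorial(l + am))
  norm * pival * ang
}

#' Evaluate the solid-harmonic probing matrix at probe positions
#'
#' Builds the Np x Nb matrix P of real solid-harmonic basis values at each
#' probe position, mapping k-coefficients (rad/m^l) to probe phase (rad).
#'
#' @param probes a [ProbeArray-class].
#' @param maxOrder highest harmonic order to evaluate.
#' @return A [ProbingMatrix-class]. Column 1 is all ones; columns 2-4 are the
#'   y, z and x coordinates.
#' @examples
#' pa <- ProbeArray(cbind(0.1, 0, 0))
#' probingValues(evaluateBasis(pa, 1))
#' @export
evaluateBasis <- function(probes, maxOrder) {
  if (!is(probes, "ProbeArray")) probes <- ProbeArray(probes)
  nb <- countBasis(maxOrder)
  if (nProbes(probes) < 1L)
    invalidArgument("probe set must not be empty")
  pos <- positions(probes)
  idx <- harmonicIndices(maxOrder)
  P <- matrix(0, nrow(pos), nb)
  for (j in seq_len(nb)) {
    P[, j] <- .solidHarmonic(pos[, 1], pos[, 2], pos[, 3], idx$l[j], idx$m[j])
  }
  colnames(P) <- sprintf("l%dm%+d", idx$l, idx$m)
  new("ProbingMatrix", values = P, maxOrder = as.integer(maxOrder),
      positionsHash = .positionsHash(pos))
}

## cheap deterministic provenance token for a position matrix
.positionsHash <- function(pos) {
  v <- c(dim(pos), round(as.numeric(pos), 12))
  sprintf("p%08x", sum(as.integer((abs(v) * 1e6) %% 2^20) *
                         (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Order-dependent diagonal weighting
#'
#' Diagonal of the order weighting matrix Gamma with entries base^l for each
#' basis function of order l. With the default base 0.1 this equalises the
#' scale of the orders over a 10-cm-radius volume (equivalently, converts
#' rad/m^l to rad/dm^l). With `protectLow = TRUE` the first four entries
#' (orders 0 and 1) are set to exactly 1, matching the identity block used
#' when building block-diagonal compression weights.
#'
#' @param maxOrder highest harmonic order.
#' @param base positive base of the weighting (default 0.1).
#' @param protectLow force the four order-0/1 entries to 1.
#' @return numeric vector of length (maxOrder+1)^2: the diagonal of Gamma.
#' @examples
#' orderWeights(2)              # 1, 0.1 x3, 0.01 x5
#' orderWeights(2, protectLow = TRUE)
#' @export
orderWeights <- function(maxOrder, base = 0.1, protectLow = FALSE) {
  if (length(base) != 1L || !is.finite(base) || base <= 0)
    invalidArgument("base must be a single positive number")
  l <- harmonicIndices(maxOrder)$l
  w <- base^l
  if (protectLow) w[seq_len(min(4L, length(w)))] <- 1
  w
}
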