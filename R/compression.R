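## Building the compression matrix from calibration k-coefficients and
## compressed fitting / decompression.

#' Build a basis-function compression model from calibration k-coefficients
#'
#' Takes the order-weighted high-order block (orders >= 2) of the calibration
#' k-coefficients, computes its economy singular value decomposition, and
#' retains the leading `L` left-singular vectors as the high-order
#' compression matrix. The zeroth- and first-order rows never enter the SVD;
#' they are carried by the 4 x 4 identity block of the full compression
#' matrix. A deterministic sign convention (largest-magnitude entry of each
#' singular vector positive) makes models reproducible.
#'
#' Multiple calibration scans can be combined by concatenating their
#' k-coefficients along time before calling this function (see
#' [bindKCoefficients()]).
#'
#' @param kCalib a [KCoefficients-class] from a calibration fit covering
#'   orders 0..maxOrder.
#' @param L number of singular vectors to retain, 1 <= L <= Nb - 4. If L
#'   exceeds the numerical rank of the weighted high-order block a warning is
#'   issued and L is clamped.
#' @param gammaBase base of the order weighting applied before the SVD
#'   (default 0.1).
#' @return A [CompressionModel-class].
#' @export
buildCompression <- function(kCalib, L, gammaBase = 0.1) {
  if (!is(kCalib, "KCoefficients"))
    invalidArgument("kCalib must be a KCoefficients")
  nb <- nrow(kCalib@k)
  nbh <- nb - 4L
  if (nbh < 1L)
    invalidArgument("calibration must cover at least order 2")
  if (length(L) != 1L || L < 1L || L %% 1 != 0)
    invalidArgument("L must be a single positive integer")
  if (L > nbh)
    invalidArgument(sprintf("L = %d exceeds the %d high-order basis functions",
                            L, nbh))
  nt <- ncol(kCalib@k)
  if (nt < nbh)
    warning(sprintf(
      "calibration has fewer samples (%d) than high-order basis functions (%d); model is rank-limited",
      nt, nbh))
  w <- orderWeights(kCalib@maxOrder, base = gammaBase)[-(1:4)]
  X <- w * kCalib@k[-(1:4), , drop = FALSE]
  sv <- svd(X)
  d <- sv$d
  rank <- sum(d > max(d[1], .Machine$double.eps) * max(dim(X)) *
                .Machine$double.eps)
  Luse <- as.integer(L)
  if (Luse > rank) {
    warning(sprintf("L = %d exceeds the numerical rank %d; clamping", Luse,
                    rank))
    Luse <- max(1L, rank)
  }
  U <- sv$u[, seq_len(Luse), drop = FALSE]
  ## deterministic sign: largest-magnitude entry of each vector positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  new("CompressionModel", maxOrder = kCalib@maxOrder, L = Luse,
      gammaBase = as.numeric(gammaBase), Chigh = U, singularValues = d)
}

#' Concatenate k-coefficient sets along time
#'
#' Utility for combining several calibration scans into one calibration set
#' before building a compression model. No per-scan renormalisation is
#' applied.
#'
#' @param ... [KCoefficients-class] objects with identical maxOrder.
#' @return A [KCoefficients-class] with columns concatenated; segment labels
#'   are prefixed scan1., scan2., ... to stay unique.
#' @export
bindKCoefficients <- function(...) {
  ks <- list(...)
  if (length(ks) == 1L && is.list(ks[[1]]) && !is(ks[[1]], "KCoefficients"))
    ks <- ks[[1]]
  mo <- unique(vapply(ks, function(k) k@maxOrder, integer(1)))
  if (length(mo) != 1L)
    invalidArgument("all k-coefficient sets must share maxOrder")
  kmat <- do.call(cbind, lapply(ks, function(k) k@k))
  tt <- numeric(0); seg <- character(0); off <- 0
  for (i in seq_along(ks)) {
    tt <- c(tt, ks[[i]]@time + off)
    off <- max(tt) + .medianStep(ks[[i]]@time)
    seg <- c(seg, paste0("scan", i, ".", ks[[i]]@segments))
  }
  KCoefficients(kmat, maxOrder = mo, time = tt, segments = seg)
}

## Full block-diagonal compression matrix C = blockdiag(I4, Chigh),
## Nb x (L + 4).
compressionC <- function(model) {
  nbh <- nrow(model@Chigh)
  C <- matrix(0, nbh + 4L, model@L + 4L)
  C[1:4, 1:4] <- diag(4)
  C[-(1:4), -(1:4)] <- model@Chigh
  C
}

## Diagonal of the block Gamma = blockdiag(I4, Gamma_high).
compressionGamma <- function(model) {
  orderWeights(model@maxOrder, base = model@gammaBase, protectLow = TRUE)
}

#' Compress k-coefficients
#'
#' Projects full harmonic k-coefficients into the compressed basis:
#' khat = C' Gamma k. Rows 1-4 of the result equal rows 1-4 of the input
#' (identity block); the remaining L rows are order-weighted projections
#' onto the retained singular vectors.
#'
#' @param k a [KCoefficients-class] with Nb rows matching `model`.
#' @param model a [CompressionModel-class].
#' @return (L + 4) x Nt numeric matrix of compressed coefficients.
#' @export
compressK <- function(k, model) {
  kmat <- if (is(k, "KCoefficients")) k@k else as.matrix(k)
  if (nrow(kmat) != nrow(model@Chigh) + 4L)
    invalidArgument("k row count does not match the compression model")
  gam <- compressionGamma(model)
  crossprod(compressionC(model), gam * kmat)
}

#' Decompress k-coefficients
#'
#' Inverse map k ~= Gamma^{-1} C khat; exact for coefficients lying in the
#' retained subspace, approximate otherwise (discarded singular vectors).
#'
#' @param kHat (L + 4) x Nt matrix of compressed coefficients.
#' @param model a [CompressionModel-class].
#' @param time,segments optional axes for the returned object.
#' @return A [KCoefficients-class] in the full solid-harmonic basis.
#' @export
decompressK <- function(kHat, model, time = NULL, segments = NULL) {
  kHat <- as.matrix(kHat)
  if (nrow(kHat) != model@L + 4L)
    invalidArgument("kHat row count does not match the compression model")
  gam <- compressionGamma(model)
  kmat <- (compressionC(model) %*% kHat) / gam
  KCoefficients(kmat, maxOrder = model@maxOrder, time = time,
                segments = segments)
}

#' Compressed probing matrix
#'
#' Phat = P Gamma^{-1} C: the probing matrix expressed on the compressed
#' basis functions. Its leading four columns equal those of P.
#'
#' @param P a [ProbingMatrix-class] built at the model's maxOrder.
#' @param model a [CompressionModel-class].
#' @return Np x (L + 4) numeric matrix.
#' @export
compressedProbing <- function(P, model) {
  if (!is(P, "ProbingMatrix")) invalidArgument("P must be a ProbingMatrix")
  if (P@maxOrder != model@maxOrder)
    invalidArgument(sprintf(
      "order mismatch: probing matrix order %d, model order %d",
      P@maxOrder, model@maxOrder))
  gam <- compressionGamma(model)
  (P@values / rep(gam, each = nrow(P@values))) %*% compressionC(model)
}

#' Weighted least-squares fit in the compressed basis
#'
#' Solves phi = Phat khat (with Phat the compressed probing matrix) by the
#' (weighted) pseudoinverse and returns both the compressed coefficients and
#' their decompressed solid-harmonic form for downstream use.
#'
#' @param phase a [PhaseData-class].
#' @param P a [ProbingMatrix-class] at the model's maxOrder.
#' @param model a [CompressionModel-class]; requires Np >= L + 4.
#' @param weights optional per-probe weights.
#' @return list with elements `kHat` ((L+4) x Nt matrix) and `k`
#'   ([KCoefficients-class], decompressed).
#' @export
fitCompressed <- function(phase, P, model, weights = NULL) {
  if (!is(phase, "PhaseData")) invalidArgument("phase must be a PhaseData")
  Phat <- compressedProbing(P, model)
  np <- nrow(Phat)
  if (np < ncol(Phat))
    illPosedFit(sprintf(
      "%d probes cannot determine %d compressed terms; with %d probes a maximum of %d higher order compressed basis functions is permitted",
      np, ncol(Phat), np, np - 4L))
  y <- phase@phi
  if (nrow(y) != np)
    invalidArgument("phase and probing matrix disagree on probe count")
  w <- .resolveWeights(weights, np)
  A <- Phat
  if (!is.null(w)) {
    A <- w * A
    y <- w * y
  }
  kHat <- .wlsSolve(A, y, what = "compressed probing matrix")
  k <- decompressK(kHat, model, time = phase@time, segments = phase@segments)
  list(kHat = kHat, k = k)
}
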