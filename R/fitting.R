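## Conventional (uncompressed) weighted least-squares k-coefficient fitting
## and the iterative concomitant-phase refit loop.

.CONDITION_LIMIT <- 1e10

#' Forward model: synthesize probe phase from k-coefficients
#'
#' Computes phi = P k exactly (no noise).
#'
#' @param P a [ProbingMatrix-class].
#' @param k a [KCoefficients-class] whose row count matches ncol(P).
#' @return A [PhaseData-class] with the time axis and segment labels of `k`.
#' @export
synthesizePhase <- function(P, k) {
  if (!is(P, "ProbingMatrix")) invalidArgument("P must be a ProbingMatrix")
  if (!is(k, "KCoefficients")) invalidArgument("k must be a KCoefficients")
  if (ncol(P@values) != nrow(k@k))
    invalidArgument(sprintf(
      "dimension mismatch: P has %d basis columns but k has %d rows",
      ncol(P@values), nrow(k@k)))
  PhaseData(P@values %*% k@k, time = k@time, segments = k@segments)
}

## Resolve a weights argument into a per-probe numeric vector or NULL.
.resolveWeights <- function(weights, np) {
  if (is.null(weights)) return(NULL)
  if (is(weights, "ProbeArray")) weights <- probeWeights(weights)
  if (is.null(weights)) return(NULL)
  w <- as.numeric(weights)
  if (length(w) != np || any(!is.finite(w)) || any(w <= 0))
    invalidArgument("weights must be strictly positive, one per probe")
  w
}

## Weighted least-squares solve of A k = y with condition-number guard.
## Returns the coefficient matrix; names the near-deficient columns on error.
.wlsSolve <- function(A, y, what = "probing matrix") {
  if (nrow(A) < ncol(A))
    illPosedFit(sprintf(
      "underdetermined fit: %d probes for %d basis functions", nrow(A), ncol(A)))
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  if (!is.finite(cond) || cond > .CONDITION_LIMIT) {
    null_dirs <- sv$v[, sv$d < sv$d[1] / .CONDITION_LIMIT, drop = FALSE]
    bad <- unique(unlist(apply(null_dirs, 2, function(v)
      which(abs(v) > 0.3 * max(abs(v))))))
    cols <- colnames(A)
    badnames <- if (is.null(cols)) paste(bad, collapse = ", ")
                else paste(cols[bad], collapse = ", ")
    illPosedFit(sprintf(
      "%s is rank-deficient (condition number %.3g); deficient columns: %s",
      what, cond, badnames))
  }
  k <- qr.coef(qr(A), y)
  dimnames(k) <- NULL
  k
}

#' Weighted least-squares k-coefficient fit
#'
#' Solves phi = P k in the (weighted) least-squares sense. With per-probe
#' weights w (diagonal of W) the solution is the weighted pseudoinverse
#' solution k = (P' W^2 P)^{-1} P' W^2 phi, computed stably by QR of W P.
#' Without weights this is the plain Moore-Penrose pseudoinverse solution.
#'
#' @param phase a [PhaseData-class].
#' @param P a [ProbingMatrix-class]; requires nrow >= ncol and full column
#'   rank (condition number below 1e10).
#' @param weights optional per-probe weights, or a [ProbeArray-class] whose
#'   weights are used.
#' @return A [KCoefficients-class].
#' @export
fitK <- function(phase, P, weights = NULL) {
  if (!is(phase, "PhaseData")) invalidArgument("phase must be a PhaseData")
  if (!is(P, "ProbingMatrix")) invalidArgument("P must be a ProbingMatrix")
  A <- P@values
  y <- phase@phi
  if (nrow(A) != nrow(y))
    invalidArgument("phase and probing matrix disagree on probe count")
  w <- .resolveWeights(weights, nrow(A))
  if (!is.null(w)) {
    A <- w * A
    y <- w * y
  }
  kmat <- .wlsSolve(A, y)
  KCoefficients(kmat, maxOrder = P@maxOrder, time = phase@time,
                segments = phase@segments)
}

#' Concomitant (Maxwell) field at probe positions
#'
#' Lowest-order concomitant field accompanying linear gradients on a
#' symmetric gradient system,
#' \deqn{B_c = \frac{1}{2 B_0}\left(G_x^2 z^2 + G_y^2 z^2 +
#'   G_z^2 \frac{x^2+y^2}{4} - G_x G_z x z - G_y G_z y z\right),}
#' integrated to phase per probe: phase = gamma * cumsum(B_c) * dt, with the
#' integral restarted at each segment boundary (each excitation).
#'
#' @param positions Np x 3 matrix of probe positions (m).
#' @param g 3 x Nt gradient waveform (T/m).
#' @param dt raster time (s).
#' @param B0 main field strength (T), > 0.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @param segments optional per-sample segment labels; integration restarts
#'   at each new segment.
#' @return Np x Nt matrix of concomitant phase (rad).
#' @export
concomitantPhase <- function(positions, g, dt, B0, gamma = GAMMA_1H,
                             segments = NULL) {
  if (B0 <= 0) invalidArgument("B0 must be positive")
  positions <- as.matrix(positions)
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  S <- cbind(z^2, z^2, (x^2 + y^2) / 4, -x * z, -y * z)  # Np x 5
  G <- rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2, g[1, ] * g[3, ], g[2, ] * g[3, ])
  Bc <- (S %*% G) / (2 * B0)                              # Np x Nt
  if (is.null(segments)) segments <- rep("s", ncol(Bc))
  out <- Bc
  for (s in unique(segments)) {
    j <- which(segments == s)
    out[, j] <- t(apply(Bc[, j, drop = FALSE], 1, cumsum))
  }
  gamma * out * dt
}

#' Iterative concomitant-phase k-coefficient refit
#'
#' Fits k-coefficients (conventionally, or compressed when a
#' [CompressionModel-class] is supplied), derives the gradient waveform from
#' the time-derivative of the three first-order rows, evaluates the
#' accumulated lowest-order concomitant phase at each probe, subtracts it
#' from the measured phase and refits. Repeats for `iterations` passes, with
#' early exit when max |delta k| / max |k| falls below `tol`.
#'
#' @param phase a [PhaseData-class].
#' @param P a [ProbingMatrix-class].
#' @param B0 main field strength in tesla (> 0).
#' @param iterations number of refit passes (default 2).
#' @param model optional [CompressionModel-class]; when given the fit is the
#'   compressed fit and the decompressed coefficients are returned.
#' @param weights optional per-probe weights.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @param tol relative convergence tolerance for early exit.
#' @return A [KCoefficients-class] (decompressed when `model` is supplied).
#' @export
concomitantRefit <- function(phase, P, B0, iterations = 2, model = NULL,
                             weights = NULL, gamma = GAMMA_1H, tol = 1e-6) {
  if (B0 <= 0) invalidArgument("B0 must be positive")
  if (iterations < 1) invalidArgument("iterations must be >= 1")
  doFit <- function(ph) {
    if (is.null(model)) fitK(ph, P, weights)
    else fitCompressed(ph, P, model, weights)$k
  }
  fit <- doFit(phase)
  dt <- .medianStep(phase@time)
  ax <- axisRows()
  pos <- NULL
  for (it in seq_len(iterations)) {
    kprev <- fit@k
    ## gradient estimate from the linear rows, per segment
    g <- matrix(0, 3, ncol(kprev))
    for (s in unique(phase@segments)) {
      j <- which(phase@segments == s)
      kl <- kprev[ax, j, drop = FALSE]
      g[, j] <- cbind(kl[, 1], t(diff(t(kl)))) / (dt * gamma)
    }
    if (is.null(pos)) pos <- .positionsFromP(P)
    phc <- concomitantPhase(pos, g, dt, B0, gamma, phase@segments)
    corrected <- PhaseData(phase@phi - phc, time = phase@time,
                           segments = phase@segments)
    fit <- doFit(corrected)
    rel <- max(abs(fit@k - kprev)) / max(abs(fit@k), 1e-300)
    if (rel < tol) break
  }
  fit
}

.medianStep <- function(tt) {
  d <- diff(tt)
  d <- d[d > 0]
  if (!length(d)) 1 else stats::median(d)
}

## Probe positions can be read back off the probing matrix: columns 2-4 are
## y, z, x under the package convention.
.positionsFromP <- function(P) {
  v <- P@values
  cbind(x = v[, 4], y = v[, 2], z = v[, 3])
}
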