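#' @import methods
NULL

#' Gyromagnetic ratio of the proton
#'
#' Gyromagnetic ratio of \eqn{^1}H in rad/s/T, the default conversion between
#' magnetic field and phase accrual rate for field probes doped with water.
#'
#' @export
GAMMA_1H <- 2.6752218744e8

## ---------------------------------------------------------------------------
## ProbeArray
## ---------------------------------------------------------------------------

#' Field-probe array
#'
#' Positions of NMR field probes in the scanner frame (origin at isocenter,
#' meters) with optional strictly positive per-probe weights used as the
#' diagonal of the fitting weight matrix W.
#'
#' @slot positions numeric matrix, Np x 3 (x, y, z in meters).
#' @slot weights numeric vector of length Np (or length 0 when unweighted).
#'
#' @export
setClass("ProbeArray",
  representation(positions = "matrix", weights = "numeric"),
  prototype(positions = matrix(numeric(0), 0, 3), weights = numeric(0))
)

setValidity("ProbeArray", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 3L)
    return("positions must be a numeric Np x 3 matrix")
  if (nrow(p) < 1L)
    return("at least one probe position is required")
  if (!all(is.finite(p)))
    return("probe positions must be finite")
  w <- object@weights
  if (length(w) > 0L) {
    if (length(w) != nrow(p))
      return("weights must have one entry per probe")
    if (!all(is.finite(w)) || any(w <= 0))
      return("probe weights must be finite and strictly positive")
  }
  TRUE
})

#' Construct a ProbeArray
#'
#' @param positions Np x 3 numeric matrix of probe coordinates in meters
#'   (scanner frame, origin at isocenter).
#' @param weights optional strictly positive per-probe weights (diagonal of W).
#' @return A [ProbeArray-class] object.
#' @examples
#' pa <- ProbeArray(cbind(c(0.1, -0.1), 0, c(0, 0.05)))
#' nProbes(pa)
#' @export
ProbeArray <- function(positions, weights = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  new("ProbeArray", positions = positions,
      weights = if (is.null(weights)) numeric(0) else as.numeric(weights))
}

## ---------------------------------------------------------------------------
## PhaseData
## ---------------------------------------------------------------------------

#' Probe phase time-series
#'
#' Accrued phase of each probe over time (radians), with the sample time axis
#' and per-sample segment labels identifying the volume (excitation) each
#' sample belongs to. Per-volume statistics and concomitant phase integration
#' are computed within segments.
#'
#' @slot phi numeric matrix, Np x Nt, radians.
#' @slot time numeric vector of Nt sample times in seconds, strictly
#'   increasing within each segment.
#' @slot segments character vector of Nt volume labels.
#'
#' @export
setClass("PhaseData",
  representation(phi = "matrix", time = "numeric", segments = "character")
)

setValidity("PhaseData", function(object) {
  if (nrow(object@phi) < 1L || ncol(object@phi) < 1L)
    return("phi must have at least one probe and one sample")
  if (!all(is.finite(object@phi)))
    return("phase values must be finite")
  if (length(object@time) != ncol(object@phi))
    return("time must have one entry per sample")
  if (length(object@segments) != ncol(object@phi))
    return("segments must have one entry per sample")
  for (s in unique(object@segments)) {
    ts <- object@time[object@segments == s]
    if (length(ts) > 1L && any(diff(ts) <= 0))
      return(sprintf("time must be strictly increasing within segment '%s'", s))
  }
  TRUE
})

#' Construct a PhaseData object
#'
#' @param phi Np x Nt numeric matrix of probe phases (radians).
#' @param time sample times in seconds (default: 0, 1, 2, ...).
#' @param segments per-sample volume labels (default: a single volume).
#' @return A [PhaseData-class] object.
#' @export
PhaseData <- function(phi, time = NULL, segments = NULL) {
  phi <- as.matrix(phi)
  nt <- ncol(phi)
  if (is.null(time)) time <- as.numeric(seq_len(nt) - 1L)
  if (is.null(segments)) segments <- rep("vol1", nt)
  new("PhaseData", phi = phi, time = as.numeric(time),
      segments = as.character(segments))
}

## ---------------------------------------------------------------------------
## KCoefficients
## ---------------------------------------------------------------------------

#' Harmonic expansion coefficients over time
#'
#' Time-courses of the coefficients of a real solid-harmonic expansion of
#' accrued phase ("k-coefficients"). Row i carries units rad/m^l where l is
#' the harmonic order of basis function i; the basis ordering is the one
#' returned by [harmonicIndices()].
#'
#' @slot k numeric matrix, Nb x Nt, row i in rad/m^{l_i}.
#' @slot maxOrder integer, highest harmonic order; Nb = (maxOrder + 1)^2.
#' @slot time numeric sample times (seconds).
#' @slot segments character per-sample volume labels.
#'
#' @export
setClass("KCoefficients",
  representation(k = "matrix", maxOrder = "integer", time = "numeric",
                 segments = "character")
)

setValidity("KCoefficients", function(object) {
  nb <- (object@maxOrder + 1L)^2
  if (nrow(object@k) != nb)
    return(sprintf("k must have (maxOrder+1)^2 = %d rows", nb))
  if (!all(is.finite(object@k)))
    return("k-coefficients must be finite")
  if (length(object@time) != ncol(object@k))
    return("time must have one entry per sample")
  if (length(object@segments) != ncol(object@k))
    return("segments must have one entry per sample")
  TRUE
})

#' Construct a KCoefficients object
#'
#' @param k Nb x Nt numeric matrix; Nb must be a perfect square
#'   (maxOrder + 1)^2.
#' @param maxOrder highest harmonic order (inferred from nrow(k) if missing).
#' @param time sample times in seconds.
#' @param segments per-sample volume labels.
#' @return A [KCoefficients-class] object.
#' @export
KCoefficients <- function(k, maxOrder = NULL, time = NULL, segments = NULL) {
  k <- as.matrix(k)
  if (is.null(maxOrder)) {
    mo <- sqrt(nrow(k)) - 1
    if (abs(mo - round(mo)) > 1e-9)
      stop("nrow(k) is not a perfect square; supply maxOrder explicitly")
    maxOrder <- as.integer(round(mo))
  }
  nt <- ncol(k)
  if (is.null(time)) time <- as.numeric(seq_len(nt) - 1L)
  if (is.null(segments)) segments <- rep("vol1", nt)
  new("KCoefficients", k = k, maxOrder = as.integer(maxOrder),
      time = as.numeric(time), segments = as.character(segments))
}

## ---------------------------------------------------------------------------
## ProbingMatrix
## ---------------------------------------------------------------------------

#' Probing matrix
#'
#' Real solid-harmonic basis function values evaluated at the probe
#' positions: an Np x Nb matrix mapping k-coefficients to probe phases,
#' phi = P k. Column 1 is the constant term; columns 2-4 are the three
#' first-order (linear) terms.
#'
#' @slot values numeric Np x Nb matrix.
#' @slot maxOrder integer, highest harmonic order represented.
#' @slot positionsHash character provenance token derived from the probe
#'   positions the matrix was evaluated at.
#'
#' @export
setClass("ProbingMatrix",
  representation(values = "matrix", maxOrder = "integer",
                 positionsHash = "character")
)

setValidity("ProbingMatrix", function(object) {
  if (ncol(object@values) != (object@maxOrder + 1L)^2)
    return("column count must equal (maxOrder+1)^2")
  if (!all(is.finite(object@values)))
    return("probing matrix entries must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## CompressionModel
## ---------------------------------------------------------------------------

#' Basis-function compression model
#'
#' Low-rank compression of high-order solid harmonics learned from
#' calibration k-coefficients. The high-order block \code{Chigh} holds the
#' leading L left-singular vectors of the order-weighted high-order
#' calibration coefficients; the full compression matrix C is block diagonal
#' with a 4 x 4 identity protecting the zeroth- and first-order terms.
#'
#' @slot maxOrder integer, harmonic order of the calibration fit.
#' @slot L integer, number of retained singular vectors.
#' @slot gammaBase numeric, base of the order weighting (default 0.1,
#'   equivalent to expressing row l in rad/dm^l).
#' @slot Chigh numeric (Nb-4) x L matrix with orthonormal columns.
#' @slot singularValues full non-increasing singular spectrum (diagnostics).
#'
#' @export
setClass("CompressionModel",
  representation(maxOrder = "integer", L = "integer", gammaBase = "numeric",
                 Chigh = "matrix", singularValues = "numeric")
)

setValidity("CompressionModel", function(object) {
  nbh <- (object@maxOrder + 1L)^2 - 4L
  if (object@L < 1L || object@L > nbh)
    return("L must lie in 1..(Nb-4)")
  if (nrow(object@Chigh) != nbh || ncol(object@Chigh) != object@L)
    return("Chigh must be (Nb-4) x L")
  ctc <- crossprod(object@Chigh)
  if (max(abs(ctc - diag(object@L))) > 1e-8)
    return("columns of Chigh must be orthonormal")
  sv <- object@singularValues
  if (any(sv < 0) || (length(sv) > 1L && any(diff(sv) > 1e-12)))
    return("singular values must be nonnegative and non-increasing")
  if (object@gammaBase <= 0)
    return("gammaBase must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## GradientWaveform
## ---------------------------------------------------------------------------

#' Gradient waveform
#'
#' A three-axis gradient waveform at a fixed raster time. For spin-echo
#' diffusion waveforms \code{refocus} records the time of the refocusing
#' pulse; the stored waveform is the physically played-out one (which drives
#' eddy currents), while [bValue()] reverses the effective gradient sign
#' after \code{refocus}.
#'
#' @slot g numeric 3 x Nt matrix of gradient amplitudes (T/m; rows x, y, z).
#' @slot dt raster time in seconds.
#' @slot kind label: spiral, epi, pgse, ogse, chirp or composite.
#' @slot gmax configured maximum gradient (T/m).
#' @slot smax configured maximum slew rate (T/m/s).
#' @slot refocus refocusing time in seconds (NA when not a spin echo).
#'
#' @export
setClass("GradientWaveform",
  representation(g = "matrix", dt = "numeric", kind = "character",
                 gmax = "numeric", smax = "numeric", refocus = "numeric")
)

setValidity("GradientWaveform", function(object) {
  if (nrow(object@g) != 3L)
    return("g must have three rows (x, y, z)")
  if (object@dt <= 0)
    return("raster time must be positive")
  tol <- 1.02  # small numeric headroom on the hardware limits
  if (max(abs(object@g)) > object@gmax * tol)
    return("gradient amplitude exceeds the configured maximum")
  slew <- abs(cbind(object@g[, 1], t(diff(t(object@g))))) / object@dt
  if (max(slew) > object@smax * tol)
    return("slew rate exceeds the configured maximum")
  TRUE
})

#' Construct a GradientWaveform
#'
#' @param g 3 x Nt matrix of gradients (T/m).
#' @param dt raster time (s).
#' @param kind waveform label.
#' @param gmax,smax hardware limits used for validity checking (defaults:
#'   0.08 T/m and 400 T/m/s, a high-performance head gradient).
#' @param refocus refocusing-pulse time (s) for spin-echo waveforms, else NA.
#' @return A [GradientWaveform-class] object.
#' @export
GradientWaveform <- function(g, dt, kind = "composite", gmax = 0.08,
                             smax = 400, refocus = NA_real_) {
  new("GradientWaveform", g = as.matrix(g), dt = as.numeric(dt),
      kind = as.character(kind), gmax = as.numeric(gmax),
      smax = as.numeric(smax), refocus = as.numeric(refocus))
}

## ---------------------------------------------------------------------------
## EddyGradientScene
## ---------------------------------------------------------------------------

#' Gradient scene with eddy-current responses
#'
#' Ground-truth generative model for one monitored volume: a gradient
#' waveform plus a set of linear time-invariant eddy-current modes. Each
#' mode couples the slew of one gradient axis to one harmonic basis function
#' through a single-exponential impulse response \eqn{A e^{-t/\tau}}.
#'
#' @slot waveform a [GradientWaveform-class].
#' @slot modes data.frame with columns \code{basis} (1-based basis row
#'   index, >= 2), \code{axis} ("x", "y" or "z"), \code{amplitude}
#'   ((T/m^l) per (T/m/s), i.e. field-coefficient per unit slew) and
#'   \code{tau} (seconds, > 0).
#' @slot gamma gyromagnetic ratio (rad/s/T).
#' @slot noiseSd phase noise standard deviation (radians).
#' @slot label volume label used as the segment identifier.
#'
#' @export
setClass("EddyGradientScene",
  representation(waveform = "GradientWaveform", modes = "data.frame",
                 gamma = "numeric", noiseSd = "numeric", label = "character")
)

setValidity("EddyGradientScene", function(object) {
  m <- object@modes
  need <- c("basis", "axis", "amplitude", "tau")
  if (nrow(m) > 0L) {
    if (!all(need %in% names(m)))
      return("modes needs columns basis, axis, amplitude, tau")
    if (any(m$tau <= 0)) return("eddy time constants must be positive")
    if (any(m$basis < 2L)) return("eddy modes apply to basis rows >= 2")
    if (!all(m$axis %in% c("x", "y", "z")))
      return("mode axis must be x, y or z")
    if (!all(is.finite(m$amplitude)))
      return("mode amplitudes must be finite")
  }
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (object@gamma <= 0) return("gamma must be positive")
  TRUE
})

#' Construct an EddyGradientScene
#'
#' @param waveform a [GradientWaveform-class].
#' @param modes data.frame of eddy modes (columns basis, axis, amplitude,
#'   tau); may have zero rows for an eddy-free scene.
#' @param gamma gyromagnetic ratio in rad/s/T.
#' @param noiseSd probe phase noise SD in radians (default 0.05).
#' @param label segment/volume label.
#' @return An [EddyGradientScene-class] object.
#' @export
eddyScene <- function(waveform, modes = emptyModes(), gamma = GAMMA_1H,
                      noiseSd = 0.05, label = "vol1") {
  new("EddyGradientScene", waveform = waveform, modes = as.data.frame(modes),
      gamma = as.numeric(gamma), noiseSd = as.numeric(noiseSd),
      label = as.character(label))
}

#' An empty eddy-mode table
#' @return zero-row data.frame with the mode columns.
#' @export
emptyModes <- function() {
  data.frame(basis = integer(0), axis = character(0),
             amplitude = numeric(0), tau = numeric(0))
}

## ---------------------------------------------------------------------------
## RMSEReport
## ---------------------------------------------------------------------------

#' Order-weighted RMSE report
#'
#' Per-volume order-weighted root-mean-square error between estimated and
#' ground-truth k-coefficients, with the mean and SD across volumes.
#'
#' @slot perVolume data.frame with columns \code{segment} and \code{rmse}.
#' @slot mean mean RMSE across volumes.
#' @slot sd standard deviation across volumes (NA for a single volume).
#' @slot nBasis number of leading basis functions evaluated.
#' @slot gammaBase base of the order weighting.
#'
#' @export
setClass("RMSEReport",
  representation(perVolume = "data.frame", mean = "numeric", sd = "numeric",
                 nBasis = "integer", gammaBase = "numeric")
)

setValidity("RMSEReport", function(object) {
  if (!all(c("segment", "rmse") %in% names(object@perVolume)))
    return("perVolume needs columns segment and rmse")
  if (any(object@perVolume$rmse < 0))
    return("rmse must be nonnegative")
  TRUE
})
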