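## Gradient waveform generators: spiral readout, EPI readout, PGSE and OGSE
## diffusion encodings, chirped calibration pulses. All waveforms respect
## configurable amplitude and slew limits (defaults 80 mT/m, 400 T/m/s).

## trapezoid lobe sampled at dt: ramp, flat, ramp; `delta` is the time from
## ramp-up start to ramp-down start (the usual diffusion delta convention)
.trapezoid <- function(G, delta, rampTime, dt) {
  nr <- max(1L, round(rampTime / dt))
  nf <- max(0L, round(delta / dt) - nr)
  c(seq_len(nr) / nr, rep(1, nf), rev(seq_len(nr) - 1L) / nr) * G
}

#' Numerical b-value of a diffusion waveform
#'
#' Computes b = integral of |q(t)|^2 dt with q(t) = gamma * integral of the
#' effective gradient. For spin-echo waveforms (refocus time set) the
#' effective gradient is sign-reversed after the refocusing pulse.
#'
#' @param waveform a [GradientWaveform-class].
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return b-value in s/mm^2.
#' @export
bValue <- function(waveform, gamma = GAMMA_1H) {
  g <- waveform@g
  dt <- waveform@dt
  if (!is.na(waveform@refocus)) {
    j <- which(seq_len(ncol(g)) * dt > waveform@refocus)
    g[, j] <- -g[, j]
  }
  q <- t(apply(g, 1, cumsum)) * dt * gamma   # rad/m
  sum(q^2) * dt * 1e-6                       # s/m^2 -> s/mm^2
}

## Build a PGSE/OGSE scalar lobe pair into a 3 x Nt waveform along `direction`
.lobesToWaveform <- function(lobe, direction, lead, gap, tail, dt, kind,
                             gmax, smax) {
  nz <- function(tsec) rep(0, max(0L, round(tsec / dt)))
  d <- c(nz(lead), lobe, nz(gap), lobe, nz(tail))
  refocus <- (length(nz(lead)) + length(lobe) + length(nz(gap)) / 2) * dt
  direction <- direction / sqrt(sum(direction^2))
  GradientWaveform(outer(direction, d), dt, kind = kind, gmax = gmax,
                   smax = smax, refocus = refocus)
}

#' Pulsed gradient spin echo (PGSE) diffusion waveform
#'
#' A matched pair of trapezoidal diffusion lobes about a refocusing gap,
#' scaled so the numerically computed b-value matches the request. The
#' stored waveform is the physically played-out one (both lobes positive);
#' [bValue()] accounts for the refocusing pulse.
#'
#' @param b target b-value in s/mm^2 (0 gives zero lobes).
#' @param smallDelta lobe duration delta (s), ramp-up start to ramp-down
#'   start.
#' @param bigDelta lobe separation Delta (s), onset to onset.
#' @param direction unit diffusion direction (length-3).
#' @param dt raster time (s).
#' @param gmax,smax hardware limits (T/m, T/m/s).
#' @param lead,tail zero padding before/after the lobes (s).
#' @return A [GradientWaveform-class] of kind "pgse".
#' @export
waveformPGSE <- function(b = 1000, smallDelta = 0.015, bigDelta = 0.020,
                         direction = c(1, 0, 0), dt = 1e-5, gmax = 0.08,
                         smax = 400, lead = 0.001, tail = 0.002) {
  if (b < 0) invalidArgument("b must be nonnegative")
  if (bigDelta < smallDelta)
    invalidArgument("bigDelta must be at least smallDelta")
  mk <- function(G) {
    rampTime <- max(dt, ceiling(G / (0.9 * smax) / dt) * dt)
    lobe <- .trapezoid(G, smallDelta, rampTime, dt)
    gap <- bigDelta - smallDelta - rampTime
    if (gap < 0) invalidArgument("lobes overlap: increase bigDelta")
    .lobesToWaveform(lobe, direction, lead, gap, tail, dt, "pgse", gmax, smax)
  }
  if (b == 0) {
    G0 <- gmax / 2  # shape only, then zero out
    wf <- mk(G0)
    wf@g[] <- 0
    return(wf)
  }
  ## analytic start, then fixed-point refinement on the numerical b-value
  G <- sqrt(b * 1e6 / (GAMMA_1H^2 * smallDelta^2 * (bigDelta - smallDelta / 3)))
  for (i in 1:6) {
    if (G > gmax)
      infeasibleWaveform(sprintf(
        "b = %g s/mm^2 needs %.1f mT/m > limit %.1f mT/m", b, G * 1e3,
        gmax * 1e3))
    wf <- mk(G)
    bnum <- bValue(wf)
    if (abs(bnum / b - 1) < 5e-3) return(wf)
    G <- G * sqrt(b / bnum)
  }
  wf
}

#' Oscillating gradient spin echo (OGSE) diffusion waveform
#'
#' Two apodised oscillating lobes at the requested frequency about a
#' refocusing gap, amplitude-scaled to the requested b-value. Edges of each
#' lobe are raised-cosine apodised over one quarter period so the waveform
#' starts and ends softly while keeping its spectral peak at `frequency`.
#'
#' @param b target b-value in s/mm^2.
#' @param frequency oscillation frequency in Hz.
#' @param cycles full oscillation cycles per lobe.
#' @param direction unit diffusion direction.
#' @param dt raster time (s).
#' @param gmax,smax hardware limits.
#' @param lead,gap,tail zero padding (s); `gap` separates the two lobes and
#'   defaults to the smallest value of at least 5 ms that keeps the lobe
#'   separation an integer number of oscillation periods (so the two lobes
#'   stay spectrally coherent at `frequency`).
#' @return A [GradientWaveform-class] of kind "ogse".
#' @export
waveformOGSE <- function(b = 400, frequency = 40, cycles = 2,
                         direction = c(1, 0, 0), dt = 1e-5, gmax = 0.08,
                         smax = 400, lead = 0.001, gap = NULL,
                         tail = 0.002) {
  if (frequency <= 0) invalidArgument("frequency must be positive")
  if (is.null(gap)) {
    lobeLen <- cycles / frequency
    gap <- ceiling(frequency * (lobeLen + 0.005)) / frequency - lobeLen
  }
  nlobe <- round(cycles / frequency / dt)
  tt <- (seq_len(nlobe) - 0.5) * dt
  env <- rep(1, nlobe)
  napo <- max(1L, round(1 / (4 * frequency) / dt))
  ramp <- 0.5 * (1 - cos(pi * seq_len(napo) / napo))
  env[seq_len(napo)] <- ramp
  env[nlobe + 1L - seq_len(napo)] <- ramp
  shape <- sin(2 * pi * frequency * tt) * env
  mk <- function(A)
    .lobesToWaveform(A * shape, direction, lead, gap, tail, dt, "ogse",
                     gmax, smax)
  if (b == 0) return(mk(0))
  A <- min(0.5 * gmax, 0.8 * smax / (2 * pi * frequency))
  for (i in 1:8) {
    wf <- mk(A)
    bnum <- bValue(wf)
    if (bnum <= 0) infeasibleWaveform("degenerate OGSE waveform")
    Anew <- A * sqrt(b / bnum)
    if (Anew > gmax || Anew * 2 * pi * frequency > smax)
      infeasibleWaveform(sprintf(
        "b = %g s/mm^2 at %g Hz violates the gradient limits", b, frequency))
    if (abs(bnum / b - 1) < 5e-3) return(wf)
    A <- Anew
  }
  wf
}

#' Slew-limited Archimedean spiral readout
#'
#' Numerically integrated constant-density spiral: the gradient magnitude
#' ramps at the available slew (accounting for rotational slew) up to the
#' amplitude limit while the trajectory follows k(theta) proportional to
#' theta * exp(i theta) out to the k-space radius set by the resolution.
#'
#' @param fov field of view (m).
#' @param resolution in-plane resolution (m).
#' @param undersampling in-plane undersampling factor (spacing between
#'   spiral turns in units of Nyquist spacing).
#' @param dt raster time (s).
#' @param gmax,smax hardware limits.
#' @param maxDuration readout cap in seconds; integration stops there.
#' @return A [GradientWaveform-class] of kind "spiral" (z row all zero).
#' @export
spiralReadout <- function(fov = 0.192, resolution = 0.0013,
                          undersampling = 2, dt = 1e-5, gmax = 0.08,
                          smax = 400, maxDuration = 0.08) {
  kmax <- 1 / (2 * resolution)                # cycles/m
  nturns <- kmax * fov / undersampling
  thetamax <- 2 * pi * nturns
  lambda <- kmax / thetamax
  gbar <- GAMMA_1H / (2 * pi)                 # Hz/T
  nmax <- round(maxDuration / dt)
  gx <- numeric(nmax); gy <- numeric(nmax)
  theta <- 0
  gmag <- 0.9 * smax * dt
  n <- 0L
  while (theta < thetamax && n < nmax) {
    n <- n + 1L
    om <- gbar * gmag / (lambda * sqrt(1 + theta^2))
    if (gmag * om > 0.9 * smax) {
      gmag <- 0.9 * smax / om
      om <- gbar * gmag / (lambda * sqrt(1 + theta^2))
    }
    gc <- (lambda * om / gbar) * complex(real = 1, imaginary = theta) *
      exp(1i * theta)
    gx[n] <- Re(gc); gy[n] <- Im(gc)
    theta <- theta + om * dt
    dg <- sqrt(max(0, (0.9 * smax)^2 - (gmag * om)^2))
    gmag <- min(gmax * 0.98, gmag + dg * dt)
  }
  g <- rbind(gx[seq_len(n)], gy[seq_len(n)], rep(0, n))
  GradientWaveform(g, dt, kind = "spiral", gmax = gmax, smax = smax)
}

#' EPI readout gradient train
#'
#' Alternating trapezoidal frequency-encode lobes on x with triangular
#' phase-encode blips on y.
#'
#' @param nLines number of readout lines.
#' @param gRead readout plateau amplitude (T/m).
#' @param flatTime plateau duration per line (s).
#' @param blipArea area of each phase blip (T/m * s).
#' @param dt raster time (s).
#' @param gmax,smax hardware limits.
#' @return A [GradientWaveform-class] of kind "epi".
#' @export
waveformEPI <- function(nLines = 32, gRead = 0.03, flatTime = 4e-4,
                        blipArea = 1.3e-7, dt = 1e-5, gmax = 0.08,
                        smax = 400) {
  if (gRead > gmax) infeasibleWaveform("gRead exceeds the gradient limit")
  nr <- max(2L, ceiling(gRead / (0.9 * smax) / dt))
  nf <- max(1L, round(flatTime / dt))
  ramp <- seq_len(nr) / nr
  lobe <- c(ramp, rep(1, nf), rev(ramp) - 1 / nr)
  nblip <- max(2L, 2L * ceiling(sqrt(blipArea / (0.9 * smax)) / dt))
  tri <- c(seq_len(nblip / 2), rev(seq_len(nblip / 2)))
  blip <- tri / sum(tri) * blipArea / dt
  if (max(blip) > gmax) infeasibleWaveform("blip exceeds the gradient limit")
  gx <- numeric(0); gy <- numeric(0)
  for (line in seq_len(nLines)) {
    s <- if (line %% 2 == 1) 1 else -1
    gx <- c(gx, s * gRead * lobe)
    gy <- c(gy, rep(0, length(lobe)))
    if (line < nLines) {
      gx <- c(gx, rep(0, nblip))
      gy <- c(gy, blip)
    }
  }
  GradientWaveform(rbind(gx, gy, rep(0, length(gx))), dt, kind = "epi",
                   gmax = gmax, smax = smax)
}

#' Chirped calibration gradient pulse
#'
#' Linear frequency sweep from `f0` to `f1` on one axis with raised-cosine
#' edge apodisation, as used for broadband characterisation of the gradient
#' chain's eddy-current response.
#'
#' @param f0,f1 sweep start and end frequencies (Hz).
#' @param duration sweep duration (s).
#' @param amplitude gradient amplitude (T/m).
#' @param axis "x", "y" or "z".
#' @param dt raster time (s).
#' @param gmax,smax hardware limits.
#' @return A [GradientWaveform-class] of kind "chirp".
#' @export
waveformChirp <- function(f0 = 10, f1 = 800, duration = 0.05,
                          amplitude = 0.02, axis = "x", dt = 1e-5,
                          gmax = 0.08, smax = 400) {
  if (amplitude > gmax) infeasibleWaveform("amplitude exceeds gradient limit")
  if (amplitude * 2 * pi * max(f0, f1) > smax)
    infeasibleWaveform("chirp sweep violates the slew limit")
  nt <- round(duration / dt)
  tt <- (seq_len(nt) - 0.5) * dt
  phase <- 2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * duration))
  env <- rep(1, nt)
  napo <- max(1L, round(0.05 * nt))
  ramp <- 0.5 * (1 - cos(pi * seq_len(napo) / napo))
  env[seq_len(napo)] <- ramp
  env[nt + 1L - seq_len(napo)] <- ramp
  d <- amplitude * sin(phase) * env
  g <- matrix(0, 3, nt)
  g[match(axis, c("x", "y", "z")), ] <- d
  GradientWaveform(g, dt, kind = "chirp", gmax = gmax, smax = smax)
}

#' Construct a gradient waveform by kind
#'
#' Thin dispatcher over the waveform generators.
#'
#' @param kind one of "spiral", "epi", "pgse", "ogse", "chirp".
#' @param params named list of arguments passed to the generator.
#' @return A [GradientWaveform-class].
#' @export
makeWaveform <- function(kind = c("spiral", "epi", "pgse", "ogse", "chirp"),
                         params = list()) {
  kind <- match.arg(kind)
  fun <- switch(kind, spiral = spiralReadout, epi = waveformEPI,
                pgse = waveformPGSE, ogse = waveformOGSE,
                chirp = waveformChirp)
  do.call(fun, params)
}

#' Concatenate gradient waveforms in time
#'
#' Appends waveforms at the shared raster time; the refocusing time of the
#' first spin-echo segment is kept.
#'
#' @param ... [GradientWaveform-class] objects with identical dt.
#' @return A [GradientWaveform-class] of kind "composite".
#' @export
appendWaveforms <- function(...) {
  ws <- list(...)
  dts <- unique(vapply(ws, function(w) w@dt, numeric(1)))
  if (length(dts) != 1L)
    invalidArgument("all waveforms must share the raster time")
  g <- do.call(cbind, lapply(ws, function(w) w@g))
  ref <- NA_real_
  off <- 0
  for (w in ws) {
    if (is.na(ref) && !is.na(w@refocus)) ref <- off + w@refocus
    off <- off + ncol(w@g) * w@dt
  }
  GradientWaveform(g, dts, kind = "composite",
                   gmax = max(vapply(ws, function(w) w@gmax, numeric(1))),
                   smax = max(vapply(ws, function(w) w@smax, numeric(1))),
                   refocus = ref)
}
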