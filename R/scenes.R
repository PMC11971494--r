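## Ground-truth field dynamics: eddy-current-driven k-coefficient
## simulation, default scenes, and noisy monitoring data generation.

#' Simulate ground-truth k-coefficients for a gradient scene
#'
#' The three first-order rows receive the nominal gradient phase
#' gamma * cumsum(g) * dt. Each eddy mode adds, on its basis row,
#' \deqn{k_b(t) = \gamma \int_0^t A\,(-\dot g_a \ast e^{-t'/\tau})\,dt',}
#' evaluated as a discrete convolution at the raster time (an O(Nt)
#' recursive filter). Modes on basis row 1 model B0 eddy currents.
#'
#' @param scene an [EddyGradientScene-class].
#' @param maxOrder harmonic order of the returned coefficient set.
#' @return A [KCoefficients-class] (single segment labelled as the scene).
#' @export
simulateKTrue <- function(scene, maxOrder) {
  wf <- scene@waveform
  g <- wf@g
  dt <- wf@dt
  nt <- ncol(g)
  nb <- countBasis(maxOrder)
  gamma <- scene@gamma
  k <- matrix(0, nb, nt)
  ax <- axisRows()
  for (a in 1:3) k[ax[a], ] <- gamma * cumsum(g[a, ]) * dt
  modes <- scene@modes
  if (nrow(modes) > 0L) {
    ## gradient increments = slew * dt, treated as an impulse train driving
    ## the exponential response; the response integral between samples is
    ## then exact (tau * (1 - alpha) per unit response), so a rectangular
    ## gradient step reproduces the analytic A * dg * tau * (1 - e^{-t/tau})
    ## to machine precision.
    dg <- t(apply(g, 1, function(row) c(row[1], diff(row))))
    alpha <- exp(-dt / modes$tau)
    for (m in seq_len(nrow(modes))) {
      b <- modes$basis[m]
      if (b > nb)
        invalidArgument(sprintf("mode basis index %d exceeds Nb = %d", b, nb))
      a <- match(modes$axis[m], c("x", "y", "z"))
      resp <- as.numeric(stats::filter(-dg[a, ], alpha[m],
                                       method = "recursive"))
      integ <- modes$tau[m] * (1 - alpha[m]) *
        c(0, cumsum(resp)[-length(resp)])
      k[b, ] <- k[b, ] + gamma * modes$amplitude[m] * integ
    }
  }
  tt <- (seq_len(nt) - 1L) * dt
  KCoefficients(k, maxOrder = maxOrder, time = tt,
                segments = rep(scene@label, nt))
}

#' Default eddy-current mode set
#'
#' Six spatial eddy modes spread over harmonic orders 2 to 5 with time
#' constants between 0.1 and 100 ms, the regime in which both short-lived
#' readout-driven and long-lived diffusion-lobe-driven perturbations are
#' present. The (l = 2, m = +-1) pair shares one amplitude and time
#' constant on the x/y axes, making that mode rotationally covariant about
#' z. Amplitudes are relative; [calibrateModeAmplitudes()] sets the
#' absolute scale.
#'
#' @return data.frame of modes (columns basis, axis, amplitude, tau).
#' @export
defaultEddyModes <- function() {
  idx <- function(l, m) l^2 + l + m + 1L
  data.frame(
    basis = c(idx(2, 1), idx(2, -1), idx(2, 0), idx(3, 0), idx(3, 2),
              idx(4, 1), idx(5, 0)),
    axis = c("x", "y", "z", "z", "y", "x", "z"),
    amplitude = c(1, 1, 0.8, 0.6, 0.5, 0.35, 0.25),
    tau = c(0.030, 0.030, 0.100, 0.008, 0.0006, 0.003, 0.0002)
  )
}

#' Scale eddy-mode amplitudes to a target high-order phase fraction
#'
#' Multiplies all mode amplitudes by a common factor so that, for the given
#' waveform, the RMS phase contributed by orders >= 2 at probes 0.14 m from
#' isocenter is the requested fraction of the RMS first-order phase.
#' Deterministic (12 fixed quasi-uniform evaluation directions).
#'
#' @param modes relative mode table.
#' @param waveform a [GradientWaveform-class] used as the reference drive.
#' @param maxOrder harmonic order for the evaluation.
#' @param targetFraction desired high/linear RMS phase ratio (default 0.07).
#' @param radius evaluation radius in meters (default 0.14).
#' @param gamma gyromagnetic ratio.
#' @return the mode table with scaled amplitudes.
#' @export
calibrateModeAmplitudes <- function(modes, waveform, maxOrder = 5,
                                    targetFraction = 0.07, radius = 0.14,
                                    gamma = GAMMA_1H) {
  i <- 1:12
  theta <- acos(1 - 2 * (i - 0.5) / 12)
  phi <- i * 137.50776 * pi / 180
  pts <- radius * cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                        cos(theta))
  P <- probingValues(evaluateBasis(ProbeArray(pts), maxOrder))
  sc <- eddyScene(waveform, modes, gamma = gamma, noiseSd = 0)
  k <- kMatrix(simulateKTrue(sc, maxOrder))
  lin <- P[, 2:4] %*% k[2:4, ]
  high <- P[, -(1:4), drop = FALSE] %*% k[-(1:4), , drop = FALSE]
  ratio <- sqrt(mean(high^2) / mean(lin^2))
  if (ratio <= 0) invalidArgument("modes contribute no high-order phase")
  modes$amplitude <- modes$amplitude * targetFraction / ratio
  modes
}

#' Build the scene list for a monitored diffusion scan
#'
#' A multi-direction diffusion "scan" is a list of scenes sharing the
#' readout waveform while the diffusion gradient rotates through a set of
#' uniformly distributed directions (electrostatic repulsion), preceded by
#' non-diffusion-weighted (b = 0) volumes. All scenes share the eddy-mode
#' set, whose absolute scale is calibrated on the first diffusion-weighted
#' waveform.
#'
#' Defaults mirror a high-resolution single-shot spiral DTI protocol on a
#' head gradient: 30 directions plus 2 b = 0 volumes, PGSE encoding at
#' b = 1000 s/mm^2 (OGSE: b = 400 s/mm^2 at 40 Hz).
#'
#' @param diffusion "pgse", "ogse" or "none".
#' @param nDirections number of diffusion directions.
#' @param nB0 number of b = 0 volumes.
#' @param readout "spiral", "epi" or "none".
#' @param b b-value in s/mm^2 (default 1000 for PGSE, 400 for OGSE).
#' @param frequency OGSE frequency in Hz.
#' @param dt raster time (s).
#' @param modes eddy-mode table (relative amplitudes); default
#'   [defaultEddyModes()].
#' @param targetFraction high-order phase fraction for amplitude
#'   calibration.
#' @param noiseSd probe phase noise SD (radians).
#' @param directionSeed seed for the direction set.
#' @param readoutParams,diffusionParams extra arguments for the waveform
#'   generators.
#' @param gamma gyromagnetic ratio.
#' @return list of [EddyGradientScene-class] objects labelled b0###/dwi###.
#' @export
makeScanScenes <- function(diffusion = c("pgse", "ogse", "none"),
                           nDirections = 30, nB0 = 2,
                           readout = c("spiral", "epi", "none"),
                           b = NULL, frequency = 40, dt = 1e-5,
                           modes = defaultEddyModes(),
                           targetFraction = 0.07, noiseSd = 0.05,
                           directionSeed = 1, readoutParams = list(),
                           diffusionParams = list(), gamma = GAMMA_1H) {
  diffusion <- match.arg(diffusion)
  readout <- match.arg(readout)
  if (is.null(b)) b <- if (diffusion == "ogse") 400 else 1000
  rd <- switch(readout,
    spiral = do.call(spiralReadout, c(list(dt = dt), readoutParams)),
    epi = do.call(waveformEPI, c(list(dt = dt), readoutParams)),
    none = NULL)
  mkdiff <- function(dir, bval) {
    switch(diffusion,
      pgse = do.call(waveformPGSE,
        c(list(b = bval, direction = dir, dt = dt), diffusionParams)),
      ogse = do.call(waveformOGSE,
        c(list(b = bval, frequency = frequency, direction = dir, dt = dt),
          diffusionParams)),
      none = NULL)
  }
  compose <- function(dwf) {
    parts <- Filter(Negate(is.null), list(dwf, rd))
    if (!length(parts))
      invalidArgument("scan needs a diffusion encoding or a readout")
    do.call(appendWaveforms, parts)
  }
  ## calibrate mode amplitudes on the first diffusion-weighted waveform
  refdir <- c(1, 0, 0)
  refwf <- compose(if (diffusion == "none") NULL else mkdiff(refdir, b))
  if (nrow(modes) > 0L && targetFraction > 0)
    modes <- calibrateModeAmplitudes(modes, refwf, maxOrder = 5,
                                     targetFraction = targetFraction,
                                     gamma = gamma)
  scenes <- list()
  for (i in seq_len(nB0)) {
    wf <- compose(if (diffusion == "none") NULL else mkdiff(refdir, 0))
    scenes[[length(scenes) + 1L]] <-
      eddyScene(wf, modes, gamma = gamma, noiseSd = noiseSd,
                label = sprintf("b0%03d", i))
  }
  if (diffusion != "none" && nDirections > 0) {
    dirs <- electrostaticDirections(nDirections, seed = directionSeed)
    for (i in seq_len(nDirections)) {
      wf <- compose(mkdiff(dirs[i, ], b))
      scenes[[length(scenes) + 1L]] <-
        eddyScene(wf, modes, gamma = gamma, noiseSd = noiseSd,
                  label = sprintf("dwi%03d", i))
    }
  }
  scenes
}

#' Generate noisy monitoring data for a set of scenes
#'
#' For each scene: simulates ground-truth k-coefficients, synthesizes probe
#' phase phi = P k_true (optionally adding the concomitant phase of the
#' scene's gradients), and adds iid Gaussian phase noise. Scenes are
#' concatenated along time with their labels as segments. Reproducible for
#' a fixed seed.
#'
#' @param scenes an [EddyGradientScene-class] or a list of them.
#' @param probes a [ProbeArray-class].
#' @param maxOrder harmonic order of the simulation and probing matrix.
#' @param seed integer seed (mandatory for reproducibility).
#' @param addConcomitant add the concomitant (Maxwell) phase of the scene
#'   gradients to the probe phase (default FALSE).
#' @param B0 main field strength (T), used when `addConcomitant` is TRUE.
#' @return list with `phase` ([PhaseData-class]), `kTrue`
#'   ([KCoefficients-class]) and `P` ([ProbingMatrix-class]).
#' @export
generateMonitoringData <- function(scenes, probes, maxOrder, seed,
                                   addConcomitant = FALSE, B0 = 7) {
  if (is(scenes, "EddyGradientScene")) scenes <- list(scenes)
  if (missing(seed)) invalidArgument("a seed is required")
  set.seed(as.integer(seed))
  P <- evaluateBasis(probes, maxOrder)
  pos <- positions(probes)
  phis <- list(); ks <- list(); times <- list(); segs <- list()
  toff <- 0
  for (sc in scenes) {
    ktrue <- simulateKTrue(sc, maxOrder)
    phi <- probingValues(P) %*% kMatrix(ktrue)
    if (addConcomitant) {
      wf <- sc@waveform
      phi <- phi + concomitantPhase(pos, wf@g, wf@dt, B0, sc@gamma)
    }
    if (sc@noiseSd > 0)
      phi <- phi + matrix(stats::rnorm(length(phi), sd = sc@noiseSd),
                          nrow(phi), ncol(phi))
    phis[[length(phis) + 1L]] <- phi
    ks[[length(ks) + 1L]] <- kMatrix(ktrue)
    times[[length(times) + 1L]] <- sampleTimes(ktrue) + toff
    toff <- max(times[[length(times)]]) + sc@waveform@dt
    segs[[length(segs) + 1L]] <- segmentLabels(ktrue)
  }
  tt <- unlist(times)
  sg <- unlist(segs)
  list(
    phase = PhaseData(do.call(cbind, phis), time = tt, segments = sg),
    kTrue = KCoefficients(do.call(cbind, ks), maxOrder = maxOrder,
                          time = tt, segments = sg),
    P = P
  )
}
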