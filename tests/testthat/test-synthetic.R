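test_that("PGSE waveforms hit the requested b-value within hardware limits", {
  wf0 <- waveformPGSE(b = 0, dt = 2e-5)
  expect_equal(max(abs(gradientMatrix(wf0))), 0)

  wf <- waveformPGSE(b = 1000, dt = 1e-5)
  expect_lt(abs(bValue(wf) / 1000 - 1), 0.01)
  expect_lte(max(abs(gradientMatrix(wf))), 0.08)

  # an impossible b-value under the limits is refused
  expect_error(waveformPGSE(b = 40000, smallDelta = 0.01, bigDelta = 0.015),
               class = "fcInfeasibleWaveform")
})

test_that("OGSE waveforms oscillate at the requested frequency", {
  og <- waveformOGSE(b = 400, frequency = 40, dt = 1e-5)
  expect_lt(abs(bValue(og) / 400 - 1), 0.01)
  d <- gradientMatrix(og)[1, ]
  n <- 2^18
  amp <- Mod(stats::fft(c(d, rep(0, n - length(d)))))[seq_len(n / 2)]
  freq <- (seq_len(n / 2) - 1) / (n * 1e-5)
  peak <- freq[which.max(amp[-1]) + 1]
  expect_lt(abs(peak - 40), 1)
})

test_that("generated waveforms respect amplitude and slew limits", {
  for (wf in list(spiralReadout(resolution = 0.0026, dt = 1e-5),
                  waveformEPI(dt = 1e-5),
                  waveformChirp(dt = 1e-5))) {
    g <- gradientMatrix(wf)
    dt <- rasterTime(wf)
    expect_lte(max(abs(g)), wf@gmax * 1.02)
    slew <- abs(cbind(g[, 1], t(diff(t(g))))) / dt
    expect_lte(max(slew), wf@smax * 1.02)
  }
})

test_that("eddy simulation matches the closed-form step response", {
  # single-exponential response to a rectangular gradient step:
  # k_b(t) = -gamma A dg tau (1 - exp(-t/tau)) after the step
  g <- matrix(0, 3, 400); g[1, 51:400] <- 0.02
  wf <- GradientWaveform(g, 1e-5, smax = 4000)
  sc <- eddyScene(wf, data.frame(basis = 5L, axis = "x", amplitude = 1e-4,
                                 tau = 0.001), noiseSd = 0)
  k5 <- kMatrix(simulateKTrue(sc, 2))[5, ]
  tt <- (0:349) * 1e-5
  closed <- -GAMMA_1H * 1e-4 * 0.02 * 0.001 * (1 - exp(-tt / 0.001))
  expect_lt(max(abs(k5[51:400] - closed)) / max(abs(closed)), 1e-6)

  # zero amplitudes: high-order rows identically zero, linear rows = gamma int g
  sc0 <- eddyScene(wf, emptyModes(), noiseSd = 0)
  k0 <- kMatrix(simulateKTrue(sc0, 2))
  expect_equal(k0[-(2:4), ], matrix(0, 6, 400))
  expect_equal(k0[axisRows()["x"], ], GAMMA_1H * cumsum(g[1, ]) * 1e-5)

  # two modes on one basis row superpose linearly
  m1 <- data.frame(basis = 5L, axis = "x", amplitude = 1e-4, tau = 0.001)
  m2 <- data.frame(basis = 5L, axis = "x", amplitude = 3e-5, tau = 0.01)
  kk <- function(mm) kMatrix(simulateKTrue(eddyScene(wf, mm, noiseSd = 0), 2))
  expect_equal(kk(rbind(m1, m2)), kk(m1) + kk(m2) - k0, tolerance = 1e-12)
})

test_that("calibration probe arrays follow the multi-position geometry", {
  # single orientation and no filtering reproduces the base array
  lay1 <- probeLayout(nZShifts = 1, nRotations = 1, rMax = Inf, axisMax = Inf)
  arr1 <- buildProbeArray(lay1)
  expect_equal(positions(arr1$calibration), positions(arr1$single),
               ignore_attr = TRUE)

  # 9 orientations x 16 probes = 144 candidates before filtering
  layAll <- probeLayout(rMax = Inf, axisMax = Inf)
  expect_equal(nProbes(buildProbeArray(layAll)$calibration), 144L)

  # the distance filters match a brute-force evaluation of both rules
  lay <- probeLayout()
  arr <- buildProbeArray(lay)
  all144 <- positions(buildProbeArray(layAll)$calibration)
  keep <- sqrt(rowSums(all144^2)) <= lay$rMax &
    abs(all144[, 1]) <= lay$axisMax & abs(all144[, 2]) <= lay$axisMax &
    abs(all144[, 3]) <= lay$axisMax
  expect_equal(nProbes(arr$calibration), sum(keep))
  expect_equal(positions(arr$calibration), all144[keep, ], ignore_attr = TRUE)

  # base probes sit at the documented distances from isocenter
  r <- sqrt(rowSums(positions(arr$single)^2))
  expect_equal(mean(r), 0.135, tolerance = 0.01)
  expect_gte(min(r), 0.119); expect_lte(max(r), 0.149 + 1e-12)

  expect_error(buildProbeArray(probeLayout(rMax = 1e-4)),
               class = "fcInvalidArgument")
})

test_that("monitoring data are reproducible and noise behaves as least squares predicts", {
  pa <- randomProbes(30, seed = 50)
  g <- matrix(0, 3, 60); g[1, 11:30] <- 0.01
  sc <- eddyScene(GradientWaveform(g, 1e-4, smax = 4000), noiseSd = 0.05)
  d1 <- generateMonitoringData(sc, pa, 2, seed = 99)
  d2 <- generateMonitoringData(sc, pa, 2, seed = 99)
  expect_identical(phaseMatrix(d1$phase), phaseMatrix(d2$phase))
  d3 <- generateMonitoringData(sc, pa, 2, seed = 100)
  expect_false(identical(phaseMatrix(d1$phase), phaseMatrix(d3$phase)))

  # noiseless data refit exactly
  sc0 <- eddyScene(GradientWaveform(g, 1e-4, smax = 4000), noiseSd = 0)
  d0 <- generateMonitoringData(sc0, pa, 2, seed = 1)
  fit <- fitK(d0$phase, d0$P)
  expect_lt(max(abs(kMatrix(fit) - kMatrix(d0$kTrue))) /
              max(max(abs(kMatrix(d0$kTrue))), 1), 1e-8)

  # residual mean square ~= sigma^2 (Np - Nb) / Np across 50 seeds
  np <- 30; nb <- 9
  ms <- vapply(1:50, function(s) {
    d <- generateMonitoringData(sc, pa, 2, seed = s)
    r <- phaseMatrix(d$phase) -
      probingValues(d$P) %*% kMatrix(fitK(d$phase, d$P))
    mean(r^2)
  }, numeric(1))
  expect_lt(abs(mean(ms) / (0.05^2 * (np - nb) / np) - 1), 0.1)
})

test_that("diffusion direction sets are uniform by the repulsion criterion", {
  d <- electrostaticDirections(12, seed = 2)
  expect_equal(rowSums(d^2), rep(1, 12), tolerance = 1e-12)
  best <- min(vapply(1:100, function(s) {
    set.seed(s + 1000)
    p <- matrix(rnorm(36), 12, 3)
    repulsionEnergy(p / sqrt(rowSums(p^2)))
  }, numeric(1)))
  expect_lt(repulsionEnergy(d), 1.05 * best)
})

test_that("simulated phase is invariant under rigid z-rotation of a covariant scene", {
  # the (l = 2, m = +-1) x/y mode pair transforms into itself under
  # rotations about z, so rotating probes and gradients together leaves
  # every probe's phase unchanged
  idx <- function(l, m) l^2 + l + m + 1L
  modes <- data.frame(basis = c(idx(2, 1), idx(2, -1)), axis = c("x", "y"),
                      amplitude = c(2e-4, 2e-4), tau = c(0.002, 0.002))
  g <- matrix(0, 3, 80)
  g[1, 11:40] <- 0.015; g[2, 21:60] <- -0.01
  a <- 0.7
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  pa <- randomProbes(10, seed = 60)
  phi <- function(gg, probes) {
    sc <- eddyScene(GradientWaveform(gg, 1e-4, smax = 4000), modes,
                    noiseSd = 0)
    phaseMatrix(generateMonitoringData(sc, probes, 2, seed = 1)$phase)
  }
  p0 <- phi(g, pa)
  pR <- phi(R %*% g, ProbeArray(positions(pa) %*% t(R)))
  expect_equal(pR, p0, tolerance = 1e-9)
})

test_that("scan scenes share the readout and calibrated eddy amplitudes", {
  scenes <- testScanScenes(nDirections = 3, nB0 = 1)
  expect_length(scenes, 4L)
  expect_equal(unique(vapply(scenes, function(s) s@label, character(1))),
               c("b0001", "dwi001", "dwi002", "dwi003"))
  # every scene carries the same calibrated mode table
  amps <- vapply(scenes, function(s) s@modes$amplitude[1], numeric(1))
  expect_equal(diff(range(amps)), 0)
  # high-order phase fraction at r = 0.14 lands near the 7 % design target
  sc <- scenes[[2]]
  pts <- 0.14 * electrostaticDirections(10, seed = 3)
  P <- probingValues(evaluateBasis(ProbeArray(pts), 5))
  k <- kMatrix(simulateKTrue(sc, 5))
  ratio <- sqrt(mean((P[, -(1:4)] %*% k[-(1:4), ])^2) /
                  mean((P[, 2:4] %*% k[2:4, ])^2))
  expect_gt(ratio, 0.03); expect_lt(ratio, 0.15)
})
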