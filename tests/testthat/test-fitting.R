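test_that("forward model is exact and shape-checked", {
  pa <- randomProbes(10, seed = 2)
  P <- evaluateBasis(pa, 2)
  kz <- KCoefficients(matrix(0, 9, 5))
  expect_equal(phaseMatrix(synthesizePhase(P, kz)), matrix(0, 10, 5))

  # constant basis: only row 1 nonzero -> every probe sees c(t)
  kc <- matrix(0, 9, 5); kc[1, ] <- sin(1:5)
  ph <- synthesizePhase(P, KCoefficients(kc))
  for (i in 1:10) expect_equal(phaseMatrix(ph)[i, ], sin(1:5))

  expect_error(synthesizePhase(P, randomK(3, 5)), class = "fcInvalidArgument")
})

test_that("noiseless overdetermined fit recovers k exactly", {
  pa <- randomProbes(countBasis(3) + 4, seed = 3)
  P <- evaluateBasis(pa, 3)
  k <- randomK(3, 30, seed = 8)
  fit <- fitK(synthesizePhase(P, k), P)
  expect_lt(max(abs(kMatrix(fit) - kMatrix(k))) / max(abs(kMatrix(k))), 1e-10)
})

test_that("weighted fit matches the explicit normal-equations solve", {
  pa <- randomProbes(30, seed = 6, weights = TRUE)
  P <- evaluateBasis(pa, 3)
  k <- randomK(3, 40, seed = 9)
  set.seed(10)
  phi <- phaseMatrix(synthesizePhase(P, k)) + matrix(rnorm(30 * 40, sd = 0.3), 30, 40)
  phase <- PhaseData(phi)
  w <- probeWeights(pa)

  fw <- fitK(phase, P, weights = w)
  A <- probingValues(P)
  kne <- solve(t(A) %*% diag(w^2) %*% A, t(A) %*% diag(w^2) %*% phi)
  expect_lt(max(abs(kMatrix(fw) - kne)) / max(abs(kne)), 1e-8)

  # unit weights coincide with the unweighted pseudoinverse solution
  f1 <- fitK(phase, P, weights = rep(1, 30))
  f0 <- fitK(phase, P)
  expect_equal(kMatrix(f1), kMatrix(f0), tolerance = 1e-12)
})

test_that("the fit is linear in phase and leaves W-orthogonal residuals", {
  pa <- randomProbes(25, seed = 12, weights = TRUE)
  P <- evaluateBasis(pa, 2)
  set.seed(13)
  phi1 <- matrix(rnorm(25 * 20), 25, 20)
  phi2 <- matrix(rnorm(25 * 20), 25, 20)
  w <- probeWeights(pa)
  f <- function(phi) kMatrix(fitK(PhaseData(phi), P, weights = w))
  expect_equal(f(2 * phi1 - 3 * phi2), 2 * f(phi1) - 3 * f(phi2),
               tolerance = 1e-9)

  resid <- w * (phi1 - probingValues(P) %*% f(phi1))
  proj <- crossprod(w * probingValues(P), resid)
  expect_lt(max(abs(proj)) / max(abs(phi1)), 1e-8)
})

test_that("fitting below the data's true order projects error into low orders", {
  # probes far from isocenter, data with order-4 content
  set.seed(14)
  pa <- ProbeArray(matrix(rnorm(3 * 40, sd = 0.13), 40, 3))
  P4 <- evaluateBasis(pa, 4)
  k4 <- randomK(4, 25, seed = 15)
  phase <- synthesizePhase(P4, k4)
  fitLow <- fitK(phase, evaluateBasis(pa, 2))
  fitFull <- fitK(phase, P4)
  errLow <- mean(kRMSE(fitLow, k4, nBasis = 9))
  errFull <- mean(kRMSE(fitFull, k4, nBasis = 9))
  expect_gt(errLow, errFull)
  expect_gt(errLow, 1e-6)
})

test_that("ill-posed fits fail loudly, naming the deficient columns", {
  # all probes in the z = 0 plane: every z-bearing column degenerates
  set.seed(16)
  pos <- cbind(rnorm(20, sd = 0.1), rnorm(20, sd = 0.1), 0)
  P <- evaluateBasis(ProbeArray(pos), 2)
  phase <- PhaseData(matrix(rnorm(20 * 6), 20, 6))
  expect_error(fitK(phase, P), class = "fcIllPosedFit")
  expect_error(fitK(phase, P), "l1m\\+0")

  # underdetermined
  pa <- randomProbes(8, seed = 17)
  expect_error(fitK(PhaseData(matrix(0, 8, 3)), evaluateBasis(pa, 2)),
               class = "fcIllPosedFit")
})

test_that("concomitant refit reduces to the plain fit when it should", {
  pa <- buildProbeArray()$single
  P <- evaluateBasis(pa, 2)
  # zero gradients: nothing to correct
  k <- KCoefficients(matrix(0, 9, 12)); kmat <- kMatrix(k)
  kmat[1, ] <- 0.2; k <- KCoefficients(kmat)
  phase <- synthesizePhase(P, k)
  kref <- concomitantRefit(phase, P, B0 = 7, iterations = 2)
  expect_equal(kMatrix(kref), kMatrix(fitK(phase, P)), tolerance = 1e-12)

  # 1/B0 scaling: the huge-B0 limit converges to the plain fit
  wf <- waveformPGSE(b = 1000, direction = c(0.6, 0.5, 0.62), dt = 2e-5)
  dat <- generateMonitoringData(eddyScene(wf, noiseSd = 0), pa, 3, seed = 1)
  k0 <- fitK(dat$phase, dat$P)
  kinf <- concomitantRefit(dat$phase, dat$P, B0 = 1e12, iterations = 2)
  expect_lt(max(abs(kMatrix(kinf) - kMatrix(k0))) / max(abs(kMatrix(k0))),
            1e-12)
  expect_error(concomitantRefit(dat$phase, dat$P, B0 = 0),
               class = "fcInvalidArgument")
})

test_that("two concomitant iterations strip analytically added Maxwell phase", {
  pa <- buildProbeArray()$single
  wf <- waveformPGSE(b = 1000, direction = c(0.6, 0.5, 0.62), dt = 2e-5)
  sc <- eddyScene(wf, noiseSd = 0)
  dat <- generateMonitoringData(sc, pa, 3, seed = 1, addConcomitant = TRUE,
                                B0 = 7)
  errPlain <- mean(kRMSE(fitK(dat$phase, dat$P), dat$kTrue, nBasis = 4))
  kref <- concomitantRefit(dat$phase, dat$P, B0 = 7, iterations = 2)
  errRefit <- mean(kRMSE(kref, dat$kTrue, nBasis = 4))
  expect_lt(errRefit, errPlain / 10)
})
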