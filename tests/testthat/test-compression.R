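# helpers used across the compression tests
fullC <- function(m) fieldcompress:::compressionC(m)
fullGamma <- function(m) fieldcompress:::compressionGamma(m)

test_that("rank-1 calibration yields one singular value aligned with the mode", {
  set.seed(20)
  mode <- rnorm(12)                    # spatial mode over the 12 high rows
  tc <- sin(seq(0, 6, length.out = 40))  # shared time-course
  kmat <- rbind(matrix(rnorm(4 * 40), 4, 40), outer(mode, tc))
  kc <- KCoefficients(kmat, maxOrder = 3)
  m <- buildCompression(kc, L = 1)
  sv <- singularValues(m)
  expect_gt(sv[1], 0)
  expect_lt(sv[2] / sv[1], 1e-12)
  gmode <- orderWeights(3)[-(1:4)] * mode
  gmode <- gmode / sqrt(sum(gmode^2))
  expect_lt(min(max(abs(m@Chigh[, 1] - gmode)),
                max(abs(m@Chigh[, 1] + gmode))), 1e-10)
})

test_that("unit gamma base reduces to the plain SVD of the high-order block", {
  kc <- randomK(3, 50, seed = 21)
  m <- buildCompression(kc, L = 4, gammaBase = 1)
  sv <- svd(kMatrix(kc)[-(1:4), ])
  U <- sv$u[, 1:4]
  for (j in 1:4) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  expect_equal(m@Chigh, U, tolerance = 1e-10)
  expect_equal(singularValues(m), sv$d, tolerance = 1e-10)
})

test_that("rank is bounded by min(Nb-4, Nt) and short calibrations warn", {
  expect_warning(m <- buildCompression(randomK(3, 6, seed = 22), L = 2),
                 "rank-limited")
  expect_lte(sum(singularValues(m) > 1e-10 * singularValues(m)[1]), 6L)
  expect_error(buildCompression(randomK(3, 30), L = 13),
               class = "fcInvalidArgument")
  expect_warning(
    mclamp <- buildCompression(
      KCoefficients(rbind(matrix(rnorm(4 * 30), 4, 30),
                          outer(rnorm(12), rnorm(30))), maxOrder = 3),
      L = 5),
    "rank")
  expect_lte(retainedRank(mclamp), 2L)
})

test_that("compression identities: CtC = I, projector idempotent, round trips", {
  for (seed in 23:25) {
    kc <- randomK(3, 40, seed = seed)
    L <- c(3, 7, 12)[seed - 22]
    m <- buildCompression(kc, L = L)
    C <- fullC(m)
    expect_lt(max(abs(crossprod(C) - diag(L + 4L))), 1e-10)
    gam <- fullGamma(m)
    proj <- (C %*% t(C) * rep(gam, each = 16)) / gam
    expect_lt(max(abs(proj %*% proj - proj)), 1e-8)
    sv <- singularValues(m)
    expect_true(all(diff(sv) <= 1e-12))
    expect_true(all(diff(cumsum(sv^2) / sum(sv^2)) >= -1e-15))
  }

  kc <- randomK(3, 40, seed = 26)
  k <- randomK(3, 15, seed = 27)
  # zero high block compresses to [k_low; 0]
  klow <- kMatrix(k); klow[-(1:4), ] <- 0
  mh <- buildCompression(kc, L = 5)
  kh <- compressK(KCoefficients(klow, maxOrder = 3), mh)
  expect_equal(kh[1:4, ], klow[1:4, ])
  expect_equal(kh[-(1:4), ], matrix(0, 5, 15))

  # full-rank round trip is exact for arbitrary k
  mfull <- buildCompression(kc, L = 12)
  expect_lt(max(abs(kMatrix(decompressK(compressK(k, mfull), mfull)) -
                      kMatrix(k))), 1e-10)

  # truncated round trip equals the Gamma-metric projector applied to k
  C5 <- fullC(mh); gam <- fullGamma(mh)
  proj <- (C5 %*% t(C5) * rep(gam, each = 16)) / gam
  expect_equal(kMatrix(decompressK(compressK(k, mh), mh)), proj %*% kMatrix(k),
               tolerance = 1e-10)

  # decompression basics
  expect_equal(kMatrix(decompressK(matrix(0, 9, 7), mh)), matrix(0, 16, 7))
  e6 <- matrix(0, 9, 1); e6[6, 1] <- 1
  expect_equal(as.numeric(kMatrix(decompressK(e6, mh))), C5[, 6] / gam)
  set.seed(28)
  khr <- matrix(rnorm(9 * 11), 9, 11)
  expect_lt(max(abs(compressK(decompressK(khr, mh), mh) - khr)), 1e-10)
})

test_that("compressed probing matrix is P Gamma^-1 C with protected low orders", {
  kc <- randomK(3, 40, seed = 29)
  m <- buildCompression(kc, L = 6)
  pa <- randomProbes(14, seed = 30)
  P <- evaluateBasis(pa, 3)
  Phat <- compressedProbing(P, m)
  expect_equal(Phat[, 1:4], probingValues(P)[, 1:4], ignore_attr = TRUE)

  # hand triple product on a 3-probe toy
  pa3 <- ProbeArray(rbind(c(0.05, 0, 0.02), c(0, -0.06, 0.01), c(0.03, 0.04, -0.05)))
  P3 <- evaluateBasis(pa3, 3)
  hand <- probingValues(P3) %*% diag(1 / fullGamma(m)) %*% fullC(m)
  expect_equal(compressedProbing(P3, m), hand, tolerance = 1e-12)

  # a probe at the origin sees only the constant term, whatever C is
  Porig <- evaluateBasis(ProbeArray(cbind(0, 0, 0)), 3)
  expect_equal(as.numeric(compressedProbing(Porig, m)),
               c(1, rep(0, 9)))

  expect_error(compressedProbing(evaluateBasis(pa, 2), m),
               class = "fcInvalidArgument")
})

test_that("compressed fit: subspace recovery, full-rank equivalence, probe bound", {
  kc <- randomK(3, 40, seed = 31)
  m5 <- buildCompression(kc, L = 5)
  # ground truth inside the retained subspace, Np = L + 8
  kin <- decompressK(matrix(rnorm(9 * 20), 9, 20), m5)
  pa <- randomProbes(13, seed = 32)
  P <- evaluateBasis(pa, 3)
  fit <- fitCompressed(synthesizePhase(P, kin), P, m5)
  expect_lt(max(abs(kMatrix(fit$k) - kMatrix(kin))) / max(abs(kMatrix(kin))),
            1e-8)

  # keeping every singular vector reproduces the conventional fit
  mfull <- buildCompression(kc, L = 12)
  pa2 <- randomProbes(20, seed = 33, weights = TRUE)
  P2 <- evaluateBasis(pa2, 3)
  set.seed(34)
  phase <- PhaseData(matrix(rnorm(20 * 25), 20, 25))
  w <- probeWeights(pa2)
  expect_equal(kMatrix(fitCompressed(phase, P2, mfull, w)$k),
               kMatrix(fitK(phase, P2, w)), tolerance = 1e-8)
  # and phi = Phat khat reproduces P k exactly at full rank
  k <- randomK(3, 10, seed = 35)
  expect_equal(compressedProbing(P2, mfull) %*% compressK(k, mfull),
               probingValues(P2) %*% kMatrix(k), tolerance = 1e-10,
               ignore_attr = TRUE)

  # too few probes: the error explains the admissible budget
  pa8 <- randomProbes(8, seed = 36)
  P8 <- evaluateBasis(pa8, 3)
  expect_error(fitCompressed(PhaseData(matrix(0, 8, 4)), P8, m5),
               "maximum of 4 higher order")
})

test_that("compressed residual shrinks with L while ground-truth error need not", {
  # nested subspaces: the data residual is monotone non-increasing in L
  scenes <- testScanScenes(nDirections = 2, nB0 = 1)
  arrs <- buildProbeArray()
  cal <- generateMonitoringData(scenes, arrs$calibration, 5, seed = 40)
  kCalib <- fitK(cal$phase, cal$P)
  test <- generateMonitoringData(scenes, arrs$single, 5, seed = 41)
  resid <- vapply(1:12, function(L) {
    m <- buildCompression(kCalib, L)
    fit <- fitCompressed(test$phase, test$P, m)
    sqrt(mean((phaseMatrix(test$phase) -
                 compressedProbing(test$P, m) %*% fit$kHat)^2))
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-8 + 1e-6 * resid[-12]))
})
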