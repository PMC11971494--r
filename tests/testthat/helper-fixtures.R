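# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no data files.

# random probe cloud comfortably inside a 10-cm sphere
randomProbes <- function(n, sd = 0.05, seed = 1, weights = FALSE) {
  set.seed(seed)
  ProbeArray(matrix(rnorm(3 * n, sd = sd), n, 3),
             weights = if (weights) runif(n, 0.5, 2) else NULL)
}

randomK <- function(maxOrder, nt, seed = 1, segments = NULL) {
  set.seed(seed)
  KCoefficients(matrix(rnorm(countBasis(maxOrder) * nt), ncol = nt),
                maxOrder = maxOrder, segments = segments)
}

# a short desk-scale diffusion scan shared by the simulation tests:
# spiral readout at 2.6 mm with a PGSE or OGSE encoding, 2e-5 s raster
testScanScenes <- function(diffusion = "pgse", nDirections = 3, nB0 = 1,
                           noiseSd = 0.05) {
  makeScanScenes(diffusion, nDirections = nDirections, nB0 = nB0,
                 readout = "spiral", dt = 2e-5, noiseSd = noiseSd,
                 readoutParams = list(resolution = 0.0026),
                 directionSeed = 7)
}
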