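## Probe array layouts: a 16-probe helmet-style base array and the
## multi-position calibration array obtained by z-shifting and rotating it.

#' Default probe layout specification
#'
#' Describes a 16-probe helmet-style array (quasi-uniform golden-angle
#' placement over a spherical cap, radii modulated between 0.119 and 0.149 m
#' with mean 0.135 m) and the multi-position calibration geometry: 3
#' z-positions spaced 0.05 m apart and 3 equiangular rotations about z,
#' with retained probes required to lie within 0.16 m Euclidean distance of
#' isocenter and within 0.14 m along each axis.
#'
#' @param nZShifts number of z-positions (default 3).
#' @param zSpacing spacing between z-positions (m, default 0.05).
#' @param nRotations number of equiangular rotations about z (default 3).
#' @param rMax maximum Euclidean distance from isocenter (m, default 0.16).
#' @param axisMax maximum |x|, |y|, |z| coordinate (m, default 0.14).
#' @param basePositions optional 16 x 3 matrix overriding the built-in base
#'   array.
#' @return list with the layout fields, class "probeLayout".
#' @export
probeLayout <- function(nZShifts = 3, zSpacing = 0.05, nRotations = 3,
                        rMax = 0.16, axisMax = 0.14, basePositions = NULL) {
  if (is.null(basePositions)) basePositions <- .baseProbePositions()
  structure(list(basePositions = basePositions, nZShifts = nZShifts,
                 zSpacing = zSpacing, nRotations = nRotations, rMax = rMax,
                 axisMax = axisMax),
            class = "probeLayout")
}

## 16 probes on a helmet-like cap: golden-angle azimuths, polar angles from
## 15 to 130 degrees, radii modulated over two cycles between 0.121 and
## 0.149 m (mean 0.135 m).
.baseProbePositions <- function() {
  i <- 0:15
  theta <- (15 + 115 * i / 15) * pi / 180
  phi <- i * 137.50776 * pi / 180
  r <- 0.135 + 0.014 * cos(2 * pi * i / 8)
  cbind(x = r * sin(theta) * cos(phi),
        y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

#' Build single-position and multi-position calibration probe arrays
#'
#' The single-position array is the base layout itself. The calibration
#' array is the union of the base layout under every z-shift x z-rotation
#' combination, filtered to probes within `rMax` Euclidean distance of
#' isocenter and within `axisMax` along each coordinate axis. With the
#' default layout this yields a calibration array of roughly a hundred
#' probes from 9 coil orientations.
#'
#' @param layout a [probeLayout()] specification.
#' @return list with elements `calibration` and `single`, both
#'   [ProbeArray-class] objects.
#' @export
buildProbeArray <- function(layout = probeLayout()) {
  base <- layout$basePositions
  zshifts <- (seq_len(layout$nZShifts) - (layout$nZShifts + 1) / 2) *
    layout$zSpacing
  angles <- 2 * pi * (seq_len(layout$nRotations) - 1) / layout$nRotations
  pts <- do.call(rbind, lapply(zshifts, function(dz) {
    do.call(rbind, lapply(angles, function(a) {
      R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
      p <- base %*% t(R)
      p[, 3] <- p[, 3] + dz
      p
    }))
  }))
  keep <- sqrt(rowSums(pts^2)) <= layout$rMax &
    apply(abs(pts) <= layout$axisMax, 1, all)
  if (!any(keep))
    invalidArgument("all candidate probes removed by the distance filters")
  list(calibration = ProbeArray(pts[keep, , drop = FALSE]),
       single = ProbeArray(base))
}

#' Select a well-spread probe subset by electrostatic repulsion
#'
#' Picks `n` probes from an array so that the subset is maximally spread:
#' greedy minimisation of the pairwise 1/distance repulsion energy followed
#' by single-swap local improvement. Deterministic.
#'
#' @param probes a [ProbeArray-class].
#' @param n subset size, 1 <= n <= nProbes(probes).
#' @param maxSweeps cap on local-improvement sweeps.
#' @return A [ProbeArray-class] with `n` probes (weights subset accordingly).
#' @export
selectProbeSubset <- function(probes, n, maxSweeps = 20) {
  np <- nProbes(probes)
  if (n < 1 || n > np)
    invalidArgument("subset size must lie in 1..nProbes")
  if (n == np) return(probes)
  pos <- positions(probes)
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  inv <- 1 / D
  ## greedy: start from the probe farthest from the centroid
  ctr <- colMeans(pos)
  sel <- which.max(rowSums((pos - rep(ctr, each = np))^2))
  while (length(sel) < n) {
    cand <- setdiff(seq_len(np), sel)
    addE <- vapply(cand, function(j) sum(inv[j, sel]), numeric(1))
    sel <- c(sel, cand[which.min(addE)])
  }
  energy <- function(s) sum(inv[s, s]) / 2
  e <- energy(sel)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (i in seq_along(sel)) {
      for (j in setdiff(seq_len(np), sel)) {
        trial <- sel
        trial[i] <- j
        et <- energy(trial)
        if (et < e - 1e-12) {
          sel <- trial
          e <- et
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  w <- probeWeights(probes)
  ProbeArray(pos[sel, , drop = FALSE], weights = w[sel])
}
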