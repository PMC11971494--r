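## Diffusion gradient direction sets uniformly distributed by electrostatic
## repulsion of antipodally symmetric charges on the sphere.

#' Repulsion energy of a direction set
#'
#' Sum of 1/distance over all pairs, counting each direction together with
#' its antipode (diffusion directions are sign-symmetric).
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @return scalar energy.
#' @export
repulsionEnergy <- function(dirs) {
  n <- nrow(dirs)
  if (n < 2L) return(0)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm <- dirs[i, ] - dirs[j, ]
      dp <- dirs[i, ] + dirs[j, ]
      e <- e + 1 / sqrt(sum(dm^2)) + 1 / sqrt(sum(dp^2))
    }
  }
  e
}

#' Uniform diffusion directions by electrostatic repulsion
#'
#' Gradient descent on the antipodally symmetric 1/distance energy, started
#' from a seeded random configuration and projected back to the unit sphere
#' after every step. Iteration-capped and deterministic given the seed.
#'
#' @param n number of directions.
#' @param seed integer seed for the starting configuration.
#' @param iterations iteration cap (default 1000).
#' @param stepSize initial descent step.
#' @return n x 3 matrix of unit direction vectors.
#' @export
electrostaticDirections <- function(n, seed = 1, iterations = 1000,
                                    stepSize = 0.05) {
  if (n < 1) invalidArgument("n must be positive")
  set.seed(as.integer(seed))
  p <- matrix(stats::rnorm(3 * n), n, 3)
  p <- p / sqrt(rowSums(p^2))
  if (n == 1L) return(p)
  e <- repulsionEnergy(p)
  h <- stepSize
  for (it in seq_len(iterations)) {
    grad <- matrix(0, n, 3)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dm <- p[i, ] - p[j, ]
        dp <- p[i, ] + p[j, ]
        fm <- dm / sum(dm^2)^1.5
        fp <- dp / sum(dp^2)^1.5
        grad[i, ] <- grad[i, ] + fm + fp
        grad[j, ] <- grad[j, ] - fm + fp
      }
    }
    trial <- p + h * grad          # repulsion pushes along +grad of -energy
    trial <- trial / sqrt(rowSums(trial^2))
    et <- repulsionEnergy(trial)
    if (et < e) {
      p <- trial
      e <- et
      h <- h * 1.1
    } else {
      h <- h / 2
      if (h < 1e-8) break
    }
  }
  p
}
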