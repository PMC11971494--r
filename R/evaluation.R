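## Order-weighted k-coefficient RMSE and the singular-value / probe-count
## sweep experiments.

#' Order-weighted RMSE between estimated and ground-truth k-coefficients
#'
#' For each volume (segment) computes
#' \deqn{\mathrm{RMSE} = \sqrt{\sum_{i=1}^{n} \frac{1}{N_t}\sum_{j=1}^{N_t}
#'   \left(\Gamma_{ii}\,(k_{ij} - k^{GT}_{ij})\right)^2},}
#' with \eqn{\Gamma_{ii} = \mathrm{base}^{l_i}} starting at order zero, over
#' the first `nBasis` basis functions (default 9, i.e. orders 0-2), then
#' reports the mean and SD across volumes.
#'
#' @param kEst,kGT [KCoefficients-class] objects on matching time axes and
#'   segment labels. `kEst` may have a different maxOrder as long as both
#'   cover `nBasis` rows.
#' @param nBasis number of leading basis functions evaluated.
#' @param gammaBase base of the order weighting (default 0.1).
#' @return An [RMSEReport-class].
#' @export
kRMSE <- function(kEst, kGT, nBasis = 9, gammaBase = 0.1) {
  if (!is(kEst, "KCoefficients") || !is(kGT, "KCoefficients"))
    invalidArgument("kEst and kGT must be KCoefficients")
  if (ncol(kEst@k) != ncol(kGT@k) ||
      !isTRUE(all.equal(kEst@time, kGT@time)) ||
      !identical(kEst@segments, kGT@segments))
    invalidArgument("kEst and kGT must share time axis and segment labels")
  if (nBasis > nrow(kEst@k) || nBasis > nrow(kGT@k))
    invalidArgument("nBasis exceeds the available basis functions")
  maxl <- ceiling(sqrt(nBasis)) - 1
  w <- orderWeights(maxl, base = gammaBase)[seq_len(nBasis)]
  diff2 <- (w * (kEst@k[seq_len(nBasis), , drop = FALSE] -
                   kGT@k[seq_len(nBasis), , drop = FALSE]))^2
  segs <- kEst@segments
  ulab <- unique(segs)
  rmse <- vapply(ulab, function(s) {
    j <- segs == s
    sqrt(sum(rowMeans(diff2[, j, drop = FALSE])))
  }, numeric(1))
  new("RMSEReport",
      perVolume = data.frame(segment = ulab, rmse = as.numeric(rmse)),
      mean = mean(rmse),
      sd = if (length(rmse) > 1L) stats::sd(rmse) else NA_real_,
      nBasis = as.integer(nBasis), gammaBase = as.numeric(gammaBase))
}

#' Sweep the number of retained singular values
#'
#' Rebuilds the compression model and refits the phase data at each
#' candidate L, reporting the mean order-weighted RMSE against ground truth
#' and the minimising L.
#'
#' @param phase a [PhaseData-class] measured with the fitting probe array.
#' @param P [ProbingMatrix-class] of the fitting array.
#' @param kCalib calibration [KCoefficients-class] (input to
#'   [buildCompression()]).
#' @param kGT ground-truth [KCoefficients-class] on the axes of `phase`.
#' @param LRange integer vector of candidate L values (within 1..Np-4).
#' @param weights optional per-probe weights.
#' @param nBasis,gammaBase RMSE evaluation parameters.
#' @return data.frame with columns `L` and `rmse`; attribute `optimalL`
#'   holds the argmin.
#' @export
sweepSingularValues <- function(phase, P, kCalib, kGT, LRange,
                                weights = NULL, nBasis = 9,
                                gammaBase = 0.1) {
  np <- nrow(probingValues(P))
  LRange <- as.integer(LRange)
  if (any(LRange < 1L) || any(LRange > np - 4L))
    invalidArgument("LRange must lie within 1..Np-4")
  rmse <- vapply(LRange, function(L) {
    model <- buildCompression(kCalib, L, gammaBase = gammaBase)
    fit <- fitCompressed(phase, P, model, weights)
    mean(kRMSE(fit$k, kGT, nBasis = nBasis, gammaBase = gammaBase))
  }, numeric(1))
  out <- data.frame(L = LRange, rmse = rmse)
  attr(out, "optimalL") <- LRange[which.min(rmse)]
  out
}

#' Sweep the number of probes used for compressed fitting
#'
#' For each requested probe count, selects a maximally spread subset of the
#' array by electrostatic repulsion, generates monitoring data for the
#' scenes with that subset, performs the compressed fit, and reports the
#' mean order-weighted RMSE against the simulated ground truth. Counts
#' below the minimum L + 4 are skipped with a warning.
#'
#' @param scenes scene list (see [makeScanScenes()]).
#' @param probes full [ProbeArray-class] to draw subsets from.
#' @param counts integer vector of probe counts.
#' @param model a [CompressionModel-class] used for the compressed fits.
#' @param seed integer seed for the simulated monitoring noise.
#' @param maxOrder simulation order (default: model's).
#' @param nBasis,gammaBase RMSE evaluation parameters.
#' @return data.frame with columns `np` and `rmse`.
#' @export
sweepProbeCount <- function(scenes, probes, counts, model, seed,
                            maxOrder = NULL, nBasis = 9, gammaBase = 0.1) {
  if (is.null(maxOrder)) maxOrder <- model@maxOrder
  lmin <- model@L + 4L
  res <- lapply(as.integer(counts), function(np) {
    if (np < lmin) {
      warning(sprintf("skipping count %d: below the %d required for L = %d",
                      np, lmin, model@L))
      return(NULL)
    }
    sub <- selectProbeSubset(probes, np)
    dat <- generateMonitoringData(scenes, sub, maxOrder, seed = seed)
    fit <- fitCompressed(dat$phase, dat$P, model)
    data.frame(np = np,
               rmse = mean(kRMSE(fit$k, dat$kTrue, nBasis = nBasis,
                                 gammaBase = gammaBase)))
  })
  do.call(rbind, Filter(Negate(is.null), res))
}
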