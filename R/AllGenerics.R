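## Accessor generics and show methods.

#' @name accessors
#' @title Accessors for fieldcompress classes
#' @description Small accessor functions used instead of direct slot access.
#' @param object an object of the documented class.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "ProbeArray", function(object) object@positions)

#' @rdname accessors
#' @export
setGeneric("probeWeights", function(object) standardGeneric("probeWeights"))
#' @rdname accessors
#' @export
setMethod("probeWeights", "ProbeArray", function(object)
  if (length(object@weights)) object@weights else NULL)

#' @rdname accessors
#' @export
setGeneric("nProbes", function(object) standardGeneric("nProbes"))
#' @rdname accessors
#' @export
setMethod("nProbes", "ProbeArray", function(object) nrow(object@positions))

#' @rdname accessors
#' @export
setGeneric("phaseMatrix", function(object) standardGeneric("phaseMatrix"))
#' @rdname accessors
#' @export
setMethod("phaseMatrix", "PhaseData", function(object) object@phi)

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setMethod("sampleTimes", "PhaseData", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "KCoefficients", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setMethod("segmentLabels", "PhaseData", function(object) object@segments)
#' @rdname accessors
#' @export
setMethod("segmentLabels", "KCoefficients", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("kMatrix", function(object) standardGeneric("kMatrix"))
#' @rdname accessors
#' @export
setMethod("kMatrix", "KCoefficients", function(object) object@k)

#' @rdname accessors
#' @export
setGeneric("maxOrder", function(object) standardGeneric("maxOrder"))
#' @rdname accessors
#' @export
setMethod("maxOrder", "KCoefficients", function(object) object@maxOrder)
#' @rdname accessors
#' @export
setMethod("maxOrder", "ProbingMatrix", function(object) object@maxOrder)
#' @rdname accessors
#' @export
setMethod("maxOrder", "CompressionModel", function(object) object@maxOrder)

#' @rdname accessors
#' @export
setGeneric("probingValues", function(object) standardGeneric("probingValues"))
#' @rdname accessors
#' @export
setMethod("probingValues", "ProbingMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setMethod("singularValues", "CompressionModel", function(object)
  object@singularValues)

#' @rdname accessors
#' @export
setGeneric("retainedRank", function(object) standardGeneric("retainedRank"))
#' @rdname accessors
#' @export
setMethod("retainedRank", "CompressionModel", function(object) object@L)

#' @rdname accessors
#' @export
setGeneric("gradientMatrix", function(object) standardGeneric("gradientMatrix"))
#' @rdname accessors
#' @export
setMethod("gradientMatrix", "GradientWaveform", function(object) object@g)

#' @rdname accessors
#' @export
setGeneric("rasterTime", function(object) standardGeneric("rasterTime"))
#' @rdname accessors
#' @export
setMethod("rasterTime", "GradientWaveform", function(object) object@dt)

#' @rdname accessors
#' @export
setGeneric("eddyModes", function(object) standardGeneric("eddyModes"))
#' @rdname accessors
#' @export
setMethod("eddyModes", "EddyGradientScene", function(object) object@modes)

#' @rdname accessors
#' @export
setGeneric("perVolume", function(object) standardGeneric("perVolume"))
#' @rdname accessors
#' @export
setMethod("perVolume", "RMSEReport", function(object) object@perVolume)

#' @rdname accessors
#' @export
setMethod("mean", "RMSEReport", function(x, ...) x@mean)

#' @rdname accessors
#' @export
setGeneric("rmseSD", function(object) standardGeneric("rmseSD"))
#' @rdname accessors
#' @export
setMethod("rmseSD", "RMSEReport", function(object) object@sd)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ProbeArray", function(object) {
  r <- sqrt(rowSums(object@positions^2))
  cat(sprintf("ProbeArray with %d probes%s\n", nProbes(object),
              if (length(object@weights)) " (weighted)" else ""))
  cat(sprintf("  distance from isocenter: mean %.3f m, range %.3f-%.3f m\n",
              mean(r), min(r), max(r)))
})

setMethod("show", "PhaseData", function(object) {
  cat(sprintf("PhaseData: %d probes x %d samples, %d volume(s)\n",
              nrow(object@phi), ncol(object@phi),
              length(unique(object@segments))))
})

setMethod("show", "KCoefficients", function(object) {
  cat(sprintf(
    "KCoefficients: order %d (%d basis functions) x %d samples, %d volume(s)\n",
    object@maxOrder, nrow(object@k), ncol(object@k),
    length(unique(object@segments))))
})

setMethod("show", "ProbingMatrix", function(object) {
  cat(sprintf("ProbingMatrix: %d probes x %d basis functions (order %d)\n",
              nrow(object@values), ncol(object@values), object@maxOrder))
})

setMethod("show", "CompressionModel", function(object) {
  sv <- object@singularValues
  frac <- sum(sv[seq_len(object@L)]^2) / sum(sv^2)
  cat(sprintf(
    "CompressionModel: order %d, %d of %d high-order singular vectors retained\n",
    object@maxOrder, object@L, nrow(object@Chigh)))
  cat(sprintf("  gammaBase %.3g; retained variance fraction %.4f\n",
              object@gammaBase, frac))
})

setMethod("show", "GradientWaveform", function(object) {
  cat(sprintf(
    "GradientWaveform '%s': %d samples at %.2g s raster (%.1f ms), |g|max %.1f mT/m\n",
    object@kind, ncol(object@g), object@dt, ncol(object@g) * object@dt * 1e3,
    1e3 * max(abs(object@g))))
})

setMethod("show", "EddyGradientScene", function(object) {
  cat(sprintf("EddyGradientScene '%s': %s waveform, %d eddy mode(s), noise %.3g rad\n",
              object@label, object@waveform@kind, nrow(object@modes),
              object@noiseSd))
})

setMethod("show", "RMSEReport", function(object) {
  cat(sprintf(
    "RMSEReport over %d volume(s), first %d basis functions (gammaBase %.2g)\n",
    nrow(object@perVolume), object@nBasis, object@gammaBase))
  cat(sprintf("  mean %.6g, SD %.6g\n", object@mean, object@sd))
})

## internal error helpers -----------------------------------------------------

fcStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fcError")))
}

invalidArgument <- function(msg) fcStop(msg, "fcInvalidArgument")
illPosedFit <- function(msg) fcStop(msg, "fcIllPosedFit")
infeasibleWaveform <- function(msg) fcStop(msg, "fcInfeasibleWaveform")
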