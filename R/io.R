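## Plain-text interchange: CSV for probe arrays and k time-courses, JSON for
## compression models, and a directory-based dataset container.

#' Read and write probe arrays as CSV
#'
#' Columns: probe_id, x_m, y_m, z_m, weight (weight optional/NA for
#' unweighted arrays).
#'
#' @param file path to a CSV file.
#' @return [ProbeArray-class] (for the reader).
#' @export
readProbeArray <- function(file) {
  d <- utils::read.csv(file)
  need <- c("x_m", "y_m", "z_m")
  if (!all(need %in% names(d)))
    invalidArgument("probe CSV needs columns x_m, y_m, z_m")
  w <- if ("weight" %in% names(d) && !all(is.na(d$weight))) d$weight else NULL
  ProbeArray(cbind(d$x_m, d$y_m, d$z_m), weights = w)
}

#' @rdname readProbeArray
#' @param probes a [ProbeArray-class].
#' @export
writeProbeArray <- function(probes, file) {
  pos <- positions(probes)
  w <- probeWeights(probes)
  d <- data.frame(probe_id = seq_len(nrow(pos)), x_m = pos[, 1],
                  y_m = pos[, 2], z_m = pos[, 3],
                  weight = if (is.null(w)) NA_real_ else w)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read and write k-coefficient time-courses as CSV
#'
#' One column per basis function (named l#m#), plus time_s and segment
#' columns.
#'
#' @param file path to a CSV file.
#' @return [KCoefficients-class] (for the reader).
#' @export
readKCoefficients <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE)
  kcols <- grep("^l[0-9]+m", names(d))
  KCoefficients(t(as.matrix(d[, kcols])), time = d$time_s,
                segments = d$segment)
}

#' @rdname readKCoefficients
#' @param k a [KCoefficients-class].
#' @export
writeKCoefficients <- function(k, file) {
  idx <- harmonicIndices(k@maxOrder)
  d <- data.frame(time_s = k@time, segment = k@segments)
  km <- t(k@k)
  colnames(km) <- sprintf("l%dm%+d", idx$l, idx$m)
  utils::write.csv(cbind(d, km), file, row.names = FALSE)
  invisible(file)
}

#' Read and write compression models as JSON
#'
#' Portable serialisation of a [CompressionModel-class]: order, retained
#' rank, weighting base, high-order compression matrix and the singular
#' spectrum.
#'
#' @param file path to a JSON file.
#' @return [CompressionModel-class] (for the reader).
#' @export
readCompressionModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("CompressionModel", maxOrder = as.integer(j$max_order),
      L = as.integer(j$L), gammaBase = as.numeric(j$gamma_base),
      Chigh = matrix(as.numeric(j$C_high), nrow = j$nrow_C_high),
      singularValues = as.numeric(j$singular_values))
}

#' @rdname readCompressionModel
#' @param model a [CompressionModel-class].
#' @export
writeCompressionModel <- function(model, file) {
  jsonlite::write_json(list(
    max_order = model@maxOrder, L = model@L, gamma_base = model@gammaBase,
    nrow_C_high = nrow(model@Chigh),
    C_high = as.numeric(model@Chigh),
    singular_values = model@singularValues
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Directory-based dataset container
#'
#' Writes a monitored dataset as a plain-text directory: manifest.json plus
#' probes.csv, phase.csv, k.csv and compression.json as available.
#'
#' @param dir container directory (created if needed).
#' @param probes optional [ProbeArray-class].
#' @param phase optional [PhaseData-class].
#' @param k optional [KCoefficients-class].
#' @param model optional [CompressionModel-class].
#' @return the directory path, invisibly.
#' @export
writeContainer <- function(dir, probes = NULL, phase = NULL, k = NULL,
                           model = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "fieldcompress-container", version = 1L,
                   contents = list())
  if (!is.null(probes)) {
    writeProbeArray(probes, file.path(dir, "probes.csv"))
    manifest$contents$probes <- "probes.csv"
  }
  if (!is.null(phase)) {
    d <- data.frame(time_s = phase@time, segment = phase@segments)
    pm <- t(phase@phi)
    colnames(pm) <- sprintf("probe%03d", seq_len(ncol(pm)))
    utils::write.csv(cbind(d, pm), file.path(dir, "phase.csv"),
                     row.names = FALSE)
    manifest$contents$phase <- "phase.csv"
  }
  if (!is.null(k)) {
    writeKCoefficients(k, file.path(dir, "k.csv"))
    manifest$contents$k <- "k.csv"
  }
  if (!is.null(model)) {
    writeCompressionModel(model, file.path(dir, "compression.json"))
    manifest$contents$compression <- "compression.json"
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeContainer
#' @return for the reader, a list with any of `probes`, `phase`, `k`,
#'   `model`.
#' @export
readContainer <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) invalidArgument("not a container: missing manifest")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list()
  cc <- manifest$contents
  if (!is.null(cc$probes))
    out$probes <- readProbeArray(file.path(dir, cc$probes))
  if (!is.null(cc$phase)) {
    d <- utils::read.csv(file.path(dir, cc$phase), check.names = FALSE)
    pcols <- grep("^probe[0-9]+$", names(d))
    out$phase <- PhaseData(t(as.matrix(d[, pcols])), time = d$time_s,
                           segments = d$segment)
  }
  if (!is.null(cc$k))
    out$k <- readKCoefficients(file.path(dir, cc$k))
  if (!is.null(cc$compression))
    out$model <- readCompressionModel(file.path(dir, cc$compression))
  out
}
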