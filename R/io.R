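#' Read a trial-by-time matrix from delimited text
#'
#' Parses a header-free numeric CSV/TSV body (delimiter auto-detected from
#' the first line) into an \linkS4class{ErpEpochs}; the time axis is
#' constructed from the sampling rate and the time of the first sample.
#' Ragged rows and non-numeric or non-finite cells are rejected with the
#' offending coordinates.
#'
#' @param path File path.
#' @param sfreq Sampling frequency in Hz.
#' @param tmin Time of the first sample in ms (default 0).
#' @return An \linkS4class{ErpEpochs}.
#' @export
readTrialMatrix <- function(path, sfreq, tmin = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t"
         else if (grepl(",", first)) ","
         else if (grepl(";", first)) ";" else ""
  rows <- utils::read.table(path, sep = sep, header = FALSE,
                            colClasses = "character",
                            strip.white = TRUE, fill = TRUE,
                            blank.lines.skip = TRUE)
  nc <- ncol(rows)
  mat <- matrix(NA_real_, nrow(rows), nc)
  for (j in seq_len(nc)) {
    v <- suppressWarnings(as.numeric(rows[[j]]))
    bad <- which(!is.finite(v) | rows[[j]] == "")
    if (length(bad))
      stop("non-numeric, non-finite or missing cell at row ", bad[1L],
           ", column ", j, " of ", path)
    mat[, j] <- v
  }
  ErpEpochs(mat, sfreq = sfreq, tmin = tmin)
}

#' Write a trial matrix as delimited text
#'
#' @param epochs \linkS4class{ErpEpochs} or \linkS4class{SwaleSim} (noisy
#'   data written).
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, the path.
#' @export
writeTrialMatrix <- function(epochs, path, sep = ",") {
  if (is(epochs, "SwaleSim")) epochs <- simEpochs(epochs)
  utils::write.table(format(epochData(epochs), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.FIT_SCHEMA <- "swale-fit/1"

#' Serialize a fitted model to JSON
#'
#' Writes a schema-versioned JSON document holding the waveform
#' coefficients and support masks, the evaluated waveforms, per-trial
#' (amplitude, rho, latency shift), the RSS trace, AIC, and a config echo;
#' \code{readFit} reconstructs the \linkS4class{SwaleFit} to full
#' precision.
#'
#' @param fit A \linkS4class{SwaleFit}.
#' @param path Output path for \code{writeFit}; input for \code{readFit}.
#' @return \code{writeFit}: invisibly, the path. \code{readFit}: a
#'   \linkS4class{SwaleFit}.
#' @export
writeFit <- function(fit, path) {
  doc <- list(
    schema = .FIT_SCHEMA,
    sfreq = fit@sfreq,
    time_axis_ms = timeAxis(fit),
    n_basis = nBasis(fit),
    waveforms = lapply(seq_along(fit@waveforms), function(w) {
      wf <- fit@waveforms[[w]]
      list(coeffs = wf@coeffs, support = wf@support,
           values = evalWaveform(wf, fit@basis))
    }),
    trials = lapply(seq_along(fit@params), function(w) {
      p <- fit@params[[w]]
      list(amplitude = p@amplitude, rho = p@rho,
           latency_shift_ms = latencyShifts(p),
           low_amplitude = lowAmplitude(p), amp_floor = p@ampFloor)
    }),
    rss_trace = fit@rssTrace, n_iter = fit@nIter,
    converged = fit@converged, aic = fit@aic, k = fit@k, n = fit@n,
    collinear_fallback = fit@collinearFallback,
    control = fit@control)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeFit
#' @export
readFit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, .FIT_SCHEMA))
    stop("unrecognised fit schema: ", doc$schema)
  Tn <- length(doc$time_axis_ms)
  basis <- makePolynomialBasis(Tn, doc$n_basis, doc$time_axis_ms)
  getW <- function(i, f) {
    if (is.data.frame(doc$waveforms)) doc$waveforms[i, ][[f]][[1]]
    else doc$waveforms[[i]][[f]]
  }
  getP <- function(i, f) {
    if (is.data.frame(doc$trials)) doc$trials[i, ][[f]][[1]]
    else doc$trials[[i]][[f]]
  }
  nW <- if (is.data.frame(doc$waveforms)) nrow(doc$waveforms)
        else length(doc$waveforms)
  wfs <- lapply(seq_len(nW), function(i)
    Waveform(getW(i, "coeffs"), support = getW(i, "support")))
  params <- lapply(seq_len(nW), function(i) {
    af <- getP(i, "amp_floor")
    TrialParams(getP(i, "amplitude"), getP(i, "rho"),
                ampFloor = if (length(af)) af[[1]] else 0.05)
  })
  new("SwaleFit", waveforms = wfs, params = params, basis = basis,
      sfreq = doc$sfreq, rssTrace = as.numeric(doc$rss_trace),
      nIter = as.integer(doc$n_iter), converged = doc$converged,
      aic = doc$aic, k = as.integer(doc$k), n = as.integer(doc$n),
      control = as.list(doc$control),
      collinearFallback = isTRUE(doc$collinear_fallback))
}

#' Write a single-trial peaks table as CSV
#'
#' @param peaks data.frame from \code{\link{extractPeaks}} or
#'   \code{\link{peakPick}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePeaks <- function(peaks, path) {
  stopifnot(all(c("trial", "latency_ms", "amplitude",
                  "at_boundary") %in% names(peaks)))
  utils::write.csv(peaks[, c("trial", "latency_ms", "amplitude",
                             "at_boundary")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth as CSV
#'
#' Columns: trial, peak, amplitude, latency_shift_ms.
#'
#' @param sim A \linkS4class{SwaleSim}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTruth <- function(sim, path) {
  utils::write.csv(simTruth(sim), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
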