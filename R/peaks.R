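## Windowed extremum on the sample grid. Ties broken by the earliest
## sample; boundary hits are flagged, not suppressed.
.gridExtremum <- function(y, idx, polarity) {
  v <- switch(polarity,
              max = y[idx],
              min = -y[idx],
              absolute = abs(y[idx]))
  at <- idx[which.max(v)]       # which.max returns the first tie
  list(at = at, boundary = at == idx[1L] || at == idx[length(idx)])
}

#' Single-trial peak amplitude and latency from a fitted model
#'
#' For each trial, evaluates the selected waveform component's modelled
#' contribution a_i (B b) + rho_i (D b) on the sample grid restricted to
#' the range, and takes the extremum of the requested polarity: its time is
#' the single-trial latency, its value the single-trial amplitude. With
#' multiple components the extraction is performed on one component at a
#' time. The search is on the sample grid (no sub-sample interpolation);
#' ties go to the earliest sample and range-edge extrema are flagged in
#' \code{at_boundary}.
#'
#' @param fit A \linkS4class{SwaleFit}.
#' @param range A \linkS4class{PeakRange}.
#' @param waveform Index of the component to extract from (default 1).
#' @return A data.frame with columns trial, latency_ms, amplitude,
#'   at_boundary. Trials whose component support does not intersect the
#'   range get NA latency/amplitude.
#' @export
extractPeaks <- function(fit, range, waveform = 1L) {
  if (waveform < 1L || waveform > length(fit@waveforms))
    stop("waveform index out of bounds")
  tax <- timeAxis(fit)
  if (range@tLo < min(tax) - 1e-9 || range@tHi > max(tax) + 1e-9)
    stop("range lies outside the epoch's time axis")
  wf <- fit@waveforms[[waveform]]
  idx <- which(tax >= range@tLo & tax <= range@tHi & wf@support)
  N <- nTrials(fit)
  out <- data.frame(trial = seq_len(N), latency_ms = NA_real_,
                    amplitude = NA_real_, at_boundary = FALSE)
  if (length(idx) == 0L) {
    warning("waveform support does not overlap the range; all trials NA")
    return(out)
  }
  g <- evalWaveform(wf, fit@basis)
  h <- evalWaveform(wf, fit@basis, deriv = TRUE)
  a <- fit@params[[waveform]]@amplitude
  r <- fit@params[[waveform]]@rho
  for (i in seq_len(N)) {
    yi <- a[i] * g + r[i] * h
    ex <- .gridExtremum(yi, idx, range@polarity)
    out$latency_ms[i] <- tax[ex$at]
    out$amplitude[i] <- yi[ex$at]
    out$at_boundary[i] <- ex$boundary
  }
  out
}

## Discrete Gaussian kernel: sd in samples, truncated at +-4 sd,
## renormalised to unit sum.
.gaussKernel <- function(sdSamples) {
  half <- max(1L, ceiling(4 * sdSamples))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sdSamples^2))
  k / sum(k)
}

## Reflect-padded convolution of each row with kernel k (odd length).
.smoothRows <- function(Y, k) {
  half <- (length(k) - 1L) %/% 2L
  Tn <- ncol(Y)
  if (half >= Tn)
    stop("smoothing kernel wider than the epoch")
  padIdx <- c(rev(seq_len(half) + 1L), seq_len(Tn),
              Tn - seq_len(half))
  Yp <- Y[, padIdx, drop = FALSE]
  out <- matrix(0, nrow(Y), Tn)
  for (i in seq_len(nrow(Y)))
    out[i, ] <- stats::filter(Yp[i, ], k, sides = 2)[half + seq_len(Tn)]
  out
}

#' Peak-picking with Gaussian smoothing (comparator method)
#'
#' The standard single-trial baseline: smooth each raw trial with a
#' normalised Gaussian kernel and take the windowed extremum per trial as
#' that trial's amplitude and latency. Provided for comparison with the
#' model-based \code{\link{extractPeaks}}.
#'
#' @param data \linkS4class{ErpEpochs} (or \linkS4class{SwaleSim}).
#' @param widthMs Kernel width in ms, interpreted as the Gaussian standard
#'   deviation (set \code{widthIsFwhm = TRUE} to give full width at half
#'   maximum instead). A sub-sample width degenerates to a delta kernel,
#'   i.e. raw windowed peak-picking.
#' @param window A \linkS4class{PeakRange}.
#' @param widthIsFwhm Interpret widthMs as FWHM rather than sd.
#' @return A data.frame with columns trial, latency_ms, amplitude,
#'   at_boundary.
#' @export
peakPick <- function(data, widthMs, window, widthIsFwhm = FALSE) {
  if (is(data, "SwaleSim")) data <- simEpochs(data)
  stopifnot(widthMs > 0)
  if (widthIsFwhm) widthMs <- widthMs / (2 * sqrt(2 * log(2)))
  Y <- epochData(data)
  tax <- timeAxis(data)
  if (window@tLo < min(tax) - 1e-9 || window@tHi > max(tax) + 1e-9)
    stop("window lies outside the epoch's time axis")
  sdSamples <- widthMs * samplingRate(data) / 1000
  Ys <- if (sdSamples < 0.25) Y else .smoothRows(Y, .gaussKernel(sdSamples))
  idx <- which(tax >= window@tLo & tax <= window@tHi)
  N <- nrow(Y)
  out <- data.frame(trial = seq_len(N), latency_ms = NA_real_,
                    amplitude = NA_real_, at_boundary = FALSE)
  for (i in seq_len(N)) {
    ex <- .gridExtremum(Ys[i, ], idx, window@polarity)
    out$latency_ms[i] <- tax[ex$at]
    out$amplitude[i] <- Ys[i, ex$at]
    out$at_boundary[i] <- ex$boundary
  }
  out
}
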