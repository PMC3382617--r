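#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- ErpEpochs

#' Epoched single-channel EEG/MEG data
#'
#' Container for a trial-by-time matrix of baseline-corrected epochs from one
#' channel, together with the sampling rate and a time axis in milliseconds.
#'
#' @slot data Numeric N x T matrix; trials in rows.
#' @slot sfreq Sampling frequency in Hz.
#' @slot timeAxis Numeric vector of T sample times in ms.
#'
#' @export
setClass("ErpEpochs",
         representation(data = "matrix", sfreq = "numeric",
                        timeAxis = "numeric"),
         validity = function(object) {
           msg <- character(0)
           d <- object@data
           if (nrow(d) < 1L || ncol(d) < 2L)
             msg <- c(msg, "need at least 1 trial and 2 samples")
           if (!all(is.finite(d)))
             msg <- c(msg, "data contain non-finite values")
           if (length(object@sfreq) != 1L || object@sfreq <= 0)
             msg <- c(msg, "sfreq must be a positive scalar")
           if (length(object@timeAxis) != ncol(d))
             msg <- c(msg, "timeAxis length must equal the number of columns")
           else if (ncol(d) >= 2L) {
             dt <- diff(object@timeAxis)
             if (any(abs(dt - 1000 / object@sfreq) > 1e-6))
               msg <- c(msg, "timeAxis spacing inconsistent with sfreq")
           }
           if (length(msg)) msg else TRUE
         })

#' Construct an ErpEpochs object
#'
#' @param data Numeric matrix, trials as rows and time samples as columns.
#' @param sfreq Sampling frequency in Hz.
#' @param tmin Time of the first sample in ms (default 0, i.e. stimulus
#'   onset at the first sample).
#' @param timeAxis Optional explicit time axis in ms; overrides \code{tmin}.
#' @return An \linkS4class{ErpEpochs} object.
#' @examples
#' ep <- ErpEpochs(matrix(rnorm(20), 4, 5), sfreq = 1000)
#' nTrials(ep); nSamples(ep)
#' @export
ErpEpochs <- function(data, sfreq, tmin = 0, timeAxis = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(timeAxis))
    timeAxis <- tmin + (seq_len(ncol(data)) - 1) * 1000 / sfreq
  new("ErpEpochs", data = data, sfreq = as.numeric(sfreq),
      timeAxis = as.numeric(timeAxis))
}

#' @rdname nTrials
#' @export
setMethod("nTrials", "ErpEpochs", function(x) nrow(x@data))
#' @rdname nSamples
#' @export
setMethod("nSamples", "ErpEpochs", function(x) ncol(x@data))
#' @rdname timeAxis
#' @export
setMethod("timeAxis", "ErpEpochs", function(x) x@timeAxis)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ErpEpochs", function(x) x@sfreq)
#' @rdname epochData
#' @export
setMethod("epochData", "ErpEpochs", function(x) x@data)

## ----------------------------------------------------------------- BasisSet

#' Orthonormal polynomial basis with analytic derivatives
#'
#' @slot nSamples Number of time samples T.
#' @slot nBasis Number of basis functions q (q <= T).
#' @slot timeAxis Sample times in ms.
#' @slot B T x q matrix of basis values; columns orthonormal under the
#'   discrete inner product over the sample grid, column j a polynomial of
#'   exact degree j.
#' @slot D T x q matrix of analytic first derivatives of the same
#'   polynomials with respect to time in ms.
#'
#' @export
setClass("BasisSet",
         representation(nSamples = "integer", nBasis = "integer",
                        timeAxis = "numeric", B = "matrix", D = "matrix"),
         validity = function(object) {
           msg <- character(0)
           Tn <- object@nSamples; q <- object@nBasis
           if (q < 1L || q > Tn)
             msg <- c(msg, "need 1 <= nBasis <= nSamples")
           if (!identical(dim(object@B), c(Tn, q)) ||
               !identical(dim(object@D), c(Tn, q)))
             msg <- c(msg, "B and D must both be nSamples x nBasis")
           if (length(object@timeAxis) != Tn)
             msg <- c(msg, "timeAxis length must equal nSamples")
           if (identical(dim(object@B), c(Tn, q))) {
             G <- crossprod(object@B)
             if (max(abs(G - diag(q))) > 1e-10)
               msg <- c(msg, "basis columns are not orthonormal")
             if (max(abs(object@D[, 1])) != 0)
               msg <- c(msg, "derivative of constant column must be zero")
           }
           if (length(msg)) msg else TRUE
         })

#' @rdname nSamples
#' @export
setMethod("nSamples", "BasisSet", function(x) x@nSamples)
#' @rdname nBasis
#' @export
setMethod("nBasis", "BasisSet", function(x) x@nBasis)
#' @rdname timeAxis
#' @export
setMethod("timeAxis", "BasisSet", function(x) x@timeAxis)
#' @rdname basisMatrix
#' @export
setMethod("basisMatrix", "BasisSet", function(x) x@B)
#' @rdname derivMatrix
#' @export
setMethod("derivMatrix", "BasisSet", function(x) x@D)

## ----------------------------------------------------------------- Waveform

#' A basis-coefficient waveform with optional support mask
#'
#' The waveform evaluates to (B b) masked by \code{support}; its time
#' derivative to (D b) under the same mask. Split waveforms produced by the
#' multi-signal search carry masks covering disjoint time windows.
#'
#' @slot coeffs Numeric q-vector of basis coefficients.
#' @slot support Logical T-vector; all-TRUE for an unsplit waveform.
#'
#' @export
setClass("Waveform",
         representation(coeffs = "numeric", support = "logical"),
         validity = function(object) {
           msg <- character(0)
           if (length(object@coeffs) < 1L)
             msg <- c(msg, "coeffs must be non-empty")
           if (!any(object@support))
             msg <- c(msg, "support mask must cover at least one sample")
           if (anyNA(object@coeffs) || anyNA(object@support))
             msg <- c(msg, "coeffs and support must not contain NA")
           if (length(msg)) msg else TRUE
         })

#' Construct a Waveform
#'
#' @param coeffs Basis coefficient vector (length q).
#' @param support Logical support mask of length T (default: the full
#'   epoch, i.e. an unsplit waveform).
#' @param nSamples Number of samples T, used to build the default mask.
#' @return A \linkS4class{Waveform}.
#' @export
Waveform <- function(coeffs, support = NULL, nSamples = NULL) {
  if (is.null(support)) {
    if (is.null(nSamples))
      stop("either 'support' or 'nSamples' must be given")
    support <- rep(TRUE, nSamples)
  }
  new("Waveform", coeffs = as.numeric(coeffs), support = as.logical(support))
}

## -------------------------------------------------------------- TrialParams

#' Per-trial amplitude and latency-coefficient estimates
#'
#' Holds the amplitude a_i and derivative coefficient rho_i (= a_i tau_i)
#' for every trial, for one waveform component. Latency shifts are always
#' derived on access as lambda_i = -rho_i / a_i (positive = later); trials
#' with |a_i| below \code{ampFloor} times the median absolute amplitude are
#' flagged and their shift reported as NA.
#'
#' @slot amplitude Numeric N-vector of amplitude scale factors.
#' @slot rho Numeric N-vector of derivative-regressor coefficients.
#' @slot ampFloor Relative amplitude floor for latency reporting.
#'
#' @export
setClass("TrialParams",
         representation(amplitude = "numeric", rho = "numeric",
                        ampFloor = "numeric"),
         validity = function(object) {
           msg <- character(0)
           if (length(object@amplitude) != length(object@rho))
             msg <- c(msg, "amplitude and rho must have equal length")
           if (length(object@ampFloor) != 1L || object@ampFloor < 0)
             msg <- c(msg, "ampFloor must be a nonnegative scalar")
           if (length(msg)) msg else TRUE
         })

#' Construct a TrialParams object
#'
#' @param amplitude Numeric vector of per-trial amplitudes.
#' @param rho Numeric vector of per-trial derivative coefficients.
#' @param ampFloor Relative amplitude floor below which latency shifts are
#'   reported as NA (default 0.05 of the median absolute amplitude).
#' @return A \linkS4class{TrialParams}.
#' @export
TrialParams <- function(amplitude, rho, ampFloor = 0.05) {
  new("TrialParams", amplitude = as.numeric(amplitude),
      rho = as.numeric(rho), ampFloor = as.numeric(ampFloor))
}

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialParams", function(x) length(x@amplitude))
#' @rdname trialAmplitudes
#' @export
setMethod("trialAmplitudes", "TrialParams",
          function(x, waveform = 1L) x@amplitude)
#' @rdname trialRho
#' @export
setMethod("trialRho", "TrialParams", function(x, waveform = 1L) x@rho)
#' @rdname lowAmplitude
#' @export
setMethod("lowAmplitude", "TrialParams", function(x, waveform = 1L) {
  abs(x@amplitude) < x@ampFloor * stats::median(abs(x@amplitude))
})
#' @rdname latencyShifts
#' @export
setMethod("latencyShifts", "TrialParams", function(x, waveform = 1L) {
  lam <- -x@rho / x@amplitude
  lam[lowAmplitude(x)] <- NA_real_
  lam
})

## ---------------------------------------------------------------- NoiseSpec

#' Noise specification for the simulator
#'
#' @slot kind Either "white" or "ar".
#' @slot arCoeffs Autoregressive coefficients (empty for white noise);
#'   the AR polynomial must be stationary.
#' @slot sigma Innovation standard deviation.
#'
#' @export
setClass("NoiseSpec",
         representation(kind = "character", arCoeffs = "numeric",
                        sigma = "numeric"),
         validity = function(object) {
           msg <- character(0)
           if (!object@kind %in% c("white", "ar"))
             msg <- c(msg, "kind must be 'white' or 'ar'")
           if (object@kind == "white" && length(object@arCoeffs) > 0L)
             msg <- c(msg, "white noise must have empty arCoeffs")
           if (object@kind == "ar" && length(object@arCoeffs) > 0L) {
             roots <- polyroot(c(1, -object@arCoeffs))
             if (any(Mod(roots) <= 1 + 1e-10))
               msg <- c(msg, "AR coefficients are not stationary")
           }
           if (length(object@sigma) != 1L || object@sigma < 0)
             msg <- c(msg, "sigma must be a nonnegative scalar")
           if (length(msg)) msg else TRUE
         })

#' Construct a NoiseSpec
#'
#' @param kind "white" or "ar".
#' @param arCoeffs AR coefficients (stationary), ignored for white noise.
#' @param sigma Innovation standard deviation (default 1; the simulator
#'   rescales the realization to hit a target SNR anyway).
#' @return A \linkS4class{NoiseSpec}.
#' @export
NoiseSpec <- function(kind = c("white", "ar"), arCoeffs = numeric(0),
                      sigma = 1) {
  kind <- match.arg(kind)
  if (kind == "white") arCoeffs <- numeric(0)
  new("NoiseSpec", kind = kind, arCoeffs = as.numeric(arCoeffs),
      sigma = as.numeric(sigma))
}

## ---------------------------------------------------------------- PeakRange

#' A time range and polarity defining a peak of interest
#'
#' @slot tLo Lower bound of the range in ms.
#' @slot tHi Upper bound of the range in ms.
#' @slot polarity "max", "min" or "absolute".
#'
#' @export
setClass("PeakRange",
         representation(tLo = "numeric", tHi = "numeric",
                        polarity = "character"),
         validity = function(object) {
           msg <- character(0)
           if (!(length(object@tLo) == 1L && length(object@tHi) == 1L &&
                 object@tLo < object@tHi))
             msg <- c(msg, "need tLo < tHi, both scalars")
           if (!object@polarity %in% c("max", "min", "absolute"))
             msg <- c(msg, "polarity must be 'max', 'min' or 'absolute'")
           if (length(msg)) msg else TRUE
         })

#' Construct a PeakRange
#'
#' @param tLo,tHi Closed interval bounds in ms.
#' @param polarity Whether the peak of interest is a maximum, a minimum,
#'   or the largest absolute deflection.
#' @return A \linkS4class{PeakRange}.
#' @examples
#' peakRange(250, 400, "max")
#' @export
peakRange <- function(tLo, tHi, polarity = c("max", "min", "absolute")) {
  new("PeakRange", tLo = as.numeric(tLo), tHi = as.numeric(tHi),
      polarity = match.arg(polarity))
}

## ----------------------------------------------------------------- SwaleFit

#' A fitted single-trial waveform/amplitude/latency model
#'
#' @slot waveforms List of \linkS4class{Waveform} components.
#' @slot params List of \linkS4class{TrialParams}, one per waveform.
#' @slot basis The \linkS4class{BasisSet} the coefficients refer to.
#' @slot sfreq Sampling rate of the fitted data (Hz).
#' @slot rssTrace RSS after every half-step of the alternating solver.
#' @slot nIter Number of full iterations performed.
#' @slot converged TRUE if the relative RSS decrease fell below tolerance.
#' @slot aic Gaussian least-squares AIC of the final model.
#' @slot k Parameter count used in the AIC.
#' @slot n Number of data points (N * T).
#' @slot control The control list used for fitting.
#' @slot collinearFallback TRUE if any trial-parameter update dropped the
#'   derivative regressors because of numerical collinearity.
#'
#' @export
setClass("SwaleFit",
         representation(waveforms = "list", params = "list",
                        basis = "BasisSet", sfreq = "numeric",
                        rssTrace = "numeric", nIter = "integer",
                        converged = "logical", aic = "numeric",
                        k = "integer", n = "integer", control = "list",
                        collinearFallback = "logical"),
         validity = function(object) {
           msg <- character(0)
           if (length(object@waveforms) != length(object@params))
             msg <- c(msg, "need one TrialParams per Waveform")
           if (length(object@rssTrace) &&
               any(diff(object@rssTrace) > 1e-8 * object@rssTrace[1]))
             msg <- c(msg, "rssTrace must be non-increasing")
           if (length(msg)) msg else TRUE
         })

#' @rdname nTrials
#' @export
setMethod("nTrials", "SwaleFit", function(x) nTrials(x@params[[1]]))
#' @rdname nSamples
#' @export
setMethod("nSamples", "SwaleFit", function(x) nSamples(x@basis))
#' @rdname nBasis
#' @export
setMethod("nBasis", "SwaleFit", function(x) nBasis(x@basis))
#' @rdname timeAxis
#' @export
setMethod("timeAxis", "SwaleFit", function(x) timeAxis(x@basis))
#' @rdname waveforms
#' @export
setMethod("waveforms", "SwaleFit", function(x) x@waveforms)
#' @rdname trialParams
#' @export
setMethod("trialParams", "SwaleFit", function(x) x@params)
#' @rdname trialAmplitudes
#' @export
setMethod("trialAmplitudes", "SwaleFit",
          function(x, waveform = 1L) x@params[[waveform]]@amplitude)
#' @rdname trialRho
#' @export
setMethod("trialRho", "SwaleFit",
          function(x, waveform = 1L) x@params[[waveform]]@rho)
#' @rdname latencyShifts
#' @export
setMethod("latencyShifts", "SwaleFit",
          function(x, waveform = 1L) latencyShifts(x@params[[waveform]]))
#' @rdname lowAmplitude
#' @export
setMethod("lowAmplitude", "SwaleFit",
          function(x, waveform = 1L) lowAmplitude(x@params[[waveform]]))
#' @rdname rssTrace
#' @export
setMethod("rssTrace", "SwaleFit", function(x) x@rssTrace)
#' @rdname isConverged
#' @export
setMethod("isConverged", "SwaleFit", function(x) x@converged)
#' @rdname modelAIC
#' @export
setMethod("modelAIC", "SwaleFit", function(x) x@aic)

## ----------------------------------------------------------------- SwaleSim

#' A simulated multi-trial dataset with ground truth
#'
#' @slot epochs The noisy data as \linkS4class{ErpEpochs}.
#' @slot clean Noise-free N x T signal matrix.
#' @slot noise The realized (rescaled) noise matrix, data = clean + noise.
#' @slot truthAmplitude N x P matrix of true per-peak amplitude draws.
#' @slot truthLatency N x P matrix of true per-peak latency shifts in ms
#'   (positive = later).
#' @slot config The simulation configuration list (echo).
#'
#' @export
setClass("SwaleSim",
         representation(epochs = "ErpEpochs", clean = "matrix",
                        noise = "matrix", truthAmplitude = "matrix",
                        truthLatency = "matrix", config = "list"),
         validity = function(object) {
           msg <- character(0)
           if (!identical(dim(object@clean), dim(object@epochs@data)))
             msg <- c(msg, "clean matrix must match data dimensions")
           if (max(abs(object@epochs@data - object@clean - object@noise)) >
               1e-9 * max(1, max(abs(object@epochs@data))))
             msg <- c(msg, "data must equal clean + noise")
           if (length(msg)) msg else TRUE
         })

#' @rdname nTrials
#' @export
setMethod("nTrials", "SwaleSim", function(x) nrow(x@clean))
#' @rdname nSamples
#' @export
setMethod("nSamples", "SwaleSim", function(x) ncol(x@clean))
#' @rdname epochData
#' @export
setMethod("epochData", "SwaleSim", function(x) x@epochs@data)
#' @rdname timeAxis
#' @export
setMethod("timeAxis", "SwaleSim", function(x) timeAxis(x@epochs))

#' Accessors for simulated ground truth
#'
#' @param x A \linkS4class{SwaleSim}.
#' @return \code{simEpochs}: the \linkS4class{ErpEpochs}; \code{simClean} /
#'   \code{simNoise}: N x T matrices; \code{simTruth}: a data.frame with
#'   columns trial, peak, amplitude, latency_shift_ms.
#' @name sim-accessors
NULL

#' @rdname sim-accessors
#' @export
simEpochs <- function(x) x@epochs
#' @rdname sim-accessors
#' @export
simClean <- function(x) x@clean
#' @rdname sim-accessors
#' @export
simNoise <- function(x) x@noise
#' @rdname sim-accessors
#' @export
simTruth <- function(x) {
  P <- ncol(x@truthAmplitude)
  N <- nrow(x@truthAmplitude)
  data.frame(trial = rep(seq_len(N), P),
             peak = rep(seq_len(P), each = N),
             amplitude = as.vector(x@truthAmplitude),
             latency_shift_ms = as.vector(x@truthLatency))
}
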