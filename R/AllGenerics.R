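#' @import methods
NULL

#' Number of trials (epochs)
#'
#' @param x An object holding epoched data or a fitted model.
#' @return Integer scalar.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of time samples per trial
#'
#' @param x An object with a time dimension.
#' @return Integer scalar.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Time axis in milliseconds
#'
#' @param x An object with a time dimension.
#' @return Numeric vector of sample times in ms.
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' Sampling rate in Hz
#'
#' @param x An epochs object.
#' @return Numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Epoch data matrix
#'
#' @param x An epochs object.
#' @return Numeric matrix, trials in rows, samples in columns.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Basis function matrix
#'
#' @param x A basis set.
#' @return T x q numeric matrix with orthonormal columns.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' Basis derivative matrix
#'
#' @param x A basis set.
#' @return T x q numeric matrix of first derivatives (per ms).
#' @export
setGeneric("derivMatrix", function(x) standardGeneric("derivMatrix"))

#' Number of basis functions
#'
#' @param x A basis set or fitted model.
#' @return Integer scalar.
#' @export
setGeneric("nBasis", function(x) standardGeneric("nBasis"))

#' Fitted waveforms
#'
#' @param x A fitted model.
#' @return List of \linkS4class{Waveform} objects.
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))

#' Per-trial parameter sets
#'
#' @param x A fitted model.
#' @return List of \linkS4class{TrialParams}, one per waveform.
#' @export
setGeneric("trialParams", function(x) standardGeneric("trialParams"))

#' Per-trial amplitude estimates
#'
#' @param x A fitted model or parameter set.
#' @param waveform Which waveform component (ignored for TrialParams).
#' @return Numeric vector of length N.
#' @export
setGeneric("trialAmplitudes",
           function(x, waveform = 1L) standardGeneric("trialAmplitudes"))

#' Per-trial derivative (latency) regression coefficients
#'
#' The raw coefficient of the derivative regressor, rho_i = a_i * tau_i.
#'
#' @param x A fitted model or parameter set.
#' @param waveform Which waveform component (ignored for TrialParams).
#' @return Numeric vector of length N.
#' @export
setGeneric("trialRho",
           function(x, waveform = 1L) standardGeneric("trialRho"))

#' Per-trial latency shifts in milliseconds
#'
#' Derived as lambda_i = -rho_i / a_i so that positive values mean the
#' trial's signal peaks later than the average waveform. Trials whose
#' amplitude magnitude falls below the configured relative floor are
#' returned as NA (the ratio is numerically meaningless there); use
#' \code{lowAmplitude} to retrieve the flags.
#'
#' @param x A fitted model or parameter set.
#' @param waveform Which waveform component (ignored for TrialParams).
#' @return Numeric vector of length N (ms), NA where flagged.
#' @export
setGeneric("latencyShifts",
           function(x, waveform = 1L) standardGeneric("latencyShifts"))

#' Low-amplitude flags for latency reporting
#'
#' @param x A fitted model or parameter set.
#' @param waveform Which waveform component (ignored for TrialParams).
#' @return Logical vector of length N.
#' @export
setGeneric("lowAmplitude",
           function(x, waveform = 1L) standardGeneric("lowAmplitude"))

#' Residual sum-of-squares trace
#'
#' RSS recorded after every half-step (trial-parameter update and waveform
#' update) of the alternating solver; non-increasing by construction.
#'
#' @param x A fitted model.
#' @return Numeric vector.
#' @export
setGeneric("rssTrace", function(x) standardGeneric("rssTrace"))

#' Convergence state
#'
#' @param x A fitted model.
#' @return Logical scalar.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Model AIC
#'
#' @param x A fitted model.
#' @return Numeric scalar.
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))
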