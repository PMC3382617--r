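## Generative model: trial i = a_i * (B b) + rho_i * (D b), summed over
## waveform components, plus noise. rho_i = a_i * tau_i encodes the latency
## shift through the first-order Taylor expansion W(t - lambda) ~ W(t) -
## lambda W'(t), so lambda_i = -rho_i / a_i (positive = later).

.maskedB <- function(waveform, basis) basisMatrix(basis) * waveform@support
.maskedD <- function(waveform, basis) derivMatrix(basis) * waveform@support

#' Evaluate a waveform on the sample grid
#'
#' @param waveform A \linkS4class{Waveform}.
#' @param basis The \linkS4class{BasisSet} its coefficients refer to.
#' @param deriv If TRUE, return the time derivative instead.
#' @return Numeric T-vector (zero outside the support mask).
#' @export
evalWaveform <- function(waveform, basis, deriv = FALSE) {
  .checkCompatible(waveform, basis)
  M <- if (deriv) .maskedD(waveform, basis) else .maskedB(waveform, basis)
  drop(M %*% waveform@coeffs)
}

.checkCompatible <- function(waveform, basis) {
  if (length(waveform@coeffs) != nBasis(basis))
    stop("waveform has ", length(waveform@coeffs),
         " coefficients but the basis has ", nBasis(basis), " functions")
  if (length(waveform@support) != nSamples(basis))
    stop("support mask length does not match the basis sample count")
  invisible(TRUE)
}

#' Predict one trial from a single waveform component
#'
#' Returns a * (B b) + rho * (D b), masked by the waveform's support.
#'
#' @param waveform A \linkS4class{Waveform}.
#' @param basis The matching \linkS4class{BasisSet}.
#' @param amplitude Scalar amplitude a.
#' @param rho Scalar derivative coefficient.
#' @return Numeric T-vector.
#' @examples
#' bs <- makePolynomialBasis(64, 6)
#' wf <- Waveform(rnorm(6), nSamples = 64)
#' y <- predictTrial(wf, bs, amplitude = 1, rho = 0)
#' stopifnot(all.equal(y, evalWaveform(wf, bs)))
#' @export
predictTrial <- function(waveform, basis, amplitude, rho) {
  .checkCompatible(waveform, basis)
  amplitude * evalWaveform(waveform, basis) +
    rho * evalWaveform(waveform, basis, deriv = TRUE)
}

#' Predict all trials from one or more waveform components
#'
#' Row i is the sum over components w of a_iw * (B b_w) + rho_iw * (D b_w).
#' This is the row-wise evaluation of the stacked (Kronecker) form of the
#' multi-trial model; both give identical results.
#'
#' @param waveforms List of \linkS4class{Waveform} (or a single Waveform).
#' @param basis The shared \linkS4class{BasisSet}.
#' @param params List of \linkS4class{TrialParams}, one per waveform.
#' @return N x T numeric matrix of model predictions.
#' @export
predictTrials <- function(waveforms, basis, params) {
  if (is(waveforms, "Waveform")) waveforms <- list(waveforms)
  if (is(params, "TrialParams")) params <- list(params)
  if (length(waveforms) != length(params))
    stop("need one TrialParams per waveform")
  N <- unique(vapply(params, nTrials, integer(1)))
  if (length(N) != 1L)
    stop("inconsistent trial counts across TrialParams")
  pred <- matrix(0, N, nSamples(basis))
  for (w in seq_along(waveforms)) {
    g <- evalWaveform(waveforms[[w]], basis)
    h <- evalWaveform(waveforms[[w]], basis, deriv = TRUE)
    pred <- pred + tcrossprod(params[[w]]@amplitude, g) +
      tcrossprod(params[[w]]@rho, h)
  }
  pred
}

#' Model predictions of a fitted model
#'
#' @param object A \linkS4class{SwaleFit}.
#' @param ... Unused.
#' @return N x T matrix of fitted values.
#' @export
setMethod("fitted", "SwaleFit", function(object, ...) {
  predictTrials(object@waveforms, object@basis, object@params)
})

#' Residual sum of squares between observed and predicted trials
#'
#' @param observed An \linkS4class{ErpEpochs} or an N x T matrix.
#' @param predicted N x T matrix of model predictions.
#' @return Nonnegative scalar: the sum of squared differences over all
#'   N * T points.
#' @export
residualSS <- function(observed, predicted) {
  if (is(observed, "ErpEpochs")) observed <- epochData(observed)
  observed <- as.matrix(observed)
  predicted <- as.matrix(predicted)
  if (!identical(dim(observed), dim(predicted)))
    stop("observed and predicted dimensions differ")
  sum((observed - predicted)^2)
}
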