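setMethod("show", "ErpEpochs", function(object) {
  cat("ErpEpochs:", nTrials(object), "trials x", nSamples(object),
      "samples @", samplingRate(object), "Hz\n")
  tax <- timeAxis(object)
  cat("  epoch:", round(tax[1], 2), "to", round(tax[length(tax)], 2),
      "ms\n")
})

setMethod("show", "BasisSet", function(object) {
  cat("BasisSet:", nBasis(object), "orthonormal polynomial functions on",
      nSamples(object), "samples\n")
})

setMethod("show", "Waveform", function(object) {
  cat("Waveform:", length(object@coeffs), "coefficients; support",
      sum(object@support), "/", length(object@support), "samples\n")
})

setMethod("show", "TrialParams", function(object) {
  cat("TrialParams:", nTrials(object), "trials; mean amplitude",
      signif(mean(object@amplitude), 4), "\n")
})

setMethod("show", "SwaleFit", function(object) {
  W <- length(object@waveforms)
  cat("SwaleFit:", W, if (W == 1L) "waveform," else "waveforms,",
      nTrials(object), "trials,", nBasis(object), "basis functions\n")
  cat("  iterations:", object@nIter,
      if (object@converged) "(converged)" else "(max iterations)", "\n")
  cat("  final RSS:", signif(utils::tail(object@rssTrace, 1), 6),
      " AIC:", signif(object@aic, 6), "\n")
  if (object@collinearFallback)
    cat("  note: derivative regressors dropped at least once",
        "(collinearity)\n")
})

setMethod("show", "SwaleSim", function(object) {
  cfg <- object@config
  cat("SwaleSim:", nTrials(object), "trials x", nSamples(object),
      "samples;", nrow(cfg$peaks), "peak(s);",
      cfg$condition, "condition; target SNR", cfg$snr, "\n")
})

setMethod("show", "NoiseSpec", function(object) {
  if (object@kind == "white")
    cat("NoiseSpec: white Gaussian, sigma", object@sigma, "\n")
  else
    cat("NoiseSpec: AR(", length(object@arCoeffs), "), sigma ",
        object@sigma, "\n", sep = "")
})

setMethod("show", "PeakRange", function(object) {
  cat("PeakRange: [", object@tLo, ",", object@tHi, "] ms,",
      object@polarity, "\n")
})
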