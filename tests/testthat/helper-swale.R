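# Shared fixture builders; everything is generated in code.

arSpec <- function() NoiseSpec("ar", c(0.35, 0.20, 0.10, 0.05, 0.02))

# compact two-peak configuration used for replicate experiments
smallCfg <- function(seed, condition = "fixed", latencySd = 20, snr = 1,
                     noise = arSpec(), nTrials = 60L) {
  simConfig(nTrials = nTrials, nSamples = 256L, sfreq = 250,
            condition = condition, latencySd = latencySd, snr = snr,
            noise = noise, seed = seed)
}

singlePeak <- function() {
  data.frame(center_ms = 300, width_ms = 40, polarity = 1,
             base_amplitude = 1)
}

# random basis + waveform pair for oracle tests
randomModel <- function(Tn = 64L, q = 6L, seed = 1) {
  set.seed(seed)
  basis <- makePolynomialBasis(Tn, q)
  list(basis = basis, wf = Waveform(rnorm(q), nSamples = Tn))
}

# true two-bump waveform evaluated on the small grid
smallTruthWave <- function() {
  tax <- (0:255) * 4
  exp(-(tax - 300)^2 / 3200) + exp(-(tax - 450)^2 / 3200)
}
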