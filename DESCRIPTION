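Package: swale
Title: Single-Trial Waveform, Amplitude and Latency Estimation for EEG/MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simultaneous estimation of the common waveform and of
    trial-specific amplitude and latency of event-related EEG/MEG signals.
    Each epoch is modelled as an amplitude-scaled waveform plus a scaled
    first-derivative term encoding a small latency shift; the waveform is
    represented on an orthogonal polynomial basis and all parameters are
    obtained by an alternating linear least-squares algorithm. Includes
    AIC-based selection of the number of basis functions and of the number
    of underlying waveforms (via a split-search over the fitted waveform),
    single-trial peak extraction, a Gaussian-smoothing peak-picking
    comparator, and a synthetic-data generator producing multi-peak epochs
    with lognormal amplitude variation, Gaussian latency jitter and
    autoregressive noise at controlled signal-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'basis.R'
    'estimation.R'
    'io.R'
    'model.R'
    'peaks.R'
    'selection.R'
    'show-methods.R'
    'simulate.R'
    'swale-package.R'
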