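---
title: "Single-trial waveform, amplitude and latency estimation: model and methods"
author: "swale package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial waveform, amplitude and latency estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swale)
```

## The problem

Single EEG/MEG epochs carry trial-to-trial information — amplitude changes
with learning or fatigue, latency variability with age or attention — that
the averaged evoked response destroys. Worse, latency jitter biases the
average itself: the grand average of jittered signals is a smeared, wider,
lower version of the true waveform. Naive single-trial measures
(peak-picking on smoothed epochs) are noisy and cannot say whether one or
several underlying signals are present.

`swale` addresses this by fitting a *generative model* of the epoch matrix
in which a common waveform is shared across trials while each trial gets
its own amplitude and latency.

## Model

Let $Y$ be the $N \times T$ matrix of baseline-corrected epochs from one
channel. Trial $i$ is modelled as

$$
y_i = a_i\,B b + \rho_i\,D b + \varepsilon_i ,
$$

where $B$ is a $T\times q$ matrix of basis functions, $D$ the matrix of
their first derivatives with respect to time, $b \in \mathbb R^q$ the
waveform coefficients, $a_i$ the trial amplitude, and $\rho_i$ the
coefficient of the derivative regressor. The derivative term is the
first-order Taylor expansion of a time shift,
$W(t-\lambda) \approx W(t) - \lambda W'(t)$, so $\rho_i = -a_i\lambda_i$
and the reported latency shift is $\lambda_i = -\rho_i/a_i$, with the sign
convention that positive $\lambda$ means the trial's signal peaks *later*
than the average model. Noise $\varepsilon_i$ is treated as Gaussian;
estimation is ordinary (unwhitened) least squares.

### Basis

The basis is a discretely orthonormal polynomial sequence built by a
Stieltjes three-term recurrence on the sample grid, with the time variable
rescaled to $[-1,1]$ (raw monomials at $T \sim 500$ samples are numerically
singular; the rescaled recurrence keeps $\max|B^\top B - I|$ at the
$10^{-14}$ level up to $T = 2048$, $q = 20$). Derivatives are obtained by
differentiating the recurrence itself — never by finite differences — and
carry the $2/(t_{\max}-t_{\min})$ chain-rule factor so $D$ is in basis
units per millisecond. Column $j$ is a polynomial of exact degree $j$.

The default $q = 20$ follows the method's standard configuration. For a
1024 ms epoch this resolves features of roughly 80 ms and wider; narrower
transients are represented with visible ripple (see *Limitations*).
`selectNBasis()` chooses $q$ by AIC when the order is in doubt.

### Estimation

Both conditional problems are linear:

* **Trial parameters given the waveform.** For fixed $b$ the regressors
  $(Bb, Db)$ are common to all trials, so one QR factorization serves all
  $N$ two-column regressions (with $W$ waveform components, $2W$ columns).
  If the regressors are numerically collinear — a flat waveform makes the
  derivative term unidentifiable — the fit falls back to amplitude-only
  regression with $\rho = 0$ and flags the fit.
* **Waveform given the trial parameters.** The stacked least-squares
  problem over all trials is solved through normal equations assembled
  from $q \times q$ cross-product blocks. Masked (split) components make
  high-degree global polynomials nearly dependent on a sub-window, so each
  component block is first re-orthonormalized on its own support by a
  rank-revealing pivoted QR and the system is solved in those
  well-conditioned coordinates.

The alternation starts from the grand average projected onto the basis and
stops when the relative RSS decrease per iteration falls below
`relTol` ($10^{-8}$ by default; the stopping rule is a package choice) or
after `maxIter` (200) iterations. Both half-steps are exact conditional
minimizers, so the RSS trace is non-increasing; increases below
$10^{-12}\sum Y^2$ (pure roundoff) are clamped.

### Gauges and a flat ridge

The model has two indeterminacies worth knowing about:

* **Scale.** $(b, a, \rho) \to (cb, a/c, \rho/c)$ leaves predictions
  unchanged. After every waveform update the fit rescales so that each
  component's mean amplitude is exactly 1, which makes $a_i$ readable as
  relative amplitude and stabilizes AIC comparisons.
* **Position.** Because derivative polynomials stay inside the polynomial
  span, shifting the waveform while subtracting the same shift from every
  trial's latency changes predictions only to *second* order. Plain
  alternation crawls along this nearly flat ridge (convergence factors of
  0.999+ per iteration when the true latencies have nonzero mean). The
  solver therefore takes an exact line-search step along the ridge after
  each waveform update: predictions along the transform
  $(b + \delta s,\ \rho - \delta a)$, with $Bs = Db$, change by
  $\delta\rho_i u - \delta^2 a_i u$ ($u = Ds$), making the RSS an explicit
  quartic in $\delta$ that is minimized in closed form and accepted only
  when it lowers the RSS. With this step, noiseless model-generated data
  are recovered to machine precision, and the fit agrees with a
  variable-projection BFGS oracle to $\sim 10^{-4}$ relative RSS within a
  few thousand iterations (the remaining gap is the shallow bilinear
  valley both solvers crawl through; they coincide in the limit).

The identifiable configuration of the model has mean amplitude 1 and mean
latency 0; recovery experiments generate truth in that gauge.

### Single-trial peaks

After fitting, the analyst specifies a peak of interest as a time range
and polarity (`peakRange(t_lo, t_hi, "max"|"min"|"absolute")`). For each
trial the modelled contribution $a_i Bb + \rho_i Db$ of the selected
component is evaluated on the sample grid restricted to the range; the
extremum's time is the trial's latency, its value the trial's amplitude.
The search is on the sample grid (no sub-sample interpolation), ties break
to the earliest sample, and extrema at a range endpoint are flagged
(`at_boundary`), since they usually signal a mis-specified range.

`peakPick()` provides the classical comparator: each raw trial is smoothed
with a normalized Gaussian kernel (width given as the standard deviation
in ms; FWHM selectable), truncated at $\pm 4$ sd, reflect-padded, and the
windowed extremum is returned. A sub-sample width degenerates to raw
windowed peak-picking.

### Multiple signals and model selection

A single waveform forces every part of the epoch to share one amplitude
and one latency per trial. To test for multiple signals, the fitted
waveform is split at every sample lying strictly between two adjacent
local extrema inside the analyst's range (extrema are detected on the
sample grid with strict inequalities; plateaus take the leftmost sample).
For each candidate the coefficients are frozen, the two masked half
waveforms get jointly re-estimated per-trial parameters, and the RSS is
recorded; the minimum-RSS split wins and the full alternating fit is
re-run with the winning masks (the frozen variant is available via
`refit = FALSE`). `selectModel()` accepts a split whenever it strictly
lowers the AIC

$$
\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k , \qquad k = q + 2WN ,
$$

with $n = NT$ data points, $W$ components, and greedily recurses while
$W <$ `maxWaveforms`. The split location is not counted as a parameter;
this literal count of estimated quantities is a documented choice.

**Choosing the range.** The range must contain both peaks *and* the
valley between them as they appear in the fitted average — with 30 ms
jitter the valley of a smeared two-peak waveform can sit 100+ ms after the
later peak's nominal position. A range clipped just past the second peak
makes the split search abort with "no candidates" in a noticeable fraction
of datasets; in the package's own experiments with peaks at 300/450 ms the
range [150, 700] ms is used.

## The simulation bench

`simConfig()`/`simulateErp()` generate the study conditions used
throughout the tests: $T = 512$ samples at 500 Hz (a 1024 ms epoch), two
positive Gaussian peaks at 300 and 450 ms with 40 ms standard deviation,
$N = 100$ trials, amplitudes lognormal(meanlog 0, sdlog 0.25) truncated to
[0.5, 2] by rejection, latency shifts Normal(0, sd) with the jitter grid
{0, 10, 20, 30} ms, SNR grid {0.5, 1, 2}, and stationary AR(5) noise with
coefficients (0.35, 0.20, 0.10, 0.05, 0.02); white noise is available.
These constants are configuration, not hard-coded. In the **fixed**
condition one amplitude and one latency draw per trial is shared by both
peaks (one underlying signal); in the **free** condition each peak draws
independently — a deliberately adversarial case in which overlapping
signals may cancel. Peaks are shifted *analytically* (evaluated at shifted
times), not rolled by integer samples, so sub-sample jitter is
representable. Noise is rescaled so the realized RMS amplitude ratio
$\mathrm{rms(signal)}/\mathrm{rms(noise)}$ over the whole matrix equals
the target SNR exactly (a power-ratio option exists; the definition
matters because EEG usage varies).

`simulateFromModel()` generates data for which the one-waveform model is
*exactly* true ($y_i = a_i Bb + \rho_i Db + \varepsilon_i$): this isolates
model-selection behaviour from model misspecification, which is how the
white-noise versus AR-noise selection experiments are run.

Replicate-based experiments (waveform robustness, model-selection rates,
split location) use a reduced size of $N = 60$ trials and $T = 256$
samples at 250 Hz — the same 1024 ms epoch and generative structure — with
50 replicates; single-dataset recovery checks use the full default size.

**What the bench does not emulate.** Real EEG background activity is
non-stationary and its spectrum varies across subjects; the AR(5)
coefficients here are fixed, generic values rather than estimates from
real baselines. Real signals are not Gaussian bumps, electrode noise is
correlated across channels (this package is single-channel by design),
and genuine latency distributions can be skewed. Passing recovery tests on
this bench therefore demonstrates correctness of the estimator under its
assumed conditions, not field performance.

## Numerical choices

* Degenerate time axes (duplicate times), `nBasis > nSamples`, non-finite
  data cells, unstable AR coefficients and inverted truncation bounds are
  rejected at construction with specific messages.
* Trials whose fitted $|a_i|$ falls below 0.05 of the median absolute
  amplitude get `NA` latency (the ratio $-\rho/a$ is meaningless there)
  and a flag, rather than an exploding value.
* A perfect fit (RSS = 0) has no finite least-squares AIC; it is reported
  as $-\infty$ and excluded from comparisons.
* All randomness in a simulation flows through the single seed in its
  configuration; repeated calls are bit-identical.

## Known limitations

* **Basis resolution.** With $q = 20$ over a 1024 ms epoch, 40 ms-sd
  bumps are represented with ~18 % relative error. This floor is shared by
  every waveform estimate (it also limits how much closer the fitted
  waveform can get to the truth than the basis-projected grand average):
  at jitter/width ratios up to ~0.75 and SNR ~1 the fitted waveform is
  *not* systematically closer to the truth than the average — the
  first-order latency model cannot remove the symmetric (second-order)
  component of jitter smearing. The advantage appears at larger jitter
  and better SNR.
* **Latency accuracy at low SNR.** At SNR 1 under AR(5) noise the
  latency-recovery correlation saturates near 0.87; regressing on the
  *true* waveform gives only ~0.89, so this is an information limit of
  the derivative model at these conditions, not an estimation defect.
  Under white noise at the same SNR the correlation reaches ~0.97.
* **AIC's nominal count under-penalizes the basis dimension.** Each extra
  basis function is free to align with noise through all $N$ per-trial
  regressions, absorbing ~4–5 deviance units on pure noise against a
  nominal penalty of 2, so on signal-free data the criterion drifts
  slightly toward larger $q$. The same mechanism — optimistic deviance
  gains under dependent errors — makes the AIC prefer two waveforms under
  correlated noise in the fixed condition, which the selection
  experiments reproduce as a directional property.
* **Single channel, no prewhitening.** Temporal noise covariance is not
  modelled; estimation is ordinary least squares throughout.
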