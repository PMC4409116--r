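---
title: "Event-related modes: EEMD analysis of condition differences in event-related EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related modes: EEMD analysis of condition differences in event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a contour-integration experiment, observers view fields of oriented Gabor
elements that either contain a chain of near-collinear elements (a contour,
condition CT) or are orientation-scrambled so that no chain exists (condition
NCT). Event-related EEG recorded during such a task carries small,
time-localized amplitude differences between the two conditions, classically
summarized by the evoked components P100 and N200. The question this package
addresses is *where* (which electrodes) and *when* (which post-stimulus
window) the two conditions differ — and whether those differences become more
detectable when the EEG is first decomposed into narrow-band oscillatory
modes rather than analyzed as a raw evoked potential.

`ermtools` implements that analysis end to end: a generator for the Gabor
stimulus fields and for synthetic multi-subject EEG with *known* planted
effects, an ensemble empirical mode decomposition (EEMD) engine, Hilbert
spectral analysis of the resulting modes, and channel-wise paired statistics
with electrode-cluster pooling and scalp topographies.

## The decomposition model

Empirical mode decomposition writes a signal $x(t)$ as

$$x(t) = \sum_{j=1}^{7} c^{(j)}(t) + r(t),
\qquad c^{(j)}(t) = \mathrm{Re}\{a_j(t)\,e^{i\phi_j(t)}\},$$

where each intrinsic mode function (IMF) $c^{(j)}$ is a zero-mean,
amplitude- and frequency-modulated oscillation and $r(t)$ is the
non-oscillating trend. Each IMF is extracted by *sifting*: the mean of the
cubic-spline envelopes through the local maxima and minima is subtracted
from the running signal, a fixed number of times per mode. The instantaneous
frequency of a mode is $\nu_j(t) = \phi_j'(t)/2\pi$, obtained from the
unwrapped phase of the analytic signal; amplitude, phase and frequency per
mode constitute the Hilbert–Huang spectrum.

EEMD is the noise-assisted variant: plain EMD is applied to $E$ copies of
the signal perturbed by white noise of standard deviation
$\sigma_{noise} = 0.2\,\sigma_{signal}$, and corresponding modes are
averaged across the ensemble. This stabilizes mode assignment (reduces mode
mixing) at the cost of an $O(\sigma_{noise}/\sqrt{E})$ residual in the
additive reconstruction.

Event-related modes (ERMs) are condition-specific, trial-aggregated IMFs per
channel. Two routes are provided:

* **Approach A** — average the trials of a condition to an ERP, z-score it,
  then decompose. Retains only stimulus-phase-locked activity.
* **Approach B** — z-score and decompose every single trial, then average
  corresponding modes over trials. Retains non-phase-locked activity too.

In the degenerate case where all trials are identical the two approaches
coincide exactly; this is asserted by the test suite, and is the reason the
ensemble noise substream is derived per (channel, condition) rather than per
trial — noise averaged out *within* each trial's ensemble need not differ
*between* trials, and sharing it makes A/B comparisons exact.

## Fixed analysis choices

* **Modes per decomposition.** Seven IMFs; the trend is stored as the 8th
  mode. The mode count is fixed in advance because modes must be averaged
  across trials and subjects, which requires a stable indexing.
* **Sifting iterations.** A fixed iteration count (default 10) replaces the
  formal IMF stopping criterion, keeping extraction deterministic and
  comparable across trials. The count is a configuration knob and is echoed
  into output metadata.
* **Envelope boundaries.** The spline envelopes are fitted after mirroring
  two extrema beyond each end of the series (reflection about the first and
  last sample). This suppresses the end swings that otherwise contaminate
  short 500-sample epochs. Plateaus count once, at their first sample.
* **Ensemble parameters.** $E = 20$ and noise ratio $0.2$ by default.
* **Epochs.** 500 samples at 500 samples/s: 75 samples (150 ms) before
  stimulus onset, 425 samples (850 ms) after. Sample 76 of the epoch is the
  onset sample.
* **Standardization.** Each (channel, condition) series is z-scored over the
  whole epoch before decomposition; no separate pre-stimulus baseline
  subtraction is applied, since centring over the full interval subsumes it.
* **Analysis windows.** Fixed intervals relative to onset, half-open in ms:
  P100 early (60, 120), P100 late (120, 180), N200 early (150, 210),
  N200 late (200, 260). The ms-to-sample map is
  `onset + round_half_up(ms * rate / 1000)` with half-open `[lo, hi)`
  indexing, so window sample counts are bit-stable.
* **The statistic.** Per channel, the per-subject difference of absolute
  window-mean amplitudes, $d_i = |A_{CT,i}| - |A_{NCT,i}|$, tested against
  zero with a two-sided paired t-test and tiered at
  $\alpha \in \{0.05, 0.01, 0.001\}$. No multiple-comparison correction is
  applied; reporting is per channel.
* **Mode of interest.** Mode 5 is the default for pooling and reporting (its
  peaks track the classical ERP components), but all 8 modes are computed
  and any subset can be analyzed. For end-to-end recovery experiments the
  windowed statistic is computed on the *partial reconstruction* summing
  modes 3–7: a transient planted in a 60 ms window does not map onto a
  single predictable mode index, and partial reconstruction — including some
  modes, excluding others — is the intended way to denoise with EMD. Modes
  1–2 carry the broadband high-frequency residue and the trend carries no
  oscillatory signal, so the 3–7 sum is the natural "signal" reconstruction.
* **Instantaneous frequency.** Centred finite differences of the unwrapped
  phase; one-sided at the endpoints. Transiently negative frequencies are
  reported, not clamped. All spectral summaries exclude the outer 10% of
  samples at each end, where the discrete Hilbert transform is unreliable;
  the median over the central 80% is reported alongside the mean.

## The stimulus generator

A stimulus is an invisible 10 × 10 grid of cells of size
$2s/(1+\sqrt{2}) = 1.66$ deg for element separation $s = 2$ deg. The
contour path is a chain of 10 segment centres with neighbour separation
$2 \pm 0.55$ deg and a turn of $\pm(\alpha + \Delta\alpha)$ at each joint,
where $\alpha$ is the path angle and $\Delta\alpha$ is uniform within a
configurable bound (default ±1°, interpreting the unitless jitter interval
as degrees). The turn *direction* is random per joint, which preserves the
stated magnitude of adjacent orientation differences. A valid path keeps
every centre on the grid, none in the inner 2 × 2 cells, at least four in
the inner 6 × 6 cells, and all ten in distinct cells — the last constraint
guarantees the filled field cannot exceed 100 elements. Remaining cells
receive distractors at their centres, jittered ±0.55 deg per axis, with
uniform random orientation in [0°, 180°) (orientation of an odd Gabor is
defined modulo 180°; whether distractor orientation should instead span a
full turn is unknowable from the construction and would be visually
indistinguishable for the carrier used).

The element luminance follows
$L(x,y) = L_0\,(1 + s(x,y)\,g(x,y))$ with carrier
$s(x,y) = C \sin(k x \cos\theta + k y \sin\theta)$, $k = 2\pi f$,
$C = 0.9$, $f = 3$ cpd, and Gaussian envelope of $\sigma = 0.25$ deg. The
carrier argument is implemented literally in this form; note it is not the
conventional rotated-coordinate Gabor (the two coincide at $\theta = 0$),
a choice made deliberately to keep the generator faithful to the stated
expression.

Overlap control: the *visible part* of an element is taken as the disc
where the envelope exceeds $e^{-2}$ of its peak (radius $2\sigma$ = 0.5
deg). A new element is skipped when its visible disc would share more than
5 raster pixels with an existing one, evaluated at the projector geometry
(800 px across 16.6 deg). Since the shared-pixel count is monotone in
centre distance, the rule is applied as a distance threshold computed once
by bisection on the exact lattice count. A stimulus in which more than 10
elements are skipped is withdrawn and rebuilt from fresh randomness; valid
fields therefore contain 90–100 elements. The NCT twin of a CT field keeps
every position and rotates the 10 path elements by alternating ±45°.

## The synthetic EEG generator

Each subject's trial is the sum of

* Gaussian-windowed evoked bumps — P100 (+1.0 a.u., σ 15 ms), N200 (−1.2,
  σ 20 ms), P300 (+0.8, σ 35 ms), N400 (−0.6, σ 40 ms) — with
  region-dependent latencies: posterior channels (clusters OC/P/PT) receive
  the early latency (P100 at 100 ms, N200 at 180 ms), frontal channels
  (FR/AT) the late latency (170 / 240 ms), central channels (CE) both at
  half amplitude. Amplitudes are in units of the single-trial noise
  standard deviation;
* band-limited oscillations at 25, 10, 5 and 2 Hz (amplitudes 0.15, 0.25,
  0.3, 0.3) with an independent uniform phase per trial and channel, so
  they behave as induced activity and average out of the ERP;
* $1/f$ background noise (spectral exponent 1), demeaned and rescaled to
  unit sample standard deviation per trial.

Between-subject variability multiplies each component's amplitude by
$\mathcal{N}(1, 0.1)$ and jitters its latency by $\mathcal{N}(0, 5)$ ms.
These magnitudes are typical of the across-subject spread of evoked
component parameters in adult visual ERP data; they are deliberately modest
because they enter the paired statistic as subject-level variance.

Planted condition effects are Gaussian bumps spanning a named window
(σ = width/6), added to CT trials at named channels, and scaled so that the
bump's *mean over the window* equals the requested `delta` — the planted
quantity is thus exactly the window-mean amplitude difference that the
analysis measures, which makes recovery quantitative rather than merely
qualitative.

What the generator does *not* emulate: volume-conduction correlation
between channels (channels are independent), non-Gaussian artifacts
(blinks, muscle), latency jitter across trials within a subject, and any
coupling between oscillatory phase and the evoked response. Passing the
recovery suite therefore shows the pipeline is correct and calibrated under
realistic noise and amplitude regimes — it does not show robustness to
artifacts or to spatially correlated noise, which real recordings would add.

## What the validation suite establishes

* Plain EMD reconstructs 100 random signals to $10^{-9}$ relative error,
  and a 25 Hz + 3 Hz mixture separates into two modes with correlation at
  least 0.95 to the true components and Hilbert frequencies within 25 ± 3
  and 3 ± 1 Hz (central 80%).
* The ensemble reconstruction residual shrinks with ensemble size
  (E = 80 versus E = 5 over 20 seeds) and stays below
  $3 \cdot 0.2\,\sigma/\sqrt{E}$.
* The paired test is calibrated: type-I rate within [0.035, 0.065] over
  1000 null channels; power at a planted unit paired difference with 18
  subjects within 3 points of the closed-form noncentral-t value
  (≈ 0.98).
* End-to-end, with effects of window-mean size 1.2 planted at four
  posterior channels (N200 early window) and four frontal channels (N200
  late window) in a 16-channel montage — 6 subjects, 60 trials per
  condition, E = 10, 10 seeds — the pipeline flags at least 90% of the
  planted (channel, window) pairs at α = 0.05 while flagging at most 10%
  of the channels that carry no effect, and the pooled posterior-cluster
  N200 peak leads the pooled frontal-cluster peak in every seed. These
  problem sizes are the package's validation design; they keep each
  experiment to a few seconds per subject.

One caveat is worth stating explicitly because it is a property of the
method, not a bug: z-scoring each (channel, condition) epoch renormalizes
the whole series, so a large planted amplitude change at one channel
slightly rescales that channel's standardized amplitudes in *every*
window. A channel carrying a big early effect can therefore reach
significance in the late window as well. This is a genuine condition
difference created by the normalization, which is why window specificity
is assessed at channels carrying no effect at all.

## Worked example

```{r, eval = FALSE}
library(ermtools)

chans <- c("O1", "O2", "P4", "P8", "C4", "CP4", "F4", "AF4")
sim <- eeg_sim_config(
  n_subjects = 6, channels = chans, n_trials_per_condition = 60,
  effect_map = list(
    list(channels = c("O2", "P4"), window_ms = c(150, 210), delta = -1.2),
    list(channels = c("F4", "AF4"), window_ms = c(200, 260), delta = -1.2)
  ),
  seed = 1
)
res <- run_pipeline(run_config(
  sim = sim, eemd = eemd_config(ensemble_size = 10),
  windows = list(window_def("N200", "early"), window_def("N200", "late")),
  seed = 1, out_dir = "erm_run"
))
res$stats$N200_early        # channel table: mean_diff, t, p, tier
res$pooled$OC               # pooled occipital mode-5 series, CT and NCT
```

## Known limitations

* EMD has no closed-form theory; all guarantees here are empirical, at the
  tested signal classes and lengths.
* The fixed 7-mode, fixed-iteration scheme can leave residual oscillation in
  the trend slot for signals with fewer than 7 separable scales; by
  construction the remaining IMF slots are then zero and the trend is stored
  last.
* The instantaneous-frequency estimator degrades near epoch boundaries;
  summaries must use the central window (the package's summaries do).
* The cluster memberships of the default layout are a schematic 10-10
  assignment intended for synthetic studies; real montages should supply
  their own layout TSV.
* EDF import/export is not provided; the interchange format is delimited
  text plus JSON sidecars.
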