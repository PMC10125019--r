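---
title: "Detecting and mapping sharp-wave ripple propagation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping sharp-wave ripple propagation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`ripplemapr`, the parameters that matter and why their defaults are what
they are, what the bundled simulator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## The detection model

A sharp-wave ripple is treated as a transient elevation of the 120–250 Hz
envelope of a CA1 LFP channel. Detection on a channel proceeds as:

1. **Band-pass.** A Butterworth band-pass with 6 poles between
   `band_low = 120` Hz and `band_high = 250` Hz, applied forward and
   backward (`signal::filtfilt`). Zero-phase filtering matters because the
   event *boundaries* are the measurement: a causal filter would shift
   every start time by the filter delay.
2. **Envelope.** The magnitude of the analytic signal, computed by the FFT
   construction. For trace lengths with large prime factors the trace is
   mirror-padded to the next 5-smooth length and truncated afterwards;
   this only perturbs the envelope within a few samples of the edges and
   keeps the transform O(n log n) for any session length.
3. **Dual thresholds.** Candidate events are contiguous runs where the
   smoothed envelope (trailing moving average over
   `smooth_window_samples = 5` samples, 4 ms at 1250 Hz) exceeds
   mean + `boundary_threshold_sd = 2` SD, provided the run contains a raw
   envelope sample above mean + `peak_threshold_sd = 5` SD. The mean and
   SD are computed over artifact-free, behaviour-covered, non-running
   samples of the whole session, giving one fixed threshold per channel.
   Thresholding at mean + k·SD (rather than k·SD) is the default because
   the Rayleigh-like envelope of band-limited noise has a substantial
   mean; `threshold_mode = "sd_only"` is available for sensitivity
   analyses.
4. **Merging, duration, spectrum, behaviour.** Candidates whose starts are
   closer than `merge_gap_s = 0.05` are merged transitively (a chain
   1.000 s, 1.040 s, 1.080 s becomes one event spanning the union).
   Durations are gated to the *open* interval
   (`min_duration_s = 0.015`, `max_duration_s = 0.25`) s. Each surviving
   candidate's raw LFP segment is validated with a constant-detrend
   periodogram (`stats::spec.pgram`, taper 0, demeaned, no padding): the
   frequency of maximum power above `spectral_floor_hz = 50` must exceed
   `spectral_peak_hz = 100` Hz. The floor keeps slow 1/f power from
   swamping the argmax on short segments while still letting genuine
   low-frequency artifacts (line noise and its leakage) win the argmax and
   disqualify the candidate; `spectral_peak_mode = "local_max"` offers the
   laxer any-local-maximum variant. Finally, candidates whose start falls
   in a running sample (standardized speed above its 10th percentile
   + 0.06) or outside behavioural coverage are discarded, as are events
   overlapping artifact-masked samples.
5. **Metrics.** Per event: ripple strength ∫Ripple (trapezoidal integral
   of the band-passed envelope over [start, stop), in volt-seconds of the
   recording's unit), RIVD (integral of the raw-LFP envelope over
   −100/+200 ms around start — the broad window absorbs travel delays),
   amplitude (90th envelope percentile within the event) and the spectral
   peak. Strong ripples are those with ∫Ripple strictly above the 90th
   percentile on the session's reference channel; ties fall to common, so
   a degenerate all-equal session has no strong ripples.

**Best channel.** Within an area the detection channel is the one with the
largest envelope SD; when several channels are local SD maxima along depth
(sharp waves in stratum radiatum compete with ripples in stratum
pyramidale), the one with the larger envelope skewness wins — ripple
activity is sparse and right-skewed, dipole-like sharp-wave contamination
is not.

## Pairwise coupling and propagation

Per-ripple strength on every channel is the integral of that channel's
band-passed envelope over −100/+200 ms around each reference ripple start;
channels with envelope variance below 5 (native units squared) are treated
as ripple-free and dropped. The correlation matrix is the Pearson
correlation of these per-ripple strengths across channel pairs, and an OLS
of correlation on 3D channel distance quantifies how much of its
variability distance explains. Pair distance classes use linear-
interpolation quantiles (type 7) at 25%/75% so the thresholds are
reproducible on any input.

Lags use nearest-neighbour matching of start times within ±60 ms, with the
more medial site as reference (positive lag = medial→lateral travel) and
equidistant ties resolved to the earlier target event. Clusters keep the
first event per probe inside the window; the seed is the earliest member,
with simultaneous starts resolved to the more medial probe — a
deterministic, documented convention where the underlying data give no
ordering.

Three M-L sections (medial/central/lateral) partition the probes into
contiguous, equal-count groups, remainders allotted medial-first; the rule
is order-invariant because ties in M-L break on probe id. Per-probe
position is the probe's selected CA1 channel (exposed through
`probe_positions()`), the same convention the detector uses.

The **SCI** of a cluster is the fraction of detecting sections in which
the cluster's member exceeds that section's 90th-percentile strength,
computed on the section's strongest-activity channel over the session. The
denominator is the number of sections with any ripple-detecting probe, not
a fixed 3, so sessions with silent sections are not penalised.
**Propagation speed** regresses member M-L position on lag (µm/ms): the
inverted regression keeps near-synchronous clusters finite, and a minimum
lag range of 1 ms (plus ≥3 members spanning ≥2 sections) marks genuinely
synchronous clusters as undefined rather than returning explosive values.
Propagation maps are per-probe mean lags, linearly interpolated onto a
50-point M-L grid without extrapolation so sessions with different probe
geometries can be averaged. Axis attribution uses squared partial
correlations of lag with M-L controlling A-P and vice versa, with
Student-t p-values on n − 3 degrees of freedom.

## Spiking engagement and modulation

Peri-ripple histograms pool the spikes of each probe's clusters in a ±250
ms window around ripple start, binned at 10 ms (the bin is configurable;
the default matches the scale on which ripple-locked firing is usually
displayed) and divided by the ripple count. The seed difference map is the
medial-minus-lateral difference of such histograms interpolated over M-L
per time bin. Active fraction and spike rate use the 0–120 ms post-start
window, with the early/late split at 50 ms; rates average over ripples
within a cluster, then over clusters, so high-rate clusters do not
dominate the population mean. The putative E/I split thresholds waveform
duration at 0.4 ms (configurable and reported with the output): narrow
spikes are putative inhibitory.

The modulation index of a cluster for a seed type and window is
(ripple rate − baseline rate)/baseline rate, with the baseline taken from
the 120 ms before each of that seed type's ripple starts. A cluster is
*modulated* when either seed type reaches an index of at least 0.5
(inclusive, "at least a 50% increase"). A cluster *prefers* a seed type
when that type's index is at least 0.5 and the other type's index is at
most half of it; phrasing the two-fold rule as `other ≤ preferred/2`
extends it cleanly to non-positive comparison indices. The pre-onset
window (−20–0 ms) reuses the same −120–0 ms baseline; the overlap is a
known approximation and a sensitivity flag would move the baseline
earlier. Variance explained by M-L position is the OLS R² of the
medial-minus-lateral index contrast on cluster M-L position per subfield
and window; the contrast (not the raw index) is the response because the
question is where along the axis the *seed-type difference* lives; the
raw-modulation variant is available via `contrast = FALSE`.

## The synthetic-data generator

`simulate_session()` is a forward model of the statistical structure the
analysis assumes, not a biophysical simulation. Defaults describe one
plausible awake multi-probe session:

* **Geometry.** 6 probes spanning 3 mm of M-L (one CA1 channel each),
  A-P jittered by 150 µm so axis attribution is testable.
* **Events.** A shifted-exponential point process with rate 0.249/s
  (≈2.5 per 10 s) and a 0.3 s refractory gap; 10% of events come from a
  high-amplitude "strong" class. Seed sections are drawn with
  class-specific probabilities (common ripples mostly lateral, strong
  ripples mostly medial). Per probe, arrival = seed time + M-L
  distance/speed (170 µm/ms default) + Gaussian jitter (SD 3 ms, truncated
  at ±60 ms, none on the seed probe), and amplitude decays exponentially
  with distance, faster lateral→medial (0.4/mm) than medial→lateral
  (0.2/mm).
* **Waveform.** A ~150 Hz sinusoid under a fast-attack (6 ms) /
  exponential-decay envelope plus a slower sharp-wave deflection, added to
  1/f noise (exponent 1, SD 100 µV). Amplitudes are specified in
  *detection units*: an amplitude of k places the envelope peak at
  mean + k·SD of the channel's background ripple-band envelope, using a
  per-duration calibration of the band-pass filter's envelope loss. This
  makes "a 7 SD ripple" a well-defined generator input. The fast attack
  is what keeps detected start times within a few ms of truth — a
  symmetric Gaussian envelope would make "start" systematically
  threshold-dependent.
* **Spiking.** Homogeneous Poisson baselines (log-normal rates, median
  3 Hz) with window-specific multiplicative gains around each event's
  *local* arrival: early (0–50 ms), late (50–120 ms) and pre (−20–0 ms)
  windows per seed type and region group. Defaults give hippocampal
  units a late-phase gain that persists for medial seeds (2.4) but decays
  for lateral seeds (1.4), a seed-proximity effect on the early gain
  (exponential decay 0.3/mm from the seed) and a small medial pre-onset
  bias — the qualitative phenomena the analysis is designed to expose.
  Gains below 1 thin the baseline train, above 1 superpose extra Poisson
  spikes, so rates multiply exactly.
* **Behaviour and QC.** A speed trace (10 Hz) with ~5 running bouts of
  5–15 s at ~30 cm/s over a 0.5 cm/s resting level; the resting noise
  (0.05 cm/s) is deliberately small relative to bout amplitude so that,
  after z-scoring, the 10th-percentile + 0.06 running rule separates the
  two regimes the way it does on real wheel data. 8% of units are planted
  to fail one QC criterion.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* establish about real data: no within-ripple frequency
dynamics or phase coupling, no sharp-wave/ripple depth profile beyond a
single channel per probe, no theta or slow oscillations, no spatially
correlated noise across probes, no bursting or refractory spike-train
structure, no electrode drift, and stationary rates throughout. Recovery
results certify the *pipeline* (that the estimators return the planted
parameters under the assumed model), not the model's fidelity to any
particular recording.

## Numerical choices and degenerate inputs

* Event intervals are half-open [start, stop) in seconds; starts snap to
  the sample grid.
* Integrals are trapezoidal at the sampling step.
* A zero-variance envelope yields no events with a warning; fewer than 10
  events yields no strong class; an empty speed trace discards all
  candidates (no behaviour = no event, matching the exclusion rule).
* Quantiles are type-7 (linear interpolation) throughout.
* The trailing smoother leaves its first window−1 samples sub-threshold
  rather than imputing partial windows.
* `spec.pgram` runs with `fast = FALSE` so the periodogram grid is exactly
  the segment's Fourier grid.
* Collinear M-L/A-P coordinates make partial correlations an error, not a
  number.

## Verification problem sizes

The test suite and the acceptance script verify parameter recovery on
simulated sessions sized to give stable statistics while staying desk
scale: 10 minutes of 3-probe LFP (≈150 events) for detector recall and
precision, a noise-only session with 20 clipped 60 Hz bursts for the
false-positive path, 2000 s of 6-probe LFP (≈500 events) for lag
recovery, 4000 s (≈1000 clusters) for seed recovery, 3600 s for SCI
directionality (with the attenuation asymmetry set to 0.05 vs 0.5/mm so
the directional conservation contrast is well inside detectability),
events-only sessions of ≈2000 ripples for modulation recovery, and a
4-minute session for pipeline determinism and the inclusion-rule audit.
The SCI contrast between seed groups is assessed with a one-sided Welch
t-test on group means, the natural test for unpaired per-cluster values
from a single session. One caveat is recorded openly: a planted Poisson
gain of exactly 1.5 puts the expected modulation index exactly on the 0.5
"modulated" decision boundary, so no unbiased estimator can classify such
clusters consistently — the recovery checks therefore report the mean
index (which concentrates at 0.5) and the classification accuracy of the
clearly separated 1.2-gain control group, while whole-set classification
accuracy hovers near 75% by construction.

## Known limitations

* The session reader uses a documented flat directory layout
  (Parquet/CSV/JSON); NWB files are not parsed directly.
* Sectioning assumes the M-L coordinate proxies the long axis over the
  septal/intermediate half of the hippocampus; it is not a full
  longitudinal-axis parameterisation.
* Per-probe position is the selected CA1 channel's position; if a probe's
  CA1 span is large, the single-point convention blurs distances at the
  ~100 µm scale.
* The modulation analysis thresholds indices; it deliberately performs no
  per-cluster significance testing.
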