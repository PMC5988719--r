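---
title: "Methods: models, parameters and design choices in ornpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ornpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ornpulse)
```

## Scope

`ornpulse` quantifies two kinds of experiment on *Drosophila* larval
olfactory receptor neurons (ORNs): calcium-imaging recordings of
spontaneous ("prior") and optogenetically evoked activity, and the
four-quadrant optogenetic choice assay. Every quantification has a
matching seeded generator with ground truth, so the whole pipeline can be
validated by parameter recovery without any raw recordings.

## Trace quantification

### dF/F0

Raw ROI fluorescence F is normalized as dF/F0 = (F − F0)/F0. Two
baselines are implemented, matching the two recording regimes:

* **`prior_percentile`** — F0 is the mean of the lowest quartile of
  samples, i.e. the lowest `ceiling(0.25 N)` values. The phrase "mean of
  the 25th percentile" admits other readings (e.g. the single type-7
  25th-percentile value); we use the lowest-quartile mean and state it
  prominently, since for well-behaved traces the two differ by less than
  the noise floor but they are not identical.
* **`stim_onset_frames`** — F0 is the mean of the nine frames from the
  first stimulus onset. Taken literally this makes dF/F0 at onset ~0 by
  construction, which is why a third mode, **`pre_onset`** (mean over the
  2 s before onset), is provided and used for response metrics where the
  onset amplitude itself is the quantity of interest.

F0 ≤ 0 is rejected as corrupted input rather than silently producing
infinite ratios.

### Event detection and frequency

Following the 2-sigma convention, sigma is the standard deviation of the
full dF/F0 series and the baseline is its median (the source convention
names "the baseline" without defining it; the median is robust to the
events themselves). An event is a maximal run of consecutive samples
above `baseline + 2 sigma`, scored once at its maximum. Constant traces
define sigma = 0 and yield zero events. A MAD-based sigma
(`sigma_method = "mad"`), a minimum run duration and a refractory gap are
available but all off by default: the default is the literal reading.
Frequency is events per second over the analysis window, with the window
an explicit argument because the original analysis window is unstated.

This estimator is biased low at high rates: distinct events closer than
the excursion duration merge into one run, and because sigma includes
the event-driven variance the threshold rises with activity. The
generator calibration below quantifies this.

### Power spectra

The periodogram of the mean-subtracted series uses a rectangular window
and is normalized as a one-sided density: `sum(power) * df` equals the
population variance (Parseval, checked to 1e-6 relative in the tests).
Averaging across traces is a pointwise mean with SEM = sd/sqrt(n),
requiring equal lengths and rates. Welch-style segment averaging was
deliberately not made the default because no windowing details are
stated for the original analysis.

### Response metrics

For stimulation experiments, `response_metrics()` reports: `dff_max`,
the maximum dF/F0 inside the stimulation windows; `undershoot`, the
minimum dF/F0 within a post-offset window minus the pre-stimulus
baseline (mean over 2 s before onset) — negative values mean the
response dipped below the pre-stimulus level; and `return_time`, the
first post-offset time at which dF/F0 falls to or below that baseline
(`NA` if not reached within the window). The undershoot/return-time
formalization is this package's own; the source describes the
phenomenon qualitatively.

## Image preprocessing

The stated preprocessing chain is mean filter (radius 2 px) followed by
rolling-ball background subtraction (radius 50 px). The mean filter uses
a Euclidean disk neighborhood (the "radius" semantics of mainstream
image tools; a square option exists) with edge truncation. The rolling
ball is implemented as grayscale opening with a spherical-cap
structuring element whose height defaults to the radius in intensity
units — the intensity scaling of the ball is not standardized anywhere,
so it is exposed as a parameter. Opening guarantees background <=
image, hence a non-negative corrected image; the tests verify exact
agreement with a brute-force erosion-then-dilation oracle.

Because no TIFF package ships with the target environment, the package
includes a minimal baseline TIFF 6.0 codec (uncompressed little-endian
grayscale, multi-page, 32-bit float or 8/16-bit unsigned) verified by
round trip.

## The synthetic calcium world

`simulate_calcium_trace()` draws Poisson event times (optionally with a
sinusoidal rate modulation for rhythmic activity), log-normal amplitudes
in dF/F0 units, and convolves them with a unit-peak
difference-of-exponentials kernel:

F(t) = B (1 + sum_i a_i k(t − t_i)) + drift · t + N(0, noise_sigma).

Stated-world defaults and their provenance:

| parameter | default | why |
|---|---|---|
| `event_rate` | 0.9 /s | wild-type median prior-activity frequency (mutant-like: 0.06 /s) |
| `event_amplitude_mean` | 0.413 dF/F0 | 61.1% of the wild-type evoked maximum 0.676 |
| `event_amplitude_cv` | 0.1 | calibration study, below |
| `kernel_rise_tau` | 0.05 s | fast indicator rise |
| `kernel_decay_tau` | 0.12 s | calibration study, below |
| `sample_rate` | 20 /s | imaging acquisition rate |
| `duration` | 60 s | one recording |
| `baseline_level`, `noise_sigma` | 100, 1 | camera units; noise-induced dF/F0 sd 0.01, SNR >= 5 versus 0.413 events |

**Calibration study (done once, then frozen).** The recovery requirement
— the median detected frequency within ±20% of the generator rate for
rates 0.3 and 0.9 /s — constrains the kernel and amplitude spread,
because the 2-sigma run detector merges events that overlap and loses
events below a threshold that itself grows with activity. With a 0.4 s
decay (a common slow-indicator figure) the median recovery at 0.9 /s is
only ~0.3/s regardless of amplitude spread: the detector, applied
exactly as specified, cannot count overlapping events. The expected
excursion rate for run-counting is approximately
`lambda * exp(-lambda * t_run)`, so recovery at 0.9 /s needs run
durations well under 0.25 s. We therefore fixed `kernel_decay_tau` at
0.12 s — the fast edge of reported single-event decay for fast
indicators — and `event_amplitude_cv` at 0.1, giving median recoveries
0.067 / 0.250 / 0.750 events/s at true rates 0.06 / 0.3 / 0.9 and mean
prior-to-evoked ratios of 63–68%. These values were frozen before the
acceptance tests were written and are not revisited. What a green
recovery test establishes is that the analysis chain is calibrated for
*this* stated world of brief, well-separated, narrowly dispersed
transients; it does not establish that the 2-sigma method is unbiased on
slower indicators or bursty activity — on those it undercounts, which is
a property of the method, not of this implementation.

The stimulus-response generator is phenomenological: during
stimulation, either a sustained level with AR(1) fluctuation
(wild-type-like) or an exponential adaptation from the onset gain
(mutant-like); after offset, either a below-baseline undershoot
recovering exponentially, or a slow exponential return to baseline from
above. Closed forms for all noiseless cases are asserted in the tests
(e.g. the residual `exp(-18/6)` of the onset gain at the end of an 18-s
stimulus with a 6-s adaptation constant).

## The synthetic behavior world

`simulate_trajectories()` places the stated ten larvae at the center of
a 5-cm-radius plate and tracks them at 1 frame/s for 300 s. Locomotion
is a persistent random walk: per-frame heading change N(0, (1 −
persistence) π) with persistence 0.9, gamma-distributed step lengths
with mean 0.1 cm/frame (a realistic crawl speed), and specular (radial)
reflection at the dish wall — wall behavior is this package's choice, as
no source describes it.

Boundary decisions are drawn **once per band visit**, not per frame,
matching how discrete approach outcomes are scored by a human observer:
when a larva enters the 0.5-cm band around a quadrant-boundary line from
side S, a single Bernoulli draw decides turn-back versus cross
(wild-type-like turn-back 0.955 from the lit side; mutant-like 0.51;
dark-side entry probability 0.75). The drawn outcome is then enforced on
the realized path — a pending turn-back reflects any step that would
flip the larva's lit/dark flag (both lines matter near the center), and
a completed cross is committed — so the ground-truth event list and the
trajectory are always consistent, and the >=95% event-agreement test
genuinely tests the analyzer. The first excursion from the center band
is unscored on both sides (the larva starts *on* the boundary corner).

The analyzer (`detect_boundary_events()`) re-derives events from
positions alone with the same band rule: a visit opens on band entry,
closes as *cross* if the lit flag flips inside the band, as *turn-back*
if the larva exits on its origin side, and one outcome is scored per
visit. A visit older than `max_dwell` (10 s) without a flip closes as
turn-back — the source scored manually and states no criterion, so both
the band width and the dwell limit are explicit parameters.

### Performance index

PI = (positions in lit quadrants − positions in dark) / total counted
positions, pooled over larvae and frames. Positions exactly on a
boundary line belong to neither side and are excluded from numerator
*and* denominator, avoiding tie-break artifacts. The literal reading of
the source formula divides by "the total number of larvae", which does
not normalize frame counts and escapes [−1, 1]; it is available as
`denominator = "larvae"` but is not the default, since the published
PI axis is clearly bounded by [−1, 1].

## Statistics

* **Wilcoxon rank-sum**: exact mode (default up to combined n = 20)
  builds the full permutation distribution of the group-1 rank sum over
  doubled mid-ranks by dynamic programming and reports twice the smaller
  tail, capped at 1; ties are handled exactly, not approximately. The
  normal approximation applies the tie-corrected variance and a 0.5
  continuity correction.
* **Fisher's exact test**: two-sided p by the probability-mass rule (sum
  of all same-margin tables with probability <= observed, with a 1+1e-7
  relative tolerance), the convention of mainstream implementations.
  Degenerate margins give p = 1 with a warning.
* **Adjustments**: Bonferroni (`min(1, m p)`) and Benjamini–Hochberg
  step-up, with the family size `m` always an explicit argument because
  the number of comparisons behind published figure panels is unstated.
* **Box summaries**: type-7 quantiles. The published legend describes
  whiskers as "the data range" *and* shows outliers, which is
  self-contradictory; the default is Tukey 1.5 IQR whiskers with
  outliers, and a `"range"` mode (whiskers to extremes, no outliers) is
  provided.

## Pipeline and determinism

`run_experiment()` composes a whole experiment from one config (JSON or
list): generators → quantification → tests → tables, manifest and log.
All randomness flows from the single config seed through a deterministic
linear-congruential child-seed scheme (`derive_seed`), so identical
configs give byte-identical outputs; no function touches the global RNG
state (each generator saves and restores `.Random.seed`).

## Known limitations

* The generators state a world, not the recordings: real prior activity
  may be bursty, rhythmic or amplitude-heteroscedastic in ways the
  Poisson/log-normal model is not; the recovery guarantees quantified
  here do not transfer to such data.
* The 2-sigma run detector saturates near ~1 event/s at these kernel
  time constants; frequencies beyond that are reported but biased low.
* The trajectory model has no posture, no head casts and no
  run/turn state; it reproduces occupancy and boundary-outcome
  statistics only.
* `performance_index` at the default excludes on-line positions, which
  with real tracking data (finite precision) is a measure-zero set;
  with synthetic integer-free coordinates it never triggers.
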