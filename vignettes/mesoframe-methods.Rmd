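---
title: "Models and methods behind mesoframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesoframe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`mesoframe` quantifies memory-guided navigation and its frontal-cortical
correlates: spontaneous alternation in a Y-maze, position-binned ensemble
activity of neurons recorded with a head-mounted miniature microscope at
30 Hz, responses of the mesofrontal circuit to stimulation, and the
anatomy of dopaminergic axons and synaptic boutons in confocal sections.
Every stage has a seeded synthetic-data generator with exhaustive ground
truth, so the whole pipeline is testable without any recording.

This vignette explains the models each stage assumes, the parameters that
matter, the numerical conventions, and the design choices that were
genuinely open.

```{r setup}
library(mesoframe)
```

## Spontaneous alternation

A mouse exploring a three-arm maze tends to visit the arm it has seen
least recently. The score is computed from the entry letter sequence:
a *triplet* of consecutive entries counts as alternating when its three
arms are pairwise distinct, and

$$\mathrm{alternation\ \%} = 100 \times
  \frac{\#\,\text{alternating triplets}}{\#\,\text{entries} - 2}.$$

Because consecutive entries never repeat, a triplet alternates exactly
when its third arm differs from its first. An agent that chooses
uniformly between the two available arms takes the new arm with
probability 1/2, so chance level is 50%:

```{r chance}
e <- simulate_arm_entries(behavior_sim_config(p_alternate = 0.5, seed = 1),
                          n_entries = 10000)
score_alternation(e)
```

The generator's entry process is first-order Markov on (previous arm,
current arm): the next entry is the new arm with probability
`p_alternate`, otherwise the previously visited arm, never the current
one. This is the minimal process whose alternation statistic equals
`p_alternate` exactly, and successive triplet outcomes are independent,
so the score of a simulated sequence is a binomial proportion — which is
what the calibration tests rely on. Sessions with fewer than three
entries report the score as missing and are excluded from group means.

### From video tracking to entries, trials and bins

The package consumes a centre-of-mass position series in maze
coordinates (cm). Three conventions, all configurable, operationalize
definitions that a tracked centroid cannot reproduce verbatim:

* **Entry** (`detect_arm_entries`): the centroid must penetrate beyond
  `entry_fraction` (default 0.2) of the arm length from the centre. This
  stands in for "all four paws entered"; brief pokes do not count.
* **Stopped** (`segment_trials`): speed below `stop_speed` (default
  2 cm/s) sustained for 0.5 s, measured over a 0.2 s window so tracking
  jitter does not masquerade as movement. A trial runs from the last
  frame at the origin terminal to the first stopped frame at the
  destination terminal; traversals that never reach the destination
  terminal are counted and excluded.
* **Bins** (`bin_position`): the path-length coordinate from origin
  terminal (0) to destination terminal (1) is split into 20 half-open
  equal bins, the top bin closed, 1-based, in the direction of travel.
  With equal arm lengths the maze centre sits exactly on the bin 10/11
  boundary, so "before the centre" means bins at or below 10.

A trial is labelled alternating when its destination completes a
non-repeating triplet; the first trial of a session is unlabelled.

## Calcium traces

### ΔF/F0 and events

Raw fluorescence is converted to ΔF/F0 with F0 either the session mean
(navigation sessions) or the mean of the first 15 s (stimulation
series). The event detector looks for the rising phase of calcium
transients: the first derivative of ΔF/F0 — the least-squares slope over
a centred 200 ms window — must cross zero upward and exceed 5× the
baseline SD of the derivative before its next downward crossing; the
event ends at the trace's local maximum there, and is kept only if the
trace at that point exceeds 3× the baseline SD of the trace. Event
magnitude is the ΔF/F0 difference between end and start.

Two readings of "5 standard deviations of baseline fluctuation" are
possible for the rise rule — the derivative's own SD, or the trace SD
applied to the cumulative rise. The package implements the
derivative-SD reading (both SDs live in `baseline_stats()`); the
alternative would make the 3-SD peak rule redundant. Baseline SDs are
estimated robustly as 1.4826 × MAD over the full trace, per neuron:
events are sparse, so the MAD tracks the event-free baseline. The peak
criterion is measured relative to the trace median, which makes
detection invariant to adding a constant — ΔF/F0 traces are zero-based,
so this changes nothing for well-formed input while keeping the
invariance exact.

Numerical conventions: ties at derivative zero-crossings resolve to the
earlier frame; events separated by fewer than 2 frames are merged; the
derivative window must span at least 2 frames; trace edges get zero
derivative, so no event can start in the first or last window.

With a 200 ms window at 30 Hz, the largest windowed slope a transient
can produce is about (amplitude / 0.2 s), while the 5-SD derivative
threshold sits at ≈ 0.94 of that value for a transient of 6× the noise
SD — the detector's sensitivity floor is therefore right at 6× noise,
and validation uses transients of ~10× noise SD (generator defaults:
amplitude 0.5 ΔF/F0, noise SD 0.05, typical of GCaMP6s miniscope data),
where recall and precision both exceed 0.95. In the accuracy benchmark,
ground-truth impulses closer than 10 frames are counted as one event:
impulses inside one derivative window form a single rising phase, which
is the unit the detector (and the rising-phase definition itself)
reports.

### Component selection and background subtraction

Spatiotemporal decomposition of movies is delegated to standard
PCA/ICA tooling; the package implements the *selection* criteria:
components whose temporal skewness is below 1 are rejected (calcium
signals rise fast and decay slowly, so genuine somatic signals are
positively skewed), and components whose brightest 5% of spatial-filter
pixels fall at least half inside the blood-vessel shadow mask are
rejected as blood-flow artifacts. Spatial filters are rectified at zero
before the overlap computation. Per-cell traces are extracted as the
soma-mask mean minus the median of a surrounding annulus, which removes
shared background drift exactly for spatially uniform contamination.

### The trace generator

`simulate_trace_set()` drives each neuron with a position-tuned event
rate: a Gaussian bump over track bins (width `tuning_width`, default 3
bins) centred on the neuron's tuning bin, rising from `baseline_rate`
(0.3 Hz) to `peak_rate` (1.5 Hz) — frontal neurons fire throughout the
task, unlike hippocampal place cells, hence the substantial baseline.
Events are impulses of fixed ΔF/F0 amplitude convolved with a
difference-of-exponentials kernel (rise 0.1 s, decay 1.0 s,
peak-normalized — a GCaMP6s approximation; the indicator choice is a
design decision, not data). Gaussian noise is added i.i.d. per frame.

One subtlety: the slow kernel smears binned activity forward along the
track, which would displace every measured tuning curve by one to three
bins. The generator therefore defines tuning on the *measured calcium
signal*: the event rate is driven by the bin the animal occupies a fixed
lag later, where the lag is the mode shift the kernel imposes on a bump
of the configured width (computed numerically per configuration). This
is anticipatory firing — consistent with premotor position coding — and
it makes "argmax of the binned map equals the tuning centre" hold for
interior bins. Terminal bins (1–2 and 19–20) remain contaminated by
dwell-period transients leaking across the trial boundary, so recovery
tests use interior tuning centres; real terminal bins carry the same
caveat.

## Ensemble analysis

`build_spatial_map()` averages each neuron's ΔF/F0 over the frames in
each bin, per trial, then across trials (all, alternating,
non-alternating). Bins a trial never visited are linearly interpolated
from neighbours and flagged. `peak_position_distribution()` reports the
proportion of neurons peaking in each bin (argmax ties break to the
lowest bin and are counted; constant neurons are excluded and counted)
with Wilson score confidence intervals — the score interval behaves
sensibly at the near-zero proportions most bins have. For raster
displays each row is normalized to its own maximum; statistics always
use unnormalized values.

### Alternation selectivity

For each neuron, `d(b)` is the difference between its mean alternating
and non-alternating maps at bin `b`; the neuron is *selective at b* when
`|d(b)|` exceeds 2 SDs of its differences at the 19 other positions. The
absolute value makes the rule two-sided (selectivity in either
direction); bins where the other-position SD is zero are flagged
degenerate.

This rule is self-normalizing: if the `d(b)` are i.i.d. normal,
`d(b)/sd(d(-b))` is exactly Student-t with 18 degrees of freedom, so the
per-bin chance rate is `2 * pt(-2, 18)` ≈ 6.1% (`selectivity_chance_rate()`)
*regardless of the noise scale*. Three consequences shape the design:

* **Neuron-level summary.** Over 20 bins, ~85% of null neurons are
  flagged *somewhere*, so "selective at any bin" is useless as a
  neuron-level label. The package defines the neuron-level flag as
  *selective at the neuron's own peak-activity bin*
  (`selective_at_peak`) — the position where Fig-style example traces
  show the differential activity — which has the 6.1% per-neuron chance
  rate.
* **Null calibration.** On cohorts of trial-noise-only maps
  (`simulate_spatial_map_cohort()` with `amp = 0`), no bin's selective
  proportion should exceed the Wilson upper bound of the chance rate;
  because that is a joint statement over 20 bins, the bound is taken at
  the Bonferroni-adjusted level `1 - 0.05/20`. The same simultaneous
  convention is used wherever all 20 bins are tested jointly against a
  single value (e.g. uniform-tuning peak proportions against 1/20).
* **Power.** With 20% of neurons given a gain of 2 on alternating
  trials, the neuron-level flag recovers the selective set with F1
  ≥ 0.8 at the map level, where trial noise is homoscedastic across
  bins. In full trace-level simulations, trial-to-trial variance
  concentrates at the tuning bin (event-count noise scales with rate),
  which inflates the peak-bin false-positive rate for *any* noise scale
  — a real limitation of the self-normalized rule on peaky tuning that
  the map-level calibration does not exhibit, and the reason the power
  analysis is defined at the map interface.

Group comparisons (`compare_peak_proportions`) use a Pearson chi-square
without continuity correction on the 2×2 table of neurons peaking (or
selective) inside versus outside an explicit `center_bins` window;
which bins count as "near the centre" is deliberately a required
argument, not a default. Neurons are pooled across animals within a
group, as in the cell-count reporting conventions of this literature;
per-animal tables are available for hierarchy-aware reanalysis.

## Stimulation-response summaries

Validation imaging summarizes overall cortical activity as the SD of
the ΔF/F trace and reports treatment effects as
`(SD2 - SD1)/SD1`. Stimulation time series are 115 frames at
0.351 s/frame with the stimulus 20 s after imaging start; F0 is the mean
of the first 15 s, and `stim_onset_frame()` places the onset at 0-based
frame `round(20/0.351) = 57` (1-based frame 58). The simulated response
is an instant-rise exponential decay whose peak scales linearly with
pulse count (`amplitude` is the peak at 10 pulses); pulse-count
saturation is deliberately not modelled.

## Morphology

Boutons are detected with a scale-normalized Laplacian-of-Gaussian at
σ = 0.8 µm, somata with the same filter at σ = 8 µm, and axons with a
multiscale Hessian ridge (tubeness) filter at σ ∈ {0.5, 1, 1.5} µm —
scales chosen from typical bouton, soma and axon dimensions, all
configurable. "k SD above background" thresholds are read as SDs of the
*raw background intensity*: the filter response must exceed its own
background mean by `k` × SD(raw background), where background pixels are
those inside the ROI but outside the dilated robust signal mask
(median + 2 MAD). Measuring the SD on the raw image rather than on the
filter response makes the three detectors behave consistently across
filter scales (a response-SD reading lets smoothed noise pass a 2-SD
cut, flagging structure in blank images).

The axon pipeline thresholds the ridge response, discards binary
fragments smaller than a 5 µm ribbon equivalent, thins the mask with
Zhang–Suen two-subiteration thinning, prunes skeleton spurs up to 4 px,
and sums length with the 1/√2 step convention (1 px for 4-neighbour
steps, √2 px for diagonals, corner shortcuts not double-counted), which
is unbiased for diagonal segments. Two corrections matter numerically:
the ridge response is regularized with a 2 px Gaussian before
thresholding, so the medial axis tracks the ridge centre rather than
boundary noise (unregularized skeletons wiggle and read 10–20% long);
and since pruning retracts every surviving terminal by the pruning
depth, that length is added back per remaining endpoint (removed side
spurs leave no endpoint and get no credit). Soma maxima closer than one
soma radius merge — two touching somata count as one, by design.

Per-animal aggregation sums counts and lengths across sections *before*
taking ratios (ratio of sums, not mean of ratios): bouton density =
total boutons / total axon length, axon per cell = total axon length /
total labelled midbrain cells, each also expressed as a percentage of
the control-group mean (the control group averages 100% by
construction). Animals with zero axon length or zero cells are flagged
and excluded. Boutons are counted from the green channel alone within
the ROI; requiring colocalization with red axon signal is exposed as an
option in spirit but off by default, since the green label is already
axon-targeted.

The image generator draws axons as cubic-spline-smoothed random walks
(heading SD 0.25 rad per 5 µm control step) with per-axon length jitter
of ±20%, stamps Gaussian boutons on the axons at the configured linear
density (counts are exact per axon: `round(length × density / 100)`),
and adds Gaussian background noise. Draws that run along an existing
axon or fold back onto themselves are rejected and redrawn: merged
ribbons make length unrecoverable for any centerline method, and the
generator's job is to be hard but solvable. Brief crossings are kept.

## Pipeline, seeding, determinism

`run_pipeline()` executes simulate → behavior → traces → ensemble →
report from a validated configuration (YAML or list; unknown keys and
missing stage dependencies are errors before anything runs). One global
seed deterministically derives a child seed per stage, so stages can be
rerun in isolation; every output is CSV or JSON with floats at 9
significant digits, and the manifest lists MD5 checksums — reruns with
the same configuration are byte-identical. All generator functions take
their seed from their configuration object and restore the caller's RNG
state.

## What the generators do and do not emulate

The behavior generator produces clean terminal-to-terminal runs at
constant speed with dwell pauses and centimetre-scale tracking jitter;
it does not produce mid-arm turnarounds, grooming bouts, or variable
running speeds, so trial segmentation is easier than on real video. The
trace generator uses a single fixed kernel and i.i.d. Gaussian noise; it
omits neuropil contamination, motion artifacts, and slow drift, so
event-detection scores here bound what cleaner preprocessing could
achieve, not what raw miniscope movies give. The image generator omits
stitching seams, uneven illumination and z-projection artifacts.
Passing tests demonstrate that the analysis code implements its
definitions correctly and recovers known structure under realistic
noise; they do not certify performance on degraded real recordings.

## Problem sizes

The shipped tests run sessions of 8–24 simulated minutes, populations
of 100–400 neurons, cohorts of 40–100 maps, 20 section images of
256×256 px at 0.5 µm/px, and 2,000-replicate statistical calibrations —
sizes chosen so the full suite completes in a few minutes on one core
while keeping binomial standard errors well inside the asserted
tolerances.
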