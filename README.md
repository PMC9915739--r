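# mesoframe

Analysis of memory-guided navigation and its mesofrontal circuit
correlates, for labs that pair Y-maze behavior with miniature-microscope
calcium imaging and confocal anatomy. The package covers four stages,
each with a seeded synthetic-data generator carrying exhaustive ground
truth, so the whole pipeline is testable end to end without any
recordings:

* **Behavior** — arm-entry detection from tracked positions, spontaneous
  alternation scoring, trial segmentation, and mapping of each traversal
  onto 20 track-position bins.
* **Calcium traces** — ΔF/F0 conversion, PCA/ICA component selection by
  temporal skewness and blood-vessel overlap, annulus background
  subtraction, detection of calcium-event rising phases, and
  activity/stimulation summaries.
* **Ensemble statistics** — position-binned activity maps, peak-position
  distributions with Wilson confidence intervals, alternation-selective
  neurons, and chi-square group comparisons.
* **Morphology** — Laplacian-of-Gaussian bouton and soma detection,
  Hessian ridge axon skeletonization with calibrated length measurement,
  and per-animal normalized metrics (bouton density per axon length,
  axon length per labelled cell, percent of control).

## The statistics at the core

Spontaneous alternation over an entry sequence with `n` entries:

    alternation % = 100 x (# non-repeating triplets) / (n - 2)

with chance level 50% for a uniform-random navigator (two available
arms, one of them new).

Calcium events are rising phases of ΔF/F0: start at an upward
zero-crossing of the 200-ms-window derivative that then exceeds 5 SD of
the baseline derivative, end where the derivative turns negative,
accepted if the trace there exceeds 3 SD of baseline; magnitude is the
ΔF/F0 difference between end and start.

A neuron is *alternation-selective* at track bin `b` when
`|d(b)| > 2 sd({d(j) : j != b})`, where `d` is the difference between
its mean alternating and non-alternating binned activity. Under an
i.i.d. normal null this self-normalized rule has a fixed per-bin chance
rate of `2 * pt(-2, 18)` ≈ 6.1% (`selectivity_chance_rate()`); see the
methods vignette for the calibration consequences.

Morphology metrics per animal are ratios of sums across sections:
`bouton_density = Σ boutons / Σ axon length`,
`axon_per_cell = Σ axon length / Σ cells`, each expressed as a
percentage of the control-group mean.

## Worked example

```r
library(mesoframe)

## one 8-minute session of a well-performing animal
cfg     <- behavior_sim_config(p_alternate = 0.67, seed = 42)
traj    <- simulate_trajectory(simulate_arm_entries(cfg), cfg)
entries <- detect_arm_entries(traj)
score_alternation(entries)
#> Alternation: 56.8% (25/44 triplets, 46 entries)

trials <- segment_trials(traj, entries)
nrow(trials)          # 45 terminal-to-terminal trials

## 80 neurons, 20% with alternation-dependent gain
tc  <- trace_sim_config(n_neurons = 80, frac_selective = 0.2, seed = 42)
sim <- simulate_trace_set(traj, tc, trials = trials)
nrow(detect_events_all(sim$traces))
#> [1] 2193            # calcium events across the population

map <- build_spatial_map(sim$traces, sim$trials, sim$bins)
peak_position_distribution(map)
#> Peak-position distribution: 80 neurons (0 excluded, 1 ties)
#>   modal bin 4 (proportion 0.138)

sel <- alternation_selectivity(map)
sum(sel$selective_at_peak)
#> [1] 32              # flagged at their peak bin (16 were injected;
                      # trace-level flags run hot — see the vignette)

## a confocal section with known anatomy
img <- simulate_morphology_image(image_sim_config(seed = 42))
detect_boutons(img)$count                     # 19 (truth: 19)
round(detect_axons(img)$length_um, 1)         # 388.9 um (truth: 369.4)

## group comparison, pooled-variance t with Shapiro-Wilk check
two_sample_t(c(67.2, 64.1, 70.3, 66.0, 69.5),
             c(55.1, 52.8, 58.7, 50.9, 54.4))
#> t(8) = 7.560, p = 6.543e-05  (means 67.4 vs 54.4)
```

The 56.8% score against a 67% generator setting is ordinary binomial
noise at 44 triplets (SE ≈ 7 points); calibration tests run 5,000–10,000
entries where the estimate pins down.

An end-to-end run with manifest and logs:

```r
run_pipeline(demo_config(seed = 1), "out/demo")
```

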