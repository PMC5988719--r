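# ornpulse

Quantification of **prior (pre-stimulus) and optogenetically evoked
activity** in *Drosophila* larval olfactory receptor neurons (ORNs), and
of the **optogenetic four-quadrant choice assay** — as a tested, seeded,
end-to-end reproducible R pipeline.

Larval ORNs show calcium fluctuations before any defined stimulus
("prior activity"), which depends on the olfactory receptor complex:
*Orco* co-receptor mutants lose it almost entirely, and also behave
differently when their ORNs are driven optogenetically. Analyzing that
phenomenology takes four quantification families, all implemented here:

1. **Trace analysis.** dF/F0 = (F − F0)/F0 with F0 either the mean of
   the lowest quartile of samples (spontaneous recordings) or the mean
   of nine frames from stimulus onset (stimulation recordings). Events
   are maximal runs of dF/F0 above `median + 2σ` (σ = s.d. of the whole
   series), frequency is events/s, and one-sided periodograms
   (Parseval-normalized) are averaged across traces with SEM bands.
   Stimulus-response metrics: maximum dF/F0 in the stimulation window,
   post-offset undershoot relative to the pre-stimulus baseline, and
   return time to baseline.
2. **Imaging preprocessing.** Disk mean filter (radius in px) followed
   by rolling-ball background subtraction (grayscale opening with a
   spherical-cap element), then ROI mean-intensity extraction; TIFF
   stack and tabular trace I/O.
3. **Behavior.** Quadrant assignment in a circular arena, performance
   index PI = (n_lit − n_dark)/n_total over a 5-min assay, and boundary
   approach events classified as *cross* or *turn back* with entry
   (dark→lit) and turn-back (lit side) probabilities.
4. **Statistics.** Exact Wilcoxon rank-sum (full permutation
   distribution, mid-ranks under ties), Fisher's exact test
   (probability-mass two-sided rule), Bonferroni and Benjamini–Hochberg
   adjustment, and box-plot summaries.

A **synthetic-data module** generates calcium traces (Poisson events ×
double-exponential kernel), stimulus responses, image stacks and arena
trajectories (persistent random walk with per-approach Bernoulli
boundary decisions), each with ground truth, so every stage has a
parameter-recovery test. See `vignettes/ornpulse-methods.Rmd` for the
models, the calibrated defaults and the design choices.

## Worked example

Simulate wild-type-like (0.9 events/s) and mutant-like (0.06 events/s)
recordings, quantify prior-activity frequency, and test the contrast:

```r
library(ornpulse)

wt <- sapply(1:20, function(i) {
  sim <- simulate_calcium_trace(calcium_sim_params(event_rate = 0.9, seed = i))
  event_frequency(detect_events(compute_dff(sim$trace, "prior_percentile")))
})
orco <- sapply(1:20, function(i) {
  sim <- simulate_calcium_trace(calcium_sim_params(event_rate = 0.06, seed = 100 + i))
  event_frequency(detect_events(compute_dff(sim$trace, "prior_percentile")))
})
box_summary(wt)
#> <box_summary: median 0.725 [Q1 0.6667, Q3 0.7792], whiskers 0.5833..0.9333, 0 outlier(s)>
box_summary(orco)
#> <box_summary: median 0.05833 [Q1 0.05, Q3 0.07083], whiskers 0.03333..0.08333, 4 outlier(s)>
rank_sum_test(wt, orco, mode = "normal_approx")
#> <wilcoxon_rank_sum_normal_approx: statistic = 400, p = 6.153e-08 (adjusted 6.153e-08, none), n = 20/20>
```

The wild-type-like group's median lands near the generator rate (the
2σ run counter is slightly conservative at high rates — quantified in
the vignette), the mutant-like group sits an order of magnitude lower,
and the rank-sum test separates them decisively (U = 400 is the maximum
possible for 20 vs 20: complete separation).

The choice assay, with the wild-type-like turn-back probability 0.955:

```r
sim <- simulate_trajectories(behavior_sim_params(p_turn_back_lit_to_dark = 0.955, seed = 1))
performance_index(sim$trajectories, arena_config())
#> <PI = +0.581 (lit 2364, dark 626, total 2990; 10 larvae)>
ev <- detect_boundary_events(sim$trajectories, arena_config())
boundary_probabilities(ev)$p_turn_back
#> [1] 0.9722222  # 36 lit-side approaches on this plate
```

A strong lit-side preference (PI = +0.58) emerges from the turn-back
bias alone; the re-detected turn-back probability matches the generator
setting within sampling error.

End-to-end runs from one config (tables, stats, manifest, log):

```r
run_experiment(list(experiment = "choice_assay", seed = 7), "results/choice")
```

or from the command line via the installed script:

```sh
inst/exec/ornpulse run --config cfg.json --out results/
inst/exec/ornpulse simulate traces --out sim/ --seed 3 --n 10
```

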