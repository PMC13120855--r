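# dyadica

Quantification of social behavior in interacting flies, starting from
frame-indexed action-bout annotations.

Comparative studies of fly social behavior reduce video of interacting
animals to *bouts* — intervals during which one fly performs one scored
action (lunge, unilateral wing extension, ovipositor extrusion, ...).
`dyadica` owns everything downstream of that reduction, for researchers in
computational ethology and fly social behavior:

* **Ethograms** — action nodes with frequencies normalized to summed bouts,
  and first-transition edges within a 1 s cutoff;
* **Expressivity traces** — sliding-window fraction of frames in an action,
  with group mean ± SEM envelopes;
* **Scalar metrics** — time fractions, events/min, latencies (censored at
  assay end), cumulative event curves;
* **Social indices** — all built on the difference-over-sum convention:
  target preference `(t1 − t2)/(t1 + t2)`, dominance ("one-sidedness")
  `|tA − tB|/(tA + tB)`, normalized ovipositor extrusion, a group
  receptivity index from strictly binarized acceptance/rejection, and
  pair→trio priming concordance;
* **Photostimulation analyses** — protocol objects (the canonical 2 min
  baseline + six 30 s blocks + 1 min IBI frequency ramp), exact
  baseline/ON/IBI/post frame partitions, PS−/PS+ aggregation, onset-locked
  suppression curves with a ±0.5 s qualification filter, sham persistence
  baselines (fraction of bouts strictly > 2 s), penetrance/expressivity;
* **Courtship song** — peak refinement (max |amplitude| in a 20 ms window)
  and pulse/clack train segmentation (gaps strictly < 0.2 s / 0.4 s);
* **Place preference** — median background modeling, blob detection,
  normalized arm occupancy excluding the central bowl;
* **Statistics** — Mann-Whitney/KS/Kruskal-Wallis wrappers, hand-rolled
  Dunn post-hoc tests with compact letter displays, Benjamini-Hochberg
  correction, Cohen's d, Tukey outlier fences (flag, never remove);
* **A semi-Markov simulator** with known ground truth (renewal bout
  generation, dominance asymmetry, copulation hazard, photostimulation
  gain/persistence, song synthesis, biased arena walks) backing every
  oracle test.

Preprocessing follows the field's conventions exactly: minimum bout
duration `round(min_s × frame_rate)` frames, inclusive (0.5 s ⇔ 15 frames
at 30 Hz), and truncation of all analysis at copulation with the copulation
latency as the normalization denominator.

## Worked example

Simulate a 20-minute male-male dyad with a dominance asymmetry, then
quantify it:

```r
library(dyadica)

pr <- behavior_profile(
  c(UWE = 0.05, lunge = 0.02),                       # initiations / s
  dwell = tibble::tibble(action = c("UWE", "lunge"),
                         shape = 2, mean_s = c(2, 0.5)),
  delta = 0.4)                                       # fly A favored

sim <- simulate_dyad(pr, pr, duration_s = 1200, seed = 42)
sim$trial
#> <dyadica_trial 'sim_dyad'> dyad assay, 30 Hz, 36000 frames (1200.0 s), 2 flies

fraction_time(sim$bouts, "UWE", sim$trial$duration)
#> [1] 0.1809167
event_rate(sim$bouts, "lunge", sim$trial$duration, 30)
#> [1] 2.05

pf <- fraction_time(sim$bouts, "UWE", sim$trial$duration, per_fly = TRUE)
dominance(1200 * pf$fraction[pf$fly_id == "A"],
          1200 * pf$fraction[pf$fly_id == "B"])
#> # A tibble: 1 × 5
#>    bias dominant    tA    tB defined
#>   <dbl> <chr>    <dbl> <dbl> <lgl>
#> 1 0.179 A         135.  93.9 TRUE

glance(build_ethogram(sim$bouts, frame_rate = 30))
#> # A tibble: 1 × 4
#>   n_actions n_bouts n_edges window_s
#>       <int>   <int>   <int>    <dbl>
#> 1         2     156       4        1
```

The pair performed UWE 18.1% of the interaction and lunged about twice a
minute; fly A (the `delta`-favored fly) holds a courtship dominance bias of
0.18; the ethogram summarizes 156 bouts into 2 nodes and 4 first-transition
edges. `tidy()` returns the edge table, `autoplot()` draws the graph, and
the same bout tibble feeds every other metric.

Bout tables round-trip through a flat CSV + JSON sidecar
(`write_bout_table()` / `read_bout_table()`), with all invariants —
known actions, positive half-open intervals, no same-fly same-action
overlap — enforced on read.

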