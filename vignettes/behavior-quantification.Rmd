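---
title: "Quantifying dyadic social behavior from bout annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic social behavior from bout annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadica)
library(tibble)
```

## The data model

Everything in `dyadica` starts from a *bout table*: a flat record of who did
what, when. Upstream tracking and classification (pose trackers, supervised
behavior classifiers, or manual annotation) reduce a video of interacting
flies to intervals during which one fly performs one action — a lunge, a
unilateral wing extension (UWE), an ovipositor extrusion. We deliberately do
not touch video or classifiers here; the package consumes their output and
owns everything that happens after.

Frames are 0-based and intervals half-open `[start, end)`. This makes
adjacency unambiguous (a bout ending at frame 100 and one starting at frame
100 do not overlap, and together cover exactly their summed frames) and
makes clipping at a copulation onset a single `pmin`. A bout's duration in
seconds is `(end - start) / frame_rate`; standard video runs at 30 Hz and
the y-maze camera at 45 Hz.

Two preprocessing rules are applied before any metric:

* **Minimum bout duration.** Classifier output for UWE is filtered to bouts
  lasting at least 0.5 s. The threshold in frames is
  `round(min_s * frame_rate)` — 15 frames at 30 Hz — and the comparison is
  inclusive, so a bout of exactly 15 frames survives. Computing the
  threshold by rounding (rather than flooring a real-valued product) is
  what makes the 0.5 s ⇔ 15 frame equivalence exact.
* **Copulation truncation.** For male–female pairings, analysis ends at
  copulation when it occurred: straddling bouts are clipped, later bouts
  dropped, and the copulation latency replaces the recording length as the
  normalization denominator everywhere. The operation is idempotent, and
  the test suite asserts that every metric computed after truncation equals
  the same metric on a manually cropped table.

Copulation lives in the trial metadata, not in the bout list: a
"copulation attempt" is an ordinary bout, while the terminal copulation
event is a property of the trial.

## Ethograms

```{r ethogram}
b <- tibble(fly_id = "A", action = c("lunge", "UWE"),
            start = c(0L, 45L), end = c(30L, 60L))
build_ethogram(b, frame_rate = 30)
```

Nodes are per-action bout counts pooled over the two flies of a pair,
normalized by the total scored bouts. Edges are *first transitions*: for a
bout of action A by fly f, the destination is the action of f's earliest
subsequent bout starting within 1 s (inclusive) of A's end, and the edge
weight is the fraction of A bouts with that destination. Three choices here
were genuinely open:

* **Within-fly transitions.** A transition is a property of one
  individual's action sequence, not of the pair's interleaved timeline.
  This is the conservative reading; the alternative (crossing flies) would
  conflate sequencing with turn-taking.
* **First successor only.** When a bout is followed by two different
  actions inside the window, only the earliest counts. Under this rule each
  bout contributes at most one transition, so per-origin outgoing weights
  sum to at most 1. The multi-edge variant is available via `rule = "all"`.
* **Self-transitions allowed**, since repeated same-action bouts are real
  structure (e.g. chains of lunges).

The first-transition computation is validated against a brute-force
double-loop scan of the same bout list — an independent implementation that
must agree exactly, bout for bout.

## Expressivity traces and scalar metrics

`sliding_fraction()` computes, per frame, the fraction of frames within a
centered window (10 s by default) annotated as the action. At trial edges
the window is truncated and the denominator renormalized to the available
frames: without renormalization every trace would ramp artificially toward
0 at both ends. One consequence worth knowing: with renormalization the
trace mean is only approximately the overall time fraction (edge frames are
reweighted); the identity becomes exact when the window covers the whole
trial from every center, which the tests assert.

Scalar metrics are deliberately plain: `fraction_time()` is the union
length of an action's bouts over the effective duration (union, so pooling
two flies can never exceed 1); `event_rate()` is bouts per effective
minute; `latency()` is the first onset in seconds, censored at the
effective duration when the action never occurs. Censored latencies are
flagged and retained — they enter rank tests at their censoring value, the
usual convention for fixed-length assays. `cumulative_event_curve()` turns
a set of latencies into the nondecreasing fraction-responded step function
whose final value is the event rate.

## Social indices

All indices share one convention, difference over sum:

* preference for target 1 over target 2: `(t1 - t2) / (t1 + t2)`;
* normalized ovipositor extrusion: `(t_OE - t_UWE) / (t_OE + t_UWE)`,
  female rejection scaled against male courtship drive;
* dominance ("one-sidedness") of a behavior within a pair:
  `|tA - tB| / (tA + tB)`, in `[0, 1]`. The absolute form is an
  assumption — it is consistent with the signed preference formula and
  with a `[0, 1]` axis, but a signed variant is trivially recoverable from
  the per-fly times that every result carries.

Degenerate cases are explicit: an index with a zero denominator is
undefined and flagged, never silently 0, and undefined entries are excluded
from group statistics.

The receptivity index binarizes each female strictly — acceptance present
when wing-spreading time is positive, rejection present when normalized OE
exceeds −0.25 — and averages the per-female differences, so each female
contributes 1, 0 or −1. Both inequalities are strict, so a normalized OE of
exactly −0.25 counts as rejection-absent. A female with neither
wing spreading nor any OE/UWE signal is unscorable and excluded; only if
every female is unscorable is the group index undefined.

Priming concordance compares male–male courtship dominance in a pair phase
with female-directed dominance after a female joins. Pairs with under 20 s
of male-directed courtship are filtered out; the pair-dominant fly's
trio-phase signed dominance must be strictly positive to count as
concordant (ties and courtship-free trios are non-concordant — a
conservative convention that affects only zero-measure events in
continuous data). A configurable high-bias threshold (default 0.8) is
reported separately and never gates the main fraction.

## Photostimulation analyses

`ps_protocol()` represents optogenetic light delivery as non-overlapping ON
blocks over a pre-stimulus baseline. The canonical assay is
`make_ramp_protocol()`: a 2 min baseline, then six 30 s blocks at
monotonically increasing pulse frequency with 1 min inter-block intervals,
putting onsets at 120, 210, 300, 390, 480 and 570 s. The default frequency
ladder is {1, 2, 5, 10, 20, 40} Hz — the endpoints and monotone ramp are
fixed by the assay design, the interior rungs are a configurable default.
Pulse width and intensity are carried through serialization as labels;
analyses treat ON blocks as plain intervals.

`segment_masks()` partitions every frame into baseline / ON / IBI / post
(asserted to be an exact partition), and `aggregate_by_segment()` pools
them by the reporting convention: PS− is the baseline only; PS+ means the
ON blocks cumulatively for courtship but the light-off segments (IBIs plus
post-final) for aggression, which is expressed mostly after the light goes
off.

`ps_locked_fraction()` builds the onset-aligned suppression curve: a
(trial, block) event qualifies when an action bout overlaps
`[onset − 0.5 s, onset + 0.5 s]` — the literal, symmetric reading of
"spontaneous courtship within 0.5 s of onset" — and qualifying events'
binary action indicators are averaged over a window around the onset. The
6 s window is registered as `[−1 s, +5 s]` by default; the exact
registration was an open choice, so both bounds are configurable. The
implementation is held to exact equality with a brute-force per-frame
indicator average in the tests.

The sham baseline is the fraction of spontaneous bouts lasting strictly
more than 2 s (a 2.0 s bout does not count), and `suppression_summary()`
reports, per condition, the fraction of qualifying bouts that persist
through the entire ON block — any monotonicity in intensity is an empirical
finding, never an assumption.

## Song

Song analysis consumes coarse manual annotations plus the waveform; no
automatic event detection is attempted. `refine_peak()` finds the maximum
signal intensity in a 20 ms window centered on each annotation. Intensity
is the absolute amplitude by default because song pulses are biphasic — the
larger lobe may be negative; a signed mode exists. Ties resolve to the
earlier sample, and a perfectly flat window returns the annotation point
itself. `segment_trains()` chains same-type events whose consecutive gaps
are strictly below the type threshold (200 ms for pulse, 400 ms for clack);
chaining is equivalent to single-linkage clustering, and the tests hold it
to exact agreement with an O(n²) transitive-closure oracle. Thresholds are
strict: a gap of exactly 200 ms splits.

## Place preference

The y-maze pipeline is classical background subtraction: per-pixel median
over an evenly spaced frame subset (exact wherever a moving fly occupies a
pixel in under half the subset), absolute-difference thresholding (with an
Otsu fallback), connected-component labelling via EBImage, and centroids of
components above a 5 px minimum area. Multi-fly frames are scored per
centroid without identity tracking, pooling all positions. Normalized
occupancy is `(t_left - t_right) / (t_left + t_right)` over frames falling
in either arm mask — the central bowl is excluded — matching the
package-wide difference-over-sum convention; a fraction-of-total variant
sits behind `mode = "fraction"`.

## The simulator

No generative model of fly behavior is fitted anywhere in this package; the
simulator exists to provide data with *known* structure so that every
analysis has a ground-truth oracle. Its distributions are artifact choices,
flagged as such:

* **Semi-Markov renewal generation** rather than per-frame Bernoulli
  draws. Bouts are the native data structure, and renewal theory gives
  closed-form oracles: with initiation rate λ and mean dwell μ, the
  expected bout count over T seconds is `T / (1/λ + μ)`, and the expected
  trio preference index is `(λF μF − λM μM) / (λF μF + λM μM)`.
* **Dominance as a single scalar δ** scaling initiation `(1 + δ)` vs
  `(1 − δ)` for both courtship and aggression, so "the same fly courts and
  attacks more" emerges by construction.
* **Per-fly substreams** derived deterministically from the trial seed, so
  adding a fly never perturbs another fly's draws, and identical seeds give
  bit-identical output.
* **Photostimulation modulation by thinning**: time-varying initiation
  rates are simulated exactly (not discretized), with courtship multiplied
  by the ON gain inside blocks and aggression by `1 + A·exp(−Δt/τ)` after
  each offset. When the modulation is null the thinning bound equals the
  rate and no extra random draws are consumed, so a sham stimulated trial
  reproduces the protocol-free trial bit for bit — asserted in the tests.
* **Rounding**: continuous event times are rounded half-up to frames at
  the very end; zero-length bouts are discarded. Stimulus modulation
  affects initiation only — an ongoing bout's dwell is already drawn — so
  suppression of *ongoing* behavior is tested against hand-built bout
  tables rather than simulated ones.
* Song synthesis places carrier bursts under Gaussian envelopes with peaks
  snapped onto samples (so noiseless refinement must recover them within
  one sample); walks are reflected Gaussian steps confined to a synthetic
  dumbbell-shaped two-arm arena with an additive drift toward the odor arm.
  The arena geometry is invented; only the occupancy logic is under test.

What the simulator does *not* emulate — correlated actions between
partners, diurnal drift, classifier noise, acoustic realism beyond
peaks-and-gaps, real maze geometry — bounds what passing tests show: they
validate the *measurements*, not any claim about real flies.

## Statistics

The statistical layer wraps the standard nonparametric battery (Wilcoxon /
Mann-Whitney including the one-sample form, Kolmogorov–Smirnov,
Kruskal–Wallis, exact binomial) from base R, adds Benjamini–Hochberg
correction (held to exact agreement with an independently coded step-up
formula), and implements two pieces by hand: Dunn's post-hoc z-tests on
pooled ranks with tie correction, and Cohen's d with pooled n−1-weighted SD
and a normal-approximation CI. Compact letters come from the maximal
cliques of the non-significance graph, which makes the defining property —
two groups share a letter iff their adjusted p ≥ α — hold exactly rather
than approximately; the tests assert it pair by pair.

Conventions, each logged here because the alternatives were defensible:
quartiles for the Tukey outlier fences use linear interpolation (R type 7),
giving Q1 = 2, Q3 = 4 and an upper fence of 7 on {1, 2, 3, 4, 100};
outliers are *flagged only* and retained in every downstream computation;
the two-sample binomial comparison is the exact conditional
(hypergeometric) form for determinism; tests default to two-sided; stars
follow * < 0.05, ** < 0.01, *** < 0.001.

## Problem sizes and numerical checks

The validation suite runs its Monte-Carlo checks at sizes chosen to make
the oracles sharp while keeping a full run comfortably interactive:
preference-index recovery uses 200 seeds of 20-minute trios (the mean's
standard error is then ≈ 0.013 against a ±0.05 band); the ethogram oracle
runs on a kernel-driven chain of > 5000 bouts; segmentation and BH oracles
use 1000 random instances each and demand exact equality; type-I
calibration uses 500 replicate Mann-Whitney comparisons of 10 vs 10 null
dyads; tracking uses 80 rendered frames plus 50 ten-minute unbiased walks.
The same computations, re-run from scratch, back the numbers in
`scripts/acceptance.R`.

## Known limitations

* No identity-preserving multi-animal tracking; occupancy pools centroids.
* No classifier post-processing beyond the minimum-duration filter (no
  gap-bridging); none was assumed upstream either.
* The dominance and occupancy index formulas are stated conventions
  (difference over sum); variants are configurable but the defaults are
  what every test and example uses.
* Rank tests on censored latencies use the censoring-value convention
  rather than survival models; with heavy censoring a proper survival
  analysis would be preferable.
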