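---
title: "Quantifying circuitoid network activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circuitoid network activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitnet)
```

circuitnet quantifies the emergent population activity of stem-cell-derived
neural networks ("circuitoids") from calcium-imaging movies. This vignette
is the package's own account of the underlying procedure: what is computed,
under which assumptions, which constants matter, where genuine design
freedom existed and how it was resolved, and what the synthetic-movie
validation does and does not demonstrate.

## The analysis model

The pipeline treats a movie as a field of partially overlapping regions of
interest whose mean-intensity traces are noisy, low-pass observations of a
common underlying population process. Six stages follow, implemented by
`tile_rois()`, `extract_traces()`, `smooth_traces()`, `dff()`,
`pca_split()`, `detect_bursts_all()`, `catalog_bursts()`/`filter_catalog()`
and `build_graph()`/`complexity_score()`; `analyze_movie()` orchestrates
them.

**ROI lattice.** 11 × 11 px oval ROIs at 9 px spacing; on the standard
128 × 128 frame this yields a 14 × 14 lattice of 196 signals with slight
overlap between neighbours. The oval footprint is the ellipse inscribed in
the ROI square (center pixel included) — symmetric and reproducible, with
97 of 121 pixels inside.

**Smoothing and ΔF/F.** A centered running mean of `round(window_s × fps)`
frames, forced to an odd count so the window is symmetric; at the record
edges the window shrinks symmetrically rather than inventing padding
values. The ΔF/F baseline `F₀` is the per-trace 10th percentile: robust as
long as bursts occupy a minority of frames, and preferable to a mean or
minimum (the former is contaminated by bursts, the latter by noise).

**PCA split.** ROIs are the observations; each trace is mean-centered over
time, the centered matrix is decomposed by singular values, and the elbow
of the descending eigenvalue spectrum is located as the point of maximum
perpendicular distance from the line joining the first and last
eigenvalues (both axes normalized to [0, 1] — the triangle method, which
is otherwise sensitive to axis units). Component selection keeps the elbow
index **plus two**: selection at the bare elbow loses real signal.
The retained components, with the removed means added back, form the
signal matrix; the remainder is the noise matrix, so `signal + noise`
reproduces the input to numerical precision — an identity the tests
enforce at relative error < 1e-8.

**Burst detection.** Rising edges are local-minimum-to-next-local-maximum
segments of the signal trace (extrema by first-difference sign change;
plateaus break at their first frame). An edge is a burst when its
base-to-peak amplitude exceeds `k_sigma = 1.96` times the standard
deviation of the same ROI's noise trace, computed over the full record.
Three refinements make the literal rule robust, all derived from the
amplitude definition rather than tuned:

* *Base refinement* (`base_frac = 0.05`): the base frame is the last frame
  before the peak within 5% of the segment amplitude above the segment
  minimum. Without it the "pre-rise minimum" lands wherever baseline noise
  last dipped and onset localization becomes noise-dependent; with it the
  base sits at the foot of the steep rise, stable to within a frame.
* *No endpoint peaks*: the final frame never counts as a maximum. A
  transient truncated by the end of the record has no measurable
  base-to-peak amplitude, and an endpoint "peak" would let half a noise
  excursion — any upward drift into the record end — pass the threshold.
* *Edge guard* (`edge_guard_s = 0.5`, half the default smoothing window):
  the whole rising edge must lie in the fully smoothed interior. The
  shrinking-window frames at the record edges are under-smoothed, and
  because the PCA reconstruction shares temporal components across ROIs,
  their excess noise produces *coincident* spurious events in many ROIs —
  which would then survive the support filter.

Events whose bases fall within `min_separation_s = 0.5` s merge, keeping
the larger amplitude; this suppresses double-counting of noisy edges
within one calcium transient and can be disabled with `0`.

**Catalog.** All events pool and cluster greedily: the earliest unassigned
event seeds an entry; every unassigned event within ±1 s joins it, at most
one per ROI (nearest to the seed wins, the earlier on ties); the entry
time is the mean of its members. Greedy earliest-seed clustering is
order-deterministic and directly realizes "distinct burst positions within
a window"; an agglomerative variant would need extra tie-breaking rules
the procedure does not define. Entries supported by strictly less than 4%
of ROIs are removed and ROIs are re-described from the survivors; the
re-described events are what downstream metrics consume, since they are
the robust activity by construction.

**Complexity.** Nodes are catalog entries; a directed edge joins every
pair of bursts adjacent in some ROI's sequence, deduplicated across ROIs.
The score is the mean of `E / #{v : outdeg ≥ 1}` and
`E / #{v : indeg ≥ 1}` — the mean out-degree among source nodes and mean
in-degree among sink nodes. This definition was one of two readings of
"ratio of nodes with more than one outgoing edge"; the literal fraction
reading scores 0 rather than the required baseline 1 when all ROIs share
one sequence, so the degree-ratio reading is canonical and the fraction
variant is available for comparison via
`complexity_score(g, variant = "literal_fraction")`. An edgeless graph is
reported as not computable rather than 0 or 1: a burst-free movie has no
defined complexity. With at least one edge the canonical score is ≥ 1.

**Statistics.** Complexity distributions are non-normal with unequal
variances across conditions, so groups are compared with the two-sample
Kolmogorov–Smirnov test (`compare_groups_ks()`; exact p-values for
combined n ≤ 25, asymptotic otherwise, regime reported) and summarized as
median ± bootstrap standard error (`bootstrap_median_se()`). Other
metrics use two-sided Student t-tests (`group_ttest()`, pooled variance;
paired where the design is paired).

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `roi_size`, `spacing` | 11, 9 | px | ROI side and lattice spacing |
| `smooth_s` | 1.0 | s | running-mean window |
| `dff_percentile` | 10 | % | ΔF/F baseline percentile |
| `k_sigma` | 1.96 | – | burst threshold in noise SDs |
| `window_s` | 1.0 | s | catalog half-window |
| `min_support` | 0.04 | fraction | catalog support filter |
| `min_separation_s` | 0.5 | s | event merge separation |
| `edge_guard_s` | 0.5 | s | record-edge exclusion |
| `icv_threshold` | 0.2 | – | rhythmic / non-rhythmic cut |
| `fps` | 20 | frames/s | acquisition rate |

The rhythmicity cut is strict: I.C.V. < 0.2 is rhythmic, and the boundary
value 0.2 counts as non-rhythmic. All C.V.s use the sample (n − 1)
standard deviation. "Cross-correlation" synchrony is the zero-lag Pearson
correlation of ΔF/F trace pairs, averaged over pairs; a
maximum-over-lags variant (±`max_lag_s`) exists behind a flag but is not
the default, as network bursts here are far slower than any plausible
inter-ROI lag.

## The synthetic-movie generator

`render_movie()` renders pixel fluorescence as

```
I(p, t) = baseline × (1 + Σ_b A_b · K(t − t_b)) + N(0, noise_sd²)
```

summed over the burst schedule of the pixel's subnetwork, where `K` is a
difference-of-exponentials calcium kernel (`tau_rise = 0.1` s,
`tau_decay = 1` s, peak normalized to 1) — the simplest waveform with the
fast-rise/slow-decay morphology the detector assumes. Frames are clipped
to [0, 255] and quantized to 8 bits with round-half-up.

Burst schedules are gamma renewal processes: intervals with mean
`mean_period` and CV `period_jitter_cv` drawn from a gamma with shape
`1/cv²`. The gamma was chosen over a truncated normal deliberately: a
normal truncated at the 2×`tau_rise` resolvability floor biases the
realized interval CV downward by ~9% at CV 0.5 (the floor sits at
z ≈ −1.96), whereas the gamma has exactly the requested mean and CV on
positive support, with the floor kept as a rejection step of negligible
(< 1e-5) probability. Zero jitter produces exactly periodic schedules.

Partitions are vertical stripes of near-equal width by default (contiguous
and trivially checkable); a seeded Voronoi "blobs" mode provides irregular
territories. For `k` subnetworks with `shared_fraction = s`, each
subnetwork's schedule is the union of its own renewal schedule (rate
`(1−s)/mean_period`) and one schedule shared by all (rate
`s/mean_period`), keeping each subnetwork's total burst rate at
`1/mean_period` while `s` controls how many burst times all subnetworks
have in common. Per-burst amplitudes are gamma with mean `amplitude_mean`
and CV `amplitude_cv` (no published amplitude distribution exists to
calibrate against; the CV is a free knob). Identical configurations render
bit-identical movies.

Defaults describe the standard acquisition: 20 frames/s, 128 × 128 px,
two minutes, baseline 50 intensity units, burst amplitude 1.0 ΔF/F,
pixel noise SD 2. What the generator does *not* emulate: motion,
bleaching, photon statistics, cell bodies (activity is uniform within a
subnetwork), or any biophysics of the excitatory/inhibitory mechanism.
Passing tests therefore certify the *analysis* — detection, cataloging,
scoring — against a known ground truth, not the generator's realism as
tissue.

## Numerical choices and degenerate inputs

* Detected burst positions are reported on the smoothed timeline. A
  centered running mean of `w` frames spreads a transient's onset earlier
  by `(w − 1)/2` frames, so detected bases lead true onsets by that
  constant minus the one-to-two frames the base refinement walks forward.
  Validation against ground truth compensates exactly `(w − 1)/2` frames;
  inter-burst intervals, and hence the I.C.V., are unaffected by any
  constant lead. Detected times are frame-quantized, so interval-CV
  comparisons carry a resolution floor of `√2/(2·fps·mean_period)`
  (~0.0035 for 10 s periods at 20 fps) below which agreement is not
  meaningful.
* Downscaling uses exact area-overlap pooling (a constant image stays
  constant and total intensity is conserved); upscaling is bilinear with
  border clamping.
* A zero-variance noise trace makes the threshold fall back to an
  epsilon-scale value with a warning; zero-variance PCA input assigns
  everything to signal with one component and a warning; traces with zero
  variance are excluded from synchrony means with a message; paired
  t-tests on identical samples, complexity of edgeless graphs and I.C.V.
  of trains with fewer than three bursts all report "not computable"
  (`NA`) rather than inventing a number.
* Ties: catalog assignment prefers the earlier event; entry renumbering
  after filtering is by representative time; plateau extrema break at
  their first frame.

## Validation design and problem sizes

Routine validation uses 64 × 64 px two-minute movies (36 ROIs) — large
enough that the 4% support filter (≥ 2 of 36 ROIs) and the PCA leak
geometry behave as at full scale, small enough that the whole suite runs
in a couple of minutes. Detector recovery is checked on low-noise
rhythmic movies (recall 1, no false events, bases within ±2 frames after
the filter-lead compensation above); interval-CV recovery over 20 seeds
per jitter level; segmentation discrimination over k ∈ {1, 2, 4}
partially shared subnetworks × 10 seeds, with medians strictly increasing
in k and an exact KS test separating k = 1 from k = 4. Segmentation runs
use `period_jitter_cv = 0.5`: with perfectly periodic schedules all
subnetworks burst in phase and are indistinguishable after ±1 s
cataloging, so irregularity is precisely the regime in which segmentation
is observable. Hand-worked oracles (the X→Y→Z / X→Z graph scoring 1.5,
intervals {1, 2, 3} s giving I.C.V. 0.5, the 8/196-kept vs 7/196-dropped
support boundary) are asserted exactly.

## Known limitations

* The ROI lattice is fixed; cell-resolved analysis requires caller-supplied
  per-cell traces (`pairwise_synchrony()`, `detect_bursts()` and the metric
  functions accept plain matrices and vectors for this purpose).
* The complexity score is a single scalar per movie; it does not localize
  *where* the network fragmented, and movies without any shared bursts
  across ROIs are outside its design (such cases were never observed in
  the data the method was built for, and the all-disjoint limit scores 1).
* Whether PCA treats ROIs or time points as observations is a genuine
  ambiguity of the procedure; the choice affects the split only through
  the centering direction. ROIs-as-observations with per-trace centering
  is implemented, and the reconstruction identity holds either way.
* Burst amplitudes are measured on the smoothed trace and are therefore
  compressed by a known, roughly constant factor relative to the
  underlying transient; ratios and C.V.s are unaffected.
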