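# circuitnet

Network-activity analysis for calcium-imaging movies of neural
"circuitoids" — self-assembling networks of stem-cell-derived spinal
neurons whose emergent population bursting resembles central pattern
generator output. The package answers the questions such recordings pose:
how often does the network burst, how rhythmic is it, how synchronized is
the field of view, and — when inhibition decouples the network into
sub-networks — how far has its activity fragmented?

## The method

A grayscale movie (nominally 20 frames/s, 128 × 128 px, 8-bit) is processed
as follows:

1. **ROI traces.** The field is tiled with 11 × 11 px oval ROIs at 9 px
   spacing (196 signals on a 128 × 128 frame); each trace is the mean
   intensity over the oval footprint.
2. **Smoothing and ΔF/F.** Traces get a 1 s running mean and are
   ΔF/F-transformed, `ΔF/F(t) = (F(t) − F₀)/F₀`, with `F₀` the trace's
   10th percentile.
3. **PCA signal/noise split.** The ROI × time matrix is decomposed by PCA;
   components up to the scree-plot elbow plus two are recombined as the
   *signal* matrix, the remainder as the *noise* matrix, with
   `signal + noise` equal to the input.
4. **Burst detection.** Rising edges of each signal trace are bursts when
   the base-to-peak change exceeds `1.96 × SD(noise trace)` of the same
   ROI.
5. **Burst catalog.** Burst positions from all ROIs are merged into
   distinct network burst positions within ±1 s windows; entries supported
   by fewer than 4% of ROIs are discarded and each ROI is re-described as
   its sequence of catalog entries.
6. **Network complexity.** A directed graph connects catalog entries that
   occur adjacently in any ROI's sequence (edges deduplicated). The
   complexity score is the mean of `E / #{v : outdeg(v) ≥ 1}` and
   `E / #{v : indeg(v) ≥ 1}`; identical sequences give a chain and score
   exactly 1, partial sharing pushes the score above 1.
7. **Metrics and statistics.** Burst frequency (bursts/min), the interval
   coefficient of variation (I.C.V.; rhythmic when < 0.2), amplitude mean
   and C.V., pairwise-correlation synchrony, two-sample
   Kolmogorov–Smirnov tests for complexity, Student t-tests otherwise,
   and bootstrap standard errors of medians.

A ground-truthed synthetic movie generator (difference-of-exponentials
calcium kernel, gamma-renewal burst schedules with controllable interval
CV, stripe or blob subnetwork partitions, additive Gaussian noise, 8-bit
quantization) makes every stage testable without recordings.

## Worked example

Simulate a two-minute movie of a field segmented into two sub-networks
that share 30% of their (irregular) burst schedule, then analyze it:

```r
library(circuitnet)

cfg <- synth_config(n_frames = 2400, height = 64, width = 64,
                    n_subnetworks = 2, period_jitter_cv = 0.5,
                    shared_fraction = 0.3, seed = 42)
sim <- render_movie(cfg)
res <- analyze_movie(sim$movie, pipeline_config())
res
#> <circuit_analysis>
#>   36 ROIs, 464 events, 19/21 catalog entries (filtered/raw)
#>   graph: 19 nodes, 27 edges; complexity score 1.5000
#>   network: 9.50 bursts/min, I.C.V. 0.681, mean synchrony 0.711
```

The 36 ROI traces yield 464 burst events that collapse into 19 robust
network burst positions. Because the two sub-networks only partially share
bursts, nodes of the burst-sequence graph acquire multiple incoming and
outgoing edges and the complexity score rises to 1.5; the same generator
with `n_subnetworks = 1` scores exactly 1.0 and has mean pairwise
synchrony 1.0 (vs 0.711 here). The network train is non-rhythmic
(I.C.V. 0.681 > 0.2), as expected for `period_jitter_cv = 0.5`.

Per-ROI metrics, the catalog, the graph and the synchrony matrix are in
`res$roi_metrics`, `res$catalog`, `res$graph`, `res$synchrony`;
`run_simulate()` / `run_analyze()` write the same results as TIFF/CSV/JSON
files, and `inst/cli/circuitnet.R` exposes `simulate`, `analyze` and
`compare` subcommands for shell use. Group comparisons use
`run_compare(a, b, metric = "complexity")` (KS test plus bootstrap median
standard errors).

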