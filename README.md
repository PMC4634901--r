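# trackqc

Quality control and visualization for time-lapse cell-tracking data.

## The problem

Automated tracking of cells in time-lapse microscopy (e.g. CellProfiler's
LAP tracker) produces, for every movie, three tables: an **image** table
(one row per acquired frame), an **object** table (one row per detected
object per frame, with its centroid and any number of measured features),
and a **relationship** table linking each object to its tracked
predecessor(s). Tuning a tracker's many parameters is hard without a way
to *see* what the tracks look like and where they go wrong — especially in
high-content experiments with hundreds of movies.

trackqc treats the trajectories as a directed lineage graph — one node per
object observation, one time-forward edge per parent–child link — and
flags the graph topologies that real cells rarely produce:

- **Loops** — a split whose branches re-merge downstream. A cell divides
  one-to-many or merges many-to-one, but a transient split-then-re-merge
  almost always marks a brief mis-segmentation. Formally: a split node
  `u` (out-degree ≥ 2) with ≥ 2 internally vertex-disjoint directed paths
  to a common descendant `m`; one loop is reported per split, at its
  earliest reconvergence.
- **Crossings** — a merge followed, along an unbranched chain, by a
  split: two tracks erroneously fused, travelling together, then
  re-separating. The degenerate case is a single node with in-degree ≥ 2
  and out-degree ≥ 2.
- **Singletons** — weakly connected components spanning at most *L*
  occupied frames (researcher-chosen threshold, default 1): usually
  spurious detections. These can be pruned into a corrected edge set that
  is saved as a *derived* relationship table alongside the original data.

Around the detectors sit track-length statistics (count, median,
10th/90th percentile, histogram), per-timepoint feature means min-max
normalized to [0, 1] for heatmap display, and the four standard views for
visual track assessment: the XYT plot (centroid vs. time polylines), the
lineage tree, synchrograms (a cell's image patch sequence, motion
removed by centering each patch on the centroid), and the feature
heatmap. Every renderer writes a machine-readable manifest sidecar so
outputs can be checked without parsing pixels.

A ground-truthed simulator (`simulate_tracking()`) generates tracked
nuclei with divisions, gap-closed disappearances, and injected artifacts
at known, isolated locations — so detector behaviour is testable exactly.

## Worked example

```r
library(trackqc)

# a 10-track, 30-frame movie with one loop, one crossing, two singletons
sim <- simulate_tracking(n_initial = 10, n_frames = 30,
                         division_prob = 0.01, gap_prob = 0.02,
                         n_loops = 1, n_crossings = 1, n_singletons = 2,
                         seed = 11)
g <- build_graph(sim$dataset)
g
#> <lineage_graph> 314 nodes, 304 edges, 30 timepoints

report <- qc_report(g, singleton_max_length = 1)
report
#> <qc_report>
#>   loops:      1
#>   crossings:  1
#>   singletons: 2 (span <= 1)
#>   tracks:     11; median length 30 (p10 1, p90 30)

tidy(report)
#> # A tibble: 4 × 5
#>   type      node_a node_b duration_frames n_nodes
#>   <chr>     <chr>  <chr>            <int>   <int>
#> 1 loop      26_1   29_1                 3       6
#> 2 crossing  4_2    6_2                  2       3
#> 3 singleton 1_11   <NA>                 1       1
#> 4 singleton 11_11  <NA>                 1       1
```

Node ids are `"<image_index>_<object_index>"`. The loop starts at the
object observed in frame 26 and re-merges three frames later; the two
singletons are single-frame components — exactly what was injected. The
`tracks: 11` line counts weakly connected components: the crossing fused
two of the 10 initial tracks into one family, and the two singletons add
one-node components (10 − 1 + 2 = 11); the p10 of 1 reflects those
single-frame tracks.

Prune the singletons and persist the corrected edges with the data:

```r
pruned <- prune_singletons(g, max_length = 1)
save_derived_relationships(sim$dataset,
                           graph_edges_as_relationships(pruned$graph),
                           "pruned_v1", path = "movie.sqlite",
                           dialect = "sqlite")
```

Per-timepoint feature means, normalized per feature to [0, 1]:

```r
m <- minmax_normalize(timepoint_feature_matrix(sim$dataset))
tibble::as_tibble(m)
#> # A tibble: 30 × 4
#>   timepoint Signal_1 Signal_2 Timepoint_Ramp
#>       <int>    <dbl>    <dbl>          <dbl>
#> 1         0    0.903    0.839         0
#> 2         1    0.835    0.961         0.0345
#> 3         2    0.886    1             0.0690
#> # ℹ 27 more rows
autoplot(m)                      # or render_heatmap(m, "heatmap.png")
```

Figures: `render_lineage()`, `render_xyt()` (PNG, or a standalone
drag-to-rotate HTML), `render_synchrogram()` after
`extract_synchrogram()`.

## Command line

```sh
inst/scripts/trackqc simulate --n-initial 10 --n-frames 30 --seed 11 \
    --render --dialect sqlite --out run --prefix movie
inst/scripts/trackqc qc run/movie.sqlite --out run --prune --save-as pruned_v1
inst/scripts/trackqc heatmap run/movie.sqlite --out run
```

Exit codes: 0 success, 1 validation failure, 2 usage error. Every command
writes a run-manifest JSON recording inputs, parameters, and version.

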