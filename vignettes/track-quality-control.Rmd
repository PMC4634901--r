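---
title: "Graph-based quality control of cell-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based quality control of cell-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(trackqc.verbose = FALSE)
library(trackqc)
```

## The data model

trackqc consumes tracking output in a minimal three-table schema, the
form in which image-analysis pipelines such as CellProfiler export it:

* an **image table**: one row per acquired frame, keyed by an integer
  `image_index`, optionally carrying a `group_index` (field of view), an
  explicit `timepoint`, a file path, and arbitrary metadata columns;
* an **object table**: one row per detected object per frame, keyed by
  `(image_index, object_index)`, with an `(x, y)` centroid in pixels and
  any number of numeric feature columns (features are consumed as opaque
  measurements and never computed here);
* a **relationship table**: one row per parent→child link between an
  object and its tracked predecessor. One-to-many rows encode splits,
  many-to-one rows encode merges, and a link whose endpoints are more
  than one frame apart encodes gap closing (the object was undetected in
  between).

When no explicit timepoint column exists, the timepoint is derived as the
0-based rank of `image_index` within its group — matching how exporters
number frames. Centroids are 0-based pixel coordinates, x = column,
y = row, origin top-left; this convention must (and does) match the
synchrogram cropping. Any numeric object column that is not a key or a
centroid is a feature; non-numeric columns are ignored with a logged
warning, because the feature set is open-ended in practice. Column names
are matched case-insensitively against configurable aliases
(`read_config()`), with centroid columns also matched by the
`Location_Center_X` / `Location_Center_Y` substring convention.

Both a SQLite file and a CSV triplet (`<prefix>_image.csv`, `_object.csv`,
`_relationships.csv`) are supported; the two dialects are interchangeable
and round-trip losslessly (the CSV writer emits shortest round-tripping
decimals and the reader parses them exactly). A MySQL backend would
satisfy the same contract but is deliberately out of scope.

## The lineage graph and its expected topology

`build_graph()` makes one node per object observation and one directed
edge per relationship row. Edges always point forward in time, so the
graph is a DAG by construction (validation rejects any backward or
same-frame link before a graph is built). Gap-closing links are kept as
single edges with `frame_gap > 1` rather than interpolated phantom
nodes — the schema stores observed objects only, and inventing
observations would corrupt every downstream statistic.

Normal cell behaviour produces only a few topologies: chains (movement),
one-to-many splits (division), and occasionally many-to-one merges
(contact or over-merging). Three deviations from this repertoire are
flagged because they usually indicate segmentation or tracking error,
not biology:

* **Loop** — a split whose branches reconverge. Definition: a split node
  `u` and the earliest node `m` (by timepoint, then node id) reachable
  from `u` by at least two internally vertex-disjoint directed paths.
  Reporting one loop per split, at the earliest reconvergence, captures
  the transient-split pattern while bounding output size. Disjointness is
  decided by max-flow on the node-split network (every vertex except the
  endpoints given capacity 1), which is exact; the test suite checks it
  against an independent brute-force enumeration of simple-path pairs.
* **Crossing** — a merge node `m` joined to a split node `s` by an
  unbranched chain: every node after `m` on the chain has in-degree 1 and
  every node before `s` has out-degree 1, with `m = s` (a node with
  in-degree ≥ 2 and out-degree ≥ 2) as the degenerate duration-0 case. A
  chain interrupted by another merge is not followed further — that merge
  starts its own candidate chain — so no chain is counted twice. At most
  one crossing exists per merge node under this definition.
* **Singleton** — a weakly connected component whose temporal span
  (number of *distinct occupied* timepoints; gap frames are not counted)
  is at most a researcher-chosen threshold, default 1. Components, not
  root-to-leaf paths, are the unit of track counting and of the length
  statistics, because splits and merges make path enumeration
  combinatorial while the component is exactly what a lineage-tree panel
  groups together. Counting occupied timepoints rather than nodes was a
  genuinely open choice; spanned-occupied-frames was chosen because a
  gappy but long-lived track is not spurious.

Loops and crossings are detected independently and a node may participate
in both; they answer different questions and are displayed separately.
"Transient" is operationalized as an optional `max_duration` filter on
`timepoint(end) − timepoint(start)`; the default reports all durations,
since no universal cutoff exists — it depends on frame rate and biology.

`qc_report()` aggregates the three detectors plus track-length statistics
(median and 10th/90th percentiles by linear interpolation between closest
order statistics — R quantile type 7, pinned so tests are exact) and the
union of flagged nodes for highlighting. Reports serialize to versioned
JSON, byte-identical for identical inputs. Detection only *suggests*
problems: an artifact-free report does not prove correct tracking, and no
automatic correction of loops or crossings is attempted. Singletons are
the exception — `prune_singletons()` removes flagged components and the
corrected edge set can be stored as a derived relationship table
(`relationship__<name>`) next to the original data, which is never
modified.

## Feature summaries

`timepoint_feature_matrix()` averages each feature over all objects at
each timepoint — pooled across fields of view by default, since a movie
is typically one site; per-group averaging is a switch. Timepoints with
no objects yield missing cells that are rendered as gaps, never
interpolated: the heatmap exists to reveal exactly such dropouts (an
out-of-focus frame shows up as a stripe). `minmax_normalize()` then maps
each feature column over its finite cells onto [0, 1]; raw values are
averaged first and the matrix normalized afterwards, so the display is an
affine rescaling of true population means. Zero-range (constant) columns
map to 0 rather than 0.5 — a constant carries no signal — and the
operation is idempotent. Node color maps for the XYT and lineage views
use the same convention, with an optional percentile scale (default
window 2–98%) that clips heavy tails instead of letting outliers flatten
the dynamic range.

## Rendering choices

Every renderer writes a `<file>.manifest.json` sidecar with glyph,
segment, and patch counts and the color range, so correctness is checked
structurally rather than by pixel comparison; manifests are deterministic.

* **Lineage layout**: x = timepoint; within a component, leaves get
  consecutive integer rows in depth-first order from the roots (children
  visited in object-index order — the ordering itself is arbitrary but
  must be deterministic), internal nodes sit at the mean row of their
  children, components stack with at least a one-row gap. When two
  parents share a merge and have no other children they would coincide;
  small deterministic offsets restore injectivity. Gap edges are drawn
  dashed.
* **Flag styling**: when a node belongs to several deviation types, the
  precedence crossing > loop > singleton decides its highlight — an
  arbitrary but fixed constant recorded in the manifest.
* **XYT**: one polyline per maximal branch-free trajectory segment
  (every edge belongs to exactly one segment; split and merge nodes
  terminate segments and appear in each incident one). The static export
  is an isometric projection; the `.html` export embeds the polylines and
  a small dependency-free canvas renderer with drag-to-rotate, keeping
  the core library headless. Whether a trajectory's identity "continues"
  through a merge is deliberately left undefined; segments end there.
* **Synchrograms**: fixed-size patches (default 61×61 px) cut from the
  original frames, centered on the nearest-integer centroid (R's
  round-half-to-even), zero-padded at frame borders; timepoints skipped
  by gap closing produce labeled blank placeholders rather than silently
  shortening the strip.

## The simulator

`simulate_tracking()` emulates tracked nuclei at toy scale: Gaussian
random-walk motion (default step SD 2 px/frame) with reflecting
boundaries in a default 128×128 px frame, per-object per-frame division
probability, per-link single-frame gap probability, smooth per-track
sinusoid features plus N(0, 0.1) noise, and one feature column exactly
equal to the timepoint (after normalization it must become an exact 0–1
ramp — a built-in sanity check). A synchronized-division mode makes all
tracks divide at shared frames (thirds of the movie), mimicking the
synchronous nuclear divisions of an early embryo for heatmap
demonstrations.

Artifacts are injected post hoc by rewiring relationship rows on
dedicated host tracks that never divide or gap — one host per loop, two
per crossing — so injections are topologically isolated and detector
counts can be asserted *exactly* rather than statistically. A loop adds a
two-frame phantom branch (split, re-merge three frames later); a crossing
fuses two hosts for three frames and removes the second track's
observations in between (duration 2); a singleton is an unlinked
single-frame object. Requests that cannot be placed (too few initial
objects for the hosts, or fewer than six frames) error with advice rather
than degrading silently. Everything is reproducible from the seed.

What the simulator does *not* emulate — photorealistic microscopy,
uneven illumination, segmentation noise correlated across neighbours,
3-D objects, or a real tracker's error distribution. Passing tests
therefore demonstrate that the detectors and renderers are correct on
data satisfying the schema, not that any particular tracker is well
tuned. `render_frames()` draws objects as Gaussian blobs (peak exactly at
the rounded centroid; overlaps combine by maximum so peaks stay exact)
into one 32-bit TIFF per frame, which is what the synchrogram tests cut
patches from. TIFF samples quantize at ~2⁻³², so intensity comparisons
against rendered frames should test "peak at the expected pixel", not
exact floating-point equality.

## Problem sizes and numerical notes

The test suite and the acceptance script run entirely on simulated data:
round-trip checks use 50 datasets of 3–5 tracks × 6–9 frames in both
dialects; detector–oracle equivalence uses 100 random sparse DAGs of
20–60 nodes (sparse so that the brute-force path enumeration the oracle
relies on stays exhaustive); artifact recovery sweeps injected counts
over {0, 2, 5}³ × 20 seeds with 16 tracks × 14 frames, sized so the
largest request (5 loops + 5 crossings = 15 hosts) is satisfiable; the
end-to-end CLI run uses a 10-track, 30-frame movie. These sizes exercise
every code path of interest; all quantities are either exact counts or
agree with independent oracles to 1e-12 (means) — nothing about the
method is scale-dependent beyond runtime.

Degenerate inputs are pinned down by tests: empty relationship tables
(all tracks length 1), graphs with a single node, constant features,
all-missing features (an error), empty graphs for statistics (an error),
and singleton thresholds below 1 (an error).

## Known limitations

* Detection highlights *candidate* errors; false negatives (e.g. a
  mis-link that produces a biologically plausible topology) are invisible
  to topology-based QC by construction.
* The loop search is exact but per-split quadratic in the worst case; on
  pathological dense graphs (far denser than tracking data) it would be
  slow before it would be wrong.
* Per-site image indices that restart at 1 within each group are not
  supported; the image index is assumed globally unique (a composite-key
  variant would be a small extension).
* 3-D data are handled only through a 2-D centroid per object (maximum
  projection or a chosen slice).
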