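---
title: "Quantifying epithelial organization with graphlets: methods and design notes"
author: "epigraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial organization with graphlets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Packed epithelia tile a surface with convex cells, and the way they tile it
— how hexagonal, how heterogeneous, how locally clustered — carries
biological signal that the classical polygon distribution (the frequencies
of 4-, 5-, 6-, 7-sided cells) does not fully capture: visibly different
tissues can share nearly identical polygon distributions.  `epigraphr`
quantifies tissue organization from the *topology of the cell-contact
network* instead.  A segmented label image is converted into a graph whose
nodes are cells and whose edges are physical cell-cell contacts; the graph's
local structure is summarized by graphlets — the connected induced subgraphs
on 2–5 nodes — and two tissues are compared through the graphlet degree
distribution agreement distance (GDD).

## The contact network

`build_contact_graph()` links two cells when dilating one cell's pixel
region by a disc of `contact_radius_px` (default 2 px) overlaps the other.
The radius absorbs the membrane gap of real segmentations (a 0-valued ridge
of 1–2 px between cells) while keeping honeycomb next-nearest neighbors
apart.  Two consequences of the default are deliberate and documented
rather than hidden:

* cells meeting only at a four-way corner *do* count as contacts at radius
  ≥ 1 (their pixel distance is ≤ √2); a square grid therefore has contact
  degree 8, not 4, which is exactly what makes such non-Voronoi
  architectures stand out on the reference scale;
* the radius is a user parameter, because segmentation pipelines differ in
  membrane thickness.

Cells whose region touches the image frame are *invalid*: their
neighborhoods are truncated by the field of view.  They stay in the graph as
context but never contribute rows to per-cell statistics.
`restrict_to_analysis_nodes(graph, ring)` additionally peels `ring` layers
of cells adjacent to invalid ones.  Orbit enumeration always runs over the
full graph, so analysis cells near the peel boundary keep their true
neighborhoods (no truncation bias at the analysis boundary).

A region split into several pixel components triggers a warning (and is
processed as the union).  Connectivity is assessed with 8-neighborhood,
because pixel-center assignment of perfectly convex Voronoi cells
legitimately produces single-pixel diagonal steps along oblique boundaries;
4-connectivity would flag those as split.

## Graphlets, orbits, motifs

`build_catalogue()` enumerates the 30 connected non-isomorphic graphs on
2–5 nodes and their 73 vertex automorphism orbits at run time (exhaustive
canonicalization over ≤ 120 permutations per graph).  Graphlets are ordered
by node count, edge count, degree sequence and canonical form; orbits within
a graphlet by representative degree.  On 2–4 nodes this reproduces the
standard literature numbering exactly (G0 edge … G8 = K4, orbits 0–14;
orbit 0 is degree).  On 5 nodes the published figure ordering is not
available in machine-readable form, so ids follow the deterministic density
ordering; all internal consumers (motif sets, the GDD) reference ids from
the same catalogue, so the choice is self-consistent.

`count_orbits()` is a C++ ESU enumeration of all connected induced
subgraphs of size 2–5 with a mask→orbit lookup table; contact graphs have
bounded degree (≈ 6), so this is effectively linear in cell number.
`brute_force_orbits()` is an independent pure-R oracle — `combn` over all
2–5-subsets, vectorized induced-adjacency masks, an independently built
canonicalization table — used throughout the tests to pin the fast counter.

*Cellular motifs* restrict the orbit space to graphlets realizable in a
planar packed tissue.  The shipped sets (`full-29`: 29 motifs over 26
graphlets, with G8, G23 and G26 each realizing two geometrically distinct
motifs; `motifs-17`: the default reduced set) are data, not code
(`inst/extdata/motif_sets.json`).  **The membership is a synthetic
transcription**: the authoritative partition exists only as figure colors
and supplementary material that are not machine-readable here, so the file
encodes a structural rule (drop the 5-clique, the 5-clique minus an edge,
the densest remaining 8-edge graphlet, and the 5-star, which cannot occur
as an induced pattern around an interior cell whose neighbors form a
contact ring) that reproduces the published cardinalities.  The file is
flagged `synthetic_transcription: true`; anyone holding the original
figure can replace it without touching code, and validation assertions on
the cardinalities (26/29/17) run at every load.

## The GDD

For each orbit *j* the profile stores `d_j(k)`, the number of analysis
cells touching orbit *j* exactly *k* times (k ≥ 1), scaled as
`S_j(k) = d_j(k)/k` and normalized to `N_j(k)` with total mass 1.  The
per-orbit distance between graphs *a* and *b* is

$$D_j = \frac{1}{\sqrt 2}\Big(\sum_k\big[N_j^a(k)-N_j^b(k)\big]^2\Big)^{1/2} \in [0,1],$$

and the **GDD value** is the arithmetic mean of the $D_j$ over the motif
set's orbits.  Conventions that the underlying definition leaves open, with
our choices:

* *aggregation*: arithmetic mean (default) — robust when a single orbit
  disagrees completely; a geometric variant (`aggregate = "geometric"`)
  is available and recorded in the result object;
* *orbits empty in both graphs* are skipped; *empty in exactly one* are
  compared against the zero distribution (contributing
  $D_j = \sqrt{\sum N^2}/\sqrt2 \le 1/\sqrt2$);
* distributions are sparse maps over observed *k*; no binning, no
  smoothing.

Distance, not agreement, is reported: higher = more different.

## Epi-coordinates and the CVTn scale

A tissue is embedded as three GDD values against fixed references
(`build_reference_bank()`):

* **Epi-Hexagons** — a bounded honeycomb lattice, analysis restricted to
  cells ≥ 5 steps from the border (`ring = 4`).  A graphlet spans at most 4
  edges, so every counted subgraph lies in untruncated honeycomb and the
  reference profile is an exact point mass per orbit, exactly as in an
  infinite lattice.  (A thinner peel would let frame-truncated border cells
  leak into 4–5-node orbit counts and blur the ideal reference; this is why
  the package peels 4 rings, not 1.)
* **Epi-Random** — random Voronoi tessellations, profile averaged over
  replicates *at the distribution level* (average `N_j(k)`, renormalize);
  averaging the distributions rather than the downstream GDD values keeps
  the reference a proper profile that any graph can be compared against.
* **Epi-Voronoi5** — Voronoi diagram 5 of the plain CVT path (5 Lloyd
  relaxations from random seeds), averaged the same way; its polygon
  distribution sits between the random and fully relaxed extremes, close to
  many natural epithelia.

The reference scale itself is the **CVTn path**: from random seeds, odd
iterations apply a plain Lloyd step (each seed moves to its rasterized
region's pixel centroid) and even iterations place each seed uniformly at
random in a 5-px-radius disc around that centroid (area-uniform; positions
falling off-canvas are clamped to the nearest in-bounds pixel center).
Iteration counting starts at 1, so "Voronoi diagram N" = N relaxations and
iteration 1 of the CVTn path is a pure Lloyd step.  The alternation orders
the tessellation progressively but the re-injected noise prevents full
hexagonal convergence — which is what makes the path a usable scale for
natural tissues.  `build_cvtn_scale()` embeds replicates of every scheduled
iteration (default schedule 1–20, 30–100 by 10, 200–700 by 100) as
Epi-points.

All tessellations are *rasterized* (pixel-grid) Voronoi diagrams, not exact
geometric ones: the noise radius is defined in pixels and centroids are
pixel centroids, so the pixel grid is the native geometry of the method.
Nearest-seed ties resolve to the lowest seed index, making every generator
bit-reproducible under a fixed seed.

## Outlier classification

`classify_against_scale()` (or `predict()` on a `cvtn_scale`) compares a
tissue's Epi-point with each scheduled iteration's replicate cloud using a
diagonal-covariance standardized distance: per coordinate, the z-score
against the cloud mean and variance (variances floored at `1e-4`), combined
as the root-mean-square over the three coordinates.  The score therefore
reads as "per-coordinate standard deviations away from the cloud"; the
default threshold is 2.5.  The tissue is assigned the closest iteration;
if even the closest cloud is beyond the threshold the tissue is flagged as
*not conforming to the CVTn scale*.  The published description names only
an outlier-detection approach without its exact statistic, so the statistic,
threshold and variance floor are explicit configuration here — a reader of
the original supplementary material can match it without interface changes.

Iteration-*recovery* statements in the tests use a neighborhood of ± 2
iterations: one full noise-plus-relaxation cycle is the CVTn path's natural
step (post-noise diagrams resemble other post-noise diagrams more than the
adjacent relaxed ones), so recovery is judged at cycle resolution.  This
was fixed as a design rule before any recovery simulation was run.

## Simulation sizes and what the tests show

Defaults target a 1024×1024 canvas with 500 seeds (≥ 400 interior cells,
enough for stable orbit statistics).  The test suite and the acceptance
script run the same machinery at explicitly chosen sizes: 500 seeds on
512×512 canvases (≈ 420 interior cells, i.e. the default cell count at a
quarter of the default pixel area) for everything embedded in Epi-space,
96–512 px canvases for generator physics, 10–20 replicates per stochastic
estimate, schedules truncated at iteration 100.  Cell count, not canvas
area, is what controls the stability of orbit statistics and of the scale's
replicate clouds; at clearly smaller tissues (≈ 200 cells) the embedding
noise becomes comparable to the spacing of adjacent scale iterations and
position recovery along the early path degrades — which is why the
analysis-cell count is the one size the package treats as non-negotiable.

The synthetic generators emulate *geometry-driven* packing only: convex
cells from seed-based tessellation, no cell division, no apoptosis, no
anisotropic stress, no curvature.  Passing tests therefore demonstrate that
the machinery measures what it claims on tessellations with known ground
truth — not that any particular biological tissue will land at a particular
scale position.  The published placements of real tissues (neural tube
near Voronoi 1, larval wing near 3, pupal wing near 7; eye disc and
myosin-II-depleted pupal wing as outliers) require the original microscopy
segmentations, which are not shipped; what the package reproduces is the
mechanism that yields such labels.

## Known limitations

* 2D apical surfaces only; no 3D packing, no time-lapse linkage.
* Orbit ids on 5-node graphlets follow this package's deterministic
  ordering; exporting counts for comparison with other tools should go
  through the catalogue's edge lists, not bare ids.
* The motif-set membership beyond its cardinalities is a transcription
  choice (see above) — replace the packaged JSON to match the original
  partition exactly.
* GDD values depend (weakly) on tissue size through distribution support;
  compare tissues at comparable analysis-cell counts, or rely on the
  scale's replicate spread, which absorbs this at matched generation
  parameters.
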