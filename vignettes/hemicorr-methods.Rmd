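---
title: "Landmark-based homotopic correspondence and functional symmetry: methods"
author: "hemicorr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based homotopic correspondence and functional symmetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemicorr)
```

## The problem

Standardized cortical surface meshes give the two hemispheres equal vertex
counts, but vertex *i* on the left is not anatomically homologous to vertex
*i* on the right: folding patterns differ between hemispheres and the
meshes are built independently. Volume-based studies sidestep this by
negating the x coordinate in a standard space ("coordinate flipping"),
which lands in the wrong gyrus — or outside grey matter — wherever folding
is asymmetric. `hemicorr` implements a landmark-based alternative and uses
it to ask how symmetric resting-state functional connectivity is across
the hemispheres.

## Label vectors and anatomical correspondence

Every vertex is assigned a K-dimensional **label vector** whose j-th entry
is the geodesic distance (mm) along the cortical surface from the vertex
to the centroid landmark of the j-th parcellation region of its own
hemisphere (K = 74 regions by default, the granularity of a standard
gyral parcellation). Label vectors re-express position *relative to
gyral/sulcal landmarks*, which is what makes them comparable across
hemispheres: the **anatomical correspondence (AC)** of a seed vertex is
the contralateral vertex whose label vector has the largest Pearson
correlation with the seed's.

Design choices a user should know:

* **Geodesics** are shortest paths on the mesh edge graph with Euclidean
  edge weights (Dijkstra, via `igraph`). Edge-graph distances overestimate
  exact polyhedral geodesics by a small factor that depends on the
  tessellation, but they are deterministic and exactly checkable against
  an all-pairs oracle, which the test suite does. Absolute distances from
  other geodesic engines will differ slightly.
* **Centroid** of a region is the region vertex nearest (Euclidean) to the
  arithmetic mean of the region's vertex coordinates, ties to the lowest
  index. Any centroid-like landmark works; this one is reproducible and
  parameter-free.
* **Pearson matching** standardizes label-vector rows once and computes
  all correlations as one matrix product (identical to per-pair
  correlation within 1e-10; asserted in tests). Argmax ties break to the
  lowest vertex index so results are platform-independent.
* **Region pairing** across hemispheres is by region *name*, because
  annotation files may order regions differently per hemisphere.
* **Medial wall** vertices (reserved label 0) are kept in the edge graph
  — paths may cross them — but are never seeds, match targets, or
  landmark members. Every metric whose index chain touches an excluded
  vertex propagates an `NA` sentinel rather than being silently dropped.
* Cosine similarity is a defensible alternative reading of "most similar
  label vector"; standard Pearson is implemented because correlation is
  what the matching statistic is named after, and on mirrored geometry the
  two agree at the optimum.

The **flip-distance benchmark** (`flipDistance()`) quantifies what the
landmark method buys: for each seed at (x, y, z) in volume space it
reports the Euclidean distance between the landmark-based correspondence
and the flipped location (−x, y, z), a 1 mm cumulative histogram, and the
fraction of flipped locations falling outside a grey-matter mask. The
operation is transform-agnostic: the caller supplies volume coordinates,
and any template-specific surface-to-volume transform is upstream.

## Functional correspondence

For resting time series, the **functional correspondence (FC)** of a seed
is the contralateral vertex with the maximally correlated time course.
Per-subject left x right correlation matrices are averaged entrywise into
a group matrix (optionally on the Fisher-z scale; arithmetic mean of
correlations is the default), and the group FC is the argmax of the
*averaged* matrix — not the average of per-subject argmaxes, which would
not be a vertex. The computation is blockwise, so the full 36k x 36k
matrix of a full-resolution mesh is never materialized; dense blocks are
kept only for small meshes or on request.

**Heat-kernel smoothing** (`heatSmooth()`) iterates a row-normalized
Gaussian 1-ring weighting (bandwidth `targetFwhm/4`, capped at twice the
mean edge length) and re-estimates the achieved smoothness after each
step, stopping when the estimate reaches the target. The contract is the
*achieved* FWHM (within about 10 percent), not an iteration count: the
estimator assumes a Gaussian spatial autocorrelation and inverts the
neighbour correlation implied by first differences across edges,
`FWHM = d * sqrt(-2 log 2 / log r)` with `r = 1 - var(diff)/(2 var)`,
pooled over edge-length classes weighted by edge count. This assumes a
quasi-uniform tessellation; on strongly graded meshes the estimate blends
scales. The spatial mean of each timepoint is restored exactly after
every step, so constant fields are fixed points. Nuisance regression,
volume-to-surface mapping and motion handling are upstream of this
package: it consumes clean per-vertex series.

## AFCD and FAD

Two per-vertex geodesic metrics summarize functional symmetry:

* **AFCD** (anatomy-to-functional-correspondence distance): the distance
  on the *target* hemisphere between a seed's AC and its FC. Small AFCD
  means resting fluctuations correlate maximally near the homotopic
  location.
* **FAD** (functional asymmetry distance): take an anatomically matched
  pair (v, w = AC(v)). Project v's FC (a right-hemisphere vertex) back to
  the left hemisphere through the right-to-left anatomical map; w's FC is
  already a left vertex. FAD is the distance between the two. A pair of
  seeds whose FCs criss-cross — each lands at the anatomical
  correspondence of the other's — has large AFCD but FAD near zero, so
  FAD isolates genuinely asymmetric patterns. Large AFCD alone does not.

FAD is reported on left-hemisphere seeds; recomputing with the right
hemisphere as reference is a matter of swapping the map arguments, and on
near-mirror geometry the two differ only through discretization.

High-FAD cortex is summarized by `highFadClusters()`: supra-threshold
vertices (absolute mm threshold, or a percentile such as `"p95"`) are
split into connected components under mesh edge adjacency and components
below a minimum vertex count are dropped. The reference rule — threshold
100 mm, minimum 20 vertices — isolates roughly the most asymmetric 5% of
a full-resolution cortex; the size filter is by exact vertex count, with
cluster surface area reported alongside for reference since vertex count
is resolution-dependent. `mapSimilarity()` and `averageCorrMap()` then
inspect whether a high-FAD cluster reflects a qualitatively different
correlation pattern or merely a shifted maximum within one shared
network, and `tsnrAsymmetry()` (Wilcoxon signed-rank across subjects on
anatomically paired temporal-SNR values; exact null up to 25 subjects,
normal approximation with continuity correction beyond, uncorrected
p-values) checks whether hemispheric signal-quality differences could
account for flagged locations.

## The synthetic scene generator

Every stage is testable without external data via `makeScene()`:

* **Geometry.** The left hemisphere is an icosphere (subdivision 4 by
  default: 2,562 vertices) scaled to 80 mm radius — matching a human
  hemisphere's cortical area to order of magnitude — with a smooth random
  radial deformation (relative amplitude 0.03) standing in for
  folding-scale shape variation. The right hemisphere is its exact mirror
  (x negated, face orientation fixed), optionally perturbed by an
  independent radial field of stated amplitude in mm. The true homotopic
  map is explicit, so recovery claims are checked against ground truth.
  A sphere has no folds; the correspondence method never assumes folding,
  only mesh geometry, so what the synthetic tests cannot show is
  robustness to the anisotropic, high-curvature tessellations of real
  cortex.
* **Parcellation.** Geodesic Voronoi regions from farthest-point-sampled
  seeds (connected by construction), mirrored across hemispheres so
  region j pairs with region j.
* **Signals.** Functional networks tile the cortex (default: a 6-network
  geodesic Voronoi partition). Each network k has a latent Gaussian
  course z_k; each homotopic pair additionally shares a pair latent u_v.
  With noise SD sigma and homotopic coupling rho, the total signal
  amplitude is `s = sigma * sqrt(rho / (1 - rho))`, split evenly between
  network and pair latents, so the correlation between mirror partners is
  rho in expectation (0.6 by default, checked by simulation at large T)
  while within-network off-pair correlation is rho/2. The defaults — 10
  subjects, 140 timepoints, TR 3.5 s — are the study scale the package
  treats as its reference conditions. An optional Gaussian spatial
  falloff of loading can down-weight network borders; it defaults to off
  (uniform loading) so the nominal coupling holds at every member. The
  generator does not model hemodynamics, temporal autocorrelation, or
  physiological noise spectra: passing tests demonstrate the estimators'
  correctness, not robustness to realistic fMRI artifacts.
* **Injected asymmetries.** A *shift* displaces the right-hemisphere
  loading peak of a patch (geodesic ball) by D mm: the dominant share of
  each pair latent (`gammaDisp = 0.9`) moves to a unique same-network
  vertex at geodesic distance D, while a reduced share (`gammaSym = 0.4`)
  stays at the mirror vertex and the removed variance is replaced by
  noise. This yields a one-sided asymmetry — left-seed FCs displaced by
  D, right-seed FCs still symmetric — so patch AFCD and FAD both recover
  D. Three constraints make the construction self-consistent: targets
  must share the seed's network latent and must be unique (else variance
  normalization favours the depleted mirror vertex or the pooled target),
  and the patch radius should stay below D/2 so displaced loadings land
  outside the mirrored patch. A naive alternative — permuting pair
  latents by a rigid +D shift — displaces *both* directions' argmax and
  forces FAD toward 2D; that construction is deliberately not used. A
  *swap* exchanges the right-hemisphere pair latents of two distant
  same-network vertices, producing the criss-cross pattern: AFCD equal to
  the swap distance, FAD near zero.
* All generators are deterministic given their seed, restore the caller's
  RNG state, and record their parameters in the scene's `truth` list.

## Numerical conventions

* Vertex and region indices are 1-based in R; all on-disk formats (TSV
  tables, GIFTI indices) are 0-based with -1/`nan` sentinels.
* Tabular output uses tabs, LF endings and 9-significant-digit floats, so
  repeated runs are byte-identical.
* Tolerance bands for recovery claims are quoted in multiples of the mean
  edge length (`meanEdgeLength()`), the mesh's natural resolution unit
  (about 6 mm at subdivision 4 and 80 mm radius).
* Dijkstra-vs-oracle equality is asserted at 1e-12: the two algorithms
  associate floating-point sums differently, so "exact" means agreement
  to numerical precision.
* Disconnected meshes are a hard error in every distance computation;
  `validateMesh()` is the one function that reports rather than raises.

## Problem sizes used in checks

The packaged tests and the acceptance script run at subdivision 4 (2,562
vertices per hemisphere, 74 regions, 10 subjects, 140 timepoints) for the
mirror-identity, symmetric-recovery and displacement-recovery checks;
subdivision 3 for the criss-cross construction and cluster-rule checks;
50 random meshes of up to 200 vertices for the geodesic oracle; and a
60 x 60 unit grid for the smoothing contract. These sizes were chosen so
the whole suite completes in about a minute on a laptop while keeping the
±2-edge-length tolerance bands meaningfully narrower than the injected
20 mm effect.

## Known limitations

* Edge-graph geodesics, not exact polyhedral geodesics: distances are
  slight overestimates and mildly tessellation-dependent.
* The FWHM estimator assumes Gaussian spatial autocorrelation and
  quasi-uniform edge lengths.
* The generator's spherical geometry and white temporal noise are
  idealizations; results on real cortical meshes inherit none of the
  synthetic ground-truth guarantees.
* Whether the upper-5% FAD clustering of a real dataset should pool
  hemispheres or treat them separately is a user decision; the API takes
  an explicit threshold or percentile.
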