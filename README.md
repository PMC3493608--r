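# hemicorr

Landmark-based interhemispheric correspondence and functional symmetry of
the cortical surface.

## The problem

The two cerebral hemispheres are grossly symmetric, and resting-state
fMRI time series at a location are typically most correlated with the
*homotopic* (mirror-corresponding) location in the opposite hemisphere.
But standardized surface meshes do not make vertex indices homologous
across hemispheres, and the common workaround — flipping the x
coordinate in a standard volume space — is at the mercy of asymmetric
cortical folding. `hemicorr` is for researchers working with surface-based
resting-state data who need (1) a precise per-vertex homotopic
correspondence and (2) quantitative maps of how symmetric the functional
connectivity actually is.

## The method

**Anatomical correspondence (AC).** Each cortical vertex gets a label
vector

> v = (δ₁, δ₂, …, δ_K)

where δⱼ is the geodesic distance along the surface from the vertex to
the centroid of the j-th parcellation region of its own hemisphere
(K = 74 by default). Label vectors locate a vertex relative to
gyral/sulcal landmarks rather than in Cartesian space, so they are
comparable across hemispheres: the AC of a seed is the contralateral
vertex whose label vector has the largest Pearson correlation ρ with the
seed's.

**Functional correspondence (FC).** The contralateral vertex whose
resting time series is maximally correlated with the seed's, taken from
the argmax of the group-averaged cross-hemispheric correlation matrix.

**Symmetry metrics.** Per vertex,

* **AFCD** = geodesic distance between AC and FC on the target
  hemisphere — small where resting activity correlates maximally near the
  homotopic location;
* **FAD** = geodesic distance between the FCs of an anatomically
  corresponding seed pair after projecting both to one hemisphere through
  the anatomical mapping — distinguishes true asymmetry from symmetric
  "criss-cross" patterns, for which AFCD is large but FAD ≈ 0.

Supporting operations: surface heat-kernel smoothing to a target FWHM,
the x-flip baseline comparison in volume space (`flipDistance`),
supra-threshold FAD clustering, average correlation maps and
contralateral map similarity, a temporal-SNR asymmetry test, and a
synthetic-scene generator with exact ground truth (mirrored deformed
icospheres, geodesic Voronoi parcellations, latent-network time series
with controllable homotopic coupling and injectable asymmetries).

## Worked example

A synthetic study at reduced resolution (642 vertices per hemisphere,
24 regions, 10 subjects, 140 timepoints, homotopic coupling 0.6) with a
40 mm functional displacement injected into a small right-hemisphere
patch:

```r
library(hemicorr)

scene <- makeScene(nSubdiv = 3, nRegions = 24, nSubjects = 10,
                   nTimepoints = 140, rho = 0.6, seed = 42,
                   asymmetry = list(type = "shift", center = 200L,
                                    radius = 15, displacement = 40))

lvL  <- buildLabelVectors(scene@leftMesh,  scene@leftParcellation)
lvR  <- buildLabelVectors(scene@rightMesh, scene@rightParcellation)
acLR <- matchAnatomical(lvL, lvR)
acRL <- matchAnatomical(lvR, lvL)

fc     <- functionalCorrespondence(scene@subjects)
afcdLR <- afcd(acLR, fc$lr, scene@rightMesh)
fadv   <- fad(acLR, fc$lr, fc$rl, scene@leftMesh, acRL)

patch <- scene@truth$patch
cat(sprintf("median AFCD: %.1f mm, median FAD: %.1f mm\n",
            median(afcdLR, na.rm = TRUE), median(fadv, na.rm = TRUE)))
cat(sprintf("patch (n=%d) mean AFCD: %.1f mm, mean FAD: %.1f mm\n",
            length(patch), mean(afcdLR[patch]), mean(fadv[patch])))
highFadClusters(fadv, scene@leftMesh, threshold = "p95",
                minVertices = 3)[, c("cluster", "size", "meanFad", "areaMm2")]
```

Output:

```
median AFCD: 0.0 mm, median FAD: 0.0 mm
patch (n=7) mean AFCD: 41.7 mm, mean FAD: 41.7 mm
  cluster size  meanFad areaMm2
1       1    7 41.73164 798.369
```

Reading it: over the symmetric bulk of the cortex the functional
correspondence coincides with the anatomical one (median AFCD and FAD of
0 mm — the argmax lands exactly on the homotopic vertex), while in the
7-vertex patch both metrics recover the injected 40 mm displacement
(41.7 mm, within half a mean edge length of the truth), and the cluster
rule isolates exactly that patch.

The full pipeline — read surfaces/parcellations/time series, AC and FC in
both directions, optional smoothing, AFCD/FAD, clustering, TSV + JSON
report with a manifest — runs from one config via `runPipeline()`, or
from the shell through the thin wrapper installed at
`inst/cli/hemicorr.R` (subcommands `simulate`, `ac`, `flipbench`, `run`).

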