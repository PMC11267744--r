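---
title: "Validating short association fibre connectivity with retinotopic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating short association fibre connectivity with retinotopic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safmap)
```

## The problem

Short association fibres (SAF, "U-fibres") are thin, short (roughly 3-30 mm)
white-matter pathways connecting mainly adjacent cortical areas through the
superficial white matter. Mapping them in vivo requires sub-millimetre
diffusion tractography, and validating the resulting maps is hard because
no comprehensive ground truth exists. Early visual cortex offers a partial
ground truth: retinotopic organisation predicts strong SAF connectivity
between points of V1, V2 and V3 that represent the *same* visual-field
position, and none between retinotopically non-corresponding points.

`safmap` implements the full analysis chain that exploits this prediction:
it segments V1/V2/V3 into six retinotopic sub-areas each (dorsal/ventral x
three eccentricity bins), maps streamline counts between the 18 sub-areas
into an 18x18 connectivity matrix, quantifies retinotopic order as the
ratio of retinotopic to non-retinotopic percent connectivity, and tests
each matrix element against null tractography that captures the length
bias of streamline tracking. Because real sub-millimetre diffusion data
cannot be bundled, the package ships a synthetic-cortex module that
generates every input the pipeline consumes, with planted ground truth, so
the whole chain is testable end to end.

## Surface phase-map processing

**SNR.** The reliability of the phase-encoded retinotopy signal at a vertex
is the magnitude of the discrete Fourier spectrum at the stimulus
frequency divided by the standard deviation of the one-sided,
DC-excluded amplitude spectrum (`compute_snr()`). Two conventions were
left open by the protocol and are exposed as options: whether the
stimulus bin itself enters the spectrum standard deviation (default
`exclude_stimulus_bin = TRUE`, so the denominator estimates the noise
floor and the gate responds to signal strength), and the neighbourhood
used for smoothing (below). Vertices with SNR below 5 are treated as
unreliable throughout.

**Smoothing.** `smooth_phase_map()` replaces each vertex value by the mean
over its closed 1-ring (the vertex and its mesh neighbours), restricted to
vertices with SNR at or above the threshold, repeated 4 times by default.
Unreliable vertices receive smoothed values from reliable neighbours but
never contribute their own value, and a vertex with no reliable
neighbour keeps its value. Polar angle is a circular quantity (wraps at
360 degrees), so it is smoothed with the unit-vector (resultant) mean;
eccentricity is smoothed linearly. Whether the original protocol smoothed
circularly is not documented; the circular mean is the only choice that
treats 359 and 1 degrees as neighbours, so it is the default for angle
maps. Linear smoothing is contraction-like: the value range never grows.

**Parcellation.** `segment_subareas()` splits each area's reliable
vertices by hemifield — polar angle strictly inside (0, 180) degrees is
the upper visual field and maps to ventral cortex; meridian values (0 or
180 exactly) go to the dorsal set, a fixed tie-break convention — and then
cuts eccentricity, min-max normalised per area, at 1/3 and 2/3. The bins
are equally spaced in the visual-field domain; for a 0-6 degree stimulus
span they correspond approximately to 0-2, 2-4 and 4-6 degrees, and with
the 0.89 degree minimum of the emulated experiment the first bin is
slightly smaller. Bins are lower-inclusive with the last bin closed, so
boundary values are deterministic. Vertices excluded by the SNR gate are
omitted from the parcellation entirely: sub-areas contain only
retinotopically reliable cortex. An area whose reliable vertices all fall
in one hemifield stops with an error by default (`allow_empty_hemifield`
overrides), as does an area with fewer than six reliable vertices.

## Tractography

Propagation is discretised on an icosphere direction set: at each 0.2 mm
step the next direction is drawn from the set members within 30 degrees of
the previous direction (the curvature threshold read as a per-step angle
cap). Fibre tracking (`track_odf()`) weights admissible directions by the
trilinearly interpolated ODF amplitude and requires amplitude above 0.1;
null tracking (`track_null()`) draws uniformly from the cone and instead
requires the step to stay inside the white-matter mask (trilinear value at
least 0.5) — identical mechanics, no orientation information, which is
exactly what isolates the length bias. Null tracking is repeated 10 times
by default to estimate the per-hemisphere null mean counts. Whether null
streamlines were length-filtered before counting is not documented; the
same 3-120 mm window as fibre tracking is applied, which keeps the two
tractogram populations comparable.

Seeding places `seeds_per_voxel_axis`^3 (default 4x4x4 = 64) regularly
spaced points per seed voxel. Each seed propagates bidirectionally: the
initial direction is sampled once, the second half starts from its
antipode, and both halves take their first step along that axis so the
junction has zero turning. Each half is capped at half the maximum
length, so a never-terminating walk ends at exactly 120 mm and is
retained rather than discarded; walks are otherwise terminated by the
amplitude/mask rule or by leaving the grid, and lengths outside 3-120 mm
are discarded.

The direction set size is configurable (12/42/162/642); the default of
162 gives ~15 degree angular spacing, adequate under a 30 degree cone,
at a fraction of the memory of denser tessellations. Voxel-to-mm uses a
voxel-centre affine with 0-based indices throughout.

## Streamline assignment

The cortical ribbon is modelled as the shell between the grey/white
interface mesh and a constant-thickness (2.5 mm) offset along the outward
normals. A point is inside the cortex when its signed height along the
nearest inner-triangle normal lies in [0, thickness] and it sits over
that triangle to within a small lateral slack (0.8 mm) — the slack
absorbs curvature and patch-edge effects. Nearest-triangle queries use a
2-D spatial hash that is exact near the surface (the only regime where
exactness matters) with exact distance ties broken towards the lowest
triangle index.

Streamlines with more than 80% of their arc length inside the ribbon
(segment-midpoint rule) are removed as intracortical. For the rest, the
terminations are the first and last points inside the cortex; each
termination's "surrounding vertices" are the three vertices of the
nearest inner-surface triangle — the protocol's vertex-search rule is not
published, and nearest-triangle is the simplest faithful reading, with a
2 mm distance tolerance beyond which the end is unresolved. A streamline
is assigned to a sub-area pair only if each end's vertex triple is fully
contained in a single sub-area (the subset rule); triples spanning a
border are rejected, never guessed. Pairs are normalised so i <= j, so
assignment is invariant to streamline orientation.

## Connectivity and statistics

Counts of accepted streamlines per sub-area pair form a symmetric 18x18
matrix with the diagonal (self connections) forced to zero. Percent
matrices divide each unique off-diagonal element by the total off-diagonal
count (upper-triangle sum = 100). Closeness is the mean reciprocal
streamline length per element (1/mm), undefined (NA) where no streamline
connects a pair. Percent matrices are computed per hemisphere and then
averaged element-wise into the group matrix; the retinotopic-order ratio
of a 6x6 inter-area block is the summed diagonal over the summed
off-diagonal percent, reported raw and rounded to one decimal as
conventionally presented.

The Poisson sum test treats the observed count of element (i, j) in
hemisphere h as Poisson with that hemisphere's null-tractography mean;
counts and means are summed over hemispheres (a sum of independent
Poissons is Poisson with the summed mean) and the one-tailed p-value is
P(X >= S), inclusive of the observed value — the standard exact
convention, conservative under discreteness. A summed mean of exactly
zero gives p = 1 for zero observed counts and p = 0 otherwise. Null means
are kept as non-integer means of the 10 repeats. The paired t-test works
on per-element differences between observed counts and null means across
hemispheres, one-tailed for a positive mean; zero-variance differences
are defined explicitly (p = 1 for non-positive mean, p = 0 for positive
mean, the t-statistic limits). How zero-variance elements entered the
original analysis is unknown; the limits above make the behaviour
testable. No multiple-testing correction is applied, matching the
published procedure; significance masks are simply p < 0.05 (0.01
available). Sensitivity is the fraction of retinotopic (equal-numbered)
elements detected as significant; specificity the fraction of
non-retinotopic elements left non-significant, per 6x6 block or pooled
over the three inter-area blocks.

## The synthetic cortex, and what it does and does not emulate

`make_mesh()` builds a rectangular grey/white-interface sheet folded
sinusoidally along the row axis, so gyral crowns and sulcal fundi exist
and run orthogonally to the eccentricity axis; the fold phase is
randomised per seed so area borders fall at varying positions relative to
crowns. The six hemifield strips are stacked in the mirrored flatmap
order of early visual cortex, V3d | V2d | V1d | V1v | V2v | V3v: this is
the arrangement in which every V1/V2 and V2/V3 border is shared by
anatomically adjacent strips — vertical meridians at the V1/V2 borders,
horizontal meridians at the V2/V3 borders and the middle of V1 — so
nearest-neighbour retinotopic sub-areas are also spatially adjacent and
V1-V3 pairs are next-neighbours separated by V2, the adjacency structure
the retinotopic hypothesis and the length-bias argument both rest on.
Eccentricity spans 0.89-6 degrees (the emulated experiment's mapped
range) linearly along the orthogonal axis. Gaussian phase noise and a
configurable fraction of low-SNR vertices emulate acquisition noise.

`make_planted_tractogram()` plants U-shaped arcs (cubic Bezier dipping
into the white matter, resampled to ~0.25 mm) whose ends terminate 0.4 mm
above triangles fully interior to the intended sub-areas. Retinotopic
streamlines connect equal-numbered sub-areas of two areas, uniformly.
Noise streamlines (non-retinotopic and intra-area) are sampled with
probability decaying exponentially in the minimum distance between the
two sub-areas' vertex sets: endpoint misassignment in real data comes
from gyral bias and tractography dispersion, which displace terminations
*locally* across borders, so noise concentrates on border-proximal pairs.
The arc geometry makes retinotopic V1-V2 connections shortest and V1-V3
connections longest, as in real cortex.

In the planted validation configuration used by the recovery test
(3 hemispheres, noiseless retinotopy, 600 retinotopic + 30 intra-area
streamlines per hemisphere, i.e. 95% retinotopic), the planted noise is
intra-area. Two reasons: intra-area connectivity is the dominant
false-positive class the method encounters in practice, and inter-area
non-retinotopic counts planted *independently of the null model* are, by
construction, connectivity that length bias cannot explain — the Poisson
test then detects them as significant, which is correct behaviour of the
test, not a specificity failure of the method. Inter-area noise
streamlines remain available (`n_nonretinotopic`) and are exercised by
the recovery and matrix-tabulation tests.

`make_odf_field()` assigns an isotropic baseline amplitude (0.3) to the
slab from 8 mm below the interface up through the ribbon — so the
0.1-amplitude mask covers superficial white matter *and* cortex, as a
multi-tissue ODF fit does, letting streamlines terminate intracortically
— and superimposes sharply tangent-peaked amplitudes along planted bundle
arcs. The mask is by construction exactly the voxels whose maximum
amplitude exceeds the threshold.

Not emulated: BOLD physics and haemodynamics, realistic diffusion signal
formation, fibre crossings, surface reconstruction error, and
DWI-to-structural registration error (all synthetic objects live in one
space; registration is external tooling in the real protocol). Hemisphere
replicates share one geometry and differ only in noise realisations, so
inter-individual anatomical variability is not represented. Passing the
planted-recovery tests therefore demonstrates the correctness of the
analysis chain — segmentation, assignment, counting, normalisation and
inference — under the stated noise model, not the performance of
tractography on real tissue.

## Problem sizes and numerical defaults

The package defaults target desk-scale reproducibility: a 36 x 60 vertex
sheet (1 mm spacing, 2 mm folds, 12 mm wavelength), 6 hemispheres (3 in
the heaviest tests), 600-650 planted streamlines per hemisphere, 1 mm
ODF voxels with 42 directions in the pipeline (162 for direct tracking,
642 where a test needs angular resolution), and null tractography seeded
at every 5th cortical-ribbon voxel with one seed per voxel. The last
choice departs from the 4x4x4-per-voxel seed resolution (which remains
the default of `tracking_params()` and of direct `track_odf()` /
`track_null()` calls): at desk scale, broad spatial coverage of the
cortex with fewer seeds per voxel estimates the null mean across *all*
matrix elements far better than dense seeding of few voxels, and it is
coverage, not per-voxel density, that the Poisson means need. All
generators take explicit seeds, never touch the global RNG state, and are
byte-reproducible; derived seeds are small integers.

Other conventions worth knowing: angles wrap to [0, 360) with values
within rounding error of 360 mapped to 0; the percent denominator errors
on an all-zero count matrix rather than returning NaN; the
retinotopic ratio returns +Inf when the off-diagonal mass is exactly
zero; TCK files default to the format's standard Float32LE (use
Float64LE for bit-exact round trips).

## Limitations

The null tractogram of a hemisphere shares the geometry of its
fibre tractogram by design, but at desk scale its element-wise means are
sparse; elements never visited by the null have mean zero, where the
Poisson test is maximally sensitive (any observed count is significant).
This mirrors the behaviour of the published method and is the main reason
null seeding coverage matters. The t-test variant is markedly less
sensitive at small hemisphere counts, as expected from n-1 degrees of
freedom on 3-6 hemispheres. The ribbon model uses constant thickness; a
true pial surface would make the intracortical filter sharper on curved
cortex. The nearest-triangle reading of "surrounding vertices" is one
faithful interpretation of an unpublished rule and is flagged as such.
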