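---
title: "Methods: image-based morphometry of EC-MSC crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based morphometry of EC-MSC crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`angiocross` quantifies sprouting angiogenesis and endothelial-cell (EC)
to mesenchymal-stem-cell (MSC) crosstalk in microvessel-on-a-chip
cultures from multi-channel fluorescence images: a needle-templated
parent vessel of roughly 200 um diameter runs horizontally through a
collagen gel seeded with MSCs; the endothelium is imaged in red, MSCs in
green, nuclei in blue. Because no suitable public image set exists at
desk scale, every analysis here runs on a synthetic phantom generator
that produces both the images and the exact ground truth behind them.
That choice sets what passing tests can and cannot show: the pipeline
demonstrably recovers known geometry, labels and contrasts under
realistic blur and noise, but the phantoms do not emulate uneven
illumination, cell-shape dynamics beyond rigid ellipsoids, optical
aberrations beyond a Gaussian point-spread function (PSF), or flow; on
real microscope data the preprocessing defaults (background subtraction,
band-pass cut-offs, thresholds) will need adjustment, and conclusions
about biology obviously cannot come from phantoms at all.

# The phantom generators

**3D stacks.** The parent vessel is a cylinder of radius 100 um along x
whose endothelium is rendered as a 10 um thick shell - a hollow lumen,
which is what the edge- and surface-based analyses assume. Sprouts are
tapered tubes (default base/tip radius 40/25 um) growing from the wall;
their radius can be modulated sinusoidally (`roughness_amplitude`,
`roughness_wavelength`) to produce the rough, immature surfaces seen in
monoculture versus the smooth surfaces of supported sprouts. This gives
a surface whose area, volume, curvature statistics and coverage are
known in closed form or by dense parametric sampling. MSCs are rigid
ellipsoids, optionally centred on a named surface so they straddle it.
Imaging is modelled as Gaussian PSF blur, then Poisson photon noise
(`poisson_scale` photons per unit intensity), then Gaussian read noise -
the standard confocal model. All randomness is governed by one integer
seed and the output is bit-reproducible.

**2D time series.** One frame per "day" for ten days at 0.89 um/px, so a
50 px kernel window is 44.5 um. MSCs migrate toward the vessel at
`migration_rate` um/frame (default 10) and, once inside the neighbor
band, their tilt angle decays by `alignment_rate` degrees/frame toward
the vessel axis; a configurable fraction never responds and stays
distant. Two object classes exist only in projection: day-1 intraluminal
seeds, which calibrate the frozen margin band (the deepest sits
`margin_px` = 12 px inside the edge), and wall-adhered cells that wrap
around the tube so their projections overlie the vessel band. The wall
population grows linearly over the frames and is what drives the
red-green colocalization upward over time, exactly as wall adhesion does
in real co-cultures; since such projected objects fall inside the
extracted edges, the particle analysis excludes them, which mirrors how
intraluminal green objects are treated. Cell placement is laid out so no
analysable centroid ever comes within ~5 px of a margin line: the
ground-truth labels are then unambiguous under the pipeline's measured
edge error (under 2 px), which is what makes exact label scoring
meaningful.

# 2D analysis

Colocalization tiles the two channels into non-overlapping windows
(default 50 px), sums intensity per window, and computes Pearson's r
between the red and green window sums; r > 0.6 is called correlated.
The r statistic is invariant to per-channel affine rescaling with
positive gain, so staining brightness does not matter. Larger windows
average out sub-cellular texture and raise r on genuinely colocalized
pairs - the suite checks this monotonicity on the day-10 phantom frame.

Edge extraction processes the red channel by optional white top-hat
background subtraction, Gaussian smoothing (sigma 2 px), a 1-D band-pass
along the vessel axis via the discrete Fourier transform, and Otsu
binarization; per column, the most distant foreground pixels above and
below the vessel centre line are the edges, then a 15-column running
median smooths the traces. Three numerical choices deserve note.
First, the band-pass keeps the DC component along with wavelengths
between 8 px and half the image width: a straight vessel is constant
along x and would otherwise be annihilated; the long-wavelength cut is
aimed at slow illumination gradients, not at the mean. Second,
background subtraction is *off by default here*: a flat-disc top-hat
removes any structure wider than its element, and the vessel band
(~225 px) dwarfs any practical disc, so a 50 px top-hat reduces the
vessel to thin rims and biases both edges inward by 2-4 px. On real,
unevenly illuminated images enable it with a radius well above the
vessel half-height. Third, the vessel centre is estimated from the first
frame and frozen per chip, as are the margins below. For particle
detection the objects (MSCs, tens of px) are smaller than the 101 px
disc, so the top-hat default stays on there. The cited binarization
method is a "modified" Otsu whose modification is not described
anywhere we could find; standard Otsu on the preprocessed image is used
and documented as such.

Particles are 8-connected components of the binarized green channel
(minimum area 20 px^2); each gets an ellipse via second central moments
(with the 1/12 pixel-footprint correction), and the tilt angle is the
undirected angle to the vessel axis folded into [0, 90] degrees. The
margin band comes from day 1: the deepest intraluminal centroid sets
`d_in`, the extraluminal margin equals it, and both freeze for the whole
series. With no day-1 intraluminal object the fallback is the mean
major-axis length of the day-1 objects (a cell-sized band), logged via a
message. Classification is inclusive toward "neighbor" at both
boundaries. One caveat is inherent to the margin construction: the
boundary-defining object itself sits exactly on the band edge, so even
tiny per-frame changes in the Otsu threshold (the green frame content
changes as cells arrive) move its measured depth across the line and
flip its label between neighbor and excluded. This is a tie-break, not
a recoverable truth; ground-truth label scoring therefore runs on
noise-free phantoms and on objects at least 3 px clear of either margin
line, where classification is well-posed. All other objects are scored
exactly.

# 3D reconstruction and tagging

The red channel is median-filtered (cubic neighbourhood, radius 1
voxel) and thresholded (Otsu, or a fixed value reusable across samples,
mirroring same-settings binarization across samples); the largest
26-connected component keeps the vessel with its attached sprouts.
Anisotropic stacks are resampled to isotropic voxels by linear
interpolation first, so that voxel-denominated morphology (the 10-voxel
erosion below) is direction-independent. The lumen is filled by flood
fill, treating the two x faces of the stack as closed since the vessel
axis crosses them.

Meshing is by marching tetrahedra on the 0/1 field sampled at voxel
centres (vertex at `(i + 0.5) * d`), after Gaussian pre-smoothing of the
field with sigma = 1 voxel by default; the six-tetrahedra decomposition
with shared-vertex deduplication yields watertight meshes with
outward-consistent winding for interior masks, and the mask is always
padded by two background voxels so border-touching structures still
close. Pre-smoothing at sigma 1 keeps cylinder area within 0.5% of the
closed form; for sharp-edged objects (calibration cubes, plates) use
`smooth_sigma = 0`, which reproduces a 10 um cube's area and volume to
3% and 0.7%.

The parent vessel region is recovered by morphological opening of the
filled mask with a Euclidean ball of radius 0.6 x nominal radius
(default nominal 100 um, the needle radius): sprouts are thinner than
the ball and vanish, the tube survives; the opening is computed by exact
squared Euclidean distance transforms. The voxel region *outside* the
parent is then eroded by `erosion_px` voxels (default 10) and mesh
vertices inside the eroded outside-region - equivalently, farther than
10 voxels from any parent voxel - are tagged "sprout", the rest
"parent". Reading "outside the parent vessel" as the full complement
(background included) is the only reading under which erosion moves the
boundary *away* from the parent so that parent-surface vertices stay
parent while sprout surfaces beyond the band become sprout; eroding only
the solid-minus-parent region would hollow out the sprouts themselves.
Coverage tagging is voxel-wise: a vertex is "covered" exactly when its
containing voxel is positive in the binarized green channel. Both
taggings are idempotent and partition the vertices.

# Morphometry and curvature

Surface area is the sum of triangle areas, filtered by tag with a
majority rule (a face counts when at least two of its vertices carry the
tag), which keeps parent + sprout areas within 1% of the total on
phantom meshes. Enclosed volume is the absolute sum of signed
tetrahedron volumes over faces of a watertight mesh (non-watertight
input is an error reporting the open-edge count). Surface roughness is
area/volume (1/um), the maturity index; sprout range is the y extent of
sprout-tagged vertices; MSC coverage is covered area over total area,
optionally restricted to the sprout region. All of these obey the exact
scaling laws (s^2, s^3, 1/s) under uniform scaling.

Mean curvature uses the cotangent Laplace-Beltrami mean-curvature
normal, projected on the outward vertex normal, with the sign convention
that a convex bulge is negative and a concave pit positive (solid
sphere: H = -1/r; solid cylinder lateral surface: H = -1/(2r)). Two
numerical choices depart from the most common textbook presentation,
both anchored by the analytic-primitive oracles in the test suite.
Vertex areas are *barycentric* (one third of each incident triangle)
rather than Meyer's mixed Voronoi areas: on lattice-extracted meshes the
many obtuse triangles make the mixed-area allocation systematically
wrong and bias the median curvature by 8-27% on spheres and cylinders,
while barycentric areas keep it within a few percent. Second, meshes
destined for curvature work are faired by one implicit backward-Euler
step of Laplace-Beltrami smoothing, `(M + tL) X = M V`, with t = 10 um^2:
without it, lattice-frequency vertex noise drowns curvature signals as
small as |H| = 0.005 1/um (a 100 um vessel meshed at 1 um). The fairing
time has units of squared length; t = 10 removes sub-3 um detail while
moving a 100 um tube's radius by well under a voxel. Fairing is a mesh
construction option (`fair_t`), not part of `mean_curvature()` itself,
so the exact 1/s curvature scaling law holds identically. Boundary and
non-manifold vertices get `NA` curvature and are counted.

On the phantom contrast this machinery reproduces the expected biology
qualitatively: rough (monoculture-like) sprout surfaces show a wider
curvature histogram with a farther-from-zero median than smooth
(co-culture-like) sprouts, the distributions separate decisively under a
two-sample KS test, and surface roughness (area/volume) is strictly
larger for the rough phantom. Published curvature medians from chip
experiments are reported on an unstated unit scale and are not
comparable to the um-calibrated values here; this is documented rather
than reconciled.

# Statistics

Morphometric endpoints are compared with two-sided Mann-Whitney U tests
(exact null for group sizes up to 8 without ties, normal approximation
with tie and continuity correction otherwise), Bonferroni-adjusted with
an explicit comparison count m - the analysis scripts use m = 3 for the
three endpoints compared together (sprout range, roughness, coverage).
Curvature distributions are compared with the two-sample
Kolmogorov-Smirnov test using the asymptotic p (vertex samples are
large). Orientation time courses use a day x location two-way ANOVA with
type-II sums of squares (robust to the mild imbalance of per-day object
counts) followed by Bonferroni-adjusted pairwise location contrasts
within each day via estimated marginal means; observations are objects,
as in the source analyses, which treats repeated observations of one
chip as independent - a known limitation flagged here rather than
modelled away. The coverage-volume relationship is ordinary least
squares. Significance is p < 0.05 everywhere, held in the exported
constant `SIGNIFICANCE_LEVEL`. A property test calibrates the type-I
error of both rank tests at 0.05 +/- 0.02 over 2000 null simulations
(Mann-Whitney at n = 10 per group, KS at n = 50, where the asymptotic
p is accurate; at n = 20 the asymptotic KS test is conservative,
rejecting at ~0.03).

# Transcriptomic stage

Expression matrices carry mono- and co-culture samples per cell type and
timepoint. Fold changes are `log2((co + eps) / (mono + eps))` with eps
= 1 for count data and half the smallest positive value otherwise. A
gene is a DEG when any timepoint's fold change strictly exceeds +1 or
falls strictly below -1 (so exactly 1.0 is not differential), with
direction taken from the largest-|FC| timepoint. The published
description normalizes (mean 0, sd 1) "and" log-transforms without
fixing the order; both quantities are computed, and the clustering input
is the z-normalized profile, recorded here as an interpretation. With
only two timepoints z-profiles collapse onto two patterns, so planted
cluster-recovery checks use four timepoints. Clustering is agglomerative
Ward (ward.D2) on cosine distances, cut at the smallest k at which every
cluster's mean pairwise Pearson correlation exceeds 0.6 - "correlation
within each cluster" is aggregated as the mean over member pairs, since
the source does not define the aggregation; singletons pass vacuously,
and an unreachable criterion returns singletons with a warning. Cluster
labels encode cell type, dominant direction and peak-time order
(EC-U1, MSC-D2, ...).

PPI screening consumes a local candidate table (gene pairs with
database, experimental and text-mining confidence scores in [0, 1]) -
a deliberate file contract in place of live database queries. An edge
survives when all three scores strictly exceed 0.9, its endpoints are
DEGs in two *different* cell types, and neither gene is differential in
both cell types. The bundled `ppi_candidates_synthetic.tsv` is a
synthetic fixture (as its name says): it demonstrates the filter
retaining the documented high-confidence ligand-receptor pairs
(BMP2-BMPR1A, BMP4-BMPR1A, IL1B-IL1R1) against decoys, and makes no
claim about live database content.

# Problem sizes and determinism

The test and acceptance workloads use: curvature/geometry oracles at
1 um voxels (sphere r = 25, cylinder r = 100 x 100, plate 60 x 60 x 20);
the 2D series at 800 x 600 px for 10 frames; the 3D contrast pair at
2.5 um voxels over a 400 x 560 x 300 um domain; 2000 null simulations
for the type-I calibration; and a 2000-gene expression phantom. These
sizes were chosen so each suite completes in minutes on a single core
while leaving comfortable margins to the tolerances; halving the voxel
size strictly reduces the geometric errors (a convergence property the
suite also checks). Every stochastic step is seeded explicitly, and the
generators are bit-reproducible for a given spec and seed.
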