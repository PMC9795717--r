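# angiocross

Image-based morphometry of endothelial cell (EC) – mesenchymal stem cell
(MSC) crosstalk in microvessel-on-a-chip cultures.

## The problem

In needle-templated chips, a ~200 µm-diameter endothelial tube (the
*parent vessel*) runs through a collagen gel seeded with MSCs. Over days
of co-culture, MSCs migrate to the vessel wall, align with it, adhere,
and support the outgrowth of capillary sprouts whose surfaces become
smoother and longer than in EC monoculture. `angiocross` implements the
quantitative imaging pipeline behind those observations, for anyone
analysing two-channel (red = endothelium, green = MSC) microscopy of
engineered microvessels:

- **2D time series** — colocalization by kernel-window Pearson
  correlation (the image is tiled into windows, default
  50 × 50 px = 44.5 × 44.5 µm; per-window intensity sums of the two
  channels are correlated, r > 0.6 ⇒ colocalized); vessel-edge
  extraction (Gaussian smoothing, 1-D Fourier band-pass along the
  vessel axis, Otsu binarization, per-column extremal foreground);
  MSC particle analysis (connected components → moment ellipses → tilt
  angle ∈ [0°, 90°] vs the vessel axis) with neighbor/distant
  classification inside a margin band frozen from day 1.
- **3D z-stacks** — 3D median filter + Otsu, largest connected
  component, iso-surface reconstruction by marching tetrahedra,
  parent/sprout vertex tagging (ball-opening parent region; the region
  outside the parent eroded by 10 voxels), MSC-coverage tagging from
  the binarized green channel, and morphometry: sprout range, surface
  area (Σ triangle areas), enclosed volume (signed tetrahedra),
  surface roughness = area/volume (µm⁻¹, a maturity index), coverage
  ratio, and per-vertex signed mean curvature
  H = −⟨K, n̂⟩ / (2A) from the cotangent Laplace–Beltrami
  mean-curvature normal K (convex bulge ⇒ H < 0; a solid sphere has
  H = −1/r, a cylinder's side −1/(2r)).
- **Statistics** — Mann–Whitney U (exact for n ≤ 8) with explicit
  Bonferroni m, two-sample Kolmogorov–Smirnov for curvature
  distributions, day × location two-way ANOVA with Bonferroni post hoc
  contrasts, OLS regression of coverage vs sprout volume; significance
  at p < 0.05.
- **Transcriptomics** — log2 fold changes of co- vs monoculture per
  cell type and timepoint, DEG calling at |log2FC| > 1 (strict),
  Ward/cosine temporal clustering cut at the smallest k with all
  within-cluster mean pairwise Pearson correlations > 0.6, and
  cross-cell-type PPI screening keeping edges whose database,
  experimental and text-mining confidence scores all exceed 0.9.

Because no raw chip images are publicly deposited, the package ships a
first-class synthetic phantom generator (2D series and 3D stacks with
PSF blur, Poisson + Gaussian noise, and exact ground truth) on which
every stage is validated; see the methods vignette
(`vignettes/angiocross-methods.Rmd`) for the model and its limits.

## Worked example

```r
library(angiocross)

# a 10-day co-culture phantom at 0.89 um/px
ph <- make_coculture_series_2d(phantom_spec_2d(seed = 3))

# daily colocalization
sapply(1:10, function(t) {
  m <- kernel_density_maps(ph$series$frames[[t]], 50)
  density_correlation(m$red, m$green)$r
})
#>  [1] -0.292  0.160  0.329  0.428  0.508  0.574  0.652  0.663  0.673  0.692
```

The correlation starts negative on day 1 (MSCs scattered in the gel,
away from the red vessel band), rises as cells migrate and adhere, and
exceeds the 0.6 colocalization threshold from day 7 — the dynamics that
in real co-cultures accompany sprout maturation. Window-size dependence
on the day-10 frame shows the expected monotone rise (10 px: 0.48,
25 px: 0.58, 50 px: 0.69).

```r
# 3D: mesh a 100-um-radius vessel segment and check its curvature
mask <- primitive_mask("cylinder", radius = 100, length = 100,
                       voxel_size = c(1, 1, 1))
mesh <- mean_curvature(mesh_from_mask(mask, smooth_sigma = 1, fair_t = 10))
median(mesh$H, na.rm = TRUE)     # ~ -0.005 = -1/(2r), convex => negative
```

The numbered scripts under `analysis/` run the full study on the
phantoms — `01_simulate_phantoms.R`, `02_coculture_2d_analysis.R`,
`03_reconstruct_3d.R`, `04_morphometry_stats.R`,
`05_transcriptomics_ppi.R` — each writing tables under `results/`.

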