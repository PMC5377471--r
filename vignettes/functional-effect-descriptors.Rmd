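---
title: "Measuring functional effects of benthic fauna: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional effects of benthic fauna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioturb)
```

`bioturb` quantifies three routes by which sediment-dwelling invertebrates
mediate ecosystem processes — particle reworking, burrow construction, and
bioirrigation — and provides the heteroscedastic inference machinery used to
relate them to species identity. This vignette documents the models behind
each stage, the parameters that matter, the numerical choices, and the
limits of what the synthetic validation can show.

## 1. Particle reworking from profile images (f-SPI)

A profile image is a photograph of an aquarium wall under UV illumination:
dark water above a rough sediment–water interface, a mid-gray sediment
matrix, and saturated magenta tracer particles (pink fluorescent
luminophores). The stage proceeds in three steps, each an exported function:

1. **`detect_tracers()`** marks pixels inside an HSV window (hue 0.75–0.97
   around magenta, saturation ≥ 0.5, value ≥ 0.3) and removes isolated
   single pixels (no true 8-neighbour). A real tracer particle (~80 µm,
   imaged at 56 µm/px with UV bloom) always spans at least two adjacent
   pixels, so the filter removes only sensor speckle. The filter matters
   most for `L_max`, which is a single order statistic and therefore
   maximally sensitive to one spurious deep pixel.
2. **`detect_interface()`** takes, per column, the first row (top-down)
   whose luminance exceeds a threshold (Otsu split of the luminance
   histogram by default — water and sediment are strongly bimodal), then
   smooths the elevations with an 11-column running median. Columns with no
   supra-threshold pixel are flagged invalid; if more than half the columns
   are invalid the image is rejected as degraded rather than silently
   producing nonsense.
3. **`reworking_metrics()`** converts each tracer pixel to a depth below
   the *local* interface of its own column. Depths are clamped at zero
   (tracer resting on the surface), pixel-weighted (particle identity is not
   recoverable from a still image), and reported in cm: `L_med`, `L_mean`,
   `L_max`, plus `SBR` = (max − min valid elevation) × pixel size.

Measuring depths from the local interface rather than a global mean plane is
deliberate: whenever `SBR > 0` a global plane would systematically bias the
shallow statistics by up to half the relief.

**Known quantisation limit.** Per-column interface elevations are recovered
to within one pixel, but `SBR` is a *range* statistic of a median-filtered
profile: when the true elevation extremum spans fewer columns than the
median window, each extreme can be clipped by one pixel, so `SBR` can
deviate from the true relief by up to two pixels while every individual
column is within one. The tests assert one-pixel agreement on the
per-column profile and on the depth statistics.

## 2. Burrow morphometrics from CT volumes

Volumes are 8-bit grids (x, y, z; z = 1 at the top, depth increasing
downward) where bright voxels are dense sediment and dark voxels are voids.

**Segmentation.** `grow_regions()` implements threshold-based seed-point
region growing: a segmented region is the maximal connected set of voxels
with gray ≤ threshold reachable from a seed. Connectivity defaults to 26
because thin diagonal burrow segments fragment under 6-connectivity.
Reachability is delegated to igraph's connected-components routine on an
explicitly built voxel adjacency; the test suite proves exact voxel-set
equality against an independent breadth-first flood fill on random volumes
up to 32³ under both connectivities. `auto_seed()` places one deterministic
seed per sub-threshold component below the sediment surface (components
living only in the water column are excluded), and `segment_burrows()`
chains surface estimation, Otsu thresholding of the below-surface histogram
(the acquisition threshold is instrument-specific, so it is exposed and
estimated rather than hard-coded), water-column masking, seeding and
growing.

**Surface map.** `estimate_surface()` is the 2-D analogue of the interface
detector: first supra-threshold voxel per (x, y) column, median-filtered
5 × 5. Burrow openings leave deep first-hit outliers that are lumen, not
surface, so elevations are capped at median + 3 MAD before smoothing; wide
opening clusters would otherwise drag the local surface down and swallow
whole burrows.

**Metrics.** `B_vol` is the exact voxel count × voxel size³ — no estimate,
an identity checked in the tests. `B_max` is the maximum depth of any
labelled voxel below the local surface. `B_SA` is the area of an
iso-surface mesh: the labelled set is smoothed with a Gaussian (σ = 1
voxel), meshed by marching tetrahedra (six tetrahedra per cell around the
main diagonal, consistent face diagonals, hence watertight), and the
triangle areas are summed. Voxel-face counting was rejected because its
staircase artifact overestimates smooth surfaces by up to ~50%, and `B_SA`
feeds biogeochemical interpretation; the mesh reproduces a carved cylinder's
lateral + base area to within 0.2% and a sphere's area to within 0.5% at
radius 15 voxels (asserted at 3% in the tests). Mesh faces capping burrow
openings at the sediment surface are excluded by default — a lumen opening
is not a sediment–water interface created by the burrow wall — by extending
open burrows upward past the smoothing support and discarding triangles
above the local surface; `include_openings = TRUE` reverses this.

## 3. Bioirrigation and overyielding

`delta_br()` is deliberately minimal: Δ[Br⁻] = end − start concentration of
an inert bromide tracer in the overlying water, optionally minus a
faunal-free control drift. Negative values mean tracer drawn into the
sediment, i.e. stronger irrigation. No normalisation by duration or water
volume is applied by default because the statistic is conventionally
reported in mg L⁻¹ over a fixed 8 h incubation; `per_hour = TRUE` divides by
duration. No control correction is applied by default since absolute changes
are the conventional report.

`d_max()` computes transgressive overyielding against the *maximally*
performing monoculture. Responses are first mapped to a performance scale
(negation for "lower is more" responses such as Δ[Br⁻]) so that mixtures
and monocultures are compared on a common footing; `D_max` is computed per
mixture replicate and averaged, with a Student-t CI over replicates
(n = 5 by default in the designs generated here). The per-replicate-then-
average choice (rather than a bootstrap over treatment means) was made
because it yields an honest replicate-level dispersion estimate at the
small n typical of these designs.

## 4. The varIdent GLS engine

The observation model is

$$y = X\beta + \varepsilon,\qquad
  \varepsilon \sim N\!\big(0,\ \sigma^2\,\mathrm{diag}(\delta_{g(i)}^2)\big),
  \qquad \delta_{\mathrm{ref}} = 1,$$

a linear model whose residual standard deviation differs by the level of a
grouping factor. Estimation profiles everything possible out of the
likelihood: given the log-ratios, the fixed effects are exactly weighted
least squares with weights $1/\delta^2$ and $\sigma^2$ has a closed form, so
the optimiser (L-BFGS-B) works only on the $g-1$ free log-ratios. This both
reduces dimension and guarantees the WLS identity at the optimum.
Numerical choices:

* log-ratios start at per-group OLS residual sds and are box-bounded at
  ±6 (sd ratios within ~400×) — without the bound, a group whose few
  residuals are nearly collinear with the fit drives its weight to infinity
  and makes $X'WX$ numerically singular;
* the homoscedastic case bypasses optimisation entirely (closed form), so
  the OLS reduction is exact, not approximate;
* REML uses the standard restricted likelihood including the
  $\log|X'WX|$ term; ML and REML log-likelihoods agree with the independent
  `nlme::gls` reference to better than 10⁻⁴ on every fixture in the test
  suite (typically 10⁻¹⁰);
* `AIC = −2·logLik + 2(p + (g−1) + 1)`, counting the fixed effects, the
  free ratios and the reference sd;
* t statistics use `df = n − p`; rank-deficient designs are rejected with
  the aliased terms named; non-convergence is flagged on the result, never
  silent.

**Model selection.** `backward_select()` follows the two-stage protocol
standard for heteroscedastic linear models: (1) choose the variance
structure by REML AIC between the homoscedastic and varIdent fits with the
full fixed structure; (2) reduce the fixed structure by backward
elimination under ML — at each step every droppable term (respecting
marginality) is refitted without that term; among the terms whose
likelihood-ratio p ≥ α (default 0.05) the one whose removal most lowers AIC
is dropped; elimination stops when all remaining terms are significant.
The final model is refitted by REML. The trace records every candidate's
AIC, L-ratio, df and p. Dropping by the ML LRT with AIC as the tie-breaking
guide (rather than by AIC alone) reflects the protocol this package
implements: the LRT is the declared arbiter of fixed-structure reduction,
with AIC informing the order.

**Small-sample calibration — a known limitation.** At the design scale of
these experiments (4 groups × 5 replicates, n = 20) the χ² reference for a
3-df ML likelihood-ratio test is anticonservative: the exact rejection
probability of the nominal 5% test is
$P\{F_{3,16} > \tfrac{16}{3}(e^{\chi^2_{3,0.95}/20} - 1)\} = 0.092$,
and simulation reproduces ~0.10. Consequently backward selection on pure
null data retains the factor in ~11% of runs rather than 5%, returning the
intercept-only model in ~87–94 of 100 seeds depending on the seed stream.
This is a property of the χ² approximation itself, shared by any
implementation that uses it (including the standard mixed-modelling
software this engine is checked against); the package reports it rather
than substituting a small-sample correction. The REML comparison of
variance structures, by contrast, is well calibrated (~5.7% rejection under
the null in the suite's 200-seed check).

## 5. What the synthetic generators emulate — and what they do not

The generators exist so that every stage has an exact oracle, and their
defaults encode the study conditions of the assembly experiment they
emulate: four community treatments (three monocultures and an equal-biomass
mixture), two core shapes sharing a 1178 cm³ habitat volume, five replicates
per cell, 56 µm profile pixels, 81 µm CT voxels, an 8 h bromide incubation,
and burrow archetypes whose maximum depths (7.2, 2.2, 2.8 cm) sit inside
the depth ranges observed by CT for gallery, U-tube and I-shaft burrows.

* **Profile images** draw tracer depths from a half-normal kernel (scale =
  `mixing_depth_scale`) plus a 2% deep-transport fraction placed uniformly
  along burrow tracks down to `burrow_max_depth`. The half-normal was
  chosen because it reproduces the qualitative contrast between a surficial
  `L_med` and a deep `L_max` characteristic of real profiles; it is a
  placement model, not a transport model. Mean mixed-depth scales were set
  so the half-normal mean (scale·√(2/π)) spans the observed ~0.29–0.87 cm
  range across archetypes. The interface is a smoothed, slope-limited
  Gaussian random walk whose amplitude parameter fixes the true relief.
  Each particle is rendered as two interface-following adjacent pixels, so
  the ground truth is exact at pixel resolution and the isolation filter
  can never remove signal.
* **Volumes** carve burrows as unions of spheres along parametric paths: a
  persistent correlated random walk with Poisson branching for galleries, a
  two-limb semicircular-bend path for U-tubes, a near-vertical shaft for
  I-shafts, and the 1/3-scaled union of all three for the mixture. The
  carved voxel set *is* the ground truth; matrix/void gray levels (200/30)
  and Gaussian noise are applied afterwards, so a noise-free volume is
  segmented exactly.
* **Experiment tables** are group mean + Normal noise with group-specific
  sd. Default means sit on the bromide scale (−486.79 for the strongest
  irrigator, with the remaining treatment means reconstructed from its
  printed contrasts) and default sds (230/120/120/100 mg L⁻¹) were chosen
  once from the reported CI half-widths; the additive core-shape effect
  (−312 mg L⁻¹ toward circular cores) reproduces the observed shape
  contrast.

What passing these tests does **not** show about real data: no hydrodynamic
or diagenetic transport is modelled (tracer placement is statistical, not
mechanistic); sediment texture, lighting gradients and stitching seams of
real composites are absent, so the colour rule's field robustness is
untested here; CT artefacts (beam hardening, rings, partial-volume blur)
are not simulated, only Gaussian gray noise; and real burrow walls are
compacted and lined, which affects gray levels in ways a binary
carve-and-noise model cannot capture. Tidal immersion–emersion behaviour
is deliberately out of scope.

## 6. Problem sizes and reproducibility

Every generator takes an explicit integer seed and is bit-reproducible;
nothing touches the global random state except through those seeds
(`derive_seed()` maps a master seed to per-stage streams). The validation
suite uses desk-scale problem sizes chosen to keep the oracles exhaustive:
220 × 400 px images at 25 mm⁻¹ (0.025 cm/px), volumes up to 64 × 64 × 176
voxels at 0.05–0.085 cm, 100 random ≤ 32³ volumes for the flood-fill
equivalence, 1000 null datasets for LRT calibration, and 100 for selection
behaviour. The physical geometry (8 cm sediment, 4 cm water, burrow depth
ranges) is preserved at these resolutions; only the pixel/voxel pitch is
coarser than the 56/81 µm type defaults.

## 7. Known limitations

* JPEG composites must be converted to PNG/TIFF before reading (no JPEG
  reader among the package's dependencies).
* `B_SA` and `B_max` depend on the estimated surface map; very wide burrow
  openings (wider than the 5 × 5 median window plus the MAD cap can
  absorb) can still bias the local surface downward.
* The χ²-based LRT and the selection procedure built on it are
  anticonservative at n = 5/group (section 4); treat borderline p-values
  near 0.05 accordingly at that scale.
* `D_max` is undefined when the best monoculture performance is exactly
  zero and is reported as an explicit error; responses whose performance
  direction is ambiguous must be declared, not guessed.
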