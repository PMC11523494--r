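---
title: "Dental topographic analysis of chewing-surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental topographic analysis of chewing-surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molartopo)
```

Dental topographic analysis (DTA) quantifies the form of a chewing surface
without landmarks or homology assumptions, which makes it usable across
deeply divergent taxa — mammalian molars and the molariform (pars molaris)
region of insect mandibles alike. `molartopo` implements the full measuring
chain on triangle meshes: preprocessing, six metrics, a synthetic-surface
generator for validation, an orientation-sensitivity protocol, and the
statistical layer used to compare groups of specimens.

## The metrics and what they measure

All operations act on a `trimesh` (vertices in mm, triangular faces,
occlusal surface facing +z).

**Dirichlet normal energy (DNE)** integrates the squared variation of the
unit-normal field over the surface; for a smooth surface the density is
$\kappa_1^2 + \kappa_2^2$, so DNE grows with curvature — a sharpness
measure. We compute angle-weighted vertex normals, interpolate them
linearly over each face, and measure the squared differential in the
face's first-fundamental-form metric; the per-face contribution is density
times area. Two conventions from standard practice are applied: the top 1%
of per-face contributions is discarded ("DNE 99%", count-based: the
$\lceil 0.01F\rceil$ largest; a mass-based variant is available), and
boundary triangles are retained. Each face is labelled convex or concave by
the sign of the mean curvature of the same interpolated field, giving the
exact split `dne_total = dne_convex + dne_concave`. DNE is invariant under
rigid motions and under uniform scaling (density scales as $L^{-2}$, area
as $L^2$).

**Relief index (RFI)** is the log ratio of 3D surface area to the 2D
projected occlusal area, a crown-height (hypsodonty) proxy. We use the
half-log (square-root) convention $\mathrm{RFI} = \tfrac12\ln(SA/OA)$: on
published group means this convention — not the raw log — reproduces the
relief values that accompany them (e.g. $0.5\ln(3.058/1.181) = 0.476$,
$0.5\ln(2.963/1.118) = 0.487$), so the half-log is the default and the raw
log is a config switch (`rfi_half_log = FALSE`).

**Projected occlusal area (OA)** defaults to the *exact union* of all
projected triangles (`oa_mode = "union"`), computed by a Green's-theorem
sweep over edge sub-segments: parameter-free and exact up to floating
point. For parity with alpha-shape-based tools, `oa_mode = "alpha_auto"`
triangulates the projected vertices (Bowyer–Watson Delaunay), keeps
triangles with circumradius at most alpha, and sweeps alpha upward on a
geometric grid from the mean projected edge length until the complex is a
single connected polygon containing every point; the alpha used is
reported, and a Check2D-style flag marks a >5% disagreement with the
union area.

**Orientation patch count rotated (OPCR)** counts the "tools" of the
surface: faces are binned into 8 azimuth sectors (boundaries at
$22.5^\circ + k\,45^\circ$, i.e. sectors centred on the compass
directions), edge-connected same-sector runs form patches, patches smaller
than 3 faces are dropped, and the count is averaged over 8 rotations of
the mesh about z in steps of $5.625^\circ$. Faces whose normal is within
$0.1^\circ$ of vertical carry no meaningful aspect and are left unbinned;
this flatness cutoff (configurable) makes a flat sheet report OPCR 0 and
keeps wear facets from fragmenting into noise patches. Both the sector
layout and the cutoff are package choices exposed in `topo_config()`.

**PCV (portion de ciel visible)** estimates morphological wear resistance
as ambient-occlusion visibility: 256 directions are laid out
deterministically (Fibonacci spiral) on the +z hemisphere, and a vertex
sees a direction if it faces it ($d \cdot n > 0$) and a ray from the
vertex (offset $10^{-4}$ of the bounding-box diagonal along its normal)
escapes the mesh. Rays are cast against a bounding-volume hierarchy; a
brute-force all-faces caster in the test suite certifies exact agreement.
The reported PCV is the area-weighted mean of per-vertex visibility
(weights: one third of incident triangle areas); the unweighted mean is
reported alongside because published values do not state the reduction.
No RNG is involved anywhere, so PCV is exactly reproducible.

**3D surface area** and **enclosed volume** are the usual summed triangle
areas and divergence-theorem volume.

## Preprocessing chain

Real scans go through `clean_mesh()` (drop zero-area faces, floating
vertices and connected components below 1% of the face total — the
isolated-pieces threshold is not standardised anywhere, so 1% is our
configurable default), `decimate()` (Garland–Heckbert quadric edge
collapse to ~10 000 faces, with boundary-constraint planes and a
normal-flip guard; achieved counts land within ±2% of the target and
surface area changes by well under 1% on smooth meshes), and
`taubin_smooth()` (λ = 0.9, μ = −0.95, 10 iterations, uniform umbrella
weights). Our Taubin step restricts the displacement to the vertex-normal
direction: this attacks geometric noise identically to the full-vector
step but eliminates tangential sliding, so boundary vertices of open
crops participate without creeping inward and an exactly planar sheet is
a fixed point. On a closed sphere the (0.9, −0.95) pair preserves volume
to within 2% over 10 iterations where a pure positive-step Laplacian
shrinks it by more than 5%.

Triangle-count sensitivity is why decimation precedes smoothing: several
metrics are summative, and comparisons are only meaningful at a common
resolution.

## Synthetic molars, wear, and what passing tests show

`make_molar()` builds height-field surfaces from Gaussian cusps (round
bumps, the forb-feeder form) and Gaussian crests (full-width ridges, the
grass-feeder form) over a ~1.5 mm base with mild height noise (0.5% of
the extent, so nothing is exactly flat). The default cusped preset
carries ~1 mm cusps and lands in the observed range of real grasshopper
molars (DNE a few hundred, RFI ≈ 0.4, OPCR ≈ 150–200, PCV ≈ 0.55,
SA ≈ 5 mm²); the default grid (72² vertices) triangulates to ~10 000
faces, matching the decimation target of real scans. What the generator
does *not* emulate: overhangs and re-entrant anatomy (a height field has
none), enamel-like layering, segmentation artefacts, and realistic noise
spectra. Tests passing on these surfaces certify the measuring chain, not
biological conclusions.

`apply_wear()` models attrition as a soft planar abrasion: the height
field is clamped at the $(1-w)$ quantile of vertex heights through
$z' = z - \delta\,\mathrm{softplus}((z - z_c)/\delta)$, with the rounding
scale $\delta$ set to a quarter of the removed depth, so heavier wear
gives blunter rims. The soft clamp does two physically motivated things a
hard truncation does not: it rounds the facet rim analytically (no
post-hoc mesh smoothing, whose diffusion dishes the facet and *inflates*
patch counts), and it squashes height variation on the facet toward zero
— worn facets are polished. Under this operator, increasing wear applied
before the scan-processing chain (the order in which real specimens reach
the scanner) drives every metric monotonically in the empirically
observed direction: DNE, RFI, OPCR and 3D SA fall, PCV rises. Note that
quantile truncation is nearly idempotent — after clamping, the clamped
mass sits at the cut, so wearing twice at 20% digs only slightly deeper
than once; repeated wear nests pointwise between the single stage and the
compounded quantile rather than equalling either.

## Orientation sensitivity

Occlusal alignment is partly subjective, so `orientation_sensitivity()`
re-measures a mesh under five variants — original and ±tilt about x and y
— and reports a population CV per metric (population SD over mean, the
convention for such reliability summaries). The default tilt is 5°: small
enough that the surface is still "approximately occlusal", large enough
to move the projection-dependent metrics; published protocols describe
the tilt qualitatively, so exact CV magnitudes are not reproducible, only
the pattern. The pattern is sharp: DNE and 3D SA are rigid-motion
invariants, so their CVs sit at numerical zero (≤ 1e-6 and ≤ 1e-9
respectively), while RFI, OPCR, PCV and OA move with orientation. This
zero-CV check is the module's core regression test.

## Statistics

`signed_rank_exact()` (the paired test) drops zero differences (Pratt's
method is an option), mid-ranks ties, and for n ≤ 25 computes the null
distribution of the positive-rank sum exactly by convolution over all
$2^n$ sign assignments (doubled midranks keep tied ranks integral). The
two-sided p is the doubled smaller tail, capped at 1 — the convention
required to produce p = 1 at the null-mean statistic. `mann_whitney_exact()`
computes $U_a = \#\{(a,b): a > b\}$ (+½ per tie) and reports the smaller
of $U_a, U_b$; tie-free samples with $n_1+n_2 \le 25$ get the exact
doubled-tail p from the count recurrence. With ties the exact distribution
is data-dependent: the default follows the behaviour of the standard R
test — a normal approximation with tie and continuity correction, flagged
as `normal_approx` in the result — and `ties = "enumerate"` computes the
exact permutation p for small samples. Both tests are verified against
brute-force enumeration in the suite, and the tie fallback is the route by
which one published 7-vs-11 comparison (U = 11, p printed as 0.014) is
reproducible: its tie-free exact p is 0.011.

`effect_sizes()` reports pooled Cohen's d, paired Cohen's d and the
rank-based $r = |z|/\sqrt{N}$ side by side; published "Cohen's d" columns
are not always reproducible from summary tables with any single formula,
so all three are given and none is forced to agree.

`fit_model_family()` fits all 8 subsets of {side, sex, species} for one
metric — by OLS or with a per-individual random intercept (lme4, ML
rather than REML so that AICc is comparable across fixed-effect sets;
k counts fixed effects plus two variance components) — and ranks them by
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ with Akaike weights.
Factors are coded left/female/first-species as reference, so positive
coefficients mean right, male, or second species greater. With constant
cell-mean data the fits reduce to exact group-difference identities,
which is how printed model coefficients are recomputed in the acceptance
script.

## Numerical choices and limitations

* Exact union area splits each candidate edge at every intersection and
  classifies sub-segments by coverage at points offset $10^{-7}$ of the
  bounding-box diagonal; coincident outlines are de-duplicated on a
  $10^{-12}$-relative grid. Edges whose exact reverse exists are interior
  and skipped outright.
* Delaunay triangulation jitters input deterministically by $10^{-9}$ of
  the diagonal to break the exact cocircularity of grid-sampled points;
  the area effect is far below every tolerance used.
* Rotations are about the origin of the input coordinates (the only
  reproducible pivot when none is recorded).
* Decimation cannot preserve area that lives in sub-facet roughness: on a
  surface whose noise wavelength is near the target edge length, area
  loss is genuine, so the area-preservation guarantee applies to smooth
  meshes (and the pipeline smooths after decimating).
* Simulation sizes in the test suite are chosen for calibration, not
  drama: exact-test size checks use 2 000 null replicates; mixed-model
  coefficient recovery uses 200 simulations of 100 individuals, the
  regime where ML Wald intervals attain their nominal coverage.
* The convex/concave DNE partition rule and the vertex-to-surface PCV
  reduction are not standardised in the literature we follow; both are
  documented package choices (mean-curvature sign; area-weighted mean)
  and both alternatives are exported.
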