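---
title: "Methods: quantifying hierarchical frustule porosity from voxel volumes"
author: "frustule3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying hierarchical frustule porosity from voxel volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices
behind the package: what each stage computes, which parameters matter,
what the synthetic generators do and do not emulate, and where the
design was genuinely open.

## The system and the data model

The valve of a *Coscinodiscus* sp. frustule is a stack of three porous
silica layers — foramen (bottom, one large central pore per hexagonal
unit), areola chambers (middle, large cavities joined by small
connecting pores), cribrum (top, small circular macropores) — and the
silica itself carries a sparse population of elongated nanopores.
Tomographic reconstructions of such material arrive as 3D scalar grids
with a physical voxel size.

Volumes are stored as R arrays with `dim = c(y, x, z)`: a slice
`[, , k]` is an ordinary image matrix and `z`, the third dimension, is
the slicing/projection axis by default. Every direction-dependent
operation takes an explicit `axis` argument, so the memory layout is a
convention, not a constraint. The `GridSpec` carries the voxel edge
length in nanometres and a cumulative voxel offset so that crops retain
provenance. Binary volumes use `TRUE` for pore/void (the "black voxel =
void" display convention is metadata, not storage).

## Segmentation chain

**Threshold.** The intensity histogram of a two-phase reconstruction is
bimodal; the threshold is selected by between-class variance
maximization (Otsu) on a 256-bin histogram of the whole volume. Two
guards matter in practice: a constant or unimodal histogram is rejected
with advice to pass a manual threshold (Otsu would silently split a
single mode), and extremely unbalanced mixtures — e.g. a nanopore phase
at a volume fraction of 10⁻³ with no free space in the field of view —
do not produce a visible second mode, so the same rejection applies;
segmentation of such data should use a manual threshold or start from
binary input. The selector is equivariant under affine intensity
rescaling because the bins scale with the data range.

**Cleanup.** `morphologicalCleanup(bin, nPairs)` applies `nPairs`
opening passes (erosion then dilation) with the 6-connected structuring
element. The number of passes applied to real data is an
acquisition-dependent choice; the default is one pass, and zero is the
right value for noise-free synthetic volumes.

**Connectivity.** The pore phase uses 26-connectivity and the solid
phase 6-connectivity, a complementary pair that avoids topological
paradoxes in the Euler characteristic downstream.

**Watershed.** Touching pores are separated on the Euclidean distance
transform (computed exactly by the separable parabola method, with the
outside of the volume counted as solid). Markers are the regional
maxima that survive h-maxima suppression: a maximum seeds its own
object only if its dynamics — its height above the saddle towards a
deeper basin — reaches `hMin`, which is expressed in nanometres so the
setting is resolution-independent. Flooding proceeds in decreasing
distance order from the markers; ties are resolved by queue insertion
order (first-in, first-out), which keeps equal-distance fronts flat so
that a uniform cylindrical throat is cut near its waist, and which is
fully deterministic, so labellings are bit-reproducible. For the
default valve unit, `hMin = 200` nm sits between the dynamics of
chamber maxima (hundreds of nm) and every spurious maximum
(≤ ~100 nm); any value in that window returns one label per chamber.

## Porosity and layer metrology

Porosity is the exact voxel-count ratio. The pore volume distribution
Prob(v) uses logarithmic bins, ten per decade, matching the three-decade
spread of nanopore volumes; the density normalizes to one over its
support and the per-pore volumes are kept raw.

Layer boundaries are placed at inflection points of the solid-fraction
profile: the profile is smoothed with a moving average whose window is
physical (default 50 nm), differentiated centrally, and local maxima of
the derivative magnitude above `minSlope` (default 0.02) of the global
maximum become candidates. Candidates are then ranked not by the
derivative peak but by a *detrended step score*: a straight line is
fitted to the smoothed profile on each side of the candidate (windows
from one to three smoothing widths out, truncated before any
neighbouring candidate so a large adjacent step cannot leak in), both
lines are extrapolated to the candidate position, and the gap between
the two predictions is the score. A genuine step keeps its full height
under this score, while a smooth ramp (both fits extrapolate to the
same value), digitization wiggles on a ramp, and transient features
such as a band of connecting pores all score near zero. The strongest
`nLayers − 1` candidates are kept — necessary because the porosity
contrast between the foramen and the narrow chamber bottoms is an
order of magnitude weaker than the cribrum step at the printed
dimensions. Sub-slice positions come from the derivative-weighted
centroid around each peak.
Per-layer porosities are exact voxel ratios over the resulting slabs,
and the total porosity is their thickness-weighted mean — the only
combination that reproduces the whole-volume porosity when the layers
tile the axis (checked as an invariant in the tests). Applied to the
published per-layer values (180 nm at 33%, 200 nm at 27%, 2500 nm at
78%) this weighting gives 71.6%, not the ~64% quoted alongside them;
the package reports the coherent weighted value and leaves the
discrepancy visible rather than emulating an unstated combination rule.

Chamber metrology reports the mid-plane equivalent diameter (the circle
with the chamber's cross-section area — robust to hexagonal sections,
unlike an inscribed circle), the height, and the volume, all measured
within the areola slab when a layer model is supplied so that foramen
and cribrum pores absorbed into a chamber label do not bias the chamber
dimensions. The connectivity graph joins labels whose voxels touch
across the watershed boundary; the throat equivalent diameter comes
from the contact area estimated by the Cauchy projection of the
per-normal face counts, `sqrt(n_y² + n_x² + n_z²)` face units, which is
exact for a flat cut of any orientation and removes the systematic
staircase inflation (up to ~√3) that a raw face count suffers on
oblique throats.

## Minkowski functionals and the shape finder

Per pore, the package computes V0 = V, V1 = S/6, V2 = H/(3π) and
V3 = χ. All discrete estimators are linear functionals of the 2×2×2
local configuration statistics of the padded object mask:

* **V0** is exact: voxel count × h³.
* **S** uses the Crofton line formula over the 13 lattice directions
  (3 axis, 6 face-diagonal, 4 body-diagonal): S = 4h² Σ w_r C_r/|v_r|,
  where C_r counts phase changes along offset v_r and the weights are
  the spherical Voronoi measures of the direction set (0.045778,
  0.036981, 0.035196; they sum to ½ over the 13 unoriented directions).
* **H** uses the Crofton plane formula, H = 2π ⟨∫ χ₂D dt⟩, averaged
  over 9 lattice plane normals (3 axis, 6 face-diagonal) with the
  spherical Voronoi weights of that set (0.093566 for axis normals and
  (1 − 3·0.093566)/6 for diagonal normals, computed once by numerical
  integration of the nearest-direction partition of the sphere); the 2D
  Euler characteristic of each section lattice comes from
  inclusion–exclusion cell counting.
* **χ** is the Euler characteristic of the union of closed voxel cubes
  (vertices − edges + faces − cubes), i.e. the 26-connected foreground
  convention; it is exact on digitized topologies (ball 1, solid torus
  0, thick shell 2).

On a digitized ball of radius 20 voxels these estimators land within
1% (V0), 3% (S) and 3% (H) of the analytic values, with χ exact — the
test suite pins these bounds, together with a closed-form prolate
spheroid oracle (surface by the standard formula, integral mean
curvature by quadrature over the profile curve).

The shape finder follows the standard construction: x = πV0V2/(4V1²),
y = 8V1V3/(3πV2²), planarity P = (1−x)/(1+x), filamentarity
F = (1−y)/(1+y). Both vanish for a sphere; elongation raises F,
flattening raises P. Because the analysis targets flattening and
elongation of isolated, handle-free pores, the Euler characteristic
entering y is fixed at 1 by default (`forceEuler`), while the measured
χ is reported separately. Objects touching the volume boundary carry
truncated functionals and are flagged and excluded from the F–P
centroid by default; a non-positive V2 (possible for very small or
rough objects, where the formulas lose meaning) marks the label invalid
rather than dropping it silently.

## Chords and specific surface

A chord is a maximal same-phase run along a ray with both endpoints on
the interface. The default ray set is the three lattice axes pooled:
runs are exact there, and for isotropic bodies any single direction
already samples the full chord distribution (for a ball the mean chord
is 2D/3 regardless of direction). Uniformly sampled orientations are available for anisotropic media,
traced at half-voxel steps with trilinear phase lookup thresholded at
0.5 — interpolation smooths the staircase boundary, which otherwise
sheds spurious sub-voxel chords on grazing rays. Chords
touching the volume boundary are discarded by default — truncation
biases the mean downward — with a `truncate` policy available since the
solid-phase distribution of a dilute field is dominated by finite-size
effects either way. The specific surface of the isolated pores is
S/V = 4/⟨l_p⟩, reported in nm⁻¹ and m² cm⁻³ (1 nm⁻¹ = 1000 m² cm⁻³).
The engine is pinned against a brute-force run-length oracle on random
volumes and against the sphere limits (⟨l_p⟩ → 2D/3, 4/⟨l_p⟩ → 6/D).

## Spectral anisotropy

The 2D Fourier transform of a projection is the central slice of the
3D spectrum, so the squared modulus of the transformed projection reads
as a small-angle scattering pattern I(qx, qy). Conventions, chosen once
and recorded in the objects: q = 2π × spatial frequency, so a feature
at q corresponds to a half-period r = π/q; the projection mean is
subtracted before the transform (removing the q = 0 spike); no window
is applied by default, which keeps Parseval's identity exact and is
appropriate for fields without strong edge discontinuities (a Hann
window is available). Azimuthal averages pool both half-axes of a ±15°
sector and bin radially at one q-grid step.

The Porod fit is a least-squares log-log slope over a stated q band;
smooth interfaces give −4. The cutoff scans downward from the fit band
and reports the largest q whose intensity departs from the fitted line
by more than a tolerance in log10 units (default 0.15 — the cutoff was
located by eye in the original analyses, and a fixed documented
tolerance makes it reproducible); a profile that never departs has no
cutoff and says so. Characteristic distances are r = π/q. For fit
bands on digitized data, the usable Porod window sits between the
structure scale and the voxel scale — roughly q ∈ [0.6, 1.5] nm⁻¹ for
5–10 nm objects at 1 nm voxels; closer to the Nyquist limit (π nm⁻¹)
digitization flattens the spectrum.

## Synthetic generators and what passing tests mean

All generators voxelize by centre-sampling (a voxel is pore iff its
centre lies inside the continuous shape), an unbiased volume estimator
with trivial analytic oracles, and all are pure functions of
(spec, grid, seed).

**Nanopore fields.** Pore sizes are drawn by volume — log-uniform over
the 10–1000 nm³ envelope — with an aspect ratio uniform in [2, 4] and
semi-axes a = b = (3v/4πρ)^{1/3}, c = ρa. Parameterizing by volume
rather than by raw semi-axis ranges pins the generator to the measured
quantity and guarantees every ground-truth volume lies in the envelope.
Orientations follow a one-parameter axial Watson distribution
(density ∝ exp(κ cos²θ) about the preferred axis); κ = 0 is isotropic
and the default κ = 8 produces the clear but imperfect global
orientation seen in the nanopore population. The default volume
fraction is the measured 1.922×10⁻³. Pores are placed by rejection
sampling with a bounded attempt budget (default 100 per pore), a
minimum separation of two voxels, and a per-pore single-component
check; exhausting the budget fails loudly with the achieved fraction.
Note the scale coupling: at this fraction with the 10–1000 nm³ size
law, a 256³ nm³ volume holds ~160 pores; populations of ~2000 pores
require the full reconstruction scale (~2×10⁸ voxels). The tests
therefore check exact count recovery against the generator's own
ground truth, at 256³.

**Frustule units.** A hexagonal patch (1, 7 or 19 chambers) between a
foramen and a cribrum layer, at the published dimensions (180/1200 nm
foramen, 200/300 nm cribrum, 2500 nm chambers, 140 nm connecting
pores, chamber mid-diameters drawn from the 1200/1500 nm modes with
30 nm jitter). The lattice parameter is not a published quantity; the
2 µm default was chosen because it makes the foramen porosity of the
unit ≈ π·600²/(hexagonal cell area) ≈ 33%, consistent with the
measured layer porosity, and it is user-overridable. Chamber
cross-sections are regular hexagons whose across-flats width holds a
narrow bottom value over the dividing-wall band (230 nm) and then
widens linearly to the cribrum — a trapezoidal vertical section —
scaled so the area-equivalent diameter at mid-height equals the
requested mid diameter (bottom width 0.9× the mid width; the top
follows from the linear profile). Connecting pores are 140 nm
horizontal cylinders between neighbouring centres, placed at
deterministically staggered heights across the bottom third of the
chamber height, so the porosity profile shows no sharp throat band
that could shadow the gentle foramen inflection. Ground truth records
the exact per-layer porosities of the emitted volume, the boundary
slices, the chamber table and the adjacency list.

What the generators do **not** emulate: image-formation physics
(curtaining, beam damage, missing wedge), section-alignment errors,
anisotropic resolution, the cribellum layer, surface roughness of real
silica, or spatial clustering of nanopores. Passing recovery tests
therefore demonstrates that the estimators are correct on clean
geometry at realistic scales and noise from digitization alone — not
that segmentation of a particular real acquisition is automatic.

## Problem sizes and determinism

The test and acceptance runs use a 256³ nanopore field (1 nm voxels), a
7-chamber valve unit at 20 nm voxels (~19M voxels) with one 19-chamber
unit at 25 nm voxels for the diameter histogram, and 192³ ball fields
for the Porod property — sizes at which every stage, including the C++
distance transform and watershed, completes in seconds to about a
minute. All randomness flows through explicit integer seeds; generators
restore the caller's RNG state, the watershed is deterministic by
construction, and rerunning the pipeline with the same config and seed
reproduces the summary JSON byte for byte.

## Known limitations

* Otsu thresholding cannot segment phases at ~10⁻³ volume fraction
  without free space in the histogram (see above); this is inherent to
  between-class variance, not to the implementation.
* The Crofton surface estimator carries a known orientation bias of up
  to ~7% for perfectly axis-aligned flat faces (the 13-direction
  average of |cos| under-integrates); for smooth curved bodies the
  residual is well under the tested 3%.
* Throat diameters assume a roughly flat watershed cut through the
  throat; strongly funnel-shaped necks bias the contact-area estimate
  upward by a few percent even after the Cauchy correction.
* The layer detector assumes plateau-like layers separated by sustained
  level changes; gradual compositional gradients have no well-defined
  inflection and are reported as "no layering detected".
* `r = π/q` reads a cutoff as a half-period; it is an order-of-size
  estimate (the tests assert bracketing within a factor of two of the
  generator's semi-axes, not equality).
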