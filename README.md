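# frustule3d

Multiscale 3D porosity quantification for diatom frustule volumes.

Centric diatoms such as *Coscinodiscus* sp. build a silica shell (the
frustule) whose valves are a stack of three nested porous layers: an
internal **foramen** (a honeycomb of hexagons, each with one ~1.2 µm
central pore, ~180 nm thick), an intermediate layer of **areola
chambers** (~2.5 µm high cavities with roughly trapezoidal vertical
sections, linked by ~140 nm connecting pores), and an external
**cribrum** (~200 nm thick, perforated by ~300 nm circular macropores).
On top of this hierarchy, the silica walls themselves contain a sparse
population of elongated ellipsoidal **nanopores** (volumes 10–1000 nm³,
volume fraction ≈ 2×10⁻³) with a preferred orientation. Quantifying
this hierarchical pore network from tomographic reconstructions
(FIB-SEM slice-and-view, serial-section array tomography, electron
tomography) is the problem this package addresses, for microscopists and
porous-materials researchers who have voxel volumes and need numbers.

## What it computes

Starting from a grayscale or binary voxel volume with a physical voxel
size (multi-page TIFF, MRC2014, or raw + JSON sidecar):

* **Segmentation** — Otsu bimodal threshold on the volume histogram,
  erosion/dilation cleanup, 6/26-connected component labelling, and a
  deterministic 3D distance-transform **watershed** with h-maxima
  marker suppression to separate chambers touching through throats.
* **Porosity metrics** — exact pore fractions (global, masked,
  per-layer), the pore volume distribution Prob(v) over log bins,
  equivalent sizes v^(1/3), layer-boundary detection from inflections of
  the solid-fraction profile, chamber metrology (mid-plane equivalent
  diameter, height, volume) and the chamber connectivity graph with
  throat diameters.
* **Minkowski shape finder** — per-pore functionals V0 = V,
  V1 = S/6, V2 = H/(3π), V3 = χ, and the planarity/filamentarity pair

  P = (1−x)/(1+x), F = (1−y)/(1+y), with
  x = π·V0·V2/(4·V1²), y = 8·V1·V3/(3π·V2²),

  both zero for a sphere, F large for elongated pores, P for flattened
  ones (the F–P diagram).
* **Chord analysis** — pore/solid chord-length distributions f(r) along
  lattice rays (or sampled orientations), their first moments, and the
  specific surface of isolated pores S/V = 4/⟨l_p⟩.
* **Spectral anisotropy** — 2D projections P(x,y), their power spectra
  I(qx,qy) (q = 2π × spatial frequency), ±15° azimuthal sector
  averages, Porod log-log slopes (−4 for smooth interfaces), cutoff
  detection, and characteristic distances r = π/q.
* **Synthetic volumes** — generators for geometric primitives,
  ellipsoidal nanopore fields, and full three-layer frustule units, all
  with exact ground truth, so every estimator has a parameter-recovery
  test.

## Worked example

Generate a nanopore field at the study conditions and push it through
the full pipeline:

```r
library(frustule3d)

g    <- gridSpec(c(256, 256, 256), voxelSize = 1)   # 1 nm voxels
spec <- nanoporeFieldSpec(orientationAxis = "y", seed = 42)
nf   <- generateNanoporeField(spec, g)

res <- runPipeline(list(input = nf$volume, openPairs = 0,
                        projectionAxes = "z", seed = 1))
str(res$summary[c("porosity", "pore_count", "mean_pore_chord_nm",
                  "specific_surface_m2_cm3", "fp_centroid")])
#> List of 5
#>  $ porosity               : num 0.00192
#>  $ pore_count             : int 160
#>  $ mean_pore_chord_nm     : num 4.89
#>  $ specific_surface_m2_cm3: num 818
#>  $ fp_centroid            :List of 2
#>   ..$ F: num 0.129
#>   ..$ P: num 0.0223
```

Reading the output: the recovered volume fraction (0.00192) sits within
a tenth of a percent of the generator's target (1.922×10⁻³); the pore
count equals the number of pores placed by the generator; the mean pore
chord ⟨l_p⟩ of ~4.9 nm gives a specific surface 4/⟨l_p⟩ ≈ 818 m² cm⁻³;
and the shape-finder centroid (F ≈ 0.13 ≫ P ≈ 0.02) classifies the population
as elongated rather than flattened, consistent with the generator's
axial Watson orientation distribution. Projecting along z and comparing
the ±15° sector averages of I(qx,qy) shows the qy curve (the elongation
axis) shifted to low q relative to qx — the spectral signature of the
anisotropy.

The same workflow applies to a synthetic valve unit:

```r
sp <- frustuleSpec(seed = 1)                 # printed layer dimensions
fr <- generateFrustule(sp, frustuleGridFor(sp, voxelSize = 20))
layers <- detectLayerBoundaries(fr$volume)   # inflection-point model
ws <- watershedSeparate(fr$volume, hMin = 200)
chamberMetrics(ws, layers)                   # 7 chambers, D, h, V
connectivityGraph(ws, minFaces = 4)          # 12 throats, ~140 nm
```

A thin command-line wrapper for shell use lives at
`inst/scripts/frustule3d.R` (`generate`, `convert`, `segment`, `run`
subcommands).

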