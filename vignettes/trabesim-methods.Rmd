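---
title: "Methods: image-based finite-element localization of trabecular bone damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite-element localization of trabecular bone damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabesim)
```

## The problem

Trabecular bone — the porous strut-and-plate architecture inside vertebrae —
fails under cyclic compression by the progressive collapse of its weakest
cross-section, often initiated at a single overloaded trabecula. `trabesim`
implements a two-track, image-based linear-elastic finite-element (FE)
workflow for locating that weak region:

* a **2D track** driven by DXA-like areal density maps (clinical
  resolution, ~0.5 mm/pixel), producing the *strain index of bone* (SIB)
  and its per-cross-section profile; and
* a **3D track** driven by micro-CT-like volumes (~25.6 µm voxels),
  producing minimum-principal-strain fields, damage-progression metrics
  across interrupted-fatigue conditions, and two levels of sub-models down
  to the single-trabecula scale.

A Wöhler (S-N) module relates the SIB of an undamaged specimen to its
fatigue life through the power law `SIB = a · N_f^b`, fitted by least
squares in log-log space with t-based 95% prediction bounds.

All models are linear elastic; this is a deliberate idealization. The
damage quantity is the **minimum principal strain** ε_p,min (the most
negative principal strain under compression); the 2D summary statistic is

> SIB = max |ε_p,min| · 10⁴

over all integration points, and the per-row profile averages the four
integration-point values of each element before taking the per-row
maximum, so a SIB value is attached to every cross-section height.

## Image processing and morphometry

Micro-CT style volumes are processed exactly as a standard bone-imaging
chain would: Gaussian smoothing (σ = 1.5 voxels by default, separable
kernel, reflective borders — a flat field is preserved exactly), linear
min-max rescale to 8-bit, Otsu thresholding (the threshold minimizing
intra-class variance over the 256-bin histogram; voxels strictly above the
threshold are bone), and removal of floating specks by keeping the largest
26-connected component. 26-connectivity preserves thin oblique
trabeculae; exact ties between components are broken toward the first
component in scan order. Otsu is applied globally by default; a per-slice
mode exists behind a flag because per-slice ("local") thresholding is a
plausible alternative reading of common practice, but the global
intra-class-variance definition is the one we implement as primary.

BV/TV profiles divide bone voxels by the voxels of the *nominal circular
footprint* of the core, not the bounding box — the specimens are
cylindrical cores, and a box denominator would bias BV/TV low. Heights are
normalized with 0 at the clamped (bottom) face. Effective areas follow
`A_eff,i = A_n · (BV/TV)_i` with `A_n` the nominal cross-section
(153.94 mm² for a Ø14 mm core). Stacked profiles average 8 consecutive
slices by default.

## Meshing

Meshing is direct voxel-to-hexahedron conversion: one cube element per
(optionally coarsened) bone voxel, shared nodes deduplicated, restricted
to the largest *face-connected* element set — corner-only contacts
transmit no stiffness and would make the system singular. Coarsening uses
a majority vote over each block with ties counted as bone (conservative
for load paths). We chose this over isosurface-plus-shrink-wrap surface
meshing because it is the standard micro-FE approach, fully reproducible,
and satisfies the customary image-based hexahedral quality thresholds
(aspect ratio ≤ 3, corner angles < 160°, scaled Jacobian > 0.7) by
construction: an undistorted voxel mesh reports exactly (1, 90°, 1). The
quality report nevertheless computes all three measures from the actual
node coordinates, so distorted meshes are diagnosed rather than assumed
good.

The 2D model is one square plane-strain element per nonzero map pixel.
Its uniform thickness equates the model cross-section with the real
cylinder: `t = A_n / W`, `W` being the nonzero-column width.

## The FE solver

Both element types use full Gauss integration (2×2 and 2×2×2). We did not
reproduce reduced integration with hourglass control: without
stabilization it is unstable, and for voxel meshes at trabecular
resolution shear locking of the fully integrated trilinear brick is
negligible. Materials are isotropic with ν = 0.3; Young's modulus is
uniform for 3D models (calibrated per damage condition from the
experimental stiffness) and per-element for 2D models (below). Units are
mm / N / MPa throughout.

The load case mirrors the uniaxial test: a total compressive force `F`
(1200 N default) applied to the top face and a clamped bottom face. Three
load idealizations are available:

* `"equal"` (default) — equal nodal shares on the loaded face, the plain
  reading of "uniformly distributed" nodal loads;
* `"consistent"` — tributary-area lumping, the exact lumping of a uniform
  traction. Equal shares are *not* a consistent traction (corner nodes are
  overloaded), so analytic patch tests use this mode, where a homogeneous
  column reproduces the closed-form strain to machine precision;
* `"platen"` — the loaded face moves as a rigid platen (uniform prescribed
  axial displacement, lateral dofs free), scaled to transmit exactly `F`.
  This emulates a specimen glued into a rigid aluminum endcap. The
  localization pipelines use it: pushing a fixed nodal force into a
  locally compliant boundary voxel or pixel produces a strain spike at the
  loaded face that is an artifact of the load idealization, not damage.

The roller (axial-only) bottom constraint exists for validation; its
remaining rigid-body modes are pinned at two bottom nodes chosen so the
pins are strain-free (the second pin controls only the in-plane rotation).

The assembled sparse system is solved by Jacobi-preconditioned conjugate
gradients to a relative residual of 1e-8 (configurable), with a dense
direct factorization below 500 free degrees of freedom. Equilibrium is
checked by summing bottom-face reactions against the applied force.
Principal strains use a vectorized closed form (trigonometric solution of
the symmetric 3×3 eigenproblem); plane-strain states include the zero
out-of-plane strain as a principal value. Tests verify both against
`eigen()`.

## The 2D DXA-based model

The global modulus comes from the initial force-displacement response,
referred to the weakest cross-section:
`E₀ = (F / min(A_eff)) / (u / L_eff)` with `L_eff` = 16 mm between the
endcaps. Gray levels are mapped to local moduli by the mean-normalized
linear law `E_e = E₀ · g_e / mean(g)` over nonzero pixels — the unique
linear map whose average reproduces the measured global modulus; whether
real DXA grays are density-linear or display-scaled is not knowable from
the data, so a power-law exponent is exposed as an option (default 1).
Zero pixels are excluded from the mesh, and rows are indexed from the
clamped bottom with normalized height `(row − ½)/n_rows`.

## 3D damage series, sub-modeling

The damage series solves one independent mesh per interrupted-fatigue
condition (pre-fatigue, interruptions, post-fatigue) with that condition's
measured uniform modulus; no mesh morphing or registration is attempted,
matching how re-scanned conditions are treated. Percentage differences use
the earlier (or experimental) value as denominator — the convention that
reproduces the published deltas (73%, 112%, 16%) from their printed
operands — and are quoted as rounded magnitudes.

Sub-model I extracts an axial slab (disk) centered on the global model's
critical slice, re-voxelized from the *full-resolution* volume (never by
subdividing coarsened elements, so thinner trabeculae invisible to the
global model are resolved), and is force-driven exactly like the global
model (top load, clamped bottom); a displacement-driven variant is
available behind `drive = "displacement"`. Sub-model II is a brick
centered on sub-model I's peak location; all its boundary-plane nodes are
driven by trilinear interpolation of sub-model I's displacement field
(cut nodes falling in a pore are snapped to the nearest parent element
within half an edge, else an error is raised), the interior is
unconstrained, and element components not anchored by any driven node are
dropped. Because trilinear interpolation is exact for linear fields, a
homogeneous parent state is reproduced inside the brick to solver
precision — the consistency check the tests enforce.

The "weakest trabecula" is segmented as the face-connected set of
elements, grown from the peak element, whose element-averaged |ε_p,min|
is at least half the peak; its orientation is the angle between the
principal axis of the member-centroid scatter and the load axis. The 50%
threshold is a reporting choice (it isolates the overloaded strut from
the background field), not a failure criterion.

## Wöhler regression

`fit_wohler()` is ordinary least squares of log₁₀(SIB) on log₁₀(N_f)
(`a = 10^intercept`, `b = slope`), with R², adjusted R², and the
two-sided slope test on n−2 degrees of freedom. Runouts (tests stopped at
the 8·10⁵-cycle ceiling without failure) are plotted apart and excluded
from the fit by default — no censoring machinery is implied by the
source workflow — with `include_runouts = TRUE` as a sensitivity refit.
Prediction bounds are the standard t-based interval
`ŷ ± t · s · √(1 + 1/n + (x − x̄)²/Sxx)`, symmetric in log space and
narrowest at the mean log-life. Note that a fitted `b` on decreasing data
is negative; magnitude and sign are reported separately because published
coefficient tables sometimes quote |b|.

## Synthetic phantoms: what they emulate, and what they do not

The generator produces a *miniature trabecular core*: a 64³ grid at
25.6 µm spacing (a 1.64 mm cylinder inscribed in the grid) built from
Gaussian-filtered white noise, thresholded per slice at the quantile that
realizes a target BV/TV profile (default 0.30, a typical vertebral
value), optionally depressed inside a weak band, and cleaned to the
largest 26-connected component. The threshold is iterated a few times so
the *realized* profile after cleanup meets the target. Two structural
choices matter:

* **Correlation length 0.03 mm.** At desk scale the phantom cannot match
  both the absolute trabecular width (~0.1-0.2 mm) and the number of
  trabeculae across the core. We preserve the *architecture-to-diameter
  ratio* (structural wavelength ≈ 1/20 of the diameter, as in a real
  14 mm core) rather than the absolute strut width; with the absolute
  width the miniature specimen would contain only a handful of structural
  units, and single pores would dominate every projection.
* **Axial elongation 2.** Vertebral trabecular bone is transversely
  isotropic, with plates and rods aligned with the habitual load. The
  axial correlation length is twice the transverse one, which also makes
  a transverse weak band the structurally critical feature it is in
  reality.

Specimen-scale dimensions (Ø14 × 22 mm, L_eff 16 mm, A_n 153.94 mm²)
enter the workflow through the morphometry and calibration parameters,
not the phantom grid.

DXA projection sums the bone path length along one transverse axis,
block-averages to the pixel size, and min-max rescales to 8-bit; before
rescaling the map conserves bone mass exactly. The pipeline's DXA
emulation adds two detector-realism steps: a point-spread blur (0.7 px,
of the order of a clinical densitometer's ~2-pixel FWHM in-plane
resolution) and a region-of-interest erosion (pixels not fully inside the
specimen silhouette, plus a one-pixel margin, are background) — rim
partial-volume pixels would otherwise become near-zero-modulus elements
whose strain diverges as 1/gray. Both are available as plain options of
`project_dxa()` and default off there (the pure geometric projection),
on in `localize_damage_2d()`.

The fatigue generator samples lives log-uniformly over 10³-1.2·10⁶
cycles, places SIB on `a·N_f^b` (defaults a = 450, b = −0.25, chosen to
emulate a 21-specimen campaign with SIB a few tens over that life range)
with lognormal scatter σ_log = 0.15, and flags lives at or beyond the
8·10⁵ ceiling as runouts.

**What passing tests show — and what they do not.** The phantoms exercise
every code path with known ground truth (band location, volume fraction,
generating fatigue law), so the tests demonstrate correctness of the
machinery and the internal consistency of the localization chain. They do
not demonstrate clinical validity on real DXA/micro-CT data: real scans
add beam hardening, registration error, anisotropic noise, marrow
contrast and segmentation ambiguity that the generator deliberately omits.

## Problem sizes and numerical choices

The shipped analyses use sizes chosen for a desk-scale, single-CPU run:
64³ phantoms; the 2D model at 2-voxel pixels (32 × 32 map); the 3D global
model at coarsen = 2 (51.2 µm elements, ~10⁴ elements, ~4·10⁴ dofs);
sub-model I at full voxel resolution over a 0.3-0.4 mm disk; sub-model II
on a ~0.5 mm brick subdivided ×2. Solver tolerance 1e-8; PCG iteration cap
50 000; degenerate meshes (empty bone sets, all-zero maps, floating
components) raise early, descriptive errors rather than singular solves.
Deterministic tie-breaks: first-in-scan-order for equal components and
equal peaks; Otsu ties resolve to the midpoint of the optimal range.

At these sizes the 3D critical-slice localization is near its resolution
limit: the weak band spans ~6 voxel layers and its factor-2 strain
elevation competes with strut-level extreme-value fluctuations, so
band-localization of the *global peak* is reliable for the shipped
configuration but not guaranteed for every random seed — the per-row /
per-slice profiles, which average over cross-sections, are the robust
readout, exactly as they are for real specimens.

## Known limitations

Linear elasticity only (no damage evolution, contact, or buckling — the
identified trabecula's instability is discussed, not simulated);
isotropic tissue modulus; no image registration between damage
conditions; the DXA track ignores true X-ray attenuation physics; TBS is
out of scope (proprietary); runouts are excluded rather than treated by
censored likelihood.
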