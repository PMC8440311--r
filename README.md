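# trabesim

Image-based linear-elastic finite-element localization of damage in
trabecular bone cores.

Cylindrical trabecular cores (nominally Ø14 × 22 mm) tested in cyclic
compression fail by the collapse of their weakest cross-section.
`trabesim` locates that region from imaging alone, along two tracks:

* **2D, DXA-based.** The areal density map (≈0.5 mm/pixel) becomes a
  plane-strain quadrilateral model, one square element per pixel, with
  local moduli `E_e = E0 · g_e / mean(g)` distributed around the global
  modulus `E0 = (F / min(A_eff)) / (u / L_eff)` calibrated from the
  initial compression response. The damage statistic is the strain index
  of bone, `SIB = max |ε_p,min| · 10⁴`, with a per-row profile (the four
  integration-point values averaged per element, then the per-row
  maximum) that flags the weakest cross-section height.
* **3D, micro-CT-based.** The segmented volume (Gaussian blur σ = 1.5,
  8-bit Otsu, largest-component cleanup) becomes a voxel hexahedral mesh
  (aspect ratio 1, scaled Jacobian 1 by construction), solved under the
  experimental load case (compressive F at the top face, clamped bottom,
  ν = 0.3, condition-specific uniform E). Damage progression across
  interrupted-fatigue conditions is summarized by peak |ε_p,min|,
  percentage changes vs pre-fatigue, and the critical slice; two-level
  sub-modeling (force-driven disk, then a displacement-driven brick fed
  by trilinearly interpolated boundary displacements) descends to the
  single overloaded trabecula and its orientation.

A Wöhler module fits `SIB = a · N_f^b` by least squares in log-log space
(runouts at the 8·10⁵-cycle ceiling excluded by default) with t-based 95%
prediction bounds, and seeded generators produce trabecular phantoms with
controllable BV/TV profiles and weak bands, DXA-like projections, and
fatigue datasets, so the full toolchain runs without any external data.

## Worked example

A 64³ phantom with a weak band (BV/TV halved) centered at 75% of the
specimen height, pushed through both tracks:

```r
library(trabesim)

spec    <- phantom_spec(weak_band = c(0.75, 0.05, 0.5), seed = 7)
phantom <- make_phantom(spec)
phantom
#> <binary_volume> 64 x 64 x 64 voxels @ 0.0256 mm, 59051 bone voxels (22.5%)

bvtv_profile(phantom, stack_size = 8)
#> <morphometry_profile> 64 slices, BV/TV 0.286 (min 0.150 @ z=0.71), A_n 2.11 mm^2

p2 <- localize_damage_2d(phantom, e0 = 3029, f = 1200)
p2$sib
#> <sib_result> SIB = 4584, weakest row 25 (z = 0.766)

p3 <- localize_damage_3d(phantom, e = 3029, f = 1200, coarsen = 2)
p3$critical$z_norm       # 0.766
p3$quality
#> <mesh_quality> AR = 1.000, max angle = 90.0 deg, min scaled J = 1.000
```

Both tracks place the weakest cross-section at normalized height ≈ 0.77,
inside the generated band and co-located with the BV/TV minimum (0.15 at
z = 0.71): the 2D clinical-resolution model and the 3D micro-FE model
agree on where damage will start. The SIB magnitude is large because the
desk-scale phantom (1.64 mm cylinder) carries the full 1200 N test load;
localization, the model's purpose, is scale-free under linear elasticity.

Fatigue regression on a generated 21-specimen campaign:

```r
fit <- fit_wohler(make_fatigue_dataset(n = 21, seed = 11))
fit
#> <wohler_fit> SIB = 337.5 * N_f^-0.2286  (n = 20, R2 = 0.667, R2_adj = 0.648, p = 1.12e-05)
prediction_bounds(fit, c(1e4, 1e5))   # 95% t-based envelope
```

One runout was excluded (`n = 20`); the negative exponent reflects the
decreasing SIB-life trend.

A thin command-line front end over the same functions is installed at
`inst/cli/trabesim.R` (subcommands `synth-phantom`, `synth-fatigue`,
`dxa2d`, `micro3d`, `submodel`, `fatigue`).

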