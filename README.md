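# fluorscan

Forward simulation of planar fluorescence imaging in deep, multiply
scattering tissue, for people comparing **full-field illumination** (camera
imaging under wide-area excitation) with **point-scanning illumination**
(a raster-scanned pencil beam read out by one integrating detector) — in
reflection (epi-) or transmission (trans-illumination) geometry, across the
visible/near-infrared window where tissue optical properties change
strongly with wavelength.

## The model

Light transport through the digital phantom — a 55 × 55 × 15 mm slab with
embedded cylindrical fluorescent targets (r = 1 mm, h = 2 mm, quantum-dot
photophysics) — uses the continuous-wave diffusion approximation

    −∇·(κ∇Φ) + μₐΦ = q,   κ = 1/(3(μₐ + μs′)),

with Robin partial-current boundaries and buried isotropic sources.
Fluorescence is the standard three-step chain: excitation solve → volumetric
emission source S_fl = Φ σ N₀ A_ex at the targets → emission solve → surface
radiance at the detector plane.  Tissue spectra come from the scattering
power law μs′(λ) = a(λ/500)⁻ᵇ and a whole-blood chromophore sum
μₐ(λ) = B·S·μₐ,oxy + B(1−S)·μₐ,deoxy (+ optional water/fat/melanosome
hooks).

The scanning instrument has a fast path: because the background is
homogeneous and the slab is effectively infinite relative to the scan area,
scanning the beam is equivalent to translating the target-and-detector
assembly, so a single reference solve plus a per-mode **coupling factor**
renders the whole 45 × 45 raster; the brute-force per-position instrument is
retained as its validation oracle.  Spatial resolution is quantified by the
Sparrow criterion: the mean of the two per-target FWHMs of the profile
through a two-target image.

## Worked example

```r
library(fluorscan)

ph <- slab_phantom(targets = two_targets(z = 0))   # two targets, mid-slab

ff <- full_field_image(ph, lambda_ex = 600, lambda_em = 620, mode = "reflection")
sc <- scan_image_fast(ph,  lambda_ex = 600, lambda_em = 620, mode = "reflection")

sparrow_resolution(ff)
#> <Sparrow resolution>  per-target FWHM 7.27 / 7.27 mm -> 7.27 mm (full_field, reflection)
sparrow_resolution(sc)
#> <Sparrow resolution>  per-target FWHM 5.60 / 5.60 mm -> 5.60 mm (scanning, reflection)
```

With the targets in the middle of the slab the full-field system resolves
the 16 mm pair at about 7.3 mm while the scanning system reaches about
5.6 mm — the point-scanning geometry narrows the sensitivity profile and
buys roughly a quarter better resolution under identical illumination power
density.  Everything is tibble/ggplot2-friendly:

```r
glance(sparrow_resolution(sc))
autoplot(sc, trans = "log10")

run_depth_sweep(z = -5:5, instrument = "scanning",
                mode = "reflection", lambda_em = 700)
# one row per depth: mean/peak detected radiance + Sparrow resolution
```

Experiments can also be driven from YAML configurations
(`load_config()` / `run_experiment()`, with a thin CLI in `inst/cli/`), and
`make_mini_fixture()` provides a sub-second geometry for development.

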