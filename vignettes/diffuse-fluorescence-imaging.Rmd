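---
title: "Simulating full-field and scanning fluorescence imaging in diffuse slabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating full-field and scanning fluorescence imaging in diffuse slabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorscan)
```

## The problem

Planar fluorescence imaging of small animals is limited by scattering,
absorption and autofluorescence: at the centimetre depths relevant to imaging
mouse organs, light is multiply scattered and image formation is governed by
diffusion rather than geometrical optics.  Two instrument families dominate:
*full-field* systems that illuminate the whole field of view and image the
emerging fluorescence with a camera, and *scanning* systems that raster a
pencil beam across the surface and record one integrated detector reading per
beam position.  `fluorscan` implements a quantitative forward model of both,
on the same digital phantom, so that their surface radiance and spatial
resolution can be compared across wavelengths, target depths and detection
geometries (epi-illumination "reflection" vs trans-illumination
"transmission").

## Forward model

Light transport is modelled with the continuous-wave diffusion approximation
to the radiative transport equation,

$$-\nabla\cdot(\kappa\nabla\Phi) + \mu_a\,\Phi = q,
  \qquad \kappa = \frac{1}{3(\mu_a + \mu_s')},$$

with the Robin (partial-current) boundary condition
$\Phi + 2A\kappa\,\partial\Phi/\partial n = 0$ on all slab faces.  The
internal-reflection parameter $A$ comes from the standard cubic-polynomial
approximation in the refractive index (`internal_reflection_A()`, $A \approx
2.79$ for $n = 1.33$ against air).  Collimated sources are replaced by
isotropic point sources buried one transport mean free path $1/\mu_s'$ below
the entry surface; the full-field disc illuminator is a superposition of such
buried points under its footprint.

Fluorescence is computed in three steps: (a) solve the excitation problem at
$\lambda_{ex}$ for the fluence $A_{ex}$; (b) convert fluence at the target
cells into a volumetric emission source $S_{fl} = \Phi\,\sigma\,N_0\,A_{ex}$,
where $\sigma = \ln(10)\cdot 1000\,\xi_{ex}/N_A$ is the per-molecule
absorption cross-section derived from the molar extinction coefficient; (c)
solve the emission problem at $\lambda_{em}$ with $S_{fl}$ as the source and
read the surface radiance on the detector face.  For the default quantum-dot
parameters ($\Phi = 0.6$, $\xi_{ex} = 2\times10^4\,$M$^{-1}$cm$^{-1}$,
$N_0 = 10^{20}\,$m$^{-3}$) the chain collapses to $S_{fl} \approx
4.59\times10^{-4}\,\mathrm{mm}^{-1} \cdot A_{ex}$.  Detected radiance is the
outward partial current per steradian, $\Phi_{face}/(2A)/(2\pi)$; the
per-steradian constant is a fixed convention and cancels in every ratio and
width the package reports.

### Tissue optics

Spectral inputs follow the two standard models: the scattering power law
$\mu_s'(\lambda) = a(\lambda/500)^{-b}$ with defaults $a = 1.89\,$mm$^{-1}$,
$b = 1.286$, and a chromophore sum for absorption with blood as the only
non-zero default ($B = 0.0511$, $S = 0.8$; water/fat/melanosome hooks default
to zero because blood dominates between 500 and 1000 nm).  The packaged
whole-blood table was compiled from the standard haemoglobin extinction
tabulation (150 g/L, 64500 g/mol) and calibrated at six anchor wavelengths
(600, 620, 700, 800, 900, 1000 nm) so that the default composition
reproduces the reference tissue values $\mu_a$ = 0.1504, 0.0563, 0.0162,
0.0220, 0.0304, 0.0236 mm$^{-1}$ exactly; the calibration factors are below
0.5% except at 1000 nm (−4%), where extinction tabulations disagree most.
Between anchors the shape is approximate — simulations at non-anchor
wavelengths inherit that uncertainty.  Interpolation is linear and
extrapolation is refused.

```{r}
tidy(optical_properties(600))
tidy(optical_properties(620))
```

### Discretisation and solvers

The slab (default $55\times55\times15$ mm, surfaces at $z = \pm 7.5$ mm) is
discretised with a cell-centred finite-volume scheme on a regular grid,
default spacing $h = 1$ mm, cells at integer coordinates so the standard
target geometry (cylinders $r = 1$, $h = 2$ mm at $(0, \pm 8, z)$) and the
1 mm scan grid align with cell centres.  The 7-point stencil with
harmonic-mean face diffusivity and the Robin closure yields a symmetric
positive-definite sparse system.  Grids up to about $1.2\times10^5$ cells are
factorised once per wavelength with sparse Cholesky and the factor is cached,
so the many right-hand sides of a raster scan or a depth sweep reuse it;
larger grids (refinement studies) switch to Jacobi-preconditioned conjugate
gradients with relative tolerance $10^{-8}$, which converges in under a
hundred iterations for these well-conditioned systems.

Accuracy was checked against the closed-form infinite-medium Green's function
$P e^{-\mu_{eff} r}/(4\pi\kappa r)$: at the strongly absorbing excitation
wavelength ($\mu_{eff} \approx 0.86\,$mm$^{-1}$) the $h = 1$ mm grid
overestimates the near-field by roughly 20% (the discrete decay rate of a
7-point stencil lags the true $\mu_{eff}$ when $\mu_{eff} h$ approaches 1),
while $h = 0.5$ mm is within 10% at 2–6 mm from a point source — the grid
used by the solver-validation test.  Width-type observables are far less
sensitive than amplitudes: refining $h = 1 \to 0.5$ mm shifts the
mid-depth resolutions by 6–10%, and most of that shift is the discrete
target volume (the boundary-inclusive cell rule makes the $h = 1$ cylinder
15 mm$^3$ against the true 6.3 mm$^3$) rather than the transport solution
itself.

### The two instruments

`full_field_image()` runs the three-step model with the $r = 20$ mm disc
source and returns the radiance image over the $[-26, 26]$ mm field of view.
`scan_image_direct()` is the brute-force scanning instrument: one excitation
and one emission solve per beam position, with the reading integrated over
the fixed $r = 7.5$ mm detector disc.  `scan_image_fast()` exploits the
translation equivalence: outside the targets the slab is homogeneous and
laterally much larger than the scanned area, so moving the beam is
equivalent to moving the target-and-detector assembly, and the detector
reading is proportional to the total excitation fluence over the target
cells.  The proportionality constant (`coupling_factor()`, one per mode and
emission wavelength) is measured from a single reference solve; each scan
reading then costs one trilinear interpolation of the cached reference
field.  The package keeps the reference beam at $(0,0)$; a 3 mm reference
shift changes the factor by about 3% (the excitation weighting across the
finite target changes slightly with beam position), which bounds the
systematic error of the method.

Two numerical choices matter here.  Translated target cells can leave the
cached grid (the default scan area plus the 8 mm target offset exceeds the
27.5 mm half-extent by up to 2.5 mm); the fluence there is below $10^{-9}$
of its peak, so it is sampled as zero (`strict = TRUE` raises an error
instead).  And the point beam carries the power of 1 mm$^2$ of the
full-field source's power density, making the two instruments' readings
directly comparable, as a shared-power-density comparison requires.

The equivalence itself degrades near the lateral slab boundary, where the
"effectively infinite slab" premise weakens: against the per-position
oracle the fast method is within 3% wherever the reading exceeds a tenth
of the scan peak, but reaches ~9% for beam positions 8 mm or more from the
centre on the weakest (corner) readings, and grows further as the beam
approaches the slab edge.  Quantitative use of the weak far tail of a scan
image should bear this in mind.

## Resolution analysis

Spatial resolution is quantified with the Sparrow criterion for two
identical targets, operationalised as the mean of the two per-target FWHMs
of the image profile through the targets (`sparrow_resolution()`).  The
profile (the $x = 0$ pixel line along $y$) is spline-resampled to 0.25 mm —
scan images are pixelated at the 1 mm step, and widths read off a 1 mm grid
would quantise — split at the central minimum, and each half is
baseline-subtracted (window minimum) before the half-maximum crossings are
located by linear interpolation.  When the two peaks overlap so strongly
that the dip never falls below half maximum, the inner crossing does not
exist; each peak is then assumed symmetric and its width taken as twice the
outer half-width.  This fallback is what makes the strongly blurred
long-wavelength transmission configurations measurable, and the measurement
method is recorded in the result.  If a profile shows fewer than two peaks
the targets are reported as unresolved rather than given a number.

Two summary statistics accompany every sweep row: the *mean* radiance over
all pixels and the *peak* radiance.  They answer different questions.  The
peak tracks how strongly the signal from a fixed target is attenuated as its
depth changes; the mean additionally dilutes that attenuation with lateral
broadening (a deep target spreads its light over many more pixels), so
depth-attenuation factors quoted from scan images correspond to the
peak-based statistic, and that is what the package's depth-sweep attribute
and the acceptance script report.  For the standard conditions
($\lambda_{em} = 700$ nm, $z = -5 \to +5$ mm) the exponential-order factors
are $\sim 5\times10^5$ in reflection and $\sim 2\times10^3$ in transmission;
their ratio-of-ratios is insensitive to the statistic because the excitation
path is common to both modes.

## What the tests do and do not show

The test-suite phantoms are generated in code.  The mini fixture
(`make_mini_fixture()`: $20\times20\times10$ mm, one target) exercises every
code path in under a second but is *not* the study geometry; study-scale
checks (the acceptance tests) run the full slab at $h = 1$ mm.  The digital
phantom is homogeneous with ideal wavelength filtering, no detector noise, no
photobleaching and no refractive-index structure — passing tests demonstrate
the internal consistency of the diffusion model and the equivalence
algorithm, not agreement with any particular animal.  Autofluorescence is
modelled ($S_{AF} = \beta A_{ex}$ on a 5 mm lattice of intrinsic
fluorophores) but only demonstratively: no reliable literature value of
$\beta$ at 600 nm excitation ships with the package, so background-to-target
ratios depend entirely on the user-supplied $\beta$.

## Design choices and limitations

* **Voxels, not tetrahedra.**  A regular grid with $h = 1$ mm resolves
  resolution-scale observables (widths of 5 mm and above) and keeps a full
  acceptance run in minutes; $h = 0.5$ mm refinement is available for
  convergence checks (the phantom-geometry tests verify cell assignment
  against brute-force enumeration at both spacings).  The boundary-inclusive
  cell-assignment rule makes the discrete target slightly larger than the
  continuous cylinder at $h = 1$ (15 cells vs 6.3 mm$^3$); this acts like a
  marginally bigger target and is one reason resolutions at coarse $h$ sit a
  few percent below their converged values.
* **Boundary constants.**  The Robin parameter uses $n = 1.33$ tissue
  against air; the source burial depth is $1/\mu_s'$.  Both are standard
  diffuse-optics conventions, both are configurable, and all reported
  comparisons are ratios or widths that are only weakly sensitive to them.
* **Detector integrates radiance.**  The disc detector sums radiance ×
  pixel area over cells whose centres fall in the disc.  Integrating fluence
  instead would rescale readings by a constant and leave every reported
  ratio and width unchanged.
* **Degenerate inputs.**  Zero sources, zero compositions and flat profiles
  return zeros or explicit errors (never NaN); solver output is clipped at
  zero where rounding produces $-10^{-16}$-scale negatives, which the
  M-matrix structure otherwise forbids.
* **Out of scope.**  Time- and frequency-domain solutions, Monte-Carlo or
  radiative-transfer validation, line-scanning and spatial-frequency-domain
  illumination, detector noise/SNR modelling, and reconstruction.

## A worked comparison

```{r, eval = FALSE}
ph <- slab_phantom(targets = two_targets(z = 0))

ff <- full_field_image(ph, mode = "reflection")
sc <- scan_image_fast(ph, mode = "reflection")

glance(sparrow_resolution(ff))   # resolution ~7.3 mm
glance(sparrow_resolution(sc))   # resolution ~5.6 mm

autoplot(sc, trans = "log10")
autoplot(sparrow_resolution(sc))

run_depth_sweep(z = -5:5, instrument = "scanning", mode = "reflection",
                lambda_em = 700)
```

Problem sizes used throughout: 45,375 cells for the study slab at
$h = 1$ mm, 45 × 45 scan positions, 132,651 cells for the $h = 0.5$ mm
Green's-function cube.
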