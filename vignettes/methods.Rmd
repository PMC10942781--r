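---
title: "Models and numerical methods in opentoplsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in opentoplsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

opentoplsm simulates and reconstructs open-top two-photon light-sheet
microscopy (OT-TP-LSM) with Bessel-beam illumination: a dual-objective
geometry in which all optics sit below the sample holder at 45°, an
axicon-generated Bessel beam is galvo-scanned into an extended-depth-of-field
excitation sheet, and large flat specimens are imaged strip by strip while a
stage steps them laterally. This vignette records the models the package
implements, the parameters that matter, and the numerical and design choices
behind them.

## The excitation beam and sheet

The focal-region beam is modelled as a Bessel–Gauss beam: the scalar field
produced by a thin annular pupil whose radial profile is Gaussian. The field
is evaluated by a Debye-type quadrature over pupil zones,

$$U(r, s) = \int A(\nu)\, J_0\!\left(\frac{2\pi \nu r}{\lambda}\right)
  \exp\!\left(-\frac{i\pi s \nu^2}{n\lambda}\right) \nu\, d\nu,$$

where $\nu$ is the zone's numerical aperture, $A(\nu)$ the Gaussian ring
centred on the effective illumination NA, $r$ the transverse (thickness)
coordinate, $s$ the propagation coordinate, and $n$ the immersion index. At
focus the intensity is $\propto J_0(2\pi\,\mathrm{NA}\,r/\lambda)^2$ under a
Gaussian envelope; the ring width sets the length of the Bessel zone. The
model is scalar, monochromatic, paraxial in the phase term, and
aberration-free; polarization and femtosecond pulse structure are out of
scope.

Two representations exist side by side. The radial Debye form above is the
workhorse; a Cartesian single-plane form (`as_transverse()`) feeds the
FFT-based angular-spectrum propagator `propagate()`, which applies
$\exp(i 2\pi d \sqrt{(n/\lambda)^2 - f_x^2 - f_y^2})$ per spatial frequency.
The two routes are independent implementations of the same physics, and the
test suite uses one to check the other: the propagated annular field must
reproduce the analytic $J_0^2$ central-lobe width within 2%, and the
unpadded transform must conserve power to 0.1% (it is exactly unitary on
propagating waves; the padded variant trades exact unitarity on the retained
window for suppressed wrap-around).

Scanning the beam along y turns the radial intensity $I(r, s)$ into a sheet:
the excitation density at thickness coordinate $t$ is the scan average of
$I(\sqrt{t^2+y^2}, s)$ — one-photon — or of its square — two-photon. Squaring
before averaging is what suppresses the Bessel side lobes: the scanned
one-photon sheet puts most of its integrated energy into the $J_0$ tails
(side-lobe fraction ≈ 0.8 at the default optics), the two-photon sheet less
than half of that.

### Definitions of the sheet metrics

The instrument community rarely states these operationally, so the package
fixes them:

* **DOF** — FWHM of the on-axis ($t = 0$) excitation density along $s$, for
  the scanned two-photon sheet. Linear interpolation of the half-max
  crossings throughout.
* **Profile FWHM** — FWHM along $t$ of the scan-averaged excitation map at
  focus. For the two-photon sheet this is ≈ 0.6 µm at NA 0.34 and is fixed
  by the NA alone.
* **Sheet thickness** (`thickness_fwhm_um`) — the *design* thickness: the
  central-lobe FWHM of the excitation-beam intensity at focus,
  $2 x_{1/2} \lambda / (2\pi\,\mathrm{NA})$ with $J_0(x_{1/2})^2 = 1/2$,
  ≈ 0.81 µm at the defaults. We report this, rather than the scan-averaged
  two-photon FWHM, as "thickness" because it is the quantity a designer
  quotes for the sheet (≈ 0.9 µm for this instrument class) and the only
  thickness-like metric that is independent of the scan model; the
  scan-averaged width is also reported, separately, as `profile_fwhm_um`.
* **Side-lobe fraction** — fraction of the focal thickness profile's
  integrated density beyond the first local minimum outside the central
  lobe, within the sampled support (the $J_0$ line integral has no finite
  total off-grid, so the support matters and is recorded with the sheet).

### Calibrated annulus width

The paper-level design states the outcome (DOF ≈ 180 µm at NA 0.34,
λ = 770 nm) but not the pupil ring thickness, which cannot be derived from
the published relay chain. The annulus fractional width is therefore a
calibrated parameter: `scripts/calibrate.R` sweeps it and stores the value
(0.0235, i.e. ring FWHM = 2.35% of NA) for which the simulated two-photon
sheet reports DOF ≈ 180 µm. The closed-form seed for that sweep comes from
the Gaussian-ring axial transform: the on-axis two-photon density is
Gaussian in $s$ with
$\mathrm{DOF} = \sqrt{\ln 2 / 2}\; n\lambda / (\pi\,\mathrm{NA}\,\sigma_{NA})$.

## Synthetic specimens

`phantom` generators emulate what the instrument is pointed at, not tissue
biophysics: each produces a fluorophore-density field (nuclear labelling)
and an SHG-scatterer field (fibrillar collagen) on a voxel grid, plus the
exact ground truth (object centers, radii, per-object integrated mass) so
downstream metrology never re-detects blindly. All generators are pure
functions of (spec, seed).

* Bead grids: 0.5 µm microspheres at 0.1 µm pitch, rendered with
  partial-volume supersampling (4³ sub-voxels at the rim) so the integrated
  mass matches the analytic sphere volume within 2%.
* Layered skin: dense epidermal nuclei above sparser dermal nuclei; collagen
  as random anisotropic line segments blurred by one voxel, with fibre cores
  kept three voxels below the epidermis–dermis boundary so the SHG field is
  exactly zero above it.
* Ducts and glands (pancreas, prostate): rings of cuboidal epithelial
  nuclei — exactly `wall_cells` of them — optionally with membrane-bright
  labelling (dim core, shell peaking at the nuclear boundary, 3:1 default
  contrast), surrounded by fibrous SHG tissue.
* Tumour-like presets: BCC-style nests filled to a controlled multiple
  (default 4×) of the achieved background nuclear number density;
  PDAC-style irregular gland rings amid dense stroma.

Nuclear positions use dart-throwing Poisson-disc sampling with a minimum
separation of one nuclear diameter. Dart throwing saturates near half the
close-packing density, so presets request ~50% of $V/\mathrm{sep}^3$;
tissue voxel pitch is 0.5 µm (0.1 µm for beads) to keep volumes desk-scale.

What the phantoms deliberately do not emulate: histological texture,
refractive-index heterogeneity, vasculature, immune infiltrate, and any
quantitative fluorophore contrast beyond configurable intensity ratios.
Passing tests on these phantoms therefore demonstrates that the *pipeline*
is geometrically and radiometrically correct, not that real tissue would
produce these images.

## Forward imaging model

Frame $i$ samples the phantom on the tilted plane
$\{X = x_i + v p \cos\theta,\; Y = u p,\; Z = v p \sin\theta\}$ (θ = 45°,
$p$ the sample-space pixel pitch, $x_i = x_0 + i\,\Delta x$), by trilinear
interpolation, with:

* **Attenuation** — single-scattering Beer–Lambert on vertical ballistic
  paths: $\exp(-m d/l_{ex})\exp(-d/l_{em})$ with $m = 2$ for two-photon
  excitation, 1 for one-photon. No Monte-Carlo transport: the model is meant
  to reproduce depth *ordering* and contrast decay, not radiometry.
* **Detection PSF** — an isotropic Gaussian of FWHM 0.9 µm (the measured
  system resolution of this instrument class, which already folds in sheet
  thickness and aberrations), applied in-frame on (u, v) and out-of-plane by
  Gaussian-weighted taps along the plane normal. Taps span ±2σ; the default
  is 5 taps, and metrology-grade runs use 9 because coarser combs leave a
  measurable dip in axis-aligned bead profiles.
* **Noise** — Poisson photon noise plus Gaussian read noise (σ = 10 counts),
  a camera baseline offset of 100 counts (so read noise is not clipped at
  zero, as on a real sCMOS), rounding, and 16-bit clipping with the
  saturated-pixel count reported in metadata.

Planes that leave the phantom raise an explicit error by default
(`oob = "zero"` opts into treating outside as empty, which the studies use
to sweep in and out of a block).

Scattering lengths are not published for these tissues; the skin preset's
values ($l_{ex}$ = 100 µm at 770 nm, 8 µm for the blue one-photon
comparison; $l_{em}$ = 30/50/80 µm at 385/515/640 nm, increasing with
wavelength) and the surface photon scale (125) are calibrations chosen so
the contrast-to-noise crossing depths land near the 64 µm (two-photon) and
20 µm (one-photon) reference depths — `scripts/calibrate.R` holds the sweep.

## Inverse pipeline

`deskew()` inverts the acquisition mapping by gather (pull) resampling:
output voxel (X, Y, Z) reads frame coordinates $v = Z/(p\sin\theta)$,
$u = Y/p$, $i = (X - Z\cot\theta - x_0)/\Delta x$. The output grid
($p, p, p\sin\theta$) makes $u$ and $v$ exact, so only the frame index is
interpolated (nearest or linear); gather resampling cannot leave
normalization holes. Out-of-swath voxels are `NA`, never zero. Voxels are
half-open, 0-based; θ = 0 degenerates the mapping and is returned as a
bitwise restack. Tilted-plane distances convert to vertical depth by
$d\sin\theta$ (90 µm → 64 µm at 45°).

`stitch()` places volumes at their stage offsets, optionally refines
consecutive pairs by maximizing normalized cross-correlation over
integer-voxel shifts (±4 by default, along the strip axis), and blends
overlaps with linear feather weights so constant inputs merge seamlessly.
This replaces manual strip joining; offsets come from metadata first,
correlation second, and both are reported.

`extract_enface()` linearly interpolates a constant-depth plane and
propagates the mask.

## Metrology

* **Resolution** — per-bead axis profiles through the (ground-truth) center
  snapped to the local maximum, background from the profile ends, FWHM by
  linear interpolation of the half-max crossings; a least-squares Gaussian
  fit is the cross-check estimator. Beads closer than 3× the expected FWHM
  are excluded and counted. The estimator is unbiased within 2% on
  noiseless Gaussian spots for σ between 0.3 and 1.5 µm.
* **Imaging depth** — the deepest 5 µm depth bin, contiguous from the
  surface, whose nuclear contrast-to-noise ratio
  (mean nuclear − mean background)/sd(background) stays ≥ 1. Threshold and
  bin width are package definitions, stated here because "imaging depth" is
  otherwise underspecified; both are parameters.
* **Budgets** — strips = ⌈W/600 µm⌉, frames = strips × ⌈L/step⌉,
  time = frames/fps, bytes = frames × 1850 × 512 × 2; GB is decimal (10⁹).
  `budget_report()` rounds time to whole minutes and recomputes the frame
  count and data size from the rounded minutes, which is how such budgets
  are quoted in practice (7 min and 318 GB per channel per cm², against the
  exact 425 s / 322 GB); both forms are exposed and tested. Strip tiling
  ignores inter-strip overlap by default, with an overlap fraction knob.

## Patch pipeline and virtual H&E

Style-transfer training consumes 512×512 crops augmented six-fold in the
fixed order identity, rot90, rot180, rot270, flip-vertical,
flip-horizontal — the factor that turns 2,387 source crops into 14,322
training patches. The six-fold factor is an inference from the exact
divisibility of the published dataset totals; stride and edge handling are
not published, so the tiler drops partial edge tiles and records the count.

The adversarial style-transfer network itself (two generators, two
discriminators, cycle-consistency training on GPU) is deliberately not
implemented: its value is trained weights, which have no desk-scale
acceptance surface. The package implements everything up to that hand-off
and a deterministic stand-in renderer so the end-to-end demo still produces
an H&E-like image: per pixel and RGB band,
$T_b = w_b \exp(-(c_{nuc}\,OD_{H,b} + c_{str}\,OD_{E,b}))$, with the
standard hematoxylin/eosin color-deconvolution OD vectors, the nuclear
channel driving hematoxylin and the SHG channel eosin. Nuclei render
purple, stroma pink, empty pixels white; the transform is pixel-wise,
deterministic, and monotone in each concentration.

## Problem sizes and limitations

The characterization studies run on one CPU in minutes: the sheet on a
0.05 µm × 2 µm (r × s) grid out to ±240 µm; the bead study on a
12×12×6 µm phantom at 0.1 µm pitch acquired at 0.15 µm pixels; the depth
study on a 40×24×92 µm skin block at 0.5 µm voxels, 48×256 px frames and
1 µm steps. These are deliberately small: they exercise every pipeline
stage at full fidelity while keeping the whole test suite under a minute
and the acceptance script under two.

Known limitations: scalar aberration-free optics (the instrument's reported
spherical-aberration excess is not modelled — no coefficients are
published); ballistic-only attenuation; no rolling-shutter or sheet-camera
synchronization artifacts; no photobleaching; registration refinement is
integer-voxel and single-axis; and the virtual H&E renderer is a
deterministic surrogate, not a learned mapping.
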