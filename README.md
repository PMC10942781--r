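# opentoplsm

Simulation and reconstruction toolkit for **open-top two-photon light-sheet
microscopy (OT-TP-LSM) with Bessel-beam illumination** — the class of
instrument used for nondestructive 3D pathology of fresh or
paraffin-embedded surgical specimens. In that geometry both objectives sit
below the sample holder at 45°, an axicon-generated Bessel beam is scanned
into a thin extended-depth-of-field excitation sheet, and centimetre-scale
specimens are imaged strip by strip while a stage steps them laterally;
nuclear fluorescence and intrinsic second-harmonic (collagen) contrast are
collected on two cameras, and the oblique raw stacks are sheared back into
upright volumes.

The package is for instrument builders and image-analysis developers who
need a faithful, fully seeded desk-scale model of that pipeline:

* **Optics** — scalar Debye simulation of the Bessel–Gauss beam from its
  annular pupil; angular-spectrum propagation as an independent numerical
  oracle; scanned one-/two-photon sheet maps with thickness, depth-of-field
  and side-lobe metrics. The focal intensity follows
  $J_0(2\pi\,\mathrm{NA}\,r/\lambda)^2$; the scanned two-photon sheet at
  NA 0.34 / 770 nm reaches a ~180 µm depth of field at sub-micron
  thickness.
* **Phantoms** — seeded bead grids (0.5 µm microspheres) and tissue-like
  presets (layered skin with SHG collagen, BCC-like nests, pancreatic
  ducts, PDAC glands, prostate gland rings), all with exact ground truth.
* **Acquisition** — the 45° oblique strip-scan forward model: frame
  *i* samples the plane $X = x_i + v p\cos\theta$, $Z = v p\sin\theta$,
  with Beer–Lambert attenuation ($\exp(-2d/l_{ex})\exp(-d/l_{em})$ for
  two-photon), a 0.9 µm isotropic detection PSF, and Poisson + read noise
  at 16 bits.
* **Reconstruction** — deskew (gather resampling), tilted-depth conversion
  ($d\sin\theta$), feathered mosaic stitching with cross-correlation
  refinement, en-face extraction.
* **Metrology** — bead FWHM resolution reports, contrast-to-noise imaging
  depth, and the acquisition throughput/data budgets
  (0.24 mm²/s at 400 fps and 1 µm steps; 7 min and 318 GB per channel per
  cm²).
* **Staining** — 512×512 patch extraction with the six-fold
  rotation/flip augmentation used to build style-transfer training sets,
  and a deterministic Beer–Lambert virtual-H&E renderer for the two-channel
  volumes.

## Worked example

```r
library(opentoplsm)

## the calibrated default optics and the two-photon excitation sheet
cfg <- optical_config()
sheet <- make_sheet(bessel_gauss_field(cfg), scan_range_um = 40,
                    mode = "two_photon")
sheet_metrics(sheet)
#> # A tibble: 1 × 5
#>   mode       thickness_fwhm_um profile_fwhm_um dof_um side_lobe_fraction
#> 1 two_photon             0.812           0.594   181.              0.334
```

The sheet keeps a 0.81 µm central-lobe thickness over a 181 µm depth of
field — the extended Bessel zone that lets a 45° sheet span the whole
512-pixel oblique field of view — and two-photon excitation halves the
side-lobe energy fraction relative to the one-photon sheet.

```r
## what imaging 1 cm^2 costs at 400 fps, 1 um steps, 1850 x 512 px, 2 B/px
geom <- acquisition_geometry()
b <- acquisition_budget(10000, 10000, geom)
budget_report(b, geom)
#> # A tibble: 1 × 4
#>   time_min frames_reported gb_per_channel throughput_mm2_s
#> 1        7          168000            318             0.24
```

Seven minutes and 318 decimal gigabytes of raw 16-bit frames per channel
per square centimetre, at 0.24 mm²/s of specimen surface.

```r
## end-to-end resolution: bead phantom -> oblique acquisition -> deskew -> FWHM
bead_resolution_study(seed = 1)
#> <resolution_report> 7 beads (1 excluded), method 'interp'
#>   FWHM x: 0.939 +/- 0.034 um
#>   FWHM y: 0.922 +/- 0.026 um
#>   FWHM z: 0.918 +/- 0.067 um

## imaging depth in the skin phantom: two-photon vs one-photon excitation
d2 <- imaging_depth_study(seed = 2, mode = "two_photon")   # 65 um
d1 <- imaging_depth_study(seed = 2, mode = "one_photon")   # 20 um
as.numeric(d2) / as.numeric(d1)
#> [1] 3.25
```

The measured bead widths (~0.93 µm) are the 0.9 µm system PSF convolved
with the 0.5 µm bead; the two-photon configuration images ≈3× deeper than
the one-photon comparison because long excitation wavelengths scatter far
less and the excitation term enters the Beer–Lambert exponent squared.

`plot_sheet()`, `plot_resolution()`, `plot_depth_profile()` and
`plot_enface()` give ggplot views of each result; `inst/cli/opentoplsm` is
a thin command-line front end (`simulate-sheet`, `make-phantom`, `acquire`,
`deskew`, `budget`, `virtual-he`) over the same functions.

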