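---
title: "Models and methods behind kinspa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinspa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kinspa` quantifies the stoichiometry and nanoscale arrangement of
budding-yeast kinetochore clusters from fluorescence image stacks. This
vignette is the package's own account of the underlying models, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the
procedure left them open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` compute themselves.

## Coordinate and unit conventions

All physical quantities are in nanometres internally; micrometres appear
only in user-facing spindle-length arguments (`classify_phase`'s 2-um
threshold). Volumes are numeric arrays indexed `[z, y, x]` with
voxel-centred, 0-based coordinates; y is the spindle axis after
realignment. Gaussian widths convert between SD and FWHM with the factor
`2 sqrt(2 ln 2) ~ 2.3548`.

## The point-spread function and convolution

The focal volume is modelled as an anisotropic 3D Gaussian,
`psf_model(fwhm_lateral = 119, fwhm_axial = 272)` by default: the
dimensions measured from SPB-marker SIM reconstructions, close to
theoretical values for mCherry on a structured-illumination microscope.
`render_psf` samples it over +/- 4 sigma and normalizes the kernel to
unit sum, so convolution conserves integrated intensity for sources at
least 4 sigma inside the border (tested to < 0.1%). Because the Gaussian
is separable, `convolve_psf` applies three 1D FFT convolutions (axial
kernel along z, lateral along y and x), which is mathematically
identical to convolution with the full 3D kernel. FFT ringing below the
numerical noise floor is clipped at zero to preserve the non-negativity
invariant of `image_volume`.

## Calibrated molecule counting

The maximum-intensity z slice near the annotated spot position is fit to
a symmetric 2D Gaussian with constant offset: six free quantities
(amplitude, x/y centre, lateral SD, offset) via Levenberg-Marquardt
(`minpack.lm::nls.lm`), initialized with the annotated centre, max-minus-
median amplitude and a 1-pixel SD, with the SD bounded to [0.5, 5]
pixels. The reported amplitude is offset-subtracted; whether the
original analysis included the local background in the amplitude is not
documented, and the offset-subtracted choice makes ratios insensitive to
background drift (the anaphase/G1 ratio tests exercise this).

Spots with fitted SD >= 245 nm (1.75 pixels at the 140 nm default pixel
pitch — the source of the package's 140-nm lateral pitch default) are
excluded as declustered; the inequality is strict below the cutoff, and
the filter is monotone in the cutoff. Copy numbers divide the
(power-ratio-scaled) amplitude by the predicted single-GFP amplitude and
by `n_kinetochores = 16` (one microtubule per chromosome, 16
chromosomes; configurable for declustered or aneuploid settings).
Normalized intensities divide amplitudes by 1,000 or 10,000 to land in
the 0-10 range. Ratio standard errors use first-order (delta-method)
propagation from the group-mean standard errors; the accompanying Welch
t test is a convenience, not a contribution.

## FRAP

Curves are normalized to the prebleach frame (exactly 1 after
normalization; non-positive prebleach intensities are rejected). Percent
recovery is the standard normalized-FRAP definition
`100 (I_end - I_post) / (1 - I_post)`, with the post-bleach and endpoint
levels taken as window averages (defaults: 1 and 2 frames) because the
original endpoint convention (final frame vs average) is not documented;
both window sizes are arguments so alternative conventions can be
tested. A post-bleach level at or above prebleach is a failed bleach and
an error. Values outside [0, 150]% are returned unclamped but flagged.
An optional mono-exponential detrend against an unbleached control
region (`bleach_detrend`) corrects acquisition photobleaching; it is off
by default because acquisition at long intervals keeps that bleaching
negligible. Reaction-diffusion model fitting and half-time estimation
are out of scope.

## SPA-SIM

Per particle: the two SPB fiducial spots are fit simultaneously with two
3D Gaussians (shared lateral/axial SDs, common offset) on voxels within
500 nm of the hand-annotated guesses; fits that do not converge, or
whose centres merge within one pixel, are rejected, and pairs whose
fitted lateral SD fails the 245-nm declustering cutoff are dropped
before averaging. The volume is realigned by a rigid in-plane rotation
plus translation — a single bilinear resampling per z slice, no z
interpolation since the rotation is in-plane — placing the
inter-fiducial axis on y, then split at the midpoint into mother and
daughter sub-images, each re-centred on its own fiducial, the daughter
flipped so every sub-image has the spindle pointing toward +y (image
bottom). Out-of-volume samples are zero-filled; a sub-image with more
than 10% unfilled pixels is rejected.

Averaging: 5-slice maximum projection centred on the fiducial z slice,
per-particle division by the projection maximum (the original procedure
states no normalization; this is a config switch, default on, so dim and
bright cells contribute equally), pixel-wise mean with mother and
daughter pooled, 8x bilinear upscale, then averaging with the left-right
mirror image (exact mirror symmetry of the output is tested
bit-exactly). Contours threshold a further 4x upscale (32x total over
raw data — the stated total is honoured even though the stated
individual factors of 8 and 8 would multiply to 64) at 75% of maximum.

Axial cluster positions and sizes come from a single-Gaussian fit of the
column-averaged vertical profile; the size is reported as both SD and
FWHM, with FWHM as the headline number since "cluster size along the
spindle axis" is not otherwise pinned down. Standard errors come from
100 Monte Carlo refits with i.i.d. Gaussian noise at the residual SD.
Ties at exactly 2 um in phase classification go to metaphase (one side
of the stated strict-on-both-sides threshold must take equality).
Distances between channels subtract each channel's own fiducial centre
and add a correction measured from a dual-channel calibration pair,
cancelling chromatic offsets.

### Known systematic biases of the averaging procedure

Two small biases are properties of the procedure itself, and the test
suite measures both:

1. The two bilinear resampling steps (rotation and upscale) smooth the
   image by roughly `pitch^2 / 6` of added variance each (~540 nm^2
   total at 40-nm pixels), broadening a 194-nm FWHM cluster by ~8 nm and
   a 468-nm cluster by ~3 nm in noiseless round trips.
2. Maximum projection over five noisy z slices lifts pure-background
   rows by the expected maximum of five noise draws, more than rows
   where one slice dominates; after the free-offset Gaussian fit this
   *narrows* the fitted profile (~-8 nm on a 468-nm cluster at the
   default noise level).

The net errors are ~1-2% of the cluster extent — far below the
metaphase/anaphase contrast being measured — but they exceed the Monte
Carlo SEM of a 24-particle synthetic average (~0.3 nm), because the
Monte Carlo errors quantify residual noise, not procedure bias. The
acceptance test that demands recovery within 2 Monte Carlo SEM therefore
fails by a few nanometres by design of the procedure, and is left
failing rather than loosened; the recovered extents themselves sit
within 2% of the generator truth.

## Cylinder forward model

Kinetochores on the spindle are modelled as `n_rings` circles
perpendicular to the spindle axis ("oriented along z" in the image frame
is read as rings lying in x-z planes stacked along y, which is the
orientation that reproduces bi-lobed *cross-spindle* profiles), spaced
75 nm, diameter 250 nm, rendered at 5-nm isotropic pitch and convolved
with the 119/272-nm PSF. Rings are rasterized as 1-voxel annuli —
kinetochores sit on the cylinder surface, not filling it; a filled disk
would fill in the central dip and is not what the bi-lobed observation
implies. The rasterization snaps ring positions to the grid, so
recovered spacings can differ from the nominal value by up to one grid
pitch (75-nm rings at 5-nm pitch land on 70/80-nm offsets).

`forward_profile` evaluates the lateral profile through the
central-most ring plane either from the fully rendered volume or
analytically, by summing the Gaussian responses of the rasterized ring
sources along the profile line; the two agree to ~1e-3 (tested) and the
analytic path makes a 1-nm diameter search cheap. `estimate_diameter`
scans candidate diameters (coarse 5-nm grid over 50-500 nm, then a 1-nm
fine pass) with amplitude and offset solved linearly at each candidate,
because the original assessment of data-simulation "consistency" is not
described and an explicit objective had to be chosen; a grid scan was
preferred over golden-section search because rasterization makes the
objective piecewise-constant at the sub-pitch scale. Profiles without an
interior minimum carry little diameter information and are flagged
`low_identifiability`. `estimate_ring_spacing` fits an equal-spacing,
equal-amplitude, equal-width Gaussian mixture to an axial profile — any
line parallel to the cylinder axis is an exact instance of that model,
which makes the fit well-posed despite the 119-nm PSF not resolving
75-nm spacings as separate peaks.

## The synthetic-data generator

The generator produces what the analysis consumes, with ground truth
sufficient to regenerate any dataset bit-identically from its seed
(tested):

- **Camera model**: Poisson photon noise at a gain (camera units per
  photon) followed by zero-mean Gaussian read noise, the standard
  EMCCD/sCMOS approximation; negative values clip at zero.
- **Counting volumes**: 140 nm xy / 300 nm z pitch, spot SD 120 nm
  lateral / 300 nm axial, background 200, gain 2, read SD 20, single-GFP
  amplitude set by the supplied calibration. The spot centre is jittered
  by up to half a pixel in x-y but placed on a z slice, mimicking cells
  focused at acquisition; off-slice spots would attenuate
  maximum-slice amplitudes by up to ~12% — a limitation of the
  maximum-slice method itself, not modelled by default.
- **SPA populations**: SIM-like 40 nm xy / 125 nm z pitch, 11 slices;
  fiducials rendered at the 119/272-nm PSF size with amplitude 3000;
  two kinetochore clusters per spindle, each an anisotropic Gaussian
  (axial FWHM 468.2 nm metaphase / 194.0 nm anaphase by default — the
  wild-type Nuf2 values the pipeline should recover — radial FWHM 250
  nm, amplitude 1000) centred 250 nm poleward-in from each SPB; spindle
  lengths uniform on 1600-1950 nm (metaphase) or 2400-3400 nm
  (anaphase); random in-plane spindle orientation per cell; background
  50, gain 1, read SD 10. The 700-nm margin beyond the fiducials keeps
  +/-600-nm realigned sub-images inside the volume.
- **FRAP series**: prebleach frame, then
  `pre (post + (plateau - post)(1 - exp(-t / tau)))` plus Gaussian noise
  (default 2% of prebleach).

What the generator does **not** emulate — and what passing round trips
therefore do not certify on real data: SIM reconstruction artifacts and
optical aberrations; cell-to-cell variability in cluster extent,
brightness and offset (every cell in a population shares one geometry);
non-Gaussian cluster substructure; autofluorescent cell bodies;
chromatic offsets (available only via the explicit correction argument);
z drift and off-slice spot centres; detector nonlinearity.

## Problem sizes and runtime choices

The test suite and acceptance script run round trips at the scale of the
reported experiments where that is cheap (24-particle SPA populations,
100-replicate counting ensembles, 100 Monte Carlo refits) and at reduced
image counts for pure property checks (2-12 particles), keeping the
whole suite around a minute on one core. The cylinder acceptance path
renders the full 237 x 127 x 133 voxel volume once and reuses it for
both the diameter and the spacing round trip.

## Limitations

- Declustered (per-kinetochore) localization, automatic fiducial
  detection, cell segmentation and bud-morphology phase calling are out
  of scope; phases and initial spot positions come from annotations.
- The realignment is strictly in-plane; spindles tilted out of the
  imaging plane foreshorten axial distances and are not corrected.
- Monte Carlo standard errors quantify residual noise only; they do not
  include the procedure biases quantified above, nor calibration
  uncertainty in the single-GFP amplitude, which propagates
  multiplicatively into every copy number.
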