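---
title: "Sizing submicron PS-positive vesicles from TIRF line scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing submicron PS-positive vesicles from TIRF line scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freckletrace)
```

## The measurement problem

Cells exposed to intense pulsed electric fields externalize
phosphatidylserine (PS) not diffusely but as submicron punctate spots —
"freckles" — visible in total internal reflection fluorescence (TIRF)
recordings of the basal membrane. These spots behave like shed
extracellular vesicles: they appear after a pulse-type-dependent delay,
move laterally and vertically, and their apparent brightness fluctuates
severalfold while their apparent width barely changes. Their physical
size is close to the diffraction limit, so the width of the imaged spot
is dominated by the point spread function (PSF) and cannot be read off
the image directly. freckletrace implements the full quantification
chain: spot detection and per-cell intensity statistics, Gaussian
line-scan fitting, bead-based PSF calibration, and a
sphere-in-evanescent-field model that converts fitted widths into
physical diameters. A seeded forward simulator renders TIRF-like stacks
with known ground truth so every stage can be validated end to end.

## The optical model

TIRF excitation decays exponentially with height $z$ above the glass,
$I(z) = e^{-z/d}$, with penetration depth $d = 100$ nm by default. The
intensity halves at $z_{1/2} = d\ln 2 \approx 69.3$ nm. For a uniformly
fluorescent sphere of diameter $D$ resting on the glass, emission falls
to half of its maximum on the circle where the sphere surface crosses
$z_{1/2}$; the diameter of that circle is the *intrinsic footprint*

$$\mathrm{FWHM}_\mathrm{int} = 2\sqrt{D\,z_{1/2} - z_{1/2}^2},$$

defined for $D \ge z_{1/2}$. Widths are assumed to combine in
quadrature with the PSF, so a measured spot width is deblurred as
$\sqrt{\mathrm{meas}^2 - \mathrm{PSF}^2}$ and the footprint inverted to

$$D = \frac{(\mathrm{FWHM}_\mathrm{deblur}/2)^2 + z_{1/2}^2}{z_{1/2}}.$$

The PSF itself is estimated the same way from 110-nm calibration beads:
their intrinsic footprint (about 106 nm) is removed in quadrature from
their measured width. With a measured bead width of 308 nm this gives
an effective PSF of about 289 nm:

```{r}
om <- optical_model()                    # d = 100 nm, 46-nm pixels
psf_from_beads(308, 110, om$half_height_nm)
diameter_from_measurements(350, 289, om) # the headline ~210 nm
```

$z_{1/2}$ is carried unrounded (69.31 nm) in every computation; rounding
to 69 or 69.3 nm is left to display. The model deliberately ignores how
fluorophores are distributed within the sphere (surface versus volume
labelling) and treats emission as proportional to local excitation;
both are simplifications, and the resulting diameters are estimates,
not super-resolution measurements. Note the strong error amplification
near the resolution floor: at a measured width of 350 nm and PSF of
289 nm, the derivative of diameter with respect to measured width
exceeds 2.5 nm/nm, so a 2% width error moves the diameter by roughly
8%. This is why the line-scan fitting below is engineered for sub-1%
width accuracy.

## Line-scan fitting

Spot widths are measured exactly as in the underlying experimental
protocol: a 50-sample, 2-pixel-wide line is laid through the spot
centre, the mean of the 10 samples at each end is subtracted as
background, the origin is placed on the maximum, and

$$Y = A \exp\!\left(-4\ln 2\, \frac{X^2}{W^2}\right)$$

is fitted by Levenberg–Marquardt least squares, so $W$ is directly the
FWHM. The centre is fixed at $X = 0$; the fit is bounded to
$W \in (0.05, 5)$ µm and started at $W_0 = 0.3$ µm. Fit quality is
reported as the Pearson correlation between observed and fitted values,
$R^2$, and the p value of the observed-on-fitted regression F test;
fits with $R^2 < 0.78$ are flagged and excluded from diameter
estimates.

Two numerical choices matter at the accuracy the deblurring chain
demands:

* **Interpolation.** Profiles along arbitrary angles are sampled by
  separable Catmull-Rom (bicubic) interpolation, and the sample grid
  always contains the line centre. Bilinear interpolation with an
  off-centre grid inflates fitted widths by about 2% (half from the
  linear smoothing, half from the forced half-pixel recentring), which
  after error amplification would bias a 110-nm bead round trip to
  ~120 nm. With the bicubic sampler the residual width bias is below
  0.1%.
* **Recentring under noise.** The profile maximum is located on a
  3-point smoothed copy of the profile (the reported values stay raw).
  Otherwise single-pixel noise excursions shift the assumed centre by
  1–2 pixels on dim spots and broaden their fitted widths
  systematically.

## The forward simulator

`sim_config()` defines the study conditions; `simulate_vesicles()` and
`render_stack()` turn them into ground truth and images. The defaults
were chosen once to emulate the published phenomenology:

* **Emergence**: a deterministic lag followed by homogeneous Poisson
  arrivals (rate per 100 µm²). The `ns400` preset (400-ns, 9.3 kV/cm
  class exposure) uses a 60 s lag and 0.17 /s, reaching roughly 40
  spots per 10 × 10 µm field by five minutes; the `us20` preset (20-µs,
  2.5 kV/cm class) uses no lag and 0.25 /s, so spots typically appear
  already in the first 10-s frame. The Poisson form is a stand-in: the
  source data constrain only the lag and the plateau trend.
* **Diameters**: truncated normal, mean 200 nm, sd 20 nm, truncated
  below 80 nm — the "submicron vesicles of about 200 nm" population.
* **Brightness**: lognormal fluorophore loads; coefficient of variation
  0.3 for `ns400` and 1.0 (with 5× the mean load) for `us20`,
  reproducing the dim/uniform versus bright/heterogeneous contrast
  between pulse types phenomenologically, not mechanistically.
* **Motion**: a configurable fraction of vesicles is laterally
  immobile; the rest take Gaussian steps per frame. Height follows an
  exactly discretised Ornstein–Uhlenbeck process reflected at zero
  (stationary sd 60 nm, reversion 0.1 /s) — the source observations say
  only "stochastic vertical movements", so the process form is a
  modelling choice exposed in the config.
* **Rendering**: each vesicle contributes a Gaussian spot whose
  integrated signal is its load times the volume-averaged evanescent
  attenuation over the sphere (closed form), and whose FWHM is the
  intrinsic footprint combined in quadrature with the channel PSF. This
  single-effective-Gaussian choice mirrors the quadrature approximation
  used in the inversion, which keeps the expected fit results analytic
  — the simulator validates the pipeline's self-consistency, not the
  quadrature approximation itself.
* **Camera**: Poisson shot noise, Gaussian read noise (sd 5 levels),
  background 200 levels, clipping to 16 bits.

What passing tests on this simulator do *not* show: robustness to
structured cellular background (diffuse membrane staining, debris),
drift, uneven illumination, or non-spherical vesicles. Real recordings
contain all of these.

## Detection

Freckles are connected components (8-connectivity by default) of pixels
at least 100 grayscale levels above the local background, restricted to
a 10 × 10 µm region of interest and discarded at ≥ 5 µm equivalent
diameter. The local background is a grayscale morphological opening
with a 2-µm disc — wide enough to pass broad gradients and remove
spot-scale peaks; the original protocol does not specify its estimator.
Components below 4 pixels are rejected as shot-noise excursions.
Overlapping spots are kept merged (a watershed split is available but
off by default), and the recovery score in `detection_recovery()`
credits a merged component to every truth spot it covers, since a
manual check would also count the merged blob once per visible maximum
at best. ROI placement is automatic by default — the 10 × 10 µm window
maximising the post-pulse object count, emulating manual placement over
the densest region — with a manual override.

Centroids are intensity-weighted, giving sub-pixel centres; this is
what lets the line scans be centred accurately enough for the width
chain.

## A worked demo run

```{r}
report <- suppressWarnings(
  run_pipeline(run_config(preset = "ns400", seed = 2)))
report
```

The demo renders a 30-frame, 10 × 10 µm stack (218 × 218 pixels at
46 nm), calibrates the PSF from nine rendered beads, detects freckles
per frame, fits orthogonal line scans through every final-frame spot,
and inverts the widths to diameters. Problem sizes throughout the
package's tests are of this order — single cells, tens of vesicles,
tens of frames — matching the scale of one experiment.

## Limitations

* Diameters are model-based estimates; the sphere-on-glass geometry
  breaks down for vesicles hovering above the glass, and the
  quadrature rule is an approximation to the true convolution.
* Spots dimmer than about 3× the detection threshold carry width
  uncertainties that the steep inversion amplifies; the $R^2 \ge 0.78$
  gate removes the worst fits but not the amplification.
* Mobility classification is pairwise-overlay only (any-pixel overlap,
  or an optional centroid rule); there is no trajectory linking, and
  colocalization is object-based, not intensity-correlation-based.
* The diffraction-limited widths quoted for ideal optics (181/216 nm)
  are not reproduced here; the package always works with the measured
  effective PSF.
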