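# freckletrace

Quantification of punctate phosphatidylserine (PS) externalization in
TIRF microscopy. Cells exposed to pulsed electric fields shed submicron
PS-positive vesicles that appear as diffraction-limited spots
("freckles") in total internal reflection fluorescence time-lapse
recordings. This package implements the analysis chain for such
recordings, for microscopists and bioelectrics researchers:

* **Detection** — spots are connected components at least 100 grayscale
  levels above a morphological-opening local background, restricted to
  a 10 × 10 µm ROI and < 5 µm in size, with per-freckle mean/peak/
  integrated intensities and per-cell summary statistics over time.
* **Line-scan fitting** — 50-sample, 2-pixel-wide profiles through each
  spot, edge-mean background subtraction, and a least-squares fit of
  `Y = A exp(−4 ln2 · X²/W²)`, so `W` is directly the FWHM (µm).
* **Optics** — the evanescent field decays as `exp(−z/d)` with
  `d = 100` nm and halves at `z½ = d·ln2 ≈ 69.3` nm. A sphere of
  diameter `D` on the glass has intrinsic half-intensity footprint
  `2·√(D·z½ − z½²)`; widths add in quadrature with the PSF. The PSF is
  calibrated from 110-nm beads
  (`PSF = √(FWHM²_bead,meas − FWHM²_bead,int)`), measured spot widths
  are deblurred the same way, and the footprint is inverted to the
  physical diameter `D = ((FWHM/2)² + z½²)/z½`.
* **Dynamics** — frame-to-frame mobility classification by mask
  overlap, object-based two-channel colocalization (percent of
  reference-object pixels inside the other channel's objects), and
  ΔF/F = 100 % × (F − F₀)/F₀ fluorescence traces.
* **Synthetic TIRF** — a seeded forward model (vesicle emergence,
  diameters, brightness, lateral/axial motion, PSF blur, camera noise)
  that renders ground-truthed stacks and bead calibration fields, so
  the whole chain is testable without any experimental data.

## Worked example

```r
library(freckletrace)

om <- optical_model()            # d = 100 nm, PSFs 289/312 nm, 46-nm px
psf_from_beads(308, 110, om$half_height_nm)
#> [1] 289.1084
quadrature_deblur(350, 289)
#> [1] 197.431
diameter_from_measurements(350, 289, om)
#> [1] 209.9017
```

A measured bead width of 308 nm yields an effective PSF of 289 nm;
deblurring a typical 350-nm freckle width leaves a 197-nm intrinsic
footprint, which the sphere-in-evanescent-field geometry converts to a
physical vesicle diameter of ~210 nm.

The end-to-end demo simulates a 400-ns-pulse-class experiment, renders
it, calibrates, detects and sizes:

```r
report <- run_pipeline(run_config(preset = "ns400", seed = 2))
report
#> freckletrace run report (v0.1.0)
#>   preset ns400, seed 2
#>   calibration: 9 beads, median FWHM 308 nm -> PSF 289 nm
#>   30 frames; 36 freckle(s) in the final frame
#>   estimated diameters: median 206 nm (n = 14)
#>   true median diameter: 194 nm (n = 29)
```

The report carries the per-frame time course (`report$time_course`),
the per-freckle diameter table with fit quality (`report$diameters`;
fits with R² < 0.78 are flagged), and the calibration record. A thin
command-line wrapper lives at `inst/scripts/freckletrace.R`
(`simulate`, `detect`, `run` subcommands over key-value config files).

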