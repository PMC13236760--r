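# analytic frame: background plus 2-D Gaussian spots given as
# (x_um, y_um, amplitude, fwhm_x_um[, fwhm_y_um])
make_spot_frame <- function(n_px = 101, pixel_size_nm = 46, background = 0,
                            spots = NULL) {
  px_um <- pixel_size_nm / 1000
  xs <- (seq_len(n_px) - 0.5) * px_um
  f <- matrix(background, n_px, n_px)
  if (is.null(spots)) return(f)
  k <- 4 * log(2)
  for (s in spots) {
    fx <- s[4]
    fy <- if (length(s) >= 5) s[5] else s[4]
    gx <- exp(-k * (xs - s[1])^2 / fx^2)
    gy <- exp(-k * (xs - s[2])^2 / fy^2)
    f <- f + s[3] * outer(gy, gx)
  }
  f
}

# hand-built vesicle truth: grid of immobile vesicles with given loads and
# diameters, all present in frame 1 (or frames 1..n_frames)
make_grid_truth <- function(loads, diameter_nm = 200, fov_um = 16,
                            z_nm = 0, n_frames = 1) {
  n <- length(loads)
  g <- ceiling(sqrt(n))
  step <- fov_um / (g + 1)
  structure(lapply(seq_len(n), function(i) {
    gx <- (i - 1) %% g
    gy <- (i - 1) %/% g
    list(id = i, diameter_nm = diameter_nm, emergence_time_s = 0,
         mobile = FALSE, load = loads[i], frame = seq_len(n_frames),
         x_um = rep(step * (gx + 1) + 0.13, n_frames),
         y_um = rep(step * (gy + 1) - 0.21, n_frames),
         z_nm = rep(z_nm, n_frames)[seq_len(n_frames)])
  }), class = "vesicle_truth")
}

# noiseless line-profile object built directly from the Gaussian model
make_profile <- function(A = 1000, W = 0.35, n = 50, pixel_size_nm = 46,
                         noise_sd = 0, offset = 0, shift_um = 0,
                         seed = NULL, subtracted = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  s <- seq_len(n) - 1 - floor((n - 1) / 2)
  x <- s * pixel_size_nm / 1000
  y <- A * exp(-4 * log(2) * (x - shift_um)^2 / W^2) + offset
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  structure(list(values = y, x_um = x, angle_deg = 0,
                 center_um = c(0, 0), pixel_size_nm = pixel_size_nm,
                 width_px = 1, background_subtracted = subtracted,
                 suspect = FALSE, center_shift_um = 0),
            class = "line_profile")
}
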