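#' Simulation configuration for synthetic TIRF stacks
#'
#' Defines the conditions under which ground-truth vesicles are generated
#' and rendered: pulse metadata, emergence kinetics (a deterministic lag
#' followed by Poisson arrivals), the vesicle diameter distribution,
#' brightness heterogeneity, the mobile/immobile split, lateral and axial
#' motion parameters, acquisition timing, field of view, and the camera
#' model (Poisson shot noise, Gaussian read noise, clipping to bit depth).
#'
#' Times are in seconds relative to pulse delivery at t = 0; the stack
#' contains `n_prepulse` frames before the pulse.
#'
#' @param pulse_duration_s pulse duration, s (metadata only).
#' @param field_strength_kvcm field strength, kV/cm (metadata only).
#' @param lag_s delay between the pulse and the first possible vesicle, s.
#' @param emergence_rate vesicle arrival rate after the lag, count/s per
#'   100 um^2 of field.
#' @param diameter_mean_nm,diameter_sd_nm,diameter_min_nm truncated-normal
#'   vesicle diameter distribution, nm.
#' @param brightness_cv coefficient of variation of the lognormal
#'   fluorophore-load distribution.
#' @param load_mean expected photon rate per frame for a vesicle at the
#'   interface (z = 0), grayscale levels.
#' @param immobile_fraction fraction of vesicles with zero lateral steps.
#' @param lateral_step_sd_um per-frame lateral random-walk step SD, um.
#' @param axial_rate mean-reversion rate of the axial process, 1/s.
#' @param axial_sd_nm stationary SD of the axial process, nm.
#' @param frame_interval_s acquisition interval, s.
#' @param n_frames total frames in the stack.
#' @param n_prepulse frames acquired before the pulse; default
#'   `min(6, n_frames - 1)`.
#' @param fov_um square field-of-view side, um.
#' @param background camera background level, grayscale levels.
#' @param gain camera gain (levels per photon).
#' @param read_noise_sd Gaussian read-noise SD, levels.
#' @param bit_depth camera bit depth (8 or 16).
#' @param seed integer seed from which all randomness derives.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_preset()] for the two pulse-type presets.
#' @export
sim_config <- function(pulse_duration_s = 400e-9, field_strength_kvcm = 9.3,
                       lag_s = 60, emergence_rate = 0.17,
                       diameter_mean_nm = 200, diameter_sd_nm = 20,
                       diameter_min_nm = 80,
                       brightness_cv = 0.3, load_mean = 2e5,
                       immobile_fraction = 0.5, lateral_step_sd_um = 0.1,
                       axial_rate = 0.1, axial_sd_nm = 60,
                       frame_interval_s = 10, n_frames = 30,
                       n_prepulse = NULL,
                       fov_um = 10, background = 200, gain = 1,
                       read_noise_sd = 5, bit_depth = 16, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_prepulse)) cfg$n_prepulse <- min(6, n_frames - 1)
  stopifnot(cfg$immobile_fraction >= 0, cfg$immobile_fraction <= 1,
            cfg$emergence_rate >= 0, cfg$lag_s >= 0,
            cfg$bit_depth %in% c(8, 16), cfg$n_frames >= 1,
            cfg$n_prepulse >= 0, cfg$n_prepulse < cfg$n_frames,
            cfg$frame_interval_s > 0, cfg$fov_um > 0,
            cfg$diameter_mean_nm > 0, cfg$axial_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Pulse-type simulation presets
#'
#' Two canned conditions mirroring the qualitative contrast between
#' nanosecond and microsecond pulse exposures: `"ns400"` (400-ns pulse,
#' 9.3 kV/cm) produces relatively dim, uniform vesicles that start
#' emerging only after a ~60 s lag; `"us20"` (20-us pulse, 2.5 kV/cm)
#' produces vesicles with no lag — typically present already in the first
#' post-pulse frame — that are on average several-fold brighter and far
#' more heterogeneous.
#'
#' @param name `"ns400"` or `"us20"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("ns400", "us20"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    ns400 = list(pulse_duration_s = 400e-9, field_strength_kvcm = 9.3,
                 lag_s = 60, emergence_rate = 0.17,
                 brightness_cv = 0.3, load_mean = 2e5),
    us20 = list(pulse_duration_s = 20e-6, field_strength_kvcm = 2.5,
                lag_s = 0, emergence_rate = 0.25,
                brightness_cv = 1.0, load_mean = 1e6)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

#' Frame acquisition times of a configuration
#' @param config a [sim_config()].
#' @return numeric vector of frame times, s relative to the pulse at 0.
#' @export
frame_times <- function(config) {
  (seq_len(config$n_frames) - 1 - config$n_prepulse) * config$frame_interval_s
}

#' Simulate ground-truth vesicles
#'
#' Draws a seeded population of vesicles: emergence times are a
#' deterministic lag plus exponential waiting times at the configured
#' area-scaled rate; diameters come from the truncated normal; a fraction
#' is laterally immobile while the rest follow a 2-D Gaussian random walk;
#' height above the glass follows a mean-reverting (exact-discretisation
#' Ornstein-Uhlenbeck) process reflected at zero.
#'
#' @param config a [sim_config()].
#' @return list of vesicle records (class `vesicle_truth`), each with
#'   `id`, `diameter_nm`, `emergence_time_s`, `mobile`, `load`, and
#'   per-frame `frame`, `x_um`, `y_um`, `z_nm` restricted to frames at or
#'   after emergence.
#' @export
simulate_vesicles <- function(config) {
  set.seed(config$seed)
  tt <- frame_times(config)
  t_end <- tt[length(tt)]
  rate <- config$emergence_rate * config$fov_um^2 / 100
  times <- numeric(0)
  if (rate > 0 && t_end > config$lag_s) {
    t <- config$lag_s
    repeat {
      t <- t + stats::rexp(1, rate)
      if (t > t_end) break
      times <- c(times, t)
    }
  }
  n <- length(times)
  if (n == 0) return(structure(list(), class = "vesicle_truth"))

  # truncated-normal diameters by rejection
  draw_diam <- function(k) {
    out <- numeric(0)
    while (length(out) < k) {
      d <- stats::rnorm(k, config$diameter_mean_nm, config$diameter_sd_nm)
      out <- c(out, d[d >= config$diameter_min_nm])
    }
    out[seq_len(k)]
  }
  diam <- draw_diam(n)
  s <- sqrt(log(1 + config$brightness_cv^2))
  load <- config$load_mean * stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  mobile <- stats::runif(n) >= config$immobile_fraction

  dt <- config$frame_interval_s
  decay <- exp(-config$axial_rate * dt)
  innov <- config$axial_sd_nm * sqrt(1 - decay^2)
  margin <- min(1, config$fov_um / 4)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- which(tt >= times[i])
    nf <- length(fr)
    x <- y <- z <- numeric(nf)
    x[1] <- stats::runif(1, margin, config$fov_um - margin)
    y[1] <- stats::runif(1, margin, config$fov_um - margin)
    z[1] <- abs(stats::rnorm(1, 0, config$axial_sd_nm))
    if (nf > 1) for (k in 2:nf) {
      if (mobile[i]) {
        x[k] <- x[k - 1] + stats::rnorm(1, 0, config$lateral_step_sd_um)
        y[k] <- y[k - 1] + stats::rnorm(1, 0, config$lateral_step_sd_um)
      } else {
        x[k] <- x[k - 1]; y[k] <- y[k - 1]
      }
      z[k] <- abs(z[k - 1] * decay + innov * stats::rnorm(1))
    }
    out[[i]] <- list(id = i, diameter_nm = diam[i],
                     emergence_time_s = times[i], mobile = mobile[i],
                     load = load[i], frame = fr,
                     x_um = x, y_um = y, z_nm = z)
  }
  structure(out, class = "vesicle_truth")
}

#' @export
print.vesicle_truth <- function(x, ...) {
  cat(sprintf("vesicle truth: %d vesicle(s)\n", length(x)))
  invisible(x)
}

#' Ground truth as a data frame
#' @param x a `vesicle_truth` list.
#' @param ... unused.
#' @return data frame with one row per vesicle per frame.
#' @export
as.data.frame.vesicle_truth <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(id = integer(), frame = integer(), x_um = numeric(),
                      y_um = numeric(), z_nm = numeric(),
                      diameter_nm = numeric(), mobile = logical()))
  }
  do.call(rbind, lapply(x, function(v) {
    data.frame(id = v$id, frame = v$frame, x_um = v$x_um, y_um = v$y_um,
               z_nm = v$z_nm, diameter_nm = v$diameter_nm,
               mobile = v$mobile)
  }))
}

# volume-averaged evanescent attenuation for a sphere whose bottom sits at
# height z0: exp(-z0/d) * (3/(2 a^3)) * exp(-a) * ((a+1)exp(-a)+(a-1)exp(a)),
# a = R/d. Tends to exp(-z0/d) as the sphere shrinks to a point.
sphere_attenuation <- function(z0_nm, diameter_nm, penetration_depth_nm) {
  a <- diameter_nm / (2 * penetration_depth_nm)
  shape <- ifelse(a < 1e-6, 1,
                  1.5 / a^3 * exp(-a) * ((a + 1) * exp(-a) + (a - 1) * exp(a)))
  exp(-z0_nm / penetration_depth_nm) * shape
}

# effective rendered FWHM (nm): intrinsic sphere footprint (0 when the
# sphere does not reach z1/2) combined in quadrature with the channel PSF
.render_fwhm <- function(diameter_nm, psf_nm, z_half_nm) {
  intr <- ifelse(diameter_nm > z_half_nm,
                 2 * sqrt(pmax(diameter_nm * z_half_nm - z_half_nm^2, 0)), 0)
  sqrt(intr^2 + psf_nm^2)
}

# add one Gaussian spot (peak `amp`, sd `sigma_px`) to matrix `m` at the
# continuous pixel-index position (row0, col0)
.add_spot <- function(m, row0, col0, amp, sigma_px) {
  hw <- ceiling(6 * sigma_px)
  rr <- max(1, floor(row0 - hw)):min(nrow(m), ceiling(row0 + hw))
  cc <- max(1, floor(col0 - hw)):min(ncol(m), ceiling(col0 + hw))
  if (!length(rr) || !length(cc)) return(m)
  gr <- exp(-(rr - row0)^2 / (2 * sigma_px^2))
  gc <- exp(-(cc - col0)^2 / (2 * sigma_px^2))
  m[rr, cc] <- m[rr, cc] + amp * outer(gr, gc)
  m
}

# camera model: shot noise on the expected levels, then read noise, then
# clipping to the bit depth
.apply_camera_noise <- function(frames, config, seed) {
  set.seed(seed)
  full <- 2^config$bit_depth - 1
  lapply(frames, function(f) {
    v <- stats::rpois(length(f), pmax(as.vector(f), 0)) * config$gain
    v <- v + stats::rnorm(length(v), 0, config$read_noise_sd)
    matrix(pmin(pmax(v, 0), full), nrow(f), ncol(f))
  })
}

#' Render ground-truth vesicles into a TIRF-like image stack
#'
#' Forward model: each vesicle contributes, per frame, a Gaussian spot
#' whose integrated signal is its fluorophore load times the
#' volume-averaged evanescent attenuation over the sphere at its current
#' height, and whose FWHM is the sphere's intrinsic half-intensity
#' footprint combined in quadrature with the channel PSF. A constant
#' background is added; with `noise = TRUE` Poisson shot noise and
#' Gaussian read noise are applied and values clipped to the bit depth.
#'
#' @param truth a `vesicle_truth` list from [simulate_vesicles()].
#' @param optics an [optical_model()].
#' @param config the [sim_config()] used to generate `truth`.
#' @param channel channel whose PSF is used for rendering.
#' @param noise apply the camera noise model?
#' @param noise_seed seed for the camera noise (defaults to
#'   `config$seed + 1000`).
#' @return list with `stack` (a [tirf_stack()]), `truth` (per-frame truth
#'   table with expected total signal, expected peak amplitude and
#'   expected FWHM of every rendered spot), and `omitted` (ids of
#'   vesicles that fell outside the field and were skipped).
#' @export
render_stack <- function(truth, optics = optical_model(), config,
                         channel = "red", noise = TRUE,
                         noise_seed = config$seed + 1000) {
  px_nm <- optics$pixel_size_nm
  npx <- round(config$fov_um * 1000 / px_nm)
  psf <- .psf_of(optics, channel)
  zh <- optics$half_height_nm
  tt <- frame_times(config)
  frames <- replicate(config$n_frames,
                      matrix(config$background, npx, npx), simplify = FALSE)
  rows <- list()
  omitted <- integer(0)
  for (v in truth) {
    for (k in seq_along(v$frame)) {
      fi <- v$frame[k]
      x <- v$x_um[k]; y <- v$y_um[k]; z <- v$z_nm[k]
      if (x < 0 || x > config$fov_um || y < 0 || y > config$fov_um) {
        omitted <- c(omitted, v$id)
        next
      }
      atten <- sphere_attenuation(z, v$diameter_nm,
                                  optics$penetration_depth_nm)
      signal <- v$load * atten
      fwhm_nm <- .render_fwhm(v$diameter_nm, psf, zh)
      sigma_px <- fwhm_nm / (2 * sqrt(2 * log(2))) / px_nm
      amp <- signal / (2 * pi * sigma_px^2)
      col0 <- x * 1000 / px_nm + 0.5
      row0 <- y * 1000 / px_nm + 0.5
      frames[[fi]] <- .add_spot(frames[[fi]], row0, col0, amp, sigma_px)
      rows[[length(rows) + 1]] <- data.frame(
        id = v$id, frame = fi, time_s = tt[fi], x_um = x, y_um = y,
        z_nm = z, diameter_nm = v$diameter_nm, signal = signal,
        peak_expected = amp, fwhm_expected_nm = fwhm_nm)
    }
  }
  omitted <- unique(omitted)
  if (length(omitted))
    message("render_stack: ", length(omitted),
            " vesicle(s) outside the field were omitted")
  if (noise) frames <- .apply_camera_noise(frames, config, noise_seed)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), frame = integer(), time_s = numeric(),
               x_um = numeric(), y_um = numeric(), z_nm = numeric(),
               diameter_nm = numeric(), signal = numeric(),
               peak_expected = numeric(), fwhm_expected_nm = numeric())
  list(stack = tirf_stack(frames, px_nm, config$frame_interval_s,
                          time_s = tt, channel = channel),
       truth = tab, omitted = omitted)
}

#' Render a calibration-bead field
#'
#' Single-frame field of isolated sub-resolution spheres resting on the
#' glass (z = 0), placed on a jittered grid with spacing at least ten
#' times the PSF FWHM so every bead can be fitted in isolation.
#'
#' @param n number of beads (>= 1).
#' @param optics an [optical_model()].
#' @param seed integer seed for the sub-pixel position jitter.
#' @param bead_diameter_nm bead diameter, nm.
#' @param channel channel whose PSF is used.
#' @param load expected photon count per bead per frame at z = 0.
#' @param noise apply camera noise (uses a default [sim_config()] camera)?
#' @param background background level, grayscale levels.
#' @return list with `stack` (single-frame [tirf_stack()]) and
#'   `positions` (data frame of bead centres, um).
#' @export
render_beads <- function(n, optics = optical_model(), seed = 1,
                         bead_diameter_nm = 110, channel = "red",
                         load = 2e5, noise = FALSE, background = 200) {
  stopifnot(n >= 1)
  set.seed(seed)
  px_nm <- optics$pixel_size_nm
  psf <- .psf_of(optics, channel)
  spacing_um <- 10 * psf / 1000
  g <- ceiling(sqrt(n))
  fov_um <- (g + 1) * spacing_um
  npx <- ceiling(fov_um * 1000 / px_nm)
  m <- matrix(background, npx, npx)
  zh <- optics$half_height_nm
  atten <- sphere_attenuation(0, bead_diameter_nm,
                              optics$penetration_depth_nm)
  fwhm_nm <- .render_fwhm(bead_diameter_nm, psf, zh)
  sigma_px <- fwhm_nm / (2 * sqrt(2 * log(2))) / px_nm
  amp <- load * atten / (2 * pi * sigma_px^2)
  gx <- rep(seq_len(g), times = g)[seq_len(n)]
  gy <- rep(seq_len(g), each = g)[seq_len(n)]
  jit <- matrix(stats::runif(2 * n, -0.5, 0.5) * px_nm / 1000, ncol = 2)
  x <- gx * spacing_um + jit[, 1]
  y <- gy * spacing_um + jit[, 2]
  for (i in seq_len(n)) {
    m <- .add_spot(m, y[i] * 1000 / px_nm + 0.5, x[i] * 1000 / px_nm + 0.5,
                   amp, sigma_px)
  }
  frames <- list(m)
  if (noise) {
    cfg <- sim_config(seed = seed)
    frames <- .apply_camera_noise(frames, cfg, seed + 1)
  }
  list(stack = tirf_stack(frames, px_nm, 1, channel = channel),
       positions = data.frame(id = seq_len(n), x_um = x, y_um = y,
                              fwhm_expected_nm = fwhm_nm,
                              peak_expected = amp))
}

#' Simulate a two-channel labelling experiment
#'
#' A subset of the vesicles carries both labels and is rendered in both
#' channels; the remainder is split evenly between the channels.
#' `coloc_fraction` is the expected fraction of each channel's objects
#' that carry both labels — i.e. the object colocalization an ideal
#' detector would measure — so the double-labelled share of all vesicles
#' is `coloc_fraction / (2 - coloc_fraction)`. Channel B additionally
#' receives `bleedthrough` times the clean channel-A signal before
#' camera noise is applied.
#'
#' @param config a [sim_config()].
#' @param coloc_fraction expected per-channel object colocalization, 0-1.
#' @param bleedthrough fraction of channel-A signal leaking into B.
#' @param optics an [optical_model()] with PSFs for both channels.
#' @param channels names of the two channels (must index `optics`).
#' @param noise apply camera noise?
#' @return list with `stacks` (named list of two [tirf_stack()]s),
#'   `truth` (per-frame truth with a `channel` column: "A", "B" or
#'   "both"), and `assignment` (per-vesicle channel membership).
#' @export
simulate_two_channel <- function(config, coloc_fraction = 0.45,
                                 bleedthrough = 0,
                                 optics = optical_model(),
                                 channels = c("red", "green"),
                                 noise = TRUE) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1,
            bleedthrough >= 0, bleedthrough <= 1)
  truth <- simulate_vesicles(config)
  n <- length(truth)
  set.seed(config$seed + 500)
  grp <- character(n)
  if (n > 0) {
    p_both <- coloc_fraction / (2 - coloc_fraction)
    both <- stats::runif(n) < p_both
    grp[both] <- "both"
    rest <- which(!both)
    a <- rest[stats::runif(length(rest)) < 0.5]
    grp[rest] <- "B"
    grp[a] <- "A"
  }
  sub <- function(keep) structure(truth[grp %in% keep],
                                  class = "vesicle_truth")
  ra <- render_stack(sub(c("A", "both")), optics, config,
                     channel = channels[1], noise = FALSE)
  rb <- render_stack(sub(c("B", "both")), optics, config,
                     channel = channels[2], noise = FALSE)
  if (bleedthrough > 0) {
    for (i in seq_along(rb$stack$frames)) {
      rb$stack$frames[[i]] <- rb$stack$frames[[i]] + bleedthrough *
        (ra$stack$frames[[i]] - config$background)
    }
  }
  if (noise) {
    ra$stack$frames <- .apply_camera_noise(ra$stack$frames, config,
                                           config$seed + 1001)
    rb$stack$frames <- .apply_camera_noise(rb$stack$frames, config,
                                           config$seed + 1002)
  }
  tr <- rbind(
    if (nrow(ra$truth)) cbind(ra$truth, channel_set = grp[ra$truth$id]),
    if (nrow(rb$truth)) cbind(rb$truth, channel_set = grp[rb$truth$id]))
  stacks <- list(ra$stack, rb$stack)
  names(stacks) <- channels
  list(stacks = stacks, truth = tr,
       assignment = if (n) data.frame(id = seq_len(n), channel = grp)
                    else data.frame(id = integer(), channel = character()))
}
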