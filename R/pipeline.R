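#' Calibrate the effective PSF from a bead field
#'
#' Detects isolated calibration beads, fits each with two orthogonal
#' Gaussian line scans, takes the median per-bead FWHM as the measured
#' bead width, and removes the bead's intrinsic evanescent-field
#' footprint in quadrature ([psf_from_beads()]) to obtain the effective
#' lateral PSF of the imaging pipeline.
#'
#' @param bead_stack single-frame [tirf_stack()] of the bead field.
#' @param optics an [optical_model()] carrying the penetration depth and
#'   pixel size; its PSF entry for `channel` is replaced.
#' @param bead_diameter_nm known bead diameter, nm.
#' @param channel channel being calibrated.
#' @param params [detection_params()] used to find the beads.
#' @param min_beads minimum number of isolated beads required.
#' @param min_separation_um beads closer than this to a neighbour are
#'   excluded as non-isolated.
#' @return the updated `optical_model`; the calibration record (bead
#'   FWHMs, median, derived PSF) is attached as
#'   `attr(, "calibration")`.
#' @export
calibrate <- function(bead_stack, optics = optical_model(psf_fwhm_nm = NULL),
                      bead_diameter_nm = 110, channel = "red",
                      params = detection_params(), min_beads = 5,
                      min_separation_um = 2.4) {
  frame <- bead_stack$frames[[1]]
  px <- bead_stack$pixel_size_nm
  det <- detect_freckles(frame, px, params)
  n <- nrow(det)
  if (n >= 2) {
    d2 <- as.matrix(stats::dist(det[, c("x_um", "y_um")]))
    diag(d2) <- Inf
    iso <- apply(d2, 1, min) >= min_separation_um
  } else iso <- rep(TRUE, n)
  det <- det[iso, , drop = FALSE]
  if (nrow(det) < min_beads)
    stop("calibration insufficient: only ", nrow(det),
         " isolated bead(s) detected (need ", min_beads, ")")
  fw <- vapply(seq_len(nrow(det)), function(i) {
    o <- orthogonal_fwhm(frame, c(det$x_um[i], det$y_um[i]),
                         pixel_size_nm = px)
    mean(c(o$w1_um, o$w2_um)) * 1000
  }, numeric(1))
  fwhm_meas <- stats::median(fw)
  psf <- psf_from_beads(fwhm_meas, bead_diameter_nm, optics$half_height_nm)
  new_psf <- optics$psf_fwhm_nm
  if (is.null(new_psf)) new_psf <- stats::setNames(psf, channel)
  else new_psf[channel] <- psf
  out <- optical_model(optics$penetration_depth_nm, new_psf,
                       optics$pixel_size_nm)
  attr(out, "calibration") <- list(
    channel = channel, n_beads = nrow(det), bead_fwhm_nm = fw,
    fwhm_bead_measured_nm = fwhm_meas,
    bead_diameter_nm = bead_diameter_nm, psf_fwhm_nm = psf)
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param mode `"demo"` (generate synthetic data first, then analyse it
#'   and append a truth-vs-estimate comparison) — the only built-in data
#'   source; analysis of user stacks goes through the individual module
#'   functions.
#' @param preset simulation preset name ([sim_preset()]).
#' @param seed master seed; every stage derives its sub-seed from it.
#' @param sim overrides for the preset's [sim_config()] fields.
#' @param psf_fwhm_nm numeric PSF (nm) to use directly; when `NULL` a
#'   bead field is rendered and [calibrate()] runs.
#' @param psf_true_nm PSF used by the demo renderer, nm.
#' @param channel channel label.
#' @param detection a [detection_params()].
#' @param min_r_squared fits below this R^2 are flagged and excluded
#'   from diameter estimates.
#' @param output_dir directory for CSV outputs, or `NULL` to skip
#'   writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = "demo", preset = "ns400", seed = 1,
                       sim = list(), psf_fwhm_nm = NULL,
                       psf_true_nm = 289, channel = "red",
                       detection = detection_params(),
                       min_r_squared = 0.78, output_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full freckle-analysis pipeline
#'
#' Demo mode: simulates ground-truth vesicles under the configured
#' preset, renders the stack and a bead-calibration field, calibrates
#' the PSF (unless a numeric PSF is supplied, in which case calibration
#' is skipped), runs the detection time course, fits orthogonal line
#' scans through every spot detected in the final frame, deblurs the
#' fitted widths and converts them to physical diameters, and assembles
#' a report. All randomness derives from the single master seed, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @return object of class `freckle_report`: the per-frame summary
#'   table, the per-freckle diameter table, the calibration record, the
#'   configuration echo and (in demo mode) the truth comparison. When
#'   `output_dir` is set, `time_course.csv`, `diameters.csv` and
#'   `truth.csv` are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"), config$mode == "demo")
  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_preset, c(list(name = config$preset), sim_args))

  optics_true <- optical_model(
    psf_fwhm_nm = stats::setNames(config$psf_true_nm, config$channel))
  truth <- simulate_vesicles(cfg)
  rend <- render_stack(truth, optics_true, cfg, channel = config$channel)

  calib <- NULL
  if (is.null(config$psf_fwhm_nm)) {
    beads <- render_beads(9, optics_true, seed = config$seed + 77,
                          channel = config$channel)
    om <- calibrate(beads$stack,
                    optical_model(psf_fwhm_nm = NULL,
                                  pixel_size_nm = optics_true$pixel_size_nm),
                    channel = config$channel)
    calib <- attr(om, "calibration")
  } else {
    om <- optical_model(
      psf_fwhm_nm = stats::setNames(config$psf_fwhm_nm, config$channel),
      pixel_size_nm = optics_true$pixel_size_nm)
  }
  psf <- .psf_of(om, config$channel)

  pulse_frame <- cfg$n_prepulse + 1
  tc <- time_course(rend$stack, config$detection, pulse_frame)

  last <- length(rend$stack$frames)
  det <- detect_freckles(rend$stack$frames[[last]],
                         rend$stack$pixel_size_nm, config$detection)
  rows <- lapply(seq_len(nrow(det)), function(i) {
    o <- tryCatch(
      orthogonal_fwhm(rend$stack$frames[[last]],
                      c(det$x_um[i], det$y_um[i]),
                      pixel_size_nm = rend$stack$pixel_size_nm),
      error = function(e) NULL)
    if (is.null(o) || !o$fit1$converged || !o$fit2$converged) {
      return(data.frame(id = det$id[i], x_um = det$x_um[i],
                        y_um = det$y_um[i], fwhm_meas_nm = NA_real_,
                        r_squared = NA_real_, fwhm_deblur_nm = NA_real_,
                        diameter_nm = NA_real_, flag = "fit_failed"))
    }
    fw <- mean(c(o$w1_um, o$w2_um)) * 1000
    r2 <- min(o$fit1$r_squared, o$fit2$r_squared)
    flag <- ""
    deb <- diam <- NA_real_
    if (!is.finite(r2) || r2 < config$min_r_squared) {
      flag <- "low_r2"
    } else if (fw <= psf) {
      flag <- "below_resolution"
    } else {
      deb <- quadrature_deblur(fw, psf)
      diam <- footprint_to_diameter(deb, om$half_height_nm)
    }
    data.frame(id = det$id[i], x_um = det$x_um[i], y_um = det$y_um[i],
               fwhm_meas_nm = fw, r_squared = r2, fwhm_deblur_nm = deb,
               diameter_nm = diam, flag = flag)
  })
  diameters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
               fwhm_meas_nm = numeric(), r_squared = numeric(),
               fwhm_deblur_nm = numeric(), diameter_nm = numeric(),
               flag = character())

  truth_cmp <- NULL
  if (length(truth)) {
    true_d <- vapply(truth, `[[`, numeric(1), "diameter_nm")
    est <- diameters$diameter_nm[is.finite(diameters$diameter_nm)]
    truth_cmp <- list(
      n_true = length(truth), n_estimated = length(est),
      true_median_nm = stats::median(true_d),
      estimated_median_nm = if (length(est)) stats::median(est) else NA_real_)
  }

  report <- structure(list(
    time_course = tc, diameters = diameters, calibration = calib,
    psf_fwhm_nm = psf, optics = om, stack = rend$stack,
    truth = rend$truth, truth_comparison = truth_cmp,
    pulse_frame = pulse_frame,
    version = as.character(utils::packageVersion("freckletrace")),
    config = config), class = "freckle_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(tc),
                     file.path(config$output_dir, "time_course.csv"),
                     row.names = FALSE)
    utils::write.csv(diameters,
                     file.path(config$output_dir, "diameters.csv"),
                     row.names = FALSE)
    utils::write.csv(rend$truth,
                     file.path(config$output_dir, "truth.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.freckle_report <- function(x, ...) {
  cat("freckletrace run report (v", x$version, ")\n", sep = "")
  cat(sprintf("  preset %s, seed %d\n", x$config$preset, x$config$seed))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration: %d beads, median FWHM %.0f nm -> PSF %.0f nm\n",
                x$calibration$n_beads, x$calibration$fwhm_bead_measured_nm,
                x$calibration$psf_fwhm_nm))
  else
    cat(sprintf("  PSF from config: %.0f nm\n", x$psf_fwhm_nm))
  nlast <- utils::tail(x$time_course$freckle_count, 1)
  cat(sprintf("  %d frames; %d freckle(s) in the final frame\n",
              nrow(x$time_course), nlast))
  ok <- is.finite(x$diameters$diameter_nm)
  if (any(ok))
    cat(sprintf("  estimated diameters: median %.0f nm (n = %d)\n",
                stats::median(x$diameters$diameter_nm[ok]), sum(ok)))
  if (!is.null(x$truth_comparison))
    cat(sprintf("  true median diameter: %.0f nm (n = %d)\n",
                x$truth_comparison$true_median_nm,
                x$truth_comparison$n_true))
  invisible(x)
}

#' Read / write a key-value run configuration file
#'
#' Plain `key = value` text with one entry per line; `#` starts a
#' comment. Recognised keys are the arguments of [run_config()] plus
#' `sim.*` entries forwarded to the simulation config (for example
#' `sim.n_frames = 12`).
#'
#' @param path file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  args <- list(); sim <- list()
  for (i in seq_along(keys)) {
    v <- if (is.na(num[i])) vals[i] else num[i]
    if (startsWith(keys[i], "sim.")) sim[[sub("^sim\\.", "", keys[i])]] <- v
    else args[[keys[i]]] <- v
  }
  args$sim <- sim
  do.call(run_config, args)
}
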