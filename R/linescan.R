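# separable Catmull-Rom (bicubic) interpolation of a frame at continuous
# pixel-index coordinates (row, col in pixel units; pixel centres at
# integers). Falls back to clamped indices at the border; errors when the
# requested point itself is outside the image.
.interp2 <- function(frame, row, col) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (any(row < 1) || any(row > nr) || any(col < 1) || any(col > nc))
    stop("line exits the image")
  cr_w <- function(t) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    cbind(((-t + 2) * t - 1) * t / 2,
          ((3 * t - 5) * t^2 + 2) / 2,
          ((-3 * t + 4) * t + 1) * t / 2,
          (t - 1) * t^2 / 2)
  }
  r0 <- floor(row); c0 <- floor(col)
  wr <- cr_w(row - r0); wc <- cr_w(col - c0)
  out <- numeric(length(row))
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 1), nr)
    acc <- numeric(length(row))
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 1), nc)
      acc <- acc + wc[, j + 2] * frame[cbind(ri, cj)]
    }
    out <- out + wr[, i + 2] * acc
  }
  out
}

#' Extract an intensity profile along a line
#'
#' Samples the frame by separable Catmull-Rom (bicubic) interpolation at
#' one-pixel spacing along a line of `length_px` samples centred on
#' `center_um`, at the given angle (degrees, 0 = along x); the sample
#' grid always includes the line centre itself. For `width_px = 2` the profile is the
#' mean of the two parallel lines offset half a pixel to either side
#' perpendicular to the scan; wider scans average `width_px` parallel
#' lines at one-pixel spacing.
#'
#' @param frame numeric matrix.
#' @param center_um line centre `c(x, y)` in um.
#' @param angle_deg scan direction, degrees.
#' @param pixel_size_nm pixel size, nm.
#' @param length_px number of samples along the line (default 50).
#' @param width_px averaging width in pixels (default 2).
#' @return object of class `line_profile`: `values`, `x_um` (signed
#'   distance from the line centre), plus the scan geometry.
#' @export
extract_profile <- function(frame, center_um, angle_deg = 0,
                            pixel_size_nm = 46, length_px = 50,
                            width_px = 2) {
  stopifnot(length_px >= 2, width_px >= 1)
  px_um <- pixel_size_nm / 1000
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))          # along the line (x, y)
  v <- c(-sin(th), cos(th))         # perpendicular
  # sample grid includes the line centre itself (s = 0)
  s <- seq_len(length_px) - 1 - floor((length_px - 1) / 2)  # pixel units
  offs <- if (width_px == 1) 0 else
    seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  cpx <- center_um * 1000 / pixel_size_nm + 0.5   # (col, row) pixel coords
  acc <- 0
  for (o in offs) {
    colp <- cpx[1] + s * u[1] + o * v[1]
    rowp <- cpx[2] + s * u[2] + o * v[2]
    acc <- acc + .interp2(frame, rowp, colp)
  }
  structure(list(values = acc / length(offs), x_um = s * px_um,
                 angle_deg = angle_deg, center_um = center_um,
                 pixel_size_nm = pixel_size_nm, width_px = width_px,
                 background_subtracted = FALSE),
            class = "line_profile")
}

#' Background-subtract and centre a line profile
#'
#' Averages the `edge_px` samples at each end of the profile and
#' subtracts that edge mean as background, then shifts the coordinate
#' origin to the maximum-intensity sample. A maximum falling within the
#' edge region raises a suspect-profile warning.
#'
#' @param profile a [extract_profile()] result.
#' @param edge_px samples averaged at each end (default 10).
#' @return recentred, background-subtracted `line_profile` (with the
#'   applied shift recorded as `center_shift_um` and a `suspect` flag).
#' @export
subtract_background_and_center <- function(profile, edge_px = 10) {
  n <- length(profile$values)
  stopifnot(n >= 3 * edge_px)
  bg <- mean(profile$values[c(seq_len(edge_px), (n - edge_px + 1):n)])
  vals <- profile$values - bg
  # locate the maximum on a lightly smoothed copy so that single-pixel
  # noise excursions do not shift the centring; values stay raw
  sm <- stats::filter(vals, rep(1 / 3, 3))
  sm[c(1, n)] <- vals[c(1, n)]
  imax <- which.max(sm)
  suspect <- imax <= edge_px || imax > n - edge_px
  if (suspect)
    warning("profile maximum lies in the edge region; fit is suspect")
  shift <- profile$x_um[imax]
  profile$values <- vals
  profile$x_um <- profile$x_um - shift
  profile$background <- bg
  profile$center_shift_um <- shift
  profile$suspect <- suspect
  profile$background_subtracted <- TRUE
  profile
}

#' Fit a Gaussian to a line profile
#'
#' Least-squares fit of `Y = A exp(-4 ln2 X^2 / W^2)` to a centred,
#' background-subtracted profile, where `W` is directly the full width at
#' half maximum (um). The centre is fixed at X = 0 (the profile is
#' centred on its maximum by construction). Fit quality is reported as
#' the Pearson correlation R between observed and fitted values, the
#' coefficient of determination R^2, and the p value of the F test of
#' the observed-on-fitted regression.
#'
#' @param profile a `line_profile`; if not yet background-subtracted it
#'   is passed through [subtract_background_and_center()] first.
#' @param start_fwhm_um optimiser start for W (default 0.3 um).
#' @param bounds_fwhm_um lower/upper bounds on W, um.
#' @return object of class `linescan_fit` with elements `amplitude`,
#'   `fwhm_um`, `center_offset_um`, `r`, `r_squared`, `p_value`,
#'   `converged`, `suspect`, plus the data and fitted values. Standard
#'   methods `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot` apply.
#' @export
fit_gaussian <- function(profile, start_fwhm_um = 0.3,
                         bounds_fwhm_um = c(0.05, 5)) {
  if (!isTRUE(profile$background_subtracted))
    profile <- subtract_background_and_center(profile)
  x <- profile$x_um
  y <- profile$values
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-4 * log(2) * x^2 / W^2),
      start = list(A = a0, W = start_fwhm_um),
      lower = c(0, bounds_fwhm_um[1]), upper = c(Inf, bounds_fwhm_um[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(amplitude = NA_real_, fwhm_um = NA_real_,
                center_offset_um = profile$center_shift_um %||% 0,
                r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                converged = FALSE, suspect = TRUE,
                diagnostics = conditionMessage(fit),
                profile = profile, fitted_values = rep(NA_real_, length(y)))
    class(out) <- "linescan_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  r <- if (stats::sd(yhat) > 0 && stats::sd(y) > 0)
    stats::cor(y, yhat) else NA_real_
  pv <- tryCatch({
    lmfit <- stats::lm(y ~ yhat)
    fs <- suppressWarnings(summary(lmfit))$fstatistic
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }, error = function(e) NA_real_)
  out <- list(amplitude = unname(cf["A"]), fwhm_um = unname(cf["W"]),
              center_offset_um = profile$center_shift_um %||% 0,
              r = r, r_squared = r2, p_value = pv,
              converged = TRUE,
              suspect = isTRUE(profile$suspect) ||
                (is.finite(r2) && r2 < 0.5),
              profile = profile, fitted_values = yhat)
  class(out) <- "linescan_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linescan_fit <- function(x, ...) {
  cat("Gaussian line-scan fit\n")
  if (!x$converged) {
    cat("  did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  A (peak)   : %.4g a.u.\n", x$amplitude))
  cat(sprintf("  W (FWHM)   : %.4f um\n", x$fwhm_um))
  cat(sprintf("  R = %.4f, R^2 = %.4f, p = %.3g\n",
              x$r, x$r_squared, x$p_value))
  if (x$suspect) cat("  [flagged: low fit quality or edge maximum]\n")
  invisible(x)
}

#' @export
summary.linescan_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    res <- residuals(object)
    cat(sprintf("  residual SD: %.4g over %d samples\n",
                stats::sd(res), length(res)))
  }
  invisible(object)
}

#' @export
coef.linescan_fit <- function(object, ...) {
  c(A = object$amplitude, W = object$fwhm_um)
}

#' @export
fitted.linescan_fit <- function(object, ...) object$fitted_values

#' @export
residuals.linescan_fit <- function(object, ...) {
  object$profile$values - object$fitted_values
}

#' Predict profile values from a line-scan fit
#' @param object a `linescan_fit`.
#' @param x_um positions (um from centre); defaults to the fitted data.
#' @param ... unused.
#' @export
predict.linescan_fit <- function(object, x_um = object$profile$x_um, ...) {
  object$amplitude * exp(-4 * log(2) * x_um^2 / object$fwhm_um^2)
}

#' @export
plot.linescan_fit <- function(x, ...) {
  graphics::plot(x$profile$x_um, x$profile$values,
                 xlab = "distance from centre (um)",
                 ylab = "intensity (a.u.)", ...)
  xs <- seq(min(x$profile$x_um), max(x$profile$x_um), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2)
  invisible(x)
}

#' FWHM along two orthogonal scans and the oval footprint area
#'
#' Fits Gaussian profiles along two scans 90 degrees apart through the
#' same centre and reports both FWHM values together with the area of
#' the oval whose diameters they are: `pi * W1 * W2 / 4`.
#'
#' @inheritParams extract_profile
#' @param angle_deg angle of the first scan.
#' @param ... passed to [extract_profile()].
#' @return list with `fit1`, `fit2` (class `linescan_fit`), `w1_um`,
#'   `w2_um` and `oval_area_um2`.
#' @export
orthogonal_fwhm <- function(frame, center_um, angle_deg = 0,
                            pixel_size_nm = 46, ...) {
  f1 <- fit_gaussian(extract_profile(frame, center_um, angle_deg,
                                     pixel_size_nm, ...))
  f2 <- fit_gaussian(extract_profile(frame, center_um, angle_deg + 90,
                                     pixel_size_nm, ...))
  list(fit1 = f1, fit2 = f2, w1_um = f1$fwhm_um, w2_um = f2$fwhm_um,
       oval_area_um2 = pi * f1$fwhm_um * f2$fwhm_um / 4)
}

#' Track one freckle's FWHM over time
#'
#' Follows a single spot across frames: in each frame the scan centre is
#' re-placed on the brightest pixel within a search window (3x the
#' current FWHM by default) around the previous centre, then the profile
#' is fitted. The series is truncated, with the reason recorded, when
#' the background-subtracted peak falls below `min_peak`.
#'
#' @param stack a [tirf_stack()].
#' @param center_um initial spot centre `c(x, y)`, um.
#' @param frames frame indices to track (default: all).
#' @param angle_deg scan angle.
#' @param min_peak minimum background-subtracted peak to keep tracking.
#' @param search_factor search-window half-size as a multiple of the
#'   current FWHM.
#' @param ... passed to [extract_profile()].
#' @return data frame with `frame`, `time_s`, `A`, `W_um`, `R`, `R2`,
#'   `x_um`, `y_um`; a truncation reason, if any, is in
#'   `attr(, "truncated")`.
#' @export
track_freckle_fwhm <- function(stack, center_um,
                               frames = seq_along(stack$frames),
                               angle_deg = 0, min_peak = 100,
                               search_factor = 3, ...) {
  px_nm <- stack$pixel_size_nm
  w_cur <- 0.35
  rows <- list()
  truncated <- NULL
  cen <- center_um
  for (fi in frames) {
    frame <- stack$frames[[fi]]
    half_um <- search_factor * w_cur / 2
    cpx <- cen * 1000 / px_nm + 0.5
    hpx <- max(1, round(half_um * 1000 / px_nm))
    rr <- max(1, round(cpx[2]) - hpx):min(nrow(frame), round(cpx[2]) + hpx)
    cc <- max(1, round(cpx[1]) - hpx):min(ncol(frame), round(cpx[1]) + hpx)
    sub <- frame[rr, cc, drop = FALSE]
    im <- arrayInd(which.max(sub), dim(sub))
    cen <- c((cc[im[2]] - 0.5) * px_nm / 1000,
             (rr[im[1]] - 0.5) * px_nm / 1000)
    prof <- tryCatch(
      subtract_background_and_center(
        extract_profile(frame, cen, angle_deg, px_nm, ...)),
      error = function(e) e)
    if (inherits(prof, "error")) {
      truncated <- paste("frame", fi, ":", conditionMessage(prof))
      break
    }
    if (max(prof$values) < min_peak) {
      truncated <- paste0("frame ", fi, ": peak below ", min_peak,
                          " (spot lost)")
      break
    }
    ft <- fit_gaussian(prof)
    if (ft$converged && is.finite(ft$fwhm_um)) w_cur <- ft$fwhm_um
    rows[[length(rows) + 1]] <- data.frame(
      frame = fi, time_s = stack$time_s[fi], A = ft$amplitude,
      W_um = ft$fwhm_um, R = ft$r, R2 = ft$r_squared,
      x_um = cen[1], y_um = cen[2])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), time_s = numeric(), A = numeric(),
               W_um = numeric(), R = numeric(), R2 = numeric(),
               x_um = numeric(), y_um = numeric())
  attr(out, "truncated") <- truncated
  out
}
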