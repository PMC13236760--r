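#' Detection parameters
#'
#' Parameters of the automated spot ("freckle") detector: spots are
#' connected components of pixels at least `threshold` grayscale levels
#' above the local background, restricted to a rectangular region of
#' interest, and discarded when larger than `max_size_um`.
#'
#' @param threshold grayscale levels above local background (default 100).
#' @param max_size_um maximum object size, um (default 5); objects at or
#'   above this size are discarded.
#' @param min_area_px minimum component area in pixels (default 4);
#'   smaller components are rejected as single-pixel noise excursions.
#' @param background_window_um structuring-element diameter for the
#'   local-background estimate, um. Must be well above the spot scale.
#' @param roi region of interest `c(x, y, w, h)` in um, or `NULL` for the
#'   whole frame, or `"auto"` (resolved by [time_course()]).
#' @param connectivity pixel connectivity for components, 4 or 8.
#' @param size_metric how "size" is measured: equivalent-circle diameter
#'   of the component (default) or the larger bounding-box side.
#' @param watershed split touching spots along sub-threshold saddles?
#'   Off by default: overlapping spots are kept merged.
#' @param saturation_level pixel value at or above which an object is
#'   flagged as saturated.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold = 100, max_size_um = 5,
                             min_area_px = 4,
                             background_window_um = 2, roi = NULL,
                             connectivity = 8,
                             size_metric = c("equivalent_diameter", "bbox"),
                             watershed = FALSE,
                             saturation_level = 65535) {
  stopifnot(threshold > 0, max_size_um > 0, min_area_px >= 1,
            background_window_um > 0, connectivity %in% c(4, 8))
  size_metric <- match.arg(size_metric)
  structure(list(threshold = threshold, max_size_um = max_size_um,
                 min_area_px = min_area_px,
                 background_window_um = background_window_um, roi = roi,
                 connectivity = connectivity, size_metric = size_metric,
                 watershed = watershed,
                 saturation_level = saturation_level),
            class = "detection_params")
}

#' Local background of a frame
#'
#' Grayscale morphological opening with a disc whose diameter is the
#' configured background window: peaks narrower than the disc (i.e.
#' spot-scale structure) are removed while broad gradients are tracked.
#'
#' @param frame numeric matrix, grayscale levels.
#' @param pixel_size_nm pixel size, nm.
#' @param params a [detection_params()].
#' @param expected_spot_fwhm_um optional expected spot FWHM; if given,
#'   the background window must be at least three times it.
#' @return background matrix of the same dimension.
#' @export
estimate_local_background <- function(frame, pixel_size_nm = 46,
                                      params = detection_params(),
                                      expected_spot_fwhm_um = NULL) {
  if (!is.null(expected_spot_fwhm_um) &&
      params$background_window_um < 3 * expected_spot_fwhm_um)
    stop("background window smaller than 3x the expected spot FWHM")
  r_px <- max(1, round(params$background_window_um * 1000 /
                         pixel_size_nm / 2))
  size <- 2 * r_px + 1
  brush <- EBImage::makeBrush(size, shape = "disc")
  # EBImage clamps grayscale images to [0, 1]; rescale around the opening
  hi <- max(frame, 1)
  out <- EBImage::opening(frame / hi, brush) * hi
  matrix(as.numeric(out), nrow(frame), ncol(frame))
}

# sparse connected-component labelling with selectable 4/8 connectivity
# (returns an integer label matrix; 0 = background)
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  queue <- integer(length(idx))
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    queue[1] <- p
    head <- 1L; tail <- 1L
    while (head <= tail) {
      q <- queue[head]; head <- head + 1L
      r <- ((q - 1L) %% nr) + 1L
      cl <- ((q - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        qq <- (cc - 1L) * nr + rr
        if (mask[qq] && lab[qq] == 0L) {
          lab[qq] <- cur
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- qq
        }
      }
    }
  }
  lab
}

#' Detect freckles in one frame
#'
#' Thresholds the frame at local background + `threshold`, labels
#' connected components within the ROI, discards components at or above
#' `max_size_um`, and computes per-object statistics on the
#' background-subtracted values: mean, peak and integrated intensity,
#' pixel area, and an intensity-weighted (sub-pixel) centroid.
#'
#' @inheritParams estimate_local_background
#' @param background optional precomputed background matrix.
#' @return data frame of class `freckle_set` with one row per object
#'   (columns `id`, `area_px`, `equiv_diameter_um`, `x_um`, `y_um`,
#'   `mean_intensity`, `peak_intensity`, `integrated_intensity`,
#'   `saturated`); the pixel masks are kept in `attr(, "masks")` as
#'   two-column (row, col) matrices, and the label image in
#'   `attr(, "labels")`.
#' @export
detect_freckles <- function(frame, pixel_size_nm = 46,
                            params = detection_params(),
                            background = NULL) {
  if (is.null(background))
    background <- estimate_local_background(frame, pixel_size_nm, params)
  resid <- frame - background
  mask <- resid > params$threshold
  if (!is.null(params$roi) && !identical(params$roi, "auto"))
    mask <- mask & .roi_mask(dim(frame), pixel_size_nm, params$roi)
  lab <- label_components(mask, params$connectivity)
  if (params$watershed && max(lab) > 0) {
    ws <- EBImage::watershed(resid * (lab > 0))
    lab <- matrix(as.integer(ws), nrow(frame), ncol(frame))
  }
  px_um <- pixel_size_nm / 1000
  nlab <- max(lab)
  rows <- list(); masks <- list()
  keep <- 0L
  for (l in seq_len(nlab)) {
    pix <- which(lab == l)
    r <- ((pix - 1L) %% nrow(frame)) + 1L
    cl <- ((pix - 1L) %/% nrow(frame)) + 1L
    area <- length(pix)
    if (area < params$min_area_px) next
    size_um <- switch(params$size_metric,
      equivalent_diameter = 2 * sqrt(area / pi) * px_um,
      bbox = max(diff(range(r)) + 1, diff(range(cl)) + 1) * px_um)
    if (size_um >= params$max_size_um) next
    vals <- resid[pix]
    keep <- keep + 1L
    w <- pmax(vals, 0)
    if (sum(w) <= 0) w <- rep(1, area)
    rows[[keep]] <- data.frame(
      id = keep, area_px = area,
      equiv_diameter_um = 2 * sqrt(area / pi) * px_um,
      x_um = sum((cl - 0.5) * w) / sum(w) * px_um,
      y_um = sum((r - 0.5) * w) / sum(w) * px_um,
      mean_intensity = mean(vals), peak_intensity = max(vals),
      integrated_intensity = sum(vals),
      saturated = any(frame[pix] >= params$saturation_level))
    masks[[keep]] <- cbind(row = r, col = cl)
  }
  out <- if (keep) do.call(rbind, rows) else
    data.frame(id = integer(), area_px = integer(),
               equiv_diameter_um = numeric(), x_um = numeric(),
               y_um = numeric(), mean_intensity = numeric(),
               peak_intensity = numeric(),
               integrated_intensity = numeric(), saturated = logical())
  attr(out, "masks") <- masks
  attr(out, "labels") <- lab
  attr(out, "dim_px") <- dim(frame)
  class(out) <- c("freckle_set", "data.frame")
  out
}

#' Per-frame summary statistics of detected freckles
#'
#' Count, mean of per-freckle mean intensities, mean of per-freckle peak
#' intensities, cumulative (summed) integrated intensity, and the
#' between-freckle variability as the sample standard deviation of the
#' per-freckle integrated intensities (0 by convention when n <= 1).
#' All statistics are 0 for an empty frame.
#'
#' @param freckles a `freckle_set` from [detect_freckles()].
#' @return one-row data frame.
#' @export
summarize_frame <- function(freckles) {
  n <- nrow(freckles)
  data.frame(
    freckle_count = n,
    mean_of_mean_intensity = if (n) mean(freckles$mean_intensity) else 0,
    mean_of_peak_intensity = if (n) mean(freckles$peak_intensity) else 0,
    cumulative_integrated_intensity =
      if (n) sum(freckles$integrated_intensity) else 0,
    sd_of_integrated =
      if (n > 1) stats::sd(freckles$integrated_intensity) else 0)
}

# choose the 10x10 um (or roi_side) window maximising the post-pulse
# object count over a sliding grid
auto_roi <- function(centroids, fov_um, roi_side = 10, step_um = 0.5) {
  if (!nrow(centroids)) return(c(0, 0, min(roi_side, fov_um),
                                 min(roi_side, fov_um)))
  side <- min(roi_side, fov_um)
  xs <- seq(0, max(fov_um - side, 0), by = step_um)
  ys <- xs
  best <- c(0, 0); best_n <- -1
  for (x0 in xs) for (y0 in ys) {
    nn <- sum(centroids$x_um >= x0 & centroids$x_um <= x0 + side &
              centroids$y_um >= y0 & centroids$y_um <= y0 + side)
    if (nn > best_n) { best_n <- nn; best <- c(x0, y0) }
  }
  c(best, side, side)
}

#' Freckle time course of a stack
#'
#' Runs detection on every frame and assembles the per-frame summary
#' table with a time axis in seconds relative to the pulse. With
#' `roi = "auto"` in the parameters, a square window (10 x 10 um by
#' default) is placed so as to maximise the total post-pulse object
#' count, emulating manual placement over the densest region.
#'
#' @param stack a [tirf_stack()].
#' @param params a [detection_params()].
#' @param pulse_frame index of the frame acquired at pulse delivery.
#' @param roi_side side of the automatic ROI, um.
#' @return data frame (class `stack_summary`) with columns `frame`,
#'   `time_s` and the [summarize_frame()] statistics; the resolved ROI is
#'   in `attr(, "roi")` and the per-frame detections in
#'   `attr(, "detections")`.
#' @export
time_course <- function(stack, params = detection_params(),
                        pulse_frame = 1, roi_side = 10) {
  stopifnot(pulse_frame >= 1, pulse_frame <= length(stack$frames))
  px <- stack$pixel_size_nm
  fov_um <- ncol(stack$frames[[1]]) * px / 1000
  if (identical(params$roi, "auto")) {
    p0 <- params; p0$roi <- NULL
    post <- seq(pulse_frame, length(stack$frames))
    cents <- do.call(rbind, lapply(post, function(i) {
      f <- detect_freckles(stack$frames[[i]], px, p0)
      f[, c("x_um", "y_um")]
    }))
    params$roi <- auto_roi(cents, fov_um, roi_side)
  }
  tt <- stack$time_s - stack$time_s[pulse_frame]
  dets <- vector("list", length(stack$frames))
  rows <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    dets[[i]] <- detect_freckles(stack$frames[[i]], px, params)
    rows[[i]] <- cbind(frame = i, time_s = tt[i],
                       summarize_frame(dets[[i]]))
  }
  out <- do.call(rbind, rows)
  attr(out, "roi") <- params$roi
  attr(out, "detections") <- dets
  class(out) <- c("stack_summary", "data.frame")
  out
}

#' Object-level detection recovery against ground truth
#'
#' Scores detection on a rendered synthetic stack against its truth
#' table. A truth spot counts as recovered when its true position falls
#' inside a detected component's pixel mask or within `match_radius_um`
#' of a detected centroid — so overlapping spots that the detector
#' (deliberately) reports as one merged component are credited to all
#' constituents. Precision, recall and F1 are computed over truth spots
#' with expected peak at or above `min_peak`; detections explained by
#' dimmer truth spots are not counted as false positives.
#'
#' @param rendered a [render_stack()] result (stack plus truth table).
#' @param params a [detection_params()].
#' @param min_peak expected-peak cutoff defining the scored truth subset.
#' @param match_radius_um centroid matching radius, um.
#' @return list with `tp`, `fn`, `fp`, `precision`, `recall`, `f1`.
#' @export
detection_recovery <- function(rendered, params = detection_params(),
                               min_peak = 300, match_radius_um = 0.35) {
  stack <- rendered$stack
  truth <- rendered$truth
  px <- stack$pixel_size_nm
  tp <- fn <- fp <- 0
  for (fi in seq_along(stack$frames)) {
    tr <- truth[truth$frame == fi, ]
    det <- detect_freckles(stack$frames[[fi]], px, params)
    masks <- attr(det, "masks")
    dims <- attr(det, "dim_px")
    recovered <- logical(nrow(tr))
    hitdet <- rep(FALSE, nrow(det))
    if (nrow(tr) && nrow(det)) {
      for (ti in seq_len(nrow(tr))) {
        r0 <- min(max(round(tr$y_um[ti] * 1000 / px + 0.5), 1), dims[1])
        c0 <- min(max(round(tr$x_um[ti] * 1000 / px + 0.5), 1), dims[2])
        hits <- vapply(masks, function(m)
          any(m[, 1] == r0 & m[, 2] == c0), TRUE)
        dcen <- sqrt((det$x_um - tr$x_um[ti])^2 +
                     (det$y_um - tr$y_um[ti])^2)
        hits <- hits | dcen <= match_radius_um
        recovered[ti] <- any(hits)
        hitdet <- hitdet | hits
      }
    }
    bright <- tr$peak_expected >= min_peak
    tp <- tp + sum(bright & recovered)
    fn <- fn + sum(bright & !recovered)
    fp <- fp + sum(!hitdet)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision + recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fn = fn, fp = fp, precision = precision,
       recall = recall, f1 = f1)
}
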