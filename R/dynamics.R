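# pixel masks -> linear-index sets (needs the frame dimension)
.mask_pixels <- function(freckles) {
  d <- attr(freckles, "dim_px")
  lapply(attr(freckles, "masks"), function(m) (m[, 2] - 1L) * d[1] + m[, 1])
}

#' Classify freckle motion between two registered frames
#'
#' Implements the two-colour overlay logic: an object in the new frame is
#' "stationary" if its pixel mask shares at least one pixel with any
#' object of the reference frame (the overlap that renders yellow in a
#' red/green overlay); otherwise it "moved or emerged anew". Reference
#' objects not overlapped by any new object are counted as disappeared.
#' An alternative centroid rule classifies a new object as stationary
#' when its centroid lies within `centroid_threshold_px` pixels of a
#' reference centroid.
#'
#' @param objects_ref `freckle_set` of the reference frame.
#' @param objects_new `freckle_set` of the later frame.
#' @param rule `"overlap"` (default, any shared pixel) or `"centroid"`.
#' @param centroid_threshold_px distance threshold for the centroid rule.
#' @param pixel_size_nm pixel size, nm (used by the centroid rule).
#' @return list of class `motion_summary`: counts `n_ref`, `n_new`,
#'   `stationary`, `moved_or_new`, `disappeared`,
#'   `fraction_stationary` (= stationary / n_ref), and `classes`, a data
#'   frame with one row per new object.
#' @export
classify_motion <- function(objects_ref, objects_new,
                            rule = c("overlap", "centroid"),
                            centroid_threshold_px = 1,
                            pixel_size_nm = 46) {
  rule <- match.arg(rule)
  n_ref <- nrow(objects_ref); n_new <- nrow(objects_new)
  if (rule == "overlap") {
    ref_px <- .mask_pixels(objects_ref)
    new_px <- .mask_pixels(objects_new)
    ref_all <- unlist(ref_px)
    stat <- vapply(new_px, function(p) any(p %in% ref_all), TRUE)
    new_all <- unlist(new_px)
    gone <- vapply(ref_px, function(p) !any(p %in% new_all), TRUE)
  } else {
    thr_um <- centroid_threshold_px * pixel_size_nm / 1000
    near <- function(x, y, xs, ys)
      length(xs) > 0 && any(sqrt((xs - x)^2 + (ys - y)^2) <= thr_um)
    stat <- vapply(seq_len(n_new), function(i)
      near(objects_new$x_um[i], objects_new$y_um[i],
           objects_ref$x_um, objects_ref$y_um), TRUE)
    gone <- vapply(seq_len(n_ref), function(i)
      !near(objects_ref$x_um[i], objects_ref$y_um[i],
            objects_new$x_um, objects_new$y_um), TRUE)
  }
  if (n_new == 0) stat <- logical(0)
  if (n_ref == 0) gone <- logical(0)
  classes <- data.frame(
    object_id = seq_len(n_new),
    class = ifelse(stat, "stationary", "moved_or_new"))
  structure(list(
    n_ref = n_ref, n_new = n_new,
    stationary = sum(stat), moved_or_new = sum(!stat),
    disappeared = sum(gone),
    fraction_stationary = if (n_ref > 0) sum(stat) / n_ref else NA_real_,
    rule = rule, classes = classes),
    class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf(
    "motion (%s rule): %d reference, %d new; %d stationary, %d moved/new, %d disappeared\n",
    x$rule, x$n_ref, x$n_new, x$stationary, x$moved_or_new, x$disappeared))
  if (!is.na(x$fraction_stationary))
    cat(sprintf("  fraction stationary: %.2f\n", x$fraction_stationary))
  invisible(x)
}

#' Object-based colocalization between two channels
#'
#' Percentage of reference-channel object pixels that also fall inside
#' objects detected in the other channel:
#' `100 * |ref pixels in other objects| / |ref pixels|`. The measure is
#' asymmetric; swap the arguments for the reciprocal direction.
#'
#' @param objects_ref `freckle_set` of the reference channel.
#' @param objects_other `freckle_set` of the other channel (same frame
#'   geometry).
#' @return percent overlap in \[0, 100\], or `NA` (with a message) when
#'   the reference channel has no objects.
#' @export
object_colocalization <- function(objects_ref, objects_other) {
  ref <- unlist(.mask_pixels(objects_ref))
  if (!length(ref)) {
    message("no reference objects: colocalization undefined")
    return(NA_real_)
  }
  other <- unlist(.mask_pixels(objects_other))
  100 * sum(ref %in% other) / length(ref)
}

#' Delta-F/F fluorescence trace
#'
#' Per-frame fluorescence is the mean over the cell ROI minus the mean
#' over the background ROI; the baseline F0 is the mean of the pre-pulse
#' frames, and the trace is expressed as
#' `dF = 100% x (F - F0) / F0`.
#'
#' @param stack a [tirf_stack()].
#' @param cell_roi logical matrix selecting cell-body pixels.
#' @param background_roi logical matrix selecting background pixels, or
#'   `NULL` to skip background subtraction.
#' @param pulse_frame index of the pulse frame; frames before it define
#'   the baseline.
#' @return data frame of class `calcium_trace` with `frame`, `time_s`,
#'   `F` and `dF_percent`; the baseline is stored in `attr(, "F0")`.
#' @export
delta_f_over_f <- function(stack, cell_roi, background_roi = NULL,
                           pulse_frame) {
  stopifnot(pulse_frame >= 2, pulse_frame <= length(stack$frames))
  f <- vapply(stack$frames, function(fr) {
    v <- mean(fr[cell_roi])
    if (!is.null(background_roi)) v <- v - mean(fr[background_roi])
    v
  }, numeric(1))
  f0 <- mean(f[seq_len(pulse_frame - 1)])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline F0 is not positive; check the ROIs")
  out <- data.frame(frame = seq_along(f),
                    time_s = stack$time_s - stack$time_s[pulse_frame],
                    F = f, dF_percent = 100 * (f - f0) / f0)
  attr(out, "F0") <- f0
  class(out) <- c("calcium_trace", "data.frame")
  out
}
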