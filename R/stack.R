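#' TIRF image stack container
#'
#' A light container for a multi-frame grayscale time-lapse: a list of
#' numeric matrices (rows = y, columns = x; values in camera grayscale
#' levels) plus the calibration metadata every downstream stage needs.
#' Image coordinates are expressed in micrometres, with the centre of
#' pixel `[r, c]` at `x = (c - 0.5) * pixel / 1000`,
#' `y = (r - 0.5) * pixel / 1000`.
#'
#' @param frames list of numeric matrices of identical dimension.
#' @param pixel_size_nm pixel size, nm.
#' @param frame_interval_s time between frames, s.
#' @param time_s optional vector of frame times (s); when omitted, frames
#'   are at `(i - 1) * frame_interval_s`.
#' @param channel optional channel label.
#' @return An object of class `tirf_stack`.
#' @export
tirf_stack <- function(frames, pixel_size_nm = 46, frame_interval_s = 10,
                       time_s = NULL, channel = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, TRUE)))
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must share the same dimensions")
  if (is.null(time_s)) time_s <- (seq_along(frames) - 1) * frame_interval_s
  stopifnot(length(time_s) == length(frames))
  structure(
    list(frames = frames, pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s, time_s = time_s,
         channel = channel),
    class = "tirf_stack"
  )
}

#' @export
print.tirf_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "TIRF stack: %d frame(s), %d x %d px (%.0f nm/px), %.3g s interval\n",
    length(x$frames), d[1], d[2], x$pixel_size_nm, x$frame_interval_s))
  if (!is.null(x$channel)) cat("  channel:", x$channel, "\n")
  invisible(x)
}

#' @export
length.tirf_stack <- function(x) length(x$frames)

#' Extract one frame of a stack
#' @param stack a [tirf_stack()].
#' @param i frame index.
#' @return numeric matrix.
#' @export
stack_frame <- function(stack, i) {
  stopifnot(i >= 1, i <= length(stack$frames))
  stack$frames[[i]]
}

#' Read a multi-page TIFF into a TIRF stack
#'
#' @param path TIFF file path.
#' @inheritParams tirf_stack
#' @param scale grayscale full-scale value the file was written against;
#'   TIFF stores values normalised to \[0, 1\], so levels are recovered as
#'   `value * scale`. Default 65535 (16-bit).
#' @return a [tirf_stack()].
#' @export
read_tirf_stack <- function(path, pixel_size_nm = 46, frame_interval_s = 10,
                            scale = 65535, channel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * scale
  })
  tirf_stack(frames, pixel_size_nm, frame_interval_s, channel = channel)
}

#' Write a TIRF stack to a multi-page 16-bit TIFF
#'
#' @param stack a [tirf_stack()].
#' @param path output path.
#' @param scale full-scale grayscale value mapped to TIFF white
#'   (default 65535).
#' @return `path`, invisibly.
#' @export
write_tirf_stack <- function(stack, path, scale = 65535) {
  imgs <- lapply(stack$frames,
                 function(f) round(pmin(pmax(f, 0), scale)) / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

# rectangular ROI (x, y, w, h in um) -> logical pixel mask
.roi_mask <- function(dim_px, pixel_size_nm, roi_um) {
  px <- pixel_size_nm / 1000
  cx <- (seq_len(dim_px[2]) - 0.5) * px
  cy <- (seq_len(dim_px[1]) - 0.5) * px
  inx <- cx >= roi_um[1] & cx <= roi_um[1] + roi_um[3]
  iny <- cy >= roi_um[2] & cy <= roi_um[2] + roi_um[4]
  outer(iny, inx, `&`)
}
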