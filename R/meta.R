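#' Acquisition metadata for a video angiography sequence
#'
#' Bundles the acquisition parameters that every downstream stage needs:
#' frame rate, recording duration, spatial scale and the optic nerve head
#' (ONH) position. Time zero is the start of fluorescein infusion, so frame
#' \code{i} (1-based) is acquired at \code{(i - 1) / frame_rate_hz} seconds.
#'
#' @param frame_rate_hz Frames per second, > 0. Typical video angiography
#'   runs at 30 Hz.
#' @param duration_s Total recorded seconds, > 0 (30 s for a control
#'   acquisition, 60 s when prolonged leakage must be captured).
#' @param um_per_px Micrometres per pixel, > 0. Fundus cameras differ; this
#'   must be supplied by the user (e.g. calibrated from a scale bar).
#' @param onh_center_px Optional numeric length-2 \code{c(row, col)} of the
#'   optic nerve head centre, 1-based pixel coordinates, row 1 at the top.
#' @param t0_is_infusion_start Logical; \code{TRUE} (default) declares that
#'   frame 1 coincides with the start of dye infusion.
#'
#' @return An object of class \code{"acquisition_meta"}.
#' @export
#' @examples
#' acquisition_meta(30, 30, um_per_px = 31)
acquisition_meta <- function(frame_rate_hz, duration_s, um_per_px,
                             onh_center_px = NULL,
                             t0_is_infusion_start = TRUE) {
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L,
            is.finite(frame_rate_hz), frame_rate_hz > 0)
  stopifnot(is.numeric(duration_s), length(duration_s) == 1L,
            is.finite(duration_s), duration_s > 0)
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L,
            is.finite(um_per_px), um_per_px > 0)
  if (!is.null(onh_center_px)) {
    stopifnot(is.numeric(onh_center_px), length(onh_center_px) == 2L,
              all(is.finite(onh_center_px)))
    onh_center_px <- as.numeric(onh_center_px)
  }
  structure(list(frame_rate_hz = as.numeric(frame_rate_hz),
                 duration_s = as.numeric(duration_s),
                 um_per_px = as.numeric(um_per_px),
                 onh_center_px = onh_center_px,
                 t0_is_infusion_start = isTRUE(t0_is_infusion_start)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("Acquisition metadata\n")
  cat(sprintf("  frame rate : %g Hz\n", x$frame_rate_hz))
  cat(sprintf("  duration   : %g s (%d frames nominal)\n", x$duration_s,
              round(x$frame_rate_hz * x$duration_s)))
  cat(sprintf("  scale      : %g um/px\n", x$um_per_px))
  if (!is.null(x$onh_center_px))
    cat(sprintf("  ONH centre : (row %g, col %g)\n",
                x$onh_center_px[1], x$onh_center_px[2]))
  invisible(x)
}

#' Image sequence container
#'
#' A registered or raw grayscale video stack with its acquisition metadata
#' and a per-pixel validity mask. Frames are stored as an H x W x T array;
#' \code{valid_mask} is FALSE wherever a pixel is unusable in at least one
#' frame (e.g. border padding introduced by translation).
#'
#' @param frames Numeric H x W x T array of non-negative intensities
#'   (arbitrary units), T >= 2.
#' @param meta An \code{\link{acquisition_meta}} object.
#' @param valid_mask Optional logical H x W matrix; defaults to all TRUE.
#'
#' @return An object of class \code{"image_sequence"} with elements
#'   \code{frames}, \code{meta}, \code{valid_mask}.
#' @export
image_sequence <- function(frames, meta, valid_mask = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  if (d[3] < 2L) stop("an image sequence needs at least 2 frames, got ", d[3])
  if (any(frames < 0, na.rm = TRUE))
    stop("frame intensities must be non-negative")
  stopifnot(inherits(meta, "acquisition_meta"))
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, d[1], d[2])
  } else {
    stopifnot(is.logical(valid_mask), identical(dim(valid_mask), d[1:2]))
  }
  structure(list(frames = frames, meta = meta, valid_mask = valid_mask),
            class = "image_sequence")
}

#' Frame timestamps of a sequence
#'
#' @param seq An \code{image_sequence}.
#' @return Numeric vector of length T: \code{(0:(T-1)) / frame_rate_hz},
#'   seconds from infusion start.
#' @export
frame_times <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  (seq_len(dim(seq$frames)[3]) - 1) / seq$meta$frame_rate_hz
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image sequence: %d x %d px, %d frames @ %g Hz (%.2f s)\n",
              d[1], d[2], d[3], x$meta$frame_rate_hz,
              d[3] / x$meta$frame_rate_hz))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid_mask), d[1] * d[2]))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.image_sequence <- function(x) dim(x$frames)

# translate a matrix by (dy, dx): out[i + dy, j + dx] = m[i, j].
# Uncovered cells get `fill`. Integer shifts only.
translate_frame <- function(m, dy, dx, fill = 0) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- max(1L, 1L - dy):min(h, h - dy)   # source rows
  sc <- max(1L, 1L - dx):min(w, w - dx)
  if (length(sr) > 0 && length(sc) > 0 && sr[1] <= sr[length(sr)] &&
      sc[1] <= sc[length(sc)])
    out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

# coverage mask of translate_frame: TRUE where out received a source pixel
translate_coverage <- function(h, w, dy, dx) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  out <- matrix(FALSE, h, w)
  rr <- max(1L, 1L + dy):min(h, h + dy)
  cc <- max(1L, 1L + dx):min(w, w + dx)
  if (rr[1] <= rr[length(rr)] && cc[1] <= cc[length(cc)])
    out[rr, cc] <- TRUE
  out
}

# bilinear translation for subpixel shifts; NA-free interior, border filled
translate_frame_subpx <- function(m, dy, dx, fill = 0) {
  if (dy == round(dy) && dx == round(dx))
    return(translate_frame(m, dy, dx, fill))
  h <- nrow(m); w <- ncol(m)
  ri <- seq_len(h) - dy
  ci <- seq_len(w) - dx
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0;  fc <- ci - c0
  out <- matrix(fill, h, w)
  okr <- r0 >= 1 & r0 + 1 <= h
  okc <- c0 >= 1 & c0 + 1 <= w
  if (!any(okr) || !any(okc)) return(out)
  R0 <- r0[okr]; C0 <- c0[okc]
  FR <- fr[okr]; FC <- fc[okc]
  a <- m[R0, C0, drop = FALSE];     b <- m[R0, C0 + 1, drop = FALSE]
  cc <- m[R0 + 1, C0, drop = FALSE]; d <- m[R0 + 1, C0 + 1, drop = FALSE]
  wfr <- matrix(FR, length(R0), length(C0))
  wfc <- matrix(FC, length(R0), length(C0), byrow = TRUE)
  out[okr, okc] <- a * (1 - wfr) * (1 - wfc) + b * (1 - wfr) * wfc +
    cc * wfr * (1 - wfc) + d * wfr * wfc
  out
}
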