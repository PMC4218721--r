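#' Read a grayscale image stack
#'
#' Reads a multi-page TIFF, or a directory of numbered single-page TIFFs
#' (as video-capture software often exports), into an
#' \code{\link{image_sequence}}.
#' Multi-channel pages are converted to grayscale by averaging channels
#' (luminance average), with a message. Integer pages are read bit-exactly;
#' 32-bit float pages are read as stored. If a metadata sidecar written by
#' \code{\link{write_stack}} sits next to \code{path} it is used to restore
#' the original intensity scale of float stacks and, when \code{meta} is
#' \code{NULL}, the acquisition metadata.
#'
#' @param path A multi-page TIFF file or a directory of numbered
#'   single-page TIFF files.
#' @param meta An \code{\link{acquisition_meta}}, or \code{NULL} to read it
#'   from the sidecar.
#' @return An \code{\link{image_sequence}} with an all-TRUE valid mask.
#' @export
read_stack <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such path: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("directory contains no TIFF pages: ", path)
    files <- files[order(files)]
    pages <- lapply(files, function(f) read_tiff_pages(f, f)[[1L]])
    names(pages) <- basename(files)
  } else {
    pages <- read_tiff_pages(path, path)
    if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
    names(pages) <- sprintf("page %d", seq_along(pages))
  }
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      message("averaging ", dim(p)[3], " channels to luminance in ",
              names(pages)[i])
      p <- apply(p, c(1, 2), mean)
    }
    p
  })
  d1 <- dim(pages[[1L]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d1))
      stop(sprintf("page %d is %dx%d but page 1 is %dx%d", i,
                   dim(pages[[i]])[1], dim(pages[[i]])[2], d1[1], d1[2]))
  }
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(d1[1], d1[2], length(pages)))
  sc <- sidecar_path(path)
  side <- if (file.exists(sc)) read_sidecar(sc) else NULL
  if (!is.null(side) && identical(side[["storage"]], "float")) {
    frames <- frames * as.numeric(side[["scale"]]) +
      as.numeric(side[["offset"]])
    frames[frames < 0 & frames > -1e-9] <- 0   # guard float round-off
  }
  if (is.null(meta)) {
    if (is.null(side))
      stop("no acquisition metadata given and no sidecar found at ", sc)
    meta <- sidecar_to_meta(side)
  }
  n_expected <- round(meta$frame_rate_hz * meta$duration_s)
  if (dim(frames)[3] != n_expected)
    message("stack has ", dim(frames)[3], " frames; metadata implies ",
            n_expected, " (frame count recorded from the stack)")
  image_sequence(frames, meta)
}

# read all pages of one TIFF, choosing raw-integer vs float decoding from
# the declared bits per sample (32 => IEEE float, stored as written)
read_tiff_pages <- function(file, label) {
  info <- tiff::readTIFF(file, payload = FALSE, all = TRUE)
  if (is.data.frame(info)) bits <- info$bits.per.sample[1L]
  else bits <- info[[1L]]$bits.per.sample
  as_is <- !identical(as.integer(bits), 32L)
  pg <- tiff::readTIFF(file, all = TRUE, as.is = as_is)
  if (!is.list(pg)) pg <- list(pg)
  lapply(pg, function(p) { storage.mode(p) <- "double"; p })
}

#' Write an image sequence as a multi-page TIFF with a metadata sidecar
#'
#' Integer-valued stacks (all values integral, within 0..65535) are stored
#' as 16-bit pages and round-trip bit-exactly through
#' \code{\link{read_stack}}. Other stacks are stored as 32-bit float pages
#' after an affine rescale to [0,1]; the offset and scale are recorded in
#' the sidecar so the read-back restores original units within float
#' tolerance. The sidecar (\code{<path minus extension>.meta.txt}) is a
#' plain-text \code{key: value} file carrying the acquisition metadata.
#'
#' @param seq An \code{\link{image_sequence}}.
#' @param path Output TIFF filename.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  fr <- seq$frames
  d <- dim(fr)
  integral <- all(fr == round(fr)) && max(fr) <= 65535 && min(fr) >= 0
  if (integral) {
    storage <- "uint16"; offset <- 0; scale <- 1
    pages <- lapply(seq_len(d[3]), function(t) fr[, , t] / 65535)
    bits <- 16L
  } else {
    storage <- "float"
    offset <- min(fr)
    scale <- max(fr) - offset
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(d[3]), function(t) (fr[, , t] - offset) / scale)
    bits <- 32L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF at ", path, ": ", attr(ok, "condition")$message)
  write_sidecar(seq, sidecar_path(path), storage, offset, scale, d[3])
  invisible(path)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "stack.meta.txt")
  else paste0(tools::file_path_sans_ext(path), ".meta.txt")
}

write_sidecar <- function(seq, file, storage, offset, scale, n_frames) {
  m <- seq$meta
  lines <- c(
    sprintf("frame_rate_hz: %.17g", m$frame_rate_hz),
    sprintf("duration_s: %.17g", m$duration_s),
    sprintf("um_per_px: %.17g", m$um_per_px),
    sprintf("t0_is_infusion_start: %s",
            if (m$t0_is_infusion_start) "true" else "false"),
    sprintf("n_frames: %d", n_frames),
    sprintf("storage: %s", storage),
    sprintf("offset: %.17g", offset),
    sprintf("scale: %.17g", scale))
  if (!is.null(m$onh_center_px))
    lines <- c(lines,
               sprintf("onh_center_row: %.17g", m$onh_center_px[1]),
               sprintf("onh_center_col: %.17g", m$onh_center_px[2]))
  writeLines(lines, file)
}

read_sidecar <- function(file) {
  txt <- readLines(file, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  kv <- regmatches(txt, regexec("^([^:]+):\\s*(.*)$", txt))
  keys <- vapply(kv, function(x) trimws(x[2]), "")
  vals <- vapply(kv, function(x) trimws(x[3]), "")
  stats::setNames(as.list(vals), keys)
}

sidecar_to_meta <- function(side) {
  onh <- NULL
  if (!is.null(side[["onh_center_row"]]))
    onh <- c(as.numeric(side[["onh_center_row"]]),
             as.numeric(side[["onh_center_col"]]))
  acquisition_meta(as.numeric(side[["frame_rate_hz"]]),
                   as.numeric(side[["duration_s"]]),
                   as.numeric(side[["um_per_px"]]),
                   onh_center_px = onh,
                   t0_is_infusion_start =
                     identical(side[["t0_is_infusion_start"]], "true"))
}

#' Read a binary mask image
#'
#' Any nonzero pixel is TRUE. PNG and TIFF are accepted; multi-channel
#' images count a pixel as set when any channel is nonzero.
#'
#' @param path Mask image file.
#' @param shape Expected \code{c(H, W)}; a mismatch is an error naming both
#'   shapes.
#' @return Logical H x W matrix.
#' @export
read_mask <- function(path, shape) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  if (!identical(dim(img), as.integer(shape)) &&
      !identical(dim(img), as.numeric(shape)) &&
      !all(dim(img) == shape))
    stop(sprintf("mask is %dx%d but expected %dx%d",
                 dim(img)[1], dim(img)[2], shape[1], shape[2]))
  m <- img != 0
  message(sum(m), " mask pixels set in ", basename(path))
  m
}

#' Write a binary mask image
#'
#' @param mask Logical matrix.
#' @param path Output file; extension picks the format (png or tif).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write a parameter map as a 32-bit float TIFF
#'
#' Values are affinely rescaled to [0,1] for storage; the offset and scale
#' go to a sidecar so \code{\link{read_map}} restores original units.
#' NA pixels are stored as the minimum and flagged in the sidecar-recorded
#' validity companion file (\code{<path>.valid.png}) when any NA exists.
#'
#' @param map Numeric matrix (NAs allowed).
#' @param path Output TIFF filename.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  ok <- is.finite(map)
  vals <- map[ok]
  offset <- if (length(vals)) min(vals) else 0
  scale <- if (length(vals)) max(vals) - offset else 1
  if (scale <= 0) scale <- 1
  m01 <- (map - offset) / scale
  m01[!ok] <- 0
  tiff::writeTIFF(m01, path, bits.per.sample = 32L, compression = "none")
  writeLines(c(sprintf("offset: %.17g", offset),
               sprintf("scale: %.17g", scale)),
             paste0(tools::file_path_sans_ext(path), ".meta.txt"))
  if (any(!ok))
    write_mask(ok, paste0(tools::file_path_sans_ext(path), ".valid.png"))
  invisible(path)
}

#' Read a parameter map written by \code{\link{write_map}}
#'
#' @param path TIFF filename.
#' @return Numeric matrix in original units, NA where the validity
#'   companion marks pixels invalid.
#' @export
read_map <- function(path) {
  img <- tiff::readTIFF(path)
  sc <- paste0(tools::file_path_sans_ext(path), ".meta.txt")
  if (file.exists(sc)) {
    side <- read_sidecar(sc)
    img <- img * as.numeric(side[["scale"]]) + as.numeric(side[["offset"]])
  }
  vp <- paste0(tools::file_path_sans_ext(path), ".valid.png")
  if (file.exists(vp)) img[!read_mask(vp, dim(img))] <- NA_real_
  img
}
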