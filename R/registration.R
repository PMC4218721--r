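#' Choose a reference frame for registration
#'
#' Registration needs a reference in which all vessels carry dye; the frame
#' with maximal total intensity over currently-valid pixels is a robust
#' proxy (in practice ~15 s into a control acquisition, when arteries,
#' veins and capillaries are all filled). Ties take the earliest frame.
#'
#' @param seq An \code{\link{image_sequence}}.
#' @return Integer frame index (1-based).
#' @export
choose_reference <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  v <- which(seq$valid_mask)
  np <- prod(dim(seq$frames)[1:2])
  totals <- vapply(seq_len(dim(seq$frames)[3]), function(t)
    sum(seq$frames[, , t][v]), 0)
  which.max(totals)
}

#' Per-frame translational shifts relative to a reference
#'
#' Container produced by \code{\link{estimate_shifts}}: a T x 2 matrix of
#' (dy, dx) pixel shifts such that frame t is (approximately) the reference
#' translated by \code{shifts[t, ]}. The reference frame's own shift is
#' (0, 0).
#'
#' @param shifts Numeric T x 2 matrix, columns dy (rows, downward positive)
#'   and dx (columns, rightward positive).
#' @param reference_index 1-based index of the reference frame.
#' @param max_shift_px Length-2 bound c(max |dy|, max |dx|) the shifts were
#'   constrained to.
#' @return An object of class \code{"shift_track"}.
#' @export
shift_track <- function(shifts, reference_index, max_shift_px) {
  stopifnot(is.matrix(shifts), ncol(shifts) == 2L, all(is.finite(shifts)))
  if (any(shifts[reference_index, ] != 0))
    stop("the reference frame must have shift (0, 0)")
  colnames(shifts) <- c("dy", "dx")
  structure(list(shifts = shifts,
                 reference_index = as.integer(reference_index),
                 max_shift_px = max_shift_px),
            class = "shift_track")
}

#' @export
print.shift_track <- function(x, ...) {
  mags <- sqrt(rowSums(x$shifts^2))
  cat(sprintf(
    "Shift track: %d frames, reference %d, |shift| max %.2f px (median %.2f)\n",
    nrow(x$shifts), x$reference_index, max(mags), stats::median(mags)))
  invisible(x)
}

#' Estimate per-frame translational shifts by cross-correlation
#'
#' Each frame is mean-centred (to remove DC bias) and circularly
#' cross-correlated with the mean-centred reference in the frequency
#' domain; the correlation argmax gives the frame's (dy, dx) translation
#' relative to the reference. Shifts are integer pixels by default; with
#' \code{subpixel = TRUE} the peak is refined by a separable three-point
#' quadratic fit. Ties at the correlation maximum are broken toward the
#' smaller shift magnitude, then lexicographically on (dy, dx). A flat
#' (zero-variance) frame gets shift (0, 0) with a warning.
#'
#' @param seq An \code{\link{image_sequence}}.
#' @param reference_index Reference frame (default
#'   \code{\link{choose_reference}}).
#' @param max_shift_px Bound on |dy|, |dx|; default \code{c(H, W) / 4}.
#' @param subpixel Logical, default FALSE.
#' @param min_variance_frac Frames whose centred variance is below this
#'   fraction of the reference frame's carry too little structure to
#'   register (e.g. pre-dye darkness) and keep shift (0, 0); default 0.02.
#' @return A \code{\link{shift_track}}.
#' @export
estimate_shifts <- function(seq, reference_index = choose_reference(seq),
                            max_shift_px = NULL, subpixel = FALSE,
                            min_variance_frac = 0.02) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]
  stopifnot(reference_index >= 1, reference_index <= nt)
  if (is.null(max_shift_px)) max_shift_px <- c(floor(h / 4), floor(w / 4))
  ref <- seq$frames[, , reference_index]
  refc <- ref - mean(ref)
  Fr <- stats::fft(refc)
  # wrapped shift value of each correlation index
  dy_of <- ((seq_len(h) - 1 + floor(h / 2)) %% h) - floor(h / 2)
  dx_of <- ((seq_len(w) - 1 + floor(w / 2)) %% w) - floor(w / 2)
  allow <- outer(abs(dy_of) <= max_shift_px[1],
                 abs(dx_of) <= max_shift_px[2], "&")
  mag2 <- outer(dy_of^2, dx_of^2, "+")
  shifts <- matrix(0, nt, 2)
  flat <- logical(nt)
  ref_var <- mean(refc^2)
  if (ref_var == 0) stop("reference frame is flat (zero variance)")
  n_weak <- 0L
  for (t in seq_len(nt)) {
    if (t == reference_index) next
    f <- seq$frames[, , t]
    fc <- f - mean(f)
    if (all(fc == 0)) { flat[t] <- TRUE; next }
    if (mean(fc^2) < min_variance_frac * ref_var) {
      n_weak <- n_weak + 1L
      next
    }
    cc <- Re(stats::fft(stats::fft(fc) * Conj(Fr), inverse = TRUE))
    cc[!allow] <- -Inf
    mx <- max(cc)
    tol <- 1e-8 * max(abs(mx), 1)
    cand <- which(cc >= mx - tol)
    if (length(cand) > 1L) {
      o <- order(mag2[cand], dy_of[(cand - 1L) %% h + 1L],
                 dx_of[(cand - 1L) %/% h + 1L])
      cand <- cand[o[1L]]
    }
    i <- (cand - 1L) %% h + 1L
    j <- (cand - 1L) %/% h + 1L
    dy <- dy_of[i]; dx <- dx_of[j]
    if (subpixel) {
      dy <- dy + quad_refine(cc[c((i - 2L) %% h + 1L, i, i %% h + 1L), j])
      dx <- dx + quad_refine(cc[i, c((j - 2L) %% w + 1L, j, j %% w + 1L)])
    }
    shifts[t, ] <- c(dy, dx)
  }
  if (any(flat))
    warning("flat (zero-variance) frame(s) ",
            paste(which(flat), collapse = ", "),
            ": shift set to (0, 0)")
  if (n_weak > 0L)
    message(n_weak,
            " low-structure frame(s) left unshifted (variance below ",
            min_variance_frac, " of reference)")
  shift_track(shifts, reference_index, max_shift_px)
}

# sub-sample peak offset from a 3-point quadratic fit; 0 when degenerate
quad_refine <- function(y3) {
  den <- y3[1] - 2 * y3[2] + y3[3]
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (y3[1] - y3[3]) / den
  if (abs(off) > 0.5) 0 else off
}

#' Align a sequence by undoing estimated shifts
#'
#' Each frame is translated by minus its estimated shift. Border pixels
#' left uncovered by the translation are set to zero and removed from the
#' sequence's \code{valid_mask} (never interpolated, so per-pixel kinetics
#' are computed on observed data only). The resulting mask is the
#' conjunction of coverage over all frames with the input mask.
#'
#' @param seq An \code{\link{image_sequence}}.
#' @param track A \code{\link{shift_track}}.
#' @return A registered \code{\link{image_sequence}}.
#' @export
apply_shifts <- function(seq, track) {
  stopifnot(inherits(seq, "image_sequence"), inherits(track, "shift_track"))
  d <- dim(seq$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]
  stopifnot(nrow(track$shifts) == nt)
  bound <- track$max_shift_px
  out <- array(0, dim = d)
  valid <- seq$valid_mask
  for (t in seq_len(nt)) {
    s <- track$shifts[t, ]
    if (any(abs(s) > bound))
      stop(sprintf("frame %d shift (%g, %g) exceeds bound (%g, %g)",
                   t, s[1], s[2], bound[1], bound[2]))
    if (all(s == 0)) {
      out[, , t] <- seq$frames[, , t]
      next
    }
    if (s[1] == round(s[1]) && s[2] == round(s[2])) {
      out[, , t] <- translate_frame(seq$frames[, , t], -s[1], -s[2])
      valid <- valid & translate_coverage(h, w, -s[1], -s[2])
    } else {
      out[, , t] <- translate_frame_subpx(seq$frames[, , t], -s[1], -s[2])
      valid <- valid & translate_coverage(h, w, -ceiling(abs(s[1])) *
                                            sign(s[1]),
                                          -ceiling(abs(s[2])) * sign(s[2]))
    }
  }
  image_sequence(out, seq$meta, valid)
}

#' Write a shift track as CSV
#'
#' @param track A \code{\link{shift_track}}.
#' @param path CSV filename (columns frame, dy_px, dx_px).
#' @return \code{path}, invisibly.
#' @export
write_shifts <- function(track, path) {
  utils::write.csv(data.frame(frame = seq_len(nrow(track$shifts)),
                              dy_px = track$shifts[, 1],
                              dx_px = track$shifts[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
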