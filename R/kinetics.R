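# core per-profile parameter extraction shared by extract_pixel/extract_maps.
# y: intensity series; times: uniform timestamps; dur: nominal duration (s);
# nb: baseline frames; nl: "last second" frames. Returns NULL for flat
# (non-perfused/blank) profiles.
kinetics_core <- function(y, times, dur, nb, nl) {
  baseline <- mean(y[seq_len(nb)])
  peak_idx <- which.max(y)
  peak <- y[peak_idx]
  rng <- peak - min(y)
  if (rng <= 0 || peak <= baseline) return(NULL)
  nt <- length(y)
  offset_amp <- mean(y[(nt - nl + 1L):nt])
  offset_pct <- 100 * (offset_amp - baseline) / (peak - baseline)
  offset_pct <- min(max(offset_pct, 0), 100)

  # half-rise: first upward crossing of the baseline-referenced 50% level
  # before the peak, linearly interpolated between frames
  lr <- baseline + 0.5 * (peak - baseline)
  if (y[1L] >= lr) {
    t_rise <- times[1L]
  } else {
    above <- which(y[seq_len(peak_idx)] >= lr)
    i <- above[1L]
    t_rise <- times[i - 1L] + (lr - y[i - 1L]) / (y[i] - y[i - 1L]) *
      (times[i] - times[i - 1L])
  }

  # half-fall: first downward crossing of offset + 0.5 (peak - offset)
  # after the peak; capped at the nominal duration when never crossed
  lf <- offset_amp + 0.5 * (peak - offset_amp)
  eps <- 1e-9 * max(peak - baseline, 1)
  capped <- FALSE
  if (peak - offset_amp <= eps || peak_idx == nt) {
    t_fall <- dur
    capped <- TRUE
  } else {
    post <- y[(peak_idx + 1L):nt]
    below <- which(post < lf)
    if (length(below) == 0L) {
      t_fall <- dur
      capped <- TRUE
    } else {
      i <- peak_idx + below[1L]
      t_fall <- times[i - 1L] + (lf - y[i - 1L]) / (y[i] - y[i - 1L]) *
        (times[i] - times[i - 1L])
    }
  }
  c(half_rise_s = t_rise, peak_time_s = times[peak_idx],
    peak_value = peak, offset_pct = offset_pct, half_fall_s = t_fall,
    capped = as.numeric(capped))
}

#' Extract kinetic parameters from one pixel's intensity profile
#'
#' Computes the baseline (mean of the first \code{baseline_window_s},
#' before dye arrival), the peak, the offset amplitude (mean of the last
#' second of recording, expressed relative to peak as a percentage), the
#' half-rise (first upward crossing of the baseline-referenced 50\% level
#' before the peak) and the half-fall (first downward crossing, after the
#' peak, of the level halfway between peak and offset amplitude). Both
#' crossings are linearly interpolated between frames and reported on the
#' common clock starting at infusion. A profile that never crosses the
#' decay level by the end of the sequence gets
#' \code{half_fall_s = duration_s} and \code{half_fall_capped = TRUE}.
#'
#' @param profile Numeric intensity series, at least two seconds long.
#' @param times Uniform timestamps in seconds (same length).
#' @param baseline_window_s Baseline window, default 1 s.
#' @param duration_s Nominal recording duration used for capping; default
#'   one frame interval past the last timestamp.
#' @return A list of class \code{"pixel_kinetics"} (\code{half_rise_s},
#'   \code{peak_time_s}, \code{peak_value}, \code{offset_pct},
#'   \code{half_fall_s}, \code{half_fall_capped}), or \code{NULL} for a
#'   flat profile (non-perfused or blank pixel).
#' @export
#' @examples
#' t <- seq(0, 30, by = 1/30)
#' p <- kinetics_params(7.6, 9.5, 11.9, 0.4, 100)
#' extract_pixel(canonical_profile(p, t), t)
extract_pixel <- function(profile, times, baseline_window_s = 1,
                          duration_s = NULL) {
  stopifnot(is.numeric(profile), is.numeric(times),
            length(profile) == length(times), length(profile) >= 3L)
  dt <- diff(times)
  if (any(abs(dt - dt[1L]) > 1e-9 * dt[1L]))
    stop("times must be uniformly spaced")
  fr <- 1 / dt[1L]
  if (length(profile) < 2 * fr)
    stop("profile must span at least two seconds (", length(profile),
         " frames at ", fr, " Hz)")
  if (is.null(duration_s)) duration_s <- times[length(times)] + dt[1L]
  nb <- max(1L, round(baseline_window_s * fr))
  nl <- max(1L, round(fr))
  k <- kinetics_core(profile, times, duration_s, nb, nl)
  if (is.null(k)) return(NULL)
  structure(list(half_rise_s = unname(k["half_rise_s"]),
                 peak_time_s = unname(k["peak_time_s"]),
                 peak_value = unname(k["peak_value"]),
                 offset_pct = unname(k["offset_pct"]),
                 half_fall_s = unname(k["half_fall_s"]),
                 half_fall_capped = k["capped"] > 0),
            class = "pixel_kinetics")
}

#' @export
print.pixel_kinetics <- function(x, ...) {
  cat(sprintf(
    "half-rise %.3f s | peak %.3f s (%.4g a.u.) | half-fall %.3f s%s | offset %.1f%%\n",
    x$half_rise_s, x$peak_time_s, x$peak_value, x$half_fall_s,
    if (x$half_fall_capped) " (capped)" else "", x$offset_pct))
  invisible(x)
}

#' Per-pixel kinetic parameter maps
#'
#' Applies the per-pixel extraction to every valid pixel of a registered,
#' filtered sequence. Flat (non-perfused/blank) pixels are removed from
#' the result's valid mask rather than zero-filled, keeping population
#' statistics honest.
#'
#' @param seq A registered and temporally filtered
#'   \code{\link{image_sequence}}.
#' @param baseline_window_s Baseline window in seconds, default 1.
#' @return An object of class \code{"kinetics_maps"}: H x W matrices
#'   \code{half_rise_s}, \code{half_fall_s}, \code{offset_pct},
#'   \code{peak_time_s}, \code{peak_value} (NA off the valid mask), the
#'   logical \code{capped} map, \code{valid_mask}, and \code{meta}.
#' @export
extract_maps <- function(seq, baseline_window_s = 1) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$frames)
  times <- frame_times(seq)
  fr <- seq$meta$frame_rate_hz
  dur <- d[3] / fr
  nb <- max(1L, round(baseline_window_s * fr))
  nl <- max(1L, round(fr))
  X <- matrix(seq$frames, d[1] * d[2], d[3])
  idx <- which(seq$valid_mask)
  maps <- list()
  for (nm in c("half_rise_s", "half_fall_s", "offset_pct", "peak_time_s",
               "peak_value"))
    maps[[nm]] <- matrix(NA_real_, d[1], d[2])
  capped <- matrix(FALSE, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  n_flat <- 0L
  for (p in idx) {
    k <- kinetics_core(X[p, ], times, dur, nb, nl)
    if (is.null(k)) { n_flat <- n_flat + 1L; next }
    valid[p] <- TRUE
    maps$half_rise_s[p] <- k["half_rise_s"]
    maps$half_fall_s[p] <- k["half_fall_s"]
    maps$offset_pct[p] <- k["offset_pct"]
    maps$peak_time_s[p] <- k["peak_time_s"]
    maps$peak_value[p] <- k["peak_value"]
    capped[p] <- k["capped"] > 0
  }
  message(sprintf("kinetics: %d valid, %d flat, %d capped pixels",
                  sum(valid), n_flat, sum(capped)))
  structure(c(maps, list(capped = capped, valid_mask = valid,
                         meta = seq$meta,
                         baseline_window_s = baseline_window_s)),
            class = "kinetics_maps")
}

#' @export
print.kinetics_maps <- function(x, ...) {
  cat(sprintf("Kinetic parameter maps: %d x %d px, %d valid (%d capped)\n",
              nrow(x$half_rise_s), ncol(x$half_rise_s), sum(x$valid_mask),
              sum(x$capped)))
  for (nm in c("half_rise_s", "half_fall_s", "offset_pct")) {
    v <- x[[nm]][x$valid_mask]
    cat(sprintf("  %-12s median %.2f [%.2f, %.2f]\n", nm,
                stats::median(v), stats::quantile(v, 0.05),
                stats::quantile(v, 0.95)))
  }
  invisible(x)
}

#' Write kinetic maps to a directory
#'
#' One 32-bit float TIFF per parameter plus a CSV of per-pixel records.
#'
#' @param maps A \code{"kinetics_maps"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_kinetics_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "kinetics_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("half_rise_s", "half_fall_s", "offset_pct", "peak_time_s",
               "peak_value"))
    write_map(maps[[nm]], file.path(dir, paste0(nm, ".tif")))
  write_mask(maps$capped, file.path(dir, "capped.png"))
  write_mask(maps$valid_mask, file.path(dir, "valid.png"))
  ij <- which(maps$valid_mask, arr.ind = TRUE)
  utils::write.csv(data.frame(row = ij[, 1], col = ij[, 2],
                              half_rise_s = maps$half_rise_s[ij],
                              half_fall_s = maps$half_fall_s[ij],
                              offset_pct = maps$offset_pct[ij],
                              peak_time_s = maps$peak_time_s[ij],
                              peak_value = maps$peak_value[ij],
                              capped = maps$capped[ij]),
                   file.path(dir, "pixels.csv"), row.names = FALSE)
  invisible(dir)
}
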