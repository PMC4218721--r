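#' Kinetic parameters of a canonical fill-and-decay profile
#'
#' Parameterizes one pixel class's fluorescence time course: time to half
#' of peak on the rise, time of the maximum, time of half decay from peak
#' toward the plateau, the plateau as a fraction of peak, and the peak
#' amplitude.
#'
#' @param t_half_rise_s Time (s) at which the rising limb crosses 50\% of
#'   peak.
#' @param t_peak_s Time (s) of the maximum; must exceed
#'   \code{t_half_rise_s}.
#' @param t_half_fall_s Time (s) at which the decay crosses halfway from
#'   peak to plateau; must exceed \code{t_peak_s}.
#' @param offset_frac Plateau level as a fraction of peak, in [0, 1].
#' @param peak_amp Peak intensity in arbitrary camera units.
#' @return An object of class \code{"kinetics_params"}.
#' @export
kinetics_params <- function(t_half_rise_s, t_peak_s, t_half_fall_s,
                            offset_frac, peak_amp) {
  stopifnot(is.finite(t_half_rise_s), is.finite(t_peak_s),
            is.finite(t_half_fall_s), is.finite(offset_frac),
            is.finite(peak_amp), peak_amp > 0)
  if (!(0 < t_half_rise_s && t_half_rise_s < t_peak_s &&
        t_peak_s < t_half_fall_s))
    stop(sprintf(
      "need 0 < t_half_rise_s (%g) < t_peak_s (%g) < t_half_fall_s (%g)",
      t_half_rise_s, t_peak_s, t_half_fall_s))
  if (offset_frac < 0 || offset_frac > 1)
    stop("offset_frac must lie in [0, 1], got ", offset_frac)
  structure(list(t_half_rise_s = t_half_rise_s, t_peak_s = t_peak_s,
                 t_half_fall_s = t_half_fall_s, offset_frac = offset_frac,
                 peak_amp = peak_amp),
            class = "kinetics_params")
}

#' Canonical dye transit profile
#'
#' The model profile is a logistic rise multiplied by an exponential decay
#' to a plateau:
#' \deqn{f(t) = A \cdot \frac{\min(r(t), r(t_p))}{r(t_p)} \cdot d(t)}
#' with \eqn{r(t) = 1/(1 + e^{-k (t - t_{hr})})} and, for \eqn{t > t_p},
#' \eqn{d(t) = \phi + (1-\phi)\, 2^{-(t - t_p)/(t_{hf} - t_p)}} (and
#' \eqn{d = 1} before the peak). Clamping the rise at its peak value and
#' renormalizing makes the curve reach exactly \code{peak_amp} at the peak,
#' stay monotone on each side, and cross the half-decay level
#' \eqn{\phi + (1-\phi)/2} exactly at \code{t_half_fall_s}; the half-rise
#' crossing sits at \code{t_half_rise_s} up to a term of order
#' \eqn{r(t_p)^{-1} - 1} (negligible for profiles whose rise saturates
#' before the peak).
#'
#' @param p A \code{\link{kinetics_params}}.
#' @param times Non-decreasing numeric vector of seconds.
#' @param rise_rate_per_s Logistic steepness k (1/s); default 2.2 gives a
#'   10--90\% rise of about 2 s, matching the fast fill seen in rodent
#'   angiography.
#' @return Numeric vector \code{f(times)}.
#' @export
#' @examples
#' p <- kinetics_params(7.6, 9.5, 11.9, 0.35, 200)
#' f <- canonical_profile(p, seq(0, 30, by = 1/30))
canonical_profile <- function(p, times, rise_rate_per_s = 2.2) {
  stopifnot(inherits(p, "kinetics_params"), is.numeric(times))
  if (is.unsorted(times)) stop("times must be non-decreasing")
  r <- stats::plogis(rise_rate_per_s * (times - p$t_half_rise_s))
  rp <- stats::plogis(rise_rate_per_s * (p$t_peak_s - p$t_half_rise_s))
  rise <- pmin(r, rp) / rp
  dec <- rep(1, length(times))
  post <- times > p$t_peak_s
  dec[post] <- p$offset_frac + (1 - p$offset_frac) *
    2^(-(times[post] - p$t_peak_s) / (p$t_half_fall_s - p$t_peak_s))
  p$peak_amp * rise * dec
}

# profile of a focal leak lesion: either keeps rising through the whole
# sequence (blood-retinal-barrier breakdown with ongoing accumulation) or
# plateaus with minimal decay (retained dye)
lesion_profile <- function(kind, times, duration_s, peak_amp) {
  if (kind == "continuous_rise") {
    # slow logistic, still climbing at the end of the sequence
    k <- 3.5 / duration_s
    thr <- 0.55 * duration_s
    peak_amp * stats::plogis(k * (times - thr)) /
      stats::plogis(k * (duration_s - thr))
  } else if (kind == "minimal_decay") {
    p <- kinetics_params(t_half_rise_s = 7.8, t_peak_s = 10,
                         t_half_fall_s = min(40, 0.66 * duration_s + 10),
                         offset_frac = 0.8, peak_amp = peak_amp)
    canonical_profile(p, times)
  } else stop("unknown lesion kind: ", kind)
}

#' Specification of a synthetic angiography phantom
#'
#' Describes everything needed to render a ground-truth video angiogram:
#' image size, acquisition metadata, per-class kinetics, vessel geometry,
#' focal lesions, frame jitter and noise.
#'
#' @param image_shape \code{c(H, W)} in pixels.
#' @param meta An \code{\link{acquisition_meta}} (must carry
#'   \code{onh_center_px}).
#' @param vessel_classes Named list with elements \code{artery},
#'   \code{vein}, \code{capillary}, each a \code{\link{kinetics_params}}.
#'   The capillary class stands for the capillary/choroid background.
#' @param vessel_geometry List of strokes, each
#'   \code{list(class =, angle_deg =, bend_deg_per_px =, width_px =)}:
#'   curved radial vessels emanating from the ONH centre.
#' @param lesions List of lesions, each \code{list(center_px = c(row, col),
#'   radius_px =, kind = "continuous_rise"|"minimal_decay", severity =)}
#'   with severity in (0, 1] blending the lesion profile over the local
#'   background.
#' @param onh_radius_px Radius of the rendered optic nerve head disc.
#' @param jitter_sd_px SD of per-frame translational jitter (>= 0).
#' @param noise_sd Additive gaussian noise SD in intensity units (>= 0).
#' @param subpixel_jitter If TRUE jitter shifts are not rounded to whole
#'   pixels (robustness testing); default FALSE matches a translation-only
#'   registration model.
#' @param seed Integer seed; rendering is a pure function of the spec.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(image_shape, meta, vessel_classes,
                         vessel_geometry = list(), lesions = list(),
                         onh_radius_px = 6, jitter_sd_px = 0, noise_sd = 0,
                         subpixel_jitter = FALSE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            inherits(meta, "acquisition_meta"),
            !is.null(meta$onh_center_px),
            jitter_sd_px >= 0, noise_sd >= 0)
  for (cl in c("artery", "vein", "capillary"))
    stopifnot(inherits(vessel_classes[[cl]], "kinetics_params"))
  for (L in lesions) {
    stopifnot(L$radius_px > 0,
              L$kind %in% c("continuous_rise", "minimal_decay"),
              L$severity > 0, L$severity <= 1)
    if (L$center_px[1] < 1 || L$center_px[1] > image_shape[1] ||
        L$center_px[2] < 1 || L$center_px[2] > image_shape[2])
      stop("lesion centre outside image bounds")
  }
  structure(list(image_shape = as.integer(image_shape), meta = meta,
                 vessel_classes = vessel_classes,
                 vessel_geometry = vessel_geometry, lesions = lesions,
                 onh_radius_px = onh_radius_px,
                 jitter_sd_px = jitter_sd_px, noise_sd = noise_sd,
                 subpixel_jitter = isTRUE(subpixel_jitter),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %dx%d px, %g s @ %g Hz\n", x$image_shape[1],
              x$image_shape[2], x$meta$duration_s, x$meta$frame_rate_hz))
  cat(sprintf("  %d vessel strokes, %d lesions, jitter sd %g px, noise sd %g\n",
              length(x$vessel_geometry), length(x$lesions),
              x$jitter_sd_px, x$noise_sd))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# rasterize curved radial strokes into a class map:
# 0 = capillary/choroid, 1 = artery, 2 = vein, 3 = ONH
rasterize_geometry <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  ctr <- spec$meta$onh_center_px
  cls <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (st in spec$vessel_geometry) {
    rmax <- sqrt(h^2 + w^2)
    s <- seq(spec$onh_radius_px * 0.5, rmax, by = 0.5)
    th <- (st$angle_deg + st$bend_deg_per_px * s) * pi / 180
    pr <- ctr[1] - s * cos(th)      # angle 0 points up (decreasing row)
    pc <- ctr[2] + s * sin(th)
    keep <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
    pr <- pr[keep]; pc <- pc[keep]
    half <- st$width_px / 2
    id <- if (st$class == "artery") 1L else 2L
    for (k in seq_along(pr)) {
      rr <- max(1L, floor(pr[k] - half)):min(h, ceiling(pr[k] + half))
      cc <- max(1L, floor(pc[k] - half)):min(w, ceiling(pc[k] + half))
      sub <- (rows[rr, cc, drop = FALSE] - pr[k])^2 +
        (cols[rr, cc, drop = FALSE] - pc[k])^2 <= half^2
      block <- cls[rr, cc, drop = FALSE]
      # arteries take precedence over veins where strokes cross
      block[sub & (block == 0L | (id == 1L & block == 2L))] <- id
      cls[rr, cc] <- block
    }
  }
  onh <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= spec$onh_radius_px^2
  cls[onh] <- 3L
  cls
}

# smooth multiplicative amplitude field for the capillary/choroid layer:
# low-resolution gaussian grid, bilinearly upsampled, mean 1
smooth_field <- function(h, w, rel_sd = 0.15, cell_px = 16) {
  gh <- max(2L, ceiling(h / cell_px) + 1L)
  gw <- max(2L, ceiling(w / cell_px) + 1L)
  g <- matrix(stats::rnorm(gh * gw, 1, rel_sd), gh, gw)
  ri <- seq(1, gh, length.out = h)
  ci <- seq(1, gw, length.out = w)
  r0 <- pmin(floor(ri), gh - 1L); c0 <- pmin(floor(ci), gw - 1L)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0, w), rep(c0, each = h))]
  b <- g[cbind(rep(r0, w), rep(c0 + 1L, each = h))]
  cc <- g[cbind(rep(r0 + 1L, w), rep(c0, each = h))]
  d <- g[cbind(rep(r0 + 1L, w), rep(c0 + 1L, each = h))]
  wr <- rep(fr, w); wc <- rep(fc, each = h)
  f <- matrix(a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
                cc * wr * (1 - wc) + d * wr * wc, h, w)
  pmax(f / mean(f), 0.05)
}

#' Render a synthetic video angiogram with full ground truth
#'
#' Every pixel's noiseless time course is the \code{\link{canonical_profile}}
#' of its vessel class (the ONH disc gets a bright capillary-like course;
#' lesion pixels blend in a \code{continuous_rise} or \code{minimal_decay}
#' leak profile). Whole-frame jitter is applied as integer translation
#' (zero-filled borders), then seeded gaussian noise is added and clipped
#' at zero. Rendering is deterministic in the spec (including its seed).
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list of class \code{"phantom"}:
#'   \describe{
#'     \item{seq}{the rendered \code{\link{image_sequence}}, whose
#'       \code{valid_mask} excludes pixels ever lost to jitter padding}
#'     \item{truth}{ground truth: \code{class_map} (0 capillary, 1 artery,
#'       2 vein, 3 ONH), per-parameter maps in \code{params}
#'       (\code{t_half_rise_s}, \code{t_peak_s}, \code{t_half_fall_s},
#'       \code{offset_frac}, \code{peak_amp}; NA where the class profile is
#'       overridden by a non-decaying lesion), \code{lesion_mask},
#'       \code{lesion_kind_map}, per-frame true \code{shifts} (T x 2,
#'       dy/dx), and \code{amp_field}}
#'   }
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  fr_hz <- spec$meta$frame_rate_hz
  nt <- round(fr_hz * spec$meta$duration_s)
  times <- (seq_len(nt) - 1) / fr_hz
  cls <- rasterize_geometry(spec)
  np <- h * w

  curves <- list(
    capillary = canonical_profile(spec$vessel_classes$capillary, times),
    artery    = canonical_profile(spec$vessel_classes$artery, times),
    vein      = canonical_profile(spec$vessel_classes$vein, times))
  # ONH: bright, capillary-shaped filling (it is masked from analysis)
  onh_curve <- curves$capillary / max(curves$capillary) *
    spec$vessel_classes$artery$peak_amp

  amp_field <- smooth_field(h, w)
  amp <- matrix(1, h, w)
  amp[cls == 0L] <- amp_field[cls == 0L]

  M <- matrix(0, np, nt)
  for (id in 0:3) {
    idx <- which(cls == id)
    if (!length(idx)) next
    curve <- switch(as.character(id), "0" = curves$capillary,
                    "1" = curves$artery, "2" = curves$vein, "3" = onh_curve)
    M[idx, ] <- amp[idx] %o% curve
  }

  # ground-truth parameter maps
  par_names <- c("t_half_rise_s", "t_peak_s", "t_half_fall_s",
                 "offset_frac", "peak_amp")
  params <- lapply(par_names, function(nm) {
    m <- matrix(NA_real_, h, w)
    for (id in 0:2) {
      kp <- switch(as.character(id), "0" = spec$vessel_classes$capillary,
                   "1" = spec$vessel_classes$artery,
                   "2" = spec$vessel_classes$vein)
      m[cls == id] <- kp[[nm]]
    }
    m
  })
  names(params) <- par_names
  params$peak_amp[cls == 0L] <- params$peak_amp[cls == 0L] *
    amp_field[cls == 0L]

  lesion_mask <- matrix(FALSE, h, w)
  lesion_kind <- matrix(NA_character_, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  les_amp <- spec$vessel_classes$artery$peak_amp
  for (L in spec$lesions) {
    disc <- (rows - L$center_px[1])^2 + (cols - L$center_px[2])^2 <=
      L$radius_px^2
    idx <- which(disc)
    lcurve <- lesion_profile(L$kind, times, spec$meta$duration_s, les_amp)
    M[idx, ] <- (1 - L$severity) * M[idx, , drop = FALSE] +
      L$severity * matrix(lcurve, length(idx), nt, byrow = TRUE)
    lesion_mask[disc] <- TRUE
    lesion_kind[disc] <- L$kind
    for (nm in par_names) params[[nm]][disc] <- NA_real_
  }

  # per-frame jitter: integer by default (translation-only motion model)
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  if (spec$jitter_sd_px > 0) {
    shifts[] <- stats::rnorm(2 * nt, 0, spec$jitter_sd_px)
    if (!spec$subpixel_jitter) shifts[] <- round(shifts)
    lim <- c(floor(h / 4), floor(w / 4))
    shifts[, 1] <- pmin(pmax(shifts[, 1], -lim[1]), lim[1])
    shifts[, 2] <- pmin(pmax(shifts[, 2], -lim[2]), lim[2])
  }

  frames <- array(0, dim = c(h, w, nt))
  valid <- matrix(TRUE, h, w)
  for (t in seq_len(nt)) {
    f <- matrix(M[, t], h, w)
    if (any(shifts[t, ] != 0)) {
      f <- if (spec$subpixel_jitter)
        translate_frame_subpx(f, shifts[t, 1], shifts[t, 2])
      else translate_frame(f, shifts[t, 1], shifts[t, 2])
      valid <- valid & translate_coverage(h, w, ceiling(abs(shifts[t, 1])) *
                                            sign(shifts[t, 1]),
                                          ceiling(abs(shifts[t, 2])) *
                                            sign(shifts[t, 2]))
    }
    frames[, , t] <- f
  }
  if (spec$noise_sd > 0)
    frames <- pmax(frames + array(stats::rnorm(length(frames), 0,
                                               spec$noise_sd),
                                  dim = dim(frames)), 0)

  seq <- image_sequence(frames, spec$meta, valid)
  structure(list(seq = seq,
                 truth = list(class_map = cls, params = params,
                              lesion_mask = lesion_mask,
                              lesion_kind_map = lesion_kind,
                              shifts = shifts, amp_field = amp_field),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic angiography phantom\n")
  print(x$spec)
  print(x$seq)
  invisible(x)
}

#' Default control-eye phantom specification
#'
#' 30 s at 30 frames/s over a 96 x 96 px posterior-pole field
#' (31 um/px, so the field spans ~3 mm). Eight curved radial vessels
#' alternate artery/vein around the ONH; vein kinetics rise ~1 s later and
#' decay ~2 s later than arteries, all classes plateau well before 25 s.
#' Per-frame jitter SD 1 px and additive noise SD 5 a.u. emulate breathing
#' motion and camera noise.
#'
#' @param seed Integer seed for the rendered realization.
#' @return A \code{\link{phantom_spec}}.
#' @export
default_control_spec <- function(seed = 1L) {
  meta <- acquisition_meta(frame_rate_hz = 30, duration_s = 30,
                           um_per_px = 31, onh_center_px = c(48, 48))
  classes <- list(
    artery    = kinetics_params(7.6, 9.5, 11.9, 0.35, 200),
    vein      = kinetics_params(8.6, 10.5, 13.9, 0.55, 200),
    capillary = kinetics_params(7.8, 9.8, 11.8, 0.40, 60))
  geom <- lapply(seq_len(8), function(i)
    list(class = if (i %% 2 == 1) "artery" else "vein",
         angle_deg = (i - 1) * 45 + 4 * ((i %% 3) - 1),
         bend_deg_per_px = 0.25 * ((-1)^i),
         width_px = if (i %% 2 == 1) 3 else 4))
  phantom_spec(image_shape = c(96, 96), meta = meta,
               vessel_classes = classes, vessel_geometry = geom,
               lesions = list(), onh_radius_px = 6,
               jitter_sd_px = 1, noise_sd = 5, seed = seed)
}

#' Default laser-injury phantom specification
#'
#' Same field and vasculature as \code{\link{default_control_spec}} but
#' recorded for 60 s (prolonged leakage capture) with four circular leak
#' lesions placed between the major vessels, one per retinal sector. Two
#' lesions keep accumulating dye through the whole sequence
#' (\code{continuous_rise}) and two retain dye with minimal decay
#' (\code{minimal_decay}).
#'
#' @param seed Integer seed for the rendered realization.
#' @return A \code{\link{phantom_spec}}.
#' @export
default_injury_spec <- function(seed = 1L) {
  ctl <- default_control_spec(seed)
  meta <- acquisition_meta(frame_rate_hz = 30, duration_s = 60,
                           um_per_px = 31, onh_center_px = c(48, 48))
  ang <- c(22.5, 112.5, 202.5, 292.5) * pi / 180
  lesions <- lapply(seq_along(ang), function(i)
    list(center_px = c(48 - 30 * cos(ang[i]), 48 + 30 * sin(ang[i])),
         radius_px = 5,
         kind = if (i %% 2 == 1) "continuous_rise" else "minimal_decay",
         severity = 0.9))
  phantom_spec(image_shape = ctl$image_shape, meta = meta,
               vessel_classes = ctl$vessel_classes,
               vessel_geometry = ctl$vessel_geometry, lesions = lesions,
               onh_radius_px = ctl$onh_radius_px,
               jitter_sd_px = ctl$jitter_sd_px, noise_sd = ctl$noise_sd,
               seed = seed)
}

#' Write a rendered phantom to disk
#'
#' Writes the stack TIFF + sidecar, vessel/ONH/lesion masks (PNG), the
#' ground-truth parameter maps (32-bit float TIFF) and the spec summary.
#'
#' @param ph A \code{"phantom"} from \code{\link{render_phantom}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(ph$seq, file.path(dir, "stack.tif"))
  cm <- ph$truth$class_map
  write_mask(cm == 1L, file.path(dir, "artery.png"))
  write_mask(cm == 2L, file.path(dir, "vein.png"))
  write_mask(cm == 3L, file.path(dir, "onh.png"))
  write_mask(ph$truth$lesion_mask, file.path(dir, "lesion.png"))
  for (nm in names(ph$truth$params))
    write_map(ph$truth$params[[nm]], file.path(dir, paste0("true_", nm,
                                                           ".tif")))
  utils::write.csv(data.frame(frame = seq_len(nrow(ph$truth$shifts)),
                              dy_px = ph$truth$shifts[, 1],
                              dx_px = ph$truth$shifts[, 2]),
                   file.path(dir, "true_shifts.csv"), row.names = FALSE)
  sp <- ph$spec
  writeLines(c(sprintf("preset_like: %s",
                       if (length(sp$lesions)) "injury" else "control"),
               sprintf("seed: %d", sp$seed),
               sprintf("jitter_sd_px: %g", sp$jitter_sd_px),
               sprintf("noise_sd: %g", sp$noise_sd),
               sprintf("n_lesions: %d", length(sp$lesions))),
             file.path(dir, "phantom_spec.txt"))
  invisible(dir)
}
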