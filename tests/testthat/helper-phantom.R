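# Compact phantom specs and small fixtures used across the suite.
# The tiny phantom keeps the default field structure (radial vessels around
# an ONH, artery/vein/capillary classes) at 48x48 px with accelerated
# kinetics so full renders stay fast; the artery-vein half-rise gap is
# 1.0 s like the default control spec.

tiny_classes <- function() {
  list(artery    = kinetics_params(3.0, 4.9, 5.90, 0.35, 200),
       vein      = kinetics_params(4.0, 5.9, 6.75, 0.55, 200),
       capillary = kinetics_params(3.2, 5.1, 6.05, 0.40, 60))
}

tiny_geometry <- function() {
  lapply(seq_len(8), function(i)
    list(class = if (i %% 2 == 1) "artery" else "vein",
         angle_deg = (i - 1) * 45 + 4 * ((i %% 3) - 1),
         bend_deg_per_px = 0.25 * ((-1)^i),
         width_px = if (i %% 2 == 1) 2 else 3))
}

tiny_spec <- function(seed = 1L, jitter_sd_px = 0, noise_sd = 0,
                      duration_s = 12, lesions = list(),
                      subpixel_jitter = FALSE) {
  meta <- acquisition_meta(frame_rate_hz = 30, duration_s = duration_s,
                           um_per_px = 31, onh_center_px = c(24, 24))
  phantom_spec(image_shape = c(48, 48), meta = meta,
               vessel_classes = tiny_classes(),
               vessel_geometry = tiny_geometry(), lesions = lesions,
               onh_radius_px = 4, jitter_sd_px = jitter_sd_px,
               noise_sd = noise_sd, subpixel_jitter = subpixel_jitter,
               seed = seed)
}

tiny_injury_lesions <- function() {
  ang <- c(22.5, 112.5, 202.5, 292.5) * pi / 180
  lapply(seq_along(ang), function(i)
    list(center_px = c(24 - 14 * cos(ang[i]), 24 + 14 * sin(ang[i])),
         radius_px = 3,
         kind = if (i %% 2 == 1) "continuous_rise" else "minimal_decay",
         severity = 0.9))
}

# translate a ground-truth map into the coordinates of the registration
# reference frame (whose true jitter shift is sref)
gt_to_ref <- function(m, sref, fill = NA) {
  angiokinetics:::translate_frame(m, sref[1], sref[2], fill = fill)
}

# circular shift of a matrix (used by the brute-force correlation oracle)
circshift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# brute-force centred circular cross-correlation argmax over integer
# shifts within +-max_shift, with the same tie-break as estimate_shifts
# (smaller magnitude first, then lexicographic dy, dx)
bf_shift <- function(frame, ref, max_shift = 4) {
  fc <- frame - mean(frame)
  rc <- ref - mean(ref)
  best <- NULL; best_cc <- NULL
  grid <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  grid <- grid[order(grid$dy^2 + grid$dx^2, grid$dy, grid$dx), ]
  for (g in seq_len(nrow(grid))) {
    cc <- sum(fc * circshift(rc, grid$dy[g], grid$dx[g]))
    if (is.null(best_cc) || cc > best_cc + 1e-8 * max(abs(best_cc), 1)) {
      best_cc <- cc
      best <- c(grid$dy[g], grid$dx[g])
    }
  }
  best
}

# stack of T copies of one frame translated by given integer shifts
shifted_stack <- function(base, shifts, fr_hz = 30) {
  nt <- nrow(shifts)
  fr <- array(0, c(nrow(base), ncol(base), nt))
  for (t in seq_len(nt))
    fr[, , t] <- angiokinetics:::translate_frame(base, shifts[t, 1],
                                                 shifts[t, 2])
  image_sequence(fr, acquisition_meta(fr_hz, nt / fr_hz, 31))
}

# a smooth textured test image (sum of gaussian blobs) that correlates
# sharply under translation
blob_image <- function(h, w, n_blobs = 6, seed = 1) {
  set.seed(seed)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- matrix(0, h, w)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, h * 0.25, h * 0.75); cx <- runif(1, w * 0.25, w * 0.75)
    s <- runif(1, 1.5, 4)
    img <- img + runif(1, 50, 150) *
      exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * s^2))
  }
  img
}

# hand-built kinetics_maps object for region-summary unit tests
fake_maps <- function(value_map, valid = NULL, capped = NULL,
                      meta = acquisition_meta(30, 30, 31)) {
  h <- nrow(value_map); w <- ncol(value_map)
  if (is.null(valid)) valid <- !is.na(value_map)
  if (is.null(capped)) capped <- matrix(FALSE, h, w)
  structure(list(half_rise_s = value_map, half_fall_s = value_map,
                 offset_pct = value_map, peak_time_s = value_map,
                 peak_value = value_map, capped = capped,
                 valid_mask = valid, meta = meta, baseline_window_s = 1),
            class = "kinetics_maps")
}
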