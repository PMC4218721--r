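test_that("canonical profile hits its construction points exactly", {
  t <- seq(0, 30, by = 1 / 30)
  p <- kinetics_params(7.6, 9.5, 11.9, 0.4, 100)
  f <- canonical_profile(p, t)
  # half-decay level crossed exactly at t_half_fall_s
  expect_equal(canonical_profile(p, 11.9), (0.4 + 0.5 * 0.6) * 100)
  # peak value is peak_amp, reached at t_peak
  expect_equal(max(f), 100, tolerance = 1e-12)
  expect_equal(canonical_profile(p, 9.5), 100)
  # monotone nondecreasing up to the peak, nonincreasing after
  pre <- f[t <= 9.5]; post <- f[t >= 9.5]
  expect_true(all(diff(pre) >= -1e-12))
  expect_true(all(diff(post) <= 1e-12))
  # starts at (essentially) zero
  expect_lt(f[1], 1e-4 * 100)
})

test_that("offset_frac = 1 gives a profile that never decays", {
  t <- seq(0, 30, by = 0.1)
  p <- kinetics_params(5, 8, 12, 1, 50)
  f <- canonical_profile(p, t)
  expect_equal(unique(f[t >= 8]), 50)
})

test_that("invalid parameter orderings are rejected", {
  expect_error(kinetics_params(5, 4, 8, 0.3, 10), "t_half_rise")
  expect_error(kinetics_params(2, 4, 3, 0.3, 10), "t_half_rise")
  expect_error(kinetics_params(2, 4, 8, 1.2, 10), "offset_frac")
  p <- kinetics_params(2, 4, 8, 0.3, 10)
  expect_error(canonical_profile(p, c(3, 2, 1)), "non-decreasing")
})

test_that("rendering is deterministic in the seed", {
  s <- tiny_spec(seed = 9, jitter_sd_px = 1, noise_sd = 4)
  a <- render_phantom(s)
  b <- render_phantom(s)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$truth$shifts, b$truth$shifts)
  c <- render_phantom(tiny_spec(seed = 10, jitter_sd_px = 1, noise_sd = 4))
  expect_false(identical(a$seq$frames, c$seq$frames))
})

test_that("noiseless jitter-free pixels equal their class canonical profile exactly", {
  ph <- render_phantom(tiny_spec(seed = 3))
  t <- frame_times(ph$seq)
  cls <- ph$truth$class_map
  classes <- tiny_classes()
  # one representative pixel per class, away from the amplitude field = 1?
  for (id in 1:2) {  # artery, vein: amplitude exactly peak_amp
    p <- which(cls == id)[10]
    ij <- arrayInd(p, dim(cls))
    curve <- canonical_profile(classes[[c("artery", "vein")[id]]], t)
    expect_equal(ph$seq$frames[ij[1], ij[2], ], curve, tolerance = 1e-12)
  }
  # capillary pixels are the class curve scaled by the smooth field
  p <- which(cls == 0L)[50]
  ij <- arrayInd(p, dim(cls))
  curve <- canonical_profile(classes$capillary, t)
  expect_equal(ph$seq$frames[ij[1], ij[2], ] /
                 ph$truth$amp_field[ij[1], ij[2]], curve, tolerance = 1e-12)
})

test_that("minimal-decay lesions retain more end-of-sequence fluorescence", {
  ph <- render_phantom(tiny_spec(seed = 4, duration_s = 20,
                                 lesions = tiny_injury_lesions()))
  nt <- dim(ph$seq$frames)[3]
  lastfrac <- function(mask) {
    px <- which(mask)
    mean(vapply(px, function(p) {
      ij <- arrayInd(p, dim(mask))
      y <- ph$seq$frames[ij[1], ij[2], ]
      y[nt] / max(y)
    }, 0))
  }
  md <- ph$truth$lesion_kind_map == "minimal_decay" & !is.na(ph$truth$lesion_kind_map)
  bg <- ph$truth$class_map == 0L & !ph$truth$lesion_mask
  expect_gt(lastfrac(md), lastfrac(bg) + 0.3)
})

test_that("default specs encode the stated acquisition conditions", {
  ctl <- default_control_spec(1)
  expect_equal(ctl$meta$duration_s, 30)
  expect_equal(ctl$meta$frame_rate_hz, 30)
  inj <- default_injury_spec(1)
  expect_equal(inj$meta$duration_s, 60)
  expect_equal(length(inj$lesions), 4)
  # vein rises ~1 s after artery, both plateau before 25 s
  expect_equal(ctl$vessel_classes$vein$t_half_rise_s -
                 ctl$vessel_classes$artery$t_half_rise_s, 1.0)
  t <- seq(25, 30, by = 0.5)
  for (cl in ctl$vessel_classes) {
    f <- canonical_profile(cl, t)
    expect_lt(max(f) - min(f), 0.02 * cl$peak_amp)
  }
})

test_that("phantom invariants: lesion bounds, jitter bookkeeping, valid mask", {
  expect_error(tiny_spec(lesions = list(list(center_px = c(100, 10),
                                             radius_px = 3,
                                             kind = "minimal_decay",
                                             severity = 1))),
               "outside")
  ph <- render_phantom(tiny_spec(seed = 5, jitter_sd_px = 2))
  sh <- ph$truth$shifts
  expect_true(all(sh == round(sh)))
  expect_equal(nrow(sh), dim(ph$seq$frames)[3])
  # valid mask excludes exactly the union of jitter paddings
  lost <- !ph$seq$valid_mask
  expect_gt(sum(lost), 0)
  expect_true(all(which(lost) %in%
                    which(!Reduce(`&`, lapply(seq_len(nrow(sh)), function(t)
                      angiokinetics:::translate_coverage(48, 48, sh[t, 1],
                                                         sh[t, 2]))))))
})

test_that("write_phantom emits a readable self-contained bundle", {
  d <- file.path(tempdir(), "phantom_out")
  on.exit(unlink(d, recursive = TRUE))
  ph <- render_phantom(tiny_spec(seed = 6, noise_sd = 2))
  suppressMessages(write_phantom(ph, d))
  back <- read_stack(file.path(d, "stack.tif"))
  expect_equal(back$frames, ph$seq$frames, tolerance = 1e-5)
  am <- suppressMessages(read_mask(file.path(d, "artery.png"), c(48, 48)))
  expect_identical(am, ph$truth$class_map == 1L)
  tr <- suppressMessages(read_map(file.path(d, "true_t_half_rise_s.tif")))
  expect_equal(tr, ph$truth$params$t_half_rise_s, tolerance = 1e-5)
})
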