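empty_masks <- function(h = 48, w = 48) {
  list(a = matrix(FALSE, h, w), v = matrix(FALSE, h, w),
       o = matrix(FALSE, h, w))
}

test_that("eccentricity boundaries are closed on the inner side", {
  m <- empty_masks(96, 96)
  meta <- acquisition_meta(30, 30, um_per_px = 32, onh_center_px = c(48, 48))
  lay <- build_layout(m$a, m$v, m$o, meta)
  # pixel 20 px right of centre: exactly 640 um -> inner
  expect_equal(as.character(lay$zone_map[48, 68]), "inner")
  expect_equal(as.character(lay$zone_map[48, 69]), "outer")
  # exactly 1280 um -> still outer, one farther -> beyond
  expect_equal(lay$distance_um[48, 88], 1280)
  expect_equal(as.character(lay$zone_map[48, 88]), "outer")
  expect_equal(as.character(lay$zone_map[48, 89]), "beyond")
})

test_that("quadrants are 90-degree sectors with a configurable superior axis", {
  m <- empty_masks()
  meta <- acquisition_meta(30, 30, 31, onh_center_px = c(24, 24))
  lay <- build_layout(m$a, m$v, m$o, meta)
  expect_equal(as.character(lay$quadrant_map[4, 24]), "superior")
  expect_equal(as.character(lay$quadrant_map[44, 24]), "inferior")
  expect_equal(as.character(lay$quadrant_map[24, 44]), "nasal")
  expect_equal(as.character(lay$quadrant_map[24, 4]), "temporal")
  # rotating the superior axis by 90 degrees relabels accordingly
  lay90 <- build_layout(m$a, m$v, m$o, meta, orientation_deg = 90)
  expect_equal(as.character(lay90$quadrant_map[24, 44]), "superior")
  # quadrants partition the field
  expect_false(any(is.na(lay$quadrant_map)))
})

test_that("inner-zone pixel count matches the analytic circle area within 2%", {
  m <- empty_masks(128, 128)
  meta <- acquisition_meta(30, 30, um_per_px = 16,
                           onh_center_px = c(64.5, 64.5))
  lay <- build_layout(m$a, m$v, m$o, meta)
  r_px <- 640 / 16
  n_inner <- sum(lay$zone_map == "inner")
  expect_lt(abs(n_inner - pi * r_px^2) / (pi * r_px^2), 0.02)
})

test_that("mask precedence is ONH > artery > vein and classes are disjoint", {
  h <- 10; w <- 10
  a <- matrix(FALSE, h, w); v <- matrix(FALSE, h, w); o <- matrix(FALSE, h, w)
  a[3:5, 3] <- TRUE
  v[4:6, 3] <- TRUE          # overlaps artery at (4:5, 3)
  o[5, 3] <- TRUE            # overlaps both
  meta <- acquisition_meta(30, 30, 31, onh_center_px = c(5, 5))
  expect_message(lay <- build_layout(a, v, o, meta), "overlap")
  expect_false(any(lay$artery_mask & lay$vein_mask))
  expect_false(any(lay$artery_mask & lay$onh_mask))
  expect_true(lay$artery_mask[4, 3])   # artery beats vein
  expect_false(lay$artery_mask[5, 3])  # ONH beats artery
  expect_true(all((lay$artery_mask | lay$vein_mask | lay$onh_mask |
                     lay$capillary_mask)))
  expect_error(build_layout(a, v, o, meta, onh_center_px = c(50, 5)),
               "outside")
})

test_that("summaries report every cell with honest n, mean, SEM", {
  vals <- matrix(NA_real_, 6, 6)
  vals[1, 1] <- 4; vals[1, 2] <- 6   # two superior-inner capillary pixels
  vals[6, 6] <- 10                   # one lone pixel elsewhere
  maps <- fake_maps(vals, meta = acquisition_meta(30, 30, 100))
  m <- empty_masks(6, 6)
  meta <- acquisition_meta(30, 30, um_per_px = 100, onh_center_px = c(3, 3))
  lay <- build_layout(m$a, m$v, m$o, meta)
  expect_warning(s <- summarize_regions(maps, lay), "single-pixel")
  expect_equal(nrow(s), 3 * 4 * 3 * 5)  # class x quadrant x zone x parameter
  cell <- s[s$vessel_class == "capillary" & s$quadrant == "superior" &
              s$zone == "inner" & s$parameter == "half_rise_s", ]
  expect_equal(cell$n, 2)
  expect_equal(cell$mean, 5)
  expect_equal(cell$sem, stats::sd(c(4, 6)) / sqrt(2))
  # the lone pixel: SEM 0 by convention
  lone <- s[s$n == 1 & s$parameter == "half_rise_s", ]
  expect_equal(lone$sem, 0)
  # empty cells present with n = 0
  expect_true(any(s$n == 0))
  # pixel counts sum to the classified total
  expect_equal(sum(s$n[s$parameter == "half_rise_s"]), 3)
})

test_that("uniform maps give equal cell means and zero SEM", {
  vals <- matrix(7, 8, 8)
  maps <- fake_maps(vals, meta = acquisition_meta(30, 30, 50))
  m <- empty_masks(8, 8)
  meta <- acquisition_meta(30, 30, 50, onh_center_px = c(4, 4))
  lay <- build_layout(m$a, m$v, m$o, meta)
  s <- suppressWarnings(summarize_regions(maps, lay))
  filled <- s[s$n > 1, ]
  expect_true(all(filled$mean == 7))
  expect_true(all(filled$sem == 0))
})

test_that("vein half-rise lags artery by the constructed ~1 s on a phantom", {
  ph <- render_phantom(tiny_spec(seed = 41, noise_sd = 3))
  reg <- ph$seq  # no jitter rendered
  model <- fit_pca(reg)
  maps <- suppressMessages(extract_maps(reconstruct(reg, model, 2)))
  cls <- ph$truth$class_map
  lay <- build_layout(cls == 1L, cls == 2L, cls == 3L, ph$seq$meta)
  s <- suppressWarnings(summarize_regions(maps, lay))
  hr <- s[s$parameter == "half_rise_s" & s$n > 0, ]
  cls_mean <- function(cl) {
    r <- hr[hr$vessel_class == cl, ]
    sum(r$mean * r$n) / sum(r$n)
  }
  expect_equal(cls_mean("vein") - cls_mean("artery"), 1.0, tolerance = 0.15)
  # capped fraction is reported for half-fall rows only
  expect_true(all(is.na(s$capped_fraction[s$parameter == "half_rise_s"])))
  hf <- s[s$parameter == "half_fall_s" & s$n > 0, ]
  expect_true(all(hf$capped_fraction >= 0 & hf$capped_fraction <= 1))
})

test_that("finer annuli are supported for eccentricity binning", {
  m <- empty_masks()
  meta <- acquisition_meta(30, 30, 31, onh_center_px = c(24, 24))
  lay <- build_layout(m$a, m$v, m$o, meta,
                      zone_radii_um = seq(200, 1400, by = 200))
  expect_equal(levels(lay$zone_map[1, 1]),
               c(paste0("z", 1:7), "beyond"))
  # annuli partition pixels inside the outermost radius
  inside <- lay$distance_um <= 1400
  expect_false(any(lay$zone_map[inside] == "beyond"))
})
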