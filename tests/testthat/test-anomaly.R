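test_that("z-scores follow the definition and the level map its thresholds", {
  set.seed(50)
  m <- matrix(rnorm(400, 10, 2), 20, 20)
  inc <- matrix(TRUE, 20, 20)
  am <- zscore_map(m, inc)
  mu <- mean(m); sg <- stats::sd(m)
  m[1, 1] <- mu
  m[1, 2] <- mu + 2 * sg
  # recompute with pinned values excluded from the null for exactness
  inc2 <- inc; inc2[1, 1:2] <- FALSE
  am <- zscore_map(m, inc2)
  expect_equal(am$z_map[1, 1], (mu - am$mu) / am$sigma)
  expect_equal(am$level_map[1, 2],
               findInterval((m[1, 2] - am$mu) / am$sigma, 1:4))
  # normalization over the included pixels
  expect_equal(mean(am$z_map[am$included_mask]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(am$z_map[am$included_mask]), 1, tolerance = 1e-12)
  # level 0 wherever z < 1, NA propagates
  expect_true(all(am$level_map[am$z_map < 1] == 0, na.rm = TRUE))
  m[3, 3] <- NA
  am2 <- zscore_map(m, inc2 & !is.na(m))
  expect_true(is.na(am2$level_map[3, 3]))
})

test_that("exact z landmarks: x = mu gives level 0, x = mu + 2 sigma gives level 2", {
  # null values sum to zero exactly, so mu = 0 and z arithmetic is exact
  m <- matrix(c(-2, -1, 1, 2, 0, 0, 0, 0, 0, 99), 2, 5)
  inc <- matrix(TRUE, 2, 5); inc[2, 5] <- FALSE   # exclude the probe pixel
  am <- zscore_map(m, inc)
  expect_equal(am$mu, 0)
  expect_equal(am$z_map[1, 3], 0)        # a pixel exactly at mu
  expect_equal(am$level_map[1, 3], 0L)
  m2 <- m; m2[2, 5] <- am$mu + 2 * am$sigma
  am2 <- zscore_map(m2, inc)
  expect_equal(am2$z_map[2, 5], 2)
  expect_equal(am2$level_map[2, 5], 2L)
})

test_that("z maps are invariant under positive affine rescaling of the parameter", {
  set.seed(51)
  m <- matrix(rexp(144, 0.1), 12, 12)
  inc <- matrix(TRUE, 12, 12)
  a1 <- zscore_map(m, inc)
  a2 <- zscore_map(2.5 * m + 7, inc)
  expect_equal(a2$z_map, a1$z_map, tolerance = 1e-10)
  expect_identical(a2$level_map, a1$level_map)
})

test_that("degenerate fields and empty masks are refused", {
  m <- matrix(5, 6, 6)
  expect_error(zscore_map(m, matrix(TRUE, 6, 6)), "degenerate")
  expect_error(zscore_map(m, matrix(FALSE, 6, 6)), "at least 2")
})

test_that("two-tailed mode flags both tails symmetrically", {
  set.seed(52)
  m <- matrix(rnorm(1e4), 100, 100)
  inc <- matrix(TRUE, 100, 100)
  pos <- zscore_map(m, inc)
  two <- zscore_map(m, inc, two_tailed = TRUE)
  expect_true(all(two$level_map >= pos$level_map))
  expect_equal(sum(two$level_map >= 2),
               sum(abs(pos$z_map) >= 2))
})

test_that("on pure gaussian noise the z >= 2 fraction matches the normal tail", {
  set.seed(53)
  m <- matrix(rnorm(200 * 200, 12, 0.4), 200, 200)
  am <- zscore_map(m, matrix(TRUE, 200, 200))
  frac <- mean(am$z_map >= 2)
  p <- stats::pnorm(2, lower.tail = FALSE)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / length(m)))
})

test_that("abnormal-area indices: empty maps, known blobs, monotonicity", {
  meta <- acquisition_meta(30, 30, um_per_px = 10)
  # all-background map -> zero everywhere
  set.seed(54)
  m <- matrix(rnorm(400, 0, 1e-3), 20, 20)
  am <- zscore_map(m, matrix(TRUE, 20, 20))
  am$z_map[] <- 0; am$level_map[] <- 0L
  idx <- abnormality_indices(am, meta)
  expect_equal(idx$n_pixels, rep(0L, 4))
  expect_equal(idx$n_components, rep(0L, 4))
  # a single 10-px blob at level 3
  z <- matrix(0, 20, 20)
  z[5:9, 5:6] <- 3.5
  am$z_map <- z
  am$level_map[] <- findInterval(z, 1:4)
  idx <- abnormality_indices(am, meta)
  expect_equal(idx$n_pixels[1:3], rep(10L, 3))
  expect_equal(idx$n_components[1:3], rep(1L, 3))
  expect_equal(idx$area_um2[1], 10 * 100)
  expect_equal(idx$largest_component_um2[3], 1000)
  expect_equal(idx$n_pixels[4], 0L)
  # counts never increase with the threshold
  set.seed(55)
  zr <- matrix(rnorm(2500, 1, 1), 50, 50)
  am$z_map <- zr
  am$level_map <- matrix(findInterval(zr, 1:4), 50, 50)
  idx <- abnormality_indices(am, meta)
  expect_true(all(diff(idx$n_pixels) <= 0))
  expect_true(all(diff(idx$area_um2) <= 0))
})

test_that("8-connectivity labelling agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    set.seed(60 + s)
    mask <- matrix(runif(20 * 20) < 0.4, 20, 20)
    lab <- connected_components(mask)
    expect_identical(lab > 0L, mask)
    # oracle: graph over mask pixels, edges between 8-neighbours
    idx <- which(mask)
    coord <- arrayInd(idx, dim(mask))
    edges <- c()
    for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
      if (max(abs(coord[a, ] - coord[b, ])) <= 1)
        edges <- c(edges, a, b)
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    comp <- igraph::components(g)
    expect_equal(max(lab), comp$no)
    # identical partitions up to label naming
    expect_equal(length(unique(paste(lab[idx], comp$membership))),
                 comp$no)
  }
  # diagonal touching joins components
  diagm <- matrix(FALSE, 3, 3)
  diagm[1, 1] <- diagm[2, 2] <- diagm[3, 3] <- TRUE
  expect_equal(max(connected_components(diagm)), 1L)
})

test_that("injury phantom: lesion cores light up, background stays quiet", {
  ph <- render_phantom(tiny_spec(seed = 61, duration_s = 20, noise_sd = 5,
                                 lesions = tiny_injury_lesions()))
  maps <- suppressMessages(extract_maps(moving_median3(ph$seq)))
  cls <- ph$truth$class_map
  lesion <- ph$truth$lesion_mask
  cr <- ph$truth$lesion_kind_map == "continuous_rise" &
    !is.na(ph$truth$lesion_kind_map)
  cap <- maps$valid_mask & cls == 0L
  # half-fall map flags continuous accumulation
  amh <- zscore_map(ifelse(cap, maps$half_fall_s, NA),
                    cap & !maps$capped, parameter = "half_fall")
  expect_gte(mean(amh$level_map[cr & cap] >= 2, na.rm = TRUE), 0.9)
  # offset map flags all retention; background z>=2 matches the normal
  # tail when the null excludes the lesions themselves
  amo <- zscore_map(ifelse(cap, maps$offset_pct, NA), cap & !lesion,
                    parameter = "offset")
  expect_gte(mean(amo$level_map[lesion & cap] >= 2, na.rm = TRUE), 0.9)
  bgfrac <- mean(amo$z_map[cap & !lesion] >= 2, na.rm = TRUE)
  expect_lt(bgfrac, 0.05)
  # the four lesions come back as connected components
  idx <- abnormality_indices(amo, ph$seq$meta)
  expect_gte(idx$n_components[idx$threshold_sd == 2], 4)
})
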