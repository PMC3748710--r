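test_that("lane_profile validates its invariants", {
  expect_error(lane_profile(c(1, 2, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(lane_profile(1:3, c(0, NA, 0)), "finite")
  expect_error(lane_profile(1:3, 1:2), "equal length")
  expect_error(lane_profile(1:3, 1:3, calibration = c(intercept = 1, slope = 1)),
               "slope")
})

test_that("background subtraction removes baselines and is idempotent", {
  # pure constant baseline -> all zero
  flat <- lane_profile(0:999, rep(7, 1000))
  expect_true(all(subtract_background(flat, window = 100)$intensity == 0))

  # Gaussian peak + constant, window >> peak width -> height within 2%
  prof <- gaussian_profile(500, 40, sigma = 8, baseline = 12,
                           background_subtracted = FALSE)
  sub <- subtract_background(prof, window = 200)
  expect_rel_equal(max(sub$intensity), 40, 0.02)
  expect_true(sub$background_subtracted)

  # idempotence: re-applying changes nothing (morphological opening)
  sub2 <- subtract_background(sub, window = 200)
  expect_equal(sub2$intensity, sub$intensity, tolerance = 1e-9)

  # linear_anchors removes a linear drift
  x <- 0:999
  drift <- lane_profile(x, 5 + 0.01 * x +
                          40 * exp(-(x - 500)^2 / (2 * 64)))
  la <- subtract_background(drift, "linear_anchors", window = 50)
  expect_rel_equal(max(la$intensity), 40, 0.05)

  expect_error(subtract_background(flat, window = 5000), "window exceeds")
})

test_that("locate_bands finds apexes, flags degenerate ramps, errors on empty windows", {
  # two triangular peaks
  x <- 0:999
  tri <- function(c0, h, w) pmax(0, h * (1 - abs(x - c0) / w))
  prof <- lane_profile(x, tri(600, 10, 40) + tri(450, 8, 40),
                       background_subtracted = TRUE)
  w <- band_windows(di = c(550, 650), tri = c(400, 500))
  b <- locate_bands(prof, w)
  expect_equal(b$p2$position, 600)
  expect_equal(b$p2$height, 10)
  expect_equal(b$p3$position, 450)
  expect_equal(b$p3$height, 8)
  expect_true(b$p2_local && b$p3_local)
  expect_true(b$v$position > 450 && b$v$position < 600)

  # monotone ramp: maxima at window edges, flagged non-local
  ramp <- lane_profile(x, x / 100, background_subtracted = TRUE)
  br <- locate_bands(ramp, w)
  expect_equal(br$p2$position, 650)
  expect_equal(br$p3$position, 500)
  expect_false(br$p2_local)

  expect_error(locate_bands(prof, band_windows(di = c(2000, 2100),
                                               tri = c(400, 500))),
               "band not found")
})

test_that("spacing index implements 0.5*(P2+P3) - V with its invariances", {
  w <- band_windows(di = c(550, 650), tri = c(400, 500))
  prof <- gaussian_profile(c(600, 450), c(10, 8), sigma = 15)
  r <- compute_spacing_index(prof, w)
  expect_equal(r$index, 0.5 * (r$P2 + r$P3) - r$V)
  expect_true(r$v_pos > r$p3_pos && r$v_pos < r$p2_pos)
  expect_true(r$P2 >= r$V && r$P3 >= r$V)

  # constructed P2 = 10, P3 = 8, V = 4: narrow peaks on a 4-high plateau
  x <- 0:999
  plateau <- lane_profile(x, 4 + 6 * exp(-(x - 600)^2 / 50) +
                            4 * exp(-(x - 450)^2 / 50),
                          background_subtracted = TRUE)
  rp <- compute_spacing_index(plateau, w)
  expect_equal(rp$P2, 10, tolerance = 1e-6)
  expect_equal(rp$P3, 8, tolerance = 1e-6)
  expect_equal(rp$V, 4, tolerance = 1e-6)
  expect_equal(rp$index, 5, tolerance = 1e-6)

  # flat profile: index 0
  flat <- lane_profile(x, rep(3, 1000), background_subtracted = TRUE)
  expect_equal(compute_spacing_index(flat, w)$index, 0)

  # additive shift invariance and positive-scale equivariance
  set.seed(21)
  for (i in 1:20) {
    y <- stats::runif(1000, 0, 5)
    p0 <- lane_profile(x, y, background_subtracted = TRUE)
    i0 <- compute_spacing_index(p0, w)
    pc <- lane_profile(x, 3.7 * y + 11, background_subtracted = TRUE)
    ic <- compute_spacing_index(pc, w)
    expect_equal(ic$index, 3.7 * i0$index, tolerance = 1e-9)
  }
})

test_that("detected band positions match generator ground truth", {
  # trimmed di/tri fragments from a 200-bp repeat are 347 and 547 bp
  g <- gel_model()
  for (s in 1:5) {
    lane <- simulate_mnase_lane("spaced", jitter_sd = 2, seed = s)
    r <- compute_spacing_index(subtract_background(lane, window = 300))
    expect_lt(abs(r$p2_pos - migration_of_length(g, 347)), 2.5)
    expect_lt(abs(r$p3_pos - migration_of_length(g, 547)), 2.5)
  }
})

test_that("spacing index separates spaced from random and degrades with jitter", {
  gaps <- vapply(c(0, 40, 80), function(j) {
    d <- vapply(1:8, function(s) {
      p <- spacing_index_pair(seed = 100 + s, jitter_sd = j)
      p[["spaced"]] - p[["random"]]
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_gt(gaps[1], 0)
})

test_that("lane extraction from images averages columns", {
  base <- gaussian_profile(300, 50, sigma = 20, n = 600)
  img <- matrix(rep(base$intensity, 10), ncol = 10)
  prof <- extract_lane_profiles(img, list(c(1, 10)))[[1]]
  expect_equal(prof$intensity, base$intensity)

  # noise averaging: extracted noise sd ~ sigma / sqrt(lane width)
  set.seed(5)
  sigma <- 4; wdt <- 25
  imgn <- matrix(stats::rnorm(600 * wdt, 0, sigma), ncol = wdt)
  profn <- extract_lane_profiles(imgn, list(c(1, wdt)))[[1]]
  expect_rel_equal(stats::sd(profn$intensity), sigma / sqrt(wdt), 0.2)

  expect_error(extract_lane_profiles(img, list(c(5, 11))), "outside")
  expect_error(extract_lane_profiles(img, list(c(1, 5), c(4, 8))), "overlap")
  expect_error(extract_lane_profiles(img, list()), "non-empty")
})
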