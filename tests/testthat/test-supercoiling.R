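sc_windows <- list(nicked = c(100, 200), relaxed = c(300, 400), sc = c(600, 700))

test_that("percent supercoiling follows the nicked-in-total convention", {
  # constant blocks of known integral: value * width
  # trapezoid of a sampled 50-px step of height v is 51*v (two half-height
  # edge segments); the common factor cancels in the percentage
  prof <- block_profile(list(c(610, 660, 1), c(310, 360, 0.6), c(110, 160, 0.4)))
  r <- quantify_supercoiling(prof, sc_windows)
  expect_equal(r$sc_intensity, 51, tolerance = 1e-9)
  expect_equal(r$relaxed_intensity, 30.6, tolerance = 1e-9)
  expect_equal(r$nicked_intensity, 20.4, tolerance = 1e-9)
  expect_equal(r$percent_supercoiling, 50, tolerance = 1e-9)

  # no supercoiled signal -> 0%
  prof0 <- block_profile(list(c(310, 360, 0.6), c(110, 160, 0.4)))
  expect_equal(quantify_supercoiling(prof0, sc_windows)$percent_supercoiling, 0)

  # growing only the nicked band strictly decreases the percentage
  pct <- vapply(c(0.2, 0.5, 1, 2), function(nk) {
    p <- block_profile(list(c(610, 660, 1), c(310, 360, 0.6), c(110, 160, nk)))
    quantify_supercoiling(p, sc_windows)$percent_supercoiling
  }, numeric(1))
  expect_true(all(diff(pct) < 0))

  # scale invariance
  p1 <- block_profile(list(c(610, 660, 1), c(310, 360, 0.6), c(110, 160, 0.4)))
  p2 <- lane_profile(p1$position, 5 * p1$intensity, background_subtracted = TRUE)
  expect_equal(quantify_supercoiling(p2, sc_windows)$percent_supercoiling,
               quantify_supercoiling(p1, sc_windows)$percent_supercoiling,
               tolerance = 1e-12)
})

test_that("window and signal errors are explicit", {
  prof <- block_profile(list(c(610, 660, 1)))
  expect_error(quantify_supercoiling(prof,
                 list(nicked = c(100, 350), relaxed = c(300, 400),
                      sc = c(600, 700))), "overlap")
  empty <- block_profile(list(c(850, 900, 1)))  # outside every window
  expect_error(quantify_supercoiling(empty, sc_windows), "zero total signal")
})

test_that("delta supercoiling compares like with like", {
  a <- quantify_supercoiling(
    block_profile(list(c(610, 660, 1.3), c(310, 360, 0.7))), sc_windows)
  b <- quantify_supercoiling(
    block_profile(list(c(610, 660, 0.1), c(310, 360, 1.9))), sc_windows)
  expect_equal(delta_supercoiling(a, a)$delta_percent, 0)
  d <- delta_supercoiling(a, b)
  expect_equal(d$delta_percent, a$percent_supercoiling - b$percent_supercoiling)
  expect_equal(delta_supercoiling(b, a)$delta_percent, -d$delta_percent)

  other <- quantify_supercoiling(
    block_profile(list(c(610, 660, 1))),
    list(nicked = c(100, 200), relaxed = c(300, 400), sc = c(590, 700)))
  expect_error(delta_supercoiling(a, other), "comparability")
})

test_that("quantification recovers generator ground truth", {
  lane <- simulate_supercoiling_lane(0.6, nick_fraction = 0.2, seed = 31)
  truth <- attr(lane, "truth")$percent_supercoiling
  r <- quantify_supercoiling(subtract_background(lane, window = 200))
  expect_lt(abs(r$percent_supercoiling - truth), 2)

  # ATP lane vs matched AMP-PNP lane: delta ~ 100 * 0.7 * (1 - nick)
  atp <- quantify_supercoiling(subtract_background(
    simulate_supercoiling_lane(0.7, nick_fraction = 0.1, seed = 32),
    window = 200))
  pnp <- quantify_supercoiling(subtract_background(
    simulate_supercoiling_lane(0, nick_fraction = 0.1, seed = 33),
    window = 200))
  d <- delta_supercoiling(atp, pnp)
  expect_lt(abs(d$delta_percent - 100 * 0.7 * 0.9), 4)
})
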