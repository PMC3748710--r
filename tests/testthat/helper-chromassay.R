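# Shared fixture builders. Everything is generated in code; no data files.

# Profile with Gaussian peaks of given centers/heights/sigmas on a constant
# baseline (heights are peak heights, not areas).
gaussian_profile <- function(centers, heights, sigma = 8, baseline = 0,
                             n = 1000, lane_id = "fixture",
                             background_subtracted = baseline == 0) {
  x <- seq_len(n) - 1
  y <- rep(baseline, n)
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  lane_profile(x, y, lane_id = lane_id,
               background_subtracted = background_subtracted)
}

# Piecewise-constant profile: `blocks` is a list of c(lo, hi, value).
block_profile <- function(blocks, n = 1000, lane_id = "blocks") {
  x <- seq_len(n) - 1
  y <- rep(0, n)
  for (b in blocks) y[x >= b[1] & x <= b[2]] <- b[3]
  lane_profile(x, y, lane_id = lane_id, background_subtracted = TRUE)
}

# Default di/tri windows for the default gel model and 200-bp repeat:
# trimmed di/tri fragments are 347 and 547 bp.
default_mnase_windows <- function() {
  g <- gel_model()
  band_windows(calibration = c(intercept = g$intercept, slope = g$slope))
}

# One spaced-vs-random spacing-index pair at a given seed.
spacing_index_pair <- function(seed, jitter_sd = 5, n_molecules = 60) {
  idx <- function(kind) {
    lane <- simulate_mnase_lane(kind, n_molecules = n_molecules,
                                jitter_sd = jitter_sd, seed = seed)
    compute_spacing_index(subtract_background(lane, window = 300))$index
  }
  c(spaced = idx("spaced"), random = idx("random"))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol * abs(expected),
              label = sprintf("%.8g vs %.8g (rel tol %g)", object, expected, tol))
}
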