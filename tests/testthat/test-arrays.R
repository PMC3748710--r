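test_that("random array generation handles edge cases and enforces packing", {
  a <- generate_random_array(3000, 0, 147, seed = 1)
  expect_length(a$dyads, 0)

  # saturated circle: the only packing is two dyads exactly 147 bp apart
  for (s in c(1, 2, 42)) {
    a <- generate_random_array(294, 2, 147, circular = TRUE, seed = s)
    gaps <- diff(a$dyads)
    expect_equal(min(gaps, 294 - gaps), 147)
  }

  expect_error(generate_random_array(1000, 10, 147), "packing failure")
  expect_error(nucleosome_array(3000, c(100, 200), 147), "exclusion")
  expect_error(nucleosome_array(3000, c(-5), 147), "dyad positions")
})

test_that("footprint exclusion holds for every generated array", {
  for (s in 1:25) {
    a <- generate_random_array(3000, 10, 147, seed = s)
    expect_length(a$dyads, 10)
    gaps <- diff(a$dyads)
    gaps <- c(gaps, 3000 - a$dyads[10] + a$dyads[1])
    expect_true(all(gaps >= 147))

    b <- generate_spaced_array(3000, 200, jitter_sd = 40, seed = s)
    gb <- diff(b$dyads)
    gb <- c(gb, 3000 - max(b$dyads) + min(b$dyads))
    expect_true(all(gb >= 147 - 1e-9))

    l <- generate_random_array(3000, 10, 147, circular = FALSE, seed = s)
    expect_true(all(diff(l$dyads) >= 147))
    expect_true(all(l$dyads >= 0 & l$dyads < 3000))
  }
})

test_that("spaced arrays are periodic with bounded jitter", {
  a <- generate_spaced_array(3000, 200, jitter_sd = 0, seed = 3)
  expect_length(a$dyads, 15)
  expect_equal(unique(round(diff(a$dyads), 9)), 200)

  b <- generate_spaced_array(3000, 200, jitter_sd = 10, seed = 3)
  expect_length(b$dyads, 15)
  expect_lt(abs(mean(diff(b$dyads)) - 200), 3)

  expect_error(generate_spaced_array(3000, 147, 0, 147, seed = 1),
               "repeat_length must exceed")
})

test_that("random arrays match the brute-force rejection oracle (KS)", {
  # Oracle: resample whole configurations of iid uniform integer dyads until
  # the hard-core constraint holds -- an exact (if slow) sampler of the
  # uniform hard-core measure. The implementation uses an independent
  # constructive gap-decomposition sampler.
  L <- 3000L; n <- 10L; f <- 147L; n_arrays <- 400L
  nn_dist <- function(dyads) {
    d <- sort(dyads)
    gaps <- c(diff(d), L - d[n] + d[1])
    pmin(gaps, c(gaps[n], gaps[-n]))  # per-dyad nearest neighbour
  }
  set.seed(7)
  oracle <- list(); got <- 0L
  while (got < n_arrays) {
    d <- sample.int(L, n, replace = TRUE) - 1L
    g <- sort(d); gaps <- c(diff(g), L - g[n] + g[1])
    if (length(unique(g)) == n && all(gaps >= f)) {
      got <- got + 1L
      oracle[[got]] <- nn_dist(d)
    }
  }
  oracle <- unlist(oracle)
  impl <- unlist(lapply(seq_len(n_arrays), function(s)
    nn_dist(generate_random_array(L, n, f, seed = 7000 + s)$dyads)))
  # smooth identical integer ties so the KS statistic is well behaved
  set.seed(99)
  p <- suppressWarnings(
    stats::ks.test(impl + stats::runif(length(impl)),
                   oracle + stats::runif(length(oracle)))$p.value)
  expect_gt(p, 0.01)
})

test_that("array generation is deterministic per seed", {
  expect_identical(generate_random_array(3000, 10, seed = 5)$dyads,
                   generate_random_array(3000, 10, seed = 5)$dyads)
  expect_identical(generate_spaced_array(3000, 200, 10, seed = 5)$dyads,
                   generate_spaced_array(3000, 200, 10, seed = 5)$dyads)
})
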