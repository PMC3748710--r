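test_that("time_course validates input", {
  expect_error(time_course(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(time_course(c(-1, 0), c(1, 2)), "nonnegative")
  expect_error(time_course(c(0, 1), c(1, Inf)), "finite")
})

test_that("initial_rate is the early OLS slope per nM", {
  tc <- time_course(0:5, 2 * (0:5), protein_nM = 30)
  # zero-residual regressions make summary.lm grumble; that is expected here
  r <- suppressWarnings(initial_rate(tc, n_points = 4))
  expect_equal(r$rate, 2 / 30, tolerance = 1e-12)
  expect_equal(r$se, 0, tolerance = 1e-9)

  flat <- time_course(0:5, rep(3, 6), protein_nM = 30)
  expect_equal(suppressWarnings(initial_rate(flat, 4))$rate, 0)

  expect_error(initial_rate(tc, n_points = 10), "exceeds")
  expect_error(initial_rate(time_course(0:5, 0:5), 4), "protein_nM")

  # first-order data sampled well inside the linear regime: slope ~ A*k
  t <- c(0, 0.1, 0.2, 0.3)
  tc2 <- time_course(t, 60 * (1 - exp(-0.2 * t)), protein_nM = 1)
  expect_rel_equal(initial_rate(tc2, 4)$rate, 60 * 0.2, 0.05)
})

test_that("noiseless fits recover generating parameters to 6 significant digits", {
  t <- 0:10
  tc <- time_course(t, 50 * (1 - exp(-0.3 * t)), observable = "supercoiling")
  f <- fit_first_order(tc)
  expect_rel_equal(f$k, 0.3, 1e-6)
  expect_rel_equal(f$amplitude, 50, 1e-6)
  expect_equal(f$half_time, log(2) / f$k)          # exact identity
  expect_rel_equal(f$half_time, 2.310490, 1e-5)    # ln2 / 0.3
  expect_gt(f$r_squared, 0.999999)

  # sliding-scale rate constant (wild-type kcat ~ 2.2/min)
  ts <- seq(0, 2.5, by = 0.25)
  tcs <- time_course(ts, 0.8 * (1 - exp(-2.2 * ts)), observable = "sliding")
  fs <- fit_single_exponential(tcs)
  expect_rel_equal(fs$k, 2.2, 1e-6)
  expect_identical(fs$model, "single_exponential")

  # degenerate: no amplitude
  expect_error(fit_single_exponential(time_course(0:5, rep(0.5, 6))),
               "amplitude")
})

test_that("Michaelis-Menten fit recovers parameters and identities", {
  S <- c(10, 25, 50, 80, 150, 300, 500)
  kobs <- 20 + 115 * S / (80 + S)
  f <- fit_michaelis_menten(S, kobs, basal = 20)
  expect_rel_equal(f$kcat, 115, 1e-6)
  expect_rel_equal(f$Km, 80, 1e-6)
  # half-saturation identity at S = Km
  expect_equal(115 * 80 / (80 + 80), 115 / 2)
  v_at_km <- f$kcat * f$Km / (f$Km + f$Km)
  expect_rel_equal(v_at_km, f$kcat / 2, 1e-9)
  # saturation limit and initial slope from the fitted parameters
  expect_rel_equal(f$kcat * 1e9 / (f$Km + 1e9), f$kcat, 1e-6)
  ds <- 1e-6
  expect_rel_equal((f$kcat * ds / (f$Km + ds)) / ds, f$kcat / f$Km, 1e-4)

  expect_warning(fit_michaelis_menten(c(10, 50, 200, 600),
                                      20 + 115 * c(10, 50, 200, 600) /
                                        (80 + c(10, 50, 200, 600)),
                                      basal = 20), "500 nM")
  expect_error(fit_michaelis_menten(c(10, 50, 100, 200), rep(5, 4), basal = 10),
               "corrected rates")
  expect_error(fit_michaelis_menten(c(10, 50, 100), c(1, 2, 3)), "at least 4")
})

test_that("half-time identity holds for every fit", {
  set.seed(77)
  for (i in 1:10) {
    k <- stats::runif(1, 0.05, 2)
    A <- stats::runif(1, 10, 80)
    t <- seq(0, 5 / k, length.out = 10)
    y <- A * (1 - exp(-k * t)) + stats::rnorm(10, 0, 0.02 * A)
    f <- fit_first_order(time_course(t, y))
    expect_identical(f$half_time, log(2) / f$k)
    expect_gt(f$r_squared, 0.9)
  }
})

test_that("noisy recovery is reliable (reduced-size simulation)", {
  # protocol: mean of N = 3 replicate series, rise-resolving time grid
  set.seed(12)
  ok <- 0L
  t <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15, 20)
  for (i in 1:40) {
    y <- rowMeans(sapply(1:3, function(j)
      60 * (1 - exp(-0.3 * t)) + stats::rnorm(length(t), 0, 3)))
    f <- tryCatch(fit_first_order(time_course(t, y), fit_offset = FALSE),
                  error = function(e) NULL)
    if (!is.null(f) && abs(f$k - 0.3) / 0.3 <= 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 36L)
})

test_that("relative rates and error propagation follow the quadrature rule", {
  r <- relative_rate(1.7, 1.7, 0.3, 0.3)
  expect_equal(r$percent, 100)
  expect_equal(r$percent_se, 100 * sqrt(2) * (0.3 / 1.7), tolerance = 1e-12)

  r2 <- relative_rate(0.045, 2.2, 0.009, 0.2, digits = 1)
  expect_equal(r2$percent_rounded, 2.0)
  expect_equal(r2$percent_se_rounded, 0.4)

  expect_error(relative_rate(1, 0), "positive")
  expect_error(relative_rate(1, -2), "positive")

  # rounding is half away from zero, as in printed tables
  expect_equal(relative_rate(0.255, 1, digits = 0)$percent_rounded, 26)
})
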