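test_that("mono-exponential fit round-trips the water standard", {
  w <- water_standard_curve()
  fit <- fit_mono(w)
  expect_equal(fit$d, 2.7e-9, tolerance = 1e-12)
  expect_equal(fit$population, 1, tolerance = 1e-12)
})

test_that("mono fit recovers rate and population of a scaled curve", {
  b <- b_values <- seq(0, 3e9, length.out = 20)
  cu <- decay_curve(b, 0.5 * exp(-b * 1e-9))
  fit <- fit_mono(cu)
  expect_equal(fit$d, 1e-9, tolerance = 1e-12)
  expect_equal(fit$population, 0.5, tolerance = 1e-12)
})

test_that("mono fit rejects degenerate input", {
  flat <- decay_curve(seq(0, 1e9, length.out = 10), rep(1, 10))
  expect_error(fit_mono(flat), class = "pfg_degenerate_fit")
  tiny <- decay_curve(c(0, 1e8), c(1, 0.9))
  expect_error(fit_mono(tiny), class = "pfg_insufficient_data")
})

test_that("initial-slope ADC estimates the weighted ADC", {
  # single exponential: constant slope regardless of the window
  w <- water_standard_curve()
  for (k in c(2, 5, 25)) expect_equal(initial_slope_adc(w, k), 2.7e-9,
                                      tolerance = 1e-10)

  # biexponential on a fine small-b grid: the 3-point estimate matches the
  # population-weighted ADC
  cs <- control_compartments()
  fine <- decay_curve(seq(0, 2e7, length.out = 21),
                      biexp_signal(seq(0, 2e7, length.out = 21), cs))
  expect_equal(initial_slope_adc(fine, 3), weighted_adc(cs), tolerance = 0.01)

  # widening the window on a convex log-curve only lowers the estimate,
  # and never above the weighted ADC
  grid <- seq(0, 5e9, length.out = 40)
  cu <- decay_curve(grid, biexp_signal(grid, cs))
  est <- vapply(2:40, function(k) initial_slope_adc(cu, k), numeric(1))
  expect_true(all(diff(est) < 1e-22))
  expect_true(all(est <= weighted_adc(cs) * (1 + 1e-9)))

  expect_error(initial_slope_adc(cu, 1), class = "pfg_invalid_input")
  expect_error(initial_slope_adc(cu, 99), class = "pfg_invalid_input")
})

test_that("peel-off recovers noise-free biexponential parameters", {
  cs <- control_compartments()
  cu <- synthesize_curve(acquisition_extended(), cs, 0)
  fit <- suppressWarnings(peel_off_fit(cu))
  expect_lt(rel_err(fit$fast$d, cs$d_fast), 1e-3)
  expect_lt(rel_err(fit$slow$d, cs$d_slow), 1e-3)
  expect_lt(rel_err(fit$fast$population, cs$p1), 1e-3)
  expect_equal(fit$fast$population + fit$slow$population, 1)
  expect_identical(fit$method, "peel_off_refined")
  expect_equal(fit$adc_initial_slope, weighted_adc(cs), tolerance = 0.01)
})

test_that("refined estimates match generating parameters across the (p1, ratio) sweep", {
  # oracle-equivalence property: forward-simulate then invert, noise-free
  for (p1 in c(0.2, 0.35, 0.5, 0.7, 0.9)) {
    for (ratio in c(20, 50, 200)) {
      d_fast <- 1.25e-9
      d_slow <- d_fast / ratio
      cu <- synthesize_curve(acquisition_extended(),
                             compartment_set(d_fast, d_slow, p1), 0)
      fit <- suppressWarnings(peel_off_fit(cu))
      expect_lt(rel_err(fit$fast$d, d_fast), 1e-3)
      expect_lt(rel_err(fit$slow$d, d_slow), 1e-3)
      expect_lt(rel_err(fit$fast$population, p1), 1e-3)
    }
  }
})

test_that("weighted ADC of fitted components agrees with the initial-slope ADC", {
  cs <- control_compartments()
  cu <- synthesize_curve(acquisition_extended(), cs, 0)
  fit <- suppressWarnings(peel_off_fit(cu))
  fitted_adc <- fit$fast$population * fit$fast$d + fit$slow$population * fit$slow$d
  expect_equal(fitted_adc, fit$adc_initial_slope, tolerance = 0.05)
})

test_that("mono-exponential input triggers a stripping failure", {
  w <- water_standard_curve(acquisition_extended())
  expect_error(peel_off_fit(w), class = "pfg_stripping_failure")
})

test_that("refinement never worsens the amplitude-domain objective", {
  cs <- control_compartments()
  for (s in 1:5) {
    cu <- synthesize_curve(acquisition_extended(), cs, 0.01, seed = s)
    stripped <- suppressWarnings(peel_off_fit(cu, refine = FALSE))
    refined <- suppressWarnings(peel_off_fit(cu, refine = TRUE))
    expect_lte(refined$residual_rms, stripped$residual_rms)
  }
})

test_that("peel_off_fit validates its inputs", {
  cu <- synthesize_curve(acquisition_default(), control_compartments(), 0)
  expect_error(peel_off_fit(cu, tail_fraction = 0), class = "pfg_invalid_input")
  expect_error(peel_off_fit(cu, tail_fraction = 0.9), class = "pfg_invalid_input")
  short <- decay_curve(seq(0, 1e9, length.out = 5),
                       exp(-seq(0, 1e9, length.out = 5) * 1e-9))
  expect_error(peel_off_fit(short), class = "pfg_insufficient_data")
})

test_that("fit_decay_curves falls back to mono fits on single-phase curves", {
  cs <- control_compartments()
  curves <- list(bi = synthesize_curve(acquisition_extended(), cs, 0),
                 mono = water_standard_curve(acquisition_extended()))
  fits <- suppressWarnings(fit_decay_curves(curves))
  expect_identical(fits$method, c("peel_off_refined", "mono"))
  expect_equal(fits$p1[2], 1)
  expect_equal(fits$d_fast_1e9[2], 2.7, tolerance = 1e-9)
  # scaled-unit contract of the exported table
  expect_equal(fits$d_fast_1e9[1], 1.25, tolerance = 1e-6)
  expect_equal(fits$d_slow_1e11[1], 1.67, tolerance = 1e-6)
})
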