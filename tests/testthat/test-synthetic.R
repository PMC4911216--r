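test_that("parametric maps hit the requested wavelength and are seeded", {
  gt <- synth_maps("parametric", seed = 5, size = 96, wavelength = 24)
  lam <- map_wavelength(gt$op)
  ## within one spectral bin of the target frequency
  expect_gt(lam, 1 / (1 / 24 + 1 / 96))
  expect_lt(lam, 1 / (1 / 24 - 1 / 96))
  expect_gt(nrow(detect_pinwheels(gt$op)), 0)
  ## determinism
  gt2 <- synth_maps("parametric", seed = 5, size = 96, wavelength = 24)
  expect_identical(gt$op$field, gt2$op$field)
  expect_identical(gt$od$field, gt2$od$field)
  ## size guard
  expect_error(synth_maps("parametric", size = 40, wavelength = 24))
})

test_that("uncoupled OP and OD maps give a flat pinwheel histogram", {
  props <- rowMeans(vapply(1:4, function(s) {
    gt <- synth_maps("parametric", seed = 300 + s, size = 96,
                     wavelength = 24, coupling = 0)
    pinwheel_od_histogram(detect_pinwheels(gt$op), gt$od)$proportions
  }, numeric(5)))
  expect_lt(max(abs(props - 0.2)), 0.1)
})

test_that("coupling steers pinwheels towards OD centres or borders", {
  bin1 <- function(cp) mean(vapply(1:4, function(s) {
    gt <- synth_maps("parametric", seed = 200 + s, size = 96,
                     wavelength = 24, coupling = cp)
    pinwheel_od_histogram(detect_pinwheels(gt$op), gt$od)$proportions[1]
  }, numeric(1)))
  b0 <- bin1(0)
  expect_gt(bin1(0.8), b0)   # towards centres
  expect_lt(bin1(-0.8), b0)  # towards borders
})

test_that("synthetic stacks scale linearly with gain and carry OD sign", {
  gt <- synth_maps("parametric", seed = 6, size = 48, wavelength = 12)
  rec <- function(g) stack_recipe(gain = g, n_trials = 1, vessel_n = 0,
                                  vessel_amplitude = 0,
                                  drift_amplitude = 0, noise_sd = 0,
                                  n_directions = 4)
  s1 <- synth_stack(gt, rec(0.01), seed = 3)
  s2 <- synth_stack(gt, rec(0.02), seed = 3)
  dev1 <- 1 - s1$data
  dev2 <- 1 - s2$data
  expect_equal(dev2, 2 * dev1, tolerance = 1e-12)
  ## stimulus-locked decrease: stimulus frames darker than baseline
  expect_lt(mean(s1$data[1, 1, 25, , ]), mean(s1$data[1, 1, 1, , ]))

  ## an all-positive OD map yields a one-signed extracted OD map when
  ## read out without the DC-removing band-pass (which by design
  ## subtracts any global eye bias)
  gtp <- gt
  gtp$od$field <- abs(gtp$od$field) + 0.1
  stk <- synth_stack(gtp, stack_recipe(n_trials = 1, vessel_n = 0,
                                       vessel_amplitude = 0,
                                       drift_amplitude = 0,
                                       noise_sd = 0), seed = 3)
  cs <- average_conditions(stk)
  cs$data <- 1 - cs$data  # reflectance decrease -> positive response
  base <- vector_average_baseline(cs)
  expect_true(all(base$od$field > 0))
})

test_that("stack generation is seed-deterministic", {
  gt <- synth_maps("parametric", seed = 6, size = 48, wavelength = 12)
  rec <- stack_recipe(n_trials = 2, n_directions = 4)
  a <- synth_stack(gt, rec, seed = 8)
  b <- synth_stack(gt, rec, seed = 8)
  expect_identical(a$data, b$data)
})

test_that("unit generator closes the loop with the fitting code", {
  ## noiseless: planted parameters recovered exactly
  u <- synth_units(15, "control", seed = 3, noise_sigma = 0)
  fits <- fit_units(u)
  tp_true <- vapply(u, function(x) x$truth$theta_p[[x$dominant_eye]],
                    numeric(1))
  expect_lt(max(abs(wrap_diff180(fits$theta_p - tp_true))), 1e-6)
  fp_true <- vapply(u, function(x) x$truth$fp_sf, numeric(1))
  expect_lt(max(abs(fits$fp_sf - fp_true) / fp_true), 1e-6)
  sig_true <- vapply(u, function(x) x$truth$sigma_c, numeric(1))
  expect_lt(max(abs(fits$sigma_c - sig_true) / sig_true), 1e-4)

  ## zero modulation: flat orientation density
  u0 <- synth_units(300, "control", seed = 4, noise_sigma = 0,
                    modulation = 0)
  h <- population_orientation_histogram(fit_units(u0)$theta_p)
  expect_lt(h$fit_90$amplitude, 0.04)

  ## cross-reared left-eye peak lands near the lens orientation
  u1 <- synth_units(200, "cross_reared", seed = 9, noise_sigma = 0.1,
                    left_peak = 0)
  f1 <- fit_units(u1)
  h1 <- population_orientation_histogram(
    f1$theta_p[f1$dominant_eye == "L"])
  d <- h1$fit_180$peaks[1] %% 180
  expect_lt(min(d, 180 - d), 10)

  ## monocularity rises from control to cross-reared
  expect_gt(median(f1$mi),
            median(fit_units(synth_units(200, "control", seed = 9,
                                         noise_sigma = 0.1))$mi))
})
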