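test_that("tuning models obey their closed-form anchor points", {
  ## peak of the von Mises curve is exactly Rp + R0
  expect_equal(von_mises_rate(60, Rp = 20, theta_p = 60, k = 2, R0 = 3), 23)
  ## peak of the skewed Gaussian is exactly Rp + R0 at f = fp
  expect_equal(skew_gauss_rate(0.24, 25, 0.24, 1.2, 0.3, 2), 27)
  ## lambda = 0 is symmetric in log frequency: R(fp x) = R(fp / x)
  x <- c(1.3, 2, 3.7)
  expect_equal(skew_gauss_rate(0.2 * x, 25, 0.2, 1.2, 0, 2),
               skew_gauss_rate(0.2 / x, 25, 0.2, 1.2, 0, 2))
  ## Naka-Rushton at c = sigma is exactly Rm/2 + R0, and approaches
  ## Rm + R0 within (sigma/c)^n at high contrast
  expect_equal(naka_rushton_rate(20, 30, 20, 2.5, 2), 17)
  expect_lt(abs(naka_rushton_rate(100, 30, 5, 2.5, 2) - 32),
            32 * (5 / 100)^2.5)
})

test_that("noiseless curves are recovered to four digits", {
  dirs <- (0:15) * 22.5
  vm <- fit_von_mises(dirs, von_mises_rate(dirs, 20, 60, 2, 3))
  expect_equal(vm$Rp, 20, tolerance = 1e-4)
  expect_equal(vm$theta_p, 60, tolerance = 1e-4)
  expect_equal(vm$k, 2, tolerance = 1e-4)
  expect_equal(vm$R0, 3, tolerance = 1e-4)
  expect_equal(vm$r_squared, 1, tolerance = 1e-8)
  ## bandwidth agrees with the closed form acos(1 - log 2 / k)
  expect_equal(vm$bandwidth, acos(1 - log(2) / 2) * 180 / pi,
               tolerance = 1e-6)

  f <- exp(seq(log(0.05), log(1.6), length.out = 9))
  sg <- fit_skewed_gaussian(f, skew_gauss_rate(f, 25, 0.24, 1.2, 0.3, 2))
  expect_equal(sg$fp, 0.24, tolerance = 1e-4)
  expect_equal(sg$k, 1.2, tolerance = 1e-4)
  expect_equal(sg$lambda, 0.3, tolerance = 1e-4)

  cc <- c(1, 2, 4, 8, 16, 32, 64, 100)
  cr <- fit_contrast_response(cc, naka_rushton_rate(cc, 30, 20, 2.5, 2))
  expect_equal(cr$Rm, 30, tolerance = 1e-4)
  expect_equal(cr$sigma, 20, tolerance = 1e-4)
  expect_equal(cr$n, 2.5, tolerance = 1e-4)
  expect_true(cr$saturating)
})

test_that("direction tuning is folded before the orientation fit", {
  dirs <- (0:15) * 22.5
  r <- von_mises_rate(dirs, 15, 120, 1.5, 2)
  r[dirs >= 180] <- r[dirs >= 180] * 1.4  # direction-selective unit
  fit <- fit_von_mises(dirs, r)
  ## folding averages opposite directions; preference survives
  expect_equal(fit$theta_p, 120, tolerance = 1)
  expect_equal(length(fit$data$theta), 8L)
})

test_that("flat responses are flagged unselective, non-finite rejected", {
  dirs <- (0:15) * 22.5
  f <- fit_von_mises(dirs, rep(5, 16))
  expect_false(f$selective)
  expect_true(is.na(f$theta_p))
  expect_error(fit_von_mises(dirs, c(rep(5, 15), NA)), "non-finite")
  expect_error(fit_contrast_response(c(1, 2, 4, 8, 16),
                                     rep(0, 5)), "all-zero")
  expect_error(fit_skewed_gaussian(c(-0.1, 0.2, 0.4, 0.8, 1.6),
                                   rep(1, 5)), "positive")
})

test_that("non-saturating contrast responses are flagged for exclusion", {
  cc <- c(1, 2, 4, 8, 16, 32, 64, 100)
  cr <- fit_contrast_response(cc, naka_rushton_rate(cc, 30, 400, 2, 1))
  expect_false(cr$saturating)
})

test_that("preferred orientation survives 10% response noise", {
  set.seed(42)
  dirs <- (0:15) * 22.5
  errs <- replicate(100, {
    tp <- runif(1, 0, 180)
    r <- pmax(0, von_mises_rate(dirs, 20, tp, 2, 3) + rnorm(16, 0, 2))
    abs(wrap_diff180(fit_von_mises(dirs, r)$theta_p - tp))
  })
  expect_lt(median(errs), 3)
})

test_that("monocularity index follows its definition and invariances", {
  expect_equal(monocularity_index(5, 5), 0)
  expect_equal(monocularity_index(7, 0), 1)
  expect_equal(monocularity_index(2, 1), 1 / 3)
  ## invariant under common scaling
  expect_equal(monocularity_index(20, 10), monocularity_index(2, 1))
  expect_error(monocularity_index(0, 0), "undefined")
})

test_that("interocular orientation difference wraps and antisymmetrises", {
  expect_equal(interocular_op_difference(100, 90), 10)
  expect_equal(interocular_op_difference(5, 175), 10)
  expect_equal(interocular_op_difference(90, 90), 0)
  ## antisymmetric under eye swap away from the boundary
  expect_equal(interocular_op_difference(30, 70),
               -interocular_op_difference(70, 30))
  ## output always in (-90, 90]
  set.seed(2)
  a <- runif(200, 0, 180); b <- runif(200, 0, 180)
  d <- interocular_op_difference(a, b)
  expect_true(all(d > -90 & d <= 90))
})

test_that("population histograms separate the two sine periodicities", {
  ## all units at one orientation: a single occupied bin
  h1 <- population_orientation_histogram(rep(40, 20))
  expect_equal(sum(h1$proportions > 0), 1L)
  ## uniform population: both sine amplitudes near zero
  h2 <- population_orientation_histogram(seq(0.5, 179.5, length.out = 400))
  expect_lt(h2$fit_90$amplitude, 1e-3)
  expect_lt(h2$fit_180$amplitude, 1e-3)
  ## population drawn from a period-180 density peaked at 0: the
  ## period-180 fit wins the model comparison
  u <- synth_units(200, "cross_reared", seed = 9, noise_sigma = 0.1)
  fits <- fit_units(u)
  left <- fits$theta_p[fits$dominant_eye == "L"]
  h3 <- population_orientation_histogram(left)
  expect_gt(h3$fit_180$r_squared, h3$fit_90$r_squared)
})
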