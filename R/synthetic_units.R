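#' Generate synthetic single-unit response records
#'
#' Draws a population of units with known tuning parameters and emits
#' noisy response curves on the standard stimulus grids (16 drift
#' directions; spatial frequencies 0.05-1.6 cycles/degree; temporal
#' frequencies 0.25-24 Hz; contrasts 1-100%), per eye.
#'
#' Preferred orientations are drawn from a sine-modulated density:
#' period 90 degrees peaking at the cardinals for the control
#' population, or period 180 degrees per eye (left eye peaking at
#' `left_peak`, right eye at `right_peak`) for the cross-reared
#' population, emulating rearing through orthogonally oriented lenses.
#' Monocularity indices are drawn from Beta distributions whose medians
#' match the reported control (0.24) and cross-reared (0.38) medians;
#' the right/left response split of each unit follows its MI with a
#' random (control) or orientation-linked (cross-reared) dominant eye.
#'
#' @param n number of units.
#' @param population "control" or "cross_reared".
#' @param seed integer seed.
#' @param noise_sigma response noise s.d. relative to each unit's peak
#'   rate (0 = noiseless curves).
#' @param modulation amplitude of the orientation-density sine
#'   modulation in [0, 1]; 0 gives a uniform distribution.
#' @param left_peak,right_peak per-eye density peaks (degrees) for the
#'   cross-reared population.
#' @return list of `unit_record` objects; each has `unit_id`,
#'   `dominant_eye`, per-eye `orientation`, `sf`, `tf`, `contrast`
#'   response data.frames, and the generating `truth` parameters.
#' @export
synth_units <- function(n, population = c("control", "cross_reared"),
                        seed = 1, noise_sigma = 0.1, modulation = 0.8,
                        left_peak = 0, right_peak = 90) {
  population <- match.arg(population)
  stopifnot(n >= 1, noise_sigma >= 0, modulation >= 0, modulation <= 1)
  set.seed(derive_seed(seed, 37L))

  dirs <- (0:15) * 22.5
  sf_grid <- exp(seq(log(0.05), log(1.6), length.out = 9))
  tf_grid <- exp(seq(log(0.25), log(24), length.out = 9))
  con_grid <- c(1, 2, 4, 8, 16, 32, 64, 100)

  units <- vector("list", n)
  for (i in seq_len(n)) {
    dominant <- sample(c("L", "R"), 1)
    ## dominant-eye preferred orientation from the population density
    theta_p <- switch(
      population,
      control = sample_orientation(function(t)
        1 + modulation * cos(4 * t * pi / 180), 1),
      cross_reared = {
        peak <- if (dominant == "L") left_peak else right_peak
        sample_orientation(function(t)
          1 + modulation * cos(2 * (t - peak) * pi / 180), 1)
      })
    ## torsional interocular offset, right minus left
    delta_op <- rnorm(1, 10, 6)
    theta_eye <- c(
      L = if (dominant == "L") theta_p else wrap_orientation(theta_p - delta_op),
      R = if (dominant == "R") theta_p else wrap_orientation(theta_p + delta_op))

    mi <- switch(population,
                 control = rbeta(1, 2, 6),      # median ~ 0.24
                 cross_reared = rbeta(1, 2, 3)) # median ~ 0.39
    Rsum <- runif(1, 20, 60)
    Rdom <- Rsum * (1 + mi) / 2
    Rnod <- Rsum * (1 - mi) / 2
    Rp_eye <- c(L = if (dominant == "L") Rdom else Rnod,
                R = if (dominant == "R") Rdom else Rnod)

    truth <- list(
      theta_p = theta_eye, Rp = Rp_eye, k = runif(1, 1, 3),
      R0 = runif(1, 0, 4), mi = mi, dominant_eye = dominant,
      fp_sf = rlnorm(1, log(if (population == "control") 0.16 else 0.24),
                     0.35),
      fp_tf = rlnorm(1, log(3), 0.4),
      k_f = runif(1, 0.9, 1.6), lambda = runif(1, -0.3, 0.3),
      Rm = runif(1, 15, 40), sigma_c = runif(1, 10, 40),
      n_c = runif(1, 2, 4))
    truth$fp_sf <- min(max(truth$fp_sf, 0.06), 1.4)
    truth$fp_tf <- min(max(truth$fp_tf, 0.3), 20)

    noisy <- function(mu, peak)
      pmax(0, mu + if (noise_sigma > 0)
        rnorm(length(mu), 0, noise_sigma * peak) else 0)
    per_eye <- lapply(c(L = "L", R = "R"), function(e) {
      Rp <- truth$Rp[[e]]
      list(
        orientation = data.frame(
          direction = dirs,
          rate = noisy(von_mises_rate(dirs, Rp, truth$theta_p[[e]],
                                      truth$k, truth$R0), Rp)),
        sf = data.frame(
          f = sf_grid,
          rate = noisy(skew_gauss_rate(sf_grid, Rp, truth$fp_sf,
                                       truth$k_f, truth$lambda,
                                       truth$R0), Rp)),
        tf = data.frame(
          f = tf_grid,
          rate = noisy(skew_gauss_rate(tf_grid, Rp, truth$fp_tf,
                                       truth$k_f, truth$lambda,
                                       truth$R0), Rp)),
        contrast = data.frame(
          contrast = con_grid,
          rate = noisy(naka_rushton_rate(con_grid, truth$Rm,
                                         truth$sigma_c, truth$n_c,
                                         truth$R0), truth$Rm)))
    })
    units[[i]] <- structure(
      list(unit_id = i, dominant_eye = dominant, population = population,
           responses = per_eye, truth = truth),
      class = "unit_record")
  }
  units
}

## rejection sampler for an orientation density on [0, 180)
sample_orientation <- function(density_fn, n) {
  out <- numeric(0)
  ## densities used here are bounded by 2
  while (length(out) < n) {
    cand <- runif(2 * n + 8, 0, 180)
    acc <- runif(length(cand), 0, 2) < density_fn(cand)
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

#' @export
print.unit_record <- function(x, ...) {
  cat(sprintf(
    "<unit_record> #%d (%s): dominant eye %s, theta_p %.1f deg, MI %.2f\n",
    x$unit_id, x$population, x$dominant_eye,
    x$truth$theta_p[[x$dominant_eye]], x$truth$mi))
  invisible(x)
}

#' Unit records as a long-format response table
#'
#' Flattens a list of `unit_record`s into the CSV-style long format
#' (unit_id, eye, stimulus_type, stimulus_value, rate).
#'
#' @param units list from [synth_units()].
#' @return data.frame.
#' @export
units_to_table <- function(units) {
  rows <- lapply(units, function(u) {
    per <- lapply(c("L", "R"), function(e) {
      r <- u$responses[[e]]
      rbind(
        data.frame(unit_id = u$unit_id, eye = e,
                   stimulus_type = "direction",
                   stimulus_value = r$orientation$direction,
                   rate = r$orientation$rate),
        data.frame(unit_id = u$unit_id, eye = e, stimulus_type = "sf",
                   stimulus_value = r$sf$f, rate = r$sf$rate),
        data.frame(unit_id = u$unit_id, eye = e, stimulus_type = "tf",
                   stimulus_value = r$tf$f, rate = r$tf$rate),
        data.frame(unit_id = u$unit_id, eye = e,
                   stimulus_type = "contrast",
                   stimulus_value = r$contrast$contrast,
                   rate = r$contrast$rate))
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}

#' Fit all tuning models to a set of unit records
#'
#' Runs [fit_von_mises()], [fit_skewed_gaussian()] and
#' [fit_contrast_response()] on the dominant-eye curves of each unit and
#' computes the monocularity index and interocular orientation
#' difference.
#'
#' @param units list from [synth_units()] (or equivalently structured
#'   records).
#' @return data.frame with one row per unit: fitted `theta_p`, `fp_sf`,
#'   `fp_tf`, `sigma_c`, `mi`, `delta_op` and fit r-squared values.
#' @export
fit_units <- function(units) {
  rows <- lapply(units, function(u) {
    dom <- u$responses[[u$dominant_eye]]
    vm <- fit_von_mises(dom$orientation$direction, dom$orientation$rate)
    sf <- fit_skewed_gaussian(dom$sf$f, dom$sf$rate, "spatial")
    tf <- fit_skewed_gaussian(dom$tf$f, dom$tf$rate, "temporal")
    cr <- fit_contrast_response(dom$contrast$contrast, dom$contrast$rate)
    vmL <- fit_von_mises(u$responses$L$orientation$direction,
                         u$responses$L$orientation$rate)
    vmR <- fit_von_mises(u$responses$R$orientation$direction,
                         u$responses$R$orientation$rate)
    RR <- max(u$responses$R$orientation$rate)
    RL <- max(u$responses$L$orientation$rate)
    data.frame(
      unit_id = u$unit_id, dominant_eye = u$dominant_eye,
      theta_p = vm$theta_p, r2_orientation = vm$r_squared,
      bandwidth = vm$bandwidth,
      fp_sf = sf$fp, r2_sf = sf$r_squared,
      fp_tf = tf$fp, r2_tf = tf$r_squared,
      sigma_c = cr$sigma, saturating = cr$saturating,
      r2_contrast = cr$r_squared,
      mi = monocularity_index(RR, RL),
      delta_op = if (!is.na(vmR$theta_p) && !is.na(vmL$theta_p))
        interocular_op_difference(vmR$theta_p, vmL$theta_p)
      else NA_real_)
  })
  do.call(rbind, rows)
}
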