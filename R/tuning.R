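## Single-unit tuning-curve models: von Mises orientation tuning, skewed
## log-Gaussian frequency tuning, Naka-Rushton contrast response.

#' Von Mises orientation tuning curve
#'
#' \deqn{R(\theta) = R_p \exp(k(\cos 2(\theta-\theta_p) - 1)) + R_0}
#' The response equals exactly Rp + R0 at the preferred orientation.
#'
#' @param theta orientation in degrees.
#' @param Rp peak response above baseline.
#' @param theta_p preferred orientation in degrees.
#' @param k width parameter (larger = narrower tuning).
#' @param R0 spontaneous baseline.
#' @export
von_mises_rate <- function(theta, Rp, theta_p, k, R0) {
  Rp * exp(k * (cos(2 * (theta - theta_p) * pi / 180) - 1)) + R0
}

#' Skewed log-Gaussian frequency tuning curve
#'
#' \deqn{R(f) = R_p \exp(-(\log(f/f_p) / (k + \lambda\log(f/f_p)))^2)
#'       + R_0}
#' At \eqn{f = f_p} the response is exactly Rp + R0; at \eqn{\lambda = 0}
#' the curve is a symmetric Gaussian in log frequency; \eqn{\lambda}
#' skews the curve towards high (positive) or low (negative)
#' frequencies. The same form serves spatial (cycles/degree) and
#' temporal (Hz) frequency tuning.
#'
#' @param f frequency (> 0).
#' @param Rp peak response above baseline.
#' @param fp preferred frequency.
#' @param k bandwidth parameter.
#' @param lambda skew parameter.
#' @param R0 spontaneous baseline.
#' @export
skew_gauss_rate <- function(f, Rp, fp, k, lambda, R0) {
  x <- log(f / fp)
  den <- k + lambda * x
  r <- ifelse(den > 0, Rp * exp(-(x / den)^2) + R0, R0)
  r
}

#' Naka-Rushton contrast response function
#'
#' \deqn{R(c) = R_m c^n / (c^n + \sigma^n) + R_0}
#' At \eqn{c = \sigma} the response is exactly Rm/2 + R0.
#'
#' @param c_ stimulus contrast in percent.
#' @param Rm maximal response above baseline.
#' @param sigma semi-saturation contrast.
#' @param n exponent.
#' @param R0 spontaneous baseline.
#' @export
naka_rushton_rate <- function(c_, Rm, sigma, n, R0) {
  Rm * c_^n / (c_^n + sigma^n) + R0
}

#' Fit a von Mises orientation tuning curve
#'
#' If 16 drift directions are supplied, responses to opposite directions
#' are averaged first. The fit is bounded nonlinear least squares with a
#' multi-start over preferred-orientation candidates (the model is
#' 180-degree periodic in theta_p, so local minima recur every half
#' period). Bandwidth is the full width at half maximum of the fitted
#' curve, computed numerically.
#'
#' @param theta stimulus angles in degrees: orientations in [0, 180) or
#'   directions in [0, 360).
#' @param rates mean spike rates (same length).
#' @param n_starts number of theta_p starting values.
#' @return object of class `von_mises_fit`: `Rp`, `theta_p`, `k`, `R0`,
#'   `r_squared`, `bandwidth` (FWHM, degrees), `selective` flag,
#'   `fitted`, `data`.
#' @export
fit_von_mises <- function(theta, rates, n_starts = 8) {
  stopifnot(length(theta) == length(rates))
  if (any(!is.finite(rates))) stop("non-finite responses")
  if (max(theta) >= 180) {  # directions: average opposite pairs
    ori <- wrap_orientation(theta)
    agg <- tapply(rates, round(ori, 6), mean)
    theta <- as.numeric(names(agg))
    rates <- as.numeric(agg)
  }
  if (length(theta) < 8) stop("need >= 8 orientation samples")

  if (sd(rates) < 1e-12) {
    return(structure(list(Rp = 0, theta_p = NA_real_, k = 0,
                          R0 = mean(rates), r_squared = 0,
                          bandwidth = NA_real_, selective = FALSE,
                          fitted = rep(mean(rates), length(rates)),
                          data = data.frame(theta = theta, rate = rates)),
                     class = "von_mises_fit"))
  }

  df <- data.frame(theta = theta, rate = rates)
  span <- max(rates) - min(rates)
  best <- NULL
  for (tp0 in (seq_len(n_starts) - 1) * 180 / n_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ von_mises_rate(theta, Rp, theta_p, k, R0), data = df,
        start = list(Rp = max(span, 1e-3), theta_p = tp0, k = 1.5,
                     R0 = max(min(rates), 0)),
        lower = c(0, -360, 1e-4, 0),
        upper = c(Inf, 720, 500, max(rates) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("von Mises fit failed from all starts")
  p <- as.list(coef(best$fit))
  p$theta_p <- wrap_orientation(p$theta_p)
  fitted_r <- von_mises_rate(theta, p$Rp, p$theta_p, p$k, p$R0)
  r2 <- squared_cor(rates, fitted_r)
  structure(list(Rp = p$Rp, theta_p = p$theta_p, k = p$k, R0 = p$R0,
                 r_squared = r2,
                 bandwidth = von_mises_fwhm(p$k),
                 selective = p$k > 1e-3,
                 fitted = fitted_r,
                 data = df),
            class = "von_mises_fit")
}

## FWHM (degrees) of the von Mises orientation curve: R - R0 falls to
## half its peak where cos(2 dtheta) = 1 - log(2)/k
von_mises_fwhm <- function(k) {
  if (k <= log(2) / 2) return(NA_real_)  # never falls to half: unselective
  acos(1 - log(2) / k) * 180 / pi
}

#' Fit a skewed log-Gaussian frequency tuning curve
#'
#' Least-squares fit in log frequency with a multi-start over the
#' stimulus grid for the preferred frequency; the identical code path
#' serves spatial (cycles/degree) and temporal (Hz) tuning. Bandwidth is
#' the FWHM of the fitted curve in octaves, computed numerically.
#'
#' @param f stimulus frequencies (> 0, strictly increasing).
#' @param rates mean spike rates.
#' @param domain "spatial" or "temporal" (annotation only).
#' @return object of class `skew_gauss_fit`: `Rp`, `fp`, `k`, `lambda`,
#'   `R0`, `r_squared`, `bandwidth_octaves`, `domain`, `fitted`, `data`.
#' @export
fit_skewed_gaussian <- function(f, rates, domain = c("spatial", "temporal")) {
  domain <- match.arg(domain)
  stopifnot(length(f) == length(rates), length(f) >= 5)
  if (any(f <= 0)) stop("frequencies must be positive")
  df <- data.frame(f = f, rate = rates)
  span <- max(rates) - min(rates)
  best <- NULL
  for (fp0 in f[rates >= quantile(rates, 0.5)]) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ skew_gauss_rate(f, Rp, fp, k, lambda, R0), data = df,
        start = list(Rp = max(span, 1e-3), fp = fp0, k = 1.2, lambda = 0,
                     R0 = max(min(rates), 0)),
        lower = c(0, min(f), 1e-3, -0.55, 0),
        upper = c(Inf, max(f), 20, 0.55, max(rates) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("skewed Gaussian fit failed from all starts")
  p <- as.list(coef(best$fit))
  fitted_r <- skew_gauss_rate(f, p$Rp, p$fp, p$k, p$lambda, p$R0)
  structure(list(Rp = p$Rp, fp = p$fp, k = p$k, lambda = p$lambda,
                 R0 = p$R0, r_squared = squared_cor(rates, fitted_r),
                 bandwidth_octaves =
                   skew_gauss_fwhm_octaves(p$fp, p$k, p$lambda),
                 domain = domain, fitted = fitted_r, data = df),
            class = "skew_gauss_fit")
}

## numeric FWHM in octaves of the skewed log-Gaussian
skew_gauss_fwhm_octaves <- function(fp, k, lambda) {
  x <- seq(-12, 12, length.out = 20001)  # log(f/fp) grid
  den <- k + lambda * x
  r <- ifelse(den > 0, exp(-(x / den)^2), 0)
  above <- which(r >= 0.5)
  if (length(above) < 2) return(NA_real_)
  (x[max(above)] - x[min(above)]) / log(2)
}

#' Fit a Naka-Rushton contrast response function
#'
#' Bounded nonlinear least squares over contrast levels. Units whose
#' fitted semi-saturation contrast lies beyond the largest tested
#' contrast did not saturate within the tested range and are flagged
#' (`saturating = FALSE`) for exclusion.
#'
#' @param contrast contrasts in percent (>= 5 levels).
#' @param rates mean spike rates.
#' @return object of class `contrast_fit`: `Rm`, `sigma`, `n`, `R0`,
#'   `r_squared`, `saturating`, `fitted`, `data`.
#' @export
fit_contrast_response <- function(contrast, rates) {
  stopifnot(length(contrast) == length(rates), length(contrast) >= 5)
  if (all(rates == 0)) stop("all-zero responses")
  df <- data.frame(c_ = contrast, rate = rates)
  best <- NULL
  for (s0 in quantile(contrast, c(0.25, 0.5, 0.75))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ naka_rushton_rate(c_, Rm, sigma, n, R0), data = df,
        start = list(Rm = max(rates) - min(rates), sigma = s0, n = 2,
                     R0 = max(min(rates), 0)),
        lower = c(0, 1e-3, 0.1, 0),
        upper = c(Inf, 1000, 10, max(rates) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("contrast fit failed from all starts")
  p <- as.list(coef(best$fit))
  fitted_r <- naka_rushton_rate(contrast, p$Rm, p$sigma, p$n, p$R0)
  structure(list(Rm = p$Rm, sigma = p$sigma, n = p$n, R0 = p$R0,
                 r_squared = squared_cor(rates, fitted_r),
                 saturating = p$sigma <= max(contrast),
                 fitted = fitted_r, data = df),
            class = "contrast_fit")
}

squared_cor <- function(y, yhat) {
  if (sd(y) < 1e-300 || sd(yhat) < 1e-300) return(0)
  cor(y, yhat)^2
}

#' Monocularity index
#'
#' \deqn{MI = |R_R - R_L| / (R_R + R_L)}: 0 for perfectly binocular
#' units, 1 for purely monocular units. Invariant under common scaling
#' of the two responses.
#'
#' @param RR,RL responses to the optimal grating in the right and left
#'   eye.
#' @return MI in \[0, 1\].
#' @export
monocularity_index <- function(RR, RL) {
  if (any(RR + RL <= 0)) stop("MI undefined: RR + RL must be > 0")
  abs(RR - RL) / (RR + RL)
}

#' Signed interocular difference in preferred orientation
#'
#' Right-eye minus left-eye preferred orientation as a circular
#' difference with period 180 degrees, wrapped to (-90, 90]. Positive
#' values are a consistent torsional offset of the right eye relative to
#' the left. Antisymmetric under eye swap (up to the +90 boundary).
#'
#' @param theta_right,theta_left preferred orientations in degrees.
#' @return signed difference in (-90, 90].
#' @export
interocular_op_difference <- function(theta_right, theta_left) {
  wrap_diff180(theta_right - theta_left)
}

#' Population histogram of preferred orientations with sine fits
#'
#' Bins the units' preferred orientations into 22.5-degree bins and fits
#' sine curves of period 90 (cardinal bias) and 180 degrees (single
#' orientation bias) to the proportions, reporting both fits so their
#' r-squared values can be compared.
#'
#' @param theta_p preferred orientations in degrees, or a list of
#'   `von_mises_fit` objects.
#' @param bin_width histogram bin width in degrees.
#' @return list with `proportions`, `counts`, `centers`, `fit_90`,
#'   `fit_180`.
#' @export
population_orientation_histogram <- function(theta_p, bin_width = 22.5) {
  if (is.list(theta_p) && !is.numeric(theta_p))
    theta_p <- vapply(theta_p, function(f) f$theta_p, numeric(1))
  theta_p <- theta_p[!is.na(theta_p)]
  if (length(theta_p) < 8) stop("need >= 8 units")
  h <- orientation_proportions(theta_p, bin_width)
  list(proportions = h$proportions, counts = h$counts,
       centers = h$centers,
       fit_90 = fit_sine_distribution(h$proportions, 90, h$centers),
       fit_180 = fit_sine_distribution(h$proportions, 180, h$centers))
}
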