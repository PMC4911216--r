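#' Generate ground-truth OP/OD maps
#'
#' Parametric mode: the OP field is complex Gaussian white noise
#' band-pass filtered with an annular (Gaussian ring) spectrum centred
#' on 1/wavelength, giving a smooth quasi-periodic orientation map with
#' pinwheels; the OD field is independently band-pass-filtered real
#' noise on the same spectral annulus. An optional coupling parameter
#' steers pinwheels relative to the OD map (see Details). Elastic-net
#' mode delegates to [run_simulation()].
#'
#' @details
#' Coupling works by adding a constant-phase complex bias to the OP
#' field whose local amplitude depends on |OD|: pinwheels (zeros of the
#' field) are destroyed or displaced where the bias is large and survive
#' where it vanishes. `coupling > 0` concentrates pinwheels towards OD
#' column centres (the normally reared arrangement), `coupling < 0`
#' towards OD borders; 0 leaves the maps independent.
#'
#' @param mode "parametric" or "elastic_net".
#' @param seed integer seed; same seed, same maps.
#' @param size map side length in pixels (parametric mode; must be at
#'   least 4 wavelengths).
#' @param wavelength target map wavelength in pixels.
#' @param bandwidth relative width of the spectral annulus.
#' @param coupling pinwheel/OD coupling in [-1, 1].
#' @param config a [sim_config()] (elastic-net mode).
#' @return object of class `ground_truth`: list with `op`, `od`,
#'   `provenance`, `seed`, `params`.
#' @export
synth_maps <- function(mode = c("parametric", "elastic_net"), seed = 1,
                       size = 128, wavelength = 20, bandwidth = 0.25,
                       coupling = 0, config = NULL) {
  mode <- match.arg(mode)
  if (mode == "elastic_net") {
    if (is.null(config)) config <- sim_config(seed = seed)
    maps <- extract_maps(run_simulation(config))
    return(structure(list(op = maps$op, od = maps$od,
                          provenance = "elastic_net", seed = config$seed,
                          params = unclass(config)),
                     class = "ground_truth"))
  }
  stopifnot(size >= 4 * wavelength, abs(coupling) <= 1)
  set.seed(derive_seed(seed, 11L))

  z <- bandpass_noise(size, wavelength, bandwidth, complex_field = TRUE)
  odf <- Re(bandpass_noise(size, wavelength, bandwidth,
                           complex_field = FALSE))
  odf <- odf / max(abs(odf))

  if (coupling != 0) {
    m <- abs(odf)                        # 1 at OD extremes, 0 at borders
    a <- if (coupling > 0) 1 - m else m  # bias amplitude field
    u <- exp(complex(imaginary = runif(1, 0, 2 * pi)))
    z <- z + abs(coupling) * 2 * sqrt(mean(Mod(z)^2)) * a * u
  }
  z <- z / max(Mod(z)) * 0.08  # selectivity on the feature-radius scale

  structure(list(op = op_map(z), od = od_map(odf),
                 provenance = "parametric", seed = seed,
                 params = list(size = size, wavelength = wavelength,
                               bandwidth = bandwidth, coupling = coupling)),
            class = "ground_truth")
}

## band-pass filtered Gaussian noise with an annular Gaussian spectrum
bandpass_noise <- function(size, wavelength, bandwidth,
                           complex_field = TRUE) {
  n <- size
  f0 <- 1 / wavelength
  fr <- (seq_len(n) - 1) / n
  fr <- pmin(fr, 1 - fr)
  fmag <- sqrt(outer(fr^2, fr^2, `+`))
  amp <- exp(-(fmag - f0)^2 / (2 * (bandwidth * f0)^2))
  amp[fmag == 0] <- 0  # no DC
  noise <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)),
                  n, n)
  filt <- fft(fft(noise) * amp, inverse = TRUE) / (n * n)
  if (complex_field) filt else Re(filt) * sqrt(2)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s maps, %d x %d px, seed %d\n",
              x$provenance, nrow(x$od$field), ncol(x$od$field), x$seed))
  invisible(x)
}
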