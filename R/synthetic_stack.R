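#' Recipe for a synthetic intrinsic-signal imaging stack
#'
#' Bundles the generative parameters of [synth_stack()]. The frame grid
#' defaults to the reference timing: 50 frames at 5 Hz (10 s), stimulus
#' on during frames 11-35 (2-7 s after acquisition onset). The
#' stimulus-locked response follows a hemodynamic kernel with a short
#' latency, a linear rise to plateau and an exponential return to
#' baseline, emulating the canonical reflectance-decrease time course.
#' Nuisance components emulate what makes real green-light data hard:
#' dark curvilinear blood-vessel artifacts with independent temporal
#' jitter, a global low-frequency illumination drift, and white pixel
#' noise.
#'
#' @param gain peak fractional reflectance change of the strongest
#'   stimulus-locked response (e.g. 0.01 = 1% dR/R).
#' @param n_trials trials per condition (the reference protocol
#'   presents every stimulus at least 30 times).
#' @param n_frames frames per trial.
#' @param frame_rate frames per second.
#' @param stim_frames stimulus-on frame indices.
#' @param kernel_latency response latency after stimulus onset (s).
#' @param kernel_rise linear rise time to plateau (s).
#' @param kernel_decay_tau exponential decay time constant after
#'   stimulus offset (s).
#' @param vessel_n number of vessel artifacts.
#' @param vessel_amplitude vessel darkening relative to `gain` (1 =
#'   artifacts as strong as the signal).
#' @param vessel_jitter relative temporal jitter of vessel intensity.
#' @param vessel_width vessel Gaussian profile sigma in pixels.
#' @param drift_amplitude global illumination drift relative to `gain`.
#' @param noise_sd white pixel noise standard deviation relative to
#'   `gain` (0.1 = 10% of the peak signal).
#' @param eye_gain slope of the tanh ocularity weighting.
#' @param n_directions number of drift directions (two per orientation).
#' @return object of class `stack_recipe`.
#' @export
stack_recipe <- function(gain = 0.01, n_trials = 30, n_frames = 50,
                         frame_rate = 5, stim_frames = 11:35,
                         kernel_latency = 0.6, kernel_rise = 2,
                         kernel_decay_tau = 2,
                         vessel_n = 4, vessel_amplitude = 1,
                         vessel_jitter = 0.3, vessel_width = 2,
                         drift_amplitude = 1, noise_sd = 0.1,
                         eye_gain = 1, n_directions = 16) {
  structure(as.list(environment()), class = "stack_recipe")
}

## hemodynamic kernel evaluated at the frame times (seconds)
hemodynamic_kernel <- function(t, onset, offset, latency, rise, decay_tau) {
  k <- numeric(length(t))
  t0 <- onset + latency
  up <- t >= t0 & t < t0 + rise
  k[up] <- (t[up] - t0) / rise
  k[t >= t0 + rise & t <= offset] <- 1
  post <- t > offset
  k_off <- min(1, max(0, (offset - t0) / rise))
  k[post] <- k_off * exp(-(t[post] - offset) / decay_tau)
  k
}

## one smooth curvilinear dark structure: Gaussian profile along a
## random-walk path
vessel_image <- function(H, W, width) {
  n_steps <- 2 * max(H, W)
  pos <- c(runif(1, 1, H), runif(1, 1, W))
  ang <- runif(1, 0, 2 * pi)
  img <- matrix(0, H, W)
  rr <- row(img); cc <- col(img)
  pts <- matrix(NA_real_, n_steps, 2)
  for (s in seq_len(n_steps)) {
    pts[s, ] <- pos
    ang <- ang + rnorm(1, 0, 0.15)
    pos <- pos + c(cos(ang), sin(ang))
    if (pos[1] < -width * 3 || pos[1] > H + width * 3 ||
        pos[2] < -width * 3 || pos[2] > W + width * 3) break
  }
  pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
  ## stamp the Gaussian profile (coarse but adequate: max over path)
  for (s in seq_len(nrow(pts))) {
    d2 <- (rr - pts[s, 1])^2 + (cc - pts[s, 2])^2
    img <- pmax(img, exp(-d2 / (2 * width^2)))
  }
  img
}

#' Simulate an intrinsic-signal imaging stack from ground-truth maps
#'
#' For each condition (drift direction x eye), every pixel responds with
#' amplitude \eqn{(1 + s\,\cos 2(\theta - OP))/2} - an untuned component
#' plus a tuned component weighted by the pixel's orientation
#' selectivity \eqn{s} - scaled by a smooth ocularity weight
#' \eqn{(1 \pm \tanh(g\,OD))/2}; the reflectance *decreases* by gain x
#' amplitude x hemodynamic kernel during the response. Blood-vessel artifacts
#' (shared across conditions, temporally jittered per frame), global
#' illumination drift and white pixel noise are added on top of a unit
#' baseline. Per-trial realisations differ; everything is reproducible
#' from `seed`.
#'
#' When `average_trials = TRUE` (the default) the per-condition trial
#' mean is generated directly instead of materialising every trial: the
#' generator is linear in its random components, so the pixel noise,
#' vessel jitter and drift of the averaged stack are drawn at their
#' exact n-trial-average distributions (noise and jitter s.d. scaled by
#' 1/sqrt(n_trials), drift as the resultant of n random phases). This
#' keeps a 30-trial experiment within a single trial's memory. Set
#' `average_trials = FALSE` to materialise individual trials (e.g. to
#' exercise trial averaging itself).
#'
#' @param truth a `ground_truth` from [synth_maps()].
#' @param recipe a [stack_recipe()].
#' @param seed integer seed.
#' @param average_trials generate the per-condition trial mean directly
#'   (see above).
#' @return an [imaging_stack()]; the ground truth and recipe are
#'   attached as attributes `truth` and `recipe`.
#' @export
synth_stack <- function(truth, recipe = stack_recipe(), seed = 1,
                        average_trials = TRUE) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(recipe, "stack_recipe"))
  set.seed(derive_seed(seed, 23L))
  H <- nrow(truth$od$field); W <- ncol(truth$od$field)
  r <- recipe

  ori <- op_angle(truth$op)
  sel <- op_selectivity(truth$op)
  sel <- sel / max(sel)
  odn <- truth$od$field / max(abs(truth$od$field))
  w_right <- (1 + tanh(r$eye_gain * odn)) / 2

  dirs <- (seq_len(r$n_directions) - 1) * 360 / r$n_directions
  conds <- rbind(
    expand.grid(direction = dirs, eye = c("L", "R"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(direction = NA_real_, eye = NA_character_))
  conds$blank <- is.na(conds$direction)

  tt <- (seq_len(r$n_frames) - 1) / r$frame_rate
  onset <- (min(r$stim_frames) - 1) / r$frame_rate
  offset <- max(r$stim_frames) / r$frame_rate
  kern <- hemodynamic_kernel(tt, onset, offset, r$kernel_latency,
                             r$kernel_rise, r$kernel_decay_tau)

  vessels <- if (r$vessel_n > 0)
    lapply(seq_len(r$vessel_n), function(i)
      vessel_image(H, W, r$vessel_width))
  else list()

  ## smooth spatial pattern of the illumination drift
  drift_pattern <- matrix(1, H, W) +
    outer(seq_len(H) / H - 0.5, seq_len(W) / W - 0.5, function(a, b)
      runif(1, -1, 1) * a + runif(1, -1, 1) * b)

  n_real <- if (average_trials) 1L else r$n_trials
  ## 1/sqrt(n) scaling of the averaged i.i.d. components
  nsc <- if (average_trials) 1 / sqrt(r$n_trials) else 1

  data <- array(0, c(n_real, nrow(conds), r$n_frames, H, W))
  for (tr in seq_len(n_real)) {
    for (ci in seq_len(nrow(conds))) {
      if (conds$blank[ci]) {
        amp <- matrix(0, H, W)
      } else {
        th <- wrap_orientation(conds$direction[ci])
        w_eye <- if (conds$eye[ci] == "R") w_right else 1 - w_right
        amp <- 0.5 * (1 + sel * cos(2 * (th - ori) * pi / 180)) * w_eye
      }
      ## global illumination drift: slow sinusoid, fresh phase per trial;
      ## the n-trial mean is the resultant of n unit phasors
      n_eff <- if (average_trials) r$n_trials else 1L
      ph <- runif(n_eff, 0, 2 * pi)
      drift_freq <- runif(1, 0.02, 0.06)  # Hz: slow
      drift_t <- r$drift_amplitude * r$gain / n_eff *
        Reduce(`+`, lapply(ph, function(p)
          sin(2 * pi * drift_freq * tt + p)))
      vess_jit <- matrix(rnorm(length(vessels) * r$n_frames, 1,
                               r$vessel_jitter * nsc),
                         nrow = max(1, length(vessels)))
      for (fr in seq_len(r$n_frames)) {
        img <- matrix(1, H, W) - r$gain * amp * kern[fr]
        for (vi in seq_along(vessels))
          img <- img - r$vessel_amplitude * r$gain *
            vess_jit[vi, fr] * vessels[[vi]]
        img <- img + drift_t[fr] * drift_pattern
        if (r$noise_sd > 0)
          img <- img + rnorm(H * W, 0, r$noise_sd * r$gain * nsc)
        data[tr, ci, fr, , ] <- img
      }
    }
  }
  out <- imaging_stack(data, conds, r$frame_rate, r$stim_frames)
  attr(out, "truth") <- truth
  attr(out, "recipe") <- r
  out
}
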