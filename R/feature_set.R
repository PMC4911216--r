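#' Build the elastic-net training feature set
#'
#' Constructs the 5-D stimulus feature points: `nx * ny` retinotopic
#' positions on a square grid in the unit square, crossed with two
#' ocularity values (-d, +d) and `n_op` orientations equally spaced on
#' [0, 180) encoded as double-angle vectors of radius `r`. The reference
#' configuration (20 x 20 x 2 x 6) yields 4800 points.
#'
#' Over-representation of an (eye, orientation) combination - the model of
#' cross-rearing with orthogonally oriented cylindrical lenses - is
#' expressed as a multiplicative coverage weight `alpha_over` on the
#' matching feature points; all other points have weight 1. The default
#' assignment over-represents horizontal (0 deg) contours in the left eye
#' and vertical (90 deg) contours in the right eye.
#'
#' @param nx,ny retinotopic grid size.
#' @param d ocularity magnitude; the two OD feature values are -d and +d.
#' @param r radius of the orientation double-angle vector (selectivity).
#' @param n_op number of orientations, equally spaced on [0, 180).
#' @param alpha_over coverage weight (>= 1) for over-represented points.
#' @param over_assignments data.frame with columns `eye` ("left"/"right")
#'   and `theta` (degrees); which (eye, orientation) pairs get
#'   `alpha_over`. Only pairs whose `theta` matches a generated
#'   orientation have an effect.
#' @return an object of class `feature_set`: list with `points` (M x 5
#'   matrix, columns sx, sy, od, opx, opy), `weights` (length M), and the
#'   generating parameters.
#' @examples
#' fs <- build_feature_set()
#' nrow(fs$points)  # 4800
#' @export
build_feature_set <- function(nx = 20, ny = 20, d = 0.05, r = 0.08,
                              n_op = 6, alpha_over = 1,
                              over_assignments = default_over_assignments()) {
  stopifnot(nx >= 1, ny >= 1, n_op >= 1, d > 0, r > 0)
  if (alpha_over < 1)
    stop("`alpha_over` must be >= 1 (1 = no over-representation)")

  sx <- (seq_len(nx) - 0.5) / nx
  sy <- (seq_len(ny) - 0.5) / ny
  od <- c(-d, d)
  theta <- (seq_len(n_op) - 1) * 180 / n_op

  g <- expand.grid(sx = sx, sy = sy, od = od, theta = theta,
                   KEEP.OUT.ATTRS = FALSE)
  points <- cbind(sx = g$sx, sy = g$sy, od = g$od,
                  opx = r * cos(2 * g$theta * pi / 180),
                  opy = r * sin(2 * g$theta * pi / 180))

  weights <- rep(1, nrow(points))
  if (alpha_over > 1 && nrow(over_assignments) > 0) {
    for (i in seq_len(nrow(over_assignments))) {
      eye_sign <- switch(over_assignments$eye[i],
                         left = -1, right = 1,
                         stop("eye must be 'left' or 'right'"))
      hit <- sign(g$od) == eye_sign &
        abs(wrap_diff180(g$theta - over_assignments$theta[i])) < 1e-9
      weights[hit] <- alpha_over
    }
  }

  ## product structure: point i = (s, f) with s varying fastest
  ## (expand.grid order), s over nx*ny spatial positions, f over the
  ## 2*n_op (ocularity, orientation) combinations
  gf <- expand.grid(od = od, theta = theta, KEEP.OUT.ATTRS = FALSE)
  fcomb <- cbind(od = gf$od,
                 opx = r * cos(2 * gf$theta * pi / 180),
                 opy = r * sin(2 * gf$theta * pi / 180))
  spatial <- cbind(sx = rep(sx, times = ny), sy = rep(sy, each = nx))
  weight_sf <- matrix(weights, nrow(spatial), nrow(fcomb))

  structure(
    list(points = points, weights = weights,
         spatial = spatial, fcomb = fcomb, weight_sf = weight_sf,
         nx = nx, ny = ny, d = d, r = r, n_op = n_op,
         theta = theta, alpha_over = alpha_over,
         over_assignments = over_assignments),
    class = "feature_set")
}

#' Default cross-rearing over-representation assignment
#'
#' Left eye sees predominantly horizontal (0 deg) contours, right eye
#' vertical (90 deg), matching the axes of the rearing lenses.
#' @return data.frame with columns `eye`, `theta`.
#' @export
default_over_assignments <- function() {
  data.frame(eye = c("left", "right"), theta = c(0, 90),
             stringsAsFactors = FALSE)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d points (%dx%d spatial x 2 OD x %d OP)\n",
              nrow(x$points), x$nx, x$ny, x$n_op))
  cat(sprintf("  d = %g, r = %g, alpha_over = %g (%d weighted points)\n",
              x$d, x$r, x$alpha_over, sum(x$weights > 1)))
  invisible(x)
}

#' Simulation configuration for the elastic-net model
#'
#' Bundles all parameters of a map-development run. Defaults are the
#' reference configuration: 20x20x2x6 = 4800 features, 128x128 cortex,
#' continuity weight beta = 10, annealing from K = 0.2 by a factor 0.9925
#' per iteration down to K = 0.0358 (229 iterations).
#'
#' @param nx,ny,d,r,n_op,alpha_over,over_assignments passed to
#'   [build_feature_set()].
#' @param width,height cortical sheet size.
#' @param beta continuity weight.
#' @param K0,decay,K_end annealing schedule: one update at each K value
#'   K0 * decay^k, stopping once K has dropped to K_end or below.
#' @param seed integer RNG seed; fixes the cortical initialisation.
#' @param od_noise,op_noise initial perturbation amplitudes of the OD and
#'   OP components (uniform on +/- amplitude).
#' @param step_size multiplier on the elastic-net update (1 = standard).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(nx = 20, ny = 20, d = 0.05, r = 0.08, n_op = 6,
                       alpha_over = 1,
                       over_assignments = default_over_assignments(),
                       width = 128, height = 128, beta = 10,
                       K0 = 0.2, decay = 0.9925, K_end = 0.0358,
                       seed = 1, od_noise = 0.005, op_noise = 0.008,
                       step_size = 1) {
  stopifnot(beta > 0, K0 > 0, decay > 0, decay < 1, K_end < K0,
            width >= 2, height >= 2, alpha_over >= 1, step_size > 0)
  structure(
    list(nx = nx, ny = ny, d = d, r = r, n_op = n_op,
         alpha_over = alpha_over, over_assignments = over_assignments,
         width = width, height = height, beta = beta,
         K0 = K0, decay = decay, K_end = K_end, seed = as.integer(seed),
         od_noise = od_noise, op_noise = op_noise, step_size = step_size),
    class = "sim_config")
}

#' Number of annealing iterations implied by a schedule
#' @param config a [sim_config()].
#' @return integer: smallest n with K0 * decay^n <= K_end.
#' @export
n_iterations <- function(config) {
  K <- config$K0
  n <- 0L
  while (K > config$K_end) {
    K <- K * config$decay
    n <- n + 1L
  }
  n
}

#' Initialise the cortical sheet
#'
#' Retinotopic components are a smooth affine embedding of the grid into
#' the unit square (node centres); OD and OP components are independent
#' zero-mean uniform perturbations of amplitude `od_noise` / `op_noise`,
#' small compared with the feature values d and r. Identical seeds give
#' identical sheets.
#'
#' @param config a [sim_config()].
#' @return object of class `cortical_sheet`: list with `Y` (N x 5 matrix,
#'   N = width*height, column-major node order), `width`, `height`.
#' @export
init_cortex <- function(config) {
  W <- config$width; H <- config$height
  set.seed(derive_seed(config$seed, 1L))
  gc_ <- rep(seq_len(W), each = H)   # grid column per node (column-major)
  gr_ <- rep(seq_len(H), times = W)  # grid row per node
  Y <- cbind(
    sx = (gc_ - 0.5) / W,
    sy = (gr_ - 0.5) / H,
    od = runif(W * H, -config$od_noise, config$od_noise),
    opx = runif(W * H, -config$op_noise, config$op_noise),
    opy = runif(W * H, -config$op_noise, config$op_noise))
  structure(list(Y = Y, width = W, height = H), class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("<cortical_sheet> %d x %d nodes (5-D)\n", x$height, x$width))
  if (!is.null(attr(x, "iterations")))
    cat(sprintf("  simulated: %d iterations, final K = %g\n",
                attr(x, "iterations"), attr(x, "final_K")))
  invisible(x)
}
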