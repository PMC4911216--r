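#' Proportion of map area per orientation bin
#'
#' Bins the preferred orientation of every masked pixel into eight
#' 22.5-degree bins centred on 11.25, 33.75, ..., 168.75 degrees (edges
#' at 0, 22.5, ..., 180; left-closed, right-open; 180 wraps to 0) and
#' returns the proportions.
#'
#' @param op an `op_map`, or a numeric matrix/vector of orientations in
#'   degrees.
#' @param bin_width bin width in degrees (default 22.5 -> 8 bins).
#' @return list with `proportions`, `counts`, `centers` (bin centres in
#'   degrees).
#' @export
orientation_proportions <- function(op, bin_width = 22.5) {
  theta <- if (inherits(op, "op_map")) op_angle(op)[op$mask]
           else wrap_orientation(as.numeric(op))
  if (length(theta) == 0) stop("empty mask: no orientations to bin")
  n_bins <- round(180 / bin_width)
  idx <- floor(theta / bin_width) + 1
  idx[idx > n_bins] <- 1L  # 180 wraps to 0
  counts <- tabulate(idx, nbins = n_bins)
  list(proportions = counts / sum(counts), counts = counts,
       centers = (seq_len(n_bins) - 0.5) * bin_width)
}

#' Fixed-period sine fit to a binned angular distribution
#'
#' Least-squares fit of \eqn{y(\theta) = A \sin(2\pi(\theta-\phi)/P) + C}
#' with the period P fixed (90 degrees for a cardinal over-representation,
#' 180 degrees for a single-orientation bias). The model is linear in a
#' sin/cos basis; the amplitude is reported non-negative with the sign
#' absorbed into the phase. Goodness of fit is the squared correlation of
#' the data and the fitted values.
#'
#' @param y proportions (or counts) at the bin centres.
#' @param period fixed period in degrees: 90 or 180.
#' @param centers bin centres in degrees; defaults to 8 bins of 22.5.
#' @return object of class `sine_fit`: list with `amplitude`, `phase`,
#'   `offset`, `period`, `r_squared`, `peaks` (peak angles in [0, 180)),
#'   `fitted`.
#' @export
fit_sine_distribution <- function(y, period,
                                  centers = (seq_along(y) - 0.5) *
                                    180 / length(y)) {
  stopifnot(length(y) == length(centers))
  if (length(y) < 4) stop("need at least 4 bins to fit a sine curve")
  w <- 2 * pi / period
  S <- sin(w * centers); Cc <- cos(w * centers)
  fit <- lm(y ~ S + Cc)
  a <- coef(fit)[["S"]]; b <- coef(fit)[["Cc"]]
  A <- sqrt(a^2 + b^2)
  ## a sin(wt) + b cos(wt) = A sin(w(t - phi)) with phi = -atan2(b, a)/w
  phase <- if (A > 0) (-atan2(b, a) / w) %% period else 0
  fitted_y <- as.numeric(fitted(fit))
  r2 <- if (sd(y) == 0 || sd(fitted_y) == 0) 0 else cor(y, fitted_y)^2
  peaks <- sort(wrap_orientation(phase + period / 4 +
                                   period * (0:(180 / period - 1))))
  structure(list(amplitude = A, phase = phase, offset = coef(fit)[[1]],
                 period = period, r_squared = r2,
                 peaks = if (A > 0) peaks else numeric(0),
                 fitted = fitted_y, centers = centers),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "<sine_fit> period %g deg: A = %.4g, peak(s) %s deg, r^2 = %.3f\n",
    x$period, x$amplitude,
    paste(sprintf('%.1f', x$peaks), collapse = ", "), x$r_squared))
  invisible(x)
}

#' Crossing angles between OP and OD map contours
#'
#' Extracts the zero-level contour of the OD map and the iso-orientation
#' contours of the OP map at 0, 22.5, ..., 157.5 degrees (computed on the
#' doubled-angle complex field, which avoids the 0/180 wrap), finds all
#' polyline intersections, and returns the absolute difference between
#' the tangent orientations of the two contours at each intersection,
#' folded into [0, 90]. For unrelated maps the expected distribution of
#' these angles follows a sine density on [0, 90] (transversal crossings
#' are length-biased by the sine of the angle).
#'
#' @param op an `op_map`.
#' @param od an `od_map` on the same grid.
#' @param levels iso-orientation levels in degrees.
#' @return numeric vector of crossing angles in degrees, possibly empty.
#' @export
crossing_angles <- function(op, od, levels = seq(0, 157.5, by = 22.5)) {
  stopifnot(all(dim(op$field) == dim(od$field)))
  od_segs <- contour_segments(od$field, 0)
  if (is.null(od_segs)) return(numeric(0))
  angles <- numeric(0)
  for (phi in levels) {
    g <- Arg(op$field * exp(complex(imaginary = -2 * phi * pi / 180)))
    op_segs <- contour_segments(g, 0)
    if (is.null(op_segs)) next
    hits <- segment_crossings(od_segs, op_segs)
    if (length(hits)) angles <- c(angles, hits)
  }
  angles
}

## polyline segments of the level-`lev` contour of matrix z, as a matrix
## with columns x1, y1, x2, y2 (x = row coordinate, y = column coordinate)
contour_segments <- function(z, lev) {
  cl <- contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z, levels = lev)
  if (length(cl) == 0) return(NULL)
  segs <- lapply(cl, function(p) {
    n <- length(p$x)
    if (n < 2) return(NULL)
    cbind(p$x[-n], p$y[-n], p$x[-1], p$y[-1])
  })
  out <- do.call(rbind, segs)
  if (is.null(out) || nrow(out) == 0) NULL else out
}

## crossing angles at all transversal intersections between two segment
## sets; vectorised over the second set, chunked over the first
segment_crossings <- function(A, B) {
  angles <- numeric(0)
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 3]; by2 <- B[, 4]
  b_ang <- atan2(by2 - by1, bx2 - bx1) * 180 / pi
  for (i in seq_len(nrow(A))) {
    ax1 <- A[i, 1]; ay1 <- A[i, 2]; ax2 <- A[i, 3]; ay2 <- A[i, 4]
    ## quick bounding-box rejection
    ok <- pmin(bx1, bx2) <= max(ax1, ax2) & pmax(bx1, bx2) >= min(ax1, ax2) &
      pmin(by1, by2) <= max(ay1, ay2) & pmax(by1, by2) >= min(ay1, ay2)
    if (!any(ok)) next
    dax <- ax2 - ax1; day <- ay2 - ay1
    dbx <- bx2[ok] - bx1[ok]; dby <- by2[ok] - by1[ok]
    denom <- dax * dby - day * dbx
    nz <- abs(denom) > 1e-12
    if (!any(nz)) next
    rx <- bx1[ok] - ax1; ry <- by1[ok] - ay1
    t <- (rx * dby - ry * dbx) / denom
    u <- (rx * day - ry * dax) / denom
    hit <- nz & t >= 0 & t <= 1 & u >= 0 & u <= 1
    if (!any(hit)) next
    a_ang <- atan2(day, dax) * 180 / pi
    d <- abs(wrap_diff180(a_ang - b_ang[ok][hit]))
    d[d > 90] <- 180 - d[d > 90]
    angles <- c(angles, d)
  }
  angles
}
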