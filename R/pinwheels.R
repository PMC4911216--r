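#' Detect orientation pinwheels by winding number
#'
#' For every interior masked pixel, the orientation difference between
#' consecutive pixels of the closed 8-neighbour loop (radius 1) is
#' wrapped into (-90, 90] and accumulated; pixels whose total winding is
#' +180 or -180 degrees are flagged. Eight-connected clusters of flagged
#' pixels are merged and each cluster's centre of mass is reported as one
#' pinwheel, with the winding direction as its sign.
#'
#' @param op an `op_map`, at least 3 x 3.
#' @param tol numeric tolerance on the winding total (degrees).
#' @return data.frame with columns `row`, `col` (sub-pixel centre of
#'   mass), `sign` (+1/-1) and `n_pixels` (cluster size).
#' @export
detect_pinwheels <- function(op, tol = 1e-6) {
  stopifnot(inherits(op, "op_map"))
  H <- nrow(op$field); W <- ncol(op$field)
  if (H < 3 || W < 3) stop("map must be at least 3 x 3")
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      sign = integer(0), n_pixels = integer(0))
  if (!any(op$mask)) return(empty)

  theta <- op_angle(op)
  ## closed loop around each pixel, consecutive 8-neighbour offsets
  loop <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  winding <- matrix(0, H - 2, W - 2)
  prev <- theta[ri + loop[8, 1], ci + loop[8, 2]]
  for (k in 1:8) {
    cur <- theta[ri + loop[k, 1], ci + loop[k, 2]]
    winding <- winding + wrap_diff180(cur - prev)
    prev <- cur
  }
  flagged <- abs(abs(winding) - 180) < tol & op$mask[ri, ci]
  if (!any(flagged)) return(empty)

  idx <- which(flagged, arr.ind = TRUE)
  pts <- cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  sgn <- sign(winding)[flagged]

  ## merge 8-connected flagged pixels (single-linkage on Chebyshev <= 1)
  n <- nrow(pts)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    near <- which(abs(pts[, 1] - pts[i, 1]) <= 1 &
                    abs(pts[, 2] - pts[i, 2]) <= 1)
    m <- min(comp[near])
    comp[comp %in% comp[near]] <- m
  }
  out <- do.call(rbind, lapply(unique(comp), function(cid) {
    sel <- comp == cid
    data.frame(row = mean(pts[sel, 1]), col = mean(pts[sel, 2]),
               sign = as.integer(sign(sum(sgn[sel]))),
               n_pixels = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Mean Fourier wavelength of a map
#'
#' The mean-subtracted complex field is Fourier transformed and the
#' wavelength of every spectral component (the reciprocal of its spatial
#' frequency magnitude, pooling all directions) is averaged with the
#' component powers as weights; DC and frequencies beyond the Nyquist
#' circle are excluded. For a single plane wave this is exactly its
#' wavelength; for an equal-power mixture of 8 px and 12 px waves it is
#' 10 px.
#'
#' @param op an `op_map` (or a plain complex/numeric matrix).
#' @return wavelength in pixels.
#' @export
map_wavelength <- function(op) {
  field <- if (inherits(op, "op_map")) {
    f <- op$field
    f[!op$mask] <- 0
    f
  } else op
  field <- field - mean(field)
  if (all(Mod(field) == 0)) stop("all-zero field: wavelength undefined")
  H <- nrow(field); W <- ncol(field)
  P <- Mod(fft(field))^2
  fr <- (seq_len(H) - 1) / H
  fc <- (seq_len(W) - 1) / W
  fr <- pmin(fr, 1 - fr)  # signed-frequency magnitude
  fc <- pmin(fc, 1 - fc)
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- fmag > 0 & fmag <= 0.5
  sum(P[keep] / fmag[keep]) / sum(P[keep])
}

#' Pinwheel density relative to the squared map wavelength
#'
#' Number of pinwheels per masked pixel multiplied by the square of the
#' map wavelength; the dimensionless density whose theoretically
#' predicted value for quasi-periodic orientation maps is pi.
#'
#' @param op an `op_map`.
#' @param pinwheels optional precomputed [detect_pinwheels()] output.
#' @param wavelength optional precomputed [map_wavelength()].
#' @return list with `density`, `n_pinwheels`, `wavelength`,
#'   `n_pixels`.
#' @export
pinwheel_density <- function(op, pinwheels = NULL, wavelength = NULL) {
  if (is.null(pinwheels)) pinwheels <- detect_pinwheels(op)
  if (nrow(pinwheels) < 1) stop("no pinwheels: density undefined")
  if (is.null(wavelength)) wavelength <- map_wavelength(op)
  n_px <- sum(op$mask)
  list(density = nrow(pinwheels) / n_px * wavelength^2,
       n_pinwheels = nrow(pinwheels), wavelength = wavelength,
       n_pixels = n_px)
}

#' Mean displacement between matched pinwheel sets
#'
#' Greedy nearest-neighbour matching between two pinwheel sets (e.g. the
#' same seed simulated at different over-representation strengths):
#' candidate pairs within `wavelength / 2` are accepted smallest distance
#' first, same-sign pairs before opposite-sign pairs, ties broken by
#' smallest index. Returns the mean matched distance in units of the map
#' wavelength.
#'
#' @param pwA,pwB data.frames from [detect_pinwheels()].
#' @param wavelength map wavelength in pixels (sets the distance cap).
#' @return list with `mean_displacement` (in wavelength units),
#'   `n_matched`, `n_unmatched`, and the matched pair table.
#' @export
pinwheel_displacement <- function(pwA, pwB, wavelength) {
  if (nrow(pwA) == 0 || nrow(pwB) == 0)
    stop("pinwheel set empty: displacement undefined")
  D <- outer(pwA$row, pwB$row, `-`)^2 + outer(pwA$col, pwB$col, `-`)^2
  D <- sqrt(D)
  cap <- wavelength / 2
  same <- outer(pwA$sign, pwB$sign, `==`)
  cand <- which(D <= cap, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(mean_displacement = NA_real_, n_matched = 0L,
                n_unmatched = nrow(pwA) + nrow(pwB),
                pairs = data.frame()))
  ord <- order(!same[cand], D[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(nrow(pwA)); usedB <- logical(nrow(pwB))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(a = i, b = j, distance = D[i, j])
    }
  }
  pairs <- do.call(rbind, pairs)
  list(mean_displacement = mean(pairs$distance) / wavelength,
       n_matched = nrow(pairs),
       n_unmatched = sum(!usedA) + sum(!usedB),
       pairs = pairs)
}
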