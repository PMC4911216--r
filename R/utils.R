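## Small numeric helpers shared across modules.

#' Wrap angular differences of a 180-degree periodic variable
#'
#' Wraps values into the half-open interval (-90, 90], the principal
#' difference between two orientations.
#'
#' @param x numeric vector of angle differences in degrees.
#' @return wrapped differences in (-90, 90].
#' @export
wrap_diff180 <- function(x) {
  w <- ((x + 90) %% 180) - 90
  w[w == -90] <- 90
  w
}

#' Map angles to the canonical orientation interval [0, 180)
#' @param x numeric vector of angles in degrees.
#' @return angles in [0, 180).
#' @export
wrap_orientation <- function(x) x %% 180

#' Boundary-renormalised Gaussian smoothing of an image
#'
#' Separable Gaussian blur implemented as banded-matrix multiplication.
#' The truncated kernel rows are renormalised at the image boundary, so a
#' constant image is mapped to itself exactly (and a constant image
#' high-pass filters to exactly zero). Away from the boundary this equals
#' ordinary convolution with a Gaussian truncated at `radius` sigma.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param radius kernel truncation radius in units of sigma.
#' @return smoothed matrix of the same dimension.
#' @export
gaussian_blur <- function(img, sigma, radius = 4) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  Kr <- gauss_band(nrow(img), sigma, radius)
  Kc <- gauss_band(ncol(img), sigma, radius)
  Kr %*% img %*% t(Kc)
}

# n x n row-stochastic banded Gaussian kernel matrix (cached: the
# imaging pipeline filters hundreds of frames with the same kernel)
gauss_band <- function(n, sigma, radius = 4) {
  key <- sprintf("%d_%g_%g", n, sigma, radius)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  K <- gauss_band_build(n, sigma, radius)
  .kernel_cache[[key]] <- K
  K
}

.kernel_cache <- new.env(parent = emptyenv())

gauss_band_build <- function(n, sigma, radius = 4) {
  h <- min(n - 1, max(1L, ceiling(radius * sigma)))
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (k in -h:h) {
    i <- idx[idx + k >= 1 & idx + k <= n]
    K[cbind(i, i + k)] <- g[k + h + 1]
  }
  K / rowSums(K)
}

# deterministic sub-stream seeds derived from one master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483629L
}
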