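#' Intrinsic-signal imaging stack
#'
#' Container for a per-trial frame sequence experiment: images acquired
#' at `frame_rate` Hz while drifting gratings are shown in one of 16
#' directions to one eye at a time (plus optional blanks). The reference
#' timing is 50 frames at 5 Hz (10 s), stimulus on during frames 11-35
#' (2-7 s).
#'
#' @param data 5-D numeric array `[trial, condition, frame, row, col]`.
#' @param conditions data.frame with one row per condition: `direction`
#'   (degrees, NA for blank), `eye` ("L"/"R", NA for blank), `blank`
#'   (logical).
#' @param frame_rate frames per second.
#' @param stim_frames indices of the stimulus-on frames.
#' @return object of class `imaging_stack`.
#' @export
imaging_stack <- function(data, conditions, frame_rate = 5,
                          stim_frames = 11:35) {
  stopifnot(length(dim(data)) == 5, nrow(conditions) == dim(data)[2],
            all(c("direction", "eye", "blank") %in% names(conditions)))
  structure(list(data = data, conditions = conditions,
                 frame_rate = frame_rate, stim_frames = stim_frames),
            class = "imaging_stack")
}

#' @export
print.imaging_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<imaging_stack> %d trials x %d conditions x %d frames x %dx%d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Align every frame to a reference by integer translation
#'
#' Exhaustively searches integer shifts within `max_shift` pixels and
#' applies, per image, the translation maximising the linear correlation
#' with the reference frame over the overlap region. Out-of-frame pixels
#' are filled with the frame mean. Flat (zero-variance) frames get zero
#' shift with a warning.
#'
#' @param stack an `imaging_stack`.
#' @param reference reference image (matrix); defaults to the first
#'   frame of the first trial and condition.
#' @param max_shift search half-width in pixels.
#' @return the aligned `imaging_stack`, with attribute `shifts`.
#' @export
align_frames <- function(stack, reference = NULL, max_shift = 10) {
  stopifnot(max_shift >= 0)
  d <- dim(stack$data)
  if (is.null(reference)) reference <- stack$data[1, 1, 1, , ]
  shifts <- array(0L, c(d[1], d[2], d[3], 2))
  flat_seen <- FALSE
  for (tr in seq_len(d[1])) for (co in seq_len(d[2])) for (fr in seq_len(d[3])) {
    img <- stack$data[tr, co, fr, , ]
    if (sd(img) == 0) { flat_seen <- TRUE; next }
    s <- best_shift(img, reference, max_shift)
    if (any(s != 0)) {
      stack$data[tr, co, fr, , ] <- translate_image(img, s[1], s[2])
      shifts[tr, co, fr, ] <- s
    }
  }
  if (flat_seen) warning("flat (zero-variance) frame(s): zero shift applied")
  attr(stack, "shifts") <- shifts
  stack
}

## integer (row, col) shift of img maximising correlation with ref
best_shift <- function(img, ref, max_shift) {
  H <- nrow(img); W <- ncol(img)
  best <- c(0L, 0L); best_cor <- -Inf
  for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
    r1 <- max(1, 1 + dr):min(H, H + dr)  # ref rows
    c1 <- max(1, 1 + dc):min(W, W + dc)
    a <- ref[r1, c1]
    b <- img[r1 - dr, c1 - dc]
    if (sd(a) == 0 || sd(b) == 0) next
    cc <- cor(as.vector(a), as.vector(b))
    if (cc > best_cor + 1e-12 ||
        (cc > best_cor - 1e-12 && sum(best^2) > dr^2 + dc^2)) {
      best_cor <- cc; best <- c(dr, dc)
    }
  }
  best
}

## shift image by (dr, dc), filling vacated pixels with the frame mean
translate_image <- function(img, dr, dc) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(mean(img), H, W)
  r_dst <- max(1, 1 + dr):min(H, H + dr)
  c_dst <- max(1, 1 + dc):min(W, W + dc)
  out[r_dst, c_dst] <- img[r_dst - dr, c_dst - dc]
  out
}

#' Average trials into per-(orientation, eye) condition stacks
#'
#' Pools trials from opposite drift directions (orientation = direction
#' mod 180) and pixel-wise averages all trials of each condition, giving
#' one `n_frames`-frame stack per orientation (0, 22.5, ..., 157.5) and
#' eye.
#'
#' @param stack an `imaging_stack`.
#' @return object of class `condition_stack`: list with `data`
#'   `[orientation, eye, frame, row, col]`, `orientations`, `eyes`,
#'   `frame_rate`, `stim_frames`.
#' @export
average_conditions <- function(stack) {
  d <- dim(stack$data)
  cond <- stack$conditions
  grating <- !cond$blank
  oris <- sort(unique(wrap_orientation(cond$direction[grating])))
  eyes <- c("L", "R")
  out <- array(0, c(length(oris), 2, d[3], d[4], d[5]))
  missing <- character(0)
  for (oi in seq_along(oris)) for (ei in 1:2) {
    sel <- which(grating & eyes[ei] == cond$eye &
                   wrap_orientation(cond$direction) == oris[oi])
    if (length(sel) == 0) {
      missing <- c(missing, sprintf("%g deg / eye %s", oris[oi], eyes[ei]))
      next
    }
    ## mean over trials and pooled directions (colMeans over the
    ## flattened leading [trial, condition] dimensions)
    sub <- stack$data[, sel, , , , drop = FALSE]
    ds <- dim(sub)
    out[oi, ei, , , ] <- colMeans(matrix(sub, ds[1] * ds[2],
                                         prod(ds[3:5])))
  }
  if (length(missing) > 0)
    stop("missing conditions: ", paste(missing, collapse = "; "))
  structure(list(data = out, orientations = oris, eyes = eyes,
                 frame_rate = stack$frame_rate,
                 stim_frames = stack$stim_frames),
            class = "condition_stack")
}

#' Band-pass preprocess condition-averaged frames
#'
#' Per frame: subtract a large-sigma Gaussian blur (high-pass, removes
#' global illumination changes), apply a small-sigma Gaussian blur
#' (low-pass, the decorrelation step requires smooth sources), then
#' reverse the sign so that the stimulus-locked reflectance *decrease*
#' becomes a positive activity signal. The Gaussian smoothing is
#' boundary-renormalised ([gaussian_blur()]), so constant frames
#' high-pass to exactly zero.
#'
#' @param cstack a `condition_stack`.
#' @param hp_sigma high-pass Gaussian sigma in pixels.
#' @param lp_sigma low-pass Gaussian sigma in pixels.
#' @return the filtered `condition_stack`.
#' @export
preprocess_frames <- function(cstack, hp_sigma = 20, lp_sigma = 2) {
  stopifnot(hp_sigma > lp_sigma)
  d <- dim(cstack$data)
  for (oi in seq_len(d[1])) for (ei in seq_len(d[2])) for (fr in seq_len(d[3])) {
    img <- cstack$data[oi, ei, fr, , ]
    img <- img - gaussian_blur(img, hp_sigma)
    img <- gaussian_blur(img, lp_sigma)
    cstack$data[oi, ei, fr, , ] <- -img
  }
  cstack
}

#' Compose OP/OD feature stacks from condition averages
#'
#' Frame-wise weighted sums of the per-orientation responses
#' \eqn{R_{\theta,eye}}:
#' \deqn{real(OP) = \sum_\theta \bar R_\theta \cos 2\theta, \quad
#'       imag(OP) = \sum_\theta \bar R_\theta \sin 2\theta, \quad
#'       OD = \sum_\theta R_{\theta,R} - \sum_\theta R_{\theta,L}}
#' where \eqn{\bar R_\theta} is the two-eye average (binocular mode) or
#' the single eye's response (monocular modes).
#'
#' @param cstack a `condition_stack` (typically preprocessed).
#' @param mode "binocular", "left" or "right" (OP composition; OD always
#'   uses both eyes).
#' @return list of three `[frame, row, col]` arrays: `op_real`,
#'   `op_imag`, `od`, plus `frame_rate` and `stim_frames`.
#' @export
compose_feature_stacks <- function(cstack,
                                   mode = c("binocular", "left", "right")) {
  mode <- match.arg(mode)
  d <- dim(cstack$data)
  op_real <- array(0, d[3:5]); op_imag <- array(0, d[3:5])
  od <- array(0, d[3:5])
  for (oi in seq_along(cstack$orientations)) {
    th <- cstack$orientations[oi] * pi / 180
    RL <- cstack$data[oi, 1, , , ]
    RR <- cstack$data[oi, 2, , , ]
    Rbar <- switch(mode, binocular = 0.5 * (RL + RR), left = RL, right = RR)
    op_real <- op_real + Rbar * cos(2 * th)
    op_imag <- op_imag + Rbar * sin(2 * th)
    od <- od + RR - RL
  }
  list(op_real = op_real, op_imag = op_imag, od = od,
       frame_rate = cstack$frame_rate, stim_frames = cstack$stim_frames)
}

#' Single-shift extended spatial decorrelation of a map stack
#'
#' Blind source separation of a multi-frame map stack: (i) each frame is
#' centred (spatial mean removed); (ii) the frames are whitened by
#' eigendecomposition of the frame-by-frame covariance, making every
#' frame unit variance and mutually uncorrelated; (iii) the
#' cross-covariance between the whitened frames and their copies shifted
#' by `shift` pixels is formed over the valid overlap region,
#' symmetrised, and eigendecomposed, yielding an orthogonal rotation;
#' (iv) the rotated whitened frames are the spatial sources, and the
#' projection of the original frames onto them gives each source's
#' coefficient time series. Deterministic up to per-source sign.
#'
#' @details
#' Whitening amplifies every retained component to unit variance, so
#' components that merely sample the flat noise floor of the eigenvalue
#' spectrum would be blown up and then mixed into the signal source by
#' the finite-sample rotation. Components whose covariance eigenvalue is
#' indistinguishable from that bulk (below `bulk_factor` times the
#' median eigenvalue) are therefore dropped before rotation, along with
#' numerically rank-deficient ones; the number dropped is reported. Set
#' `bulk_factor = 0` to retain every component above `tol`.
#'
#' @param map_stack `[frame, row, col]` array (>= 2 frames).
#' @param shift integer `(rows, cols)` spatial shift, default `c(5, 5)`.
#' @param tol relative eigenvalue tolerance below which rank-deficient
#'   components are dropped.
#' @param bulk_factor multiple of the median eigenvalue below which a
#'   component counts as noise-floor bulk (0 disables).
#' @return object of class `source_set`: `sources` `[k, row, col]`,
#'   `coefficients` (frames x k), `rotation`, `n_dropped`, `frame_rate`,
#'   `stim_frames`.
#' @export
esd_unmix <- function(map_stack, shift = c(5, 5), tol = 1e-10,
                      bulk_factor = 10) {
  d <- dim(map_stack)
  stopifnot(length(d) == 3, d[1] >= 2,
            abs(shift[1]) < d[2], abs(shift[2]) < d[3])
  n_f <- d[1]; H <- d[2]; W <- d[3]
  F0 <- matrix(map_stack, n_f, H * W)  # frames x pixels
  F0 <- F0 - rowMeans(F0)

  C <- tcrossprod(F0) / ncol(F0)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 0)
  if (bulk_factor > 0)
    keep <- keep & eg$values > bulk_factor * median(eg$values)
  if (!any(keep)) keep <- seq_along(eg$values) == 1
  if (max(eg$values) <= 0) stop("map stack has no variance")
  n_dropped <- sum(!keep)
  Wm <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- Wm %*% F0  # whitened frames: tcrossprod(Z)/P = I

  ## shifted cross-covariance over the overlap region only (no wrap)
  px <- matrix(seq_len(H * W), H, W)
  r1 <- seq_len(H - abs(shift[1])); c1 <- seq_len(W - abs(shift[2]))
  ra <- if (shift[1] >= 0) r1 else r1 + abs(shift[1])
  ca <- if (shift[2] >= 0) c1 else c1 + abs(shift[2])
  i1 <- as.vector(px[ra, ca])
  i2 <- as.vector(px[ra + shift[1], ca + shift[2]])
  Cs <- Z[, i1, drop = FALSE] %*% t(Z[, i2, drop = FALSE]) / length(i1)
  Cs <- (Cs + t(Cs)) / 2
  eg2 <- eigen(Cs, symmetric = TRUE)
  V <- eg2$vectors  # orthogonal

  S <- t(V) %*% Z  # sources (unit variance, uncorrelated)
  A <- F0 %*% t(S) / ncol(F0)  # coefficients: F0 ~ A %*% S
  structure(list(
    sources = array(S, c(nrow(S), H, W)),
    coefficients = A,
    rotation = V, n_dropped = n_dropped,
    shift = shift), class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d sources (%d x %d px), shift (%d, %d)\n",
              dim(x$sources)[1], dim(x$sources)[2], dim(x$sources)[3],
              x$shift[1], x$shift[2]))
  invisible(x)
}

#' Stimulus-response template for source selection
#'
#' Zero during the pre-stimulus frames, a linear rise over the first half
#' of the stimulus frames up to a plateau of 1 held until stimulus
#' offset, then a linear decay back to zero: the canonical shape of the
#' stimulus-locked intrinsic-signal time course.
#'
#' @param n_frames total frames.
#' @param stim_frames stimulus-on frame indices.
#' @return numeric vector of length `n_frames`.
#' @export
response_template <- function(n_frames = 50, stim_frames = 11:35) {
  tmpl <- numeric(n_frames)
  on <- min(stim_frames); off <- max(stim_frames)
  rise <- on:min(on + 9, off)
  tmpl[rise] <- seq_along(rise) / length(rise)
  tmpl[(max(rise) + 1):off] <- 1
  if (off < n_frames) {
    dec <- (off + 1):n_frames
    tmpl[dec] <- pmax(0, 1 - seq_along(dec) / length(dec))
  }
  tmpl
}

#' Select the signal source and extract the feature map
#'
#' Subtracts the pre-stimulus mean from every source's coefficient time
#' series and scores each series by its Pearson correlation (in absolute
#' value, since source signs are arbitrary) with the rise-to-plateau
#' [response_template()]. Because the stimulus-locked signal usually
#' dominates the stack variance, its time course leaks weakly into the
#' coefficients of other sources, so several sources can match the
#' template. A single spatial shift cannot resolve rotations within a
#' subspace of sources sharing the same shifted autocorrelation, so when
#' the signal straddles several template-matching sources the map is
#' reconstructed from all of them, each weighted by its own coefficient
#' plateau (mean over `avg_frames`) - a weighting invariant to the
#' arbitrary per-source signs, which reduces to the classical
#' single-source readout when one source passes the threshold. The
#' overall sign makes the dominant plateau positive. The reconstruction
#' is averaged over `avg_frames` (the final stimulus frames) and
#' low-pass Gaussian filtered with `final_lp_sigma`.
#'
#' @param srcset a `source_set`.
#' @param prestim_frames pre-stimulus frame indices for baselining.
#' @param avg_frames frames averaged into the map.
#' @param final_lp_sigma final low-pass sigma in pixels.
#' @param selection "auto" or an explicit source index.
#' @param threshold minimum auto-selection score; below it an advisory
#'   error asks for a manual index.
#' @return the feature map (matrix), with attributes `source_index`,
#'   `score`, `scores`.
#' @export
extract_feature_map <- function(srcset, prestim_frames = 1:10,
                                avg_frames = 31:35, final_lp_sigma = 12,
                                selection = "auto", threshold = 0.6) {
  A <- srcset$coefficients
  n_f <- nrow(A)
  tmpl <- response_template(n_f,
                            (max(prestim_frames) + 1):max(avg_frames))
  Ab <- sweep(A, 2, colMeans(A[prestim_frames, , drop = FALSE]))
  scores <- apply(Ab, 2, function(a)
    if (sd(a) == 0) 0 else abs(cor(a, tmpl)))
  if (identical(selection, "auto")) {
    if (max(scores) < threshold)
      stop(sprintf(paste0(
        "no source coefficient series matches the stimulus-response ",
        "template (best score %.2f < %.2f); supply a manual source ",
        "index via `selection`"), max(scores), threshold))
    cand <- which(scores >= threshold)
  } else {
    cand <- as.integer(selection)
    stopifnot(all(cand >= 1), all(cand <= ncol(A)))
  }
  ## plateau-weighted reconstruction over the selected sources; each
  ## term is invariant to the source's arbitrary sign
  w <- colMeans(Ab[avg_frames, cand, drop = FALSE])
  m <- matrix(0, dim(srcset$sources)[2], dim(srcset$sources)[3])
  for (i in seq_along(cand)) m <- m + w[i] * srcset$sources[cand[i], , ]
  ## no sign fix needed: the reconstruction's own plateau is sum(w^2) > 0
  s <- cand[which.max(abs(w))]
  m <- gaussian_blur(m, final_lp_sigma)
  attr(m, "source_index") <- s
  attr(m, "sources_used") <- cand
  attr(m, "score") <- scores[s]
  attr(m, "scores") <- scores
  m
}

#' Full ESD map extraction from an imaging stack
#'
#' Convenience wrapper: align, average conditions, preprocess, compose
#' the three feature stacks, unmix each by single-shift ESD and extract
#' the OP-real, OP-imaginary and OD maps.
#'
#' @param stack an `imaging_stack`.
#' @param mode OP composition mode (see [compose_feature_stacks()]).
#' @param shift ESD spatial shift.
#' @param hp_sigma,lp_sigma,final_lp_sigma filter parameters in pixels.
#' @param align whether to run frame alignment first.
#' @param max_shift alignment search half-width.
#' @param selection source selection, "auto" or an index (recycled over
#'   the three maps).
#' @return list with `op` ([op_map()]), `od` ([od_map()]) and the three
#'   raw component maps.
#' @export
esd_extract_maps <- function(stack, mode = "binocular", shift = c(5, 5),
                             hp_sigma = 20, lp_sigma = 2,
                             final_lp_sigma = 12, align = FALSE,
                             max_shift = 10, selection = "auto") {
  if (align) stack <- align_frames(stack, max_shift = max_shift)
  cs <- average_conditions(stack)
  cs <- preprocess_frames(cs, hp_sigma, lp_sigma)
  fs <- compose_feature_stacks(cs, mode)
  one <- function(x) extract_feature_map(
    esd_unmix(x, shift), final_lp_sigma = final_lp_sigma,
    selection = selection)
  op_re <- one(fs$op_real)
  op_im <- one(fs$op_imag)
  od <- one(fs$od)
  field <- matrix(complex(real = op_re, imaginary = op_im),
                  nrow(op_re), ncol(op_re))
  list(op = op_map(field), od = od_map(od),
       op_real = op_re, op_imag = op_im, od_raw = od)
}

#' Vector-average baseline map readout
#'
#' The classical difference-map estimate used for red-light data: the
#' per-condition mean over the stimulus frames enters a complex sum over
#' orientations (doubled angles) for OP, and a right-minus-left sum for
#' OD. Provided as a comparison baseline for the ESD pipeline; it has no
#' source separation, so structured noise (blood-vessel artifacts) maps
#' straight into the estimates.
#'
#' @param cstack a `condition_stack` (typically preprocessed).
#' @return list with `op` ([op_map()]) and `od` ([od_map()]).
#' @export
vector_average_baseline <- function(cstack) {
  d <- dim(cstack$data)
  sf <- cstack$stim_frames
  op <- matrix(0 + 0i, d[4], d[5])
  od <- matrix(0, d[4], d[5])
  for (oi in seq_along(cstack$orientations)) {
    th <- cstack$orientations[oi] * pi / 180
    RL <- apply(cstack$data[oi, 1, sf, , ], c(2, 3), mean)
    RR <- apply(cstack$data[oi, 2, sf, , ], c(2, 3), mean)
    op <- op + 0.5 * (RL + RR) * exp(2i * th)
    od <- od + RR - RL
  }
  list(op = op_map(op), od = od_map(od))
}
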