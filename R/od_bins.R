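#' Ocular dominance quintile bins from column centre to border
#'
#' The positive (right-eye) and negative (left-eye) masked pixels of the
#' OD map are separately split into five equal-count bins by |OD| value,
#' then pooled: bin 1 contains the strongest fifth of each eye's pixels
#' (OD column centres), bin 5 the fifth closest to zero (OD borders).
#' Treating each eye's region separately respects OD borders and any
#' contralateral bias in the map.
#'
#' @param od an `od_map` with both signs present in the mask.
#' @return integer matrix (NA outside mask / at exact zeros beyond the
#'   binned sets) with values 1 (centre) to 5 (border).
#' @export
od_quintile_bins <- function(od) {
  stopifnot(inherits(od, "od_map"))
  v <- od$field
  bins <- matrix(NA_integer_, nrow(v), ncol(v))
  pos <- od$mask & v > 0
  neg <- od$mask & v < 0
  if (!any(pos) || !any(neg))
    stop("OD map must contain both signs within the mask")
  for (side in list(pos, neg)) {
    x <- abs(v[side])
    ## rank descending: strongest |OD| (column centre) -> bin 1
    rk <- rank(-x, ties.method = "first")
    bins[side] <- as.integer(ceiling(5 * rk / length(rk)))
  }
  bins
}

#' Pinwheel locations relative to OD column centres and borders
#'
#' Assigns each pinwheel the OD quintile bin ([od_quintile_bins()]) of
#' its nearest pixel and pools the two eyes, giving a 5-bin histogram
#' from OD column centre (bin 1) to border (bin 5). Under the null of
#' uniformly placed pinwheels every bin has expected proportion 0.2,
#' since the bins are equal-area by construction.
#'
#' @param pinwheels data.frame from [detect_pinwheels()].
#' @param od an `od_map`.
#' @return list with `counts` (length 5), `proportions` (sums to 1),
#'   `n_assigned` and `n_excluded`.
#' @export
pinwheel_od_histogram <- function(pinwheels, od) {
  bins <- od_quintile_bins(od)
  H <- nrow(od$field); W <- ncol(od$field)
  counts <- integer(5)
  excluded <- 0L
  for (k in seq_len(nrow(pinwheels))) {
    r <- min(max(round(pinwheels$row[k]), 1L), H)
    c <- min(max(round(pinwheels$col[k]), 1L), W)
    b <- bins[r, c]
    if (is.na(b)) {
      ## nearest binned pixel (pinwheel sits outside mask or on a zero)
      cand <- which(!is.na(bins), arr.ind = TRUE)
      d2 <- (cand[, 1] - pinwheels$row[k])^2 + (cand[, 2] - pinwheels$col[k])^2
      if (min(d2) > 2) {  # farther than one diagonal pixel: drop it
        warning("pinwheel outside mask excluded from OD histogram")
        excluded <- excluded + 1L
        next
      }
      b <- bins[cand[which.min(d2), , drop = FALSE]]
    }
    counts[b] <- counts[b] + 1L
  }
  n <- sum(counts)
  list(counts = counts,
       proportions = if (n > 0) counts / n else rep(NA_real_, 5),
       n_assigned = n, n_excluded = excluded)
}

#' Mean normalised orientation selectivity per OD quintile bin
#'
#' Selectivity is |OP field| normalised to its maximum within the mask;
#' means are taken over the pixels of each OD bin (1 = column centre,
#' 5 = border).
#'
#' @param op an `op_map`.
#' @param od an `od_map` on the same grid.
#' @return numeric vector of length 5.
#' @export
selectivity_by_od_bin <- function(op, od) {
  stopifnot(all(dim(op$field) == dim(od$field)))
  s <- op_selectivity(op)
  smax <- max(s[op$mask])
  if (smax == 0) stop("zero maximum selectivity")
  s <- s / smax
  bins <- od_quintile_bins(od)
  vapply(1:5, function(b) mean(s[which(bins == b)]), numeric(1))
}
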