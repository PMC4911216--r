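#' Orientation preference map
#'
#' A complex-valued image whose angle is twice the preferred orientation
#' (so the 180-degree periodicity of orientation becomes 360-degree
#' periodicity of the field) and whose magnitude is the orientation
#' selectivity, plus a boolean analysis mask.
#'
#' @param field complex matrix.
#' @param mask logical matrix of the same dimension; defaults to the full
#'   grid.
#' @return object of class `op_map` with elements `field`, `mask`.
#' @export
op_map <- function(field, mask = NULL) {
  stopifnot(is.matrix(field))
  if (!is.complex(field)) {
    ## interpret a real matrix as orientation angles in degrees, unit
    ## selectivity
    field <- matrix(complex(argument = 2 * field * pi / 180),
                    nrow(field), ncol(field))
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field), ncol(field))
  stopifnot(is.logical(mask), all(dim(mask) == dim(field)))
  structure(list(field = field, mask = mask), class = "op_map")
}

#' Ocular dominance map
#'
#' A signed scalar image: negative values prefer the left eye, positive
#' the right eye; zero crossings are OD borders, extrema are OD column
#' centres.
#'
#' @param field numeric matrix.
#' @param mask logical matrix; defaults to the full grid.
#' @return object of class `od_map`.
#' @export
od_map <- function(field, mask = NULL) {
  stopifnot(is.matrix(field), is.numeric(field))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field), ncol(field))
  stopifnot(is.logical(mask), all(dim(mask) == dim(field)))
  structure(list(field = field, mask = mask), class = "od_map")
}

#' Preferred orientation of an OP map in degrees
#' @param op an `op_map`.
#' @return numeric matrix of orientations in [0, 180).
#' @export
op_angle <- function(op) {
  wrap_orientation(Arg(op$field) * 90 / pi)
}

#' Orientation selectivity (field magnitude) of an OP map
#' @param op an `op_map`.
#' @return numeric matrix.
#' @export
op_selectivity <- function(op) Mod(op$field)

#' Default analysis mask from orientation selectivity
#'
#' Keeps pixels lying in regions whose smoothed selectivity exceeds a
#' lower quantile of the smoothed-selectivity distribution, the
#' package's stand-in for removing areas without strong orientation
#' preference. The smoothing matters: pinwheel cores are pointwise
#' selectivity zeros sitting inside well-tuned domains, and a pixelwise
#' threshold would cut out exactly those singularities; a region-level
#' threshold keeps them while still discarding genuinely weakly tuned
#' territory.
#'
#' @param op an `op_map`.
#' @param quantile_cut quantile of smoothed |field| below which pixels
#'   are masked out (default 0.1).
#' @param smooth_sigma Gaussian sigma (pixels) of the selectivity
#'   smoothing.
#' @return logical matrix.
#' @export
selectivity_mask <- function(op, quantile_cut = 0.1, smooth_sigma = 3) {
  s <- gaussian_blur(op_selectivity(op), smooth_sigma)
  s > quantile(s, quantile_cut)
}

#' @export
print.op_map <- function(x, ...) {
  cat(sprintf("<op_map> %d x %d, %d masked-in pixels\n",
              nrow(x$field), ncol(x$field), sum(x$mask)))
  invisible(x)
}

#' @export
print.od_map <- function(x, ...) {
  f <- x$field[x$mask]
  cat(sprintf("<od_map> %d x %d, range [%.3g, %.3g]\n",
              nrow(x$field), ncol(x$field), min(f), max(f)))
  invisible(x)
}

#' Write OP/OD maps to a directory of TSV matrices plus JSON metadata
#'
#' Plain-text on-disk schema: `op_real.tsv`, `op_imag.tsv`, `od.tsv`,
#' `mask.tsv` (tab-separated matrices) and `meta.json`.
#'
#' @param maps list with elements `op` and `od` as from [extract_maps()].
#' @param dir output directory (created if needed).
#' @param meta optional named list written into `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_maps <- function(maps, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f)
    write.table(m, file.path(dir, f), sep = "\t",
                row.names = FALSE, col.names = FALSE)
  wr(Re(maps$op$field), "op_real.tsv")
  wr(Im(maps$op$field), "op_imag.tsv")
  wr(maps$od$field, "od.tsv")
  wr(maps$op$mask * 1L, "mask.tsv")
  meta$dim <- dim(maps$od$field)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read maps written by [write_maps()]
#' @param dir directory containing the TSV/JSON schema.
#' @return list with `op`, `od` and `meta`.
#' @export
read_maps <- function(dir) {
  rd <- function(f) as.matrix(read.table(file.path(dir, f), sep = "\t"))
  re <- rd("op_real.tsv"); im <- rd("op_imag.tsv")
  od <- rd("od.tsv")
  mask <- rd("mask.tsv") > 0
  dimnames(od) <- dimnames(mask) <- NULL
  field <- matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
  list(op = op_map(field, mask), od = od_map(od, mask),
       meta = jsonlite::read_json(file.path(dir, "meta.json")))
}
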