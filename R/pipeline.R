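#' Map statistics summary
#'
#' Computes the standard statistics bundle for an OP/OD map pair:
#' pinwheels, map wavelength, pinwheel density, the 5-bin OD quintile
#' histogram of pinwheel locations, mean normalised selectivity per OD
#' bin, orientation proportions with period-90 and period-180 sine fits,
#' and crossing angles.
#'
#' @param op an `op_map`.
#' @param od an `od_map` on the same grid.
#' @param mask_quantile optional smoothed-selectivity quantile for a
#'   [selectivity_mask()] applied to both maps; the default NULL keeps
#'   the maps' own masks (simulated maps are analysed over the full
#'   grid; imaging maps carry their own analysis mask or can pass e.g.
#'   0.1 here).
#' @return named list of statistics (JSON-serialisable apart from the
#'   pinwheel table).
#' @export
map_statistics <- function(op, od, mask_quantile = NULL) {
  if (!is.null(mask_quantile)) {
    m <- selectivity_mask(op, mask_quantile)
    op$mask <- m; od$mask <- m
  }
  pw <- detect_pinwheels(op)
  lam <- map_wavelength(op)
  oh <- orientation_proportions(op)
  out <- list(
    n_pinwheels = nrow(pw),
    wavelength = lam,
    pinwheel_density = if (nrow(pw) > 0)
      pinwheel_density(op, pw, lam)$density else NA_real_,
    od_bin_proportions = if (nrow(pw) > 0)
      pinwheel_od_histogram(pw, od)$proportions else rep(NA_real_, 5),
    selectivity_by_od_bin = selectivity_by_od_bin(op, od),
    orientation_proportions = oh$proportions,
    sine_fit_90 = unclass_fit(fit_sine_distribution(oh$proportions, 90,
                                                    oh$centers)),
    sine_fit_180 = unclass_fit(fit_sine_distribution(oh$proportions, 180,
                                                     oh$centers)),
    crossing_angles_mean = {
      ca <- crossing_angles(op, od)
      if (length(ca)) mean(ca) else NA_real_
    })
  attr(out, "pinwheels") <- pw
  out
}

unclass_fit <- function(f)
  list(amplitude = f$amplitude, phase = f$phase, offset = f$offset,
       period = f$period, r_squared = f$r_squared, peaks = f$peaks)

#' Run a multi-stage analysis pipeline
#'
#' Orchestrates end-to-end runs with one master seed: per stage, the
#' seed is combined with the stage index so fixed-seed comparisons
#' across parameter values (e.g. the same initial cortex at different
#' over-representation strengths) are possible. Stages:
#' \describe{
#'   \item{simulate}{elastic-net simulation (params: a [sim_config()]
#'     or arguments for one) -> maps + statistics}
#'   \item{synth_stack}{parametric ground truth + synthetic imaging
#'     stack -> ESD extraction -> maps + statistics}
#'   \item{fit_units}{synthetic unit population -> tuning fits +
#'     population histogram}
#' }
#' Each stage writes its outputs (TSV maps, JSON statistics) under
#' `out_dir` and the run finishes with a machine-readable
#' `summary.json`. A failing stage halts the run with the stage named;
#' outputs of completed stages are retained.
#'
#' @param stages character vector of stage names, run in order.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param params named list of per-stage parameter lists.
#' @return (invisibly) the summary list; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(stages = c("simulate"), out_dir, seed = 1,
                         params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = seed, stages = as.list(stages))
  for (si in seq_along(stages)) {
    st <- stages[si]
    res <- tryCatch(
      switch(st,
        simulate = stage_simulate(out_dir, seed, params$simulate),
        synth_stack = stage_synth_stack(out_dir, seed,
                                        params$synth_stack),
        fit_units = stage_fit_units(out_dir, seed, params$fit_units),
        stop(sprintf("unknown stage '%s'", st))),
      error = function(e)
        stop(sprintf("pipeline halted in stage '%s': %s", st,
                     conditionMessage(e)), call. = FALSE))
    summary[[st]] <- res
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

stage_simulate <- function(out_dir, seed, p) {
  cfg <- if (inherits(p, "sim_config")) p
         else do.call(sim_config, c(list(seed = seed), p))
  sheet <- run_simulation(cfg)
  maps <- extract_maps(sheet)
  dir <- file.path(out_dir, "simulate")
  write_maps(maps, dir,
             meta = list(iterations = attr(sheet, "iterations"),
                         final_K = attr(sheet, "final_K"),
                         alpha_over = cfg$alpha_over, seed = cfg$seed))
  stats <- map_statistics(maps$op, maps$od)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stats
}

stage_synth_stack <- function(out_dir, seed, p) {
  if (is.null(p)) p <- list()
  truth <- do.call(synth_maps, c(list(seed = seed),
                                 p$maps %||% list(size = 96,
                                                  wavelength = 24)))
  recipe <- do.call(stack_recipe, p$recipe %||% list())
  stack <- synth_stack(truth, recipe, seed = seed)
  maps <- esd_extract_maps(stack,
                           final_lp_sigma = p$final_lp_sigma %||% 3)
  dir <- file.path(out_dir, "synth_stack")
  write_maps(maps, dir, meta = list(seed = seed))
  stats <- list(
    op_recovery_cor = map_cor(maps$op$field, truth$op$field),
    od_recovery_cor = abs(cor(as.vector(maps$od$field),
                              as.vector(truth$od$field))))
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stats
}

stage_fit_units <- function(out_dir, seed, p) {
  if (is.null(p)) p <- list()
  units <- do.call(synth_units,
                   c(list(seed = seed), p[setdiff(names(p), "")]))
  fits <- fit_units(units)
  dir <- file.path(out_dir, "fit_units")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(fits, file.path(dir, "fits.tsv"), sep = "\t",
              row.names = FALSE)
  hist <- population_orientation_histogram(fits$theta_p)
  stats <- list(n_units = nrow(fits),
                median_mi = median(fits$mi),
                r2_period90 = hist$fit_90$r_squared,
                r2_period180 = hist$fit_180$r_squared)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation magnitude between two complex maps
#'
#' Absolute value of the complex correlation between two complex-valued
#' fields (invariant to an overall scale and sign/phase flip), the
#' round-trip score used for planted-map recovery.
#'
#' @param a,b complex matrices of the same dimension.
#' @return |r| in [0, 1].
#' @export
map_cor <- function(a, b) {
  a <- as.vector(a) - mean(a); b <- as.vector(b) - mean(b)
  Mod(sum(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}
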