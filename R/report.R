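# Tabular output writers and run manifests used by the analysis scripts.

#' Write a tidy cohort trace to CSV
#'
#' One row per (cycle, state) with the occupancy fraction, plus the
#' per-cycle discounted cost and QALY increments merged in.
#'
#' @param result A `bph_result` from [run_cohort()] with a trace.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(result, path) {
  if (is.null(result$trace)) stop("result carries no trace", call. = FALSE)
  tr <- result$trace
  cs <- attr(tr, "cycle_summary")
  out <- merge(tr, cs, by = "cycle", sort = FALSE)
  names(out)[names(out) == "cost"] <- "cycle_cost"
  names(out)[names(out) == "qaly"] <- "cycle_qaly"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an incremental cost-effectiveness report as JSON
#'
#' Mirrors the base-case results layout: per-category average costs,
#' episode counts and QALYs per arm, and the incremental summary.
#'
#' @param result_combination,result_monotherapy `bph_result` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_icer_report <- function(result_combination, result_monotherapy, path) {
  ic <- compute_icer(result_combination, result_monotherapy)
  arm_block <- function(r) list(
    "Average cost per patient (US$ 2018)" = c(
      list(Drug = unname(r$cost["drug"]), BPH = unname(r$cost["bph"]),
           AUR = unname(r$cost["aur"]), TURP = unname(r$cost["turp"]),
           `Medical intervention` = unname(r$cost["medical"]),
           Total = r$cost_total)),
    "Health outcomes per patient (by episode)" = list(
      BPH = unname(r$episodes["bph"]), AUR = unname(r$episodes["aur"]),
      TURP = unname(r$episodes["turp"]),
      Death = unname(r$episodes["deaths"]), QALY = r$qaly))
  doc <- list(
    horizon_years = result_combination$horizon_years,
    `Combination therapy` = arm_block(result_combination),
    Monotherapy = arm_block(result_monotherapy),
    Difference = list(delta_cost = ic$delta_cost,
                      delta_qaly = ic$delta_qaly,
                      `Cost per QALY gained` = ic$icer,
                      label = ic$label))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write sensitivity-analysis outputs to CSV
#'
#' `write_tornado_csv` writes the one-way table sorted by spread;
#' `write_psa_csv` writes the scatter (draw, deltas, quadrant);
#' `write_ceac_csv` writes the acceptability curve.
#'
#' @param x The `bph_tornado`, `bph_psa` or `bph_ceac` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tornado_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_psa_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado_csv
#' @export
write_ceac_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run: the subcommand, seed,
#' horizon, configuration file and its hash, timestamp and package
#' version.  Rerunning with an identical manifest reproduces identical
#' numbers (deterministic engines bit-wise; seeded stochastic runs
#' number-wise).
#'
#' @param subcommand Analysis step name (e.g. `"basecase"`).
#' @param seed Seed used, if any.
#' @param horizon_years Horizon(s) run.
#' @param config Path to the configuration file used, if any.
#' @return Named list.
#' @export
run_manifest <- function(subcommand, seed = NA, horizon_years = NA,
                         config = NA) {
  list(subcommand = subcommand,
       seed = seed,
       horizon_years = horizon_years,
       config = config,
       config_md5 = if (!is.na(config) && file.exists(config))
         unname(tools::md5sum(config)) else NA,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       package_version = as.character(utils::packageVersion("bphce")))
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param dir Output directory; the manifest is written as
#'   `manifest_<subcommand>.json`.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("manifest_", manifest$subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
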