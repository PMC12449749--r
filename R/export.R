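# CSV / JSON export of runs, curves and events.

#' Write snapshot profiles of a run to CSV
#'
#' One file per stored snapshot (`snapshot_<time>s.csv`) with columns `x_mm`,
#' one column per constituent (mol/m^3), `pH` and `conductivity_S_m`.
#'
#' @param run A `ce_run`.
#' @param dir Output directory (created if needed).
#' @param times Snapshot times to write (default: all stored).
#' @return Paths written, invisibly.
#' @export
write_snapshots <- function(run, dir, times = run$times) {
  stopifnot(inherits(run, "ce_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in times) {
    snap <- snapshot_profile(run, t)
    sp <- cpp_speciate(snap, run$system$cpp)
    df <- data.frame(x_mm = run$x_mm, t(snap), check.names = FALSE)
    df$pH <- -log10(sp$h)
    df$conductivity_S_m <- sp$kappa
    p <- file.path(dir, sprintf("snapshot_%gs.csv", attr(snap, "time")))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the current trace of a run to CSV
#' @param run A `ce_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_current_trace <- function(run, path) {
  utils::write.csv(current_trace(run), path, row.names = FALSE)
  invisible(path)
}

#' Write events to CSV
#' @param events A list of `ce_event` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- do.call(rbind, lapply(events, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a mobility curve to CSV
#'
#' Columns `c_ligand_mM` and `mu_eff_e-8` (units of 1e-8 m^2/(V s)).
#'
#' @param curve A `ce_mobility_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(curve, path) {
  df <- data.frame(c_ligand_mM = curve$c_ligand_mM,
                   `mu_eff_e-8` = curve$mu_eff_e8, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Echoes everything needed to reproduce a run bit-identically: scenario
#' name, grid, CFL safety, limiter, drive parameters and package version.
#' The pipeline is deterministic, so re-running an identical manifest
#' reproduces the outputs exactly.
#'
#' @param run A `ce_run`.
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(run) {
  stopifnot(inherits(run, "ce_run"))
  cfg <- run$config
  list(scenario = cfg$name, n_cells = cfg$n_cells, until_s = cfg$until,
       safety = cfg$safety, limiter = cfg$limiter, boundary = cfg$boundary,
       voltage_V = cfg$voltage, diameter_m = cfg$diameter,
       bulk_velocity_m_s = cfg$bulk_velocity, steps = run$steps,
       package = "cesim",
       version = as.character(utils::packageVersion("cesim")))
}

#' Write the figure-pack of a run
#'
#' Snapshot CSVs at the stored times, the current trace and the manifest, in
#' one directory.
#'
#' @param run A `ce_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
figure_pack <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_snapshots(run, dir)
  write_current_trace(run, file.path(dir, "current_trace.csv"))
  jsonlite::write_json(run_manifest(run), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
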