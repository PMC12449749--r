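# Scenario library: initial column states for the partial-filling
# configurations studied in the simulations.

scenario_library <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "cesim",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Names of the packaged scenarios
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() names(scenario_library()$scenarios)

#' Build a packaged scenario
#'
#' Constructs the fully specified initial column state for one of the
#' packaged partial-filling configurations: anodic section filled with the
#' selector-containing BGE, sample compartment centred at 25 mm, selector
#' plug of the stated length immediately cathodic of the sample, selector-
#' free catholyte beyond it, 400 V across 50 mm. Sodium scales
#' stoichiometrically with the selector (19 mM -> 247 mM NaOH, 7.6 -> 98.8,
#' 3.8 -> 49.4, 1.9 -> 24.7).
#'
#' @param name Scenario name (see [scenario_names()]).
#' @param system A `ce_system`; defaults to [ketamine_cd_system()].
#' @param n_cells Number of grid cells.
#' @return A list of class `ce_scenario` with elements `state` (a
#'   [build_column()] result) and `config` (name, voltage, diameter,
#'   duration, zone geometry).
#' @examples
#' sc <- scenario("fig2_base", n_cells = 500)
#' sc$config$voltage
#' @export
scenario <- function(name, system = ketamine_cd_system(), n_cells = 2000) {
  lib <- scenario_library()
  if (!name %in% names(lib$scenarios))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib$scenarios), collapse = ", "))
  p <- utils::modifyList(lib$defaults,
                         lib$scenarios[[name]] %||% list(),
                         keep.null = FALSE)
  cd <- p$cd_mM
  naoh <- p$naoh_mM %||% (13 * cd)
  bge <- bge_composition(cd = cd, naoh = naoh)
  cath <- catholyte_composition()
  samp <- sample_composition(analyte_uM = p$analyte_uM,
                             acetic_acid = p$acetic_mM,
                             bge_fraction = p$sample_bge_fraction, bge = bge)
  s0 <- 25 - p$sample_mm / 2
  s1 <- 25 + p$sample_mm / 2
  plug_end <- s1 + p$plug_mm
  L <- p$column_mm

  if (p$gradient_mm > 0) {
    plug_start <- s1 + p$gradient_mm
    zones <- list(ce_zone(0, s0, bge),
                  ce_zone(s0, s1, samp),
                  ce_zone(s1, plug_start, cath, ramp = "linear"),
                  ce_zone(plug_start, plug_end, bge),
                  ce_zone(plug_end, L, cath))
    # junctions: BGE|sample, sample|ramp, ramp|plug (continuous), plug|cath
    widths <- c(p$boundary_mm, p$boundary_mm, p$other_boundary_mm,
                p$other_boundary_mm)
  } else {
    plug_start <- s1
    zones <- list(ce_zone(0, s0, bge),
                  ce_zone(s0, s1, samp),
                  ce_zone(plug_start, plug_end, bge),
                  ce_zone(plug_end, L, cath))
    widths <- c(p$boundary_mm, p$boundary_mm, p$other_boundary_mm)
  }

  state <- build_column(zones, system, n_cells = n_cells,
                        boundary_width = widths)
  config <- list(name = name, voltage = p$voltage,
                 diameter = p$diameter_um * 1e-6, duration = p$duration_s,
                 sample_mm = c(s0, s1), plug_mm = c(plug_start, plug_end),
                 cd_mM = cd, naoh_mM = naoh, column_mm = L,
                 description = p$description %||% name,
                 snapshot_times = c(0, 1, 5, 10, 25, 35, 45, 60, 90, 120, 180))
  config$snapshot_times <-
    config$snapshot_times[config$snapshot_times <= p$duration_s]
  structure(list(state = state, config = config), class = "ce_scenario")
}

#' @export
print.ce_scenario <- function(x, ...) {
  cat(sprintf("<ce_scenario> %s: %s\n", x$config$name, x$config$description))
  cat(sprintf("  %g mm column, sample %.2f-%.2f mm, plug %.2f-%.2f mm, %g V, %g s\n",
              x$config$column_mm, x$config$sample_mm[1], x$config$sample_mm[2],
              x$config$plug_mm[1], x$config$plug_mm[2], x$config$voltage,
              x$config$duration))
  invisible(x)
}
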