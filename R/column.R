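#' Define a column zone
#'
#' Zones tile the column without gaps or overlaps. A `ramp = "linear"` zone
#' interpolates every constituent linearly from its own composition at
#' `start` to the next zone's composition at `end` (used for shallow selector
#' gradients); plateau zones hold their composition and are joined to their
#' neighbours by smooth raised-cosine transitions of the stated boundary
#' width.
#'
#' @param start,end Zone limits in mm from the anodic end.
#' @param comp Composition (named vector, mol/m^3).
#' @param ramp `"none"` (plateau) or `"linear"`.
#' @return An object of class `ce_zone`.
#' @export
ce_zone <- function(start, end, comp, ramp = c("none", "linear")) {
  ramp <- match.arg(ramp)
  stopifnot(is.finite(start), is.finite(end), start >= 0, end > start)
  structure(list(start = start, end = end, comp = comp, ramp = ramp),
            class = "ce_zone")
}

#' Build a discretized initial column state
#'
#' Lays the zones down on a uniform grid of cell centers. Plateau junctions
#' are smoothed with a raised-cosine transition of total span equal to the
#' boundary width, centred on the nominal zone edge, so integrated amounts
#' equal the analytic zone integrals; `boundary_width = 0` recovers exact
#' steps. End cells are the reservoir compositions.
#'
#' @param zones List of [ce_zone()] objects tiling `[0, L]`.
#' @param system A `ce_system`.
#' @param n_cells Number of uniform cells (>= 100).
#' @param boundary_width Transition span in mm; a scalar, or one value per
#'   interior junction.
#' @return An object of class `ce_column` with `x_mm` (cell centers), `dx_mm`,
#'   `totals` (constituent x cell matrix, mol/m^3), `length_mm`, `system`.
#' @examples
#' sys <- ketamine_cd_system()
#' zones <- list(ce_zone(0, 25, bge_composition()),
#'               ce_zone(25, 50, catholyte_composition()))
#' col <- build_column(zones, sys, n_cells = 200)
#' @export
build_column <- function(zones, system, n_cells = 2000, boundary_width = 0.05) {
  stopifnot(inherits(system, "ce_system"), n_cells >= 100,
            length(zones) >= 1,
            all(vapply(zones, inherits, TRUE, "ce_zone")))
  ns <- vapply(zones, `[[`, 0, "start")
  ne <- vapply(zones, `[[`, 0, "end")
  if (ns[1] != 0) stop("zones must start at 0 mm")
  if (length(zones) > 1 && any(abs(ns[-1] - ne[-length(ne)]) > 1e-12))
    stop("zones must tile the column without gaps or overlaps")
  L <- ne[length(ne)]
  nj <- length(zones) - 1
  w <- rep_len(boundary_width, max(nj, 1))
  if (any(w < 0)) stop("boundary_width must be >= 0")
  if (nj > 0) {
    span <- ne - ns
    for (j in seq_len(nj))
      if (w[j] > min(span[j], span[j + 1]))
        stop("boundary_width exceeds the span of an adjacent zone")
  }

  dx <- L / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  nm <- constituent_names(system)
  comps <- vapply(zones, function(z) composition(z$comp, system),
                  numeric(length(nm)))  # nm x nzones
  totals <- matrix(0, nrow = length(nm), ncol = n_cells,
                   dimnames = list(nm, NULL))

  # base profile: plateau or linear ramp per zone
  zone_of <- findInterval(x, c(ns, L), rightmost.closed = TRUE)
  zone_of[zone_of < 1] <- 1
  zone_of[zone_of > length(zones)] <- length(zones)
  for (zi in seq_along(zones)) {
    idx <- which(zone_of == zi)
    if (!length(idx)) next
    if (zones[[zi]]$ramp == "linear" && zi < length(zones)) {
      f <- (x[idx] - ns[zi]) / (ne[zi] - ns[zi])
      totals[, idx] <- comps[, zi] %o% (1 - f) + comps[, zi + 1] %o% f
    } else {
      totals[, idx] <- comps[, zi]
    }
  }

  # raised-cosine smoothing at plateau junctions
  if (nj > 0) {
    for (j in seq_len(nj)) {
      if (w[j] <= 0) next
      if (zones[[j]]$ramp == "linear")
        next  # a ramp ends at the next zone's composition: already continuous
      xj <- ne[j]
      idx <- which(x > xj - w[j] / 2 & x < xj + w[j] / 2)
      if (!length(idx)) next
      s <- 0.5 * (1 - cos(pi * (x[idx] - xj + w[j] / 2) / w[j]))
      totals[, idx] <- comps[, j] %o% (1 - s) + comps[, j + 1] %o% s
    }
  }

  structure(list(x_mm = x, dx_mm = dx, totals = totals, length_mm = L,
                 boundary_width = w, system = system),
            class = "ce_column")
}

#' @export
print.ce_column <- function(x, ...) {
  cat(sprintf("<ce_column> %.3g mm, %d cells (dx = %.3g um), %d constituents\n",
              x$length_mm, ncol(x$totals), x$dx_mm * 1000, nrow(x$totals)))
  invisible(x)
}

#' Integrated amount of a constituent over (part of) the column
#'
#' @param column A `ce_column` (or a bare totals matrix with `x_mm`/`dx_mm`
#'   supplied via a `ce_column`).
#' @param constituent Constituent name.
#' @param from,to Limits in mm (defaults: whole column).
#' @return Amount per unit cross-section, mol/m^2 (dx in m times mol/m^3).
#' @export
zone_amount <- function(column, constituent, from = -Inf, to = Inf) {
  stopifnot(inherits(column, "ce_column"))
  sel <- column$x_mm >= from & column$x_mm <= to
  sum(column$totals[constituent, sel]) * column$dx_mm * 1e-3
}
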