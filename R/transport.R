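#' Solve the electric field over a column state at constant voltage
#'
#' Speciate every cell, compute the conductivity profile, and integrate the
#' series resistance: j = U / sum(dx / kappa), E(x) = j / kappa(x),
#' I = j * pi * (d/2)^2.
#'
#' @param state A `ce_column`.
#' @param voltage Applied voltage in V.
#' @param diameter Capillary inner diameter in m.
#' @return An object of class `ce_field` with `kappa` (S/m per cell), `E`
#'   (V/m per cell), `current_density` (A/m^2), `current` (A), `current_uA`,
#'   `voltage`, `pH` per cell.
#' @examples
#' sc <- scenario("fig2_base", n_cells = 500)
#' field_solve(sc$state)$current_uA
#' @export
field_solve <- function(state, voltage = 400, diameter = 50e-6) {
  stopifnot(inherits(state, "ce_column"), voltage >= 0, diameter > 0)
  sp <- cpp_speciate(state$totals, state$system$cpp)
  kappa <- sp$kappa
  if (any(kappa <= 0)) stop("non-positive conductivity")
  dx <- state$dx_mm * 1e-3
  j <- if (voltage > 0) voltage / sum(dx / kappa) else 0
  area <- pi * (diameter / 2)^2
  structure(list(kappa = kappa, E = j / kappa, current_density = j,
                 current = j * area, current_uA = j * area * 1e6,
                 voltage = voltage, diameter = diameter,
                 pH = -log10(sp$h), x_mm = state$x_mm),
            class = "ce_field")
}

#' @export
print.ce_field <- function(x, ...) {
  cat(sprintf("<ce_field> %g V, I = %.4g uA, kappa in [%.3g, %.3g] S/m\n",
              x$voltage, x$current_uA, min(x$kappa), max(x$kappa)))
  invisible(x)
}

#' Largest stable explicit time step
#'
#' dt = safety * min(dx / max|v|, dx^2 / (2 max D)) over all transported
#' forms and cells, with v = u * E locally and D from the Nernst-Einstein
#' relation.
#'
#' @param state A `ce_column`.
#' @param field A matching `ce_field`.
#' @param safety CFL safety factor in (0, 1].
#' @param bulk_velocity Optional constant bulk velocity (m/s).
#' @return Time step in s.
#' @export
stable_dt <- function(state, field, safety = 0.4, bulk_velocity = 0) {
  stopifnot(inherits(state, "ce_column"), inherits(field, "ce_field"),
            safety > 0, safety <= 1)
  fd <- form_table(state$system)
  dx <- state$dx_mm * 1e-3
  vmax <- max(abs(fd$su)) * max(abs(field$E)) + abs(bulk_velocity)
  dmax <- max(fd$D)
  adv <- if (vmax > 0) dx / vmax else Inf
  safety * min(adv, dx^2 / (2 * dmax))
}

# Internal: map the limiter argument (logical or name) to the engine code.
limiter_code <- function(limiter) {
  if (is.logical(limiter)) return(if (limiter) 2L else 0L)
  match(match.arg(as.character(limiter), c("none", "minmod", "mc")),
        c("none", "minmod", "mc")) - 1L
}

# Internal: the transported forms of a system (signed mobility, diffusivity),
# mirroring the compiled stepper's form set.
form_table <- function(system) {
  cs <- system$constituents
  k <- system$constants
  RTF <- k$gas_constant * k$temperature / k$faraday
  su <- D <- numeric(0)
  owner <- character(0)
  for (z in cs) {
    if (z$kind == "multi-site-anion") {
      su <- c(su, -z$ionic_mobility)
      D <- c(D, RTF * z$ionic_mobility / z$site_count)
      owner <- c(owner, z$name)
    } else {
      sgn <- if (z$kind == "weak-base") 1 else -1
      su <- c(su, sgn * z$ionic_mobility, 0)
      D <- c(D, RTF * z$ionic_mobility, RTF * z$ionic_mobility)
      owner <- c(owner, z$name, z$name)
    }
  }
  for (cx in system$complexations) {
    zl <- cs[[cx$ligand]]$site_count
    su <- c(su, cx$complex_mobility)
    D <- c(D, RTF * abs(cx$complex_mobility) / max(zl - 1, 1))
    owner <- c(owner, paste0(cx$analyte, ".", cx$ligand))
  }
  data.frame(owner = owner, su = su, D = D, stringsAsFactors = FALSE)
}

#' Constituent fluxes at the interior cell faces
#'
#' Sum over each constituent's forms (charged, neutral, complexes) of
#' sign(z) u c E - D dc/dx; a complex contributes to both its analyte's and
#' its ligand's flux. Water ions are not transported (electroneutrality sets
#' them) but contribute to the conductivity that shapes E.
#'
#' @param state A `ce_column`.
#' @param field A matching `ce_field` (used for its voltage).
#' @param limiter Limiter choice (see [run_simulation()]).
#' @param bulk_velocity Constant bulk velocity (m/s), default 0.
#' @return Matrix (constituent x face) of fluxes in mol/(m^2 s) at the
#'   N - 1 interior faces.
#' @export
constituent_fluxes <- function(state, field, limiter = TRUE,
                               bulk_velocity = 0) {
  stopifnot(inherits(state, "ce_column"), inherits(field, "ce_field"))
  fl <- cpp_fluxes(state$totals, state$system$cpp, state$dx_mm * 1e-3,
                   field$voltage, limiter_code(limiter), bulk_velocity)
  rownames(fl) <- rownames(state$totals)
  fl
}

#' Advance a column state by a fixed time step
#'
#' One explicit finite-volume step: per-cell equilibrium speciation, field
#' solve, upwind (optionally minmod-limited) advection plus central diffusion
#' of every form, reservoir end cells re-imposed.
#'
#' @param state A `ce_column`.
#' @param dt Time step in s; must not exceed the stable limit.
#' @param voltage,diameter Drive parameters.
#' @param limiter Limiter choice (see [run_simulation()]).
#' @param boundary `"dirichlet"` (reservoir ends) or `"closed"` (zero-flux).
#' @param bulk_velocity Constant bulk velocity (m/s).
#' @return The updated `ce_column`.
#' @export
step_state <- function(state, dt, voltage = 400, diameter = 50e-6,
                       limiter = TRUE, boundary = c("dirichlet", "closed"),
                       bulk_velocity = 0) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(state, "ce_column"), dt > 0)
  res <- cpp_advance(state$totals, state$system$cpp, state$dx_mm * 1e-3,
                     pi * (diameter / 2)^2, voltage, 0, dt, 1.0,
                     limiter_code(limiter), boundary == "dirichlet",
                     bulk_velocity, dt, numeric(0), numeric(0), fixed_dt = dt)
  out <- state
  out$totals <- res$totals
  dimnames(out$totals) <- dimnames(state$totals)
  out
}

#' Run a scenario (or column state) to a target time
#'
#' Integrates the coupled electromigration-diffusion continuity equations for
#' the constituent totals at constant voltage, under local equilibrium and
#' electroneutrality, with an adaptive CFL-limited explicit step. Snapshots of
#' the full column state and the current trace are recorded. The pipeline is
#' deterministic: identical inputs give bit-identical outputs.
#'
#' @param x A scenario name, a `ce_scenario`, or a `ce_column` (then `voltage`
#'   etc. must be supplied).
#' @param until End time in s (defaults to the scenario duration).
#' @param n_cells Grid cells (used when `x` is a scenario name).
#' @param safety CFL safety factor.
#' @param limiter Slope-limited second-order reconstruction: `TRUE` (the
#'   default monotonized-central limiter), `"mc"`, `"minmod"`, or
#'   `FALSE`/`"none"` for plain first-order upwind.
#' @param snapshot_times Times (s) at which to store the column state; the
#'   default is the scenario's figure times plus `until`.
#' @param snapshot_dt Alternative to `snapshot_times`: uniform spacing in s.
#' @param trace_dt Current-trace sampling interval in s.
#' @param boundary `"dirichlet"` reservoirs or `"closed"` box.
#' @param bulk_velocity Constant bulk velocity in m/s (0 = quiescent column;
#'   a small positive value mimics residual electroosmotic flow
#'   qualitatively).
#' @param voltage,diameter Drive parameters (defaults from the scenario).
#' @param system System used when `x` is a scenario name.
#' @return An object of class `ce_run`: `times`, `snapshots` (list of
#'   constituent x cell matrices), `trace` (data.frame `t_s`, `I_uA`),
#'   `x_mm`, `dx_mm`, `system`, `config`, `steps`.
#' @examples
#' \donttest{
#' run <- run_simulation("fig2_base", until = 1, n_cells = 500)
#' tail(current_trace(run), 1)
#' }
#' @export
run_simulation <- function(x, until = NULL, n_cells = 2000, safety = 0.4,
                           limiter = TRUE, snapshot_times = NULL,
                           snapshot_dt = NULL, trace_dt = 0.1,
                           boundary = c("dirichlet", "closed"),
                           bulk_velocity = 0, voltage = NULL, diameter = NULL,
                           system = ketamine_cd_system()) {
  boundary <- match.arg(boundary)
  if (is.character(x)) x <- scenario(x, system = system, n_cells = n_cells)
  if (inherits(x, "ce_scenario")) {
    state <- x$state
    config <- x$config
  } else if (inherits(x, "ce_column")) {
    state <- x
    config <- list(name = "custom", voltage = 400, diameter = 50e-6,
                   duration = until %||% 60,
                   snapshot_times = NULL)
  } else stop("x must be a scenario name, ce_scenario or ce_column")
  voltage <- voltage %||% config$voltage
  diameter <- diameter %||% config$diameter
  until <- until %||% config$duration
  if (is.null(snapshot_times)) {
    snapshot_times <- if (!is.null(snapshot_dt))
      seq(0, until, by = snapshot_dt)
    else config$snapshot_times %||% c(0, until)
  }
  snapshot_times <- sort(unique(c(0, snapshot_times[snapshot_times <= until],
                                  until)))
  area <- pi * (diameter / 2)^2
  dx <- state$dx_mm * 1e-3

  totals <- state$totals
  h <- numeric(0); cL <- numeric(0)
  snapshots <- vector("list", length(snapshot_times))
  snapshots[[1]] <- totals
  tr_t <- numeric(0); tr_I <- numeric(0)
  steps <- 0
  for (k in seq_along(snapshot_times)[-1]) {
    res <- cpp_advance(totals, state$system$cpp, dx, area, voltage,
                       snapshot_times[k - 1], snapshot_times[k], safety,
                       limiter_code(limiter), boundary == "dirichlet",
                       bulk_velocity, trace_dt, h, cL)
    totals <- res$totals
    h <- res$h; cL <- res$cL
    keep <- if (length(tr_t)) res$trace_t > tr_t[length(tr_t)] + 1e-12 else
      rep(TRUE, length(res$trace_t))
    tr_t <- c(tr_t, res$trace_t[keep])
    tr_I <- c(tr_I, res$trace_I[keep])
    steps <- steps + res$steps
    dimnames(totals) <- dimnames(state$totals)
    snapshots[[k]] <- totals
  }
  if (length(snapshot_times) == 1) {
    fd <- field_solve(state, voltage, diameter)
    tr_t <- 0; tr_I <- fd$current
  }
  structure(
    list(times = snapshot_times, snapshots = snapshots,
         trace = data.frame(t_s = tr_t, I_uA = tr_I * 1e6),
         x_mm = state$x_mm, dx_mm = state$dx_mm, system = state$system,
         config = utils::modifyList(config, list(
           n_cells = ncol(totals), voltage = voltage, diameter = diameter,
           until = until, safety = safety, limiter = limiter,
           boundary = boundary, bulk_velocity = bulk_velocity)),
         steps = steps),
    class = "ce_run")
}

#' @export
print.ce_run <- function(x, ...) {
  cat(sprintf("<ce_run> %s: %d cells, t = 0..%g s (%d snapshots, %.0f steps)\n",
              x$config$name, x$config$n_cells, max(x$times), length(x$times),
              x$steps))
  if (nrow(x$trace))
    cat(sprintf("  current %.4g -> %.4g uA\n", x$trace$I_uA[1],
                x$trace$I_uA[nrow(x$trace)]))
  invisible(x)
}

#' Current trace of a run
#' @param run A `ce_run`.
#' @return data.frame with `t_s` and `I_uA`.
#' @export
current_trace <- function(run) {
  stopifnot(inherits(run, "ce_run"))
  run$trace
}

#' Extract a snapshot profile
#'
#' @param run A `ce_run`.
#' @param time Requested time (s); the nearest stored snapshot is used and
#'   must lie within `tol` of it.
#' @param constituent Optional constituent name; otherwise the full matrix.
#' @param tol Tolerance on the snapshot time match (s).
#' @return A numeric vector (one constituent) or the totals matrix, with the
#'   matched time as attribute `time`.
#' @export
snapshot_profile <- function(run, time, constituent = NULL, tol = 0.51) {
  stopifnot(inherits(run, "ce_run"))
  k <- which.min(abs(run$times - time))
  if (abs(run$times[k] - time) > tol)
    stop("no snapshot within ", tol, " s of t = ", time)
  out <- run$snapshots[[k]]
  if (!is.null(constituent)) {
    if (!constituent %in% rownames(out))
      stop("unknown constituent: ", constituent)
    out <- out[constituent, ]
  }
  attr(out, "time") <- run$times[k]
  out
}

#' Grid-extrapolated current at a target time
#'
#' Runs a scenario at a sequence of grid resolutions, reads the current at
#' `at` from each trace, and Richardson-extrapolates in the grid spacing
#' using the observed convergence order. Falls back to the finest-grid value
#' when the sequence is not monotone.
#'
#' @param name Scenario name.
#' @param at Time (s) at which to read the current.
#' @param cells Increasing grid resolutions (coarse to fine, ratio 2).
#' @param ... Passed to [run_simulation()].
#' @return List with `value` (extrapolated current, uA), `currents` per grid,
#'   `order` (estimated convergence order), `cells`.
#' @export
richardson_current <- function(name, at = 120, cells = c(1000, 2000, 4000),
                               ...) {
  stopifnot(length(cells) >= 2)
  runs <- lapply(cells, function(nc)
    run_simulation(name, until = at, n_cells = nc,
                   snapshot_times = c(0, at), ...))
  Is <- vapply(runs, function(r) {
    tr <- current_trace(r)
    stats::approx(tr$t_s, tr$I_uA, xout = at, rule = 2)$y
  }, 0)
  m <- length(Is)
  value <- Is[m]; ord <- NA_real_
  if (m >= 3) {
    d1 <- Is[m - 1] - Is[m - 2]
    d2 <- Is[m] - Is[m - 1]
    if (is.finite(d1 / d2) && d1 / d2 > 1) {
      ord <- log2(d1 / d2)
      value <- Is[m] + d2 / (d1 / d2 - 1)
    }
  } else {
    value <- Is[m] + (Is[m] - Is[m - 1])  # assume first order
    ord <- 1
  }
  list(value = value, currents = Is, order = ord, cells = cells)
}
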