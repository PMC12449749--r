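# Reduction of simulation results to reported quantities: peak metrics,
# departure / arrival / reversal events, focusing diagnostics.

ce_event <- function(kind, name, time, location = NA_real_, criterion = "",
                     status = "ok") {
  structure(list(kind = kind, name = name, time = time, location = location,
                 criterion = criterion, status = status),
            class = "ce_event")
}

#' @export
print.ce_event <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<ce_event> %s of %s at %.3g s (%.3g mm): %s\n", x$kind,
                x$name, x$time, x$location, x$criterion))
  else
    cat(sprintf("<ce_event> %s of %s: %s (%s)\n", x$kind, x$name, x$status,
                x$criterion))
  invisible(x)
}

#' @export
as.data.frame.ce_event <- function(x, ...) {
  data.frame(kind = x$kind, name = x$name, time_s = x$time,
             location_mm = x$location, criterion = x$criterion,
             status = x$status, stringsAsFactors = FALSE)
}

# Internal: positions of local maxima of a profile above a height floor.
local_maxima <- function(x, c, floor_frac = 0.01) {
  n <- length(c)
  gmax <- max(c)
  if (!is.finite(gmax) || gmax <= 0) return(integer(0))
  idx <- which(c >= c[pmax(seq_len(n) - 1, 1)] &
                 c > c[pmin(seq_len(n) + 1, n)] &
                 c >= floor_frac * gmax)
  # collapse plateau runs to their midpoint
  if (length(idx) > 1) {
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    idx <- vapply(runs, function(r) r[ceiling(length(r) / 2)], 1L)
  }
  sort(unname(idx))
}

#' Peak metrics of an analyte profile at a snapshot
#'
#' Finds all local maxima above 1% of the profile's global maximum, with the
#' width at half height obtained by linear interpolation; multimodal profiles
#' (partial peak splitting) return one record per maximum.
#'
#' @param run A `ce_run`.
#' @param time Snapshot time (s).
#' @param analyte Constituent name.
#' @return data.frame of class `ce_peaks` with `analyte`, `time_s`,
#'   `position_mm`, `height` (mol/m^3), `width_half_mm`; zero rows if the
#'   analyte is absent (below 1e-12 everywhere).
#' @export
peak_metrics <- function(run, time, analyte) {
  prof <- snapshot_profile(run, time, analyte)
  t_used <- attr(prof, "time")
  x <- run$x_mm
  empty <- data.frame(analyte = character(0), time_s = numeric(0),
                      position_mm = numeric(0), height = numeric(0),
                      width_half_mm = numeric(0))
  class(empty) <- c("ce_peaks", "data.frame")
  if (max(prof) < 1e-12) return(empty)
  idx <- local_maxima(x = x, c = as.numeric(prof))
  if (!length(idx)) return(empty)
  cross <- function(x0, x1, c0, c1, half) {
    if (c1 == c0) return((x0 + x1) / 2)
    x0 + (half - c0) / (c1 - c0) * (x1 - x0)
  }
  n <- length(prof)
  rows <- lapply(idx, function(i) {
    half <- prof[i] / 2
    # walk out to the half-height crossings (clipped at the domain ends)
    ri <- i
    while (ri < n && prof[ri + 1] > half) ri <- ri + 1
    xr <- if (ri < n) cross(x[ri], x[ri + 1], prof[ri], prof[ri + 1], half)
          else x[n]
    li <- i
    while (li > 1 && prof[li - 1] > half) li <- li - 1
    xl <- if (li > 1) cross(x[li - 1], x[li], prof[li - 1], prof[li], half)
          else x[1]
    data.frame(analyte = analyte, time_s = t_used, position_mm = x[i],
               height = unname(prof[i]), width_half_mm = xr - xl)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ce_peaks", "data.frame")
  out
}

# Internal: trajectory of the global-maximum position of an analyte.
peak_trajectory <- function(run, analyte) {
  pos <- vapply(seq_along(run$times), function(k) {
    prof <- run$snapshots[[k]][analyte, ]
    if (max(prof) < 1e-12) NA_real_ else run$x_mm[which.max(prof)]
  }, 0)
  data.frame(t_s = run$times, position_mm = pos)
}

#' Departure time of an analyte across a boundary
#'
#' First time the analyte's global concentration maximum crosses the stated
#' boundary in the stated direction, linearly interpolated between snapshots.
#'
#' @param run A `ce_run`.
#' @param analyte Constituent name.
#' @param boundary_mm Boundary position (mm).
#' @param side `"anodic"` (crossing toward smaller x) or `"cathodic"`.
#' @return A `ce_event` (status `"not observed"` when the crossing never
#'   happens).
#' @export
departure_time <- function(run, analyte, boundary_mm = 24.5,
                           side = c("anodic", "cathodic")) {
  side <- match.arg(side)
  tr <- peak_trajectory(run, analyte)
  crit <- sprintf("global maximum of %s crosses %.3g mm %sally", analyte,
                  boundary_mm, side)
  ok <- !is.na(tr$position_mm)
  beyond <- if (side == "anodic") tr$position_mm < boundary_mm else
    tr$position_mm > boundary_mm
  k <- which(ok & beyond)
  k <- k[k > 1][1]
  if (is.na(k) || !ok[k - 1])
    return(ce_event("departure", analyte, NA_real_, criterion = crit,
                    status = "not observed"))
  t0 <- tr$t_s[k - 1]; t1 <- tr$t_s[k]
  p0 <- tr$position_mm[k - 1]; p1 <- tr$position_mm[k]
  tt <- if (p1 == p0) t1 else t0 + (boundary_mm - p0) / (p1 - p0) * (t1 - t0)
  ce_event("departure", analyte, tt, boundary_mm, crit)
}

#' Arrival of a constituent boundary at a position
#'
#' First time the constituent's concentration at `x_mm` falls below
#' `threshold_fraction` of its initial plateau (taken at the plateau
#' reference position, default the selector plug mid-point), linearly
#' interpolated in time. `threshold_fraction = 1` returns time 0 by
#' convention.
#'
#' @param run A `ce_run`.
#' @param constituent Constituent name.
#' @param x_mm Observation position (mm).
#' @param threshold_fraction Fraction of the initial plateau.
#' @param reference_mm Position where the initial plateau is read; default
#'   the mid-point of the scenario's selector plug (else `x_mm`).
#' @return A `ce_event`.
#' @export
boundary_arrival <- function(run, constituent = "hs-g-cd", x_mm = 25.5,
                             threshold_fraction = 0.5, reference_mm = NULL) {
  stopifnot(inherits(run, "ce_run"))
  reference_mm <- reference_mm %||%
    (if (!is.null(run$config$plug_mm)) mean(run$config$plug_mm) else x_mm)
  ref <- stats::approx(run$x_mm, run$snapshots[[1]][constituent, ],
                       xout = reference_mm, rule = 2)$y
  crit <- sprintf("%s at %.3g mm drops below %.3g x initial plateau (%.4g)",
                  constituent, x_mm, threshold_fraction, ref)
  if (threshold_fraction >= 1)
    return(ce_event("arrival", constituent, 0, x_mm, crit))
  thr <- threshold_fraction * ref
  cc <- vapply(run$snapshots, function(s)
    stats::approx(run$x_mm, s[constituent, ], xout = x_mm, rule = 2)$y, 0)
  # the observation point may start inside the initial boundary ramp, at or
  # below threshold; the arriving boundary is a drop from above, so require
  # the concentration to have been above threshold first
  k0 <- which(cc >= thr)[1]
  if (is.na(k0))
    return(ce_event("arrival", constituent, NA_real_, x_mm, crit,
                    status = "not observed"))
  k <- which(cc < thr & seq_along(cc) > k0)[1]
  if (is.na(k))
    return(ce_event("arrival", constituent, NA_real_, x_mm, crit,
                    status = "not observed"))
  tt <- stats::approx(cc[(k - 1):k], run$times[(k - 1):k], xout = thr)$y
  ce_event("arrival", constituent, tt, x_mm, crit)
}

#' Migration-direction reversal time of an analyte
#'
#' Time at which the analyte's peak-position velocity changes sign, from
#' central differences over the snapshot trajectory. Velocities smaller than
#' a grid-noise dead band (half a cell per snapshot interval) are treated as
#' zero. By default the event is the reversal from sustained anodic motion to
#' cathodic motion (the transition that makes an analyte available again at a
#' cathodic detector); the brief cathodic displacement while the sample loads
#' into the selector gradient is thereby ignored. `from = "cathodic"` finds
#' the opposite flip, `from = "any"` the first of either.
#'
#' @param run A `ce_run` with at least 3 snapshots.
#' @param analyte Constituent name.
#' @param from Direction of the preceding sustained motion: `"anodic"`,
#'   `"cathodic"`, or `"any"`.
#' @return A `ce_event` (status `"not observed"` for monotone or stationary
#'   trajectories).
#' @export
reversal_time <- function(run, analyte,
                          from = c("anodic", "cathodic", "any")) {
  from <- match.arg(from)
  stopifnot(inherits(run, "ce_run"), length(run$times) >= 3)
  tr <- peak_trajectory(run, analyte)
  tr <- tr[!is.na(tr$position_mm), ]
  crit <- sprintf("%s peak-position velocity turns %s", analyte,
                  switch(from, anodic = "anodic -> cathodic",
                         cathodic = "cathodic -> anodic", any = "around"))
  not_obs <- function() ce_event("reversal", analyte, NA_real_,
                                 criterion = crit, status = "not observed")
  if (nrow(tr) < 3) return(not_obs())
  n <- nrow(tr)
  v <- (tr$position_mm[c(2:n, n)] - tr$position_mm[c(1, 1:(n - 1))]) /
    (tr$t_s[c(2:n, n)] - tr$t_s[c(1, 1:(n - 1))])
  dead <- 0.5 * run$dx_mm / stats::median(diff(tr$t_s))
  s <- sign(v) * (abs(v) > dead)
  nz <- which(s != 0)
  if (length(nz) < 2) return(not_obs())
  step_sign <- diff(s[nz])
  want <- switch(from, anodic = which(s[nz[-length(nz)]] < 0 & step_sign > 0),
                 cathodic = which(s[nz[-length(nz)]] > 0 & step_sign < 0),
                 any = which(step_sign != 0))
  if (!length(want)) return(not_obs())
  k0 <- nz[want[1]]
  k1 <- nz[want[1] + 1]
  # interpolate the zero crossing of the raw velocity between k0 and k1
  tt <- if (v[k1] != v[k0])
    tr$t_s[k0] + (0 - v[k0]) / (v[k1] - v[k0]) * (tr$t_s[k1] - tr$t_s[k0])
  else mean(tr$t_s[c(k0, k1)])
  ce_event("reversal", analyte, tt,
           stats::approx(tr$t_s, tr$position_mm, xout = tt)$y, crit)
}

#' Focusing diagnostic: local selector concentration at an analyte's peak
#'
#' Reads the selector concentration at the analyte's concentration maximum
#' and compares it with the analyte's zero-mobility transition concentration:
#' a focused analyte sits where its effective mobility vanishes.
#'
#' @param run A `ce_run`.
#' @param time Snapshot time (s).
#' @param analyte Constituent name.
#' @param ligand Selector constituent name.
#' @param dominance Maximum allowed secondary/primary peak height ratio for
#'   the profile to count as focused (single dominant peak).
#' @return List with `position_mm`, `local_selector_mM`, `transition_mM`,
#'   `relative_gap`.
#' @export
focusing_check <- function(run, time, analyte, ligand = "hs-g-cd",
                           dominance = 0.5) {
  pk <- peak_metrics(run, time, analyte)
  if (!nrow(pk)) stop("analyte ", analyte, " absent at t = ", time)
  pk <- pk[order(-pk$height), ]
  if (nrow(pk) > 1 && pk$height[2] > dominance * pk$height[1])
    stop("analyte ", analyte, " is not focused at t = ", time,
         " (multimodal profile)")
  pos <- pk$position_mm[1]
  cd <- stats::approx(run$x_mm, snapshot_profile(run, time, ligand),
                      xout = pos)$y
  if (cd < 1e-6)
    stop("analyte ", analyte, " sits in selector-free solution at t = ", time)
  tc <- transition_concentration(analyte, run$system)
  if (tc$status != "ok") stop("no transition concentration for ", analyte)
  list(position_mm = pos, local_selector_mM = cd, transition_mM = tc$c_star,
       relative_gap = (cd - tc$c_star) / tc$c_star)
}

#' Concentration seen by a detector at a fixed position
#'
#' @param run A `ce_run`.
#' @param x_mm Detector position (mm).
#' @param constituents Constituent names (default: the analytes).
#' @return data.frame with `t_s` and one column per constituent (mol/m^3).
#' @export
detector_trace <- function(run, x_mm,
                           constituents = analyte_names(run$system)) {
  stopifnot(inherits(run, "ce_run"))
  out <- data.frame(t_s = run$times)
  for (nm in constituents)
    out[[nm]] <- vapply(run$snapshots, function(s)
      stats::approx(run$x_mm, s[nm, ], xout = x_mm, rule = 2)$y, 0)
  out
}
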