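# Effective mobility versus selector concentration: curves, zero-mobility
# transition points, migration-direction classification.

default_isotherm_background <- function() {
  # selector-free formic acid / ammonium formate buffer (pH ~1.9); sodium is
  # co-added with the titrated selector so the pH stays fixed along a curve
  c(formic = 2380, ammonia = 20)
}

#' Effective-mobility curve of an analyte versus selector concentration
#'
#' Evaluates the equilibrium effective mobility of a trace analyte while the
#' selector is titrated over a concentration grid in a fixed background
#' buffer. Sodium hydroxide is co-added at `na_per_cd` times the selector
#' concentration (the stoichiometry of the neutralized selector salt), so
#' the background pH is essentially constant along the curve.
#'
#' @param analyte Analyte constituent name.
#' @param c_grid Selector concentrations, mol/m^3 (== mM), strictly
#'   increasing, >= 0.
#' @param system A `ce_system`.
#' @param background Background composition; default formic acid / ammonium
#'   formate buffer.
#' @param na_per_cd Sodium equivalents added per selector molecule.
#' @param trace Analyte concentration used for the evaluation (mol/m^3);
#'   infinite-dilution property, so a true trace amount.
#' @return An object of class `ce_mobility_curve`: data.frame with
#'   `c_ligand_mM`, `mu_eff` (m^2/(V s)), `mu_eff_e8`, plus attributes
#'   `analyte` and `pH` (at the last grid point).
#' @examples
#' sys <- ketamine_cd_system()
#' mc <- mobility_curve("S-ketamine", c(0, 5, 19), sys)
#' mc$mu_eff_e8
#' @export
mobility_curve <- function(analyte, c_grid, system,
                           background = default_isotherm_background(),
                           na_per_cd = 13, trace = 1e-6) {
  stopifnot(all(is.finite(c_grid)), all(c_grid >= 0),
            !is.unsorted(c_grid, strictly = TRUE))
  lig <- unique(vapply(system$complexations, `[[`, "", "ligand"))
  if (!length(lig)) stop("system has no complexation entries")
  mu <- numeric(length(c_grid))
  pH <- NA_real_
  for (i in seq_along(c_grid)) {
    comp <- c(background, stats::setNames(trace, analyte),
              stats::setNames(c_grid[i], lig),
              sodium = na_per_cd * c_grid[i])
    st <- tryCatch(solve_equilibrium(comp, system), error = function(e)
      stop("equilibrium failed at c_ligand = ", c_grid[i], " mM: ",
           conditionMessage(e)))
    mu[i] <- effective_mobility(analyte, st)
    pH <- st$pH
  }
  out <- data.frame(c_ligand_mM = c_grid, mu_eff = mu, mu_eff_e8 = mu * 1e8)
  attr(out, "analyte") <- analyte
  attr(out, "pH") <- pH
  class(out) <- c("ce_mobility_curve", "data.frame")
  out
}

#' Zero-mobility transition concentration of an analyte
#'
#' Finds the unique selector concentration c* at which the analyte's
#' effective mobility vanishes (cationic below, anionic above). The root of
#' the full equilibrium model is bracketed on (0, `c_max`] and polished with
#' [stats::uniroot()]; the closed form c* = alpha u_f / (|u_c| K) (alpha =
#' protonated fraction at the background pH) is returned alongside as a
#' consistency check.
#'
#' @inheritParams mobility_curve
#' @param c_max Upper search bound, mol/m^3 (default 1 M).
#' @param tol Relative tolerance on c*.
#' @return List of class `ce_transition`: `c_star` (mol/m^3 == mM; `NA` if no
#'   sign change, with `status = "no transition"`), `c_star_closed_form`,
#'   `analyte`, `status`.
#' @examples
#' sys <- ketamine_cd_system()
#' transition_concentration("S-hydroxynorketamine", sys)$c_star
#' @export
transition_concentration <- function(analyte, system,
                                     background = default_isotherm_background(),
                                     na_per_cd = 13, trace = 1e-6,
                                     c_max = 1000, tol = 1e-8) {
  f <- function(cc) {
    mobility_curve(analyte, cc, system, background, na_per_cd, trace)$mu_eff
  }
  lo <- 1e-9
  flo <- f(lo); fhi <- f(c_max)
  cx <- system$complexations[
    vapply(system$complexations, `[[`, "", "analyte") == analyte]
  closed <- NA_real_
  if (length(cx)) {
    an <- system$constituents[[analyte]]
    bg0 <- solve_equilibrium(c(background, stats::setNames(trace, analyte)),
                             system)
    alpha <- bg0$h / (bg0$h + 10^(-an$pKa))
    closed <- alpha * an$ionic_mobility /
      (abs(cx[[1]]$complex_mobility) * cx[[1]]$binding_constant) * 1000
  }
  if (!length(cx) || sign(flo) == sign(fhi) || flo == 0) {
    return(structure(list(c_star = NA_real_, c_star_closed_form = closed,
                          analyte = analyte, status = "no transition"),
                     class = "ce_transition"))
  }
  r <- stats::uniroot(f, c(lo, c_max), f.lower = flo, f.upper = fhi,
                      tol = tol * max(closed, 1e-3, na.rm = TRUE))
  structure(list(c_star = r$root, c_star_closed_form = closed,
                 analyte = analyte, status = "ok"),
            class = "ce_transition")
}

#' @export
print.ce_transition <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<ce_transition> %s: c* = %.4g mM (closed form %.4g mM)\n",
                x$analyte, x$c_star, x$c_star_closed_form))
  else
    cat(sprintf("<ce_transition> %s: no transition on the search interval\n",
                x$analyte))
  invisible(x)
}

#' Classify the migration direction of an analyte in an equilibrium state
#'
#' Sign of the effective mobility with a dead band: |u_eff| below `dead_band`
#' is reported as stationary.
#'
#' @param analyte Constituent name.
#' @param state A `ce_equilibrium`.
#' @param dead_band Dead band in m^2/(V s).
#' @return `"cationic"`, `"stationary"` or `"anionic"`.
#' @export
classify_direction <- function(analyte, state, dead_band = 1e-12) {
  mu <- effective_mobility(analyte, state)
  if (abs(mu) < dead_band) "stationary" else
    if (mu > 0) "cationic" else "anionic"
}
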