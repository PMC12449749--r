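#' Validate a mixture composition
#'
#' A composition is a named numeric vector of total analytical concentrations
#' in mol/m^3 (numerically identical to mM). Names must be constituents of
#' the system; missing constituents are taken as zero.
#'
#' @param x Named numeric vector (mol/m^3 == mM).
#' @param system A `ce_system`.
#' @return A full-length named vector over all constituents of the system.
#' @export
composition <- function(x, system) {
  stopifnot(inherits(system, "ce_system"))
  nm <- constituent_names(system)
  out <- stats::setNames(numeric(length(nm)), nm)
  if (length(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("composition must be a named vector")
    bad <- setdiff(names(x), nm)
    if (length(bad)) stop("unknown constituent(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(x)) || any(x < 0))
      stop("concentrations must be finite and >= 0")
    out[names(x)] <- out[names(x)] + x   # duplicated names accumulate
  }
  out
}

#' Solve the local acid-base and complexation equilibrium
#'
#' Computes the self-consistent speciation of a mixture under
#' electroneutrality: pH from the charge balance (water autoprotolysis,
#' protonation-averaged charges of every constituent, strong-ion terms), the
#' free-ligand concentration from the 1:1 complexation mass balance, per-form
#' and complex concentrations, conductivity and ionic strength. No activity,
#' ionic-strength or viscosity corrections are applied; ionic strength is
#' reported but never used.
#'
#' @param comp Composition (named vector, mol/m^3; see [composition()]).
#' @param system A `ce_system`.
#' @return An object of class `ce_equilibrium` with elements `pH`,
#'   `free_species` (named concentrations, mol/m^3, including `H+`, `OH-`,
#'   every protonation form, free ligand and each complex), `species` (a
#'   data.frame with charge and mobility per species), `conductivity` (S/m),
#'   `ionic_strength` (mol/L) and `totals`.
#' @examples
#' sys <- ketamine_cd_system()
#' eq <- solve_equilibrium(bge_composition(), sys)
#' eq$pH
#' @export
solve_equilibrium <- function(comp, system) {
  stopifnot(inherits(system, "ce_system"))
  tot <- composition(comp, system)
  sp <- cpp_speciate(matrix(tot, ncol = 1), system$cpp)
  h <- sp$h[1]
  cs <- system$constituents
  nm <- names(cs)
  Kw <- system$constants$water_ion_product
  FF <- system$constants$faraday

  species <- data.frame(species = "H+", constituent = "water", charge = 1,
                        concentration = 1000 * h,
                        mobility = system$constants$h_mobility,
                        stringsAsFactors = FALSE)
  species <- rbind(species, data.frame(
    species = "OH-", constituent = "water", charge = -1,
    concentration = 1000 * Kw / h,
    mobility = -system$constants$oh_mobility))
  for (i in seq_along(cs)) {
    z <- cs[[i]]
    cf <- sp$cfree[i, 1]
    Ka <- 10^(-z$pKa)
    if (z$kind == "multi-site-anion") {
      f <- Ka / (Ka + h)
      species <- rbind(species, data.frame(
        species = paste0(z$name, sprintf("(%.4g-)", z$site_count * f)),
        constituent = z$name, charge = -z$site_count * f,
        concentration = cf, mobility = -z$ionic_mobility))
    } else if (z$kind == "weak-acid") {
      f <- Ka / (Ka + h)
      species <- rbind(species,
        data.frame(species = paste0(z$name, "-"), constituent = z$name,
                   charge = -1, concentration = f * cf,
                   mobility = -z$ionic_mobility),
        data.frame(species = paste0(z$name, "0"), constituent = z$name,
                   charge = 0, concentration = (1 - f) * cf, mobility = 0))
    } else {
      a <- h / (h + Ka)
      species <- rbind(species,
        data.frame(species = paste0(z$name, "+"), constituent = z$name,
                   charge = 1, concentration = a * cf,
                   mobility = z$ionic_mobility),
        data.frame(species = paste0(z$name, "0"), constituent = z$name,
                   charge = 0, concentration = (1 - a) * cf, mobility = 0))
    }
  }
  cx <- system$complexations
  for (k in seq_along(cx)) {
    an <- cs[[cx[[k]]$analyte]]
    lg <- cs[[cx[[k]]$ligand]]
    za <- if (an$kind == "weak-base") h / (h + 10^(-an$pKa)) else
      -10^(-an$pKa) / (10^(-an$pKa) + h)
    fl <- 10^(-lg$pKa) / (10^(-lg$pKa) + h)
    species <- rbind(species, data.frame(
      species = paste0(cx[[k]]$analyte, ".", cx[[k]]$ligand),
      constituent = cx[[k]]$analyte, charge = za - lg$site_count * fl,
      concentration = sp$cplx[k, 1], mobility = cx[[k]]$complex_mobility))
  }
  free <- stats::setNames(species$concentration, species$species)
  structure(
    list(pH = -log10(h), h = h, free_species = free, species = species,
         cfree = stats::setNames(sp$cfree[, 1], nm),
         complexes = if (length(cx))
           stats::setNames(sp$cplx[seq_along(cx), 1],
                           vapply(cx, function(z)
                             paste0(z$analyte, ".", z$ligand), "")) else
           numeric(0),
         conductivity = sp$kappa[1], ionic_strength = sp$ionic_strength[1],
         totals = tot, system = system),
    class = "ce_equilibrium")
}

#' @export
print.ce_equilibrium <- function(x, ...) {
  cat(sprintf("<ce_equilibrium> pH %.4f, conductivity %.4g S/m, I %.4g mol/L\n",
              x$pH, x$conductivity, x$ionic_strength))
  nz <- x$species[x$species$concentration > 0, ]
  print(nz, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conductivity of an equilibrium state
#'
#' kappa = F * sum over charged species (water ions, ionic forms at their
#' averaged charge, complexes at their net charge) of |z| c u; strictly
#' positive.
#'
#' @param state A `ce_equilibrium`.
#' @return Conductivity in S/m.
#' @export
conductivity <- function(state) {
  stopifnot(inherits(state, "ce_equilibrium"))
  state$conductivity
}

#' Ionic strength of an equilibrium state (reported only, never used)
#' @param state A `ce_equilibrium`.
#' @return Ionic strength in mol/L.
#' @export
ionic_strength <- function(state) {
  stopifnot(inherits(state, "ce_equilibrium"))
  state$ionic_strength
}

#' Effective mobility of an analyte in an equilibrium state
#'
#' Concentration-weighted signed mean over the analyte's forms (charged form,
#' neutral form, complex). For a fully protonated base at free-ligand
#' concentration cL this reduces to (u_f + u_c K cL) / (1 + K cL).
#'
#' @param analyte Constituent name (present in the state at any trace amount).
#' @param state A `ce_equilibrium`.
#' @return Signed effective mobility in m^2/(V s).
#' @examples
#' sys <- ketamine_cd_system()
#' st <- solve_equilibrium(c(bge_composition(), "S-ketamine" = 1e-6), sys)
#' effective_mobility("S-ketamine", st)
#' @export
effective_mobility <- function(analyte, state) {
  stopifnot(inherits(state, "ce_equilibrium"))
  sp <- state$species
  rows <- sp[sp$constituent == analyte, ]
  if (!nrow(rows)) stop("unknown constituent: ", analyte)
  ctot <- sum(rows$concentration)
  if (ctot <= 0)
    stop("effective mobility undefined: zero total concentration of ", analyte)
  sum(rows$mobility * rows$concentration) / ctot
}
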