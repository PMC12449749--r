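#' Define a buffer or analyte constituent
#'
#' A constituent is a chemical species family transported as one analytical
#' total: a mono-protic weak acid or weak base, or a multi-site anion such as
#' a highly sulfated cyclodextrin with identical, independent acidic sites.
#' Strong ions are represented as weak acids/bases with extreme pKa (e.g.
#' chloride as a weak acid of pKa -2, sodium as a weak base of pKa 13.7).
#'
#' @param name Constituent identifier.
#' @param kind One of `"weak-acid"`, `"weak-base"`, `"multi-site-anion"`.
#' @param mobility Magnitude of the ionic mobility of the singly charged form
#'   (fully charged form for a multi-site anion), in 1e-8 m^2/(V s) as
#'   conventionally tabulated.
#' @param pKa Negative log10 acid dissociation constant (per site for a
#'   multi-site anion).
#' @param site_count Number of identical acidic sites (1 unless multi-site).
#' @return An object of class `ce_constituent`.
#' @examples
#' ce_constituent("formic", "weak-acid", 5.66, 3.75)
#' @export
ce_constituent <- function(name,
                           kind = c("weak-acid", "weak-base",
                                    "multi-site-anion"),
                           mobility, pKa, site_count = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), nchar(name) > 0, is.finite(mobility),
            mobility > 0, is.finite(pKa), site_count >= 1)
  if (kind != "multi-site-anion" && site_count != 1)
    stop("site_count > 1 requires kind = 'multi-site-anion'")
  structure(
    list(name = name, kind = kind,
         ionic_mobility = mobility * 1e-8,   # stored SI
         pKa = pKa, site_count = as.integer(site_count),
         charge_sign = if (kind == "weak-base") 1L else -1L),
    class = "ce_constituent")
}

#' Define a 1:1 analyte-ligand complexation entry
#'
#' The apparent binding constant applies to both the charged and the neutral
#' form of the analyte; the complex mobility is stored signed (negative =
#' anionic), following the usual tabulation.
#'
#' @param analyte,ligand Constituent names.
#' @param K Apparent 1:1 binding constant in 1/M.
#' @param complex_mobility Signed complex mobility in 1e-8 m^2/(V s).
#' @return An object of class `ce_complexation`.
#' @examples
#' ce_complexation("S-ketamine", "hs-g-cd", 579, -1.34)
#' @export
ce_complexation <- function(analyte, ligand, K, complex_mobility) {
  stopifnot(is.character(analyte), is.character(ligand), is.finite(K), K >= 0,
            is.finite(complex_mobility))
  structure(
    list(analyte = analyte, ligand = ligand, binding_constant = K,
         complex_mobility = complex_mobility * 1e-8),
    class = "ce_complexation")
}

#' Assemble a chemical system
#'
#' Collects constituents, complexation entries and physical constants into the
#' object consumed by the equilibrium solver and the transport engine. At most
#' one ligand (multi-site anion appearing in complexation entries) is allowed,
#' and at most one entry per (analyte, ligand) pair.
#'
#' @param constituents List of [ce_constituent()] objects.
#' @param complexations List of [ce_complexation()] objects (may be empty).
#' @param constants A [ce_constants()] object.
#' @return An object of class `ce_system`.
#' @seealso [ketamine_cd_system()] for the packaged parameter set.
#' @export
ce_system <- function(constituents, complexations = list(),
                      constants = ce_constants()) {
  stopifnot(length(constituents) > 0,
            all(vapply(constituents, inherits, TRUE, "ce_constituent")),
            all(vapply(complexations, inherits, TRUE, "ce_complexation")),
            inherits(constants, "ce_constants"))
  nm <- vapply(constituents, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate constituent names")
  for (cp in complexations) {
    if (!cp$analyte %in% nm || !cp$ligand %in% nm)
      stop("complexation entry refers to unknown constituent: ",
           cp$analyte, " / ", cp$ligand)
  }
  pairs <- vapply(complexations, function(cp) paste(cp$analyte, cp$ligand), "")
  if (anyDuplicated(pairs)) stop("duplicate (analyte, ligand) pair")
  ligs <- unique(vapply(complexations, `[[`, "", "ligand"))
  if (length(ligs) > 1) stop("at most one ligand constituent is supported")
  sys <- structure(
    list(constituents = stats::setNames(constituents, nm),
         complexations = complexations, constants = constants),
    class = "ce_system")
  sys$cpp <- sys_to_cpp(sys)
  sys
}

#' @export
print.ce_system <- function(x, ...) {
  cat("<ce_system>", length(x$constituents), "constituents,",
      length(x$complexations), "complexation entries\n")
  df <- data.frame(
    name = names(x$constituents),
    kind = vapply(x$constituents, `[[`, "", "kind"),
    mobility_e8 = vapply(x$constituents, function(z) z$ionic_mobility, 0) * 1e8,
    pKa = vapply(x$constituents, `[[`, 0, "pKa"),
    sites = vapply(x$constituents, `[[`, 1L, "site_count"),
    row.names = NULL, check.names = FALSE)
  print(df, row.names = FALSE)
  if (length(x$complexations)) {
    cdf <- data.frame(
      analyte = vapply(x$complexations, `[[`, "", "analyte"),
      ligand = vapply(x$complexations, `[[`, "", "ligand"),
      K_Minv = vapply(x$complexations, `[[`, 0, "binding_constant"),
      u_complex_e8 = vapply(x$complexations, function(z)
        z$complex_mobility, 0) * 1e8,
      row.names = NULL, check.names = FALSE)
    print(cdf, row.names = FALSE)
  }
  invisible(x)
}

#' Constituent names of a system
#' @param system A `ce_system`.
#' @return Character vector.
#' @export
constituent_names <- function(system) {
  stopifnot(inherits(system, "ce_system"))
  names(system$constituents)
}

#' Analyte names of a system (constituents appearing in complexation entries)
#' @param system A `ce_system`.
#' @return Character vector.
#' @export
analyte_names <- function(system) {
  stopifnot(inherits(system, "ce_system"))
  vapply(system$complexations, `[[`, "", "analyte")
}

# Internal: flatten a ce_system into the list consumed by the C++ core.
sys_to_cpp <- function(sys) {
  cs <- sys$constituents
  nm <- names(cs)
  kind <- vapply(cs, function(z)
    match(z$kind, c("weak-acid", "weak-base", "multi-site-anion")) - 1L, 1L)
  cx <- sys$complexations
  k <- sys$constants
  lig <- if (length(cx)) match(cx[[1]]$ligand, nm) - 1L else -1L
  list(
    kind = as.integer(kind),
    u = vapply(cs, `[[`, 0, "ionic_mobility"),
    Ka = 10^(-vapply(cs, `[[`, 0, "pKa")),
    nsite = as.numeric(vapply(cs, `[[`, 1L, "site_count")),
    cplx_analyte = as.integer(vapply(cx, function(z) match(z$analyte, nm), 1L) - 1L),
    cplx_ligand = as.integer(vapply(cx, function(z) match(z$ligand, nm), 1L) - 1L),
    cplx_K = vapply(cx, `[[`, 0, "binding_constant") / 1000,  # 1/M -> m^3/mol
    cplx_u = vapply(cx, `[[`, 0, "complex_mobility"),
    ligand = as.integer(lig),
    faraday = k$faraday,
    RT = k$gas_constant * k$temperature,
    Kw = k$water_ion_product,
    uH = k$h_mobility,
    uOH = k$oh_mobility)
}

#' Read a chemical system from a YAML document
#'
#' The document has three blocks: `constants` (optional overrides for
#' [ce_constants()]), `constituents` (name, kind, mobility_e8, pKa,
#' site_count) and `complexation` (analyte, ligand, K, complex_mobility_e8).
#'
#' @param path Path to the YAML file.
#' @return A `ce_system`.
#' @export
read_system_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  const <- do.call(ce_constants, as.list(doc$constants %||% list()))
  cons <- lapply(doc$constituents, function(d)
    ce_constituent(d$name, d$kind, d$mobility_e8, d$pKa,
                   d$site_count %||% 1L))
  cplx <- lapply(doc$complexation %||% list(), function(d)
    ce_complexation(d$analyte, d$ligand, d$K, d$complex_mobility_e8))
  ce_system(cons, cplx, const)
}

#' Write a chemical system to a YAML document
#'
#' Inverse of [read_system_yaml()]; `read(write(x))` reproduces `x`.
#'
#' @param system A `ce_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_yaml <- function(system, path) {
  stopifnot(inherits(system, "ce_system"))
  k <- system$constants
  doc <- list(
    constants = list(temperature = k$temperature,
                     water_ion_product = k$water_ion_product,
                     h_mobility = k$h_mobility, oh_mobility = k$oh_mobility,
                     faraday = k$faraday, gas_constant = k$gas_constant),
    constituents = lapply(unname(system$constituents), function(z)
      list(name = z$name, kind = z$kind,
           mobility_e8 = z$ionic_mobility * 1e8, pKa = z$pKa,
           site_count = z$site_count)),
    complexation = lapply(system$complexations, function(z)
      list(analyte = z$analyte, ligand = z$ligand, K = z$binding_constant,
           complex_mobility_e8 = z$complex_mobility * 1e8)))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' The packaged ketamine / HS-gamma-CD parameter set
#'
#' Loads the constituent and complexation table shipped with the package:
#' the formic acid / ammonium formate background electrolyte constituents,
#' sodium, chloride, the highly sulfated gamma-cyclodextrin selector (13
#' sulfate sites of per-site pKa -3), and the six analytes (S/R-ketamine,
#' S/R-norketamine, S/R-hydroxynorketamine) with their apparent 1:1 binding
#' constants and complex mobilities.
#'
#' @return A `ce_system`.
#' @examples
#' sys <- ketamine_cd_system()
#' constituent_names(sys)
#' @export
ketamine_cd_system <- function() {
  read_system_yaml(system.file("extdata", "constituents.yaml",
                               package = "cesim", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
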