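#' Physical constants for electrophoresis calculations
#'
#' Bundles the constants used throughout the simulator. Temperature is fixed
#' for a run; no activity or viscosity corrections are applied anywhere. The
#' water-ion mobilities are the values conventional in electrophoresis
#' simulators and are not part of the constituent table.
#'
#' @param temperature Absolute temperature in K.
#' @param water_ion_product Ionic product of water Kw in mol^2/L^2.
#' @param h_mobility Mobility of H+ in m^2/(V s).
#' @param oh_mobility Mobility of OH- in m^2/(V s).
#' @param faraday Faraday constant in C/mol.
#' @param gas_constant Molar gas constant in J/(mol K).
#' @return An object of class `ce_constants`.
#' @examples
#' ce_constants()
#' @export
ce_constants <- function(temperature = 298.15, water_ion_product = 1e-14,
                         h_mobility = 362.5e-9, oh_mobility = 205.5e-9,
                         faraday = 96485.33212, gas_constant = 8.314463) {
  vals <- c(temperature, water_ion_product, h_mobility, oh_mobility,
            faraday, gas_constant)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  structure(
    list(temperature = temperature, water_ion_product = water_ion_product,
         h_mobility = h_mobility, oh_mobility = oh_mobility,
         faraday = faraday, gas_constant = gas_constant),
    class = "ce_constants")
}

#' @export
print.ce_constants <- function(x, ...) {
  cat("<ce_constants> T =", x$temperature, "K, Kw =", x$water_ion_product,
      "\n  u(H+) =", x$h_mobility, "m2/Vs, u(OH-) =", x$oh_mobility,
      "m2/Vs\n")
  invisible(x)
}
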