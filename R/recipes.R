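#' Background electrolyte, catholyte and sample recipes
#'
#' Builders for the compositions used by the scenario library, in mol/m^3
#' (== mM). The selector-containing background electrolyte (BGE) is 2.36 M
#' formic acid + 20 mM ammonium formate (counted as 20 mM ammonia + 20 mM
#' additional formic acid) + the selector + sodium hydroxide; sodium is
#' stoichiometric at 13 x the selector concentration unless overridden
#' (19 mM selector, a 5% solution, carries 247 mM NaOH). The catholyte is
#' the same buffer without the selector and without its neutralizing sodium.
#' The sample is the stereoisomer mixture as hydrochloride salts in 83 mM
#' acetic acid, optionally spiked with a fraction of the BGE to emulate
#' matrix variants.
#'
#' @param cd Selector concentration in mol/m^3 (mM).
#' @param naoh Sodium concentration in mol/m^3; default `13 * cd`.
#' @param formic_acid Total formic acid from the acid itself (mol/m^3).
#' @param ammonium_formate Ammonium formate concentration (mol/m^3).
#' @return Named composition vector.
#' @export
bge_composition <- function(cd = 19, naoh = 13 * cd, formic_acid = 2360,
                            ammonium_formate = 20) {
  c(formic = formic_acid + ammonium_formate, ammonia = ammonium_formate,
    "hs-g-cd" = cd, sodium = naoh)
}

#' @rdname bge_composition
#' @export
catholyte_composition <- function(formic_acid = 2360, ammonium_formate = 20) {
  bge_composition(cd = 0, naoh = 0, formic_acid = formic_acid,
                  ammonium_formate = ammonium_formate)
}

#' @rdname bge_composition
#' @param analyte_uM Concentration of each stereoisomer in micromol/L.
#' @param analytes Analyte constituent names (chloride is added at their sum,
#'   hydrochloride salts).
#' @param acetic_acid Acetic acid concentration (mol/m^3).
#' @param bge_fraction Fraction of the selector BGE added to the sample
#'   matrix (0 = none, 0.1 = ten-fold diluted BGE, 1 = undiluted).
#' @param bge Composition used for the `bge_fraction` admixture.
#' @export
sample_composition <- function(analyte_uM = 20,
                               analytes = c("S-ketamine", "R-ketamine",
                                            "S-norketamine", "R-norketamine",
                                            "S-hydroxynorketamine",
                                            "R-hydroxynorketamine"),
                               acetic_acid = 83, bge_fraction = 0,
                               bge = bge_composition()) {
  a <- stats::setNames(rep(analyte_uM / 1000, length(analytes)), analytes)
  out <- c(a, chloride = sum(a), acetic = acetic_acid)
  if (bge_fraction > 0) out <- c(out, bge_fraction * bge)
  out
}
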