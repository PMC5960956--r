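# Shared constants: atomic weights, physical constants, the fermentation
# compound registry and substrate presets.

# IUPAC 2021 conventional atomic weights (g/mol), abridged to the elements
# that occur in biomass and fermentation-product formulas.
.ATOMIC_WEIGHTS <- c(
  H  = 1.008,   C  = 12.011,  N  = 14.007,  O  = 15.999,
  P  = 30.974,  S  = 32.06,   K  = 39.098,  Mg = 24.305,
  Ca = 40.078,  Na = 22.990,  Cl = 35.45,   Fe = 55.845
)

# Molar gas constant, J mol^-1 K^-1
.R_GAS <- 8.31446

# Standard atmosphere, kPa
.ATM_KPA <- 101.325

# Molar volume of an ideal gas at STP (273.15 K, 1 atm), L/mol; used to
# convert Bunsen-coefficient gas volumes into moles.
.MOLAR_VOLUME_STP <- 22.414

#' Physical constants for gas speciation
#'
#' Bundles the gas-solubility coefficients, the first dissociation constant
#' of carbonic acid and the gas constant used by the speciation functions.
#'
#' Solubilities are dimensionless Bunsen-style coefficients: the volume of
#' gas (at STP) absorbed per volume of water when the partial pressure of
#' the gas is 1 atm. Shipped defaults are interpolated to 22 degC (the
#' midpoint of a 21-24 degC room-temperature incubation) from standard
#' solubility tables: H2 0.0179, CO2 0.829, N2 0.0153, O2 0.0306,
#' CH4 0.0335.
#'
#' @param bunsen named numeric vector of Bunsen coefficients per gas.
#' @param pKa_co2 first dissociation constant of carbonic acid (default
#'   6.35, the 25 degC freshwater value; no ionic-strength correction).
#' @param solubility_temperature_K temperature at which the Bunsen
#'   coefficients apply (documentation only).
#' @return an object of class `physical_constants`.
#' @export
#' @examples
#' k <- physical_constants()
#' k$bunsen[["CO2"]] / k$bunsen[["H2"]]   # ~46: CO2 is far more soluble
physical_constants <- function(bunsen = c(H2 = 0.0179, CO2 = 0.829,
                                          N2 = 0.0153, O2 = 0.0306,
                                          CH4 = 0.0335),
                               pKa_co2 = 6.35,
                               solubility_temperature_K = 295.15) {
  stopifnot(is.numeric(bunsen), all(bunsen >= 0), !is.null(names(bunsen)))
  stopifnot(is.numeric(pKa_co2), length(pKa_co2) == 1L, pKa_co2 > 0)
  structure(
    list(bunsen = bunsen, pKa_co2 = pKa_co2,
         solubility_temperature_K = solubility_temperature_K,
         R = .R_GAS, atm_kPa = .ATM_KPA,
         molar_volume_stp = .MOLAR_VOLUME_STP),
    class = "physical_constants"
  )
}

#' Fermentation-product stoichiometry registry
#'
#' The default registry of fermentation products with their carbon atom
#' counts and reducing equivalents (electrons released on complete
#' oxidation of the neutral, undissociated compound). Acid anions are
#' represented by their neutral acids, so acetate counts as C2H4O2.
#'
#' @return a data.frame with columns `name`, `formula` (neutral molecular
#'   formula), `carbon` (atoms per molecule) and `electrons` (reducing
#'   equivalents per molecule).
#' @export
#' @examples
#' reg <- compound_registry()
#' reg[reg$name == "acetate", ]   # 2 carbons, 8 electrons
compound_registry <- function() {
  data.frame(
    name = c("acetate", "butyrate", "CO2", "formate", "H2",
             "methyl_butyrate", "propionate", "succinate", "lactate",
             "ethanol"),
    formula = c("C2H4O2", "C4H8O2", "CO2", "CH2O2", "H2",
                "C5H10O2", "C3H6O2", "C4H6O4", "C3H6O3", "C2H6O"),
    carbon = c(2L, 4L, 1L, 1L, 0L, 5L, 3L, 4L, 3L, 2L),
    electrons = c(8L, 20L, 0L, 2L, 2L, 26L, 14L, 14L, 12L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Substrate presets
#'
#' Shipped elemental-formula presets for common microcosm substrates.
#' Each preset carries the condensed formula, the oxidation-state
#' convention under which its degree of reduction is computed, and an
#' optional published `n_r_C` override used in preference to the computed
#' value (the computed value is always retained alongside, see
#' [preset_substrate()]).
#'
#' @return named list of preset definitions.
#' @export
substrate_presets <- function() {
  list(
    yeast_lysate = list(
      label = "S. cerevisiae cell lysate",
      formula = "CH1.613O0.557N0.158P0.012S0.003K0.022Mg0.003Ca0.001",
      convention = "biomass", n_r_C_override = 4.019),
    ecoli_lysate = list(
      label = "E. coli cell lysate",
      formula = "CH1.59O0.374N0.263P0.0234S0.006",
      convention = "biomass", n_r_C_override = NA_real_),
    bsa_protein = list(
      label = "bovine serum albumin",
      formula = "CH1.57N0.27O0.30S0.013",
      convention = "biomass", n_r_C_override = 4.145),
    yeast_rna = list(
      label = "yeast RNA (per-nucleotide unit, 50% GC)",
      formula = "C9.5H11.75N3.75O7P",
      convention = "nucleic_acid", n_r_C_override = 3.1,
      rna_basis = list(carbon_per_unit = 9.5, ribose_carbon = 5,
                       ribose_electrons = 20)),
    casamino = list(
      label = "casamino acids (protein-like approximation)",
      formula = "CH1.57N0.27O0.30S0.013",
      convention = "biomass", n_r_C_override = NA_real_),
    ribose = list(
      label = "D-ribose",
      formula = "C5H10O5",
      convention = "biomass", n_r_C_override = NA_real_),
    glucose = list(
      label = "D-glucose",
      formula = "C6H12O6",
      convention = "biomass", n_r_C_override = NA_real_)
  )
}
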