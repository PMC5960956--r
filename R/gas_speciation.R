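# Gas/liquid speciation: from raw microcosm measurements (headspace mixing
# ratios, dissolved concentrations, pH) to total umol per gram fresh weight.

#' Vial geometry of a sealed microcosm
#'
#' @param total_ml total vial volume (ml).
#' @param liquid_ml liquid (aqueous) volume (ml); the headspace is the
#'   difference.
#' @param fresh_weight_g grams fresh weight of gut content, the
#'   normalization basis for all amounts.
#' @return object of class `vial_geometry` with an additional
#'   `headspace_ml` field.
#' @export
#' @examples
#' vial_geometry()  # the 27-ml tube with 10 ml liquid and 1 g fresh weight
vial_geometry <- function(total_ml = 27, liquid_ml = 10, fresh_weight_g = 1) {
  stopifnot(is.numeric(total_ml), is.numeric(liquid_ml),
            is.numeric(fresh_weight_g))
  if (!(liquid_ml > 0 && liquid_ml < total_ml)) {
    stop("need 0 < liquid_ml < total_ml")
  }
  if (fresh_weight_g <= 0) stop("fresh_weight_g must be > 0")
  structure(list(total_ml = total_ml, liquid_ml = liquid_ml,
                 fresh_weight_g = fresh_weight_g,
                 headspace_ml = total_ml - liquid_ml),
            class = "vial_geometry")
}

#' Headspace amount of a gas from the ideal gas law
#'
#' `n = x * P * V_headspace / (R * T)`, returned in micromoles.
#'
#' @param mixing_ratio headspace mol fraction of the gas, in `[0, 1]`.
#' @param pressure_kPa absolute headspace pressure (kPa).
#' @param temperature_K headspace temperature (K).
#' @param geom [vial_geometry()].
#' @return umol of gas in the headspace. Vectorized over the observation
#'   arguments.
#' @export
#' @examples
#' headspace_amount(0.01, 161.325, 295.15, vial_geometry())  # ~11.2 umol
headspace_amount <- function(mixing_ratio, pressure_kPa, temperature_K,
                             geom = vial_geometry()) {
  stopifnot(inherits(geom, "vial_geometry"))
  if (any(mixing_ratio < 0 | mixing_ratio > 1, na.rm = TRUE)) {
    stop("mixing_ratio must lie in [0, 1]")
  }
  if (any(pressure_kPa <= 0, na.rm = TRUE)) stop("pressure must be > 0")
  if (any(temperature_K <= 0, na.rm = TRUE)) stop("temperature must be > 0")
  # kPa * ml / (J mol^-1 K^-1 * K) = 1e-3 J / (J/mol) = mmol -> x1000 = umol
  1000 * mixing_ratio * pressure_kPa * geom$headspace_ml /
    (.R_GAS * temperature_K)
}

#' Dissolved amount of a gas at equilibrium with the headspace
#'
#' Uses the Bunsen-style solubility coefficient: the dissolved gas volume
#' (at STP) equals `alpha * (p / 1 atm) * V_liquid`, converted to moles by
#' the STP molar volume.
#'
#' @param mixing_ratio,pressure_kPa as in [headspace_amount()]; the
#'   partial pressure is their product.
#' @param gas gas name; must have an entry in `constants$bunsen`.
#' @param geom [vial_geometry()].
#' @param constants [physical_constants()].
#' @return umol of gas dissolved in the liquid phase.
#' @export
dissolved_gas_amount <- function(mixing_ratio, pressure_kPa, gas,
                                 geom = vial_geometry(),
                                 constants = physical_constants()) {
  stopifnot(inherits(geom, "vial_geometry"),
            inherits(constants, "physical_constants"))
  if (!(gas %in% names(constants$bunsen))) {
    stop("no solubility coefficient configured for gas ", sQuote(gas))
  }
  alpha <- constants$bunsen[[gas]]
  p_atm <- mixing_ratio * pressure_kPa / constants$atm_kPa
  # alpha * p * V_liq [ml gas at STP] -> umol via molar volume (L/mol)
  alpha * p_atm * geom$liquid_ml / constants$molar_volume_stp * 1000
}

#' Bicarbonate pool from dissolved CO2 and pH
#'
#' Henderson-Hasselbalch: `HCO3- = CO2(aq) * 10^(pH - pKa)`. The second
#' dissociation (carbonate) is neglected, valid for pH well below pKa2.
#'
#' @param dissolved_co2 umol of dissolved CO2.
#' @param pH measured pH of the liquid phase.
#' @param constants [physical_constants()] carrying `pKa_co2`.
#' @return umol of bicarbonate.
#' @export
#' @examples
#' bicarbonate_amount(10, 7.0)  # ~44.7 umol at pKa 6.35
bicarbonate_amount <- function(dissolved_co2, pH,
                               constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(dissolved_co2 < 0, na.rm = TRUE)) stop("dissolved_co2 must be >= 0")
  dissolved_co2 * 10^(pH - constants$pKa_co2)
}

#' Total analyte amount per gram fresh weight at one time point
#'
#' For a gas: headspace plus dissolved pools, plus the bicarbonate pool
#' for CO2 (pH is then required -- there is no silent omission of the
#' bicarbonate pool). For a dissolved organic: concentration times liquid
#' volume. The sum is divided by the fresh weight of gut content.
#'
#' @param analyte analyte name (gases must be present in
#'   `constants$bunsen`; anything else is treated as a dissolved organic).
#' @param mixing_ratio,pressure_kPa,temperature_K gas observation (ignored
#'   for organics).
#' @param concentration_mM liquid-phase concentration (organics only).
#' @param pH required when `analyte == "CO2"`.
#' @param geom [vial_geometry()].
#' @param constants [physical_constants()].
#' @return umol per g fresh weight.
#' @export
total_amount_per_gfw <- function(analyte,
                                 mixing_ratio = NULL, pressure_kPa = NULL,
                                 temperature_K = NULL,
                                 concentration_mM = NULL,
                                 pH = NULL,
                                 geom = vial_geometry(),
                                 constants = physical_constants()) {
  stopifnot(inherits(geom, "vial_geometry"))
  is_gas <- analyte %in% names(constants$bunsen)
  if (is_gas) {
    if (is.null(mixing_ratio) || is.null(pressure_kPa) ||
        is.null(temperature_K)) {
      stop("gas analyte ", sQuote(analyte),
           " needs mixing_ratio, pressure_kPa and temperature_K")
    }
    total <- headspace_amount(mixing_ratio, pressure_kPa, temperature_K,
                              geom) +
      dissolved_gas_amount(mixing_ratio, pressure_kPa, analyte, geom,
                           constants)
    if (analyte == "CO2") {
      if (is.null(pH) || any(is.na(pH))) {
        stop("CO2 speciation requires pH (bicarbonate pool)")
      }
      diss <- dissolved_gas_amount(mixing_ratio, pressure_kPa, analyte,
                                   geom, constants)
      total <- total + bicarbonate_amount(diss, pH, constants)
    }
  } else {
    if (is.null(concentration_mM)) {
      stop("dissolved analyte ", sQuote(analyte), " needs concentration_mM")
    }
    # mM * ml = umol
    total <- concentration_mM * geom$liquid_ml
  }
  total / geom$fresh_weight_g
}

#' Convert umol per g fresh weight into microcosm millimolar
#'
#' `mM = amount * fresh_weight / liquid_volume`. With the standard
#' geometry (1 g fresh weight in 10 ml) the factor is 0.1: 100 umol/g_FW
#' equals 10 mM.
#'
#' @param amount_per_gfw umol per g fresh weight.
#' @param geom [vial_geometry()].
#' @return concentration in mmol per liter of microcosm liquid.
#' @export
to_millimolar <- function(amount_per_gfw, geom = vial_geometry()) {
  stopifnot(inherits(geom, "vial_geometry"))
  amount_per_gfw * geom$fresh_weight_g / geom$liquid_ml
}

#' @rdname to_millimolar
#' @param mM concentration in mmol per liter of microcosm.
#' @export
from_millimolar <- function(mM, geom = vial_geometry()) {
  stopifnot(inherits(geom, "vial_geometry"))
  mM * geom$liquid_ml / geom$fresh_weight_g
}

#' Speciate a measurement table
#'
#' Applies [total_amount_per_gfw()] row-wise to a tidy measurement table
#' and returns per-(treatment, replicate, time, analyte) amounts.
#'
#' The expected columns are `treatment`, `replicate`, `time_h`, `analyte`,
#' `phase` (`"headspace"` or `"liquid"`), `value`, `unit` (`"mol_fraction"`
#' for headspace rows, `"mM"` for liquid rows), and for headspace rows
#' `pressure_kPa`, `temperature_K` and (CO2 only) `pH`.
#'
#' @param measurements data.frame in the measurement schema.
#' @param geom [vial_geometry()].
#' @param constants [physical_constants()].
#' @return data.frame with columns `treatment`, `replicate`, `time_h`,
#'   `analyte`, `amount_umol_per_gfw`.
#' @export
speciate <- function(measurements, geom = vial_geometry(),
                     constants = physical_constants()) {
  req <- c("treatment", "replicate", "time_h", "analyte", "phase",
           "value", "unit")
  missing <- setdiff(req, names(measurements))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_phase <- setdiff(unique(measurements$phase), c("headspace", "liquid"))
  if (length(bad_phase) > 0) {
    stop("unknown phase value(s): ", paste(bad_phase, collapse = ", "))
  }
  n <- nrow(measurements)
  amount <- numeric(n)
  for (i in seq_len(n)) {
    row <- measurements[i, ]
    if (row$phase == "headspace") {
      if (!identical(row$unit, "mol_fraction")) {
        stop("headspace rows must be in mol_fraction (row ", i, ")")
      }
      amount[i] <- total_amount_per_gfw(
        analyte = row$analyte, mixing_ratio = row$value,
        pressure_kPa = row$pressure_kPa, temperature_K = row$temperature_K,
        pH = if ("pH" %in% names(row)) row$pH else NULL,
        geom = geom, constants = constants)
    } else {
      if (!identical(row$unit, "mM")) {
        stop("liquid rows must be in mM (row ", i, ")")
      }
      amount[i] <- total_amount_per_gfw(
        analyte = row$analyte, concentration_mM = row$value,
        geom = geom, constants = constants)
    }
  }
  out <- measurements[, c("treatment", "replicate", "time_h", "analyte")]
  out$amount_umol_per_gfw <- amount
  rownames(out) <- NULL
  out
}
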