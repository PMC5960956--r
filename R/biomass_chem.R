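# Elemental-formula chemistry: parsing, per-carbon molar mass, carbon
# oxidation state and degree of reduction.

#' Parse a condensed elemental formula
#'
#' Parses strings such as `"CH1.57N0.27O0.30S0.013"` into a coefficient
#' map. Brackets, parentheses, underscores and a trailing polymer marker
#' (`_n` or `n`) are tolerated and stripped, so the common printed form
#' `"[CH1.613O0.557N0.158]n"` parses too. An element symbol without an
#' explicit coefficient counts once; repeated symbols accumulate.
#'
#' @param text formula string.
#' @param label free-text label stored on the result (defaults to the
#'   input string).
#' @return an object of class `elemental_formula`: a list with
#'   `coefficients` (named numeric, element -> per-unit coefficient) and
#'   `label`.
#' @export
#' @examples
#' parse_formula("CH1.57N0.27O0.30S0.013")
#' parse_formula("H2")
parse_formula <- function(text, label = text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  raw <- text
  # strip decoration: brackets, parens, whitespace, underscores, trailing n
  s <- gsub("[][()_ ]", "", raw)
  s <- sub("n$", "", s)
  if (!nzchar(s)) stop("empty formula: ", sQuote(raw))
  coef <- numeric(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substring(s, i)
    sym <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    if (length(sym) == 0L) {
      stop("malformed formula ", sQuote(raw), ": unexpected character ",
           sQuote(substring(s, i, i)), " at offset ", i)
    }
    # prefer the 2-letter symbol only if it is a known element
    if (nchar(sym) == 2L && !(sym %in% names(.ATOMIC_WEIGHTS))) {
      sym <- substring(sym, 1L, 1L)
    }
    if (!(sym %in% names(.ATOMIC_WEIGHTS))) {
      stop("unknown element symbol ", sQuote(sym), " at offset ", i,
           " in formula ", sQuote(raw))
    }
    i <- i + nchar(sym)
    rest <- substring(s, i)
    num <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+", rest))
    if (length(num) == 1L && nzchar(num)) {
      k <- suppressWarnings(as.numeric(num))
      if (is.na(k)) {
        stop("malformed coefficient ", sQuote(num), " at offset ", i,
             " in formula ", sQuote(raw))
      }
      i <- i + nchar(num)
    } else {
      k <- 1
    }
    coef[sym] <- (if (sym %in% names(coef)) coef[[sym]] else 0) + k
  }
  elemental_formula(coef, label = label)
}

#' Construct an elemental formula from a coefficient map
#'
#' @param coefficients named numeric vector, element symbol -> coefficient.
#' @param label free-text label.
#' @return `elemental_formula` object.
#' @export
elemental_formula <- function(coefficients, label = "") {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (any(!nzchar(names(coefficients)))) stop("unnamed coefficient")
  unknown <- setdiff(names(coefficients), names(.ATOMIC_WEIGHTS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(coefficients)) || any(coefficients < 0)) {
    stop("coefficients must be finite and >= 0")
  }
  structure(list(coefficients = coefficients, label = label),
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", if (nzchar(x$label)) x$label else "", "\n")
  cat(" ", format_formula(x), "\n")
  invisible(x)
}

#' Serialize an elemental formula back to condensed text
#'
#' Round-trip stable with [parse_formula()]: parsing the output yields the
#' same coefficient map.
#'
#' @param f `elemental_formula`.
#' @return character scalar.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  co <- f$coefficients
  paste0(names(co),
         ifelse(co == 1, "", format(co, trim = TRUE, scientific = FALSE)),
         collapse = "")
}

.coef <- function(f, el) {
  if (el %in% names(f$coefficients)) f$coefficients[[el]] else 0
}

#' Molar mass of one formula unit
#'
#' @param f `elemental_formula`.
#' @return g per mol of formula unit.
#' @export
molar_mass <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  sum(f$coefficients * .ATOMIC_WEIGHTS[names(f$coefficients)])
}

#' Molar mass per mole of carbon
#'
#' Total formula-unit mass divided by the carbon coefficient, i.e. the
#' grams of substrate that carry one mole of carbon. For a one-carbon
#' biomass formula this is simply the formula mass.
#'
#' @param f `elemental_formula` with carbon coefficient > 0.
#' @return g per mol C.
#' @export
#' @examples
#' f <- parse_formula("CH1.613O0.557N0.158P0.012S0.003K0.022Mg0.003Ca0.001")
#' molar_mass_per_carbon(f)   # ~26.2 g per mol C
molar_mass_per_carbon <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  c_coef <- .coef(f, "C")
  if (c_coef <= 0) stop("formula has no carbon; per-carbon mass undefined")
  molar_mass(f) / c_coef
}

#' Oxidation-state convention
#'
#' Fixed oxidation states assigned to every element except carbon, which
#' is solved for from the charge balance. Elements in `ignore` contribute
#' nothing to the balance. Two stock conventions cover the substrates
#' handled here:
#'
#' * `"biomass"` (default): H +1, O -2, N -3, S -2; K, Mg, Ca and P
#'   ignored. Mineral counter-ions and phosphate are treated as redox
#'   spectators of the organic carbon skeleton.
#' * `"nucleic_acid"`: as above but phosphorus counted at +5 (the
#'   phosphodiester backbone is part of the formula unit), net charge 0.
#'
#' @param states named numeric, element -> fixed oxidation state.
#' @param ignore character vector of elements excluded from the balance.
#' @param charge net charge of the formula unit.
#' @return object of class `oxidation_convention`.
#' @export
oxidation_convention <- function(states = c(H = 1, O = -2, N = -3, S = -2),
                                 ignore = c("K", "Mg", "Ca", "P"),
                                 charge = 0) {
  stopifnot(is.numeric(states), !is.null(names(states)))
  if ("C" %in% names(states)) stop("carbon cannot have a fixed state; it is solved for")
  structure(list(states = states, ignore = ignore, charge = charge),
            class = "oxidation_convention")
}

#' @rdname oxidation_convention
#' @export
convention_biomass <- function() oxidation_convention()

#' @rdname oxidation_convention
#' @export
convention_nucleic_acid <- function() {
  oxidation_convention(states = c(H = 1, O = -2, N = -3, S = -2, P = 5),
                       ignore = c("K", "Mg", "Ca"))
}

.get_convention <- function(conv) {
  if (inherits(conv, "oxidation_convention")) return(conv)
  if (is.character(conv) && length(conv) == 1L) {
    return(switch(conv,
                  biomass = convention_biomass(),
                  nucleic_acid = convention_nucleic_acid(),
                  stop("unknown convention name: ", sQuote(conv))))
  }
  stop("conv must be an oxidation_convention or a stock convention name")
}

#' Mean carbon oxidation state
#'
#' Solves the charge balance `sum(coef_e * state_e) + n_C * C_ox = charge`
#' for the mean oxidation state of carbon, with ignored elements excluded.
#'
#' @param f `elemental_formula` with carbon coefficient > 0.
#' @param conv an [oxidation_convention()] or a stock name
#'   (`"biomass"`, `"nucleic_acid"`).
#' @return dimensionless mean oxidation state of carbon.
#' @export
#' @examples
#' carbon_oxidation_state(parse_formula("CH4"))               # -4
#' carbon_oxidation_state(parse_formula("C9.5H11.75N3.75O7P"),
#'                        "nucleic_acid")                     # ~ +0.9
carbon_oxidation_state <- function(f, conv = convention_biomass()) {
  stopifnot(inherits(f, "elemental_formula"))
  conv <- .get_convention(conv)
  c_coef <- .coef(f, "C")
  if (c_coef <= 0) stop("formula has no carbon; oxidation state undefined")
  other <- setdiff(names(f$coefficients), c("C", conv$ignore))
  missing <- setdiff(other, names(conv$states))
  if (length(missing) > 0) {
    stop("element(s) ", paste(missing, collapse = ", "),
         " have no oxidation state in the convention and are not ignored")
  }
  contrib <- if (length(other)) {
    sum(f$coefficients[other] * conv$states[other])
  } else 0
  (conv$charge - contrib) / c_coef
}

#' Degree of reduction per carbon
#'
#' Electrons released per mole of carbon on complete oxidation:
#' `4 - carbon_oxidation_state`. This is the substrate-side electron
#' currency `n_r_C` of the recovery accounting.
#'
#' @inheritParams carbon_oxidation_state
#' @return electrons per mol C.
#' @export
#' @examples
#' degree_of_reduction_per_carbon(parse_formula("CH2O"))  # 4
degree_of_reduction_per_carbon <- function(f, conv = convention_biomass()) {
  4 - carbon_oxidation_state(f, conv)
}

#' Reducing equivalents of a neutral C-H-O compound
#'
#' Electrons obtained by complete oxidation of a neutral compound
#' containing only carbon, hydrogen and oxygen: `4c + h - 2o`. Compounds
#' with other elements must come from the [compound_registry()] instead.
#'
#' @param f `elemental_formula` (or formula string) over C, H, O only.
#' @return integer electron count.
#' @export
#' @examples
#' reducing_equivalents_of("C2H4O2")  # acetate (as acetic acid): 8
#' reducing_equivalents_of("H2")      # 2
reducing_equivalents_of <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"))
  extra <- setdiff(names(f$coefficients), c("C", "H", "O"))
  if (length(extra) > 0) {
    stop("unsupported element(s) ", paste(extra, collapse = ", "),
         " for electron counting; use the compound registry")
  }
  4 * .coef(f, "C") + .coef(f, "H") - 2 * .coef(f, "O")
}
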