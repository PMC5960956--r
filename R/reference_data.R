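# Published reference values used for internal-consistency validation.

#' Published recovery percentages for the three microcosm treatments
#'
#' The published end-of-incubation carbon and reducing-equivalent
#' recovery percentages for gut-content microcosms supplemented with
#' yeast cell lysate, protein (bovine serum albumin) or yeast RNA. These
#' printed values serve as inputs for internal-consistency checks of the
#' stoichiometric conversion identity
#' `electron_pct = carbon_pct * (gamma_X / c_X) / n_r_C`
#' and of the column totals; they are not outputs of this package's
#' pipeline.
#'
#' `NA` in the carbon column marks a product that carries no carbon (H2);
#' `NA` in the electron column marks one that carries no reducing
#' equivalents (CO2). Products with no net increase during the incubation
#' are absent from a treatment's rows. The attribute `"printed_totals"`
#' holds the published column totals (including the ribose-basis
#' parenthetical totals for the RNA treatment), and `"n_r_C"` the
#' published substrate degrees of reduction per carbon.
#'
#' @return data.frame with columns `treatment`
#'   (`"lysate"`, `"protein"`, `"rna"`), `product`, `carbon_pct`,
#'   `electron_pct`.
#' @export
reference_recoveries <- function() {
  df <- rbind(
    data.frame(treatment = "lysate",
               product = c("CO2", "H2", "acetate", "methyl_butyrate",
                           "succinate", "propionate", "butyrate",
                           "lactate"),
               carbon_pct = c(5.2, NA, 20.2, 18.1, 9.0, 0.8, 1.9, 0.1),
               electron_pct = c(NA, 0.7, 20.1, 23.4, 7.8, 0.9, 2.4, 0.1),
               stringsAsFactors = FALSE),
    data.frame(treatment = "protein",
               product = c("CO2", "H2", "acetate", "methyl_butyrate",
                           "propionate", "butyrate"),
               carbon_pct = c(3.1, NA, 15.0, 13.8, 4.8, 4.0),
               electron_pct = c(NA, 0.1, 14.5, 17.4, 5.4, 4.9),
               stringsAsFactors = FALSE),
    data.frame(treatment = "rna",
               product = c("CO2", "H2", "acetate", "succinate",
                           "propionate", "formate", "lactate"),
               carbon_pct = c(6.9, NA, 8.9, 4.7, 0.3, 1.1, 1.7),
               electron_pct = c(NA, 3.1, 11.5, 5.3, 0.4, 0.7, 2.2),
               stringsAsFactors = FALSE)
  )
  rownames(df) <- NULL
  structure(df,
            printed_totals = list(
              lysate = c(carbon_pct = 55.3, electron_pct = 55.4),
              protein = c(carbon_pct = 40.4, electron_pct = 42.1),
              rna = c(carbon_pct = 23.6, electron_pct = 23.2),
              rna_ribose_basis = c(carbon_pct = 44.9, electron_pct = 34.1)),
            n_r_C = c(lysate = 4.019, protein = 4.145, rna = 3.1))
}
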