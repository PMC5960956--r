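# Net fermentation-product profiles over unsupplemented controls and the
# carbon / reducing-equivalent recovery accounting.

#' Substrate specification for recovery accounting
#'
#' Carries the total carbon supplemented per microcosm (`n_c_S`, umol C),
#' the degree of reduction per carbon (`n_r_C`, electrons per mol C) and
#' the derived total reducing equivalents `n_r_S = n_c_S * n_r_C`.
#'
#' @param label substrate label.
#' @param carbon_umol total carbon added per microcosm (umol C), > 0.
#' @param n_r_C degree of reduction per carbon, > 0.
#' @param n_r_C_provenance `"computed"` if derived from the elemental
#'   formula, `"printed-override"` if a published constant was imposed.
#' @param n_r_C_computed the convention-derived value, kept for reporting
#'   when an override is in force.
#' @param rna_basis optional list describing the RNA/ribose carbon basis
#'   (`carbon_per_unit`, `ribose_carbon`, `ribose_electrons`); required by
#'   [ribose_basis()].
#' @return object of class `substrate_spec`.
#' @export
substrate_spec <- function(label, carbon_umol, n_r_C,
                           n_r_C_provenance = "computed",
                           n_r_C_computed = n_r_C,
                           rna_basis = NULL) {
  stopifnot(is.numeric(carbon_umol), length(carbon_umol) == 1L,
            is.numeric(n_r_C), length(n_r_C) == 1L)
  if (carbon_umol <= 0) stop("carbon_umol must be > 0")
  if (n_r_C <= 0) stop("n_r_C must be > 0")
  structure(list(label = label,
                 n_c_S = carbon_umol,
                 n_r_C = n_r_C,
                 n_r_S = carbon_umol * n_r_C,
                 n_r_C_provenance = n_r_C_provenance,
                 n_r_C_computed = n_r_C_computed,
                 rna_basis = rna_basis),
            class = "substrate_spec")
}

#' Build a substrate spec from a shipped preset
#'
#' Looks up the preset formula (see [substrate_presets()]), computes the
#' convention-based degree of reduction, and applies the published
#' override when the preset carries one; the computed value is retained in
#' `n_r_C_computed` for comparison.
#'
#' @param name preset name, e.g. `"yeast_lysate"`, `"bsa_protein"`,
#'   `"yeast_rna"`.
#' @param carbon_umol total carbon added per microcosm (umol C).
#' @return [substrate_spec()].
#' @export
#' @examples
#' s <- preset_substrate("yeast_lysate", carbon_umol = 2290)
#' s$n_r_C            # 4.019 (published constant)
#' s$n_r_C_computed   # identical here; differs for the protein preset
preset_substrate <- function(name, carbon_umol) {
  presets <- substrate_presets()
  if (!(name %in% names(presets))) {
    stop("unknown preset ", sQuote(name), "; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  f <- parse_formula(p$formula, label = p$label)
  computed <- degree_of_reduction_per_carbon(f, p$convention)
  override <- p$n_r_C_override
  use_override <- !is.na(override)
  substrate_spec(
    label = p$label,
    carbon_umol = carbon_umol,
    n_r_C = if (use_override) override else computed,
    n_r_C_provenance = if (use_override) "printed-override" else "computed",
    n_r_C_computed = computed,
    rna_basis = p$rna_basis
  )
}

#' Substrate carbon from an amount descriptor
#'
#' Mass of substrate divided by its per-carbon molar mass. The mass comes
#' either from a dry-weight fraction of a liquid volume (cell lysates) or
#' from a mass concentration (protein/RNA stock solutions).
#'
#' @param volume_ml volume of substrate solution added (ml).
#' @param molar_mass_per_c grams per mol carbon of the substrate, e.g.
#'   from [molar_mass_per_carbon()].
#' @param dry_weight_fraction dry mass per ml expressed as a fraction of
#'   1 g/ml (so 6.0% dry weight is 0.060); mutually exclusive with
#'   `mass_conc_mg_ml`.
#' @param mass_conc_mg_ml substrate concentration in mg/ml.
#' @return umol of carbon.
#' @export
#' @examples
#' y <- parse_formula(substrate_presets()$yeast_lysate$formula)
#' substrate_carbon(1, molar_mass_per_carbon(y),
#'                  dry_weight_fraction = 0.060) / 1000  # ~2.3 mmol C
substrate_carbon <- function(volume_ml, molar_mass_per_c,
                             dry_weight_fraction = NULL,
                             mass_conc_mg_ml = NULL) {
  if (!is.numeric(molar_mass_per_c) || molar_mass_per_c <= 0) {
    stop("molar_mass_per_c must be > 0")
  }
  if (is.null(dry_weight_fraction) == is.null(mass_conc_mg_ml)) {
    stop("give exactly one of dry_weight_fraction or mass_conc_mg_ml")
  }
  mass_g <- if (!is.null(dry_weight_fraction)) {
    volume_ml * dry_weight_fraction
  } else {
    volume_ml * mass_conc_mg_ml / 1000
  }
  mass_g / molar_mass_per_c * 1e6
}

#' Net product profiles: treatment minus unsupplemented control
#'
#' Replicate means are computed per arm at each matched time point and
#' subtracted; negative net values are retained in the series. Sampling
#' grids must match exactly between arms (no interpolation) and every
#' analyte must be present in both arms.
#'
#' @param amounts tidy amounts table as returned by [speciate()]:
#'   columns `treatment`, `replicate`, `time_h`, `analyte`,
#'   `amount_umol_per_gfw`.
#' @param treatment,control treatment labels selecting the two arms.
#' @param transient_tol amounts at or below this value (umol/g_FW) count
#'   as "no net product" when flagging transients.
#' @return object of class `net_profiles`: a data.frame with columns
#'   `analyte`, `time_h`, `net_umol_per_gfw`, plus a per-analyte summary
#'   in `attr(, "summary")` (`end_net`, `max_net`, `transient`).
#' @export
net_products <- function(amounts, treatment, control = "control",
                         transient_tol = 0.5) {
  req <- c("treatment", "replicate", "time_h", "analyte",
           "amount_umol_per_gfw")
  missing <- setdiff(req, names(amounts))
  if (length(missing) > 0) {
    stop("amounts table lacks column(s): ", paste(missing, collapse = ", "))
  }
  trt <- amounts[amounts$treatment == treatment, ]
  ctl <- amounts[amounts$treatment == control, ]
  if (nrow(trt) == 0) stop("no rows for treatment ", sQuote(treatment))
  if (nrow(ctl) == 0) stop("no rows for control ", sQuote(control))
  grid_t <- sort(unique(trt$time_h))
  grid_c <- sort(unique(ctl$time_h))
  if (!identical(grid_t, grid_c)) {
    stop("sampling grids differ between arms (no interpolation is done): ",
         "treatment {", paste(grid_t, collapse = ", "), "} vs control {",
         paste(grid_c, collapse = ", "), "}")
  }
  an_t <- sort(unique(trt$analyte))
  an_c <- sort(unique(ctl$analyte))
  only <- c(setdiff(an_t, an_c), setdiff(an_c, an_t))
  if (length(only) > 0) {
    stop("analyte(s) present in only one arm: ", paste(only, collapse = ", "))
  }
  mean_by <- function(d) {
    aggregate(amount_umol_per_gfw ~ analyte + time_h, data = d, FUN = mean)
  }
  mt <- mean_by(trt)
  mc <- mean_by(ctl)
  m <- merge(mt, mc, by = c("analyte", "time_h"),
             suffixes = c("_trt", "_ctl"))
  m <- m[order(m$analyte, m$time_h), ]
  out <- data.frame(analyte = m$analyte, time_h = m$time_h,
                    net_umol_per_gfw =
                      m$amount_umol_per_gfw_trt - m$amount_umol_per_gfw_ctl,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  end_t <- max(grid_t)
  summ <- do.call(rbind, lapply(split(out, out$analyte), function(d) {
    d <- d[order(d$time_h), ]
    end_net <- d$net_umol_per_gfw[d$time_h == end_t]
    interior <- d$net_umol_per_gfw[d$time_h > min(d$time_h) &
                                     d$time_h < end_t]
    max_interior <- if (length(interior)) max(interior) else -Inf
    data.frame(analyte = d$analyte[1], end_net = end_net,
               max_net = max(d$net_umol_per_gfw),
               transient = (max_interior > transient_tol &&
                              end_net <= transient_tol),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(out, summary = summ, end_time = end_t,
            transient_tol = transient_tol,
            class = c("net_profiles", "data.frame"))
}

#' Carbon and reducing-equivalent recovery table
#'
#' For each analyte with a positive end-of-incubation net amount, the
#' carbon recovery is `net * c_X / n_c_S * 100` and the electron recovery
#' `net * gamma_X / n_r_S * 100`, where `c_X` and `gamma_X` are the
#' registry carbon atoms and reducing equivalents of the compound.
#' Hydrogen (0 carbons) contributes only to the electron column and CO2
#' (0 electrons) only to the carbon column. Analytes without a net
#' increase are excluded rather than clipped to zero, and totals are sums
#' of unrounded included entries.
#'
#' @param net [net_products()] result.
#' @param substrate [substrate_spec()].
#' @param registry [compound_registry()]-shaped data.frame.
#' @param at time point (h) at which nets are evaluated; defaults to the
#'   final grid point.
#' @param exclusion_tol nets at or below this value (umol/g_FW) are marked
#'   excluded ("no net increase").
#' @return object of class `recovery_table`: data.frame with columns
#'   `product`, `net_umol_per_gfw`, `carbon_pct`, `electron_pct`,
#'   `included`; totals in `attr(, "totals")`.
#' @export
recovery_table <- function(net, substrate, registry = compound_registry(),
                           at = NULL, exclusion_tol = 0.5) {
  stopifnot(inherits(net, "net_profiles"),
            inherits(substrate, "substrate_spec"))
  if (substrate$n_r_C <= 0) stop("substrate n_r_C must be > 0")
  grid <- sort(unique(net$time_h))
  if (is.null(at)) at <- max(grid)
  if (!(at %in% grid)) {
    stop("time ", at, " h is not a grid point; available: ",
         paste(grid, collapse = ", "))
  }
  end <- net[net$time_h == at, ]
  unknown <- setdiff(end$analyte, registry$name)
  if (length(unknown) > 0) {
    stop("analyte(s) missing from the compound registry: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(end$analyte, registry$name)
  cx <- registry$carbon[idx]
  gx <- registry$electrons[idx]
  included <- end$net_umol_per_gfw > exclusion_tol
  carbon_pct <- ifelse(included & cx > 0,
                       end$net_umol_per_gfw * cx / substrate$n_c_S * 100,
                       NA_real_)
  electron_pct <- ifelse(included & gx > 0,
                         end$net_umol_per_gfw * gx / substrate$n_r_S * 100,
                         NA_real_)
  out <- data.frame(product = end$analyte,
                    net_umol_per_gfw = end$net_umol_per_gfw,
                    carbon_pct = carbon_pct,
                    electron_pct = electron_pct,
                    included = included,
                    stringsAsFactors = FALSE)
  out <- out[order(-replace(out$carbon_pct, is.na(out$carbon_pct), -Inf)), ]
  rownames(out) <- NULL
  totals <- c(carbon_pct = sum(out$carbon_pct[out$included], na.rm = TRUE),
              electron_pct = sum(out$electron_pct[out$included],
                                 na.rm = TRUE))
  structure(out, totals = totals, substrate = substrate, at = at,
            exclusion_tol = exclusion_tol,
            class = c("recovery_table", "data.frame"))
}

#' @export
print.recovery_table <- function(x, digits = 1, ...) {
  s <- attr(x, "substrate")
  cat("Recovery table --", s$label, "\n")
  cat(sprintf("  n_c_S = %.0f umol C, n_r_C = %.3f (%s), at %g h\n",
              s$n_c_S, s$n_r_C, s$n_r_C_provenance, attr(x, "at")))
  fmt <- function(v, inc) {
    ifelse(!inc, "-", ifelse(is.na(v), "NA", formatC(v, format = "f",
                                                     digits = digits)))
  }
  disp <- data.frame(product = x$product,
                     carbon_pct = fmt(x$carbon_pct, x$included),
                     electron_pct = fmt(x$electron_pct, x$included))
  print(disp, row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("  Total: C %.1f%%, e- %.1f%%\n",
              tot[["carbon_pct"]], tot[["electron_pct"]]))
  invisible(x)
}

#' Ribose-only recovery basis for RNA treatments
#'
#' Rescales the recovery totals of an RNA-substrate table onto the carbon
#' and electrons available from the RNA-derived ribose alone: of the 9.5
#' carbons of the per-nucleotide unit only the 5 ribose carbons (carrying
#' 20 electrons as the free pentose) are assumed fermentable. Carbon
#' totals are divided by `5/9.5`; electron totals by
#' `20 / (n_r_C * 9.5)`.
#'
#' @param table [recovery_table()] built against an RNA substrate (one
#'   whose spec carries an `rna_basis`).
#' @return named numeric vector `c(carbon_pct, electron_pct)` of rescaled
#'   totals.
#' @export
ribose_basis <- function(table) {
  stopifnot(inherits(table, "recovery_table"))
  s <- attr(table, "substrate")
  b <- s$rna_basis
  if (is.null(b)) {
    stop("ribose_basis applies only to RNA substrates (no rna_basis on ",
         sQuote(s$label), ")")
  }
  tot <- attr(table, "totals")
  c_frac <- b$ribose_carbon / b$carbon_per_unit
  e_frac <- b$ribose_electrons / (s$n_r_C * b$carbon_per_unit)
  c(carbon_pct = unname(tot[["carbon_pct"]] / c_frac),
    electron_pct = unname(tot[["electron_pct"]] / e_frac))
}
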