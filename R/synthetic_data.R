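# Synthetic-data generators: measurement tables and amplicon count tables
# with known ground truth, so every pipeline stage is testable offline.

# normalized logistic rising from exactly 0 at grid start to exactly 1 at
# grid end (recoveries are read at the final grid point, so the end value
# must hit the configured yield exactly)
.logistic_shape <- function(t, t0, t_end, lag, rate) {
  g <- function(u) 1 / (1 + exp(-rate * (u - lag)))
  (g(t) - g(t0)) / (g(t_end) - g(t0))
}

# transient bump: difference of two normalized logistics, peak scaled to 1;
# starts and ends at exactly 0
.transient_shape <- function(t, t0, t_end, rate) {
  rise <- .logistic_shape(t, t0, t_end, lag = t0 + (t_end - t0) / 4, rate)
  fall <- .logistic_shape(t, t0, t_end, lag = t0 + (t_end - t0) * 0.7,
                          rate)
  d <- rise - fall
  fine <- seq(t0, t_end, length.out = 512)
  peak <- max(.logistic_shape(fine, t0, t_end, t0 + (t_end - t0) / 4, rate) -
                .logistic_shape(fine, t0, t_end, t0 + (t_end - t0) * 0.7,
                                rate))
  d / peak
}

#' Fermentation scenario: the stated world of a microcosm experiment
#'
#' Describes a triplicate anoxic-microcosm experiment with known product
#' stoichiometry: a substrate, per-compound true carbon-yield fractions,
#' an optional hydrogen electron-yield fraction (H2 carries no carbon),
#' transient intermediates that rise and fall within the incubation, a
#' control-arm baseline, and a multiplicative measurement-noise level.
#'
#' @param substrate [substrate_spec()] (e.g. from [preset_substrate()]).
#' @param yields named vector of true carbon-yield fractions per compound
#'   (fraction of substrate carbon ending up in that product); must sum
#'   to at most 1 and every name must be in the registry.
#' @param h2_electron_yield fraction of substrate reducing equivalents
#'   recovered as H2.
#' @param transient_peaks named vector of peak carbon fractions for
#'   transient products (zero net at the end of incubation).
#' @param control_baseline named vector of end-of-incubation control-arm
#'   amounts (umol/g_FW) produced from endogenous substrates.
#' @param grid sampling grid in hours; default the 5-point design
#'   `c(0, 6, 12, 20, 30)` (the 4-point alternative is
#'   `c(0, 10, 20, 30)`).
#' @param replicates microcosms per arm (default 3).
#' @param noise_sd relative standard deviation of the multiplicative
#'   Gaussian measurement noise (default 0.05, typical chromatography
#'   repeatability); 0 disables noise.
#' @param lag,rate shared logistic time-course parameters (h, 1/h).
#' @param pH,pressure_kPa,temperature_K conditions at which observations
#'   are emitted.
#' @param geometry [vial_geometry()].
#' @param constants [physical_constants()].
#' @param registry [compound_registry()].
#' @return object of class `fermentation_scenario`.
#' @export
fermentation_scenario <- function(substrate,
                                  yields,
                                  h2_electron_yield = 0,
                                  transient_peaks = numeric(0),
                                  control_baseline = numeric(0),
                                  grid = c(0, 6, 12, 20, 30),
                                  replicates = 3,
                                  noise_sd = 0.05,
                                  lag = 8, rate = 0.35,
                                  pH = 7,
                                  pressure_kPa = 161.325,
                                  temperature_K = 295.15,
                                  geometry = vial_geometry(),
                                  constants = physical_constants(),
                                  registry = compound_registry()) {
  stopifnot(inherits(substrate, "substrate_spec"))
  if (is.null(names(yields)) || any(!nzchar(names(yields)))) {
    stop("yields must be a named vector")
  }
  unknown <- setdiff(c(names(yields), names(transient_peaks),
                       names(control_baseline)), registry$name)
  if (length(unknown) > 0) {
    stop("compound(s) not in registry: ", paste(unknown, collapse = ", "))
  }
  if (any(yields < 0 | yields > 1)) stop("yield fractions must lie in [0, 1]")
  if (sum(yields) > 1 + 1e-12) stop("carbon-yield fractions sum to > 1")
  idx <- match(names(yields), registry$name)
  if (any(registry$carbon[idx] == 0)) {
    stop("carbon-basis yields cannot include zero-carbon compounds; ",
         "use h2_electron_yield for H2")
  }
  e_frac <- yields * (registry$electrons[idx] / registry$carbon[idx]) /
    substrate$n_r_C
  if (sum(e_frac) + h2_electron_yield > 1 + 1e-9) {
    stop("implied electron fractions sum to > 1")
  }
  if (!identical(grid, sort(grid)) || anyDuplicated(grid) > 0) {
    stop("grid must be strictly increasing")
  }
  structure(list(substrate = substrate, yields = yields,
                 h2_electron_yield = h2_electron_yield,
                 transient_peaks = transient_peaks,
                 control_baseline = control_baseline,
                 grid = grid, replicates = replicates, noise_sd = noise_sd,
                 lag = lag, rate = rate, pH = pH,
                 pressure_kPa = pressure_kPa,
                 temperature_K = temperature_K,
                 geometry = geometry, constants = constants,
                 registry = registry),
            class = "fermentation_scenario")
}

# invert the speciation model: total umol in the vial -> headspace mixing
# ratio at the scenario's P/T (CO2 additionally split through the
# bicarbonate equilibrium); the total is linear in the mixing ratio
.gas_mixing_ratio <- function(total_umol, gas, sc) {
  g <- sc$geometry
  k <- sc$constants
  denom <- 1000 * sc$pressure_kPa * g$headspace_ml /
    (.R_GAS * sc$temperature_K) +
    k$bunsen[[gas]] * (sc$pressure_kPa / k$atm_kPa) * g$liquid_ml *
    1000 / k$molar_volume_stp *
    (1 + if (gas == "CO2") 10^(sc$pH - k$pKa_co2) else 0)
  total_umol / denom
}

#' Simulate a microcosm measurement table
#'
#' Generates the raw measurement table a wet-lab campaign would produce
#' under the scenario's stated world: per replicate and time point, true
#' product amounts follow the configured yields and logistic time
#' courses; gases are inverted through the speciation model into
#' headspace mixing ratios; organics are emitted as liquid-phase mM;
#' multiplicative noise is applied last. The true net amounts are
#' returned alongside as ground truth.
#'
#' @param sc [fermentation_scenario()].
#' @param seed integer seed; fixing it makes the output byte-identical
#'   across regenerations.
#' @return list with `measurements` (speciation-input schema),
#'   `truth` (data.frame `analyte`, `time_h`, `true_net_umol_per_gfw`)
#'   and the scenario.
#' @export
simulate_microcosm <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "fermentation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  g <- sc$geometry
  reg <- sc$registry
  t0 <- min(sc$grid)
  t_end <- max(sc$grid)
  s_t <- .logistic_shape(sc$grid, t0, t_end, sc$lag, sc$rate)
  d_t <- if (length(sc$transient_peaks)) {
    .transient_shape(sc$grid, t0, t_end, sc$rate)
  } else NULL

  analytes <- unique(c(names(sc$yields),
                       if (sc$h2_electron_yield > 0) "H2",
                       names(sc$transient_peaks),
                       names(sc$control_baseline)))
  # true net amount per g fresh weight, per analyte and time
  net_gfw <- sapply(analytes, function(a) {
    per_vial <- numeric(length(sc$grid))
    if (a %in% names(sc$yields)) {
      cx <- reg$carbon[reg$name == a]
      per_vial <- per_vial + sc$yields[[a]] * sc$substrate$n_c_S / cx * s_t
    }
    if (a == "H2" && sc$h2_electron_yield > 0) {
      per_vial <- per_vial + sc$h2_electron_yield * sc$substrate$n_r_S / 2 *
        s_t
    }
    if (a %in% names(sc$transient_peaks)) {
      cx <- reg$carbon[reg$name == a]
      per_vial <- per_vial +
        sc$transient_peaks[[a]] * sc$substrate$n_c_S / cx * d_t
    }
    per_vial / g$fresh_weight_g
  })
  ctrl_gfw <- sapply(analytes, function(a) {
    if (a %in% names(sc$control_baseline)) {
      sc$control_baseline[[a]] * s_t
    } else {
      numeric(length(sc$grid))
    }
  })

  gases <- names(sc$constants$bunsen)
  rows <- list()
  for (arm in c("treatment", "control")) {
    totals_gfw <- if (arm == "treatment") net_gfw + ctrl_gfw else ctrl_gfw
    for (rep_i in seq_len(sc$replicates)) {
      for (ti in seq_along(sc$grid)) {
        for (a in analytes) {
          total_vial <- totals_gfw[ti, a] * g$fresh_weight_g
          if (a %in% gases) {
            value <- .gas_mixing_ratio(total_vial, a, sc)
            phase <- "headspace"
            unit <- "mol_fraction"
          } else {
            value <- total_vial / g$liquid_ml
            phase <- "liquid"
            unit <- "mM"
          }
          if (sc$noise_sd > 0) {
            value <- max(0, value * (1 + stats::rnorm(1, 0, sc$noise_sd)))
            if (phase == "headspace") value <- min(value, 1)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            treatment = arm, replicate = rep_i, time_h = sc$grid[ti],
            analyte = a, phase = phase, value = value, unit = unit,
            pressure_kPa = sc$pressure_kPa,
            temperature_K = sc$temperature_K, pH = sc$pH,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  truth <- data.frame(
    analyte = rep(analytes, each = length(sc$grid)),
    time_h = rep(sc$grid, times = length(analytes)),
    true_net_umol_per_gfw = as.vector(net_gfw),
    stringsAsFactors = FALSE)
  list(measurements = measurements, truth = truth, scenario = sc)
}

#' Community scenario: a stable background with designated responders
#'
#' @param background named vector of background taxon proportions
#'   (summing to 1) shared by both arms at every period.
#' @param taxonomy data.frame `taxon`, `phylum`, `family` covering all
#'   background taxa.
#' @param responders data.frame `taxon`, `time_h`, `increase_pp` giving
#'   the true treatment-arm increase (percentage points of relative
#'   abundance) per sampling period; or a named numeric vector applied at
#'   every period after 0 h.
#' @param periods sampling periods in hours (default `c(0, 10, 20, 30)`).
#' @param depth sequencing depth per sample (reads).
#' @param dispersion Dirichlet concentration parameter for between-sample
#'   overdispersion (larger = milder; default 200); 0 disables the
#'   perturbation entirely.
#' @return object of class `community_scenario`.
#' @export
community_scenario <- function(background, taxonomy, responders,
                               periods = c(0, 10, 20, 30),
                               depth = 50000, dispersion = 200) {
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background proportions must sum to 1")
  }
  if (any(background < 0)) stop("background proportions must be >= 0")
  if (!all(names(background) %in% taxonomy$taxon)) {
    stop("taxonomy does not cover all background taxa")
  }
  if (is.numeric(responders) && !is.null(names(responders))) {
    responders <- do.call(rbind, lapply(names(responders), function(tx) {
      data.frame(taxon = tx, time_h = setdiff(periods, 0),
                 increase_pp = responders[[tx]], stringsAsFactors = FALSE)
    }))
  }
  if (nrow(responders) > 0) {
    if (!all(responders$taxon %in% names(background))) {
      stop("responder taxa must be present in the background")
    }
    if (!all(responders$time_h %in% periods)) {
      stop("responder periods must be sampling periods")
    }
  }
  if (depth <= 0 || depth != round(depth)) stop("depth must be a positive integer")
  sc <- structure(list(background = background, taxonomy = taxonomy,
                       responders = responders, periods = periods,
                       depth = depth, dispersion = dispersion),
                  class = "community_scenario")
  # fail at construction, not at generation time
  for (p in periods) .arm_proportions(sc, p, "treatment")
  sc
}

# treatment-arm true proportions at one period: responders elevated by
# their target increases, background renormalized over the rest
.arm_proportions <- function(sc, period, arm) {
  p <- sc$background
  if (arm == "control" || nrow(sc$responders) == 0) return(p)
  r <- sc$responders[sc$responders$time_h == period, ]
  if (nrow(r) == 0) return(p)
  inc <- r$increase_pp / 100
  new_resp <- p[r$taxon] + inc
  if (any(new_resp < 0) || any(new_resp > 1)) {
    stop("target increase drives a responder proportion outside [0, 1]")
  }
  others <- setdiff(names(p), r$taxon)
  scale <- (1 - sum(new_resp)) / sum(p[others])
  if (scale < 0) {
    stop("target increases leave no mass for the background community")
  }
  p[r$taxon] <- new_resp
  p[others] <- p[others] * scale
  p
}

#' Simulate amplicon count tables with known responders
#'
#' Draws multinomial counts per arm and period around the scenario's true
#' proportions (optionally Dirichlet-perturbed for overdispersion), or
#' returns exact expected counts with `expected = TRUE`. Ground truth is
#' reported as each taxon's maximum true increase over the control across
#' periods.
#'
#' @param sc [community_scenario()].
#' @param seed integer seed for reproducible draws.
#' @param expected if TRUE, emit noiseless expected counts
#'   (proportions times depth, rounded) instead of random draws.
#' @return list with `counts` (taxa x samples matrix), `metadata`
#'   (data.frame `sample`, `arm`, `time_h`), `taxonomy`, and `truth`
#'   (data.frame `taxon`, `max_true_increase_pp`).
#' @export
simulate_counts <- function(sc, seed = NULL, expected = FALSE) {
  stopifnot(inherits(sc, "community_scenario"))
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(sc$background)
  samples <- expand.grid(arm = c("treatment", "control"),
                         time_h = sc$periods, stringsAsFactors = FALSE)
  samples$sample <- paste0(substr(samples$arm, 1, 1), "_", samples$time_h,
                           "h")
  counts <- matrix(0L, nrow = length(taxa), ncol = nrow(samples),
                   dimnames = list(taxa, samples$sample))
  true_inc <- matrix(0, nrow = length(taxa), ncol = length(sc$periods),
                     dimnames = list(taxa, as.character(sc$periods)))
  for (i in seq_len(nrow(samples))) {
    p <- .arm_proportions(sc, samples$time_h[i], samples$arm[i])
    if (samples$arm[i] == "treatment") {
      pc <- .arm_proportions(sc, samples$time_h[i], "control")
      true_inc[, as.character(samples$time_h[i])] <- (p - pc) * 100
    }
    if (expected) {
      counts[, i] <- as.integer(round(p * sc$depth))
    } else {
      if (sc$dispersion > 0) {
        gam <- stats::rgamma(length(p), shape = sc$dispersion * p, rate = 1)
        if (sum(gam) > 0) p <- gam / sum(gam)
      }
      counts[, i] <- as.integer(stats::rmultinom(1, sc$depth, p))
    }
  }
  truth <- data.frame(taxon = taxa,
                      max_true_increase_pp = apply(true_inc, 1, max),
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(counts = counts,
       metadata = samples[, c("sample", "arm", "time_h")],
       taxonomy = sc$taxonomy, truth = truth)
}
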