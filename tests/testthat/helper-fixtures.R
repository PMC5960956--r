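# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# the published lysate-style world: yeast substrate, yields matching the
# published carbon recoveries, a transient formate intermediate
lysate_like_scenario <- function(noise_sd = 0, ...) {
  fermentation_scenario(
    substrate = preset_substrate("yeast_lysate", carbon_umol = 2290),
    yields = c(acetate = 0.202, CO2 = 0.052, methyl_butyrate = 0.181,
               succinate = 0.090, propionate = 0.008, butyrate = 0.019,
               lactate = 0.001),
    h2_electron_yield = 0.007,
    transient_peaks = c(formate = 0.01),
    control_baseline = c(acetate = 20, CO2 = 30),
    noise_sd = noise_sd,
    ...
  )
}

# RNA-style world on the 4-point grid with the published RNA recoveries
rna_like_scenario <- function(noise_sd = 0, ...) {
  fermentation_scenario(
    substrate = preset_substrate("yeast_rna", carbon_umol = 996),
    yields = c(acetate = 0.089, CO2 = 0.069, succinate = 0.047,
               propionate = 0.003, formate = 0.011, lactate = 0.017),
    h2_electron_yield = 0.031,
    grid = c(0, 10, 20, 30),
    noise_sd = noise_sd,
    ...
  )
}

# a random valid fermentation scenario drawn from the registry
random_scenario <- function(seed, noise_sd = 0) {
  set.seed(seed)
  reg <- compound_registry()
  carbon_compounds <- reg$name[reg$carbon > 0]
  k <- sample(2:5, 1)
  picked <- sample(carbon_compounds, k)
  # keep the electron budget open even for highly reduced products
  # (ethanol on an RNA substrate carries ~1.9 e- fractions per C fraction)
  y <- runif(k, 0.01, 0.45 / k)
  names(y) <- picked
  fermentation_scenario(
    substrate = preset_substrate(
      sample(c("yeast_lysate", "bsa_protein", "yeast_rna"), 1),
      carbon_umol = runif(1, 500, 5000)),
    yields = y,
    h2_electron_yield = runif(1, 0, 0.05),
    control_baseline = stats::setNames(runif(1, 0, 50), picked[1]),
    noise_sd = noise_sd
  )
}

# run the full pipeline on a simulated scenario and return the recovery
# table (exclusion_tol = 0 keeps arbitrarily small configured yields)
pipeline_recoveries <- function(sc, seed = 1, at = NULL) {
  sim <- simulate_microcosm(sc, seed = seed)
  amt <- speciate(sim$measurements, sc$geometry, sc$constants)
  net <- net_products(amt, "treatment", "control")
  recovery_table(net, sc$substrate, registry = sc$registry, at = at,
                 exclusion_tol = 0)
}

# small community world: 20 background taxa in 5 families
small_community <- function(responders, periods = c(0, 10, 20, 30),
                            depth = 50000, dispersion = 0) {
  taxa <- sprintf("PT%02d", 1:20)
  bg <- c(20, 15, 12, 10, 8, 7, 6, 5, 4, 3, 2, 2, 1.5, 1.2, 1, 0.9,
          0.6, 0.4, 0.25, 0.15)
  bg <- bg / sum(bg)
  names(bg) <- taxa
  taxonomy <- data.frame(
    taxon = taxa,
    phylum = rep(c("Firmicutes", "Proteobacteria", "Tenericutes",
                   "Actinobacteria", "Planctomycetes"), each = 4),
    family = rep(c("Peptostreptococcaceae", "Aeromonadaceae",
                   "Mycoplasmataceae", "unclassified",
                   "Planctomycetaceae"), each = 4),
    stringsAsFactors = FALSE)
  community_scenario(background = bg, taxonomy = taxonomy,
                     responders = responders, periods = periods,
                     depth = depth, dispersion = dispersion)
}
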