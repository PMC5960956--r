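# helper: tidy amounts table from per-analyte time series (one replicate)
amounts_table <- function(treatment, series, grid) {
  do.call(rbind, lapply(names(series), function(a) {
    data.frame(treatment = treatment, replicate = 1L, time_h = grid,
               analyte = a, amount_umol_per_gfw = series[[a]],
               stringsAsFactors = FALSE)
  }))
}

test_that("net_products subtracts control means at matched times", {
  grid <- c(0, 6, 12, 20, 30)
  trt <- amounts_table("trt", list(acetate = c(0, 10, 25, 40, 50)), grid)
  ctl <- amounts_table("control", list(acetate = c(0, 5, 10, 15, 20)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  expect_equal(net$net_umol_per_gfw[net$time_h == 30], 30)
  expect_equal(net$net_umol_per_gfw[net$time_h == 0], 0)
  # replicate means per arm: duplicate the treatment with a shifted curve
  trt2 <- trt
  trt2$replicate <- 2L
  trt2$amount_umol_per_gfw <- trt2$amount_umol_per_gfw + 10
  net2 <- net_products(rbind(trt, trt2, ctl), "trt")
  expect_equal(net2$net_umol_per_gfw[net2$time_h == 30], 35)
})

test_that("self-comparison yields an all-zero net profile", {
  grid <- c(0, 10, 20, 30)
  a <- amounts_table("a", list(acetate = c(0, 3, 7, 9),
                               CO2 = c(1, 2, 3, 4)), grid)
  b <- a
  b$treatment <- "control"
  net <- net_products(rbind(a, b), "a")
  expect_true(all(net$net_umol_per_gfw == 0))
})

test_that("transient products are flagged and excluded from recoveries", {
  grid <- c(0, 6, 12, 20, 30)
  trt <- amounts_table("trt", list(formate = c(0, 6, 12, 4, 0),
                                   acetate = c(0, 10, 30, 45, 50)), grid)
  ctl <- amounts_table("control", list(formate = rep(0, 5),
                                       acetate = rep(0, 5)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  s <- attr(net, "summary")
  expect_true(s$transient[s$analyte == "formate"])
  expect_false(s$transient[s$analyte == "acetate"])
  expect_equal(s$end_net[s$analyte == "formate"], 0)
  sub <- substrate_spec("test", carbon_umol = 1000, n_r_C = 4)
  rt <- recovery_table(net, sub)
  expect_false(rt$included[rt$product == "formate"])
  expect_true(is.na(rt$carbon_pct[rt$product == "formate"]))
})

test_that("mismatched grids and panels are hard errors", {
  t1 <- amounts_table("trt", list(acetate = c(0, 1, 2)), c(0, 10, 30))
  c1 <- amounts_table("control", list(acetate = c(0, 1, 2)), c(0, 20, 30))
  expect_error(net_products(rbind(t1, c1), "trt"), "grids differ")
  t2 <- amounts_table("trt", list(acetate = c(0, 1, 2),
                                  CO2 = c(0, 1, 2)), c(0, 10, 30))
  c2 <- amounts_table("control", list(acetate = c(0, 1, 2)), c(0, 10, 30))
  expect_error(net_products(rbind(t2, c2), "trt"), "CO2")
})

test_that("substrate_carbon reproduces the published carbon inputs", {
  p <- substrate_presets()
  mm_yeast <- molar_mass_per_carbon(parse_formula(p$yeast_lysate$formula))
  mm_bsa <- molar_mass_per_carbon(parse_formula(p$bsa_protein$formula))
  mm_rna <- molar_mass_per_carbon(parse_formula(p$yeast_rna$formula))
  # 1 ml of 6.0% dry-weight lysate: ~2.3 mmol C
  expect_equal(substrate_carbon(1, mm_yeast, dry_weight_fraction = 0.060),
               2300, tolerance = 50 / 2300)
  # 1 ml of 22.5 mg/ml BSA and 3.83 ml of 8.8 mg/ml RNA: ~1 mmol C each
  expect_equal(substrate_carbon(1, mm_bsa, mass_conc_mg_ml = 22.5),
               1000, tolerance = 50 / 1000)
  expect_equal(substrate_carbon(3.83, mm_rna, mass_conc_mg_ml = 8.8),
               1000, tolerance = 50 / 1000)
  expect_error(substrate_carbon(1, 0, dry_weight_fraction = 0.06), "> 0")
  expect_error(substrate_carbon(1, 26.2), "exactly one")
  expect_error(substrate_carbon(1, 26.2, dry_weight_fraction = 0.06,
                                mass_conc_mg_ml = 22.5), "exactly one")
})

test_that("recovery_table computes hand-checkable stoichiometry", {
  grid <- c(0, 10, 20, 30)
  trt <- amounts_table("trt", list(acetate = c(0, 20, 40, 50),
                                   H2 = c(0, 5, 10, 20),
                                   CO2 = c(0, 10, 20, 30)), grid)
  ctl <- amounts_table("control", list(acetate = rep(0, 4),
                                       H2 = rep(0, 4),
                                       CO2 = rep(0, 4)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  sub <- substrate_spec("test", carbon_umol = 1000, n_r_C = 4)
  rt <- recovery_table(net, sub)
  # acetate: 50 * 2 / 1000 = 10% C; 50 * 8 / 4000 = 10% e-
  expect_equal(rt$carbon_pct[rt$product == "acetate"], 10)
  expect_equal(rt$electron_pct[rt$product == "acetate"], 10)
  # H2 contributes only electrons, CO2 only carbon
  expect_true(is.na(rt$carbon_pct[rt$product == "H2"]))
  expect_equal(rt$electron_pct[rt$product == "H2"], 20 * 2 / 4000 * 100)
  expect_true(is.na(rt$electron_pct[rt$product == "CO2"]))
  expect_equal(rt$carbon_pct[rt$product == "CO2"], 3)
  tot <- attr(rt, "totals")
  expect_equal(tot[["carbon_pct"]], 13)
  expect_equal(tot[["electron_pct"]], 11)
  # the electron/carbon ratio identity holds for included carbon products
  reg <- compound_registry()
  for (i in which(rt$included & !is.na(rt$carbon_pct) &
                    !is.na(rt$electron_pct))) {
    j <- match(rt$product[i], reg$name)
    expect_equal(rt$electron_pct[i] / rt$carbon_pct[i],
                 (reg$electrons[j] / reg$carbon[j]) / sub$n_r_C)
  }
})

test_that("all-negative nets give an empty table with zero totals", {
  grid <- c(0, 10, 20, 30)
  trt <- amounts_table("trt", list(acetate = c(0, 1, 1, 1)), grid)
  ctl <- amounts_table("control", list(acetate = c(0, 5, 8, 10)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  rt <- recovery_table(net, substrate_spec("s", 1000, 4))
  expect_false(any(rt$included))
  expect_equal(unname(attr(rt, "totals")), c(0, 0))
})

test_that("recoveries are invariant under joint scaling", {
  grid <- c(0, 10, 20, 30)
  make <- function(k) {
    trt <- amounts_table("trt", list(acetate = k * c(0, 20, 40, 50),
                                     butyrate = k * c(0, 4, 9, 12)), grid)
    ctl <- amounts_table("control", list(acetate = rep(0, 4),
                                         butyrate = rep(0, 4)), grid)
    net <- net_products(rbind(trt, ctl), "trt")
    recovery_table(net, substrate_spec("s", k * 1000, 4))
  }
  r1 <- make(1)
  r7 <- make(7)
  expect_equal(r1$carbon_pct, r7$carbon_pct)
  expect_equal(attr(r1, "totals"), attr(r7, "totals"))
})

test_that("unknown analytes and bad time points are errors", {
  grid <- c(0, 10, 20, 30)
  trt <- amounts_table("trt", list(mystery = c(0, 1, 2, 3)), grid)
  ctl <- amounts_table("control", list(mystery = rep(0, 4)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  expect_error(recovery_table(net, substrate_spec("s", 1000, 4)), "mystery")
  trt2 <- amounts_table("trt", list(acetate = c(0, 1, 2, 3)), grid)
  ctl2 <- amounts_table("control", list(acetate = rep(0, 4)), grid)
  net2 <- net_products(rbind(trt2, ctl2), "trt")
  expect_error(recovery_table(net2, substrate_spec("s", 1000, 4), at = 15),
               "grid point")
})

test_that("ribose_basis rescales RNA totals by the ribose fractions", {
  grid <- c(0, 10, 20, 30)
  trt <- amounts_table("trt", list(acetate = c(0, 20, 40, 50)), grid)
  ctl <- amounts_table("control", list(acetate = rep(0, 4)), grid)
  net <- net_products(rbind(trt, ctl), "trt")
  rna <- preset_substrate("yeast_rna", carbon_umol = 996)
  rt <- recovery_table(net, rna)
  tot <- attr(rt, "totals")
  rb <- ribose_basis(rt)
  # carbon: only 5 of the 9.5 unit carbons are ribose carbon
  expect_equal(rb[["carbon_pct"]], tot[["carbon_pct"]] * 9.5 / 5)
  # electrons: ribose carries 20 e- vs n_r_C * 9.5 for the whole unit
  expect_equal(rb[["electron_pct"]],
               tot[["electron_pct"]] * 3.1 * 9.5 / 20)
  # zero totals stay zero
  ctl0 <- rbind(trt, ctl)
  ctl0$amount_umol_per_gfw <- 0
  net0 <- net_products(ctl0, "trt")
  expect_equal(unname(ribose_basis(recovery_table(net0, rna))), c(0, 0))
  # non-RNA substrates are rejected
  rt_y <- recovery_table(net, preset_substrate("yeast_lysate", 2290))
  expect_error(ribose_basis(rt_y), "RNA")
})
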