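test_that("BMF approximation is the identity with provenance", {
  out <- tmf_from_bmf(2.5)
  expect_equal(as.numeric(out), 2.5)
  expect_identical(attr(out, "provenance"), "approximated_from_bmf")
  expect_identical(attr(out, "uncertainty"), "fallback_tier_1")
  expect_equal(as.numeric(tmf_from_bmf(1.0)), 1.0)
  expect_error(tmf_from_bmf(0), "bmf")
})

test_that("k_M from BCF inverts the fish mass balance", {
  fish <- fish_params(weight = 1, lipid_fraction = 0.05,
                      growth_rate = 0.002, gill_uptake_coeff = 150)
  k1 <- 150 / 1^0.25
  k2 <- k1 / (0.05 * 10^5)
  # no-metabolism fixed point: BCF = k1 / (k2 + kG) -> k_M = 0
  bcf0 <- k1 / (k2 + 0.002)
  p0 <- chemical_profile("x", 5, bcf_ww = bcf0)
  expect_equal(km_from_bcf(p0, fish), 0, tolerance = 1e-12)
  # half that BCF -> k_M = k2 + kG
  p1 <- chemical_profile("x", 5, bcf_ww = bcf0 / 2)
  expect_equal(km_from_bcf(p1, fish), k2 + 0.002)
  # BCF above the fixed point clips to 0 with a warning
  p2 <- chemical_profile("x", 5, bcf_ww = bcf0 * 2)
  expect_warning(km <- km_from_bcf(p2, fish), "not identifiable")
  expect_equal(km, 0)
  # dicofol-like inputs: carp BCF within the laboratory range gives a
  # small positive rate in the 1e-3 to 1e-2 per-day decade
  dic <- chemical_profile("dicofol", 5.02, bcf_ww = 10^3.6,
                          bcf_species = "carp")
  km_dic <- km_from_bcf(dic)
  expect_gt(km_dic, 0)
  expect_gt(km_dic, 1e-3)
  expect_lt(km_dic, 5e-2)
  expect_error(km_from_bcf(chemical_profile("y", 5)), "no BCF")
})

test_that("steady-state model matches a hand-computed two-node chain", {
  cfg <- foodweb_model_config(nodes = list(
    list(id = "algae", kind = "producer", lipid_fraction = 0.02,
         diet = numeric(0)),
    list(id = "snail", kind = "invertebrate", weight = 1e-3,
         lipid_fraction = 0.04, feeding_rate = 0.1, growth_rate = 0.01,
         diet = c(algae = 1)),
    list(id = "trout", kind = "fish", weight = 0.5, lipid_fraction = 0.1,
         feeding_rate = 0.03, growth_rate = 0.003, diet = c(snail = 1))),
    water_conc = 2e-4, gill_uptake_coeff = 100,
    diet_assimilation_eff = 0.5, egestion_ratio = 0.25)
  prof <- chemical_profile("x", 5.5, km = 0.004)
  est <- steady_state_foodweb_tmf(cfg, prof)

  # independent hand algebra for every node
  kow <- 10^5.5; w <- 2e-4
  c_algae <- w * 0.02 * kow
  k1_s <- 100 / (1e-3)^0.25; k2_s <- k1_s / (0.04 * kow)
  kd_s <- 0.5 * 0.1; ke_s <- 0.25 * kd_s
  c_snail <- (k1_s * w + kd_s * c_algae) / (k2_s + ke_s + 0.01)
  k1_t <- 100 / 0.5^0.25; k2_t <- k1_t / (0.1 * kow)
  kd_t <- 0.5 * 0.03; ke_t <- 0.25 * kd_t
  c_trout <- (k1_t * w + kd_t * c_snail) / (k2_t + ke_t + 0.003 + 0.004)
  nodes <- est$nodes
  expect_equal(nodes$concentration[nodes$id == "algae"], c_algae)
  expect_equal(nodes$concentration[nodes$id == "snail"], c_snail)
  expect_equal(nodes$concentration[nodes$id == "trout"], c_trout)
  # TMF is the antilog of the OLS slope of log10 C_lipid on TL 1,2,3
  y <- log10(c(c_algae / 0.02, c_snail / 0.04, c_trout / 0.1))
  expect_equal(est$slope, unname(coef(lm(y ~ c(1, 2, 3)))[2]))
  expect_identical(est$tmf, 10^est$slope)
})

test_that("model limits: equilibrium partitioning, high metabolism, scaling", {
  prof <- chemical_profile("x", 5.02)
  cfg <- default_foodweb_config()
  # equilibrium-partitioning limit: no losses, no dietary uptake -> TMF 1
  eq_nodes <- lapply(cfg$nodes, function(n) {
    if (!is.null(n$growth_rate)) n$growth_rate <- 0
    n$km <- 0
    n
  })
  eq_cfg <- foodweb_model_config(eq_nodes, water_conc = cfg$water_conc,
                                 gill_uptake_coeff = 150,
                                 diet_assimilation_eff = 0,
                                 egestion_ratio = 0)
  eq <- steady_state_foodweb_tmf(eq_cfg, prof)
  expect_equal(eq$tmf, 1.0, tolerance = 1e-12)
  expect_equal(unique(round(log10(eq$nodes$c_lipid), 10)),
               round(log10(cfg$water_conc * 10^5.02), 10))

  # very fast metabolism in fish forces trophic dilution
  fast <- steady_state_foodweb_tmf(cfg, prof, km_override = 10)
  expect_lt(fast$tmf, 1)

  # TMF invariant to water-concentration scaling; concentrations linear
  a <- steady_state_foodweb_tmf(default_foodweb_config(1e-4), prof)
  b <- steady_state_foodweb_tmf(default_foodweb_config(1e-2), prof)
  expect_equal(b$tmf, a$tmf)
  expect_equal(b$nodes$concentration, a$nodes$concentration * 100)

  # piscivore sits at diet-weighted TL 4 in the default web
  expect_equal(a$nodes$tl[a$nodes$id == "piscivorous_fish"], 4.0)
})

test_that("k_M scan is monotone and finds the trophic-magnification threshold", {
  cfg <- default_foodweb_config()
  prof <- chemical_profile("x", 5.02)
  scan <- km_threshold_scan(cfg, prof, km_grid = c(0, 0.01, 0.025, 0.05, 0.1))
  expect_true(all(diff(scan$scan$tmf) < 0))
  expect_gt(scan$scan$tmf[1], scan$scan$tmf[nrow(scan$scan)])
  expect_true(is.finite(scan$threshold_km))
  # a scenario already diluting at the start of the grid reports threshold 0:
  # fish nodes carrying their own fast metabolism dominate the scan rate
  fast_nodes <- lapply(cfg$nodes, function(n) {
    if (n$kind == "fish") n$km <- 0.05
    n
  })
  fast_cfg <- foodweb_model_config(fast_nodes, water_conc = 1e-4)
  dil <- km_threshold_scan(fast_cfg, chemical_profile("pah", 5.02),
                           km_grid = c(0, 0.05))
  expect_equal(dil$threshold_km, 0)

  # dicofol-like scenario: BCF-derived k_M band implies trophic dilution
  for (km in c(0.0062, 0.0083)) {
    est <- steady_state_foodweb_tmf(cfg, chemical_profile("dicofol", 5.02),
                                    km_override = km)
    expect_lt(est$tmf, 1)
  }
})

test_that("model configs validate structure and read from YAML", {
  expect_error(foodweb_model_config(list(
    list(id = "a", kind = "producer", lipid_fraction = 0.02,
         diet = numeric(0)),
    list(id = "b", kind = "fish", weight = 1, lipid_fraction = 0.05,
         feeding_rate = 0.02, growth_rate = 0.002, diet = c(a = 0.6))),
    water_conc = 1e-4), "sum to 1")
  path <- system.file("extdata", "foodweb_model_lake.yaml",
                      package = "tmfkit")
  cfg <- read_foodweb_model_config(path)
  ref <- default_foodweb_config()
  est_file <- steady_state_foodweb_tmf(cfg, chemical_profile("x", 5.02))
  est_ref <- steady_state_foodweb_tmf(ref, chemical_profile("x", 5.02))
  expect_equal(est_file$tmf, est_ref$tmf)
  prof <- read_chemical_profile(
    system.file("extdata", "dicofol_profile.yaml", package = "tmfkit"))
  expect_identical(prof$name, "dicofol")
  expect_equal(prof$bcf_ww, 10^3.6, tolerance = 1e-12)
})
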