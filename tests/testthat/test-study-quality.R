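test_that("quality screen scores criteria and derives the overall verdict", {
  rep_ok <- evaluate_study(make_good_record())
  expect_identical(rep_ok$overall, "meets_criteria")
  expect_length(rep_ok$deficiency_actions, 0)
  expect_true(all(rep_ok$verdicts == "pass"))

  # heavy censoring (the 70%-nondetect cautionary case) fails the
  # detection criterion and calls for expert statistical judgment
  rep_cen <- evaluate_study(make_good_record(censored_fraction = 0.70))
  expect_identical(unname(rep_cen$verdicts["above_detection"]), "fail")
  expect_true("expert_judgment_censoring" %in% rep_cen$deficiency_actions)
  expect_identical(rep_cen$overall, "expert_judgment_required")

  # no diet-linkage evidence + different habitat -> do not proceed
  rep_rej <- evaluate_study(make_good_record(diet_linkage_evidence = "none",
                                             same_habitat = FALSE))
  expect_identical(rep_rej$overall, "reject")
  expect_true("do_not_proceed" %in% rep_rej$deficiency_actions)

  # endotherms or unbalance alone -> usable after recalculation
  rep_endo <- evaluate_study(make_good_record(includes_endotherms = TRUE))
  expect_identical(rep_endo$overall, "usable_after_recalc")
  expect_true("recalc_excluding_endotherms" %in% rep_endo$deficiency_actions)
  rep_bal <- evaluate_study(make_good_record(balance_index = 0.7))
  expect_identical(rep_bal$overall, "usable_after_recalc")
  expect_true("recalc_mixed_model" %in% rep_bal$deficiency_actions)

  # fillet tissue -> conversion action
  rep_fil <- evaluate_study(make_good_record(tissue = "muscle_fillet"))
  expect_true("convert_fillet" %in% rep_fil$deficiency_actions)
  rep_fil2 <- evaluate_study(make_good_record(tissue = "muscle_fillet"),
                             prefer_lipid_normalization = TRUE)
  expect_true("lipid_normalize_fillet" %in% rep_fil2$deficiency_actions)

  # small TL range and few invertebrate taxa route to expert judgment
  rep_tl <- evaluate_study(make_good_record(tl_range_width = 1.5))
  expect_true("expert_judgment_tl_range" %in% rep_tl$deficiency_actions)
  rep_tax <- evaluate_study(make_good_record(n_nonvertebrate_taxa = 1))
  expect_true("expert_judgment_low_taxa" %in% rep_tax$deficiency_actions)

  # unknown fields never silently pass
  rep_unk <- evaluate_study(make_good_record(baseline_used = NA))
  expect_identical(unname(rep_unk$verdicts["isotope_baseline"]), "unknown")
  expect_identical(rep_unk$overall, "expert_judgment_required")
})

test_that("balance index measures unit-TL bin concentration", {
  expect_equal(balance_index(c(2.1, 2.5, 3.1, 3.5, 4.1, 4.5)), 1 / 3)
  expect_equal(balance_index(rep(3.5, 10)), 1.0)
  # one top-bin species holding half the samples flags >= 0.5
  tls <- c(rep(2.2, 3), rep(3.2, 3), rep(4.4, 6))
  expect_gte(balance_index(tls), 0.5)
})

test_that("tier matching is a deterministic rule table", {
  site <- make_lake_site()
  expect_identical(tier_match(make_good_record(), site),
                   "similar_ecosystem_and_species")
  expect_identical(
    tier_match(make_good_record(species_list = c("Rutilus rutilus")), site),
    "similar_ecosystem")
  expect_identical(
    tier_match(make_good_record(ecosystem = "marine"), site),
    "similar_species")
  expect_identical(
    tier_match(make_good_record(ecosystem = "river",
                                species_list = c("Chironomidae")), site),
    "other")
  expect_identical(
    tier_match(make_good_record(system_id = "lake_x"),
               make_lake_site(system_id = "lake_x")),
    "same_system")
})

test_that("selection pools by geometric mean and is order-invariant", {
  site <- make_lake_site()
  a <- make_good_record("a", tmf = 2)
  b <- make_good_record("b", tmf = 8)
  sel <- select_tmf(list(a, b), site)
  expect_equal(sel$selected_tmf, 4.0)
  expect_setequal(sel$pooled_from, c("a", "b"))
  expect_identical(sel$fallback, "none")
  # order invariance and determinism of the decision path
  sel2 <- select_tmf(list(b, a), site)
  expect_equal(sel2$selected_tmf, sel$selected_tmf)
  expect_identical(select_tmf(list(a, b), site)$decision_path,
                   sel$decision_path)
  # adding a failing study never changes the selected TMF
  bad <- make_good_record("bad", tmf = 100,
                          diet_linkage_evidence = "none",
                          same_habitat = FALSE)
  expect_equal(select_tmf(list(a, b, bad), site)$selected_tmf, 4.0)
  # a better tier displaces a worse one
  far <- make_good_record("far", tmf = 9, ecosystem = "marine",
                          species_list = "Gadus morhua")
  expect_equal(select_tmf(list(a, far), site)$selected_tmf, 2.0)
})

test_that("fallback chain routes BMF, then BCF model, then estimated k_M", {
  site <- make_lake_site(chemical = "dicofol")
  sel0 <- select_tmf(list(), site)
  expect_identical(sel0$fallback, "none")
  expect_true(is.na(sel0$selected_tmf))

  prof_bcf <- chemical_profile("dicofol", 5.02, bcf_ww = 10^3.6,
                               bcf_species = "carp")
  sel_bcf <- select_tmf(list(), site, profile = prof_bcf)
  expect_identical(sel_bcf$fallback, "use_bcf_model")

  prof_bmf <- chemical_profile("dicofol", 5.02, bmf = 2.5,
                               bmf_species = "Perca fluviatilis")
  expect_identical(select_tmf(list(), site, profile = prof_bmf)$fallback,
                   "use_bmf")
  prof_km <- chemical_profile("dicofol", 5.02, km = 0.01)
  expect_identical(select_tmf(list(), site, profile = prof_km)$fallback,
                   "use_estimated_km_model")
})

test_that("trophic dilution of readily metabolized chemicals is flagged", {
  site <- make_lake_site(chemical = "benzo[a]pyrene",
                         chemical_class = "readily_metabolized")
  s1 <- make_good_record("pah1", chemical = "benzo[a]pyrene", tmf = 0.45)
  s2 <- make_good_record("pah2", chemical = "benzo[a]pyrene", tmf = 0.6)
  sel <- select_tmf(list(s1, s2), site)
  expect_identical(sel$fallback, "not_advisable_trophic_dilution")
  expect_match(sel$recommendation, "bivalves")
  expect_equal(sel$selected_tmf, sqrt(0.45 * 0.6))
})

test_that("study catalogue and site context round-trip through files", {
  cat_path <- system.file("extdata", "studies_synthetic.csv",
                          package = "tmfkit")
  site_path <- system.file("extdata", "site_lake.yaml", package = "tmfkit")
  cand <- read_study_catalog(cat_path)
  expect_length(cand, 6)
  site <- read_site_context(site_path)
  expect_identical(site$chemical, "PCB153")
  sel <- select_tmf(cand, site)
  # the fillet/endotherm river study fails; the two lake studies pool
  expect_equal(sel$selected_tmf, sqrt(2.4 * 3.1))
})
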