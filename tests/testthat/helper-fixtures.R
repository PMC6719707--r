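# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# A fully satisfactory published-study record; override fields as needed.
make_good_record <- function(study_id = "s1", chemical = "PCB153",
                             tmf = 2.4, ...) {
  args <- modifyList(
    list(study_id = study_id, chemical = chemical, tmf = tmf,
         ecosystem = "lake", latitude_class = "temperate",
         species_list = c("Perca fluviatilis", "Daphnia"),
         tissue = "whole_body", basis = "lipid_weight",
         tl_range_width = 2.3, n_obs = 40, n_nonvertebrate_taxa = 3,
         balance_index = 0.35, diet_linkage_evidence = "gut_contents",
         same_habitat = TRUE, baseline_used = TRUE, censored_fraction = 0,
         single_season = TRUE, includes_endotherms = FALSE),
    list(...))
  do.call(study_record, args)
}

make_lake_site <- function(...) {
  args <- modifyList(
    list(ecosystem = "lake", latitude_class = "temperate",
         target_species = "Perca fluviatilis", chemical = "PCB153",
         chemical_class = "lipophilic"),
    list(...))
  do.call(site_context, args)
}

# Minimal hand-built sample table (3 species, one censored row optional).
make_samples <- function(censored = FALSE) {
  df <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    species = c("zoop", "zoop", "roach", "roach", "perch", "perch"),
    taxon_group = c("zooplankton", "zooplankton", "fish", "fish",
                    "fish", "fish"),
    endotherm = FALSE,
    tissue = "whole_body",
    habitat = "pelagic",
    d15n = c(8, 8, 11.4, 11.4, 14.8, 14.8),
    concentration = c(1, 1.2, 2, 2.2, 4, 4.4),
    basis = "wet_weight",
    lipid_fraction = 0.05,
    water_fraction = c(0.9, 0.9, 0.74, 0.74, 0.74, 0.74),
    detected = TRUE,
    detection_limit = NA_real_,
    pool_size = 1,
    stringsAsFactors = FALSE)
  if (censored) {
    df$detected[1] <- FALSE
    df$concentration[1] <- NA_real_
    df$detection_limit[1] <- 0.5
  }
  df
}

make_dataset <- function(censored = FALSE) {
  foodweb_dataset(make_samples(censored), baseline_species = "zoop")
}
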