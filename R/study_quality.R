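# Study-quality screening, tiering, pooling and the fallback routing that
# together form the TMF selection decision tree.

# The eleven screening criteria applied to a published TMF study.
.quality_criteria <- c(
  "tl_range",         # trophic-level range >= 2.0
  "whole_body_tissue",# fish residues measured on whole bodies
  "normalization",    # lipid/dry-weight normalization appropriate
  "lower_tl_taxa",    # several lower-TL nonvertebrate taxa included
  "sample_balance",   # balanced sampling across trophic levels
  "diet_linkage",     # organisms linked by diet (gut contents, d13C, d34S)
  "same_habitat",     # organisms from the same habitat type
  "isotope_baseline", # isotope data with an appropriate baseline organism
  "above_detection",  # concentrations above the detection limit
  "single_season",    # collected within one sampling period
  "no_endotherms")    # no birds or mammals in the regression

#' Quality-screening thresholds
#'
#' Configurable thresholds for [evaluate_study()]: minimum trophic-level
#' range 2.0; at least 3 distinct lower-trophic-level nonvertebrate taxa
#' ("several"); balance flag when one unit-TL bin holds more than half the
#' samples; censoring warning above 20% nondetects and severe above 50%.
#'
#' @param min_tl_range Minimum TL range width.
#' @param min_nonvertebrate_taxa Minimum number of nonvertebrate taxa.
#' @param balance_flag Maximum tolerated share of samples in one unit-TL bin.
#' @param censor_warn Censored fraction above which the detection criterion
#'   fails and expert statistical judgment is required.
#' @param censor_fail Censored fraction flagged as severe.
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function(min_tl_range = 2.0,
                               min_nonvertebrate_taxa = 3,
                               balance_flag = 0.5,
                               censor_warn = 0.2,
                               censor_fail = 0.5) {
  list(min_tl_range = min_tl_range,
       min_nonvertebrate_taxa = min_nonvertebrate_taxa,
       balance_flag = balance_flag,
       censor_warn = censor_warn,
       censor_fail = censor_fail)
}

#' Construct a published-study record
#'
#' Curated metadata for one published TMF (or BMF) study, carrying the
#' fields the quality screen and similarity tiering evaluate. Unknown fields
#' may be left `NA`; they yield `"unknown"` verdicts, never silent passes.
#'
#' @param study_id,chemical Identifiers.
#' @param tmf Reported TMF (optional; > 0 when present).
#' @param slope,log_base,slope_se Underlying regression slope (optional).
#' @param ecosystem,latitude_class System descriptors.
#' @param species_list Character vector of species in the food web.
#' @param tissue Fish tissue analyzed.
#' @param basis Concentration basis of the regression.
#' @param tl_range_width Trophic-level range of the food web.
#' @param n_obs,n_nonvertebrate_taxa Sample and lower-TL taxon counts.
#' @param balance_index Share of samples in the fullest unit-TL bin
#'   (see [balance_index()]).
#' @param diet_linkage_evidence `"gut_contents"`, `"d13c"`, `"d34s"` or
#'   `"none"`.
#' @param same_habitat Organisms from the same habitat type.
#' @param baseline_used Appropriate isotopic baseline organism used.
#' @param censored_fraction Fraction of concentrations below detection.
#' @param single_season Collected within one sampling period.
#' @param includes_endotherms Birds or mammals in the regression.
#' @param system_id Optional site identifier for same-system tier matches.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, chemical,
                         tmf = NA_real_, slope = NA_real_,
                         log_base = "log10", slope_se = NA_real_,
                         ecosystem = NA_character_,
                         latitude_class = NA_character_,
                         species_list = character(0),
                         tissue = NA_character_,
                         basis = NA_character_,
                         tl_range_width = NA_real_,
                         n_obs = NA_integer_,
                         n_nonvertebrate_taxa = NA_integer_,
                         balance_index = NA_real_,
                         diet_linkage_evidence = NA_character_,
                         same_habitat = NA,
                         baseline_used = NA,
                         censored_fraction = NA_real_,
                         single_season = NA,
                         includes_endotherms = NA,
                         system_id = NA_character_) {
  if (!is.na(tmf) && tmf <= 0) stop("tmf must be > 0", call. = FALSE)
  if (!is.na(censored_fraction) &&
        (censored_fraction < 0 || censored_fraction > 1)) {
    stop("censored_fraction must lie in [0,1]", call. = FALSE)
  }
  if (!is.na(ecosystem)) .match_enum(ecosystem, "ecosystem")
  if (!is.na(latitude_class)) .match_enum(latitude_class, "latitude_class")
  if (!is.na(tissue)) .match_enum(tissue, "tissue")
  if (!is.na(basis)) .match_enum(basis, "basis")
  if (!is.na(diet_linkage_evidence) &&
        !diet_linkage_evidence %in% c("gut_contents", "d13c", "d34s", "none")) {
    stop("diet_linkage_evidence must be gut_contents, d13c, d34s or none",
         call. = FALSE)
  }
  structure(list(study_id = study_id, chemical = chemical, tmf = tmf,
                 slope = slope, log_base = log_base, slope_se = slope_se,
                 ecosystem = ecosystem, latitude_class = latitude_class,
                 species_list = species_list, tissue = tissue, basis = basis,
                 tl_range_width = tl_range_width, n_obs = n_obs,
                 n_nonvertebrate_taxa = n_nonvertebrate_taxa,
                 balance_index = balance_index,
                 diet_linkage_evidence = diet_linkage_evidence,
                 same_habitat = same_habitat, baseline_used = baseline_used,
                 censored_fraction = censored_fraction,
                 single_season = single_season,
                 includes_endotherms = includes_endotherms,
                 system_id = system_id),
            class = "study_record")
}

#' Construct a site context
#'
#' Describes the monitoring site and target of the adjustment: ecosystem
#' type and latitude class, the monitored target species, the reference
#' trophic level (4 for continental waters, 5 for marine by default) and
#' the chemical with its accumulation class.
#'
#' @param ecosystem,latitude_class Site descriptors.
#' @param target_species Monitored species name.
#' @param chemical Chemical of interest.
#' @param chemical_class `"lipophilic"`, `"protein_associated"` or
#'   `"readily_metabolized"`.
#' @param target_tl Reference trophic level; defaults to 5 for marine
#'   ecosystems and 4 otherwise.
#' @param system_id Optional site identifier matched against
#'   `study_record$system_id`.
#' @return An object of class `site_context`.
#' @export
site_context <- function(ecosystem, latitude_class = "unknown",
                         target_species = NA_character_,
                         chemical = NA_character_,
                         chemical_class = "lipophilic",
                         target_tl = NULL,
                         system_id = NA_character_) {
  .match_enum(ecosystem, "ecosystem")
  .match_enum(latitude_class, "latitude_class")
  chemical_class <- match.arg(chemical_class, .tmf_enums$chemical_class)
  if (is.null(target_tl)) target_tl <- if (ecosystem == "marine") 5 else 4
  structure(list(ecosystem = ecosystem, latitude_class = latitude_class,
                 target_species = target_species, chemical = chemical,
                 chemical_class = chemical_class, target_tl = target_tl,
                 system_id = system_id),
            class = "site_context")
}

#' Sampling balance index
#'
#' Share of samples falling in the fullest unit-trophic-level bin. Equal
#' counts in bins \[2,3), \[3,4), \[4,5) give 1/3; a dataset where one
#' species holds half the samples in the top bin gives >= 0.5; a single-bin
#' dataset gives 1.0.
#'
#' @param tls Numeric vector of per-sample trophic levels, or a
#'   [foodweb_dataset()] (assignments computed internally).
#' @return Fraction in (0, 1\].
#' @export
balance_index <- function(tls) {
  if (inherits(tls, "foodweb_dataset")) {
    tls <- assign_trophic_levels(tls)$tl
  }
  stopifnot(is.numeric(tls), length(tls) > 0)
  bins <- floor(tls)
  max(table(bins)) / length(tls)
}

.verdict <- function(cond) {
  if (is.na(cond)) "unknown" else if (cond) "pass" else "fail"
}

#' Screen a published study against the quality criteria
#'
#' Scores a [study_record()] against the eleven screening criteria
#' (pass/fail/unknown each) and derives the deficiency actions and the
#' overall verdict. Missing diet-linkage evidence combined with a different
#' habitat means the organisms cannot be assumed to share a food chain, and
#' the study is rejected outright; a fillet-based study can be converted; an
#' endotherm-bearing or unbalanced study can be recalculated; small TL
#' ranges, few invertebrate taxa and nondetect-rich data are routed to
#' expert judgment.
#'
#' @param record A [study_record()].
#' @param thresholds A [quality_thresholds()] list.
#' @param prefer_lipid_normalization For nonionic organic chemicals, when
#'   whole-body conversion is not possible, emit
#'   `lipid_normalize_fillet` instead of `convert_fillet`.
#' @return An object of class `quality_report` with elements `verdicts`
#'   (named character), `deficiency_actions`, `notes` and `overall`
#'   (`meets_criteria`, `usable_after_recalc`, `expert_judgment_required`
#'   or `reject`).
#' @export
evaluate_study <- function(record, thresholds = quality_thresholds(),
                           prefer_lipid_normalization = FALSE) {
  stopifnot(inherits(record, "study_record"))
  th <- thresholds
  v <- setNames(rep("unknown", length(.quality_criteria)), .quality_criteria)
  actions <- character(0)
  notes <- character(0)

  v["tl_range"] <- .verdict(record$tl_range_width >= th$min_tl_range)
  if (identical(v[["tl_range"]], "fail")) {
    actions <- c(actions, "expert_judgment_tl_range")
  }

  v["whole_body_tissue"] <- .verdict(
    if (is.na(record$tissue)) NA else record$tissue == "whole_body")
  if (!is.na(record$tissue) && record$tissue == "muscle_fillet") {
    actions <- c(actions,
                 if (prefer_lipid_normalization) "lipid_normalize_fillet"
                 else "convert_fillet")
  } else if (identical(v[["whole_body_tissue"]], "fail")) {
    notes <- c(notes, paste0("tissue ", record$tissue,
                             " has no standard whole-body conversion"))
  }

  v["normalization"] <- .verdict(
    if (is.na(record$basis)) NA
    else if (record$basis %in% c("lipid_weight", "dry_weight",
                                 "protein_weight")) TRUE
    else NA)  # wet weight: appropriateness depends on the chemical
  if (!is.na(record$basis) && record$basis == "wet_weight") {
    notes <- c(notes, "wet-weight basis: check against the chemical class")
  }

  v["lower_tl_taxa"] <- .verdict(
    record$n_nonvertebrate_taxa >= th$min_nonvertebrate_taxa)
  if (identical(v[["lower_tl_taxa"]], "fail")) {
    actions <- c(actions, "expert_judgment_low_taxa")
  }

  v["sample_balance"] <- .verdict(record$balance_index <= th$balance_flag)
  if (identical(v[["sample_balance"]], "fail")) {
    actions <- c(actions, "recalc_mixed_model")
  }

  v["diet_linkage"] <- .verdict(
    if (is.na(record$diet_linkage_evidence)) NA
    else record$diet_linkage_evidence != "none")
  v["same_habitat"] <- .verdict(record$same_habitat)
  if (identical(v[["diet_linkage"]], "fail") &&
        identical(v[["same_habitat"]], "fail")) {
    actions <- c(actions, "do_not_proceed")
    notes <- c(notes,
               "organisms cannot be assumed to belong to the same food chain")
  }

  v["isotope_baseline"] <- .verdict(record$baseline_used)

  v["above_detection"] <- .verdict(
    if (is.na(record$censored_fraction)) NA
    else record$censored_fraction <= th$censor_warn)
  if (identical(v[["above_detection"]], "fail")) {
    actions <- c(actions, "expert_judgment_censoring")
    if (record$censored_fraction > th$censor_fail) {
      notes <- c(notes, sprintf(
        "severe censoring: %.0f%% of samples below detection",
        100 * record$censored_fraction))
    }
  }

  v["single_season"] <- .verdict(record$single_season)

  v["no_endotherms"] <- .verdict(
    if (is.na(record$includes_endotherms)) NA
    else !record$includes_endotherms)
  if (identical(v[["no_endotherms"]], "fail")) {
    actions <- c(actions, "recalc_excluding_endotherms")
  }

  recalc_actions <- c("convert_fillet", "lipid_normalize_fillet",
                      "recalc_excluding_endotherms", "recalc_mixed_model")
  expert_actions <- c("expert_judgment_tl_range", "expert_judgment_low_taxa",
                      "expert_judgment_censoring")
  fails <- names(v)[v == "fail"]
  unknowns <- names(v)[v == "unknown"]

  overall <- if ("do_not_proceed" %in% actions) {
    "reject"
  } else if (any(actions %in% expert_actions) ||
               length(setdiff(fails,
                              c("whole_body_tissue", "sample_balance",
                                "no_endotherms"))) > 0 ||
               length(unknowns) > 0) {
    "expert_judgment_required"
  } else if (length(fails) > 0) {
    "usable_after_recalc"
  } else {
    "meets_criteria"
  }

  structure(list(study_id = record$study_id, verdicts = v,
                 deficiency_actions = unique(actions), notes = notes,
                 overall = overall),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Quality report for study", x$study_id, "- overall:", x$overall, "\n")
  for (k in names(x$verdicts)) {
    cat(sprintf("  %-18s %s\n", k, x$verdicts[[k]]))
  }
  if (length(x$deficiency_actions) > 0) {
    cat("  actions:", paste(x$deficiency_actions, collapse = ", "), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# Similarity tiers from most to least preferred.
.tier_levels <- c("same_system", "similar_ecosystem_and_species",
                  "similar_ecosystem", "similar_species", "other")

#' Tier a study by similarity to the monitoring site
#'
#' Deterministic similarity tier: same system (matching `system_id`);
#' similar ecosystem (same ecosystem type and latitude class) with or
#' without an overlap in species; species overlap only; or other. Species
#' overlap means the site's target species appears in the study species
#' list (case-insensitive).
#'
#' @param record A [study_record()].
#' @param site A [site_context()].
#' @return One of `"same_system"`, `"similar_ecosystem_and_species"`,
#'   `"similar_ecosystem"`, `"similar_species"`, `"other"`.
#' @export
tier_match <- function(record, site) {
  stopifnot(inherits(record, "study_record"), inherits(site, "site_context"))
  if (!is.na(record$system_id) && !is.na(site$system_id) &&
        record$system_id == site$system_id) {
    return("same_system")
  }
  eco <- !is.na(record$ecosystem) && record$ecosystem == site$ecosystem &&
    (is.na(record$latitude_class) || is.na(site$latitude_class) ||
       record$latitude_class == site$latitude_class ||
       record$latitude_class == "unknown" || site$latitude_class == "unknown")
  spec <- !is.na(site$target_species) &&
    tolower(site$target_species) %in% tolower(record$species_list)
  if (eco && spec) "similar_ecosystem_and_species"
  else if (eco) "similar_ecosystem"
  else if (spec) "similar_species"
  else "other"
}

#' Select the TMF to apply at a site
#'
#' Runs the full decision tree: screens every candidate study against the
#' quality criteria, keeps those that meet them outright or after a
#' recalculation, tiers the survivors by similarity to the site, pools the
#' best available tier by geometric mean, and otherwise routes down the
#' fallback chain (BMF for the species of interest, then a similar species,
#' then any fish; BCF-derived biotransformation plus a food-web model; an
#' estimated biotransformation rate plus a model). For readily metabolized
#' chemicals whose pooled TMF indicates trophic dilution (< 1),
#' trophic-level adjustment of monitoring data is flagged as not advisable
#' and application of the quality standard in lower-trophic-level taxa
#' (bivalves, crustaceans) is recommended instead.
#'
#' The outcome is a deterministic function of its inputs; the
#' `decision_path` records every node visited for audit.
#'
#' @param candidates List of [study_record()] objects (possibly empty).
#' @param site A [site_context()].
#' @param thresholds A [quality_thresholds()] list.
#' @param profile Optional [chemical_profile()] supplying surrogate data
#'   (BMF, BCF, estimated k_M) for the fallback chain.
#' @return An object of class `tmf_selection` with `selected_tmf` (or `NA`),
#'   `pooled_from`, `tier`, `fallback` (`"none"`, `"use_bmf"`,
#'   `"use_bcf_model"`, `"use_estimated_km_model"` or
#'   `"not_advisable_trophic_dilution"`), `recommendation` and
#'   `decision_path`.
#' @export
select_tmf <- function(candidates, site,
                       thresholds = quality_thresholds(),
                       profile = NULL) {
  stopifnot(inherits(site, "site_context"))
  path <- character(0)
  note <- function(...) path <<- c(path, paste0(...))

  chem <- tolower(trimws(site$chemical))
  cand <- Filter(function(r) !is.na(r$chemical) &&
                   tolower(trimws(r$chemical)) == chem, candidates)
  note("section1: ", length(cand), " candidate TMF stud",
       if (length(cand) == 1) "y" else "ies", " for ", site$chemical)

  reports <- lapply(cand, evaluate_study, thresholds = thresholds)
  usable <- logical(length(cand))
  for (i in seq_along(cand)) {
    note("section1: ", cand[[i]]$study_id, " -> ", reports[[i]]$overall)
    usable[i] <- reports[[i]]$overall %in%
      c("meets_criteria", "usable_after_recalc") && !is.na(cand[[i]]$tmf)
  }
  cand <- cand[usable]

  if (length(cand) > 0) {
    tiers <- vapply(cand, tier_match, character(1), site = site)
    for (i in seq_along(cand)) {
      note("section2: ", cand[[i]]$study_id, " tier = ", tiers[i])
    }
    best <- .tier_levels[min(match(tiers, .tier_levels))]
    pick <- cand[tiers == best]
    note("section2: best available tier = ", best)
    tmfs <- vapply(pick, function(r) r$tmf, numeric(1))
    ids <- vapply(pick, function(r) r$study_id, character(1))
    pooled <- geometric_mean_tmf(tmfs)
    note("section3: geometric mean of ", length(tmfs), " TMF value",
         if (length(tmfs) == 1) "" else "s", " (",
         paste(ids, collapse = ", "), ") = ", format(pooled, digits = 6))
    if (site$chemical_class == "readily_metabolized" && pooled < 1) {
      note("section4: readily metabolized chemical with pooled TMF < 1 -> ",
           "trophic dilution; TL adjustment of monitoring data not advisable")
      return(structure(list(
        selected_tmf = pooled, pooled_from = ids, tier = best,
        fallback = "not_advisable_trophic_dilution",
        recommendation = paste(
          "Do not adjust monitoring data with this TMF; apply the quality",
          "standard in lower-trophic-level taxa such as bivalves and",
          "crustaceans."),
        decision_path = path), class = "tmf_selection"))
    }
    return(structure(list(
      selected_tmf = pooled, pooled_from = ids, tier = best,
      fallback = "none",
      recommendation = paste0("Apply TMF ", format(pooled, digits = 6),
                              " pooled from tier ", best, "."),
      decision_path = path), class = "tmf_selection"))
  }

  note("section5: no qualifying TMF study; entering fallback chain")
  fallback <- "none"
  rec <- "No recommendation: no TMF study and no surrogate data supplied."
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "chemical_profile"))
    if (!is.na(profile$bmf)) {
      tier_note <- if (!is.na(profile$bmf_species) &&
                         !is.na(site$target_species) &&
                         tolower(profile$bmf_species) ==
                           tolower(site$target_species)) {
        "species of interest"
      } else if (!is.na(profile$bmf_species)) {
        paste0("fish species ", profile$bmf_species)
      } else "unspecified fish species"
      note("section5: BMF available (", tier_note,
           ") -> TMF approximated as BMF")
      fallback <- "use_bmf"
      rec <- paste0("Approximate the TMF by the one-trophic-step BMF (",
                    format(profile$bmf, digits = 6), ", ", tier_note, ").")
    } else if (!is.na(profile$bcf_ww)) {
      note("section5: no BMF; BCF available -> derive k_M by fish ",
           "mass balance and estimate the TMF with a food-web model")
      fallback <- "use_bcf_model"
      rec <- paste("Derive the biotransformation rate from the BCF with",
                   "km_from_bcf() and estimate the TMF with",
                   "steady_state_foodweb_tmf().")
    } else if (!is.na(profile$km)) {
      note("section5: no BMF or BCF; estimated k_M available -> ",
           "estimate the TMF with a food-web model")
      fallback <- "use_estimated_km_model"
      rec <- paste("Estimate the TMF with steady_state_foodweb_tmf() using",
                   "the supplied biotransformation rate.")
    } else {
      note("section5: no BMF, BCF or estimated k_M available")
    }
  } else {
    note("section5: no surrogate data supplied")
  }
  structure(list(selected_tmf = NA_real_, pooled_from = character(0),
                 tier = NA_character_, fallback = fallback,
                 recommendation = rec, decision_path = path),
            class = "tmf_selection")
}

#' @export
print.tmf_selection <- function(x, ...) {
  if (!is.na(x$selected_tmf)) {
    cat("Selected TMF:", format(x$selected_tmf, digits = 6),
        "(tier", paste0(x$tier, ")"), "\n")
  } else {
    cat("No TMF selected; fallback:", x$fallback, "\n")
  }
  cat(" ", x$recommendation, "\n")
  cat("Decision path:\n")
  for (p in x$decision_path) cat("  -", p, "\n")
  invisible(x)
}

#' Read a study catalogue from CSV
#'
#' Reads curated [study_record()] rows from a CSV file. `species_list` is a
#' semicolon-separated field; logical fields accept TRUE/FALSE; missing
#' values are empty cells.
#'
#' @param path CSV path with columns named after [study_record()] arguments.
#' @return List of `study_record` objects.
#' @export
read_study_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  lapply(seq_len(nrow(raw)), function(i) {
    row <- as.list(raw[i, , drop = FALSE])
    row <- lapply(row, function(x) if (is.factor(x)) as.character(x) else x)
    if (!is.null(row$species_list) && !is.na(row$species_list)) {
      row$species_list <- trimws(strsplit(row$species_list, ";")[[1]])
    } else {
      row$species_list <- character(0)
    }
    known <- intersect(names(row), names(formals(study_record)))
    row <- row[known]
    row <- row[!vapply(row, function(x) length(x) == 1 && is.na(x),
                       logical(1)) | names(row) == "species_list"]
    do.call(study_record, row)
  })
}

#' Read a site context from YAML or JSON
#'
#' @param path Path to a YAML or JSON file with [site_context()] fields.
#' @return A `site_context`.
#' @export
read_site_context <- function(path) {
  cfg <- .read_dataset_config(path)
  known <- intersect(names(cfg), names(formals(site_context)))
  do.call(site_context, cfg[known])
}
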