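# Fallback TMF estimation: BMF approximation, biotransformation rate from a
# BCF by fish mass balance, and a simplified steady-state food-web
# bioaccumulation model.

#' Construct a chemical profile
#'
#' Physicochemical and surrogate bioaccumulation data for one chemical,
#' feeding the fallback chain of the decision tree and the food-web model.
#'
#' @param name Chemical name.
#' @param log_kow log10 n-octanol/water partition coefficient. Values
#'   outside \[0, 10\] warn.
#' @param bcf_ww Steady-state wet-weight bioconcentration factor, L/kg
#'   (water-only exposure), with the fish species it was measured in.
#' @param bcf_species Fish species of the BCF measurement.
#' @param bmf One-trophic-step biomagnification factor (optional).
#' @param bmf_species Species the BMF refers to.
#' @param km Whole-organism biotransformation rate, per day (optional).
#' @param chemical_class `"lipophilic"`, `"protein_associated"` or
#'   `"readily_metabolized"`.
#' @return An object of class `chemical_profile`.
#' @export
chemical_profile <- function(name, log_kow,
                             bcf_ww = NA_real_, bcf_species = NA_character_,
                             bmf = NA_real_, bmf_species = NA_character_,
                             km = NA_real_,
                             chemical_class = "lipophilic") {
  stopifnot(is.finite(log_kow))
  if (log_kow < 0 || log_kow > 10) {
    warning("log_kow ", log_kow, " outside the usual [0,10] window",
            call. = FALSE)
  }
  for (v in c(bcf_ww = bcf_ww, bmf = bmf, km = km)) {
    if (!is.na(v) && v <= 0) {
      stop("rates and factors must be positive when provided", call. = FALSE)
    }
  }
  chemical_class <- match.arg(chemical_class, .tmf_enums$chemical_class)
  structure(list(name = name, log_kow = log_kow, bcf_ww = bcf_ww,
                 bcf_species = bcf_species, bmf = bmf,
                 bmf_species = bmf_species, km = km,
                 chemical_class = chemical_class),
            class = "chemical_profile")
}

#' Read a chemical profile from YAML or JSON
#'
#' @param path Path to a YAML/JSON file with [chemical_profile()] fields.
#' @return A `chemical_profile`.
#' @export
read_chemical_profile <- function(path) {
  cfg <- .read_dataset_config(path)
  known <- intersect(names(cfg), names(formals(chemical_profile)))
  do.call(chemical_profile, cfg[known])
}

#' Approximate a TMF by a BMF
#'
#' First fallback: the TMF is taken equal to the biomagnification factor,
#' which is defensible because the TMF is a diet-weighted average BMF across
#' the food web. The caller asserts that the BMF reflects one trophic step.
#'
#' @param bmf One-trophic-step biomagnification factor (> 0).
#' @return The BMF, with attributes `provenance = "approximated_from_bmf"`
#'   and `uncertainty = "fallback_tier_1"`.
#' @export
tmf_from_bmf <- function(bmf) {
  if (!is.finite(bmf) || bmf <= 0) stop("bmf must be > 0", call. = FALSE)
  structure(bmf, provenance = "approximated_from_bmf",
            uncertainty = "fallback_tier_1")
}

#' Default fish parameters for the mass balance
#'
#' @param weight Body weight, kg.
#' @param lipid_fraction Whole-body lipid fraction.
#' @param growth_rate Growth dilution rate k_G, per day.
#' @param gill_uptake_coeff Allometric gill uptake coefficient; the gill
#'   uptake rate is `k1 = gill_uptake_coeff / weight^0.25` (L/kg/day).
#' @return Named list of parameters.
#' @export
fish_params <- function(weight = 1, lipid_fraction = 0.05,
                        growth_rate = 0.002, gill_uptake_coeff = 150) {
  stopifnot(weight > 0, lipid_fraction > 0, lipid_fraction < 1,
            growth_rate >= 0, gill_uptake_coeff > 0)
  list(weight = weight, lipid_fraction = lipid_fraction,
       growth_rate = growth_rate, gill_uptake_coeff = gill_uptake_coeff)
}

#' Biotransformation rate from a bioconcentration factor
#'
#' Second fallback: inverts the steady-state fish mass balance under
#' water-only exposure. With gill uptake `k1 = gill_uptake_coeff / W^0.25`
#' and gill elimination from lipid partitioning
#' `k2 = k1 / (lipid_fraction * 10^log_kow)`, the observed BCF satisfies
#' `BCF = k1 / (k2 + k_G + k_M)`, so
#' `k_M = k1/BCF - k2 - k_G`. A BCF at the no-metabolism fixed point
#' `k1/(k2 + k_G)` yields `k_M = 0`; a BCF above it (within measurement
#' error) would yield a negative rate, which is clipped to 0 with a warning
#' that metabolism is not identifiable from the data.
#'
#' @param profile A [chemical_profile()] with `bcf_ww` present.
#' @param fish Fish parameters, see [fish_params()].
#' @return Biotransformation rate `k_M`, per day.
#' @export
km_from_bcf <- function(profile, fish = fish_params()) {
  stopifnot(inherits(profile, "chemical_profile"))
  if (is.na(profile$bcf_ww)) {
    stop("no BCF available for ", profile$name,
         "; route back to the decision tree", call. = FALSE)
  }
  k1 <- fish$gill_uptake_coeff / fish$weight^0.25
  k2 <- k1 / (fish$lipid_fraction * 10^profile$log_kow)
  km <- k1 / profile$bcf_ww - k2 - fish$growth_rate
  if (km < 0) {
    warning("BCF exceeds the no-metabolism fixed point; ",
            "metabolism not identifiable, k_M clipped to 0", call. = FALSE)
    km <- 0
  }
  km
}

#' Construct a food-web model configuration
#'
#' Nodes and rate parameters for the steady-state bioaccumulation model.
#' Each node is a list with `id`, `kind` (`"sediment"`, `"producer"`,
#' `"invertebrate"`, `"fish"`), `weight` (kg), `lipid_fraction`, `diet`
#' (named prey-fraction vector, empty for producers and sediment),
#' `feeding_rate` (kg food / kg body / day), `growth_rate` (per day) and
#' optionally `km` (per day; otherwise fish nodes take the chemical's rate
#' and other nodes 0).
#'
#' @param nodes List of node lists.
#' @param water_conc Freely dissolved water concentration, ug/L (> 0).
#' @param gill_uptake_coeff Allometric gill-uptake coefficient shared by all
#'   animal nodes (`k1 = coeff / weight^0.25`).
#' @param diet_assimilation_eff Dietary chemical assimilation efficiency;
#'   dietary uptake rate `kD = eff * feeding_rate`.
#' @param egestion_ratio Fecal egestion as a fraction of dietary uptake;
#'   `kE = egestion_ratio * kD`.
#' @param temperature Annotation only, degrees C.
#' @return An object of class `foodweb_model_config`.
#' @export
foodweb_model_config <- function(nodes, water_conc = 1e-4,
                                 gill_uptake_coeff = 150,
                                 diet_assimilation_eff = 0.8,
                                 egestion_ratio = 0.2,
                                 temperature = NA_real_) {
  stopifnot(is.list(nodes), length(nodes) >= 2, water_conc > 0,
            gill_uptake_coeff > 0, diet_assimilation_eff >= 0,
            egestion_ratio >= 0)
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  for (n in nodes) {
    if (!n$kind %in% c("sediment", "producer", "invertebrate", "fish")) {
      stop("unknown node kind ", sQuote(n$kind), call. = FALSE)
    }
    d <- n$diet
    if (n$kind %in% c("sediment", "producer")) {
      if (length(d) > 0) stop("node ", n$id, " must have an empty diet",
                              call. = FALSE)
    } else {
      if (length(d) == 0 || abs(sum(d) - 1) > 1e-9) {
        stop("diet fractions of ", n$id, " must sum to 1", call. = FALSE)
      }
      if (!all(names(d) %in% ids)) {
        stop("diet of ", n$id, " references unknown nodes", call. = FALSE)
      }
      if (is.null(n$weight) || n$weight <= 0 ||
            is.null(n$feeding_rate) || n$feeding_rate < 0 ||
            is.null(n$growth_rate) || n$growth_rate < 0) {
        stop("node ", n$id,
             " needs positive weight and nonnegative feeding/growth rates",
             call. = FALSE)
      }
    }
    if (is.null(n$lipid_fraction) || n$lipid_fraction <= 0 ||
          n$lipid_fraction >= 1) {
      stop("node ", n$id, " needs lipid_fraction in (0,1)", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, water_conc = water_conc,
                 gill_uptake_coeff = gill_uptake_coeff,
                 diet_assimilation_eff = diet_assimilation_eff,
                 egestion_ratio = egestion_ratio,
                 temperature = temperature),
            class = "foodweb_model_config")
}

#' Read a food-web model configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose top level holds the
#'   [foodweb_model_config()] arguments; each node's `diet` is a mapping of
#'   prey id to fraction.
#' @return A `foodweb_model_config`.
#' @export
read_foodweb_model_config <- function(path) {
  cfg <- .read_dataset_config(path)
  cfg$nodes <- lapply(cfg$nodes, function(n) {
    n$diet <- if (is.null(n$diet)) numeric(0) else unlist(n$diet)
    n
  })
  known <- intersect(names(cfg), names(formals(foodweb_model_config)))
  do.call(foodweb_model_config, cfg[known])
}

#' Default five-node lake food web
#'
#' Sediment, phytoplankton, zooplankton, forage fish and piscivorous fish in
#' a linear pelagic chain (the piscivore sits at diet-weighted trophic level
#' 4). Weights, lipid fractions and rates are representative temperate-lake
#' values; the sediment `lipid_fraction` is read as an organic-carbon proxy
#' and the node never enters the TMF regression.
#'
#' @param water_conc Freely dissolved water concentration, ug/L.
#' @return A [foodweb_model_config()].
#' @export
default_foodweb_config <- function(water_conc = 1e-4) {
  foodweb_model_config(nodes = list(
    list(id = "sediment", kind = "sediment", lipid_fraction = 0.02,
         diet = numeric(0)),
    list(id = "phytoplankton", kind = "producer", lipid_fraction = 0.01,
         diet = numeric(0)),
    list(id = "zooplankton", kind = "invertebrate", weight = 1e-5,
         lipid_fraction = 0.01, feeding_rate = 0.5, growth_rate = 0.04,
         diet = c(phytoplankton = 1)),
    list(id = "forage_fish", kind = "fish", weight = 0.01,
         lipid_fraction = 0.05, feeding_rate = 0.05, growth_rate = 0.005,
         diet = c(zooplankton = 1)),
    list(id = "piscivorous_fish", kind = "fish", weight = 1,
         lipid_fraction = 0.08, feeding_rate = 0.02, growth_rate = 0.002,
         diet = c(forage_fish = 1))),
    water_conc = water_conc)
}

#' Steady-state food-web TMF estimation
#'
#' Third fallback: generates biota concentrations with a simplified
#' steady-state mass-balance model and regresses them on diet-weighted
#' trophic levels. Producers (and the sediment node) sit at equilibrium
#' partitioning, `C = water_conc * lipid_fraction * 10^log_kow`; each
#' consumer satisfies
#' `C = (k1 * water_conc + kD * sum_j p_ij C_j) / (k2 + kE + kG + kM)` with
#' `k1 = gill_uptake_coeff / weight^0.25`,
#' `k2 = k1 / (lipid_fraction * 10^log_kow)` (lipid partitioning),
#' `kD = diet_assimilation_eff * feeding_rate` and
#' `kE = egestion_ratio * kD`. The biotransformation rate `kM` defaults to
#' the chemical's `km` for fish nodes (0 elsewhere) unless a node carries
#' its own `km`. The TMF is the base-10 antilog of the slope of log
#' lipid-normalized concentration on diet-weighted trophic level over the
#' biota nodes; sediment is excluded because the TMF is defined over biota.
#'
#' Steady-state concentrations scale linearly with `water_conc`, so the
#' estimated TMF is invariant to the water concentration; with all loss
#' processes off and no dietary uptake every node collapses to equilibrium
#' partitioning and the TMF is 1.
#'
#' @param config A [foodweb_model_config()].
#' @param profile A [chemical_profile()] (uses `log_kow` and `km`).
#' @param km_override Optional biotransformation rate, per day, replacing
#'   the profile's `km` for fish nodes (used by [km_threshold_scan()]).
#' @return List with `tmf`, `slope` (log10 per TL), `nodes` (data frame of
#'   id, kind, trophic level, concentration and lipid-normalized
#'   concentration) and `water_conc`.
#' @export
steady_state_foodweb_tmf <- function(config, profile, km_override = NULL) {
  stopifnot(inherits(config, "foodweb_model_config"),
            inherits(profile, "chemical_profile"))
  kow <- 10^profile$log_kow
  km_chem <- if (!is.null(km_override)) km_override
             else if (!is.na(profile$km)) profile$km else 0
  stopifnot(km_chem >= 0)
  nodes <- config$nodes
  ids <- vapply(nodes, function(n) n$id, character(1))
  kinds <- vapply(nodes, function(n) n$kind, character(1))
  names(nodes) <- ids

  diets <- lapply(nodes, function(n) n$diet)
  consumers <- ids[kinds %in% c("invertebrate", "fish")]
  basal <- ids[kinds %in% c("sediment", "producer")]
  tl <- diet_weighted_trophic_levels(diets[consumers], producers = basal)

  conc <- setNames(rep(NA_real_, length(ids)), ids)
  for (id in basal) {
    conc[id] <- config$water_conc * nodes[[id]]$lipid_fraction * kow
  }
  remaining <- consumers
  while (length(remaining) > 0) {
    progressed <- FALSE
    for (id in remaining) {
      n <- nodes[[id]]
      prey <- names(n$diet)
      if (any(is.na(conc[prey]))) next
      k1 <- config$gill_uptake_coeff / n$weight^0.25
      k2 <- k1 / (n$lipid_fraction * kow)
      kD <- config$diet_assimilation_eff * n$feeding_rate
      kE <- config$egestion_ratio * kD
      kM <- if (!is.null(n$km)) n$km else if (n$kind == "fish") km_chem else 0
      denom <- k2 + kE + n$growth_rate + kM
      if (denom <= 0) stop("nonpositive total elimination for node ", id,
                           call. = FALSE)
      conc[id] <- (k1 * config$water_conc + kD * sum(n$diet * conc[prey])) /
        denom
      remaining <- setdiff(remaining, id)
      progressed <- TRUE
    }
    if (!progressed) stop("cyclic diet graph", call. = FALSE)
  }

  biota <- ids[kinds != "sediment"]
  lipid <- vapply(nodes[biota], function(n) n$lipid_fraction, numeric(1))
  df <- data.frame(id = biota, kind = kinds[match(biota, ids)],
                   tl = unname(tl[biota]),
                   concentration = unname(conc[biota]),
                   c_lipid = unname(conc[biota]) / lipid,
                   stringsAsFactors = FALSE)
  fit <- lm(log10(c_lipid) ~ tl, data = df)
  slope <- unname(coef(fit)["tl"])
  list(tmf = 10^slope, slope = slope, nodes = df,
       water_conc = config$water_conc)
}

#' Scan the biotransformation rate for the trophic-magnification threshold
#'
#' Evaluates the food-web model over a grid of biotransformation rates. The
#' estimated TMF is non-increasing in `k_M` (all else fixed): faster
#' metabolism shifts a chemical from magnification toward trophic dilution.
#' Returns the smallest grid rate at which the TMF drops to 1 or below, if
#' any.
#'
#' @param config A [foodweb_model_config()].
#' @param profile A [chemical_profile()].
#' @param km_grid Sorted nonnegative rates, per day.
#' @return List with `scan` (data frame of km and tmf) and `threshold_km`
#'   (smallest grid rate with TMF <= 1, or `NA` if none).
#' @export
km_threshold_scan <- function(config, profile,
                              km_grid = c(0, 0.01, 0.025, 0.05, 0.1)) {
  stopifnot(is.numeric(km_grid), length(km_grid) > 0, all(km_grid >= 0),
            !is.unsorted(km_grid))
  tmfs <- vapply(km_grid, function(km) {
    steady_state_foodweb_tmf(config, profile, km_override = km)$tmf
  }, numeric(1))
  below <- which(tmfs <= 1)
  list(scan = data.frame(km = km_grid, tmf = tmfs),
       threshold_km = if (length(below) > 0) km_grid[min(below)] else
         NA_real_)
}
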