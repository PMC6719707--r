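# Trophic-level assignment from stable nitrogen isotopes and from diet
# matrices, and the trophic-level range used for study screening.

#' Trophic level from delta-15N
#'
#' Computes the trophic level of a consumer relative to an isotopic baseline:
#' `TL = baseline_tl + (d15n_consumer - d15n_baseline) / enrichment_factor`.
#' The baseline organism (mussels, zooplankton, midges, ...) is assumed to
#' occupy `baseline_tl`, conventionally 2.0 for a primary consumer, and the
#' enrichment factor is the per-trophic-step increase in delta-15N, typically
#' 3.4 per mil for aquatic poikilotherm food webs.
#'
#' @param d15n_consumer,d15n_baseline delta-15N of consumer and baseline,
#'   per mil. Vectorized over the consumer.
#' @param enrichment_factor Per-mil increase per trophic step; must be > 0.
#' @param baseline_tl Assumed trophic level of the baseline species.
#' @return Numeric trophic level(s). Values below `baseline_tl` are returned
#'   unclipped with a warning, since they usually indicate baseline
#'   misspecification rather than a sub-baseline consumer.
#' @export
trophic_level_from_d15n <- function(d15n_consumer, d15n_baseline,
                                    enrichment_factor = 3.4,
                                    baseline_tl = 2.0) {
  if (!is.finite(enrichment_factor) || enrichment_factor <= 0) {
    stop("enrichment_factor must be > 0", call. = FALSE)
  }
  tl <- baseline_tl + (d15n_consumer - d15n_baseline) / enrichment_factor
  if (any(tl < baseline_tl, na.rm = TRUE)) {
    warning(sum(tl < baseline_tl, na.rm = TRUE),
            " trophic level(s) fall below the baseline TL; ",
            "check the baseline designation", call. = FALSE)
  }
  tl
}

#' Assign isotope-based trophic levels to every sample of a dataset
#'
#' The baseline delta-15N is the arithmetic mean over the samples of the
#' designated baseline species; samples of the baseline species itself are
#' assigned `baseline_tl` exactly.
#'
#' @param dataset A [foodweb_dataset()].
#' @return Data frame with columns `sample_id`, `species`, `taxon_group`,
#'   `tl` and `method` (`"isotope_baseline"`).
#' @export
assign_trophic_levels <- function(dataset) {
  stopifnot(inherits(dataset, "foodweb_dataset"))
  s <- dataset$samples
  base <- s$species == dataset$baseline_species
  d15n_base <- mean(s$d15n[base])
  tl <- trophic_level_from_d15n(s$d15n, d15n_base,
                                dataset$enrichment_factor,
                                dataset$baseline_tl)
  tl[base] <- dataset$baseline_tl
  data.frame(sample_id = s$sample_id, species = s$species,
             taxon_group = s$taxon_group, tl = tl,
             method = "isotope_baseline", stringsAsFactors = FALSE)
}

#' Diet-weighted trophic levels for a model food web
#'
#' Solves `TL_i = 1 + sum_j p_ij TL_j` over an acyclic diet graph, with
#' producers (and sediment/detritus nodes) fixed at TL 1. A strictly linear
#' chain phytoplankton -> zooplankton -> forage fish -> piscivorous fish thus
#' yields TLs 1, 2, 3, 4.
#'
#' @param diet_matrix Named list: for each consumer node id, a named numeric
#'   vector of prey fractions summing to 1 (tolerance 1e-9).
#' @param producers Character vector of node ids with no diet (producers,
#'   sediment, detritus); assigned TL 1.
#' @return Named numeric vector of trophic levels for all nodes.
#' @export
diet_weighted_trophic_levels <- function(diet_matrix, producers) {
  stopifnot(is.list(diet_matrix), is.character(producers))
  consumers <- names(diet_matrix)
  if (length(diet_matrix) == 0) consumers <- character(0)
  else if (is.null(consumers) || any(consumers == "")) {
    stop("diet_matrix must be a named list of consumer diets", call. = FALSE)
  }
  for (id in consumers) {
    d <- diet_matrix[[id]]
    if (is.null(names(d)) || any(names(d) == "")) {
      stop("diet of ", sQuote(id), " must be a named prey-fraction vector",
           call. = FALSE)
    }
    if (abs(sum(d) - 1) > 1e-9) {
      stop("prey fractions of ", sQuote(id), " sum to ", sum(d),
           ", not 1", call. = FALSE)
    }
  }
  all_prey <- unique(unlist(lapply(diet_matrix, names)))
  nodes <- unique(c(producers, consumers, all_prey))
  unknown <- setdiff(all_prey, nodes)  # nodes is a superset by construction
  tl <- setNames(rep(NA_real_, length(nodes)), nodes)
  tl[producers] <- 1.0
  base_only <- setdiff(nodes, c(producers, consumers))
  if (length(base_only) > 0) {
    stop("node(s) ", paste(sQuote(base_only), collapse = ", "),
         " appear as prey but are neither producers nor consumers",
         call. = FALSE)
  }
  remaining <- setdiff(consumers, producers)
  # topological sweep; if a full pass resolves nothing the graph is cyclic
  while (length(remaining) > 0) {
    progressed <- FALSE
    for (id in remaining) {
      d <- diet_matrix[[id]]
      if (all(!is.na(tl[names(d)]))) {
        tl[id] <- 1 + sum(d * tl[names(d)])
        remaining <- setdiff(remaining, id)
        progressed <- TRUE
      }
    }
    if (!progressed) {
      stop("cyclic diet graph involving: ",
           paste(sQuote(remaining), collapse = ", "), call. = FALSE)
    }
  }
  tl
}

#' Trophic-level range of a food-web dataset
#'
#' The quality-screening range: trophic level of the highest-TL fish species
#' (species arithmetic mean) minus that of the lowest-TL nonvertebrate taxon.
#' When no trophic levels are supplied the range is computed from the
#' delta-15N spread divided by the enrichment factor. A minimum width of 2.0
#' (roughly TL 2 to TL 4) is expected of a high-quality trophic
#' magnification study.
#'
#' @param dataset A [foodweb_dataset()].
#' @param assignments Optional output of [assign_trophic_levels()]; computed
#'   from the dataset when `NULL`.
#' @return List with `width`, `high_species`, `low_taxon`, `undefined`
#'   (logical) and `reason` (when undefined).
#' @export
tl_range <- function(dataset, assignments = NULL) {
  stopifnot(inherits(dataset, "foodweb_dataset"))
  s <- dataset$samples
  nonvert <- !(s$taxon_group %in% c("fish", .endotherm_groups))
  fish <- s$taxon_group == "fish"
  if (!any(fish)) {
    return(list(width = NA_real_, undefined = TRUE, reason = "no fish taxa"))
  }
  if (!any(nonvert)) {
    return(list(width = NA_real_, undefined = TRUE,
                reason = "no nonvertebrate taxa"))
  }
  if (is.null(assignments)) assignments <- assign_trophic_levels(dataset)
  tlv <- assignments$tl[match(s$sample_id, assignments$sample_id)]
  sp_mean <- tapply(tlv, s$species, mean)
  fish_sp <- unique(s$species[fish])
  nonvert_sp <- unique(s$species[nonvert])
  hi <- names(which.max(sp_mean[fish_sp]))
  lo <- names(which.min(sp_mean[nonvert_sp]))
  list(width = unname(sp_mean[hi] - sp_mean[lo]),
       high_species = hi, low_taxon = lo, undefined = FALSE)
}

#' Trophic-level range from a delta-15N spread
#'
#' Converts a difference in delta-15N between the highest fish and lowest
#' nonvertebrate taxon into a trophic-level range by dividing by the
#' enrichment factor.
#'
#' @param d15n_spread delta-15N difference, per mil.
#' @param enrichment_factor Per-mil per trophic step (> 0).
#' @return Trophic-level range width.
#' @export
tl_range_from_d15n <- function(d15n_spread, enrichment_factor = 3.4) {
  if (enrichment_factor <= 0) stop("enrichment_factor must be > 0",
                                   call. = FALSE)
  d15n_spread / enrichment_factor
}
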