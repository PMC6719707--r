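# Concentration-basis conversions: wet weight, dry weight, lipid weight,
# protein proxy, and fillet -> whole body.

#' Default water fraction by taxon group
#'
#' Literature water contents used when a sample-level `water_fraction` is
#' absent: fish 0.74, zooplankton 0.90, benthic invertebrates and other
#' invertebrate groups 0.80, phytoplankton 0.90, endotherms 0.70.
#'
#' @param taxon_group One of the taxon-group enumeration values.
#' @return Water fraction in (0, 1).
#' @export
default_water_fraction <- function(taxon_group) {
  switch(taxon_group,
         fish = 0.74,
         zooplankton = 0.90,
         phytoplankton = 0.90,
         benthic_invertebrate = 0.80,
         mollusk = 0.80,
         crustacean = 0.80,
         bird = 0.70,
         mammal = 0.70,
         other = 0.80,
         stop("unknown taxon_group ", sQuote(taxon_group), call. = FALSE))
}

#' Lipid-weight normalization
#'
#' `C_lipid = C_ww / lipid_fraction`. The standard basis for nonionic organic
#' chemicals, removing the effect of tissue lipid content on accumulation.
#'
#' @param c_ww Wet-weight concentration, ug/kg.
#' @param lipid_fraction Tissue lipid fraction, strictly in (0, 1).
#' @return Lipid-normalized concentration, ug/kg lipid.
#' @export
to_lipid_weight <- function(c_ww, lipid_fraction) {
  if (any(!is.finite(lipid_fraction) | lipid_fraction <= 0 |
            lipid_fraction >= 1)) {
    stop("lipid_fraction must lie in (0,1)", call. = FALSE)
  }
  c_ww / lipid_fraction
}

#' Dry-weight normalization
#'
#' `C_dw = C_ww / (1 - water_fraction)`. Preferred for protein-associated
#' chemicals (e.g. methylmercury, PFOS) whose accumulation is not driven by
#' lipid content.
#'
#' @param c_ww Wet-weight concentration, ug/kg.
#' @param water_fraction Tissue water fraction in \[0, 1).
#' @return Dry-weight concentration, ug/kg dw.
#' @export
to_dry_weight <- function(c_ww, water_fraction) {
  if (any(!is.finite(water_fraction) | water_fraction < 0 |
            water_fraction >= 1)) {
    stop("water_fraction must lie in [0,1)", call. = FALSE)
  }
  c_ww / (1 - water_fraction)
}

#' Fillet to whole-body conversion
#'
#' Whole-body fish residues are preferred for trophic magnification work;
#' when only muscle/fillet was analyzed, a literature conversion factor can
#' be applied: `C_whole_body = factor * C_fillet`. The default factor of 3
#' (literature range roughly 2.6-4.9 for PBDE-like lipophilic organics) is
#' species- and chemical-specific and should be overridden when a measured
#' ratio is available.
#'
#' @param c_fillet Fillet concentration, ug/kg.
#' @param factor Whole-body to fillet concentration ratio (> 0).
#' @return Whole-body concentration, ug/kg.
#' @export
fillet_to_whole_body <- function(c_fillet, factor = 3.0) {
  if (any(!is.finite(factor) | factor <= 0)) {
    stop("conversion factor must be > 0", call. = FALSE)
  }
  factor * c_fillet
}

#' Protein-proxy normalization
#'
#' Normalizes by approximate protein content using the tissue nitrogen
#' fraction: `C_protein = C_ww / (nitrogen_fraction * n_to_protein)`, with
#' the conventional nitrogen-to-protein factor 6.25. Useful for
#' protein-associated chemicals when %N is reported but protein content
#' is not.
#'
#' @param c_ww Wet-weight concentration, ug/kg.
#' @param nitrogen_fraction Tissue nitrogen mass fraction in (0, 1).
#' @param n_to_protein Nitrogen-to-protein conversion factor (> 0).
#' @return Protein-normalized concentration, ug/kg protein.
#' @export
to_protein_proxy <- function(c_ww, nitrogen_fraction, n_to_protein = 6.25) {
  if (any(!is.finite(nitrogen_fraction) | nitrogen_fraction <= 0 |
            nitrogen_fraction >= 1)) {
    stop("nitrogen_fraction must lie in (0,1)", call. = FALSE)
  }
  if (any(!is.finite(n_to_protein) | n_to_protein <= 0)) {
    stop("n_to_protein must be > 0", call. = FALSE)
  }
  c_ww / (nitrogen_fraction * n_to_protein)
}

# Per-row multiplicative factor taking a stored concentration to the
# requested basis. Returns concentrations and detection limits converted
# identically so that censoring thresholds stay on the analysis basis.
.concentration_on_basis <- function(samples, basis,
                                    fillet_factor = NULL) {
  basis <- match.arg(basis, .tmf_enums$basis)
  if (basis == "protein_weight") {
    stop("protein basis requires tissue nitrogen data; ",
         "use to_protein_proxy() explicitly", call. = FALSE)
  }
  n <- nrow(samples)
  wf <- samples$water_fraction
  need_wf <- is.na(wf)
  wf[need_wf] <- vapply(samples$taxon_group[need_wf],
                        default_water_fraction, numeric(1))
  lf <- samples$lipid_fraction

  # factor from stored basis to wet weight
  to_ww <- numeric(n)
  for (i in seq_len(n)) {
    to_ww[i] <- switch(samples$basis[i],
                       wet_weight = 1,
                       dry_weight = 1 - wf[i],
                       lipid_weight = lf[i],
                       protein_weight =
                         stop("cannot convert from protein_weight basis ",
                              "without nitrogen data (row ", i, ")",
                              call. = FALSE))
  }
  if (any(is.na(to_ww))) {
    stop("lipid_fraction required to convert from lipid_weight basis (rows ",
         paste(which(is.na(to_ww)), collapse = ", "), ")", call. = FALSE)
  }
  from_ww <- switch(basis,
                    wet_weight = rep(1, n),
                    dry_weight = 1 / (1 - wf),
                    lipid_weight = {
                      if (any(is.na(lf))) {
                        stop("lipid_fraction required for lipid-weight ",
                             "normalization (rows ",
                             paste(which(is.na(lf)), collapse = ", "), ")",
                             call. = FALSE)
                      }
                      1 / lf
                    })
  fac <- to_ww * from_ww
  # fillet tissues first scaled to whole-body on the wet-weight scale
  if (!is.null(fillet_factor)) {
    fillet <- samples$tissue == "muscle_fillet"
    fac[fillet] <- fac[fillet] * fillet_factor
  }
  list(concentration = samples$concentration * fac,
       detection_limit = samples$detection_limit * fac,
       factor = fac)
}
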