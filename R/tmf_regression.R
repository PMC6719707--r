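# TMF estimation: slope conversions, OLS, mixed-effects and censored
# maximum-likelihood fits, censoring policies, bootstrap intervals,
# geometric-mean pooling.

#' TMF from a regression slope
#'
#' The trophic magnification factor is the antilog of the slope of the
#' regression of log concentration on trophic level: `TMF = 10^b` for
#' base-10 logarithms, `TMF = e^b` for natural logarithms.
#'
#' @param b Regression slope, log concentration per trophic level.
#' @param log_base `"log10"` or `"ln"`.
#' @return TMF (dimensionless ratio). Vectorized over `b`.
#' @examples
#' tmf_from_slope(-0.52)        # 0.30: trophic dilution
#' tmf_from_slope(0.3)          # 2.0
#' @export
tmf_from_slope <- function(b, log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  stopifnot(all(is.finite(b)))
  if (log_base == "log10") 10^b else exp(b)
}

#' TMF from a delta-15N regression slope
#'
#' When concentrations were regressed on delta-15N rather than trophic
#' level, the slope is first multiplied by the trophic enrichment factor:
#' `TMF = base^(b * EF)`, with EF conventionally 3.4 per mil per trophic
#' step.
#'
#' @param b Slope, log concentration per per-mil delta-15N.
#' @param enrichment_factor Per-mil per trophic step (> 0).
#' @param log_base `"log10"` or `"ln"`.
#' @return TMF (dimensionless ratio).
#' @export
tmf_from_d15n_slope <- function(b, enrichment_factor = 3.4,
                                log_base = c("log10", "ln")) {
  if (!is.finite(enrichment_factor) || enrichment_factor <= 0) {
    stop("enrichment_factor must be > 0", call. = FALSE)
  }
  tmf_from_slope(b * enrichment_factor, log_base)
}

#' Geometric mean of TMF values
#'
#' Pools several qualifying TMFs for the same chemical into a single applied
#' value: `exp(mean(log(tmfs)))`.
#'
#' @param tmfs Nonempty numeric vector of positive TMFs.
#' @return Pooled TMF.
#' @export
geometric_mean_tmf <- function(tmfs) {
  if (length(tmfs) == 0) stop("empty TMF list", call. = FALSE)
  if (any(!is.finite(tmfs) | tmfs <= 0)) {
    stop("all TMFs must be positive and finite", call. = FALSE)
  }
  exp(mean(log(tmfs)))
}

#' Apply a censoring policy to concentrations with nondetects
#'
#' Prepares analysis-ready values from a mix of detected concentrations and
#' nondetects reported as detection limits. Substitution policies replace
#' nondetects by DL/2 or DL/sqrt(2); `drop` removes them; `censored_mle`
#' keeps the detection limit as a left-censoring bound for a censored
#' lognormal likelihood fit.
#'
#' @param concentration Numeric concentrations (NA for nondetects).
#' @param detected Logical detection flags.
#' @param detection_limit Detection limits (required where `detected` is
#'   `FALSE`).
#' @param policy One of `"substitute_half_lod"`, `"substitute_lod_sqrt2"`,
#'   `"drop"`, `"censored_mle"`.
#' @return List with `values` (analysis values; for `censored_mle` the
#'   censoring bound for nondetects), `event` (TRUE = observed, FALSE =
#'   left-censored), `keep` (logical row filter) and `censored_fraction`.
#' @export
apply_censoring_policy <- function(concentration, detected, detection_limit,
                                   policy = c("substitute_half_lod",
                                              "substitute_lod_sqrt2",
                                              "drop", "censored_mle")) {
  policy <- match.arg(policy)
  cen <- !detected
  if (any(cen & (is.na(detection_limit) | detection_limit <= 0))) {
    stop("nondetects must carry a positive detection_limit", call. = FALSE)
  }
  cen_frac <- mean(cen)
  if (policy == "censored_mle" && cen_frac > 0.9) {
    stop("censored_mle refused: ", round(100 * cen_frac),
         "% of samples are censored; the regression is not identifiable",
         call. = FALSE)
  }
  values <- concentration
  event <- rep(TRUE, length(concentration))
  keep <- rep(TRUE, length(concentration))
  if (policy == "substitute_half_lod") {
    values[cen] <- detection_limit[cen] / 2
  } else if (policy == "substitute_lod_sqrt2") {
    values[cen] <- detection_limit[cen] / sqrt(2)
  } else if (policy == "drop") {
    keep <- !cen
  } else {
    values[cen] <- detection_limit[cen]
    event[cen] <- FALSE
  }
  list(values = values, event = event, keep = keep,
       censored_fraction = cen_frac, policy = policy)
}

.new_tmf_result <- function(slope_b, intercept_a, log_base, slope_se,
                            slope_ci, p_value, n_obs, n_species, basis,
                            method, excluded_endotherms, censored_fraction,
                            diagnostics, tmf_ci_boot = NULL) {
  base_fun <- if (log_base == "log10") function(x) 10^x else exp
  structure(list(
    slope_b = slope_b, intercept_a = intercept_a, log_base = log_base,
    slope_se = slope_se, slope_ci = slope_ci, p_value = p_value,
    n_obs = n_obs, n_species = n_species,
    tmf = base_fun(slope_b), tmf_ci = base_fun(slope_ci),
    basis = basis, method = method,
    excluded_endotherms = excluded_endotherms,
    censored_fraction = censored_fraction,
    diagnostics = diagnostics, tmf_ci_boot = tmf_ci_boot),
    class = "tmf_result")
}

#' @export
print.tmf_result <- function(x, ...) {
  cat(sprintf("TMF = %.3g (95%% CI %.3g-%.3g), method = %s, basis = %s\n",
              x$tmf, x$tmf_ci[1], x$tmf_ci[2], x$method, x$basis))
  cat(sprintf("  slope (%s) = %.4g (SE %.3g), p = %.3g\n",
              x$log_base, x$slope_b, x$slope_se, x$p_value))
  cat(sprintf("  n = %d observations, %d species; censored fraction %.2f%s\n",
              x$n_obs, x$n_species, x$censored_fraction,
              if (x$excluded_endotherms) "; endotherms excluded" else ""))
  if (!is.null(x$tmf_ci_boot)) {
    cat(sprintf("  bootstrap 95%% CI %.3g-%.3g (%d reps)\n",
                x$tmf_ci_boot[1], x$tmf_ci_boot[2],
                attr(x$tmf_ci_boot, "reps")))
  }
  invisible(x)
}

# Shared preparation for the regression fitters: endotherm filter, basis
# conversion, censoring policy, trophic-level join.
.prepare_regression_data <- function(dataset, assignments, basis,
                                     exclude_endotherms, censoring,
                                     fillet_factor) {
  stopifnot(inherits(dataset, "foodweb_dataset"))
  s <- dataset$samples
  if (is.null(assignments)) assignments <- assign_trophic_levels(dataset)
  tl <- assignments$tl[match(s$sample_id, assignments$sample_id)]
  if (any(is.na(tl))) {
    stop("trophic assignments missing for sample(s) ",
         paste(s$sample_id[is.na(tl)], collapse = ", "), call. = FALSE)
  }
  if (exclude_endotherms) {
    keep <- !s$endotherm
    s <- s[keep, , drop = FALSE]
    tl <- tl[keep]
  }
  conv <- .concentration_on_basis(s, basis, fillet_factor)
  if (all(!s$detected)) stop("all observations are censored", call. = FALSE)
  cp <- apply_censoring_policy(conv$concentration, s$detected,
                               conv$detection_limit, censoring)
  keep <- cp$keep
  data.frame(sample_id = s$sample_id[keep], species = s$species[keep],
             tl = tl[keep], value = cp$values[keep], event = cp$event[keep],
             stringsAsFactors = FALSE) ->
    d
  list(data = d, censored_fraction = cp$censored_fraction)
}

.logfun <- function(log_base) if (log_base == "log10") log10 else log

#' Fit a TMF by ordinary least squares
#'
#' Regresses log concentration (on the requested basis) on trophic level and
#' converts the slope to a TMF. The 95% confidence interval for the slope
#' uses the t distribution with n - 2 degrees of freedom; a nonparametric
#' observation-level bootstrap percentile interval can be attached. With
#' `censoring = "censored_mle"`, the same log-linear model is instead fitted
#' by maximum likelihood with nondetects treated as left-censored at their
#' detection limit (normal errors on the log scale), and the interval is
#' Wald-type.
#'
#' @param dataset A [foodweb_dataset()].
#' @param assignments Optional [assign_trophic_levels()] output; computed
#'   when `NULL`.
#' @param basis Concentration basis for the regression: `"lipid_weight"`
#'   (default, for lipophilic chemicals), `"dry_weight"` (protein-associated
#'   chemicals) or `"wet_weight"`.
#' @param log_base `"log10"` (default) or `"ln"`.
#' @param exclude_endotherms Drop birds and mammals before fitting (the
#'   water-respiring food chain is the adjustment reference).
#' @param censoring Censoring policy, see [apply_censoring_policy()].
#' @param species_mean Fit on species means of log concentration and trophic
#'   level instead of individual samples.
#' @param bootstrap_reps Number of bootstrap resamples for a percentile CI
#'   on the TMF (0 = skip). Requires `seed`.
#' @param seed Integer seed for the bootstrap.
#' @param fillet_factor Whole-body/fillet ratio applied to muscle-fillet
#'   tissues before normalization (see [fillet_to_whole_body()]).
#' @return A `tmf_result` object: slope, intercept, SE, 95% CI, p value,
#'   TMF and its CI, sample/species counts, censored fraction and
#'   diagnostics (residual SD, maximum leverage, balance index).
#' @export
fit_tmf_ols <- function(dataset, assignments = NULL,
                        basis = "lipid_weight",
                        log_base = c("log10", "ln"),
                        exclude_endotherms = FALSE,
                        censoring = "substitute_half_lod",
                        species_mean = FALSE,
                        bootstrap_reps = 0, seed = NULL,
                        fillet_factor = 3.0) {
  log_base <- match.arg(log_base)
  prep <- .prepare_regression_data(dataset, assignments, basis,
                                   exclude_endotherms, censoring,
                                   fillet_factor)
  d <- prep$data
  lf <- .logfun(log_base)
  d$y <- lf(d$value)
  mle <- any(!d$event)

  if (species_mean) {
    if (mle) stop("species_mean is not available with censored_mle",
                  call. = FALSE)
    agg <- aggregate(cbind(y, tl) ~ species, data = d, FUN = mean)
    d <- data.frame(sample_id = agg$species, species = agg$species,
                    tl = agg$tl, y = agg$y, event = TRUE,
                    value = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(unique(d$tl)) < 3) {
    stop("insufficient design: fewer than 3 distinct trophic levels",
         call. = FALSE)
  }

  if (!mle) {
    fit <- lm(y ~ tl, data = d)
    cf <- coef(fit)
    sm <- summary(fit)
    slope <- unname(cf["tl"])
    se <- sm$coefficients["tl", "Std. Error"]
    p <- sm$coefficients["tl", "Pr(>|t|)"]
    ci <- unname(confint(fit, "tl", level = 0.95))
    resid_sd <- sm$sigma
    lev <- stats::hatvalues(fit)
    method <- if (prep$censored_fraction > 0 &&
                    censoring %in% c("substitute_half_lod",
                                     "substitute_lod_sqrt2"))
      "substitution" else "ols"
  } else {
    sv <- survival::survreg(
      survival::Surv(y, event, type = "left") ~ tl,
      data = d, dist = "gaussian")
    slope <- unname(coef(sv)["tl"])
    se <- sqrt(diag(vcov(sv))["tl"])
    se <- unname(se)
    z <- slope / se
    p <- 2 * stats::pnorm(-abs(z))
    ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
    resid_sd <- sv$scale
    lev <- rep(NA_real_, nrow(d))
    method <- "censored_mle"
    fit <- sv
    cf <- coef(sv)
  }

  diagnostics <- list(residual_sd = resid_sd,
                      max_leverage = suppressWarnings(max(lev)),
                      balance_index = balance_index(d$tl))

  boot_ci <- NULL
  if (bootstrap_reps > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed", call. = FALSE)
    set.seed(seed)
    n <- nrow(d)
    slopes <- rep(NA_real_, bootstrap_reps)
    for (r in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- d[idx, , drop = FALSE]
      if (length(unique(db$tl)) < 2) next
      slopes[r] <- if (!mle) {
        unname(coef(lm(y ~ tl, data = db))["tl"])
      } else {
        if (all(db$event)) unname(coef(lm(y ~ tl, data = db))["tl"])
        else tryCatch(unname(coef(survival::survreg(
          survival::Surv(y, event, type = "left") ~ tl,
          data = db, dist = "gaussian"))["tl"]),
          error = function(e) NA_real_)
      }
    }
    qb <- quantile(slopes, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    base_fun <- if (log_base == "log10") function(x) 10^x else exp
    boot_ci <- base_fun(qb)
    attr(boot_ci, "reps") <- bootstrap_reps
  }

  .new_tmf_result(slope_b = slope, intercept_a = unname(cf[1]),
                  log_base = log_base, slope_se = se, slope_ci = ci,
                  p_value = p, n_obs = nrow(d),
                  n_species = length(unique(d$species)),
                  basis = basis, method = method,
                  excluded_endotherms = exclude_endotherms,
                  censored_fraction = prep$censored_fraction,
                  diagnostics = diagnostics, tmf_ci_boot = boot_ci)
}

#' Fit a TMF with a species random intercept
#'
#' Linear mixed model `log(C) ~ TL + (1 | species)`: the recommended
#' recalculation for unbalanced sampling designs, where some species
#' dominate the sample and would otherwise drag the OLS slope toward their
#' own concentration level. The fixed trophic-level slope is converted to
#' the TMF; the slope SE comes from the fitted model and the interval and p
#' value are Wald-type (normal reference).
#'
#' @inheritParams fit_tmf_ols
#' @param grouping Random-effect grouping; only `"species"` is supported.
#' @return A `tmf_result` with `method = "mixed"`.
#' @export
fit_tmf_mixed <- function(dataset, assignments = NULL,
                          basis = "lipid_weight",
                          log_base = c("log10", "ln"),
                          grouping = "species",
                          exclude_endotherms = FALSE,
                          censoring = "substitute_half_lod",
                          fillet_factor = 3.0) {
  log_base <- match.arg(log_base)
  grouping <- match.arg(grouping, "species")
  prep <- .prepare_regression_data(dataset, assignments, basis,
                                   exclude_endotherms, censoring,
                                   fillet_factor)
  d <- prep$data
  if (any(!d$event)) {
    stop("censored_mle is not available in the mixed model; ",
         "use a substitution or drop policy", call. = FALSE)
  }
  d$y <- .logfun(log_base)(d$value)
  if (length(unique(d$species)) < 4) {
    stop("insufficient design: mixed model requires >= 4 species groups",
         call. = FALSE)
  }
  grp_tl <- tapply(d$tl, d$species, mean)
  if (length(unique(round(grp_tl, 10))) < 2) {
    stop("insufficient design: species groups span < 2 distinct trophic ",
         "levels", call. = FALSE)
  }
  fit <- tryCatch(
    lme4::lmer(y ~ tl + (1 | species), data = d, REML = TRUE),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- lme4::fixef(fit)
  slope <- unname(cf["tl"])
  se <- sqrt(diag(as.matrix(vcov(fit)))["tl"])
  se <- unname(se)
  z <- slope / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
  diagnostics <- list(residual_sd = stats::sigma(fit),
                      max_leverage = NA_real_,
                      balance_index = balance_index(d$tl))
  .new_tmf_result(slope_b = slope, intercept_a = unname(cf[1]),
                  log_base = log_base, slope_se = se, slope_ci = ci,
                  p_value = p, n_obs = nrow(d),
                  n_species = length(unique(d$species)),
                  basis = basis, method = "mixed",
                  excluded_endotherms = exclude_endotherms,
                  censored_fraction = prep$censored_fraction,
                  diagnostics = diagnostics)
}

#' Serialize a TMF result to JSON
#'
#' @param result A `tmf_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tmf_json <- function(result, path) {
  stopifnot(inherits(result, "tmf_result"))
  out <- unclass(result)
  out$tmf_ci_boot <- if (is.null(out$tmf_ci_boot)) NULL else
    as.numeric(out$tmf_ci_boot)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
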