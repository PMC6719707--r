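test_that("slope-to-TMF conversions match the defining antilogs", {
  expect_equal(tmf_from_slope(0, "log10"), 1.0)
  expect_equal(tmf_from_slope(0, "ln"), 1.0)
  expect_equal(tmf_from_slope(0.1, "ln"), exp(0.1))
  expect_equal(tmf_from_d15n_slope(0, 3.4), 1.0)
  expect_equal(tmf_from_d15n_slope(0.1, 3.4), 10^0.34)
  # algebraic identity between the TL-slope and d15N-slope forms
  for (b in c(-0.2, 0, 0.05, 0.4)) {
    for (ef in c(3.0, 3.4, 5.0)) {
      expect_identical(tmf_from_d15n_slope(b, ef),
                       tmf_from_slope(b * ef))
    }
  }
  expect_error(tmf_from_d15n_slope(0.1, 0), "enrichment_factor")
})

test_that("geometric-mean pooling behaves like a geometric mean", {
  expect_equal(geometric_mean_tmf(c(2, 8)), 4.0)
  expect_equal(geometric_mean_tmf(3.7), 3.7)
  expect_equal(geometric_mean_tmf(c(0.30, 0.24)), sqrt(0.30 * 0.24))
  expect_error(geometric_mean_tmf(numeric(0)), "empty")
  expect_error(geometric_mean_tmf(c(2, -1)), "positive")
})

test_that("OLS fit recovers the generating slope and honors its invariants", {
  d <- generate_synthetic_foodweb(true_tmf = 2, resid_sd = 0.3, seed = 1)
  f <- fit_tmf_ols(d)
  expect_s3_class(f, "tmf_result")
  expect_identical(f$tmf, 10^f$slope_b)               # bit-identical antilog
  expect_identical(f$tmf_ci, 10^f$slope_ci)
  expect_identical(tmf_from_slope(f$slope_b, f$log_base), f$tmf)
  expect_equal(f$n_obs, 60)
  expect_equal(f$n_species, 6)
  expect_lt(abs(f$slope_b - log10(2)), 3 * f$slope_se)

  # scaling all concentrations changes the intercept only
  d2 <- d
  d2$samples$concentration <- d$samples$concentration * 7
  f2 <- fit_tmf_ols(d2)
  expect_equal(f2$slope_b, f$slope_b)
  expect_equal(f2$intercept_a - f$intercept_a, log10(7))

  # natural-log fit encodes the same TMF
  fln <- fit_tmf_ols(d, log_base = "ln")
  expect_equal(fln$tmf, f$tmf, tolerance = 1e-9)
  expect_identical(fln$tmf, exp(fln$slope_b))

  # insufficient design: fewer than 3 distinct TLs
  two_sp <- make_samples()[1:4, ]
  d3 <- foodweb_dataset(two_sp, baseline_species = "zoop")
  expect_error(fit_tmf_ols(d3), "insufficient design")
})

test_that("endotherm exclusion flags and agrees on a shared law", {
  d <- generate_synthetic_foodweb(n_species = 6, samples_per_species = 10,
                                  true_tmf = 2, resid_sd = 0.3, seed = 9)
  # make the top species a bird following the same log-linear law
  s <- d$samples
  top <- s$species == "species_06"
  s$taxon_group[top] <- "bird"
  s$endotherm[top] <- TRUE
  d2 <- foodweb_dataset(s, baseline_species = "species_01",
                        enrichment_factor = d$enrichment_factor)
  with_birds <- fit_tmf_ols(d2, exclude_endotherms = FALSE)
  without_birds <- fit_tmf_ols(d2, exclude_endotherms = TRUE)
  expect_false(with_birds$excluded_endotherms)
  expect_true(without_birds$excluded_endotherms)
  expect_equal(without_birds$n_obs, with_birds$n_obs - sum(top))
  expect_lt(abs(with_birds$slope_b - without_birds$slope_b),
            2 * max(with_birds$slope_se, without_birds$slope_se))
})

test_that("censoring policies substitute, drop or censor as documented", {
  cp <- apply_censoring_policy(c(NA, 2), c(FALSE, TRUE), c(1.0, NA),
                               "substitute_half_lod")
  expect_equal(cp$values, c(0.5, 2))
  cp2 <- apply_censoring_policy(c(NA, 2), c(FALSE, TRUE), c(1.0, NA),
                                "substitute_lod_sqrt2")
  expect_equal(cp2$values, c(1 / sqrt(2), 2))
  cp3 <- apply_censoring_policy(c(NA, 2), c(FALSE, TRUE), c(1.0, NA), "drop")
  expect_identical(cp3$keep, c(FALSE, TRUE))
  cp4 <- apply_censoring_policy(c(NA, 2), c(FALSE, TRUE), c(1.0, NA),
                                "censored_mle")
  expect_equal(cp4$values, c(1.0, 2))
  expect_identical(cp4$event, c(FALSE, TRUE))
  expect_equal(cp4$censored_fraction, 0.5)
  expect_error(
    apply_censoring_policy(rep(NA_real_, 10), rep(FALSE, 10), rep(1, 10),
                           "censored_mle"),
    "not identifiable")

  # with no censoring every policy yields identical fits
  d <- generate_synthetic_foodweb(seed = 4)
  fits <- lapply(c("substitute_half_lod", "substitute_lod_sqrt2", "drop"),
                 function(p) fit_tmf_ols(d, censoring = p))
  expect_equal(fits[[1]]$slope_b, fits[[2]]$slope_b)
  expect_equal(fits[[1]]$slope_b, fits[[3]]$slope_b)
  fmle <- fit_tmf_ols(d, censoring = "censored_mle")
  expect_equal(fmle$slope_b, fits[[1]]$slope_b, tolerance = 1e-6)
})

test_that("censored MLE is less biased than substitution under censoring", {
  n_seeds <- 150
  err_mle <- err_sub <- rep(NA_real_, n_seeds)
  for (s in seq_len(n_seeds)) {
    d <- generate_synthetic_foodweb(true_tmf = 2, resid_sd = 0.3,
                                    censor_fraction = 0.3, seed = s)
    err_mle[s] <- fit_tmf_ols(d, censoring = "censored_mle")$slope_b -
      log10(2)
    err_sub[s] <- fit_tmf_ols(d, censoring = "substitute_half_lod")$slope_b -
      log10(2)
  }
  expect_lt(abs(mean(err_mle)), abs(mean(err_sub)))
})

test_that("mixed model matches OLS in balanced data and helps when unbalanced", {
  # balanced data, no species-level noise: slopes agree closely
  d <- generate_synthetic_foodweb(true_tmf = 2, resid_sd = 0.2, seed = 2)
  fo <- fit_tmf_ols(d)
  fm <- suppressMessages(fit_tmf_mixed(d))
  expect_equal(fm$slope_b, fo$slope_b, tolerance = 1e-5)
  expect_identical(fm$method, "mixed")

  # 3 species only -> insufficient design
  d3 <- foodweb_dataset(make_samples(), baseline_species = "zoop")
  expect_error(suppressWarnings(fit_tmf_mixed(d3)), ">= 4 species")

  # unbalanced design with species-level noise: mixed slope RMSE <= OLS
  n_sims <- 120
  err_ols <- err_mix <- rep(NA_real_, n_sims)
  for (s in seq_len(n_sims)) {
    d <- generate_synthetic_foodweb(
      n_species = 6, samples_per_species = c(4, 4, 4, 4, 4, 30),
      true_tmf = 2, resid_sd = 0.1, seed = 1000 + s)
    set.seed(2000 + s)
    # add species-level intercept noise on the log scale
    sp_eff <- setNames(rnorm(6, 0, 0.3), unique(d$samples$species))
    d$samples$concentration <-
      d$samples$concentration * 10^sp_eff[d$samples$species]
    err_ols[s] <- fit_tmf_ols(d)$slope_b - log10(2)
    err_mix[s] <- suppressMessages(
      suppressWarnings(fit_tmf_mixed(d)))$slope_b - log10(2)
  }
  expect_lte(sqrt(mean(err_mix^2)), sqrt(mean(err_ols^2)))
})

test_that("bootstrap interval brackets the OLS interval location", {
  d <- generate_synthetic_foodweb(true_tmf = 2, resid_sd = 0.3, seed = 6)
  f <- fit_tmf_ols(d, bootstrap_reps = 400, seed = 99)
  expect_length(f$tmf_ci_boot, 2)
  expect_lt(f$tmf_ci_boot[1], f$tmf)
  expect_gt(f$tmf_ci_boot[2], f$tmf)
  expect_error(fit_tmf_ols(d, bootstrap_reps = 100), "seed")
})
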