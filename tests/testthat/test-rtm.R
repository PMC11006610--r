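# A deterministic multi-species site: constant counts, so full and
# censored fits agree and every correction factor is zero.
flat_populations <- function() {
  taxa <- sprintf("g%02d_sp%03d", 1:10, 1:10)
  counts <- c(40, 25, 16, 9, 6, 4, 3, 2, 1, 1)
  do.call(rbind, lapply(2001:2016, function(y) {
    data.frame(study_id = "S1", area_id = "A1", site_id = "P1", year = y,
               taxon_id = taxa, count = counts)
  }))
}

test_that("identical full and censored fits give zero correction factors", {
  corr <- suppressWarnings(
    estimate_rtm_correction(flat_populations(), min_years = 15, censor = 1,
                            ar1 = FALSE))
  expect_true(all(abs(corr$factor) < 1e-6))
})

test_that("too-short series raise an actionable error", {
  pops <- flat_populations()
  pops <- pops[pops$year <= 2005, ]
  expect_error(estimate_rtm_correction(pops, min_years = 15), "lower `min_years`")
})

test_that("correction application is additive and guards group mismatch", {
  pops <- flat_populations()
  corr <- suppressWarnings(
    estimate_rtm_correction(pops, min_years = 15, censor = 1, ar1 = FALSE))
  fits <- attr(corr, "full_fits")
  shifted <- corr
  shifted$factor <- rep(0.004, nrow(shifted))
  out <- apply_rtm_correction(fits, shifted)
  for (g in names(fits$fits)) {
    expect_equal(out$fits[[g]]$slope, fits$fits[[g]]$slope + 0.004, tolerance = 1e-12)
    expect_equal(out$fits[[g]]$ci, fits$fits[[g]]$ci + 0.004, tolerance = 1e-12)
    # interval widths unchanged
    expect_equal(out$fits[[g]]$ci[, 2] - out$fits[[g]]$ci[, 1],
                 fits$fits[[g]]$ci[, 2] - fits$fits[[g]]$ci[, 1])
  }
  expect_true(out$corrected)
  bad <- corr[corr$group != corr$group[1], , drop = FALSE]
  class(bad) <- class(corr)
  expect_error(apply_rtm_correction(fits, bad), "missing")
})

test_that("three-year censoring matches one-year censoring in sign", {
  set.seed(5)
  cfg <- sim_config(n_studies = 1, n_sites_per_study = 6, n_species = 40,
                    years = 18, trend_spec = 0, dispersion = 0.5,
                    genus_fraction = 0, seed = 31)
  tab <- simulate_dataset(cfg)
  pops <- merge(assemblage_counts(tab, keep_zero = TRUE),
                unique(as.data.frame(tab)[, c("study_id", "area_id", "site_id")]),
                by = "site_id")
  c1 <- suppressWarnings(estimate_rtm_correction(pops, min_years = 15, censor = 1,
                                                 ar1 = FALSE))
  c3 <- suppressWarnings(estimate_rtm_correction(pops, min_years = 15, censor = 3,
                                                 ar1 = FALSE))
  shared <- intersect(c1$group, c3$group)
  s1 <- sign(c1$factor[match(shared, c1$group)])
  s3 <- sign(c3$factor[match(shared, c3$group)])
  # the RtM direction agrees for the extreme intervals
  ext <- shared %in% range(shared)
  expect_equal(s1[ext], s3[ext])
})

test_that("dataset-level effect association finds engineered correlation", {
  mk_fit <- function(effects) {
    structure(list(fits = list(`5` = structure(list(
      ranef = list(study_id = data.frame(level = names(effects), term = "year_c",
                                         mode = effects, condsd = 1e-6)),
      slope = 0, family = "poisson_log"), class = "trend_fit"))),
      class = "population_trend_fit")
  }
  eff <- c(S1 = -0.02, S2 = -0.01, S3 = 0.005, S4 = 0.015, S5 = -0.03)
  ab <- structure(list(ranef = list(study_id = data.frame(
    level = names(eff), term = "year_c", mode = eff, condsd = 1e-6))),
    class = "trend_fit")
  out <- relate_dataset_effects(mk_fit(eff), ab, n_draws = 200, seed = 1)
  expect_equal(out$correlation, 1, tolerance = 1e-9)
  expect_gt(out$ci95_lower, 0.9)

  # independent effect vectors with realistic conditional uncertainty
  # (condsd of the same order as the effect spread, as shrinkage gives)
  set.seed(2)
  indep <- stats::setNames(rnorm(20, 0, 0.01), sprintf("S%02d", 1:20))
  ab2 <- structure(list(ranef = list(study_id = data.frame(
    level = names(indep), term = "year_c", mode = rnorm(20, 0, 0.01), condsd = 0.01))),
    class = "trend_fit")
  out2 <- relate_dataset_effects(mk_fit(indep), ab2, n_draws = 500, seed = 3)
  expect_lt(out2$ci95_lower, 0)
  expect_gt(out2$ci95_upper, 0)

  few <- eff[1:2]
  ab3 <- structure(list(ranef = list(study_id = data.frame(
    level = names(few), term = "year_c", mode = few, condsd = 1e-6))),
    class = "trend_fit")
  expect_error(relate_dataset_effects(mk_fit(few), ab3), "fewer than 3")
})
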