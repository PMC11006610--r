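test_that("skewed SAD generation honours shape and edge cases", {
  expect_equal(generate_skewed_sad(1, list(model = "lognormal"), seed = 1),
               sum(generate_skewed_sad(1, list(model = "lognormal"), seed = 1)))
  expect_equal(generate_skewed_sad(43, list(model = "fixture")),
               sort(box1_fixture(), decreasing = TRUE))
  expect_error(generate_skewed_sad(10, list(model = "fixture")), "43 species")
  expect_error(generate_skewed_sad(10, list(model = "logseries", p = 1.2)), "p")

  sad <- generate_skewed_sad(200, list(model = "logseries", p = 0.9), seed = 7)
  expect_true(all(sad >= 1))
  expect_equal(length(sad), 200)
  expect_false(is.unsorted(rev(sad)))
  # many rare, few abundant: singleton share exceeds the share above 10
  expect_gt(mean(sad == 1), mean(sad > 10))
})

test_that("community series follows its deterministic closed form", {
  sad <- c(100, 50, 10)
  tab0 <- simulate_community_series(sad, trend_spec = 0, years = 5, dispersion = 0)
  totals <- tapply(tab0$count, tab0$year, sum)
  expect_true(all(totals == sum(sad)))

  tab <- simulate_community_series(sad, trend_spec = -0.015, years = 21, dispersion = 0)
  tot <- tapply(tab$count, tab$year, sum)
  expect_equal(unname(tot[21]), sum(floor(sad * 0.985^20 + 0.5)))
})

test_that("noisy series is unbiased around the trend's closed form", {
  sad <- c(200, 100, 50)
  tot20 <- replicate(400, {
    tab <- simulate_community_series(sad, trend_spec = -0.015, years = 21,
                                     dispersion = 0.2)
    sum(tab$count[tab$year == max(tab$year)])
  })
  expected <- sum(sad * 0.985^20)
  se <- stats::sd(tot20) / sqrt(length(tot20))
  expect_lt(abs(mean(tot20) - expected), 2 * se + 1e-9)
})

test_that("sampling design conserves individuals and deletes reproducibly", {
  tab <- simulate_community_series(c(150, 100, 50), years = 10, dispersion = 0)
  em <- list(n_traps = 6L, n_periods = 1L, p_missing = 0)
  out <- impose_sampling_design(tab, em, seed = 3)
  expect_equal(tapply(out$count, out$year, sum), tapply(tab$count, tab$year, sum))
  expect_equal(length(unique(out$sample_id)), 6L)

  ident <- impose_sampling_design(tab, list(n_traps = 1L, n_periods = 1L, p_missing = 0))
  expect_equal(as.data.frame(ident), as.data.frame(tab), ignore_attr = TRUE)
  expect_error(impose_sampling_design(tab, list(n_traps = 0L)), "at least one trap")

  em2 <- list(n_traps = 6L, n_periods = 1L, p_missing = 0.2)
  a <- impose_sampling_design(tab, em2, seed = 11)
  b <- impose_sampling_design(tab, em2, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # some samples deleted
  expect_lt(length(unique(paste(a$year, a$sample_id))), 60L)
})

test_that("taxonomy degradation conserves individuals at every fraction", {
  tab <- simulate_community_series(rep(400, 25), years = 2, dispersion = 0)
  expect_equal(as.data.frame(degrade_taxonomy(tab, 0)), as.data.frame(tab),
               ignore_attr = TRUE)

  all_gen <- degrade_taxonomy(tab, 1, seed = 1)
  expect_true(all(all_gen$rank[all_gen$count > 0] == "genus"))
  expect_equal(sum(all_gen$count), sum(tab$count))

  some <- degrade_taxonomy(tab, 0.1, seed = 5)
  share <- sum(some$count[some$rank == "genus"]) / sum(some$count)
  expect_gt(share, 0.08)
  expect_lt(share, 0.12)
})

test_that("the generator is deterministic given its config", {
  cfg <- sim_config(n_studies = 2, n_sites_per_study = 2, n_species = 20,
                    years = 6, seed = 99,
                    effort_model = list(n_traps = 3L, n_periods = 2L, p_missing = 0.1))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  expect_identical(unclass(read_sim_config(path))[order(names(cfg))],
                   unclass(cfg)[order(names(cfg))])
})

test_that("noise-free series recovers the injected trend to 4 decimals", {
  sad <- rep(500, 10)
  tab <- simulate_community_series(sad, trend_spec = -0.015, years = 20, dispersion = 0)
  tot <- tapply(tab$count, tab$year, sum)
  sl <- stats::coef(stats::lm(log10(tot + 1) ~ as.numeric(names(tot))))[2]
  expect_lt(abs(unname(sl) - log10(1 - 0.015)), 1e-4)
})
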