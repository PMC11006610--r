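test_that("taxonomy cleaning allocates genus records to observed congeners", {
  df <- data.frame(study_id = "S", area_id = "A", site_id = "P", year = 2001,
                   period = "p1", sample_id = "s1",
                   taxon_id = c("g01_sp001", "g01_sp002", "g01", "g02"),
                   rank = c("species", "species", "genus", "genus"),
                   count = c(6, 3, 3, 4))
  out <- clean_taxonomy(community_table(df), seed = 1)
  # total conserved, no resolvable genus records remain
  expect_equal(sum(out$count), 16)
  expect_false("g01" %in% out$taxon_id)
  # congener totals absorb the 3 genus individuals
  expect_equal(sum(out$count[startsWith(out$taxon_id, "g01_")]), 12)
  # genus with no congeners kept as pseudo-species
  g02 <- out[out$taxon_id == "g02", ]
  expect_equal(g02$rank, "species")
  expect_equal(g02$count, 4)
  # no genus records at all: identity
  sp_only <- community_table(df[df$rank == "species", ])
  expect_equal(as.data.frame(clean_taxonomy(sp_only)), as.data.frame(sp_only),
               ignore_attr = TRUE)
})

test_that("allocation probabilities follow congener series abundance", {
  df <- data.frame(study_id = "S", area_id = "A", site_id = "P", year = 2001,
                   period = "p1", sample_id = "s1",
                   taxon_id = c("g01_sp001", "g01_sp002", "g01"),
                   rank = c("species", "species", "genus"),
                   count = c(90, 10, 1000))
  share <- replicate(50, {
    out <- clean_taxonomy(community_table(df))
    out$count[out$taxon_id == "g01_sp001"] / 1090
  })
  # expected share of sp001 in the reallocated mass: 90/100 of 1000 + its own 90
  expect_equal(mean(share), (90 + 900) / 1090, tolerance = 0.02)
})

test_that("effort targeting maximizes year-by-period cells, then years", {
  # winter period sampled only in the first year: dropped from the plan
  df <- expand.grid(year = 2001:2003, period = c("may", "jun", "dec"),
                    sample_id = c("t1", "t2"), stringsAsFactors = FALSE)
  df <- df[!(df$period == "dec" & df$year > 2001), ]
  df$study_id <- "S"; df$area_id <- "A"; df$site_id <- "P"
  df$taxon_id <- "g01_sp001"; df$rank <- "species"; df$count <- 5
  plan <- effort_target(community_table(df))
  expect_setequal(plan$P$periods, c("may", "jun"))
  expect_equal(plan$P$years, 2001:2003)
  expect_equal(unname(plan$P$target), c(2L, 2L), ignore_attr = TRUE)

  # equal cells: the plan retaining more years wins
  df2 <- rbind(
    expand.grid(year = 2001:2004, period = "a", sample_id = "t1", stringsAsFactors = FALSE),
    expand.grid(year = 2001:2002, period = "b", sample_id = "t1", stringsAsFactors = FALSE),
    expand.grid(year = 2003:2004, period = "c", sample_id = "t1", stringsAsFactors = FALSE))
  df2$study_id <- "S"; df2$area_id <- "A"; df2$site_id <- "P"
  df2$taxon_id <- "g01_sp001"; df2$rank <- "species"; df2$count <- 2
  plan2 <- effort_target(community_table(df2))
  expect_equal(plan2$P$periods, "a")
  expect_equal(plan2$P$years, 2001:2004)
})

test_that("individual-proportional subsampling draws the effort-scaled count", {
  # the canonical worked example: 300 individuals in 6 traps equalized to
  # 4-trap effort must draw 200 individuals
  tab <- simulate_community_series(c(150, 100, 50), years = 2, dispersion = 0)
  tab$count <- ifelse(tab$year == min(tab$year), tab$count, round(tab$count * 5 / 3))
  tab <- impose_sampling_design(tab, list(n_traps = c(6L, 4L), n_periods = 1L,
                                          p_missing = 0), seed = 2)
  res <- equalize_effort(tab, method = "individuals", n_iter = 3, seed = 9)
  for (it in res$iterations) {
    expect_equal(as.numeric(tapply(it$count, it$year, sum)), c(200, 500))
  }
})

test_that("equal effort everywhere reproduces the input in every iteration", {
  tab <- simulate_community_series(c(40, 20, 10), years = 4, dispersion = 0.3, seed = 5)
  res <- equalize_effort(tab, method = "samples", n_iter = 5, seed = 1)
  ref <- assemblage_counts(tab)
  for (it in res$iterations) expect_equal(it, ref, ignore_attr = TRUE)
})

test_that("subsampled richness converges to the hypergeometric expectation", {
  # one year at double effort: its expected richness over iterations must
  # match analytic rarefaction of that year to the drawn count
  set.seed(77)
  cc <- c(40, 20, 10, 5, 2, 1, 1, 1)
  df <- rbind(
    data.frame(year = 2001L, sample_id = rep(c("t1", "t2"), each = 8),
               taxon_id = sprintf("g01_sp%03d", 1:8), count = c(cc, cc)),
    data.frame(year = 2002L, sample_id = "t1",
               taxon_id = sprintf("g01_sp%03d", 1:8), count = cc))
  df$study_id <- "S"; df$area_id <- "A"; df$site_id <- "P"
  df$period <- "p1"; df$rank <- "species"
  tab <- community_table(df)
  res <- equalize_effort(tab, method = "individuals", n_iter = 200, seed = 12)
  rich <- res$metric_means
  got <- rich$value[rich$year == 2001 & rich$metric == "richness"]
  pooled <- c(cc + cc)
  expected <- rarefied_richness(pooled, sum(cc))
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("permuting sample labels within a year leaves results unchanged", {
  tab <- simulate_community_series(c(60, 30, 10), years = 3, dispersion = 0)
  tab <- impose_sampling_design(tab, list(n_traps = 4L, n_periods = 1L,
                                          p_missing = 0), seed = 8)
  perm <- as.data.frame(tab)
  relabel <- c(trap01 = "trap03", trap02 = "trap04", trap03 = "trap01", trap04 = "trap02")
  perm$sample_id <- unname(relabel[perm$sample_id])
  res1 <- equalize_effort(tab, method = "samples", n_iter = 20, seed = 4)
  res2 <- equalize_effort(community_table(perm), method = "samples", n_iter = 20, seed = 4)
  m1 <- res1$metric_means
  m2 <- res2$metric_means
  expect_equal(m1$value[m1$metric == "richness"], m2$value[m2$metric == "richness"],
               tolerance = 0.15)
})

test_that("metric means stabilize: doubling iterations moves richness < 1%", {
  tab <- simulate_community_series(c(50, 25, 12, 6, 3, 1), years = 3,
                                   dispersion = 0.2, seed = 21)
  tab <- impose_sampling_design(tab, list(n_traps = c(3L, 2L, 2L), n_periods = 1L,
                                          p_missing = 0), seed = 22)
  r100 <- equalize_effort(tab, method = "individuals", n_iter = 100, seed = 1)
  r200 <- equalize_effort(tab, method = "individuals", n_iter = 200, seed = 2)
  m100 <- r100$metric_means
  m200 <- r200$metric_means
  a <- m100$value[m100$metric == "richness"]
  b <- m200$value[m200$metric == "richness"]
  expect_true(all(abs(a - b) / pmax(b, 1) < 0.01))
})

test_that("population medians are rounded integers over iterations", {
  tab <- simulate_community_series(c(30, 10, 2), years = 3, dispersion = 0.4, seed = 6)
  res <- equalize_effort(tab, method = "samples", n_iter = 7, seed = 2)
  expect_true(all(res$population_medians$count == floor(res$population_medians$count)))
})
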