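test_that("slope back-transforms invert exactly", {
  expect_equal(slope_to_percent(0, "gaussian_log10p1"), 0)
  expect_equal(slope_to_percent(log10(0.9851), "gaussian_log10p1"), -1.49)
  expect_equal(slope_to_percent(log(2), "poisson_log"), 100)
  expect_true(is.na(slope_to_percent(0.1, "beta")))
  for (x in c(-0.02, 0, 0.013)) {
    expect_equal(percent_to_slope(slope_to_percent(x, "gaussian_log10p1"),
                                  "gaussian_log10p1"), x, tolerance = 1e-12)
    expect_equal(percent_to_slope(slope_to_percent(x, "poisson_log"),
                                  "poisson_log"), x, tolerance = 1e-12)
  }
})

test_that("evidence tiers read nested credible intervals correctly", {
  ci <- function(l80, u80, l90, u90, l95, u95) {
    matrix(c(l80, u80, l90, u90, l95, u95), ncol = 2, byrow = TRUE,
           dimnames = list(c("80%", "90%", "95%"), c("lower", "upper")))
  }
  expect_equal(classify_evidence(ci(-1.8, -1.2, -2.0, -1.0, -2.18, -0.79)), "strong")
  expect_equal(classify_evidence(ci(-0.5, -0.2, -0.55, -0.1, -0.64, 0.06)), "moderate")
  expect_equal(classify_evidence(ci(-0.4, -0.1, -0.5, 0.1, -0.6, 0.2)), "weak")
  expect_equal(classify_evidence(ci(-0.3, 0.2, -0.4, 0.3, -0.5, 0.4)), "none")
  expect_error(classify_evidence(ci(-2, 2, -1, 1, -0.5, 0.5)), "nested")
})

test_that("noise-free exponential decline recovers its rate deterministically", {
  d <- data.frame(site_id = "P", year = 2001:2020, value = 1000 * 0.985^(0:19))
  f <- suppressWarnings(fit_metric_trend(d))
  expect_lt(abs(f$slope - log10(0.985)), 5e-4)
  expect_lt(abs(f$percent - (-1.5)), 0.05)
  expect_equal(classify_evidence(f), "strong")
})

test_that("a flat series shows no evidence of trend", {
  d <- data.frame(site_id = "P", year = 2001:2020, value = 500)
  f <- suppressWarnings(fit_metric_trend(d))
  expect_equal(classify_evidence(f), "none")
  expect_lt(abs(f$percent), 0.01)
})

test_that("non-finite responses and single years are rejected", {
  expect_error(fit_metric_trend(data.frame(site_id = "P", year = 1:3,
                                           value = c(1, NA, 3))), "non-finite")
  expect_error(fit_metric_trend(data.frame(site_id = "P", year = rep(2001, 3),
                                           value = 1:3)), "two distinct years")
})

test_that("evenness model handles boundary values and recovers a logit trend", {
  set.seed(14)
  d <- expand.grid(site_id = sprintf("P%d", 1:4), year = 2001:2020)
  d$value <- plogis(qlogis(0.5) + 0.06 * (d$year - 2010) + rnorm(nrow(d), 0, 0.2))
  d$value[1] <- 1  # exact boundary: handled by the shrink, no error
  f <- suppressWarnings(fit_evenness_trend(d))
  expect_gt(f$slope, 0)
  expect_equal(classify_evidence(f), "strong")
  expect_true(is.na(f$percent))

  dc <- expand.grid(site_id = sprintf("P%d", 1:3), year = 2001:2010)
  dc$value <- 0.5
  fc <- suppressWarnings(fit_evenness_trend(dc))
  expect_equal(classify_evidence(fc), "none")
})

test_that("poisson population fits recover growth in the deterministic limit", {
  d <- data.frame(site_id = "P", taxon_id = "g01_sp001", year = 2001:2015,
                  count = round(40 * 1.03^(0:14)))
  cls <- data.frame(site_id = "P", taxon_id = "g01_sp001", rule = "year1", class = 1L)
  attr(cls, "k") <- 5L
  f <- suppressWarnings(fit_population_trends(d, cls, ar1 = FALSE))
  expect_lt(abs(f$fits[["1"]]$slope - log(1.03)), 2e-3)

  # population observed once is dropped; all-absent group skipped with warning
  d2 <- rbind(d, data.frame(site_id = "P", taxon_id = "g01_sp002",
                            year = 2001, count = 5))
  cls2 <- rbind(cls, data.frame(site_id = "P", taxon_id = "g01_sp002",
                                rule = "year1", class = 2L))
  attr(cls2, "k") <- 5L
  f2 <- suppressWarnings(fit_population_trends(d2, cls2, ar1 = FALSE))
  expect_false("2" %in% names(f2$fits))
})

test_that("extreme short-series site slopes are shrunk toward the study mean", {
  set.seed(88)
  d <- do.call(rbind, lapply(1:6, function(s) {
    yrs <- 2001:2015
    data.frame(study_id = "S1", site_id = sprintf("P%d", s), year = yrs,
               value = 10^(2 - 0.004 * (yrs - 2008) + rnorm(length(yrs), 0, 0.05)) - 1)
  }))
  wild <- data.frame(study_id = "S1", site_id = "P7", year = c(2007, 2008),
                     value = c(50, 5000))
  ols <- stats::coef(stats::lm(log10(value + 1) ~ year, wild))[2]
  f <- suppressWarnings(fit_metric_trend(rbind(d, wild)))
  re <- f$ranef$site_id
  site_slope <- f$slope + re$mode[re$level == "P7" & re$term == "year_c"]
  expect_lt(abs(site_slope), abs(ols))
})

test_that("AR1 intervals recover a known autocorrelation", {
  cover <- 0
  n_fit <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    d <- do.call(rbind, lapply(1:10, function(s) {
      e <- as.numeric(stats::arima.sim(list(ar = 0.6), 30, sd = 0.15))
      b <- rnorm(1, -0.004, 0.002)
      data.frame(site_id = sprintf("P%02d", s), year = 2000 + (1:30),
                 value = 10^(2 + b * (1:30 - 15) + e + rnorm(30, 0, 0.08)) - 1)
    }))
    f <- suppressWarnings(fit_metric_trend(d))
    if (!is.na(f$rho_ci[["lower"]])) {
      n_fit <- n_fit + 1
      cover <- cover + (f$rho_ci[["lower"]] <= 0.6 && 0.6 <= f$rho_ci[["upper"]])
    }
  }
  expect_gte(n_fit, 17)   # the AR1 term must actually be retained
  expect_gte(cover, 16)   # and its interval must cover the truth
})

test_that("trend_fit methods expose coefficients and intervals", {
  d <- data.frame(site_id = "P", year = 2001:2015, value = 200 * 0.98^(0:14))
  f <- suppressWarnings(fit_metric_trend(d))
  expect_named(coef(f), "year")
  ci <- confint(f, level = 0.95)
  expect_equal(unname(ci[1, ]), unname(f$ci["95%", ]), tolerance = 1e-10)
  expect_output(print(f), "Year-trend fit")
  expect_output(print(summary(f)), "evidence")
})
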