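# Conceptual three-scenario model of community decline: an idealized
# skewed SAD projected forward 20 years under (1) proportional declines,
# (2) stronger declines of abundant species, (3) stronger declines of rare
# species, with Gaussian noise, rounding, and an extinction display rule.

# The 21 non-rare fixture abundances are a documented constant chosen to
# satisfy every design constraint: together with 12 singletons and 10
# doubletons they give 43 species and 211 individuals, maximum abundance
# 32, and all five equal-log10 SAD intervals (scaled to 32) populated.
BOX1_HIGHER <- c(32L, 20L, 18L, 14L, 12L, 10L, 9L, 8L, 7L, 6L, 6L,
                 5L, 5L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L)

#' The idealized 43-species starting community
#'
#' A typical skewed SAD: 12 singletons, 10 doubletons and 21 species with
#' higher abundances (maximum 32), totalling 211 individuals. Used as the
#' starting point of the three conceptual decline scenarios.
#'
#' @return integer vector of length 43, sorted descending.
#' @export
box1_fixture <- function() {
  c(BOX1_HIGHER, rep(2L, 10L), rep(1L, 12L))
}

#' Specify one of the three conceptual decline scenarios
#'
#' * `"proportional"`: every species declines at the same annual rate `r`.
#'   When `r` is `NULL` it is set so that total abundance after
#'   `match_years` years matches the abundant-decline scenario on the
#'   fixture community (the scenarios are meant to share the same overall
#'   abundance loss).
#' * `"abundant_decline"`: `N_t = N0^(1 - a t)`; the annual multiplier
#'   `N0^(-a)` shrinks with initial abundance, so abundant species decline
#'   fastest and singletons not at all.
#' * `"rare_decline"`: `N_t = N0 * (10^b + c * log10(N0))^t`; the annual
#'   multiplier grows with initial abundance, so rare species decline
#'   fastest.
#'
#' @param scenario one of `"proportional"`, `"abundant_decline"`,
#'   `"rare_decline"`.
#' @param r annual rate for the proportional scenario (negative = decline).
#' @param a exponent coefficient of the abundant-decline rule (> 0).
#' @param b,c intercept and slope of the rare-decline annual multiplier on
#'   the log10 scale (`c` > 0).
#' @param match_years horizon used to match the proportional rate.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("proportional", "abundant_decline",
                                       "rare_decline"),
                          r = NULL, a = 0.018, b = -0.027, c = 0.035,
                          match_years = 20L) {
  scenario <- match.arg(scenario)
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (!is.numeric(c) || c <= 0) stop("`c` must be positive", call. = FALSE)
  if (scenario == "proportional" && is.null(r)) {
    r <- match_proportional_rate(box1_fixture(), years = match_years, a = a)
  }
  structure(list(scenario = scenario, r = r, a = a, b = b, c = c),
            class = "scenario_spec")
}

#' Proportional rate matching the abundant-decline scenario's total loss
#'
#' Solves for the single annual rate under which total community abundance
#' after `years` years equals the total under the abundant-decline rule
#' applied to the same community.
#'
#' @param fixture abundance vector.
#' @param years horizon in years.
#' @param a abundant-decline exponent coefficient.
#' @return annual rate (negative for decline).
#' @export
match_proportional_rate <- function(fixture = box1_fixture(), years = 20L,
                                    a = 0.018) {
  total_end <- sum(fixture^(1 - a * years))
  (total_end / sum(fixture))^(1 / years) - 1
}

#' Expected population abundance under a decline scenario
#'
#' Deterministic projection of an initial abundance `N0` to time `t`.
#' At `t = 0` the initial abundance is returned for every scenario.
#'
#' @param N0 initial abundance(s), >= 1 for the abundance-dependent rules.
#' @param t years elapsed (>= 0); vectorized with `N0`.
#' @param spec a [scenario_spec()].
#' @return expected abundance (real-valued).
#' @export
project_population <- function(N0, t, spec) {
  stopifnot(inherits(spec, "scenario_spec"), all(t >= 0))
  switch(spec$scenario,
    proportional = N0 * (1 + spec$r)^t,
    abundant_decline = {
      if (any(N0 < 1)) {
        stop("abundance-dependent rules need N0 >= 1 (log of sub-unit abundance)",
             call. = FALSE)
      }
      N0^(1 - spec$a * t)
    },
    rare_decline = {
      if (any(N0 < 1)) {
        stop("abundance-dependent rules need N0 >= 1 (log of sub-unit abundance)",
             call. = FALSE)
      }
      N0 * (10^spec$b + spec$c * log10(N0))^t
    })
}

#' Annual percent decline of a population under a scenario
#'
#' Convenience wrapper: `(1 - N1/N0) * 100` from [project_population()].
#'
#' @inheritParams project_population
#' @return percent decline per year (positive = declining).
#' @export
annual_percent_decline <- function(N0, spec) {
  (1 - project_population(N0, 1, spec) / N0) * 100
}

#' Run a decline scenario forward with noise, rounding and extinction
#'
#' Projects each species of the starting community for `years` years
#' (times 0..years), adds independent Gaussian noise (mean `noise_mean`,
#' sd `noise_sd`) to the deterministic yearly values (noise is not
#' compounded into the dynamics), rounds to integers and floors at zero.
#' A parallel display series additionally declares species extinct
#' (count 0) in years where the pre-rounding noisy value falls below
#' `extinction_threshold`; the analysis series uses the rounded counts.
#'
#' @param spec a [scenario_spec()].
#' @param fixture starting abundance vector.
#' @param years projection horizon (output covers years 0..`years`).
#' @param noise_mean,noise_sd Gaussian noise parameters.
#' @param extinction_threshold display-extinction cutoff (> 0).
#' @param seed integer seed or `NULL`.
#' @param site_id site label for the emitted table.
#' @return a `community_table` (single site, period and sample) with an
#'   extra `count_display` column; scenario and seed are recorded in the
#'   `"scenario_meta"` attribute.
#' @export
run_scenario <- function(spec, fixture = box1_fixture(), years = 20L,
                         noise_mean = 0, noise_sd = 0.5,
                         extinction_threshold = 0.6, seed = NULL,
                         site_id = "box1") {
  stopifnot(inherits(spec, "scenario_spec"), length(fixture) >= 1,
            noise_sd >= 0, extinction_threshold > 0)
  n_sp <- length(fixture)
  taxa <- sprintf("g%03d_sp%03d", seq_len(n_sp), seq_len(n_sp))
  tt <- rep(0:years, each = n_sp)
  expected <- project_population(rep(fixture, years + 1L), tt, spec)
  noisy <- expected + with_seed(seed, stats::rnorm(length(expected), noise_mean, noise_sd))
  counts <- pmax(0, round_half_up(noisy))
  display <- ifelse(noisy < extinction_threshold, 0, counts)
  out <- data.frame(
    study_id = "scenario", area_id = "scenario-A1", site_id = site_id,
    year = tt + 1L, period = "p1", sample_id = "smp1",
    taxon_id = rep(taxa, years + 1L), rank = "species",
    count = as.numeric(counts), count_display = as.numeric(display),
    stringsAsFactors = FALSE)
  tab <- community_table(out)
  attr(tab, "scenario_meta") <- list(scenario = spec$scenario, spec = unclass(spec),
                                     years = years, noise_mean = noise_mean,
                                     noise_sd = noise_sd,
                                     extinction_threshold = extinction_threshold,
                                     seed = seed)
  tab
}
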