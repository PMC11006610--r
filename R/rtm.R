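# Regression-to-the-mean (RtM) correction for population trends.
# Classifying species by a stochastic initial abundance biases the
# apparent trends: populations drawn high in the classification year(s)
# regress downward, those drawn low regress upward. The correction
# estimates the RtM component on the longest series by refitting the
# trends with the classification year(s) left-censored out of the trend
# window (but still used for classification), and adds the difference to
# the full-series estimates, shrinking them towards zero.

#' Estimate RtM correction factors per initial-abundance group
#'
#' Restricts to robust sites (at least `min_years` sampled years), then per
#' group fits the population trend twice: (a) on the full series and (b)
#' with the first `censor` year(s) excluded from trend fitting while still
#' defining the classification. The correction factor is
#' `slope(censored) - slope(full)` on the log-link scale.
#'
#' @param populations data frame `site_id`, `taxon_id`, `year`, `count`
#'   (plus optional `study_id`, `area_id`).
#' @param rule classification rule (see [classify_initial_abundance()]).
#' @param min_years minimum number of sampled years for a site to enter
#'   the correction estimate (data points, not span).
#' @param censor number of initial years to left-censor (1, or 3 as a
#'   sensitivity variant).
#' @param k number of abundance intervals.
#' @param ar1 passed to the population model.
#' @return an `rtm_correction` data frame (`group`, `raw_slope`,
#'   `censored_slope`, `factor`, `censor`, `min_years`) with the full-series
#'   fits attached as attribute `"full_fits"` (a `population_trend_fit`).
#' @export
estimate_rtm_correction <- function(populations, rule = "year1",
                                    min_years = 15L, censor = 1L, k = 5L,
                                    ar1 = TRUE) {
  stopifnot(censor >= 1)
  d <- as.data.frame(populations)
  yrs_per_site <- tapply(d$year, d$site_id, function(y) length(unique(y)))
  robust <- names(yrs_per_site)[yrs_per_site >= min_years]
  if (!length(robust)) {
    stop(sprintf(paste0("no sites with at least %d sampled years; ",
                        "lower `min_years` to estimate an RtM correction"),
                 min_years), call. = FALSE)
  }
  d <- d[d$site_id %in% robust, , drop = FALSE]
  classes <- classify_initial_abundance(d, rule = rule, k = k)
  full <- fit_population_trends(d, classes, ar1 = ar1)
  # censor the first `censor` sampled years of each site out of the trend window
  keep <- rep(TRUE, nrow(d))
  for (s in unique(d$site_id)) {
    yrs <- sort(unique(d$year[d$site_id == s]))
    cens <- utils::head(yrs, censor)
    keep[d$site_id == s & d$year %in% cens] <- FALSE
  }
  censored <- fit_population_trends(d[keep, , drop = FALSE], classes, ar1 = ar1)
  groups <- intersect(names(full$fits), names(censored$fits))
  out <- data.frame(
    group = as.integer(groups),
    raw_slope = vapply(groups, function(g) full$fits[[g]]$slope, numeric(1)),
    censored_slope = vapply(groups, function(g) censored$fits[[g]]$slope, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$factor <- out$censored_slope - out$raw_slope
  out$censor <- as.integer(censor)
  out$min_years <- as.integer(min_years)
  class(out) <- c("rtm_correction", "data.frame")
  attr(out, "full_fits") <- full
  attr(out, "censored_fits") <- censored
  out
}

#' Apply an RtM correction to population trend estimates
#'
#' Adds each group's correction factor to the group's slope, its credible
#' intervals (translated, widths unchanged) and its species-level random
#' slope summaries, and recomputes the percent back-transform.
#'
#' @param estimates a `population_trend_fit`.
#' @param corr an `rtm_correction` whose groups match `estimates`.
#' @return the corrected `population_trend_fit` (`corrected = TRUE`).
#' @export
apply_rtm_correction <- function(estimates, corr) {
  stopifnot(inherits(estimates, "population_trend_fit"),
            inherits(corr, "rtm_correction"))
  have <- as.integer(names(estimates$fits))
  if (!all(have %in% corr$group)) {
    stop("correction factors missing for some initial-abundance groups",
         call. = FALSE)
  }
  for (g in names(estimates$fits)) {
    f <- estimates$fits[[g]]
    delta <- corr$factor[corr$group == as.integer(g)]
    f$slope <- f$slope + delta
    f$ci <- f$ci + delta
    f$percent <- slope_to_percent(f$slope, f$family)
    f$percent_ci <- apply(f$ci, 2, slope_to_percent, family = f$family)
    if (!is.null(f$ranef$sp_site)) {
      # random-effect summaries deviate from the fixed slope, which has shifted
      attr(f$ranef$sp_site, "rtm_shift") <- delta
    }
    f$rtm_factor <- delta
    estimates$fits[[g]] <- f
  }
  if (!is.null(estimates$species_slopes)) {
    shift <- corr$factor[match(estimates$species_slopes$group, corr$group)]
    estimates$species_slopes$slope <- estimates$species_slopes$slope + shift
  }
  estimates$corrected <- TRUE
  estimates$correction <- as.data.frame(corr)
  estimates
}

#' Relate dataset-level population-trend effects to total-abundance effects
#'
#' For each initial-abundance group, correlates the study-level random
#' year-slope effects of the population model with the study-level random
#' year-slope effects of the total-abundance model fitted on the same
#' datasets, propagating the conditional uncertainty of both sets of
#' effects by Monte-Carlo draws.
#'
#' @param pop_fits a `population_trend_fit` (fitted across >= 3 studies).
#' @param abundance_fit a `trend_fit` for total abundance on the same data.
#' @param n_draws Monte-Carlo draws for the uncertainty of the correlation.
#' @param seed integer seed or `NULL`.
#' @return data frame `group`, `correlation`, `ci80_lower` ...
#'   `ci95_upper`, `n_studies`.
#' @export
relate_dataset_effects <- function(pop_fits, abundance_fit, n_draws = 1000L,
                                   seed = NULL) {
  stopifnot(inherits(pop_fits, "population_trend_fit"),
            inherits(abundance_fit, "trend_fit"))
  ab <- abundance_fit$ranef$study_id
  if (is.null(ab)) stop("abundance fit carries no study-level effects", call. = FALSE)
  ab <- ab[ab$term == "year_c", , drop = FALSE]
  rows <- lapply(names(pop_fits$fits), function(g) {
    pe <- pop_fits$fits[[g]]$ranef$study_id
    if (is.null(pe)) return(NULL)
    pe <- pe[pe$term == "year_c", , drop = FALSE]
    shared <- intersect(pe$level, ab$level)
    if (length(shared) < 3) {
      stop(sprintf("group %s: fewer than 3 shared datasets; association undefined", g),
           call. = FALSE)
    }
    p_mode <- pe$mode[match(shared, pe$level)]
    p_sd <- pe$condsd[match(shared, pe$level)]
    a_mode <- ab$mode[match(shared, ab$level)]
    a_sd <- ab$condsd[match(shared, ab$level)]
    p_sd[!is.finite(p_sd)] <- 0
    a_sd[!is.finite(a_sd)] <- 0
    draws <- with_seed(derive_seed(seed, paste0("assoc-", g)), {
      vapply(seq_len(n_draws), function(i) {
        stats::cor(p_mode + stats::rnorm(length(shared), 0, p_sd),
                   a_mode + stats::rnorm(length(shared), 0, a_sd))
      }, numeric(1))
    })
    draws <- draws[is.finite(draws)]
    qs <- stats::quantile(draws, c(0.1, 0.9, 0.025, 0.975))
    data.frame(group = as.integer(g),
               correlation = stats::cor(p_mode, a_mode),
               ci80_lower = qs[[1]], ci80_upper = qs[[2]],
               ci95_lower = qs[[3]], ci95_upper = qs[[4]],
               n_studies = length(shared), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
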