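# Ground-truth community simulator. Generates long-format survey tables
# with the statistical structure the downstream analysis assumes: skewed
# species abundance distributions, multiplicative per-species trends,
# overdispersed count noise, uneven trap/period effort with missing
# samples, and partial genus-level identification.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator; together with its
#' `seed` it fully determines the output of [simulate_dataset()].
#'
#' Defaults describe a typical long-term insect monitoring compilation:
#' 20-year series (the median duration in such compilations), a log-series
#' SAD with many rare species, a mean decline of -1.5% per year with
#' site-level heterogeneity, moderate overdispersion, and ~7% of
#' individuals identified only to genus.
#'
#' @param n_studies,n_sites_per_study,n_species,years community dimensions.
#' @param sad_model list; `model` is one of `"logseries"` (`p` in (0,1)),
#'   `"lognormal"` (`meanlog`, `sdlog`) or `"fixture"` (the built-in 43-species
#'   SAD, see [box1_fixture()]).
#' @param trend_spec per-species annual multiplicative rate: a scalar, a
#'   vector of length `n_species`, or `list(type = "random", mean, sd)`
#'   drawing site-level rates from a normal on `log(1 + r)`.
#' @param dispersion negative-binomial overdispersion of observation noise
#'   (variance = mu + dispersion * mu^2); `0` gives the deterministic limit.
#' @param effort_model list with `n_traps`, `n_periods`, `p_missing`; see
#'   [impose_sampling_design()].
#' @param genus_fraction expected share of individuals demoted to
#'   genus-level identification.
#' @param seed integer; fully determines the generated table.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 2L, n_sites_per_study = 5L, n_species = 60L,
                       years = 20L,
                       sad_model = list(model = "logseries", p = 0.93),
                       trend_spec = list(type = "random", mean = -0.015, sd = 0.005),
                       dispersion = 0.25,
                       effort_model = list(n_traps = 1L, n_periods = 1L, p_missing = 0),
                       genus_fraction = 0.07,
                       seed = 1L) {
  stopifnot(n_studies >= 1, n_sites_per_study >= 1, n_species >= 1, years >= 2)
  assert_prob(genus_fraction, "genus_fraction")
  assert_prob(effort_model$p_missing %||% 0, "p_missing")
  stopifnot(dispersion >= 0)
  cfg <- list(n_studies = as.integer(n_studies),
              n_sites_per_study = as.integer(n_sites_per_study),
              n_species = as.integer(n_species), years = as.integer(years),
              sad_model = sad_model, trend_spec = trend_spec,
              dispersion = dispersion, effort_model = effort_model,
              genus_fraction = genus_fraction, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Read or write a simulation configuration as YAML
#' @param path file path.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Draw a skewed species abundance distribution
#'
#' Generates per-species abundances with "a few abundant species and many
#' rare species", the canonical shape of insect assemblage SADs.
#'
#' @param n_species number of species (>= 1).
#' @param sad_model list with element `model`: `"logseries"` draws i.i.d.
#'   from a logarithmic-series distribution with parameter `p`;
#'   `"lognormal"` rounds a lognormal (`meanlog`, `sdlog`) up to at least 1;
#'   `"fixture"` returns the built-in 43-species SAD.
#' @param seed integer seed or `NULL`.
#' @return integer vector of positive abundances, sorted descending.
#' @export
generate_skewed_sad <- function(n_species,
                                sad_model = list(model = "logseries", p = 0.9),
                                seed = NULL) {
  stopifnot(is.numeric(n_species), length(n_species) == 1L, n_species >= 1)
  n_species <- as.integer(n_species)
  model <- sad_model$model %||% "logseries"
  ab <- switch(model,
    logseries = {
      p <- sad_model$p %||% 0.9
      if (!is.numeric(p) || p <= 0 || p >= 1) {
        stop("logseries parameter `p` must lie in (0, 1)", call. = FALSE)
      }
      with_seed(seed, rlogseries(n_species, p))
    },
    lognormal = {
      meanlog <- sad_model$meanlog %||% 1
      sdlog <- sad_model$sdlog %||% 1.5
      if (!is.numeric(sdlog) || sdlog <= 0) {
        stop("lognormal parameter `sdlog` must be positive", call. = FALSE)
      }
      with_seed(seed, pmax(1, round_half_up(stats::rlnorm(n_species, meanlog, sdlog))))
    },
    fixture = {
      if (n_species != 43L) {
        stop("the fixture SAD has exactly 43 species", call. = FALSE)
      }
      box1_fixture()
    },
    stop(sprintf("unknown sad_model '%s'", model), call. = FALSE)
  )
  if (n_species == 1L) ab <- sum(ab)  # single-species community: all individuals
  sort(as.integer(ab), decreasing = TRUE)
}

# Logarithmic-series distribution P(k) = -p^k / (k log(1 - p)), sampled by
# inversion over a truncated support covering all but < 1e-12 of the mass.
rlogseries <- function(n, p) {
  kmax <- 10L
  repeat {
    k <- seq_len(kmax)
    pmf <- -p^k / (k * log1p(-p))
    if (sum(pmf) > 1 - 1e-12 || kmax > 1e7) break
    kmax <- kmax * 4L
  }
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(stats::runif(n), cdf) + 1L
}

# Resolve a trend specification to one annual multiplicative rate per species.
resolve_trend_rates <- function(trend_spec, n_species, seed = NULL) {
  if (is.numeric(trend_spec)) {
    if (any(trend_spec <= -1)) stop("rates must exceed -1", call. = FALSE)
    return(rep_len(trend_spec, n_species))
  }
  if (is.list(trend_spec) && identical(trend_spec$type, "random")) {
    m <- trend_spec$mean %||% 0
    s <- trend_spec$sd %||% 0
    return(with_seed(seed, exp(stats::rnorm(n_species, log1p(m), s)) - 1))
  }
  stop("trend_spec must be numeric or list(type = 'random', mean, sd)", call. = FALSE)
}

#' Simulate one site's community time series with known trends
#'
#' Expected count of species i in year t (t = 0, 1, ...) is
#' `sad[i] * (1 + r[i])^t`; observation noise is negative-binomial with the
#' given overdispersion (`dispersion = 0` gives the deterministic rounded
#' expectation). Output is one site, one period, one sample per year, with
#' explicit zero counts so population series are complete.
#'
#' @param sad integer abundance vector (initial expected abundances).
#' @param trend_spec see [sim_config()].
#' @param years number of years (>= 2); years are consecutive integers.
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param seed integer seed or `NULL`.
#' @param study_id,area_id,site_id,year0 identifiers and first calendar year.
#' @param genus_size species are grouped into genera of this size when
#'   assigning taxon identifiers (used by the taxonomy-degradation step).
#' @return a `community_table`.
#' @export
simulate_community_series <- function(sad, trend_spec = 0, years = 20L,
                                      dispersion = 0, seed = NULL,
                                      study_id = "S1", area_id = "S1-A1",
                                      site_id = "S1-P1", year0 = 2001L,
                                      genus_size = 3L) {
  stopifnot(years >= 2, all(sad >= 0), dispersion >= 0)
  n_sp <- length(sad)
  rates <- resolve_trend_rates(trend_spec, n_sp, derive_seed(seed, "rates"))
  genus <- sprintf("g%03d", ((seq_len(n_sp) - 1L) %/% genus_size) + 1L)
  taxa <- sprintf("%s_sp%03d", genus, seq_len(n_sp))
  tt <- rep(0:(years - 1L), each = n_sp)
  mu <- rep(sad, years) * (1 + rep(rates, years))^tt
  counts <- if (dispersion == 0) {
    round_half_up(mu)
  } else {
    with_seed(derive_seed(seed, "noise"),
              stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
  }
  out <- data.frame(
    study_id = study_id, area_id = area_id, site_id = site_id,
    year = as.integer(year0) + tt, period = "p1", sample_id = "smp1",
    taxon_id = rep(taxa, years), rank = "species", count = as.numeric(counts),
    stringsAsFactors = FALSE)
  tab <- community_table(out)
  attr(tab, "true_rates") <- stats::setNames(rates, taxa)
  tab
}

#' Impose a trap/period sampling design on a one-sample-per-year table
#'
#' Splits each site-year's individuals multinomially (uniformly) across
#' `n_traps x n_periods` samples, then deletes whole samples independently
#' with probability `p_missing`. Totals are conserved before deletion.
#'
#' @param table a `community_table` with one sample per site-year.
#' @param effort_model list with `n_traps` (scalar or per-year vector),
#'   `n_periods`, `p_missing`.
#' @param seed integer seed or `NULL`.
#' @return a `community_table`.
#' @export
impose_sampling_design <- function(table,
                                   effort_model = list(n_traps = 1L, n_periods = 1L,
                                                       p_missing = 0),
                                   seed = NULL) {
  df <- as.data.frame(table)
  n_periods <- as.integer(effort_model$n_periods %||% 1L)
  p_missing <- effort_model$p_missing %||% 0
  assert_prob(p_missing, "p_missing")
  n_traps <- as.integer(effort_model$n_traps %||% 1L)
  if (any(n_traps < 1) || n_periods < 1) {
    stop("effort model needs at least one trap and one period", call. = FALSE)
  }
  if (nrow(df) && anyDuplicated(unique(df[, c("site_id", "year", "period", "sample_id")])[, c("site_id", "year")])) {
    stop("input must have one sample per site-year", call. = FALSE)
  }
  if (all(n_traps == 1L) && n_periods == 1L && p_missing == 0) {
    return(community_table(df))  # identity design
  }
  with_seed(seed, {
    pieces <- lapply(split(df, list(df$site_id, df$year), drop = TRUE), function(g) {
      yr_index <- g$year[1] - min(df$year) + 1L
      k_traps <- n_traps[((yr_index - 1L) %% length(n_traps)) + 1L]
      cells <- k_traps * n_periods
      cell_period <- rep(sprintf("p%02d", seq_len(n_periods)), each = k_traps)
      cell_trap <- rep(sprintf("trap%02d", seq_len(k_traps)), times = n_periods)
      split_counts <- lapply(seq_len(nrow(g)), function(i) {
        if (g$count[i] == 0) return(NULL)
        alloc <- stats::rmultinom(1, g$count[i], rep(1 / cells, cells))[, 1]
        keep <- alloc > 0
        if (!any(keep)) return(NULL)
        data.frame(study_id = g$study_id[i], area_id = g$area_id[i],
                   site_id = g$site_id[i], year = g$year[i],
                   period = cell_period[keep], sample_id = cell_trap[keep],
                   taxon_id = g$taxon_id[i], rank = g$rank[i],
                   count = as.numeric(alloc[keep]), stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, split_counts)
      if (is.null(out)) return(NULL)
      if (p_missing > 0) {
        cells_present <- unique(out[, c("period", "sample_id")])
        drop <- stats::runif(nrow(cells_present)) < p_missing
        if (any(drop)) {
          dropped <- cells_present[drop, , drop = FALSE]
          key <- paste(out$period, out$sample_id)
          out <- out[!(key %in% paste(dropped$period, dropped$sample_id)), , drop = FALSE]
        }
      }
      out
    })
    out <- do.call(rbind, pieces)
    if (is.null(out)) out <- df[0, CT_COLS]
    rownames(out) <- NULL
    community_table(out)
  })
}

#' Demote a fraction of individuals to genus-level identification
#'
#' Per species-rank record, a binomial share of the individuals (expected
#' `genus_fraction`) is reassigned to the genus-level taxon (the part of
#' the identifier before the first underscore) with `rank = "genus"`.
#' Acting per individual means a species can be partially identified
#' within one sample, as in real surveys. Total individuals are conserved.
#'
#' @param table a `community_table` whose species identifiers carry a genus
#'   prefix (`"g01_sp003"`).
#' @param genus_fraction probability in \[0, 1\].
#' @param seed integer seed or `NULL`.
#' @return a `community_table`.
#' @export
degrade_taxonomy <- function(table, genus_fraction, seed = NULL) {
  assert_prob(genus_fraction, "genus_fraction")
  df <- as.data.frame(table)
  if (genus_fraction == 0 || !nrow(df)) return(community_table(df))
  with_seed(seed, {
    is_sp <- df$rank == "species" & df$count > 0
    demoted <- integer(nrow(df))
    demoted[is_sp] <- stats::rbinom(sum(is_sp), size = as.integer(df$count[is_sp]),
                                    prob = genus_fraction)
    genus_rows <- df[demoted > 0, , drop = FALSE]
    if (nrow(genus_rows)) {
      genus_rows$count <- demoted[demoted > 0]
      genus_rows$taxon_id <- genus_of(genus_rows$taxon_id)
      genus_rows$rank <- "genus"
      df$count <- df$count - demoted
      df <- rbind(df, genus_rows)
    }
    agg <- stats::aggregate(count ~ study_id + area_id + site_id + year + period +
                              sample_id + taxon_id + rank, data = df, FUN = sum)
    agg <- agg[agg$count > 0 | agg$rank == "species", , drop = FALSE]
    rownames(agg) <- NULL
    community_table(agg)
  })
}

#' Generate a full multi-study synthetic dataset
#'
#' Composes [generate_skewed_sad()], [simulate_community_series()],
#' [impose_sampling_design()] and [degrade_taxonomy()] per site, under
#' per-stage seeds derived from `cfg$seed`. The true per-species rates are
#' attached as the `"true_rates"` attribute.
#'
#' @param cfg a [sim_config()].
#' @return a `community_table`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- list()
  tables <- list()
  for (s in seq_len(cfg$n_studies)) {
    study <- sprintf("S%02d", s)
    for (p in seq_len(cfg$n_sites_per_study)) {
      site <- sprintf("%s-P%02d", study, p)
      sseed <- derive_seed(cfg$seed, paste0("site-", site))
      sad <- generate_skewed_sad(cfg$n_species, cfg$sad_model,
                                 seed = derive_seed(sseed, "sad"))
      tab <- simulate_community_series(
        sad, trend_spec = cfg$trend_spec, years = cfg$years,
        dispersion = cfg$dispersion, seed = derive_seed(sseed, "series"),
        study_id = study, area_id = paste0(study, "-A1"), site_id = site)
      truth[[site]] <- attr(tab, "true_rates")
      tab <- impose_sampling_design(tab, cfg$effort_model,
                                    seed = derive_seed(sseed, "design"))
      tab <- degrade_taxonomy(tab, cfg$genus_fraction,
                              seed = derive_seed(sseed, "taxonomy"))
      tables[[site]] <- as.data.frame(tab)
    }
  }
  out <- community_table(do.call(rbind, tables))
  rownames(out) <- NULL
  attr(out, "true_rates") <- truth
  out
}
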