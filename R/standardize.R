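# Effort standardization: equalize sampling effort across years within
# each site (by resampling individuals or whole samples) and clean partial
# genus-level identifications, so that each site-year contributes one
# assemblage based on the same effort. Effort is equalized within sites,
# not across sites.

#' Probabilistically resolve genus-level records to congeneric species
#'
#' Individuals identified only to genus are allocated to one of the
#' species of the same genus observed anywhere in the same site's series,
#' with probabilities proportional to each congener's total abundance
#' across the series (the maximum-likelihood assignment if identification
#' failure is independent of species). Genera with no observed congeners
#' are kept and re-ranked as pseudo-species. Total individuals per sample
#' are conserved.
#'
#' @param table a `community_table`.
#' @param seed integer seed or `NULL`.
#' @return a `community_table` free of resolvable genus-level records.
#' @export
clean_taxonomy <- function(table, seed = NULL) {
  df <- as.data.frame(table)
  is_genus <- df$rank == "genus"
  if (!any(is_genus)) return(community_table(df))
  with_seed(seed, {
    sp <- df[df$rank == "species", , drop = FALSE]
    # congener weights: per site x genus, total species abundance over the series
    sp_gen <- genus_of(sp$taxon_id)
    weight_key <- paste(sp$site_id, sp_gen, sp$taxon_id, sep = "\r")
    wtab <- tapply(sp$count, weight_key, sum)
    new_rows <- list()
    keep <- rep(TRUE, nrow(df))
    for (i in which(is_genus)) {
      site <- df$site_id[i]
      gen <- df$taxon_id[i]
      congeners <- unique(sp$taxon_id[sp$site_id == site & sp_gen == gen])
      if (!length(congeners)) {
        df$rank[i] <- "species"  # pseudo-species: no congeners in the series
        next
      }
      w <- wtab[paste(site, gen, congeners, sep = "\r")]
      w[is.na(w) | w <= 0] <- 0
      if (sum(w) == 0) w[] <- 1
      alloc <- stats::rmultinom(1, df$count[i], w / sum(w))[, 1]
      keep[i] <- FALSE
      nz <- alloc > 0
      if (any(nz)) {
        rows <- df[rep(i, sum(nz)), , drop = FALSE]
        rows$taxon_id <- congeners[nz]
        rows$rank <- "species"
        rows$count <- as.numeric(alloc[nz])
        new_rows[[length(new_rows) + 1L]] <- rows
      }
    }
    out <- rbind(df[keep, , drop = FALSE], do.call(rbind, new_rows))
    agg <- stats::aggregate(count ~ study_id + area_id + site_id + year + period +
                              sample_id + taxon_id + rank, data = out, FUN = sum)
    rownames(agg) <- NULL
    community_table(agg)
  })
}

#' Choose retained periods/years and per-period target effort for a site
#'
#' For sample-level data with variable trap/period coverage, selects the
#' subset of within-year periods (and the years complete in all of them)
#' that maximizes the number of retained year-by-period cells, breaking
#' ties in favour of more years. Within each retained period the target
#' effort is the minimum number of samples observed in any retained year.
#'
#' @param table a `community_table` (may span several sites).
#' @return an `effort_plan`: per site, the retained `periods`, `years` and
#'   per-period `target` sample counts.
#' @export
effort_target <- function(table) {
  df <- as.data.frame(table)
  plans <- lapply(split(df, df$site_id), function(sdat) {
    samples <- unique(sdat[, c("year", "period", "sample_id")])
    effort <- stats::aggregate(sample_id ~ year + period, data = samples, FUN = length)
    names(effort)[3] <- "n_samples"
    periods <- sort(unique(effort$period))
    if (length(periods) > 12L) {
      stop("more than 12 within-year periods; aggregate periods first", call. = FALSE)
    }
    best <- NULL
    for (size in rev(seq_along(periods))) {
      combos <- utils::combn(periods, size, simplify = FALSE)
      for (subset in combos) {
        yrs_per_period <- lapply(subset, function(p) effort$year[effort$period == p])
        yrs <- Reduce(intersect, yrs_per_period)
        if (!length(yrs)) next
        cand <- list(periods = subset, years = sort(yrs),
                     cells = length(subset) * length(yrs))
        if (is.null(best) ||
            cand$cells > best$cells ||
            (cand$cells == best$cells && length(cand$years) > length(best$years))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      stop(sprintf("site '%s': no year complete in any period; empty plan",
                   sdat$site_id[1]), call. = FALSE)
    }
    keep <- effort$period %in% best$periods & effort$year %in% best$years
    target <- tapply(effort$n_samples[keep], effort$period[keep], min)
    list(site_id = sdat$site_id[1], periods = best$periods, years = best$years,
         target = target, method = "samples")
  })
  structure(plans, class = "effort_plan")
}

#' @export
print.effort_plan <- function(x, ...) {
  cat(sprintf("Effort plan for %d site(s):\n", length(x)))
  for (p in x) {
    cat(sprintf("  %s: %d year(s) x %d period(s); targets: %s\n",
                p$site_id, length(p$years), length(p$periods),
                paste(sprintf("%s=%d", names(p$target), p$target), collapse = ", ")))
  }
  invisible(x)
}

# Per-year individual-count targets for the individual-proportional
# strategy (studies reporting per-year effort but not per-sample data).
# A year whose effort minimum would force discarding more than
# `drop_threshold` of the other years' individuals is dropped instead
# (equalizing to it would lose too much data), and the targets recomputed.
individual_targets <- function(effort, totals, drop_threshold = 0.5) {
  dropped <- character()
  repeat {
    if (length(effort) < 2L) break
    e_min <- min(effort)
    target <- round_half_up(e_min / effort * totals)
    m <- names(effort)[which.min(effort)]
    rest <- setdiff(names(effort), m)
    discarded <- sum(totals[rest] - target[rest])
    if (length(rest) && discarded / sum(totals[rest]) > drop_threshold) {
      dropped <- c(dropped, m)
      effort <- effort[rest]
      totals <- totals[rest]
    } else break
  }
  e_min <- min(effort)
  list(targets = round_half_up(e_min / effort * totals), dropped = dropped)
}

#' Equalize sampling effort by repeated resampling
#'
#' Produces `n_iter` resampled per-site-year assemblages with equal effort
#' across years within each site, following one of two strategies:
#'
#' * `method = "individuals"`: per-year effort (number of samples) is
#'   known but individual samples are pooled. Years with more effort are
#'   subsampled without replacement down to
#'   `round(min_effort / effort * N)` individuals (a year of 300
#'   individuals in 6 traps equalized to 4-trap effort yields 200 drawn
#'   individuals).
#' * `method = "samples"`: whole samples are drawn without replacement per
#'   retained period down to that period's target count (from
#'   [effort_target()]), then summed into one yearly sample.
#'
#' Genus-level records are re-resolved with [clean_taxonomy()] inside
#' every iteration (cleaning happens just before metric calculation, also
#' in randomizations). Biodiversity metrics are averaged over iterations;
#' per-species yearly counts are summarized by their rounded medians.
#'
#' @param table a `community_table`.
#' @param plan an `effort_plan` (required for `method = "samples"`; built
#'   automatically when omitted).
#' @param method `"samples"` or `"individuals"`.
#' @param n_iter number of resampling iterations (100 by default).
#' @param seed integer seed or `NULL`.
#' @param clean re-resolve genus records inside each iteration.
#' @param drop_threshold year-dropping rule for `method = "individuals"`:
#'   drop the minimum-effort year when matching it would discard more than
#'   this share of the other years' individuals.
#' @param target_coverage passed to [metric_series()].
#' @return a `standardization_result`: list with `iterations` (list of
#'   assemblage data frames), `metric_means`, `population_medians`,
#'   `plan`, `dropped_years`.
#' @export
equalize_effort <- function(table, plan = NULL,
                            method = c("samples", "individuals"),
                            n_iter = 100L, seed = NULL, clean = TRUE,
                            drop_threshold = 0.5, target_coverage = 0.8) {
  method <- match.arg(method)
  df <- as.data.frame(table)
  if (!nrow(df)) stop("empty community table: nothing to standardize", call. = FALSE)
  if (method == "samples" && is.null(plan)) plan <- effort_target(df)
  dropped_years <- list()

  site_setup <- lapply(split(df, df$site_id), function(sdat) {
    site <- sdat$site_id[1]
    if (method == "individuals") {
      samples <- unique(sdat[, c("year", "sample_id")])
      effort <- tapply(samples$sample_id, samples$year, length)
      totals <- tapply(sdat$count, sdat$year, sum)[names(effort)]
      tg <- individual_targets(effort, totals, drop_threshold)
      if (length(tg$dropped)) {
        warning(sprintf("site '%s': dropped year(s) %s to preserve data volume",
                        site, paste(tg$dropped, collapse = ", ")), call. = FALSE)
        dropped_years[[site]] <<- tg$dropped
      }
      list(site = site, data = sdat[!(sdat$year %in% as.integer(tg$dropped)), , drop = FALSE],
           targets = tg$targets)
    } else {
      pl <- plan[[site]]
      if (is.null(pl)) stop(sprintf("no plan for site '%s'", site), call. = FALSE)
      keep <- sdat$year %in% pl$years & sdat$period %in% pl$periods
      list(site = site, data = sdat[keep, , drop = FALSE], plan = pl)
    }
  })

  one_iteration <- function() {
    pieces <- lapply(site_setup, function(st) {
      sdat <- st$data
      if (!nrow(sdat)) return(NULL)
      if (method == "individuals") {
        per_year <- lapply(split(sdat, sdat$year), function(ydat) {
          yr <- as.character(ydat$year[1])
          n_target <- st$targets[[yr]]
          pool <- rep(seq_len(nrow(ydat)), ydat$count)
          if (n_target < length(pool)) {
            drawn <- sample(pool, n_target)
            cnt <- tabulate(drawn, nbins = nrow(ydat))
            ydat$count <- as.numeric(cnt)
            ydat <- ydat[ydat$count > 0, , drop = FALSE]
          }
          ydat
        })
        do.call(rbind, per_year)
      } else {
        pl <- st$plan
        per_year <- lapply(split(sdat, sdat$year), function(ydat) {
          per_period <- lapply(pl$periods, function(p) {
            pdat <- ydat[ydat$period == p, , drop = FALSE]
            ids <- unique(pdat$sample_id)
            k <- pl$target[[p]]
            drawn <- if (k < length(ids)) sample(ids, k) else ids
            pdat[pdat$sample_id %in% drawn, , drop = FALSE]
          })
          do.call(rbind, per_period)
        })
        do.call(rbind, per_year)
      }
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  }

  iterations <- vector("list", n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      samp <- one_iteration()
      tab <- community_table(samp)
      if (clean) tab <- clean_taxonomy(tab)
      iterations[[it]] <- assemblage_counts(tab)
    }
  })

  metric_tabs <- lapply(iterations, metric_series, target_coverage = target_coverage)
  all_metrics <- do.call(rbind, metric_tabs)
  metric_means <- stats::aggregate(value ~ site_id + year + metric,
                                   data = all_metrics, FUN = mean)
  metric_means <- metric_means[order(metric_means$site_id, metric_means$year,
                                     metric_means$metric), ]
  rownames(metric_means) <- NULL

  # per-species rounded median yearly counts across iterations (absences = 0)
  pop_long <- do.call(rbind, lapply(seq_along(iterations), function(i) {
    cbind(iterations[[i]], iter = i)
  }))
  key <- paste(pop_long$site_id, pop_long$year, pop_long$taxon_id, sep = "\r")
  med <- vapply(split(pop_long$count, key), function(v) {
    stats::median(c(v, rep(0, n_iter - length(v))))
  }, numeric(1))
  med_keys <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  population_medians <- data.frame(site_id = med_keys[, 1],
                                   year = as.integer(med_keys[, 2]),
                                   taxon_id = med_keys[, 3],
                                   count = round_half_up(med),
                                   stringsAsFactors = FALSE)
  population_medians <- population_medians[order(population_medians$site_id,
                                                 population_medians$year,
                                                 population_medians$taxon_id), ]
  rownames(population_medians) <- NULL

  structure(list(iterations = iterations, metric_means = metric_means,
                 population_medians = population_medians,
                 plan = if (method == "samples") plan else NULL,
                 method = method, n_iter = n_iter,
                 dropped_years = dropped_years),
            class = "standardization_result")
}

#' @export
print.standardization_result <- function(x, ...) {
  cat(sprintf("Standardization result: %d iteration(s), method '%s'\n",
              x$n_iter, x$method))
  cat(sprintf("  %d site-year metric means, %d population median records\n",
              nrow(unique(x$metric_means[, c("site_id", "year")])),
              nrow(x$population_medians)))
  if (length(x$dropped_years)) {
    cat("  dropped years:", paste(names(x$dropped_years), collapse = ", "), "\n")
  }
  invisible(x)
}
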