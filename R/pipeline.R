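# End-to-end orchestration: input (CSV, simulation config or scenario) ->
# sensitivity filters -> effort standardization (with taxonomic cleaning)
# -> biodiversity metrics -> SAD intervals -> trend models -> population
# classification and RtM correction -> result tables on disk. A run is
# reproducible from its config and global seed alone; every discard is
# written to a machine-readable audit log.

#' Pipeline configuration
#'
#' @param input data source: a CSV path, a [sim_config()], a
#'   [scenario_spec()] (run through [run_scenario()]), or a
#'   `community_table`.
#' @param filters list of sensitivity filters (see
#'   [apply_sensitivity_filter()]).
#' @param metrics metrics to model (subset of the seven).
#' @param interval_schemes SAD binning schemes to tabulate.
#' @param classification_rule initial-abundance classification rule.
#' @param standardize_method `"samples"` or `"individuals"`.
#' @param n_iter standardization iterations.
#' @param rtm list: `enabled`, `min_years`, `censor`.
#' @param fit_populations fit the per-group Poisson population models.
#' @param ar1 include AR1 terms in the trend models.
#' @param scenario_noise_sd,scenario_years forwarded to [run_scenario()]
#'   when `input` is a `scenario_spec`.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param seed global seed; expanded into per-stage child seeds.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            filters = list(),
                            metrics = c("abundance", "richness",
                                        "rarefied_richness", "coverage_richness",
                                        "shannon_effective", "simpson_effective",
                                        "evenness"),
                            interval_schemes = "equal_log5",
                            classification_rule = "year1",
                            standardize_method = "samples",
                            n_iter = 100L,
                            rtm = list(enabled = FALSE, min_years = 15L, censor = 1L),
                            fit_populations = TRUE,
                            ar1 = TRUE,
                            scenario_noise_sd = 0.5, scenario_years = 20L,
                            out_dir = NULL, seed = 1L) {
  cfg <- list(input = input, filters = filters, metrics = metrics,
              interval_schemes = interval_schemes,
              classification_rule = classification_rule,
              standardize_method = standardize_method,
              n_iter = as.integer(n_iter), rtm = rtm,
              fit_populations = fit_populations, ar1 = ar1,
              scenario_noise_sd = scenario_noise_sd,
              scenario_years = as.integer(scenario_years),
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Apply a sensitivity filter to a community table
#'
#' Available filters:
#' * `list(type = "min_span", years = 20)`: keep sites with at least that
#'   many years between the first and last sampled year.
#' * `list(type = "last_n_years", n = 10)`: keep only each site's last `n`
#'   years (sites whose span is shorter are discarded).
#' * `list(type = "top_n_sites", n = 10)`: per study, keep the `n` sites
#'   with the most sampled years (ties broken by site_id order).
#' * `list(type = "region", keep = c(...))`: keep listed regions (requires
#'   a `region` column).
#'
#' Filters are composable; each records retained/discarded counts in the
#' `"filter_log"` attribute.
#'
#' @param table a `community_table`.
#' @param filter a filter specification list with a `type` element.
#' @return the filtered `community_table`.
#' @export
apply_sensitivity_filter <- function(table, filter) {
  df <- as.data.frame(table)
  type <- filter$type %||% stop("filter needs a `type`", call. = FALSE)
  before_sites <- unique(df$site_id)
  out <- switch(type,
    min_span = {
      span <- tapply(df$year, df$site_id, function(y) diff(range(y)) + 1L)
      keep <- names(span)[span >= (filter$years %||% 20L)]
      df[df$site_id %in% keep, , drop = FALSE]
    },
    last_n_years = {
      n <- filter$n %||% 10L
      pieces <- lapply(split(df, df$site_id), function(s) {
        yrs <- range(s$year)
        if (diff(yrs) + 1L < n) return(NULL)
        s[s$year > yrs[2] - n, , drop = FALSE]
      })
      do.call(rbind, pieces)
    },
    top_n_sites = {
      n <- filter$n %||% 10L
      keep <- unlist(lapply(split(df, df$study_id), function(s) {
        yrs <- tapply(s$year, s$site_id, function(y) length(unique(y)))
        ord <- order(-yrs, names(yrs))  # most years first, site_id breaks ties
        names(yrs)[utils::head(ord, n)]
      }))
      df[df$site_id %in% keep, , drop = FALSE]
    },
    region = {
      if (!"region" %in% names(df)) {
        stop("region filter requires a `region` column", call. = FALSE)
      }
      df[df$region %in% filter$keep, , drop = FALSE]
    },
    stop(sprintf("unknown filter '%s'", type), call. = FALSE))
  if (is.null(out)) out <- df[0, , drop = FALSE]
  rownames(out) <- NULL
  out <- community_table(out)
  log_entry <- list(type = type,
                    sites_before = length(before_sites),
                    sites_after = length(unique(out$site_id)),
                    records_before = nrow(df), records_after = nrow(out))
  attr(out, "filter_log") <- c(attr(table, "filter_log"), list(log_entry))
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full biodiversity-trend pipeline
#'
#' Stages, in order: `input` (load or simulate), `filter`, `standardize`
#' (effort equalization with in-iteration taxonomic cleaning), `metrics`,
#' `metric_trends` (Gaussian log10(x+1) models; beta model for evenness),
#' `sad` (interval counts and per-interval trends), `populations`
#' (classification and Poisson models), `rtm` (optional correction), and
#' `write`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with all intermediate and final
#'   objects; written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  audit <- list()

  table <- run_stage("input", {
    inp <- config$input
    if (is.character(inp)) {
      read_community_csv(inp)
    } else if (inherits(inp, "sim_config")) {
      simulate_dataset(inp)
    } else if (inherits(inp, "scenario_spec")) {
      run_scenario(inp, years = config$scenario_years,
                   noise_sd = config$scenario_noise_sd,
                   seed = derive_seed(seed, "scenario"))
    } else if (inherits(inp, "community_table") || is.data.frame(inp)) {
      community_table(inp)
    } else {
      stop("unsupported input type", call. = FALSE)
    }
  })

  table <- run_stage("filter", {
    for (f in config$filters) table <- apply_sensitivity_filter(table, f)
    audit$filters <- attr(table, "filter_log")
    table
  })

  standardized <- run_stage("standardize", {
    if (!nrow(table)) stop("empty community table", call. = FALSE)
    equalize_effort(table, method = config$standardize_method,
                    n_iter = config$n_iter,
                    seed = derive_seed(seed, "standardize"))
  })
  audit$dropped_years <- standardized$dropped_years

  metrics_tab <- run_stage("metrics", standardized$metric_means)

  metric_trends <- run_stage("metric_trends", {
    md <- merge(metrics_tab,
                unique(as.data.frame(table)[, c("study_id", "area_id", "site_id")]),
                by = "site_id")
    fits <- list()
    for (m in config$metrics) {
      fits[[m]] <- if (m == "evenness") {
        fit_evenness_trend(md, metric = m, ar1 = config$ar1)
      } else {
        fit_metric_trend(md, metric = m, ar1 = config$ar1)
      }
    }
    fits
  })

  sad <- run_stage("sad", {
    assemblages <- standardized$population_medians
    out <- list()
    for (kind in config$interval_schemes) {
      counts <- interval_series(assemblages, kind = kind)
      fits <- lapply(split(counts, counts$interval), function(ic) {
        md <- merge(ic, unique(as.data.frame(table)[, c("study_id", "area_id", "site_id")]),
                    by = "site_id")
        md$value <- md$n_species
        fit_metric_trend(md, ar1 = config$ar1)
      })
      out[[kind]] <- list(counts = counts, trends = fits)
    }
    out
  })

  populations <- run_stage("populations", {
    if (!config$fit_populations) NULL else {
      pops <- merge(standardized$population_medians,
                    unique(as.data.frame(table)[, c("study_id", "area_id", "site_id")]),
                    by = "site_id")
      classes <- classify_initial_abundance(pops, rule = config$classification_rule)
      audit$classification_discards <- attr(classes, "discards")
      if (!nrow(classes)) {
        stop("all sites discarded by the classification rules", call. = FALSE)
      }
      list(classes = classes, fits = fit_population_trends(pops, classes, ar1 = config$ar1),
           data = pops)
    }
  })

  rtm <- run_stage("rtm", {
    if (is.null(populations) || !isTRUE(config$rtm$enabled)) NULL else {
      corr <- estimate_rtm_correction(populations$data,
                                      rule = config$classification_rule,
                                      min_years = config$rtm$min_years %||% 15L,
                                      censor = config$rtm$censor %||% 1L,
                                      ar1 = config$ar1)
      list(correction = corr,
           corrected = apply_rtm_correction(populations$fits, corr))
    }
  })

  result <- structure(list(
    table = table, standardized = standardized, metrics = metrics_tab,
    metric_trends = metric_trends, sad = sad, populations = populations,
    rtm = rtm, audit = audit, config = config, seed = seed),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) run_stage("write", write_pipeline_result(result))
  result
}

trend_summary_row <- function(name, fit) {
  data.frame(term = name, slope = fit$slope, se = fit$se,
             ci80_lower = fit$ci["80%", 1], ci80_upper = fit$ci["80%", 2],
             ci90_lower = fit$ci["90%", 1], ci90_upper = fit$ci["90%", 2],
             ci95_lower = fit$ci["95%", 1], ci95_upper = fit$ci["95%", 2],
             percent = fit$percent, evidence = classify_evidence(fit),
             family = fit$family, backend = fit$backend,
             stringsAsFactors = FALSE)
}

#' Summarize every fitted trend of a pipeline run as one table
#'
#' @param result a `pipeline_result`.
#' @return data frame with one row per fitted trend (term, slope,
#'   intervals, percent per year, evidence tier).
#' @export
trend_table <- function(result) {
  rows <- list()
  for (m in names(result$metric_trends)) {
    rows[[length(rows) + 1L]] <- trend_summary_row(m, result$metric_trends[[m]])
  }
  for (kind in names(result$sad)) {
    for (i in names(result$sad[[kind]]$trends)) {
      rows[[length(rows) + 1L]] <-
        trend_summary_row(sprintf("%s_interval%s", kind, i),
                          result$sad[[kind]]$trends[[i]])
    }
  }
  pf <- if (!is.null(result$rtm)) result$rtm$corrected else result$populations$fits
  if (!is.null(pf)) {
    for (g in names(pf$fits)) {
      rows[[length(rows) + 1L]] <-
        trend_summary_row(sprintf("population_group%s%s", g,
                                  if (isTRUE(pf$corrected)) "_corrected" else ""),
                          pf$fits[[g]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_result <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$out_dir
  utils::write.csv(result$metrics, file.path(od, "metric_series.csv"), row.names = FALSE)
  utils::write.csv(trend_table(result), file.path(od, "trends.csv"), row.names = FALSE)
  for (kind in names(result$sad)) {
    utils::write.csv(result$sad[[kind]]$counts,
                     file.path(od, sprintf("sad_counts_%s.csv", kind)),
                     row.names = FALSE)
  }
  if (!is.null(result$populations)) {
    utils::write.csv(result$populations$classes,
                     file.path(od, "initial_abundance_classes.csv"), row.names = FALSE)
  }
  if (!is.null(result$rtm)) {
    utils::write.csv(as.data.frame(result$rtm$correction),
                     file.path(od, "rtm_correction.csv"), row.names = FALSE)
  }
  cfg <- result$config
  cfg$input <- if (is.character(cfg$input)) cfg$input else class(cfg$input)[1]
  jsonlite::write_json(list(config = cfg, seed = result$seed, audit = result$audit),
                       file.path(od, "run_meta.json"), auto_unbox = TRUE,
                       force = TRUE, null = "null")
  invisible(od)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  input: %d records, %d site(s)\n", nrow(x$table),
              length(unique(x$table$site_id))))
  cat(sprintf("  trends fitted: %d metric, %d SAD-interval, %d population group(s)\n",
              length(x$metric_trends),
              sum(vapply(x$sad, function(s) length(s$trends), integer(1))),
              if (!is.null(x$populations)) length(x$populations$fits$fits) else 0L))
  if (!is.null(x$rtm)) cat("  RtM correction applied\n")
  invisible(x)
}
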