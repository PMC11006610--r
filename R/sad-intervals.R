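# Binning the species abundance distribution into abundance intervals:
# five equal-width intervals on the log10 scale (spanning zero to the
# site's maximum observed log10 abundance), or four quartiles of the
# pooled abundance values. Also the initial-abundance classification used
# by the population-trend analysis.

#' Build equal-width log10 abundance intervals
#'
#' `k` equal intervals on `[0, log10(max_abundance)]`; the reference
#' maximum is the highest abundance of any taxon observed at the site over
#' the whole series, so interval 5 always holds the site's most abundant
#' species and interval 1 its singletons. Interval membership is half-open
#' `[low, high)` with the top edge inclusive.
#'
#' @param max_abundance site maximum abundance (>= 2; a maximum of 1 gives
#'   a degenerate log range and the site is unusable).
#' @param k number of intervals.
#' @return an `interval_scheme`.
#' @export
build_equal_log_intervals <- function(max_abundance, k = 5L) {
  stopifnot(k >= 2)
  if (!is.numeric(max_abundance) || max_abundance < 2) {
    stop("degenerate abundance range: maximum abundance must be >= 2", call. = FALSE)
  }
  structure(list(kind = "equal_log5",
                 edges = seq(0, log10(max_abundance), length.out = k + 1L),
                 k = as.integer(k),
                 reference = max_abundance),
            class = "interval_scheme")
}

#' Build abundance quartiles from pooled abundance values
#'
#' Edges at the 25th/50th/75th percentiles of all positive abundance
#' values in the series; each quartile holds approximately the same number
#' of observations. Values tied with a quartile edge are assigned upward,
#' so the lower bin counts only observations strictly smaller than the
#' edge.
#'
#' @param all_abundance_values pooled positive abundance values (>= 4).
#' @return an `interval_scheme`.
#' @export
build_quartile_intervals <- function(all_abundance_values) {
  vals <- all_abundance_values[all_abundance_values > 0]
  if (length(vals) < 4) {
    stop("need at least 4 positive abundance values for quartiles", call. = FALSE)
  }
  structure(list(kind = "quartile4",
                 edges = unname(stats::quantile(vals, c(0.25, 0.5, 0.75))),
                 k = 4L,
                 reference = vals),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("Interval scheme '%s' with %d intervals\n", x$kind, x$k))
  if (x$kind == "equal_log5") {
    cat("log10 edges:", paste(signif(x$edges, 4), collapse = ", "), "\n")
  } else {
    cat("quartile edges:", paste(signif(x$edges, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign abundances to intervals of a scheme
#'
#' Equal-log intervals: half-open on the log10 scale with the top edge
#' inclusive (`log10(1) = 0` lands in interval 1). Quartiles: a value goes
#' to `1 + number of edges <= value` (ties assigned upward).
#'
#' @param x positive abundance values.
#' @param scheme an `interval_scheme`.
#' @return integer interval indices (1-based).
#' @export
assign_interval <- function(x, scheme) {
  stopifnot(inherits(scheme, "interval_scheme"), all(x > 0))
  if (scheme$kind == "equal_log5") {
    la <- log10(x)
    top <- scheme$edges[length(scheme$edges)]
    if (any(la > top + 1e-9)) {
      stop("abundance exceeds the scheme's reference maximum", call. = FALSE)
    }
    la <- pmin(pmax(la, 0), top)  # sub-unit means (fractional counts) clamp to bin 1
    idx <- findInterval(la, scheme$edges, rightmost.closed = TRUE)
    pmin(idx, scheme$k)
  } else {
    1L + rowSums(outer(x, scheme$edges, FUN = ">="))
  }
}

#' Number of species per interval in one assemblage-year
#'
#' Species with zero counts are excluded; every positive-count species is
#' assigned to exactly one interval.
#'
#' @param counts species abundance vector (or data frame with a `count`
#'   column) for one site-year.
#' @param scheme an `interval_scheme` built from this site's series.
#' @return integer vector of species counts, one per interval.
#' @export
count_species_by_interval <- function(counts, scheme) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[counts > 0]
  if (!length(counts)) return(integer(scheme$k))
  tabulate(assign_interval(counts, scheme), nbins = scheme$k)
}

#' Per-year species counts per SAD interval for a set of assemblages
#'
#' Builds one scheme per site (equal-log intervals from the site's series
#' maximum, or quartiles from the site's pooled values) and counts species
#' per interval each year.
#'
#' @param assemblages data frame `site_id`, `year`, `taxon_id`, `count`.
#' @param kind `"equal_log5"` or `"quartile4"`.
#' @param k number of intervals for the equal-log scheme.
#' @return data frame `site_id`, `year`, `scheme`, `interval`, `n_species`.
#' @export
interval_series <- function(assemblages, kind = c("equal_log5", "quartile4"),
                            k = 5L) {
  kind <- match.arg(kind)
  pieces <- lapply(split(assemblages, assemblages$site_id), function(sdat) {
    scheme <- if (kind == "equal_log5") {
      build_equal_log_intervals(max(sdat$count), k = k)
    } else {
      build_quartile_intervals(sdat$count)
    }
    per_year <- lapply(split(sdat, sdat$year), function(ydat) {
      n <- count_species_by_interval(ydat$count, scheme)
      data.frame(site_id = sdat$site_id[1], year = ydat$year[1], scheme = kind,
                 interval = seq_along(n), n_species = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_year)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Classify species into initial-abundance groups per site
#'
#' Five equal log10 intervals are built from the classification years only
#' (spanning zero to the log10 of the highest classification abundance);
#' each species detected then is assigned to one of groups 1-5 by its
#' classification abundance (the arithmetic mean over the classification
#' years), and species absent in the classification years go to group 6
#' (excluded from trend averaging downstream, since their mean trends are
#' positive by construction).
#'
#' Sites are discarded -- recorded in the `"discards"` attribute, not
#' returned -- when fewer than two species are detected in the
#' classification years, or when all detected species share one abundance
#' value (degenerate log range, no interval geometry possible).
#'
#' @param assemblages data frame `site_id`, `year`, `taxon_id`, `count`.
#' @param rule classification rule: `"year1"` (first sampled year),
#'   `"years1to2"`, `"years1to5"`, or `"whole_series_mean"`.
#' @param k number of abundance intervals.
#' @return data frame `site_id`, `taxon_id`, `rule`, `class` (1..k, or
#'   k + 1 for species absent in the classification years), with
#'   attributes `"discards"` (data frame of discarded sites and reasons)
#'   and `"edges"` (per-site interval edges).
#' @export
classify_initial_abundance <- function(assemblages,
                                       rule = c("year1", "years1to2", "years1to5",
                                                "whole_series_mean"),
                                       k = 5L) {
  rule <- match.arg(rule)
  n_class_years <- switch(rule, year1 = 1L, years1to2 = 2L, years1to5 = 5L,
                          whole_series_mean = NA_integer_)
  discards <- list()
  edges_by_site <- list()
  pieces <- lapply(split(assemblages, assemblages$site_id), function(sdat) {
    site <- sdat$site_id[1]
    yrs <- sort(unique(sdat$year))
    cls_years <- if (is.na(n_class_years)) yrs else utils::head(yrs, n_class_years)
    in_cls <- sdat[sdat$year %in% cls_years, , drop = FALSE]
    # arithmetic mean over the classification years (absent years count 0)
    ab <- tapply(in_cls$count, in_cls$taxon_id, sum) / length(cls_years)
    ab <- ab[ab > 0]
    if (length(ab) < 2) {
      discards[[site]] <<- "fewer than two species detected in classification years"
      return(NULL)
    }
    if (length(unique(ab)) == 1L) {
      discards[[site]] <<- "all classification-year species equally abundant"
      return(NULL)
    }
    if (max(ab) < 2) {
      discards[[site]] <<- "degenerate classification abundance range (max < 2)"
      return(NULL)
    }
    scheme <- build_equal_log_intervals(max(ab), k = k)
    edges_by_site[[site]] <<- scheme$edges
    cls <- assign_interval(as.numeric(ab), scheme)
    all_taxa <- unique(sdat$taxon_id[sdat$count > 0])
    absent <- setdiff(all_taxa, names(ab))
    data.frame(site_id = site,
               taxon_id = c(names(ab), absent),
               rule = rule,
               class = c(cls, rep(k + 1L, length(absent))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(site_id = character(), taxon_id = character(),
                      rule = character(), class = integer())
  }
  rownames(out) <- NULL
  attr(out, "discards") <- if (length(discards)) {
    data.frame(site_id = names(discards), reason = unlist(discards),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(site_id = character(), reason = character())
  }
  attr(out, "edges") <- edges_by_site
  attr(out, "k") <- as.integer(k)
  out
}
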