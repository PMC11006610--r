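# Hierarchical autoregressive year-trend models. One fixed effect (year),
# nested random intercepts (study, area, site, within-year period) and
# random year slopes (study, area, site, and species-by-site for the
# population models), plus a gap-aware AR1 process on the site-level
# residuals (the discrete equivalent of a continuous-time
# Ornstein-Uhlenbeck process: correlation rho^dt across a gap of dt
# years). Fitted by Laplace approximation (glmmTMB); posterior summaries
# are the Gaussian approximation around the mode, with equal-tailed
# intervals at 80/90/95%.

TREND_FAMILIES <- c("gaussian_log10p1", "beta", "poisson_log")
CI_LEVELS <- c(0.80, 0.90, 0.95)

#' Back-transform a year slope to percent change per year
#'
#' `gaussian_log10p1` models fit log10(value + 1), so a slope `b` means a
#' multiplicative change of `10^b` per year; `poisson_log` models use a
#' natural-log link (`e^b`). Beta-family (evenness) slopes live on the
#' logit scale and have no percent interpretation (`NA` returned).
#'
#' @param slope slope on the link scale.
#' @param family one of `"gaussian_log10p1"`, `"beta"`, `"poisson_log"`.
#' @return percent change per year.
#' @export
slope_to_percent <- function(slope, family) {
  family <- match.arg(family, TREND_FAMILIES)
  switch(family,
         gaussian_log10p1 = (10^slope - 1) * 100,
         poisson_log = (exp(slope) - 1) * 100,
         beta = rep(NA_real_, length(slope)))
}

#' @rdname slope_to_percent
#' @param percent percent change per year.
#' @export
percent_to_slope <- function(percent, family) {
  family <- match.arg(family, TREND_FAMILIES)
  switch(family,
         gaussian_log10p1 = log10(percent / 100 + 1),
         poisson_log = log(percent / 100 + 1),
         beta = rep(NA_real_, length(percent)))
}

# ---- engine -----------------------------------------------------------

# Decide which grouping levels carry random terms: a level enters only if
# it is strictly finer than the level above it (single-area studies
# collapse into the study term, etc.).
re_structure <- function(d) {
  n_study <- length(unique(d$study_id %||% character()))
  n_area <- length(unique(d$area_id %||% character()))
  n_site <- length(unique(d$site_id %||% character()))
  n_period <- length(unique(d$period %||% character()))
  list(study = n_study >= 2,
       area = n_area >= 2 && n_area > n_study,
       site = n_site >= 2 && n_site > max(n_area, n_study),
       period = n_period >= 2,
       n_site = n_site)
}

build_formulas <- function(resp, st, use_species, ar1_ok) {
  slope_terms <- function(g) c(sprintf("(1 | %s)", g), sprintf("(0 + year_c | %s)", g))
  upper <- c(if (st$study) slope_terms("study_id"),
             if (st$area) slope_terms("area_id"),
             if (st$site) slope_terms("site_id"),
             if (st$period) "(1 | period)")
  lower <- c(if (st$site) slope_terms("site_id"),
             if (st$period) "(1 | period)")
  spp <- if (use_species) slope_terms("sp_site") else NULL
  ar1_term <- "ar1(yearf + 0 | site_id)"
  mk <- function(terms) {
    rhs <- paste(c("year_c", terms), collapse = " + ")
    stats::as.formula(paste(resp, "~", rhs))
  }
  # with an AR1 term present, the site intercept duplicates the AR1
  # process's stationary level variation and often sits at a variance
  # boundary; offer variants without it before giving up on AR1
  drop_site_int <- function(terms) setdiff(terms, "(1 | site_id)")
  cands <- list()
  add <- function(terms) {
    f <- mk(terms)
    key <- paste(deparse(f), collapse = "")
    if (!key %in% names(cands)) cands[[key]] <<- f
  }
  if (ar1_ok) {
    add(c(spp, upper, ar1_term))
    add(c(spp, drop_site_int(upper), ar1_term))
  }
  add(c(spp, upper))
  if (ar1_ok) {
    add(c(spp, lower, ar1_term))
    add(c(spp, drop_site_int(lower), ar1_term))
    add(c(spp, ar1_term))
  }
  add(c(spp, lower))
  if (use_species) add(spp) else if (st$site) add("(1 | site_id)")
  unname(cands)
}

fit_one <- function(formula, d, tmb_family) {
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(formula, data = d, family = tmb_family,
                                      REML = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- tryCatch(summary(fit)$coefficients$cond, error = function(e) NULL)
  if (is.null(co) || !"year_c" %in% rownames(co)) return(NULL)
  se <- co["year_c", "Std. Error"]
  ok <- isTRUE(fit$sdr$pdHess) && is.finite(se) && se > 0
  list(fit = fit, ok = ok, slope = co["year_c", "Estimate"], se = se)
}

fixed_only_fit <- function(d, family) {
  if (family == "poisson_log") {
    m <- stats::glm(resp ~ year_c, data = d, family = stats::poisson())
    backend <- "glm"
  } else {
    m <- stats::lm(resp ~ year_c, data = d)
    backend <- if (family == "beta") "lm-logit" else "lm"
  }
  co <- suppressWarnings(summary(m)$coefficients)
  se <- co["year_c", 2]
  # numerically perfect fits leave rounding noise in both slope and se;
  # floor the se so machine-epsilon slopes are not read as evidence
  floor_se <- 1e-8 * (1 + abs(co["year_c", 1]))
  if (!is.finite(se) || se < floor_se) se <- floor_se
  list(model = m, backend = backend, slope = co["year_c", 1], se = se)
}

# Conditional modes and sds per grouping factor and term. glmmTMB merges
# all blocks on one factor (intercept, slope, AR1 year effects) into a
# single data frame whose "condVar" attribute is a list of per-block
# covariance arrays; the AR1 columns (yearf*) are dropped from the
# summary and the remaining columns matched back to their blocks.
extract_ranef <- function(fit) {
  re <- tryCatch(glmmTMB::ranef(fit, condVar = TRUE)$cond, error = function(e) NULL)
  if (is.null(re)) return(list())
  out <- list()
  for (g in names(re)) {
    df_g <- re[[g]]
    terms <- colnames(df_g)
    keep <- which(!grepl("^yearf", terms))
    if (!length(keep)) next
    cv <- attr(df_g, "condVar")
    blocks <- if (is.list(cv)) cv else if (!is.null(cv)) list(cv) else list()
    block_dim <- vapply(blocks, function(a) dim(a)[1], integer(1))
    col_block <- rep(seq_along(blocks), block_dim)
    col_within <- unlist(lapply(block_dim, seq_len))
    sds <- matrix(NA_real_, nrow(df_g), length(keep))
    if (length(col_block) == length(terms)) {
      for (j in seq_along(keep)) {
        a <- blocks[[col_block[keep[j]]]]
        w <- col_within[keep[j]]
        sds[, j] <- tryCatch(sqrt(a[w, w, ]), error = function(e) NA_real_)
      }
    }
    df <- data.frame(level = rep(rownames(df_g), times = length(keep)),
                     term = rep(terms[keep], each = nrow(df_g)),
                     mode = as.vector(as.matrix(df_g[, keep, drop = FALSE])),
                     condsd = as.vector(sds),
                     stringsAsFactors = FALSE)
    key <- sub("\\.\\d+$", "", g)
    out[[key]] <- if (is.null(out[[key]])) df else rbind(out[[key]], df)
  }
  out
}

# AR1 correlation and its Wald interval. glmmTMB parameterizes the ar1
# correlation internally as rho = t / sqrt(1 + t^2); the interval is
# computed on t (where the Gaussian approximation is better) and mapped
# through the monotone transform.
extract_rho <- function(fit, level = 0.95) {
  out <- c(rho = NA_real_, lower = NA_real_, upper = NA_real_)
  idx <- tryCatch({
    V <- stats::vcov(fit, full = TRUE)
    nm <- rownames(V)
    i <- grep("^theta_yearf\\+0 \\| site_id\\.2$|^theta_yearf\\+0\\|site_id\\.2$", nm)
    if (!length(i)) i <- grep("theta_yearf.*\\.2$", nm)
    list(i = i[1], V = V)
  }, error = function(e) NULL)
  if (is.null(idx) || !length(idx$i) || is.na(idx$i)) return(out)
  t_hat <- fit$fit$par[idx$i]
  se <- sqrt(diag(idx$V))[idx$i]
  z <- stats::qnorm(1 - (1 - level) / 2)
  tr <- function(t) t / sqrt(1 + t^2)
  c(rho = unname(tr(t_hat)),
    lower = unname(tr(t_hat - z * se)), upper = unname(tr(t_hat + z * se)))
}

ci_matrix <- function(slope, se, levels = CI_LEVELS) {
  z <- stats::qnorm(1 - (1 - levels) / 2)
  m <- cbind(lower = slope - z * se, upper = slope + z * se)
  rownames(m) <- sprintf("%d%%", round(levels * 100))
  m
}

# Core fitting routine shared by the metric, evenness and population
# models. `d` must carry `value` (or `count`), `year`, and the available
# grouping columns among study_id, area_id, site_id, period, sp_site.
fit_trend_engine <- function(d, family, ar1 = TRUE, use_species = FALSE) {
  family <- match.arg(family, TREND_FAMILIES)
  d <- as.data.frame(d)
  resp_raw <- d$value %||% d$count
  if (is.null(resp_raw)) stop("data must carry a `value` or `count` column", call. = FALSE)
  if (any(!is.finite(resp_raw))) stop("non-finite responses in input", call. = FALSE)
  if (length(unique(d$year)) < 2) stop("need at least two distinct years", call. = FALSE)
  d$resp <- switch(family,
    gaussian_log10p1 = log10(resp_raw + 1),
    beta = {
      if (any(resp_raw <= 0 | resp_raw > 1)) {
        stop("beta responses must lie in (0, 1]", call. = FALSE)
      }
      n <- length(resp_raw)
      (resp_raw * (n - 1) + 0.5) / n  # shrink off the boundary
    },
    poisson_log = {
      if (any(resp_raw < 0)) stop("counts must be non-negative", call. = FALSE)
      round_half_up(resp_raw)
    })
  if (family == "beta") d$resp_link <- stats::qlogis(d$resp)

  # centre year within study (or globally); slope stays per calendar year
  if (!is.null(d$study_id) && length(unique(d$study_id)) > 1) {
    mu_y <- tapply(d$year, d$study_id, mean)
    d$year_c <- d$year - mu_y[d$study_id]
  } else {
    d$year_c <- d$year - mean(d$year)
  }
  if (is.null(d$site_id)) d$site_id <- "site1"
  d$yearf <- factor(d$year, levels = seq(min(d$year), max(d$year)))
  for (col in intersect(c("study_id", "area_id", "site_id", "period", "sp_site"),
                        names(d))) {
    d[[col]] <- factor(d[[col]])
  }

  st <- re_structure(d)
  ar1_ok <- isTRUE(ar1) && length(levels(d$yearf)) >= 3 &&
    stats::var(d$resp) > 0
  tmb_family <- switch(family,
                       gaussian_log10p1 = stats::gaussian(),
                       beta = glmmTMB::beta_family(link = "logit"),
                       poisson_log = stats::poisson())
  resp_name <- "resp"
  formulas <- build_formulas(resp_name, st, use_species, ar1_ok)

  chosen <- NULL
  tried <- 0L
  for (f in formulas) {
    if (length(all.vars(f)) <= 2L) break  # no random terms left: use fixed-only
    tried <- tried + 1L
    res <- fit_one(f, d, tmb_family)
    if (!is.null(res) && res$ok) { chosen <- c(res, list(formula = f)); break }
  }

  if (!is.null(chosen)) {
    backend <- "glmmTMB"
    slope <- chosen$slope
    se <- chosen$se
    model <- chosen$fit
    ranefs <- extract_ranef(model)
    rho_info <- extract_rho(model)
    rho <- rho_info[["rho"]]
    rho_ci <- rho_info[c("lower", "upper")]
    converged <- TRUE
    formula_used <- chosen$formula
  } else {
    # deterministic / degenerate limit: fixed-effects fit
    dd <- d
    if (family == "beta") dd$resp <- dd$resp_link
    fo <- fixed_only_fit(dd, family)
    backend <- fo$backend
    slope <- fo$slope
    se <- fo$se
    model <- fo$model
    ranefs <- list()
    rho <- NA_real_
    rho_ci <- c(lower = NA_real_, upper = NA_real_)
    converged <- TRUE
    formula_used <- stats::as.formula("resp ~ year_c")
  }

  ci <- ci_matrix(slope, se)
  structure(list(
    slope = unname(slope), se = unname(se), ci = ci,
    percent = slope_to_percent(slope, family),
    percent_ci = apply(ci, 2, slope_to_percent, family = family),
    family = family, backend = backend, converged = converged,
    rho = rho, rho_ci = rho_ci, ranef = ranefs, formula = formula_used,
    n_obs = nrow(d), n_sites = st$n_site,
    n_years = length(unique(d$year)),
    model = model),
    class = "trend_fit")
}

# ---- user-facing fitting functions ------------------------------------

#' Fit the hierarchical year-trend model for a biodiversity metric
#'
#' Gaussian model on `log10(value + 1)` with a single fixed year effect,
#' random intercepts and year slopes at the study/area/site levels
#' (collapsing levels that duplicate the level above), a random intercept
#' on within-year period, and a gap-aware AR1 term on site-level
#' residuals. When the random structure is unidentifiable (single site,
#' noise-free series) the engine falls back to progressively simpler fits,
#' down to ordinary least squares; the backend used is recorded on the
#' returned object.
#'
#' @param data data frame with columns `year`, `value` and any of
#'   `study_id`, `area_id`, `site_id`, `period`; optionally a `metric`
#'   column filtered by `metric`.
#' @param metric if `data` is a tidy metric series, the metric to model.
#' @param ar1 include the AR1 autocorrelation term.
#' @return a `trend_fit`: posterior mean year slope (link scale),
#'   equal-tailed 80/90/95% intervals, percent change per year,
#'   random-effect summaries, AR1 correlation.
#' @export
fit_metric_trend <- function(data, metric = NULL, ar1 = TRUE) {
  d <- as.data.frame(data)
  if (!is.null(metric)) {
    stopifnot("metric" %in% names(d))
    d <- d[d$metric == metric, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("no rows for metric '%s'", metric), call. = FALSE)
  }
  fit_trend_engine(d, "gaussian_log10p1", ar1 = ar1)
}

#' Fit the beta-family trend model for evenness
#'
#' Evenness lies in (0, 1]; values are shrunk off the boundary with
#' `y' = (y (n-1) + 0.5) / n` and modelled with a logit-link beta
#' likelihood. The slope is reported on the logit scale (no percent
#' back-transform).
#'
#' @inheritParams fit_metric_trend
#' @export
fit_evenness_trend <- function(data, metric = "evenness", ar1 = TRUE) {
  d <- as.data.frame(data)
  if ("metric" %in% names(d) && !is.null(metric)) {
    d <- d[d$metric == metric, , drop = FALSE]
  }
  fit_trend_engine(d, "beta", ar1 = ar1)
}

#' Fit Poisson population-trend models per initial-abundance group
#'
#' For each initial-abundance group (1..k from
#' [classify_initial_abundance()]; the absent-in-classification-years
#' group is never analysed), fits a Poisson model of yearly counts with a
#' log link, adding species-by-site random intercepts and slopes beneath
#' the study/area/site hierarchy; the AR1 term is retained at the site
#' level. Counts are rounded to integers; populations with fewer than two
#' observed years or with no non-zero counts are dropped.
#'
#' @param populations data frame `site_id`, `taxon_id`, `year`, `count`
#'   (plus optional `study_id`, `area_id`).
#' @param classes classification from [classify_initial_abundance()].
#' @param ar1 include the site-level AR1 term.
#' @return a `population_trend_fit`: one `trend_fit` per group, plus
#'   species-level slope summaries.
#' @export
fit_population_trends <- function(populations, classes, ar1 = TRUE) {
  d <- merge(as.data.frame(populations), as.data.frame(classes),
             by = c("site_id", "taxon_id"))
  if (!nrow(d)) stop("no populations left after classification merge", call. = FALSE)
  k <- attr(classes, "k") %||% 5L
  d <- d[d$class <= k, , drop = FALSE]  # group k+1 (absent in classification years): excluded
  d$count <- round_half_up(d$count)
  d$sp_site <- paste(d$site_id, d$taxon_id, sep = ":")
  # drop populations observed fewer than twice or never non-zero
  n_rec <- table(d$sp_site)
  n_pos <- tapply(d$count > 0, d$sp_site, sum)
  keep <- names(n_rec)[n_rec >= 2 & n_pos[names(n_rec)] >= 1]
  d <- d[d$sp_site %in% keep, , drop = FALSE]
  groups <- sort(unique(d$class))
  fits <- list()
  for (g in groups) {
    dg <- d[d$class == g, , drop = FALSE]
    if (!nrow(dg) || all(dg$count == 0)) {
      warning(sprintf("initial-abundance group %d has no usable counts; skipped", g),
              call. = FALSE)
      next
    }
    fits[[as.character(g)]] <- fit_trend_engine(dg, "poisson_log", ar1 = ar1,
                                                use_species = TRUE)
  }
  species_slopes <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    re <- f$ranef$sp_site
    re <- re[re$term == "year_c", , drop = FALSE]
    if (is.null(re) || !nrow(re)) return(NULL)
    data.frame(group = as.integer(g), sp_site = re$level,
               slope = f$slope + re$mode, condsd = re$condsd,
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, species_slopes = species_slopes,
                 classes = classes, corrected = FALSE),
            class = "population_trend_fit")
}

#' Classify the strength of evidence for a directional trend
#'
#' Zero outside the 95% interval is strong evidence; inside 95% but
#' outside 90% is moderate; inside 90% but outside 80% is weak; inside the
#' 80% interval is no evidence.
#'
#' @param x a `trend_fit` or a 3x2 matrix of equal-tailed intervals with
#'   rows `"80%"`, `"90%"`, `"95%"`.
#' @return one of `"strong"`, `"moderate"`, `"weak"`, `"none"`.
#' @export
classify_evidence <- function(x) {
  ci <- if (inherits(x, "trend_fit")) x$ci else x
  stopifnot(is.matrix(ci), nrow(ci) == 3)
  rn <- rownames(ci) %||% sprintf("%d%%", c(80, 90, 95))
  ci <- ci[order(as.numeric(sub("%", "", rn))), , drop = FALSE]
  widths <- ci[, 2] - ci[, 1]
  if (is.unsorted(widths)) stop("credible intervals are not nested", call. = FALSE)
  outside <- function(row) 0 < ci[row, 1] || 0 > ci[row, 2]
  if (outside(3)) "strong" else if (outside(2)) "moderate" else if (outside(1)) "weak" else "none"
}

# ---- methods ----------------------------------------------------------

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Year-trend fit (%s, backend %s)\n", x$family, x$backend))
  cat(sprintf("  slope: %.5f (se %.5f), 95%% CI [%.5f, %.5f]\n",
              x$slope, x$se, x$ci["95%", 1], x$ci["95%", 2]))
  if (!is.na(x$percent)) {
    cat(sprintf("  percent per year: %+.2f%% [%+.2f, %+.2f]\n",
                x$percent, x$percent_ci["95%", "lower"], x$percent_ci["95%", "upper"]))
  }
  cat(sprintf("  evidence: %s | obs %d, sites %d, years %d%s\n",
              classify_evidence(x), x$n_obs, x$n_sites, x$n_years,
              if (!is.na(x$rho)) sprintf(", AR1 rho %.2f", x$rho) else ""))
  invisible(x)
}

#' @export
summary.trend_fit <- function(object, ...) {
  out <- list(slope = object$slope, se = object$se, ci = object$ci,
              percent = object$percent, family = object$family,
              backend = object$backend, evidence = classify_evidence(object),
              rho = object$rho,
              ranef_sd = lapply(object$ranef, function(df) {
                tapply(df$mode, df$term, stats::sd)
              }))
  class(out) <- "summary.trend_fit"
  out
}

#' @export
print.summary.trend_fit <- function(x, ...) {
  cat(sprintf("slope %.5f (se %.5f), %s evidence, family %s (%s)\n",
              x$slope, x$se, x$evidence, x$family, x$backend))
  print(x$ci)
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) c(year = object$slope)

#' @export
confint.trend_fit <- function(object, parm = "year", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$slope - z * object$se, object$slope + z * object$se), nrow = 1)
  dimnames(m) <- list("year", sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  m
}

#' @export
print.population_trend_fit <- function(x, ...) {
  cat(sprintf("Population trend fits (%d initial-abundance groups%s)\n",
              length(x$fits), if (isTRUE(x$corrected)) ", RtM-corrected" else ""))
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat(sprintf("  group %s: %+.2f%%/yr [%+.2f, %+.2f] (%s)\n", g,
                f$percent, f$percent_ci["95%", "lower"],
                f$percent_ci["95%", "upper"], classify_evidence(f)))
  }
  invisible(x)
}
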