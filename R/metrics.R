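# Per site-year biodiversity metrics: total abundance, observed richness,
# size-based rarefied richness, coverage-based richness at 80% sample
# coverage, Shannon and Simpson diversity as effective numbers of species,
# and the evenness ratio (1/D)/S. All are functions of one year's
# species-by-count vector; the rarefaction depth is a property of the
# whole site series.

#' Rarefaction depth for a site's series of yearly totals
#'
#' The common subsample size used for size-based rarefaction: the lowest
#' total abundance observed in any year, floored at ten individuals (years
#' smaller than the depth are reported as observed richness downstream).
#'
#' @param yearly_totals numeric vector of per-year total abundances.
#' @return integer depth `m`.
#' @export
rarefaction_depth <- function(yearly_totals) {
  stopifnot(length(yearly_totals) >= 1)
  if (all(yearly_totals == 0)) {
    stop("rarefaction depth undefined: all years have zero individuals",
         call. = FALSE)
  }
  as.integer(max(min(yearly_totals), 10))
}

#' Expected richness of an m-individual subsample (size-based rarefaction)
#'
#' Hypergeometric expectation
#' `E[S_m] = sum_i 1 - choose(N - N_i, m) / choose(N, m)`.
#' If the assemblage holds fewer than `m` individuals (possible only via
#' the min-10 depth rule), the observed richness is returned unchanged
#' rather than extrapolated.
#'
#' @param counts species abundance vector (zeros allowed, ignored).
#' @param m subsample size (>= 1).
#' @return expected species count.
#' @export
rarefied_richness <- function(counts, m) {
  stopifnot(m >= 1)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (!length(counts)) return(0)
  if (N < m) return(length(counts))
  sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
}

# Expected sample coverage of an m-individual subsample drawn without
# replacement from the assemblage: E[C(m)] = 1 - sum_i p_i P(i not drawn).
# Exactly matches the Monte-Carlo definition of coverage (share of
# individuals belonging to sampled species).
expected_coverage <- function(counts, m) {
  N <- sum(counts)
  1 - sum((counts / N) * exp(lchoose(N - counts, m) - lchoose(N, m)))
}

#' Expected richness at a target sample coverage (coverage-based rarefaction)
#'
#' Finds the smallest subsample whose expected coverage (the share of the
#' assemblage's individuals belonging to species present in the subsample)
#' reaches `target_coverage`, and returns the expected richness at that
#' size, linearly interpolated in coverage between adjacent integer
#' subsample sizes. When even the complete sample falls short of the
#' target -- judged by the singleton/doubleton coverage estimate at full
#' size -- richness is extrapolated beyond the sample with the Chao-Jost
#' coverage-based extrapolation (capped at the Chao1-style asymptotic
#' richness when the target is unreachable).
#'
#' @param counts species abundance vector.
#' @param target_coverage coverage target in (0, 1\]; 0.8 by default.
#' @return expected species count (real-valued).
#' @export
coverage_richness <- function(counts, target_coverage = 0.8) {
  stopifnot(target_coverage > 0, target_coverage <= 1)
  counts <- counts[counts > 0]
  N <- sum(counts)
  S <- length(counts)
  if (S == 0) return(0)
  if (S == 1) return(1)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  # coverage of the complete sample, singleton/doubleton adjusted
  C_full <- if (f1 > 0) {
    A <- if ((N - 1) * f1 + 2 * f2 > 0) (N - 1) * f1 / ((N - 1) * f1 + 2 * f2) else 1
    1 - (f1 / N) * A
  } else 1
  if (target_coverage > C_full) {
    return(coverage_extrapolate(counts, N, S, f1, f2, C_full, target_coverage))
  }
  # smallest m in 1..N with expected coverage >= target (monotone in m)
  lo <- 1L
  hi <- N
  if (expected_coverage(counts, 1L) >= target_coverage) return(rarefied_richness(counts, 1L))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (expected_coverage(counts, mid) >= target_coverage) hi <- mid else lo <- mid
  }
  c_lo <- expected_coverage(counts, lo)
  c_hi <- expected_coverage(counts, hi)
  s_lo <- rarefied_richness(counts, lo)
  s_hi <- rarefied_richness(counts, hi)
  if (c_hi == c_lo) return(s_hi)
  s_lo + (target_coverage - c_lo) / (c_hi - c_lo) * (s_hi - s_lo)
}

# Chao-Jost coverage-based extrapolation beyond the observed sample size.
coverage_extrapolate <- function(counts, N, S, f1, f2, C_full, target) {
  f0 <- if (f2 > 0) {
    (N - 1) / N * f1^2 / (2 * f2)
  } else {
    (N - 1) / N * f1 * (f1 - 1) / 2
  }
  if (f0 <= 0 || f1 == 0) return(S)
  A <- (N - 1) * f1 / ((N - 1) * f1 + 2 * f2)
  s_at <- function(mstar) S + f0 * (1 - (1 - f1 / (N * f0 + f1))^mstar)
  if (A >= 1 || target >= 1) return(S + f0)  # target unreachable: asymptote
  # coverage at N + m*: 1 - (f1/N) A^(m*+1); solve smallest integer m*
  mstar <- ceiling(log(N * (1 - target) / f1) / log(A) - 1)
  if (!is.finite(mstar)) return(S + f0)
  mstar <- max(mstar, 1)
  c_at <- function(ms) 1 - (f1 / N) * A^(ms + 1)
  c_lo <- if (mstar == 1) C_full else c_at(mstar - 1)
  c_hi <- c_at(mstar)
  s_lo <- if (mstar == 1) S else s_at(mstar - 1)
  s_hi <- s_at(mstar)
  if (c_hi == c_lo) return(s_hi)
  s_lo + (target - c_lo) / (c_hi - c_lo) * (s_hi - s_lo)
}

#' Shannon and Simpson diversity as effective numbers of species
#'
#' Shannon entropy `H' = -sum p_i log p_i` is returned as `exp(H')`;
#' Simpson concentration `D = sum p_i^2` (probability of intraspecific
#' encounter, with replacement) is returned as `1/D`.
#'
#' @param counts species abundance vector.
#' @return named vector `c(shannon_effective, simpson_effective)`.
#' @export
hill_diversities <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(length(counts) >= 1)
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  D <- sum(p^2)
  c(shannon_effective = exp(H), simpson_effective = 1 / D)
}

#' Evenness as the ratio of inverse-Simpson diversity to richness
#'
#' `I = (1/D) / S`, in (0, 1\]; 1 when all species are equally abundant.
#'
#' @param counts species abundance vector.
#' @return evenness value.
#' @export
evenness <- function(counts) {
  counts <- counts[counts > 0]
  stopifnot(length(counts) >= 1)
  unname(hill_diversities(counts)["simpson_effective"]) / length(counts)
}

#' All seven biodiversity metrics for one assemblage-year
#'
#' @param counts species abundance vector.
#' @param m rarefaction depth from [rarefaction_depth()]; skip the
#'   rarefied-richness entry when `NULL`.
#' @param target_coverage coverage target for [coverage_richness()].
#' @return named numeric vector: `abundance`, `richness`,
#'   `rarefied_richness` (if `m` given), `coverage_richness`,
#'   `shannon_effective`, `simpson_effective`, `evenness`, plus the
#'   intermediates `f1` (singletons) and `f2` (doubletons).
#' @export
assemblage_metrics <- function(counts, m = NULL, target_coverage = 0.8) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    out <- c(abundance = 0, richness = 0, coverage_richness = NA_real_,
             shannon_effective = NA_real_, simpson_effective = NA_real_,
             evenness = NA_real_, f1 = 0, f2 = 0)
    if (!is.null(m)) out <- append(out, c(rarefied_richness = NA_real_), after = 2)
    return(out)
  }
  hill <- hill_diversities(counts)
  out <- c(abundance = sum(counts), richness = length(counts))
  if (!is.null(m)) out <- c(out, rarefied_richness = rarefied_richness(counts, m))
  c(out,
    coverage_richness = coverage_richness(counts, target_coverage),
    hill,
    evenness = unname(hill["simpson_effective"]) / length(counts),
    f1 = sum(counts == 1), f2 = sum(counts == 2))
}

#' Metric series for a set of assemblages
#'
#' Computes the seven metrics for every site-year of an assemblage table
#' (one rarefaction depth per site, from its yearly totals).
#'
#' @param assemblages data frame `site_id`, `year`, `taxon_id`, `count`
#'   (from [assemblage_counts()] or a standardization iteration).
#' @param target_coverage coverage target for [coverage_richness()].
#' @return tidy data frame `site_id`, `year`, `metric`, `value`.
#' @export
metric_series <- function(assemblages, target_coverage = 0.8) {
  pieces <- lapply(split(assemblages, assemblages$site_id), function(sdat) {
    totals <- tapply(sdat$count, sdat$year, sum)
    m <- rarefaction_depth(as.numeric(totals))
    per_year <- lapply(split(sdat, sdat$year), function(ydat) {
      vals <- assemblage_metrics(ydat$count, m = m, target_coverage = target_coverage)
      data.frame(site_id = sdat$site_id[1], year = ydat$year[1],
                 metric = names(vals), value = as.numeric(vals),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_year)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
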