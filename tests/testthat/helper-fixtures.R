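# Shared fixture builders and independent oracles.

# Minimal valid community table from a site x year x taxon count spec.
make_table <- function(counts, study = "S1", area = "S1-A1", site = "S1-P1",
                       period = "p1", sample = "smp1") {
  # counts: data.frame(year, taxon_id, count) or named list per year
  df <- as.data.frame(counts)
  df$study_id <- study
  df$area_id <- area
  df$site_id <- site
  if (is.null(df$period)) df$period <- period
  if (is.null(df$sample_id)) df$sample_id <- sample
  if (is.null(df$rank)) df$rank <- "species"
  community_table(df)
}

# Exhaustive-enumeration oracle for size-based rarefaction: average species
# count over every m-subset of the individual vector. Only viable for
# communities of <= ~12 individuals.
rarefy_enumerate <- function(counts, m) {
  ind <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(ind), m)
  mean(apply(subs, 2, function(ix) length(unique(ind[ix]))))
}

# Monte-Carlo oracle for coverage-based rarefaction. Coverage of an
# m-subsample is measured directly as the share of the community's
# individuals belonging to the species present in the subsample. One
# random permutation yields all subsample sizes at once via first-
# occurrence positions, so `draws` permutations estimate the full
# E[coverage(m)] and E[S(m)] curves; the oracle then finds the smallest m
# reaching the target and interpolates richness linearly in coverage.
coverage_mc_oracle <- function(counts, target = 0.8, draws = 1e5, seed = 1) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  S <- length(counts)
  spid <- rep(seq_len(S), counts)
  rich_acc <- numeric(N)
  cov_acc <- numeric(N)
  set.seed(seed)
  for (i in seq_len(draws)) {
    first <- match(seq_len(S), spid[sample.int(N)])
    rich_acc[first] <- rich_acc[first] + 1
    cov_acc[first] <- cov_acc[first] + counts
  }
  rich_curve <- cumsum(rich_acc) / draws     # E[S(m)], m = 1..N
  cov_curve <- cumsum(cov_acc) / (N * draws) # E[C(m)]
  if (cov_curve[1] >= target) return(rich_curve[1])
  hi <- which(cov_curve >= target)[1]
  if (is.na(hi)) return(rich_curve[N])
  lo <- hi - 1L
  rich_curve[lo] + (target - cov_curve[lo]) / (cov_curve[hi] - cov_curve[lo]) *
    (rich_curve[hi] - rich_curve[lo])
}

# Random community generator for property tests.
random_community <- function(n_species = NULL) {
  n <- n_species %||% sample(2:30, 1)
  pmax(1, round(stats::rlnorm(n, meanlog = 1.2, sdlog = 1.2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
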