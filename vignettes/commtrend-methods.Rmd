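---
title: "Estimating biodiversity trends from long-term community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biodiversity trends from long-term community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commtrend)
```

## The problem

Long-term insect monitoring programs produce count tables — individuals
per taxon per trap per visit per site per year — collected under designs
that drift over decades: traps fail, sampling seasons shift, taxonomic
effort varies. `commtrend` turns such tables into defensible estimates of
how biodiversity is changing: in total abundance, in richness and
diversity, in the shape of the species abundance distribution (SAD), and
in the populations of individually tracked species, with particular care
for two artifacts that dominate naive analyses — unequal sampling effort
and regression to the mean (RtM).

The package is organised as a pipeline of small, independently usable
stages:

1. **Simulation** (`sim_config()`, `simulate_dataset()`) — synthetic
   surveys with known ground truth, used throughout the test suite.
2. **Conceptual scenarios** (`scenario_spec()`, `run_scenario()`) — an
   idealized community projected under three contrasting decline rules.
3. **Standardization** (`effort_target()`, `equalize_effort()`,
   `clean_taxonomy()`) — equal effort across years within each site.
4. **Metrics** (`metric_series()` and friends) — seven per-site-year
   biodiversity metrics.
5. **SAD intervals** (`interval_series()`,
   `classify_initial_abundance()`) — species counts per abundance bin and
   the initial-abundance classification.
6. **Trend models** (`fit_metric_trend()`, `fit_evenness_trend()`,
   `fit_population_trends()`) — hierarchical autoregressive year-slope
   models.
7. **RtM correction** (`estimate_rtm_correction()`,
   `apply_rtm_correction()`, `relate_dataset_effects()`).
8. **Orchestration** (`pipeline_config()`, `run_pipeline()`).

## The conceptual scenarios

Assuming total abundance declines, rarer species can decline (1) in
proportion to the abundant ones, (2) less, or (3) more. Each scenario
leaves a distinct fingerprint in the metric trends. The package encodes
them as projection rules for a species starting at abundance $N_0$:

* proportional: $N_t = N_0 (1+r)^t$ with one shared rate $r$;
* abundant-decline: $N_t = N_0^{1 - 0.018\,t}$, so the annual multiplier
  $N_0^{-0.018}$ falls with abundance — the most abundant species
  (starting at 32 individuals) loses about 6% per year while a singleton
  does not decline at all;
* rare-decline: $N_t = N_0\,(10^{-0.027} + 0.035 \log_{10} N_0)^t$, the
  mirror image — a singleton loses about 6% per year, the most abundant
  species 0.76%.

The starting community is a fixed, documented 43-species SAD (12
singletons, 10 doubletons, 21 more abundant species up to 32; 211
individuals). Only its printed properties are constrained; the 21
non-rare abundances are a package constant chosen to populate all five
log-abundance intervals. The proportional rate $r$ is not a free
parameter: it is solved so that total abundance loss over 20 years
matches the abundant-decline scenario on the same community
(`match_proportional_rate()`), keeping the scenarios comparable.

Projections run for 20 years; independent Gaussian noise
($\mu = 0, \sigma = 0.5$) is added to the deterministic yearly values
(not compounded into the dynamics), counts are rounded and floored at
zero. A parallel display series declares species with pre-rounding values
below 0.6 extinct; the analysis series uses the rounded counts. Whether
the extinction rule should apply before or after the noise is not
determined by the source material; we apply it after, to the noisy
values, since it is a visualization rule for realized series.

## Effort standardization

Metric trends are only meaningful if each site-year rests on the same
sampling effort. Two resampling strategies cover the data types met in
practice:

* **Individual-proportional** (`method = "individuals"`): per-year effort
  (number of samples) is known but samples are pooled. Years are
  subsampled without replacement to `round(min_effort / effort * N)`
  individuals — a 300-individual year from 6 traps equalized to 4-trap
  effort contributes 200 drawn individuals. If matching the
  minimum-effort year would discard more than half of the other years'
  individuals (configurable), that year is dropped instead; the paperless
  judgement call is replaced by a fixed, deterministic default.
* **Sample-based** (`method = "samples"`): sample-level data with
  variable trap and period coverage. `effort_target()` first chooses the
  subset of within-year periods, and the years complete in all of them,
  that maximizes retained year-by-period cells (ties favour more years,
  then the lexicographically first period set); within each retained
  period, whole samples are drawn without replacement down to the
  minimum sample count in any retained year and summed into one yearly
  sample.

Either way the resampling is repeated (100 iterations by default),
biodiversity metrics are averaged over iterations, and per-species yearly
counts are summarized by rounded medians for the population models.
Genus-level records are re-resolved inside every iteration:
`clean_taxonomy()` allocates genus-rank individuals multinomially to the
congeneric species observed in the same site's series, with
probabilities proportional to each congener's series total — the
maximum-likelihood assignment if identification failure is independent of
species. Genera without observed congeners are kept as pseudo-species.

## The seven metrics

For one site-year with counts $N_i$, $N = \sum N_i$, $S$ species,
$p_i = N_i / N$:

* abundance $N$ and richness $S$;
* rarefied richness $E[S_m] = \sum_i 1 - \binom{N - N_i}{m}/\binom{N}{m}$
  at depth $m$ = the lowest yearly total in the site's series, floored at
  10 individuals (years holding fewer than $m$ individuals report
  observed $S$ — we do not extrapolate there);
* coverage-based richness: expected richness of the smallest subsample
  whose expected coverage reaches 0.8. Interpolated coverage of an
  $m$-subsample uses the exact expectation
  $C(m) = 1 - \sum_i p_i \binom{N-N_i}{m}/\binom{N}{m}$, which matches a
  direct Monte-Carlo definition of coverage (share of individuals
  belonging to sampled species); richness is interpolated linearly in
  coverage between adjacent integer sizes. Coverage of the complete
  sample is estimated from singletons and doubletons
  ($\hat C = 1 - \tfrac{f_1}{N}\tfrac{(N-1)f_1}{(N-1)f_1 + 2f_2}$), and
  when it falls short of the target the Chao-style extrapolation beyond
  $N$ is used, capped at the asymptotic richness when the target is
  unreachable (e.g. target 1 with singletons present);
* Shannon diversity as $e^{H'}$, $H' = -\sum p_i \ln p_i$ (natural log,
  so the exponential is an effective species number);
* inverse Simpson $1/D$, $D = \sum p_i^2$;
* evenness $I = (1/D)/S \in (0, 1]$.

## SAD intervals and initial-abundance classes

Two binning schemes per site: five equal-width intervals on
$[0, \log_{10}(\text{site maximum})]$, and four quartiles of the pooled
positive abundance values. Interval membership is half-open
$[\text{low}, \text{high})$ with the top edge inclusive — the only
convention under which singletons ($\log_{10} 1 = 0$) are "rare" and the
site maximum is "abundant"; quartile ties are assigned upward, so a bin
counts only observations strictly smaller than its upper edge.

For population trends, species are classified once per site into five
groups by their abundance in the classification year(s) (first year by
default; means over years 1–2, 1–5, or the whole series as variants,
log-transformed after averaging), on intervals spanning zero to the
classification-year maximum. Species absent then form group 6 and are
excluded from trend averaging — conditioning on absence guarantees
spuriously positive trends. Sites with fewer than two detected species,
or where all detected species share one abundance value (a degenerate
log-range), are discarded and logged.

## Trend models

Every trend model has a single fixed effect — calendar year, centred
within study — and a hierarchy of random effects: intercepts for study,
area, site and within-year period; year slopes for study, area and site;
and, for the population models, intercepts and slopes for each
species-by-site series. Temporal autocorrelation enters as an AR1 process
on site-level residuals over the integer year grid; because unobserved
years are kept as levels, a gap of $\Delta t$ years carries correlation
$\rho^{\Delta t}$, the discrete equivalent of a continuous-time
Ornstein–Uhlenbeck process. Grouping levels that duplicate the level
above (a single-area study, a single-study dataset) are collapsed
automatically.

Families: Gaussian on $\log_{10}(x + 1)$ for all count-valued metrics
(slope back-transformed to percent per year as $(10^\beta - 1) \times
100$); Poisson with log link for population counts (no transformation, so
zeros are modelled; percent is $(e^\beta - 1) \times 100$); a logit-link
beta likelihood for evenness, with the standard boundary shrink
$y' = (y(n-1) + 0.5)/n$ and slopes reported on the logit scale.

Inference is by Laplace approximation (glmmTMB). Posterior summaries are
the Gaussian approximation around the mode: equal-tailed 80/90/95%
intervals from the Wald standard error, random-effect conditional modes
and sds, and the AR1 correlation with an interval computed on glmmTMB's
unbounded parameterization $\rho = t/\sqrt{1+t^2}$ and mapped through the
monotone transform. Evidence tiers follow the interval nesting: zero
outside the 95% interval is strong evidence for a directional trend,
outside 90% moderate, outside 80% weak, otherwise none.

Three numerical choices deserve note:

* Intercept/slope pairs enter as uncorrelated terms
  (`(1|g) + (0+year|g)`); the correlated parameterization routinely
  produces indefinite Hessians on realistic data without changing the
  slope.
* A fit is accepted only with a positive-definite Hessian and a finite
  slope standard error; otherwise the engine walks a fixed ladder of
  simplifications — dropping the site intercept (which duplicates the
  AR1 process's stationary level variance), then the AR1 term, then
  higher-level terms — down to ordinary least squares for deterministic
  or single-site inputs. The backend actually used is recorded on the
  `trend_fit`.
* Perfect fits leave machine-epsilon noise in both slope and standard
  error; the fixed-effects fallback floors the standard error at
  `1e-8 * (1 + |slope|)` so that a numerically flat series is classified
  as "none", not "strong".

Year is centred but deliberately not scaled per study: a single global
year coefficient cannot be reported per calendar year if each study
carries its own scale factor.

## Regression to the mean

Classifying species by a noisy initial abundance biases the apparent
trends of the extreme groups: populations drawn high regress downward,
populations drawn low upward. The correction estimates this component on
the robust subset of sites (at least 15 sampled years — data points, not
span): population trends are fitted twice, once on the full series and
once with the first year (or three, as a sensitivity variant)
left-censored out of the trend window while still defining the
classification. The per-group difference, censored minus full, is the
correction factor, added to the full-series slope, its intervals
(translated, widths unchanged) and the species-level effect summaries.
Classification by the whole-series mean abundance needs no correction and
serves as the conservative cross-check.

A subtlety uncovered while validating the correction on null
simulations: the direction of the bottom group's bias depends on the
SAD's rare tail. Species with expected abundance near one can enter
group 1 only through a *high* classification draw (a zero draw sends
them to the excluded group 6), which biases group 1 downward — opposite
to the textbook RtM geometry. With the rare tail at a few expected
individuals (as in the lognormal null fixture used by the tests, mean
log 2, sd log 1), low-draw selection dominates and the familiar pattern
appears: bottom group biased upward, top group downward, both removed by
censoring.

`relate_dataset_effects()` correlates dataset-level random year-slope
effects of each population group with those of the total-abundance
model, propagating conditional uncertainty by Monte-Carlo draws; at
least three shared datasets are required.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes:
skewed SADs (log-series by default, lognormal or the fixed 43-species
community as alternatives), a study > area > site hierarchy, consecutive
20-year series (the median duration of long-term insect compilations),
per-species multiplicative trends (mean −1.5%/yr with site-level
heterogeneity of sd 0.005 on the log scale by default), negative-binomial
observation noise (dispersion 0.25 by default; variance
$\mu + d\mu^2$ — counts cannot go negative, unlike Gaussian noise),
multinomial splitting of individuals across traps and periods with
whole-sample deletion, and binomial demotion of individuals to
genus-level identification (7% by default, matching the share typically
seen in compiled survey data). The noise family of real surveys is not
known; negative-binomial is a stand-in, and `dispersion` is a knob.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: species interactions and density
dependence (species are independent), trend changes over time (rates are
constant), colonization (no species enters after year one), spatial
structure among sites, trap-type differences between sites, and
phenological shifts within periods. Years are consecutive integers; gaps
arise only through sample deletion.

## Problem sizes used in validation

The test suite validates the stochastic guarantees at sizes chosen to
make the checked effects comfortably larger than their own sampling
noise: parameter recovery on 2 studies × 10 sites × 20 years over 20
seeded replicates (the 95% interval must cover the injected −1.5%/yr in
at least 17); AR1 recovery ($\rho = 0.6$) on 10 sites × 30 years over 20
replicates; RtM bias removal on the 15-site × 60-species lognormal null
fixture described above. Estimator correctness is checked against
exhaustive enumeration (size-based rarefaction on communities of at most
ten individuals) and a $10^5$-draw Monte-Carlo subsampling oracle
(coverage-based richness, within 1%).

## Known limitations

* Intervals are Gaussian approximations around the Laplace mode, not
  MCMC posteriors; for variance parameters near boundaries they can be
  mildly anti-conservative, and the AR1 correlation estimate is slightly
  biased downward when random year slopes compete for the same
  long-range correlation.
* The Poisson population model ignores overdispersion beyond what the
  random effects absorb; with strongly overdispersed counts its
  intervals are optimistic.
* Scale-penalizing (penalized-complexity) priors on the variance and
  correlation parameters are approximated by their flat-prior limit;
  with the data sizes targeted here the likelihood dominates, but very
  sparse groups may differ.
* Effort is equalized within sites only; between-site differences in
  trap type or efficiency are deliberately untouched.
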