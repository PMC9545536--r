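---
title: "Partitioning temporal stability across ecological scales: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning temporal stability across ecological scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierstab)
```

## The model

`hierstab` analyzes a panel `N(i,k,t)` of aboveground biomass (g/m²) for
site *i*, species *k*, year *t*.  A *regional community* is a set of M
member sites (M = 2 throughout the documented workflow).  All quantities
derive from the temporal moments over the years common to the members:
means `u(i,k)`, the covariance tensor `v(ij,kl) = cov(N(i,k,·), N(j,l,·))`
(sample covariance, denominator T−1), and the regional mean total
`u_total`.

Stability is measured by its inverse, the coefficient of variation.  The
local population CV is the biomass-weighted mean population CV,
`Σ√v(ii,kk)/u_total`.  Each upscaling step multiplies a CV by a synchrony —
the ratio of the standard deviation of an aggregate to the sum of the
standard deviations of its parts — which by sub-additivity of standard
deviations lies in [0, 1]: 1 when the parts fluctuate in perfect
proportion, 0 under perfect compensation.  Two routes lead from the local
population CV to the regional community CV: species-aggregation first
(local species synchrony, then regional community synchrony), or
spatial-aggregation first (regional population synchrony, then regional
species synchrony).  For all-species measures both routes telescope to
`√v_CR/u_total` exactly; the test suite asserts this to 1e−10 relative
error on random panels, together with the [0, 1] bounds and the
monotone ordering of CVs up the hierarchy.

**Assumptions.** Biomass series are analyzed as observed: no detrending,
gap-filling or imputation.  Absent species-site-year records are structural
zeros (an absence in a harvest is zero biomass).  A community is analyzable
when its members share at least 3 years (covariance needs 2; one more for
stability) and its total biomass is positive.

### Dominant-species variants

Dominant species are those contributing strictly more than a threshold
(default 5%) of the community biomass pooled over member sites and common
years; dominance is decided at the regional-community level, so the
indicator is shared by all member sites.  The dominant variants replace the
numerator sums by masked sums.  Two normalization conventions are
implemented:

* `convention = "typeset"` (default): dominant-species numerators over
  **all-species** denominators, following the printed form of the
  estimators.  Under this convention the two pathway estimates of the
  dominant regional community CV do not telescope identically and can
  differ slightly; both are reported (`cv_comm_regional_I`, `_II`).
* `convention = "masked"`: denominators masked as well; the two pathways
  then coincide exactly (a tested invariant).

Because the source derivation of the mixed convention is not fully
recoverable, the package makes no claim about which is "right": the default
reproduces the typeset estimators and the alternative is one switch away.
At threshold 0 every dominant variant equals its all-species counterpart
exactly under either convention (tested).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 0.05 | fraction | dominance cut on pooled biomass share, strict `>` |
| `m` | 2 | sites | regional community size; >2 supported, 2 documented |
| `n_sets` | 1000 | — | resampled disjoint pairings of the site pool |
| `min_years` | 3 | years | common-year requirement per community |
| `alpha`, `alpha_marginal` | 0.05, 0.10 | — | opposite-sign proportion cuts of the randomized examination |

Diversity: alpha richness is the mean over sites of the multi-year mean
yearly species count; gamma is the pooled count; beta their ratio.
Effective richness uses Shannon entropy in nats, `D = e^{H'}`.  Whether the
alpha level averages `e^{H'}` over site-years (default, mirroring the
mean-count definition of alpha richness) or exponentiates the averaged `H'`
is switchable (`alpha_method`); the two agree exactly for identical
site-years and differ little otherwise (Jensen gap of `exp`).

Climate series are treated as one-"species"-per-site communities and run
through the identical estimators; an exact-equality test pins
`climate_summary()` to `partition_hierarchy()` on the corresponding
pseudo-panel.  When monthly columns are supplied, the May–October growing
season is used (sum for precipitation, mean for temperature); plants in the
target steppe systems are active only in that window.

## The resampling construction and significance

`pair_partition()` chunks a uniform random permutation of the site pool
into consecutive pairs: every admissible disjoint pairing is equally likely
(chi-square-tested on the 3 pairings of 4 sites).  With 21 sites this gives
10 regional communities and one remainder per set; the remainder is
excluded from that set (rotating it elsewhere is not implied by a
construction that names a single remainder).  Each set is analyzed
independently; failed communities are recorded, never silently dropped.

The randomized examination computes a statistic (correlation, slope,
standardized path coefficient) within each set and judges the mean by the
proportion of opposite-sign sets: significant below 0.05, marginal below
0.10.  A calibration note: when the per-set statistics are independent the
opposite-sign proportion concentrates near 0.5 under a true null, so the
rule is strongly conservative; when sets share one site pool (the intended
use) the per-set statistics are highly dependent and the verdict
effectively asks whether the pooled relationship is strong enough that
almost no random pairing reverses its sign.  The acceptance suite therefore
checks calibration one-sidedly — the false-positive rate must not exceed
the nominal level beyond Monte-Carlo error — in both regimes, rather than
asserting exact attainment of the nominal level, which this rule does not
have.

## Path models

"Piecewise" path analysis fits each endogenous node of an acyclic edge list
by OLS on its parents, within each set, on variables z-scored within the
set, so coefficients are standardized and a single-predictor slope equals
the correlation (exact, tested).  Edge significance uses the randomized
examination across sets, matching the significance machinery of the rest
of the analysis rather than within-set p-values on n = 10 points.
Model score: per-equation `AICc = AIC + 2k(k+1)/(n−k−1)` summed over
equations and averaged over sets.  Pruning removes the weakest
nonsignificant unlocked edge — largest opposite-sign proportion, ties by
smallest |coefficient| then node names (deterministic) — refits, and stops
when removal would raise the mean total AICc or nothing removable remains.
Theory-mandated edges can be locked (the shipped pathway-II spec locks the
regional population synchrony path, which theory requires even where raw
regressions are equivocal).  Pruning terminates in at most |edges| steps
and never raises AICc (tested).  Saturated equations (fewer than k + 2
communities) make a set invalid; the fitter reports how many sets survived.

## The synthetic world

`generate_panel()` draws biomass as
`N(i,k,t) = a(i,k) · exp(b·(P_i(t) − MAP) + σ_idio·ε)`, with `P_i(t)`
growing-season precipitation around `map_mean` with interannual CV
`cv_env` and between-site correlation `rho_space`, and `a(i,k)` lognormal
species base abundances (spread `sad_sigma`) with site-level deviations.
The sensitivity `b` is set so the within-site between-species log-biomass
correlation equals `rho_species`; multiplicative lognormal dynamics keep
biomass positive and reproduce the mean–variance coupling of productivity
data.

Defaults state the emulated world once: 21 sites, 40 species, 5 years
(optionally dropping the first year in a random subset of sites to emulate
4–5-year runs); `sad_sigma = 2`, giving the strongly uneven abundance
distribution in which a handful of species exceed the 5% dominance cut;
`map_mean = 300` mm and `cv_env = 0.15`, a semi-arid steppe precipitation
regime within the observed 186–398 mm range of such systems;
`rho_space = 0.5`, under which a site pair's precipitation synchrony is
`√((1+ρ)/2) ≈ 0.87`, the region-wide synchronous-rainfall situation;
`rho_species = 0.4` and `sigma_log = 0.6` (population-level CV ≈ 0.65),
plausible for water-limited grassland.  `mean_site_biomass = 150` g/m²
scales the panel to typical steppe productivity.  These values were chosen
once, before any acceptance measurement, and are not tuned.

What the generator does **not** emulate: species-specific climate
sensitivities (all species share `b`, so same-species and cross-species
spatial correlations coincide at `rho_species·rho_space`), negative
within-site correlations (the shared-driver construction represents
nonnegative `rho_species` only), demographic or observation error
structure, species turnover in time, and any mechanistic population
dynamics.  A green test on synthetic data therefore establishes that the
estimators recover the moments and mappings of this stated world — not
that real grassland satisfies its assumptions.

Ground-truth mappings used by the recovery tests (exchangeable species,
small-σ limit where lognormal and normal correlations coincide):
local species synchrony `√((1+(S−1)r)/S)`; pair precipitation synchrony
`√((1+ρ)/2)`; regional community synchrony `M^{−1/2}` for independent
sites.  Recovery is run at T = 100 years and `sigma_log = 0.05` so the
Monte-Carlo confidence intervals test the structural mapping rather than
finite-T estimator bias; at the survey-like T = 5 the ratio-of-roots
estimators are visibly biased (a limitation shared with any CV/synchrony
estimate from 4–5 points, and one reason the analysis averages over 1000
resampled sets).

## Numerical choices

* Sample covariance with denominator T−1 everywhere; the multiplicative
  identities hold for any fixed denominator.
* Square roots of tiny negative diagonal aggregates (floating-point noise)
  are clamped at 0.
* Degenerate 0/0 synchronies (all relevant variances zero) raise a flagged
  `undefined` error rather than returning 0 or 1; zero-variance *species*
  are harmless (they contribute sd 0).
* Dominance uses strict `>`; an exactly-5% share is not dominant, and a
  community with no dominant species carries `NA` dominant variants with
  `dominant_defined = FALSE` instead of an invented value.
* Year alignment within a community is the intersection of member site
  years; sites keep their own observed runs at read time.
* Quadrat replicates are averaged by default (preserves per-m² units;
  summing is one switch away) — the field protocol this mirrors analyzes
  site-level series from three 1 m² quadrats.

## Known limitations

* The deposited multisite survey dataset that motivates the default world
  is not redistributable here; the full-data reproduction test runs only
  when its tables are placed under `inst/extdata/deposited/`, and fails
  (does not skip) otherwise.
* No variance-ratio or loess-detrended alternatives to this CV/synchrony
  family; no rarefaction or Hill-number generalization beyond q = 0/1; no
  latent-variable SEM or covariance-based fit statistics (χ², CFI); no
  spatially stratified pairing schemes; no climate interpolation — the
  package consumes per-site climate series.
* With 4–5-year series all CV and synchrony estimates are strongly
  sampling-noisy at the single-community level; inference is designed to
  operate on distributions across resampled sets, not on single values.
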