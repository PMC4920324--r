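---
title: "Quantifying national use of foreign crops: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying national use of foreign crops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropuse)
```

## The problem

Most food crops were domesticated, and accumulated most of their varietal
and wild-relative diversity, in a small number of geographical regions —
their *primary regions of diversity*. Modern food systems, however, are
thoroughly globalized: the wheat eaten in Mexico, the maize grown in
Malawi and the soya bean cultivated in Brazil all come from crops whose
diversity is concentrated far from where they are now consumed or grown.
`cropuse` quantifies this: for every country it estimates what share of
the national food supply (calories, protein, fat, food weight per capita
per day) and of agricultural production (production quantity, harvested
area, production value) derives from *foreign* crops — crops whose primary
regions of diversity do not overlap any of the regions the country
belongs to — and how that share has changed since 1961.

The package works on FAO-style food balance and production panels: long
tables of (country, commodity, variable, year, value), a
commodity-to-crop aggregation map, a crop-to-region origin map, a
country-to-region map over a canonical list of 23 ecogeographically
delineated regions, and a country-by-year population table.

## From panels to usage intervals

Two data-preparation steps precede everything. Commodities derived from
the same crop species (sesame seed and sesame seed oil, say) are summed
into one whole-crop category; totals per (country, variable, year) are
conserved exactly. To make a continuous 1961–2011 panel possible,
countries that split during the period are merged back into their
predecessor: production values are summed across successors, per-capita
supply values are replaced by the population-weighted mean using each
successor's population in the same reporting year. Missing
(country, commodity, year) rows mean the crop was not produced or
consumed — value zero, never imputed. Labels are matched
case-insensitively after whitespace normalization, and never fuzzily: a
silent misjoin is worse than a hard error.

The central statistic is an interval. Because some FAO commodities (e.g.
"fruits, other") cannot be attributed to any origin region, the true
foreign share of a country's supply is only known to lie between two
bounds. Starting from the assumption that everything is foreign (100%),
subtracting the share of crops native to the country's region(s) gives the
**maximum use** of foreign crops; additionally subtracting the share of
origin-unspecified commodities — assuming they were all native — gives the
**minimum use**:

$$\text{max} = 100\left(1 - \frac{N}{T}\right), \qquad
  \text{min} = \text{max} - 100\,\frac{U}{T},$$

where \(T\) is the total, \(N\) the native-attributed value and \(U\) the
unspecified value. The interval width is exactly the unspecified share. A
crop with several origin regions counts as native if *any* of them
overlaps *any* of the country's regions, and a country spanning several
regions uses their union — both choices deliberately inclusive, so
foreign use is not overestimated. Arithmetic is kept at full precision
internally; the reporting convention is one decimal.

## Regional aggregates and linkage matrices

Regional supply values are population-weighted means of national values
(each country first averaged over the year window, weighted by its
window-mean population); regional production values are plain sums.
The origin-by-consumer *linkage matrix* behind circular (chord) plots
attributes each consuming region's aggregate to the origin regions of its
crops, with an extra "not specified" origin row.

How a crop with \(k\) origin regions is apportioned is genuinely open;
the package implements both conventions. Under `split` (the default) each
origin receives \(1/k\) of the value, so column sums reproduce the
regional aggregates exactly and the chord diagram is well defined. Under
`duplicate` each origin is credited in full — faithful to the inclusive
listing convention, but totals overcount and the violation is flagged in
the output metadata. Percentile filtering (e.g. keeping the 95th
percentile of linkages) ranks only the positive attributed entries, keeps
ties at the threshold, and leaves the "not specified" row untouched.

## The interval-censored models

Point estimates inside the intervals would discard the origin
uncertainty. Instead both headline models treat the true usage as
*interval-censored*: the latent response is Normal but observed only to
lie within `[min_use, max_use]`.

**Current use** (`fit_usage_level`) models one country's recent window
(conventionally the mean of 2009–2011) with an intercept-only censored
Normal, \(y_i \sim N(\theta, \sigma^2)\). The posterior for \(\theta\)
carries the interval width into the reported uncertainty.

**Trend** (`fit_usage_trend`) is hierarchical:

$$y_{ct} \sim N(\alpha_c + \beta_c t,\ \sigma^2), \qquad
  (\alpha_c, \beta_c) \sim N_2\!\big((\mu_\alpha, \mu_\beta),\ \Sigma\big),$$

with \(t\) in years since the origin year (1961 for the historical
panels), so \(\mu_\alpha\) is the 1961 level and \(\mu_\beta\) — the
slope hyper-mean — is the global change in usage in percentage points per
year. \(\Sigma\) is parameterized by standard deviations
\(\tau_\alpha, \tau_\beta\) and a correlation \(\rho\), allowed to be
non-zero because countries that already use mostly foreign crops have
less room to trend upward. Usage in the first and last year is reported
as a *derived parameter*: \(\alpha_c + \beta_c t\) evaluated per
posterior draw per country, then averaged across countries within each
draw.

### Priors, sampler and numerical choices

Non-informative priors are stated once and overridable in spirit but
fixed in code for reproducibility: \(N(0, 10^6)\) on
\(\mu_\alpha, \mu_\beta\); \(U(0, 100)\) on \(\sigma\), \(\tau_\alpha\),
\(\tau_\beta\); \(U(-1, 1)\) on \(\rho\).

The sampler is a data-augmented Gibbs scheme written in plain R:

1. each latent \(y_{ct}\) is drawn from a Normal truncated to its
   observation interval (inverse-CDF draw; zero-width intervals are exact
   data and fix the latent);
2. \((\alpha_c, \beta_c)\) have conjugate bivariate-Normal full
   conditionals, updated for all countries at once with closed-form
   2-by-2 algebra;
3. the hyper-means are a conjugate bivariate-Normal update;
4. \(\sigma^2\) is a truncated inverse-gamma draw implied by the uniform
   prior on \(\sigma\);
5. \(\tau_\alpha, \tau_\beta, \rho\) are updated by univariate slice
   sampling (stepping-out with shrinkage). With a uniform prior on the
   scales *and* a free correlation the scale full conditionals are not
   conjugate, and slice sampling is tuning-free and exact, which we
   prefer over a random-walk Metropolis step whose step size would need
   calibration.

Defaults are 3 chains from dispersed starting points (per-country
ordinary-least-squares fits to the interval midpoints, jittered per
chain), 5,000 iterations, 1,000 burn-in, no thinning. A seed is
mandatory — there is no silent default — and a fixed seed gives
bit-identical draws. Convergence is monitored with the split-\(\hat R\)
potential scale reduction statistic; any parameter above the threshold
(default 1.1) triggers a warning and a `converged = FALSE` flag in the
diagnostics, never a silent pass. \(\hat R\) estimates below 1, which can
only arise from Monte-Carlo noise, are floored at 1. Latent usages are
*not* truncated to \([0, 100]\) beyond their observation interval (the
bounds already lie there); predictions are clipped to \([0, 100]\) only
at report time, with the number of clipped summaries recorded.

Degenerate inputs are handled explicitly: all-zero-width data reduce the
model exactly to its uncensored counterpart (this is tested against an
independent REML fit); a zero total for a (country, variable, year) cell
yields an undefined-usage record that is logged and excluded from
modelling; countries with missing years are fitted on their available
years, and the all-country endpoint means average over the countries in
the model.

## The synthetic-data generator

`generate_world()` and `generate_panel()` create FAO-style worlds with
known ground truth so the whole pipeline, including parameter recovery,
is testable without any download. Country intercepts and slopes are drawn
from the bivariate normal the trend model assumes; yearly compositional
jitter is added; and crop-level values are built compositionally: shares
for the native / foreign / unspecified classes are fixed first, then
spread across crops with symmetric Dirichlet weights.

Two design choices deserve explanation. First, the origin-unspecified
mass is placed *symmetrically* around the true usage \(y\): the foreign
attributed share is \(y/100 - u/2\) and the unspecified share is \(u\),
so the recovered interval is \([y - 50u,\ y + 50u]\) — width
\(100u\) exactly, with the truth at the midpoint. An asymmetric
construction (truth at one bound) would build a known bias of \(50u\)
into every recovery experiment; centring makes coverage statements about
the true slope meaningful. Second, region assignments are drawn
coverage-first — every region that hosts a country receives at least one
native crop while attributed crops last — and redrawn until every country
has both a native and a foreign attributed crop, keeping the spec's
multi-origin and two-region fractions exact. Trajectories are clipped to
the feasible band \([50u, 100 - 50u]\), with clip events counted.

Default generator conditions (62% mean usage at the origin, +0.12
percentage points per year mean slope, between-country standard
deviations of 18 and 0.05, correlation −0.5, jitter 2 points,
unspecified share 7%) are the package's standing study conditions,
chosen once to be realistic for national food-supply panels.

What the generator does *not* emulate: real FAO magnitudes per crop,
reporting gaps and revisions, correlated measurement error across
variables, and non-linear usage histories. Passing tests therefore
demonstrate the correctness of the arithmetic and the sampler under the
model's own assumptions, not the fidelity of FAO data.

## Validation performed by the test suite

The suite (and nothing else) establishes these empirical facts, at these
problem sizes:

- the printed Mexico calorie example (total 2400.3, native 1163.7,
  unspecified 174.7 kcal capita⁻¹ d⁻¹) reproduces max 51.5% / min 44.2%
  at one decimal;
- on a 25-country × 30-year zero-width panel the censored fit matches an
  independent uncensored mixed-model fit within 3 Monte-Carlo standard
  errors;
- over 20 replicates of a 30-country × 49-year world with true global
  slope +0.12, the 95% credible interval covers the truth in at least
  80% of replicates;
- `split` linkage matrices conserve regional aggregates to 1e-9 relative
  on 50 random worlds;
- jitter-free generation round-trips through the usage pipeline to 1e-9;
- split-\(\hat R\) is exactly 1 on identical chains and within 0.05 of 1
  on i.i.d. draws split into chains.

These sizes are the package's validation conditions; larger runs behave
identically, only more slowly.

## Worked example

```{r example, eval = FALSE}
sp <- miniworld_spec()                   # 5 regions, 8 countries, 12 crops
world <- generate_world(sp)
panel <- generate_panel(world)
usage <- usage_table(panel, world$crop_map, world$country_map)

fit <- fit_usage_trend(usage, chains = 3, iter = 5000, burnin = 1000,
                       seed = 1)
print(fit)
summary(fit)
plot(fit)

m <- linkage_matrix(panel, "calories", 2009:2011, world$crop_map,
                    world$country_map, world$population, "split")
plot(filter_top_links(m, 75))
```

## Known limitations

- The crop-to-region origin map is an input, not a computation: the
  package takes the literature-based assignment as authoritative and
  propagates none of its uncertainty.
- FAO measurement error on the panel values themselves is out of scope;
  the only uncertainty modelled is the origin-unspecified interval.
- The trend model is linear in time with Normal errors; no alternative
  likelihoods, year effects in the level model, model comparison, or
  spatial correlation between countries.
- `duplicate` attribution intentionally violates conservation; any
  analysis summing its columns must expect overcounting.
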