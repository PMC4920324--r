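#' Specification of a synthetic FAO-style world
#'
#' Describes a world with known ground truth for end-to-end validation:
#' regions, countries (some spanning two regions), crops (some with several
#' primary regions of diversity, some with unattributable origin), and a
#' linear per-country trajectory of true foreign-crop usage. Defaults mirror
#' the structure of the historical food-supply panels: 23 regions, a
#' 1961-2009 span, a global mean usage near 62% at the origin rising about
#' 0.12 percentage points per year, substantial between-country spread, a
#' negative intercept-slope correlation (high-usage countries trend more
#' weakly), and a mid-single-digit share of origin-unspecified commodities.
#'
#' @param n_regions number of regions (23 uses the canonical names).
#' @param n_countries number of countries.
#' @param two_region_frac fraction of countries assigned to two regions.
#' @param n_crops number of crop commodities.
#' @param multi_origin_frac fraction of origin-attributed crops listed in
#'   two regions.
#' @param not_specified_frac fraction of crops with unattributable origin.
#' @param years integer vector of panel years.
#' @param mu_intercept,mu_slope mean true usage at the first year (percent)
#'   and mean slope (percentage points per year).
#' @param sd_intercept,sd_slope between-country standard deviations.
#' @param cor_is correlation between country intercepts and slopes.
#' @param noise_sd standard deviation of yearly compositional jitter on the
#'   true trajectory (percentage points).
#' @param unspecified_share share of each country's total carried by
#'   origin-unspecified commodities (fraction of total; this is the usage
#'   interval width / 100).
#' @param total_supply range the per-country supply totals are drawn from
#'   (kcal per capita per day for the default calories variable).
#' @param dirichlet_conc symmetric Dirichlet concentration used to spread
#'   each origin class's mass across its crops.
#' @param variable canonical variable the panel reports.
#' @param seed integer seed; required.
#' @return validated `world_spec` object (a list).
#' @export
world_spec <- function(n_regions = 23, n_countries = 30,
                       two_region_frac = 0.2, n_crops = 40,
                       multi_origin_frac = 0.3, not_specified_frac = 0.15,
                       years = 1961:2009, mu_intercept = 62,
                       mu_slope = 0.12, sd_intercept = 18, sd_slope = 0.05,
                       cor_is = -0.5, noise_sd = 2,
                       unspecified_share = 0.07,
                       total_supply = c(1800, 3500), dirichlet_conc = 1,
                       variable = "calories", seed) {
  if (missing(seed)) stop("seed is required")
  spec <- list(n_regions = n_regions, n_countries = n_countries,
               two_region_frac = two_region_frac, n_crops = n_crops,
               multi_origin_frac = multi_origin_frac,
               not_specified_frac = not_specified_frac, years = years,
               mu_intercept = mu_intercept, mu_slope = mu_slope,
               sd_intercept = sd_intercept, sd_slope = sd_slope,
               cor_is = cor_is, noise_sd = noise_sd,
               unspecified_share = unspecified_share,
               total_supply = total_supply,
               dirichlet_conc = dirichlet_conc, variable = variable,
               seed = as.integer(seed))
  if (n_crops < 2) stop("infeasible spec: need at least 2 crops")
  if (n_regions < 2) stop("infeasible spec: need at least 2 regions")
  fr <- c(two_region_frac, multi_origin_frac, not_specified_frac,
          unspecified_share)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(cor_is) > 1) stop("|cor_is| must be <= 1")
  if (unspecified_share > 0 && round(not_specified_frac * n_crops) < 1) {
    stop("unspecified_share > 0 needs at least one not-specified crop")
  }
  if (!variable %in% ALL_VARS) stop("unknown variable: ", variable)
  class(spec) <- "world_spec"
  spec
}

#' Generate a synthetic world with known ground truth
#'
#' Builds the region list, country-region and crop-region maps, population
#' table, and the ground-truth usage trajectories. Country intercepts and
#' slopes are drawn from the bivariate normal the trend model assumes; the
#' per-year true usage adds the compositional jitter and is clipped to the
#' feasible band implied by the unspecified share (clip events are counted
#' in the ground truth). Every country is guaranteed at least one native
#' and one foreign origin-attributed crop. Deterministic under the spec
#' seed.
#'
#' @param spec a [world_spec()].
#' @return a list with elements `crop_map`, `country_map`, `population`,
#'   `truth` (per-country `intercept`, `slope`; per country-year matrix
#'   `usage` of true usage; realized `global_slope`; `n_clipped`), `weights`
#'   (per-country crop allocation), and `spec`.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  regions <- if (spec$n_regions == 23) canonical_regions() else
    sprintf("Region %02d", seq_len(spec$n_regions))
  countries <- sprintf("Country%03d", seq_len(spec$n_countries))
  crops <- sprintf("Crop%03d", seq_len(spec$n_crops))

  ## crops -> origin regions or not specified
  n_ns <- round(spec$not_specified_frac * spec$n_crops)
  ns_crops <- if (n_ns > 0) utils::tail(crops, n_ns) else character(0)
  attributed <- setdiff(crops, ns_crops)
  n_multi <- round(spec$multi_origin_frac * length(attributed))

  ## draw region assignments until every country has at least one native
  ## and one foreign attributed crop. Crop origins are assigned
  ## coverage-first: every region that hosts a country receives a native
  ## crop while attributed crops last, which keeps the spec's multi-origin
  ## and two-region fractions exact; the residual foreign-crop condition
  ## is checked and the draw repeated if violated.
  is_multi <- seq_along(attributed) <= n_multi
  feasible <- FALSE
  for (attempt in 1:50) {
    ctry_regions <- lapply(seq_len(spec$n_countries), function(i) {
      k <- if (stats::runif(1) < spec$two_region_frac) 2 else 1
      sample(regions, k)
    })
    used <- unique(unlist(ctry_regions))
    perm <- sample(seq_along(attributed))
    cover <- sample(used)
    crop_regions <- vector("list", length(attributed))
    for (j in seq_along(perm)) {
      i <- perm[j]
      first <- if (j <= length(cover)) cover[j] else sample(regions, 1)
      crop_regions[[i]] <- if (is_multi[i]) {
        c(first, sample(setdiff(regions, first), 1))
      } else first
    }
    names(crop_regions) <- attributed
    ok <- vapply(seq_len(spec$n_countries), function(i) {
      native <- vapply(crop_regions, function(r)
        length(intersect(r, ctry_regions[[i]])) > 0, logical(1))
      any(native) && !all(native)
    }, logical(1))
    if (all(ok)) { feasible <- TRUE; break }
  }
  if (!feasible) {
    stop("infeasible spec: could not give every country both a native and ",
         "a foreign attributed crop")
  }

  country_map <- data.frame(
    country = rep(countries, lengths(ctry_regions)),
    region = unlist(ctry_regions), stringsAsFactors = FALSE)
  crop_map_df <- rbind(
    data.frame(crop = rep(attributed, lengths(crop_regions)),
               region = unlist(crop_regions), stringsAsFactors = FALSE),
    if (length(ns_crops))
      data.frame(crop = ns_crops, region = "not specified",
                 stringsAsFactors = FALSE))
  crop_map <- load_crop_regions(crop_map_df, regions = regions)
  country_map <- load_country_regions(country_map, regions = regions)

  ## population: lognormal base, 1.5% yearly growth
  base <- exp(stats::rnorm(spec$n_countries, log(1e7), 1))
  tt <- spec$years - spec$years[1]
  population <- data.frame(
    country = rep(countries, each = length(spec$years)),
    year = rep(spec$years, spec$n_countries),
    population = round(rep(base, each = length(tt)) * 1.015^rep(tt,
                                                 spec$n_countries)))

  ## ground-truth trajectories
  z1 <- stats::rnorm(spec$n_countries)
  z2 <- stats::rnorm(spec$n_countries)
  intercept <- spec$mu_intercept + spec$sd_intercept * z1
  slope <- spec$mu_slope + spec$sd_slope *
    (spec$cor_is * z1 + sqrt(1 - spec$cor_is^2) * z2)
  u <- spec$unspecified_share
  lo <- 50 * u
  hi <- 100 - 50 * u
  usage <- outer(intercept, rep(1, length(tt))) +
    outer(slope, tt) +
    matrix(stats::rnorm(spec$n_countries * length(tt), 0, spec$noise_sd),
           spec$n_countries)
  n_clipped <- sum(usage < lo | usage > hi)
  usage <- pmin(pmax(usage, lo), hi)
  dimnames(usage) <- list(countries, spec$years)

  ## per-country totals and crop allocation weights (symmetric Dirichlet
  ## within each origin class), fixed across years
  totals <- stats::runif(spec$n_countries, spec$total_supply[1],
                         spec$total_supply[2])
  names(totals) <- countries
  weights <- lapply(seq_len(spec$n_countries), function(i) {
    cls <- classify_crop(crops, countries[i], crop_map, country_map)
    w <- stats::rgamma(spec$n_crops, spec$dirichlet_conc)
    lapply(c(native = "native", foreign = "foreign",
             unspecified = "unspecified"), function(cl) {
      sel <- cls == cl
      if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(w[sel] / sum(w[sel]), crops[sel])
    })
  })
  names(weights) <- countries

  list(crop_map = crop_map, country_map = country_map,
       population = population,
       truth = list(intercept = stats::setNames(intercept, countries),
                    slope = stats::setNames(slope, countries),
                    usage = usage,
                    global_slope = mean(slope),
                    n_clipped = n_clipped),
       totals = totals, weights = weights, regions = regions, spec = spec)
}

#' Generate the food panel of a synthetic world
#'
#' Converts the ground-truth trajectories to crop-level values by a
#' compositional construction: for each country-year the origin-unspecified
#' mass is `unspecified_share` of the total and is placed symmetrically
#' around the true usage, so the usage interval recovered by
#' [usage_table()] has width `100 * unspecified_share` exactly and is
#' centred on the truth; with zero unspecified share and zero jitter the
#' recovered interval collapses onto the true trajectory. Within each
#' origin class the mass is spread across crops by the world's Dirichlet
#' weights. Deterministic given the world (all randomness lives in
#' [generate_world()]).
#'
#' @param world output of [generate_world()].
#' @param variable canonical variable name (default: the spec's).
#' @return a validated food panel.
#' @export
generate_panel <- function(world, variable = world$spec$variable) {
  spec <- world$spec
  u <- spec$unspecified_share
  rows <- vector("list", spec$n_countries)
  countries <- names(world$totals)
  for (i in seq_len(spec$n_countries)) {
    ct <- countries[i]
    T_c <- world$totals[[ct]]
    y <- world$truth$usage[ct, ]      # true usage per year, percent
    U <- u * T_c
    FF <- (y / 100 - u / 2) * T_c     # foreign attributed mass
    NN <- T_c - U - FF                # native mass
    w <- world$weights[[ct]]
    blocks <- list(native = NN, foreign = FF, unspecified = rep(U,
                                                                length(y)))
    pieces <- lapply(names(blocks), function(cl) {
      wk <- w[[cl]]
      if (!length(wk)) return(NULL)
      vals <- outer(blocks[[cl]], wk)   # years x crops
      data.frame(country = ct,
                 commodity = rep(names(wk), each = length(y)),
                 variable = variable,
                 year = rep(spec$years, length(wk)),
                 value = as.numeric(vals), stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, pieces)
  }
  panel <- do.call(rbind, rows)
  panel <- panel[panel$value > 0 | TRUE, , drop = FALSE]  # keep zeros explicit
  rownames(panel) <- NULL
  validate_panel(panel)
}

#' The packaged mini-world
#'
#' A small pseudo-FAO fixture (5 regions, 8 countries, 12 crops,
#' 1961-2011) used in examples and tests. The spec ships as a YAML file;
#' the world and panel are regenerated deterministically from its seed.
#'
#' @return a `world_spec`.
#' @export
miniworld_spec <- function() {
  path <- system.file("extdata", "miniworld.yaml", package = "cropuse")
  y <- yaml::read_yaml(path)
  y$years <- y$year_first:y$year_last
  y$year_first <- y$year_last <- NULL
  y$total_supply <- as.numeric(y$total_supply)
  do.call(world_spec, y)
}
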