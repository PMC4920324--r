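# Fixtures built in code: the printed Mexico calorie example and small
# hand-checkable maps/panels.

mexico_panel <- function(year = 2010) {
  data.frame(
    country = "Mexico",
    commodity = c("maize", "wheat", "sugar cane", "fruits, other"),
    variable = "calories",
    year = year,
    value = c(1163.7, 800.0, 261.9, 174.7),
    stringsAsFactors = FALSE)
}

mexico_crop_map <- function() {
  load_crop_regions(data.frame(
    crop = c("maize", "wheat", "wheat", "wheat", "sugar cane",
             "fruits, other"),
    region = c("Central America and Mexico", "Central Asia", "West Asia",
               "South and East Mediterranean", "South Asia",
               "not specified"),
    stringsAsFactors = FALSE))
}

mexico_country_map <- function() {
  load_country_regions(data.frame(
    country = "Mexico", region = "Central America and Mexico",
    stringsAsFactors = FALSE))
}

# A tiny two-region toy world used across unit tests.
toy_maps <- function() {
  regions <- c("Region A", "Region B")
  crop_map <- load_crop_regions(data.frame(
    crop = c("alpha", "beta", "gamma", "gamma", "mystery"),
    region = c("Region A", "Region B", "Region A", "Region B",
               "not specified")), regions = regions)
  country_map <- load_country_regions(data.frame(
    country = c("Aland", "Bland", "Border"),
    region = c("Region A", "Region B", "Region A")), regions = regions)
  list(crop_map = crop_map, country_map = country_map, regions = regions)
}

# Brute-force usage oracle: classifies crop by crop with plain set
# operations and re-sums, independently of usage_interval's internals.
brute_usage <- function(panel, country, variable, year, crop_map,
                        country_map) {
  sub <- panel[panel$country == country & panel$variable == variable &
                 panel$year == year, ]
  ctry_reg <- country_map$region[country_map$country == country]
  total <- 0; native <- 0; unspec <- 0
  for (i in seq_len(nrow(sub))) {
    total <- total + sub$value[i]
    rows <- crop_map$crop == sub$commodity[i]
    if (any(crop_map$not_specified[rows])) {
      unspec <- unspec + sub$value[i]
    } else if (length(intersect(crop_map$region[rows], ctry_reg)) > 0) {
      native <- native + sub$value[i]
    }
  }
  mx <- 100 * (1 - native / total)
  c(min_use = mx - 100 * unspec / total, max_use = mx)
}

random_panel <- function(n_commodities = 20, countries = "X",
                         variables = "calories", years = 2000,
                         seed = 1) {
  set.seed(seed)
  g <- expand.grid(commodity = sprintf("c%02d", seq_len(n_commodities)),
                   country = countries, variable = variables, year = years,
                   stringsAsFactors = FALSE)
  g$value <- round(stats::runif(nrow(g), 0, 500), 3)
  g[, c("country", "commodity", "variable", "year", "value")]
}
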