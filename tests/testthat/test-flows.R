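toy_flow_world <- function(seed = 1, n_regions = 4, n_countries = 6,
                           n_crops = 10, years = 2009:2011) {
  generate_world(world_spec(n_regions = n_regions,
                            n_countries = n_countries, n_crops = n_crops,
                            years = years, noise_sd = 1,
                            not_specified_frac = 0.2,
                            unspecified_share = 0.05, seed = seed))
}

test_that("regional aggregates weight supply by population and sum production", {
  tm <- toy_maps()
  pop <- data.frame(country = rep(c("Aland", "Border"), each = 1),
                    year = 2000, population = c(2e6, 2e6))
  panel <- data.frame(country = c("Aland", "Border"), commodity = "alpha",
                      variable = "calories", year = 2000,
                      value = c(100, 200))
  # equal populations: symmetric mean
  agg <- regional_aggregate(panel, "Region A", "calories", 2000, pop,
                            tm$country_map)
  expect_equal(agg$value, 150)

  # one-country region passes the national value through
  one <- regional_aggregate(panel[panel$country == "Aland", ], "Region A",
                            "calories", 2000,
                            pop[pop$country == "Aland", ], tm$country_map)
  expect_equal(one$value, 100)

  # production sums
  prod <- panel; prod$variable <- "production_quantity"
  aggp <- regional_aggregate(prod, "Region A", "production_quantity", 2000,
                             pop, tm$country_map)
  expect_equal(aggp$value, 300)

  # three-country region against a hand-rolled weighted mean
  set.seed(5)
  cm3 <- load_country_regions(data.frame(country = c("u", "v", "w"),
                                         region = "Region A"),
                              regions = "Region A")
  vals <- runif(3, 50, 150); pops <- runif(3, 1e5, 1e7)
  p3 <- data.frame(country = c("u", "v", "w"), commodity = "alpha",
                   variable = "calories", year = 2000, value = vals)
  pop3 <- data.frame(country = c("u", "v", "w"), year = 2000,
                     population = pops)
  a3 <- regional_aggregate(p3, "Region A", "calories", 2000, pop3, cm3)
  expect_equal(a3$value, sum(vals * pops) / sum(pops))
  expect_gte(a3$value, min(vals))
  expect_lte(a3$value, max(vals))
})

test_that("split attribution conserves regional aggregates; duplicate credits all origins", {
  w <- toy_flow_world(seed = 31)
  panel <- generate_panel(w)
  window <- 2009:2011
  m <- linkage_matrix(panel, "calories", window, w$crop_map, w$country_map,
                      w$population, attribution = "split")
  for (r in colnames(m)) {
    agg <- regional_aggregate(panel, r, "calories", window, w$population,
                              w$country_map)
    expect_equal(sum(m[, r]), agg$value, tolerance = 1e-9)
  }
  expect_true(attr(m, "conserves"))

  # duplicate mode credits the full value to every origin of a crop
  cm <- load_crop_regions(data.frame(crop = c("two", "two"),
                                     region = c("Region A", "Region B")),
                          regions = c("Region A", "Region B"))
  ctm <- load_country_regions(data.frame(country = "X", region = "Region A"),
                              regions = c("Region A", "Region B"))
  p1 <- data.frame(country = "X", commodity = "two",
                   variable = "production_quantity", year = 2000, value = 10)
  md <- linkage_matrix(p1, "production_quantity", 2000, cm, ctm,
                       data.frame(country = "X", year = 2000,
                                  population = 1e6),
                       attribution = "duplicate")
  expect_equal(md["Region A", "Region A"], 10)
  expect_equal(md["Region B", "Region A"], 10)
  expect_false(attr(md, "conserves"))
  ms <- linkage_matrix(p1, "production_quantity", 2000, cm, ctm,
                       data.frame(country = "X", year = 2000,
                                  population = 1e6),
                       attribution = "split")
  expect_equal(ms["Region A", "Region A"], 5)

  # with only single-origin crops the two modes coincide
  w1 <- generate_world(world_spec(n_regions = 4, n_countries = 5,
                                  n_crops = 8, multi_origin_frac = 0,
                                  not_specified_frac = 0,
                                  unspecified_share = 0, years = 2010,
                                  seed = 17))
  p2 <- generate_panel(w1)
  a <- linkage_matrix(p2, "calories", 2010, w1$crop_map, w1$country_map,
                      w1$population, "split")
  b <- linkage_matrix(p2, "calories", 2010, w1$crop_map, w1$country_map,
                      w1$population, "duplicate")
  expect_equal(unclass(a)[, ], unclass(b)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("origin row sums give each region's contribution to global supply", {
  # under split attribution, summing flows from origin r over consumers
  # equals r's total attributed contribution, and the grand total equals
  # the sum of regional aggregates
  w <- toy_flow_world(seed = 77)
  panel <- generate_panel(w)
  m <- linkage_matrix(panel, "calories", 2009:2011, w$crop_map,
                      w$country_map, w$population, "split")
  aggs <- vapply(colnames(m), function(r) {
    regional_aggregate(panel, r, "calories", 2009:2011, w$population,
                       w$country_map)$value
  }, numeric(1))
  expect_equal(sum(m), sum(aggs), tolerance = 1e-9)
  expect_true(all(m >= 0))
})

test_that("percentile filtering keeps top links with ties retained", {
  w <- toy_flow_world(seed = 53)
  panel <- generate_panel(w)
  m <- linkage_matrix(panel, "calories", 2009:2011, w$crop_map,
                      w$country_map, w$population, "split")

  expect_equal(unclass(filter_top_links(m, 0))[, ], unclass(m)[, ],
               ignore_attr = TRUE)

  f <- filter_top_links(m, 95)
  ranked <- m[rownames(m) != "not specified", ]
  pos <- ranked[ranked > 0]
  thr <- as.numeric(quantile(pos, 0.95))
  # brute-force filter: every retained entry >= threshold, zeroed < thr
  fr <- f[rownames(f) != "not specified", ]
  expect_true(all(fr[fr > 0] >= thr))
  expect_equal(fr[ranked >= thr], ranked[ranked >= thr],
               ignore_attr = TRUE)
  expect_true(all(fr[ranked < thr] == 0))
  # the unspecified row is untouched
  expect_equal(f["not specified", ], m["not specified", ])
  expect_equal(attr(f, "threshold"), thr)

  # 100 equal entries: all are at the 95th percentile, all retained
  eq <- matrix(1, 10, 10,
               dimnames = list(origin = paste0("r", 1:10),
                               consumer = paste0("r", 1:10)))
  class(eq) <- c("linkage_matrix", "matrix")
  feq <- filter_top_links(eq, 95)
  expect_true(all(feq == 1))

  expect_error(filter_top_links(m, 100), "percentile")
  z <- m; z[] <- 0
  expect_error(filter_top_links(z, 95), "empty")
})

test_that("linkage matrices round-trip through the CSV writer with metadata", {
  w <- toy_flow_world(seed = 3)
  panel <- generate_panel(w)
  m <- linkage_matrix(panel, "calories", 2009:2011, w$crop_map,
                      w$country_map, w$population, "split")
  path <- withr::local_tempfile(fileext = ".csv")
  write_linkage(m, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$origin, rownames(m))
  expect_equal(as.matrix(back[, -1]), unclass(m)[, ], ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$variable, "calories")
  expect_equal(meta$mode, "split")
  expect_true(meta$conserves)
})
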