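test_that("crop classification follows the inclusive region-overlap rule", {
  cm <- mexico_crop_map()
  ct <- mexico_country_map()
  # wheat's regions (Central Asia / West Asia / S+E Mediterranean) do not
  # touch Central America and Mexico
  expect_equal(classify_crop("wheat", "Mexico", cm, ct), "foreign")
  expect_equal(classify_crop("maize", "Mexico", cm, ct), "native")
  expect_equal(classify_crop("fruits, other", "Mexico", cm, ct),
               "unspecified")
  expect_error(classify_crop("durian", "Mexico", cm, ct), "not in crop")
  expect_error(classify_crop("maize", "Narnia", cm, ct), "not in country")

  # multi-region country: ANY overlap makes a crop native
  tm <- toy_maps()
  two <- load_country_regions(data.frame(country = "Wide",
                                         region = c("Region A", "Region B")),
                              regions = tm$regions)
  expect_equal(classify_crop("beta", "Wide", tm$crop_map, two), "native")
})

test_that("the Mexico calorie interval reproduces the printed worked example", {
  iv <- usage_interval(mexico_panel(), "Mexico", "calories", 2010,
                       mexico_crop_map(), mexico_country_map())
  expect_equal(iv$total, 2400.3)
  expect_equal(iv$native, 1163.7)
  expect_equal(iv$unspecified, 174.7)
  expect_equal(round(100 * iv$native / iv$total, 1), 48.5)
  expect_equal(round(iv$max_use, 1), 51.5)
  expect_equal(round(100 * iv$unspecified / iv$total, 1), 7.3)
  expect_equal(round(iv$min_use, 1), 44.2)
})

test_that("usage interval bounds behave at the extremes", {
  tm <- toy_maps()
  all_native <- data.frame(country = "Aland", commodity = c("alpha", "gamma"),
                           variable = "calories", year = 2000,
                           value = c(100, 50))
  iv <- usage_interval(all_native, "Aland", "calories", 2000, tm$crop_map,
                       tm$country_map)
  expect_equal(iv$min_use, 0)
  expect_equal(iv$max_use, 0)

  all_unspec <- data.frame(country = "Aland", commodity = "mystery",
                           variable = "calories", year = 2000, value = 100)
  iv2 <- usage_interval(all_unspec, "Aland", "calories", 2000, tm$crop_map,
                        tm$country_map)
  expect_equal(iv2$min_use, 0)
  expect_equal(iv2$max_use, 100)

  zero <- all_native; zero$value <- 0
  expect_warning(
    iv3 <- usage_interval(zero, "Aland", "calories", 2000, tm$crop_map,
                          tm$country_map), "undefined")
  expect_true(iv3$undefined)
})

test_that("usage interval equals a brute-force per-crop enumeration", {
  tm <- toy_maps()
  set.seed(15)
  crops <- sprintf("rc%02d", 1:15)
  cm <- load_crop_regions(data.frame(
    crop = crops,
    region = sample(c("Region A", "Region B", "not specified"), 15,
                    replace = TRUE)), regions = tm$regions)
  panel <- data.frame(country = "Bland", commodity = crops,
                      variable = "calories", year = 2000,
                      value = round(runif(15, 1, 300), 2))
  iv <- usage_interval(panel, "Bland", "calories", 2000, cm, tm$country_map)
  oracle <- brute_usage(panel, "Bland", "calories", 2000, cm,
                        tm$country_map)
  expect_equal(iv$min_use, unname(oracle["min_use"]))
  expect_equal(iv$max_use, unname(oracle["max_use"]))
})

test_that("yearly series matches per-year calls and reports gaps", {
  tm <- toy_maps()
  base <- data.frame(country = "Aland", commodity = c("alpha", "beta"),
                     variable = "calories", value = c(60, 40))
  panel <- do.call(rbind, lapply(2000:2002, function(y) {
    d <- base; d$year <- y; d
  }))
  ser <- usage_interval_series(panel, "Aland", "calories", 2000:2002,
                               tm$crop_map, tm$country_map)
  expect_equal(nrow(ser), 3)
  expect_equal(length(unique(ser$max_use)), 1)

  # per-year single calls agree element-wise on a trending panel
  trend <- panel
  trend$value <- trend$value * (1 + 0.1 * (trend$year - 2000)) *
    ifelse(trend$commodity == "beta", 2, 1)
  ser2 <- usage_interval_series(trend, "Aland", "calories", 2000:2002,
                                tm$crop_map, tm$country_map)
  for (i in seq_len(nrow(ser2))) {
    one <- usage_interval(trend, "Aland", "calories", ser2$year[i],
                          tm$crop_map, tm$country_map)
    expect_equal(ser2$max_use[i], one$max_use)
    expect_equal(ser2$min_use[i], one$min_use)
  }

  # a zero-total year becomes a logged gap, not a row
  gap <- panel[panel$year != 2001, ]
  ser3 <- usage_interval_series(gap, "Aland", "calories", 2000:2002,
                                tm$crop_map, tm$country_map)
  expect_equal(nrow(ser3), 2)
  expect_equal(attr(ser3, "gaps"), 2001)
  expect_error(usage_interval_series(panel, "Aland", "calories",
                                     integer(0), tm$crop_map,
                                     tm$country_map), "empty")
})

test_that("adding crops moves the bounds in the documented directions", {
  tm <- toy_maps()
  panel <- data.frame(country = "Aland",
                      commodity = c("alpha", "beta", "mystery"),
                      variable = "calories", year = 2000,
                      value = c(50, 30, 20))
  iv0 <- usage_interval(panel, "Aland", "calories", 2000, tm$crop_map,
                        tm$country_map)

  # native addition strictly decreases max_use
  more_native <- rbind(panel, data.frame(country = "Aland",
                                         commodity = "gamma",
                                         variable = "calories", year = 2000,
                                         value = 25))
  iv1 <- usage_interval(more_native, "Aland", "calories", 2000, tm$crop_map,
                        tm$country_map)
  expect_lt(iv1$max_use, iv0$max_use)

  # foreign specified addition strictly increases both bounds
  cm2 <- load_crop_regions(rbind(tm$crop_map[, c("crop", "region")],
                                 data.frame(crop = "delta",
                                            region = "Region B")),
                           regions = tm$regions)
  more_foreign <- rbind(panel, data.frame(country = "Aland",
                                          commodity = "delta",
                                          variable = "calories", year = 2000,
                                          value = 25))
  iv2 <- usage_interval(more_foreign, "Aland", "calories", 2000, cm2,
                        tm$country_map)
  expect_gt(iv2$max_use, iv0$max_use)
  expect_gt(iv2$min_use, iv0$min_use)

  # reclassifying the unspecified crop as native: min unchanged, max drops
  # by exactly its share
  cm3 <- load_crop_regions(data.frame(
    crop = c("alpha", "beta", "gamma", "gamma", "mystery"),
    region = c("Region A", "Region B", "Region A", "Region B", "Region A")),
    regions = tm$regions)
  iv3 <- usage_interval(panel, "Aland", "calories", 2000, cm3,
                        tm$country_map)
  expect_equal(iv3$min_use, iv0$min_use)
  expect_equal(iv0$max_use - iv3$max_use, 100 * 20 / iv0$total)

  # interval width is exactly the unspecified share
  expect_equal(iv0$max_use - iv0$min_use,
               100 * iv0$unspecified / iv0$total)
})

test_that("usage_table agrees with cell-by-cell usage_interval", {
  tm <- toy_maps()
  set.seed(22)
  panel <- random_panel(5, countries = c("Aland", "Bland"),
                        variables = c("calories", "protein"),
                        years = 2000:2001, seed = 22)
  cm <- load_crop_regions(data.frame(
    crop = sprintf("c%02d", 1:5),
    region = c("Region A", "Region B", "Region A", "not specified",
               "Region B")), regions = tm$regions)
  tab <- usage_table(panel, cm, tm$country_map)
  expect_equal(nrow(tab), 8)
  for (i in seq_len(nrow(tab))) {
    one <- usage_interval(panel, tab$country[i], tab$variable[i],
                          tab$year[i], cm, tm$country_map)
    expect_equal(tab$min_use[i], one$min_use)
    expect_equal(tab$max_use[i], one$max_use)
  }
})
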