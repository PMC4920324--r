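#' Classify a crop as native, foreign or unspecified for a country
#'
#' A crop is native to a country when the set of its primary regions of
#' diversity intersects the set of regions the country belongs to (the
#' inclusive rule: any overlap at all counts). A crop whose origin cannot
#' be attributed is `unspecified`; everything else is `foreign`.
#'
#' @param crop character vector of crop labels.
#' @param country single country label.
#' @param crop_map crop-region map (see [load_crop_regions()]).
#' @param country_map country-region map (see [load_country_regions()]).
#' @return character vector in `c("native", "foreign", "unspecified")`.
#' @export
classify_crop <- function(crop, country, crop_map, country_map) {
  cm_crop <- norm_label(crop_map$crop)
  crop_n <- norm_label(crop)
  unknown <- setdiff(unique(crop_n), cm_crop)
  if (length(unknown)) {
    stop("crop(s) not in crop-region map: ", paste(unknown, collapse = ", "))
  }
  ctry_regions <- norm_label(
    country_map$region[norm_label(country_map$country) == norm_label(country)])
  if (!length(ctry_regions)) stop("country not in country-region map: ", country)

  vapply(crop_n, function(cr) {
    rows <- cm_crop == cr
    if (any(crop_map$not_specified[rows])) return("unspecified")
    if (any(norm_label(crop_map$region[rows]) %in% ctry_regions)) "native"
    else "foreign"
  }, character(1), USE.NAMES = FALSE)
}

new_usage_interval <- function(country, variable, year, total, native,
                               unspecified, undefined = FALSE) {
  if (undefined || total <= 0) {
    out <- list(country = country, variable = variable, year = year,
                total = total, native = NA_real_, unspecified = NA_real_,
                min_use = NA_real_, max_use = NA_real_, undefined = TRUE)
  } else {
    ## clamp float dust: the accounting guarantees bounds in [0, 100]
    max_use <- min(max(100 * (1 - native / total), 0), 100)
    min_use <- min(max(max_use - 100 * unspecified / total, 0), 100)
    out <- list(country = country, variable = variable, year = year,
                total = total, native = native, unspecified = unspecified,
                min_use = min_use, max_use = max_use, undefined = FALSE)
  }
  structure(out, class = "usage_interval")
}

#' @export
print.usage_interval <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Foreign crop use, %s / %s / %d: undefined (zero total)\n",
                x$country, x$variable, x$year))
    return(invisible(x))
  }
  cat(sprintf(
    "Foreign crop use, %s / %s / %d\n  total %.1f  native %.1f (%.1f%%)  unspecified %.1f (%.1f%%)\n  minimum use %.1f%%   maximum use %.1f%%\n",
    x$country, x$variable, x$year, x$total, x$native,
    100 * x$native / x$total, x$unspecified, 100 * x$unspecified / x$total,
    x$min_use, x$max_use))
  invisible(x)
}

#' Interval-bounded foreign-crop usage for one country, variable and year
#'
#' Starts from the assumption that the whole supply/production total is
#' foreign (100%), subtracts the share contributed by crops native to the
#' country's region(s) to obtain the maximum use of foreign crops, then
#' additionally subtracts the share of origin-unspecified commodities to
#' obtain the minimum use (which treats those commodities as if they were
#' native). The truth lies in `[min_use, max_use]`; the gap equals the
#' unspecified share. Arithmetic is kept at full precision; round only when
#' reporting (the printed convention is one decimal).
#'
#' @param panel validated food panel.
#' @param country,variable,year the cell to evaluate.
#' @param crop_map,country_map origin and region maps.
#' @return a `usage_interval` object with fields `total`, `native`,
#'   `unspecified`, `min_use`, `max_use` (percent scale), or an
#'   undefined-usage record (all-`NA` bounds, `undefined = TRUE`) when the
#'   total is zero.
#' @examples
#' panel <- data.frame(
#'   country = "Mexico",
#'   commodity = c("maize", "wheat", "fruits, other"),
#'   variable = "calories", year = 2010,
#'   value = c(1163.7, 1061.9, 174.7))
#' crop_map <- load_crop_regions(data.frame(
#'   crop = c("maize", "wheat", "fruits, other"),
#'   region = c("Central America and Mexico", "West Asia", "not specified")))
#' country_map <- load_country_regions(data.frame(
#'   country = "Mexico", region = "Central America and Mexico"))
#' usage_interval(panel, "Mexico", "calories", 2010, crop_map, country_map)
#' @export
usage_interval <- function(panel, country, variable, year, crop_map,
                           country_map) {
  rows <- norm_label(panel$country) == norm_label(country) &
    panel$variable == variable & panel$year == year
  sub <- panel[rows, , drop = FALSE]
  total <- sum(sub$value)
  if (total <= 0) {
    warning("total is zero for ", country, "/", variable, "/", year,
            "; usage undefined")
    return(new_usage_interval(country, variable, year, total, NA, NA,
                              undefined = TRUE))
  }
  cls <- classify_crop(sub$commodity, country, crop_map, country_map)
  new_usage_interval(country, variable, year, total,
                     native = sum(sub$value[cls == "native"]),
                     unspecified = sum(sub$value[cls == "unspecified"]))
}

#' Yearly series of foreign-crop usage intervals
#'
#' One interval per year with a positive total; years with zero totals are
#' reported in the `gaps` attribute and excluded (they carry no usage
#' information and are dropped from modelling).
#'
#' @inheritParams usage_interval
#' @param years integer vector of years.
#' @return data frame with one row per defined year (columns `country`,
#'   `variable`, `year`, `total`, `native`, `unspecified`, `min_use`,
#'   `max_use`), with attribute `gaps` listing skipped years.
#' @export
usage_interval_series <- function(panel, country, variable, years, crop_map,
                                  country_map) {
  if (!length(years)) stop("empty year range")
  ivs <- lapply(years, function(y) {
    suppressWarnings(
      usage_interval(panel, country, variable, y, crop_map, country_map))
  })
  ok <- !vapply(ivs, `[[`, logical(1), "undefined")
  if (!any(ok)) stop("no year with positive total for ", country, "/", variable)
  out <- do.call(rbind, lapply(ivs[ok], function(iv) {
    data.frame(country = iv$country, variable = iv$variable, year = iv$year,
               total = iv$total, native = iv$native,
               unspecified = iv$unspecified, min_use = iv$min_use,
               max_use = iv$max_use, stringsAsFactors = FALSE)
  }))
  attr(out, "gaps") <- years[!ok]
  out
}

#' Foreign-crop usage table for a whole panel
#'
#' Computes the usage interval for every (country, variable, year) cell with
#' a positive total, in one vectorized pass. This is the table behind the
#' per-country supplementary outputs and the input to the interval-censored
#' models.
#'
#' @param panel validated food panel.
#' @param crop_map,country_map origin and region maps.
#' @param variables,years optional filters (default: everything present).
#' @return data frame with columns `country`, `variable`, `year`, `total`,
#'   `native`, `unspecified`, `min_use`, `max_use`; attribute `excluded`
#'   holds zero-total cells.
#' @export
usage_table <- function(panel, crop_map, country_map, variables = NULL,
                        years = NULL) {
  panel <- validate_panel(panel)
  if (!is.null(variables)) panel <- panel[panel$variable %in% variables, ]
  if (!is.null(years)) panel <- panel[panel$year %in% years, ]
  if (!nrow(panel)) stop("no panel rows left after filtering")

  ## classify each (country, commodity) pair once
  pairs <- unique(data.frame(country = panel$country,
                             commodity = panel$commodity,
                             stringsAsFactors = FALSE))
  pairs$class <- NA_character_
  for (ct in unique(pairs$country)) {
    i <- pairs$country == ct
    pairs$class[i] <- classify_crop(pairs$commodity[i], ct, crop_map,
                                    country_map)
  }
  cls <- pairs$class[match(paste(norm_label(panel$country),
                                 norm_label(panel$commodity), sep = "\r"),
                           paste(norm_label(pairs$country),
                                 norm_label(pairs$commodity), sep = "\r"))]

  cell <- interaction(panel$country, panel$variable, panel$year, drop = TRUE,
                      sep = "\r")
  total <- tapply(panel$value, cell, sum)
  native <- tapply(panel$value * (cls == "native"), cell, sum)
  unspec <- tapply(panel$value * (cls == "unspecified"), cell, sum)
  meta <- panel[!duplicated(cell), c("country", "variable", "year")]
  meta <- meta[match(names(total), as.character(cell[!duplicated(cell)])), ]

  out <- data.frame(country = meta$country, variable = meta$variable,
                    year = meta$year, total = as.numeric(total),
                    native = as.numeric(native),
                    unspecified = as.numeric(unspec),
                    stringsAsFactors = FALSE)
  defined <- out$total > 0
  excluded <- out[!defined, c("country", "variable", "year")]
  out <- out[defined, , drop = FALSE]
  out$max_use <- pmin(pmax(100 * (1 - out$native / out$total), 0), 100)
  out$min_use <- pmin(pmax(out$max_use - 100 * out$unspecified / out$total,
                           0), 100)
  out <- out[order(out$country, out$variable, out$year),
             c("country", "variable", "year", "total", "native",
               "unspecified", "min_use", "max_use")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
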