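## Canonical variable vocabulary. Per-capita food supply variables and
## absolute production variables must never be mixed in one aggregation.
SUPPLY_VARS <- c("calories", "protein", "fat", "food_weight")
PRODUCTION_VARS <- c("production_quantity", "harvested_area", "production_value")
ALL_VARS <- c(SUPPLY_VARS, PRODUCTION_VARS)

#' Normalize a country, region, commodity or crop label
#'
#' Labels are matched case-insensitively after collapsing internal whitespace
#' and trimming. No fuzzy matching is performed: a silent misjoin is worse
#' than a hard error.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
norm_label <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", as.character(x))))
}

#' Variable classes
#'
#' `supply_variables()` returns the per-capita food supply variables
#' (calories kcal/capita/day, protein g/capita/day, fat g/capita/day,
#' food weight g/capita/day); `production_variables()` the absolute
#' production variables (production quantity tonnes, harvested area ha,
#' production value million US$).
#'
#' @return character vector of canonical variable names.
#' @export
supply_variables <- function() SUPPLY_VARS

#' @rdname supply_variables
#' @export
production_variables <- function() PRODUCTION_VARS

is_supply_var <- function(v) v %in% SUPPLY_VARS

#' The canonical 23-region world
#'
#' The region scheme partitions the world into 23 ecogeographically motivated
#' regions (Europe split north/south and west/east, South America split into
#' Andean, tropical and temperate portions, Australia and New Zealand
#' separated from the tropical Pacific Islands, and so on). Countries
#' straddling a boundary belong to every region they touch; crops with
#' several primary regions of diversity are likewise listed in all of them.
#' Synthetic worlds may declare their own region list.
#'
#' @return character vector of 23 region names.
#' @export
canonical_regions <- function() {
  path <- system.file("extdata", "regions23.csv", package = "cropuse")
  utils::read.csv(path, stringsAsFactors = FALSE)$region
}

panel_key <- function(panel) {
  paste(norm_label(panel$country), norm_label(panel$commodity),
        panel$variable, panel$year, sep = "\r")
}

#' Validate a food panel
#'
#' A food panel is a long-format data frame with columns `country`,
#' `commodity`, `variable`, `year`, `value`. Values must be non-negative,
#' variables drawn from the canonical vocabulary, and the key
#' (country, commodity, variable, year) unique. Absent rows mean value 0
#' (the crop is not produced/consumed); they are never imputed.
#'
#' @param panel data frame to validate.
#' @param year_range optional inclusive integer range `c(first, last)`.
#' @return the panel, invisibly, with `year` and `value` coerced to numeric.
#' @export
validate_panel <- function(panel, year_range = NULL) {
  need <- c("country", "commodity", "variable", "year", "value")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  panel$year <- as.integer(panel$year)
  if (!is.numeric(panel$value)) {
    suppressWarnings(val <- as.numeric(panel$value))
    bad <- which(is.na(val) & !is.na(panel$value))
    if (length(bad)) {
      stop("malformed value in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    panel$value <- val
  }
  if (anyNA(panel$value)) {
    stop("missing value in row(s): ",
         paste(utils::head(which(is.na(panel$value)), 5), collapse = ", "))
  }
  neg <- which(panel$value < 0)
  if (length(neg)) {
    stop("negative value in row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(panel$variable), ALL_VARS)
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         "; expected one of: ", paste(ALL_VARS, collapse = ", "))
  }
  if (!is.null(year_range)) {
    out <- panel$year < year_range[1] | panel$year > year_range[2]
    if (any(out)) {
      stop("year outside declared span [", year_range[1], ", ", year_range[2],
           "] in row(s): ", paste(utils::head(which(out), 5), collapse = ", "))
    }
  }
  key <- panel_key(panel)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated (country, commodity, variable, year) key(s): ",
         paste(utils::head(unique(gsub("\r", " / ", key[dup])), 3), collapse = "; "))
  }
  invisible(panel)
}

#' Read a food panel from CSV
#'
#' Reads a UTF-8 long-format CSV with header columns `country`, `commodity`,
#' `variable`, `year`, `value` and validates it (non-negative values, known
#' variables, unique keys).
#'
#' @param path path to the CSV file.
#' @param year_range optional inclusive year span to enforce.
#' @return a validated food-panel data frame.
#' @export
load_panel <- function(path, year_range = NULL) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_panel(panel, year_range = year_range)
}

#' Write a food panel (or any keyed table) to CSV
#'
#' Rows are sorted by key so repeated runs produce byte-identical files.
#'
#' @param panel food-panel data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  ord <- order(panel$country, panel$commodity, panel$variable, panel$year)
  utils::write.csv(panel[ord, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Aggregate raw commodities into whole-crop categories
#'
#' FAO reports several commodities per crop species (e.g. sesame seed and
#' sesame seed oil); these are combined into a single category representing
#' the crop as a whole by summing values within
#' (country, aggregate, variable, year). Totals per (country, variable,
#' year) are conserved exactly.
#'
#' @param panel validated food panel.
#' @param map data frame with columns `commodity` (raw label) and `crop`
#'   (aggregate label); many-to-one.
#' @return aggregated food panel with `commodity` holding the aggregate
#'   labels.
#' @export
aggregate_commodities <- function(panel, map) {
  panel <- validate_panel(panel)
  if (!all(c("commodity", "crop") %in% names(map))) {
    stop("aggregation map needs columns 'commodity' and 'crop'")
  }
  idx <- match(norm_label(panel$commodity), norm_label(map$commodity))
  if (anyNA(idx)) {
    offenders <- unique(panel$commodity[is.na(idx)])
    stop("unmapped commodity(ies): ", paste(offenders, collapse = ", "))
  }
  agg <- stats::aggregate(
    list(value = panel$value),
    by = list(country = panel$country, commodity = map$crop[idx],
              variable = panel$variable, year = panel$year),
    FUN = sum)
  validate_panel(agg[order(agg$country, agg$commodity, agg$variable, agg$year), ,
                     drop = FALSE])
}

#' Merge successor states into their historical predecessor
#'
#' To align the full 1961-2011 span, countries that split during the period
#' (e.g. the states of a former union) are aggregated back into the
#' predecessor: production variables are summed per year across successors,
#' per-capita supply variables are replaced by the population-weighted mean
#' using each successor's population in the same reporting year.
#'
#' @param panel validated food panel.
#' @param merges data frame with columns `successor`, `predecessor`; each
#'   successor appears at most once.
#' @param pop population table: data frame with columns `country`, `year`,
#'   `population` (> 0).
#' @return harmonized food panel (successor rows removed, predecessor rows
#'   inserted).
#' @export
harmonize_history <- function(panel, merges, pop) {
  panel <- validate_panel(panel)
  if (!all(c("successor", "predecessor") %in% names(merges))) {
    stop("merge spec needs columns 'successor' and 'predecessor'")
  }
  if (anyDuplicated(norm_label(merges$successor))) {
    stop("successor sets must be disjoint: a successor appears twice")
  }
  succ_idx <- match(norm_label(panel$country), norm_label(merges$successor))
  affected <- !is.na(succ_idx)
  if (!any(affected)) return(panel)

  sub <- panel[affected, , drop = FALSE]
  sub$predecessor <- merges$predecessor[succ_idx[affected]]

  pop_key <- paste(norm_label(pop$country), pop$year, sep = "\r")
  w <- pop$population[match(paste(norm_label(sub$country), sub$year, sep = "\r"),
                            pop_key)]
  percap <- is_supply_var(sub$variable)
  if (any(percap & is.na(w))) {
    miss <- unique(paste0(sub$country, "/", sub$year)[percap & is.na(w)])
    stop("missing population for successor-year(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (any(percap & w[!is.na(w)] <= 0)) stop("population must be > 0")

  merge_one <- function(d) {
    if (is_supply_var(d$variable[1])) {
      sum(d$value * d$w) / sum(d$w)
    } else {
      sum(d$value)
    }
  }
  sub$w <- w
  grp <- interaction(sub$predecessor, sub$commodity, sub$variable, sub$year,
                     drop = TRUE)
  pieces <- split(sub, grp)
  merged <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(country = d$predecessor[1], commodity = d$commodity[1],
               variable = d$variable[1], year = d$year[1],
               value = merge_one(d), stringsAsFactors = FALSE)
  }))
  out <- rbind(panel[!affected, , drop = FALSE], merged)
  rownames(out) <- NULL
  validate_panel(out[order(out$country, out$commodity, out$variable, out$year), ,
                     drop = FALSE])
}

#' Read and validate a crop-to-region map
#'
#' Two-column CSV / data frame with one row per (crop, region) pair. A crop
#' whose primary regions of diversity cannot be identified (e.g. an FAO
#' catch-all commodity like "fruits, other") carries the region label
#' `"not specified"` (or an empty field) and is flagged accordingly.
#'
#' @param x path to a CSV with columns `crop`, `region`, or an equivalent
#'   data frame.
#' @param regions character vector of admissible region labels (default: the
#'   canonical 23).
#' @return data frame with columns `crop`, `region`, `not_specified`.
#' @export
load_crop_regions <- function(x, regions = canonical_regions()) {
  map <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("crop", "region") %in% names(map))) {
    stop("crop-region map needs columns 'crop' and 'region'")
  }
  reg <- norm_label(map$region)
  ns <- reg %in% c("", "na", "not specified")
  bad <- !ns & !(reg %in% norm_label(regions))
  if (any(bad)) {
    stop("unknown region(s) in crop map: ",
         paste(unique(map$region[bad]), collapse = ", "))
  }
  ## a crop is either fully specified or fully unspecified
  by_crop <- tapply(ns, norm_label(map$crop), function(z) any(z) && !all(z))
  if (any(by_crop)) {
    stop("crop(s) mix 'not specified' with real regions: ",
         paste(names(by_crop)[by_crop], collapse = ", "))
  }
  data.frame(crop = map$crop, region = ifelse(ns, "not specified", map$region),
             not_specified = ns, stringsAsFactors = FALSE)
}

#' Read and validate a country-to-region map
#'
#' One row per (country, region) pair; a country spanning several regions
#' (e.g. one assigned to both Andean and tropical South America) appears
#' once per region. Every country must have at least one region.
#'
#' @param x path to a CSV with columns `country`, `region`, or a data frame.
#' @param regions admissible region labels.
#' @return data frame with columns `country`, `region`.
#' @export
load_country_regions <- function(x, regions = canonical_regions()) {
  map <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("country", "region") %in% names(map))) {
    stop("country-region map needs columns 'country' and 'region'")
  }
  empty <- norm_label(map$region) == ""
  if (any(empty)) {
    stop("country(ies) with empty region: ",
         paste(unique(map$country[empty]), collapse = ", "))
  }
  bad <- !(norm_label(map$region) %in% norm_label(regions))
  if (any(bad)) {
    stop("unknown region(s) in country map: ",
         paste(unique(map$region[bad]), collapse = ", "))
  }
  data.frame(country = map$country, region = map$region, stringsAsFactors = FALSE)
}

#' Read and validate a population table
#'
#' @param x path to a CSV with columns `country`, `year`, `population`, or a
#'   data frame.
#' @return validated data frame.
#' @export
load_population <- function(x) {
  pop <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("country", "year", "population") %in% names(pop))) {
    stop("population table needs columns 'country', 'year', 'population'")
  }
  if (any(pop$population <= 0)) stop("population must be > 0")
  pop
}
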