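## Regional aggregation and origin-by-consumer linkage matrices.
##
## Supply variables (per capita) aggregate as population-weighted means;
## production variables as plain sums. Country values are first averaged
## over the requested year window (absent rows count 0), population weights
## are the window-mean national populations.

window_country_values <- function(panel, variable, window) {
  sub <- panel[panel$variable == variable & panel$year %in% window, ,
               drop = FALSE]
  if (!nrow(sub)) stop("no data for variable '", variable, "' in window")
  cc <- interaction(sub$country, sub$commodity, drop = TRUE, sep = "\r")
  val <- tapply(sub$value, cc, sum) / length(window)
  meta <- sub[!duplicated(cc), c("country", "commodity")]
  meta <- meta[match(names(val), as.character(cc[!duplicated(cc)])), ]
  data.frame(country = meta$country, commodity = meta$commodity,
             value = as.numeric(val), stringsAsFactors = FALSE)
}

window_population <- function(pop, countries, window) {
  sub <- pop[pop$year %in% window & norm_label(pop$country) %in%
               norm_label(countries), , drop = FALSE]
  w <- tapply(sub$population, norm_label(sub$country), mean)
  out <- as.numeric(w[norm_label(countries)])
  if (anyNA(out)) {
    stop("missing population in window for: ",
         paste(countries[is.na(out)], collapse = ", "))
  }
  out
}

region_members <- function(country_map, region) {
  unique(country_map$country[norm_label(country_map$region) ==
                               norm_label(region)])
}

#' Regional aggregate of a national variable over a year window
#'
#' Per-capita supply variables aggregate as the population-weighted average
#' of national values (each country's value first averaged over the window);
#' production variables aggregate as the sum over member countries. A
#' country belonging to several regions contributes to each of them.
#'
#' @param panel validated food panel.
#' @param region region label.
#' @param variable canonical variable name.
#' @param window integer vector of years.
#' @param pop population table.
#' @param country_map country-region map.
#' @return a one-row data frame: `region`, `variable`, `value`, `n_countries`.
#' @export
regional_aggregate <- function(panel, region, variable, window, pop,
                               country_map) {
  members <- region_members(country_map, region)
  cv <- window_country_values(panel, variable, window)
  tot <- tapply(cv$value, norm_label(cv$country), sum)
  present <- intersect(norm_label(members), names(tot))
  if (!length(present)) stop("no member country of '", region, "' has data")
  vals <- as.numeric(tot[present])
  if (is_supply_var(variable)) {
    w <- window_population(pop, present, window)
    value <- sum(vals * w) / sum(w)
  } else {
    value <- sum(vals)
  }
  data.frame(region = region, variable = variable, value = value,
             n_countries = length(present), stringsAsFactors = FALSE)
}

#' Origin-region by consuming-region linkage matrix
#'
#' The matrix behind the circular (chord) plots: entry (origin r0,
#' consumer r1) is the portion of region r1's aggregate supply/production
#' attributable to crops whose primary regions of diversity include r0.
#' An extra `"not specified"` origin row collects commodities without an
#' attributed origin.
#'
#' Crops with several origin regions are handled per `attribution`:
#' \describe{
#'   \item{`split`}{the crop's value is divided equally among its k origins,
#'     so column sums reproduce the regional aggregates exactly (the default;
#'     makes the chord diagram well defined).}
#'   \item{`duplicate`}{the full value is credited to every origin, the
#'     inclusive listing convention; column totals then overcount and the
#'     violation is flagged in the `conserves` attribute.}
#' }
#'
#' @inheritParams regional_aggregate
#' @param crop_map crop-region map.
#' @param attribution `"split"` or `"duplicate"`.
#' @return matrix with origin regions (+ `"not specified"`) as rows and
#'   consuming regions as columns; attributes `variable`, `window`, `mode`,
#'   `conserves`.
#' @export
linkage_matrix <- function(panel, variable, window, crop_map, country_map,
                           pop, attribution = c("split", "duplicate")) {
  attribution <- match.arg(attribution)
  regions <- unique(country_map$region)
  ## origin rows cover every attributed region, even ones without any
  ## member country (a crop can originate in an unconsuming region)
  origin_regions <- unique(c(regions,
                             crop_map$region[!crop_map$not_specified]))
  origins <- c(origin_regions, "not specified")
  m <- matrix(0, nrow = length(origins), ncol = length(regions),
              dimnames = list(origin = origins, consumer = regions))

  cv <- window_country_values(panel, variable, window)
  cm_crop <- norm_label(crop_map$crop)

  ## per-crop origin credit shares (split: 1/k each; duplicate: 1 each)
  origin_share <- function(crop) {
    rows <- cm_crop == norm_label(crop)
    if (!any(rows)) stop("crop not in crop-region map: ", crop)
    if (any(crop_map$not_specified[rows])) {
      return(stats::setNames(1, "not specified"))
    }
    regs <- unique(crop_map$region[rows])
    share <- if (attribution == "split") 1 / length(regs) else 1
    stats::setNames(rep(share, length(regs)), regs)
  }
  crops <- unique(cv$commodity)
  shares <- lapply(crops, origin_share)
  names(shares) <- norm_label(crops)

  o_lookup <- stats::setNames(seq_along(origins), norm_label(origins))

  for (r in seq_along(regions)) {
    members <- norm_label(region_members(country_map, regions[r]))
    sub <- cv[norm_label(cv$country) %in% members, , drop = FALSE]
    if (!nrow(sub)) next
    if (is_supply_var(variable)) {
      ctys <- unique(norm_label(sub$country))
      w <- window_population(pop, ctys, window)
      wmap <- stats::setNames(w / sum(w), ctys)
      contrib <- sub$value * wmap[norm_label(sub$country)]
    } else {
      contrib <- sub$value
    }
    for (i in seq_len(nrow(sub))) {
      sh <- shares[[norm_label(sub$commodity[i])]]
      oi <- o_lookup[norm_label(names(sh))]
      m[oi, r] <- m[oi, r] + contrib[i] * sh
    }
  }
  structure(m, variable = variable, window = window, mode = attribution,
            conserves = attribution == "split", class = c("linkage_matrix",
                                                          "matrix"))
}

#' Keep only the strongest inter-regional linkages
#'
#' Zeroes entries below the given percentile of the positive attributed
#' entries (the `"not specified"` row is excluded from the ranking but kept
#' in the matrix). Ties at the threshold are retained.
#'
#' @param m a `linkage_matrix`.
#' @param percentile percentile in `[0, 100)`; e.g. 95 keeps the top 5%.
#' @return filtered matrix; attribute `threshold` records the cutoff.
#' @export
filter_top_links <- function(m, percentile) {
  if (!length(m) || all(m == 0)) stop("empty linkage matrix")
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  ranked <- m[rownames(m) != "not specified", , drop = FALSE]
  pos <- ranked[ranked > 0]
  thr <- if (percentile == 0) 0 else
    as.numeric(stats::quantile(pos, percentile / 100))
  out <- m
  keep_rows <- rownames(m) != "not specified"
  sel <- out[keep_rows, , drop = FALSE]
  sel[sel < thr] <- 0
  out[keep_rows, ] <- sel
  attrs <- attributes(m)
  attributes(out) <- c(attributes(out)[c("dim", "dimnames")],
                       attrs[setdiff(names(attrs), c("dim", "dimnames"))])
  attr(out, "threshold") <- thr
  out
}

#' Write a linkage matrix and its metadata sidecar
#'
#' The matrix goes to `<path>` as CSV (origin rows by consumer columns); the
#' variable, window, attribution mode and any filter threshold go to a JSON
#' sidecar `<path>.json`.
#'
#' @param m a `linkage_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(m, path) {
  df <- data.frame(origin = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(variable = attr(m, "variable"),
               window = attr(m, "window"),
               mode = attr(m, "mode"),
               conserves = attr(m, "conserves"),
               threshold = attr(m, "threshold"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Basic chord rendering of a linkage matrix
#'
#' A minimal base-graphics chord diagram: regions as arcs around a circle
#' (arc length proportional to total involvement as origin plus consumer),
#' flows as shaded ribbons from origin to consumer. Convenience only; the
#' matrix is the product.
#'
#' @param x a `linkage_matrix`.
#' @param min_frac hide flows below this fraction of the grand total.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.linkage_matrix <- function(x, min_frac = 0.01, ...) {
  m <- unclass(x)
  regs <- colnames(m)
  ## involvement: outgoing (row over consumer regions) + incoming (column)
  out_tot <- rowSums(m)[regs]
  out_tot[is.na(out_tot)] <- 0
  inv <- out_tot + colSums(m)
  inv <- inv / sum(inv)
  gap <- 0.01
  width <- inv * (1 - gap * length(regs))
  start <- cumsum(c(0, utils::head(width, -1))) + gap * (seq_along(regs) - 1)
  mid <- (start + width / 2) * 2 * pi
  cols <- grDevices::hcl.colors(length(regs), "Dark 3")

  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = attr(x, "variable"))
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_along(regs)) {
    a <- seq(start[i], start[i] + width[i], length.out = 30) * 2 * pi
    graphics::lines(1.05 * cos(a), 1.05 * sin(a), lwd = 6, col = cols[i])
    graphics::text(1.18 * cos(mid[i]), 1.18 * sin(mid[i]),
                   labels = abbreviate(regs[i], 8), cex = 0.6,
                   srt = 0, col = cols[i])
  }
  total <- sum(m)
  for (i in seq_along(regs)) {
    for (j in seq_along(regs)) {
      v <- m[regs[i], regs[j]]
      if (is.na(v) || v < min_frac * total) next
      p0 <- c(cos(mid[i]), sin(mid[i]))
      p1 <- c(cos(mid[j]), sin(mid[j]))
      tt <- seq(0, 1, length.out = 50)
      ## quadratic Bezier through the centre
      bx <- (1 - tt)^2 * p0[1] + tt^2 * p1[1]
      by <- (1 - tt)^2 * p0[2] + tt^2 * p1[2]
      graphics::lines(bx, by, col = grDevices::adjustcolor(cols[i], 0.5),
                      lwd = 1 + 8 * v / max(m[regs, ]))
    }
  }
  invisible(x)
}
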