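# Daily air-quality index (AQI) against the New South Wales regulatory
# standards: sub-index per pollutant is (concentration / standard) * 100 and
# the daily AQI is the maximum sub-index across pollutants observed that day.

#' New South Wales pollutant standards
#'
#' The regulatory standard concentrations used to scale each pollutant's
#' sub-index, one row per pollutant and averaging period (CO 8-hour, NO2
#' 1-hour, ozone 1-hour and 4-hour, SO2 1-hour, PM10 and PM2.5 24-hour).
#' Concentrations arriving in [compute_daily_aqi()] are assumed to already be
#' averaged over each pollutant's own period, in the same units as the
#' standard (ppm for gases, micrograms per cubic metre for particulates).
#'
#' @return A `data.frame` with columns `pollutant`, `averaging_period`,
#'   `standard`, `units`.
#' @export
#' @examples
#' nsw_standards()
nsw_standards <- function() {
  path <- system.file("extdata", "nsw_standards.csv", package = "gtwr",
                      mustWork = TRUE)
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(std$standard > 0))
  std
}

#' Compute the daily AQI for one station-day
#'
#' The index is the maximum over pollutants present of
#' `(concentration / standard) * 100`. Pollutants missing on a day are
#' skipped; the dominant pollutant is the one attaining the maximum ratio,
#' with ties broken by the fixed order CO, NO2, O3_1h, O3_4h, SO2, PM10,
#' PM2.5.
#'
#' @param concentrations Named numeric vector of period-averaged
#'   concentrations (names from the standards table); may be a subset of the
#'   pollutants. `NA` entries are treated as missing.
#' @param standards Standards table as returned by [nsw_standards()].
#' @return An object of class `aqi_value`: a list with `value`, `status`
#'   (see [classify_status()]) and `dominant_pollutant`.
#' @export
#' @examples
#' compute_daily_aqi(c(PM2.5 = 25))  # equals the standard, AQI = 100
compute_daily_aqi <- function(concentrations, standards = nsw_standards()) {
  concentrations <- concentrations[!is.na(concentrations)]
  if (length(concentrations) == 0L) {
    stop_gtwr("no pollutant concentrations present for this day",
              class = "gtwr_missing_data")
  }
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop_gtwr("concentrations must be a named vector",
              class = "gtwr_config_error")
  }
  unknown <- setdiff(names(concentrations), standards$pollutant)
  if (length(unknown) > 0L) {
    stop_gtwr("no standard concentration for pollutant(s): ",
              paste(unknown, collapse = ", "), class = "gtwr_config_error")
  }
  if (any(concentrations < 0)) {
    stop_gtwr("negative pollutant concentration", class = "gtwr_domain_error")
  }
  ps <- standards$standard[match(names(concentrations), standards$pollutant)]
  ratio <- 100 * as.numeric(concentrations) / ps
  # tie-break by the fixed pollutant order, not input order
  ord <- order(match(names(concentrations), AQI_POLLUTANTS))
  ratio <- ratio[ord]
  nm <- names(concentrations)[ord]
  value <- max(ratio)
  structure(
    list(value = value,
         status = classify_status(value),
         dominant_pollutant = nm[which.max(ratio)]),
    class = "aqi_value")
}

#' @export
print.aqi_value <- function(x, ...) {
  cat(sprintf("AQI %.1f (%s), dominant pollutant %s\n",
              x$value, x$status, x$dominant_pollutant))
  invisible(x)
}

#' Classify an AQI value into its status band
#'
#' Band edges follow the NSW reporting scheme: 0-33 Very good, 34-66 Good,
#' 67-99 Fair, 100-149 Poor, 150-200 Very poor, above 200 Hazardous.
#' Non-integer values are classified with half-open intervals at the
#' midpoints (e.g. values below 33.5 are Very good).
#'
#' @param value Numeric AQI value(s), must be >= 0.
#' @return Character vector of band labels.
#' @export
classify_status <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop_gtwr("AQI value must be finite and non-negative",
              class = "gtwr_domain_error")
  }
  edges <- c(0, 33.5, 66.5, 99.5, 149.5, 200.5, Inf)
  AQI_STATUS_LEVELS[findInterval(value, edges, rightmost.closed = FALSE)]
}

#' Daily AQI table from long-format pollutant observations
#'
#' Convenience wrapper applying [compute_daily_aqi()] to every station-day of
#' a long table (`station_id`, `date`, `pollutant`, `value`). Station-days
#' with no valid observation are dropped.
#'
#' @param obs Long `data.frame` of period-averaged concentrations.
#' @param standards Standards table.
#' @return `data.frame` with `station_id`, `date`, `aqi`, `status`,
#'   `dominant_pollutant`.
#' @export
daily_aqi_table <- function(obs, standards = nsw_standards()) {
  stopifnot(all(c("station_id", "date", "pollutant", "value") %in% names(obs)))
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  if (nrow(obs) == 0L) {
    return(data.frame(station_id = character(), date = character(),
                      aqi = numeric(), status = character(),
                      dominant_pollutant = character()))
  }
  key <- interaction(obs$station_id, obs$date, drop = TRUE)
  rows <- lapply(split(obs, key), function(d) {
    a <- compute_daily_aqi(stats::setNames(d$value, d$pollutant), standards)
    data.frame(station_id = d$station_id[1L], date = d$date[1L],
               aqi = a$value, status = a$status,
               dominant_pollutant = a$dominant_pollutant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$station_id, out$date), , drop = FALSE]
}

#' Aggregate daily AQI values to station-months
#'
#' Monthly AQI is the arithmetic mean of the available daily values in the
#' month. Months inside a station's observed span with no valid days are
#' retained with `NA`.
#'
#' @param daily `data.frame` with `station_id`, `date` (coercible with
#'   [as.Date()]) and `aqi` columns, e.g. from [daily_aqi_table()].
#' @return `data.frame` with `station_id`, `year`, `month`, `aqi`, `n_days`.
#'   Empty input yields an empty frame (not an error).
#' @export
monthly_aqi <- function(daily) {
  stopifnot(all(c("station_id", "date", "aqi") %in% names(daily)))
  if (nrow(daily) == 0L) {
    return(data.frame(station_id = character(), year = integer(),
                      month = integer(), aqi = numeric(), n_days = integer()))
  }
  date <- as.Date(daily$date)
  ym <- as.integer(format(date, "%Y")) * 12L + (as.integer(format(date, "%m")) - 1L)
  out <- lapply(split(seq_len(nrow(daily)), daily$station_id), function(idx) {
    # rows with NA aqi extend the station's span but contribute no days
    span <- seq(min(ym[idx]), max(ym[idx]))
    agg <- tapply(daily$aqi[idx], ym[idx], mean, na.rm = TRUE)
    agg[is.nan(agg)] <- NA_real_
    n <- tapply(!is.na(daily$aqi[idx]), ym[idx], sum)
    data.frame(station_id = daily$station_id[idx[1L]],
               year = span %/% 12L, month = span %% 12L + 1L,
               aqi = as.numeric(agg[as.character(span)]),
               n_days = ifelse(is.na(n[as.character(span)]), 0L,
                               as.integer(n[as.character(span)])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
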