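# WBGT estimation, guideline categories, lag bins, site climatology.

#' Estimate wet-bulb globe temperature from standard weather variables
#'
#' Evaluates the published estimation polynomial used by the Japanese
#' Ministry of the Environment monitoring network, which predicts WBGT from
#' air temperature, relative humidity, solar radiation and wind speed:
#'
#' \deqn{WBGT = 0.735 Ta + 0.0374 RH + 0.00292 Ta \cdot RH + 7.619 SR -
#'   4.557 SR^2 - 0.0572 WS - 4.064}
#'
#' The value is returned as-is (no clamping); callers categorize it with
#' [wbgt_category()].
#'
#' @param ta_c Air temperature in degrees Celsius.
#' @param rh_pct Relative humidity in percent (0--100). Values at or below
#'   1.5 trigger a warning because they are plausibly fractions.
#' @param sr_kwm2 Solar radiation in kW/m^2. Values above 2 trigger a
#'   warning because they are plausibly W/m^2.
#' @param ws_ms Wind speed in m/s.
#' @return Numeric vector of estimated WBGT in degrees Celsius.
#' @examples
#' estimate_wbgt(30, 60, 0.8, 1.0)
#' @export
estimate_wbgt <- function(ta_c, rh_pct, sr_kwm2, ws_ms) {
  args <- list(ta_c = ta_c, rh_pct = rh_pct, sr_kwm2 = sr_kwm2, ws_ms = ws_ms)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || any(!is.finite(args[[nm]]))) {
      stop("non-finite or non-numeric values in '", nm, "'", call. = FALSE)
    }
  }
  if (any(rh_pct < 0 | rh_pct > 100)) {
    stop("'rh_pct' must be in [0, 100] (percent)", call. = FALSE)
  }
  if (any(sr_kwm2 < 0)) stop("'sr_kwm2' must be >= 0", call. = FALSE)
  if (any(ws_ms < 0)) stop("'ws_ms' must be >= 0", call. = FALSE)
  if (any(rh_pct > 0 & rh_pct <= 1.5)) {
    warning("some 'rh_pct' values are <= 1.5; relative humidity given as a ",
            "fraction instead of percent? No rescaling is applied.",
            call. = FALSE)
  }
  if (any(sr_kwm2 > 2)) {
    warning("some 'sr_kwm2' values exceed 2 kW/m^2; solar radiation given ",
            "in W/m^2? No rescaling is applied.", call. = FALSE)
  }
  0.735 * ta_c + 0.0374 * rh_pct + 0.00292 * ta_c * rh_pct +
    7.619 * sr_kwm2 - 4.557 * sr_kwm2^2 - 0.0572 * ws_ms - 4.064
}

#' Guideline category scheme for WBGT
#'
#' The sports-guideline scheme has five categories separated at 21, 25, 28
#' and 31 degrees C. All intervals are left-open right-closed, so 28 deg C
#' falls in category 3 and 31 deg C in category 4. Category 4
#' (28 < WBGT <= 31) carries the "cease strenuous exercise" role and
#' category 5 (WBGT > 31) the "cease all exercise" role.
#'
#' @param boundaries Strictly increasing numeric vector of four interior
#'   boundaries in degrees Celsius.
#' @return A list with elements `boundaries`, `labels` (integers 1:5) and
#'   `roles` (named character vector for the two threshold categories).
#' @export
category_scheme <- function(boundaries = c(21, 25, 28, 31)) {
  stopifnot(length(boundaries) == 4, !is.unsorted(boundaries, strictly = TRUE))
  list(boundaries = boundaries, labels = 1:5,
       roles = c(`4` = "cease strenuous exercise", `5` = "cease all exercise"))
}

#' Assign WBGT guideline categories
#'
#' @param wbgt_c Numeric vector of WBGT values in degrees Celsius.
#' @param scheme A [category_scheme()].
#' @return Integer vector of categories 1..5; intervals are
#'   left-open right-closed.
#' @examples
#' wbgt_category(c(21, 28, 31.2)) # 1, 3, 5
#' @export
wbgt_category <- function(wbgt_c, scheme = category_scheme()) {
  if (any(!is.finite(wbgt_c))) stop("non-finite WBGT value", call. = FALSE)
  findInterval(wbgt_c, vec = scheme$boundaries, left.open = TRUE) + 1L
}

#' Lag-bin scheme for daily-mean WBGT
#'
#' Previous-day (WBGT-1) and two-days-prior (WBGT-2) daily means enter the
#' model in 1 degree C bins with an open-ended catch-all reference bin below
#' 15 degrees C.
#'
#' @param floor_c Lower limit in degrees Celsius; daily means below it map
#'   to the reference bin `"<15"` (for the default floor).
#' @param width_c Bin width in degrees Celsius.
#' @return List with `floor_c`, `width_c` and the reference label.
#' @export
lag_bin_scheme <- function(floor_c = 15, width_c = 1) {
  stopifnot(width_c > 0)
  list(floor_c = floor_c, width_c = width_c,
       ref_label = paste0("<", format(floor_c)))
}

#' Bin a daily-mean WBGT value
#'
#' @param x Numeric vector of daily-mean WBGT (deg C); `NA` passes through.
#' @param scheme A [lag_bin_scheme()].
#' @return Character vector of bin labels: `"<15"` below the floor,
#'   otherwise the integer floor of the value (so `"28"` means
#'   28 <= mean < 29). The top bin is open-ended.
#' @export
lag_bin <- function(x, scheme = lag_bin_scheme()) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  lab <- as.character(scheme$floor_c +
                      floor((x[ok] - scheme$floor_c) / scheme$width_c) *
                      scheme$width_c)
  lab[x[ok] < scheme$floor_c] <- scheme$ref_label
  out[ok] <- lab
  out
}

#' Order the observed lag-bin labels
#'
#' @param x Character vector of lag-bin labels.
#' @param scheme A [lag_bin_scheme()].
#' @return Character vector of levels, reference bin first then ascending.
#' @export
lag_bin_levels <- function(x, scheme = lag_bin_scheme()) {
  u <- unique(x[!is.na(x)])
  num <- suppressWarnings(as.numeric(setdiff(u, scheme$ref_label)))
  lev <- as.character(sort(num))
  if (scheme$ref_label %in% u) lev <- c(scheme$ref_label, lev)
  lev
}

# Daily means of an hourly series, as a data.frame(date, wbgt_mean, n_hours).
daily_mean_table <- function(series) {
  d <- as.Date(series$timestamp, tz = "UTC")
  m <- rowsum(series$wbgt_c, d) / as.vector(table(d))
  data.frame(date = as.Date(rownames(m)), wbgt_mean = as.vector(m),
             n_hours = as.vector(table(d)), row.names = NULL)
}

#' Daily-mean lag feature for one date
#'
#' Computes the mean of all available hourly WBGT values on the calendar day
#' `lag_days` before `date` and bins it with [lag_bin()].
#'
#' @param series Data frame with columns `timestamp` (hourly POSIXct, UTC)
#'   and `wbgt_c`.
#' @param date The index date (coerced with [as.Date()]).
#' @param lag_days 1 (previous day) or 2 (two days prior).
#' @param scheme A [lag_bin_scheme()].
#' @return The bin label, or `NA_character_` if the lagged day has no
#'   hourly values (the matched set is dropped downstream).
#' @export
daily_mean_lag <- function(series, date, lag_days, scheme = lag_bin_scheme()) {
  stopifnot(lag_days %in% c(1L, 2L))
  target <- as.Date(date) - lag_days
  vals <- series$wbgt_c[as.Date(series$timestamp, tz = "UTC") == target]
  if (length(vals) == 0) return(NA_character_)
  lag_bin(mean(vals), scheme)
}

#' Warm-season climatology of a site (WBGT-Summer)
#'
#' The arithmetic mean of all hourly WBGT values with calendar month in
#' May--October, optionally restricted to given years, with a climatology
#' band label on left-open right-closed intervals at 18, 20, 22 and 24.
#'
#' @param series Data frame with columns `timestamp` and `wbgt_c`, and
#'   optionally `site_id`.
#' @param years Optional integer vector of calendar years to include.
#' @param months Integer months defining the warm season.
#' @return A list with `site_id`, `wbgt_summer` (deg C) and `band`
#'   (one of `"<=18"`, `"18-20"`, `"20-22"`, `"22-24"`, `">24"`).
#' @export
wbgt_summer <- function(series, years = NULL, months = 5:10) {
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  keep <- (lt$mon + 1L) %in% months
  if (!is.null(years)) keep <- keep & (lt$year + 1900L) %in% years
  if (!any(keep)) stop("no hourly values in the warm-season window", call. = FALSE)
  m <- mean(series$wbgt_c[keep])
  list(site_id = if (!is.null(series$site_id)) series$site_id[1] else NA_character_,
       wbgt_summer = m, band = climatology_band(m))
}

#' Climatology band for a WBGT-Summer value
#'
#' @param x Numeric vector of May--October mean WBGT (deg C).
#' @return Character vector of band labels (`"<=18"`, `"18-20"`, `"20-22"`,
#'   `"22-24"`, `">24"`), left-open right-closed.
#' @export
climatology_band <- function(x) {
  lev <- c("<=18", "18-20", "20-22", "22-24", ">24")
  lev[findInterval(x, c(18, 20, 22, 24), left.open = TRUE) + 1L]
}

#' Derive WBGT series from a weather table
#'
#' Applies [estimate_wbgt()] to hourly weather rows, or passes through a
#' provided `wbgt_c` column (flagged `"provided"`).
#'
#' @param weather Data frame with columns `site_id`, `timestamp`, and either
#'   `wbgt_c` or all of `ta_c`, `rh_pct`, `sr_kwm2`, `ws_ms`.
#' @return Data frame with `site_id`, `timestamp`, `wbgt_c`, `source`.
#' @export
wbgt_from_weather <- function(weather) {
  if (!is.null(weather$wbgt_c)) {
    out <- data.frame(site_id = weather$site_id, timestamp = weather$timestamp,
                      wbgt_c = weather$wbgt_c, source = "provided")
  } else {
    out <- data.frame(
      site_id = weather$site_id, timestamp = weather$timestamp,
      wbgt_c = estimate_wbgt(weather$ta_c, weather$rh_pct,
                             weather$sr_kwm2, weather$ws_ms),
      source = "estimated")
  }
  ts <- out$timestamp
  if (is.unsorted(as.numeric(ts)) && length(unique(out$site_id)) == 1L) {
    stop("timestamps must be increasing within a site", call. = FALSE)
  }
  out
}
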