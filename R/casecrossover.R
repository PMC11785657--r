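# Incident eligibility filters, time-stratified referent selection,
# matched-set construction.

#' Round an incident time to the nearest hour
#'
#' Minutes of 30 or more round up; rounding 23:30+ rolls the date forward.
#'
#' @param date Incident date (coerced with [as.Date()]).
#' @param hour Hour 0--23.
#' @param minute Minute 0--59 (default 0).
#' @return List with `date` and `hour` after rounding.
#' @export
round_incident_time <- function(date, hour, minute = 0) {
  stopifnot(all(hour %in% 0:23), all(minute >= 0 & minute < 60))
  h <- as.integer(hour) + as.integer(minute >= 30)
  list(date = as.Date(date) + as.integer(h == 24L), hour = h %% 24L)
}

#' Apply the eligibility filters to incident records
#'
#' Keeps records that (1) occurred during sports club activities, (2) carry
#' a heat-illness or heat-stroke diagnosis, (3) fall in the configured aid
#' year window, and (4) lie within the linkage distance of their WBGT site
#' (haversine on WGS84, threshold inclusive). Records with missing
#' coordinates are excluded with their own reason code. The returned tally
#' counts failures per criterion; a record failing several criteria is
#' counted in each.
#'
#' @param records Data frame with columns `circumstance`, `diagnosis`,
#'   `fiscal_year`, `muni_lat`, `muni_lon`, `site_lat`, `site_lon` (plus any
#'   identifier/attribute columns, passed through).
#' @param max_distance_km Inclusive linkage threshold in km.
#' @param circumstance Label that marks club-activity records.
#' @param diagnosis_terms Substrings accepted in the diagnosis label.
#' @param years Eligible fiscal aid years.
#' @return List with `records` (the survivors, plus a `distance_km` column),
#'   `tally` (named integer vector of per-criterion failures) and
#'   `n_in`/`n_kept`.
#' @export
filter_incidents <- function(records, max_distance_km = 10,
                             circumstance = "sports club activities",
                             diagnosis_terms = c("heat illness", "heat stroke"),
                             years = 2011:2019) {
  tally <- c(circumstance = 0L, diagnosis = 0L, year = 0L,
             distance = 0L, missing_coord = 0L)
  if (nrow(records) == 0) {
    return(list(records = records, tally = tally, n_in = 0L, n_kept = 0L))
  }
  ok_circ <- !is.na(records$circumstance) & records$circumstance == circumstance
  diag_hit <- Reduce(`|`, lapply(diagnosis_terms, function(term)
    grepl(term, records$diagnosis, fixed = TRUE)))
  ok_diag <- !is.na(records$diagnosis) & diag_hit
  ok_year <- !is.na(records$fiscal_year) & records$fiscal_year %in% years

  coords <- cbind(records$muni_lon, records$muni_lat,
                  records$site_lon, records$site_lat)
  has_coord <- stats::complete.cases(coords)
  dist_km <- rep(NA_real_, nrow(records))
  if (any(has_coord)) {
    dist_km[has_coord] <- geosphere::distHaversine(
      coords[has_coord, 1:2, drop = FALSE],
      coords[has_coord, 3:4, drop = FALSE]) / 1000
  }
  ok_dist <- has_coord & dist_km <= max_distance_km

  tally["circumstance"] <- sum(!ok_circ)
  tally["diagnosis"] <- sum(!ok_diag)
  tally["year"] <- sum(!ok_year)
  tally["missing_coord"] <- sum(!has_coord)
  tally["distance"] <- sum(has_coord & dist_km > max_distance_km)

  keep <- ok_circ & ok_diag & ok_year & ok_dist
  out <- records[keep, , drop = FALSE]
  out$distance_km <- dist_km[keep]
  list(records = out, tally = tally, n_in = nrow(records), n_kept = sum(keep))
}

#' Time-stratified referent datetimes for a case
#'
#' Referents are every other day in the same calendar month and year that
#' shares the case's day of week, at the case's hour. The case's own date
#' is excluded; a complete month therefore yields 3 or 4 referents.
#'
#' @param date Case date (coerced with [as.Date()]).
#' @param hour Case hour 0--23.
#' @return POSIXct vector (UTC) of referent datetimes in ascending order.
#' @export
select_referents <- function(date, hour) {
  date <- as.Date(date)
  stopifnot(length(date) == 1, hour %in% 0:23)
  first <- as.Date(format(date, "%Y-%m-01"))
  days <- seq(first, by = "1 day", length.out = 31)
  days <- days[format(days, "%m") == format(date, "%m")]
  same <- days[as.POSIXlt(days)$wday == as.POSIXlt(date)$wday & days != date]
  as.POSIXct(paste0(sort(same), sprintf(" %02d:00:00", hour)), tz = "UTC")
}

#' Build time-stratified matched sets with exposure covariates
#'
#' For each eligible case, selects its referent datetimes with
#' [select_referents()] and attaches the same-hour WBGT (WBGT-0, in deg C
#' and as a guideline category), the previous-day daily-mean bin (WBGT-1)
#' and the two-days-prior daily-mean bin (WBGT-2) to the case and every
#' referent, relative to each observation's own date. Stratification
#' attributes are copied from the case to all observations, so they are
#' constant within a set and cancel from the conditional likelihood.
#' Sets with any missing exposure on any observation are dropped whole.
#'
#' @param cases Data frame of eligible cases with columns `record_id`,
#'   `site_id`, `date` (Date), `hour`, and optionally `school_type`, `club`,
#'   `region`, `location`.
#' @param wbgt_store Named list (by site id) of WBGT series data frames with
#'   columns `timestamp` (hourly POSIXct, UTC) and `wbgt_c`.
#' @param climatology Optional named character vector mapping site id to a
#'   [climatology_band()] label.
#' @param scheme,lag_scheme Category and lag-bin schemes.
#' @return List with `sets` (long data frame: `set_id`, `record_id`,
#'   `is_case`, `date`, `hour`, `wbgt0_c`, `wbgt0_cat`, `wbgt1_bin`,
#'   `wbgt2_bin`, attributes, `month`, `year`, `dow`, `climband`) and
#'   `dropped` (data frame of record id and reason).
#' @export
build_matched_sets <- function(cases, wbgt_store, climatology = NULL,
                               scheme = category_scheme(),
                               lag_scheme = lag_bin_scheme()) {
  n <- nrow(cases)
  if (n == 0) {
    return(list(sets = data.frame(), dropped = data.frame(record_id = character(),
                                                          reason = character())))
  }
  cases$date <- as.Date(cases$date)

  # site-level lookup tables: hourly values and daily means
  hour_lk <- new.env(parent = emptyenv())
  hvals <- numeric(0); dvals <- numeric(0)
  for (sid in names(wbgt_store)) {
    s <- wbgt_store[[sid]]
    lt <- as.POSIXlt(s$timestamp, tz = "UTC")
    hk <- paste(sid, format(s$timestamp, "%Y-%m-%d %H", tz = "UTC"))
    v <- s$wbgt_c; names(v) <- hk
    hvals <- c(hvals, v)
    dm <- daily_mean_table(s)
    dv <- dm$wbgt_mean; names(dv) <- paste(sid, dm$date)
    dvals <- c(dvals, dv)
  }

  refs <- lapply(seq_len(n), function(i) {
    as.Date(select_referents(cases$date[i], cases$hour[i]), tz = "UTC")
  })
  nref <- lengths(refs)
  set_row <- rep(seq_len(n), nref + 1L)
  obs_date <- as.Date(unlist(Map(function(d, r) c(d, r), cases$date, refs)),
                      origin = "1970-01-01")
  is_case <- unlist(lapply(nref, function(k) c(1L, rep(0L, k))))
  obs_hour <- cases$hour[set_row]
  obs_site <- as.character(cases$site_id[set_row])

  known_site <- obs_site %in% names(wbgt_store)
  hkey <- paste(obs_site, format(obs_date, "%Y-%m-%d"),
                sprintf("%02d", obs_hour))
  wbgt0 <- unname(hvals[hkey])
  w1 <- unname(dvals[paste(obs_site, obs_date - 1)])
  w2 <- unname(dvals[paste(obs_site, obs_date - 2)])

  # drop whole sets with any missing exposure, recording the first reason
  per_set <- function(bad) as.vector(rowsum(as.numeric(bad), set_row)) > 0
  site_bad <- per_set(!known_site)
  w0_bad <- per_set(is.na(wbgt0))
  w1_bad <- per_set(is.na(w1))
  w2_bad <- per_set(is.na(w2))
  reason <- rep(NA_character_, n)
  reason[w2_bad] <- "missing WBGT-2"
  reason[w1_bad] <- "missing WBGT-1"
  reason[w0_bad] <- "missing WBGT-0"
  reason[site_bad] <- "site series absent"
  keep_set <- is.na(reason)
  dropped <- data.frame(record_id = as.character(cases$record_id[!keep_set]),
                        reason = reason[!keep_set])
  keep_row <- keep_set[set_row]

  attr_or_na <- function(col) {
    if (is.null(cases[[col]])) rep(NA_character_, n) else as.character(cases[[col]])
  }
  lt <- as.POSIXlt(obs_date)
  sets <- data.frame(
    set_id = set_row,
    record_id = as.character(cases$record_id[set_row]),
    is_case = is_case,
    date = obs_date,
    hour = obs_hour,
    site_id = obs_site,
    wbgt0_c = wbgt0,
    wbgt0_cat = ifelse(is.na(wbgt0), NA_integer_, wbgt_category(ifelse(is.na(wbgt0), 0, wbgt0), scheme)),
    wbgt1_bin = lag_bin(w1, lag_scheme),
    wbgt2_bin = lag_bin(w2, lag_scheme),
    school_type = attr_or_na("school_type")[set_row],
    club = attr_or_na("club")[set_row],
    region = attr_or_na("region")[set_row],
    location = attr_or_na("location")[set_row],
    month = (as.POSIXlt(cases$date)$mon + 1L)[set_row],
    year = (as.POSIXlt(cases$date)$year + 1900L)[set_row],
    dow = as.POSIXlt(cases$date)$wday[set_row],
    stringsAsFactors = FALSE
  )
  sets$climband <- if (is.null(climatology)) NA_character_ else
    unname(climatology[sets$site_id])
  sets <- sets[keep_row, , drop = FALSE]
  # renumber retained sets 1..S
  sets$set_id <- match(sets$set_id, unique(sets$set_id))
  rownames(sets) <- NULL
  list(sets = sets, dropped = dropped)
}
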