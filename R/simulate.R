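# Synthetic WBGT series and incident records with known ground truth,
# plus a direct matched-set sampler for calibration studies.

# Restore the caller's RNG state on exit and seed locally.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Climate scenario for the WBGT generator
#'
#' Describes a small network of monitoring sites with target warm-season
#' (May--October) mean WBGT spanning the climatology bands, a seasonal
#' sinusoid peaking in early August, a diurnal sinusoid peaking
#' mid-afternoon, and AR(1) hourly noise.
#'
#' @param n_sites Number of sites.
#' @param summer_means Target May--October mean WBGT per site (deg C),
#'   recycled to `n_sites`.
#' @param years Simulated calendar years.
#' @param seasonal_amp,diurnal_amp Sinusoid amplitudes (deg C).
#' @param ar_coef AR(1) coefficient in \[0, 1).
#' @param ar_sd Innovation standard deviation (deg C).
#' @return List of class `cc_scenario`; includes site coordinates laid out
#'   along a latitude gradient with a municipality representative point
#'   a few km from each site.
#' @export
cc_scenario <- function(n_sites = 3, summer_means = c(17.5, 22.5, 25),
                        years = 2018:2019, seasonal_amp = 8,
                        diurnal_amp = 3, ar_coef = 0.7, ar_sd = 1.2) {
  stopifnot(seasonal_amp >= 0, diurnal_amp >= 0,
            ar_coef >= 0, ar_coef < 1, ar_sd >= 0)
  sm <- rep_len(summer_means, n_sites)
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    summer_mean = sm,
    site_lat = 43 - seq_len(n_sites) * 2.0,
    site_lon = 141 + seq_len(n_sites) * 0.5,
    muni_lat = 43 - seq_len(n_sites) * 2.0 + 0.03,
    muni_lon = 141 + seq_len(n_sites) * 0.5 + 0.03)
  structure(list(sites = sites, years = years, seasonal_amp = seasonal_amp,
                 diurnal_amp = diurnal_amp, ar_coef = ar_coef, ar_sd = ar_sd),
            class = "cc_scenario")
}

#' Generate hourly WBGT series for a scenario
#'
#' Each site's series is a deterministic mean structure --- site offset plus
#' a seasonal cosine peaking on day-of-year 213 (early August) and a
#' diurnal cosine peaking at 15:00 --- plus stationary AR(1) noise. The site
#' offset is chosen so that the deterministic May--October mean equals the
#' scenario's target exactly, making the realized warm-season mean unbiased.
#'
#' @param scenario A [cc_scenario()].
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @return Named list (by site id) of data frames with `site_id`,
#'   `timestamp` (hourly POSIXct, UTC), `wbgt_c`, `source = "simulated"`.
#' @export
generate_wbgt <- function(scenario = cc_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "cc_scenario"))
  y0 <- min(scenario$years); y1 <- max(scenario$years)
  ts <- seq(as.POSIXct(paste0(y0, "-01-01 00:00:00"), tz = "UTC"),
            as.POSIXct(paste0(y1, "-12-31 23:00:00"), tz = "UTC"),
            by = "hour")
  lt <- as.POSIXlt(ts, tz = "UTC")
  doy <- lt$yday + 1L
  seasonal <- scenario$seasonal_amp * cos(2 * pi * (doy - 213) / 365.25)
  diurnal <- scenario$diurnal_amp * cos(2 * pi * (lt$hour - 15) / 24)
  base <- seasonal + diurnal
  summer <- (lt$mon + 1L) %in% 5:10
  offset0 <- mean(base[summer])
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(scenario$sites))) {
      noise <- if (scenario$ar_sd > 0) {
        as.numeric(stats::filter(stats::rnorm(length(ts), 0, scenario$ar_sd),
                                 scenario$ar_coef, method = "recursive"))
      } else rep(0, length(ts))
      sid <- scenario$sites$site_id[i]
      out[[sid]] <- data.frame(
        site_id = sid, timestamp = ts,
        wbgt_c = scenario$sites$summer_mean[i] - offset0 + base + noise,
        source = "simulated")
    }
    out
  })
}

#' Risk model for the incident generator
#'
#' Log-odds structure of the per-hour event probability during eligible
#' club-activity hours: a baseline calibrated to a target case count, a
#' per-degree effect of the same-hour WBGT (centered at 25 deg C), linear
#' per-degree effects of the previous-day and two-days-prior daily means
#' (positive and negative by default, mirroring short-term risk carried by
#' yesterday's heat and behavioural adaptation after a hot day two days
#' back), and additive stratum offsets by club and location.
#'
#' @param target_cases Expected number of incident records.
#' @param logor_wbgt0 Either a single per-deg-C log odds ratio of the
#'   same-hour WBGT, or a length-5 vector of per-category log odds (first
#'   entry the reference category).
#' @param logor_wbgt1,logor_wbgt2 Per-deg-C log odds ratios of the lagged
#'   daily means (applied above the 15 deg C bin floor).
#' @param center Centering constant (deg C) for the exposure terms.
#' @param clubs,locations Named numeric vectors of stratum log-odds offsets.
#' @param months,hours,weekdays Activity calendar (eligible months, hours
#'   of day, and days of week with 0 = Sunday).
#' @param n_units Independent exposure units (school teams) sharing each
#'   site-club-hour; large values keep every per-unit event probability
#'   deep in the rare-event regime the design assumes.
#' @return List of class `cc_risk`.
#' @export
cc_risk <- function(target_cases = 2000, logor_wbgt0 = 0.7,
                    logor_wbgt1 = 0.06, logor_wbgt2 = -0.03, center = 25,
                    clubs = c(baseball = 0.3, tennis = 0.1, track = 0,
                              volleyball = -0.2),
                    locations = c(outdoor = 0.2, indoor = -0.2),
                    months = 4:10, hours = 9:18, weekdays = 1:6,
                    n_units = 50) {
  structure(list(target_cases = target_cases, logor_wbgt0 = logor_wbgt0,
                 logor_wbgt1 = logor_wbgt1, logor_wbgt2 = logor_wbgt2,
                 center = center, clubs = clubs, locations = locations,
                 months = months, hours = hours, weekdays = weekdays,
                 n_units = n_units), class = "cc_risk")
}

#' Generate incident records from WBGT series and a risk model
#'
#' Enumerates every eligible unit-hour (site x club x calendar-eligible
#' hour), computes the event log-odds from the risk model, calibrates the
#' baseline so the expected case count matches `risk$target_cases` in the
#' rare-event regime, and draws independent Bernoulli events. Incident
#' records carry the attribute fields of the incident-data schema; the
#' ground truth (all risk parameters, the calibrated baseline, the seed and
#' the generating covariates of each record) is attached for downstream
#' parameter-recovery checks.
#'
#' @param wbgt_store Named list of site series from [generate_wbgt()].
#' @param scenario The [cc_scenario()] that produced the store (for
#'   coordinates).
#' @param risk A [cc_risk()].
#' @param seed Integer seed.
#' @return List with `incidents` (data frame: `record_id`, `date`, `hour`,
#'   `municipality_id`, `site_id`, coordinates, `school_type`, `club`,
#'   `region`, `location`, `diagnosis`, `circumstance`, `fiscal_year`) and
#'   `truth` (list: parameters, baseline, seed, per-record covariates).
#' @export
generate_incidents <- function(wbgt_store, scenario = cc_scenario(),
                               risk = cc_risk(), seed = 1) {
  stopifnot(inherits(risk, "cc_risk"))
  frames <- list()
  for (sid in names(wbgt_store)) {
    s <- wbgt_store[[sid]]
    lt <- as.POSIXlt(s$timestamp, tz = "UTC")
    elig <- (lt$mon + 1L) %in% risk$months & lt$hour %in% risk$hours &
      lt$wday %in% risk$weekdays
    d <- s[elig, , drop = FALSE]
    dm <- daily_mean_table(s)
    dmv <- dm$wbgt_mean; names(dmv) <- as.character(dm$date)
    date <- as.Date(d$timestamp, tz = "UTC")
    w1 <- unname(dmv[as.character(date - 1)])
    w2 <- unname(dmv[as.character(date - 2)])
    ok <- !is.na(w1) & !is.na(w2)
    frames[[sid]] <- data.frame(
      site_id = sid, date = date[ok],
      hour = as.POSIXlt(d$timestamp[ok], tz = "UTC")$hour,
      wbgt0_c = d$wbgt_c[ok], w1 = w1[ok], w2 = w2[ok])
  }
  grid <- do.call(rbind, frames)
  clubs <- names(risk$clubs)
  grid <- grid[rep(seq_len(nrow(grid)), each = length(clubs)), ]
  grid$club <- rep(clubs, length.out = nrow(grid))
  rownames(grid) <- NULL

  with_seed(seed, {
    grid$location <- sample(names(risk$locations), nrow(grid), replace = TRUE)
    # lag effects act above the bin floor so the reference bin is neutral
    eff0 <- if (length(risk$logor_wbgt0) == 5) {
      risk$logor_wbgt0[wbgt_category(grid$wbgt0_c)]
    } else {
      risk$logor_wbgt0 * (grid$wbgt0_c - risk$center)
    }
    eff <- eff0 +
      risk$logor_wbgt1 * pmax(grid$w1 - 15, 0) +
      risk$logor_wbgt2 * pmax(grid$w2 - 15, 0) +
      unname(risk$clubs[grid$club]) +
      unname(risk$locations[grid$location])
    baseline <- log(risk$target_cases) - log(risk$n_units) -
      log(sum(exp(eff)))
    p <- stats::plogis(baseline + eff)
    if (risk$n_units * sum(p) < 50) {
      warning("expected case count below 50; downstream inference will be ",
              "unstable", call. = FALSE)
    }
    n_ev <- stats::rbinom(nrow(grid), risk$n_units, p)
    ev <- grid[rep(seq_len(nrow(grid)), n_ev), , drop = FALSE]
    sites <- scenario$sites
    si <- match(ev$site_id, sites$site_id)
    regions <- c("north", "central", "south")
    incidents <- data.frame(
      record_id = sprintf("R%06d", seq_len(nrow(ev))),
      date = ev$date, hour = ev$hour, minute = 0L,
      municipality_id = paste0("M_", ev$site_id), site_id = ev$site_id,
      muni_lat = sites$muni_lat[si], muni_lon = sites$muni_lon[si],
      site_lat = sites$site_lat[si], site_lon = sites$site_lon[si],
      school_type = sample(c("junior_high", "high"), nrow(ev), replace = TRUE),
      club = ev$club,
      region = regions[pmin(ceiling(si * 3 / max(1, nrow(sites))), 3)],
      location = ev$location,
      diagnosis = sample(c("heat illness", "heat stroke"), nrow(ev),
                         replace = TRUE),
      circumstance = "sports club activities",
      fiscal_year = as.POSIXlt(ev$date)$year + 1900L)
    truth <- list(risk = risk, baseline = baseline, seed = seed,
                  covariates = ev[, c("site_id", "date", "hour", "wbgt0_c",
                                      "w1", "w2", "club", "location")])
    list(incidents = incidents, truth = truth)
  })
}

#' Sample matched sets directly from the conditional model
#'
#' Draws exposure covariates for one case plus `n_ref` referents per set
#' and selects the case by the within-set softmax of the linear predictor
#' --- the exact sampling distribution implied by the conditional logistic
#' likelihood. This gives fast, bias-free material for coverage, type-I
#' error and selection studies without running the full pipeline.
#'
#' @param n_sets Number of matched sets.
#' @param n_ref Referents per set.
#' @param exposure `"continuous"` (a per-deg-C effect on `wbgt0_c`) or
#'   `"category"` (per-category effects on `wbgt0_cat`).
#' @param beta For `"continuous"`, the per-deg-C log odds ratio; for
#'   `"category"`, a length-5 vector of category log odds (first entry the
#'   reference, usually 0).
#' @param exposure_sd Spread of the continuous exposure around 25 deg C.
#' @param cat_probs Sampling probabilities of the five categories.
#' @param noise Number of pure-noise covariates to append: alternating a
#'   standard-normal numeric column (`noise1`, ...) and a three-level
#'   factor column.
#' @param stratum Optional character vector of stratum labels; each set is
#'   assigned one (recycled) and, for `"category"`, `stratum_shift` is added
#'   to the non-reference category log odds of sets in the *first* label.
#' @param stratum_shift Log-odds shift of the first stratum.
#' @param seed Integer seed.
#' @return Matched-set data frame compatible with [fit_clogit()], carrying
#'   a `truth` attribute with the generating parameters.
#' @export
simulate_matched_sets <- function(n_sets, n_ref = 4,
                                  exposure = c("continuous", "category"),
                                  beta = 0.7, exposure_sd = 3,
                                  cat_probs = c(0.25, 0.25, 0.2, 0.2, 0.1),
                                  noise = 0, stratum = NULL,
                                  stratum_shift = 0, seed = NULL) {
  exposure <- match.arg(exposure)
  n <- n_sets * (n_ref + 1)
  with_seed(seed, {
    set_id <- rep(seq_len(n_sets), each = n_ref + 1)
    if (exposure == "continuous") {
      x <- 25 + stats::rnorm(n, 0, exposure_sd)
      eta <- beta * x
      d <- data.frame(set_id = set_id, wbgt0_c = x,
                      wbgt0_cat = wbgt_category(x))
    } else {
      stopifnot(length(beta) == 5)
      cat_k <- sample.int(5, n, replace = TRUE, prob = cat_probs)
      eta <- beta[cat_k]
      d <- data.frame(set_id = set_id, wbgt0_cat = cat_k,
                      wbgt0_c = c(19, 23, 26.5, 29.5, 32.5)[cat_k])
    }
    if (!is.null(stratum)) {
      st <- rep_len(stratum, n_sets)[set_id]
      d$stratum <- st
      if (exposure == "category") {
        bump <- st == stratum[1] & d$wbgt0_cat > 1
        eta <- eta + stratum_shift * bump
      } else {
        eta <- eta + stratum_shift * (st == stratum[1])
      }
    }
    if (noise > 0) {
      for (j in seq_len(noise)) {
        nm <- paste0("noise", j)
        d[[nm]] <- if (j %% 2 == 1) stats::rnorm(n) else
          sample(c("a", "b", "c"), n, replace = TRUE)
      }
    }
    # pick the case within each set by the conditional softmax
    is_case <- integer(n)
    em <- matrix(eta, nrow = n_ref + 1)
    pm <- exp(sweep(em, 2, apply(em, 2, max)))
    pm <- sweep(pm, 2, colSums(pm), "/")
    pick <- vapply(seq_len(n_sets), function(s)
      sample.int(n_ref + 1, 1, prob = pm[, s]), 0L)
    is_case[(seq_len(n_sets) - 1) * (n_ref + 1) + pick] <- 1L
    d$is_case <- is_case
    attr(d, "truth") <- list(exposure = exposure, beta = beta,
                             stratum_shift = stratum_shift, seed = seed)
    d
  })
}

#' Bundled deterministic toy datasets
#'
#' A small registry of fixtures used in documentation and tests:
#' \describe{
#'   \item{`"filter6"`}{Six incident records --- one failing each
#'     eligibility criterion (circumstance, diagnosis, year, distance,
#'     missing coordinates) and one passing all.}
#'   \item{`"pairsym"`}{Two 1:1 matched sets with case/referent covariates
#'     (1, 0) and (0, 1); the conditional likelihood is maximized at 0.}
#'   \item{`"highrisk"`}{Three strata of category-exposure matched sets in
#'     which the first stratum's category log odds are shifted up by one
#'     category step (0.7), so its true category-3 odds ratio equals the
#'     others' category-4 odds ratio --- the engineered target of the
#'     one-category HST adjustment.}
#'   \item{`"nullstrata"`}{Four strata drawn from an identical category
#'     model, for family-wise-error checks.}
#' }
#'
#' @param name Fixture name.
#' @param seed Seed for the stochastic fixtures.
#' @param n_sets Sets per stratum for the stochastic fixtures.
#' @return The fixture data frame.
#' @export
make_fixture <- function(name, seed = 42, n_sets = 800) {
  base_cat <- c(0, 0.7, 1.4, 2.1, 2.8)
  switch(
    name,
    filter6 = data.frame(
      record_id = paste0("F", 1:6),
      circumstance = c("commuting", rep("sports club activities", 5)),
      diagnosis = c("heat illness", "fracture", rep("heat stroke", 4)),
      fiscal_year = c(2015L, 2015L, 2010L, 2015L, 2015L, 2015L),
      muni_lat = c(35, 35, 35, 35.2, NA, 35.01),
      muni_lon = c(135, 135, 135, 135, 135, 135),
      site_lat = rep(35, 6), site_lon = rep(135, 6),
      date = as.Date("2015-07-14"), hour = 15L, site_id = "S01",
      stringsAsFactors = FALSE),
    pairsym = data.frame(
      set_id = c(1L, 1L, 2L, 2L), is_case = c(1L, 0L, 1L, 0L),
      wbgt0_c = c(1, 0, 0, 1)),
    highrisk = simulate_matched_sets(
      3 * n_sets, exposure = "category", beta = base_cat,
      stratum = c("kyudo", "basketball", "volleyball"),
      stratum_shift = 0.7, seed = seed),
    nullstrata = simulate_matched_sets(
      4 * n_sets, exposure = "category", beta = base_cat,
      stratum = c("a", "b", "c", "d"), stratum_shift = 0, seed = seed),
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}

#' Serialize generator ground truth to a key-value text file
#'
#' @param truth The `truth` element of [generate_incidents()] or the
#'   `truth` attribute of [simulate_matched_sets()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  flat <- unlist(truth[setdiff(names(truth), "covariates")])
  lines <- paste0(names(flat), "=", vapply(flat, format, "", digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ground-truth key-value file
#'
#' @param path File written by [write_ground_truth()].
#' @return Named character vector of the stored keys; numeric-looking
#'   values can be converted with [as.numeric()].
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}
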