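# Generator contracts: determinism, climatology targets, calendar
# eligibility, null behaviour, and full-loop parameter recovery.

test_that("WBGT generation is deterministic and structurally correct", {
  sc <- cc_scenario(n_sites = 2, summer_means = c(18, 24), years = 2019)
  a <- generate_wbgt(sc, seed = 3)
  b <- generate_wbgt(sc, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, generate_wbgt(sc, seed = 4)))
  s <- a[["S01"]]
  expect_true(!is.unsorted(as.numeric(s$timestamp), strictly = TRUE))
  expect_identical(anyDuplicated(s$timestamp), 0L)
  # zero amplitudes and zero noise give a constant series at the site mean
  flat <- cc_scenario(n_sites = 1, summer_means = 20, years = 2019,
                      seasonal_amp = 0, diurnal_amp = 0, ar_sd = 0)
  f <- generate_wbgt(flat, seed = 1)[[1]]
  expect_true(all(f$wbgt_c == 20))
  # realized warm-season means track the configured targets
  expect_equal(wbgt_summer(a[["S01"]])$wbgt_summer, 18, tolerance = 0.2)
  expect_equal(wbgt_summer(a[["S02"]])$wbgt_summer, 24, tolerance = 0.2)
})

test_that("incidents honour the activity calendar and record schema", {
  sc <- cc_scenario(years = 2019)
  store <- generate_wbgt(sc, seed = 2)
  risk <- cc_risk(target_cases = 400)
  gen <- generate_incidents(store, sc, risk, seed = 5)
  inc <- gen$incidents
  expect_gt(nrow(inc), 200)
  lt <- as.POSIXlt(inc$date)
  expect_true(all((lt$mon + 1L) %in% risk$months))
  expect_true(all(inc$hour %in% risk$hours))
  expect_true(all(lt$wday %in% risk$weekdays))
  expect_true(all(inc$club %in% names(risk$clubs)))
  expect_true(all(c("record_id", "municipality_id", "school_type",
                    "diagnosis", "circumstance", "fiscal_year")
                  %in% names(inc)))
  # reproducible under the seed
  gen2 <- generate_incidents(store, sc, risk, seed = 5)
  expect_identical(gen$incidents, gen2$incidents)
  # sparse configurations warn
  expect_warning(generate_incidents(store, sc, cc_risk(target_cases = 20),
                                    seed = 1), "below 50")
})

test_that("a null exposure effect leaves the event rate flat in WBGT", {
  sc <- cc_scenario(years = 2019)
  store <- generate_wbgt(sc, seed = 8)
  risk0 <- cc_risk(target_cases = 600, logor_wbgt0 = 0, logor_wbgt1 = 0,
                   logor_wbgt2 = 0)
  n_rep <- 15
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    gen <- generate_incidents(store, sc, risk0, seed = 100 + r)
    # compare observed case categories with the eligible-hour distribution
    obs <- table(factor(wbgt_category(gen$truth$covariates$wbgt0_c),
                        levels = 1:5))
    bg <- unlist(lapply(store, function(s) {
      lt <- as.POSIXlt(s$timestamp, tz = "UTC")
      s$wbgt_c[(lt$mon + 1L) %in% risk0$months &
               lt$hour %in% risk0$hours & lt$wday %in% risk0$weekdays]
    }))
    exp_p <- table(factor(wbgt_category(bg), levels = 1:5)) / length(bg)
    keep <- exp_p > 0
    pvals[r] <- suppressWarnings(
      chisq.test(obs[keep], p = exp_p[keep] / sum(exp_p[keep]))$p.value)
  }
  # no systematic dependence: rejections at 5% stay near the nominal rate
  expect_lte(sum(pvals < 0.05), qbinom(0.999, n_rep, 0.05) + 1)
})

test_that("the full loop recovers the generating per-degree effect", {
  sc <- cc_scenario()
  store <- generate_wbgt(sc, seed = 21)
  gen <- generate_incidents(store, sc, cc_risk(target_cases = 1200), seed = 22)
  filt <- filter_incidents(gen$incidents)
  expect_identical(filt$n_kept, nrow(gen$incidents))  # generator respects filters
  ms <- build_matched_sets(filt$records, store)
  fit <- fit_clogit(ms$sets, cc_design_spec("continuous"))
  b <- fit$table[fit$table$term == "wbgt0", ]
  expect_lt(abs(b$coef - 0.7) / b$se, 3)
})

test_that("lag effect signs propagate from the generator to the fit", {
  # sign-propagation check under an amplified-contrast scenario: a cool
  # climate keeps the <15 reference bin populated, and strengthened lag
  # effects make the within-block trend identifiable at desk-scale case
  # counts (the per-bin dummies share the same ~1300 site-days, so their
  # precision does not grow with the case count alone)
  sc <- cc_scenario(summer_means = c(15.5, 18, 21))
  store <- generate_wbgt(sc, seed = 30)
  risk <- cc_risk(target_cases = 3000, logor_wbgt1 = 0.15,
                  logor_wbgt2 = -0.15)
  hits <- 0
  n_rep <- 8
  slope <- function(fit, term) {
    t <- fit$table[fit$table$term == term, ]
    b <- suppressWarnings(as.numeric(t$level))
    k <- !is.na(b)
    unname(coef(lm(t$coef[k] ~ b[k]))[2])
  }
  for (r in seq_len(n_rep)) {
    gen <- generate_incidents(store, sc, risk, seed = 300 + r)
    ms <- build_matched_sets(filter_incidents(gen$incidents)$records, store)
    fit <- fit_clogit(ms$sets, cc_design_spec("continuous"))
    if (slope(fit, "wbgt2") < 0 && slope(fit, "wbgt1") > 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("ground truth round-trips through the key-value format", {
  d <- simulate_matched_sets(10, seed = 1)
  tr <- attr(d, "truth")
  path <- withr::local_tempfile(fileext = ".txt")
  write_ground_truth(tr, path)
  back <- read_ground_truth(path)
  expect_equal(as.numeric(back[["beta"]]), tr$beta)
  expect_equal(as.numeric(back[["seed"]]), tr$seed)
  expect_identical(back[["exposure"]], "continuous")
})

test_that("fixtures are registered and deterministic", {
  expect_identical(nrow(make_fixture("filter6")), 6L)
  expect_identical(make_fixture("pairsym")$wbgt0_c, c(1, 0, 0, 1))
  h1 <- make_fixture("highrisk", n_sets = 50)
  h2 <- make_fixture("highrisk", n_sets = 50)
  expect_identical(h1, h2)
  expect_error(make_fixture("nope"), "unknown fixture")
})
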