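# Stratified odds ratios, pairwise Wald tests, multiplicity control,
# HST adjustment rule.

test_that("pairwise Wald test matches the normal-CDF oracle", {
  # identical ORs and SEs: z = 0, p = 1
  w0 <- pairwise_wald(log(2), 0.1, log(2), 0.1)
  expect_equal(w0$z, 0); expect_equal(w0$p, 1)
  # reconstructed SE from a printed interval
  se_a <- se_from_ci(9.61, 15.11)
  expect_equal(se_a, (log(15.11) - log(9.61)) / 3.92, tolerance = 1e-12)
  expect_equal(se_a, 0.1155, tolerance = 1e-3)
  wa <- pairwise_wald(log(12.05), se_a, log(12.05), se_a)
  expect_equal(wa$p, 1)
  # p equals the direct Phi evaluation
  set.seed(2)
  for (r in 1:20) {
    la <- rnorm(1); lb <- rnorm(1); sa <- runif(1, .05, .5); sb <- runif(1, .05, .5)
    w <- pairwise_wald(la, sa, lb, sb)
    z <- (la - lb) / sqrt(sa^2 + sb^2)
    expect_equal(w$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
    # antisymmetry: z flips sign, p unchanged
    wb <- pairwise_wald(lb, sb, la, sa)
    expect_equal(wb$z, -w$z, tolerance = 1e-12)
    expect_equal(wb$p, w$p, tolerance = 1e-12)
  }
  expect_error(pairwise_wald(0, 0, 0, 0), "pooled")
})

test_that("Bonferroni per-test levels reproduce the published family sizes", {
  expect_equal(bonferroni_alpha(7), 0.05 / 42)           # day of week
  expect_equal(bonferroni_alpha(7), 1.19e-3, tolerance = 1e-2)
  expect_equal(bonferroni_alpha(10), 0.05 / 90)          # years
  expect_equal(bonferroni_alpha(10), 5.56e-4, tolerance = 1e-2)
  expect_equal(bonferroni_alpha(5), 2.50e-3, tolerance = 1e-10)  # months, bands
  expect_equal(bonferroni_alpha(2), 0.025)
  expect_error(bonferroni_alpha(1), "two strata")
})

test_that("Benjamini-Hochberg step-up rule and its dominance", {
  expect_identical(bh_adjust(c(0.001, 0.02, 0.04)), rep(TRUE, 3))
  expect_identical(bh_adjust(rep(1, 5)), rep(FALSE, 5))
  # BH rejections always include the Bonferroni rejections
  set.seed(9)
  for (r in 1:20) {
    p <- runif(12)^2
    bh <- bh_adjust(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh[bonf]))
  }
})

test_that("stratified fits flag inestimable categories and scale CIs", {
  base <- c(0, 0.7, 1.4, 2.1, 2.8)
  # a stratum with category 5 never observed: inestimable flag
  d <- simulate_matched_sets(400, exposure = "category", beta = base,
                             cat_probs = c(0.3, 0.3, 0.2, 0.2, 0),
                             stratum = c("a", "b"), seed = 4)
  sf <- fit_strata(d, "stratum")
  expect_true(all(!sf$estimable[sf$category == 5]))
  expect_true(all(sf$estimable[sf$category %in% 2:4]))
  # a small stratum has wider intervals than a 10x larger one
  d_small <- simulate_matched_sets(150, exposure = "category", beta = base,
                                   seed = 5)
  d_big <- simulate_matched_sets(1500, exposure = "category", beta = base,
                                 seed = 6)
  d_small$stratum <- "small"; d_big$stratum <- "big"
  d_big$set_id <- d_big$set_id + 10000
  sf2 <- fit_strata(rbind(d_small, d_big), "stratum")
  w_small <- with(sf2[sf2$stratum == "small" & sf2$category == 5, ],
                  log(ci_hi) - log(ci_lo))
  w_big <- with(sf2[sf2$stratum == "big" & sf2$category == 5, ],
                log(ci_hi) - log(ci_lo))
  expect_gt(w_small, w_big)
  expect_identical(unique(sf2$n_cases[sf2$stratum == "big"]), 1500L)
})

test_that("an elevated stratum outranks the others at category 4", {
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    d <- simulate_matched_sets(3 * 800, exposure = "category",
                               beta = c(0, 0.7, 1.4, 2.1, 2.8),
                               stratum = c("hi", "mid", "lo"),
                               stratum_shift = 0.5, seed = 700 + r)
    sf <- fit_strata(d, "stratum")
    or4 <- sf$or[sf$category == 4]
    names(or4) <- sf$stratum[sf$category == 4]
    if (or4["hi"] > max(or4[c("mid", "lo")])) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("HST adjustment issues a one-category recommendation that heals", {
  d <- make_fixture("highrisk")
  sf <- fit_strata(d, "stratum")
  cmp <- compare_strata(sf)
  expect_s3_class(cmp, "cc_comparisons")
  expect_equal(attr(cmp, "alpha_bonf"), 0.05 / 6)  # 3 strata, 2 categories
  rec <- adjust_hst(sf, cmp)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$stratum, "kyudo")
  expect_identical(rec$orig_cat4, "28<WBGT<=31")
  expect_identical(rec$adj_cat4, "25<WBGT<=28")
  expect_identical(rec$orig_cat5, "WBGT>31")
  expect_identical(rec$adj_cat5, "28<WBGT<=31")
  expect_identical(rec$magnitude_c, 3)
  post <- c(rec$post_p_cat4, rec$post_p_cat5)
  expect_true(all(post[!is.na(post)] > attr(cmp, "alpha_bonf")))
  expect_true(rec$sufficient)
})

test_that("no recommendations arise without significant pairs", {
  d <- make_fixture("nullstrata", n_sets = 300)
  sf <- fit_strata(d, "stratum")
  cmp <- compare_strata(sf)
  rec <- adjust_hst(sf, cmp)
  expect_identical(nrow(rec), 0L)
})

test_that("family-wise error of the Bonferroni screen is controlled", {
  n_rep <- 200
  any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_matched_sets(4 * 150, exposure = "category",
                               beta = c(0, 0.7, 1.4, 2.1, 2.8),
                               stratum = c("a", "b", "c", "d"),
                               stratum_shift = 0, seed = 5000 + r)
    sf <- fit_strata(d, "stratum")
    cmp <- suppressWarnings(compare_strata(sf))
    any_sig[r] <- any(cmp$bonf_sig)
  }
  # FWER <= alpha plus 3 binomial SDs of Monte-Carlo margin
  expect_lte(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
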