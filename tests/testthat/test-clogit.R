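# Conditional likelihood correctness against enumeration oracles,
# Newton fitting, Wald geometry, diagnostics, calibration.

test_that("log-likelihood at beta = 0 is -sum log(set size)", {
  set.seed(1)
  inst <- random_instance(n_sets = 8, p = 2, max_size = 5)
  sizes <- table(inst$set)
  ll <- heatcco:::cc_loglik_core(rep(0, 2), inst$X, inst$set, inst$case,
                                 want_grad = FALSE)$loglik
  expect_equal(ll, -sum(log(sizes)), tolerance = 1e-12)
})

test_that("likelihood, gradient and Hessian match enumeration oracles", {
  set.seed(42)
  for (r in 1:10) {
    inst <- random_instance(n_sets = 5, p = 3)
    beta <- rnorm(3, 0, 0.7)
    core <- heatcco:::cc_loglik_core(beta, inst$X, inst$set, inst$case,
                                     want_hess = TRUE)
    f <- function(b) bf_loglik(b, inst$X, inst$set, inst$case)
    expect_equal(core$loglik, f(beta), tolerance = 1e-10)
    expect_equal(core$gradient, num_grad(f, beta), tolerance = 1e-6)
    expect_equal(unname(core$hessian), num_hess(f, beta), tolerance = 1e-5)
  }
})

test_that("symmetric 1:1 sets are maximized at beta = 0", {
  d <- make_fixture("pairsym")
  fit <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                      wbgt2 = FALSE))
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  # and the likelihood-ratio statistic of that fit is zero
  expect_equal(fit_diagnostics(fit)$lr, 0, tolerance = 1e-10)
})

test_that("1:1 fits equal the difference-logistic oracle", {
  d <- simulate_matched_sets(300, n_ref = 1, beta = 0.4, seed = 9)
  spec <- cc_design_spec("continuous", wbgt1 = FALSE, wbgt2 = FALSE)
  fit <- fit_clogit(d, spec)
  # classical matched-pair equivalence: logistic on within-set differences
  # with intercept omitted and all responses 1
  xc <- d$wbgt0_c[d$is_case == 1]
  xr <- d$wbgt0_c[d$is_case == 0]
  or_oracle <- suppressWarnings(
    glm(rep(1, 300) ~ 0 + I(xc - xr), family = binomial()))
  expect_equal(unname(fit$coef), unname(coef(or_oracle)), tolerance = 1e-6)
})

test_that("estimates agree with the survival-package fit", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- simulate_matched_sets(400, beta = 0.5, seed = 17)
  fit <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                      wbgt2 = FALSE))
  cl <- survival::clogit(is_case ~ wbgt0_c + strata(set_id), data = d)
  expect_equal(unname(fit$coef), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(fit$table$se), sqrt(diag(vcov(cl))[[1]]),
               tolerance = 1e-6)
})

test_that("set-constant covariates cancel from the fit", {
  d <- simulate_matched_sets(200, beta = 0.6, seed = 3)
  d$constant_attr <- c("p", "q")[(d$set_id %% 2) + 1]  # varies only between sets
  spec0 <- cc_design_spec("continuous", wbgt1 = FALSE, wbgt2 = FALSE)
  spec1 <- cc_design_spec("continuous", wbgt1 = FALSE, wbgt2 = FALSE,
                          extra = "constant_attr")
  f0 <- fit_clogit(d, spec0)
  f1 <- fit_clogit(d, spec1)
  expect_equal(f0$coef, f1$coef, tolerance = 1e-12)
  expect_true("constant_attr_q" %in% f1$dropped_constant)
})

test_that("Wald interval geometry and percent transforms", {
  ci <- wald_or_ci(0, 0.1)
  expect_equal(ci$or, 1)
  expect_equal(ci$ci_lo, exp(-0.196), tolerance = 1e-12)
  expect_equal(ci$ci_hi, exp(0.196), tolerance = 1e-12)
  # the OR is the geometric mean of its bounds, for arbitrary (beta, se)
  set.seed(5)
  b <- rnorm(20); s <- runif(20, 0.01, 1)
  ci <- wald_or_ci(b, s)
  expect_equal(sqrt(ci$ci_lo * ci$ci_hi), ci$or, tolerance = 1e-12)
  # standard-error reconstruction inverts the interval
  expect_equal(se_from_ci(ci$ci_lo, ci$ci_hi), s, tolerance = 1e-12)
  expect_equal(or_percent_change(c(7.44, 0.65, 1)),
               c(644, -35, 0), tolerance = 1e-10)
})

test_that("concordance matches brute-force pair enumeration", {
  set.seed(8)
  d <- simulate_matched_sets(60, beta = 0.3, seed = 8)
  fit <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                      wbgt2 = FALSE))
  dg <- fit_diagnostics(fit)
  eta <- drop(fit$model$X %*% fit$coef)
  expect_equal(dg$concordance,
               bf_concordance(eta, fit$model$set, fit$model$case),
               tolerance = 1e-12)
  expect_identical(dg$df, 1L)
  expect_true(all(c(dg$lr, dg$wald, dg$score) >= 0))
  # a linear predictor that strictly ranks every case first has concordance 1
  f2 <- fit
  f2$model$X <- matrix(ifelse(d$is_case == 1, 40, 20), ncol = 1,
                       dimnames = list(NULL, "wbgt0_c"))
  expect_equal(fit_diagnostics(f2)$concordance, 1.0)
})

test_that("separation is reported with the offending column", {
  d <- simulate_matched_sets(50, beta = 0.3, seed = 12)
  d$wbgt0_c <- ifelse(d$is_case == 1, 40, 20)  # perfectly separating
  expect_error(
    suppressWarnings(fit_clogit(d, cc_design_spec("continuous",
                                                  wbgt1 = FALSE,
                                                  wbgt2 = FALSE))),
    "separation")
})

test_that("the per-degree effect is recovered within 3 SE", {
  d <- simulate_matched_sets(2000, beta = 0.7, seed = 2024)
  fit <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                      wbgt2 = FALSE))
  b <- fit$table[1, ]
  expect_lt(abs(b$coef - 0.7) / b$se, 3)
})

test_that("Wald intervals have near-nominal coverage; null z is calibrated", {
  covered <- logical(100)
  for (r in seq_len(100)) {
    d <- simulate_matched_sets(300, beta = 0.7, seed = 1000 + r)
    tab <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                        wbgt2 = FALSE))$table
    covered[r] <- tab$coef - 1.96 * tab$se <= 0.7 &
      0.7 <= tab$coef + 1.96 * tab$se
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)

  reject <- logical(200)
  for (r in seq_len(200)) {
    d <- simulate_matched_sets(200, beta = 0, seed = 3000 + r)
    tab <- fit_clogit(d, cc_design_spec("continuous", wbgt1 = FALSE,
                                        wbgt2 = FALSE))$table
    reject[r] <- abs(tab$z) > 1.96
  }
  # 3 binomial SDs around 0.05 at 200 replicates
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("increasing true category effects give increasing fitted ORs", {
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    d <- simulate_matched_sets(2000, exposure = "category",
                               beta = c(0, 0.7, 1.4, 2.1, 2.8),
                               seed = 500 + r)
    tab <- fit_clogit(d, cc_design_spec("category", wbgt1 = FALSE,
                                        wbgt2 = FALSE))$table
    ors <- tab$or[tab$term == "wbgt0_cat"]
    if (!is.unsorted(ors, strictly = TRUE)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
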