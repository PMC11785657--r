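# Stratified odds ratios, pairwise Wald tests between strata under
# Bonferroni / Benjamini-Hochberg control, and the one-category
# heat-safety-threshold (HST) adjustment rule.

#' Per-stratum five-category WBGT odds ratios
#'
#' Splits the matched sets by a stratification attribute (constant within a
#' set, e.g. club, region, location, year, month, climatology band), fits
#' the five-category same-hour WBGT model within each stratum (reference:
#' category 1, WBGT <= 21) and returns one row per stratum and category.
#' Categories that cannot be estimated in a stratum (absent, no within-set
#' contrast, or separation) are flagged inestimable with a reason and are
#' excluded from pairwise comparisons.
#'
#' @param data Matched-set data frame (long format).
#' @param group_var Name of the stratification column.
#' @param spec Design used within each stratum; the default keeps only the
#'   five-category WBGT-0 term (the lag terms can be retained by passing a
#'   spec with `wbgt1`/`wbgt2` switched on).
#' @param zcrit Critical value for the 95\% Wald interval.
#' @return Object of class `cc_strata`: data frame with columns `group`,
#'   `stratum`, `category`, `n_cases`, `logor`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `estimable`, `reason`.
#' @export
fit_strata <- function(data, group_var,
                       spec = cc_design_spec(wbgt0 = "category",
                                             wbgt1 = FALSE, wbgt2 = FALSE),
                       zcrit = 1.96) {
  stopifnot(group_var %in% names(data))
  labels <- as.character(data[[group_var]])
  rows <- list()
  for (st in sort(unique(labels))) {
    d <- data[labels == st, , drop = FALSE]
    n_cases <- sum(d$is_case == 1)
    fit <- tryCatch(fit_clogit(d, spec, zcrit = zcrit),
                    error = function(e) e, warning = function(w) w)
    for (cat_k in 2:5) {
      lev <- as.character(cat_k)
      out <- data.frame(group = group_var, stratum = st, category = cat_k,
                        n_cases = n_cases, logor = NA_real_, se = NA_real_,
                        or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        estimable = FALSE, reason = NA_character_)
      if (inherits(fit, "condition")) {
        out$reason <- paste("fit failed:", conditionMessage(fit))
      } else {
        hit <- fit$table$term == "wbgt0_cat" & fit$table$level == lev
        if (!any(hit)) {
          out$reason <- "category absent or without within-set contrast"
        } else {
          r <- fit$table[hit, ]
          out[c("logor", "se", "or", "ci_lo", "ci_hi")] <-
            r[c("coef", "se", "or", "ci_lo", "ci_hi")]
          out$estimable <- is.finite(r$se) && r$se < 50
          if (!out$estimable) out$reason <- "unstable standard error"
        }
      }
      rows[[length(rows) + 1L]] <- out
    }
  }
  structure(do.call(rbind, rows), class = c("cc_strata", "data.frame"))
}

#' Pairwise Wald test on two log odds ratios
#'
#' \eqn{z = (\log OR_a - \log OR_b) / \sqrt{SE_a^2 + SE_b^2}} with a
#' two-sided p-value by default; the direction records which stratum has the
#' higher odds ratio. Standard errors may be reconstructed from printed
#' intervals with [se_from_ci()].
#'
#' @param logor_a,se_a,logor_b,se_b Log odds ratios and their standard
#'   errors.
#' @param two_sided If `FALSE`, the one-sided p-value for `a > b`.
#' @return List with `z`, `p`, `direction` (`"a_higher"`, `"b_higher"` or
#'   `"equal"`).
#' @export
pairwise_wald <- function(logor_a, se_a, logor_b, se_b, two_sided = TRUE) {
  pooled <- sqrt(se_a^2 + se_b^2)
  if (any(pooled == 0)) stop("zero pooled standard error", call. = FALSE)
  z <- (logor_a - logor_b) / pooled
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  list(z = z, p = p,
       direction = ifelse(z > 0, "a_higher", ifelse(z < 0, "b_higher", "equal")))
}

#' Bonferroni per-test significance level for stratum comparisons
#'
#' The family is every unordered pair of the k strata in a group, tested at
#' `n_categories` threshold categories, so the per-test level is
#' `alpha / (choose(k, 2) * n_categories)`. With the default two categories
#' this reproduces, e.g., 0.05/42 = 1.19e-3 for 7 day-of-week strata and
#' 0.05/90 = 5.56e-4 for 10 year strata.
#'
#' @param k Number of strata (>= 2).
#' @param n_categories Number of threshold categories tested per pair.
#' @param alpha Family-wise error rate.
#' @return Per-test significance level.
#' @export
bonferroni_alpha <- function(k, n_categories = 2, alpha = 0.05) {
  if (k < 2) stop("need at least two strata", call. = FALSE)
  alpha / (choose(k, 2) * n_categories)
}

#' Benjamini-Hochberg rejection set
#'
#' Standard step-up rule at false-discovery rate `q`: reject all p-values at
#' or below the largest p_(i) with p_(i) <= i q / m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target false-discovery rate.
#' @return Logical vector marking rejected hypotheses.
#' @export
bh_adjust <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

#' All pairwise stratum comparisons at the threshold categories
#'
#' Tests every unordered pair of strata at each requested category with
#' [pairwise_wald()], then applies Bonferroni (per-test level from
#' [bonferroni_alpha()] with k counting all strata in the fit, excluding
#' only strata with no estimable category at all) and Benjamini-Hochberg
#' (over the computed p-values of the whole group family).
#'
#' @param strata A [fit_strata()] result.
#' @param categories Threshold categories compared (4 and 5 by default:
#'   "cease strenuous exercise" and "cease all exercise").
#' @param alpha Family-wise error rate / false-discovery rate.
#' @param two_sided Passed to [pairwise_wald()].
#' @return Data frame of class `cc_comparisons` with columns `group`,
#'   `stratum_a`, `stratum_b`, `category`, `z`, `p`, `direction`,
#'   `bonf_sig`, `bh_sig`; attributes `alpha_bonf`, `k`, `alpha`.
#' @export
compare_strata <- function(strata, categories = c(4, 5), alpha = 0.05,
                           two_sided = TRUE) {
  stopifnot(inherits(strata, "cc_strata"))
  est_any <- tapply(strata$estimable, strata$stratum, any)
  strat_in <- names(est_any)[est_any]
  k <- length(strat_in)
  if (k < 2) {
    warning("fewer than two strata with estimable odds ratios; ",
            "no comparisons possible", call. = FALSE)
    out <- data.frame(group = character(), stratum_a = character(),
                      stratum_b = character(), category = integer(),
                      z = numeric(), p = numeric(), direction = character(),
                      bonf_sig = logical(), bh_sig = logical())
    return(structure(out, alpha_bonf = NA_real_, k = k, alpha = alpha,
                     class = c("cc_comparisons", "data.frame")))
  }
  a_bonf <- bonferroni_alpha(k, n_categories = length(categories),
                             alpha = alpha)
  pairs <- utils::combn(sort(strat_in), 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    for (cat_k in categories) {
      ra <- strata[strata$stratum == pairs[1, j] & strata$category == cat_k, ]
      rb <- strata[strata$stratum == pairs[2, j] & strata$category == cat_k, ]
      if (nrow(ra) != 1 || nrow(rb) != 1 || !ra$estimable || !rb$estimable)
        next
      w <- pairwise_wald(ra$logor, ra$se, rb$logor, rb$se, two_sided)
      rows[[length(rows) + 1L]] <- data.frame(
        group = strata$group[1], stratum_a = pairs[1, j],
        stratum_b = pairs[2, j], category = cat_k, z = w$z, p = w$p,
        direction = w$direction)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), stratum_a = character(),
               stratum_b = character(), category = integer(), z = numeric(),
               p = numeric(), direction = character())
  out$bonf_sig <- out$p <= a_bonf
  out$bh_sig <- if (nrow(out)) bh_adjust(out$p, q = alpha) else logical(0)
  structure(out, alpha_bonf = a_bonf, k = k, alpha = alpha,
            class = c("cc_comparisons", "data.frame"))
}

# Threshold wording for a category under the default guideline scheme,
# shifted down `shift` categories (0 = current, 1 = lowered one category).
hst_interval_label <- function(category, shift = 0,
                               scheme = category_scheme()) {
  k <- category - shift
  b <- scheme$boundaries
  if (k >= 5) return(paste0("WBGT>", b[4]))
  if (k <= 1) return(paste0("WBGT<=", b[1]))
  paste0(b[k - 1], "<WBGT<=", b[k])
}

#' One-category HST adjustment for high-risk strata
#'
#' For every stratum whose odds ratio is significantly higher than another
#' stratum's under the Bonferroni rule at a threshold category, proposes
#' lowering its heat-safety thresholds by exactly one category (3 deg C):
#' 28 < WBGT <= 31 becomes 25 < WBGT <= 28 and WBGT > 31 becomes
#' 28 < WBGT <= 31. Each significant pair is then re-tested with the
#' high-risk stratum's odds ratio at the lowered category against the other
#' stratum's odds ratio at the original category; the recommendation
#' reports the smallest post-adjustment p-value per category and flags the
#' stratum if any re-test is still significant ("one-category
#' insufficient"). Benjamini-Hochberg significance is reported
#' pre-adjustment only and drives no re-test.
#'
#' @param strata A [fit_strata()] result.
#' @param comparisons A [compare_strata()] result on the same strata.
#' @return Data frame of class `cc_hst` with one row per recommended
#'   stratum: `group`, `stratum`, `orig_cat4`, `adj_cat4`, `orig_cat5`,
#'   `adj_cat5`, `magnitude_c`, `post_p_cat4`, `post_p_cat5`,
#'   `sufficient`; attribute `alpha_bonf`.
#' @export
adjust_hst <- function(strata, comparisons) {
  stopifnot(inherits(strata, "cc_strata"), inherits(comparisons, "cc_comparisons"))
  a_bonf <- attr(comparisons, "alpha_bonf")
  sig <- comparisons[comparisons$bonf_sig, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- data.frame(group = character(), stratum = character(),
                      orig_cat4 = character(), adj_cat4 = character(),
                      orig_cat5 = character(), adj_cat5 = character(),
                      magnitude_c = numeric(), post_p_cat4 = numeric(),
                      post_p_cat5 = numeric(), sufficient = logical())
    return(structure(out, alpha_bonf = a_bonf,
                     class = c("cc_hst", "data.frame")))
  }
  sig$high <- ifelse(sig$direction == "a_higher", sig$stratum_a, sig$stratum_b)
  sig$low <- ifelse(sig$direction == "a_higher", sig$stratum_b, sig$stratum_a)
  rows <- list()
  for (st in sort(unique(sig$high))) {
    sp <- sig[sig$high == st, , drop = FALSE]
    post <- c(`4` = NA_real_, `5` = NA_real_)
    ok <- TRUE
    for (i in seq_len(nrow(sp))) {
      cat_k <- sp$category[i]
      ra <- strata[strata$stratum == st & strata$category == cat_k - 1, ]
      rb <- strata[strata$stratum == sp$low[i] & strata$category == cat_k, ]
      if (nrow(ra) != 1 || !ra$estimable || nrow(rb) != 1 || !rb$estimable) {
        ok <- FALSE
        next
      }
      w <- pairwise_wald(ra$logor, ra$se, rb$logor, rb$se)
      key <- as.character(cat_k)
      post[key] <- min(post[key], w$p, na.rm = TRUE)
      if (w$p <= a_bonf && w$direction == "a_higher") ok <- FALSE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = strata$group[1], stratum = st,
      orig_cat4 = hst_interval_label(4), adj_cat4 = hst_interval_label(4, 1),
      orig_cat5 = hst_interval_label(5), adj_cat5 = hst_interval_label(5, 1),
      magnitude_c = 3,
      post_p_cat4 = post["4"], post_p_cat5 = post["5"], sufficient = ok)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$sufficient)) {
    warning("one-category lowering does not remove all significant ",
            "differences for: ",
            paste(out$stratum[!out$sufficient], collapse = ", "),
            call. = FALSE)
  }
  structure(out, alpha_bonf = a_bonf, class = c("cc_hst", "data.frame"))
}
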