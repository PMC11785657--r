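# Conditional logistic regression from the conditional likelihood:
# design construction, exact log-likelihood / gradient / Hessian,
# Newton-Raphson fitting, Wald intervals, fit diagnostics.

#' Design specification for matched-set models
#'
#' Controls how exposure covariates enter the conditional logistic model.
#' The same-hour WBGT (WBGT-0) is coded either as a single continuous
#' column in degrees Celsius or as a five-level guideline category block
#' (reference: category 1, WBGT <= 21). WBGT-1 and WBGT-2 enter as dummy
#' blocks over their lag bins (reference: the below-floor bin). Extra
#' columns of the matched-set frame can be added by name; character columns
#' become dummy blocks (reference: first sorted level), numeric columns
#' singleton terms. Columns constant within every matched set cancel from
#' the conditional likelihood and are removed before fitting.
#'
#' @param wbgt0 `"continuous"` or `"category"`.
#' @param wbgt1,wbgt2 Logical; include the lag-bin blocks.
#' @param extra Character vector of additional column names.
#' @param min_bin_count Lag bins observed on fewer rows than this are
#'   merged into their lower neighbour before dummy coding (sparse
#'   categories otherwise invite monotone likelihoods); set to 0 to keep
#'   every observed bin.
#' @return An object of class `cc_design`.
#' @export
cc_design_spec <- function(wbgt0 = c("continuous", "category"),
                           wbgt1 = TRUE, wbgt2 = TRUE,
                           extra = character(), min_bin_count = 30) {
  wbgt0 <- match.arg(wbgt0)
  structure(list(wbgt0 = wbgt0, wbgt1 = wbgt1, wbgt2 = wbgt2, extra = extra,
                 min_bin_count = min_bin_count),
            class = "cc_design")
}

# Merge sparsely observed lag bins into their lower neighbour (the topmost
# sparse bin first); a sparse reference bin absorbs the bin above it.
merge_sparse_bins <- function(x, min_count) {
  if (min_count <= 0) return(x)
  repeat {
    lev <- lag_bin_levels(x)
    if (length(lev) <= 2) return(x)
    cnt <- table(factor(x, levels = lev))
    small <- which(cnt < min_count)
    if (!length(small)) return(x)
    j <- small[length(small)]
    tgt <- if (j > 1) j - 1 else 2
    x[!is.na(x) & x == lev[j]] <- lev[tgt]
  }
}

# Dummy columns for a character/factor vector given an explicit level order.
# Returns a matrix with one column per non-reference level.
dummy_block <- function(x, levels, term) {
  f <- factor(x, levels = levels)
  if (anyNA(f)) stop("unknown level in term '", term, "'", call. = FALSE)
  if (length(levels) < 2) return(NULL)
  X <- vapply(levels[-1], function(l) as.numeric(f == l),
              numeric(length(x)))
  colnames(X) <- paste0(term, levels[-1])
  X
}

# Build the model matrix for matched-set data.
# Returns list(X, groups, term, level, dropped_constant, set, case).
cc_model_matrix <- function(data, spec) {
  stopifnot(inherits(spec, "cc_design"))
  blocks <- list(); terms <- list()
  add <- function(X, term, levels) {
    if (is.null(X) || ncol(X) == 0) return()
    blocks[[length(blocks) + 1L]] <<- X
    terms[[length(terms) + 1L]] <<- data.frame(term = term, level = levels)
  }
  if (spec$wbgt0 == "continuous") {
    add(matrix(data$wbgt0_c, ncol = 1, dimnames = list(NULL, "wbgt0_c")),
        "wbgt0", "")
  } else {
    lev <- as.character(1:5)
    lev <- lev[lev %in% unique(as.character(data$wbgt0_cat))]
    add(dummy_block(as.character(data$wbgt0_cat), lev, "wbgt0_cat"),
        "wbgt0_cat", lev[-1])
  }
  if (isTRUE(spec$wbgt1)) {
    b1 <- merge_sparse_bins(data$wbgt1_bin, spec$min_bin_count)
    lev <- lag_bin_levels(b1)
    add(dummy_block(b1, lev, "wbgt1_"), "wbgt1", lev[-1])
  }
  if (isTRUE(spec$wbgt2)) {
    b2 <- merge_sparse_bins(data$wbgt2_bin, spec$min_bin_count)
    lev <- lag_bin_levels(b2)
    add(dummy_block(b2, lev, "wbgt2_"), "wbgt2", lev[-1])
  }
  for (v in spec$extra) {
    x <- data[[v]]
    if (is.null(x)) stop("extra term '", v, "' not found", call. = FALSE)
    if (is.numeric(x)) {
      add(matrix(x, ncol = 1, dimnames = list(NULL, v)), v, "")
    } else {
      lev <- sort(unique(as.character(x)))
      add(dummy_block(as.character(x), lev, paste0(v, "_")), v, lev[-1])
    }
  }
  if (length(blocks) == 0) stop("empty design", call. = FALSE)
  X <- do.call(cbind, blocks)
  tinfo <- do.call(rbind, terms)
  groups <- rep(seq_along(blocks), vapply(blocks, ncol, 0L))

  set <- match(data$set_id, unique(data$set_id))
  case <- as.numeric(data$is_case)
  if (any(rowsum(case, set) != 1)) {
    stop("each matched set must contain exactly one case", call. = FALSE)
  }

  # drop columns with no within-set variation (they cancel exactly)
  sizes <- tabulate(set)
  varying <- vapply(seq_len(ncol(X)), function(j) {
    mu <- (rowsum(X[, j], set) / sizes)[set]
    any(abs(X[, j] - mu) > 1e-12)
  }, logical(1))
  dropped <- colnames(X)[!varying]
  X <- X[, varying, drop = FALSE]
  tinfo <- tinfo[varying, , drop = FALSE]
  groups <- groups[varying]
  groups <- match(groups, unique(groups))
  if (ncol(X) == 0) {
    stop("no columns vary within matched sets; nothing is estimable",
         call. = FALSE)
  }
  list(X = X, groups = groups, term = tinfo$term, level = tinfo$level,
       dropped_constant = dropped, set = set, case = case)
}

# Padded index matrix for per-set reductions (sets have <= ~5 observations).
cc_setindex <- function(set) {
  o <- order(set)
  sid <- set[o]
  sizes <- tabulate(sid)
  S <- length(sizes); K <- max(sizes)
  idx <- matrix(NA_integer_, S, K)
  idx[cbind(sid, sequence(sizes))] <- o
  list(S = S, K = K, idx = idx, sizes = sizes)
}

# Conditional log-likelihood core. Returns value and optionally the
# analytic gradient and Hessian (of the log-likelihood, so the Hessian is
# negative semi-definite).
cc_loglik_core <- function(beta, X, set, case, ix = cc_setindex(set),
                           want_grad = TRUE, want_hess = FALSE) {
  eta <- drop(X %*% beta)
  em <- matrix(eta[ix$idx], ix$S, ix$K)
  m <- do.call(pmax, c(lapply(seq_len(ix$K), function(k) em[, k]),
                       list(na.rm = TRUE)))
  Z <- rowSums(exp(em - m), na.rm = TRUE)
  ll <- sum(eta[case == 1]) - sum(m + log(Z))
  out <- list(loglik = ll)
  if (want_grad || want_hess) {
    w <- exp(eta - m[set]) / Z[set]
    out$gradient <- drop(crossprod(X, case - w))
    if (want_hess) {
      Xw <- X * w
      M <- rowsum(Xw, set)
      out$hessian <- -(crossprod(X, Xw) - crossprod(M))
    }
    out$weights <- w
  }
  out
}

#' Conditional log-likelihood, gradient and Hessian
#'
#' Evaluates the exact conditional likelihood of matched-set data,
#' \eqn{\log L = \sum_s [x_{case,s}\beta - \log \sum_{j \in s} e^{x_j\beta}]},
#' with analytic first and second derivatives. Covariates constant within a
#' set contribute zero to every derivative (they cancel).
#'
#' @param beta Coefficient vector.
#' @param data Matched-set data frame (long format, see
#'   [build_matched_sets()]).
#' @param spec A [cc_design_spec()].
#' @return List with `loglik`, `gradient`, `hessian` and the column
#'   bookkeeping (`term`, `level`).
#' @export
conditional_loglik <- function(beta, data, spec = cc_design_spec()) {
  mm <- cc_model_matrix(data, spec)
  stopifnot(length(beta) == ncol(mm$X))
  core <- cc_loglik_core(beta, mm$X, mm$set, mm$case, want_hess = TRUE)
  core$term <- mm$term; core$level <- mm$level
  core
}

cc_newton <- function(X, set, case, maxit = 50, tol_grad = 1e-8,
                      tol_ll = 1e-10) {
  ix <- cc_setindex(set)
  p <- ncol(X)
  beta <- rep(0, p)
  core <- cc_loglik_core(beta, X, set, case, ix, want_hess = TRUE)
  conv <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    A <- -core$hessian
    step <- tryCatch(solve(A, core$gradient), error = function(e) NULL)
    if (is.null(step)) {  # singular information: ridge-jitter retry
      step <- tryCatch(solve(A + diag(1e-8 * max(diag(A)), p), core$gradient),
                       error = function(e) NULL)
      if (is.null(step)) {
        stop("singular information matrix; model not estimable", call. = FALSE)
      }
    }
    # step-halving to guarantee ascent
    lam <- 1
    repeat {
      cand <- beta + lam * step
      core2 <- cc_loglik_core(cand, X, set, case, ix, want_hess = TRUE)
      if (is.finite(core2$loglik) && core2$loglik >= core$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    dll <- abs(core2$loglik - core$loglik) /
      max(1, abs(core2$loglik))
    beta <- cand; core <- core2
    if (max(abs(beta)) > 20 && max(abs(core$gradient)) > tol_grad) {
      j <- which.max(abs(beta))
      stop("apparent separation (monotone likelihood) on column '",
           colnames(X)[j], "'", call. = FALSE)
    }
    if (max(abs(core$gradient)) < tol_grad || dll < tol_ll) {
      conv <- TRUE
      break
    }
  }
  # a perfect fit (log-likelihood at its upper bound 0) means some column
  # separates the cases: monotone likelihood, no finite MLE
  if (conv && core$loglik > -1e-8 * max(set)) {
    sdx <- apply(X, 2, stats::sd)
    j <- which.max(abs(beta) * sdx)
    stop("apparent separation (monotone likelihood) on column '",
         colnames(X)[j], "'", call. = FALSE)
  }
  vcov <- tryCatch(solve(-core$hessian), error = function(e)
    solve(-core$hessian + diag(1e-8 * max(diag(-core$hessian)), p)))
  list(beta = beta, vcov = vcov, loglik = core$loglik,
       gradient = core$gradient, hessian = core$hessian,
       iterations = it, converged = conv,
       loglik_null = cc_loglik_core(rep(0, p), X, set, case, ix,
                                    want_grad = FALSE)$loglik)
}

#' Fit a conditional logistic regression on matched sets
#'
#' Newton-Raphson from beta = 0 on the exact conditional likelihood;
#' standard errors come from the inverse observed information, confidence
#' intervals and p-values from the Wald normal approximation.
#'
#' @param data Matched-set data frame (long format).
#' @param spec A [cc_design_spec()].
#' @param maxit Maximum Newton iterations.
#' @param tol_grad Convergence threshold on the max absolute gradient.
#' @param tol_ll Convergence threshold on the relative log-likelihood change.
#' @param zcrit Critical value for the 95\% Wald interval.
#' @return Object of class `cc_clogit` with a tidy coefficient table
#'   (`$table`), `$vcov`, `$loglik`, `$loglik_null` and the model internals
#'   used by [fit_diagnostics()].
#' @export
fit_clogit <- function(data, spec = cc_design_spec(), maxit = 50,
                       tol_grad = 1e-8, tol_ll = 1e-10, zcrit = 1.96) {
  mm <- cc_model_matrix(data, spec)
  fit <- cc_newton(mm$X, mm$set, mm$case, maxit, tol_grad, tol_ll)
  if (!fit$converged) {
    warning("Newton-Raphson did not converge in ", maxit, " iterations",
            call. = FALSE)
  }
  se <- sqrt(diag(fit$vcov))
  ci <- wald_or_ci(fit$beta, se, zcrit = zcrit)
  z <- fit$beta / se
  tab <- data.frame(
    term = mm$term, level = mm$level, column = colnames(mm$X),
    coef = fit$beta, se = se, or = ci$or, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
    z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  structure(list(
    table = tab, coef = stats::setNames(fit$beta, colnames(mm$X)),
    vcov = fit$vcov, loglik = fit$loglik, loglik_null = fit$loglik_null,
    iterations = fit$iterations, converged = fit$converged,
    gradient = fit$gradient,
    dropped_constant = mm$dropped_constant,
    n_sets = max(mm$set), n_obs = nrow(mm$X),
    model = list(X = mm$X, set = mm$set, case = mm$case),
    spec = spec, zcrit = zcrit), class = "cc_clogit")
}

#' @export
print.cc_clogit <- function(x, ...) {
  cat("Conditional logistic regression (", x$n_sets, " matched sets, ",
      x$n_obs, " observations)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), " null:", format(x$loglik_null),
      " iterations:", x$iterations, "\n")
  if (length(x$dropped_constant)) {
    cat("dropped (constant within sets):",
        paste(x$dropped_constant, collapse = ", "), "\n")
  }
  tab <- x$table
  tab[, c("coef", "se", "or", "ci_lo", "ci_hi", "z")] <-
    lapply(tab[, c("coef", "se", "or", "ci_lo", "ci_hi", "z")],
           function(v) signif(v, 4))
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab[, c("column", "coef", "se", "or", "ci_lo", "ci_hi", "z", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Wald odds ratio and confidence interval
#'
#' `OR = exp(beta)` with `CI = exp(beta +/- zcrit * se)`; the odds ratio is
#' therefore the geometric mean of its interval bounds.
#'
#' @param beta Log odds ratio(s).
#' @param se Standard error(s), positive.
#' @param zcrit Critical value (1.96 for a 95\% interval).
#' @return Data frame with `or`, `ci_lo`, `ci_hi`.
#' @export
wald_or_ci <- function(beta, se, zcrit = 1.96) {
  stopifnot(all(se > 0))
  data.frame(or = exp(beta), ci_lo = exp(beta - zcrit * se),
             ci_hi = exp(beta + zcrit * se))
}

#' Reconstruct the standard error of a log odds ratio from its interval
#'
#' @param ci_lo,ci_hi Confidence interval bounds for the odds ratio.
#' @param zcrit Critical value used to form the interval.
#' @return `(log(ci_hi) - log(ci_lo)) / (2 * zcrit)`.
#' @export
se_from_ci <- function(ci_lo, ci_hi, zcrit = 1.96) {
  stopifnot(all(ci_hi > ci_lo), all(ci_lo > 0))
  (log(ci_hi) - log(ci_lo)) / (2 * zcrit)
}

#' Express an odds ratio as a percent change in odds
#'
#' @param or Positive odds ratio(s).
#' @return `(or - 1) * 100`: positive values are percent increases, negative
#'   values percent decreases (an OR of 0.65 is a 35 percent decrease).
#' @export
or_percent_change <- function(or) {
  stopifnot(all(or > 0))
  (or - 1) * 100
}

#' Diagnostics for a conditional logistic fit
#'
#' Concordance is the fraction of within-set (case, referent) pairs where
#' the case has the higher linear predictor, ties counted one half; its
#' standard error uses the ratio-estimator (set-clustered) variance.
#' The likelihood-ratio, Wald and score statistics compare the fitted model
#' with the null beta = 0. Variance inflation factors are computed from the
#' correlation matrix of the stacked design columns.
#'
#' @param fit A [fit_clogit()] object.
#' @return List with `concordance`, `concordance_se`, `lr`, `wald`, `score`,
#'   `df` and `vif` (named vector; `NA` if the correlation matrix is
#'   singular).
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "cc_clogit"))
  X <- fit$model$X; set <- fit$model$set; case <- fit$model$case
  eta <- drop(X %*% fit$coef)
  eta_case <- eta[case == 1][order(set[case == 1])]
  ref <- case == 0
  win <- (eta_case[set[ref]] > eta[ref]) + 0.5 * (eta_case[set[ref]] == eta[ref])
  u <- as.vector(rowsum(win, set[ref]))           # wins per set
  m <- as.vector(rowsum(rep(1, sum(ref)), set[ref]))  # pairs per set
  conc <- sum(u) / sum(m)
  conc_se <- sqrt(sum((u - conc * m)^2)) / sum(m)

  p <- ncol(X)
  lr <- 2 * (fit$loglik - fit$loglik_null)
  ix <- cc_setindex(set)
  info <- -cc_loglik_core(fit$coef, X, set, case, ix, want_hess = TRUE)$hessian
  wald <- drop(t(fit$coef) %*% info %*% fit$coef)
  null <- cc_loglik_core(rep(0, p), X, set, case, ix, want_hess = TRUE)
  score <- drop(t(null$gradient) %*% solve(-null$hessian, null$gradient))

  vif <- rep(NA_real_, p); names(vif) <- colnames(X)
  if (p == 1) {
    vif[] <- 1
  } else {
    R <- suppressWarnings(stats::cor(X))
    inv <- tryCatch(solve(R), error = function(e) NULL)
    if (!is.null(inv)) vif[] <- diag(inv)
  }
  list(concordance = conc, concordance_se = conc_se, lr = lr, wald = wald,
       score = score, df = p, vif = vif)
}
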