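# Group-lasso variable selection on the conditional likelihood:
# FISTA proximal gradient with block soft-thresholding, lambda path,
# set-level K-fold cross-validation.

# Block soft-thresholding prox for the group penalty thr_g * ||beta_g||_2.
gl_prox <- function(u, groups, thr) {
  for (g in unique(groups)) {
    j <- which(groups == g)
    nrm <- sqrt(sum(u[j]^2))
    u[j] <- if (nrm <= thr[g]) 0 else u[j] * (1 - thr[g] / nrm)
  }
  u
}

# Penalized objective: f(beta) + lambda * sum_g w_g ||beta_g||,
# f(beta) = -loglik / n_sets.
gl_pen <- function(beta, groups, w, lambda) {
  lambda * sum(w * vapply(unique(groups), function(g)
    sqrt(sum(beta[groups == g]^2)), 0))
}

# FISTA with backtracking and function-value restart.
gl_solve <- function(X, set, case, ix, groups, w, lambda, beta0,
                     maxit = 5000, tol = 1e-9, L0 = NULL) {
  S <- ix$S
  fg <- function(b) {
    core <- cc_loglik_core(b, X, set, case, ix)
    list(f = -core$loglik / S, g = -core$gradient / S)
  }
  beta <- beta0; y <- beta0; t_mom <- 1
  L <- if (is.null(L0)) 1 else L0
  cur <- fg(beta)
  obj <- cur$f + gl_pen(beta, groups, w, lambda)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    at_y <- fg(y)
    repeat {
      cand <- gl_prox(y - at_y$g / L, groups, lambda * w / L)
      d <- cand - y
      f_cand <- fg(cand)$f
      if (f_cand <= at_y$f + sum(at_y$g * d) + L / 2 * sum(d^2) + 1e-12) break
      L <- L * 2
      if (L > 1e12) break
    }
    obj_new <- fg(cand)$f + gl_pen(cand, groups, w, lambda)
    if (obj_new > obj + 1e-12) {      # restart momentum
      y <- beta; t_mom <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- cand + (t_mom - 1) / t_new * (cand - beta)
    rel <- abs(obj - obj_new) / max(1, abs(obj_new))
    beta <- cand; obj <- obj_new; t_mom <- t_new
    L <- max(L * 0.95, 1e-6)
    if (rel < tol && it > 2) { converged <- TRUE; break }
  }
  list(beta = beta, objective = obj, converged = converged, L = L)
}

#' Group-lasso path for the conditional logistic model
#'
#' Minimizes \eqn{-\frac{1}{S}\log L(\beta) + \lambda \sum_g \sqrt{p_g}
#' \|\beta_g\|_2} over a descending log-spaced lambda grid, where one group
#' is formed per categorical block (singleton groups for continuous terms)
#' and S is the number of matched sets. The smallest lambda that zeroes all
#' groups, \eqn{\lambda_{max} = \max_g \|\nabla_g f(0)\|_2 / \sqrt{p_g}},
#' anchors the grid. K-fold cross-validation assigns whole matched sets to
#' folds; the CV error is the held-out mean negative conditional
#' log-likelihood per set, and the selected lambda minimizes it.
#' Columns are scaled to unit standard deviation internally and
#' coefficients returned on the original scale.
#'
#' @param data Matched-set data frame (long format).
#' @param spec A [cc_design_spec()]; all blocks that survive within-set
#'   cancellation are penalized.
#' @param nlambda Grid size.
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda.
#' @param lambda Optional explicit lambda vector (overrides the grid);
#'   a value of 0 gives the unpenalized fit.
#' @param nfolds Number of CV folds (set to 0 to skip CV).
#' @param cv_rule `"min"` selects the lambda minimizing the CV error
#'   (prediction-optimal, tends to keep extra groups); `"1se"` selects the
#'   largest lambda within one standard error of the minimum (sparser, the
#'   usual choice when support recovery matters).
#' @param seed Seed for the fold assignment.
#' @param maxit,tol Proximal-gradient iteration cap and relative objective
#'   tolerance.
#' @return Object of class `cc_glpath`: `$path` (data frame with `lambda`,
#'   `log_lambda`, `cv_error`, `cv_se`, `n_groups`, `converged`), `$beta`
#'   (columns per lambda, original scale), `$groups`, `$group_names`,
#'   `$lambda_max`, `$selected_lambda`, `$selected_groups`, `$foldid`.
#' @export
group_lasso_path <- function(data, spec = cc_design_spec(), nlambda = 100,
                             lambda_min_ratio = 1e-4, lambda = NULL,
                             nfolds = 10, cv_rule = c("min", "1se"),
                             seed = 1, maxit = 5000, tol = 1e-8) {
  cv_rule <- match.arg(cv_rule)
  mm <- cc_model_matrix(data, spec)
  X <- mm$X; set <- mm$set; case <- mm$case; groups <- mm$groups
  ix <- cc_setindex(set)
  S <- ix$S
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Xs <- sweep(X, 2, sds, "/")
  gnames <- tapply(mm$term, groups, function(x) x[1])
  pg <- as.vector(table(groups))
  w <- sqrt(pg)

  g0 <- -cc_loglik_core(rep(0, ncol(Xs)), Xs, set, case, ix)$gradient / S
  lambda_max <- max(vapply(unique(groups), function(g)
    sqrt(sum(g0[groups == g]^2)), 0) / w)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  fit_path <- function(Xf, setf, casef, lambdas) {
    ixf <- cc_setindex(setf)
    B <- matrix(0, ncol(Xf), length(lambdas))
    conv <- logical(length(lambdas))
    b <- rep(0, ncol(Xf)); L <- NULL
    for (i in seq_along(lambdas)) {
      sol <- gl_solve(Xf, setf, casef, ixf, groups, w, lambdas[i], b,
                      maxit = maxit, tol = tol, L0 = L)
      b <- sol$beta; L <- sol$L
      B[, i] <- b; conv[i] <- sol$converged
    }
    list(beta = B, converged = conv)
  }

  full <- fit_path(Xs, set, case, lambda)
  if (any(!full$converged)) {
    warning("proximal gradient did not converge at ",
            sum(!full$converged), " lambda value(s); curve still emitted",
            call. = FALSE)
  }
  n_groups <- apply(full$beta, 2, function(b)
    sum(vapply(unique(groups), function(g) any(b[groups == g] != 0),
               logical(1))))

  cv_error <- cv_se <- rep(NA_real_, length(lambda))
  foldid <- NULL
  if (nfolds >= 2) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
                add = TRUE)
      }
      set.seed(seed)
    }
    foldid <- sample(rep_len(seq_len(nfolds), S))
    fold_err <- matrix(NA_real_, nfolds, length(lambda))
    for (k in seq_len(nfolds)) {
      in_train <- foldid[set] != k
      tr_set <- match(set[in_train], unique(set[in_train]))
      pf <- fit_path(Xs[in_train, , drop = FALSE], tr_set, case[in_train],
                     lambda)
      te <- !in_train
      te_set <- match(set[te], unique(set[te]))
      ixe <- cc_setindex(te_set)
      for (i in seq_along(lambda)) {
        ll <- cc_loglik_core(pf$beta[, i], Xs[te, , drop = FALSE], te_set,
                             case[te], ixe, want_grad = FALSE)$loglik
        fold_err[k, i] <- -ll / ixe$S
      }
    }
    cv_error <- colMeans(fold_err)
    cv_se <- apply(fold_err, 2, stats::sd) / sqrt(nfolds)
  }

  sel <- if (all(is.na(cv_error))) NA_integer_ else which.min(cv_error)
  if (!is.na(sel) && cv_rule == "1se") {
    thr <- cv_error[sel] + cv_se[sel]
    sel <- which(cv_error <= thr)[1]  # lambdas are in decreasing order
  }
  beta_orig <- sweep(full$beta, 1, sds, "/")
  rownames(beta_orig) <- colnames(X)
  selected_groups <- if (is.na(sel)) character() else
    unname(gnames[vapply(unique(groups), function(g)
      any(full$beta[groups == g, sel] != 0), logical(1))])
  structure(list(
    path = data.frame(lambda = lambda, log_lambda = log(lambda),
                      cv_error = cv_error, cv_se = cv_se,
                      n_groups = n_groups, converged = full$converged),
    beta = beta_orig, groups = groups, group_names = unname(gnames),
    lambda_max = lambda_max,
    selected_lambda = if (is.na(sel)) NA_real_ else lambda[sel],
    selected_groups = selected_groups, cv_rule = cv_rule, foldid = foldid,
    term = mm$term, level = mm$level), class = "cc_glpath")
}

#' @export
print.cc_glpath <- function(x, ...) {
  cat("Group-lasso path over", nrow(x$path), "lambda values (lambda_max =",
      format(x$lambda_max, digits = 4), ")\n")
  if (!is.na(x$selected_lambda)) {
    cat("selected lambda:", format(x$selected_lambda, digits = 4),
        "-> groups:", paste(x$selected_groups, collapse = ", "), "\n")
  }
  invisible(x)
}
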