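# Independent oracles: direct per-set enumeration of the conditional
# likelihood, numerical derivatives, and brute-force concordance. These
# deliberately avoid the package's vectorized code paths.

bf_loglik <- function(beta, X, set, case) {
  ll <- 0
  for (s in unique(set)) {
    rows <- which(set == s)
    eta <- as.vector(X[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[rows] == 1] - log(sum(exp(eta)))
  }
  ll
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

num_hess <- function(f, x, h = 1e-5) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h
    ej <- rep(0, p); ej[j] <- h
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  (H + t(H)) / 2
}

bf_concordance <- function(eta, set, case) {
  wins <- 0; pairs <- 0
  for (s in unique(set)) {
    rows <- which(set == s)
    ec <- eta[rows][case[rows] == 1]
    for (er in eta[rows][case[rows] == 0]) {
      pairs <- pairs + 1
      if (ec > er) wins <- wins + 1
      else if (ec == er) wins <- wins + 0.5
    }
  }
  wins / pairs
}

# Random small matched-set instances for oracle-equivalence checks.
random_instance <- function(n_sets = 5, p = 3, max_size = 4) {
  sizes <- sample(2:max_size, n_sets, replace = TRUE)
  set <- rep(seq_len(n_sets), sizes)
  n <- length(set)
  X <- matrix(rnorm(n * p), n, p)
  case <- unlist(lapply(sizes, function(k) {
    v <- rep(0, k); v[sample.int(k, 1)] <- 1; v
  }))
  list(X = X, set = set, case = case)
}

# Matched-set data with signal on WBGT-0 and WBGT-1 only, plus pure-noise
# covariate blocks, for selection studies.
sim_lasso_data <- function(n_sets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- 5
  n <- n_sets * k
  w0 <- 25 + rnorm(n, 0, 3)
  w1v <- 20 + rnorm(n, 0, 4)
  w2v <- 20 + rnorm(n, 0, 4)
  eta <- 0.4 * w0 + 0.15 * pmax(w1v - 15, 0)
  d <- data.frame(
    set_id = rep(seq_len(n_sets), each = k),
    wbgt0_c = w0, wbgt0_cat = wbgt_category(w0),
    wbgt1_bin = lag_bin(w1v), wbgt2_bin = lag_bin(w2v),
    noise1 = rnorm(n),
    noise2 = sample(c("a", "b", "c"), n, replace = TRUE))
  em <- matrix(eta, nrow = k)
  pm <- exp(sweep(em, 2, apply(em, 2, max)))
  pm <- sweep(pm, 2, colSums(pm), "/")
  pick <- vapply(seq_len(n_sets), function(s)
    sample.int(k, 1, prob = pm[, s]), 0L)
  d$is_case <- 0L
  d$is_case[(seq_len(n_sets) - 1) * k + pick] <- 1L
  d
}
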