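# Shared builders for small in-code fixtures.

t20 <- function(n, start = "2019-06-01") {
  as.POSIXct(start, tz = "UTC") + 1200 * (seq_len(n) - 1)
}

t10 <- function(n, start = "2019-06-01") {
  as.POSIXct(start, tz = "UTC") + 600 * (seq_len(n) - 1)
}

toy_meta <- function(m = 3, loq = rep(6, m), a = rep(0.1, m),
                     aqs = NA_real_, rac = NA_real_) {
  compoundMeta(sprintf("c%02d", seq_len(m)), loq = loq, error_fraction = a,
               aqs = aqs, rac = rac)
}

toy_cm <- function(values, meta = toy_meta(ncol(values)), start = "2019-06-01") {
  values <- as.matrix(values)
  colnames(values) <- meta$compound_id
  ConcentrationMatrix(t20(nrow(values), start), values, meta)
}

# small rank-p factorization instance with strictly positive entries
toy_factorization <- function(n, m, p, seed = 1, noise = 0) {
  set.seed(seed)
  G0 <- matrix(rgamma(n * p, shape = 2, rate = 1), n, p)
  F0 <- matrix(rgamma(p * m, shape = 2, rate = 0.1), p, m)
  X <- G0 %*% F0
  if (noise > 0) X <- X * (1 + matrix(rnorm(n * m, 0, noise), n, m))
  X[X <= 0] <- 1e-6
  list(X = X, G = G0, F = F0, U = matrix(1, n, m))
}

# a reduced synthetic campaign for fast end-to-end tests
small_campaign <- function(seed = 1, days = 10) {
  simulateCampaign(seed = seed, days = days)
}

fast_ctrl <- function(n_runs = 2, max_iter = 400)
  pmfControl(n_runs = n_runs, max_iter = max_iter, tol = 1e-7, tol_span = 5)
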