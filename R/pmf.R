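## Uncertainty-weighted, nonnegativity-constrained, robust positive matrix
## factorization. The objective is the weighted least squares
##   Q = sum_ij ((x_ij - sum_k g_ik f_kj) / u_ij)^2
## minimized over F, G >= 0 by hierarchical alternating least squares:
## each factor's contribution column and profile row is replaced by its
## exact nonnegative blockwise minimizer, so the objective descends
## monotonically for fixed weights. Robust mode re-weights iteratively: a cell whose scaled
## residual |e/u| exceeds the cutoff has its effective uncertainty inflated
## to |e|/cutoff on the next pass, capping its influence; Q_robust is
## reported excluding those cells while Q_true keeps all of them.

#' PMF fitting configuration
#'
#' @param n_runs random starts for [fitPmfMulti()] (default 20).
#' @param robust_cutoff scaled-residual threshold |e/u| beyond which a cell is
#'   down-weighted during fitting and excluded from Q_robust (default 4;
#'   \code{Inf} disables robust mode).
#' @param max_iter maximum solver sweeps.
#' @param tol relative change of the objective below which an iteration
#'   counts as converged.
#' @param tol_span consecutive converged iterations required to stop.
#' @param robust_every sweeps between robust re-weightings.
#' @param robust_burnin sweeps before the first re-weighting.
#' @return configuration list.
#' @export
pmfControl <- function(n_runs = 20, robust_cutoff = 4, max_iter = 5000,
                       tol = 1e-8, tol_span = 10, robust_every = 10,
                       robust_burnin = 30) {
  stopifnot(n_runs >= 1, robust_cutoff > 0, max_iter >= 1, tol > 0)
  list(n_runs = n_runs, robust_cutoff = robust_cutoff, max_iter = max_iter,
       tol = tol, tol_span = tol_span, robust_every = robust_every,
       robust_burnin = robust_burnin)
}

## core solver: weighted hierarchical alternating least squares. Each sweep
## updates every contribution column and profile row with its exact
## nonnegative blockwise minimizer (the per-cell weights make the problem
## separable across rows for a fixed factor), so the objective descends
## monotonically for fixed weights; X, U strictly positive matrices.
.pmf_hals <- function(X, U, p, seed, control, keep_history = FALSE) {
  n <- nrow(X); m <- ncol(X)
  set.seed(seed)
  cmean <- colMeans(X)
  Fm <- matrix(runif(p * m), p, m) * rep(cmean, each = p)
  G <- matrix(runif(n * p), n, p)
  Ueff <- U
  W2 <- 1 / Ueff^2
  GF <- G %*% Fm
  Q0 <- sum(W2 * X^2)  # objective of the zero model; absolute scale
  Qprev <- Inf
  ok_run <- 0L
  hist <- if (keep_history) numeric(control$max_iter) else NULL
  it <- 0L
  converged <- FALSE
  while (it < control$max_iter) {
    it <- it + 1L
    for (k in seq_len(p)) {
      fk <- Fm[k, ]
      Rk <- X - GF + tcrossprod(G[, k], fk)
      num <- (W2 * Rk) %*% fk
      den <- W2 %*% (fk^2)
      g <- as.numeric(num) / as.numeric(den)
      g[!is.finite(g) | g < 0] <- 0
      GF <- GF + tcrossprod(g - G[, k], fk)
      G[, k] <- g
    }
    for (k in seq_len(p)) {
      gk <- G[, k]
      Rk <- X - GF + tcrossprod(gk, Fm[k, ])
      num <- crossprod(W2 * Rk, gk)
      den <- crossprod(W2, gk^2)
      f <- as.numeric(num) / as.numeric(den)
      f[!is.finite(f) | f < 0] <- 0
      GF <- GF + tcrossprod(gk, f - Fm[k, ])
      Fm[k, ] <- f
    }
    GF <- G %*% Fm  # refresh: incremental updates accumulate round-off
    Q <- sum(W2 * (X - GF)^2)
    if (keep_history) hist[it] <- Q
    if (Q <= 1e-12 * Q0) { converged <- TRUE; break }  # exact factorization
    if (is.finite(Qprev) &&
        abs(Qprev - Q) <= control$tol * max(Q, .Machine$double.xmin)) {
      ok_run <- ok_run + 1L
      if (ok_run >= control$tol_span) { converged <- TRUE; break }
    } else ok_run <- 0L
    Qprev <- Q
    if (is.finite(control$robust_cutoff) && it >= control$robust_burnin &&
        it %% control$robust_every == 0L) {
      E <- X - GF
      r <- abs(E) / U
      over <- r > control$robust_cutoff
      nchg <- sum(over != (Ueff > U))
      if (nchg > 0L) {
        Ueff <- U
        Ueff[over] <- abs(E[over]) / control$robust_cutoff
        W2 <- 1 / Ueff^2
        ## a materially different mask changes the objective: restart the
        ## convergence counter; borderline single-cell flips do not
        if (nchg > max(1, 0.001 * n * m)) { Qprev <- Inf; ok_run <- 0L }
      }
    }
  }
  list(G = G, F = Fm, iterations = it, converged = converged,
       history = if (keep_history) hist[seq_len(it)] else NULL)
}

## fix scale/order ambiguity: contribution columns to mean 1, factors ordered
## by decreasing fitted mass
.pmf_normalize <- function(G, Fm) {
  s <- colMeans(G)
  s[s <= 0] <- 1
  G <- sweep(G, 2L, s, `/`)
  Fm <- sweep(Fm, 1L, s, `*`)
  mass <- colSums(G) * rowSums(Fm)
  ord <- order(mass, decreasing = TRUE)
  list(G = G[, ord, drop = FALSE], F = Fm[ord, , drop = FALSE])
}

.pmf_is_degenerate <- function(G, Fm) {
  mass <- colSums(G) * rowSums(Fm)
  any(mass < 1e-8 * sum(mass))
}

#' Fit a single PMF model
#'
#' One random start of the weighted nonnegative HALS solver, with
#' iterative robust re-weighting. Deterministic given \code{seed}.
#'
#' @param X strictly positive data matrix (samples x species), typically the
#'   LOQ/2-substituted output of [preparePmfInput()].
#' @param U matching strictly positive uncertainty matrix.
#' @param p number of factors (1 <= p < min(n, m)).
#' @param seed integer RNG seed for the random start.
#' @param control a [pmfControl()] list.
#' @param m_good number of good-class species for the expected objective;
#'   defaults to \code{ncol(X)}.
#' @param keep_history if TRUE, the per-iteration objective is attached as
#'   attribute \code{"qHistory"}.
#' @return A \linkS4class{PMFModel}.
#' @export
fitPmf <- function(X, U, p, seed = 1L, control = pmfControl(),
                   m_good = ncol(X), keep_history = FALSE) {
  X <- as.matrix(X); U <- as.matrix(U)
  if (!all(dim(X) == dim(U))) stop("X and U must be conformable")
  if (any(X <= 0) || any(U <= 0)) stop("X and U must be strictly positive")
  if (p < 1 || p >= min(dim(X))) stop("need 1 <= p < min(n, m)")
  fit <- .pmf_hals(X, U, p, seed, control, keep_history)
  if (.pmf_is_degenerate(fit$G, fit$F)) {
    fit2 <- .pmf_hals(X, U, p, seed + 5000L, control, keep_history)
    if (!.pmf_is_degenerate(fit2$G, fit2$F)) fit <- fit2
    else warning("degenerate factor (near-zero fitted mass) after re-seeding")
  }
  nf <- .pmf_normalize(fit$G, fit$F)
  E <- X - nf$G %*% nf$F
  r2 <- (E / U)^2
  excluded <- sqrt(r2) > control$robust_cutoff
  Qtrue <- sum(r2)
  Qrobust <- sum(r2[!excluded])
  qe <- tryCatch(qExpected(nrow(X), m_good, p), error = function(e) NA_real_)
  model <- new("PMFModel", F = nf$F, G = nf$G, X = X, U = U,
               Qtrue = Qtrue, Qrobust = Qrobust,
               Qexp = qe,
               excluded = excluded, converged = fit$converged,
               iterations = as.integer(fit$iterations), runQ = Qrobust,
               seed = as.integer(seed))
  if (keep_history) attr(model, "qHistory") <- fit$history
  model
}

#' Multi-start PMF fit with stability report
#'
#' Runs \code{control$n_runs} fits from seeds \code{seed .. seed + n_runs - 1}
#' and keeps the lowest-Q_robust model. The relative spread of the run
#' objectives is the stability diagnostic: a solution is considered stable
#' when the runs agree closely.
#'
#' @inheritParams fitPmf
#' @return The best \linkS4class{PMFModel}; its \code{runQ} slot holds all
#'   run objectives and attribute \code{"stability"} their relative spread
#'   \code{(max - min)/min}.
#' @export
fitPmfMulti <- function(X, U, p, seed = 1L, control = pmfControl(),
                        m_good = ncol(X)) {
  seeds <- seed + seq_len(control$n_runs) - 1L
  best <- NULL
  runQ <- numeric(control$n_runs)
  for (i in seq_along(seeds)) {
    mod <- fitPmf(X, U, p, seed = seeds[i], control = control, m_good = m_good)
    runQ[i] <- qRobust(mod)
    if (is.null(best) || qRobust(mod) < qRobust(best)) best <- mod
  }
  best@runQ <- runQ
  attr(best, "stability") <- (max(runQ) - min(runQ)) / min(runQ)
  best
}

#' Expected value of the weighted objective
#'
#' \code{n * m_good - p * (n + m_good)}: data points minus the degrees of
#' freedom of the factorization. Errors when the factorization is
#' over-parameterized (result not positive).
#'
#' @param n samples.
#' @param m_good good-class species.
#' @param p factors.
#' @return the expected objective (dimensionless).
#' @export
qExpected <- function(n, m_good, p) {
  stopifnot(n > 0, m_good > 0, p >= 0)
  q <- n * m_good - p * (n + m_good)
  if (q <= 0) stop("over-parameterized: n*m_good - p*(n+m_good) <= 0")
  q
}

#' Scan candidate factor numbers
#'
#' Fits every p in \code{p_range} with [fitPmfMulti()] and tabulates the best
#' robust objective, its ratio to the expected objective, and the multi-run
#' stability. The choice of p stays with the analyst; [detectElbow()] offers
#' a reproducible default.
#'
#' @inheritParams fitPmf
#' @param p_range integer vector of candidate factor counts.
#' @return data.frame: p, Qrobust, Qexp, ratio, stability, converged.
#' @export
scanFactorNumbers <- function(X, U, p_range = 2:(ncol(X) - 1), seed = 1L,
                              control = pmfControl(), m_good = ncol(X)) {
  rows <- lapply(p_range, function(p) {
    mod <- fitPmfMulti(X, U, p, seed = seed, control = control, m_good = m_good)
    data.frame(p = p, Qrobust = qRobust(mod), Qexp = mod@Qexp,
               ratio = qRobust(mod) / mod@Qexp,
               stability = attr(mod, "stability"),
               converged = mod@converged)
  })
  do.call(rbind, rows)
}

#' Locate the elbow of a factor-number scan
#'
#' The elbow is the largest p whose Q_robust/Q_exp still decreases
#' substantially (relative drop from p-1 above \code{drop_tol}): beyond the
#' true factor count the ratio flattens, so the last substantial decrease
#' marks the elbow. When no drop qualifies, the p maximizing the second
#' difference of the log-ratio is returned instead.
#'
#' @param scan output of [scanFactorNumbers()].
#' @param drop_tol minimum relative decrease counting as substantial
#'   (default 0.05).
#' @return the elbow p (integer).
#' @export
detectElbow <- function(scan, drop_tol = 0.05) {
  stopifnot(nrow(scan) >= 3)
  rr <- scan$ratio
  drops <- 1 - rr[-1] / rr[-length(rr)]
  cand <- which(drops > drop_tol)
  if (length(cand)) return(scan$p[max(cand) + 1L])
  l <- log(rr)
  d2 <- l[-c(1, 2)] + l[-c(nrow(scan) - 1, nrow(scan))] -
    2 * l[-c(1, nrow(scan))]
  scan$p[which.max(d2) + 1L]
}

#' Factor fingerprints and the contribution filter
#'
#' \code{percent[k, j]} is the percentage of species j's total profile mass
#' carried by factor k (columns sum to 100 for species with nonzero mass).
#' Pairs at or above the cutoff form the filtered fingerprint set.
#'
#' @param model a \linkS4class{PMFModel}.
#' @param cutoff_percent inclusion threshold (default 25, inclusive).
#' @return list of class \code{"FingerprintTable"}: \code{percent} (p x m),
#'   \code{filtered_pairs} (data.frame factor/species/percent),
#'   \code{undefined_species} (ids with an all-zero profile column).
#' @export
fingerprints <- function(model, cutoff_percent = 25) {
  Fm <- profiles(model)
  tot <- colSums(Fm)
  pct <- sweep(Fm, 2L, ifelse(tot > 0, tot, NA), `/`) * 100
  idx <- which(!is.na(pct) & pct >= cutoff_percent, arr.ind = TRUE)
  sp <- colnames(Fm)
  if (is.null(sp)) sp <- paste0("sp", seq_len(ncol(Fm)))
  pairs <- data.frame(factor = idx[, 1], species = sp[idx[, 2]],
                      percent = pct[idx])
  pairs <- pairs[order(pairs$factor, -pairs$percent), , drop = FALSE]
  structure(list(percent = pct, filtered_pairs = pairs,
                 undefined_species = sp[tot == 0],
                 cutoff_percent = cutoff_percent),
            class = "FingerprintTable")
}

#' @export
print.FingerprintTable <- function(x, ...) {
  cat(sprintf("FingerprintTable: %d factor-species pairs at >= %g%%\n",
              nrow(x$filtered_pairs), x$cutoff_percent))
  print(x$filtered_pairs, row.names = FALSE)
  invisible(x)
}

#' Per-species goodness of fit
#'
#' R^2 of fitted versus observed concentrations per species, and their mean.
#' Zero-variance species are flagged and excluded from the mean.
#'
#' @param model a \linkS4class{PMFModel}.
#' @param X optional observed matrix (default: the model's input).
#' @return list: \code{r2} (per species), \code{mean_r2},
#'   \code{undefined_species}.
#' @export
perSpeciesFit <- function(model, X = model@X) {
  C <- fitted(model)
  ss_res <- colSums((X - C)^2)
  ctr <- sweep(X, 2L, colMeans(X))
  ss_tot <- colSums(ctr^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  names(r2) <- colnames(X)
  list(r2 = r2, mean_r2 = mean(r2, na.rm = TRUE),
       undefined_species = colnames(X)[ss_tot == 0])
}

#' Moving-block bootstrap of a PMF solution
#'
#' Resamples rows in moving blocks, refits each replicate, and maps the
#' replicate factors onto the base factors by best profile cosine
#' similarity. Unmapped factors (best cosine below \code{map_threshold}) are
#' counted, never silently dropped.
#'
#' @param model the base \linkS4class{PMFModel}.
#' @param reps bootstrap replicates (0 gives an empty result).
#' @param block rows per moving block (default 50, about 17 h of 20-min
#'   samples).
#' @param seed integer RNG seed.
#' @param control a [pmfControl()]; for speed, replicate fits default to the
#'   base control with a single run.
#' @param map_threshold cosine similarity below which a replicate factor is
#'   unmapped (default 0.6).
#' @return list of class \code{"PMFBootstrap"}: \code{mapping_rate} (per base
#'   factor), \code{profile_quantiles} (per factor, 2.5/50/97.5% of mapped
#'   profiles), \code{n_unmapped}, \code{reps}.
#' @export
pmfBootstrap <- function(model, reps = 100, block = 50, seed = 1L,
                         control = pmfControl(n_runs = 1),
                         map_threshold = 0.6) {
  p <- nFactors(model)
  if (reps == 0)
    return(structure(list(mapping_rate = numeric(0),
                          profile_quantiles = list(), n_unmapped = 0L,
                          reps = 0L), class = "PMFBootstrap"))
  X <- model@X; U <- model@U
  n <- nrow(X)
  block <- min(block, n)
  set.seed(seed)
  mapped <- matrix(0L, reps, p)
  prof <- vector("list", p)
  for (k in seq_len(p)) prof[[k]] <- matrix(NA_real_, reps, ncol(X))
  n_unmapped <- 0L
  for (b in seq_len(reps)) {
    starts <- sample.int(n - block + 1L, ceiling(n / block), replace = TRUE)
    idx <- as.vector(vapply(starts, function(s) s + seq_len(block) - 1L,
                            integer(block)))[seq_len(n)]
    fit <- fitPmf(X[idx, , drop = FALSE], U[idx, , drop = FALSE], p,
                  seed = seed + b, control = control)
    mt <- matchFactors(profiles(fit), profiles(model))
    for (k in seq_len(p)) {
      if (!is.na(mt$permutation[k]) && mt$similarity[k] >= map_threshold) {
        mapped[b, k] <- 1L
        prof[[k]][b, ] <- profiles(fit)[mt$permutation[k], ]
      } else n_unmapped <- n_unmapped + 1L
    }
  }
  pq <- lapply(seq_len(p), function(k) {
    rows <- which(mapped[, k] == 1L)
    if (!length(rows)) return(NULL)
    apply(prof[[k]][rows, , drop = FALSE], 2L, quantile,
          probs = c(0.025, 0.5, 0.975))
  })
  structure(list(mapping_rate = colMeans(mapped), profile_quantiles = pq,
                 n_unmapped = n_unmapped, reps = reps),
            class = "PMFBootstrap")
}

#' @export
print.PMFBootstrap <- function(x, ...) {
  cat(sprintf("PMFBootstrap: %d replicates; mapping rate per factor: %s\n",
              x$reps, paste(sprintf("%.2f", x$mapping_rate), collapse = ", ")))
  invisible(x)
}

.cosine_mat <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  An %*% t(Bn)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
  dimnames(out) <- NULL
  out
}

#' Match estimated factors to reference factors
#'
#' Factor order and scale are arbitrary in a factorization, so recovery is
#' judged after an assignment maximizing total profile cosine similarity
#' (scale-invariant). Exhaustive over all assignments for p <= 7, greedy
#' beyond; with unequal factor counts a best partial matching is returned.
#'
#' @param F_est estimated profile matrix (factors in rows).
#' @param F_ref reference profile matrix.
#' @return list: \code{permutation} (for each reference factor, the matched
#'   estimated factor index, \code{NA} if unmatched), \code{similarity}
#'   (cosine per reference factor), \code{mean_similarity}.
#' @export
matchFactors <- function(F_est, F_ref) {
  C <- .cosine_mat(F_est, F_ref)  # est x ref
  p_est <- nrow(C); p_ref <- ncol(C)
  perm <- rep(NA_integer_, p_ref)
  if (p_est == p_ref && p_ref <= 7) {
    perms <- .permutations(p_ref)
    sc <- perms
    total <- vapply(seq_len(nrow(perms)), function(r)
      sum(C[cbind(perms[r, ], seq_len(p_ref))]), numeric(1))
    perm <- perms[which.max(total), ]
  } else {
    avail_e <- seq_len(p_est); avail_r <- seq_len(p_ref)
    for (step in seq_len(min(p_est, p_ref))) {
      sub <- C[avail_e, avail_r, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      perm[avail_r[best[2]]] <- avail_e[best[1]]
      avail_e <- avail_e[-best[1]]; avail_r <- avail_r[-best[2]]
    }
  }
  perm <- as.integer(perm)
  sim <- as.numeric(ifelse(is.na(perm), NA_real_, C[cbind(perm, seq_len(p_ref))]))
  list(permutation = perm, similarity = sim,
       mean_similarity = mean(sim, na.rm = TRUE))
}
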