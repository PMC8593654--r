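test_that("expected objective follows n*m_good - p*(n + m_good)", {
  expect_equal(qExpected(2560, 14, 6), 20396)
  expect_equal(qExpected(10, 4, 0), 40)   # no free parameters
  expect_equal(qExpected(10, 4, 2), 12)
  expect_error(qExpected(10, 4, 3), "over-parameterized")
})

test_that("an exact rank-p factorization is found to near machine precision", {
  ## multi-start is the standard protocol: single starts can plateau
  tf <- toy_factorization(120, 6, 3, seed = 21)
  mod <- fitPmfMulti(tf$X, tf$U, 3, seed = 2,
                     control = pmfControl(n_runs = 5, max_iter = 3000))
  expect_lt(qRobust(mod) / prod(dim(tf$X)), 1e-6)
  expect_lt(max(abs(fitted(mod) - tf$X) / tf$X), 1e-3)
  expect_true(all(profiles(mod) >= 0) && all(contributions(mod) >= 0))
})

test_that("rank-1 inputs recover the profile direction", {
  set.seed(4)
  g <- rgamma(80, 2); f <- rgamma(7, 2, 0.1)
  X <- outer(g, f); U <- matrix(1, 80, 7)
  mod <- fitPmf(X, U, 1, seed = 3)
  cosv <- sum(profiles(mod) * f) / sqrt(sum(profiles(mod)^2) * sum(f^2))
  expect_gt(cosv, 0.9999)
})

test_that("best-of-20 runs matches a 200-start brute-force minimum within 1%", {
  tf <- toy_factorization(30, 5, 2, seed = 31, noise = 0.15)
  U <- 0.15 * tf$X              # correctly specified relative uncertainty
  ctrl <- pmfControl(n_runs = 20, max_iter = 1000, tol = 1e-9, tol_span = 5)
  best20 <- fitPmfMulti(tf$X, U, 2, seed = 1, control = ctrl)
  brute <- min(vapply(1:200, function(s)
    qRobust(fitPmf(tf$X, U, 2, seed = 1000 + s, control = ctrl)),
    numeric(1)))
  expect_lte(qRobust(best20), brute * 1.01)
})

test_that("the objective descends monotonically for fixed weights", {
  tf <- toy_factorization(60, 6, 3, seed = 41, noise = 0.2)
  ctrl <- pmfControl(robust_cutoff = Inf, max_iter = 300)
  mod <- fitPmf(tf$X, tf$U, 3, seed = 5, control = ctrl, keep_history = TRUE)
  h <- attr(mod, "qHistory")
  expect_true(all(diff(h) <= 1e-9 * (1 + h[-length(h)])))
})

test_that("a single-run multi fit equals the single fit", {
  tf <- toy_factorization(40, 5, 2, seed = 51, noise = 0.1)
  ctrl <- pmfControl(n_runs = 1, max_iter = 300)
  m1 <- fitPmf(tf$X, tf$U, 2, seed = 9, control = ctrl)
  m2 <- fitPmfMulti(tf$X, tf$U, 2, seed = 9, control = ctrl)
  expect_identical(profiles(m1), profiles(m2))
  expect_identical(contributions(m1), contributions(m2))
})

test_that("noiseless multi-start runs all reach a vanishing objective", {
  tf <- toy_factorization(60, 5, 2, seed = 61)
  ctrl <- pmfControl(n_runs = 6, max_iter = 2000)
  mod <- fitPmfMulti(tf$X, tf$U, 2, seed = 2, control = ctrl)
  expect_true(all(mod@runQ / prod(dim(tf$X)) < 1e-6))
})

test_that("rescaling all uncertainties rescales Q but leaves the fit unchanged", {
  tf <- toy_factorization(50, 5, 2, seed = 71, noise = 0.1)
  ctrl <- pmfControl(robust_cutoff = Inf, max_iter = 400)
  m1 <- fitPmf(tf$X, tf$U, 2, seed = 4, control = ctrl)
  m2 <- fitPmf(tf$X, 2 * tf$U, 2, seed = 4, control = ctrl)
  expect_equal(qTrue(m2), qTrue(m1) / 4, tolerance = 1e-8)
  expect_equal(fitted(m2), fitted(m1), tolerance = 1e-6)
})

test_that("Q_robust never exceeds Q_true and outliers are excluded not dropped", {
  tf <- toy_factorization(80, 6, 2, seed = 81, noise = 0.05)
  X <- tf$X
  X[cbind(c(5, 17, 40), c(1, 3, 5))] <- X[cbind(c(5, 17, 40), c(1, 3, 5))] * 10
  mod <- fitPmf(X, tf$U * mean(X) * 0.05, 2, seed = 6,
                control = pmfControl(max_iter = 400))
  expect_lte(qRobust(mod), qTrue(mod))
  expect_gt(sum(mod@excluded), 0)
})

test_that("a noiseless scan shows a constructed elbow at the true rank", {
  ## robust mode off: with a grossly underfit model every cell would sit
  ## beyond the cutoff, and the exclusion would mask the misfit
  tf <- toy_factorization(80, 7, 3, seed = 91)
  ctrl <- pmfControl(n_runs = 3, max_iter = 2000, robust_cutoff = Inf)
  scan <- scanFactorNumbers(tf$X, tf$U * mean(tf$X) * 0.02, 2:5,
                            seed = 3, control = ctrl)
  ## orders-of-magnitude drop up to the true rank, essentially zero after
  expect_gt(scan$Qrobust[1] / scan$Qrobust[2], 1e3)
  expect_lt(scan$Qrobust[3] / prod(dim(tf$X)), 1e-6)
  expect_lt(scan$Qrobust[4] / prod(dim(tf$X)), 1e-6)
  expect_equal(detectElbow(scan), 3)
})

test_that("best-of-runs Q_robust is near-monotone in p on noisy input", {
  tf <- toy_factorization(60, 7, 3, seed = 92, noise = 0.1)
  U <- 0.1 * tf$X
  ctrl <- pmfControl(n_runs = 3, max_iter = 600)
  scan <- scanFactorNumbers(tf$X, U, 2:5, seed = 4, control = ctrl)
  expect_true(all(diff(scan$Qrobust) <= 0.05 * scan$Qrobust[-nrow(scan)]))
})

test_that("fingerprints normalize to 100% and filter at the inclusive cutoff", {
  set.seed(2)
  G <- matrix(rgamma(40, 2), 20, 2)
  Fm <- rbind(c(3, 10, 2), c(1, 5, 8))
  X <- G %*% Fm; U <- matrix(1, 20, 3)
  mod <- fitPmf(X, U, 1, seed = 1)           # p = 1: everything in factor 1
  fp1 <- fingerprints(mod)
  expect_true(all(abs(fp1$percent[1, ] - 100) < 1e-9))
  ## columns normalize to 100 over factors for a 2-factor fit
  mod2 <- fitPmf(X, U, 2, seed = 1, control = pmfControl(max_iter = 3000))
  fp2 <- fingerprints(mod2, cutoff_percent = 25)
  expect_equal(colSums(fp2$percent), rep(100, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## hand-made model with a 75/25 split species: both pairs pass at 25
  mm <- new("PMFModel", F = rbind(c(3, 1), c(1, 3)), G = matrix(1, 4, 2),
            X = matrix(1, 4, 2), U = matrix(1, 4, 2), Qtrue = 0, Qrobust = 0,
            Qexp = 1, excluded = matrix(FALSE, 4, 2), converged = TRUE,
            iterations = 1L, runQ = 0, seed = 1L)
  fp3 <- fingerprints(mm)
  expect_equal(sort(fp3$percent[, 1]), c(25, 75))
  expect_equal(nrow(fp3$filtered_pairs), 4L)   # 25% is inclusive
  ## a 99/1 split keeps only the dominant pair
  mm99 <- mm; mm99@F <- rbind(c(99, 1), c(1, 99))
  expect_equal(nrow(fingerprints(mm99)$filtered_pairs), 2L)
})

test_that("per-species R2 is 1 for perfect fits and 0 for mean-only fits", {
  tf <- toy_factorization(50, 4, 2, seed = 101)
  mod <- fitPmf(tf$X, tf$U, 2, seed = 2)
  fit <- perSpeciesFit(mod)
  expect_true(all(fit$r2 > 0.999))
  ## fitted constant at the species mean -> R2 = 0
  X <- tf$X
  mconst <- new("PMFModel", F = matrix(colMeans(X), 1), G = matrix(1, 50, 1),
                X = X, U = tf$U, Qtrue = 1, Qrobust = 1, Qexp = 1,
                excluded = matrix(FALSE, 50, 4), converged = TRUE,
                iterations = 1L, runQ = 1, seed = 1L)
  expect_equal(unname(perSpeciesFit(mconst)$r2), rep(0, 4), tolerance = 1e-12)
})

test_that("factor matching is scale/permutation invariant with an exhaustive oracle", {
  set.seed(7)
  Ftrue <- matrix(rgamma(5 * 9, 2, 0.1), 5, 9)
  perm <- c(3, 5, 1, 2, 4)
  Fest <- diag(runif(5, 0.5, 3)) %*% Ftrue[perm, ]
  mt <- matchFactors(Fest, Ftrue)
  expect_equal(mt$permutation, match(seq_len(5), perm))
  expect_true(all(mt$similarity > 1 - 1e-12))
  ## near-orthogonal profiles plus noise: equals brute force over all 4!
  F0 <- diag(4) %x% t(rep(1, 2)) * 10 + 0.1
  Fn <- F0[c(2, 4, 1, 3), ] + matrix(runif(32, 0, 0.2), 4)
  got <- matchFactors(Fn, F0)
  cosm <- stormPMF:::.cosine_mat(Fn, F0)
  perms <- stormPMF:::.permutations(4)
  scores <- apply(perms, 1, function(pp) sum(cosm[cbind(pp, 1:4)]))
  best <- perms[which.max(scores), ]
  expect_equal(got$permutation, best)
  ## p = 1 is the identity
  expect_equal(matchFactors(Ftrue[1, , drop = FALSE],
                            Ftrue[1, , drop = FALSE])$permutation, 1L)
  ## unequal counts: partial matching with NA for the unmatched reference
  pm <- matchFactors(Ftrue[1:3, ], Ftrue)
  expect_equal(sum(is.na(pm$permutation)), 2L)
})

test_that("bootstrap handles the degenerate and empty cases", {
  expect_equal(pmfBootstrap(fitPmf(toy_factorization(30, 4, 2)$X,
                                   matrix(1, 30, 4), 2, seed = 1),
                            reps = 0)$reps, 0L)
  tf <- toy_factorization(60, 5, 2, seed = 111)
  mod <- fitPmf(tf$X, tf$U, 2, seed = 2)
  bs <- pmfBootstrap(mod, reps = 8, block = 10, seed = 3,
                     control = pmfControl(n_runs = 1, max_iter = 1500))
  ## exact structure: every replicate maps onto every base factor
  expect_equal(bs$mapping_rate, rep(1, 2))
  expect_equal(bs$n_unmapped, 0L)
})

test_that("model container enforces its invariants", {
  expect_error(new("PMFModel", F = matrix(-1, 1, 2), G = matrix(1, 3, 1),
                   X = matrix(1, 3, 2), U = matrix(1, 3, 2), Qtrue = 1,
                   Qrobust = 1, Qexp = 1, excluded = matrix(FALSE, 3, 2),
                   converged = TRUE, iterations = 1L, runQ = 1, seed = 1L),
               "nonnegative")
  expect_error(new("PMFModel", F = matrix(1, 1, 2), G = matrix(1, 3, 1),
                   X = matrix(1, 3, 2), U = matrix(1, 3, 2), Qtrue = 1,
                   Qrobust = 2, Qexp = 1, excluded = matrix(FALSE, 3, 2),
                   converged = TRUE, iterations = 1L, runQ = 1, seed = 1L),
               "Qrobust")
})

test_that("bootstrap maps replicate factors onto the base solution at study shape", {
  sim <- simulateCampaign(seed = 2, days = 15)
  pin <- preparePmfInput(sim$cm)
  mod <- fitPmfMulti(pin$X, pin$U, 6, seed = 3,
                     control = fast_ctrl(n_runs = 2), m_good = pin$m_good)
  bs <- pmfBootstrap(mod, reps = 8, block = 50, seed = 4,
                     control = pmfControl(n_runs = 1, max_iter = 300,
                                          tol = 1e-7, tol_span = 5))
  expect_true(all(bs$mapping_rate >= 0.8))
})
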