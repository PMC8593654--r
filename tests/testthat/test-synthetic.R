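test_that("rainfall generator is deterministic and silent at zero event rate", {
  expect_identical(hydroValue(simulateRainfall(seed = 4)),
                   hydroValue(simulateRainfall(seed = 4)))
  expect_true(all(hydroValue(simulateRainfall(eventsPerDay = 0, seed = 1)) == 0))
})

test_that("generated storms respect the generator's structural promises", {
  ## events are wet spells separated by >= 2 h dry; small events stay below
  ## 1 mm/10 min; intensities capped at 15
  for (s in 1:8) {
    r <- simulateRainfall(seed = s)
    v <- hydroValue(r)
    expect_true(all(v >= 0) && max(v) <= 15)
    ev <- eventTable(segmentEvents(r))
    if (nrow(ev)) {
      expect_true(all(ev$max_intensity[ev$kind == "small"] <= 1))
      if (nrow(ev) > 1) {
        seps <- as.numeric(ev$start[-1]) - as.numeric(ev$end[-nrow(ev)])
        expect_true(all(seps >= 2 * 3600))
      }
    }
  }
})

test_that("campaign-scale statistics fall in the generator's regime", {
  ## Monte-Carlo check of the default 41-day regime: storm counts and rain
  ## totals concentrate near two dozen events and ~110 mm
  stats <- t(vapply(1:60, function(s) {
    r <- simulateRainfall(seed = 1000 + s)
    ev <- eventTable(segmentEvents(r))
    c(n = nrow(ev), large = sum(ev$kind == "large"),
      total = sum(hydroValue(r)))
  }, numeric(3)))
  expect_gt(mean(stats[, "n"]), 15); expect_lt(mean(stats[, "n"]), 30)
  expect_gt(mean(stats[, "large"]), 5); expect_lt(mean(stats[, "large"]), 12)
  expect_gt(mean(stats[, "total"]), 70); expect_lt(mean(stats[, "total"]), 180)
})

test_that("water level obeys the linear-reservoir closed form", {
  ## zero rain at baseflow stays at baseflow
  r0 <- HydroSeries(t10(50), rep(0, 50))
  lev <- simulateWaterLevel(r0, baseflow = 10)
  expect_true(all(abs(hydroValue(lev) - 10) < 1e-12))
  ## single pulse: peak then monotone decay with half-life k ln 2
  r1 <- HydroSeries(t10(800), c(0, 1, rep(0, 798)))
  k <- 6
  lev1 <- simulateWaterLevel(r1, baseflow = 10, reservoir_k = k, gain = 2)
  excess <- hydroValue(lev1) - 10
  expect_equal(which.max(excess), 2L)
  expect_true(all(diff(excess[-1]) < 0))
  half_steps <- k * log(2) * 6          # half-life in 10-min steps
  i0 <- 2L
  i1 <- i0 + round(half_steps)
  ratio <- excess[i1] / excess[i0]
  expect_equal(ratio, exp(-round(half_steps) / (k * 6)), tolerance = 1e-10)
  expect_equal(ratio, 0.5, tolerance = 0.02)
  ## linearity: doubling gain doubles the excess everywhere
  lev2 <- simulateWaterLevel(r1, baseflow = 10, reservoir_k = k, gain = 4)
  expect_equal(hydroValue(lev2) - 10, 2 * excess, tolerance = 1e-12)
  expect_error(simulateWaterLevel(r1, reservoir_k = 0), "reservoir_k")
})

test_that("noiseless, censoring-free simulation satisfies X = G F exactly", {
  rain <- simulateRainfall(days = 6, seed = 2)
  level <- simulateWaterLevel(rain)
  sc <- defaultScenario(gapFraction = 0, kappa = 0)
  meta <- defaultCompoundMeta()
  meta$error_fraction[] <- 0
  sim <- simulateConcentrations(sc, rain, level, meta, seed = 3)
  expect_equal(unname(sim$Xclean), sim$Gtrue %*% sim$Ftrue,
               tolerance = 1e-12)
  expect_equal(unname(concValues(sim$cm)), unname(sim$Xclean),
               tolerance = 1e-12)
})

test_that("measurement noise sd matches sqrt((a x)^2 + kappa LOQ^2) within 5%", {
  meta <- toy_meta(1, loq = 6, a = 0.05)
  x <- matrix(1000, 1e5, 1)
  noisy <- addMeasurementNoise(x, meta, kappa = 1, seed = 9)
  expect_equal(sd(noisy - x), sqrt((0.05 * 1000)^2 + 36), tolerance = 0.05)
  ## kappa scales the LOQ term
  noisy0 <- addMeasurementNoise(x, meta, kappa = 0, seed = 9)
  expect_equal(sd(noisy0 - x), 50, tolerance = 0.05)
})

test_that("the legacy factor dilutes: concentration minimum at level maximum", {
  rain <- simulateRainfall(days = 8, seed = 5)
  level <- simulateWaterLevel(rain)
  sc <- defaultScenario(gapFraction = 0, kappa = 0)
  ## keep only the legacy factor
  sc$profiles[2:6, ] <- 0
  meta <- defaultCompoundMeta()
  meta$error_fraction[] <- 0
  sim <- simulateConcentrations(sc, rain, level, meta, seed = 1)
  lev20 <- hydroValue(sim$level)
  conc <- sim$Xclean[, 1]
  expect_equal(which.min(conc), which.max(lev20))
})

test_that("increasing a pulse lag shifts the clean concentration peak exactly", {
  rain <- HydroSeries(t10(1000), c(rep(0, 100), 5, 3, rep(0, 898)))
  level <- simulateWaterLevel(rain)
  meta <- defaultCompoundMeta()
  base <- defaultScenario(gapFraction = 0, kappa = 0)
  base$eventSelectivity[] <- 1   # deterministic activation
  shifted <- base
  shifted$lagMin[2] <- base$lagMin[2] + 120  # +6 steps of 20 min
  sim1 <- simulateConcentrations(base, rain, level, meta, seed = 2)
  sim2 <- simulateConcentrations(shifted, rain, level, meta, seed = 2)
  sp <- 4  # primary species of factor 2
  expect_equal(which.max(sim2$Xclean[, sp]), which.max(sim1$Xclean[, sp]) + 6L)
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  s1 <- small_campaign(seed = 12, days = 5)
  s2 <- small_campaign(seed = 12, days = 5)
  expect_identical(concValues(s1$cm), concValues(s2$cm))
  expect_identical(s1$Gtrue, s2$Gtrue)
  expect_identical(gapMask(s1$cm), gapMask(s2$cm))
})

test_that("gap flags cover the configured fraction in contiguous blocks", {
  sim <- small_campaign(seed = 3, days = 10)
  g <- gapMask(sim$cm)
  expect_equal(mean(g), 0.10, tolerance = 0.02)
  expect_true(all(is.na(concValues(sim$cm)[g, ])))
})
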