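test_that("composite means equal brute-force window means", {
  meta <- toy_meta(1, loq = 1)
  ## constant series: every composite equals the constant
  cmc <- toy_cm(matrix(7, 300, 1), meta)
  sch <- samplingScheme(window = 6 * 1200)
  cc <- compositeAverage(cmc, "c01", sch)
  expect_true(all(cc$mean == 7))
  ## six samples, one window, arithmetic mean
  cm6 <- toy_cm(matrix(c(10, 10, 10, 10, 10, 70), 6, 1), meta)
  expect_equal(compositeAverage(cm6, "c01", sch)$mean, 20)
  ## synthetic pulse train vs an independent loop, to 1e-12
  set.seed(21)
  vals <- matrix(rlnorm(500, 2, 1.5), 500, 1)
  cmp <- toy_cm(vals, toy_meta(1, loq = 1e-6))  # no censoring in play
  sch2 <- samplingScheme(window = 37 * 1200, start_offset = 3 * 1200)
  got <- compositeAverage(cmp, "c01", sch2)
  tt <- as.numeric(sampleTimes(cmp))
  for (i in seq_len(nrow(got))) {
    idx <- which(tt >= as.numeric(got$start[i]) & tt < as.numeric(got$end[i]))
    expect_equal(got$mean[i], mean(vals[idx, 1]), tolerance = 1e-12)
  }
  expect_error(compositeAverage(cmc, "c01", samplingScheme(window = 60)),
               "window shorter")
})

test_that("below-LOQ rules and gap invalidation shape the composite", {
  meta <- toy_meta(1, loq = 10)
  vals <- matrix(c(4, 4, 40, 40, NA, NA), 6, 1)
  cm <- toy_cm(vals, meta)
  sch <- function(rule, mg = 0.5)
    samplingScheme(window = 6 * 1200, below_loq_rule = rule,
                   max_gap_fraction = mg)
  expect_equal(compositeAverage(cm, "c01", sch("set_to_loq"))$mean,
               mean(c(10, 10, 40, 40)))
  expect_equal(compositeAverage(cm, "c01", sch("set_to_half_loq"))$mean,
               mean(c(5, 5, 40, 40)))
  expect_equal(compositeAverage(cm, "c01", sch("zero"))$mean,
               mean(c(0, 0, 40, 40)))
  ## gap fraction 2/6 > 0.10 invalidates the window under the default limit
  got <- compositeAverage(cm, "c01", sch("set_to_loq", mg = 0.10))
  expect_false(got$valid)
})

test_that("mass consistency: composites average back to the sample mean", {
  set.seed(22)
  meta <- toy_meta(1, loq = 0.001)  # effectively no censoring
  vals <- matrix(rlnorm(600, 2, 1), 600, 1)
  cm <- toy_cm(vals, meta)
  sch <- samplingScheme(window = 60 * 1200)  # 10 windows tile 600 samples
  got <- compositeAverage(cm, "c01", sch)
  expect_true(all(got$valid))
  expect_equal(mean(got$mean), mean(vals), tolerance = 1e-12)
})

test_that("underestimation factor is 1 for constant series at every offset", {
  meta <- toy_meta(1, loq = 1)
  cm <- toy_cm(matrix(5, 504, 1), meta)
  sch <- samplingScheme(window = 72 * 1200)
  sweep_ <- startOffsetSweep(cm, "c01", sch,
                             offsets = 1200 * c(0, 7, 19, 35))
  expect_true(all(abs(sweep_$per_offset$max_factor - 1) < 1e-12))
})

test_that("single-spike worst case matches the closed form over the sweep", {
  meta <- toy_cm_meta <- toy_meta(1, loq = 0.001)
  W <- 36
  b <- 2; h <- 500
  vals <- matrix(b, 30 * W, 1)
  vals[400, 1] <- h
  cm <- toy_cm(vals, meta)
  sch <- samplingScheme(window = W * 1200)
  sw <- startOffsetSweep(cm, "c01", sch, offsets = 1200 * (0:(W - 1)))
  expect_equal(sw$max_factor, h / ((h + b * (W - 1)) / W), tolerance = 1e-10)
  ## sweep equals brute-force recomputation per offset
  for (off in 1200 * c(3, 11)) {
    sc2 <- sch; sc2$start_offset <- off
    uf <- underestimationFactor(cm, "c01", scheme = sc2)
    expect_equal(max(uf$factor),
                 sw$per_offset$max_factor[sw$per_offset$offset == off])
  }
})

test_that("underestimation is scale-invariant without substitution", {
  set.seed(23)
  meta <- toy_meta(1, loq = 1e-9)
  vals <- matrix(rlnorm(360, 3, 1), 360, 1)
  sch <- samplingScheme(window = 36 * 1200, below_loq_rule = "zero")
  f1 <- underestimationFactor(toy_cm(vals, meta), "c01", scheme = sch)$factor
  f2 <- underestimationFactor(toy_cm(vals * 13, meta), "c01",
                              scheme = sch)$factor
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("longer windows never shrink the worst-case single-spike factor", {
  meta <- toy_meta(1, loq = 0.001)
  vals <- matrix(1, 1008, 1); vals[500, 1] <- 300
  cm <- toy_cm(vals, meta)
  worst <- vapply(c(12, 36, 72, 144), function(W) {
    sch <- samplingScheme(window = W * 1200)
    startOffsetSweep(cm, "c01", sch, offsets = 1200 * seq(0, W - 1, by = 4))$max_factor
  }, numeric(1))
  expect_true(all(diff(worst) >= -1e-9))
})

test_that("a censored composite yields a flagged lower bound", {
  ## a sharp peak on an otherwise censored record: under the half-LOQ rule
  ## the composite stays below the LOQ, so the factor is a lower bound
  ## computed with the LOQ in the denominator
  meta <- toy_meta(1, loq = 15)
  vals <- matrix(5, 252, 1)
  vals[100, 1] <- 490
  cm <- toy_cm(vals, meta)
  sch <- samplingScheme(window = 252 * 1200, below_loq_rule = "set_to_half_loq")
  comp <- compositeAverage(cm, "c01", sch)
  expect_lt(comp$mean, 15)
  uf <- underestimationFactor(cm, "c01", comp, scheme = sch)
  expect_true(uf$bound[1])
  expect_equal(uf$factor[1], 490 / 15, tolerance = 1e-12)
  ## a composite of exactly zero is undefined, never silently divided
  sch0 <- samplingScheme(window = 252 * 1200, below_loq_rule = "zero")
  vals0 <- matrix(5, 252, 1)
  cm0 <- toy_cm(vals0, meta)
  uf0 <- underestimationFactor(cm0, "c01", scheme = sch0)
  expect_false(uf0$defined[1])
})

test_that("exceedance episodes count maximal runs of consecutive samples", {
  meta <- toy_meta(1, loq = 1, aqs = 100, rac = NA_real_)
  vals <- matrix(10, 400, 1)
  vals[c(50:52, 200, 300:305), 1] <- 150   # three disjoint supra-AQS pulses
  cm <- toy_cm(vals, meta)
  rep_ <- exceedanceAssessment(cm, scheme = samplingScheme(window = 100 * 1200))
  expect_equal(rep_$per_compound$aqs_episodes, 3L)
  expect_equal(rep_$per_compound$aqs_samples, 10L)
  expect_equal(rep_$counts$ppp_aqs_20min, 1L)
  ## below all standards -> zero exceedances
  cm0 <- toy_cm(matrix(10, 60, 1), meta)
  rep0 <- exceedanceAssessment(cm0, scheme = samplingScheme(window = 60 * 1200))
  expect_equal(rep0$counts$ppp_aqs_20min, 0L)
  ## compounds lacking both standards are listed, not tallied
  meta2 <- toy_meta(2, loq = c(1, 1))
  meta2$aqs <- c(100, NA); meta2$rac <- c(NA, NA)
  cm2 <- toy_cm(matrix(c(150, 150, 150, 150), 2, 2), meta2)
  rep2 <- exceedanceAssessment(cm2, scheme = samplingScheme(window = 2 * 1200,
                                                            max_gap_fraction = 0.5))
  expect_equal(rep2$no_standard, "c02")
  expect_equal(rep2$counts$ppp_aqs_20min, 1L)
})

test_that("the bundled worked example reproduces its published summary", {
  res <- assessAcuteSummary()
  fac <- setNames(res$factors$factor, res$factors$compound)
  expect_equal(unname(fac["azoxystrobin"]), 6300 / 490, tolerance = 1e-12)
  expect_true(res$factors$bound[res$factors$compound == "diuron"])
  expect_equal(res$counts$ppp_aqs_20min, 5L)
  expect_equal(res$counts$ppp_rac_20min, 4L)
  expect_equal(res$counts$ppp_rac_composite, 1L)
})
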