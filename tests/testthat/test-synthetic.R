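test_that("generation is reproducible given a seed and leaves the RNG alone", {
  a <- generate_cohort(truth_params(), 1500, seed = 101)
  b <- generate_cohort(truth_params(), 1500, seed = 101)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  c <- generate_cohort(truth_params(), 1500, seed = 102)
  expect_false(identical(a$records$weight_kg, c$records$weight_kg))

  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(generate_cohort(truth_params(), 100, seed = 1))
  expect_identical(runif(1), before)
})

test_that("generated records satisfy the data-model invariants", {
  syn <- generate_cohort(truth_params(), 5000, seed = 103)
  rec <- syn$records
  expect_true(all(is.na(rec$gestational_month[!rec$is_pregnant])))
  expect_true(all(!is.na(rec$gestational_month[rec$is_pregnant])))
  expect_true(all(rec$sampling_weight > 0))
  expect_true(all(rec$gestational_month[rec$is_pregnant] %in% 1:10))
  expect_s3_class(syn$meta, "country_meta")
})

test_that("the closed-form total gain is additive and matches numeric integration", {
  expect_equal(true_gwg(noiseless_params(gains = c(0, 0, 0))), 0)
  expect_equal(true_gwg(truth_params()), 6.6)

  for (seed in 1:20) {
    g <- withr_local_seed(seed, round(runif(3, -1, 5), 3))
    p <- truth_params(gain_t1_kg = g[1], gain_t2_kg = g[2], gain_t3_kg = g[3])
    # independent oracle: integrate the trajectory's slope over gestation
    slope <- function(d) {
      ifelse(d <= 90, g[1] / 90, ifelse(d <= 180, g[2] / 90, g[3] / 100))
    }
    num <- stats::integrate(slope, 0, 90)$value +
      stats::integrate(slope, 90, 180)$value +
      stats::integrate(slope, 180, 280)$value
    expect_equal(true_gwg(p), num, tolerance = 1e-12)
  }
})

test_that("noiseless single-country data sit exactly on the generating line", {
  syn <- generate_cohort(noiseless_params(gains = c(0, 3, 3)), 2000, seed = 105)
  rec <- syn$records
  preg <- rec[rec$is_pregnant & rec$gestational_month < 10, ]
  emp <- tapply(preg$weight_kg, preg$gestational_month, mean)
  expect_equal(as.numeric(emp[as.character(1:9)]), syn$truth$month_means,
               tolerance = 1e-12)
})

test_that("month-window truth integrates the piecewise line over +/- 14 days", {
  p <- truth_params(day_sampling = "window")
  truth <- generate_cohort(p, 10, seed = 1)$truth
  g <- c(1.2, 2.2, 3.2)
  curve_at <- function(d) {
    ifelse(d <= 90, g[1] * d / 90,
    ifelse(d <= 180, g[1] + g[2] * (d - 90) / 90,
           g[1] + g[2] + g[3] * (d - 180) / 100))
  }
  for (m in c(2, 3, 6, 9)) {  # month 3 and 6 windows straddle trajectory knots
    num <- stats::integrate(curve_at, m * 30 - 14, m * 30 + 14,
                            subdivisions = 400L, rel.tol = 1e-12)$value / 28
    expect_equal(truth$month_means[m] - truth$pre_pregnancy_mean, num,
                 tolerance = 1e-9, info = paste("month", m))
  }
})

test_that("the at-risk fraction matches the product of the eligibility rates", {
  syn <- generate_cohort(truth_params(), 20000, seed = 107)
  nonpreg <- syn$records[!syn$records$is_pregnant, ]
  at_risk <- filter_at_risk(syn$records)
  p <- syn$truth$at_risk_rate
  expect_equal(p, (1 - 0.25) * 0.85 * 0.75 * (1 - 0.18))
  frac <- nrow(at_risk) / nrow(nonpreg)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / nrow(nonpreg)))
})

test_that("pipeline estimates converge to the closed-form truth as noise vanishes", {
  params <- noiseless_params(day_sampling = "window")
  syn <- generate_cohort(params, 100000, seed = 109)
  fit <- estimate_gwg(syn$records, syn$meta)
  truth <- syn$truth
  expect_lt(abs(fit$trajectory$pre_pregnancy$mean - truth$pre_pregnancy_mean), 0.05)
  for (m in 1:9)
    expect_lt(abs(fit$trajectory$months[[m]]$mean - truth$month_means[m]), 0.05)
  ee <- truth$expected_estimates
  expect_lt(abs(fit$gwg$w_delivery$mean - ee$delivery), 0.05)
  expect_lt(abs(fit$gwg$gain_total$mean - ee$gain_total), 0.05)
  expect_lt(abs(fit$gwg$gain_t2$mean - ee$gain_t2), 0.05)
  # and the window convention biases the extrapolated estimates only negligibly
  expect_lt(abs(ee$gain_total - truth$gain_total), 0.01)
})

test_that("linear extrapolation underestimates delivery weight under accelerating gain", {
  params <- noiseless_params(day_sampling = "window",
                             third_trimester_shape = "quadratic")
  syn <- generate_cohort(params, 60000, seed = 111)
  fit <- estimate_gwg(syn$records, syn$meta)
  # true weight at 280 days reaches baseline + 6.6 kg, but a line fitted
  # through months 6 and 9 lags an accelerating trajectory
  expect_lt(fit$gwg$w_delivery$mean, syn$truth$delivery_weight - 0.1)
  expect_equal(fit$gwg$w_delivery$mean, syn$truth$expected_estimates$delivery,
               tolerance = 0.05)
})

test_that("stratifier gain offsets shift the truth expectations coherently", {
  effects <- list(education = list(baseline = c(secondary = 2, higher = 3),
                                   gain = c(secondary = 3, higher = 3)))
  p <- truth_params(stratifier_effects = effects)
  truth <- generate_cohort(p, 10, seed = 1)$truth
  e_gain <- 0.286 * 3 + 0.049 * 3
  e_base <- 0.286 * 2 + 0.049 * 3
  expect_equal(truth$gain_total, 6.6 + e_gain, tolerance = 1e-10)
  expect_equal(true_gwg(p), 6.6 + e_gain, tolerance = 1e-10)
  # population-weighted baseline: (206*57.8 + 115*55.2 + 90*56.1 + 59*59.8)/470
  expect_equal(truth$pre_pregnancy_mean, 26832 / 470 + e_base, tolerance = 1e-10)
})

test_that("invalid generator parameters fail before any generation", {
  expect_error(truth_params(month_distribution = rep(0.1, 9)), "summing to 1")
  expect_error(truth_params(pregnant_fraction = 0), "strictly")
  expect_error(truth_params(measurement_sd_kg = -1), "nonnegative")
  expect_error(truth_params(stratifier_effects = list(age_group = list())),
               "stratifier_effects")
  expect_error(generate_cohort(truth_params(), 0), "n_women")
})
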