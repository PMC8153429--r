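test_that("the CI-overlap rule is symmetric, closed at endpoints, and NA-safe", {
  a <- mean_estimate(5.5, n = 50L, ci_low = 5.0, ci_high = 6.0)
  b <- mean_estimate(6.7, n = 50L, ci_low = 6.5, ci_high = 7.0)
  expect_false(ci_overlap(a, b))   # disjoint -> significant difference
  expect_false(ci_overlap(b, a))   # symmetric

  touching <- mean_estimate(6.5, n = 50L, ci_low = 6.0, ci_high = 7.0)
  expect_true(ci_overlap(a, touching))  # shared endpoint counts as overlap

  single <- weighted_mean(60, 1)
  expect_true(is.na(ci_overlap(a, single)))  # not evaluable
})

test_that("the overlap rule is conservative near the 5% boundary of the z-test", {
  # difference tuned so the two-sample z-test rejects at p ~= 0.04
  se <- 1
  diff <- 2.05 * sqrt(2) * se   # z = 2.05 -> p = 0.040
  a <- mean_estimate(10, se, 200L)
  b <- mean_estimate(10 + diff, se, 200L)
  z <- (b$mean - a$mean) / sqrt(a$se^2 + b$se^2)
  expect_lt(2 * stats::pnorm(-z), 0.05)
  # yet the intervals overlap, so the rule does not flag the difference
  expect_true(ci_overlap(a, b))
})

test_that("group comparison flags each gain quantity", {
  w <- mean_estimate(57, 0.1, 500L)
  lo <- gwg_from_weights(w, mean_estimate(62, 0.2, 200L))
  hi <- gwg_from_weights(w, mean_estimate(66.5, 0.2, 200L))
  cmp <- compare_gains(lo, hi, labels = c("low", "high"))
  expect_true(cmp$flagged_significant[["gain_total"]])
  expect_equal(cmp$overlapping_cis[["gain_total"]],
               ci_overlap(lo$gain_total, hi$gain_total))
  self <- compare_gains(lo, lo)
  expect_false(self$flagged_significant[["gain_total"]])
})

test_that("stratified estimates recover a constructed education contrast", {
  effects <- list(education = list(gain = c(secondary = 3, higher = 3)))
  params <- truth_params(stratifier_effects = effects)
  syn <- generate_cohort(params, 60000, seed = 17)
  strata <- stratified_estimates(syn$records, syn$meta, by = "education")
  g_none <- strata$none$estimate$gwg$gain_total
  g_sec <- strata$secondary$estimate$gwg$gain_total
  contrast <- g_sec$mean - g_none$mean
  se_contrast <- sqrt(g_sec$se^2 + g_none$se^2)
  expect_lt(abs(contrast - 3), 3 * se_contrast)
})

test_that("a single-level stratifier reproduces the unstratified estimate", {
  syn <- generate_cohort(truth_params(), 12000, seed = 19)
  rec <- syn$records
  rec$residence <- "rural"
  strata <- stratified_estimates(rec, syn$meta, by = "residence")
  full <- estimate_gwg(rec, syn$meta)
  expect_equal(strata$rural$estimate$gwg$gain_total$mean,
               full$gwg$gain_total$mean, tolerance = 1e-12)
  # the empty level is absent, with a diagnostic
  expect_null(strata$urban$estimate)
  expect_match(strata$urban$diagnostic, "no eligible|not estimable")
})

test_that("unknown stratifiers are a configuration error", {
  syn <- generate_cohort(truth_params(), 2000, seed = 21)
  expect_error(stratified_estimates(syn$records, syn$meta, by = "shoe_size"),
               "unknown stratifier")
})

test_that("country-level stratifiers join through the metadata", {
  syn <- generate_cohort(truth_params(), 40000, seed = 27)
  strata <- stratified_estimates(syn$records, syn$meta, by = "sub_region")
  expect_setequal(names(strata), c("Eastern", "Southern", "Western", "Central"))
  # single-country stratum: baseline should sit near that country's truth
  pre_southern <- strata$Southern$estimate$trajectory$pre_pregnancy
  expect_lt(abs(pre_southern$mean - 59.8), 4 * pre_southern$se + 0.05)
})

test_that("self-comparison of identical periods shows no trend", {
  syn <- generate_cohort(truth_params(), 10000, seed = 29)
  tr <- trend_compare(syn$records, syn$records, syn$meta)
  expect_equal(tr$gwg_change, 0)
  expect_equal(tr$pre_pregnancy_change, 0)
  expect_false(tr$significant_gwg_change)
  expect_setequal(tr$common_countries, syn$meta$country)
})

test_that("trend comparison restricts both periods to the common country panel", {
  syn1 <- generate_cohort(truth_params(), 12000, seed = 31)
  syn2 <- generate_cohort(truth_params(), 12000, seed = 32)
  r1 <- syn1$records[syn1$records$country != "Nigeria", , drop = FALSE]
  r2 <- syn2$records[syn2$records$country != "South Africa", , drop = FALSE]
  tr <- trend_compare(r1, r2, syn1$meta)
  expect_setequal(tr$common_countries, c("Ethiopia", "DR Congo"))
  expect_setequal(tr$estimate_2$countries, tr$common_countries)
  expect_error(trend_compare(r1[r1$country == "Ethiopia", ],
                             r2[r2$country == "DR Congo", ], syn1$meta),
               "common")
})

test_that("a baseline shift between periods moves pre-pregnancy weight, not GWG", {
  shift_baseline <- function(delta) {
    cn <- ssa_default_countries()
    cn$baseline_mean_kg <- cn$baseline_mean_kg + delta
    truth_params(countries = cn)
  }
  # population-weighted baselines 54.4 and 56.9 kg, identical gain structure
  syn1 <- generate_cohort(shift_baseline(54.4 - 57.08), 60000, seed = 33)
  syn2 <- generate_cohort(shift_baseline(56.9 - 57.08), 60000, seed = 34)
  tr <- trend_compare(syn1$records, syn2$records, syn1$meta,
                      period_labels = c("2000", "2015"))
  expect_equal(tr$pre_pregnancy_change, 2.5, tolerance = 0.4)
  se_change <- sqrt(tr$estimate_1$gwg$gain_total$se^2 +
                    tr$estimate_2$gwg$gain_total$se^2)
  expect_lt(abs(tr$gwg_change), 3 * se_change)
  expect_true(tr$significant_pre_pregnancy_change)
  expect_false(tr$significant_gwg_change)
})

test_that("a constructed gain separation at scale is flagged significant", {
  p2 <- truth_params(gain_t1_kg = 1.2 + 0.6, gain_t2_kg = 2.2 + 0.7,
                     gain_t3_kg = 3.2 + 0.7)   # +2 kg total
  syn1 <- generate_cohort(truth_params(), 300000, seed = 35)
  syn2 <- generate_cohort(p2, 300000, seed = 36)
  tr <- trend_compare(syn1$records, syn2$records, syn1$meta)
  expect_true(tr$significant_gwg_change)
  expect_equal(tr$gwg_change, 2, tolerance = 1)
})
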