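test_that("weighted mean handles degenerate and symmetric cases", {
  one <- weighted_mean(60, 1)
  expect_equal(one$mean, 60)
  expect_true(is.na(one$se))
  expect_true(is.na(one$ci_low))

  two <- weighted_mean(c(50, 70), c(2, 2))
  expect_equal(two$mean, 60)

  expect_error(weighted_mean(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean(c(1, 2), c(1, -1)), "positive")
})

test_that("weighted mean and SE match an independent brute-force computation", {
  set.seed(301)
  x <- rnorm(100, 60, 10)
  w <- runif(100, 0.2, 4)
  est <- weighted_mean(x, w)
  # independent oracle: explicit formulas, written out separately
  m_oracle <- stats::weighted.mean(x, w)
  wn <- w / sum(w) * 100
  se_oracle <- sqrt(sum(wn * (x - m_oracle)^2) / 99 / 100)
  expect_equal(est$mean, m_oracle, tolerance = 1e-10)
  expect_equal(est$se, se_oracle, tolerance = 1e-10)
  expect_equal(est$ci_low, m_oracle - 1.96 * se_oracle, tolerance = 1e-10)
  expect_equal(est$ci_high, m_oracle + 1.96 * se_oracle, tolerance = 1e-10)
  # equal weights reduce to the classical SE
  eq <- weighted_mean(x, rep(3, 100))
  expect_equal(eq$se, stats::sd(x) / 10, tolerance = 1e-10)
})

test_that("singleton clusters reproduce the independence SE under equal weights", {
  set.seed(302)
  x <- rnorm(60, 58, 9)
  a <- weighted_mean(x, rep(1, 60))
  b <- weighted_mean(x, rep(1, 60), cluster = seq_along(x))
  expect_equal(b$se, a$se, tolerance = 1e-12)
  # grouping correlated clusters inflates the SE
  cl <- rep(1:6, each = 10)
  x2 <- x + rep(rnorm(6, 0, 6), each = 10)
  clustered <- weighted_mean(x2, rep(1, 60), cluster = cl)
  naive <- weighted_mean(x2, rep(1, 60))
  expect_gt(clustered$se, naive$se)
})

test_that("an estimate built from interval endpoints recovers its SE", {
  e <- mean_estimate(9.5, n = 100L, ci_low = 8.2, ci_high = 10.9)
  expect_equal(e$se, (10.9 - 8.2) / (2 * 1.96))
  expect_error(mean_estimate(5, ci_low = 4), "both or neither")
  expect_error(mean_estimate(5, ci_low = 6, ci_high = 4), "ci_high")
})

test_that("delivery weight extrapolates the third-trimester rate by a third of a month", {
  w6 <- mean_estimate(62, 0.5, 100L)
  w9 <- mean_estimate(62, 0.4, 80L)
  expect_equal(delivery_weight(w6, w9)$mean, 62)  # flat trajectory

  w6 <- mean_estimate(59, 0.5, 100L)
  w9 <- mean_estimate(62, 0.4, 80L)
  d <- delivery_weight(w6, w9)
  expect_equal(d$mean, 62 + 1 / 3)     # rate 1 kg/month, 10 extra days
  expect_equal(d$mean, (10 / 9) * 62 - (1 / 9) * 59)
  expect_equal(d$se, sqrt((10 / 9)^2 * 0.4^2 + (1 / 9)^2 * 0.5^2))
})

test_that("trimester gains difference the anchors and telescope to the total", {
  w_pre <- mean_estimate(57.1, 0.05, 1000L)
  w3 <- mean_estimate(58.3, 0.3, 400L)
  w6 <- mean_estimate(60.5, 0.3, 400L)
  w9 <- mean_estimate(63.3, 0.5, 150L)
  g <- gwg_from_weights(w_pre, delivery_weight(w6, w9), w3 = w3, w6 = w6, w9 = w9)
  expect_equal(g$gain_t1$mean, 58.3 - 57.1)
  expect_equal(g$gain_t2$mean, 60.5 - 58.3)
  expect_equal(g$gain_total$mean, g$w_delivery$mean - 57.1)
  expect_equal(g$gain_t1$mean + g$gain_t2$mean + g$gain_t3$mean,
               g$gain_total$mean, tolerance = 1e-12)
  expect_equal(g$gain_t1$se, sqrt(0.05^2 + 0.3^2))

  # published sub-regional anchors: a slightly negative first-trimester gain
  southern <- gwg_from_weights(mean_estimate(59.8, n = 100L, ci_low = 59.5, ci_high = 60.1),
                               mean_estimate(70.3, n = 100L, ci_low = 67.7, ci_high = 73.0),
                               w3 = mean_estimate(59.6, n = 100L, ci_low = 58.2, ci_high = 61.1))
  expect_equal(southern$gain_t1$mean, -0.2, tolerance = 1e-9)

  # constant trajectory: all gains zero
  flat <- mean_estimate(60, 0.1, 100L)
  g0 <- gwg_from_weights(flat, delivery_weight(flat, flat), w3 = flat, w6 = flat, w9 = flat)
  expect_equal(g0$gain_total$mean, 0)
  expect_equal(g0$gain_t2$mean, 0)
})

test_that("gain tables expose all available quantities", {
  w <- mean_estimate(60, 0.2, 50L)
  g <- gwg_from_weights(w, delivery_weight(w, w), w3 = w, w6 = w, w9 = w)
  df <- as.data.frame(g)
  expect_equal(nrow(df), 9)
  g2 <- gwg_from_weights(w, mean_estimate(66, 0.4, 50L))
  expect_null(g2$gain_t1)
  expect_equal(nrow(as.data.frame(g2)), 3)
})
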