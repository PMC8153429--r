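# Weighted mean estimates with 95% confidence intervals, the delivery-weight
# extrapolation, and trimester-gain arithmetic.

.Z95 <- 1.96

#' Construct a mean estimate with a 95% confidence interval
#'
#' Container used throughout the pipeline for a weighted mean and its
#' uncertainty. Supply `se` to have the interval computed as
#' `mean +/- 1.96 se`, or supply the interval endpoints directly (e.g. when
#' re-using published estimates), in which case `se` is recovered as
#' `(ci_high - ci_low) / (2 * 1.96)`.
#'
#' @param mean point estimate (kg).
#' @param se standard error (kg), or `NA` when undefined (single
#'   observation).
#' @param n number of observations behind the estimate.
#' @param ci_low,ci_high optional explicit 95% interval endpoints.
#' @return object of class `gwg_wme`: list with `mean`, `se`, `n`,
#'   `ci_low`, `ci_high`.
#' @export
mean_estimate <- function(mean, se = NA_real_, n = NA_integer_,
                          ci_low = NULL, ci_high = NULL) {
  if (is.null(ci_low) != is.null(ci_high))
    .stopf("supply both or neither of ci_low / ci_high")
  if (!is.null(ci_low)) {
    if (ci_high < ci_low) .stopf("ci_high < ci_low")
    if (is.na(se)) se <- (ci_high - ci_low) / (2 * .Z95)
  } else if (!is.na(se)) {
    ci_low <- mean - .Z95 * se
    ci_high <- mean + .Z95 * se
  } else {
    ci_low <- NA_real_
    ci_high <- NA_real_
  }
  structure(list(mean = as.numeric(mean), se = as.numeric(se),
                 n = as.integer(n), ci_low = as.numeric(ci_low),
                 ci_high = as.numeric(ci_high)),
            class = "gwg_wme")
}

#' @export
print.gwg_wme <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "CI not available" else
    sprintf("95%% CI %.2f-%.2f", x$ci_low, x$ci_high)
  cat(sprintf("%.2f kg (%s; n = %s)\n", x$mean, ci,
              ifelse(is.na(x$n), "?", format(x$n))))
  invisible(x)
}

#' Weighted mean with standard error and 95% confidence interval
#'
#' The point estimate is `sum(w*x)/sum(w)`. For the standard error, weights
#' are first normalised to sum to the number of observations n; then
#' `se^2 = [sum(w*(x - xbar)^2) / (n - 1)] / n`, which reduces to the
#' classical SE under equal weights and is invariant to rescaling all
#' weights. With `cluster` supplied, a Taylor-linearised cluster-robust SE
#' is used instead (sampling in household surveys is clustered, which the
#' independence-based SE understates).
#'
#' @param x numeric values (kg).
#' @param w positive weights, same length as `x`.
#' @param cluster optional cluster identifiers, same length as `x`.
#' @return a [mean_estimate()]; with a single observation the SE is `NA`
#'   and the interval absent.
#' @export
weighted_mean <- function(x, w, cluster = NULL) {
  n <- length(x)
  if (n == 0L) .stopf("cannot average an empty set")
  if (length(w) != n) .stopf("values and weights differ in length")
  if (any(is.na(x)) || any(is.na(w))) .stopf("missing values or weights")
  if (any(w <= 0)) .stopf("weights must be positive")
  m <- sum(w * x) / sum(w)
  if (n == 1L) return(mean_estimate(m, NA_real_, 1L))
  wn <- w * n / sum(w)
  if (is.null(cluster)) {
    se2 <- sum(wn * (x - m)^2) / (n - 1) / n
  } else {
    if (length(cluster) != n) .stopf("cluster ids and values differ in length")
    z <- wn * (x - m)
    tg <- tapply(z, cluster, sum)
    g <- length(tg)
    if (g < 2L) .stopf("cluster-robust SE needs at least 2 clusters")
    se2 <- g / (g - 1) * sum(tg^2) / n^2
  }
  mean_estimate(m, sqrt(se2), n)
}

# difference of independent group means: a - b
.wme_diff <- function(a, b) {
  se <- sqrt(a$se^2 + b$se^2)
  mean_estimate(a$mean - b$mean, se, a$n + b$n)
}

#' Extrapolate weight at delivery from months 6 and 9
#'
#' Gestational age is reported to the nearest month, so the month-9 mean
#' represents the window around 270 days and undershoots weight at delivery
#' (40 weeks = 9 months 10 days = 280 days under 30-day months). The
#' third-trimester monthly gain rate `(W9 - W6)/3` is extrapolated 1/3 of a
#' month beyond month 9:
#' `W_delivery = W9 + (W9 - W6)/3 * 1/3 = (10/9) W9 - (1/9) W6`,
#' with the delta-method variance
#' `(10/9)^2 se9^2 + (1/9)^2 se6^2` (the two month means come from disjoint
#' sets of women and are treated as independent).
#'
#' @param w6,w9 [mean_estimate()]s for gestational months 6 and 9.
#' @return a [mean_estimate()] of weight at delivery; `n` is the number of
#'   records behind the two inputs.
#' @export
delivery_weight <- function(w6, w9) {
  stopifnot(inherits(w6, "gwg_wme"), inherits(w9, "gwg_wme"))
  m <- (10 / 9) * w9$mean - (1 / 9) * w6$mean
  se <- sqrt((10 / 9)^2 * w9$se^2 + (1 / 9)^2 * w6$se^2)
  mean_estimate(m, se, w6$n + w9$n)
}

#' Trimester gains and total gestational weight gain from anchor weights
#'
#' Differences the anchor mean weights: first-trimester gain `W3 - Wpre`,
#' second `W6 - W3`, third `Wdelivery - W6`, and total
#' `Wdelivery - Wpre`. The three trimester gains telescope to the total by
#' construction. Each gain's SE is `sqrt(se_a^2 + se_b^2)` (independent
#' group means: distinct women in a cross-section), with 1.96-intervals.
#' `w3`/`w6` may be omitted when only the total is needed.
#'
#' @param w_pre pre-pregnancy (at-risk) mean weight, a [mean_estimate()].
#' @param w_delivery estimated weight at delivery, a [mean_estimate()].
#' @param w3,w6 optional mean weights at gestational months 3 and 6.
#' @param w9 optional mean weight at month 9, carried through for reporting.
#' @return object of class `gwg_gains`: list of [mean_estimate()]s
#'   (`w_pre`, `w3`, `w6`, `w9`, `w_delivery`, `gain_t1`, `gain_t2`,
#'   `gain_t3`, `gain_total`); unavailable pieces are `NULL`.
#' @export
gwg_from_weights <- function(w_pre, w_delivery, w3 = NULL, w6 = NULL, w9 = NULL) {
  stopifnot(inherits(w_pre, "gwg_wme"), inherits(w_delivery, "gwg_wme"))
  out <- list(
    w_pre = w_pre, w3 = w3, w6 = w6, w9 = w9, w_delivery = w_delivery,
    gain_t1 = if (!is.null(w3)) .wme_diff(w3, w_pre),
    gain_t2 = if (!is.null(w3) && !is.null(w6)) .wme_diff(w6, w3),
    gain_t3 = if (!is.null(w6)) .wme_diff(w_delivery, w6),
    gain_total = .wme_diff(w_delivery, w_pre)
  )
  structure(out, class = "gwg_gains")
}

#' Trimester gains from a monthly trajectory
#'
#' Computes the delivery weight by third-trimester extrapolation
#' ([delivery_weight()]) and differences the trajectory anchors
#' (pre-pregnancy, months 3, 6, 9) into trimester and total gains.
#'
#' @param traj a `gwg_trajectory` from [monthly_trajectory()].
#' @return a `gwg_gains` object (see [gwg_from_weights()]).
#' @export
trimester_gains <- function(traj) {
  stopifnot(inherits(traj, "gwg_trajectory"))
  w3 <- traj$months[[3]]; w6 <- traj$months[[6]]; w9 <- traj$months[[9]]
  if (is.null(w3) || is.null(w6) || is.null(w9))
    .stopf("trajectory not estimable: months 3, 6 and 9 are all required")
  gwg_from_weights(traj$pre_pregnancy, delivery_weight(w6, w9),
                   w3 = w3, w6 = w6, w9 = w9)
}

#' @export
as.data.frame.gwg_gains <- function(x, ...) {
  rows <- c(w_pre = "pre-pregnancy weight", w3 = "weight at month 3",
            w6 = "weight at month 6", w9 = "weight at month 9",
            w_delivery = "weight at delivery",
            gain_t1 = "gain, trimester 1", gain_t2 = "gain, trimester 2",
            gain_t3 = "gain, trimester 3", gain_total = "total GWG")
  keep <- names(rows)[!vapply(x[names(rows)], is.null, logical(1))]
  data.frame(
    quantity = unname(rows[keep]),
    mean = vapply(x[keep], `[[`, numeric(1), "mean"),
    se = vapply(x[keep], `[[`, numeric(1), "se"),
    ci_low = vapply(x[keep], `[[`, numeric(1), "ci_low"),
    ci_high = vapply(x[keep], `[[`, numeric(1), "ci_high"),
    n = vapply(x[keep], function(e) as.integer(e$n), integer(1)),
    row.names = keep, stringsAsFactors = FALSE
  )
}

#' @export
print.gwg_gains <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits)
  df$se <- round(df$se, digits + 1)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
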