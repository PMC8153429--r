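# Synthetic multi-country survey generator with closed-form ground truth.
#
# The generator emulates the features of household-survey anthropometry that
# the pipeline relies on: month-binned gestational age where each reported
# month stands for a +/- 2-week window around the month centre (30-day
# months), a piecewise-linear-by-trimester weight trajectory with knots at
# 0, 90, 180 and 280 days, between-woman baseline heterogeneity, eligibility
# attributes among non-pregnant women, lognormal cluster-level sampling
# weights, and multi-country composition with known populations.

# marginal distributions used for demographic attributes (shares typical of
# the surveys the pipeline targets); also used to take expectations of
# stratifier effects in the closed-form truth
.demo <- list(
  age_group = c("15-19" = 0.302, "20-34" = 0.447, "35-49" = 0.251),
  residence = c(urban = 0.345, rural = 0.655),
  education = c(none = 0.339, primary = 0.326, secondary = 0.286, higher = 0.049),
  wealth_quintile = c(poorest = 0.165, poorer = 0.173, middle = 0.188,
                      richer = 0.207, richest = 0.268)
)

#' Default multi-country scenario
#'
#' Four countries, one per sub-region, with 2020-scale populations and
#' sub-region-typical baseline weights; the population-weighted mean
#' baseline is 57.1 kg. Equal sample shares (survey sample sizes are not
#' proportional to population, which is what makes post-stratification
#' matter). Baseline SD 9.9 kg combines with the default 8 kg measurement
#' SD to a total cross-sectional weight SD of about 12.7 kg.
#'
#' @return data frame of per-country generator settings.
#' @export
ssa_default_countries <- function() {
  data.frame(
    country = c("Nigeria", "Ethiopia", "DR Congo", "South Africa"),
    population = c(206e6, 115e6, 90e6, 59e6),
    sub_region = c("Western", "Eastern", "Central", "Southern"),
    income_class = c("lower_middle_or_upper", "low", "low", "lower_middle_or_upper"),
    sample_share = 0.25,
    baseline_mean_kg = c(57.8, 55.2, 56.1, 59.8),
    baseline_sd_kg = 9.9,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth parameters for the synthetic generator
#'
#' Defaults define the reference scenario ("ssa-default"): trimester gains
#' 1.2 / 2.2 / 3.2 kg (total 6.6 kg), measurement SD 8 kg, pregnant fraction
#' 0.198, the empirical gestational-month distribution of the target
#' surveys, plausible eligibility rates among non-pregnant women, and 0.3%
#' month-10 self-reports.
#'
#' @param countries per-country settings, see [ssa_default_countries()].
#' @param gain_t1_kg,gain_t2_kg,gain_t3_kg true trimester gains (kg) of the
#'   piecewise-linear trajectory (knots at 0, 90, 180, 280 days).
#' @param measurement_sd_kg SD (kg) of the within-woman measurement /
#'   short-term fluctuation noise added to every weight.
#' @param pregnant_fraction probability a sampled woman is pregnant.
#' @param month_distribution length-9 probabilities of the reported
#'   gestational month among pregnant women (must sum to 1).
#' @param eligibility_rates named probabilities among non-pregnant women:
#'   `contraception_use`, `menstruating`, `sexually_active`, `recent_birth`
#'   (birth within the last 12 months).
#' @param n_clusters sampling clusters per country.
#' @param cluster_weight_dispersion sdlog of the lognormal cluster sampling
#'   weights (mean 1).
#' @param month10_rate probability a pregnant woman reports month 10 (her
#'   true gestation is then placed in the month-9 window).
#' @param month_misreport_rate probability the reported month is off by
#'   +/- 1 from the true sampled month (clamped to 1-9); emulates
#'   self-report error. Default 0.
#' @param stratifier_effects optional additive offsets by level of
#'   `residence`, `education` or `wealth_quintile`: a list like
#'   `list(education = list(baseline = c(secondary = 2), gain = c(secondary = 3)))`.
#'   `baseline` shifts a woman's baseline weight (kg); `gain` shifts her
#'   total gestational gain (kg), allocated to trimesters in proportion to
#'   the base gains.
#' @param day_sampling `"window"` (gestational day uniform within the
#'   reported month's +/- 14-day window, the realistic convention) or
#'   `"center"` (exactly at the month centre; makes noiseless runs exactly
#'   recoverable).
#' @param third_trimester_shape `"linear"` or `"quadratic"` (accelerating
#'   gain reaching the same total at 280 days; used to probe the bias of
#'   linear extrapolation).
#' @param survey_year year stamped on the records.
#' @return object of class `gwg_truth_params`.
#' @export
truth_params <- function(countries = ssa_default_countries(),
                         gain_t1_kg = 1.2, gain_t2_kg = 2.2, gain_t3_kg = 3.2,
                         measurement_sd_kg = 8,
                         pregnant_fraction = 0.198,
                         month_distribution = c(934, 2070, 2638, 2640, 3182,
                                                3011, 3104, 3204, 1038) / 21821,
                         eligibility_rates = c(contraception_use = 0.25,
                                               menstruating = 0.85,
                                               sexually_active = 0.75,
                                               recent_birth = 0.18),
                         n_clusters = 50,
                         cluster_weight_dispersion = 0.3,
                         month10_rate = 0.003,
                         month_misreport_rate = 0,
                         stratifier_effects = NULL,
                         day_sampling = c("window", "center"),
                         third_trimester_shape = c("linear", "quadratic"),
                         survey_year = 2016) {
  day_sampling <- match.arg(day_sampling)
  third_trimester_shape <- match.arg(third_trimester_shape)
  need <- c("country", "population", "sub_region", "income_class",
            "sample_share", "baseline_mean_kg", "baseline_sd_kg")
  miss <- setdiff(need, names(countries))
  if (length(miss)) .stopf("countries table lacks column(s): %s", paste(miss, collapse = ", "))
  country_meta(countries[c("country", "population", "sub_region", "income_class")])
  if (any(countries$sample_share <= 0)) .stopf("sample shares must be positive")
  if (any(countries$baseline_sd_kg < 0) || measurement_sd_kg < 0)
    .stopf("standard deviations must be nonnegative")
  if (length(month_distribution) != 9L || any(month_distribution < 0) ||
      abs(sum(month_distribution) - 1) > 1e-6)
    .stopf("month_distribution must be 9 nonnegative probabilities summing to 1")
  rn <- c("contraception_use", "menstruating", "sexually_active", "recent_birth")
  if (!all(rn %in% names(eligibility_rates)))
    .stopf("eligibility_rates must name: %s", paste(rn, collapse = ", "))
  pr <- c(pregnant_fraction, eligibility_rates, month10_rate, month_misreport_rate)
  if (any(pr < 0 | pr > 1)) .stopf("probabilities must lie in [0, 1]")
  if (pregnant_fraction <= 0 || pregnant_fraction >= 1)
    .stopf("pregnant_fraction must lie strictly in (0, 1)")
  if (n_clusters < 1) .stopf("n_clusters must be at least 1")
  if (cluster_weight_dispersion < 0) .stopf("cluster_weight_dispersion must be nonnegative")
  if (!is.null(stratifier_effects)) {
    bad <- setdiff(names(stratifier_effects), c("residence", "education", "wealth_quintile"))
    if (length(bad)) .stopf("stratifier_effects supports residence, education, wealth_quintile; got: %s",
                            paste(bad, collapse = ", "))
    for (f in names(stratifier_effects)) {
      lv <- names(.demo[[f]])
      for (part in c("baseline", "gain")) {
        v <- stratifier_effects[[f]][[part]]
        if (!is.null(v) && length(setdiff(names(v), lv)))
          .stopf("unknown %s level(s) in stratifier_effects: %s", f,
                 paste(setdiff(names(v), lv), collapse = ", "))
      }
    }
  }
  structure(list(
    countries = countries, gain_t1_kg = gain_t1_kg, gain_t2_kg = gain_t2_kg,
    gain_t3_kg = gain_t3_kg, measurement_sd_kg = measurement_sd_kg,
    pregnant_fraction = pregnant_fraction,
    month_distribution = month_distribution / sum(month_distribution),
    eligibility_rates = eligibility_rates, n_clusters = as.integer(n_clusters),
    cluster_weight_dispersion = cluster_weight_dispersion,
    month10_rate = month10_rate, month_misreport_rate = month_misreport_rate,
    stratifier_effects = stratifier_effects, day_sampling = day_sampling,
    third_trimester_shape = third_trimester_shape, survey_year = survey_year
  ), class = "gwg_truth_params")
}

# allocate an additive total-gain offset to the three trimesters in
# proportion to the base gains
.effective_gains <- function(params, offset = 0) {
  g <- c(params$gain_t1_kg, params$gain_t2_kg, params$gain_t3_kg)
  if (length(offset) == 1L && offset == 0) return(matrix(g, 1))
  tot <- sum(g)
  share <- if (tot != 0) g / tot else rep(1 / 3, 3)
  t(vapply(offset, function(o) g + o * share, numeric(3)))
}

# cumulative gain (kg) at gestational day d for trimester gains g (length 3)
.gain_at <- function(d, g, shape = "linear") {
  out <- numeric(length(d))
  i1 <- d <= 90
  out[i1] <- g[1] * d[i1] / 90
  i2 <- d > 90 & d <= 180
  out[i2] <- g[1] + g[2] * (d[i2] - 90) / 90
  i3 <- d > 180
  u <- (d[i3] - 180) / 100
  out[i3] <- g[1] + g[2] + if (shape == "linear") g[3] * u else g[3] * u^2
  out
}

# antiderivative of .gain_at, for exact window means
.gain_integral <- function(d, g, shape = "linear") {
  F90 <- g[1] * 90 / 2
  F180 <- F90 + g[1] * 90 + g[2] * 90 / 2
  vapply(d, function(di) {
    if (di <= 90) return(g[1] * di^2 / 180)
    if (di <= 180) return(F90 + g[1] * (di - 90) + g[2] * (di - 90)^2 / 180)
    u <- di - 180
    F180 + (g[1] + g[2]) * u +
      if (shape == "linear") g[3] * u^2 / 200 else g[3] * u^3 / 30000
  }, numeric(1))
}

# expected gain for women reporting month m under the day-sampling convention
.month_gain_truth <- function(m, g, shape, day_sampling) {
  centre <- m * 30
  if (day_sampling == "center") return(.gain_at(centre, g, shape))
  a <- centre - 14; b <- centre + 14
  (.gain_integral(b, g, shape) - .gain_integral(a, g, shape)) / (b - a)
}

.expected_offsets <- function(params) {
  base <- 0; gain <- 0
  for (f in names(params$stratifier_effects)) {
    p <- .demo[[f]]
    eff <- params$stratifier_effects[[f]]
    for (part in c("baseline", "gain")) {
      v <- eff[[part]]
      if (is.null(v)) next
      e <- sum(p[names(v)] * v)
      if (part == "baseline") base <- base + e else gain <- gain + e
    }
  }
  c(baseline = base, gain = gain)
}

#' Closed-form true total gestational weight gain
#'
#' The trajectory's total gain at 280 days: the sum of the three trimester
#' gains (plus the population expectation of any configured stratifier gain
#' offsets). Identical for the linear and quadratic third-trimester shapes,
#' which share the 280-day endpoint.
#'
#' @param params a [truth_params()] object.
#' @return total gain in kg.
#' @export
true_gwg <- function(params) {
  stopifnot(inherits(params, "gwg_truth_params"))
  off <- .expected_offsets(params)
  sum(.effective_gains(params, off[["gain"]])[1, ])
}

# full closed-form truth for a parameter set
.truth_summary <- function(params) {
  cn <- params$countries
  popshare <- cn$population / sum(cn$population)
  off <- .expected_offsets(params)
  pre <- sum(popshare * cn$baseline_mean_kg) + off[["baseline"]]
  g <- .effective_gains(params, off[["gain"]])[1, ]
  month_means <- pre + vapply(1:9, .month_gain_truth, numeric(1), g = g,
                              shape = params$third_trimester_shape,
                              day_sampling = params$day_sampling)
  w3 <- month_means[3]; w6 <- month_means[6]; w9 <- month_means[9]
  delivery_est <- (10 / 9) * w9 - (1 / 9) * w6
  list(
    pre_pregnancy_mean = pre,
    month_means = month_means,
    delivery_weight = pre + sum(g),   # trajectory value at 280 days
    gain_total = sum(g),
    at_risk_rate = unname(
      (1 - params$eligibility_rates[["contraception_use"]]) *
        params$eligibility_rates[["menstruating"]] *
        params$eligibility_rates[["sexually_active"]] *
        (1 - params$eligibility_rates[["recent_birth"]])),
    # large-sample expectations of the pipeline's own estimators
    expected_estimates = list(
      w3 = w3, w6 = w6, w9 = w9, delivery = delivery_est,
      gain_t1 = w3 - pre, gain_t2 = w6 - w3, gain_t3 = delivery_est - w6,
      gain_total = delivery_est - pre
    )
  )
}

.sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic multi-country survey dataset
#'
#' Draws `n_women` records under the generating process described in
#' [truth_params()] and returns them together with the country metadata and
#' the closed-form truth (the trajectory's true anchors and gains, plus the
#' large-sample expectations of the pipeline's own estimators under the
#' month-window convention). Reproducible given `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param params a [truth_params()] object.
#' @param n_women number of records to draw.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return object of class `gwg_synthetic`: list with `records`
#'   (a `woman_records` data frame, including a `cluster_id` convenience
#'   column carried outside the canonical fields), `meta` (a
#'   [country_meta()]), and `truth`.
#' @export
generate_cohort <- function(params, n_women, seed = NULL) {
  stopifnot(inherits(params, "gwg_truth_params"))
  if (n_women < 1) .stopf("n_women must be at least 1")
  gen <- function() .generate_impl(params, as.integer(n_women))
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  out
}

.generate_impl <- function(params, n) {
  cn <- params$countries
  nc <- nrow(cn)
  ci <- sample.int(nc, n, replace = TRUE, prob = cn$sample_share)

  # lognormal cluster weights, mean 1, one draw per (country, cluster)
  disp <- params$cluster_weight_dispersion
  cluster <- sample.int(params$n_clusters, n, replace = TRUE)
  wmat <- matrix(stats::rlnorm(nc * params$n_clusters,
                               meanlog = -disp^2 / 2, sdlog = disp),
                 nrow = nc)
  sampling_weight <- wmat[cbind(ci, cluster)]

  age_group <- .sample_levels(n, .demo$age_group)
  age <- ifelse(age_group == "15-19", sample(15:19, n, TRUE),
         ifelse(age_group == "20-34", sample(20:34, n, TRUE),
                sample(35:49, n, TRUE)))
  residence <- .sample_levels(n, .demo$residence)
  education <- .sample_levels(n, .demo$education)
  wealth <- .sample_levels(n, .demo$wealth_quintile)
  height <- round(stats::rnorm(n, 158, 7), 1)

  base_off <- numeric(n); gain_off <- numeric(n)
  demo_values <- list(residence = residence, education = education,
                      wealth_quintile = wealth)
  for (f in names(params$stratifier_effects)) {
    eff <- params$stratifier_effects[[f]]
    lv <- demo_values[[f]]
    if (!is.null(eff$baseline)) {
      v <- eff$baseline[lv]; v[is.na(v)] <- 0; base_off <- base_off + unname(v)
    }
    if (!is.null(eff$gain)) {
      v <- eff$gain[lv]; v[is.na(v)] <- 0; gain_off <- gain_off + unname(v)
    }
  }

  pregnant <- stats::runif(n) < params$pregnant_fraction
  np <- sum(pregnant)

  month <- rep(NA_integer_, n)
  reported_month <- rep(NA_integer_, n)
  day <- rep(NA_real_, n)
  if (np > 0) {
    m <- sample.int(9L, np, replace = TRUE, prob = params$month_distribution)
    rep10 <- stats::runif(np) < params$month10_rate
    m[rep10] <- 9L
    rm_ <- m
    rm_[rep10] <- 10L
    if (params$month_misreport_rate > 0) {
      mis <- stats::runif(np) < params$month_misreport_rate & !rep10
      shift <- sample(c(-1L, 1L), np, replace = TRUE)
      rm_[mis] <- pmin(pmax(m[mis] + shift[mis], 1L), 9L)
    }
    d <- if (params$day_sampling == "center") m * 30
         else m * 30 + stats::runif(np, -14, 14)
    month[pregnant] <- m
    reported_month[pregnant] <- rm_
    day[pregnant] <- d
  }

  baseline <- stats::rnorm(n, cn$baseline_mean_kg[ci] + base_off,
                           cn$baseline_sd_kg[ci])
  gain_kg <- numeric(n)
  if (np > 0) {
    idx <- which(pregnant)
    if (all(gain_off == 0)) {
      g0 <- .effective_gains(params, 0)[1, ]
      gain_kg[idx] <- .gain_at(day[idx], g0, params$third_trimester_shape)
    } else {
      gains <- .effective_gains(params, gain_off)
      gain_kg[idx] <- vapply(idx, function(i)
        .gain_at(day[i], gains[i, ], params$third_trimester_shape), numeric(1))
    }
  }
  weight <- baseline + gain_kg + stats::rnorm(n, 0, params$measurement_sd_kg)

  er <- params$eligibility_rates
  uses_contraception <- ifelse(pregnant, FALSE, stats::runif(n) < er[["contraception_use"]])
  is_menstruating <- ifelse(pregnant, FALSE, stats::runif(n) < er[["menstruating"]])
  is_sexually_active <- ifelse(pregnant, TRUE, stats::runif(n) < er[["sexually_active"]])
  recent <- !pregnant & stats::runif(n) < er[["recent_birth"]]
  mslb <- rep(NA_integer_, n)
  mslb[recent] <- sample(0:11, sum(recent), replace = TRUE)
  older_birth <- !recent & stats::runif(n) < 0.5
  mslb[older_birth] <- sample(12:59, sum(older_birth), replace = TRUE)

  df <- data.frame(
    woman_id = sprintf("w%07d", seq_len(n)),
    country = cn$country[ci],
    survey_year = params$survey_year,
    is_pregnant = pregnant,
    gestational_month = reported_month,
    weight_kg = weight,
    age_years = age,
    residence = residence,
    education = education,
    wealth_quintile = wealth,
    height_cm = height,
    uses_contraception = uses_contraception,
    is_menstruating = is_menstruating,
    is_sexually_active = is_sexually_active,
    months_since_last_birth = mslb,
    sampling_weight = sampling_weight,
    stringsAsFactors = FALSE
  )
  rec <- woman_records(df)
  rec$cluster_id <- paste0(cn$country[ci], "_c", cluster)

  meta <- country_meta(cn[c("country", "population", "sub_region", "income_class")])
  truth <- c(list(params = params), .truth_summary(params))
  structure(list(records = rec, meta = meta, truth = truth),
            class = "gwg_synthetic")
}

#' @export
print.gwg_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic survey dataset: %d women, %d countries (%d pregnant)\n",
              nrow(x$records), nrow(x$meta), sum(x$records$is_pregnant)))
  cat(sprintf("True pre-pregnancy mean %.2f kg, true total GWG %.2f kg\n",
              x$truth$pre_pregnancy_mean, x$truth$gain_total))
  invisible(x)
}
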