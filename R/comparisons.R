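# Subgroup comparison via confidence-interval overlap, stratified
# estimation, and two-period trend comparison on a common country panel.

#' Do two 95% confidence intervals overlap?
#'
#' Intervals are treated as closed: exact endpoint contact counts as
#' overlap. Under the overlap rule a difference is flagged significant only
#' when the intervals are disjoint — a deliberately conservative criterion
#' (differences whose formal z-test would reject at p slightly below 0.05
#' frequently show overlapping intervals).
#'
#' @param a,b [mean_estimate()]s with available intervals.
#' @return `TRUE`/`FALSE`, or `NA` when either interval is absent (single
#'   observation behind a mean) — the comparison is then not evaluable.
#' @export
ci_overlap <- function(a, b) {
  stopifnot(inherits(a, "gwg_wme"), inherits(b, "gwg_wme"))
  if (is.na(a$ci_low) || is.na(b$ci_low)) return(NA)
  a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
}

#' Compare two sets of gain estimates by CI overlap
#'
#' @param est_a,est_b `gwg_gains` objects (see [gwg_from_weights()]).
#' @param labels length-2 character, group labels.
#' @return object of class `gwg_comparison`: per compared quantity
#'   (`gain_total` and each available trimester gain), the overlap and
#'   significance flags; symmetric in the two groups.
#' @export
compare_gains <- function(est_a, est_b, labels = c("group A", "group B")) {
  stopifnot(inherits(est_a, "gwg_gains"), inherits(est_b, "gwg_gains"))
  qs <- c("gain_total", "gain_t1", "gain_t2", "gain_t3")
  qs <- qs[!vapply(est_a[qs], is.null, logical(1)) &
           !vapply(est_b[qs], is.null, logical(1))]
  overlap <- vapply(qs, function(q) ci_overlap(est_a[[q]], est_b[[q]]), logical(1))
  structure(list(
    group_a_label = labels[1], group_b_label = labels[2],
    estimate_a = est_a, estimate_b = est_b,
    overlapping_cis = overlap,
    flagged_significant = !overlap
  ), class = "gwg_comparison")
}

#' @export
print.gwg_comparison <- function(x, ...) {
  cat(sprintf("CI-overlap comparison: %s vs %s\n", x$group_a_label, x$group_b_label))
  for (q in names(x$overlapping_cis)) {
    a <- x$estimate_a[[q]]; b <- x$estimate_b[[q]]
    flag <- x$flagged_significant[[q]]
    cat(sprintf("  %-10s %.2f (%.2f-%.2f) vs %.2f (%.2f-%.2f): %s\n", q,
                a$mean, a$ci_low, a$ci_high, b$mean, b$ci_low, b$ci_high,
                if (is.na(flag)) "not evaluable"
                else if (flag) "significant (disjoint CIs)" else "not significant"))
  }
  invisible(x)
}

.strat_levels <- function(records, meta, by) {
  switch(by,
    residence = list(values = records$residence, levels = .residence_levels),
    education = list(values = records$education, levels = .education_levels),
    wealth_quintile = list(values = records$wealth_quintile, levels = .wealth_levels),
    age_group = {
      a <- records$age_years
      v <- cut(a, c(14, 19, 34, 49), labels = c("15-19", "20-34", "35-49"))
      list(values = as.character(v), levels = c("15-19", "20-34", "35-49"))
    },
    height_group = {
      h <- records$height_cm
      v <- ifelse(is.na(h), NA_character_, ifelse(h < 155, "<155 cm", ">=155 cm"))
      list(values = v, levels = c("<155 cm", ">=155 cm"))
    },
    sub_region = {
      m <- stats::setNames(meta$sub_region, meta$country)
      list(values = unname(m[records$country]), levels = .sub_region_levels)
    },
    income_class = {
      m <- stats::setNames(meta$income_class, meta$country)
      list(values = unname(m[records$country]), levels = .income_levels)
    },
    .stopf("unknown stratifier '%s'; supported: residence, education, wealth_quintile, age_group, height_group, sub_region, income_class", by)
  )
}

#' Stratified GWG estimates
#'
#' Runs the full pipeline within each level of a stratifier. Record-level
#' stratifiers: `residence`, `education`, `wealth_quintile`, `age_group`
#' (15-19 / 20-34 / 35-49), `height_group` (<155 / >=155 cm); country-level
#' (joined through the metadata): `sub_region`, `income_class`. Levels where
#' the trajectory is not estimable (an anchor month empty, or an analysis
#' set empty) are reported absent with the diagnostic message.
#'
#' @inheritParams estimate_gwg
#' @param by stratifier name.
#' @return object of class `gwg_strata`: named list per level with
#'   `estimate` (a `gwg_fit` or `NULL`) and `diagnostic`.
#' @export
stratified_estimates <- function(records, meta, by,
                                 postpartum_exclusion_months = 12,
                                 cluster = NULL) {
  sl <- .strat_levels(records, meta, by)
  out <- list()
  for (lev in sl$levels) {
    idx <- which(!is.na(sl$values) & sl$values == lev)
    fit <- tryCatch(
      estimate_gwg(records[idx, , drop = FALSE], meta,
                   postpartum_exclusion_months = postpartum_exclusion_months,
                   cluster = cluster),
      error = function(e) conditionMessage(e))
    out[[lev]] <- if (is.character(fit)) list(estimate = NULL, diagnostic = fit)
                  else list(estimate = fit, diagnostic = NA_character_)
  }
  structure(out, class = "gwg_strata", stratifier = by)
}

#' @export
as.data.frame.gwg_strata <- function(x, ...) {
  rows <- lapply(names(x), function(lev) {
    e <- x[[lev]]
    if (is.null(e$estimate))
      return(data.frame(level = lev, gwg_total = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_pregnant = NA_integer_,
                        diagnostic = e$diagnostic, stringsAsFactors = FALSE))
    g <- e$estimate$gwg$gain_total
    data.frame(level = lev, gwg_total = g$mean, ci_low = g$ci_low,
               ci_high = g$ci_high, n_pregnant = e$estimate$n_pregnant,
               diagnostic = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.gwg_strata <- function(x, digits = 2, ...) {
  cat("Stratified GWG estimates by", attr(x, "stratifier"), "\n")
  df <- as.data.frame(x)
  num <- c("gwg_total", "ci_low", "ci_high")
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Compare GWG between two survey periods on a common country panel
#'
#' Restricts both period datasets to the countries present in both, runs the
#' full pipeline independently within each period (post-stratification
#' factors are recomputed per period over the common panel, since country
#' composition and survey years differ), and compares pre-pregnancy weight
#' and total GWG between periods by CI overlap.
#'
#' @param records_p1,records_p2 `woman_records` for the two periods.
#' @param meta a [country_meta()] data frame.
#' @param period_labels length-2 character.
#' @inheritParams estimate_gwg
#' @return object of class `gwg_trend`: list with the two `gwg_fit`s,
#'   `common_countries`, `pre_pregnancy_change` and `gwg_change` (kg,
#'   period 2 minus period 1), and significance flags from the overlap rule.
#' @export
trend_compare <- function(records_p1, records_p2, meta,
                          period_labels = c("period 1", "period 2"),
                          postpartum_exclusion_months = 12, cluster = NULL) {
  if (nrow(records_p1) == 0L || nrow(records_p2) == 0L)
    .stopf("both period record sets must be non-empty")
  common <- intersect(unique(records_p1$country), unique(records_p2$country))
  if (!length(common)) .stopf("no countries common to both periods")
  r1 <- records_p1[records_p1$country %in% common, , drop = FALSE]
  r2 <- records_p2[records_p2$country %in% common, , drop = FALSE]
  fit1 <- estimate_gwg(r1, meta, postpartum_exclusion_months, cluster)
  fit2 <- estimate_gwg(r2, meta, postpartum_exclusion_months, cluster)
  pre1 <- fit1$trajectory$pre_pregnancy; pre2 <- fit2$trajectory$pre_pregnancy
  g1 <- fit1$gwg$gain_total; g2 <- fit2$gwg$gain_total
  structure(list(
    period_1_label = period_labels[1], period_2_label = period_labels[2],
    common_countries = common,
    estimate_1 = fit1, estimate_2 = fit2,
    pre_pregnancy_change = pre2$mean - pre1$mean,
    gwg_change = g2$mean - g1$mean,
    significant_pre_pregnancy_change = !ci_overlap(pre1, pre2),
    significant_gwg_change = !ci_overlap(g1, g2)
  ), class = "gwg_trend")
}

#' @export
print.gwg_trend <- function(x, ...) {
  cat(sprintf("Trend comparison (%s vs %s) on %d common countries\n",
              x$period_1_label, x$period_2_label, length(x$common_countries)))
  p1 <- x$estimate_1$trajectory$pre_pregnancy
  p2 <- x$estimate_2$trajectory$pre_pregnancy
  g1 <- x$estimate_1$gwg$gain_total; g2 <- x$estimate_2$gwg$gain_total
  cat(sprintf("  pre-pregnancy: %.1f -> %.1f kg (change %+.1f, %s)\n",
              p1$mean, p2$mean, x$pre_pregnancy_change,
              if (isTRUE(x$significant_pre_pregnancy_change)) "significant" else "not significant"))
  cat(sprintf("  total GWG:     %.1f -> %.1f kg (change %+.1f, %s)\n",
              g1$mean, g2$mean, x$gwg_change,
              if (isTRUE(x$significant_gwg_change)) "significant" else "not significant"))
  invisible(x)
}
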