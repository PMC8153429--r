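# End-to-end pipeline: eligibility -> weighting -> trajectory -> gains.

#' Estimate gestational weight gain from survey records
#'
#' Runs the full pseudo-cohort pipeline: splits validated records into the
#' pregnant and at-risk analysis sets ([eligibility_split()]), derives
#' post-stratification factors over the countries represented across the two
#' sets and combines them with sampling weights (normalised per analysis set,
#' [combine_weights()]), reconstructs the monthly trajectory
#' ([monthly_trajectory()]), and differences the anchors into trimester
#' gains and total GWG with 95% confidence intervals ([trimester_gains()]).
#'
#' @param records a `woman_records` data frame.
#' @param meta a [country_meta()] data frame covering every country present.
#' @param postpartum_exclusion_months see [filter_at_risk()].
#' @param cluster optional record-column name for cluster-robust SEs.
#' @return object of class `gwg_fit`: list with `eligibility`
#'   (exclusion tally), `n_pregnant`, `n_at_risk`, `countries`,
#'   `trajectory` (`gwg_trajectory`) and `gwg` (`gwg_gains`).
#' @examples
#' syn <- generate_cohort(truth_params(), n_women = 2000, seed = 1)
#' fit <- estimate_gwg(syn$records, syn$meta)
#' fit$gwg$gain_total
#' @export
estimate_gwg <- function(records, meta, postpartum_exclusion_months = 12,
                         cluster = NULL) {
  split <- eligibility_split(records, postpartum_exclusion_months)
  preg <- split$pregnant_set
  risk <- split$at_risk_set
  if (nrow(preg) == 0L) .stopf("no eligible pregnant records")
  if (nrow(risk) == 0L) .stopf("no eligible at-risk records")
  countries <- unique(c(preg$country, risk$country))
  factors <- post_stratification_factors(meta, countries)
  wp <- combine_weights(preg, factors)
  wr <- combine_weights(risk, factors)
  traj <- monthly_trajectory(preg, risk, wp, wr, cluster = cluster)
  gains <- trimester_gains(traj)
  structure(list(
    eligibility = split$exclusion_tally,
    n_pregnant = nrow(preg), n_at_risk = nrow(risk),
    countries = countries,
    trajectory = traj, gwg = gains
  ), class = "gwg_fit")
}

#' @export
print.gwg_fit <- function(x, ...) {
  cat(sprintf("Pseudo-cohort GWG fit: %d pregnant, %d at-risk women, %d countries\n\n",
              x$n_pregnant, x$n_at_risk, length(x$countries)))
  cat("Trajectory (kg):\n")
  print(x$trajectory)
  cat("\nGains (kg):\n")
  print(x$gwg)
  invisible(x)
}
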