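# Monthly weight trajectory: pre-pregnancy (at-risk) mean plus weighted
# month-specific means W1..W9 for pregnant women.

#' Reconstruct the monthly weight trajectory
#'
#' The pseudo-cohort trajectory: the pre-pregnancy anchor is the weighted
#' mean weight of the at-risk set, and `months[[m]]` is the weighted mean
#' weight of pregnant women reporting gestational month m (1-9). Months with
#' no records are absent (`NULL`), not zero. Months 3, 6 and 9 anchor the
#' trimester-gain arithmetic, so the trajectory is not estimable when any of
#' them is empty.
#'
#' @param pregnant pregnant analysis set (from [filter_pregnant()]).
#' @param at_risk at-risk analysis set (from [filter_at_risk()]).
#' @param pregnant_weights,at_risk_weights `analysis_weights` data frames
#'   (or bare numeric vectors) aligned with the two record sets.
#' @param cluster optional name of a column in the record sets holding
#'   cluster identifiers, for cluster-robust SEs (see [weighted_mean()]).
#' @return object of class `gwg_trajectory`: list with `pre_pregnancy` (a
#'   [mean_estimate()]) and `months` (list of 9 estimates or `NULL`s).
#' @export
monthly_trajectory <- function(pregnant, at_risk, pregnant_weights,
                               at_risk_weights, cluster = NULL) {
  wp <- .weights_vector(pregnant_weights, pregnant)
  wr <- .weights_vector(at_risk_weights, at_risk)
  cl_p <- if (!is.null(cluster)) pregnant[[cluster]]
  cl_r <- if (!is.null(cluster)) at_risk[[cluster]]
  if (nrow(at_risk) == 0L) .stopf("at-risk set is empty; pre-pregnancy weight not estimable")
  pre <- weighted_mean(at_risk$weight_kg, wr, cluster = cl_r)
  months <- vector("list", 9L)
  for (m in 1:9) {
    idx <- which(pregnant$gestational_month == m)
    if (length(idx))
      months[[m]] <- weighted_mean(pregnant$weight_kg[idx], wp[idx],
                                   cluster = if (!is.null(cl_p)) cl_p[idx])
  }
  for (m in c(3L, 6L, 9L))
    if (is.null(months[[m]]))
      .stopf("trajectory not estimable: no pregnant records at gestational month %d", m)
  structure(list(pre_pregnancy = pre, months = months), class = "gwg_trajectory")
}

.weights_vector <- function(w, records) {
  if (inherits(w, "analysis_weights") || is.data.frame(w)) {
    if (nrow(w) != nrow(records)) .stopf("weights and records differ in length")
    return(w$final_weight)
  }
  if (length(w) != nrow(records)) .stopf("weights and records differ in length")
  as.numeric(w)
}

#' @export
as.data.frame.gwg_trajectory <- function(x, ...) {
  ests <- c(list(x$pre_pregnancy), x$months)
  lab <- c("pre-pregnancy", paste("month", 1:9))
  keep <- !vapply(ests, is.null, logical(1))
  ests <- ests[keep]
  data.frame(
    point = lab[keep],
    mean = vapply(ests, `[[`, numeric(1), "mean"),
    se = vapply(ests, `[[`, numeric(1), "se"),
    ci_low = vapply(ests, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ests, `[[`, numeric(1), "ci_high"),
    n = vapply(ests, function(e) as.integer(e$n), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.gwg_trajectory <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- c("mean", "se", "ci_low", "ci_high")
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
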