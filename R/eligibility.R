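# Eligibility filters: pregnant analysis set and the non-pregnant
# "at risk of conception" set, with auditable exclusion tallies.
#
# When several criteria fail, the exclusion is tallied under the first
# failing reason in a fixed precedence (pregnancy status, postpartum,
# contraception, menstruation, abstinence, missing weight), so tallies are
# reproducible and mutually exclusive. Unknown (missing) eligibility
# attributes fail their criterion, except months_since_last_birth, where a
# missing value means no recorded birth and passes the postpartum screen.

.first_reason <- function(fail_mat, reasons) {
  # fail_mat: logical matrix rows x reasons (in precedence order)
  idx <- apply(fail_mat, 1L, function(r) which(r)[1L])
  reasons[idx]
}

.tally <- function(reason_vec, reasons) {
  tab <- table(factor(reason_vec, levels = reasons))
  stats::setNames(as.integer(tab), reasons)
}

#' Select the pregnant analysis set
#'
#' Retains records of pregnant women with complete gestational month and body
#' weight. A reported gestational month of 10 (a small share of self-reports
#' run past 9) is recoded to 9 in the output. Exclusions are tallied by first
#' failing reason, in the order: not pregnant, missing gestational month,
#' missing weight.
#'
#' @param records a `woman_records` data frame (see [woman_records()]).
#' @return the retained records, with attribute `exclusion_tally` (named
#'   integer vector).
#' @export
filter_pregnant <- function(records) {
  preg_ok <- !is.na(records$is_pregnant) & records$is_pregnant
  fail <- cbind(
    not_pregnant = !preg_ok,
    missing_gestational_month = is.na(records$gestational_month),
    missing_weight = is.na(records$weight_kg)
  )
  keep <- rowSums(fail) == 0L
  out <- records[keep, , drop = FALSE]
  out$gestational_month[out$gestational_month == 10L] <- 9L
  rownames(out) <- NULL
  reasons <- colnames(fail)
  excl <- .first_reason(fail[!keep, , drop = FALSE], reasons)
  attr(out, "exclusion_tally") <- .tally(excl, reasons)
  attr(out, "validation") <- attr(records, "validation")
  out
}

#' Select the non-pregnant "at risk of conception" set
#'
#' Women whose current weight proxies pre-pregnancy weight: non-pregnant,
#' menstruating, sexually active, using no contraceptive method (modern or
#' natural), with a recorded weight, and not having given birth within the
#' postpartum exclusion window (postpartum weight retention would otherwise
#' inflate the baseline). Women with no recorded birth pass the postpartum
#' screen. Exclusions are tallied by first failing reason, in the order:
#' pregnant, recently postpartum, using contraception, not menstruating,
#' sexually abstaining, missing weight.
#'
#' @inheritParams filter_pregnant
#' @param postpartum_exclusion_months births within this many months exclude
#'   a woman (default 12, i.e. "gave birth in the last one year").
#' @return the retained records, with attribute `exclusion_tally`.
#' @export
filter_at_risk <- function(records, postpartum_exclusion_months = 12) {
  mslb <- records$months_since_last_birth
  fail <- cbind(
    pregnant = is.na(records$is_pregnant) | records$is_pregnant,
    recently_postpartum = !is.na(mslb) & mslb < postpartum_exclusion_months,
    using_contraception = is.na(records$uses_contraception) | records$uses_contraception,
    not_menstruating = is.na(records$is_menstruating) | !records$is_menstruating,
    sexually_abstaining = is.na(records$is_sexually_active) | !records$is_sexually_active,
    missing_weight = is.na(records$weight_kg)
  )
  keep <- rowSums(fail) == 0L
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  reasons <- colnames(fail)
  excl <- .first_reason(fail[!keep, , drop = FALSE], reasons)
  attr(out, "exclusion_tally") <- .tally(excl, reasons)
  attr(out, "validation") <- attr(records, "validation")
  out
}

#' Split records into pregnant and at-risk analysis sets
#'
#' Applies [filter_pregnant()] and [filter_at_risk()] and combines their
#' exclusion tallies so that every input record is accounted for exactly
#' once: retained in one of the two sets or tallied under a single exclusion
#' reason (pregnant-side reasons are prefixed `pregnant_`).
#'
#' @inheritParams filter_at_risk
#' @return object of class `gwg_eligibility`: list with `pregnant_set`,
#'   `at_risk_set`, and `exclusion_tally`.
#' @export
eligibility_split <- function(records, postpartum_exclusion_months = 12) {
  preg <- filter_pregnant(records)
  risk <- filter_at_risk(records, postpartum_exclusion_months)
  tp <- attr(preg, "exclusion_tally")
  tr <- attr(risk, "exclusion_tally")
  # pregnant-side records excluded for missing data; non-pregnant-side
  # records excluded by at-risk criteria. "not_pregnant" / "pregnant"
  # cross-tallies drop out: those rows are the other filter's input.
  tally <- c(
    pregnant_missing_gestational_month = unname(tp["missing_gestational_month"]),
    pregnant_missing_weight = unname(tp["missing_weight"]),
    tr[setdiff(names(tr), "pregnant")]
  )
  stopifnot(sum(tally) + nrow(preg) + nrow(risk) == nrow(records))
  structure(list(pregnant_set = preg, at_risk_set = risk, exclusion_tally = tally),
            class = "gwg_eligibility")
}

#' @export
print.gwg_eligibility <- function(x, ...) {
  cat("Eligibility split:", nrow(x$pregnant_set), "pregnant,",
      nrow(x$at_risk_set), "at risk of conception\n")
  cat("Exclusions:\n")
  for (r in names(x$exclusion_tally))
    cat(sprintf("  %-36s %d\n", r, x$exclusion_tally[[r]]))
  invisible(x)
}
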