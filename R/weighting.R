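# Analysis weights: survey sampling weight x country post-stratification
# factor, rescaled so the weighted and unweighted sample sizes agree.

#' Country post-stratification factors
#'
#' Each represented country's factor is its population share among the
#' countries actually present in the analysis set:
#' `factor(c) = population(c) / sum(population over countries_in_set)`.
#' Factors sum to one over the represented countries.
#'
#' @param meta a [country_meta()] data frame.
#' @param countries character vector of countries represented in the
#'   analysis set (duplicates ignored).
#' @return named numeric vector of factors.
#' @export
post_stratification_factors <- function(meta, countries) {
  meta <- country_meta(meta)
  countries <- unique(as.character(countries))
  miss <- setdiff(countries, meta$country)
  if (length(miss))
    .stopf("country absent from metadata: %s", paste(miss, collapse = ", "))
  pop <- stats::setNames(meta$population, meta$country)[countries]
  pop / sum(pop)
}

#' Combine sampling weights with post-stratification factors
#'
#' The raw analysis weight is `sampling_weight * factor(country)`; raw
#' weights are then rescaled so they sum to the unweighted record count n
#' (the normalisation that balances the weighted and unweighted sample
#' size, so n remains the effective divisor in SE formulas). Final weights
#' are invariant to rescaling all sampling weights by a constant.
#'
#' @param records a `woman_records` data frame.
#' @param factors named numeric vector from [post_stratification_factors()]
#'   covering every country present in `records`.
#' @return data frame of class `analysis_weights` with columns `woman_id`
#'   and `final_weight`, in record order; `sum(final_weight) == nrow(records)`.
#' @export
combine_weights <- function(records, factors) {
  if (nrow(records) == 0L) .stopf("no records to weight")
  miss <- setdiff(unique(records$country), names(factors))
  if (length(miss))
    .stopf("no post-stratification factor for: %s", paste(miss, collapse = ", "))
  raw <- records$sampling_weight * unname(factors[records$country])
  s <- sum(raw)
  if (!is.finite(s) || s <= 0) .stopf("degenerate weighting: raw weights sum to %g", s)
  out <- data.frame(woman_id = records$woman_id,
                    final_weight = raw * nrow(records) / s,
                    stringsAsFactors = FALSE)
  class(out) <- c("analysis_weights", "data.frame")
  out
}

#' Compute final analysis weights for a record set
#'
#' Convenience wrapper: derives post-stratification factors over the
#' countries represented in `records` and combines them with the sampling
#' weights.
#'
#' @inheritParams combine_weights
#' @param meta a [country_meta()] data frame.
#' @return an `analysis_weights` data frame (see [combine_weights()]).
#' @export
analysis_weights <- function(records, meta) {
  combine_weights(records, post_stratification_factors(meta, records$country))
}
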