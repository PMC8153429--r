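# Fixture builders used across test files; everything is generated in code.

toy_df <- function(n = 1, ...) {
  base <- data.frame(
    woman_id = sprintf("w%03d", seq_len(n)),
    country = "Atlantis",
    survey_year = 2016L,
    is_pregnant = FALSE,
    gestational_month = NA_integer_,
    weight_kg = 60,
    age_years = 25L,
    residence = "rural",
    education = "primary",
    wealth_quintile = "middle",
    height_cm = 160,
    uses_contraception = FALSE,
    is_menstruating = TRUE,
    is_sexually_active = TRUE,
    months_since_last_birth = NA_integer_,
    sampling_weight = 1,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (f in names(over)) base[[f]] <- over[[f]]
  base
}

toy_records <- function(n = 1, ...) woman_records(toy_df(n, ...))

toy_meta <- function(country = "Atlantis", population = 1e6,
                     sub_region = "Eastern", income_class = "low") {
  country_meta(data.frame(country = country, population = population,
                          sub_region = sub_region, income_class = income_class,
                          stringsAsFactors = FALSE))
}

# random records with missingness sprinkled over the eligibility-relevant
# fields, for brute-force filter checks
random_records <- function(n, seed) {
  with_na <- function(x, p) {
    x[runif(n) < p] <- NA
    x
  }
  df <- withr_local_seed(seed, {
    toy_df(
      n,
      is_pregnant = runif(n) < 0.3,
      gestational_month = with_na(sample(1:10, n, replace = TRUE), 0.25),
      weight_kg = with_na(round(runif(n, 40, 90), 1), 0.15),
      uses_contraception = runif(n) < 0.3,
      is_menstruating = runif(n) < 0.8,
      is_sexually_active = runif(n) < 0.7,
      months_since_last_birth = with_na(sample(0:48, n, replace = TRUE), 0.5),
      sampling_weight = round(runif(n, 0.2, 3), 4)
    )
  })
  df$gestational_month[!df$is_pregnant] <- NA_integer_
  woman_records(df)
}

withr_tempfile <- function() tempfile(fileext = ".csv")

# minimal local-seed helper so fixtures do not disturb test RNG state
withr_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# single-country zero-noise scenario: every estimate is exactly recoverable
noiseless_params <- function(gains = c(1.2, 2.2, 3.2), baseline = 57.1,
                             day_sampling = "center", ...) {
  cn <- data.frame(country = "Atlantis", population = 1e6,
                   sub_region = "Eastern", income_class = "low",
                   sample_share = 1, baseline_mean_kg = baseline,
                   baseline_sd_kg = 0, stringsAsFactors = FALSE)
  truth_params(countries = cn, gain_t1_kg = gains[1], gain_t2_kg = gains[2],
               gain_t3_kg = gains[3], measurement_sd_kg = 0,
               day_sampling = day_sampling, ...)
}
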