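# Data model: woman-level survey records, country metadata, tabular IO.

.residence_levels <- c("urban", "rural")
.education_levels <- c("none", "primary", "secondary", "higher")
.wealth_levels    <- c("poorest", "poorer", "middle", "richer", "richest")
.sub_region_levels <- c("Eastern", "Southern", "Western", "Central")
.income_levels     <- c("low", "lower_middle_or_upper")

# Field registry: parse class, enum levels, and whether a row is unusable
# without the field ("required"). height_cm is the only field whose source
# column may be absent altogether.
.woman_fields <- list(
  woman_id                = list(class = "character", required = TRUE),
  country                 = list(class = "character", required = TRUE),
  survey_year             = list(class = "integer",   required = TRUE),
  is_pregnant             = list(class = "logical",   required = TRUE),
  gestational_month       = list(class = "integer",   required = FALSE, range = c(1L, 10L)),
  weight_kg               = list(class = "numeric",   required = FALSE, positive = TRUE),
  age_years               = list(class = "integer",   required = FALSE, range = c(15L, 49L)),
  residence               = list(class = "enum",      required = FALSE, levels = .residence_levels),
  education               = list(class = "enum",      required = FALSE, levels = .education_levels),
  wealth_quintile         = list(class = "enum",      required = FALSE, levels = .wealth_levels),
  height_cm               = list(class = "numeric",   required = FALSE, positive = TRUE, optional_column = TRUE),
  uses_contraception      = list(class = "logical",   required = FALSE),
  is_menstruating         = list(class = "logical",   required = FALSE),
  is_sexually_active      = list(class = "logical",   required = FALSE),
  months_since_last_birth = list(class = "integer",   required = FALSE, range = c(0L, Inf)),
  sampling_weight         = list(class = "numeric",   required = TRUE,  positive = TRUE)
)

#' Build a column mapping for woman-level records
#'
#' Decouples the pipeline from source variable names. Each argument maps a
#' canonical field to the source column that holds it; unmentioned fields are
#' assumed to carry their canonical name. `recode` gives per-field value
#' translations applied before parsing (e.g. survey codes to enum labels).
#'
#' @param ... named character scalars, `field = "source_column"`. Valid field
#'   names are: `r paste(names(gwgcohort:::.woman_fields), collapse = ", ")`.
#' @param recode named list; each element is a named character vector mapping
#'   source codes to canonical values for that field, e.g.
#'   `list(residence = c("1" = "urban", "2" = "rural"))`.
#' @return an object of class `gwg_mapping`.
#' @examples
#' column_mapping(weight_kg = "v437", recode = list(residence = c("1" = "urban", "2" = "rural")))
#' @export
column_mapping <- function(..., recode = list()) {
  override <- list(...)
  bad <- setdiff(names(override), names(.woman_fields))
  if (length(bad)) .stopf("unknown record field(s) in mapping: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(recode), names(.woman_fields))
  if (length(bad)) .stopf("unknown record field(s) in recode: %s", paste(bad, collapse = ", "))
  columns <- stats::setNames(names(.woman_fields), names(.woman_fields))
  for (f in names(override)) columns[[f]] <- as.character(override[[f]])
  structure(list(columns = columns, recode = recode), class = "gwg_mapping")
}

.parse_field <- function(x, info) {
  # x: character vector (NA for empty cells); returns list(value, bad) where
  # bad marks cells that were non-empty but unparseable/invalid.
  switch(info$class,
    character = list(value = x, bad = rep(FALSE, length(x))),
    integer = {
      v <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & (is.na(v) | v != round(v))
      v[bad] <- NA
      list(value = as.integer(round(v)), bad = bad)
    },
    numeric = {
      v <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(v)
      if (isTRUE(info$positive)) {
        neg <- !is.na(v) & v <= 0
        bad <- bad | neg
        v[neg] <- NA
      }
      list(value = v, bad = bad)
    },
    logical = {
      lx <- tolower(trimws(x))
      v <- rep(NA, length(x))
      v[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
      v[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
      list(value = v, bad = !is.na(x) & is.na(v))
    },
    enum = {
      v <- ifelse(x %in% info$levels, x, NA_character_)
      list(value = v, bad = !is.na(x) & is.na(v))
    }
  )
}

# Validate a parsed data.frame of canonical columns; flags are side-band
# (attribute "validation"), values are never mutated here.
.build_records <- function(df, weight_window, issues = NULL, n_rows_read = nrow(df)) {
  issues <- issues %||% data.frame(row = integer(), field = character(),
                                   issue = character(), stringsAsFactors = FALSE)
  flag <- function(rows, field, what) {
    if (!length(rows)) return(issues)
    rbind(issues, data.frame(row = rows, field = field, issue = what,
                             stringsAsFactors = FALSE))
  }
  # required fields: rows lacking them are unusable
  req <- names(Filter(function(i) i$required, .woman_fields))
  usable <- rep(TRUE, nrow(df))
  for (f in req) {
    miss <- is.na(df[[f]])
    issues <- flag(which(miss), f, "missing required field; row excluded")
    usable <- usable & !miss
  }
  bad_w <- !is.na(df$sampling_weight) & df$sampling_weight <= 0
  issues <- flag(which(bad_w), "sampling_weight", "nonpositive; row excluded")
  usable <- usable & !bad_w

  gm <- df$gestational_month
  out_gm <- !is.na(gm) & (gm < 1L | gm > 10L)
  issues <- flag(which(out_gm), "gestational_month", "outside 1-10")
  gm_nonpreg <- !is.na(gm) & !is.na(df$is_pregnant) & !df$is_pregnant
  issues <- flag(which(gm_nonpreg), "gestational_month", "present for non-pregnant woman")

  wk <- df$weight_kg
  implaus <- !is.na(wk) & (wk < weight_window[1] | wk > weight_window[2])
  issues <- flag(which(implaus), "weight_kg",
                 sprintf("outside plausibility window [%g, %g]", weight_window[1], weight_window[2]))
  preg_miss_gm <- !is.na(df$is_pregnant) & df$is_pregnant & is.na(gm)
  issues <- flag(which(preg_miss_gm), "gestational_month", "missing for pregnant woman")

  rec <- df[usable, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("woman_records", "data.frame")
  attr(rec, "validation") <- list(
    n_rows_read = n_rows_read,
    n_records = nrow(rec),
    n_excluded_rows = sum(!usable),
    n_weight_implausible = sum(implaus & usable),
    weight_window = weight_window,
    issues = issues
  )
  rec
}

#' Validate an in-memory data frame of woman-level records
#'
#' Coerces canonical columns to their declared types, drops rows whose
#' required fields (`woman_id`, `country`, `survey_year`, `is_pregnant`,
#' `sampling_weight`) are unusable, and attaches a side-band validation
#' report (see [validation_report()]). Implausible weights are flagged, never
#' dropped or altered.
#'
#' @param df data frame with canonical column names (see [column_mapping()]).
#' @param weight_window numeric length-2; body weights outside this window
#'   (kg) are flagged as implausible.
#' @return a `woman_records` data frame.
#' @export
woman_records <- function(df, weight_window = c(25, 200)) {
  need <- setdiff(names(.woman_fields), "height_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("missing record column(s): %s", paste(miss, collapse = ", "))
  if (!"height_cm" %in% names(df)) df$height_cm <- NA_real_
  out <- df[names(.woman_fields)]
  for (f in names(.woman_fields)) {
    info <- .woman_fields[[f]]
    out[[f]] <- switch(info$class,
      character = as.character(out[[f]]),
      integer = as.integer(out[[f]]),
      numeric = as.numeric(out[[f]]),
      logical = as.logical(out[[f]]),
      enum = {
        v <- as.character(out[[f]])
        if (any(!is.na(v) & !v %in% info$levels))
          .stopf("invalid level(s) in %s: %s", f,
                 paste(unique(setdiff(v[!is.na(v)], info$levels)), collapse = ", "))
        v
      })
  }
  .build_records(out, weight_window)
}

.infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read woman-level survey records from a delimited text file
#'
#' Reads a CSV/TSV with header, applies a [column_mapping()] (source column
#' names and value recodes), parses and validates each field, and returns a
#' `woman_records` data frame with a validation report attached. Rows are
#' excluded only when a required field is unusable; all other problems
#' (missing values, implausible weights, unparseable cells) are flagged in
#' the report and the row retained. Extra columns in the file are ignored.
#'
#' @inheritParams woman_records
#' @param path file path.
#' @param mapping a [column_mapping()].
#' @param sep field separator; default inferred from the extension
#'   (`.tsv`/`.tab`/`.txt` tab, otherwise comma).
#' @return a `woman_records` data frame; retrieve the report with
#'   [validation_report()].
#' @export
read_woman_records <- function(path, mapping = column_mapping(),
                               weight_window = c(25, 200), sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (!inherits(mapping, "gwg_mapping")) .stopf("mapping must come from column_mapping()")
  raw <- utils::read.table(path, header = TRUE, sep = .infer_sep(path, sep),
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  n <- nrow(raw)
  parsed <- list()
  issues <- data.frame(row = integer(), field = character(), issue = character(),
                       stringsAsFactors = FALSE)
  for (f in names(.woman_fields)) {
    info <- .woman_fields[[f]]
    col <- mapping$columns[[f]]
    if (!col %in% names(raw)) {
      if (isTRUE(info$optional_column)) {
        parsed[[f]] <- rep(NA_real_, n)
        next
      }
      .stopf("mapped column '%s' (field %s) not found in %s", col, f, path)
    }
    x <- raw[[col]]
    rc <- mapping$recode[[f]]
    if (!is.null(rc)) {
      hit <- !is.na(x) & x %in% names(rc)
      x[hit] <- unname(rc[x[hit]])
    }
    p <- .parse_field(x, info)
    if (any(p$bad))
      issues <- rbind(issues, data.frame(row = which(p$bad), field = f,
                                         issue = "unparseable or invalid value",
                                         stringsAsFactors = FALSE))
    parsed[[f]] <- p$value
  }
  df <- as.data.frame(parsed, stringsAsFactors = FALSE)
  .build_records(df, weight_window, issues = issues, n_rows_read = n)
}

#' Retrieve the validation report attached to a set of records
#'
#' @param records a `woman_records` data frame.
#' @return list with counts (`n_rows_read`, `n_records`, `n_excluded_rows`,
#'   `n_weight_implausible`), the plausibility window, and an `issues` data
#'   frame (row, field, issue).
#' @export
validation_report <- function(records) {
  rep <- attr(records, "validation")
  if (is.null(rep)) .stopf("no validation report attached; use read_woman_records()/woman_records()")
  rep
}

#' Write records to the canonical CSV layout
#'
#' Canonical column order, empty cells for missing values; re-reading with the
#' default mapping reproduces the records field-for-field.
#'
#' @param records a `woman_records` (or compatible) data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_woman_records <- function(records, path) {
  df <- as.data.frame(records)[names(.woman_fields)]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a country metadata table
#'
#' @param df data frame with columns `country`, `population`, `sub_region`
#'   (Eastern/Southern/Western/Central), `income_class`
#'   (low/lower_middle_or_upper).
#' @return a validated `country_meta` data frame.
#' @export
country_meta <- function(df) {
  need <- c("country", "population", "sub_region", "income_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("missing country metadata column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$country <- as.character(df$country)
  df$population <- as.numeric(df$population)
  df$sub_region <- as.character(df$sub_region)
  df$income_class <- as.character(df$income_class)
  dup <- df$country[duplicated(df$country)]
  if (length(dup)) .stopf("duplicated country key(s): %s", paste(unique(dup), collapse = ", "))
  if (any(is.na(df$population) | df$population <= 0))
    .stopf("nonpositive or missing population for: %s",
           paste(df$country[is.na(df$population) | df$population <= 0], collapse = ", "))
  bad <- !df$sub_region %in% .sub_region_levels
  if (any(bad)) .stopf("unknown sub_region label(s): %s", paste(unique(df$sub_region[bad]), collapse = ", "))
  bad <- !df$income_class %in% .income_levels
  if (any(bad)) .stopf("unknown income_class label(s): %s", paste(unique(df$income_class[bad]), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("country_meta", "data.frame")
  df
}

#' Read country metadata from a delimited text file
#'
#' @inheritParams read_woman_records
#' @return a `country_meta` data frame (see [country_meta()]).
#' @export
read_country_meta <- function(path, sep = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = .infer_sep(path, sep),
                          na.strings = "", stringsAsFactors = FALSE)
  country_meta(df)
}
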