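# ---- age-band arithmetic -----------------------------------------------

#' Five-year age bands
#'
#' Registry incidence is analysed on eight 5-year age bands (40-44 through
#' 75-79). The prevalence panel must extend further down because cohort
#' matching ages a stratum backwards by the lag: a 30-year lag from the
#' 40-44 band reaches the 10-14 band.
#'
#' @param age numeric age(s) in years (lower band bound is enough).
#' @return `age_band_of()`: the "lo-hi" label of the 5-year band containing
#'   `age`. `outcome_age_bands()` / `panel_age_bands()`: character vectors of
#'   band labels in ascending age order.
#' @examples
#' age_band_of(73)          # "70-74"
#' outcome_age_bands()[1]   # "40-44"
#' @export
age_band_of <- function(age) {
  lo <- 5L * as.integer(floor(age / 5))
  sprintf("%d-%d", lo, lo + 4L)
}

#' @rdname age_band_of
#' @export
outcome_age_bands <- function() age_band_of(seq(40L, 75L, by = 5L))

#' @rdname age_band_of
#' @param lag_max maximal lag (years) the panel must support.
#' @export
panel_age_bands <- function(lag_max = 30L) {
  age_band_of(seq(5L * floor((40L - lag_max) / 5L), 75L, by = 5L))
}

band_lower <- function(band) as.integer(sub("-.*$", "", band))

# ---- strata table -------------------------------------------------------

strata_cols <- c("country", "registry", "age_group", "gender",
                 "outcome_year", "cases", "population")

#' Validate a table of demographic strata
#'
#' One row per stratum-year: a (country, registry, age group, gender)
#' population observed in one outcome year, with its lung-cancer case count
#' Y and person-years at risk P. Invariants: cases >= 0 (integer),
#' population > 0, age group one of the eight outcome bands, gender "M"/"F",
#' outcome year inside `year_range` when given.
#'
#' @param df data frame with columns country, registry, age_group, gender,
#'   outcome_year, cases, population.
#' @param year_range optional length-2 integer vector of admissible outcome
#'   years.
#' @return the validated data frame, invisibly classed `"strata_table"`.
#' @export
validate_strata <- function(df, year_range = NULL) {
  miss <- setdiff(strata_cols, names(df))
  if (length(miss)) {
    stop("strata table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, what) {
    stop(sprintf("invalid strata row %s: %s",
                 paste(utils::head(rows, 5L), collapse = ", "), what),
         call. = FALSE)
  }
  cases <- df$cases
  pop <- df$population
  if (any(bad <- !is.finite(cases) | cases < 0 | cases != round(cases))) {
    fail(which(bad), "cases must be a non-negative integer")
  }
  if (any(bad <- !is.finite(pop) | pop <= 0)) {
    fail(which(bad), "population must be > 0")
  }
  if (any(bad <- !(df$age_group %in% outcome_age_bands()))) {
    fail(which(bad), "age_group not one of the eight 40-44 .. 75-79 bands")
  }
  if (any(bad <- !(df$gender %in% c("F", "M")))) {
    fail(which(bad), 'gender must be "M" or "F"')
  }
  yr <- df$outcome_year
  if (any(bad <- !is.finite(yr) | yr != round(yr))) {
    fail(which(bad), "outcome_year must be an integer year")
  }
  if (!is.null(year_range) &&
      any(bad <- yr < min(year_range) | yr > max(year_range))) {
    fail(which(bad), sprintf("outcome_year outside [%d, %d]",
                             min(year_range), max(year_range)))
  }
  class(df) <- unique(c("strata_table", class(df)))
  invisible(df)
}

#' Read / write a strata table
#'
#' Plain CSV with an explicit header, one row per stratum-year. A schema
#' (named list mapping the canonical column names to the file's column
#' names, or the path of a YAML file holding such a mapping) renames
#' arbitrary input headers; unmapped canonical names are looked up verbatim.
#'
#' @param path CSV file path.
#' @param schema named list (canonical -> file column) or YAML file path.
#' @param year_range passed to [validate_strata()].
#' @return a validated `strata_table` data frame.
#' @export
read_strata_table <- function(path, schema = NULL, year_range = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- stats::setNames(as.list(strata_cols), strata_cols)
  if (!is.null(schema)) map[names(schema)] <- schema
  src <- unlist(map[strata_cols], use.names = FALSE)
  miss <- src[!(src %in% names(df))]
  if (length(miss)) {
    stop("input is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- df[src]
  names(out) <- strata_cols
  out$country <- as.character(out$country)
  out$registry <- as.character(out$registry)
  out$age_group <- as.character(out$age_group)
  out$gender <- as.character(out$gender)
  out$outcome_year <- as.integer(out$outcome_year)
  out$cases <- as.numeric(out$cases)
  out$population <- as.numeric(out$population)
  out <- validate_strata(out, year_range = year_range)
  message(sprintf("read %d strata rows from %s", nrow(out), path))
  out
}

#' @rdname read_strata_table
#' @param df a strata table.
#' @export
write_strata_table <- function(df, path) {
  utils::write.csv(as.data.frame(df)[strata_cols], path, row.names = FALSE)
  invisible(path)
}

#' Stable per-stratum identifier
#'
#' Used to key residual RNG sub-streams and to label exposure histories.
#' @param df a strata table.
#' @return character vector, one id per row.
#' @export
stratum_id <- function(df) {
  paste(df$country, df$registry, df$gender, df$age_group, df$outcome_year,
        sep = "/")
}

# ---- prevalence panel ---------------------------------------------------

panel_cols <- c("country", "gender", "age_band", "year", "prevalence")

#' Smoking-prevalence panel
#'
#' Long-format panel of smoking prevalence (%) by country, gender, 5-year
#' age band and calendar year; the lookup table from which lagged exposure
#' histories are assembled. Values must lie in [0, 100].
#'
#' @param df data frame with columns country, gender, age_band, year,
#'   prevalence.
#' @return the data frame classed `"prevalence_panel"`.
#' @export
prevalence_panel <- function(df) {
  miss <- setdiff(panel_cols, names(df))
  if (length(miss)) {
    stop("prevalence panel is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- df$prevalence
  if (any(!is.finite(p) | p < 0 | p > 100)) {
    stop("prevalence values must lie in [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(do.call(paste, c(df[panel_cols[1:4]], sep = "\r")))) {
    stop("duplicated (country, gender, age_band, year) cells in panel",
         call. = FALSE)
  }
  class(df) <- unique(c("prevalence_panel", class(df)))
  df
}

#' @rdname prevalence_panel
#' @param path CSV file path.
#' @export
read_prevalence_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$year <- as.integer(df$year)
  out <- prevalence_panel(df)
  message(sprintf("read %d prevalence cells from %s", nrow(out), path))
  out
}

#' @rdname prevalence_panel
#' @export
write_prevalence_panel <- function(df, path) {
  utils::write.csv(as.data.frame(df)[panel_cols], path, row.names = FALSE)
  invisible(path)
}

panel_key <- function(country, gender, band, year) {
  paste(country, gender, band, year, sep = "\r")
}

# ---- exposure histories -------------------------------------------------

#' Exposure history of a stratum
#'
#' The lagged exposure vector (x at lag 0, 1, ..., L), lag running backward
#' in time from the outcome year. All values must be in [0, 100] with no
#' gaps: the model needs a complete ordered exposure series.
#'
#' @param values numeric vector of length `lag_max + 1`.
#' @param lag_max maximal lag L.
#' @return numeric vector classed `"exposure_history"` with a `lag_max`
#'   attribute.
#' @export
exposure_history <- function(values, lag_max = length(values) - 1L) {
  values <- as.numeric(values)
  if (length(values) != lag_max + 1L) {
    stop("exposure history must have length lag_max + 1", call. = FALSE)
  }
  if (any(!is.finite(values) | values < 0 | values > 100)) {
    stop("exposure values must be complete and in [0, 100]", call. = FALSE)
  }
  structure(values, lag_max = as.integer(lag_max), class = "exposure_history")
}

#' Cohort-matched lagged exposure lookup
#'
#' Matches the exposure history of a stratum retrospectively: the exposure
#' at lag l is the panel value for calendar year (outcome_year - l) and the
#' 5-year age band containing (lower age bound - l), i.e. the band the same
#' birth cohort occupied l years before the outcome year. Example: a 75-79
#' stratum observed in 2012 takes its lag-4 exposure from the 70-74 band in
#' 2008.
#'
#' @param panel a [prevalence_panel()].
#' @param record one stratum: a list or one-row data frame with country,
#'   gender, age_group, outcome_year.
#' @param lag_max maximal lag L (years).
#' @return an [exposure_history()] of length `lag_max + 1`.
#' @export
cohort_lagged_exposure <- function(panel, record, lag_max = 30L) {
  h <- exposure_histories(panel, as.data.frame(record, stringsAsFactors = FALSE),
                          lag_max = lag_max)
  exposure_history(h[1L, ], lag_max = lag_max)
}

#' Assemble all exposure histories for a strata table
#'
#' Vectorised [cohort_lagged_exposure()] over every row of a strata table.
#'
#' @param panel a [prevalence_panel()].
#' @param strata a strata table.
#' @param lag_max maximal lag L.
#' @return numeric matrix, one row per stratum, `lag_max + 1` columns named
#'   `lag0 ... lagL`; rownames are [stratum_id()]s when the table carries a
#'   registry column.
#' @export
exposure_histories <- function(panel, strata, lag_max = 30L) {
  keys <- panel_key(panel$country, panel$gender, panel$age_band, panel$year)
  vals <- panel$prevalence
  n <- nrow(strata)
  lo <- band_lower(strata$age_group)
  out <- matrix(NA_real_, n, lag_max + 1L,
                dimnames = list(NULL, paste0("lag", 0:lag_max)))
  for (l in 0:lag_max) {
    want <- panel_key(strata$country, strata$gender, age_band_of(lo - l),
                      strata$outcome_year - l)
    idx <- match(want, keys)
    if (anyNA(idx)) {
      i <- which(is.na(idx))[1L]
      stop(sprintf(
        "prevalence panel has no value for (%s, %s, band %s, year %d)",
        strata$country[i], strata$gender[i], age_band_of(lo[i] - l),
        strata$outcome_year[i] - l), call. = FALSE)
    }
    out[, l + 1L] <- vals[idx]
  }
  if (!is.null(strata$registry)) rownames(out) <- stratum_id(strata)
  out
}
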