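test_that("strata CSV round-trips exactly and preserves row count", {
  grid <- expand.grid(outcome_year = 2010:2012, gender = c("F", "M"),
                      age_group = outcome_age_bands(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(country = "Nowhere", registry = "NW-1",
                   grid[c("age_group", "gender", "outcome_year")],
                   cases = seq_len(nrow(grid)) * 3,
                   population = 1e5 + seq_len(nrow(grid)) * 7.25,
                   stringsAsFactors = FALSE)
  expect_equal(nrow(df), 48L)  # 3 years x 2 genders x 8 bands
  path <- withr::local_tempfile(fileext = ".csv")
  write_strata_table(validate_strata(df), path)
  suppressMessages(back <- read_strata_table(path))
  expect_equal(nrow(back), 48L)
  expect_equal(as.data.frame(back)[names(df)], df)
})

test_that("validation rejects bad rows with their row index", {
  ok <- data.frame(country = "A", registry = "A-1", age_group = "40-44",
                   gender = "F", outcome_year = 2010L, cases = 3,
                   population = 100, stringsAsFactors = FALSE)
  bad_pop <- rbind(ok, transform(ok, population = 0))
  expect_error(validate_strata(bad_pop), "row 2.*population")
  bad_cases <- rbind(ok, transform(ok, cases = -1))
  expect_error(validate_strata(bad_cases), "row 2.*cases")
  expect_error(validate_strata(transform(ok, age_group = "39-43")),
               "age_group")
  expect_error(validate_strata(transform(ok, gender = "U")), "gender")
  expect_error(validate_strata(ok, year_range = c(2011, 2012)),
               "outcome_year")
  expect_error(validate_strata(ok[, -7]), "missing column.*population")
})

test_that("schema mapping renames arbitrary input headers", {
  df <- data.frame(nation = "A", reg = "A-1", ageband = "50-54", sex = "M",
                   yr = 2011L, n_cases = 5, pyears = 2e5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(country = "nation", registry = "reg", age_group = "ageband",
                 gender = "sex", outcome_year = "yr", cases = "n_cases",
                 population = "pyears")
  suppressMessages(out <- read_strata_table(path, schema = schema))
  expect_equal(out$country, "A")
  expect_equal(out$cases, 5)
  # same mapping via a YAML schema file
  spath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(schema, spath)
  suppressMessages(out2 <- read_strata_table(path, schema = spath))
  expect_equal(as.data.frame(out2), as.data.frame(out))
  expect_error(suppressMessages(read_strata_table(path)), "missing required")
})

test_that("cohort matching ages the stratum backwards through 5-year bands", {
  # panel value encodes (band lower bound, year) so lookups are checkable
  panel <- sl_toy_panel(value = function(band, year) {
    (as.integer(sub("-.*", "", band)) + (year %% 100) / 100) / 2
  })
  rec <- list(country = "X", gender = "F", age_group = "75-79",
              outcome_year = 2012L)
  h <- cohort_lagged_exposure(panel, rec, lag_max = 30L)
  expect_s3_class(h, "exposure_history")
  expect_length(h, 31L)
  # the published worked example: lag 4 of a 75-79 stratum in 2012 is the
  # 70-74 band in 2008
  expect_equal(as.numeric(h[5]), (70 + 0.08) / 2)
  # zero lag: same band, same year
  expect_equal(as.numeric(h[1]), (75 + 0.12) / 2)
  # lag 30: band containing 75 - 30 = 45 in 1982
  expect_equal(as.numeric(h[31]), (45 + 0.82) / 2)
})

test_that("constant panel gives a constant history; gaps are reported", {
  panel <- sl_toy_panel()
  rec <- list(country = "X", gender = "F", age_group = "40-44",
              outcome_year = 2010L)
  h <- cohort_lagged_exposure(panel, rec, lag_max = 30L)
  expect_equal(as.numeric(h), rep(30, 31))
  short <- prevalence_panel(as.data.frame(panel)[panel$year >= 1990, ])
  # first unresolvable lookup: lag 21 -> band containing 40 - 21, year 1989
  expect_error(cohort_lagged_exposure(short, rec, lag_max = 30L),
               "band 15-19, year 1989")
})

test_that("cohort matching is shift-equivariant in calendar time", {
  set.seed(9)
  base <- sl_toy_panel(value = function(band, year) {
    50 + 20 * sin(year / 3 + as.integer(sub("-.*", "", band)))
  })
  shifted <- as.data.frame(base)
  shifted$year <- shifted$year + 7L
  shifted <- prevalence_panel(shifted)
  rec <- list(country = "X", gender = "F", age_group = "60-64",
              outcome_year = 2009L)
  rec2 <- rec; rec2$outcome_year <- 2016L
  expect_equal(as.numeric(cohort_lagged_exposure(base, rec, 30L)),
               as.numeric(cohort_lagged_exposure(shifted, rec2, 30L)))
})

test_that("exposure history invariants hold", {
  expect_error(exposure_history(c(10, 200), 1L), "\\[0, 100\\]")
  expect_error(exposure_history(c(10, NA), 1L), "complete")
  expect_error(exposure_history(1:5, 3L), "length")
  panel <- sl_toy_panel()
  strata <- data.frame(country = "X", registry = "X-1",
                       age_group = c("40-44", "75-79"), gender = "F",
                       outcome_year = 2011L, cases = 1, population = 1e4)
  m <- exposure_histories(panel, strata, lag_max = 12L)
  expect_equal(dim(m), c(2L, 13L))
  expect_equal(colnames(m)[c(1, 13)], c("lag0", "lag12"))
})

test_that("prevalence panel validates bounds and duplicates", {
  df <- data.frame(country = "X", gender = "F", age_band = "40-44",
                   year = 2000L, prevalence = 101)
  expect_error(prevalence_panel(df), "\\[0, 100\\]")
  df$prevalence <- 50
  expect_error(prevalence_panel(rbind(df, df)), "duplicated")
})
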