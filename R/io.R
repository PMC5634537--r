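# Readers/writers for the four tabular schemas (RFC 4180 CSV, UTF-8,
# ISO-8601 dates, lowercase snake-case categorical codes) with strict
# validation, plus cohort export.

SCHEMAS <- list(
  incidents = list(
    required = c("record_id", "first_name", "surname", "age", "gender",
                 "race_ethnicity", "injury_date", "death_year", "state",
                 "county_id", "mechanism"),
    closed = list(mechanism = quote(MECHANISM_LEVELS),
                  gender = quote(c(GENDER_LEVELS, "missing")))
  ),
  mortality = list(
    required = c("mortality_id", "first_name", "surname", "birth_year",
                 "death_date", "death_state", "underlying_cause",
                 "multiple_causes"),
    closed = list()
  ),
  monthly_counts = list(required = c("month", "count"), closed = list()),
  counties = list(
    required = c("county_id", "state_id", "income_quintile", "urbanicity",
                 "investigator_type"),
    closed = list(income_quintile = quote(INCOME_LEVELS),
                  urbanicity = quote(URBANICITY_LEVELS),
                  investigator_type = quote(INVESTIGATOR_LEVELS))
  )
)

validate_table <- function(df, schema_id) {
  sc <- SCHEMAS[[schema_id]]
  if (is.null(sc)) stop("unknown schema: ", schema_id)
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop(schema_id, ": missing column(s) ", paste(miss, collapse = ", "))
  for (v in names(sc$closed)) {
    allowed <- eval(sc$closed[[v]])
    x <- df[[v]][!is.na(df[[v]])]
    bad <- setdiff(unique(x), allowed)
    if (length(bad))
      stop(schema_id, ": column `", v, "` has values outside the closed set: ",
           paste(bad, collapse = ", "))
  }
  for (v in intersect(c("injury_date", "death_date"), names(df))) {
    x <- as.character(df[[v]])
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(as.Date(x, "%Y-%m-%d"))
    if (any(!ok))
      stop(schema_id, ": column `", v, "` has non-ISO-8601 dates in rows ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
    df[[v]] <- as.Date(x)
  }
  if (schema_id == "monthly_counts") {
    if (!setequal(df$month, 1:12) || nrow(df) != 12)
      stop("monthly_counts: must have exactly one row per month 1-12")
    if (any(df$count < 0)) stop("monthly_counts: negative counts")
  }
  df
}

#' Read or write a validated pipeline table
#'
#' Validates the four CSV schemas used by the pipeline: `incidents`,
#' `mortality`, `monthly_counts`, `counties`. Validation checks required
#' columns, closed categorical sets and ISO-8601 dates; violations raise an
#' error naming the offending column and rows. A write followed by a read is
#' the identity on the validated columns.
#'
#' @param path CSV file path.
#' @param schema_id one of `"incidents"`, `"mortality"`, `"monthly_counts"`,
#'   `"counties"`.
#' @return `read_table_csv`: the validated data frame.
#' @export
read_table_csv <- function(path, schema_id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_table(df, schema_id)
}

#' @param df data frame to write.
#' @rdname read_table_csv
#' @export
write_table_csv <- function(df, path, schema_id) {
  df <- validate_table(as.data.frame(df), schema_id)
  out <- df
  for (v in intersect(c("injury_date", "death_date"), names(out)))
    out[[v]] <- format(out[[v]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic cohort as the four pipeline input files
#'
#' Writes `incidents.csv`, `mortality.csv`, `monthly_counts.csv`,
#' `counties.csv` and `truth.json` into a directory.
#'
#' @param cohort a [sim_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(cohort$incidents, file.path(dir, "incidents.csv"), "incidents")
  write_table_csv(cohort$mortality, file.path(dir, "mortality.csv"), "mortality")
  write_table_csv(cohort$monthly_counts, file.path(dir, "monthly_counts.csv"),
                  "monthly_counts")
  write_table_csv(cohort$counties, file.path(dir, "counties.csv"), "counties")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}
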