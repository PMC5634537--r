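# ICD-10 classification of legal-intervention deaths, cause grouping,
# stratified misclassification tables and state rate bands.

CAUSE_CATEGORIES <- c("legal_intervention", "assault", "undetermined_or_missing",
                      "suicide", "accident", "circulatory_respiratory",
                      "mental_behavioral", "other")

# normalize to uppercase category + optional 4th character, no decimal point
icd_normalize <- function(codes) {
  x <- toupper(gsub("\\.", "", trimws(codes)))
  bad <- !grepl("^[A-Z][0-9]{2}[0-9A-Z]?$", x)
  if (any(bad))
    stop("malformed ICD-10 code(s): ", paste(unique(codes[bad]), collapse = ", "))
  x
}

#' Does a cause-of-death code list indicate legal intervention?
#'
#' True when any of the multiple-cause codes falls in the legal-intervention
#' set Y35.0-Y35.4, Y35.6, Y35.7 or Y89.0 (late effects). Legal execution,
#' Y35.5, is deliberately excluded. A record with no qualifying code among
#' its causes is *misclassified* in the registry sense: it cannot be found by
#' a query for legal-intervention deaths.
#'
#' @param multiple_causes character vector of ICD-10 codes (decimal point
#'   optional), or a single `";"`-separated string.
#' @return logical scalar.
#' @examples
#' is_legal_intervention(c("X95", "Y35.0"))  # TRUE
#' is_legal_intervention("Y35.5")            # FALSE (legal execution)
#' @export
is_legal_intervention <- function(multiple_causes) {
  if (length(multiple_causes) == 1 && grepl(";", multiple_causes))
    multiple_causes <- strsplit(multiple_causes, ";", fixed = TRUE)[[1]]
  multiple_causes <- multiple_causes[!is.na(multiple_causes) & multiple_causes != ""]
  if (length(multiple_causes) == 0)
    stop("empty cause-of-death code list")
  any(icd_normalize(multiple_causes) %in% LEGAL_INTERVENTION_CODES)
}

#' Group an underlying cause of death into reporting categories
#'
#' Categories follow the standard external-cause ranges: legal intervention
#' (Y35 excluding legal execution Y35.5; Y89.0), assault (X95-Y09), events of
#' undetermined intent or cause missing (Y10-Y34; R99), suicide (X60-X84),
#' accident (V01-X59), circulatory/respiratory diseases (I00-J99),
#' mental/behavioral disorders (F00-F99), other. The first matching range in
#' that order wins; ranges are evaluated on the normalized three-character
#' category, compared lexicographically within letter blocks.
#'
#' @param code character vector of ICD-10 underlying-cause codes.
#' @return character vector of categories.
#' @examples
#' group_underlying_cause(c("X95", "R99", "W34", "I21.9", "Y35.5"))
#' @export
group_underlying_cause <- function(code) {
  x <- icd_normalize(code)
  cat3 <- substr(x, 1, 3)
  in_range <- function(lo, hi) cat3 >= lo & cat3 <= hi
  out <- rep("other", length(x))
  done <- logical(length(x))
  assign_cat <- function(hit, label) {
    hit <- hit & !done
    out[hit] <<- label
    done[hit] <<- TRUE
  }
  assign_cat((cat3 == "Y35" & x != "Y355") | x == "Y890", "legal_intervention")
  assign_cat(in_range("X95", "Y09"), "assault")
  assign_cat(in_range("Y10", "Y34") | cat3 == "R99", "undetermined_or_missing")
  assign_cat(in_range("X60", "X84"), "suicide")
  assign_cat(in_range("V01", "X59"), "accident")
  assign_cat(in_range("I00", "J99"), "circulatory_respiratory")
  assign_cat(in_range("F00", "F99"), "mental_behavioral")
  out
}

#' Stratified misclassification table with exact intervals
#'
#' Tabulates misclassified versus properly classified deaths by the levels of
#' one covariate: counts, percent misclassified with Clopper-Pearson 95%
#' interval, and a chi-squared test of independence (no continuity
#' correction) over the non-missing levels. A `missing` stratum is reported
#' but excluded from the test.
#'
#' @param data data frame with a logical `misclassified` column and the
#'   covariate.
#' @param covariate column name to stratify by.
#' @return data frame, one row per level plus a `total` row; the test
#'   p-value is attached to the first row.
#' @export
tabulate_misclassification <- function(data, covariate) {
  data <- as.data.frame(data)
  stopifnot("misclassified" %in% names(data), covariate %in% names(data))
  x <- as.character(data[[covariate]])
  x[is.na(x) | x == ""] <- "missing"
  lev <- unique(x)
  if (length(lev) == 0) stop("no strata to tabulate")
  lev <- c(setdiff(lev, "missing"), intersect("missing", lev))
  mis <- data$misclassified
  tab <- t(vapply(lev, function(l) c(sum(mis & x == l), sum(!mis & x == l)),
                  numeric(2)))
  test_tab <- tab[rownames(tab) != "missing", , drop = FALSE]
  p <- if (nrow(test_tab) >= 2 && all(rowSums(test_tab) > 0))
    suppressWarnings(chisq.test(test_tab, correct = FALSE)$p.value)
  else NA_real_
  ci <- t(vapply(seq_along(lev), function(k) {
    n <- sum(tab[k, ])
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(tab[k, 1], n)$conf.int) * 100
  }, numeric(2)))
  rows <- data.frame(
    covariate = covariate,
    level = c(lev, "total"),
    misclassified = c(tab[, 1], sum(mis)),
    classified = c(tab[, 2], sum(!mis)),
    total = c(rowSums(tab), length(mis)),
    percent = 100 * c(tab[, 1] / pmax(rowSums(tab), 1), mean(mis)),
    ci_low = c(ci[, 1], as.numeric(binom.test(sum(mis), length(mis))$conf.int[1]) * 100),
    ci_high = c(ci[, 2], as.numeric(binom.test(sum(mis), length(mis))$conf.int[2]) * 100),
    p_value = c(p, rep(NA_real_, length(lev))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rows
}

#' Per-state misclassification rates with reporting bands
#'
#' @param data data frame with logical `misclassified` and a `state` column.
#' @return data frame with per-state counts, rate, a rate band (`<20`,
#'   `20-40`, `40-60`, `60-80`, `>=80` percent, closed-open) and a
#'   deaths-count band (`<10`, `10-20`, `>=20`). States with zero cases are
#'   omitted.
#' @export
state_rate_bands <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("misclassified", "state") %in% names(data)))
  if (anyNA(data$state)) stop("state must be present on every record")
  st <- sort(unique(data$state))
  n <- vapply(st, function(s) sum(data$state == s), numeric(1))
  m <- vapply(st, function(s) sum(data$misclassified & data$state == s), numeric(1))
  keep <- n > 0
  st <- st[keep]; n <- n[keep]; m <- m[keep]
  rate <- 100 * m / n
  rate_band <- cut(rate, breaks = c(-Inf, 20, 40, 60, 80, Inf), right = FALSE,
                   labels = c("<20%", "20-40%", "40-60%", "60-80%", ">=80%"))
  count_band <- cut(n, breaks = c(-Inf, 10, 20, Inf), right = FALSE,
                    labels = c("<10", "10-20", ">=20"))
  data.frame(state = st, deaths = as.integer(n), misclassified = as.integer(m),
             percent = rate, rate_band = as.character(rate_band),
             count_band = as.character(count_band),
             row.names = NULL, stringsAsFactors = FALSE)
}
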