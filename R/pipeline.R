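# End-to-end orchestration: filter -> match -> cells -> estimate
# (+ sensitivity) -> misclassification, plus the desk reproduction of the
# published aggregate analysis.

# summary counts printed in the source tables, used as inputs by
# reproduce_paper(): linkage tallies and the registry's annual
# legal-intervention total for 2015
PAPER_COUNTS <- list(
  included = 1086L,            # media-list incidents after exclusions
  matched = 991L,              # linked to a mortality record
  matched_classified = 444L,   # linked, with a legal-intervention code
  matched_unclassified = 547L, # linked, misclassified
  unmatched = 95L,
  nvss_total = 523L            # registry legal-intervention deaths, 2015
)

#' Reproduce the published aggregate capture-recapture analysis
#'
#' Runs the estimation stages on the published aggregate summary counts
#' (1,086 included incidents of which 991 linked, 444 of those carrying a
#' legal-intervention code, and a registry annual total of 523): unlinked
#' incidents are redistributed with [redistribute_unmatched()], the three
#' observed capture cells are assembled, and the independence and
#' dependence-offset models are fitted with [crc_fit()].
#'
#' @param alpha_sensitivity dependence offset for the sensitivity fit.
#' @return list with the assembled `cells`, the independence `fit`, rounded
#'   headline numbers (`N_hat`, `N_ci`, `n00_hat`, `n00_ci`), the
#'   `coverage` table, and the `sensitivity` fit at `alpha_sensitivity`.
#' @examples
#' rep <- reproduce_paper()
#' rep$N_hat      # 1166
#' rep$coverage
#' @export
reproduce_paper <- function(alpha_sensitivity = 0.93) {
  pc <- PAPER_COUNTS
  red <- redistribute_unmatched(pc$unmatched, pc$matched_classified, pc$matched)
  n11 <- pc$matched_classified + red[["add_to_both"]]
  n10 <- pc$matched_unclassified + red[["add_to_media_only"]]
  n01 <- pc$nvss_total - n11
  cells <- as_crc_cells(data.frame(n10 = n10, n01 = n01, n11 = n11))
  fit <- crc_fit(cells, alpha = 0)
  sens <- crc_fit(cells, alpha = alpha_sensitivity)
  list(
    cells = cells,
    fit = fit,
    N_hat = round(fit$N_hat),
    N_ci = round(fit$N_ci),
    n00_hat = round(fit$n00_hat),
    n00_ci = round(fit$n00_ci),
    coverage = coverage_proportions(fit, media_total = pc$included,
                                    nvss_total = pc$nvss_total),
    sensitivity = list(alpha = alpha_sensitivity,
                       N_hat = round(sens$N_hat),
                       N_ci = round(sens$N_ci)),
    inputs = pc
  )
}

#' Run the full analysis pipeline
#'
#' Executes filter -> match -> capture cells -> estimate (+ optional
#' sensitivity scan) -> misclassification analysis on in-memory tables or on
#' a YAML-configured set of CSV paths. Deterministic given the seed.
#'
#' @param incidents,mortality,monthly_counts,counties input tables (see
#'   [read_table_csv()] schemas), or `config` may name CSV paths.
#' @param config optional path to a YAML file with entries `incidents`,
#'   `mortality`, `monthly_counts`, `counties` and optional parameter blocks
#'   `match` (rule arguments), `alpha`, `alpha_grid`, `seed`, `out`.
#' @param alpha dependence offset for the main fit.
#' @param alpha_grid optional offsets for a sensitivity scan.
#' @param rules linkage rules, see [match_rules()].
#' @param seed seed for the (rarely reached) Monte-Carlo branches.
#' @param out optional path; the report is written there as JSON.
#' @param verbose emit stage-scoped progress messages to stderr.
#' @return list of class `crvital_report` with each stage's output and a
#'   provenance block (seed, package version, input sizes).
#' @export
run_pipeline <- function(incidents = NULL, mortality = NULL,
                         monthly_counts = NULL, counties = NULL,
                         config = NULL, alpha = 0, alpha_grid = NULL,
                         rules = match_rules(), seed = 1L, out = NULL,
                         verbose = TRUE) {
  say <- function(stage, ...) if (verbose) message("[", stage, "] ", ...)
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    incidents <- read_table_csv(cfg$incidents, "incidents")
    mortality <- read_table_csv(cfg$mortality, "mortality")
    monthly_counts <- read_table_csv(cfg$monthly_counts, "monthly_counts")
    if (!is.null(cfg$counties)) counties <- read_table_csv(cfg$counties, "counties")
    if (!is.null(cfg$match))
      rules <- do.call(match_rules, cfg$match)
    alpha <- cfg$alpha %||% alpha
    alpha_grid <- cfg$alpha_grid %||% alpha_grid
    seed <- cfg$seed %||% seed
    out <- cfg$out %||% out
  }
  stage <- "filter"
  report <- tryCatch({
    say(stage, "applying exclusion rules to ", nrow(incidents), " incidents")
    filt <- apply_filters(incidents)

    stage <- "match"
    say(stage, "linking ", nrow(filt$included), " incidents to ",
        nrow(mortality), " mortality records")
    mres <- match_records(filt$included, mortality, rules)
    rates <- summarize_match_rates(mres, filt$included, seed = seed)

    stage <- "cells"
    inc <- filt$included
    linked <- mres[!is.na(mres$mortality_id), ]
    mrow <- mortality[match(linked$mortality_id, mortality$mortality_id), ]
    classified <- vapply(mrow$multiple_causes, is_legal_intervention, logical(1),
                         USE.NAMES = FALSE)
    year <- as.integer(format(as.Date(inc$injury_date[1]), "%Y"))
    dq <- (as.integer(format(as.Date(mrow$death_date), "%m")) - 1) %/% 3 + 1
    in_year <- as.integer(format(as.Date(mrow$death_date), "%Y")) == year
    if (any(!in_year))
      stop("linked death dates outside the study year: filter stage should have ",
           "removed next-year deaths")
    unmatched_ids <- mres$incident_id[is.na(mres$mortality_id)]
    uq <- (as.integer(format(as.Date(
      inc$injury_date[inc$record_id %in% unmatched_ids]), "%m")) - 1) %/% 3 + 1
    count4 <- function(q, w = rep(TRUE, length(q)))
      vapply(1:4, function(k) sum(q == k & w), integer(1))
    say(stage, "assembling per-quarter capture cells")
    cells <- build_capture_cells(
      matched_classified = count4(dq, classified),
      matched_unclassified = count4(dq, !classified),
      unmatched = count4(uq),
      monthly_counts = monthly_counts
    )

    stage <- "estimate"
    say(stage, "fitting capture-recapture model (alpha = ", alpha, ")")
    fit <- crc_fit(cells, alpha = alpha)
    cov <- coverage_proportions(fit, media_total = nrow(inc),
                                nvss_total = sum(monthly_counts$count))
    sens <- if (!is.null(alpha_grid)) sensitivity_scan(cells, alpha_grid)

    stage <- "misclass"
    mis <- NULL
    if (!is.null(counties)) {
      say(stage, "tabulating misclassification for ", nrow(linked), " linked cases")
      mdat <- inc[match(linked$incident_id, inc$record_id), ]
      mdat$misclassified <- !classified
      mdat <- merge(mdat, counties, by = "county_id", all.x = TRUE, sort = FALSE)
      if (anyNA(mdat$state_id))
        stop("county covariates missing for some linked incidents")
      tabs <- lapply(c("age_group", "gender", "race_ethnicity", "mechanism",
                       "investigator_type", "urbanicity", "income_quintile"),
                     function(v) if (v %in% names(mdat))
                       tabulate_misclassification(mdat, v))
      mis <- list(tables = do.call(rbind, tabs),
                  state_bands = state_rate_bands(
                    within(mdat, state <- state_id)))
    }

    list(
      filter = list(tally = filt$tally, included = nrow(filt$included)),
      match = list(results = mres, rates = rates),
      cells = cells,
      estimate = list(N_hat = fit$N_hat, N_ci = fit$N_ci,
                      n00_hat = fit$n00_hat, n00_ci = fit$n00_ci,
                      alpha = alpha, coverage = cov),
      sensitivity = sens,
      misclassification = mis,
      fit = fit,
      provenance = list(seed = seed,
                        package_version = as.character(utils::packageVersion("crvital")),
                        n_incidents = nrow(incidents),
                        n_mortality = nrow(mortality))
    )
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- c("crvital_report", "list")
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_json(report), out, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  }
  report
}

# JSON-serializable view of a pipeline report (drops model objects)
report_to_json <- function(report) {
  list(
    filter = report$filter,
    match_total = report$match$rates$total,
    cells = as.data.frame(report$cells),
    estimate = report$estimate,
    sensitivity = if (!is.null(report$sensitivity))
      as.data.frame(report$sensitivity),
    misclassification = report$misclassification,
    provenance = report$provenance
  )
}

#' @export
print.crvital_report <- function(x, ...) {
  cat("crvital pipeline report\n")
  cat(sprintf("  included incidents: %d (excluded: %d)\n",
              x$filter$included, sum(x$filter$tally)))
  cat(sprintf("  matched: %d of %d\n", x$match$rates$total$matched,
              x$match$rates$total$total))
  print(x$fit)
  invisible(x)
}
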