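# Rule-based exclusion engine mapping raw media-list records to the analysis
# set of legal-intervention deaths, with a per-reason tally.

EXCLUSION_REASONS <- c("death_next_year", "friendly_fire", "domestic_violence",
                       "vehicle_not_pursuit", "custody_no_mechanism")

#' Classify a single incident against the exclusion rules
#'
#' The rules restrict a broad media-derived list to deaths conforming to the
#' ICD-10 "legal intervention" definition. They are applied as a fixed
#' cascade, so each excluded record receives one canonical reason:
#'
#' 1. `death_next_year` — injured in the study year but died the next year
#'    (absent from the study year's mortality file);
#' 2. `friendly_fire` — one officer accidentally shot by another;
#' 3. `domestic_violence` — perpetrated by an officer outside legal action;
#' 4. `vehicle_not_pursuit` — struck by a vehicle, unless injured during a
#'    police pursuit or intentionally injured as a passenger in transport;
#' 5. `custody_no_mechanism` — death in custody without a clear causal
#'    mechanism (chokehold/Taser, withholding of essential care) and not
#'    reportedly ruled a homicide.
#'
#' @param record a one-row data frame with the incident fields (see
#'   [sim_cohort()] for the schema).
#' @param study_year calendar year defining rule 1; defaults to the injury
#'   year.
#' @return list with `record_id`, `included` (logical) and `reason`
#'   (`"included"` or one of the five exclusion reasons).
#' @export
classify_exclusion <- function(record, study_year = NULL) {
  record <- as.list(record)
  if (is.null(record$mechanism) || is.na(record$mechanism) ||
      !record$mechanism %in% MECHANISM_LEVELS)
    stop("record ", record$record_id %||% "?", ": missing or invalid mechanism")
  study_year <- study_year %||% as.integer(format(as.Date(record$injury_date), "%Y"))
  flag <- function(f) isTRUE(as.logical(record[[f]]))

  reason <- if (!is.null(record$death_year) && !is.na(record$death_year) &&
                record$death_year > study_year) {
    "death_next_year"
  } else if (flag("friendly_fire")) {
    "friendly_fire"
  } else if (flag("domestic_violence")) {
    "domestic_violence"
  } else if (record$mechanism == "motor_vehicle" && !flag("vehicle_pursuit") &&
             !flag("intentional_vehicle_transport_injury")) {
    "vehicle_not_pursuit"
  } else if (flag("in_custody") && !flag("chokehold_or_taser") &&
             !flag("essential_care_withheld") && !flag("ruled_homicide")) {
    "custody_no_mechanism"
  } else {
    "included"
  }
  list(record_id = record$record_id, included = reason == "included",
       reason = reason)
}

#' Apply the exclusion rules to a set of incidents
#'
#' @param records incident data frame.
#' @param study_year passed to [classify_exclusion()].
#' @return list with `included` (data frame of retained records), `decisions`
#'   (one row per record: `record_id`, `included`, `reason`) and `tally`
#'   (named integer count per exclusion reason).
#' @export
apply_filters <- function(records, study_year = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    return(list(included = records,
                decisions = data.frame(record_id = character(0),
                                       included = logical(0),
                                       reason = character(0)),
                tally = setNames(integer(length(EXCLUSION_REASONS)),
                                 EXCLUSION_REASONS)))
  }
  if (any(is.na(records$mechanism)) ||
      !all(records$mechanism %in% MECHANISM_LEVELS))
    stop("missing or invalid mechanism in input records")
  sy <- study_year %||% as.integer(format(as.Date(records$injury_date), "%Y"))
  fl <- function(f) if (f %in% names(records)) isTRUE_vec(records[[f]])
    else rep(FALSE, nrow(records))
  dy <- if ("death_year" %in% names(records)) records$death_year else NA
  # vectorized form of the classify_exclusion() cascade (agreement is tested)
  reason <- rep("included", nrow(records))
  custody <- fl("in_custody") & !fl("chokehold_or_taser") &
    !fl("essential_care_withheld") & !fl("ruled_homicide")
  reason[custody] <- "custody_no_mechanism"
  vehicle <- records$mechanism == "motor_vehicle" & !fl("vehicle_pursuit") &
    !fl("intentional_vehicle_transport_injury")
  reason[vehicle] <- "vehicle_not_pursuit"
  reason[fl("domestic_violence")] <- "domestic_violence"
  reason[fl("friendly_fire")] <- "friendly_fire"
  reason[!is.na(dy) & dy > sy] <- "death_next_year"
  decisions <- data.frame(record_id = records$record_id,
                          included = reason == "included", reason = reason,
                          stringsAsFactors = FALSE)
  tally <- vapply(EXCLUSION_REASONS,
                  function(r) sum(decisions$reason == r), integer(1))
  list(included = records[decisions$included, , drop = FALSE],
       decisions = decisions, tally = tally)
}
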