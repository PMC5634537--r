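# Deterministic linkage of media-list incidents to mortality records, and
# stratified match-rate tables with exact tests.

#' Linkage rule parameters
#'
#' @param max_surname_edit maximum Levenshtein distance between surnames for
#'   a candidate pair (default 2: captures single typos and transpositions).
#' @param birth_year_tol tolerance around the birth year derived from the
#'   media-reported age (`study_year - age`); the default 1 absorbs birthday
#'   effects and single-year recording errors.
#' @param death_window_days auto-accept window: a candidate whose death date
#'   falls within this many days at or after the injury date, in the same
#'   state, is a match without further evidence.
#' @return list of class `match_rules`.
#' @export
match_rules <- function(max_surname_edit = 2L, birth_year_tol = 1L,
                        death_window_days = 4L) {
  structure(list(max_surname_edit = as.integer(max_surname_edit),
                 birth_year_tol = as.integer(birth_year_tol),
                 death_window_days = as.integer(death_window_days)),
            class = "match_rules")
}

#' Deterministically link incidents to mortality records
#'
#' Candidate pairs require a case-insensitive exact first name, surname edit
#' distance within the threshold, and a birth year within tolerance of
#' `study_year - age`. Among candidates:
#'
#' * death date in `[injury, injury + window]` and same state — `matched`;
#' * death date earlier than `injury - window` — rejected;
#' * any other date/state combination (a later death, a small pre-injury
#'   discrepancy, or a differing state) — `matched_with_confirmation`, but
#'   only if the incident carries an external confirmation flag
#'   (`confirmed_late_death`), else the candidate is not used.
#'
#' Ties between surviving candidates are broken by minimal absolute
#' death-date distance to the injury date; a residual tie is ambiguous and
#' reported `unmatched` rather than guessed. Results do not depend on input
#' row order.
#'
#' @param incidents incident data frame (requires `record_id`, `first_name`,
#'   `surname`, `age`, `injury_date`, `state`; optional
#'   `confirmed_late_death`).
#' @param mortality mortality data frame (requires `mortality_id`,
#'   `first_name`, `surname`, `birth_year`, `death_date`, `death_state`).
#' @param rules a [match_rules()].
#' @param study_year year used to derive birth year from age; defaults to the
#'   injury year per record.
#' @return data frame with one row per incident: `incident_id`,
#'   `mortality_id` (NA if unmatched), `status` (`matched`,
#'   `matched_with_confirmation`, `unmatched`), `n_candidates`, and
#'   `criteria_log` (compact per-pair rule outcomes).
#' @export
match_records <- function(incidents, mortality, rules = match_rules(),
                          study_year = NULL) {
  stopifnot(inherits(rules, "match_rules"))
  incidents <- as.data.frame(incidents)
  mortality <- as.data.frame(mortality)
  if (anyDuplicated(mortality$mortality_id))
    stop("duplicate mortality ids")
  inj <- as.Date(incidents$injury_date)
  dd <- as.Date(mortality$death_date)
  sy <- study_year %||% as.integer(format(inj, "%Y"))
  derived_by <- sy - incidents$age
  fkey_i <- tolower(incidents$first_name)
  fkey_m <- tolower(mortality$first_name)
  conf <- if ("confirmed_late_death" %in% names(incidents))
    isTRUE_vec(incidents$confirmed_late_death) else rep(FALSE, nrow(incidents))
  blocks <- split(seq_len(nrow(mortality)), fkey_m)

  n <- nrow(incidents)
  res_id <- rep(NA_character_, n); res_status <- rep("unmatched", n)
  res_ncand <- integer(n); res_log <- character(n)
  for (i in seq_len(n)) {
    cand <- blocks[[fkey_i[i]]]
    log_parts <- character(0)
    pick <- NA_character_; status <- "unmatched"
    if (!is.null(cand)) {
      ed <- drop(adist(tolower(incidents$surname[i]),
                       tolower(mortality$surname[cand])))
      keep <- ed <= rules$max_surname_edit &
        abs(mortality$birth_year[cand] - derived_by[i]) <= rules$birth_year_tol
      cand <- cand[keep]
      if (length(cand)) {
        delta <- as.integer(dd[cand] - inj[i])
        same_state <- mortality$death_state[cand] == incidents$state[i]
        auto <- delta >= 0 & delta <= rules$death_window_days & same_state
        rejected <- delta < -rules$death_window_days
        needs_conf <- !auto & !rejected
        log_parts <- sprintf("%s:ed_ok,by_ok,delta=%d,state=%s,%s",
                             mortality$mortality_id[cand], delta,
                             ifelse(same_state, "same", "diff"),
                             ifelse(auto, "auto",
                                    ifelse(rejected, "rejected", "confirm")))
        choose <- function(idx) {
          d <- abs(delta[idx])
          best <- idx[d == min(d)]
          if (length(best) > 1) NA_integer_ else best  # ambiguous tie
        }
        if (any(auto)) {
          j <- choose(which(auto))
          if (!is.na(j)) { pick <- mortality$mortality_id[cand[j]]; status <- "matched" }
        } else if (any(needs_conf) && conf[i]) {
          j <- choose(which(needs_conf))
          if (!is.na(j)) {
            pick <- mortality$mortality_id[cand[j]]
            status <- "matched_with_confirmation"
          }
        }
      }
    }
    res_id[i] <- pick; res_status[i] <- status
    res_ncand[i] <- length(cand)
    res_log[i] <- paste(log_parts, collapse = "|")
  }
  res <- data.frame(incident_id = incidents$record_id, mortality_id = res_id,
                    status = res_status, n_candidates = res_ncand,
                    criteria_log = res_log, stringsAsFactors = FALSE)
  res <- res[order(res$incident_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Stratified match rates with exact intervals and Fisher tests
#'
#' For each requested covariate, tabulates linked/unlinked counts per level,
#' the match proportion with its Clopper-Pearson 95% interval, and a Fisher
#' exact test of homogeneity over the level-by-outcome table. A `missing`
#' stratum is reported but excluded from the test. Tables whose total exceeds
#' `exact_max` are tested by Monte-Carlo simulation with a fixed seed.
#'
#' @param results output of [match_records()].
#' @param incidents the incident data frame the results refer to.
#' @param covariates character vector of incident columns to stratify by.
#' @param exact_max largest table total for the exhaustive test.
#' @param mc_draws Monte-Carlo replicates beyond `exact_max`.
#' @param seed seed for the Monte-Carlo branch.
#' @return list with `total` (overall counts, proportion, CI) and `strata`
#'   (data frame: covariate, level, matched, unmatched, total, percent, CI,
#'   test p-value attached to the covariate's first row).
#' @export
summarize_match_rates <- function(results, incidents,
                                  covariates = c("age_group", "gender",
                                                 "race_ethnicity", "mechanism"),
                                  exact_max = 2000L, mc_draws = 1e5, seed = 1L) {
  incidents <- as.data.frame(incidents)
  matched <- results$status %in% c("matched", "matched_with_confirmation")
  matched <- matched[match(incidents$record_id, results$incident_id)]
  if (anyNA(matched)) stop("every incident needs a row in `results`")

  cp <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(x, n)$conf.int) * 100
  }
  tot <- c(matched = sum(matched), unmatched = sum(!matched))
  total <- data.frame(matched = tot[["matched"]], unmatched = tot[["unmatched"]],
                      total = length(matched),
                      percent = 100 * mean(matched),
                      ci_low = cp(tot[["matched"]], length(matched))[1],
                      ci_high = cp(tot[["matched"]], length(matched))[2])

  strata <- lapply(covariates, function(v) {
    x <- as.character(incidents[[v]])
    x[is.na(x) | x == ""] <- "missing"
    lev <- unique(x)
    lev <- c(setdiff(lev, "missing"), intersect("missing", lev))
    tab <- t(vapply(lev, function(l) c(sum(matched & x == l), sum(!matched & x == l)),
                    numeric(2)))
    test_tab <- tab[rownames(tab) != "missing", , drop = FALSE]
    p <- NA_real_
    if (nrow(test_tab) >= 2 && all(rowSums(test_tab) > 0)) {
      if (sum(test_tab) <= exact_max) {
        p <- fisher.test(test_tab, workspace = 2e7)$p.value
      } else {
        p <- with_seed(seed, fisher.test(test_tab, simulate.p.value = TRUE,
                                         B = mc_draws)$p.value)
      }
    } else {
      warning("covariate `", v, "` has fewer than two populated levels; test skipped")
    }
    ci <- t(vapply(seq_along(lev),
                   function(k) cp(tab[k, 1], sum(tab[k, ])), numeric(2)))
    data.frame(covariate = v, level = lev,
               matched = tab[, 1], unmatched = tab[, 2], total = rowSums(tab),
               percent = 100 * tab[, 1] / pmax(rowSums(tab), 1),
               ci_low = ci[, 1], ci_high = ci[, 2],
               p_value = c(p, rep(NA_real_, length(lev) - 1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  list(total = total, strata = do.call(rbind, strata))
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
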