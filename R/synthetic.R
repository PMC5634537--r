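# Synthetic two-list death-registry generator: county frame, joint capture
# cell probabilities with controllable dependence, covariate-driven
# misclassification, identifier noise.

URBANICITY_LEVELS <- c("large_metro_central", "large_metro_fringe", "medium_metro",
                       "small_metro", "micropolitan", "non_core")
INVESTIGATOR_LEVELS <- c("medical_examiner", "coroner_elected", "coroner_appointed")
MECHANISM_LEVELS <- c("firearm", "taser", "struck_by_against", "motor_vehicle",
                      "neglect", "other_custody")
GENDER_LEVELS <- c("man", "woman")
RACE_LEVELS <- c("black", "white", "hispanic", "aian", "api")
AGE_GROUP_LEVELS <- c("lt18", "18_44", "45_plus")
INCOME_LEVELS <- c("Q1", "Q2", "Q3", "Q4", "Q5")
LEGAL_INTERVENTION_CODES <- c("Y350", "Y351", "Y352", "Y353", "Y354",
                              "Y356", "Y357", "Y890")

#' Configuration for the synthetic death-registry generator
#'
#' Defaults describe a year of US law-enforcement-related deaths at the scale
#' and composition of the 2015 study population: 1,166 true deaths, a media
#' list capturing 93.1% of them, a baseline (firearm, highest-income-county)
#' misclassification probability of 48.6%, strongly elevated
#' misclassification odds for non-firearm mechanisms and for counties outside
#' the top income quintile, and county/state random-intercept variances 7.1
#' and 2.7 on the logit scale.
#'
#' @param true_total true number of deaths.
#' @param year calendar year of injuries.
#' @param p_media probability a death is captured by the media list; a named
#'   per-urbanicity vector may be supplied via `p_media_by_urbanicity` to
#'   override it.
#' @param dependence_alpha log odds ratio between media capture and registry
#'   classification (0 = independent lists).
#' @param misclass_intercept baseline log-odds of misclassification (all
#'   covariates at reference, random effects 0).
#' @param misclass_coefs named list of named numeric vectors: per-level
#'   log-odds contributions to misclassification for `age_group`, `gender`,
#'   `race_ethnicity`, `mechanism`, `income_quintile` (reference levels 0).
#' @param sigma2_county,sigma2_state random-intercept variances.
#' @param covariate_mix named list of probability vectors for `age_group`,
#'   `gender`, `race_ethnicity`, `mechanism` (must each sum to 1).
#' @param county_mix named list of probability vectors for `income_quintile`,
#'   `urbanicity`, `investigator_type`.
#' @param n_states,counties_per_state geography size.
#' @param identifier_noise list with `p_typo` (single-character surname edit),
#'   `p_birth_year` (birth year off by one), `p_lag0` (probability the death
#'   occurs on the injury date), `lag_mean` (mean of the geometric tail of
#'   the death-date lag in days, given a positive lag).
#' @param p_media_by_urbanicity optional named vector overriding `p_media`
#'   per urbanicity class.
#' @param confirm_prob probability that a death whose registry date falls
#'   outside the matching window carries an external confirmation (a news
#'   report of the later death date).
#' @param seed integer; all generator randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(true_total = 1166L,
                       year = 2015L,
                       p_media = 1086 / 1166,
                       dependence_alpha = 0,
                       misclass_intercept = log(0.486 / (1 - 0.486)),
                       misclass_coefs = list(
                         age_group = c(lt18 = 0, `18_44` = 0, `45_plus` = 0),
                         gender = c(man = 0, woman = 0),
                         race_ethnicity = setNames(numeric(5), RACE_LEVELS),
                         mechanism = c(firearm = 0, taser = log(68.24),
                                       struck_by_against = log(68.24),
                                       motor_vehicle = log(68.24),
                                       neglect = log(68.24),
                                       other_custody = log(68.24)),
                         income_quintile = c(Q1 = log(10.11), Q2 = log(10.39),
                                             Q3 = log(7.02), Q4 = log(8.32),
                                             Q5 = 0)
                       ),
                       sigma2_county = 7.1,
                       sigma2_state = 2.7,
                       covariate_mix = list(
                         age_group = c(lt18 = 17, `18_44` = 766, `45_plus` = 301) / 1084,
                         gender = c(man = 1043, woman = 43) / 1086,
                         race_ethnicity = c(black = 294, white = 553, hispanic = 187,
                                            aian = 12, api = 22) / 1068,
                         mechanism = c(firearm = 920, taser = 46, struck_by_against = 18,
                                       motor_vehicle = 4, neglect = 3,
                                       other_custody = 0) / 991
                       ),
                       county_mix = list(
                         income_quintile = rep(0.2, 5),
                         urbanicity = c(391, 192, 237, 82, 77, 106) / 1085,
                         investigator_type = c(628, 423, 35) / 1086
                       ),
                       n_states = 40L,
                       counties_per_state = 12L,
                       identifier_noise = list(p_typo = 0.05, p_birth_year = 0.05,
                                               p_lag0 = 0.8, lag_mean = 4),
                       p_media_by_urbanicity = NULL,
                       confirm_prob = 1,
                       seed = 1L) {
  cfg <- list(true_total = as.integer(true_total), year = as.integer(year),
              p_media = p_media, dependence_alpha = dependence_alpha,
              misclass_intercept = misclass_intercept,
              misclass_coefs = misclass_coefs,
              sigma2_county = sigma2_county, sigma2_state = sigma2_state,
              covariate_mix = covariate_mix, county_mix = county_mix,
              n_states = as.integer(n_states),
              counties_per_state = as.integer(counties_per_state),
              identifier_noise = identifier_noise,
              p_media_by_urbanicity = p_media_by_urbanicity,
              confirm_prob = confirm_prob, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$true_total >= 1, cfg$n_states >= 1, cfg$counties_per_state >= 1)
  probs <- c(cfg$p_media, cfg$identifier_noise$p_typo, cfg$identifier_noise$p_birth_year,
             cfg$identifier_noise$p_lag0, cfg$confirm_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_media <= 0 || cfg$p_media >= 1) stop("`p_media` must lie in (0, 1)")
  if (cfg$sigma2_county < 0 || cfg$sigma2_state < 0) stop("variances must be >= 0")
  for (nm in names(cfg$covariate_mix)) {
    p <- cfg$covariate_mix[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("covariate mix `", nm, "` must be nonnegative and sum to 1")
  }
  for (nm in names(cfg$county_mix)) {
    p <- cfg$county_mix[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("county mix `", nm, "` must be nonnegative and sum to 1")
  }
  invisible(cfg)
}

#' Generate the synthetic county frame
#'
#' @param config a [sim_config()].
#' @return data frame with `county_id`, `state_id`, `income_quintile`,
#'   `urbanicity`, `investigator_type`; every county belongs to exactly one
#'   state.
#' @export
sim_county_frame <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_states * config$counties_per_state
  state_id <- sprintf("S%02d", rep(seq_len(config$n_states),
                                   each = config$counties_per_state))
  county_id <- sprintf("%s_C%03d", state_id,
                       rep(seq_len(config$counties_per_state), config$n_states))
  data.frame(
    county_id = county_id, state_id = state_id,
    income_quintile = sample(INCOME_LEVELS, n, TRUE, config$county_mix$income_quintile),
    urbanicity = sample(URBANICITY_LEVELS, n, TRUE, config$county_mix$urbanicity),
    investigator_type = sample(INVESTIGATOR_LEVELS, n, TRUE,
                               config$county_mix$investigator_type),
    stringsAsFactors = FALSE
  )
}

#' Joint capture-cell probabilities with a fixed log cross-ratio
#'
#' Given marginal capture probabilities `p1` (list A) and `p2` (list B) and a
#' log odds ratio `alpha` between the two memberships, solves for the 2x2
#' joint cell probabilities. The solution is a one-dimensional root find in
#' `q11` on its Frechet interval `(max(0, p1+p2-1), min(p1, p2))`, on which
#' the log cross-ratio is strictly increasing in `q11`.
#'
#' @param p1,p2 marginal probabilities in (0, 1); `p2` may be a vector.
#' @param alpha finite log odds ratio (0 = independence).
#' @return for scalar `p2`, named vector `c(q11, q10, q01, q00)`; for vector
#'   `p2`, a matrix with one row per element.
#' @examples
#' solve_joint_capture_probs(0.5, 0.5, 0)       # all 0.25
#' solve_joint_capture_probs(0.6, 0.6, 0.93)
#' @export
solve_joint_capture_probs <- function(p1, p2, alpha) {
  stopifnot(length(p1) == 1, p1 > 0, p1 < 1, all(p2 > 0), all(p2 < 1),
            length(alpha) == 1, is.finite(alpha))
  one <- function(p2i) {
    if (abs(alpha) < 1e-12) {
      q11 <- p1 * p2i
    } else {
      lo <- max(0, p1 + p2i - 1); hi <- min(p1, p2i)
      f <- function(q) log(q) + log(1 - p1 - p2i + q) -
        log(p1 - q) - log(p2i - q) - alpha
      eps <- (hi - lo) * 1e-12
      r <- uniroot(f, c(lo + eps, hi - eps), tol = 1e-14)
      if (abs(r$f.root) > 1e-6)
        stop(sprintf("no feasible joint solution: p1=%g p2=%g alpha=%g residual=%g",
                     p1, p2i, alpha, r$f.root))
      q11 <- r$root
    }
    c(q11 = q11, q10 = p1 - q11, q01 = p2i - q11, q00 = 1 - p1 - p2i + q11)
  }
  if (length(p2) == 1) one(p2) else t(vapply(p2, one, numeric(4)))
}

# deterministic synthetic names: syllable products give a large unique pool
sim_names <- function(n) {
  syl1 <- c("bar", "cal", "dor", "fen", "gar", "hol", "jur", "kel", "lim",
            "mor", "nev", "pol", "quil", "ros", "sul", "tam", "vor", "wex",
            "yar", "zel")
  syl2 <- c("an", "ber", "cot", "den", "ez", "fin", "gat", "hin", "is", "jo",
            "kur", "lan", "mer", "nor", "ot", "per", "rud", "sen", "tol", "ul")
  syl3 <- c("a", "by", "cus", "dale", "eth", "ford", "gail", "hart", "ington",
            "kins", "ley", "man", "ner", "over", "quist", "ridge", "son",
            "ton", "ville", "worth")
  first_pool <- c("alex", "bridget", "carlos", "dana", "elias", "farrah",
                  "gideon", "hana", "ivan", "jade", "kofi", "lena", "marcus",
                  "nadia", "omar", "priya", "quentin", "rosa", "samir",
                  "tessa", "umar", "vera", "walter", "ximena", "yusuf", "zoe")
  pool <- length(syl1) * length(syl2) * length(syl3)
  # surnames unique (ambiguity-free linkage) while n fits the pool; beyond it
  # surnames may repeat, which only linkage stress tests would notice
  idx <- if (n <= pool) sample.int(pool, n) else sample.int(pool, n, TRUE)
  i1 <- (idx - 1) %% length(syl1) + 1
  i2 <- ((idx - 1) %/% length(syl1)) %% length(syl2) + 1
  i3 <- (idx - 1) %/% (length(syl1) * length(syl2)) + 1
  data.frame(first_name = sample(first_pool, n, TRUE),
             surname = paste0(syl1[i1], syl2[i2], syl3[i3]),
             stringsAsFactors = FALSE)
}

sample_age <- function(group) {
  lo <- c(lt18 = 12, `18_44` = 18, `45_plus` = 45)[group]
  hi <- c(lt18 = 17, `18_44` = 44, `45_plus` = 90)[group]
  as.integer(lo + floor(runif(length(group)) * (hi - lo + 1)))
}

# underlying-cause assignment emulating the observed cause-mix by mechanism
misclassified_cause <- function(mechanism) {
  pick <- function(codes, w) sample(codes, 1, prob = w)
  switch(mechanism,
    firearm = pick(c("X95", "Y24", "X74", "W34", "I469"),
                   c(456, 11, 16, 1, 2)),
    taser = pick(c("Y08", "Y29", "R99", "W49", "I469", "F19"),
                 c(10, 4, 4, 10, 7, 5)),
    struck_by_against = pick(c("Y00", "Y29", "W18", "I219", "F03"),
                             c(4, 2, 1, 5, 2)),
    motor_vehicle = pick(c("Y03", "V892"), c(1, 3)),
    neglect = pick(c("R99", "T71", "X59"), c(1, 1, 1)),
    other_custody = pick(c("R99", "I469", "Y29"), c(1, 1, 1))
  )
}

classified_cause <- function(mechanism) {
  switch(mechanism,
    firearm = "Y350",
    taser = sample(c("Y352", "Y357"), 1),
    struck_by_against = sample(c("Y353", "Y357"), 1),
    motor_vehicle = "Y353",
    sample(c("Y356", "Y357"), 1)
  )
}

#' Generate a synthetic cohort of law-enforcement-related deaths
#'
#' Draws `true_total` deaths with covariates from the configured mixes,
#' assigns each to a county, gives each an injury date uniform over the year,
#' draws the registry classification indicator from a logistic model with
#' nested county/state random intercepts, and draws media capture jointly
#' with classification at the configured log cross-ratio via
#' [solve_joint_capture_probs()]. Every death appears in the mortality
#' collection (the registry holds all deaths; only its ICD-10 coding varies):
#' classified deaths receive a legal-intervention code among their causes,
#' misclassified deaths an alternative underlying cause drawn by mechanism.
#' Identifier noise and the death-date lag are applied by
#' [perturb_identifiers()] (called internally unless `perturb = FALSE`).
#'
#' @param config a [sim_config()].
#' @param counties optional county frame; generated from `config` if omitted.
#' @param perturb apply identifier noise to the mortality records.
#' @return list of class `sim_cohort` with `incidents` (media-captured deaths
#'   only), `mortality` (every death), `truth` (latent capture flags and
#'   quarter), `population` (every death with covariates and the latent
#'   misclassification flag), `counties`, and `monthly_counts` (registry
#'   legal-intervention deaths per month of the study year).
#' @export
sim_cohort <- function(config, counties = NULL, perturb = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(counties)) counties <- sim_county_frame(config)
  set.seed(config$seed + 1L)
  n <- config$true_total
  mix <- config$covariate_mix

  age_group <- sample(names(mix$age_group), n, TRUE, mix$age_group)
  gender <- sample(names(mix$gender), n, TRUE, mix$gender)
  race <- sample(names(mix$race_ethnicity), n, TRUE, mix$race_ethnicity)
  mechanism <- sample(names(mix$mechanism), n, TRUE, mix$mechanism)
  age <- sample_age(age_group)
  ci <- sample.int(nrow(counties), n, TRUE)
  county <- counties$county_id[ci]
  state <- counties$state_id[ci]
  income <- counties$income_quintile[ci]
  urb <- counties$urbanicity[ci]

  year_start <- as.Date(sprintf("%d-01-01", config$year))
  days <- as.integer(as.Date(sprintf("%d-12-31", config$year)) - year_start) + 1L
  injury_date <- year_start + sample.int(days, n, TRUE) - 1L

  u_county <- setNames(rnorm(nrow(counties), 0, sqrt(config$sigma2_county)),
                       counties$county_id)
  v_state <- setNames(rnorm(config$n_states, 0, sqrt(config$sigma2_state)),
                      unique(counties$state_id))
  cf <- config$misclass_coefs
  eta <- config$misclass_intercept +
    cf$age_group[age_group] + cf$gender[gender] + cf$race_ethnicity[race] +
    cf$mechanism[mechanism] + cf$income_quintile[income] +
    u_county[county] + v_state[state]
  p_mis <- plogis(unname(eta))
  p_class <- 1 - p_mis

  p1 <- if (!is.null(config$p_media_by_urbanicity))
    unname(config$p_media_by_urbanicity[urb]) else rep(config$p_media, n)

  in_media <- logical(n); classified <- logical(n)
  if (abs(config$dependence_alpha) < 1e-12 && length(unique(p1)) >= 1) {
    # independence fast path
    in_media <- runif(n) < p1
    classified <- runif(n) < p_class
  } else {
    for (i in seq_len(n)) {
      q <- solve_joint_capture_probs(p1[i], min(max(p_class[i], 1e-12), 1 - 1e-12),
                                     config$dependence_alpha)
      cell <- sample.int(4, 1, prob = q)  # q11, q10, q01, q00
      in_media[i] <- cell %in% c(1, 2)
      classified[i] <- cell %in% c(1, 3)
    }
  }

  nm <- sim_names(n)
  incident_id <- sprintf("I%05d", seq_len(n))
  incidents <- data.frame(
    record_id = incident_id,
    first_name = nm$first_name, surname = nm$surname,
    age = age, age_group = age_group, gender = gender, race_ethnicity = race,
    injury_date = injury_date, death_year = config$year,
    state = state, county_id = county, mechanism = mechanism,
    vehicle_pursuit = mechanism == "motor_vehicle",
    intentional_vehicle_transport_injury = FALSE,
    domestic_violence = FALSE, friendly_fire = FALSE,
    in_custody = mechanism %in% c("neglect", "other_custody", "taser"),
    chokehold_or_taser = mechanism == "taser",
    essential_care_withheld = mechanism == "neglect",
    ruled_homicide = mechanism == "other_custody",
    confirmed_late_death = FALSE,
    stringsAsFactors = FALSE
  )

  underlying <- character(n); multiple <- character(n)
  for (i in seq_len(n)) {
    if (classified[i]) {
      uc <- classified_cause(mechanism[i])
      extra <- sample(c("T141", "T07", "S069"), 1)
      underlying[i] <- uc
      multiple[i] <- paste(uc, extra, sep = ";")
    } else {
      uc <- misclassified_cause(mechanism[i])
      underlying[i] <- uc
      multiple[i] <- uc
    }
  }
  mortality <- data.frame(
    mortality_id = sprintf("M%05d", seq_len(n)),
    incident_id = incident_id,   # provenance for truth-table scoring
    first_name = nm$first_name, surname = nm$surname,
    birth_year = config$year - age,
    death_date = injury_date,
    death_state = state,
    underlying_cause = underlying,
    multiple_causes = multiple,
    typo_applied = FALSE, birth_year_shifted = FALSE, lag_days = 0L,
    stringsAsFactors = FALSE
  )

  if (perturb) {
    mortality <- perturb_identifiers(mortality, config$identifier_noise,
                                     seed = config$seed + 2L)
  }

  # late deaths: external confirmation with configured probability
  late <- mortality$lag_days > 4
  if (any(late)) {
    set.seed(config$seed + 3L)
    incidents$confirmed_late_death[late] <- runif(sum(late)) < config$confirm_prob
  }
  incidents$death_year <- as.integer(format(mortality$death_date, "%Y"))

  in_year <- incidents$death_year == config$year
  month <- as.integer(format(mortality$death_date, "%m"))
  monthly_counts <- data.frame(
    month = 1:12,
    count = vapply(1:12, function(m) sum(classified & in_year & month == m),
                   numeric(1))
  )
  quarter <- ifelse(in_year, (month - 1) %/% 3 + 1, NA_integer_)
  truth <- data.frame(
    incident_id = incident_id,
    in_media_list = in_media, nvss_classified = classified,
    quarter = quarter, stringsAsFactors = FALSE
  )

  # full latent population with covariates (ground truth for recovery tests)
  population <- data.frame(
    incident_id = incident_id,
    age_group = age_group, gender = gender, race_ethnicity = race,
    mechanism = mechanism, county_id = county, state_id = state,
    income_quintile = income, urbanicity = urb,
    misclassified = !classified, in_media_list = in_media,
    stringsAsFactors = FALSE
  )

  # the media list observes only its captured deaths; the registry holds all
  incidents <- incidents[in_media, , drop = FALSE]
  rownames(incidents) <- NULL

  structure(list(incidents = incidents, mortality = mortality, truth = truth,
                 population = population, counties = counties,
                 monthly_counts = monthly_counts, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d deaths, %d in media list, %d registry-classified\n",
              nrow(x$incidents), sum(x$truth$in_media_list),
              sum(x$truth$nvss_classified)))
  invisible(x)
}

#' True per-quarter capture cells of a synthetic cohort
#'
#' Cross-tabulates the latent media-capture and classification flags into the
#' observed-cell layout used by [crc_fit()], restricted to deaths occurring
#' within the study year.
#'
#' @param cohort a [sim_cohort()].
#' @return a capture cell table (see [as_crc_cells()]).
#' @export
truth_cells <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  tt <- cohort$truth[!is.na(cohort$truth$quarter), ]
  rows <- lapply(1:4, function(q) {
    s <- tt[tt$quarter == q, ]
    data.frame(stratum = paste0("Q", q),
               n10 = sum(s$in_media_list & !s$nvss_classified),
               n01 = sum(!s$in_media_list & s$nvss_classified),
               n11 = sum(s$in_media_list & s$nvss_classified))
  })
  as_crc_cells(do.call(rbind, rows))
}

#' Apply identifier noise to mortality records
#'
#' With the configured probabilities, applies a single-character surname
#' substitution, shifts the birth year by one, and replaces the death date by
#' injury date plus a lag: zero with probability `p_lag0`, otherwise
#' `1 + Geometric` with mean `lag_mean`. Perturbations are flagged on the
#' records for linkage-accuracy scoring.
#'
#' @param mortality mortality record data frame (as from [sim_cohort()]).
#' @param noise list with `p_typo`, `p_birth_year`, `p_lag0`, `lag_mean`.
#' @param seed integer seed.
#' @return the perturbed data frame.
#' @export
perturb_identifiers <- function(mortality, noise, seed = 1L) {
  stopifnot(all(c("p_typo", "p_birth_year", "p_lag0") %in% names(noise)))
  probs <- unlist(noise[c("p_typo", "p_birth_year", "p_lag0")])
  if (any(probs < 0 | probs > 1)) stop("noise probabilities must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(mortality)
  out <- mortality

  typo <- runif(n) < noise$p_typo
  if (any(typo)) {
    out$surname[typo] <- vapply(out$surname[typo], function(s) {
      pos <- sample.int(nchar(s), 1)
      repl <- sample(setdiff(letters, substr(s, pos, pos)), 1)
      paste0(substr(s, 1, pos - 1), repl, substr(s, pos + 1, nchar(s)))
    }, character(1), USE.NAMES = FALSE)
    out$typo_applied <- typo
  }

  by_shift <- runif(n) < noise$p_birth_year
  if (any(by_shift)) {
    out$birth_year[by_shift] <- out$birth_year[by_shift] +
      sample(c(-1L, 1L), sum(by_shift), TRUE)
    out$birth_year_shifted <- by_shift
  }

  lag_mean <- noise$lag_mean %||% 4
  lagged <- runif(n) >= noise$p_lag0
  lag <- integer(n)
  if (any(lagged) && lag_mean > 0) {
    lag[lagged] <- 1L + rgeom(sum(lagged), 1 / lag_mean)
  } else if (any(lagged)) {
    lag[lagged] <- 1L
  }
  out$death_date <- out$death_date + lag
  out$lag_days <- lag
  out
}
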