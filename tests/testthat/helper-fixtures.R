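# fixtures built in code: the published exclusion tally as a record set, and
# small cohorts for linkage / estimation checks

blank_incident <- function(n, mechanism = "firearm") {
  if (n == 0) return(blank_incident(1, mechanism)[0, , drop = FALSE])
  data.frame(
    record_id = sprintf("R%04d", seq_len(n)),
    first_name = "alex", surname = sprintf("name%04d", seq_len(n)),
    age = 30L, age_group = "18_44", gender = "man", race_ethnicity = "white",
    injury_date = as.Date("2015-06-15"), death_year = 2015L,
    state = "S01", county_id = "S01_C001", mechanism = mechanism,
    vehicle_pursuit = FALSE, intentional_vehicle_transport_injury = FALSE,
    domestic_violence = FALSE, friendly_fire = FALSE, in_custody = FALSE,
    chokehold_or_taser = FALSE, essential_care_withheld = FALSE,
    ruled_homicide = FALSE, confirmed_late_death = FALSE,
    stringsAsFactors = FALSE
  )
}

# 1,146 records with the published per-reason exclusion composition:
# 27 vehicle, 6 domestic violence, 23 custody, 3 next-year, 1 friendly fire
table2_fixture <- function() {
  clean <- blank_incident(1086)
  vehicle <- blank_incident(27, mechanism = "motor_vehicle")
  dv <- blank_incident(6); dv$domestic_violence <- TRUE
  custody <- blank_incident(23); custody$in_custody <- TRUE
  nextyear <- blank_incident(3); nextyear$death_year <- 2016L
  ff <- blank_incident(1); ff$friendly_fire <- TRUE
  all <- rbind(clean, vehicle, dv, custody, nextyear, ff)
  all$record_id <- sprintf("R%04d", seq_len(nrow(all)))
  all
}

quiet_pipeline <- function(coh, ...) {
  suppressWarnings(run_pipeline(coh$incidents, coh$mortality,
                                coh$monthly_counts, verbose = FALSE, ...))
}

# small-geography config so unit tests run in milliseconds
small_config <- function(..., true_total = 400, seed = 1) {
  sim_config(true_total = true_total, n_states = 5, counties_per_state = 4,
             sigma2_county = 0.5, sigma2_state = 0.25, seed = seed, ...)
}
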