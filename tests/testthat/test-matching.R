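mini_mortality <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(mortality_id = "M1", first_name = "alex",
                     surname = "barber", birth_year = 1985L,
                     death_date = as.Date("2015-06-15"), death_state = "S01",
                     underlying_cause = "Y350", multiple_causes = "Y350")
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

mini_incident <- function(confirmed = FALSE) {
  inc <- blank_incident(1)
  inc$surname <- "barber"; inc$age <- 30L
  inc$confirmed_late_death <- confirmed
  inc
}

test_that("date and state rules decide match status", {
  inc <- mini_incident()

  # exact identity, same-day death, same state
  res <- match_records(inc, mini_mortality(list()))
  expect_equal(res$status, "matched")
  expect_equal(res$mortality_id, "M1")

  # death 10 days before injury: rejected outright
  res <- match_records(inc, mini_mortality(list(death_date = as.Date("2015-06-05"))))
  expect_equal(res$status, "unmatched")

  # death 30 days later needs (and here has) external confirmation
  late <- mini_mortality(list(death_date = as.Date("2015-07-15")))
  expect_equal(match_records(mini_incident(TRUE), late)$status,
               "matched_with_confirmation")
  expect_equal(match_records(mini_incident(FALSE), late)$status, "unmatched")

  # surname typo and birth-year shift stay within the near-match envelope
  noisy <- mini_mortality(list(surname = "barbeq", birth_year = 1986L))
  expect_equal(match_records(inc, noisy)$status, "matched")
  far <- mini_mortality(list(surname = "smithers"))  # edit distance > 2
  expect_equal(match_records(inc, far)$status, "unmatched")

  # ambiguous twin candidates are reported unmatched, not guessed
  twins <- mini_mortality(list(mortality_id = "M1"), list(mortality_id = "M2"))
  res <- match_records(inc, twins)
  expect_equal(res$status, "unmatched")
  expect_equal(res$n_candidates, 2)

  expect_error(match_records(inc, rbind(twins[1, ], twins[1, ])), "duplicate")
})

test_that("linkage results are invariant to input row order", {
  cfg <- small_config(seed = 41)
  coh <- sim_cohort(cfg)
  res1 <- match_records(coh$incidents, coh$mortality)
  shuffle_i <- coh$incidents[sample(nrow(coh$incidents)), ]
  shuffle_m <- coh$mortality[sample(nrow(coh$mortality)), ]
  res2 <- match_records(shuffle_i, shuffle_m)
  expect_equal(res1$mortality_id, res2$mortality_id)
  expect_equal(res1$status, res2$status)
})

test_that("linkage on a noisy synthetic cohort is near-perfect against truth", {
  cfg <- sim_config(true_total = 1000, n_states = 10, counties_per_state = 5,
                    seed = 42)
  coh <- sim_cohort(cfg)  # identifier noise on
  res <- match_records(coh$incidents, coh$mortality)
  truthmap <- setNames(coh$mortality$mortality_id, coh$mortality$incident_id)
  linked <- res[!is.na(res$mortality_id), ]
  # every linked pair is the true pair, and nearly every incident links
  expect_true(all(truthmap[linked$incident_id] == linked$mortality_id))
  expect_gte(nrow(linked) / nrow(res), 0.99)
})

test_that("noise-free unique-name linkage has sensitivity and specificity 1", {
  cfg <- small_config(seed = 43)
  coh <- sim_cohort(cfg, perturb = FALSE)
  res <- match_records(coh$incidents, coh$mortality)
  truthmap <- setNames(coh$mortality$mortality_id, coh$mortality$incident_id)
  expect_true(all(res$status == "matched"))
  expect_true(all(truthmap[res$incident_id] == res$mortality_id))
})

test_that("stratified match rates reproduce published totals and exact tests", {
  # overall: 991 of 1,086 -> 91.3% (89.4, 92.9)
  inc <- blank_incident(1086)
  res <- data.frame(incident_id = inc$record_id,
                    mortality_id = c(sprintf("M%04d", 1:991), rep(NA, 95)),
                    status = c(rep("matched", 991), rep("unmatched", 95)),
                    stringsAsFactors = FALSE)
  # investigator-type strata with the published 3x2 composition
  inc$investigator_type <- c(rep("medical_examiner", 582), rep("coroner_elected", 380),
                             rep("coroner_appointed", 29),   # matched block
                             rep("medical_examiner", 46), rep("coroner_elected", 43),
                             rep("coroner_appointed", 6))    # unmatched block
  out <- summarize_match_rates(res, inc, covariates = "investigator_type")
  expect_equal(round(out$total$percent, 1), 91.3)
  expect_equal(round(c(out$total$ci_low, out$total$ci_high), 1), c(89.4, 92.9))
  p <- out$strata$p_value[1]
  expect_equal(round(p, 2), 0.05)
  expect_lt(abs(p - 0.049), 0.005)

  # a fully matched level has CI upper bound 100
  inc$allmatch <- rep(c("a", "b"), length.out = 1086)
  res2 <- res; res2$status <- "matched"; res2$mortality_id <- "M1"
  res2$mortality_id <- sprintf("M%04d", seq_len(1086))
  out2 <- summarize_match_rates(res2, inc, covariates = "allmatch")
  expect_equal(out2$strata$percent, c(100, 100))
  expect_equal(out2$strata$ci_high, c(100, 100))

  # single-level covariate: test skipped with a warning
  inc$constant <- "x"
  expect_warning(summarize_match_rates(res, inc, covariates = "constant"),
                 "skipped")
})

test_that("Clopper-Pearson intervals contain the point estimate and cover
           at the nominal rate", {
  set.seed(44)
  p <- 0.9; n <- 200
  x <- rbinom(2000, n, p)
  cis <- vapply(x, function(k) binom.test(k, n)$conf.int, numeric(2))
  expect_true(all(cis[1, ] <= x / n & x / n <= cis[2, ]))
  # exact intervals are conservative: coverage >= 0.95 up to MC error
  expect_gte(mean(cis[1, ] <= p & p <= cis[2, ]), 0.945)
})
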