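test_that("legal-intervention classifier honours the code set and excludes
           legal execution", {
  expect_true(is_legal_intervention(c("X95", "Y35.0")))
  expect_true(is_legal_intervention("X95;Y890"))
  expect_false(is_legal_intervention("Y35.5"))
  expect_false(is_legal_intervention("X95"))
  expect_error(is_legal_intervention(character(0)), "empty")
  expect_error(is_legal_intervention("ZZZ9Q"), "malformed")
})

test_that("underlying causes map to the reporting categories", {
  expect_equal(group_underlying_cause(c("X95", "R99", "W34", "I21.9")),
               c("assault", "undetermined_or_missing", "accident",
                 "circulatory_respiratory"))
  expect_equal(group_underlying_cause("Y35.0"), "legal_intervention")
  expect_equal(group_underlying_cause("Y890"), "legal_intervention")
  expect_equal(group_underlying_cause("Y35.5"), "other")  # legal execution
  expect_equal(group_underlying_cause(c("Y09", "Y10", "X60", "X84", "F99", "Q99")),
               c("assault", "undetermined_or_missing", "suicide", "suicide",
                 "mental_behavioral", "other"))
  # classifier/grouper consistency on generated registry records
  coh <- sim_cohort(small_config(seed = 61), perturb = FALSE)
  grp <- group_underlying_cause(coh$mortality$underlying_cause)
  li <- vapply(coh$mortality$multiple_causes, is_legal_intervention,
               logical(1), USE.NAMES = FALSE)
  expect_true(all(li[grp == "legal_intervention"]))
})

test_that("stratified misclassification tables reproduce published rows", {
  df <- data.frame(
    misclassified = c(rep(TRUE, 486), rep(FALSE, 434), rep(TRUE, 61), rep(FALSE, 10)),
    mechanism = c(rep("firearm", 920), rep("non_firearm", 71))
  )
  tab <- tabulate_misclassification(df, "mechanism")
  nf <- tab[tab$level == "non_firearm", ]
  expect_equal(round(nf$percent, 1), 85.9)
  expect_equal(round(c(nf$ci_low, nf$ci_high), 1), c(75.6, 93.0))
  expect_lt(tab$p_value[1], 0.01)
  tot <- tab[tab$level == "total", ]
  expect_equal(round(tot$percent, 1), 55.2)
  # row sums partition each stratum
  expect_equal(tab$misclassified + tab$classified, tab$total)
  # an all-misclassified stratum has the closed-form exact lower bound
  all_mis <- data.frame(misclassified = rep(TRUE, 12), g = "a")
  t2 <- tabulate_misclassification(all_mis, "g")
  expect_equal(t2$percent[1], 100)
  expect_equal(t2$ci_low[1], 100 * 0.025^(1 / 12), tolerance = 1e-9)
})

test_that("state rate bands use closed-open intervals and drop empty states", {
  df <- data.frame(
    misclassified = c(rep(TRUE, 12), rep(TRUE, 17), rep(FALSE, 80)),
    state = c(rep("OK", 12), rep("WA", 97))
  )
  bands <- state_rate_bands(df)
  ok <- bands[bands$state == "OK", ]
  expect_equal(ok$percent, 100)
  expect_equal(ok$rate_band, ">=80%"); expect_equal(ok$count_band, "10-20")
  wa <- bands[bands$state == "WA", ]
  expect_equal(round(wa$percent, 1), 17.5)
  expect_equal(wa$rate_band, "<20%"); expect_equal(wa$count_band, ">=20")
  expect_false("ZZ" %in% bands$state)
})

test_that("with zero random-effect variance the mixed model collapses to
           ordinary logistic regression", {
  coefs <- lapply(sim_config()$misclass_coefs, function(x) x * 0)
  coefs$mechanism[-1] <- 1.5
  cfg <- sim_config(true_total = 4000, misclass_intercept = -0.3,
                    misclass_coefs = coefs, sigma2_county = 0, sigma2_state = 0,
                    n_states = 8, counties_per_state = 5, seed = 62)
  coh <- sim_cohort(cfg, perturb = FALSE)
  pop <- coh$population
  pop$mechanism_bin <- factor(ifelse(pop$mechanism == "firearm",
                                     "firearm", "non_firearm"))
  fit <- suppressWarnings(suppressMessages(
    misclass_glmm(pop, covariates = "mechanism_bin")))
  expect_lte(fit$var_county, 0.05)
  expect_lte(fit$var_state, 0.05)
  ref <- glm(misclassified ~ mechanism_bin, binomial(), data = pop)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
  # single binary covariate: the MLE slope is the log sample odds ratio
  tab <- table(pop$mechanism_bin, pop$misclassified)
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(unname(coef(fit))[2], log_or, tolerance = 1e-3)
})

test_that("marginal predicted probabilities average the inverse-logit and
           respect coefficient sign and the null model", {
  # balanced outcome x covariate: MLE at zero -> 50% for every level
  null_df <- data.frame(
    misclassified = rep(c(TRUE, FALSE), 200),
    mechanism_bin = rep(c("firearm", "firearm", "non_firearm", "non_firearm"), 100),
    county_id = rep(sprintf("C%02d", 1:10), 40),
    state_id = rep(sprintf("S%02d", 1:5), 80)
  )
  fit0 <- suppressWarnings(suppressMessages(
    misclass_glmm(null_df, covariates = "mechanism_bin")))
  mp0 <- marginal_probabilities(fit0, "mechanism_bin")
  expect_equal(mp0$probability, c(50, 50), tolerance = 1e-4)

  coefs <- lapply(sim_config()$misclass_coefs, function(x) x * 0)
  coefs$mechanism[-1] <- 2
  cfg <- sim_config(true_total = 3000, misclass_intercept = -0.5,
                    misclass_coefs = coefs, sigma2_county = 0, sigma2_state = 0,
                    n_states = 6, counties_per_state = 4, seed = 63)
  pop <- sim_cohort(cfg, perturb = FALSE)$population
  pop$mechanism_bin <- factor(ifelse(pop$mechanism == "firearm",
                                     "firearm", "non_firearm"))
  fit <- suppressWarnings(suppressMessages(
    misclass_glmm(pop, covariates = "mechanism_bin")))
  mp <- marginal_probabilities(fit, "mechanism_bin")
  # positive coefficient: non-firearm predicted probability is higher
  expect_gt(mp$probability[mp$level == "non_firearm"],
            mp$probability[mp$level == "firearm"])
  # single-covariate degenerate fit: marginal equals the direct inverse-logit
  b <- coef(fit)
  expect_equal(mp$probability[mp$level == "firearm"],
               100 * plogis(b[["(Intercept)"]]), tolerance = 1e-8)
  expect_equal(mp$probability[mp$level == "non_firearm"],
               100 * plogis(sum(b)), tolerance = 1e-8)
  expect_true(all(mp$ci_low < mp$probability & mp$probability < mp$ci_high))
  expect_error(marginal_probabilities(fit, "urbanicity"), "not a covariate")
})

test_that("univariable mode fits one model per covariate with intercepts kept", {
  cfg <- small_config(seed = 64)
  pop <- sim_cohort(cfg, perturb = FALSE)$population
  fits <- suppressWarnings(suppressMessages(
    misclass_glmm(pop, covariates = c("gender", "income_quintile"),
                  mode = "univariable")))
  expect_named(fits, c("gender", "income_quintile"))
  expect_s3_class(fits$gender, "misclass_fit")
  expect_equal(fits$gender$covariates, "gender")
})
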