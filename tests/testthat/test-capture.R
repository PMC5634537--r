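paper_cells <- data.frame(n10 = 599, n01 = 36, n11 = 487)

test_that("unmatched incidents are redistributed at the matched rate", {
  expect_equal(unname(redistribute_unmatched(95, 444, 991)), c(43L, 52L))
  expect_equal(unname(redistribute_unmatched(0, 17, 100)), c(0L, 0L))
  expect_equal(unname(redistribute_unmatched(10, 991, 991)), c(10L, 0L))
  expect_error(redistribute_unmatched(5, 1, 0), "positive")
})

test_that("quarterly cell construction reconciles with input totals", {
  # quarterly split of the published aggregate: 444 matched-classified,
  # 547 matched-unclassified, 95 unmatched, registry annual total 523
  mc <- c(111, 111, 111, 111)
  mu <- c(136, 137, 137, 137)
  um <- c(24, 24, 24, 23)
  monthly <- data.frame(month = 1:12,
                        count = rep(c(131, 131, 131, 130) / 3, each = 3))
  # distribute quarter totals onto months exactly
  monthly$count <- c(44, 44, 43, 44, 44, 43, 44, 44, 43, 44, 43, 43)
  cells <- build_capture_cells(mc, mu, um, monthly)
  expect_s3_class(cells, "crc_cells")
  expect_equal(sum(cells$n10), 599)
  expect_equal(sum(cells$n01), 36)
  expect_equal(sum(cells$n11), 487)
  # media-list and registry totals are conserved
  expect_equal(sum(cells$n10 + cells$n11), 444 + 547 + 95)
  expect_equal(sum(cells$n01 + cells$n11), sum(monthly$count))

  # degenerate: no unmatched, all classified, registry equals matched count
  m2 <- data.frame(month = 1:12, count = rep(10, 12))
  cells2 <- build_capture_cells(rep(30, 4), rep(0, 4), rep(0, 4), m2)
  expect_true(all(cells2$n10 == 0) && all(cells2$n01 == 0))

  # inconsistent registry totals are refused
  m3 <- data.frame(month = 1:12, count = rep(1, 12))
  expect_error(build_capture_cells(rep(30, 4), rep(0, 4), rep(0, 4), m3),
               "inconsistency")
  expect_error(build_capture_cells(rep(1, 4), rep(0, 4), rep(0, 4),
                                   m2[1:11, ]), "1-12")
})

test_that("pipeline cells equal latent truth cells under perfect linkage", {
  cfg <- small_config(true_total = 600, seed = 51)
  coh <- sim_cohort(cfg, perturb = FALSE)
  rep <- quiet_pipeline(coh)
  expect_equal(as.data.frame(rep$cells), as.data.frame(truth_cells(coh)))
})

test_that("closed-form estimator handles the canonical and corner cells", {
  lp <- lincoln_petersen(paper_cells)
  expect_equal(lp$n00_hat, 599 * 36 / 487, tolerance = 1e-12)
  expect_equal(round(lp$N_hat), 1166)
  expect_equal(lincoln_petersen(data.frame(n10 = 0, n01 = 7, n11 = 50))$n00_hat, 0)
  expect_equal(lincoln_petersen(data.frame(n10 = 10, n01 = 10, n11 = 100))$n00_hat, 1)
  expect_error(lincoln_petersen(data.frame(n10 = 5, n01 = 5, n11 = 0)),
               "unbounded")
})

test_that("single-stratum log-linear fit equals the closed form, including
           the log-scale Wald interval", {
  set.seed(52)
  for (k in 1:10) {
    cells <- data.frame(n10 = rpois(1, 300) + 1, n01 = rpois(1, 40) + 1,
                        n11 = rpois(1, 400) + 1)
    fit <- crc_fit(cells, alpha = 0)
    lp <- lincoln_petersen(cells)
    expect_equal(fit$n00_hat, lp$n00_hat, tolerance = 1e-6)
    expect_equal(fit$N_hat, lp$N_hat, tolerance = 1e-6)
    se <- sqrt(1 / cells$n10 + 1 / cells$n01 + 1 / cells$n11)
    expect_equal(unname(fit$n00_ci),
                 lp$n00_hat * exp(c(-1, 1) * qnorm(0.975) * se),
                 tolerance = 1e-6)
  }
})

test_that("the dependence offset scales each unobserved cell by exp(alpha)", {
  for (a in c(-0.5, 0.3, 0.93)) {
    f0 <- crc_fit(paper_cells, alpha = 0)
    fa <- crc_fit(paper_cells, alpha = a)
    expect_equal(fa$n00_hat, f0$n00_hat * exp(a), tolerance = 1e-6)
  }
})

test_that("stratified fit with shared list effects sums per-stratum cells", {
  four <- data.frame(stratum = paste0("Q", 1:4),
                     n10 = rep(150, 4), n01 = rep(9, 4), n11 = rep(122, 4))
  fit <- crc_fit(four, alpha = 0)
  expect_equal(fit$n00_hat, 4 * 150 * 9 / 122, tolerance = 1e-6)
  expect_equal(length(fit$n00_s), 4)
  # identical strata: each contributes equally
  expect_equal(unname(fit$n00_s), rep(150 * 9 / 122, 4), tolerance = 1e-6)
})

test_that("fit object methods expose coefficients and intervals coherently", {
  fit <- crc_fit(paper_cells)
  expect_equal(length(coef(fit)), 3)  # gamma, b1, b2
  expect_equal(dim(vcov(fit)), c(3, 3))
  ci <- confint(fit)
  expect_lt(ci["N", 1], fit$N_hat); expect_gt(ci["N", 2], fit$N_hat)
  expect_equal(fit$N_hat, fit$observed + fit$n00_hat)
  expect_equal(sum(fitted(fit)), sum(paper_cells), tolerance = 1e-8)
  expect_output(print(fit), "capture-recapture")
})

test_that("coverage proportions divide documented counts by the estimate", {
  fit <- crc_fit(paper_cells)
  cov <- coverage_proportions(fit, media_total = 1086, nvss_total = 523)
  expect_equal(round(cov$coverage[cov$list == "nvss"], 1), 44.9)
  expect_equal(round(cov$coverage[cov$list == "media"], 1), 93.1)
  # degenerate: a list equal to the whole population has coverage 100
  full <- suppressWarnings(crc_fit(data.frame(n10 = 0, n01 = 0, n11 = 250)))
  expect_equal(coverage_proportions(full, 250, 250)$coverage, c(100, 100))
})

test_that("sensitivity scan is strictly increasing in the offset", {
  scan <- sensitivity_scan(paper_cells, alpha_grid = c(-0.5, 0, 0.5, 1))
  expect_true(all(diff(scan$N_hat) > 0))
  f0 <- crc_fit(paper_cells, alpha = 0)
  expect_equal(scan$N_hat[scan$alpha == 0], f0$N_hat, tolerance = 1e-10)
  # closed-form e^alpha scaling of the unobserved cell across the grid
  expect_equal(scan$n00_hat, f0$n00_hat * exp(scan$alpha), tolerance = 1e-6)
})
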