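# Nested random-intercept logistic regression for correlates of
# misclassification, and average marginal predicted probabilities.

#' Multilevel logistic model for misclassification
#'
#' Fits a logistic regression of the misclassification indicator on
#' individual- and county-level covariates with random intercepts for
#' counties nested in states, maximizing the Laplace-approximate marginal
#' likelihood (via [lme4::glmer()]). Reference levels follow the reporting
#' convention: ages 18-44, men, white, firearm, medical examiner, medium
#' metro, highest income quintile.
#'
#' @param data data frame with logical/0-1 `misclassified`, the covariates,
#'   and `county_id`; county covariates are merged in from `counties` if not
#'   already present.
#' @param counties optional county frame with `county_id`, `state_id`,
#'   `income_quintile`, `urbanicity`, `investigator_type`.
#' @param covariates covariate columns to include as fixed effects.
#' @param mode `"multivariable"` (all covariates jointly) or `"univariable"`
#'   (one model per covariate, random intercepts retained; returns a list of
#'   fits).
#' @param nAGQ passed to [lme4::glmer()]; the default 1 is the Laplace
#'   approximation (adaptive quadrature is unavailable for crossed/nested
#'   multi-grouping models in lme4).
#' @return an object of class `misclass_fit` (or a named list of them in
#'   univariable mode) with the odds-ratio table, variance components and the
#'   underlying fit.
#' @export
misclass_glmm <- function(data, counties = NULL,
                          covariates = c("age_group", "gender", "race_ethnicity",
                                         "mechanism", "investigator_type",
                                         "urbanicity", "income_quintile"),
                          mode = c("multivariable", "univariable"),
                          nAGQ = 1L) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  if (!is.null(counties)) {
    add <- setdiff(names(counties), names(data))
    if (length(add))
      data <- merge(data, counties[c("county_id", add)], by = "county_id",
                    all.x = TRUE, sort = FALSE)
  }
  need <- c("misclassified", "county_id", "state_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  covariates <- intersect(covariates, names(data))
  if (length(unique(data$state_id)) < 2 || length(unique(data$county_id)) < 2)
    stop("need at least 2 states and 2 counties to identify the variance components")

  refs <- c(age_group = "18_44", gender = "man", race_ethnicity = "white",
            mechanism = "firearm", investigator_type = "medical_examiner",
            urbanicity = "medium_metro", income_quintile = "Q5")
  for (v in covariates) {
    data[[v]] <- as.factor(as.character(data[[v]]))
    if (v %in% names(refs) && refs[[v]] %in% levels(data[[v]]))
      data[[v]] <- stats::relevel(data[[v]], ref = refs[[v]])
  }
  data$misclassified <- as.numeric(data$misclassified)

  fit_one <- function(covs) {
    rhs <- paste(c(covs, "(1 | state_id)", "(1 | county_id)"), collapse = " + ")
    form <- as.formula(paste("misclassified ~", rhs))
    fit <- lme4::glmer(form, data = data, family = binomial(), nAGQ = nAGQ,
                       control = lme4::glmerControl(optimizer = "bobyqa",
                                                    calc.derivs = FALSE))
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    z <- qnorm(0.975)
    or_table <- data.frame(
      term = names(b), estimate = unname(b), se = unname(se),
      or = exp(unname(b)),
      or_low = exp(unname(b) - z * se), or_high = exp(unname(b) + z * se),
      p_value = 2 * stats::pnorm(-abs(unname(b) / se)),
      row.names = NULL, stringsAsFactors = FALSE
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_county <- vc$vcov[vc$grp == "county_id"]
    var_state <- vc$vcov[vc$grp == "state_id"]
    if (min(var_county, var_state) < 1e-8)
      warning("a random-intercept variance is at the boundary (0)")
    structure(list(
      or_table = or_table,
      var_county = var_county, var_state = var_state,
      logLik = as.numeric(stats::logLik(fit)),
      converged = length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0,
      covariates = covs, glmer = fit, data = data
    ), class = "misclass_fit")
  }

  if (mode == "multivariable") {
    fit_one(covariates)
  } else {
    setNames(lapply(covariates, function(v) fit_one(v)), covariates)
  }
}

#' @export
print.misclass_fit <- function(x, ...) {
  cat("Nested random-intercept logistic model of misclassification\n")
  cat(sprintf("  fixed effects: %s\n", paste(x$covariates, collapse = ", ")))
  cat(sprintf("  variance (county | state): %.2f   variance (state): %.2f\n",
              x$var_county, x$var_state))
  cat(sprintf("  log-likelihood: %.1f   converged: %s\n", x$logLik, x$converged))
  tab <- x$or_table[x$or_table$term != "(Intercept)", ]
  if (nrow(tab)) {
    cat("\n  Odds ratios (95% CI):\n")
    for (k in seq_len(nrow(tab)))
      cat(sprintf("   %-40s %6.2f (%.2f, %.2f)  p=%.3g\n", tab$term[k],
                  tab$or[k], tab$or_low[k], tab$or_high[k], tab$p_value[k]))
  }
  invisible(x)
}

#' @export
coef.misclass_fit <- function(object, ...) {
  setNames(object$or_table$estimate, object$or_table$term)
}

#' @export
summary.misclass_fit <- function(object, ...) summary(object$glmer, ...)

#' Average marginal predicted probabilities from a misclassification fit
#'
#' For each level of `variable`, fixes that variable at the level for every
#' record, averages the inverse-logit of the fixed-effect linear predictor
#' over the observed covariate distribution (random intercepts set to zero),
#' and attaches a delta-method 95% interval.
#'
#' @param fit a `misclass_fit`.
#' @param variable a covariate included in the fit.
#' @param data data to average over; defaults to the fitting data.
#' @return data frame with `level`, `probability` (percent), `ci_low`,
#'   `ci_high`.
#' @export
marginal_probabilities <- function(fit, variable, data = NULL) {
  stopifnot(inherits(fit, "misclass_fit"))
  if (!variable %in% fit$covariates)
    stop("`", variable, "` is not a covariate of the fit")
  data <- data %||% fit$data
  beta <- lme4::fixef(fit$glmer)
  V <- as.matrix(vcov(fit$glmer))
  levs <- levels(fit$data[[variable]])
  z <- qnorm(0.975)
  rows <- lapply(levs, function(l) {
    d <- data
    d[[variable]] <- factor(l, levels = levs)
    X <- stats::model.matrix(lme4::nobars(stats::formula(fit$glmer, fixed.only = TRUE)),
                             d)
    X <- X[, names(beta), drop = FALSE]
    p <- plogis(drop(X %*% beta))
    pbar <- mean(p)
    grad <- drop(crossprod(X, p * (1 - p))) / nrow(X)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(level = l, probability = 100 * pbar,
               ci_low = 100 * (pbar - z * se), ci_high = 100 * (pbar + z * se))
  })
  do.call(rbind, rows)
}
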