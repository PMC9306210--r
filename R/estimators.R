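#' Inverse-probability-weighted risk difference (standard estimator)
#'
#' The plain IPW estimator of the marginal risk difference
#' E\[Y(1)\] - E\[Y(0)\]:
#' \deqn{RD_{IPW} = \frac{1}{n}\sum_i \left(\frac{Y_i X_i}{PS_i} -
#'   \frac{Y_i(1-X_i)}{1-PS_i}\right)}
#' Weights are not normalised, so the estimate is not bounded to
#' \[-1, 1\] when the scores are extreme; see [rd_aug()] for the bounded
#' version.
#'
#' @param y 0/1 outcome vector.
#' @param x 0/1 exposure vector.
#' @param ps Propensity scores, strictly inside (0, 1).
#' @return The risk difference (scalar).
#' @export
rd_ipw <- function(y, x, ps) {
  check_rd_input(y, x, ps)
  mean(y * x / ps - y * (1 - x) / (1 - ps))
}

#' Augmented (normalised-weights) IPW risk difference
#'
#' IPW with the weights normalised to sum to one within each exposure arm
#' (a Hajek-type estimator), which bounds the estimate to \[-1, 1\]:
#' \deqn{RD_{AUG} = \frac{\sum_i Y_i X_i / PS_i}{\sum_i X_i / PS_i} -
#'   \frac{\sum_i Y_i (1-X_i) / (1-PS_i)}{\sum_i (1-X_i)/(1-PS_i)}}
#'
#' @inheritParams rd_ipw
#' @return The risk difference (scalar).
#' @export
rd_aug <- function(y, x, ps) {
  check_rd_input(y, x, ps)
  w1 <- sum(x / ps)
  w0 <- sum((1 - x) / (1 - ps))
  if (w1 == 0 || w0 == 0) {
    stop_degenerate_response("an exposure group is empty in the augmented estimator")
  }
  sum(y * x / ps) / w1 - sum(y * (1 - x) / (1 - ps)) / w0
}

#' Doubly-robust IPW risk difference
#'
#' Combines the propensity-score weights with the exposure-stratified
#' outcome regressions m0 (fit on the employed) and m1 (fit on the
#' unemployed), evaluated at every participant's covariates:
#' \deqn{RD_{DR} = \frac{1}{n}\sum_i\left(
#'   \frac{Y_i X_i - (X_i - PS_i)\, m_{1i}}{PS_i} -
#'   \frac{Y_i (1-X_i) + (X_i - PS_i)\, m_{0i}}{1 - PS_i}\right)}
#' The estimator is consistent when either the propensity-score model or
#' the outcome models are correctly specified.  The 1/n normaliser is
#' included so that the statistic is a risk difference and does not scale
#' with the sample size.
#'
#' @inheritParams rd_ipw
#' @param m0,m1 Predicted outcome probabilities for every participant from
#'   the employed-only and unemployed-only outcome fits (see
#'   [fit_group_outcome_models()]).
#' @param normalise Divide the sum by n (default `TRUE`).  The
#'   unnormalised raw sum is available for comparison only.
#' @return The risk difference (scalar).
#' @export
rd_dr <- function(y, x, ps, m0, m1, normalise = TRUE) {
  check_rd_input(y, x, ps)
  if (missing(m0) || missing(m1) || is.null(m0) || is.null(m1)) {
    stop_contract("the doubly-robust estimator requires m0 and m1 predictions")
  }
  if (length(m0) != length(y) || length(m1) != length(y)) {
    stop_contract("m0/m1 must have one prediction per participant")
  }
  s <- sum((y * x - (x - ps) * m1) / ps -
           (y * (1 - x) + (x - ps) * m0) / (1 - ps))
  if (normalise) s / length(y) else s
}

check_rd_input <- function(y, x, ps) {
  n <- length(y)
  if (length(x) != n || length(ps) != n) {
    stop_contract("y, x and ps must have equal lengths")
  }
  if (any(ps <= 0) || any(ps >= 1)) {
    stop_domain("propensity scores must be strictly inside (0, 1)")
  }
  invisible(TRUE)
}

#' G-computation (standardisation) risk difference
#'
#' Fits a logistic outcome model on all participants with the exposure
#' and the requested covariates (main effects by default), then averages
#' the predicted outcome probability with the exposure set to 1 for
#' everyone and to 0 for everyone; the difference of the two averages is
#' the marginal risk difference.
#'
#' @param cohort A `causalrd_cohort`.
#' @param covariates Character vector of confounder names (empty for the
#'   crude, exposure-only model).
#' @param interactions Include exposure-by-covariate interactions
#'   (saturating the model in the exposure)?  Default `FALSE`,
#'   i.e. a main-effects model.
#' @return The risk difference (scalar).
#' @export
rd_gcomp <- function(cohort, covariates = character(), interactions = FALSE) {
  X <- build_design(cohort, covariates, include_exposure = TRUE)
  xcol <- ncol(X)
  if (interactions && length(covariates) > 0) {
    Z <- X[, -c(1, xcol), drop = FALSE]
    XZ <- Z * X[, xcol]
    colnames(XZ) <- paste0("unemployed:", colnames(Z))
    X <- cbind(X, XZ)
  }
  # tighter-than-default convergence: the standardised means inherit the
  # solver precision, and the saturated-model identity with direct
  # standardisation is exact only at a near-exact MLE
  fit <- fit_logistic(X, cohort$poor_health,
                      tol_score = 1e-12, tol_ll = 0, maxit = 200L)
  X1 <- X
  X0 <- X
  X1[, xcol] <- 1
  X0[, xcol] <- 0
  if (interactions && length(covariates) > 0) {
    Z <- X[, -c(1, xcol, (xcol + 1):ncol(X)), drop = FALSE]
    X1[, (xcol + 1):ncol(X)] <- Z
    X0[, (xcol + 1):ncol(X)] <- 0
  }
  mean(predict_probability(fit, X1)) - mean(predict_probability(fit, X0))
}

#' Adjusted (or crude) odds ratio from logistic regression
#'
#' Fits the logistic model of the outcome on the exposure plus the
#' requested covariates and returns the exposure odds ratio with a 95%
#' profile-likelihood confidence interval.  With no covariates this is
#' the crude odds ratio ad/bc of the 2x2 table.
#'
#' @inheritParams rd_gcomp
#' @param level Confidence level, default 0.95.
#' @return A one-row data frame: `estimator`, `scale`, `estimate`,
#'   `lower`, `upper`, `significant`.
#' @export
or_logistic <- function(cohort, covariates = character(), level = 0.95) {
  X <- build_design(cohort, covariates, include_exposure = TRUE)
  y <- cohort$poor_health
  fit <- fit_logistic(X, y)
  ci <- profile_likelihood_ci(fit, X, y, "unemployed", level = level)
  or <- exp(unname(fit$beta["unemployed"]))
  data.frame(
    estimator = "logistic_or", scale = "odds_ratio",
    estimate = or, lower = unname(ci["lower"]), upper = unname(ci["upper"]),
    significant = significance_flag(ci["lower"], ci["upper"],
                                    scale = "odds_ratio"),
    stringsAsFactors = FALSE
  )
}

#' Point estimates for a set of estimators on one cohort
#'
#' Computes any subset of the five estimators — the adjusted odds ratio
#' (`"logistic_or"`), G-computation (`"gcomp"`) and the three
#' propensity-score risk-difference estimators (`"ipw_standard"`,
#' `"ipw_augmented"`, `"ipw_doubly_robust"`) — with a single shared
#' propensity-score fit and, for the doubly-robust estimator, shared
#' stratified outcome fits.
#'
#' @inheritParams rd_gcomp
#' @param estimators Character vector; `"all"` (default) expands to all
#'   five.
#' @return Named numeric vector of point estimates (odds ratio for
#'   `logistic_or`, risk differences otherwise).
#' @export
estimate_effects <- function(cohort, covariates = character(),
                             estimators = "all") {
  estimators <- expand_estimators(estimators)
  if (sum(cohort$unemployed == 1) < 1 || sum(cohort$unemployed == 0) < 1) {
    stop_degenerate_response("both exposure groups must be non-empty for estimation")
  }
  out <- numeric(0)
  need_ps <- any(estimators %in%
                   c("ipw_standard", "ipw_augmented", "ipw_doubly_robust"))
  if (need_ps) {
    ps <- propensity_scores(cohort, covariates)$scores
    y <- cohort$poor_health
    x <- cohort$unemployed
  }
  for (est in estimators) {
    out[[est]] <- switch(est,
      logistic_or = or_logistic(cohort, covariates)$estimate,
      gcomp = rd_gcomp(cohort, covariates),
      ipw_standard = rd_ipw(y, x, ps),
      ipw_augmented = rd_aug(y, x, ps),
      ipw_doubly_robust = {
        m <- fit_group_outcome_models(cohort, covariates)
        rd_dr(y, x, ps, m$m0, m$m1)
      }
    )
  }
  out
}

expand_estimators <- function(estimators) {
  all_est <- c("logistic_or", "gcomp", "ipw_standard", "ipw_augmented",
               "ipw_doubly_robust")
  aliases <- c(or = "logistic_or", gcomp = "gcomp", ipw = "ipw_standard",
               aug = "ipw_augmented", dr = "ipw_doubly_robust")
  if (identical(estimators, "all")) return(all_est)
  est <- ifelse(estimators %in% names(aliases), aliases[estimators],
                estimators)
  unknown <- setdiff(est, all_est)
  if (length(unknown) > 0) {
    stop_domain(paste0("unknown estimator(s): ", paste(unknown, collapse = ", ")))
  }
  unname(est)
}
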