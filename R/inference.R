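#' Bootstrap plan
#'
#' Settings for percentile-bootstrap inference: the number of replicates
#' (the study default is 10,000), the master seed, the confidence level
#' and the failure policy.  Replicates in which an estimator raises a
#' singularity-classed condition (for example a resample with too few
#' unemployed for the stratified outcome fits) are skipped and counted,
#' never silently imputed.
#'
#' @param B Number of resamples, >= 1.  Default 10000.
#' @param seed Master seed; it generates the full resample-index matrix up
#'   front so that different estimators (and different ledger models) can
#'   be evaluated on identical resamples.
#' @param level Confidence level, default 0.95.
#' @return An object of class `causalrd_boot_plan`.
#' @export
bootstrap_plan <- function(B = 10000L, seed = 1L, level = 0.95) {
  B <- as.integer(B)
  if (B < 1L) stop_domain("B must be at least 1")
  structure(list(B = B, seed = as.integer(seed), level = level),
            class = "causalrd_boot_plan")
}

#' Resample-index matrix for a bootstrap plan
#'
#' Unstratified simple random sampling of participants with replacement:
#' column b holds the participant indices of replicate b.  Generated in
#' one draw from the master seed, so a plan determines the resamples
#' bit-exactly.
#'
#' @param n Cohort size.
#' @param plan A `causalrd_boot_plan`.
#' @return Integer matrix, `n` rows by `plan$B` columns.
#' @export
resample_indices <- function(n, plan) {
  set.seed(plan$seed)
  matrix(sample.int(n, n * plan$B, replace = TRUE), nrow = n, ncol = plan$B)
}

#' Percentile bootstrap for the risk-difference estimators
#'
#' Draws `plan$B` resamples of n participants with replacement and
#' re-runs the full estimation on each: the propensity-score fit, the
#' stratified outcome fits where needed, and the estimator itself.
#' The 2.5% and 97.5% empirical percentiles of the successful replicates
#' form the 95% confidence interval, and the bootstrap mean squared error
#' is the mean squared deviation of the replicate estimates from the
#' full-data point estimate.  Replicates raising singularity-classed
#' conditions are skipped and counted; if fewer than half the replicates
#' succeed a reliability warning is issued and the result is flagged
#' unreliable, and if none succeed the call fails.
#'
#' @param cohort A `causalrd_cohort`.
#' @param covariates Character vector of confounder names.
#' @param estimators Risk-difference estimators to bootstrap: any of
#'   `"gcomp"`, `"ipw_standard"`, `"ipw_augmented"`,
#'   `"ipw_doubly_robust"` (aliases `gcomp/ipw/aug/dr`), or `"all"` for
#'   all four.  The odds-ratio estimator uses profile-likelihood
#'   intervals, not the bootstrap.
#' @param plan A `causalrd_boot_plan`.
#' @param indices Optional pre-computed resample-index matrix (to share
#'   resamples across several calls); defaults to
#'   `resample_indices(nrow(cohort), plan)`.
#' @return An object of class `causalrd_boot_result`: per-estimator point
#'   estimates, replicate matrix, percentile intervals, MSE, effective
#'   replicate counts, failure counts and reasons, significance flags and
#'   the seed.
#' @export
bootstrap_estimate <- function(cohort, covariates = character(),
                               estimators = "all",
                               plan = bootstrap_plan(),
                               indices = NULL) {
  estimators <- expand_estimators(estimators)
  estimators <- setdiff(estimators, "logistic_or")
  if (length(estimators) == 0) {
    stop_domain("the bootstrap applies to the risk-difference estimators")
  }
  n <- nrow(cohort)
  if (is.null(indices)) indices <- resample_indices(n, plan)
  B <- ncol(indices)

  y <- as.numeric(cohort$poor_health)
  x <- as.numeric(cohort$unemployed)
  X_ps <- build_design(cohort, covariates)
  X_out <- cbind(X_ps, unemployed = x)
  xcol <- ncol(X_out)

  point <- replicate_estimates(y, x, X_ps, X_out, xcol, estimators)
  if (any(is.na(point))) {
    stop_singularity(paste0(
      "full-data estimation failed for: ",
      paste(names(point)[is.na(point)], collapse = ", ")
    ))
  }

  reps <- matrix(NA_real_, nrow = B, ncol = length(estimators),
                 dimnames = list(NULL, estimators))
  reasons <- character(0)
  for (b in seq_len(B)) {
    idx <- indices[, b]
    reps[b, ] <- replicate_estimates(
      y[idx], x[idx], X_ps[idx, , drop = FALSE],
      X_out[idx, , drop = FALSE], xcol, estimators,
      on_failure = function(e) reasons[length(reasons) + 1L] <<- class(e)[1]
    )
  }

  effective <- colSums(!is.na(reps))
  if (any(effective == 0)) {
    stop_singularity("no bootstrap replicate succeeded for at least one estimator")
  }
  ci <- lapply(estimators, function(e) {
    percentile_ci(reps[!is.na(reps[, e]), e], level = plan$level)
  })
  names(ci) <- estimators
  mse <- vapply(estimators, function(e) {
    v <- reps[!is.na(reps[, e]), e]
    mean((v - point[[e]])^2)
  }, numeric(1))
  reliable <- effective >= 0.5 * B
  if (any(!reliable)) {
    warning(structure(
      class = c("causalrd_reliability_warning", "warning", "condition"),
      list(message = paste0(
        "fewer than half of the bootstrap replicates succeeded for: ",
        paste(estimators[!reliable], collapse = ", ")
      ), call = sys.call(-1))
    ))
  }
  structure(
    list(point = point, replicates = reps, requested_B = B,
         effective_B = effective, ci = ci, mse = mse,
         failures = B - effective,
         failure_reasons = table(reasons),
         reliable = reliable,
         significant = vapply(estimators, function(e) {
           significance_flag(ci[[e]]["lower"], ci[[e]]["upper"],
                             scale = "risk_difference")
         }, logical(1)),
         seed = plan$seed, level = plan$level),
    class = "causalrd_boot_result"
  )
}

# One full re-estimation of the requested estimators on (possibly
# resampled) data.  Singularity failures are handled per estimator: a
# failed propensity fit takes down the three weighting estimators but
# not G-computation, and a failed stratified outcome fit only takes down
# the doubly-robust estimator.  With `on_failure = NULL` the condition
# propagates to the caller (used for the full-data estimates).
replicate_estimates <- function(y, x, X_ps, X_out, xcol, estimators,
                                on_failure = NULL) {
  out <- stats::setNames(rep(NA_real_, length(estimators)), estimators)
  attempt <- function(expr) {
    if (is.null(on_failure)) return(expr)
    tryCatch(expr, causalrd_singularity_error = function(e) {
      on_failure(e)
      NA_real_
    })
  }
  need_ps <- any(estimators != "gcomp")
  if (need_ps) {
    ps <- attempt(fit_logistic(X_ps, x)$fitted)
    if (!anyNA(ps)) {
      if ("ipw_standard" %in% estimators) {
        out[["ipw_standard"]] <- rd_ipw(y, x, ps)
      }
      if ("ipw_augmented" %in% estimators) {
        out[["ipw_augmented"]] <- rd_aug(y, x, ps)
      }
      if ("ipw_doubly_robust" %in% estimators) {
        out[["ipw_doubly_robust"]] <- attempt({
          flag <- x == 1
          m0_fit <- fit_logistic(X_ps[!flag, , drop = FALSE], y[!flag])
          m1_fit <- fit_logistic(X_ps[flag, , drop = FALSE], y[flag])
          rd_dr(y, x, ps, predict_probability(m0_fit, X_ps),
                predict_probability(m1_fit, X_ps))
        })
      }
    }
  }
  if ("gcomp" %in% estimators) {
    out[["gcomp"]] <- attempt({
      fit <- fit_logistic(X_out, y)
      X1 <- X_out
      X0 <- X_out
      X1[, xcol] <- 1
      X0[, xcol] <- 0
      mean(predict_probability(fit, X1)) -
        mean(predict_probability(fit, X0))
    })
  }
  out
}

#' @export
print.causalrd_boot_result <- function(x, ...) {
  cat(sprintf("<causalrd_boot_result> B = %d (seed %d), level %.2f\n",
              x$requested_B, x$seed, x$level))
  for (e in names(x$point)) {
    cat(sprintf(
      "  %-18s %8.4f  (%.4f, %.4f)  MSE %.5f  effective B %d/%d%s\n",
      e, x$point[[e]], x$ci[[e]]["lower"], x$ci[[e]]["upper"],
      x$mse[[e]], x$effective_B[[e]], x$requested_B,
      if (x$reliable[[e]]) "" else "  [unreliable]"
    ))
  }
  invisible(x)
}

#' Empirical percentile confidence interval
#'
#' Quantiles at (1 - level)/2 and 1 - (1 - level)/2 of the replicate
#' estimates, using the linear-interpolation quantile rule
#' (`stats::quantile` type 7) for cross-platform determinism.
#'
#' @param values Numeric vector of replicate estimates (non-empty).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  if (length(values) == 0) stop_domain("no replicate estimates supplied")
  alpha <- (1 - level) / 2
  q <- stats::quantile(values, probs = c(alpha, 1 - alpha), type = 7,
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Is an interval statistically significant at its level?
#'
#' `TRUE` iff the null value lies outside the closed interval: 0 for risk
#' differences, 1 for odds ratios.
#'
#' @param lower,upper Interval bounds.
#' @param scale `"risk_difference"` (null 0) or `"odds_ratio"` (null 1).
#' @return Logical.
#' @export
significance_flag <- function(lower, upper,
                              scale = c("risk_difference", "odds_ratio")) {
  scale <- match.arg(scale)
  null_value <- if (scale == "odds_ratio") 1 else 0
  unname(null_value < lower | null_value > upper)
}
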