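#' Maximum-likelihood logistic regression
#'
#' Fits the binary-response log-odds-linear model by Newton/IRLS.  This is
#' the fitting routine behind the propensity-score model, the group
#' outcome models and the odds-ratio estimator.  It is self-contained and
#' raises machine-readable conditions for the two failure modes that the
#' bootstrap and the model ledger must react to: a single-class response
#' (`causalrd_degenerate_response_error`) and perfect separation
#' (`causalrd_separation_error`); both inherit from
#' `causalrd_singularity_error`.
#'
#' Convergence is declared when the maximum absolute score falls below
#' `tol_score` (1e-8) or the relative log-likelihood change falls below
#' `tol_ll` (1e-10), within `maxit` (50) iterations.
#'
#' @param x Design matrix (see [build_design()]).
#' @param y 0/1 response vector, length `nrow(x)`.
#' @param weights Optional prior (frequency) weights.
#' @param offset Optional linear-predictor offset.
#' @param tol_score,tol_ll,maxit Convergence controls.
#' @return An object of class `causalrd_logit`: `beta` (named), `loglik`,
#'   `fitted`, `converged`, `iter`, `vcov` (inverse observed information).
#' @export
fit_logistic <- function(x, y, weights = NULL, offset = NULL,
                         tol_score = 1e-8, tol_ll = 1e-10, maxit = 50L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop_domain("response length must equal design rows")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (is.null(offset)) offset <- rep(0, length(y))
  if (length(unique(y[weights > 0])) < 2L) stop_degenerate_response()

  if (ncol(x) == 1L && all(x == 1) && all(offset == 0)) {
    # intercept-only model: closed-form MLE, exact to machine precision
    p <- sum(weights * y) / sum(weights)
    beta <- stats::setNames(stats::qlogis(p), colnames(x))
    fitted <- rep(p, length(y))
    ll <- sum(weights * (y * log(p) + (1 - y) * log1p(-p)))
    return(structure(
      list(beta = beta, loglik = ll, fitted = fitted, converged = TRUE,
           iter = 0L, vcov = matrix(1 / sum(weights * p * (1 - p)), 1, 1,
                                    dimnames = list(colnames(x), colnames(x))),
           columns = colnames(x), n = nrow(x)),
      class = "causalrd_logit"
    ))
  }

  res <- .irls_logit(x, y, as.numeric(offset), as.numeric(weights),
                     tol_score, tol_ll, as.integer(maxit))
  beta <- drop(res$beta)
  names(beta) <- colnames(x)
  fitted <- drop(res$fitted)

  # Separation: fitted probabilities indistinguishable from 0/1 at the
  # optimum (the solver halts with diverged coefficients well past a
  # linear predictor of +-16, unreachable for non-separated categorical
  # designs), or a singular weighted information.  The offending column
  # is the one with the largest standardised coefficient.
  extreme <- fitted < 1e-7 | fitted > 1 - 1e-7
  if (res$singular || any(extreme)) {
    sds <- apply(x, 2, stats::sd)
    scaled <- abs(beta) * ifelse(sds > 0, sds, 1)
    scaled["(Intercept)" == names(scaled)] <- 0
    col <- if (all(scaled == 0)) colnames(x)[1] else names(which.max(scaled))
    stop_separation(col)
  }

  wvar <- weights * fitted * (1 - fitted)
  info <- crossprod(x, x * wvar)
  vcov <- tryCatch(solve(info), error = function(e) {
    stop_singularity("singular information matrix in logistic fit")
  })
  dimnames(vcov) <- list(colnames(x), colnames(x))

  structure(
    list(beta = beta, loglik = res$loglik, fitted = fitted,
         converged = res$converged, iter = res$iter, vcov = vcov,
         columns = colnames(x), n = nrow(x)),
    class = "causalrd_logit"
  )
}

#' @export
print.causalrd_logit <- function(x, ...) {
  cat(sprintf("<causalrd_logit> n = %d, logLik = %.4f, %sconverged in %d iterations\n",
              x$n, x$loglik, if (x$converged) "" else "NOT ", x$iter))
  print(cbind(estimate = x$beta, se = sqrt(diag(x$vcov))))
  invisible(x)
}

#' Predicted response probabilities from a logistic fit
#'
#' The inverse-logit of the linear predictor, `1 / (1 + exp(-x %*% beta))`.
#'
#' @param fit A `causalrd_logit`.
#' @param x Design matrix with the same columns, in the same order, as the
#'   fit.
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(fit$beta) ||
      !identical(colnames(x), fit$columns)) {
    stop_domain("design columns do not align with the fitted coefficients")
  }
  stats::plogis(drop(x %*% fit$beta))
}

#' Propensity scores for unemployment
#'
#' The propensity score is the conditional probability of being unemployed
#' given the baseline covariates, estimated with logistic regression of
#' the exposure on the covariate design.
#'
#' @param cohort A `causalrd_cohort`.
#' @param covariates Character vector of confounder names (may be empty:
#'   intercept-only model, constant score equal to the exposure
#'   prevalence).
#' @return A list with `scores` (in (0,1)), `fit`, and `range`
#'   diagnostics (min/max score).
#' @export
propensity_scores <- function(cohort, covariates = character()) {
  X <- build_design(cohort, covariates)
  fit <- fit_logistic(X, cohort$unemployed)
  scores <- fit$fitted
  list(scores = scores, fit = fit, range = range(scores))
}

#' Exposure-stratified outcome models (m0, m1)
#'
#' Fits the outcome model separately on the employed participants (`m0`)
#' and the unemployed participants (`m1`), using the same covariates as
#' the propensity-score model, and produces predictions from both fits for
#' every participant in the full cohort.  These are the regression inputs
#' of the doubly-robust estimator.  A stratum whose outcome is constant or
#' separated raises a singularity-classed error, which is what drives
#' replicate skipping in the bootstrap.
#'
#' @param cohort A `causalrd_cohort`.
#' @param covariates Character vector of confounder names.
#' @return A list with fits `m0_fit`, `m1_fit` and full-cohort prediction
#'   vectors `m0`, `m1`.
#' @export
fit_group_outcome_models <- function(cohort, covariates = character()) {
  X <- build_design(cohort, covariates)
  x_flag <- cohort$unemployed == 1
  if (!any(x_flag) || all(x_flag)) {
    stop_degenerate_response("an exposure group is empty; cannot fit stratified outcome models")
  }
  y <- cohort$poor_health
  m0_fit <- fit_logistic(X[!x_flag, , drop = FALSE], y[!x_flag])
  m1_fit <- fit_logistic(X[x_flag, , drop = FALSE], y[x_flag])
  list(
    m0_fit = m0_fit, m1_fit = m1_fit,
    m0 = predict_probability(m0_fit, X),
    m1 = predict_probability(m1_fit, X)
  )
}

#' Profile-likelihood confidence interval on the odds-ratio scale
#'
#' For the chosen coefficient, the profile log-likelihood is maximised
#' over all other coefficients at each candidate value; the interval
#' bounds are the values where twice the profile log-likelihood drop
#' equals the chi-square(1) quantile (3.841 at 95%).  Bounds are located
#' by monotone root bracketing (in Wald standard-error steps) and
#' refined until the deviance-drop equation is solved to within 1e-6;
#' results are reported as `exp(beta)`.  A profile that never reaches the
#' cut-off within 100 standard errors is reported as an open bound
#' (`0` or `Inf`).
#'
#' @param fit A converged `causalrd_logit`.
#' @param x,y The design and response the fit was obtained from.
#' @param coef Column name or index of the coefficient to profile.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)` on the odds-ratio scale.
#' @export
profile_likelihood_ci <- function(fit, x, y, coef, level = 0.95) {
  if (!fit$converged) stop_domain("profile interval requires a converged fit")
  x <- as.matrix(x)
  j <- if (is.character(coef)) match(coef, fit$columns) else as.integer(coef)
  if (is.na(j) || j < 1 || j > ncol(x)) stop_domain("unknown coefficient")
  cut <- stats::qchisq(level, df = 1)
  ll_hat <- fit$loglik
  b_hat <- fit$beta[j]
  se <- sqrt(fit$vcov[j, j])
  x_rest <- x[, -j, drop = FALSE]
  xj <- x[, j]

  # twice the profile log-likelihood drop at beta_j = t, minus the cut-off
  dev_drop <- function(t) {
    if (ncol(x_rest) == 0) {
      pf_ll <- sum(y * (t * xj) - log1p(exp(t * xj)))
    } else {
      pf <- .irls_logit(x_rest, y, t * xj, rep(1, length(y)),
                        1e-8, 1e-10, 100L)
      if (!pf$converged && !pf$singular) {
        stop_singularity("profile refit did not converge")
      }
      pf_ll <- pf$loglik
    }
    2 * (ll_hat - pf_ll) - cut
  }

  find_bound <- function(direction) {
    step <- 1
    lo <- b_hat
    repeat {
      hi <- b_hat + direction * step * se
      val <- dev_drop(hi)
      if (val > 0) break
      lo <- hi
      step <- step * 2
      if (step > 100) return(direction * Inf)  # open bound: separation direction
    }
    stats::uniroot(dev_drop, sort(c(lo, hi)), tol = 1e-9)$root
  }

  lower <- find_bound(-1)
  upper <- find_bound(1)
  c(lower = exp(lower), upper = exp(upper))
}
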