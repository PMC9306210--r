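test_that("closed-form MLEs are reproduced", {
  # intercept-only: beta0 = log(p / (1-p)) with 178 poor of 805
  y <- rep(c(1, 0), c(178, 627))
  X <- matrix(1, 805, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$beta), log(178 / 627), tolerance = 1e-10)
  expect_true(fit$converged)

  # saturated 2x2: slope = log(ad/bc)
  a <- 30; b <- 20; c <- 25; d <- 40
  y2 <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  z <- rep(c(1, 0), c(a + b, c + d))
  X2 <- cbind(`(Intercept)` = 1, z = z)
  fit2 <- fit_logistic(X2, y2)
  expect_equal(unname(fit2$beta["z"]), log(a * d / (b * c)), tolerance = 1e-9)

  expect_error(fit_logistic(X, rep(0, 805)),
               class = "causalrd_degenerate_response_error")
})

test_that("score equations vanish at the optimum and the fit matches an independent implementation", {
  co <- sim_cohort(n = 805, seed = 21)
  X <- build_design(co, c("prev_health", "education", "occupation"),
                    include_exposure = TRUE)
  y <- co$poor_health
  fit <- fit_logistic(X, y)
  score <- crossprod(X, y - fit$fitted)
  expect_lt(max(abs(score)), 1e-6)
  ref <- stats::glm.fit(X, y, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$loglik,
               sum(y * log(ref$fitted.values) +
                   (1 - y) * log(1 - ref$fitted.values)),
               tolerance = 1e-10)
})

test_that("duplicated rows and frequency weights give the same fit", {
  co <- sim_cohort(n = 200, seed = 4)
  X <- build_design(co, c("marital", "smoking"), include_exposure = TRUE)
  y <- co$poor_health
  w <- sample(1:3, 200, replace = TRUE)
  idx <- rep(seq_len(200), w)
  fit_dup <- fit_logistic(X[idx, ], y[idx])
  fit_w <- fit_logistic(X, y, weights = w)
  expect_equal(fit_dup$beta, fit_w$beta, tolerance = 1e-8)
  expect_equal(fit_dup$loglik, fit_w$loglik, tolerance = 1e-8)
})

test_that("predicted probabilities are the inverse logit of the linear predictor", {
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- structure(list(beta = c(`(Intercept)` = 0), columns = "(Intercept)"),
                   class = "causalrd_logit")
  expect_equal(predict_probability(fit, X), rep(0.5, 4))
  fit$beta <- c(`(Intercept)` = log(3))
  expect_equal(predict_probability(fit, X), rep(0.75, 4))
  Xbad <- cbind(X, z = 1)
  expect_error(predict_probability(fit, Xbad),
               class = "causalrd_domain_error")
})

test_that("perfect separation raises a classed error naming a column", {
  z <- c(rep(0, 20), rep(1, 20))
  y <- z
  X <- cbind(`(Intercept)` = 1, z = z)
  err <- expect_error(fit_logistic(X, y),
                      class = "causalrd_separation_error")
  expect_s3_class(err, "causalrd_singularity_error")
  expect_equal(err$data$column, "z")
})

test_that("stratified outcome models predict for the full cohort and flag degenerate strata", {
  co <- sim_cohort(n = 805, seed = 6)
  m <- fit_group_outcome_models(co, c("prev_health", "education"))
  expect_length(m$m0, 805)
  expect_length(m$m1, 805)
  expect_true(all(m$m0 > 0 & m$m0 < 1))
  expect_true(all(m$m1 > 0 & m$m1 < 1))

  # intercept-only strata: m1 is the unemployed outcome mean everywhere
  m0 <- fit_group_outcome_models(co, character())
  expect_equal(unique(round(m0$m1, 12)),
               round(mean(co$poor_health[co$unemployed == 1]), 12))

  # constant outcome in the unemployed stratum -> singularity-classed error
  co2 <- tiny_cohort(y = c(rep(1, 10), rbinom(50, 1, 0.4)),
                     x = rep(c(1, 0), c(10, 50)))
  expect_error(fit_group_outcome_models(co2, character()),
               class = "causalrd_singularity_error")
})

test_that("profile-likelihood intervals match an independent profiler and a grid search", {
  co <- sim_cohort(n = 805, seed = 31)
  X <- build_design(co, c("prev_health", "marital"), include_exposure = TRUE)
  y <- co$poor_health
  fit <- fit_logistic(X, y)
  ci <- profile_likelihood_ci(fit, X, y, "unemployed")

  # independent implementation (MASS profiling via confint.glm)
  g <- stats::glm(y ~ X - 1, family = binomial)
  ref <- suppressMessages(exp(stats::confint(g, "Xunemployed")))
  expect_equal(unname(ci), unname(ref), tolerance = 1e-3)

  # brute-force grid oracle: refit nuisance parameters over a dense grid
  cut <- qchisq(0.95, 1)
  grid <- seq(log(ci["lower"]) - 0.02, log(ci["upper"]) + 0.02,
              length.out = 2000)
  drop2 <- vapply(grid, function(t) {
    pf <- stats::glm.fit(X[, -ncol(X)], y, family = binomial(),
                         offset = t * X[, ncol(X)])
    2 * (fit$loglik - (-pf$deviance / 2))
  }, numeric(1))
  inside <- grid[drop2 <= cut]
  expect_equal(unname(log(ci["lower"])), min(inside), tolerance = 1e-3)
  expect_equal(unname(log(ci["upper"])), max(inside), tolerance = 1e-3)

  # the interval contains the point estimate
  or <- exp(unname(fit$beta["unemployed"]))
  expect_gt(or, ci["lower"])
  expect_lt(or, ci["upper"])
})

test_that("profile and Wald intervals agree asymptotically and straddle the null under it", {
  set.seed(8)
  n <- 1e5
  z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * z))
  X <- cbind(`(Intercept)` = 1, z = z)
  fit <- fit_logistic(X, y)
  ci <- profile_likelihood_ci(fit, X, y, "z")
  se <- sqrt(fit$vcov["z", "z"])
  wald <- exp(fit$beta["z"] + c(-1, 1) * qnorm(0.975) * se)
  expect_equal(unname(diff(log(ci))), diff(log(wald)), tolerance = 0.02)
  expect_equal(unname(log(ci)), log(wald), tolerance = 0.01)

  # null effect: interval straddles OR = 1
  y0 <- rbinom(n, 1, 0.35)
  fit0 <- fit_logistic(X, y0)
  ci0 <- profile_likelihood_ci(fit0, X, y0, "z")
  expect_lt(ci0["lower"], 1)
  expect_gt(ci0["upper"], 1)
})
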