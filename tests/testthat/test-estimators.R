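test_that("hand-evaluated weighting estimators on two participants", {
  y <- c(1, 0); x <- c(1, 0); ps <- c(0.8, 0.2)
  expect_equal(rd_ipw(y, x, ps), 0.625)  # (1/2) * [1/0.8 - 0]
  expect_equal(rd_aug(y, x, ps), 1.0)    # normalised arm means: 1 - 0
  expect_error(rd_ipw(y, x, c(1, 0.2)), class = "causalrd_domain_error")
  expect_equal(rd_ipw(c(0, 0), x, ps), 0)
  expect_equal(rd_aug(c(1, 1), x, ps), 0)  # identical outcomes cancel
})

test_that("collapse: constant propensity equals the crude risk difference", {
  set.seed(10)
  y <- rbinom(60, 1, 0.4)
  x <- rep(c(1, 0), c(25, 35))
  crude <- mean(y[x == 1]) - mean(y[x == 0])
  ps <- rep(mean(x), 60)
  expect_equal(rd_ipw(y, x, ps), crude, tolerance = 1e-12)
  expect_equal(rd_aug(y, x, ps), crude, tolerance = 1e-12)
  # dr with m == 0 equals the standard ipw estimator
  expect_equal(rd_dr(y, x, ps, rep(0, 60), rep(0, 60)),
               rd_ipw(y, x, ps), tolerance = 1e-12)
})

test_that("the doubly-robust sum matches a literal evaluator and honours its contract", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    y <- rbinom(n, 1, 0.5)
    x <- c(0, 1, rbinom(n - 2, 1, 0.5))
    ps <- runif(n, 0.2, 0.8)
    m0 <- runif(n); m1 <- runif(n)
    literal <- 0
    for (j in seq_len(n)) {
      literal <- literal +
        (y[j] * x[j] - (x[j] - ps[j]) * m1[j]) / ps[j] -
        (y[j] * (1 - x[j]) + (x[j] - ps[j]) * m0[j]) / (1 - ps[j])
    }
    expect_equal(rd_dr(y, x, ps, m0, m1), literal / n, tolerance = 1e-12)
    expect_equal(rd_dr(y, x, ps, m0, m1, normalise = FALSE), literal,
                 tolerance = 1e-12)
  }
  y <- c(1, 0); x <- c(1, 0); ps <- c(0.5, 0.5)
  expect_error(rd_dr(y, x, ps), class = "causalrd_contract_error")
  expect_error(rd_dr(y, x, ps, m0 = c(0.1, 0.2), m1 = 0.3),
               class = "causalrd_contract_error")
})

test_that("with perfect stratum fits the DR estimator standardises the model predictions", {
  # m1 = Y on the exposed, m0 = Y on the unexposed: the augmentation makes
  # the estimator the mean difference of the model predictions
  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- c(0, 1, rbinom(n - 2, 1, 0.5))
    m0 <- runif(n); m1 <- runif(n)
    y <- ifelse(x == 1, m1, m0)  # degenerate perfect fit
    ps <- runif(n, 0.2, 0.8)
    expect_equal(rd_dr(y, x, ps, m0, m1), mean(m1 - m0), tolerance = 1e-12)
  }
})

test_that("the normalised estimators are bounded while standard IPW is not", {
  # extreme-weight fixture: a rare exposed participant with tiny PS
  y <- c(1, 1, 0, 0, 1)
  x <- c(1, 0, 0, 0, 0)
  ps <- c(0.01, 0.3, 0.3, 0.3, 0.3)
  expect_gt(rd_ipw(y, x, ps), 1)        # exceeds the logical range
  expect_lte(abs(rd_aug(y, x, ps)), 1)  # bounded by normalisation
  co <- sim_cohort(n = 400, seed = 13)
  expect_lte(abs(rd_gcomp(co, c("prev_health", "education"))), 1)
})

test_that("G-computation collapses to the crude RD and standardises exactly over a binary stratum", {
  co <- sim_cohort(n = 805, seed = 14)
  crude <- mean(co$poor_health[co$unemployed == 1]) -
    mean(co$poor_health[co$unemployed == 0])
  expect_equal(rd_gcomp(co, character()), crude, tolerance = 1e-9)

  # saturated model over one binary confounder = direct standardisation
  set.seed(15)
  for (i in 1:15) {
    counts <- matrix(sample(3:30, 8, replace = TRUE), 2)  # (y, x, z) cells
    z <- rep(c("good", "poor", "good", "poor"), counts[1, ] + counts[2, ])
    x <- rep(c(0, 0, 1, 1), counts[1, ] + counts[2, ])
    y <- unlist(lapply(1:4, function(k) {
      rep(c(0, 1), c(counts[1, k], counts[2, k]))
    }))
    co2 <- tiny_cohort(y = y, x = x, prev_health = z)
    est <- rd_gcomp(co2, "prev_health", interactions = TRUE)
    std <- 0
    for (zz in c("good", "poor")) {
      pz <- mean(z == zz)
      p1 <- mean(y[x == 1 & z == zz])
      p0 <- mean(y[x == 0 & z == zz])
      std <- std + (p1 - p0) * pz
    }
    expect_equal(est, std, tolerance = 1e-10)
  }
})

test_that("the crude odds ratio is ad/bc with a profile interval, adjusted fits recover generated effects", {
  a <- 60; b <- 118; c <- 226; d <- 401
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  x <- rep(c(1, 0), c(a + b, c + d))
  co <- tiny_cohort(y = y, x = x)
  res <- or_logistic(co, character())
  expect_equal(res$estimate, a * d / (b * c), tolerance = 1e-8)
  expect_true(res$lower < res$estimate && res$estimate < res$upper)

  # parameter recovery: built-in conditional OR 1.9 at n = 1e5
  co_big <- generate_cohort(generator_config(n = 1e5), seed = 16)
  fit <- or_logistic(co_big, c("prev_health", "education", "marital",
                               "occupation"))
  expect_gt(fit$estimate, 1.8)
  expect_lt(fit$estimate, 2.0)
})

test_that("estimator names expand and unknown names fail", {
  expect_equal(causalrd:::expand_estimators("all"),
               c("logistic_or", "gcomp", "ipw_standard", "ipw_augmented",
                 "ipw_doubly_robust"))
  expect_equal(causalrd:::expand_estimators(c("ipw", "dr")),
               c("ipw_standard", "ipw_doubly_robust"))
  expect_error(causalrd:::expand_estimators("magic"),
               class = "causalrd_domain_error")
})
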