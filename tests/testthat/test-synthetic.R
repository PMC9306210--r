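test_that("the generator is deterministic per seed and seeds are independent", {
  cfg <- generator_config(n = 500)
  a <- generate_cohort(cfg, seed = 40)
  b <- generate_cohort(cfg, seed = 40)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cfg, seed = 41)
  expect_false(identical(a$unemployed, c2$unemployed))
  expect_lt(abs(cor(a$unemployed, c2$unemployed)), 0.12)
  expect_lt(abs(cor(a$poor_health, c2$poor_health)), 0.12)
})

test_that("default prevalences land on the configured targets", {
  cfg <- generator_config(n = 805)
  # binomial check across seeds: exposure prevalence within 3 points of 22%
  prev <- vapply(1:20, function(s) mean(generate_cohort(cfg, s)$unemployed),
                 numeric(1))
  expect_true(all(abs(prev - 0.22) < 0.05))
  expect_lt(abs(mean(prev) - 0.22), 0.03)
  poor <- vapply(1:20, function(s) mean(generate_cohort(cfg, s)$poor_health),
                 numeric(1))
  expect_lt(abs(mean(poor) - 0.36), 0.03)
})

test_that("generated level frequencies match the configured marginals", {
  cfg <- generator_config(n = 1e5)
  co <- generate_cohort(cfg, seed = 42)
  for (nm in names(cfg$marginals)) {
    p <- cfg$marginals[[nm]]
    obs <- table(co[[nm]])[names(p)] / nrow(co)
    # binomial 99% bounds at n = 1e5
    bound <- qnorm(0.995) * sqrt(p * (1 - p) / nrow(co))
    expect_true(all(abs(obs - p) < bound + 1e-3), label = nm)
  }
})

test_that("null exposure coefficients make the crude estimate unconfounded", {
  cfg <- generator_config(
    n = 2e4,
    exposure_coef = list(prev_health = c(poor = 0)),
    outcome_coef = default_outcome_coef()
  )
  co <- generate_cohort(cfg, seed = 43)
  crude <- mean(co$poor_health[co$unemployed == 1]) -
    mean(co$poor_health[co$unemployed == 0])
  adj <- rd_gcomp(co, c("prev_health", "education", "marital", "occupation"))
  expect_lt(abs(crude - adj), 0.02)
})

test_that("the Monte-Carlo truth matches closed forms and is stable across seeds", {
  # no confounders: RD = plogis(logit(p0) + b) - p0 exactly
  cfg0 <- generator_config(
    exposure_coef = list(),
    outcome_coef = list(unemployed = log(1.9)),
    outcome_prevalence = 0.36, exposure_prevalence = 0.22
  )
  t0 <- true_marginal_rd(cfg0, mc_n = 1e4, seed = 1)
  p0 <- plogis(cfg0$outcome_intercept)
  expect_equal(t0$rd, plogis(qlogis(p0) + log(1.9)) - p0, tolerance = 1e-10)
  expect_equal(t0$se, 0, tolerance = 1e-12)  # degenerate: no confounder draw

  # zero exposure coefficient: RD is exactly 0
  cfgnull <- generator_config(outcome_coef = list(
    unemployed = 0, prev_health = c(poor = log(4))
  ))
  expect_equal(true_marginal_rd(cfgnull, mc_n = 1e4, seed = 2)$rd, 0)

  # default config: reproducible across seeds within 3 MC SEs
  cfg <- generator_config()
  t1 <- true_marginal_rd(cfg, mc_n = 2e5, seed = 3)
  t2 <- true_marginal_rd(cfg, mc_n = 2e5, seed = 4)
  expect_lt(abs(t1$rd - t2$rd), 3 * sqrt(t1$se^2 + t2$se^2))
  expect_equal(t1$conditional_or, 1.9)
})

test_that("a correctly specified analysis recovers the generator truth at large n", {
  cfg <- generator_config(n = 1e5)
  truth <- true_marginal_rd(cfg, mc_n = 1e6, seed = 5)
  co <- generate_cohort(cfg, seed = 44)
  est <- rd_gcomp(co, c("prev_health", "education", "marital", "occupation"))
  # sampling SE of the estimator at n = 1e5 is ~0.003
  expect_lt(abs(est - truth$rd), 0.01)
})

test_that("labour histories are mode-concordant without discordance and not with it", {
  cfg <- generator_config(n = 4000)
  rec <- generate_labour_history(cfg, seed = 45)
  self <- derive_self_reported_longterm(rec)$status
  reg <- derive_register_longterm(rec)$status
  expect_identical(self, reg)  # one month = 30.4 days keeps the rules aligned

  lab <- default_labour_settings()
  lab$register_extra_spell_prob <- 0.25
  cfg2 <- generator_config(n = 4000, labour = lab)
  rec2 <- generate_labour_history(cfg2, seed = 45)
  n_self <- sum(derive_self_reported_longterm(rec2)$status == "unemployed")
  n_reg <- sum(derive_register_longterm(rec2)$status == "unemployed")
  expect_gt(n_reg, n_self)  # register-only short spells add unemployed
})

test_that("labour histories honour the follow-up and conditioning controls", {
  lab <- default_labour_settings()
  lab$p_fu_unemployed <- 0
  cfg <- generator_config(n = 1000, labour = lab)
  rec <- generate_labour_history(cfg, seed = 46)
  a <- derive_exposure(rec, "self_reported", "censor")
  expect_false(any(a$reason == "followup_unemployment"))

  # conditioning on an exposure vector reproduces it under the long-term rule
  co <- sim_cohort(n = 500, seed = 47)
  exp_status <- ifelse(co$unemployed == 1, "unemployed", "employed")
  rec2 <- generate_labour_history(generator_config(n = 500), seed = 48,
                                  exposure = exp_status)
  expect_identical(derive_self_reported_longterm(rec2)$status, exp_status)
})

test_that("misspecification scenarios expose the double-robustness structure", {
  sc <- misspecification_scenarios(n = 1500, mc_n = 1e4, seed = 6)
  expect_named(sc, c("correct_ps_wrong_outcome", "wrong_ps_correct_outcome",
                     "both_correct", "both_wrong"))
  expect_false("prev_health" %in% sc$wrong_ps_correct_outcome$ps_covariates)
  expect_true("prev_health" %in% sc$wrong_ps_correct_outcome$outcome_covariates)
  expect_equal(sc$both_correct$truth$rd, sc$both_wrong$truth$rd)
  co <- generate_cohort(sc$both_correct$config, seed = 7)
  est <- rd_dr_split(co, sc$both_correct$ps_covariates,
                     sc$both_correct$outcome_covariates)
  expect_lt(abs(est - sc$both_correct$truth$rd), 0.08)  # single-replicate noise
})
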