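test_that("self-reported mode applies the 6-month and 18-month rules", {
  # 7 months unemployed, 20 full-time -> unemployed
  a <- derive_self_reported_longterm(
    tiny_history(months_unemployed = 7, months_full_time = 20))
  expect_equal(a$status, "unemployed")
  # 0 unemployed, 18 months part-time -> employed (attachment exactly 1.5y)
  a <- derive_self_reported_longterm(
    tiny_history(months_unemployed = 0, months_part_time = 18))
  expect_equal(a$status, "employed")
  # boundary: 6 months unemployed is enough
  a <- derive_self_reported_longterm(
    tiny_history(months_unemployed = 6, months_full_time = 30))
  expect_equal(a$status, "unemployed")
  # 3 months unemployed, 30 full-time -> neither rule met -> excluded
  a <- derive_self_reported_longterm(
    tiny_history(months_unemployed = 3, months_full_time = 30))
  expect_equal(a$status, "excluded")
  expect_equal(a$reason, "some_unemployment_below_6_months")
  # 0 unemployed but only 17 attachment months -> excluded
  a <- derive_self_reported_longterm(
    tiny_history(months_unemployed = 0, months_full_time = 17))
  expect_equal(a$status, "excluded")
  # labour-market measure counts as attachment
  a <- derive_self_reported_longterm(
    tiny_history(months_labour_market_measure = 18))
  expect_equal(a$status, "employed")
})

test_that("register mode applies the 182-day rule", {
  a <- derive_register_longterm(tiny_history(reg_days = c(100, 60, 30)))
  expect_equal(a$status, "unemployed")  # 190 days
  a <- derive_register_longterm(tiny_history(reg_days = c(100, 60, 21)))
  expect_equal(a$status, "excluded")    # 181 days falls short of the boundary
  a <- derive_register_longterm(tiny_history(reg_days = c(100, 60, 22)))
  expect_equal(a$status, "unemployed")  # exactly 182
  a <- derive_register_longterm(
    tiny_history(reg_days = c(0, 0, 0), months_full_time = 24))
  expect_equal(a$status, "employed")
  # nonzero days below 182 block the employed classification
  a <- derive_register_longterm(
    tiny_history(reg_days = c(10, 0, 0), months_full_time = 24))
  expect_equal(a$status, "excluded")
  expect_error(as_labour_history(
    as.data.frame(tiny_history())[, ] |> transform(reg_days_1993 = -1)
  ), class = "causalrd_domain_error")
})

test_that("current mode maps the questionnaire ticks", {
  expect_equal(derive_current(tiny_history(current_status = "unemployed"))$status,
               "unemployed")
  expect_equal(derive_current(tiny_history(current_status = "sick_leave"))$status,
               "excluded")
  expect_equal(
    derive_current(tiny_history(current_status = "labour_market_measure"))$status,
    "employed")
  for (tick in c("studies", "other_education", "casual_job",
                 "parental_leave", "other")) {
    expect_equal(derive_current(tiny_history(current_status = tick))$status,
                 "excluded", label = tick)
  }
})

test_that("censoring flags follow-up unemployment or short attachment, never flips status", {
  rec <- tiny_history(months_unemployed = c(8, 0, 0, 0),
                      months_full_time = c(28, 36, 36, 36),
                      fu_months_unemployed = c(0, 3, 0, 0),
                      fu_months_labour_market = c(36, 40, 12, 18))
  a <- derive_self_reported_longterm(rec)
  none <- apply_censor_policy(a, rec, "none")
  expect_identical(none, a)
  cens <- apply_censor_policy(a, rec, "censor")
  expect_equal(cens$censored, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cens$reason[2], "followup_unemployment")
  expect_equal(cens$reason[3], "followup_attachment_below_18_months")
  expect_equal(cens$status, a$status)  # censoring never relabels exposure
})

test_that("each mode partitions random records, and unemployment is monotone", {
  cfg <- generator_config(n = 400)
  rec <- generate_labour_history(cfg, seed = 9)
  for (mode in c("self_reported", "register", "current")) {
    a <- derive_exposure(rec, mode, "none")
    expect_true(all(a$status %in% c("employed", "unemployed", "excluded")))
    expect_equal(nrow(a), 400)
    expect_true(all(a$reason[a$status == "excluded"] != ""))
  }
  # monotonicity: adding unemployment months cannot move unemployed -> employed
  for (m in 0:10) {
    s <- derive_self_reported_longterm(
      tiny_history(months_unemployed = m, months_full_time = 36 - m))$status
    if (m >= 6) expect_equal(s, "unemployed")
    if (m > 0) expect_false(s == "employed")
  }
})

test_that("current-mode unemployment is rarer than long-term on default histories", {
  cfg <- generator_config(n = 3000)
  rec <- generate_labour_history(cfg, seed = 5)
  p_current <- mean(derive_current(rec)$status == "unemployed")
  p_longterm <- mean(derive_self_reported_longterm(rec)$status == "unemployed")
  expect_lt(p_current, p_longterm)
})

test_that("current mode with censoring warns when few unemployed remain", {
  rec <- tiny_history(current_status = rep("full_time", 50))
  expect_warning(derive_exposure(rec, "current", "censor"),
                 class = "causalrd_small_sample_warning")
})
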