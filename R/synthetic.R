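#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' eleven categorical confounders with the study population's marginal
#' frequencies, a logistic exposure model with a health-selection
#' coefficient on previous health (poorer previous health raises the
#' probability of unemployment), and a logistic outcome model for poor
#' self-rated health at follow-up.  Defaults: n = 805 participants,
#' unemployment prevalence 22%, poor-health prevalence 36%, conditional
#' exposure odds ratio 1.9 and previous-health odds ratio 4.0 — the
#' magnitudes of the full-model analysis the package targets; they are
#' calibration anchors, not reproduction claims.  Nonzero generating
#' coefficients are carried by previous health, education, marital status
#' and occupation only, so those four variables are the generating
#' signal.
#'
#' Model intercepts are calibrated by exact enumeration over the joint
#' distribution of the coefficient-bearing confounders so that the
#' configured exposure and outcome prevalences hold marginally (the
#' confounders are generated independently by default; optional pairwise
#' couplings make the calibration approximate).
#'
#' @param n Cohort size, default 805.
#' @param seed Default seed used by [generate_cohort()] when none is
#'   passed.
#' @param marginals Named list: per confounder, a named probability
#'   vector over its codebook levels.
#' @param exposure_coef Named list of log-odds contributions to
#'   unemployment: per confounder, a named vector over non-reference
#'   levels.
#' @param outcome_coef As `exposure_coef` for the outcome model, plus a
#'   scalar element `unemployed` (the conditional log odds ratio of
#'   exposure).
#' @param exposure_prevalence,outcome_prevalence Marginal targets used to
#'   calibrate the intercepts.
#' @param couplings Optional list of pairwise dependence couplings, each
#'   `list(a =, b =, rho =)`: confounder levels are assigned by
#'   thresholding correlated standard-normal latents (a Gaussian-copula
#'   mechanism), an extension beyond independent marginals.
#' @param labour Labour-history generation settings; see
#'   [generate_labour_history()].
#' @param cb Codebook, default [default_codebook()].
#' @return An object of class `causalrd_generator_config`.
#' @export
generator_config <- function(n = 805L,
                             seed = 1L,
                             marginals = default_marginals(),
                             exposure_coef = default_exposure_coef(),
                             outcome_coef = default_outcome_coef(),
                             exposure_prevalence = 0.22,
                             outcome_prevalence = 0.36,
                             couplings = NULL,
                             labour = default_labour_settings(),
                             cb = default_codebook()) {
  if (n < 2) stop_domain("n must be at least 2")
  confs <- confounder_names(cb)
  for (nm in names(marginals)) {
    v <- cb$variables[[nm]]
    p <- marginals[[nm]]
    if (is.null(v) || !setequal(names(p), v$levels)) {
      stop_schema(sprintf("marginals for '%s' do not match codebook levels", nm))
    }
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
      stop_schema(sprintf("marginals for '%s' must be positive and sum to 1", nm))
    }
  }
  if (!setequal(names(marginals), confs)) {
    stop_schema("marginals must cover exactly the codebook confounders")
  }
  check_coef <- function(coefs, allow_exposure) {
    for (nm in names(coefs)) {
      if (nm == "unemployed" && allow_exposure) next
      v <- cb$variables[[nm]]
      if (is.null(v)) stop_schema(sprintf("coefficient for unknown variable '%s'", nm))
      extra <- setdiff(names(coefs[[nm]]), setdiff(v$levels, v$reference))
      if (length(extra) > 0) {
        stop_schema(sprintf("coefficients for '%s' name unknown level(s): %s",
                            nm, paste(extra, collapse = ", ")))
      }
    }
  }
  check_coef(exposure_coef, allow_exposure = FALSE)
  check_coef(outcome_coef, allow_exposure = TRUE)
  if (is.null(outcome_coef$unemployed)) {
    stop_schema("outcome_coef must contain an 'unemployed' element")
  }

  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marginals,
         exposure_coef = exposure_coef, outcome_coef = outcome_coef,
         exposure_prevalence = exposure_prevalence,
         outcome_prevalence = outcome_prevalence,
         couplings = couplings, labour = labour, cb = cb),
    class = "causalrd_generator_config"
  )
  cfg <- calibrate_intercepts(cfg)
  cfg
}

#' Default confounder marginals for the synthetic cohort
#'
#' Level frequencies of the 805-participant self-reported-mode study
#' population (no censoring).
#'
#' @return Named list of named probability vectors.
#' @export
default_marginals <- function() {
  list(
    prev_health = c(good = 619, poor = 186) / 805,
    education = c(university = 350, secondary = 309, upper_secondary = 146) / 805,
    marital = c(married = 591, single = 214) / 805,
    occupation = c(med_high_white = 327, blue_collar = 340, low_white = 138) / 805,
    sex = c(woman = 429, man = 376) / 805,
    avsi = c(low = 296, high = 509) / 805,
    avat = c(low = 434, high = 371) / 805,
    cash_margin = c(access = 640, no_access = 165) / 805,
    smoking = c(not_smoking = 561, le10 = 152, gt10 = 92) / 805,
    alcohol = c(low = 399, high = 406) / 805,
    bmi = c(normal = 511, overweight = 247, obese = 47) / 805
  )
}

#' @rdname default_marginals
#' @export
default_exposure_coef <- function() {
  list(
    prev_health = c(poor = 0.9),
    education = c(secondary = 0.5, upper_secondary = 0.3),
    marital = c(single = 0.4),
    occupation = c(blue_collar = 0.5, low_white = 0.2)
  )
}

#' @rdname default_marginals
#' @export
default_outcome_coef <- function() {
  list(
    unemployed = log(1.9),
    prev_health = c(poor = log(4)),
    education = c(secondary = 0.56, upper_secondary = 0.51),
    marital = c(single = 0.5),
    occupation = c(blue_collar = 0.45, low_white = 0.1)
  )
}

default_labour_settings <- function() {
  list(
    class_probs = c(unemployed = 0.21, employed = 0.70, other = 0.09),
    p_current_unemployed = 0.35,
    p_fu_unemployed = 0.18,
    p_fu_low_attachment = 0.05,
    register_extra_spell_prob = 0,
    register_extra_days = c(60, 240)
  )
}

# Linear-predictor contribution of a row's confounder levels under a
# coefficient list (reference levels contribute zero).
lp_from_levels <- function(levels_df, coefs) {
  lp <- rep(0, nrow(levels_df))
  for (nm in names(coefs)) {
    if (nm == "unemployed") next
    cf <- coefs[[nm]]
    lp <- lp + ifelse(levels_df[[nm]] %in% names(cf),
                      cf[as.character(levels_df[[nm]])], 0)
  }
  lp
}

# Calibrate the exposure- and outcome-model intercepts by enumerating the
# joint distribution of the coefficient-bearing confounders.
calibrate_intercepts <- function(cfg) {
  active <- unique(c(
    setdiff(names(cfg$exposure_coef), "unemployed"),
    setdiff(names(cfg$outcome_coef), "unemployed")
  ))
  if (length(active) == 0) {
    cfg$exposure_intercept <- stats::qlogis(cfg$exposure_prevalence)
    p1 <- cfg$exposure_prevalence
    f <- function(a) {
      p1 * stats::plogis(a + cfg$outcome_coef$unemployed) +
        (1 - p1) * stats::plogis(a) - cfg$outcome_prevalence
    }
    cfg$outcome_intercept <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
    return(cfg)
  }
  grid <- expand.grid(lapply(cfg$marginals[active], names),
                      stringsAsFactors = FALSE)
  names(grid) <- active
  pz <- rep(1, nrow(grid))
  for (nm in active) pz <- pz * cfg$marginals[[nm]][grid[[nm]]]
  lp_x <- lp_from_levels(grid, cfg$exposure_coef)
  f_x <- function(a) sum(pz * stats::plogis(a + lp_x)) - cfg$exposure_prevalence
  cfg$exposure_intercept <- stats::uniroot(f_x, c(-30, 30), tol = 1e-12)$root
  px <- stats::plogis(cfg$exposure_intercept + lp_x)
  lp_y <- lp_from_levels(grid, cfg$outcome_coef)
  b_ue <- cfg$outcome_coef$unemployed
  f_y <- function(a) {
    sum(pz * (px * stats::plogis(a + b_ue + lp_y) +
              (1 - px) * stats::plogis(a + lp_y))) - cfg$outcome_prevalence
  }
  cfg$outcome_intercept <- stats::uniroot(f_y, c(-30, 30), tol = 1e-12)$root
  cfg
}

#' @export
print.causalrd_generator_config <- function(x, ...) {
  cat(sprintf(
    "<causalrd_generator_config> n = %d, target prevalences: exposure %.0f%%, outcome %.0f%%\n",
    x$n, 100 * x$exposure_prevalence, 100 * x$outcome_prevalence))
  cat(sprintf("  intercepts: exposure %.4f, outcome %.4f; conditional exposure OR %.2f\n",
              x$exposure_intercept, x$outcome_intercept,
              exp(x$outcome_coef$unemployed)))
  invisible(x)
}

# Draw the confounder levels: independent sampling from the marginals,
# or Gaussian-copula latent thresholding when couplings are configured.
draw_confounders <- function(cfg, n) {
  confs <- names(cfg$marginals)
  out <- vector("list", length(confs))
  names(out) <- confs
  if (is.null(cfg$couplings)) {
    for (nm in confs) {
      p <- cfg$marginals[[nm]]
      out[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  latents <- sapply(confs, function(nm) stats::rnorm(n))
  for (cp in cfg$couplings) {
    za <- latents[, cp$a]
    latents[, cp$b] <- cp$rho * za + sqrt(1 - cp$rho^2) * latents[, cp$b]
  }
  for (nm in confs) {
    p <- cfg$marginals[[nm]]
    cuts <- stats::qnorm(cumsum(p))
    out[[nm]] <- names(p)[findInterval(latents[, nm], cuts[-length(cuts)]) + 1L]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws the confounders from their configured marginals (previous health
#' and the rest, optionally coupled), assigns unemployment from the
#' logistic exposure model (carrying the health-selection coefficient on
#' previous health) and draws the outcome from the logistic outcome
#' model.  Fully reproducible from the seed.
#'
#' @param cfg A `causalrd_generator_config`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `causalrd_cohort` of `cfg$n` participants.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n
  z <- draw_confounders(cfg, n)
  lp_x <- cfg$exposure_intercept + lp_from_levels(z, cfg$exposure_coef)
  x <- stats::rbinom(n, 1, stats::plogis(lp_x))
  lp_y <- cfg$outcome_intercept + lp_from_levels(z, cfg$outcome_coef) +
    cfg$outcome_coef$unemployed * x
  y <- stats::rbinom(n, 1, stats::plogis(lp_y))
  z$id <- seq_len(n)
  z$poor_health <- y
  z$unemployed <- x
  as_cohort(z, cfg$cb)
}

#' Monte-Carlo truth: the generator's marginal risk difference
#'
#' Standardisation over the confounder distribution: draws `mc_n`
#' confounder vectors and averages the outcome-model probability with the
#' exposure set to 1 and to 0 for everyone.  The difference is the true
#' marginal risk difference E\[Y(1)\] - E\[Y(0)\] of the generating
#' mechanism, with its Monte-Carlo standard error.
#'
#' @param cfg A `causalrd_generator_config`.
#' @param mc_n Monte-Carlo sample size, default 1e6.
#' @param seed Seed for the Monte-Carlo draw.
#' @return A list (`causalrd_truth`): `rd`, `se`, `conditional_or`,
#'   `mc_n`, `config_hash`.
#' @export
true_marginal_rd <- function(cfg, mc_n = 1e6, seed = 1L) {
  set.seed(seed)
  z <- draw_confounders(cfg, mc_n)
  lp_y <- cfg$outcome_intercept + lp_from_levels(z, cfg$outcome_coef)
  d <- stats::plogis(lp_y + cfg$outcome_coef$unemployed) - stats::plogis(lp_y)
  structure(
    list(rd = mean(d), se = stats::sd(d) / sqrt(mc_n),
         conditional_or = exp(cfg$outcome_coef$unemployed),
         mc_n = mc_n, config_hash = config_hash(cfg)),
    class = "causalrd_truth"
  )
}

#' @export
print.causalrd_truth <- function(x, ...) {
  cat(sprintf("<causalrd_truth> marginal RD = %.5f (MC SE %.2g, mc_n = %g); conditional OR = %.3f\n",
              x$rd, x$se, x$mc_n, x$conditional_or))
  invisible(x)
}

#' Generate synthetic labour-history records
#'
#' Per participant: a retrospective 36-month allocation over the
#' labour-market status vocabulary, register unemployment-day counts for
#' 1992-1994 consistent with the self-reported months (one month = 30.4
#' days) unless register/self-report discordance is switched on, a
#' current-status tick, and follow-up attachment and unemployment.  The
#' discordance mechanism (`register_extra_spell_prob` in the labour
#' settings) injects short register-only unemployment spells, emulating
#' short between-jobs periods that self-reports miss, so the
#' register-based mode classifies more participants as unemployed than
#' the self-reported mode.
#'
#' @param cfg A `causalrd_generator_config` (its `labour` settings are
#'   used).
#' @param n Number of records, default `cfg$n`.
#' @param seed Seed.
#' @param exposure Optional vector of `"unemployed"`/`"employed"` to
#'   condition the long-term status classes on (used to pair histories
#'   with a generated cohort); by default classes are drawn from
#'   `labour$class_probs`.
#' @return A `causalrd_labour_history`.
#' @export
generate_labour_history <- function(cfg, n = cfg$n, seed = cfg$seed,
                                    exposure = NULL) {
  set.seed(seed)
  lb <- cfg$labour
  if (is.null(exposure)) {
    cls <- sample(names(lb$class_probs), n, replace = TRUE,
                  prob = lb$class_probs)
  } else {
    cls <- ifelse(exposure == "unemployed", "unemployed", "employed")
  }
  statuses <- labour_statuses()
  m <- matrix(0L, nrow = n, ncol = length(statuses),
              dimnames = list(NULL, paste0("months_", statuses)))
  current <- character(n)

  is_ue <- cls == "unemployed"
  n_ue <- sum(is_ue)
  if (n_ue > 0) {
    ue_m <- sample(6:30, n_ue, replace = TRUE)
    m[is_ue, "months_unemployed"] <- ue_m
    m[is_ue, "months_full_time"] <- 36L - ue_m
    current[is_ue] <- ifelse(
      stats::runif(n_ue) < lb$p_current_unemployed, "unemployed",
      sample(attachment_statuses(), n_ue, replace = TRUE,
             prob = c(0.7, 0.2, 0.1))
    )
  }
  is_em <- cls == "employed"
  n_em <- sum(is_em)
  if (n_em > 0) {
    att <- sample(18:36, n_em, replace = TRUE)
    ft <- pmax(att - 6L, 12L)
    pt <- att - ft
    m[is_em, "months_full_time"] <- ft
    m[is_em, "months_part_time"] <- pt
    m[is_em, "months_studies"] <- 36L - att
    current[is_em] <- sample(attachment_statuses(), n_em, replace = TRUE,
                             prob = c(0.8, 0.15, 0.05))
  }
  is_ot <- cls == "other"
  n_ot <- sum(is_ot)
  if (n_ot > 0) {
    short_spell <- stats::runif(n_ot) < 0.5
    ue_m <- ifelse(short_spell, sample(1:5, n_ot, replace = TRUE), 0L)
    att <- ifelse(short_spell, 36L - ue_m, sample(0:17, n_ot, replace = TRUE))
    m[is_ot, "months_unemployed"] <- ue_m
    m[is_ot, "months_full_time"] <- att
    m[is_ot, "months_studies"] <- 36L - ue_m - att
    current[is_ot] <- sample(
      c("studies", "casual_job", "sick_leave", "parental_leave", "other"),
      n_ot, replace = TRUE
    )
  }

  total_days <- round(m[, "months_unemployed"] * 30.4)
  if (lb$register_extra_spell_prob > 0) {
    extra <- (stats::runif(n) < lb$register_extra_spell_prob) *
      sample(lb$register_extra_days[1]:lb$register_extra_days[2], n,
             replace = TRUE)
    total_days <- total_days + extra
  }
  d94 <- pmin(total_days, 366)
  d93 <- pmin(total_days - d94, 366)
  d92 <- pmin(total_days - d94 - d93, 366)

  fu_ue <- ifelse(stats::runif(n) < lb$p_fu_unemployed,
                  sample(1:24, n, replace = TRUE), 0L)
  fu_att <- ifelse(stats::runif(n) < lb$p_fu_low_attachment,
                   sample(0:17, n, replace = TRUE),
                   sample(18:144, n, replace = TRUE))

  rec <- data.frame(id = seq_len(n), current_status = current,
                    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(m))
  rec$reg_days_1992 <- d92
  rec$reg_days_1993 <- d93
  rec$reg_days_1994 <- d94
  rec$fu_months_labour_market <- fu_att
  rec$fu_months_unemployed <- fu_ue
  as_labour_history(rec)
}

#' Named misspecification scenarios for double-robustness studies
#'
#' All four scenarios generate from the default mechanism, in which
#' previous health is the dominant confounder (health selection); they
#' differ in the analysis models: (a) `correct_ps_wrong_outcome` omits
#' previous health from the stratified outcome models, (b)
#' `wrong_ps_correct_outcome` omits it from the propensity-score model,
#' (c) `both_correct` omits nothing, (d) `both_wrong` omits it from
#' both.  Each scenario carries the generating config, the two analysis
#' covariate sets and the generator truth.
#'
#' @param n Cohort size per replicate stored in the configs, default 2000.
#' @param mc_n Monte-Carlo size for the shared truth record.
#' @param seed Seed for the truth evaluation.
#' @return Named list of scenarios, each
#'   `list(config, ps_covariates, outcome_covariates, truth)`.
#' @export
misspecification_scenarios <- function(n = 2000L, mc_n = 1e6, seed = 1L) {
  cfg <- generator_config(n = n)
  truth <- true_marginal_rd(cfg, mc_n = mc_n, seed = seed)
  full <- c("prev_health", "education", "marital", "occupation")
  wrong <- setdiff(full, "prev_health")
  list(
    correct_ps_wrong_outcome = list(config = cfg, ps_covariates = full,
                                    outcome_covariates = wrong, truth = truth),
    wrong_ps_correct_outcome = list(config = cfg, ps_covariates = wrong,
                                    outcome_covariates = full, truth = truth),
    both_correct = list(config = cfg, ps_covariates = full,
                        outcome_covariates = full, truth = truth),
    both_wrong = list(config = cfg, ps_covariates = wrong,
                      outcome_covariates = wrong, truth = truth)
  )
}

#' Doubly-robust estimate with distinct model covariate sets
#'
#' Computes the doubly-robust risk difference with the propensity-score
#' model and the stratified outcome models built on (possibly) different
#' covariate sets — the construction used to study double robustness
#' under model misspecification.
#'
#' @param cohort A `causalrd_cohort`.
#' @param ps_covariates Covariates of the propensity-score model.
#' @param outcome_covariates Covariates of the stratified outcome models.
#' @return The risk difference (scalar).
#' @export
rd_dr_split <- function(cohort, ps_covariates, outcome_covariates) {
  ps <- propensity_scores(cohort, ps_covariates)$scores
  m <- fit_group_outcome_models(cohort, outcome_covariates)
  rd_dr(cohort$poor_health, cohort$unemployed, ps, m$m0, m$m1)
}

# 32-bit FNV-1a hash of the JSON serialisation; used to stamp outputs
# with the generating configuration.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "cb")], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
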