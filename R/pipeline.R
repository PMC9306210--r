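#' Run an end-to-end analysis from a single configuration
#'
#' Orchestrates the full sequence — obtain a cohort (simulate, or load
#' from CSV), optionally derive the exposure from labour histories under
#' a measurement mode and censoring policy, estimate the requested
#' effects with bootstrap inference, and optionally run the 24-model
#' sensitivity grid — writing the result tables, a run-metadata JSON
#' (config hash, seed, exclusion counts, effective replicate counts) and
#' stage logs to the output directory.  When fewer unemployed remain
#' than the suppression threshold (default 30), the run completes but
#' the estimates are suppressed and flagged unreliable rather than
#' reported.
#'
#' @param config A list, or the path to a YAML file, with elements:
#'   `source` (`"simulate"` or `"cohort_file"`), `cohort_file` (path,
#'   when loading), `n` and `seed` (when simulating; in YAML write the
#'   cohort size as `n_participants`, since a bare `n` key reads as a
#'   boolean), `exposure_mode` (`"none"` to keep the generated/loaded
#'   exposure, or one of `"self_reported"`, `"register"`, `"current"`
#'   to derive it from labour histories), `censor`
#'   (`"none"`/`"censor"`), `model`
#'   (`"full"`, `"reduced"`, or a character vector of confounders),
#'   `estimators`, `bootstrap` (list with `B`, `seed`, `level`),
#'   `run_ledger` (logical), `suppression_threshold`, `output_dir`.
#' @return A list (`causalrd_run`): `estimates` (data frame),
#'   `metadata`, and `ledger` when requested.  Files are written only
#'   when `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  # YAML 1.1 reads a bare `n` key as a boolean, so the cohort size is also
  # accepted under the YAML-safe name `n_participants`
  if (!is.null(config$n_participants)) config$n <- config$n_participants
  config$n_participants <- NULL
  cfgd <- list(
    source = "simulate", n = 805L, seed = 1L, exposure_mode = "none",
    censor = "none", model = "full", estimators = "all",
    bootstrap = list(B = 1000L, seed = 1L, level = 0.95),
    run_ledger = FALSE, suppression_threshold = 30L, output_dir = NULL
  )
  cfgd[names(config)] <- config
  config <- cfgd
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # -- stage: cohort ---------------------------------------------------
  excluded <- 0L
  censored <- 0L
  if (config$source == "simulate") {
    gen <- generator_config(n = config$n, seed = config$seed)
    cohort <- generate_cohort(gen)
    say("simulated cohort: %d participants (seed %d)", nrow(cohort),
        config$seed)
    if (config$exposure_mode != "none") {
      hist <- generate_labour_history(
        gen, seed = config$seed + 1L,
        exposure = ifelse(cohort$unemployed == 1, "unemployed", "employed")
      )
      assign <- derive_exposure(hist, config$exposure_mode, config$censor)
      keep <- assign$status != "excluded" & !assign$censored
      excluded <- sum(assign$status == "excluded")
      censored <- sum(assign$censored & assign$status != "excluded")
      cohort <- cohort[keep, , drop = FALSE]
      cohort$unemployed <- as.integer(assign$status[keep] == "unemployed")
      say("exposure mode '%s' (censor: %s): %d kept, %d excluded, %d censored",
          config$exposure_mode, config$censor, nrow(cohort), excluded,
          censored)
    }
  } else if (config$source == "cohort_file") {
    cohort <- load_cohort(config$cohort_file)
    rep <- attr(cohort, "validation")
    say("loaded cohort %s: %d rows read, %d dropped (incomplete)",
        config$cohort_file, rep$rows_read, rep$rows_dropped)
  } else {
    stop_schema(sprintf("unknown source '%s'", config$source))
  }

  # -- stage: model spec -----------------------------------------------
  cb <- attr(cohort, "codebook")
  full <- full_model_spec(cb)
  spec_vars <- if (identical(config$model, "full")) {
    full$variables
  } else if (identical(config$model, "reduced")) {
    select_significant(cohort, full)$variables
  } else {
    unknown <- setdiff(config$model, confounder_names(cb))
    if (length(unknown) > 0) {
      stop_schema(paste0("model names unknown confounder(s): ",
                         paste(unknown, collapse = ", ")))
    }
    config$model
  }
  say("adjustment set (%d variables): %s", length(spec_vars),
      paste(spec_vars, collapse = ", "))

  # -- stage: estimation -----------------------------------------------
  n_unemployed <- sum(cohort$unemployed == 1)
  n_employed <- sum(cohort$unemployed == 0)
  suppressed <- n_unemployed < config$suppression_threshold
  estimators <- expand_estimators(config$estimators)
  plan <- bootstrap_plan(config$bootstrap$B, config$bootstrap$seed,
                         if (is.null(config$bootstrap$level)) 0.95
                         else config$bootstrap$level)
  if (suppressed) {
    say("only %d unemployed (threshold %d): estimates suppressed",
        n_unemployed, config$suppression_threshold)
    estimates <- data.frame(
      estimator = estimators, scale = ifelse(estimators == "logistic_or",
                                             "odds_ratio", "risk_difference"),
      estimate = NA_real_, lower = NA_real_, upper = NA_real_,
      significant = NA, effective_B = NA_integer_, mse = NA_real_,
      n_employed = n_employed, n_unemployed = n_unemployed,
      suppressed = TRUE, reliable = FALSE, stringsAsFactors = FALSE
    )
  } else {
    rd_est <- setdiff(estimators, "logistic_or")
    rows <- list()
    if ("logistic_or" %in% estimators) {
      o <- or_logistic(cohort, spec_vars)
      rows[[1]] <- data.frame(
        o, effective_B = NA_integer_, mse = NA_real_,
        n_employed = n_employed, n_unemployed = n_unemployed,
        suppressed = FALSE, reliable = TRUE, stringsAsFactors = FALSE
      )
    }
    if (length(rd_est) > 0) {
      b <- bootstrap_estimate(cohort, spec_vars, rd_est, plan)
      for (e in rd_est) {
        rows[[length(rows) + 1L]] <- data.frame(
          estimator = e, scale = "risk_difference",
          estimate = unname(b$point[[e]]),
          lower = unname(b$ci[[e]]["lower"]),
          upper = unname(b$ci[[e]]["upper"]),
          significant = unname(b$significant[[e]]),
          effective_B = unname(b$effective_B[[e]]), mse = unname(b$mse[[e]]),
          n_employed = n_employed, n_unemployed = n_unemployed,
          suppressed = FALSE, reliable = unname(b$reliable[[e]]),
          stringsAsFactors = FALSE
        )
      }
    }
    estimates <- do.call(rbind, rows)
    say("estimated %d effect(s), bootstrap B = %d", nrow(estimates), plan$B)
  }

  # -- stage: ledger ---------------------------------------------------
  ledger <- NULL
  if (isTRUE(config$run_ledger) && !suppressed) {
    reduced <- select_significant(cohort, full)
    specs <- build_ledger(full, reduced)
    ledger <- run_ledger(cohort, specs, estimators, plan = NULL)
    say("sensitivity grid: %d model specs", length(specs))
  }

  metadata <- list(
    config = config[setdiff(names(config), "output_dir")],
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("causalrd")),
    n = nrow(cohort), n_employed = n_employed, n_unemployed = n_unemployed,
    excluded = excluded, censored = censored,
    suppressed = suppressed, seed = config$seed,
    bootstrap_seed = plan$seed, requested_B = plan$B
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(estimates,
                     file.path(config$output_dir, "estimates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(metadata, list(estimates = estimates)),
      file.path(config$output_dir, "run_metadata.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    if (!is.null(ledger)) {
      utils::write.csv(as.data.frame(ledger),
                       file.path(config$output_dir, "ledger.csv"),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }

  structure(list(estimates = estimates, metadata = metadata,
                 ledger = ledger, log = log_lines),
            class = "causalrd_run")
}

#' @export
print.causalrd_run <- function(x, ...) {
  cat(sprintf("<causalrd_run> n = %d (%d unemployed)%s\n", x$metadata$n,
              x$metadata$n_unemployed,
              if (x$metadata$suppressed) " [estimates suppressed]" else ""))
  print(x$estimates, digits = 4)
  invisible(x)
}
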