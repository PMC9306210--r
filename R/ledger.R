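#' Model specification: a named confounder set
#'
#' One adjustment set for one analysis, with its lineage in the
#' full/reduced sensitivity grid.
#'
#' @param id Integer model id (1-24) or `NA` for the crude model.
#' @param name Display name.
#' @param variables Character vector of confounder names.
#' @param lineage One of `"full"`, `"full_minus"`, `"reduced"`,
#'   `"reduced_minus"`, `"reduced_plus"`, `"crude"`.
#' @param alias_of Optional id of an earlier identical spec (degenerate
#'   grids deduplicate by aliasing).
#' @return A `causalrd_model_spec`.
#' @export
model_spec <- function(id, name, variables, lineage, alias_of = NA) {
  structure(
    list(id = id, name = name, variables = variables, lineage = lineage,
         alias_of = alias_of),
    class = "causalrd_model_spec"
  )
}

#' @export
print.causalrd_model_spec <- function(x, ...) {
  cat(sprintf("<causalrd_model_spec> %s [%s]: %s\n", x$name, x$lineage,
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(crude, no confounders)"))
  invisible(x)
}

#' The full adjustment model (model 1)
#'
#' All eleven confounders of the codebook, in declaration order:
#' previous health, education, marital status, occupation, sex, AVSI,
#' AVAT, cash margin, smoking, alcohol intake and body-mass index.
#'
#' @param cb Codebook, default [default_codebook()].
#' @return A `causalrd_model_spec` with id 1.
#' @export
full_model_spec <- function(cb = default_codebook()) {
  confs <- confounder_names(cb)
  if (length(confs) == 0) stop_schema("codebook declares no confounders")
  model_spec(1L, "model 1 (full)", confs, "full")
}

#' Select the significant confounders (the reduced model)
#'
#' Fits the logistic outcome model on the exposure plus all confounders
#' of the full spec, computes a profile-likelihood confidence interval
#' for every non-reference level of every confounder, and retains a
#' confounder iff any of its levels has an interval excluding an odds
#' ratio of 1 at the given alpha.  Selection is at the variable level: a
#' categorical variable is kept or dropped with all its indicator
#' columns together.  The exposure is always retained.
#'
#' @param cohort A `causalrd_cohort`.
#' @param full A `causalrd_model_spec`, typically [full_model_spec()].
#' @param alpha Significance level, default 0.05.
#' @return A `causalrd_model_spec` with id 13 and lineage `"reduced"`.
#' @export
select_significant <- function(cohort, full = full_model_spec(attr(cohort, "codebook")),
                               alpha = 0.05) {
  if (alpha >= 1) {
    return(model_spec(13L, "model 13 (reduced)", full$variables, "reduced"))
  }
  X <- build_design(cohort, full$variables, include_exposure = TRUE)
  y <- cohort$poor_health
  fit <- fit_logistic(X, y)
  if (!fit$converged) stop_singularity("full outcome model did not converge")
  keep <- vapply(full$variables, function(v) {
    cols <- design_columns_for(cohort, v)
    any(vapply(cols, function(cl) {
      ci <- profile_likelihood_ci(fit, X, y, cl, level = 1 - alpha)
      significance_flag(ci["lower"], ci["upper"], scale = "odds_ratio")
    }, logical(1)))
  }, logical(1))
  model_spec(13L, "model 13 (reduced)", full$variables[keep], "reduced")
}

#' Build the 24-model confounder-sensitivity grid
#'
#' Models 1-12: the full model and the full model minus each of its
#' eleven confounders in turn.  Models 13-17: the reduced model and the
#' reduced model minus each of its members.  Models 18-24: the reduced
#' model plus each confounder excluded from it.  A crude (unadjusted)
#' spec is appended.  Variables enter and leave atomically — removing a
#' categorical confounder removes all its indicator columns.  When the
#' reduced set equals the full set, the redundant minus-variants are
#' deduplicated by aliasing to their earlier twins.
#'
#' @param full A `causalrd_model_spec` (the 11-confounder model).
#' @param reduced A `causalrd_model_spec` whose variables are a subset of
#'   the full model's.
#' @return A list of `causalrd_model_spec` (24 models plus the crude
#'   spec when the reduced model has 4 members).
#' @export
build_ledger <- function(full, reduced) {
  if (!all(reduced$variables %in% full$variables)) {
    stop_contract("the reduced model must be a subset of the full model")
  }
  specs <- list(full)
  id <- 1L
  for (v in ledger_variable_order(full$variables)) {
    id <- id + 1L
    specs[[length(specs) + 1L]] <- model_spec(
      id, sprintf("model %d (full - %s)", id, v),
      setdiff(full$variables, v), "full_minus"
    )
  }
  id <- id + 1L
  reduced$id <- id
  reduced$name <- sprintf("model %d (reduced)", id)
  specs[[length(specs) + 1L]] <- reduced
  for (v in ledger_variable_order(reduced$variables)) {
    id <- id + 1L
    specs[[length(specs) + 1L]] <- model_spec(
      id, sprintf("model %d (reduced - %s)", id, v),
      setdiff(reduced$variables, v), "reduced_minus"
    )
  }
  for (v in ledger_variable_order(setdiff(full$variables,
                                          reduced$variables))) {
    id <- id + 1L
    specs[[length(specs) + 1L]] <- model_spec(
      id, sprintf("model %d (reduced + %s)", id, v),
      c(reduced$variables, v), "reduced_plus"
    )
  }
  specs[[length(specs) + 1L]] <- model_spec(NA, "crude", character(), "crude")
  # dedupe identical variable sets by aliasing to the earliest spec
  seen <- list()
  for (i in seq_along(specs)) {
    key <- paste(sort(specs[[i]]$variables), collapse = "|")
    if (!is.null(seen[[key]])) {
      specs[[i]]$alias_of <- seen[[key]]
    } else {
      seen[[key]] <- specs[[i]]$id
    }
  }
  specs
}

#' Run the sensitivity grid
#'
#' Computes every requested (model, estimator) cell.  With a bootstrap
#' plan, resamples are shared across models (one index matrix from the
#' plan's seed) so that between-model deviations are not bootstrap
#' noise; `share_resamples = FALSE` redraws per model from seeds derived
#' from the master seed.  Per-cell singularity failures are recorded and
#' the run continues.
#'
#' @param cohort A `causalrd_cohort`.
#' @param specs List of `causalrd_model_spec`, typically from
#'   [build_ledger()].
#' @param estimators Estimator set (see [estimate_effects()]).
#' @param plan Optional `causalrd_boot_plan`; `NULL` (default) computes
#'   point estimates only.
#' @param share_resamples Share the resample-index matrix across models?
#' @return A `causalrd_ledger_report`: a long data frame (model id,
#'   name, lineage, estimator, estimate, lower, upper, significant,
#'   effective_B, mse, failure) with attribute `deviations` (per
#'   estimator, max |estimate - reference| against the full and reduced
#'   models).
#' @export
run_ledger <- function(cohort, specs, estimators = "all", plan = NULL,
                       share_resamples = TRUE) {
  estimators <- expand_estimators(estimators)
  indices <- if (!is.null(plan) && share_resamples) {
    resample_indices(nrow(cohort), plan)
  } else NULL
  rows <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    model_plan <- if (!is.null(plan) && !share_resamples) {
      bootstrap_plan(plan$B, plan$seed + k, plan$level)
    } else plan
    for (est in estimators) {
      row <- data.frame(
        model_id = sp$id, model = sp$name, lineage = sp$lineage,
        estimator = est, estimate = NA_real_, lower = NA_real_,
        upper = NA_real_, significant = NA, effective_B = NA_integer_,
        mse = NA_real_, failure = "", stringsAsFactors = FALSE
      )
      cell <- tryCatch({
        if (est == "logistic_or") {
          o <- or_logistic(cohort, sp$variables)
          list(estimate = o$estimate, lower = o$lower, upper = o$upper,
               significant = o$significant, effective_B = NA_integer_,
               mse = NA_real_)
        } else if (is.null(model_plan)) {
          list(estimate = unname(estimate_effects(cohort, sp$variables, est)),
               lower = NA_real_, upper = NA_real_, significant = NA,
               effective_B = NA_integer_, mse = NA_real_)
        } else {
          b <- suppressWarnings(bootstrap_estimate(
            cohort, sp$variables, est, model_plan, indices = indices
          ))
          list(estimate = unname(b$point[[est]]),
               lower = unname(b$ci[[est]]["lower"]),
               upper = unname(b$ci[[est]]["upper"]),
               significant = unname(b$significant[[est]]),
               effective_B = unname(b$effective_B[[est]]),
               mse = unname(b$mse[[est]]))
        }
      }, causalrd_error = function(e) list(failure = conditionMessage(e)))
      if (!is.null(cell$failure)) {
        row$failure <- cell$failure
      } else {
        row$estimate <- cell$estimate
        row$lower <- cell$lower
        row$upper <- cell$upper
        row$significant <- cell$significant
        row$effective_B <- cell$effective_B
        row$mse <- cell$mse
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "deviations") <- ledger_deviations(report)
  class(report) <- c("causalrd_ledger_report", class(report))
  report
}

# Canonical order in which confounders are removed from / added to the
# grid's reference models (education, marital status, previous health,
# occupation, sex, AVAT, AVSI, cash margin, smoking, alcohol, BMI);
# variables outside this list keep their given order at the end.
ledger_variable_order <- function(vars) {
  canonical <- c("education", "marital", "prev_health", "occupation", "sex",
                 "avat", "avsi", "cash_margin", "smoking", "alcohol", "bmi")
  c(intersect(canonical, vars), setdiff(vars, canonical))
}

# Max absolute deviation of each estimator's estimates from the full and
# the reduced reference models.
ledger_deviations <- function(report) {
  out <- list()
  for (est in unique(report$estimator)) {
    sub <- report[report$estimator == est & !is.na(report$estimate), ]
    for (ref_lineage in c("full", "reduced")) {
      ref <- sub$estimate[sub$lineage == ref_lineage]
      if (length(ref) == 1) {
        out[[paste0(est, "_vs_", ref_lineage)]] <-
          max(abs(sub$estimate - ref))
      }
    }
  }
  out
}
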