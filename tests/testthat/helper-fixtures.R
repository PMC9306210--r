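# Shared fixtures, built in code at test time.

# A small hand-specifiable cohort: confounders default to the reference
# level so tests can control exactly the columns they care about.
tiny_cohort <- function(y, x, ...) {
  n <- length(y)
  cb <- default_codebook()
  cols <- list(...)
  df <- data.frame(id = seq_len(n), poor_health = y, unemployed = x)
  for (nm in confounder_names(cb)) {
    df[[nm]] <- if (!is.null(cols[[nm]])) cols[[nm]] else
      rep(cb$variables[[nm]]$reference, n)
  }
  as_cohort(df, cb)
}

# Default-mechanism synthetic cohort.
sim_cohort <- function(n = 805, seed = 1) {
  generate_cohort(generator_config(n = n), seed = seed)
}

# A labour-history table specified row-wise by the aggregates the modes
# consume; everything else is a benign filler.
tiny_history <- function(months_unemployed = 0, months_full_time = 0,
                         months_part_time = 0,
                         months_labour_market_measure = 0,
                         reg_days = c(0, 0, 0),
                         current_status = "full_time",
                         fu_months_labour_market = 36,
                         fu_months_unemployed = 0) {
  n <- max(lengths(list(months_unemployed, months_full_time,
                        months_part_time, current_status)))
  rec <- data.frame(
    id = seq_len(n),
    current_status = rep_len(current_status, n),
    months_full_time = rep_len(months_full_time, n),
    months_part_time = rep_len(months_part_time, n),
    months_labour_market_measure = rep_len(months_labour_market_measure, n),
    months_unemployed = rep_len(months_unemployed, n),
    months_casual_job = 0, months_studies = 0, months_other_education = 0,
    months_sick_leave = 0, months_parental_leave = 0, months_other = 0,
    stringsAsFactors = FALSE
  )
  reg <- matrix(rep_len(as.numeric(reg_days), 3 * n), nrow = n, byrow = n == 1)
  if (length(reg_days) == 3 && n > 1) {
    reg <- matrix(rep(as.numeric(reg_days), each = n), nrow = n)
  }
  rec$reg_days_1992 <- reg[, 1]
  rec$reg_days_1993 <- reg[, 2]
  rec$reg_days_1994 <- reg[, 3]
  rec$fu_months_labour_market <- rep_len(fu_months_labour_market, n)
  rec$fu_months_unemployed <- rep_len(fu_months_unemployed, n)
  as_labour_history(rec)
}
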