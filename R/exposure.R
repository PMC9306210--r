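# Labour-market status vocabulary shared by the retrospective matrix, the
# current-status question and the follow-up episodes.
labour_statuses <- function() {
  c("full_time", "part_time", "labour_market_measure", "unemployed",
    "casual_job", "studies", "other_education", "sick_leave",
    "parental_leave", "other")
}

# Statuses counting as active labour-market attachment.
attachment_statuses <- function() {
  c("full_time", "part_time", "labour_market_measure")
}

#' Labour-history records
#'
#' One row per participant holding the raw labour-market information from
#' which exposure is derived: the tick for "What is your current
#' employment situation?" (`current_status`, one of the ten response
#' alternatives), accumulated months per status over the retrospective
#' three-year window 1993-1995 (`months_<status>` columns, totalling 36),
#' registered unemployment days per year 1992-1994
#' (`reg_days_1992/1993/1994`, each 0-366), and follow-up information
#' 1995-2007 (`fu_months_labour_market` attachment months and
#' `fu_months_unemployed`).
#'
#' @param data Data frame with the columns above (plus `id`).
#' @return A validated `causalrd_labour_history` data frame.
#' @export
as_labour_history <- function(data) {
  statuses <- labour_statuses()
  month_cols <- paste0("months_", statuses)
  reg_cols <- paste0("reg_days_", 1992:1994)
  required <- c("id", "current_status", month_cols, reg_cols,
                "fu_months_labour_market", "fu_months_unemployed")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("labour history lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  bad_tick <- which(!data$current_status %in% statuses)
  if (length(bad_tick) > 0) {
    stop_coding(sprintf("row %d: unknown current-status tick '%s'",
                        bad_tick[1], data$current_status[bad_tick[1]]))
  }
  if (any(as.matrix(data[month_cols]) < 0) ||
      any(data$fu_months_labour_market < 0) ||
      any(data$fu_months_unemployed < 0)) {
    stop_domain("episode months must be non-negative")
  }
  reg <- as.matrix(data[reg_cols])
  if (any(reg < 0)) stop_domain("register day counts must be non-negative")
  if (any(reg > 366)) stop_domain("register day counts exceed calendar bounds")
  structure(data, class = c("causalrd_labour_history", "data.frame"))
}

retro_unemployed_months <- function(rec) rec$months_unemployed
retro_attachment_months <- function(rec) {
  rowSums(as.matrix(rec[paste0("months_", attachment_statuses())]))
}
register_days_total <- function(rec) {
  rowSums(as.matrix(rec[paste0("reg_days_", 1992:1994)]))
}

new_assignment <- function(rec, mode, status, reason) {
  data.frame(id = rec$id, mode = mode, status = status,
             censored = FALSE, reason = reason, stringsAsFactors = FALSE)
}

#' Self-reported long-term unemployment mode
#'
#' Unemployed: at least half a year (6 months) of self-reported
#' unemployment over the three retrospective years.  Employed: no
#' self-reported unemployment and at least 1.5 years (18 months) of
#' labour-market attachment (full-time, part-time 20-39 h, or labour
#' market measure) over the same window.  Anyone else is outside the
#' labour market and excluded, with a reason code.
#'
#' @param rec A `causalrd_labour_history`.
#' @return An exposure-assignment data frame: `id`, `mode`, `status`
#'   (employed / unemployed / excluded), `censored`, `reason`.
#' @export
derive_self_reported_longterm <- function(rec) {
  ue <- retro_unemployed_months(rec)
  att <- retro_attachment_months(rec)
  status <- ifelse(ue >= 6, "unemployed",
            ifelse(ue == 0 & att >= 18, "employed", "excluded"))
  reason <- ifelse(status == "excluded",
            ifelse(ue > 0, "some_unemployment_below_6_months",
                   "insufficient_labour_market_attachment"), "")
  new_assignment(rec, "self_reported", status, reason)
}

#' Register-based long-term unemployment mode
#'
#' Unemployed: at least 182 registered unemployment days (6 months, the
#' ceiling of half of 365) accumulated over 1992-1994.  Employed: zero
#' registered days together with the same 18-month labour-market
#' attachment rule as the self-reported mode.  Anyone else is excluded.
#'
#' @param rec A `causalrd_labour_history`.
#' @return An exposure-assignment data frame (see
#'   [derive_self_reported_longterm()]).
#' @export
derive_register_longterm <- function(rec) {
  days <- register_days_total(rec)
  if (any(days < 0)) stop_domain("negative register day counts")
  att <- retro_attachment_months(rec)
  status <- ifelse(days >= 182, "unemployed",
            ifelse(days == 0 & att >= 18, "employed", "excluded"))
  reason <- ifelse(status == "excluded",
            ifelse(days > 0, "registered_days_below_182",
                   "insufficient_labour_market_attachment"), "")
  new_assignment(rec, "register", status, reason)
}

#' Current-unemployment mode
#'
#' Status from the single tick at "What is your current employment
#' situation?": unemployed for the unemployed tick; employed for
#' full-time, part-time (20-39 h) or labour-market-measure ticks;
#' excluded (not in the labour market) for studies, other education,
#' casual job, sick leave, parental leave and other.
#'
#' @param rec A `causalrd_labour_history`.
#' @return An exposure-assignment data frame.
#' @export
derive_current <- function(rec) {
  tick <- rec$current_status
  bad <- which(!tick %in% labour_statuses())
  if (length(bad) > 0) {
    stop_coding(sprintf("row %d: unknown current-status tick '%s'",
                        bad[1], tick[bad[1]]))
  }
  status <- ifelse(tick == "unemployed", "unemployed",
            ifelse(tick %in% attachment_statuses(), "employed", "excluded"))
  reason <- ifelse(status == "excluded", "not_in_labour_market", "")
  new_assignment(rec, "current", status, reason)
}

#' Apply the follow-up censoring policy
#'
#' Under `policy = "censor"`, participants with any unemployment during
#' follow-up, or with less than 18 months of labour-market attachment
#' during follow-up, are flagged censored; censored participants are
#' excluded from estimation.  Censoring never changes an
#' employed/unemployed status, it only flags rows for removal.  Under
#' `policy = "none"` the assignment is returned unchanged.
#'
#' @param assign An exposure-assignment data frame.
#' @param rec The matching `causalrd_labour_history`.
#' @param policy `"none"` or `"censor"`.
#' @return The assignment with the `censored` flag and reason updated.
#' @export
apply_censor_policy <- function(assign, rec, policy = c("none", "censor")) {
  policy <- match.arg(policy)
  if (policy == "none") return(assign)
  cens <- rec$fu_months_unemployed > 0 | rec$fu_months_labour_market < 18
  assign$censored <- cens
  assign$reason <- ifelse(
    cens,
    ifelse(rec$fu_months_unemployed > 0, "followup_unemployment",
           "followup_attachment_below_18_months"),
    assign$reason
  )
  assign
}

#' Derive exposure for a whole labour-history table
#'
#' Runs one of the three unemployment modes and the censoring policy; the
#' current mode under censoring triggers a small-sample warning when
#' fewer than 30 uncensored unemployed remain, echoing that this design
#' rarely supports reliable estimation.
#'
#' @param rec A `causalrd_labour_history`.
#' @param mode `"self_reported"`, `"register"` or `"current"`.
#' @param policy `"none"` or `"censor"`.
#' @return An exposure-assignment data frame with a `counts` attribute
#'   (participants by status and censoring).
#' @export
derive_exposure <- function(rec, mode = c("self_reported", "register", "current"),
                            policy = c("none", "censor")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  assign <- switch(mode,
    self_reported = derive_self_reported_longterm(rec),
    register = derive_register_longterm(rec),
    current = derive_current(rec)
  )
  assign <- apply_censor_policy(assign, rec, policy)
  kept_unemployed <- sum(assign$status == "unemployed" & !assign$censored)
  if (mode == "current" && policy == "censor" && kept_unemployed < 30) {
    warning(structure(
      class = c("causalrd_small_sample_warning", "warning", "condition"),
      list(message = sprintf(
        "current mode with censoring retains only %d unemployed; estimates are unlikely to be reliable",
        kept_unemployed
      ), call = sys.call(-1))
    ))
  }
  attr(assign, "counts") <- table(status = assign$status,
                                  censored = assign$censored)
  assign
}
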