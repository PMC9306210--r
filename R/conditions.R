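# Classed conditions.  Every failure mode that the bootstrap or the model
# ledger must react to programmatically gets its own condition class; all
# inherit from "causalrd_error".  Separation and degenerate-response errors
# additionally inherit from "causalrd_singularity_error", the class the
# bootstrap's skip-and-count policy catches.

causalrd_error <- function(message, class, data = list()) {
  structure(
    class = c(class, "causalrd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
}

stop_separation <- function(column, message = NULL) {
  if (is.null(message)) {
    message <- sprintf(
      "perfect separation detected in logistic fit (offending column: %s)",
      column
    )
  }
  stop(causalrd_error(
    message,
    c("causalrd_separation_error", "causalrd_singularity_error"),
    data = list(column = column)
  ))
}

stop_degenerate_response <- function(message = "response takes a single value; logistic regression is not possible") {
  stop(causalrd_error(
    message,
    c("causalrd_degenerate_response_error", "causalrd_singularity_error")
  ))
}

stop_singularity <- function(message) {
  stop(causalrd_error(message, "causalrd_singularity_error"))
}

stop_coding <- function(message, data = list()) {
  stop(causalrd_error(message, "causalrd_coding_error", data = data))
}

stop_schema <- function(message) {
  stop(causalrd_error(message, "causalrd_schema_error"))
}

stop_domain <- function(message) {
  stop(causalrd_error(message, "causalrd_domain_error"))
}

stop_contract <- function(message) {
  stop(causalrd_error(message, "causalrd_contract_error"))
}

stop_reliability <- function(message, data = list()) {
  stop(causalrd_error(message, "causalrd_reliability_error", data = data))
}
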