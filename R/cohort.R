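#' Construct a validated cohort table
#'
#' A cohort table is a data frame with one row per participant: an `id`
#' column, integer 0/1 columns `poor_health` (outcome, 1 = poor self-rated
#' health) and `unemployed` (exposure, 1 = unemployed), and one factor
#' column per confounder with the codebook's levels (reference level
#' first).  All estimation functions operate on this object.
#'
#' @param data A data frame with the columns above (outcome/exposure may be
#'   given as level labels or 0/1).
#' @param cb Codebook; default [default_codebook()].
#' @return A `causalrd_cohort` (a data frame).
#' @export
as_cohort <- function(data, cb = default_codebook()) {
  vars <- names(cb$variables)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  out <- data.frame(
    id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
    stringsAsFactors = FALSE
  )
  for (nm in vars) {
    v <- cb$variables[[nm]]
    col <- data[[nm]]
    if (nm %in% c("poor_health", "unemployed")) {
      out[[nm]] <- code_binary_column(col, v, nm)
    } else {
      out[[nm]] <- code_factor_column(col, v, nm)
    }
  }
  structure(out, class = c("causalrd_cohort", "data.frame"), codebook = cb)
}

# Map a 0/1-or-labelled column to integer 0/1 (reference level = 0).
code_binary_column <- function(col, v, nm) {
  if (is.numeric(col)) {
    bad <- which(!is.na(col) & !(col %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_coding(sprintf("variable '%s', row %d: value '%s' is not 0/1",
                          nm, bad[1], col[bad[1]]),
                  data = list(variable = nm, row = bad[1], value = col[bad[1]]))
    }
    return(as.integer(col))
  }
  col <- as.character(col)
  bad <- which(!is.na(col) & !(col %in% v$levels))
  if (length(bad) > 0) {
    stop_coding(sprintf("variable '%s', row %d: unknown level '%s'",
                        nm, bad[1], col[bad[1]]),
                data = list(variable = nm, row = bad[1], value = col[bad[1]]))
  }
  as.integer(col == setdiff(v$levels, v$reference)[1])
}

code_factor_column <- function(col, v, nm) {
  col <- as.character(col)
  bad <- which(!is.na(col) & !(col %in% v$levels))
  if (length(bad) > 0) {
    stop_coding(sprintf("variable '%s', row %d: unknown level '%s'",
                        nm, bad[1], col[bad[1]]),
                data = list(variable = nm, row = bad[1], value = col[bad[1]]))
  }
  factor(col, levels = v$levels)
}

#' Load a cohort from a delimited text file
#'
#' Reads a comma-separated, UTF-8, header-required file, codes every study
#' variable against the codebook, drops rows with any missing study
#' variable (complete-case analysis; no imputation) and reports the
#' dropped count in the attached validation report.
#'
#' @param path Path to a CSV file whose header names all codebook
#'   variables.
#' @param cb Codebook; default [default_codebook()].
#' @return A `causalrd_cohort` with attribute `"validation"`: a list with
#'   `rows_read`, `rows_dropped` and per-variable `level_counts`.
#' @export
load_cohort <- function(path, cb = default_codebook()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  vars <- names(cb$variables)
  missing_cols <- setdiff(vars, names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  complete <- stats::complete.cases(raw[vars])
  cohort <- as_cohort(raw[complete, , drop = FALSE], cb)
  attr(cohort, "validation") <- validation_report(cohort,
                                                  rows_read = nrow(raw))
  cohort
}

#' Write a cohort to CSV
#'
#' Factor confounders are written as their level labels and the
#' outcome/exposure as 0/1; [load_cohort()] reproduces the table exactly.
#'
#' @param cohort A `causalrd_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validation report for a cohort
#'
#' @param cohort A `causalrd_cohort`.
#' @param rows_read Number of rows in the source file before complete-case
#'   filtering; defaults to the cohort size.
#' @return A list with `rows_read`, `rows_kept`, `rows_dropped` and
#'   `level_counts` (per-variable tables laid out like a study
#'   characteristics table).
#' @export
validation_report <- function(cohort, rows_read = nrow(cohort)) {
  cb <- attr(cohort, "codebook")
  counts <- lapply(names(cb$variables), function(nm) {
    v <- cb$variables[[nm]]
    col <- cohort[[nm]]
    if (is.numeric(col)) {
      col <- factor(v$levels[col + 1L], levels = v$levels)
    }
    as.list(table(col))
  })
  names(counts) <- names(cb$variables)
  list(
    rows_read = rows_read,
    rows_kept = nrow(cohort),
    rows_dropped = rows_read - nrow(cohort),
    level_counts = counts
  )
}

#' Write a JSON validation report
#'
#' @param cohort A `causalrd_cohort` (typically from [load_cohort()]).
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(cohort, path) {
  rep <- attr(cohort, "validation")
  if (is.null(rep)) rep <- validation_report(cohort)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.causalrd_cohort <- function(x, ...) {
  cat(sprintf("<causalrd_cohort> %d participants (%d unemployed, %d employed)\n",
              nrow(x), sum(x$unemployed == 1), sum(x$unemployed == 0)))
  NextMethod()
}

#' Build a reference-coded design matrix
#'
#' Intercept column followed by treatment-contrast indicator columns for
#' each requested variable, in declaration order then level order; a
#' categorical variable with L levels contributes L - 1 columns.  When
#' `include_exposure` is set the 0/1 exposure indicator is appended as the
#' final column.
#'
#' @param cohort A `causalrd_cohort`.
#' @param variables Character vector of confounder names (may be empty for
#'   an intercept-only design).
#' @param include_exposure Append the exposure column?
#' @return Numeric matrix with column names tracing each column to its
#'   (variable, level).
#' @export
build_design <- function(cohort, variables = character(),
                         include_exposure = FALSE) {
  if (nrow(cohort) == 0) stop_domain("cannot build a design for an empty cohort")
  cb <- attr(cohort, "codebook")
  if (!is.null(cb)) {
    unknown <- setdiff(variables, names(cb$variables))
    if (length(unknown) > 0) {
      stop_schema(paste0("variable(s) not in codebook: ",
                         paste(unknown, collapse = ", ")))
    }
  }
  n <- nrow(cohort)
  if (length(variables) == 0) {
    X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(variables, collapse = " + ")))
    X <- stats::model.matrix(fml, data = as.data.frame(cohort)[variables])
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
  }
  if (include_exposure) {
    X <- cbind(X, unemployed = as.numeric(cohort$unemployed))
  }
  X
}

#' @export
`[.causalrd_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "codebook") <- attr(x, "codebook")
    class(out) <- unique(c("causalrd_cohort", class(out)))
  }
  out
}

# Column names of the design that a variable contributes (used for
# atomic add/remove of categorical variables and for significance flags).
design_columns_for <- function(cohort, variable) {
  X1 <- build_design(cohort[seq_len(min(nrow(cohort), 50L)), , drop = FALSE],
                     variable)
  setdiff(colnames(X1), "(Intercept)")
}
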