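#' Variable codebook for a cohort analysis
#'
#' A codebook declares every study variable: its kind, its ordered level
#' labels (reference level first), and, for variables derived from a
#' continuous score, the thresholding rule.  All coding, design-matrix
#' construction and model specification is driven by the codebook, so the
#' mapping between raw values and analysis levels is explicit and
#' configurable rather than hard-wired.
#'
#' @param variables A named list.  Each element describes one variable and
#'   must contain `kind` (one of `"binary"`, `"categorical"`,
#'   `"thresholded"`), `levels` (character vector of unique level labels),
#'   and `reference` (one of `levels`).  Thresholded variables additionally
#'   carry a `threshold` rule (see [code_thresholded()]).
#' @return An object of class `causalrd_codebook`.
#' @seealso [default_codebook()], [read_codebook()]
#' @export
codebook <- function(variables) {
  if (is.null(names(variables)) || any(!nzchar(names(variables)))) {
    stop_schema("every codebook variable must be named")
  }
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (is.null(v$levels) || anyDuplicated(v$levels)) {
      stop_schema(sprintf("variable '%s': level labels must be unique", nm))
    }
    if (is.null(v$reference) || length(v$reference) != 1L ||
        !(v$reference %in% v$levels)) {
      stop_schema(sprintf(
        "variable '%s': exactly one reference level from its declared levels is required", nm
      ))
    }
    variables[[nm]]$levels <- c(v$reference, setdiff(v$levels, v$reference))
  }
  structure(list(variables = variables), class = "causalrd_codebook")
}

#' Default codebook: outcome, exposure and the 11 categorical confounders
#'
#' Encodes the study's variable definitions: poor/good self-rated health in
#' 2007 as the outcome, unemployed/employed labour-market status as the
#' exposure, and eleven confounders measured in 1995 — previous self-rated
#' health, education (reference: university), marital status (reference:
#' married, including cohabiting), occupation (reference: medium-high
#' white-collar), sex (reference: woman), availability of social
#' integration (AVSI, score <= 13 coded as the reference level) and of
#' attachment (AVAT, score >= 10 coded as the reference level), cash margin
#' (reference: access to 13,000 SEK within a week), smoking (reference:
#' not a current smoker), alcohol-intake index (score < 140 coded low, the
#' reference) and body-mass index (reference: normal, i.e. BMI < 25 kg/m2).
#'
#' @return A `causalrd_codebook`.
#' @export
default_codebook <- function() {
  codebook(list(
    poor_health = list(kind = "binary", levels = c("good", "poor"),
                       reference = "good"),
    unemployed = list(kind = "binary", levels = c("employed", "unemployed"),
                      reference = "employed"),
    prev_health = list(kind = "binary", levels = c("good", "poor"),
                       reference = "good"),
    education = list(kind = "categorical",
                     levels = c("university", "secondary", "upper_secondary"),
                     reference = "university"),
    marital = list(kind = "binary", levels = c("married", "single"),
                   reference = "married"),
    occupation = list(kind = "categorical",
                      levels = c("med_high_white", "blue_collar", "low_white"),
                      reference = "med_high_white"),
    sex = list(kind = "binary", levels = c("woman", "man"),
               reference = "woman"),
    avsi = list(kind = "thresholded", levels = c("low", "high"),
                reference = "low",
                threshold = list(cut = 13, reference_side = "le")),
    avat = list(kind = "thresholded", levels = c("low", "high"),
                reference = "low",
                threshold = list(cut = 10, reference_side = "ge")),
    cash_margin = list(kind = "binary", levels = c("access", "no_access"),
                       reference = "access"),
    smoking = list(kind = "categorical",
                   levels = c("not_smoking", "le10", "gt10"),
                   reference = "not_smoking"),
    alcohol = list(kind = "thresholded", levels = c("low", "high"),
                   reference = "low",
                   threshold = list(cut = 140, reference_side = "lt")),
    bmi = list(kind = "categorical",
               levels = c("normal", "overweight", "obese"),
               reference = "normal")
  ))
}

#' @export
print.causalrd_codebook <- function(x, ...) {
  cat("<causalrd_codebook>", length(x$variables), "variables\n")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    cat(sprintf("  %-12s %-12s levels: %s (ref: %s)\n",
                nm, v$kind, paste(v$levels, collapse = "/"), v$reference))
  }
  invisible(x)
}

#' Names of the confounding variables in a codebook
#'
#' Every codebook variable except the outcome (`poor_health`) and the
#' exposure (`unemployed`).
#'
#' @param cb A `causalrd_codebook`.
#' @return Character vector of confounder names in declaration order.
#' @export
confounder_names <- function(cb) {
  setdiff(names(cb$variables), c("poor_health", "unemployed"))
}

#' Read a codebook from a YAML file
#'
#' @param path Path to a YAML file whose top level maps variable names to
#'   entries with `kind`, `levels`, `reference` and optionally `threshold`.
#' @return A `causalrd_codebook`.
#' @export
read_codebook <- function(path) {
  codebook(yaml::read_yaml(path))
}

#' Categorise body-mass index from weight and height
#'
#' BMI is weight / height^2 in kg/m2.  A BMI of at least 30 is coded
#' `"obese"`, at least 25 but below 30 `"overweight"`, below 25
#' `"normal"`.  Both interval boundaries belong to the upper category.
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in metres (> 0).
#' @return Character vector of BMI levels.
#' @examples
#' code_bmi(93, 1.75)   # obese
#' code_bmi(76.5, 1.75) # normal
#' @export
code_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop_domain("weight and height must be positive")
  }
  bmi <- weight / height^2
  ifelse(bmi >= 30, "obese", ifelse(bmi >= 25, "overweight", "normal"))
}

#' Code a thresholded score to its analysis level
#'
#' Applies the codebook's cut-off rules for the score-based variables:
#' AVSI scores of 13 or lower, AVAT scores of 10 or higher, and alcohol
#' index scores strictly below 140 map to the reference level; all other
#' scores map to the non-reference level.
#'
#' @param value Numeric score(s).
#' @param variable One of `"avsi"`, `"avat"`, `"alcohol"` (case-insensitive).
#' @param cb Codebook supplying the threshold rules; default
#'   [default_codebook()].
#' @return Character vector of levels.
#' @examples
#' code_thresholded(13, "avsi")     # reference ("low")
#' code_thresholded(139.9, "alcohol") # "low"
#' @export
code_thresholded <- function(value, variable, cb = default_codebook()) {
  variable <- tolower(variable)
  v <- cb$variables[[variable]]
  if (is.null(v) || v$kind != "thresholded") {
    stop_domain(sprintf("'%s' is not a thresholded variable", variable))
  }
  thr <- v$threshold
  is_ref <- switch(thr$reference_side,
    le = value <= thr$cut,
    lt = value < thr$cut,
    ge = value >= thr$cut,
    gt = value > thr$cut,
    stop_schema("unknown threshold side")
  )
  other <- setdiff(v$levels, v$reference)[1]
  ifelse(is_ref, v$reference, other)
}
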