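# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trait, category and covariate vocabularies
#'
#' Column vocabularies used throughout the pipeline: the nine cardiometabolic
#' traits, the ten lifestyle-exposure categories, the dietary categories whose
#' models receive energy adjustment, and the traits measured on blood samples
#' (adjusted for fasting status).
#'
#' @return Character vector of names.
#' @export
cardiometabolic_traits <- function() {
  c("bmi", "sbp", "dbp", "glucose_fasting", "glucose_2h",
    "cholesterol_total", "triglycerides", "hdl", "ldl")
}

#' @rdname cardiometabolic_traits
#' @export
exposure_categories <- function() {
  c("alcohol", "beverage", "food", "nutrient", "general_health",
    "physical_activity", "psychosocial", "sleep", "social", "tobacco")
}

#' @rdname cardiometabolic_traits
#' @export
dietary_categories <- function() {
  c("alcohol", "beverage", "food", "nutrient")
}

#' @rdname cardiometabolic_traits
#' @export
fasting_adjusted_traits <- function() {
  c("glucose_fasting", "glucose_2h", "cholesterol_total",
    "triglycerides", "hdl", "ldl")
}

lipid_traits <- function() {
  c("cholesterol_total", "triglycerides", "hdl", "ldl")
}

bp_traits <- function() c("sbp", "dbp")

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop_field(field, "must be non-negative")
  invisible(x)
}

check_cols <- function(table, cols, what = "column") {
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop(sprintf("%s not found in cohort table: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
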