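# Average-association screen: one random-intercept model per exposure x
# trait. The covariate set follows the screening protocol: age, age^2, sex,
# educational level and follow-up time always; FFQ version and total energy
# intake for dietary exposures; BMI except when BMI is the outcome; fasting
# status for glycaemic and lipid outcomes. Dietary numeric exposures enter
# as their energy residuals with total energy intake alongside.

# Build the per-exposure term matrix (inverse-normalized values, energy
# residuals for dietary numerics, dummy set for categoricals) once; reused
# across all traits.
prepare_exposure_terms <- function(table, catalog) {
  out <- vector("list", nrow(catalog))
  names(out) <- catalog$exposure
  for (i in seq_len(nrow(catalog))) {
    ex <- catalog$exposure[i]
    if (!ex %in% names(table)) next
    dietary <- catalog$category[i] %in% dietary_categories()
    v <- table[[ex]]
    if (catalog$type[i] == "categorical") {
      mat <- tryCatch(encode_categorical(v, name = ex),
                      error = function(e) conditionMessage(e))
    } else if (dietary && "tei" %in% names(table)) {
      mat <- tryCatch({
        r <- energy_adjust(v, table$tei)
        matrix(r, ncol = 1, dimnames = list(NULL, ex))
      }, error = function(e) conditionMessage(e))
    } else {
      mat <- matrix(v, ncol = 1, dimnames = list(NULL, ex))
    }
    out[[i]] <- list(mat = mat, dietary = dietary,
                     category = catalog$category[i], parent = ex)
  }
  out
}

# Covariate matrix for one trait under the average-association protocol.
average_covariates <- function(table, trait) {
  age_c <- table$age - mean(table$age, na.rm = TRUE)
  X <- cbind(`(Intercept)` = 1, age = age_c, age2 = age_c^2,
             sex = table$sex, education = table$education,
             followup_time = table$followup_time)
  if (trait != "bmi" && "bmi" %in% names(table))
    X <- cbind(X, bmi = table$bmi)
  if (trait %in% fasting_adjusted_traits() && "fasting" %in% names(table))
    X <- cbind(X, fasting = table$fasting)
  X
}

screen_row <- function(term, parent, category, trait, mode,
                       estimate = NA_real_, se = NA_real_, p = NA_real_,
                       n_obs = NA_integer_, n_participants = NA_integer_,
                       var_explained = NA_real_, status = "ok") {
  data.frame(exposure = term, parent_variable = parent, category = category,
             trait = trait, mode = mode, estimate = estimate, se = se, p = p,
             n_obs = n_obs, n_participants = n_participants,
             var_explained = var_explained, status = status,
             stringsAsFactors = FALSE)
}

#' Screen all exposures against traits with the random-intercept model
#'
#' Fits one REML random-intercept model per exposure x trait on complete
#' cases and returns one result row per exposure term (per dummy indicator
#' for categorical exposures): estimate, standard error, Wald p-value,
#' sample sizes and the term's marginal variance explained. Per-model
#' failures (rank deficiency, too few cases) are recorded in the row's
#' `status` and never abort the screen.
#'
#' @param clean Harmonized cohort table, or an `exposcan_harmonized` object
#'   (in which case `catalog` is taken from it).
#' @param catalog Exposure catalog.
#' @param traits Trait names to screen; defaults to the nine cardiometabolic
#'   traits present in the table.
#' @param min_n Minimum complete cases per model.
#' @return Data frame of class `exposcan_screen` with mode `"average"`.
#' @export
screen_average <- function(clean, catalog = NULL, traits = NULL,
                           min_n = 50L) {
  if (inherits(clean, "exposcan_harmonized")) {
    if (is.null(catalog)) catalog <- clean$catalog
    clean <- clean$table
  }
  stopifnot(!is.null(catalog))
  check_cols(clean, c("participant_id", "age", "sex", "education"))
  if (is.null(traits))
    traits <- intersect(cardiometabolic_traits(), names(clean))
  clean$followup_time <-
    clean$age - ave(clean$age, clean$participant_id, FUN = min)
  terms <- prepare_exposure_terms(clean, catalog)
  dietary_cov <- cbind(ffq_version = clean$ffq_version, tei = clean$tei)
  groups <- clean$participant_id

  rows <- vector("list", length(traits) * length(terms))
  k <- 0L
  for (trait in traits) {
    y <- clean[[trait]]
    Xbase <- average_covariates(clean, trait)
    for (ex in names(terms)) {
      info <- terms[[ex]]
      k <- k + 1L
      if (is.null(info)) next
      if (is.character(info$mat)) {
        rows[[k]] <- screen_row(ex, ex, info$category, trait, "average",
                                status = info$mat)
        next
      }
      X <- if (info$dietary) cbind(Xbase, dietary_cov, info$mat)
           else cbind(Xbase, info$mat)
      cc <- !is.na(y) & rowSums(is.na(X)) == 0L
      term_names <- colnames(info$mat)
      if (sum(cc) < min_n || length(unique(groups[cc])) < 2L) {
        rows[[k]] <- screen_row(term_names, ex, info$category, trait,
                                "average", status = "too few complete cases")
        next
      }
      fit <- tryCatch(fit_random_intercept(y[cc], X[cc, , drop = FALSE],
                                           groups[cc]),
                      error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        rows[[k]] <- screen_row(term_names, ex, info$category, trait,
                                "average", status = fit)
        next
      }
      Xcc <- X[cc, , drop = FALSE]
      rows[[k]] <- screen_row(
        term_names, ex, info$category, trait, "average",
        estimate = unname(fit$coefficients[term_names]),
        se = unname(fit$se[term_names]),
        p = vapply(term_names, function(tn) wald_pvalue(fit, tn), 0),
        n_obs = fit$n_obs, n_participants = fit$n_groups,
        var_explained = vapply(term_names, function(tn)
          term_variance_explained(fit, Xcc, tn), 0))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("exposcan_screen", "data.frame")
  out
}

#' Write screen results
#'
#' Persists a screen-result table with its fixed column order as CSV and,
#' optionally, JSON.
#'
#' @param results An `exposcan_screen` data frame.
#' @param path_csv CSV output path.
#' @param path_json Optional JSON output path.
#' @return The results, invisibly.
#' @export
write_screen_results <- function(results, path_csv, path_json = NULL) {
  cols <- c("exposure", "parent_variable", "category", "trait", "mode",
            "estimate", "se", "p", "n_obs", "n_participants",
            "var_explained", "status")
  utils::write.csv(results[, cols], path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(results[, cols], path_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(results)
}
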