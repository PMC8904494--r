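# Long-term (10-year) association screen: baseline/follow-up visit pairs and
# a baseline-adjusted linear regression of the follow-up trait value on the
# baseline exposure. Covariates: baseline age and age^2, sex, follow-up time,
# the baseline trait value, FFQ version and total energy intake at baseline
# for dietary exposures, the mean of baseline and follow-up BMI (omitted when
# BMI is the outcome), and baseline/follow-up fasting status for glycaemic
# and lipid outcomes. Educational level is not part of this model's
# covariate set (in contrast with the average-association model).

#' Build ~10-year baseline/follow-up visit pairs
#'
#' At most one pair per participant: the baseline is the first visit having
#' any later visit whose gap lies within `target_years` +/-
#' `tolerance_years`; the follow-up is the later visit minimizing
#' `|gap - target_years|` (ties to the earlier visit). Participants without
#' an eligible pair are dropped. The paired table carries every baseline
#' column plus `<trait>_followup` for each trait, `fasting_followup`,
#' `followup_time` (years) and `mean_bmi` (average of baseline and follow-up
#' BMI, missing when either is).
#'
#' @param clean Harmonized cohort table with an `age` column.
#' @param target_years Target inter-visit gap (years).
#' @param tolerance_years Half-width of the admissible gap window.
#' @param traits Trait columns to carry at follow-up.
#' @return Data frame of pairs; zero rows when no participant qualifies.
#' @export
build_pairs <- function(clean, target_years = 10, tolerance_years = 2,
                        traits = NULL) {
  check_cols(clean, c("participant_id", "age"))
  if (is.null(traits))
    traits <- intersect(cardiometabolic_traits(), names(clean))
  ord <- order(clean$participant_id, clean$age)
  clean <- clean[ord, , drop = FALSE]
  idx_by_p <- split(seq_len(nrow(clean)), clean$participant_id)

  pick <- function(ii) {
    if (length(ii) < 2) return(NULL)
    ages <- clean$age[ii]
    for (b in seq_len(length(ii) - 1L)) {
      gaps <- ages[-seq_len(b)] - ages[b]
      ok <- which(abs(gaps - target_years) <= tolerance_years)
      if (length(ok)) {
        f <- ok[which.min(abs(gaps[ok] - target_years))]
        return(c(ii[b], ii[b + f]))
      }
    }
    NULL
  }
  pairs <- Filter(Negate(is.null), lapply(idx_by_p, pick))
  if (!length(pairs)) {
    out <- clean[0, , drop = FALSE]
    out$followup_time <- numeric(0)
    return(out)
  }
  ib <- vapply(pairs, `[`, 0L, 1L)
  jf <- vapply(pairs, `[`, 0L, 2L)
  out <- clean[ib, , drop = FALSE]
  rownames(out) <- NULL
  out$followup_time <- clean$age[jf] - clean$age[ib]
  for (tr in traits)
    out[[paste0(tr, "_followup")]] <- clean[[tr]][jf]
  if ("fasting" %in% names(clean))
    out$fasting_followup <- clean$fasting[jf]
  if ("bmi" %in% names(clean))
    out$mean_bmi <- (clean$bmi[ib] + clean$bmi[jf]) / 2
  out
}

change_design <- function(pairs, trait, dietary) {
  age_c <- pairs$age - mean(pairs$age, na.rm = TRUE)
  X <- cbind(age_b = age_c, age_b2 = age_c^2, sex = pairs$sex,
             followup_time = pairs$followup_time,
             trait_baseline = pairs[[trait]])
  if (dietary) {
    if ("ffq_version" %in% names(pairs))
      X <- cbind(X, ffq_version_b = pairs$ffq_version)
    if ("tei" %in% names(pairs)) X <- cbind(X, tei_b = pairs$tei)
  }
  if (trait != "bmi" && "mean_bmi" %in% names(pairs))
    X <- cbind(X, mean_bmi = pairs$mean_bmi)
  if (trait %in% fasting_adjusted_traits()) {
    if ("fasting" %in% names(pairs)) X <- cbind(X, fasting_b = pairs$fasting)
    if ("fasting_followup" %in% names(pairs))
      X <- cbind(X, fasting_f = pairs$fasting_followup)
  }
  X
}

#' Fit the baseline-adjusted 10-year change regression
#'
#' Ordinary least squares (QR decomposition via [stats::lm()]) of the
#' follow-up trait value on the baseline exposure and the change-model
#' covariate set; the exposure p-value uses the t reference with residual
#' degrees of freedom.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param exposure Exposure column name (baseline values), or a matrix of
#'   exposure term columns (e.g. a dummy set).
#' @param trait Trait name; the outcome is `<trait>_followup`.
#' @param dietary Add baseline FFQ version and total energy intake.
#' @return List of class `exposcan_change_fit`: coefficient table
#'   (`estimate`, `se`, `t`, `p`), `sigma2`, `df`, `n`, `r_squared`.
#' @export
fit_change_model <- function(pairs, exposure, trait, dietary = FALSE) {
  ycol <- paste0(trait, "_followup")
  check_cols(pairs, ycol, "follow-up trait column")
  expo <- if (is.matrix(exposure)) exposure
          else matrix(pairs[[exposure]], ncol = 1,
                      dimnames = list(NULL, exposure))
  X <- cbind(`(Intercept)` = 1, change_design(pairs, trait, dietary), expo)
  y <- pairs[[ycol]]
  cc <- !is.na(y) & rowSums(is.na(X)) == 0L
  if (sum(cc) < ncol(X) + 2L)
    stop("too few complete pairs for the change model", call. = FALSE)
  ols_qr(y[cc], X[cc, , drop = FALSE])
}

# OLS through the QR decomposition with t-based inference.
ols_qr <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    dep <- colnames(X)[fit$qr$pivot[seq.int(fit$rank + 1L, ncol(X))]]
    stop(sprintf("change-model design is rank deficient: %s",
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  n <- length(y)
  df <- n - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  piv <- fit$qr$pivot
  xtx_inv <- matrix(0, ncol(X), ncol(X))
  xtx_inv[piv, piv] <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(xtx_inv))
  b <- fit$coefficients[colnames(X)]
  tval <- b / se
  tab <- cbind(estimate = b, se = se, t = tval,
               p = 2 * stats::pt(-abs(tval), df))
  rownames(tab) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = tab, sigma2 = sigma2, df = df, n = n,
                 r_squared = 1 - rss / tss, residuals = fit$residuals,
                 y = y, X = X),
            class = "exposcan_change_fit")
}

#' @export
print.exposcan_change_fit <- function(x, ...) {
  cat(sprintf("Change regression: n = %d pairs, df = %d, R^2 = %.4f\n",
              x$n, x$df, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Screen exposures against 10-year trait changes
#'
#' Runs [fit_change_model()] for every exposure x trait on the pair table
#' and returns the same result schema as [screen_average()] with mode
#' `"change"`. Variance explained is the semi-partial R-squared: the drop in
#' the model R-squared when the exposure column(s) are removed. Dietary
#' numeric exposures enter as baseline energy residuals with baseline total
#' energy intake as a covariate.
#'
#' @param clean Harmonized cohort table or `exposcan_harmonized`.
#' @param catalog Exposure catalog.
#' @param traits Trait names; defaults to those present.
#' @param target_years,tolerance_years Pairing window, see [build_pairs()].
#' @param min_n Minimum complete pairs per model.
#' @return Data frame of class `exposcan_screen` with mode `"change"`.
#' @export
screen_change <- function(clean, catalog = NULL, traits = NULL,
                          target_years = 10, tolerance_years = 2,
                          min_n = 30L) {
  if (inherits(clean, "exposcan_harmonized")) {
    if (is.null(catalog)) catalog <- clean$catalog
    clean <- clean$table
  }
  stopifnot(!is.null(catalog))
  if (is.null(traits))
    traits <- intersect(cardiometabolic_traits(), names(clean))
  pairs <- build_pairs(clean, target_years, tolerance_years, traits)
  if (!nrow(pairs)) {
    out <- screen_row(catalog$exposure, catalog$exposure, catalog$category,
                      traits[1] %||% NA_character_, "change",
                      status = "no eligible baseline/follow-up pairs")
    class(out) <- c("exposcan_screen", "data.frame")
    return(out)
  }
  terms <- prepare_exposure_terms(pairs, catalog)

  rows <- list()
  for (trait in traits) {
    for (ex in names(terms)) {
      info <- terms[[ex]]
      if (is.null(info)) next
      key <- paste(trait, ex)
      if (is.character(info$mat)) {
        rows[[key]] <- screen_row(ex, ex, info$category, trait, "change",
                                  status = info$mat)
        next
      }
      term_names <- colnames(info$mat)
      res <- tryCatch({
        fit <- fit_change_model(pairs, info$mat, trait, info$dietary)
        # semi-partial R^2 per exposure term: R^2 drop on refit without it
        tss <- sum((fit$y - mean(fit$y))^2)
        sr2 <- vapply(term_names, function(tn) {
          Xr <- fit$X[, colnames(fit$X) != tn, drop = FALSE]
          r2_red <- 1 - sum(stats::lm.fit(Xr, fit$y)$residuals^2) / tss
          max(0, fit$r_squared - r2_red)
        }, 0)
        tab <- fit$coefficients[term_names, , drop = FALSE]
        screen_row(term_names, ex, info$category, trait, "change",
                   estimate = tab[, "estimate"], se = tab[, "se"],
                   p = tab[, "p"], n_obs = fit$n,
                   n_participants = fit$n,
                   var_explained = sr2)
      }, error = function(e)
        screen_row(term_names, ex, info$category, trait, "change",
                   status = conditionMessage(e)))
      rows[[key]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exposcan_screen", "data.frame")
  out
}
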