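# Cohort harmonization: participant-level exclusions, medication corrections,
# derived traits (BMI, Friedewald LDL, food intake level), plausibility and
# dietary-quality filtering, rank-based inverse-normal transformation, dummy
# coding, dominance filtering and energy-residual adjustment.

#' Harmonization configuration
#'
#' Defaults are the published medication-correction constants and screening
#' thresholds: +0.208 mmol/L triglycerides, +1.347 mmol/L total cholesterol,
#' -0.060 mmol/L HDL, +1.290 mmol/L LDL for lipid-lowering medication and
#' +15 / +10 mmHg for systolic / diastolic blood pressure under
#' antihypertensive medication; a 10\% FFQ-missingness limit; food-intake-level
#' (FIL) plausibility cut-offs at the bottom 5\% and top 2.5\% of the input
#' distribution; and a 90\% single-level dominance threshold for categorical
#' exposures. The trait plausibility ranges are package defaults (broad
#' physiological bounds), not published values, and should be overridden with
#' study-specific ranges where available.
#'
#' @param medication_constants Named additive constants per trait.
#' @param trait_normal_ranges Named list of `c(low, high)` plausibility bounds.
#' @param ffq_missing_limit Maximum tolerated FFQ missingness (proportion).
#' @param fil_lower_pct,fil_upper_pct FIL percentile cut-offs; the upper one
#'   counts from the top of the distribution.
#' @param dominance_threshold Modal-level frequency at or above which a
#'   categorical exposure is dropped (inclusive boundary).
#' @param exclusion_flags Boolean cohort columns that exclude a participant.
#' @param conversion_maps Optional named list of `c(slope, intercept)` linear
#'   maps applied to traits measured before an instrument change (era given
#'   by `conversion_before_year` on the `year` column).
#' @param conversion_before_year Calendar year before which the conversion
#'   maps apply.
#' @param recompute_ldl Overwrite existing LDL values with the Friedewald
#'   estimate (otherwise only missing values are filled).
#' @param inv_normal_offset Rank offset of the inverse-normal transform
#'   (3/8 = Blom).
#' @return A list of class `exposcan_harmonize_config`.
#' @export
harmonize_config <- function(medication_constants =
                               c(triglycerides = 0.208,
                                 cholesterol_total = 1.347,
                                 hdl = -0.060, ldl = 1.290,
                                 sbp = 15, dbp = 10),
                             trait_normal_ranges = list(
                               bmi = c(12, 60), sbp = c(70, 250),
                               dbp = c(40, 140), glucose_fasting = c(2, 20),
                               glucose_2h = c(2, 25),
                               cholesterol_total = c(1.5, 12),
                               triglycerides = c(0.2, 15),
                               hdl = c(0.3, 4), ldl = c(0.5, 10)),
                             ffq_missing_limit = 0.10,
                             fil_lower_pct = 5,
                             fil_upper_pct = 2.5,
                             dominance_threshold = 0.90,
                             exclusion_flags = c("diabetes", "cvd",
                                                 "nonref_origin"),
                             conversion_maps = NULL,
                             conversion_before_year = 2009,
                             recompute_ldl = FALSE,
                             inv_normal_offset = 3 / 8) {
  unknown <- setdiff(names(medication_constants),
                     c(lipid_traits(), bp_traits()))
  if (length(unknown))
    stop_field("medication_constants",
               paste("unknown trait key(s):", paste(unknown, collapse = ", ")))
  for (tr in names(trait_normal_ranges)) {
    r <- trait_normal_ranges[[tr]]
    if (length(r) != 2L || !(r[1] < r[2]))
      stop_field("trait_normal_ranges", sprintf("'%s' needs low < high", tr))
  }
  check_prob(ffq_missing_limit, "ffq_missing_limit")
  if (fil_lower_pct <= 0 || fil_lower_pct >= 100)
    stop_field("fil_lower_pct", "percentile must lie in (0, 100)")
  if (fil_upper_pct <= 0 || fil_upper_pct >= 100)
    stop_field("fil_upper_pct", "percentile must lie in (0, 100)")
  if (dominance_threshold <= 0.5 || dominance_threshold > 1)
    stop_field("dominance_threshold", "must lie in (0.5, 1]")
  structure(list(medication_constants = medication_constants,
                 trait_normal_ranges = trait_normal_ranges,
                 ffq_missing_limit = ffq_missing_limit,
                 fil_lower_pct = fil_lower_pct,
                 fil_upper_pct = fil_upper_pct,
                 dominance_threshold = dominance_threshold,
                 exclusion_flags = exclusion_flags,
                 conversion_maps = conversion_maps,
                 conversion_before_year = conversion_before_year,
                 recompute_ldl = recompute_ldl,
                 inv_normal_offset = inv_normal_offset),
            class = "exposcan_harmonize_config")
}

## ---- exclusion log ---------------------------------------------------------

new_exclusion_log <- function() {
  structure(list(entries = data.frame(rule = character(0),
                                      unit = character(0),
                                      count = integer(0),
                                      stringsAsFactors = FALSE),
                 records = list()),
            class = "exposcan_exclusion_log")
}

log_add <- function(log, rule, unit, count, records = NULL) {
  log$entries <- rbind(log$entries,
                       data.frame(rule = rule, unit = unit,
                                  count = as.integer(count),
                                  stringsAsFactors = FALSE))
  if (!is.null(records)) log$records[[rule]] <- records
  log
}

#' @export
print.exposcan_exclusion_log <- function(x, ...) {
  cat("Exclusion log:\n")
  if (!nrow(x$entries)) cat("  (no exclusions)\n")
  else for (i in seq_len(nrow(x$entries)))
    cat(sprintf("  %-28s %-12s %d\n", x$entries$rule[i],
                paste0("[", x$entries$unit[i], "]"), x$entries$count[i]))
  invisible(x)
}

#' Write an exclusion log as JSON and text
#' @param log An exclusion log from the harmonization stage.
#' @param path_json,path_txt Output paths (either may be `NULL` to skip).
#' @return The log, invisibly.
#' @export
write_exclusion_log <- function(log, path_json = NULL, path_txt = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(list(entries = log$entries, records = log$records),
                         path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w"); on.exit(close(con))
    writeLines(utils::capture.output(print(log)), con)
  }
  invisible(log)
}

## ---- operations ------------------------------------------------------------

#' Exclude flagged participants
#'
#' Removes every visit of any participant carrying a true exclusion flag at
#' any visit (prevalent disease, non-reference origin, ...). The rule acts at
#' the participant level: one flagged visit removes the whole participant.
#'
#' @param table Cohort table (long format).
#' @param config A [harmonize_config()].
#' @param log An existing exclusion log to append to.
#' @return List with `table` and `log`.
#' @export
apply_exclusions <- function(table, config = harmonize_config(),
                             log = new_exclusion_log()) {
  check_cols(table, config$exclusion_flags, "exclusion flag column")
  check_cols(table, "participant_id")
  for (flag in config$exclusion_flags) {
    flagged <- unique(table$participant_id[!is.na(table[[flag]]) &
                                             table[[flag]] != 0])
    log <- log_add(log, flag, "participant", length(flagged), flagged)
    if (length(flagged))
      table <- table[!(table$participant_id %in% flagged), , drop = FALSE]
  }
  list(table = table, log = log)
}

#' Correct trait values for medication use
#'
#' Adds the published constants to lipid traits of visits with the
#' lipid-medication flag set and to blood-pressure traits of visits with the
#' antihypertensive flag set; unflagged visits are untouched.
#'
#' @param table Cohort table.
#' @param constants Named additive constants (trait -> constant); keys must
#'   be lipid or blood-pressure traits.
#' @return The corrected table.
#' @export
correct_medication <- function(table,
                               constants = harmonize_config()$medication_constants) {
  unknown <- setdiff(names(constants), c(lipid_traits(), bp_traits()))
  if (length(unknown))
    stop(sprintf("medication constants name unknown trait(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (tr in names(constants)) {
    if (!tr %in% names(table)) next
    flag_col <- if (tr %in% lipid_traits()) "lipid_med" else "bp_med"
    check_cols(table, flag_col, "medication flag column")
    on_med <- !is.na(table[[flag_col]]) & table[[flag_col]] != 0
    table[[tr]][on_med] <- table[[tr]][on_med] + constants[[tr]]
  }
  table
}

#' Anthropometric and lipid formulas
#'
#' `bmi_from_anthropometry` is weight (kg) over squared height (m);
#' `friedewald_ldl` estimates LDL cholesterol as total cholesterol minus HDL
#' minus triglycerides / 2.2 (all mmol/L); `schofield_bmr` is the Schofield
#' sex- and age-band basal-metabolic-rate equation (kcal/day) used as the
#' default denominator of the food intake level.
#'
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @param tc,hdl,tg Total cholesterol, HDL and triglycerides (mmol/L).
#' @param sex 1 = male, 0 = female.
#' @param age Age in years.
#' @return Numeric vector.
#' @export
bmi_from_anthropometry <- function(weight, height) {
  height <- ifelse(!is.na(height) & height <= 0, NA, height)
  weight / (height / 100)^2
}

#' @rdname bmi_from_anthropometry
#' @export
friedewald_ldl <- function(tc, hdl, tg) tc - hdl - tg / 2.2

#' @rdname bmi_from_anthropometry
#' @export
schofield_bmr <- function(sex, age, weight) {
  male <- !is.na(sex) & sex == 1
  band <- findInterval(age, c(30, 60))  # 0: 18-30, 1: 30-60, 2: >60
  slope <- ifelse(male, c(15.057, 11.472, 11.711)[band + 1L],
                  c(14.818, 8.126, 9.082)[band + 1L])
  inter <- ifelse(male, c(692.2, 873.1, 587.7)[band + 1L],
                  c(486.6, 845.6, 658.5)[band + 1L])
  slope * weight + inter
}

#' Derive BMI, Friedewald LDL and food intake level
#'
#' Fills `bmi` from weight/height, `ldl` from the Friedewald formula and
#' `fil` (food intake level) as total energy intake over basal metabolic
#' rate wherever the inputs are present. Existing non-missing LDL values are
#' only overwritten when `recompute_ldl` is set; records with non-positive
#' height or BMR are set missing for the affected value.
#'
#' @param table Cohort table.
#' @param recompute_ldl Overwrite existing LDL with the Friedewald estimate.
#' @param bmr_column Optional column holding a precomputed BMR; otherwise the
#'   Schofield equation is used on `sex`, `age`, `weight`.
#' @return The table with derived columns filled.
#' @export
derive_traits <- function(table, recompute_ldl = FALSE, bmr_column = NULL) {
  if (all(c("weight", "height") %in% names(table))) {
    bmi <- bmi_from_anthropometry(table$weight, table$height)
    if (!"bmi" %in% names(table)) table$bmi <- bmi
    else table$bmi[is.na(table$bmi)] <- bmi[is.na(table$bmi)]
  }
  if (all(c("cholesterol_total", "hdl", "triglycerides") %in% names(table))) {
    ldl <- friedewald_ldl(table$cholesterol_total, table$hdl,
                          table$triglycerides)
    if (!"ldl" %in% names(table)) table$ldl <- ldl
    else if (recompute_ldl) table$ldl <- ldl
    else table$ldl[is.na(table$ldl)] <- ldl[is.na(table$ldl)]
  }
  if ("tei" %in% names(table)) {
    bmr <- if (!is.null(bmr_column)) {
      check_cols(table, bmr_column, "BMR column")
      table[[bmr_column]]
    } else if (all(c("sex", "age", "weight") %in% names(table))) {
      schofield_bmr(table$sex, table$age, table$weight)
    } else NULL
    if (!is.null(bmr)) {
      bmr[!is.na(bmr) & bmr <= 0] <- NA
      table$fil <- table$tei / bmr
    }
  }
  table
}

#' Apply instrument-era conversion maps
#'
#' Aligns trait values measured before an instrument change with later
#' measurements through user-supplied linear maps `new = slope * old +
#' intercept`, applied to visits with `year < conversion_before_year`.
#'
#' @param table Cohort table with a `year` column.
#' @param config A [harmonize_config()] carrying `conversion_maps`.
#' @return The aligned table (unchanged when no maps are configured).
#' @export
apply_conversion_maps <- function(table, config = harmonize_config()) {
  maps <- config$conversion_maps
  if (is.null(maps) || !length(maps)) return(table)
  check_cols(table, "year")
  era <- !is.na(table$year) & table$year < config$conversion_before_year
  for (tr in names(maps)) {
    check_cols(table, tr, "conversion-map trait")
    m <- maps[[tr]]
    table[[tr]][era] <- m[[1]] * table[[tr]][era] + m[[2]]
  }
  table
}

#' Plausibility and dietary-quality filtering
#'
#' Two families of cell/visit-level filters: trait values outside their
#' configured plausibility range are set missing (outliers), and visits
#' failing any dietary-quality rule (FFQ missingness above the limit, any
#' portion indication missing, or food intake level in the implausible tails
#' of the input FIL distribution) have all dietary exposure values set
#' missing.
#'
#' @param table Cohort table (after trait derivation).
#' @param catalog Exposure catalog identifying dietary columns.
#' @param config A [harmonize_config()].
#' @param log Exclusion log to append to.
#' @return List with `table` and `log`.
#' @export
filter_records <- function(table, catalog, config = harmonize_config(),
                           log = new_exclusion_log()) {
  for (tr in names(config$trait_normal_ranges)) {
    if (!tr %in% names(table)) next
    r <- config$trait_normal_ranges[[tr]]
    bad <- !is.na(table[[tr]]) & (table[[tr]] <= r[1] | table[[tr]] >= r[2])
    log <- log_add(log, paste0("range_", tr), "cell", sum(bad))
    table[[tr]][bad] <- NA
  }
  dietary <- intersect(catalog$exposure[catalog$category %in%
                                          dietary_categories()],
                       names(table))
  fail <- rep(FALSE, nrow(table))
  if ("ffq_missing_frac" %in% names(table)) {
    bad <- !is.na(table$ffq_missing_frac) &
      table$ffq_missing_frac > config$ffq_missing_limit
    log <- log_add(log, "ffq_missingness", "visit", sum(bad))
    fail <- fail | bad
  }
  if ("portion_missing" %in% names(table)) {
    bad <- !is.na(table$portion_missing) & table$portion_missing != 0
    log <- log_add(log, "portion_missing", "visit", sum(bad))
    fail <- fail | bad
  }
  if ("fil" %in% names(table)) {
    lo <- stats::quantile(table$fil, config$fil_lower_pct / 100, na.rm = TRUE)
    hi <- stats::quantile(table$fil, 1 - config$fil_upper_pct / 100,
                          na.rm = TRUE)
    bad <- !is.na(table$fil) & (table$fil < lo | table$fil > hi)
    log <- log_add(log, "fil_implausible", "visit", sum(bad))
    fail <- fail | bad
  }
  if (length(dietary) && any(fail))
    table[fail, dietary] <- NA
  if (length(dietary))
    log <- log_add(log, "dietary_quality_visits", "visit", sum(fail))
  list(table = table, log = log)
}

#' Rank-based inverse-normal transformation
#'
#' Maps non-missing values to standard-normal quantiles of offset ranks,
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default; ties receive their average rank and therefore equal output.
#' The transform addresses skewness and puts all numeric exposures on a
#' comparable scale.
#'
#' @param values Numeric vector, possibly with missing entries.
#' @param offset Rank offset `c` (3/8 = Blom, 1/2 = van der Waerden-like,
#'   1/3 = Tukey).
#' @return Transformed vector of the same length; missing stays missing.
#' @export
inverse_normal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2)
    stop("inverse_normal needs at least 2 non-missing values", call. = FALSE)
  v <- values[ok]
  if (max(v) == min(v))
    stop("inverse_normal undefined for a constant vector", call. = FALSE)
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Dummy-code a categorical exposure
#'
#' Builds the `k - 1` indicator columns of a categorical variable with `k`
#' observed levels, harmonized low to high with the lowest level as
#' reference. Column names are `<name>::<level>`; the parent variable and
#' reference level are carried as attributes.
#'
#' @param values Vector of level codes (numeric or character).
#' @param levels Optional ordered level list; defaults to the sorted observed
#'   levels.
#' @param name Parent variable name used in the indicator names.
#' @return Numeric matrix with one column per non-reference level.
#' @export
encode_categorical <- function(values, levels = NULL, name = "x") {
  obs <- sort(unique(values[!is.na(values)]))
  if (is.null(levels)) levels <- obs
  levels <- levels[levels %in% obs]
  if (length(levels) < 2)
    stop(sprintf("categorical '%s' has fewer than 2 observed levels", name),
         call. = FALSE)
  ref <- levels[1]
  out <- vapply(levels[-1], function(l) as.numeric(values == l),
                numeric(length(values)))
  colnames(out) <- paste0(name, "::", levels[-1])
  attr(out, "parent") <- name
  attr(out, "reference") <- ref
  out
}

#' Drop single-level-dominated categorical exposures
#'
#' Removes from the catalog every categorical exposure whose modal level
#' holds at least `threshold` of the non-missing observations (inclusive
#' boundary); such near-constant variables carry almost no contrast to test.
#' Numeric and ordinal exposures are untouched.
#'
#' @param catalog Exposure catalog.
#' @param table Cohort table with the exposure columns.
#' @param threshold Dominance threshold in (0.5, 1].
#' @param log Exclusion log to append to.
#' @return List with `catalog` and `log`.
#' @export
drop_dominated <- function(catalog, table, threshold = 0.90,
                           log = new_exclusion_log()) {
  if (threshold <= 0.5 || threshold > 1)
    stop("dominance threshold must lie in (0.5, 1]", call. = FALSE)
  cats <- catalog$exposure[catalog$type == "categorical"]
  dropped <- character(0)
  for (ex in intersect(cats, names(table))) {
    v <- table[[ex]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    if (max(table(v)) / length(v) >= threshold) dropped <- c(dropped, ex)
  }
  log <- log_add(log, "dominated_categorical", "exposure", length(dropped),
                 dropped)
  list(catalog = catalog[!(catalog$exposure %in% dropped), , drop = FALSE],
       log = log)
}

#' Energy-residual adjustment of a dietary variable
#'
#' Regresses a dietary variable on total energy intake (with intercept) and
#' returns the residuals, which are uncorrelated with energy intake by
#' least-squares orthogonality; in the screening models the residual enters
#' together with total energy intake itself.
#'
#' @param dietary Numeric dietary variable.
#' @param tei Total energy intake, same length.
#' @return Residual vector; pairs with either value missing stay missing.
#' @export
energy_adjust <- function(dietary, tei) {
  if (length(dietary) != length(tei))
    stop("dietary and tei must have equal length", call. = FALSE)
  ok <- !is.na(dietary) & !is.na(tei)
  if (sum(ok) < 3)
    stop("energy_adjust needs at least 3 complete pairs", call. = FALSE)
  if (max(tei[ok]) == min(tei[ok]))
    stop("energy_adjust undefined for constant energy intake", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, tei[ok]), dietary[ok])
  out <- rep(NA_real_, length(dietary))
  out[ok] <- fit$residuals
  out
}

#' Run the full harmonization pipeline
#'
#' Applies, in order: participant-level flag exclusions, instrument-era
#' conversion maps, medication corrections, trait derivation (BMI, Friedewald
#' LDL, food intake level), plausibility and dietary-quality filters, the
#' dominance filter on categorical exposures, and the inverse-normal
#' transform of numeric and ordinal exposures (ordinal integer codes are
#' treated as continuous). Exposures left constant or nearly empty after
#' filtering are dropped and logged.
#'
#' @param table Raw cohort table.
#' @param catalog Exposure catalog.
#' @param config A [harmonize_config()].
#' @return A list of class `exposcan_harmonized` with `table` (analysis-ready
#'   cohort), `catalog` (surviving exposures) and `log` (exclusion log).
#' @export
harmonize_cohort <- function(table, catalog, config = harmonize_config()) {
  log <- new_exclusion_log()
  step <- apply_exclusions(table, config, log)
  table <- step$table; log <- step$log
  table <- apply_conversion_maps(table, config)
  table <- correct_medication(table, config$medication_constants)
  table <- derive_traits(table, recompute_ldl = config$recompute_ldl)
  step <- filter_records(table, catalog, config, log)
  table <- step$table; log <- step$log
  step <- drop_dominated(catalog, table, config$dominance_threshold, log)
  catalog <- step$catalog; log <- step$log

  numericish <- catalog$exposure[catalog$type %in% c("numeric", "ordinal")]
  unusable <- character(0)
  for (ex in intersect(numericish, names(table))) {
    v <- table[[ex]]
    ok <- !is.na(v)
    if (sum(ok) < 2 || max(v[ok]) == min(v[ok])) {
      unusable <- c(unusable, ex)
      next
    }
    table[[ex]] <- inverse_normal(v, config$inv_normal_offset)
  }
  if (length(unusable)) {
    log <- log_add(log, "unusable_numeric", "exposure", length(unusable),
                   unusable)
    catalog <- catalog[!(catalog$exposure %in% unusable), , drop = FALSE]
  }
  structure(list(table = table, catalog = catalog, log = log,
                 config = config),
            class = "exposcan_harmonized")
}

#' @export
print.exposcan_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized cohort: %d visits, %d participants, %d exposures\n",
              nrow(x$table), length(unique(x$table$participant_id)),
              nrow(x$catalog)))
  print(x$log)
  invisible(x)
}
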