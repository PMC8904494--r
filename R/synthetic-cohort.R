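# Synthetic longitudinal cohort generator.
#
# Emulates the design of a repeated-measures health survey in which adults are
# examined around their 30th, 40th, 50th and 60th birthdays: 1-3 visits per
# participant spaced ~10 years apart, nine correlated cardiometabolic traits
# with participant-level random intercepts, and a block-correlated panel of
# lifestyle exposures in ten categories with planted exposure->trait effects
# providing ground truth for every downstream stage.

default_exposures_per_category <- function() {
  c(alcohol = 8L, beverage = 10L, food = 60L, nutrient = 60L,
    general_health = 30L, physical_activity = 40L, psychosocial = 30L,
    sleep = 10L, social = 18L, tobacco = 20L)
}

# Trait-level generating constants: population mean, per-year age slope and
# male-vs-female shift (means roughly those of a middle-aged Scandinavian
# screening cohort).
default_trait_model <- function() {
  traits <- cardiometabolic_traits()
  means <- c(bmi = 25.7, sbp = 126, dbp = 79, glucose_fasting = 5.4,
             glucose_2h = 6.6, cholesterol_total = 5.5, triglycerides = 1.4,
             hdl = 1.4, ldl = 3.9)
  age_slopes <- c(bmi = 0.10, sbp = 0.50, dbp = 0.20, glucose_fasting = 0.010,
                  glucose_2h = 0.030, cholesterol_total = 0.020,
                  triglycerides = 0.010, hdl = 0.000, ldl = 0.020)
  sex_effects <- c(bmi = 0.3, sbp = 4, dbp = 3, glucose_fasting = 0.15,
                   glucose_2h = -0.2, cholesterol_total = 0.1,
                   triglycerides = 0.3, hdl = -0.25, ldl = 0.25)
  list(means = means[traits], age_slopes = age_slopes[traits],
       sex_effects = sex_effects[traits])
}

#' Configuration for the synthetic-cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults emulate
#' the target study design: ~2.2 visits per participant at ages drawn from
#' \{30, 40, 50, 60\} with +/- 1 year of jitter, 286 exposures spread over the
#' ten lifestyle categories with within-category block correlation, a mix of
#' numeric, ordinal and categorical exposures (some categoricals dominated by
#' a single level), medication and exclusion flags, and completely-at-random
#' missingness on exposure cells.
#'
#' @param n_participants Number of participants.
#' @param visit_count_probs Probabilities of 1, 2 and 3 visits (sums to 1).
#' @param visit_spacing_years Mean inter-visit gap in years (the survey's
#'   decade grid) .
#' @param visit_jitter_years Half-width of the uniform jitter on visit ages.
#' @param n_exposures_per_category Named integer vector over the ten
#'   categories from [exposure_categories()].
#' @param exposure_block_correlation Within-category latent correlation,
#'   in \[0, 1).
#' @param categorical_fraction Proportion of exposures generated as
#'   categorical (by thresholding the latent normal).
#' @param ordinal_fraction Proportion of exposures generated as ordinal
#'   integer scores.
#' @param dominance_fraction Proportion of categorical exposures built so one
#'   level holds >= 90\% of observations (exercises the dominance filter).
#' @param planted_effects Data frame with columns `exposure`, `trait`,
#'   `slope`: standardized slopes, in outcome standard deviations (total:
#'   intercept plus residual) per standard deviation of the exposure's
#'   latent scale. `NULL` for a fully null cohort.
#' @param random_intercept_sd_per_trait,residual_sd_per_trait Named numeric
#'   vectors of the participant-intercept and visit-residual standard
#'   deviations per trait.
#' @param trait_intercept_cor Correlation of participant intercepts across
#'   traits (shared-factor construction).
#' @param medication_prevalence Named probabilities `lipid` and `bp` of the
#'   medication flags.
#' @param exclusion_prevalence Named probabilities of the participant-level
#'   exclusion flags (`diabetes`, `cvd`, `nonref_origin`).
#' @param missing_rate Per-cell missingness probability on exposure columns.
#' @param tei_coupling Correlation path between total energy intake and
#'   dietary-category latents (so energy adjustment has something to remove).
#' @param seed Integer RNG seed.
#' @return A list of class `exposcan_generator_config`.
#' @export
generator_config <- function(n_participants = 1000L,
                             visit_count_probs = c(0.25, 0.35, 0.40),
                             visit_spacing_years = 10,
                             visit_jitter_years = 1,
                             n_exposures_per_category =
                               default_exposures_per_category(),
                             exposure_block_correlation = 0.30,
                             categorical_fraction = 0.25,
                             ordinal_fraction = 0.15,
                             dominance_fraction = 0.45,
                             planted_effects = NULL,
                             random_intercept_sd_per_trait = NULL,
                             residual_sd_per_trait = NULL,
                             trait_intercept_cor = 0.30,
                             medication_prevalence = c(lipid = 0.03, bp = 0.08),
                             exclusion_prevalence = c(diabetes = 0.02,
                                                      cvd = 0.02,
                                                      nonref_origin = 0.16),
                             missing_rate = 0.05,
                             tei_coupling = 0.30,
                             seed = 1L) {
  traits <- cardiometabolic_traits()
  if (is.null(random_intercept_sd_per_trait))
    random_intercept_sd_per_trait <-
      c(bmi = 3.5, sbp = 12, dbp = 8, glucose_fasting = 0.50,
        glucose_2h = 1.0, cholesterol_total = 0.80, triglycerides = 0.50,
        hdl = 0.35, ldl = 0.75)[traits]
  if (is.null(residual_sd_per_trait))
    residual_sd_per_trait <-
      c(bmi = 1.5, sbp = 12, dbp = 8, glucose_fasting = 0.55,
        glucose_2h = 1.1, cholesterol_total = 0.70, triglycerides = 0.60,
        hdl = 0.30, ldl = 0.70)[traits]

  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 1)
    stop_field("n_participants", "must be a positive count")
  check_prob(visit_count_probs, "visit_count_probs")
  if (length(visit_count_probs) != 3L ||
      abs(sum(visit_count_probs) - 1) > 1e-8)
    stop_field("visit_count_probs",
               "must be 3 probabilities over {1,2,3} visits summing to 1")
  check_nonneg(visit_spacing_years, "visit_spacing_years")
  check_nonneg(visit_jitter_years, "visit_jitter_years")
  if (!all(sort(names(n_exposures_per_category)) ==
           sort(exposure_categories())))
    stop_field("n_exposures_per_category",
               "must be named by the ten exposure categories")
  if (any(n_exposures_per_category < 0))
    stop_field("n_exposures_per_category", "counts must be non-negative")
  if (!is.numeric(exposure_block_correlation) ||
      exposure_block_correlation < 0 || exposure_block_correlation >= 1)
    stop_field("exposure_block_correlation", "must lie in [0, 1)")
  check_prob(categorical_fraction, "categorical_fraction")
  check_prob(ordinal_fraction, "ordinal_fraction")
  if (categorical_fraction + ordinal_fraction > 1)
    stop_field("categorical_fraction",
               "categorical_fraction + ordinal_fraction must be <= 1")
  check_prob(dominance_fraction, "dominance_fraction")
  check_prob(medication_prevalence, "medication_prevalence")
  check_prob(exclusion_prevalence, "exclusion_prevalence")
  check_prob(missing_rate, "missing_rate")
  check_prob(trait_intercept_cor, "trait_intercept_cor")
  check_nonneg(random_intercept_sd_per_trait, "random_intercept_sd_per_trait")
  check_nonneg(residual_sd_per_trait, "residual_sd_per_trait")
  if (!all(traits %in% names(random_intercept_sd_per_trait)))
    stop_field("random_intercept_sd_per_trait", "must cover all nine traits")
  if (!all(traits %in% names(residual_sd_per_trait)))
    stop_field("residual_sd_per_trait", "must cover all nine traits")

  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    check_cols(planted_effects, c("exposure", "trait", "slope"),
               "planted_effects column")
    schema <- exposure_schema(n_exposures_per_category)
    bad <- setdiff(planted_effects$exposure, schema$exposure)
    if (length(bad))
      stop_field("planted_effects",
                 paste("unknown exposure(s):", paste(bad, collapse = ", ")))
    bad <- setdiff(planted_effects$trait, traits)
    if (length(bad))
      stop_field("planted_effects",
                 paste("unknown trait(s):", paste(bad, collapse = ", ")))
  }

  cfg <- list(
    n_participants = as.integer(n_participants),
    visit_count_probs = visit_count_probs,
    visit_spacing_years = visit_spacing_years,
    visit_jitter_years = visit_jitter_years,
    n_exposures_per_category = n_exposures_per_category,
    exposure_block_correlation = exposure_block_correlation,
    categorical_fraction = categorical_fraction,
    ordinal_fraction = ordinal_fraction,
    dominance_fraction = dominance_fraction,
    planted_effects = planted_effects,
    random_intercept_sd_per_trait = random_intercept_sd_per_trait,
    residual_sd_per_trait = residual_sd_per_trait,
    trait_intercept_cor = trait_intercept_cor,
    medication_prevalence = medication_prevalence,
    exclusion_prevalence = exclusion_prevalence,
    missing_rate = missing_rate,
    tei_coupling = tei_coupling,
    trait_model = default_trait_model(),
    seed = as.integer(seed))
  class(cfg) <- "exposcan_generator_config"
  cfg
}

# Deterministic exposure naming and type/modifiability assignment implied by
# the per-category counts (independent of the RNG so planted effects can be
# validated before any simulation).
exposure_schema <- function(n_per_category) {
  cats <- exposure_categories()
  n_per_category <- n_per_category[cats]
  data.frame(
    exposure = unlist(lapply(cats, function(cc) {
      n <- n_per_category[[cc]]
      if (n == 0L) character(0)
      else sprintf("%s_%02d", cc, seq_len(n))
    }), use.names = FALSE),
    category = rep(cats, n_per_category),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Simulates a participant-visit table, its exposure catalog and the true
#' planted effect matrix. Trait values follow a random-intercept model: fixed
#' covariate terms (age, sex) plus the planted exposure effects on the
#' standardized latent exposure scale, a participant intercept and a visit
#' residual. Exposures within a category share a latent common factor giving
#' the configured block correlation; categorical and ordinal exposures are
#' obtained by thresholding their latent normals so the correlation structure
#' survives discretization. Identical seeds give identical output.
#'
#' @param config A [generator_config()].
#' @return A list of class `exposcan_cohort_sim` with elements `cohort`
#'   (data frame, one row per participant-visit), `catalog` (exposure
#'   metadata: name, category, type, modifiable, n_levels) and `truth`
#'   (class `exposcan_true_effects`: `effect_matrix` exposures x traits,
#'   `null_set`, `cross_trait_set`).
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "exposcan_generator_config"))
    config <- do.call(generator_config, config)
  set.seed(config$seed)
  traits <- cardiometabolic_traits()
  np <- config$n_participants

  ## participant level
  pid <- sprintf("P%06d", seq_len(np))
  sex <- rbinom(np, 1L, 0.5)                       # 1 = male
  education <- sample(1:4, np, TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  diabetes <- rbinom(np, 1L, config$exclusion_prevalence[["diabetes"]])
  cvd <- rbinom(np, 1L, config$exclusion_prevalence[["cvd"]])
  nonref <- rbinom(np, 1L, config$exclusion_prevalence[["nonref_origin"]])
  n_visits <- sample(1:3, np, TRUE, prob = config$visit_count_probs)
  # first examination decade chosen so all visits fit inside 30..60
  start_slot <- vapply(n_visits, function(k) sample.int(5L - k, 1L), 1L)
  baseline_year <- sample(1990:2004, np, TRUE)

  ## visit level
  row_pid <- rep(seq_len(np), n_visits)
  visit_no <- sequence(n_visits)
  slot <- start_slot[row_pid] + visit_no - 1L
  n <- length(row_pid)
  age <- 30 + (slot - 1L) * config$visit_spacing_years +
    runif(n, -config$visit_jitter_years, config$visit_jitter_years)
  first_age <- ave(age, row_pid, FUN = min)
  year <- baseline_year[row_pid] + round(age - first_age)
  ffq_version <- ifelse(year < 1996, 1L, 2L)
  fasting <- rbinom(n, 1L, 0.90)
  lipid_med <- rbinom(n, 1L, config$medication_prevalence[["lipid"]])
  bp_med <- rbinom(n, 1L, config$medication_prevalence[["bp"]])

  ## energy intake scaffold: FIL (food intake level) drives the latent used
  ## to couple dietary exposures to total energy intake
  fil <- exp(rnorm(n, log(1.55), 0.18))
  z_fil <- as.numeric(scale(log(fil)))
  ffq_missing_frac <- runif(n)^4 * 0.35            # mostly near zero
  portion_missing <- rbinom(n, 1L, 0.03)

  ## exposures: block-correlated latents, thresholded by declared type
  schema <- exposure_schema(config$n_exposures_per_category)
  m <- nrow(schema)
  rho <- config$exposure_block_correlation
  stability <- 0.5                                  # within-person share
  u_expo <- matrix(rnorm(np * m), np, m)            # participant component
  latents <- matrix(0, n, m)
  k_tei <- config$tei_coupling
  for (cc in exposure_categories()) {
    idx <- which(schema$category == cc)
    if (!length(idx)) next
    g <- rnorm(n)                                   # category common factor
    if (cc %in% dietary_categories())
      g <- k_tei * z_fil + sqrt(1 - k_tei^2) * g
    for (j in idx) {
      own <- sqrt(stability) * u_expo[row_pid, j] +
        sqrt(1 - stability) * rnorm(n)
      latents[, j] <- sqrt(rho) * g + sqrt(1 - rho) * own
    }
  }
  colnames(latents) <- schema$exposure

  ## type assignment: within each category the tail exposures are ordinal
  ## then categorical, deterministically from the configured fractions
  type <- rep("numeric", m)
  n_levels <- rep(NA_integer_, m)
  dominated <- rep(FALSE, m)
  for (cc in exposure_categories()) {
    idx <- which(schema$category == cc)
    mc <- length(idx)
    if (!mc) next
    n_cat <- round(config$categorical_fraction * mc)
    n_ord <- round(config$ordinal_fraction * mc)
    if (n_cat + n_ord > mc) n_ord <- mc - n_cat
    if (n_ord > 0) type[idx[seq.int(mc - n_cat - n_ord + 1, mc - n_cat)]] <- "ordinal"
    if (n_cat > 0) {
      cat_idx <- idx[seq.int(mc - n_cat + 1, mc)]
      type[cat_idx] <- "categorical"
      n_dom <- round(config$dominance_fraction * n_cat)
      if (n_dom > 0) dominated[cat_idx[seq_len(n_dom)]] <- TRUE
    }
  }

  expo_obs <- matrix(NA_real_, n, m, dimnames = list(NULL, schema$exposure))
  for (j in seq_len(m)) {
    z <- latents[, j]
    expo_obs[, j] <- switch(
      type[j],
      numeric = z,
      ordinal = {
        n_levels[j] <- 5L
        findInterval(z, qnorm(c(0.15, 0.40, 0.70, 0.90))) + 1L
      },
      categorical = {
        k <- 2L + (j %% 3L)                         # 2..4 levels
        n_levels[j] <- k
        if (dominated[j]) {
          # one level absorbs ~92% of the mass
          cuts <- qnorm(cumsum(c(0.92, rep(0.08 / (k - 1), k - 2))))
        } else {
          cuts <- qnorm(seq_len(k - 1) / k)
        }
        findInterval(z, cuts) + 1L
      })
  }

  ## traits: covariates + planted effects + random intercepts + residuals
  tm <- config$trait_model
  eff <- matrix(0, m, length(traits),
                dimnames = list(schema$exposure, traits))
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe))
    eff[cbind(match(pe$exposure, schema$exposure),
              match(pe$trait, traits))] <- pe$slope
  c_ri <- config$trait_intercept_cor
  shared_f <- rnorm(np)
  trait_vals <- matrix(NA_real_, n, length(traits),
                       dimnames = list(NULL, traits))
  planted_part <- latents %*% eff                  # effects act on latents
  for (t in seq_along(traits)) {
    tr <- traits[t]
    # planted slopes are standardized: outcome SDs (total, intercept +
    # residual) per SD of the latent exposure scale
    sd_tot <- sqrt(config$random_intercept_sd_per_trait[[tr]]^2 +
                     config$residual_sd_per_trait[[tr]]^2)
    u <- config$random_intercept_sd_per_trait[[tr]] *
      (sqrt(c_ri) * shared_f + sqrt(1 - c_ri) * rnorm(np))
    e <- rnorm(n, 0, config$residual_sd_per_trait[[tr]])
    trait_vals[, t] <- tm$means[[tr]] +
      tm$age_slopes[[tr]] * (age - 45) +
      tm$sex_effects[[tr]] * sex[row_pid] +
      sd_tot * planted_part[, t] + u[row_pid] + e
  }

  ## anthropometry consistent with the BMI trait, then energy intake
  height <- ifelse(sex[row_pid] == 1L, rnorm(np, 178, 7)[row_pid],
                   rnorm(np, 165, 6)[row_pid])
  weight <- trait_vals[, "bmi"] * (height / 100)^2
  bmr <- schofield_bmr(sex[row_pid], age, weight)
  tei <- fil * bmr

  ## missingness (completely at random) on exposure cells
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n * m) < config$missing_rate, n, m)
    expo_obs[drop] <- NA
  }

  cohort <- data.frame(
    participant_id = pid[row_pid], visit = visit_no, age = age, year = year,
    sex = sex[row_pid], education = education[row_pid],
    diabetes = diabetes[row_pid], cvd = cvd[row_pid],
    nonref_origin = nonref[row_pid],
    fasting = fasting, ffq_version = ffq_version,
    lipid_med = lipid_med, bp_med = bp_med,
    height = height, weight = weight, tei = tei, fil = fil,
    ffq_missing_frac = ffq_missing_frac, portion_missing = portion_missing,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(trait_vals),
                  as.data.frame(expo_obs))

  catalog <- schema
  catalog$type <- type
  catalog$n_levels <- n_levels
  # health-status and social-circumstance items are partly outside the reach
  # of an intervention; flag a deterministic share non-modifiable
  catalog$modifiable <- TRUE
  for (cc in c(general_health = "general_health", social = "social")) {
    idx <- which(catalog$category == cc)
    nm <- round(length(idx) * if (cc == "general_health") 0.4 else 0.5)
    if (nm > 0) catalog$modifiable[idx[seq_len(nm)]] <- FALSE
  }

  nz <- rowSums(eff != 0)
  truth <- structure(list(
    effect_matrix = eff,
    null_set = rownames(eff)[nz == 0],
    cross_trait_set = rownames(eff)[nz >= 5]),
    class = "exposcan_true_effects")

  structure(list(cohort = cohort, catalog = catalog, truth = truth,
                 config = config),
            class = "exposcan_cohort_sim")
}

#' @export
print.exposcan_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d visits, %d participants, %d exposures (%d planted)\n",
    nrow(x$cohort), length(unique(x$cohort$participant_id)),
    nrow(x$catalog), sum(x$truth$effect_matrix != 0)))
  invisible(x)
}

#' Simulate a labelled p-value panel for FDR calibration
#'
#' Generates `m` two-sided p-values of which `round(frac_nonnull * m)` come
#' from shifted-mean z-statistics (`z ~ N(nonnull_mean_z, 1)`) and the rest
#' from the standard normal null, together with the true labels. Used to
#' measure the false-discovery proportion of the tentative-signal rule.
#'
#' @param m Number of tests.
#' @param frac_nonnull Proportion of non-null tests (count rounded to nearest,
#'   ties to even).
#' @param nonnull_mean_z Mean of the non-null z-statistics.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `p` and `nonnull` (logical).
#' @export
generate_pvalue_panel <- function(m, frac_nonnull, nonnull_mean_z, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("m must be a positive count", call. = FALSE)
  check_prob(frac_nonnull, "frac_nonnull")
  m <- as.integer(m)
  set.seed(as.integer(seed))
  n1 <- as.integer(round(frac_nonnull * m))
  nonnull <- c(rep(FALSE, m - n1), rep(TRUE, n1))
  z <- rnorm(m, mean = ifelse(nonnull, nonnull_mean_z, 0), sd = 1)
  data.frame(p = 2 * pnorm(-abs(z)), nonnull = nonnull)
}

#' Write and read cohort artifacts
#'
#' Plain-text persistence for the simulated (or real) inputs: the cohort and
#' catalog as UTF-8 CSV with a header row, and the true-effect labels as JSON.
#'
#' @param sim A `exposcan_cohort_sim`, or individual tables.
#' @param dir Output directory (created if absent).
#' @return `write_cohort_sim` returns the written paths invisibly.
#' @export
write_cohort_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             catalog = file.path(dir, "catalog.csv"),
             truth = file.path(dir, "true_effects.json"))
  utils::write.csv(sim$cohort, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(sim$catalog, paths[["catalog"]], row.names = FALSE)
  jsonlite::write_json(
    list(effect_matrix = as.data.frame(sim$truth$effect_matrix),
         exposures = rownames(sim$truth$effect_matrix),
         null_set = sim$truth$null_set,
         cross_trait_set = sim$truth$cross_trait_set),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_cohort_sim
#' @param path CSV file path.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_cohort_sim
#' @export
read_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(cat, c("exposure", "category", "type", "modifiable"),
             "catalog column")
  cat
}
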