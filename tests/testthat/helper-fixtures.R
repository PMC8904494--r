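# Shared fixtures: small generator configurations built in code.

# Single-exposure cohort for parameter-recovery checks: one physical
# activity exposure, unit intercept and residual SDs on every trait,
# everyone with exactly `visits` visits, no missingness.
slope_recovery_config <- function(n = 2000L, slope = 0.5, trait = "bmi",
                                  visits = 2L, seed = 1L) {
  n_expo <- setNames(rep(0L, 10), exposure_categories())
  n_expo["physical_activity"] <- 1L
  vis <- c(0, 0, 0); vis[visits] <- 1
  generator_config(
    n_participants = n,
    visit_count_probs = vis,
    n_exposures_per_category = n_expo,
    categorical_fraction = 0, ordinal_fraction = 0,
    planted_effects = data.frame(exposure = "physical_activity_01",
                                 trait = trait, slope = slope),
    random_intercept_sd_per_trait =
      setNames(rep(1, 9), cardiometabolic_traits()),
    residual_sd_per_trait = setNames(rep(1, 9), cardiometabolic_traits()),
    missing_rate = 0,
    exclusion_prevalence = c(diabetes = 0, cvd = 0, nonref_origin = 0),
    seed = seed)
}

# Design matrix of the average-association model for one trait, built from a
# generated cohort (complete cases), plus outcome and groups.
average_model_frame <- function(cohort, trait, exposure) {
  fut <- cohort$age - ave(cohort$age, cohort$participant_id, FUN = min)
  age_c <- cohort$age - mean(cohort$age)
  X <- cbind(`(Intercept)` = 1, age = age_c, age2 = age_c^2,
             sex = cohort$sex, education = cohort$education,
             followup_time = fut, exposure = cohort[[exposure]])
  if (trait != "bmi") X <- cbind(X, bmi = cohort$bmi)
  cc <- !is.na(cohort[[trait]]) & rowSums(is.na(X)) == 0
  list(y = cohort[[trait]][cc], X = X[cc, , drop = FALSE],
       groups = cohort$participant_id[cc])
}

# Brute-force step-up FDR adjustment straight from the definition: sort the
# p-values, take for each order statistic the explicit minimum of m * p_(j) / j
# over all j at or above it (double loop), cap at 1, map back.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
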