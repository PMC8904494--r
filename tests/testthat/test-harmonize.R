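toy_cohort <- function() {
  data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), each = 2),
    visit = rep(1:2, 10), age = rep(c(40, 50), 10),
    sex = rep(c(0, 1), each = 10), education = 2,
    diabetes = rep(c(1, 1, rep(0, 8)), each = 2),
    cvd = 0, nonref_origin = 0,
    lipid_med = 0, bp_med = 0,
    sbp = 120, triglycerides = 1.0,
    stringsAsFactors = FALSE)
}

test_that("flagged participants lose every visit and the log counts them", {
  d <- toy_cohort()
  out <- apply_exclusions(d, harmonize_config())
  expect_identical(length(unique(out$table$participant_id)), 8L)
  e <- out$log$entries
  expect_identical(e$count[e$rule == "diabetes"], 2L)
  expect_identical(e$unit[e$rule == "diabetes"], "participant")

  # flag at a single visit removes the whole participant
  d2 <- toy_cohort()
  d2$diabetes <- 0
  d2$diabetes[d2$participant_id == "P03" & d2$visit == 2] <- 1
  out2 <- apply_exclusions(d2, harmonize_config())
  expect_false("P03" %in% out2$table$participant_id)
  expect_identical(nrow(out2$table), 18L)

  # no flags: unchanged, all counts zero
  d3 <- toy_cohort(); d3$diabetes <- 0
  out3 <- apply_exclusions(d3, harmonize_config())
  expect_identical(out3$table, d3)
  expect_true(all(out3$log$entries$count == 0L))

  expect_error(apply_exclusions(d[, setdiff(names(d), "cvd")],
                                harmonize_config()), "cvd")
})

test_that("medication correction adds the published constants once", {
  d <- data.frame(participant_id = "P1", lipid_med = 1, bp_med = 1,
                  triglycerides = 1.0, cholesterol_total = 5.0,
                  hdl = 1.5, ldl = 3.0, sbp = 120, dbp = 80)
  out <- correct_medication(d)
  expect_equal(out$triglycerides, 1.208)
  expect_equal(out$cholesterol_total, 6.347)
  expect_equal(out$hdl, 1.440)
  expect_equal(out$ldl, 4.290)
  expect_equal(out$sbp, 135)
  expect_equal(out$dbp, 90)

  # unflagged records untouched
  d$lipid_med <- 0; d$bp_med <- 0
  expect_identical(correct_medication(d), d)

  # correcting again with flags cleared equals correcting once
  once <- out
  once$lipid_med <- 0; once$bp_med <- 0
  expect_identical(correct_medication(once), once)

  expect_error(correct_medication(d, constants = c(bmi = 1)), "bmi")
})

test_that("derived traits follow the BMI, Friedewald and FIL definitions", {
  expect_equal(bmi_from_anthropometry(81, 180), 25.0)
  expect_equal(friedewald_ldl(5.0, 1.0, 2.2), 3.0)
  expect_equal(friedewald_ldl(4.1, 0, 0), 4.1)

  d <- data.frame(weight = c(81, 70), height = c(180, -1),
                  cholesterol_total = 5.0, hdl = 1.0, triglycerides = 2.2,
                  tei = 2400, bmr = c(1600, 0))
  out <- derive_traits(d, bmr_column = "bmr")
  expect_equal(out$bmi[1], 25.0)
  expect_true(is.na(out$bmi[2]))          # non-positive height
  expect_equal(out$ldl, c(3.0, 3.0))
  expect_equal(out$fil[1], 1.5)
  expect_true(is.na(out$fil[2]))          # non-positive BMR

  # existing LDL kept unless recompute is requested
  d$ldl <- c(2.5, NA)
  expect_equal(derive_traits(d, bmr_column = "bmr")$ldl, c(2.5, 3.0))
  expect_equal(derive_traits(d, recompute_ldl = TRUE,
                             bmr_column = "bmr")$ldl, c(3.0, 3.0))
})

test_that("plausibility and dietary-quality filters blank the right cells", {
  catalog <- data.frame(exposure = c("food_01", "sleep_01"),
                        category = c("food", "sleep"),
                        type = "numeric", modifiable = TRUE)
  d <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                  sbp = c(400, 120, 118, 121),
                  ffq_missing_frac = c(0, 0.12, 0.01, 0.02),
                  portion_missing = 0,
                  food_01 = 1:4, sleep_01 = 1:4)
  out <- filter_records(d, catalog, harmonize_config())
  expect_true(is.na(out$table$sbp[1]))
  expect_false(anyNA(out$table$sbp[-1]))
  expect_true(is.na(out$table$food_01[2]))    # dietary cell blanked
  expect_equal(out$table$sleep_01, 1:4)        # non-dietary untouched
  e <- out$log$entries
  expect_identical(e$count[e$rule == "range_sbp"], 1L)
  expect_identical(e$count[e$rule == "ffq_missingness"], 1L)

  # all records inside every limit: nothing changes
  d2 <- d; d2$sbp <- 120; d2$ffq_missing_frac <- 0
  out2 <- filter_records(d2, catalog, harmonize_config())
  expect_identical(out2$table, d2)
})

test_that("cell-level filters commute: rule order never changes the table", {
  catalog <- data.frame(exposure = "food_01", category = "food",
                        type = "numeric", modifiable = TRUE)
  d <- data.frame(participant_id = sprintf("P%02d", 1:6),
                  sbp = c(400, 120, 118, 121, 60, 130),
                  ffq_missing_frac = c(0, 0.2, 0, 0.3, 0, 0),
                  portion_missing = 0, food_01 = rnorm(6))
  range_only <- harmonize_config(ffq_missing_limit = 1)
  diet_only <- harmonize_config(trait_normal_ranges = list())
  both <- filter_records(d, catalog, harmonize_config())$table
  ab <- filter_records(filter_records(d, catalog, range_only)$table,
                       catalog, diet_only)$table
  ba <- filter_records(filter_records(d, catalog, diet_only)$table,
                       catalog, range_only)$table
  expect_identical(ab, both)
  expect_identical(ba, both)
})

test_that("FIL percentile cut-offs blank the implausible dietary tails", {
  catalog <- data.frame(exposure = "food_01", category = "food",
                        type = "numeric", modifiable = TRUE)
  set.seed(1)
  d <- data.frame(participant_id = sprintf("P%03d", 1:200),
                  fil = c(sort(runif(200, 1, 2))),
                  food_01 = rnorm(200))
  out <- filter_records(d, catalog, harmonize_config())
  # bottom 5% and top 2.5% blanked
  expect_true(all(is.na(out$table$food_01[1:9])))
  expect_true(all(is.na(out$table$food_01[197:200])))
  expect_false(anyNA(out$table$food_01[30:150]))
})

test_that("inverse-normal transform matches Blom quantiles and rank symmetry", {
  expect_equal(inverse_normal(c(1, 5, 9)), c(-0.8694, 0, 0.8694),
               tolerance = 1e-4)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(inverse_normal(rev(x)), rev(inverse_normal(x)))
  expect_equal(inverse_normal(-x), -inverse_normal(x))
  # strictly monotone transforms leave the output unchanged
  expect_equal(inverse_normal(exp(x)), inverse_normal(x))
  # ties share a value; missing propagates; mean is centred
  y <- inverse_normal(c(2, 2, 7, NA))
  expect_equal(y[1], y[2])
  expect_true(is.na(y[4]))
  expect_lt(abs(mean(inverse_normal(x))), 1e-10)
  expect_error(inverse_normal(c(3, 3, 3)), "constant")
  expect_error(inverse_normal(c(1, NA, NA)), "2 non-missing")
})

test_that("dummy coding uses the lowest level as reference", {
  x <- c(1, 3, 2, 3, NA, 1)
  m <- encode_categorical(x, name = "smoke")
  expect_identical(colnames(m), c("smoke::2", "smoke::3"))
  expect_identical(attr(m, "reference"), 1)
  expect_identical(attr(m, "parent"), "smoke")
  expect_equal(m[2, ], c(`smoke::2` = 0, `smoke::3` = 1))
  expect_equal(m[3, ], c(`smoke::2` = 1, `smoke::3` = 0))
  expect_true(all(is.na(m[5, ])))
  expect_identical(ncol(encode_categorical(c(0, 1, 0), name = "b")), 1L)
  expect_error(encode_categorical(c(2, 2, 2), name = "const"), "const")
})

test_that("dominance filter drops categoricals at the inclusive 90% boundary", {
  catalog <- data.frame(
    exposure = c("a", "b", "c", "n"),
    category = "tobacco",
    type = c("categorical", "categorical", "categorical", "numeric"),
    modifiable = TRUE)
  d <- data.frame(a = rep(c(1, 2), c(91, 9)),
                  b = rep(c(1, 2), c(50, 50)),
                  c = rep(c(1, 2), c(90, 10)),
                  n = rep(c(1, 2), c(95, 5)))
  out <- drop_dominated(catalog, d, 0.90)
  expect_identical(out$catalog$exposure, c("b", "n"))  # numeric untouched
  expect_identical(
    out$log$entries$count[out$log$entries$rule == "dominated_categorical"],
    2L)
})

test_that("energy residuals are orthogonal to energy intake", {
  tei <- runif(200, 1500, 3500)
  expect_equal(energy_adjust(2 * tei, tei), rep(0, 200), tolerance = 1e-10)

  set.seed(2)
  tei2 <- runif(10000, 1500, 3500)
  diet <- rnorm(10000, sd = 2)            # independent of energy intake
  r <- energy_adjust(diet, tei2)
  expect_lt(abs(cor(r, tei2)), 1e-10)
  expect_lt(abs(var(r) / var(diet) - 1), 0.02)
  expect_lt(abs(mean(r)), 1e-10)

  # missing pairs propagate; degenerate inputs error
  d3 <- c(1, NA, 3, 4, 5, 6); t3 <- c(2000, 2100, NA, 2300, 2400, 2500)
  expect_identical(which(is.na(energy_adjust(d3, t3))), c(2L, 3L))
  expect_error(energy_adjust(1:5, rep(2000, 5)), "constant")
  expect_error(energy_adjust(1:2, c(1, 2)), "3 complete pairs")
})

test_that("harmonize_cohort reconciles exclusion counts with table sizes", {
  sim <- generate_cohort(generator_config(n_participants = 150L, seed = 21L))
  h <- harmonize_cohort(sim$cohort, sim$catalog)
  e <- h$log$entries
  excluded <- sum(e$count[e$unit == "participant"])
  expect_identical(length(unique(sim$cohort$participant_id)) -
                     length(unique(h$table$participant_id)), excluded)
  # surviving numeric exposures are inverse-normalized: centred, symmetric
  num <- h$catalog$exposure[h$catalog$type == "numeric"][1]
  expect_lt(abs(mean(h$table[[num]], na.rm = TRUE)), 0.05)
  # dominated categoricals are gone from the catalog
  dropped <- h$log$records$dominated_categorical
  expect_false(any(dropped %in% h$catalog$exposure))
})
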