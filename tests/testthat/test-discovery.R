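test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_true(is.na(bh_adjust(c(0.5, NA))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment matches brute force and the reference implementation", {
  set.seed(71)
  for (r in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)          # rounding forces ties
    ours <- bh_adjust(p)
    expect_equal(ours, bh_bruteforce(p))
    expect_equal(ours, p.adjust(p, method = "BH"))
  }
})

fake_results <- function(p, trait = "bmi", mode = "average",
                         exposure = NULL, category = "food", ve = NULL) {
  n <- length(p)
  exposure <- exposure %||% sprintf("e%02d", seq_len(n))
  data.frame(exposure = exposure, parent_variable = exposure,
             category = category, trait = trait, mode = mode,
             estimate = 1, se = 1, p = p, n_obs = 100L,
             n_participants = 50L,
             var_explained = if (is.null(ve)) rev(seq_len(n)) / (2 * n)
                             else ve,
             status = "ok", stringsAsFactors = FALSE)
}

test_that("tentative flags use strict inequality per trait-mode family", {
  res <- rbind(fake_results(c(0.049, 0.051), trait = "bmi"),
               fake_results(c(0.001, 0.2), trait = "sbp"))
  sig <- call_signals(res, alpha = 0.05)
  # singleton-free families: 2 tests per trait, adjusted within family
  expect_identical(sig$family_size, rep(2L, 4))
  expect_equal(sig$p_fdr[1], 0.051)       # min(2*0.049/1, 2*0.051/2)
  expect_false(sig$tentative[1])
  expect_true(sig$tentative[3])           # 0.002 < 0.05
  # exactly at the level: not flagged
  one <- call_signals(fake_results(0.05), alpha = 0.05)
  expect_false(one$tentative)
  expect_identical(nrow(call_signals(fake_results(0.5)[0, ])), 0L)
})

test_that("the false-discovery proportion stays controlled on null panels", {
  fdp <- vapply(1:100, function(r) {
    panel <- generate_pvalue_panel(200, 0.15, 3, seed = 7000 + r)
    adj <- bh_adjust(panel$p)
    disc <- adj < 0.05
    sum(disc & !panel$nonnull) / max(1, sum(disc))
  }, 0)
  expect_lte(mean(fdp), 0.05)
})

test_that("ranking collapses dummies and keeps the top-k by variance explained", {
  res <- fake_results(rep(0.001, 7), ve = c(0.05, 0.04, 0.06, 0.01,
                                            0.02, 0.03, 0.015))
  sig <- call_signals(res)
  top <- rank_and_select(sig, top_k = 5)
  expect_identical(nrow(top), 5L)
  expect_identical(top$variable[1], "e03")        # highest variance explained
  expect_equal(top$var_explained, sort(top$var_explained, decreasing = TRUE))
  expect_false(any(c("e04", "e07") %in% top$variable))

  # two dummies of one parent collapse to the larger variance explained
  res2 <- fake_results(c(0.001, 0.001), exposure = c("smk::2", "smk::3"),
                       ve = c(0.02, 0.05))
  res2$parent_variable <- "smk"
  top2 <- rank_and_select(call_signals(res2), top_k = 5)
  expect_identical(nrow(top2), 1L)
  expect_identical(top2$variable, "smk")
  expect_equal(top2$var_explained, 0.05)

  # no tentative signals: empty set
  empty <- rank_and_select(call_signals(fake_results(rep(0.9, 4))), 5)
  expect_identical(nrow(empty), 0L)
})

test_that("prioritization needs both trait consistency and modifiability", {
  catalog <- data.frame(exposure = c("pa", "gh", "few"),
                        category = "physical_activity",
                        type = "numeric",
                        modifiable = c(TRUE, FALSE, TRUE))
  traits9 <- cardiometabolic_traits()
  tops <- rbind(
    data.frame(mode = "average", trait = traits9[1:5], category = "pa",
               variable = "pa", var_explained = 0.02, p = 0.001, rank = 1L),
    data.frame(mode = "average", trait = traits9[1:6], category = "gh",
               variable = "gh", var_explained = 0.02, p = 0.001, rank = 1L),
    data.frame(mode = "average", trait = traits9[1:4], category = "pa",
               variable = "few", var_explained = 0.02, p = 0.001, rank = 2L))
  rep5 <- prioritize(tops, min_traits = 5, catalog = catalog)
  expect_identical(rep5$prioritized$variable, "pa")
  excl <- rep5$candidates[!rep5$candidates$modifiable, ]
  expect_identical(excl$variable, "gh")
  expect_identical(excl$reason, "non-modifiable")
  expect_false("few" %in% rep5$candidates$variable)   # only 4 traits

  # invariant to row order of the top sets
  rep5b <- prioritize(tops[sample(nrow(tops)), ], 5, catalog)
  expect_identical(rep5$candidates, rep5b$candidates)
})

test_that("correlation matrices are symmetric, unit-diagonal and masked", {
  d <- data.frame(a = c(1, 2, 3, 4, NA, NA),
                  b = -c(1, 2, 3, 4, NA, NA),
                  c = c(NA, NA, NA, NA, 1, 2))
  R <- correlation_matrix(d, c("a", "b", "c"))
  expect_equal(R["a", "a"], 1)
  expect_equal(R["a", "b"], -1)
  expect_true(is.na(R["a", "c"]))         # never co-observed 3+ times
  expect_identical(R, t(R))
  expect_error(correlation_matrix(d, "a"), "2 variables")
})

test_that("average-linkage clustering on 1 - r recovers planted blocks", {
  set.seed(73)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  d <- data.frame(
    a1 = sqrt(0.9) * f1 + sqrt(0.1) * rnorm(n),
    a2 = sqrt(0.9) * f1 + sqrt(0.1) * rnorm(n),
    b1 = sqrt(0.9) * f2 + sqrt(0.1) * rnorm(n),
    b2 = sqrt(0.9) * f2 + sqrt(0.1) * rnorm(n))
  R <- correlation_matrix(d, names(d))
  cl <- hcluster(R, k = 2)
  expect_identical(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_identical(cl$clusters[["b1"]], cl$clusters[["b2"]])
  expect_false(cl$clusters[["a1"]] == cl$clusters[["b1"]])
  # leaves of a block sit adjacent in the leaf order
  ord <- cl$labels[cl$order]
  expect_equal(abs(diff(match(c("a1", "a2"), ord))), 1)

  # identical variables merge first at height ~0
  d$a3 <- d$a1
  R2 <- correlation_matrix(d, c("a1", "a3", "b1"))
  cl2 <- hcluster(R2)
  expect_lt(cl2$heights[1], 1e-12)

  skip_if_not_installed("ape")
  nwk <- dendrogram_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
})
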