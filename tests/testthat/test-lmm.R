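intercept_only <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

test_that("REML matches the closed-form estimators on balanced one-way layouts", {
  set.seed(101)
  for (rep in 1:10) {
    g <- sample(5:25, 1)          # groups
    m <- sample(2:6, 1)           # replicates per group
    su <- runif(1, 0.5, 3); se <- runif(1, 0.5, 3)
    grp <- rep(seq_len(g), each = m)
    y <- rnorm(g, 0, su)[grp] + rnorm(g * m, 0, se)
    fit <- fit_random_intercept(y, intercept_only(g * m), grp)
    gm <- tapply(y, grp, mean)
    msw <- sum((y - gm[grp])^2) / (g * (m - 1))
    msb <- m * sum((gm - mean(y))^2) / (g - 1)
    expect_equal(fit$sigma_e2, msw, tolerance = 1e-6)
    expect_equal(fit$sigma_u2, max(0, (msb - msw) / m), tolerance = 1e-6)
  }
})

test_that("estimates agree with an independent REML implementation", {
  skip_if_not_installed("lme4")
  set.seed(7)
  g <- rep(1:200, sample(1:4, 200, replace = TRUE))
  n <- length(g)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- 1 + 0.5 * x1 - 0.3 * x2 + rnorm(200, 0, 1.2)[g] + rnorm(n, 0, 0.9)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  ours <- fit_random_intercept(y, X, g)
  ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), REML = TRUE)
  expect_equal(unname(ours$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-5)
  expect_equal(ours$sigma_u2, as.numeric(lme4::VarCorr(ref)$g),
               tolerance = 1e-5)
  expect_equal(ours$sigma_e2, stats::sigma(ref)^2, tolerance = 1e-5)
})

test_that("fixed effects are GLS at the converged variance ratio", {
  set.seed(13)
  g <- rep(1:40, each = 3)
  x <- rnorm(120)
  y <- 2 + x + rnorm(40, 0, 1.5)[g] + rnorm(120)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_random_intercept(y, X, g)
  Z <- outer(g, unique(g), `==`) * 1
  V <- diag(120) + fit$lambda * tcrossprod(Z)
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(b_gls),
               tolerance = 1e-8)
})

test_that("singleton groups reduce the fit to ordinary least squares", {
  set.seed(19)
  y <- rnorm(80); x <- rnorm(80)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_random_intercept(y, X, groups = 1:80)
  expect_identical(fit$sigma_u2, 0)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(coef(summary(ols))[, 2]),
               tolerance = 1e-8)
})

test_that("the returned optimum beats random admissible variance ratios", {
  set.seed(23)
  g <- rep(1:60, sample(1:3, 60, replace = TRUE))
  n <- length(g)
  x <- rnorm(n)
  y <- x + rnorm(60, 0, 1)[g] + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_random_intercept(y, X, g)
  for (lam in exp(runif(20, -8, 4)))
    expect_lte(fit$criterion, reml_criterion(y, X, g, lam) + 1e-6)
})

test_that("rank-deficient designs raise errors naming the dependent column", {
  y <- rnorm(30)
  X <- cbind(`(Intercept)` = 1, a = 1:30, twice_a = 2 * (1:30))
  expect_error(fit_random_intercept(y, X, rep(1:10, 3)), "twice_a")
})

test_that("Wald p-values follow the standard normal reference", {
  set.seed(29)
  g <- rep(1:50, each = 2)
  x <- rnorm(100)
  y <- 0.5 * x + rnorm(50)[g] + rnorm(100)
  fit <- fit_random_intercept(y, cbind(`(Intercept)` = 1, x = x), g)
  # direct arithmetic on the reported estimate and SE
  z <- fit$coefficients[["x"]] / fit$se[["x"]]
  expect_equal(wald_pvalue(fit, "x"), 2 * pnorm(-abs(z)))
  # zero estimate gives p = 1; z = 1.959964 gives 0.0500
  fit0 <- fit
  fit0$coefficients[["x"]] <- 0
  expect_equal(wald_pvalue(fit0, "x"), 1)
  fit0$coefficients[["x"]] <- 1.959964 * fit0$se[["x"]]
  expect_equal(wald_pvalue(fit0, "x"), 0.05, tolerance = 1e-4)
  # doubling the estimate never increases p
  fit2 <- fit
  fit2$coefficients[["x"]] <- 2 * fit$coefficients[["x"]]
  expect_lte(wald_pvalue(fit2, "x"), wald_pvalue(fit, "x"))
  expect_error(wald_pvalue(fit, "nope"), "nope")
})

test_that("marginal R2 recovers the generating variance fractions", {
  set.seed(37)
  g <- rep(1:5000, each = 2)
  x <- rnorm(10000)                       # fixed-part variance 1 at slope 1
  y <- x + rnorm(5000, 0, 1)[g] + rnorm(10000, 0, sqrt(2))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_random_intercept(y, X, g)
  expect_equal(marginal_r2(fit), 0.25, tolerance = 0.05)

  # intercept-only model explains nothing
  fit0 <- fit_random_intercept(y, intercept_only(10000), g)
  expect_identical(marginal_r2(fit0), 0)
})

test_that("term variance explained isolates an orthogonal predictor's share", {
  set.seed(41)
  g <- rep(1:5000, each = 2)
  x <- rnorm(10000); sexv <- rbinom(10000, 1, 0.5)
  b <- 0.4
  y <- b * x + 0.1 * sexv + rnorm(5000, 0, sqrt(0.42))[g] +
    rnorm(10000, 0, sqrt(0.42))
  X <- cbind(`(Intercept)` = 1, sex = sexv, x = x)
  fit <- fit_random_intercept(y, X, g)
  tve <- term_variance_explained(fit, X, "x")
  expect_equal(tve, b^2, tolerance = 0.15)
  expect_gte(tve, 0); expect_lt(tve, 1)
  expect_gte(term_variance_explained(fit, X, "sex"), 0)
  expect_error(term_variance_explained(fit, X, "ghost"), "ghost")
})
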