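test_that("Durbin-Watson quotient matches brute-force arithmetic", {
  expect_equal(durbin_watson(c(5, 5, 5, 5))$dw, 0)
  expect_equal(durbin_watson(c(1, -1, 1, -1))$dw, 3)    # 12/4
  expect_equal(durbin_watson(c(1, 0, -1))$dw, 1)        # 2/2
  # zones
  expect_equal(durbin_watson(c(5, 5, 5, 5))$dw_zone, "positive_autocorr")
  expect_equal(durbin_watson(c(1, -1, 1, -1))$dw_zone, "negative_autocorr")
  e <- rnorm(100)
  set.seed(1)
  z <- durbin_watson(rnorm(500))
  expect_true(z$dw > 0 && z$dw < 4)
  # scale invariance
  e <- c(0.3, -1.2, 0.8, 2.1, -0.4)
  for (k in c(-3, 0.01, 1e6)) {
    expect_equal(durbin_watson(k * e)$dw, durbin_watson(e)$dw)
  }
  expect_error(durbin_watson(c(0, 0, 0)), "all-zero")
})

test_that("Shapiro-Wilk wrapper enforces its domain", {
  r <- shapiro_wilk(c(-1, 0, 1))
  expect_true(r$sw_w > 0 && r$sw_w <= 1)
  expect_true(r$sw_p >= 0 && r$sw_p <= 1)
  set.seed(4)
  r <- shapiro_wilk(runif(80))           # flat alternative: low p typical
  expect_lt(r$sw_p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "zero-variance")
})

test_that("Breusch-Pagan agrees with the reference implementation", {
  skip_if_not_installed("lmtest")
  set.seed(8)
  for (i in 1:5) {
    x <- matrix(rnorm(300), ncol = 3)
    y <- 1 + x %*% c(1, -0.5, 0.2) + rnorm(100) * (1 + 0.5 * abs(x[, 1]))
    fit <- lm(y ~ x)
    e <- residuals(fit)
    mine <- breusch_pagan(e, x)
    ref <- lmtest::bptest(fit)
    expect_equal(mine$bp_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$bp_p, unname(ref$p.value), tolerance = 1e-10)
    mine0 <- breusch_pagan(e, x, studentize = FALSE)
    ref0 <- lmtest::bptest(fit, studentize = FALSE)
    expect_equal(mine0$bp_statistic, unname(ref0$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Breusch-Pagan detects variance tied to a predictor", {
  rejections <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    # variance increasing in a (positive) predictor, as in count data whose
    # spread scales with the sampling-day trajectory
    x <- cbind(runif(200, 0.5, 3), rnorm(200))
    y <- x %*% c(1, 1) + rnorm(200, sd = 0.5 * x[, 1])
    e <- residuals(lm(y ~ x))
    if (breusch_pagan(e, x)$bp_p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 36L)  # >= 90% power at n = 200
  # near-degenerate residuals: finite statistic, no crash
  e0 <- rnorm(50, sd = 1e-10)
  r <- breusch_pagan(e0, matrix(rnorm(100), ncol = 2))
  expect_true(is.finite(r$bp_statistic))
})

test_that("eigenvalue criterion matches the closed-form 2x2 spectrum", {
  # orthogonal design: identity correlation, sum of reciprocals = p
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  r <- eigen_collinearity(x)
  expect_equal(r$eigenvalues, rep(1, 3))
  expect_equal(r$reciprocal_sum, 3)
  expect_true(r$passed)
  expect_equal(sum(r$eigenvalues), 3)   # trace identity

  # correlated pair: eigenvalues 1 +/- r
  set.seed(3)
  z <- rnorm(500)
  x2 <- cbind(p = z, q = 0.9 * z + sqrt(1 - 0.81) * rnorm(500))
  rho <- cor(x2)[1, 2]
  r2 <- eigen_collinearity(x2)
  expect_equal(r2$eigenvalues, c(1 + rho, 1 - rho), tolerance = 1e-12)
  expect_equal(r2$reciprocal_sum, 1 / (1 + rho) + 1 / (1 - rho))
  # at r = 0.9 exactly the rule fails: 1/1.9 + 1/0.1 = 10.53 > 10
  expect_gt(1 / 1.9 + 1 / 0.1, 10)

  # duplicated column: zero eigenvalue, automatic failure
  x3 <- cbind(u = z, v = z)
  r3 <- eigen_collinearity(x3)
  expect_false(r3$passed)
  expect_equal(r3$reciprocal_sum, Inf)
  expect_error(eigen_collinearity(cbind(z, rep(1, 500))), "constant")
})

test_that("VIF matches its closed form and flags exact collinearity", {
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(x)), c(1, 1))

  set.seed(5)
  z <- rnorm(2000)
  x2 <- cbind(p = z, q = 0.9 * z + sqrt(1 - 0.81) * rnorm(2000))
  rho <- cor(x2)[1, 2]
  expect_equal(unname(vif(x2)), rep(1 / (1 - rho^2), 2), tolerance = 1e-10)

  x3 <- cbind(a = rnorm(50), b = rnorm(50))
  x3 <- cbind(x3, s = x3[, 1] + x3[, 2])
  expect_true(all(is.infinite(vif(x3))))
})

test_that("VIF and the eigenvalue criterion agree as collinearity grows", {
  set.seed(6)
  z <- rnorm(300)
  max_vifs <- min_eigs <- numeric(0)
  for (rho in c(0.3, 0.9, 0.99, 0.9999)) {
    x <- cbind(z, rho * z + sqrt(1 - rho^2) * rnorm(300))
    max_vifs <- c(max_vifs, max(vif(x)))
    min_eigs <- c(min_eigs, min(eigen_collinearity(x)$eigenvalues))
  }
  expect_true(all(diff(max_vifs) > 0))
  expect_true(all(diff(min_eigs) < 0))
})

test_that("the assumption gate passes clean fits and fails pathologies", {
  passes <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    df <- tibble::tibble(x1 = rnorm(120), x2 = rnorm(120), x3 = rnorm(120))
    df$y <- 1 + df$x1 - df$x2 + rnorm(120)
    m <- ols_fit(df, "y", c("x1", "x2", "x3"))
    rep_ <- assumption_gate(m, df, response_label = "y")
    if (rep_$gate_passed) passes <- passes + 1L
  }
  expect_gte(passes, 15L)  # joint calibration, nominal ~90%

  fails <- 0L
  for (seed in 1:20) {
    set.seed(seed + 500)
    df <- tibble::tibble(TIME = rep(c(0, 7, 10, 14, 17, 21, 25), 30))
    df$y <- 1 + 0.1 * df$TIME + rnorm(210, sd = 0.05 + 0.1 * df$TIME)
    df$x2 <- rnorm(210)
    m <- ols_fit(df, "y", c("TIME", "x2"))
    rep_ <- assumption_gate(m, df, response_label = "y")
    if (!rep_$gate_passed && rep_$bp_p < 0.05) fails <- fails + 1L
  }
  expect_gte(fails, 18L)  # heteroscedastic in TIME: BP catches it

  # forced alternation trips the Durbin-Watson zone and the gate invariant
  df <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40))
  df$y <- df$x1 + rep(c(0.5, -0.5), 20)
  m <- ols_fit(df, "y", c("x1", "x2"))
  rep_ <- assumption_gate(m, df, response_label = "y")
  expect_equal(rep_$dw_zone, "negative_autocorr")
  expect_false(rep_$gate_passed)
  # invariant: gate is exactly the conjunction of its components
  expect_equal(rep_$gate_passed,
               rep_$sw_p > 0.05 && rep_$bp_p > 0.05 &&
                 rep_$eigen_criterion_passed &&
                 !(rep_$dw_zone %in% c("positive_autocorr",
                                       "negative_autocorr")))
})

test_that("the gate scores fixed published models against a cohort", {
  coh <- simulate_cohort(seed = 13)
  rep_ <- assumption_gate(published_model("CBC_SCHEM"), coh)
  expect_s3_class(rep_, "diagnostics_report")
  expect_true(rep_$dw >= 0 && rep_$dw <= 4)
  expect_equal(sum(rep_$eigenvalues), 8, tolerance = 1e-8)
  expect_length(rep_$vif, 8L)
})
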