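test_that("apply_model evaluates the published equations by hand", {
  cbc <- published_model("CBC")
  zero <- tibble::tibble(day = 0, ANC = 0, ALC = 0, APC = 0)
  expect_equal(apply_model(cbc, zero), 1.93, tolerance = 1e-13)

  obs <- tibble::tibble(day = 10, ANC = 1.0, ALC = 1.0, APC = 100)
  # 1.93 + 0.9 - 0.06 - 0.36 - 0.2685
  expect_equal(apply_model(cbc, obs), 2.1415, tolerance = 1e-13)

  schem <- published_model("CBC_SCHEM")
  obs2 <- tibble::tibble(day = 10, ANC = 1, ALC = 1, APC = 100, AST = 40,
                         CK = 500, HCT = 38, LDH = 1000)
  expect_equal(apply_model(schem, obs2), 2.00432, tolerance = 1e-13)

  # missing predictor: named error, no silent imputation
  expect_error(apply_model(cbc, tibble::tibble(day = 10, ANC = 1, ALC = 1)),
               "APC")
  obs$ALC <- NA
  expect_error(apply_model(cbc, obs), "ALC")
})

test_that("apply_model is linear in the observation", {
  cbc <- published_model("CBC")
  set.seed(17)
  a <- tibble::tibble(day = 7, ANC = runif(1, 0, 4), ALC = runif(1, 0, 2),
                      APC = runif(1, 0, 400))
  b <- tibble::tibble(day = 25, ANC = runif(1, 0, 4), ALC = runif(1, 0, 2),
                      APC = runif(1, 0, 400))
  for (w in c(0, 0.25, 0.5, 1)) {
    mix <- tibble::tibble(day = w * a$day + (1 - w) * b$day,
                          ANC = w * a$ANC + (1 - w) * b$ANC,
                          ALC = w * a$ALC + (1 - w) * b$ALC,
                          APC = w * a$APC + (1 - w) * b$APC)
    expect_equal(apply_model(cbc, mix),
                 w * apply_model(cbc, a) + (1 - w) * apply_model(cbc, b))
  }
})

test_that("interval widths follow the classical leverage formulas", {
  set.seed(23)
  df <- tibble::tibble(x = rnorm(40, 10, 3))
  df$y <- 2 + 0.5 * df$x + rnorm(40, sd = 0.8)
  m <- ols_fit(df, "y", "x")
  # at the predictor centroid the leverage is exactly 1/n
  at_mean <- tibble::tibble(x = mean(df$x))
  w <- interval_widths(m, df, at_mean)
  expect_equal(w$ci_width_95,
               2 * qt(0.975, 38) * m$se_of_estimate / sqrt(40),
               tolerance = 1e-12)
  expect_equal(w$pi_width_95,
               2 * qt(0.975, 38) * m$se_of_estimate * sqrt(1 + 1 / 40),
               tolerance = 1e-12)
  # prediction interval strictly wider everywhere
  w_all <- interval_widths(m, df, df)
  expect_true(all(w_all$pi_width_95 > w_all$ci_width_95))
  # and matches lm's own intervals
  lm_ci <- predict(m$fit, newdata = as.data.frame(at_mean),
                   interval = "confidence")
  expect_equal(w$ci_width_95, unname(lm_ci[, 3] - lm_ci[, 2]),
               tolerance = 1e-10)

  # n -> large: CI width vanishes, PI width tends to 2 * z * s
  set.seed(24)
  big <- tibble::tibble(x = rnorm(1e4, 10, 3))
  big$y <- 2 + 0.5 * big$x + rnorm(1e4, sd = 0.8)
  mb <- ols_fit(big, "y", "x")
  wb <- interval_widths(mb, big, at_mean)
  expect_lt(wb$ci_width_95, 0.05)
  expect_equal(wb$pi_width_95, 2 * qnorm(0.975) * mb$se_of_estimate,
               tolerance = 0.01)
})

test_that("estimate_rc wires scores, widths and band flags together", {
  coh <- simulate_cohort(seed = 3)
  m <- published_model("CBC_SCHEM")
  irr <- coh[coh$dose_code == 3, ]
  est <- estimate_rc(m, coh, irr)
  expect_equal(nrow(est), 48L)
  expect_true(all(est$pi_width_95 > est$ci_width_95))
  expect_equal(est$in_rc3_band,
               est$rc_value > 2.5 & est$rc_value < 3.5)
})

test_that("assignment accuracy applies the strict band", {
  d7 <- tibble::tibble(day = 7,
                       rc_value = c(1.73, 2.56, 2.93, 2.78, 3.17, 2.09,
                                    2.57, 3.16))
  expect_equal(assignment_accuracy(d7)$overall$percent, 75)

  d10 <- tibble::tibble(day = 10,
                        rc_value = c(3.16, 3.22, 3.48, 3.08, 2.67, 3.06,
                                     3.47, 3.43))
  expect_equal(assignment_accuracy(d10)$overall$percent, 100)

  # boundary values are out of band (strict inequalities at both ends)
  flat <- tibble::tibble(day = 7, rc_value = rep(2.5, 5))
  expect_equal(assignment_accuracy(flat)$overall$percent, 0)
  expect_equal(assignment_accuracy(
    tibble::tibble(day = 7, rc_value = rep(3.5, 5)))$overall$percent, 0)
  # configurable band
  expect_equal(assignment_accuracy(flat, band_low = 2.4)$overall$percent,
               100)
})

test_that("packaged reference estimates match their printed summaries", {
  ref <- reference_estimates()
  expect_equal(nrow(ref), 92L)
  cbc <- reference_estimates("CBC")
  schem <- reference_estimates("CBC_SCHEM")
  expect_equal(nrow(cbc), 46L)
  expect_equal(nrow(schem), 46L)
  expect_equal(round(mean(cbc$rc_value), 2), 2.86)
  expect_equal(round(sd(cbc$rc_value), 2), 0.52)
  expect_equal(round(mean(schem$rc_value), 2), 2.90)
  expect_equal(round(sd(schem$rc_value), 2), 0.42)
  # prediction limit widths always exceed confidence widths
  expect_true(all(ref$pi_width_95 > ref$ci_width_95))
  # the anomalous printed prediction-width cell is flagged, not silently fixed
  expect_equal(sum(ref$flagged_misprint), 1L)
  expect_equal(ref$pi_width_95[ref$flagged_misprint], 20.6)
  corr <- reference_estimates(correct_misprint = TRUE)
  expect_equal(corr$pi_width_95[corr$flagged_misprint], 2.06)
  expect_equal(round(mean(corr$pi_width_95[corr$model == "CBC"]), 2), 1.91)
})
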