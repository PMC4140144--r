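test_that("packaged kinetic profiles carry the published parameterisation", {
  pr <- default_profiles()
  expect_length(pr, 7L)
  expect_named(pr, c("ANC", "ALC", "APC", "HCT", "AST", "CK", "LDH"))
  for (p in pr) expect_lt(p$baseline_low, p$baseline_high)

  expect_equal(c(pr$ANC$baseline_low, pr$ANC$baseline_high), c(2.82, 4.30))
  expect_equal(pr$ANC$nadir_window, c(10L, 17L))
  expect_equal(pr$ANC$nadir_fold_change, 23.89)
  expect_equal(pr$ANC$initial_change_day, 7L)
  expect_equal(pr$ANC$initial_fold_change, 3.7)
  expect_equal(pr$ANC$return_to_baseline_day, 21L)

  expect_equal(pr$AST$direction, "increase")
  expect_equal(pr$AST$return_to_baseline_day, 10L)
  expect_null(pr$APC$return_to_baseline_day)
})

test_that("mean trajectory interpolates the landmark kinetics", {
  pr <- default_profiles()
  mid <- (2.82 + 4.30) / 2
  expect_equal(mean_trajectory(pr$ANC, 0), mid)
  expect_equal(mean_trajectory(pr$ANC, 7), mid / 3.7)
  # nadir value held across the window
  expect_equal(mean_trajectory(pr$ANC, c(10, 14, 17)),
               rep(mid / 23.89, 3))
  # recovered by the return day and held through day 25
  expect_equal(mean_trajectory(pr$ANC, c(21, 25)), rep(mid, 2))
  # enzymes: transient day-7 rise, baseline by day 10 and thereafter
  ast_mid <- (36.86 + 44.78) / 2
  expect_equal(mean_trajectory(pr$AST, 7), ast_mid * 1.82)
  expect_equal(mean_trajectory(pr$AST, 25), ast_mid)
  # no recorded return: last landmark held
  apc_mid <- (321.82 + 370.74) / 2
  expect_equal(mean_trajectory(pr$APC, c(21, 25)),
               rep(apc_mid / 11.32, 2))
  # log-linear interpolation between landmarks
  hct_mid <- (37.93 + 39.99) / 2
  expect_equal(mean_trajectory(pr$HCT, 14),
               hct_mid * (1 / 1.33)^(4 / 7))
  expect_error(mean_trajectory(pr$ANC, 12), "sampling grid")
})

test_that("simulated cohort has the reference structure and is deterministic", {
  coh <- simulate_cohort(seed = 7)
  expect_equal(nrow(coh), 96L)
  expect_equal(sum(coh$dose_code == 0), 48L)
  expect_equal(sum(coh$dose_code == 3), 48L)
  expect_setequal(unique(coh$day[coh$dose_code == 3]),
                  c(7, 10, 14, 17, 21, 25))
  expect_true(all(coh$day[coh$dose_code == 0] == 0))
  # dose code constant per animal
  per_animal <- tapply(coh$dose_code, coh$animal_id,
                       function(x) length(unique(x)))
  expect_true(all(per_animal == 1))
  # strictly positive concentrations
  expect_true(all(as.matrix(coh[names(default_profiles())]) > 0))
  expect_identical(coh, simulate_cohort(seed = 7))
  expect_false(identical(coh, simulate_cohort(seed = 8)))
})

test_that("per-animal substreams survive cohort-size changes", {
  small <- simulate_cohort(seed = 3, n_controls = 6, n_irradiated = 3)
  big <- simulate_cohort(seed = 3, n_controls = 10, n_irradiated = 8)
  shared <- small$animal_id
  expect_identical(small, big[big$animal_id %in% shared, ])
})

test_that("zero-noise simulation reproduces every landmark fold exactly", {
  coh <- zero_noise_cohort()
  pr <- default_profiles()
  for (v in names(pr)) {
    for (d in c(7, 10, 14, 17, 21, 25)) {
      expect_equal(unique(coh[[v]][coh$day == d & coh$dose_code == 3]),
                   mean_trajectory(pr[[v]], d), tolerance = 1e-12)
    }
    expect_equal(unique(coh[[v]][coh$dose_code == 0]),
                 mean_trajectory(pr[[v]], 0), tolerance = 1e-12)
  }
  # the ANC nadir fold in particular
  expect_equal(unique(coh$ANC[coh$day == 14 & coh$dose_code == 3]),
               baseline_mid("ANC") / 23.89)
})

test_that("noisy cohort means converge to the kinetics", {
  # nadir fold from a large irradiated arm is within 3 SE of the profile fold
  coh <- simulate_cohort(n_irradiated = 200, seed = 11)
  anc14 <- coh$ANC[coh$day == 14 & coh$dose_code == 3]
  target <- baseline_mid("ANC") / 23.89
  expect_lt(abs(mean(anc14) - target), 3 * sd(anc14) / sqrt(length(anc14)))
  # control sample means stay inside the baseline range at n >= 50
  coh2 <- simulate_cohort(n_controls = 50, seed = 12)
  pr <- default_profiles()
  for (v in names(pr)) {
    m <- mean(coh2[[v]][coh2$dose_code == 0])
    expect_gt(m, pr[[v]]$baseline_low)
    expect_lt(m, pr[[v]]$baseline_high)
  }
})

test_that("dropout removes the requested irradiated animal-days", {
  coh <- simulate_cohort(seed = 1, dropout = list(`14` = 1, `17` = 1))
  expect_equal(sum(coh$day == 14), 7L)
  expect_equal(sum(coh$day == 17), 7L)
  expect_equal(sum(coh$day == 7), 8L)
})

test_that("cohort CSV round-trips exactly and malformed input is named", {
  coh <- simulate_cohort(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh))

  # blank cell becomes NA, never zero
  coh$APC[3] <- NA
  write_cohort(coh, path)
  expect_true(is.na(read_cohort(path)$APC[3]))

  # unknown cohort label reported with its row
  bad <- coh
  bad$cohort[5] <- "7Gy"
  write_cohort(bad, path)
  expect_error(read_cohort(path), "unknown cohort label '7Gy' at data row 5")

  # non-numeric cell reported with row/column
  lines <- readLines(path)
  lines[3] <- sub("^(([^,]*,){4})[^,]*", "\\1oops", lines[3])
  writeLines(lines, path)
  expect_error(read_cohort(path), "row 2, column 5")

  # missing required header
  writeLines(c("animal_id,day,dose_code,ANC", "a,0,0,1"), path)
  expect_error(read_cohort(path), "missing column\\(s\\) cohort")
})
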