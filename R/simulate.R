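# Longitudinal synthetic blood-panel cohorts: 0 Gy controls drawn at baseline
# (coded day 0) and 6.5 Gy irradiated animals followed across the six
# post-irradiation sampling days, with multiplicative lognormal noise around
# the kinetic mean trajectories.

cohort_labels <- c(control = "control_0Gy", irradiated = "irradiated_6.5Gy")

# Deterministic per-animal substream seed: changing the number of animals in
# one arm never reshuffles the draws of existing animals in either arm.
animal_seed <- function(master_seed, stream_offset, index) {
  s <- (abs(as.numeric(master_seed)) %% 2147483647) * 48271 +
    stream_offset * 97561 + index * 7919
  as.integer(s %% 2147483647)
}

# One animal-row of lognormal draws around per-variable means with
# coefficient of variation = relative_sd (exact mean preserved).
draw_values <- function(means, cvs) {
  sdlog <- sqrt(log(1 + cvs^2))
  meanlog <- log(means) - sdlog^2 / 2
  stats::rlnorm(length(means), meanlog = meanlog, sdlog = sdlog)
}

#' Simulate a control + irradiated longitudinal blood-panel cohort
#'
#' Generates one row per animal and sampling day with the study's structure:
#' each control animal contributes `control_draws` pre-irradiation draws
#' (coded day 0, dose code 0) and each irradiated animal one draw on each of
#' days 7, 10, 14, 17, 21 and 25 (dose code 3, the RC scale value of the
#' 6.5 Gy dose group). Every value is the profile's [mean_trajectory()]
#' multiplied by a positive lognormal noise factor whose coefficient of
#' variation equals the profile's `relative_sd`, so all concentrations are
#' strictly positive and zero-noise profiles reproduce the landmark kinetics
#' exactly. The defaults reproduce the reference cohort shape of 24 x 2
#' control rows plus 8 x 6 irradiated rows.
#'
#' @param profiles Named list of [kinetic_profile()] objects
#'   (default [default_profiles()]).
#' @param n_controls,n_irradiated Number of animals per arm.
#' @param control_draws Pre-irradiation draws per control animal.
#' @param seed Integer master seed; identical seeds give bit-identical
#'   cohorts, and per-animal substreams make existing animals invariant to
#'   cohort-size changes.
#' @param dropout Optional named list `day -> number of irradiated animals
#'   missing on that day` (dropped from the end of the animal roster),
#'   e.g. `list("14" = 1, "17" = 1)`.
#' @return Tibble with columns `animal_id`, `cohort`, `day`, `dose_code` and
#'   one column per profile variable.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' nrow(coh)                 # 96
#' sum(coh$dose_code == 0)   # 48
#' @export
simulate_cohort <- function(profiles = default_profiles(),
                            n_controls = 24, n_irradiated = 8,
                            control_draws = 2, seed = 1,
                            dropout = NULL) {
  stopifnot(n_controls >= 1, n_irradiated >= 1, control_draws >= 1)
  vars <- vapply(profiles, `[[`, "", "variable_name")
  cvs <- vapply(profiles, `[[`, 0, "relative_sd")
  base_means <- vapply(profiles, function(p) mean_trajectory(p, 0L), 0)
  irr_days <- setdiff(sampling_days(), 0L)
  irr_means <- vapply(profiles,
                      function(p) mean_trajectory(p, irr_days),
                      numeric(length(irr_days)))

  rows <- vector("list", n_controls + n_irradiated)
  for (i in seq_len(n_controls)) {
    set.seed(animal_seed(seed, 1L, i))
    vals <- t(vapply(seq_len(control_draws),
                     function(k) draw_values(base_means, cvs),
                     numeric(length(vars))))
    colnames(vals) <- vars
    rows[[i]] <- tibble::tibble(
      animal_id = sprintf("C%02d", i),
      cohort = cohort_labels[["control"]],
      day = 0L, dose_code = 0L,
      tibble::as_tibble(vals)
    )
  }
  for (j in seq_len(n_irradiated)) {
    set.seed(animal_seed(seed, 2L, j))
    vals <- t(vapply(seq_along(irr_days),
                     function(k) draw_values(irr_means[k, ], cvs),
                     numeric(length(vars))))
    colnames(vals) <- vars
    rows[[n_controls + j]] <- tibble::tibble(
      animal_id = sprintf("R%02d", j),
      cohort = cohort_labels[["irradiated"]],
      day = irr_days, dose_code = 3L,
      tibble::as_tibble(vals)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(dropout)) {
    for (d in names(dropout)) {
      n_miss <- dropout[[d]]
      if (n_miss > 0) {
        drop_ids <- sprintf("R%02d", seq(n_irradiated, by = -1L,
                                         length.out = n_miss))
        out <- out[!(out$day == as.integer(d) & out$animal_id %in% drop_ids), ]
      }
    }
  }
  out
}

#' Write a blood-panel cohort to a tidy CSV
#'
#' Round-trip-exact CSV with the header `animal_id, cohort, day, dose_code`
#' followed by the blood-variable columns; missing values are written as
#' empty fields.
#'
#' @param observations Cohort tibble as produced by [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(observations, path) {
  stopifnot(all(c("animal_id", "cohort", "day", "dose_code") %in%
                  names(observations)))
  readr::write_csv(observations, path, na = "")
  invisible(path)
}

#' Read a blood-panel cohort from a tidy CSV
#'
#' Validates the header, the cohort labels and the numeric cells; blank cells
#' become `NA` (never zero). Malformed input is reported with the offending
#' row and column.
#'
#' @param path CSV file written by [write_cohort()] (or hand-assembled with
#'   the same layout).
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  required <- c("animal_id", "cohort", "day", "dose_code")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop("malformed cohort header in '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  var_cols <- setdiff(header, required)
  spec <- do.call(readr::cols, c(
    list(animal_id = readr::col_character(),
         cohort = readr::col_character(),
         day = readr::col_integer(),
         dose_code = readr::col_integer()),
    stats::setNames(rep(list(readr::col_double()), length(var_cols)), var_cols)
  ))
  out <- suppressWarnings(readr::read_csv(path, col_types = spec, na = ""))
  probs <- readr::problems(out)
  if (nrow(probs)) {
    p <- probs[1, ]
    stop(sprintf(
      "non-numeric or malformed cell in '%s' at data row %d, column %d (%s): expected %s, got '%s'",
      path, p$row - 1L, p$col, header[p$col], p$expected, p$actual
    ), call. = FALSE)
  }
  bad <- which(!out$cohort %in% unname(cohort_labels))
  if (length(bad)) {
    stop(sprintf(
      "unknown cohort label '%s' at data row %d of '%s' (expected %s)",
      out$cohort[bad[1]], bad[1], path,
      paste(cohort_labels, collapse = " or ")
    ), call. = FALSE)
  }
  out
}
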