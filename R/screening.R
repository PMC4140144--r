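# Two-stage candidate-variable screen: a precision filter on the control data
# (SEM <= 10% of the mean) followed by a radioresponsiveness filter on the
# irradiated-vs-control percent differences.

sem_of <- function(x) stats::sd(x) / sqrt(length(x))

#' Precision (SEM) filter for a candidate blood variable
#'
#' A variable passes when the standard error of its mean is at most
#' `sem_fraction` (default 10%) of the absolute mean, the precision level
#' required for treating its random disturbances as well-behaved in a
#' least-squares model.
#'
#' @param values Numeric vector (at least two finite values; `NA`s dropped).
#' @param sem_fraction Maximum allowed SEM as a fraction of the mean.
#' @return List with `mean`, `sem`, `sdev` and logical `passed`.
#' @examples
#' sem_filter(c(9, 10, 11))  # sem 0.577 <= 1, passes
#' sem_filter(c(1, 19))      # sem 9 > 1, fails
#' @export
sem_filter <- function(values, sem_fraction = 0.10) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("sem_filter() needs at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("sem_filter() undefined for zero mean", call. = FALSE)
  s <- sem_of(values)
  list(mean = m, sem = s, sdev = stats::sd(values),
       passed = s <= sem_fraction * abs(m))
}

#' Radioresponsiveness filter for a candidate blood variable
#'
#' Compares each post-irradiation day with the pooled control mean. The
#' per-day percent difference is `100 * |mean(day) - mean(control)| /
#' mean(control)`; a variable passes when the mean percent difference across
#' days is at least `response_fraction` (default 10%) and the replicate SEM of
#' the percent differences is at most `sem_fraction` (default 10%). The
#' replicate SEM is the across-animal standard error of the per-observation
#' percent differences within a day, averaged over days with replicates: it
#' measures how precisely the response is estimated, is zero for noise-free
#' data and for single-observation days, and screens transient responders
#' (the serum enzymes, back at baseline by day 10) on the precision of their
#' response rather than on the shape of their time profile.
#'
#' @param control_values Numeric vector of control observations.
#' @param irradiated_values_by_day Named list `day -> numeric vector` of
#'   irradiated observations (a scalar per day is accepted).
#' @param response_fraction Minimum mean percent difference, as a fraction.
#' @param sem_fraction Maximum replicate SEM of the percent differences, as a
#'   fraction.
#' @return List with `percent_differences` (named per day),
#'   `sem_of_differences` and logical `passed`.
#' @export
radioresponse_filter <- function(control_values, irradiated_values_by_day,
                                 response_fraction = 0.10,
                                 sem_fraction = 0.10) {
  control_values <- control_values[is.finite(control_values)]
  if (!length(control_values)) {
    stop("radioresponse_filter() needs control observations", call. = FALSE)
  }
  m_ctrl <- mean(control_values)
  if (m_ctrl == 0) {
    stop("radioresponse_filter() undefined for zero control mean",
         call. = FALSE)
  }
  day_lists <- lapply(irradiated_values_by_day,
                      function(x) x[is.finite(x)])
  day_lists <- day_lists[vapply(day_lists, length, 0L) > 0L]
  if (!length(day_lists)) {
    stop("radioresponse_filter() needs irradiated observations",
         call. = FALSE)
  }
  pct_diff <- vapply(day_lists,
                     function(x) 100 * abs(mean(x) - m_ctrl) / abs(m_ctrl), 0)
  day_sems <- vapply(day_lists, function(x) {
    if (length(x) < 2L) return(NA_real_)
    100 * sem_of(x) / abs(m_ctrl)
  }, 0)
  sem_diff <- if (all(is.na(day_sems))) 0 else mean(day_sems, na.rm = TRUE)
  list(
    percent_differences = pct_diff,
    sem_of_differences = sem_diff,
    passed = mean(pct_diff) >= 100 * response_fraction &&
      sem_diff <= 100 * sem_fraction
  )
}

#' Screen a panel of blood variables on a cohort
#'
#' Applies [sem_filter()] to the control observations of each variable and,
#' in sequence, [radioresponse_filter()] to its irradiated-vs-control percent
#' differences. Variables failing either filter are flagged, never dropped;
#' the radioresponse flag implies the SEM flag (filters are applied in
#' sequence). Missing values are excluded per variable and day.
#'
#' @param cohort Cohort tibble with both dose groups (see
#'   [simulate_cohort()]).
#' @param variables Character vector of variable columns to screen.
#' @param sem_fraction,response_fraction Filter thresholds, as fractions.
#' @return Tibble with one row per variable: control summary statistics, the
#'   per-day irradiated means and percent differences (list columns), the SEM
#'   of the percent differences, and the two pass flags.
#' @export
screen_panel <- function(cohort, variables,
                         sem_fraction = 0.10, response_fraction = 0.10) {
  if (!length(variables)) {
    return(tibble::tibble(
      variable = character(), control_mean = numeric(),
      control_sem = numeric(), control_sdev = numeric(),
      irradiated_mean_by_day = list(), percent_difference_by_day = list(),
      sem_of_percent_differences = numeric(),
      passed_sem_filter = logical(), passed_radioresponse_filter = logical()
    ))
  }
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars)) {
    stop("variable(s) absent from cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (!any(cohort$dose_code == 0) || !any(cohort$dose_code != 0)) {
    stop("screen_panel() needs both dose groups in the cohort",
         call. = FALSE)
  }
  ctrl <- cohort[cohort$dose_code == 0, ]
  irr <- cohort[cohort$dose_code != 0, ]
  days <- sort(unique(irr$day))
  rows <- lapply(variables, function(v) {
    sf <- sem_filter(ctrl[[v]], sem_fraction)
    by_day <- stats::setNames(
      lapply(days, function(d) irr[[v]][irr$day == d]), days)
    rf <- radioresponse_filter(ctrl[[v]], by_day,
                               response_fraction, sem_fraction)
    tibble::tibble(
      variable = v,
      control_mean = sf$mean, control_sem = sf$sem, control_sdev = sf$sdev,
      irradiated_mean_by_day = list(vapply(by_day, function(x) {
        mean(x[is.finite(x)])
      }, 0)),
      percent_difference_by_day = list(rf$percent_differences),
      sem_of_percent_differences = rf$sem_of_differences,
      passed_sem_filter = sf$passed,
      passed_radioresponse_filter = sf$passed && rf$passed
    )
  })
  dplyr::bind_rows(rows)
}
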