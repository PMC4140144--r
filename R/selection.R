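# Correlation matrix of screened variables against the RC/dose code and each
# other, and the greedy low-collinearity downselection of predictors.

#' Pairwise-complete Pearson correlation matrix of a cohort
#'
#' Builds the symmetric Pearson correlation matrix of the dose/RC code, the
#' sampling day and the requested blood variables, using pairwise-complete
#' observations so a value missing on one day does not erase other pairs.
#' Constant columns yield `NA` correlations and are reported via a warning,
#' not an error.
#'
#' @param cohort Cohort tibble.
#' @param variables Blood-variable columns to include.
#' @param dose_label,time_label Columns holding the dose/RC code and the
#'   sampling day; they are placed first in the matrix.
#' @return Object of class `correlation_matrix`: list with `labels`, the
#'   correlation matrix `r` and the pairwise-count matrix `n_pairs`.
#' @export
pearson_matrix <- function(cohort, variables,
                           dose_label = "dose_code", time_label = "day") {
  labels <- c(dose_label, time_label, setdiff(variables,
                                              c(dose_label, time_label)))
  missing_vars <- setdiff(labels, names(cohort))
  if (length(missing_vars)) {
    stop("variable(s) absent from cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(cohort[labels])
  n_pairs <- crossprod(!is.na(x))
  if (any(n_pairs[upper.tri(n_pairs)] < 3)) {
    stop("pearson_matrix() needs >= 3 complete observations per pair",
         call. = FALSE)
  }
  r <- suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = "pearson"))
  diag(r) <- 1
  const <- labels[apply(x, 2, function(col) {
    stats::var(col, na.rm = TRUE) == 0
  })]
  if (length(const)) {
    warning("constant column(s) with undefined correlations: ",
            paste(const, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, r = r, n_pairs = n_pairs),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", length(x$labels), " variables\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' Greedy low-collinearity downselection of predictors
#'
#' Codifies the downselection of candidate predictors as a reproducible
#' greedy rule: variables are ranked by |r| with the dose/RC code
#' (descending, ties broken alphabetically) and accepted when their |r| with
#' dose is at least `min_dose_r` and their |r| with every already-accepted
#' blood variable is at most `max_mutual_r`. The time variable is always
#' retained as a predictor and is exempt from the mutual-collinearity check
#' (every scoring model is time-indexed, and the transient enzymes are
#' necessarily collinear with time).
#'
#' @param matrix A [pearson_matrix()] result.
#' @param dose_label,time_label Labels of the dose/RC code and time rows.
#' @param min_dose_r Minimum |r| with dose for acceptance (default 0.25, the
#'   lower end of the correlation range considered meaningful).
#' @param max_mutual_r Maximum tolerated |r| between accepted blood variables
#'   (default 0.67, the largest mutual coefficient tolerated in the reference
#'   models).
#' @return Tibble with one row per considered variable in rank order:
#'   `variable`, `r_with_dose`, `max_abs_r_with_selected`, `accepted` and a
#'   human-readable `reason`. Accepted predictors (time first) are in
#'   `attr(, "predictors")` and via [selected_predictors()].
#' @export
downselect <- function(matrix, dose_label = "dose_code",
                       time_label = "day",
                       min_dose_r = 0.25, max_mutual_r = 0.67) {
  stopifnot(inherits(matrix, "correlation_matrix"),
            dose_label %in% matrix$labels,
            min_dose_r > 0, min_dose_r <= 1,
            max_mutual_r > 0, max_mutual_r <= 1)
  r <- matrix$r
  candidates <- setdiff(matrix$labels, c(dose_label, time_label))
  if (!length(candidates)) stop("empty correlation matrix", call. = FALSE)
  r_dose <- r[candidates, dose_label]
  ord <- order(-abs(r_dose), candidates)
  candidates <- candidates[ord]
  r_dose <- r_dose[ord]

  accepted <- character()
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    v <- candidates[i]
    mutual <- if (length(accepted)) max(abs(r[v, accepted])) else 0
    ok_dose <- isTRUE(abs(r_dose[i]) >= min_dose_r)
    ok_mutual <- isTRUE(mutual <= max_mutual_r)
    if (ok_dose && ok_mutual) accepted <- c(accepted, v)
    rows[[i]] <- tibble::tibble(
      variable = v,
      r_with_dose = unname(r_dose[i]),
      max_abs_r_with_selected = mutual,
      accepted = ok_dose && ok_mutual,
      reason = if (!ok_dose) {
        sprintf("|r with dose| %.3f < %.2f", abs(r_dose[i]), min_dose_r)
      } else if (!ok_mutual) {
        sprintf("|r with selected| %.3f > %.2f", mutual, max_mutual_r)
      } else {
        "accepted"
      }
    )
  }
  out <- dplyr::bind_rows(rows)
  predictors <- c(if (!is.null(time_label) && time_label %in% matrix$labels)
    time_label, accepted)
  attr(out, "predictors") <- predictors
  out
}

#' Accepted predictor names from a downselection
#'
#' @param selection Result of [downselect()].
#' @return Character vector of predictors, time variable first.
#' @export
selected_predictors <- function(selection) {
  attr(selection, "predictors")
}
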