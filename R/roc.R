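# ROC validation: Mann-Whitney AUC for single markers, a deterministic
# linear-discriminant combination for biomarker panels, and stratified
# percentile-bootstrap confidence limits.

#' Mann-Whitney AUC of a single marker
#'
#' Fraction of (positive, negative) pairs in which the positive value
#' exceeds the negative, ties counted one half — the rank-sum estimator of
#' the area under the ROC curve, invariant under strictly monotone
#' transforms of the marker. By convention the reported AUC is oriented to
#' be at least 0.5, with the orientation recorded.
#'
#' @param positives,negatives Marker values in the two groups (non-empty).
#' @param orient Orient the AUC to >= 0.5 (default); `FALSE` returns the raw
#'   `P(positive > negative)` estimate with `orientation = "higher_positive"`.
#' @return List with `auc`, `orientation` (`"higher_positive"` or
#'   `"lower_positive"`) and the unoriented `auc_raw`.
#' @examples
#' auc_univariate(c(2, 4), c(1, 3))$auc  # 0.75
#' @export
auc_univariate <- function(positives, negatives, orient = TRUE) {
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  if (!length(positives) || !length(negatives)) {
    stop("auc_univariate() needs non-empty groups", call. = FALSE)
  }
  n_pos <- length(positives)
  n_neg <- length(negatives)
  ranks <- rank(c(positives, negatives))
  auc_raw <- (sum(ranks[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  if (orient && auc_raw < 0.5) {
    list(auc = 1 - auc_raw, orientation = "lower_positive",
         auc_raw = auc_raw)
  } else {
    list(auc = auc_raw, orientation = "higher_positive", auc_raw = auc_raw)
  }
}

# Deterministic combination score for a marker panel: Fisher linear
# discriminant on standardized markers; on a rank-deficient marker matrix,
# fall back to the equal-weight sum of standardized markers oriented so the
# positive group scores higher on each.
panel_scores <- function(pos_matrix, neg_matrix) {
  x <- rbind(pos_matrix, neg_matrix)
  grp <- factor(rep(c("pos", "neg"), c(nrow(pos_matrix), nrow(neg_matrix))),
                levels = c("neg", "pos"))
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  deficient <- qr(z)$rank < ncol(z)
  if (!deficient) {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(z, grouping = grp)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      return(list(scores = as.numeric(z %*% fit$scaling[, 1]),
                  method = "lda", warning = NULL))
    }
  }
  sign_ <- sign(colMeans(z[grp == "pos", , drop = FALSE]) -
                  colMeans(z[grp == "neg", , drop = FALSE]))
  sign_[sign_ == 0] <- 1
  list(scores = as.numeric(z %*% sign_),
       method = "standardized_sum",
       warning = "singular within-group covariance; equal-weight standardized sum used")
}

#' Panel (multi-marker) AUC via a linear discriminant score
#'
#' Combines two or more markers into a single discriminant score — a Fisher
#' linear discriminant fitted on standardized marker values, a deterministic
#' stand-in for black-box panel classifiers — and reports the Mann-Whitney
#' AUC of that score. A rank-deficient marker matrix (e.g. a duplicated
#' marker) falls back to the equal-weight standardized sum, recorded as a
#' warning in the result.
#'
#' @param cohort Cohort tibble.
#' @param markers Two or more marker columns.
#' @param day_filter Optional days to keep for the irradiated group
#'   (controls are always the day-0 draws); `NULL` pools all days.
#' @return Object of class `roc_result` with the marker set, day label, AUC,
#'   orientation and combination method.
#' @export
auc_panel <- function(cohort, markers, day_filter = NULL) {
  stopifnot(length(markers) >= 2)
  pos <- cohort[cohort$dose_code != 0, , drop = FALSE]
  if (!is.null(day_filter)) pos <- pos[pos$day %in% day_filter, , drop = FALSE]
  neg <- cohort[cohort$dose_code == 0, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg)) {
    stop("both cohorts must be represented after day filtering",
         call. = FALSE)
  }
  ps <- panel_scores(as.matrix(pos[markers]), as.matrix(neg[markers]))
  a <- auc_univariate(ps$scores[seq_len(nrow(pos))],
                      ps$scores[-seq_len(nrow(pos))])
  structure(
    list(marker_or_panel = markers,
         day = if (is.null(day_filter)) "pooled"
               else paste(day_filter, collapse = ","),
         auc = a$auc, orientation = a$orientation,
         cl_low = NA_real_, cl_high = NA_real_,
         method = ps$method, warning = ps$warning),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s (day %s): AUC %.3f [%s]%s\n",
              paste(x$marker_or_panel, collapse = "+"), x$day, x$auc,
              x$orientation,
              if (!is.na(x$cl_low)) sprintf(", 95%% CL %.3f-%.3f",
                                            x$cl_low, x$cl_high) else ""))
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' Stratified percentile-bootstrap 95% confidence limits for an AUC
#'
#' Resamples observations with replacement within each group, recomputes the
#' (oriented) Mann-Whitney AUC per replicate and reports the 2.5% and 97.5%
#' percentiles. Deterministic under a fixed seed.
#'
#' @inheritParams auc_univariate
#' @param n_boot Bootstrap replicates (>= 100; default 2000).
#' @param seed Integer seed.
#' @return List with `cl_low` and `cl_high`.
#' @export
auc_bootstrap_cl <- function(positives, negatives, n_boot = 2000, seed = 1) {
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  stopifnot(n_boot >= 100)
  if (length(positives) < 2 || length(negatives) < 2) {
    stop("auc_bootstrap_cl() needs at least 2 observations per group",
         call. = FALSE)
  }
  orientation <- auc_univariate(positives, negatives)$orientation
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    p <- sample(positives, replace = TRUE)
    n <- sample(negatives, replace = TRUE)
    raw <- auc_univariate(p, n, orient = FALSE)$auc_raw
    if (orientation == "lower_positive") 1 - raw else raw
  }, 0)
  q <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  list(cl_low = q[1], cl_high = q[2])
}

#' Per-day and pooled AUC table for a marker set
#'
#' Runs [auc_univariate()] (with bootstrap confidence limits) for each marker
#' at each post-irradiation day and pooled over days, mirroring the per-time
#' point biomarker AUC tables of the reference analysis.
#'
#' @param cohort Cohort tibble.
#' @param markers Marker columns.
#' @param days Post-irradiation days to analyse (default: all present).
#' @param n_boot,seed Bootstrap settings; `n_boot = 0` skips the limits.
#' @return Tibble with `marker`, `day`, `auc`, `cl_low`, `cl_high`,
#'   `orientation`.
#' @export
roc_table <- function(cohort, markers, days = NULL, n_boot = 2000,
                      seed = 1) {
  pos_all <- cohort[cohort$dose_code != 0, , drop = FALSE]
  neg <- cohort[cohort$dose_code == 0, , drop = FALSE]
  if (is.null(days)) days <- sort(unique(pos_all$day))
  slices <- c(as.list(days), list(days))
  labels <- c(as.character(days), "pooled")
  rows <- list()
  for (m in markers) {
    for (k in seq_along(slices)) {
      pos <- pos_all[pos_all$day %in% slices[[k]], , drop = FALSE]
      a <- auc_univariate(pos[[m]], neg[[m]])
      cl <- if (n_boot > 0) {
        auc_bootstrap_cl(pos[[m]], neg[[m]], n_boot = n_boot,
                         seed = seed + k)
      } else {
        list(cl_low = NA_real_, cl_high = NA_real_)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = m, day = labels[k], auc = a$auc,
        cl_low = cl$cl_low, cl_high = cl$cl_high,
        orientation = a$orientation)
    }
  }
  dplyr::bind_rows(rows)
}
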