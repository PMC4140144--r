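# Least-squares assumption gate: Durbin-Watson serial-correlation statistic,
# Shapiro-Wilk residual normality, Breusch-Pagan (Koenker) heteroscedasticity,
# the eigenvalue multicollinearity criterion and variance inflation factors.

#' Durbin-Watson statistic and its interpretive zone
#'
#' Computes `dw = sum((e_t - e_{t-1})^2) / sum(e_t^2)`, which lies in
#' \[0, 4\] with 2 indicating no serial correlation, and classifies it:
#' below 1.5 positive autocorrelation, 1.5-1.8 inconclusive, 1.8-2.5 no
#' autocorrelation detected, above 2.5 negative autocorrelation. The upper
#' cuts mirror the lower ones symmetrically around 2; critical-value table
#' lookup is deliberately out of scope.
#'
#' @param residuals Numeric vector of at least 3 residuals, not all zero,
#'   in observation order.
#' @return List with `dw` and `dw_zone`.
#' @examples
#' durbin_watson(c(1, -1, 1, -1))$dw  # 3, alternation
#' @export
durbin_watson <- function(residuals) {
  residuals <- as.numeric(residuals)
  stopifnot(length(residuals) >= 3)
  denom <- sum(residuals^2)
  if (denom == 0) stop("all-zero residual vector", call. = FALSE)
  dw <- sum(diff(residuals)^2) / denom
  zone <- if (dw < 1.5) "positive_autocorr"
  else if (dw <= 1.8) "inconclusive"
  else if (dw <= 2.5) "none_detected"
  else "negative_autocorr"
  list(dw = dw, dw_zone = zone)
}

#' Shapiro-Wilk residual normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (the standard Royston
#' approximation of the W statistic and its p-value), with the conventional
#' reading that p > 0.05 does not reject residual normality.
#'
#' @param residuals 3 to 5000 numeric values with nonzero variance.
#' @return List with `sw_w` and `sw_p`.
#' @export
shapiro_wilk <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3 || length(residuals) > 5000) {
    stop("shapiro_wilk() needs 3 <= n <= 5000 residuals", call. = FALSE)
  }
  if (stats::sd(residuals) == 0) {
    stop("shapiro_wilk() undefined for zero-variance residuals",
         call. = FALSE)
  }
  t <- stats::shapiro.test(residuals)
  list(sw_w = unname(t$statistic), sw_p = t$p.value)
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Score test of residual-variance dependence on the predictors, from the
#' auxiliary regression of the squared residuals on the design. The default
#' is Koenker's studentized form, `n * R^2` of the auxiliary regression
#' against chi-squared with p degrees of freedom, which is robust to
#' non-normal errors; `studentize = FALSE` gives the original form (half the
#' explained sum of squares of the regression of `e^2 / mean(e^2)` on the
#' design).
#'
#' @param residuals Residual vector.
#' @param design Numeric matrix or data frame of predictor columns, one row
#'   per residual (no intercept column).
#' @param studentize Use Koenker's studentized statistic (default `TRUE`).
#' @return List with `bp_statistic`, `bp_p` and `df`.
#' @export
breusch_pagan <- function(residuals, design, studentize = TRUE) {
  x <- as.matrix(design)
  storage.mode(x) <- "double"
  e <- as.numeric(residuals)
  stopifnot(nrow(x) == length(e))
  n <- length(e)
  p <- ncol(x)
  aux <- stats::lm.fit(cbind(1, x), e^2)
  if (aux$rank < p + 1) {
    stop("rank-deficient auxiliary design in breusch_pagan()",
         call. = FALSE)
  }
  fitted2 <- aux$fitted.values
  tss <- sum((e^2 - mean(e^2))^2)
  ess <- sum((fitted2 - mean(e^2))^2)
  stat <- if (tss == 0) {
    0  # perfectly constant squared residuals: no detectable pattern
  } else if (studentize) {
    n * ess / tss
  } else {
    ess / (2 * mean(e^2)^2)
  }
  list(bp_statistic = stat, bp_p = stats::pchisq(stat, df = p,
                                                 lower.tail = FALSE),
       df = p)
}

#' Eigenvalue multicollinearity criterion
#'
#' Eigen-decomposes the correlation matrix of the predictors and applies the
#' reciprocal-eigenvalue rule: the sum of 1/lambda over the spectrum should
#' not exceed five times the number of predictors, otherwise multicollinearity
#' is of concern. Eigenvalues below `tol` are reported as effectively zero
#' (exact collinearity) and fail the criterion outright.
#'
#' @param design Matrix or data frame of at least two predictor columns with
#'   nonzero variance.
#' @param tol Threshold below which an eigenvalue counts as zero.
#' @return List with `eigenvalues` (descending), `reciprocal_sum` and
#'   logical `passed`.
#' @export
eigen_collinearity <- function(design, tol = 1e-12) {
  x <- as.matrix(design)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  lambda <- sort(eigen(r, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  p <- ncol(x)
  if (any(lambda < tol)) {
    return(list(eigenvalues = lambda, reciprocal_sum = Inf, passed = FALSE))
  }
  rsum <- sum(1 / lambda)
  list(eigenvalues = lambda, reciprocal_sum = rsum, passed = rsum <= 5 * p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor j
#' on the remaining predictors; perfectly collinear predictors get `Inf`.
#'
#' @inheritParams eigen_collinearity
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- ncol(x)
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(x))
}

#' Run the full least-squares assumption gate on an RC model
#'
#' Computes the model's residuals on `cohort` (from the stored fit when the
#' model was fitted there, otherwise as observed response minus
#' [apply_model()] score), then runs the Durbin-Watson, Shapiro-Wilk and
#' Breusch-Pagan tests on the residuals and the eigenvalue criterion and VIFs
#' on the predictor design. The gate passes when normality and
#' homoscedasticity are not rejected at 0.05, the eigenvalue criterion holds
#' and the Durbin-Watson zone shows no definitive autocorrelation
#' (inconclusive values do not fail the gate).
#'
#' @param model An `rc_model`.
#' @param cohort Cohort containing the model's predictors and the response.
#' @param response_label Response column used for residuals of fixed models.
#' @return Object of class `diagnostics_report`.
#' @export
assumption_gate <- function(model, cohort, response_label = "dose_code") {
  design <- design_frame(model, cohort)
  if (!is.null(model$fit) &&
      isTRUE(all.equal(unname(stats::nobs(model$fit)), nrow(design)))) {
    e <- stats::residuals(model$fit)
  } else {
    y <- cohort[[response_label]]
    if (is.null(y)) {
      stop("response column '", response_label, "' absent from cohort",
           call. = FALSE)
    }
    scores <- apply_model(model, cohort)
    e <- y - scores
  }
  dw <- durbin_watson(e)
  sw <- shapiro_wilk(e)
  bp <- breusch_pagan(e, design)
  ec <- eigen_collinearity(design)
  v <- vif(design)
  gate <- sw$sw_p > 0.05 && bp$bp_p > 0.05 && ec$passed &&
    !(dw$dw_zone %in% c("positive_autocorr", "negative_autocorr"))
  structure(
    list(model_name = model$name,
         dw = dw$dw, dw_zone = dw$dw_zone,
         sw_w = sw$sw_w, sw_p = sw$sw_p,
         bp_statistic = bp$bp_statistic, bp_p = bp$bp_p,
         eigenvalues = ec$eigenvalues,
         reciprocal_eigenvalue_sum = ec$reciprocal_sum,
         eigen_criterion_passed = ec$passed,
         vif = v, gate_passed = gate),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> model %s\n", x$model_name))
  cat(sprintf("  DW %.3f (%s); SW W %.3f p %.3g; BP %.3f p %.3g\n",
              x$dw, x$dw_zone, x$sw_w, x$sw_p, x$bp_statistic, x$bp_p))
  cat(sprintf("  sum 1/lambda %.3f (%s); max VIF %.3g\n",
              x$reciprocal_eigenvalue_sum,
              if (x$eigen_criterion_passed) "ok" else "collinearity concern",
              max(x$vif)))
  cat(sprintf("  gate %s\n", if (x$gate_passed) "PASSED" else "FAILED"))
  invisible(x)
}

# Predictor design (no intercept) of a model evaluated on a cohort,
# mapping the published models' TIME predictor onto the day column.
design_frame <- function(model, cohort) {
  cols <- lapply(model$predictors, function(p) {
    v <- cohort[[p]]
    if (is.null(v) && p == "TIME") v <- cohort[["day"]]
    if (is.null(v)) {
      stop("predictor '", p, "' absent from cohort", call. = FALSE)
    }
    as.numeric(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- model$predictors
  m
}
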