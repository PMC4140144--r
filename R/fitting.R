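# Multivariate linear RC models: ordinary least squares, forward/backward
# stepwise selection on partial-F p-values, and the two fixed published
# scoring algorithms ("CBC" and "CBC-SCHEM").

new_rc_model <- function(name, predictors, alpha, beta, se_alpha, se_beta,
                         t_values, p_values, r_squared, f_statistic,
                         se_of_estimate, n_observations, fit = NULL,
                         annotations = list(), step_log = NULL) {
  structure(
    list(name = name, predictors = predictors,
         alpha = alpha, beta = stats::setNames(beta, predictors),
         se_alpha = se_alpha, se_beta = stats::setNames(se_beta, predictors),
         t_values = t_values, p_values = p_values,
         r_squared = r_squared, f_statistic = f_statistic,
         se_of_estimate = se_of_estimate, n_observations = n_observations,
         fit = fit, annotations = annotations, step_log = step_log),
    class = "rc_model"
  )
}

#' @export
print.rc_model <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("(%s)(%s)", format(x$beta, digits = digits,
                                            trim = TRUE), x$predictors),
                 collapse = " + ")
  cat(sprintf("<rc_model> %s\n  RC = %s + %s\n", x$name,
              format(x$alpha, digits = digits), terms))
  cat(sprintf("  R^2 = %.3f, F = %.3g, residual SE = %.3g, n = %d\n",
              x$r_squared, x$f_statistic, x$se_of_estimate,
              x$n_observations))
  if (length(x$annotations)) {
    cat("  annotations:",
        paste(names(x$annotations), unlist(x$annotations), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ordinary least-squares fit of an RC model
#'
#' Fits `response ~ predictors` by OLS and returns the coefficients with
#' classical standard errors, t statistics (coefficient / SE), two-sided p
#' values on n - p - 1 degrees of freedom, R-squared, the overall F statistic
#' and the residual standard error.
#'
#' @param cohort Data frame with the response and predictor columns.
#' @param response_label Response column (the RC/dose code for RC models).
#' @param predictors Character vector of predictor columns.
#' @return An `rc_model`; the underlying [stats::lm()] fit is carried in
#'   `$fit` for residual diagnostics and interval computations.
#' @export
ols_fit <- function(cohort, response_label = "dose_code",
                    predictors) {
  dat <- as.data.frame(cohort[c(response_label, predictors)])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors)
  if (n < p + 1) {
    stop(sprintf("ols_fit() needs at least %d observations for %d predictors; got %d",
                 p + 1, p, n), call. = FALSE)
  }
  fml <- stats::reformulate(c("1", predictors), response = response_label)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < p + 1) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  f_stat <- if (p > 0) unname(sm$fstatistic[1]) else NA_real_
  new_rc_model(
    name = "custom", predictors = predictors,
    alpha = co[1, 1], beta = co[-1, 1],
    se_alpha = co[1, 2], se_beta = co[-1, 2],
    t_values = stats::setNames(co[, 3], rownames(co)),
    p_values = stats::setNames(co[, 4], rownames(co)),
    r_squared = sm$r.squared, f_statistic = f_stat,
    se_of_estimate = sm$sigma, n_observations = n,
    fit = fit
  )
}

#' Stepwise (forward with backward elimination) RC model selection
#'
#' Classical p-to-enter / p-to-remove stepwise regression on partial-F
#' p-values: repeatedly add the candidate with the smallest partial-F p-value
#' if it is below `p_enter`, then remove any included variable whose p-value
#' exceeds `p_remove`; stops when no move is possible or a variable would
#' cycle. With `p_enter = p_remove = 1` this reduces to an OLS fit on all
#' candidates.
#'
#' @param cohort Data frame of response and candidates.
#' @param response_label Response column.
#' @param candidates Candidate predictor columns.
#' @param p_enter,p_remove Entry and removal thresholds
#'   (`0 < p_enter <= p_remove`), defaulting to the conventional 0.05/0.10.
#' @param forced Predictors always kept in the model (e.g. the time
#'   variable); they are never removal candidates.
#' @return An `rc_model` (intercept-only if nothing enters) with the step
#'   history in `$step_log`.
#' @export
stepwise_fit <- function(cohort, response_label = "dose_code", candidates,
                         p_enter = 0.05, p_remove = 0.10, forced = NULL) {
  stopifnot(p_enter > 0, p_enter <= p_remove, p_remove <= 1)
  dat <- as.data.frame(cohort[c(response_label,
                                union(forced, candidates))])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  included <- forced %||% character()
  pool <- setdiff(candidates, included)
  log_rows <- list()
  refit <- function(vars) {
    stats::lm(stats::reformulate(c("1", vars), response = response_label),
              data = dat)
  }
  fit <- refit(included)
  repeat {
    moved <- FALSE
    if (length(pool)) {
      a1 <- stats::add1(fit, scope = stats::reformulate(c(included, pool)),
                        test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      pv <- pv[is.finite(pv)]
      if (length(pv) && min(pv) < p_enter) {
        best <- names(pv)[which.min(pv)]
        included <- c(included, best)
        pool <- setdiff(pool, best)
        fit <- refit(included)
        log_rows[[length(log_rows) + 1L]] <-
          tibble::tibble(step = length(log_rows) + 1L, action = "add",
                         variable = best, p_value = min(pv))
        moved <- TRUE
      }
    }
    removable <- setdiff(included, forced)
    if (length(removable)) {
      d1 <- stats::drop1(fit, scope = stats::reformulate(removable),
                         test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- rownames(d1)[-1]
      pv <- pv[is.finite(pv)]
      if (length(pv) && max(pv) > p_remove) {
        worst <- names(pv)[which.max(pv)]
        # do not re-remove what the add step just brought in (cycle guard)
        just_added <- length(log_rows) &&
          log_rows[[length(log_rows)]]$action == "add" &&
          log_rows[[length(log_rows)]]$variable == worst && moved
        if (!just_added) {
          included <- setdiff(included, worst)
          pool <- union(pool, worst)
          fit <- refit(included)
          log_rows[[length(log_rows) + 1L]] <-
            tibble::tibble(step = length(log_rows) + 1L, action = "remove",
                           variable = worst, p_value = max(pv))
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  model <- if (length(included)) {
    ols_fit(dat, response_label, included)
  } else {
    intercept_only_model(dat[[response_label]])
  }
  model$step_log <- dplyr::bind_rows(log_rows)
  model
}

intercept_only_model <- function(y) {
  n <- length(y)
  s <- stats::sd(y)
  new_rc_model(
    name = "custom", predictors = character(0),
    alpha = mean(y), beta = numeric(0),
    se_alpha = s / sqrt(n), se_beta = numeric(0),
    t_values = c(`(Intercept)` = mean(y) / (s / sqrt(n))),
    p_values = c(`(Intercept)` = 2 * stats::pt(-abs(mean(y) / (s / sqrt(n))),
                                               df = n - 1)),
    r_squared = 0, f_statistic = NA_real_,
    se_of_estimate = s, n_observations = n,
    fit = stats::lm(y ~ 1, data = data.frame(y = y))
  )
}

#' The two fixed published RC3 scoring algorithms
#'
#' Returns the published coefficient sets exactly as printed. The `"CBC"`
#' model scores RC3 from the sampling day and the three blood counts,
#' `RC3 = 1.93 + 0.09 TIME - 0.06 ANC - 0.36 ALC - 2.685e-3 APC`; the
#' `"CBC_SCHEM"` model adds hematocrit and the three serum enzymes,
#' `RC3 = 0.42 + 0.11 TIME - 0.06 ANC - 0.26 ALC - 2.787e-3 APC + 0.01 AST +
#' 1.968e-5 CK + 0.02 HCT - 8.682e-5 LDH`. The printed fit metadata
#' (R-squared, F, residual SE, n = 92) is carried as annotations only — the
#' original 92-row animal dataset is unpublished, so these are not re-fit
#' quantities. Coefficient standard errors are derived as coefficient / t
#' from the printed t values.
#'
#' @param name `"CBC"` or `"CBC_SCHEM"`.
#' @return An `rc_model` with fixed coefficients (no `$fit`).
#' @examples
#' published_model("CBC")$alpha  # 1.93
#' @export
published_model <- function(name = c("CBC", "CBC_SCHEM")) {
  name <- match.arg(name)
  if (name == "CBC") {
    predictors <- c("TIME", "ANC", "ALC", "APC")
    beta <- c(0.09, -0.06, -0.36, -2.685e-3)
    t_all <- c(`(Intercept)` = 12.61, TIME = 13.06, ANC = -1.87,
               ALC = -4.53, APC = -4.81)
    p_all <- c(`(Intercept)` = 0.00, TIME = 0.00, ANC = 0.06,
               ALC = 0.00, APC = 0.00)
    alpha <- 1.93
    ann <- list(r_squared = 0.908, f_statistic = 39.3,
                se_of_estimate = 1.01, n_observations = 92,
                p_model = 0.00001)
  } else {
    predictors <- c("TIME", "ANC", "ALC", "APC", "AST", "CK", "HCT", "LDH")
    beta <- c(0.11, -0.06, -0.26, -2.787e-3, 0.01, 1.968e-5, 0.02,
              -8.682e-5)
    t_all <- c(`(Intercept)` = 0.85, TIME = 12.82, ANC = -2.06, ALC = -3.50,
               APC = -5.52, AST = 2.71, CK = 1.81, HCT = 1.79, LDH = -0.61)
    p_all <- c(`(Intercept)` = 0.39, TIME = 0.00, ANC = 0.04, ALC = 0.00,
               APC = 0.00, AST = 0.00, CK = 0.07, HCT = 0.07, LDH = 0.54)
    alpha <- 0.42
    ann <- list(r_squared = 0.933, f_statistic = 36,
                se_of_estimate = 0.88, n_observations = 92,
                p_model = 0.00001)
  }
  new_rc_model(
    name = name, predictors = predictors,
    alpha = alpha, beta = beta,
    se_alpha = alpha / t_all[[1]],
    se_beta = beta / t_all[predictors],
    t_values = t_all, p_values = p_all,
    r_squared = ann$r_squared, f_statistic = ann$f_statistic,
    se_of_estimate = ann$se_of_estimate, n_observations = ann$n_observations,
    annotations = ann
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
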