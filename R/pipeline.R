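# End-to-end workflow: simulate (or read) a cohort, screen, downselect, fit,
# gate on the least-squares assumptions, estimate and score RC3, and run the
# ROC validation, writing tidy per-stage CSVs, a machine-readable summary and
# a structured log of every filter decision.

#' Default pipeline configuration
#'
#' Nested list of every tunable the workflow uses, at the reference defaults:
#' cohort structure 24 controls x 2 draws + 8 irradiated, 10% screening
#' thresholds, dose-correlation floor 0.25 and mutual-correlation ceiling
#' 0.67 for downselection, stepwise p-to-enter 0.05 / p-to-remove 0.10,
#' strict RC3 band (2.5, 3.5) and a 2000-replicate ROC bootstrap. Exactly one
#' of `input$path` (a cohort CSV) or the `simulation` block is used; the
#' default simulates.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    input = list(path = NULL),
    simulation = list(n_controls = 24L, n_irradiated = 8L,
                      control_draws = 2L, seed = 1L,
                      relative_sd = NULL),
    screening = list(sem_fraction = 0.10, response_fraction = 0.10),
    selection = list(min_dose_r = 0.25, max_mutual_r = 0.67),
    stepwise = list(p_enter = 0.05, p_remove = 0.10),
    band = list(band_low = 2.5, band_high = 3.5),
    roc = list(n_boot = 2000L, seed = 1L),
    output_dir = "bloodrc-output"
  )
}

#' Validate a pipeline configuration
#'
#' Checks key names against [default_config()] (unknown keys fail fast with
#' their full path), threshold ranges, and that an input path or a
#' simulation block is present.
#'
#' @param config Nested configuration list.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_keys <- function(cfg, ref, path) {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown)) {
      stop("invalid config key(s): ",
           paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
    }
    for (k in names(cfg)) {
      if (is.list(ref[[k]]) && !is.null(cfg[[k]])) {
        if (!is.list(cfg[[k]])) {
          stop("config key ", path, k, " must be a block", call. = FALSE)
        }
        check_keys(cfg[[k]], ref[[k]], paste0(path, k, "$"))
      }
    }
  }
  check_keys(config, ref, "")
  has_input <- !is.null(config$input$path)
  has_sim <- !is.null(config$simulation)
  if (!has_input && !has_sim) {
    stop("config needs input$path or a simulation block", call. = FALSE)
  }
  if (!is.null(config$screening)) {
    stopifnot(config$screening$sem_fraction > 0,
              config$screening$sem_fraction <= 1,
              config$screening$response_fraction > 0,
              config$screening$response_fraction <= 1)
  }
  if (!is.null(config$selection)) {
    stopifnot(config$selection$min_dose_r > 0,
              config$selection$min_dose_r <= 1,
              config$selection$max_mutual_r > 0,
              config$selection$max_mutual_r <= 1)
  }
  if (!is.null(config$band)) {
    stopifnot(config$band$band_low < config$band$band_high)
  }
  invisible(config)
}

# Merge user config over the defaults (one level of nesting).
merge_config <- function(config) {
  out <- default_config()
  for (k in names(config)) {
    if (is.list(out[[k]]) && is.list(config[[k]])) {
      for (k2 in names(config[[k]])) {
        # NULL means unset; [[<- NULL would delete the key instead
        if (!is.null(config[[k]][[k2]])) out[[k]][[k2]] <- config[[k]][[k2]]
      }
    } else {
      out[[k]] <- config[[k]]
    }
  }
  out
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly through its file representation.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config()` the configuration; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  merge_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full RC3 estimation workflow
#'
#' Executes the four-step formulation process end to end — compile (simulate
#' or read a cohort), identify (precision + radioresponse screens), analyse
#' (correlation matrix and greedy downselection), formulate (stepwise OLS
#' fit, assumption gate, RC3 estimation and band scoring, per-day ROC) — and
#' writes each stage's table under `output_dir` together with `summary.json`
#' and a `pipeline.log` of key=value filter decisions. A failed assumption
#' gate is reported as a warning in the summary, not an error.
#'
#' @param config Configuration list (merged over [default_config()]).
#' @param output_dir Output directory (defaults to the config's).
#' @param roc_markers Markers for the ROC stage (default: the screened
#'   variables that passed both filters).
#' @return Invisibly, a list with every stage result (`cohort`, `screening`,
#'   `correlation`, `selection`, `model`, `diagnostics`, `estimates`,
#'   `accuracy`, `roc`).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         roc_markers = NULL) {
  config <- merge_config(config)
  validate_config(config)
  output_dir <- output_dir %||% config$output_dir
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(stage, ...) {
    kv <- c(...)
    writeLines(paste0("stage=", stage, " ",
                      paste(names(kv), unname(kv), sep = "=",
                            collapse = " ")), log_con)
  }

  # compile
  if (!is.null(config$input$path)) {
    cohort <- read_cohort(config$input$path)
    log_line("compile", c(source = config$input$path,
                          n_rows = nrow(cohort)))
  } else {
    sim <- config$simulation
    profiles <- default_profiles()
    if (!is.null(sim$relative_sd)) {
      profiles <- lapply(profiles, function(p) {
        p$relative_sd <- sim$relative_sd
        p
      })
    }
    cohort <- simulate_cohort(profiles, n_controls = sim$n_controls,
                              n_irradiated = sim$n_irradiated,
                              control_draws = sim$control_draws,
                              seed = sim$seed)
    log_line("compile", c(source = "simulation", seed = sim$seed,
                          n_rows = nrow(cohort)))
  }
  variables <- setdiff(names(cohort),
                       c("animal_id", "cohort", "day", "dose_code"))
  readr::write_csv(cohort, file.path(output_dir, "cohort.csv"), na = "")

  # identify
  scr <- screen_panel(cohort, variables,
                      sem_fraction = config$screening$sem_fraction,
                      response_fraction = config$screening$response_fraction)
  for (i in seq_len(nrow(scr))) {
    log_line("screen", c(variable = scr$variable[i],
                         control_sem = signif(scr$control_sem[i], 4),
                         sem_pct_diff = signif(
                           scr$sem_of_percent_differences[i], 4),
                         passed_sem = scr$passed_sem_filter[i],
                         passed_radioresponse =
                           scr$passed_radioresponse_filter[i]))
  }
  scr_flat <- dplyr::select(scr, -"irradiated_mean_by_day",
                            -"percent_difference_by_day")
  readr::write_csv(scr_flat, file.path(output_dir, "screening.csv"))
  screened <- scr$variable[scr$passed_radioresponse_filter]

  # analyse
  cm <- pearson_matrix(cohort, screened)
  utils::write.csv(round(cm$r, 4),
                   file.path(output_dir, "correlation_matrix.csv"))
  sel <- downselect(cm, min_dose_r = config$selection$min_dose_r,
                    max_mutual_r = config$selection$max_mutual_r)
  for (i in seq_len(nrow(sel))) {
    log_line("select", c(variable = sel$variable[i],
                         r_with_dose = signif(sel$r_with_dose[i], 4),
                         accepted = sel$accepted[i],
                         reason = gsub(" ", "_", sel$reason[i])))
  }
  readr::write_csv(sel, file.path(output_dir, "selection.csv"))
  predictors <- selected_predictors(sel)

  # formulate: stepwise fit over the selected predictors, time forced
  model <- stepwise_fit(cohort, "dose_code",
                        candidates = setdiff(predictors, "day"),
                        p_enter = config$stepwise$p_enter,
                        p_remove = config$stepwise$p_remove,
                        forced = intersect("day", predictors))
  coef_tbl <- tibble::tibble(
    term = c("(Intercept)", model$predictors),
    estimate = c(model$alpha, unname(model$beta)),
    std_error = c(model$se_alpha, unname(model$se_beta)),
    t_value = unname(model$t_values),
    p_value = unname(model$p_values))
  readr::write_csv(coef_tbl, file.path(output_dir, "model_coefficients.csv"))
  log_line("fit", c(predictors = paste(model$predictors, collapse = "+"),
                    r_squared = signif(model$r_squared, 4),
                    se_of_estimate = signif(model$se_of_estimate, 4)))

  diag_ <- assumption_gate(model, cohort)
  log_line("diagnose", c(dw = signif(diag_$dw, 4), dw_zone = diag_$dw_zone,
                         sw_p = signif(diag_$sw_p, 4),
                         bp_p = signif(diag_$bp_p, 4),
                         eigen_ok = diag_$eigen_criterion_passed,
                         gate_passed = diag_$gate_passed))

  irr <- cohort[cohort$dose_code != 0, ]
  est <- estimate_rc(model, cohort, irr,
                     band_low = config$band$band_low,
                     band_high = config$band$band_high)
  readr::write_csv(est, file.path(output_dir, "rc_estimates.csv"))
  acc <- assignment_accuracy(est, config$band$band_low,
                             config$band$band_high)
  readr::write_csv(acc$per_day, file.path(output_dir, "accuracy.csv"))

  roc_markers <- roc_markers %||% screened
  roc <- roc_table(cohort, roc_markers, n_boot = config$roc$n_boot,
                   seed = config$roc$seed)
  readr::write_csv(roc, file.path(output_dir, "roc.csv"))

  summary <- list(
    n_observations = nrow(cohort),
    screened_variables = screened,
    selected_predictors = predictors,
    model_predictors = model$predictors,
    r_squared = model$r_squared,
    gate_passed = diag_$gate_passed,
    gate_warning = if (diag_$gate_passed) NULL else
      "least-squares assumption gate failed; see diagnostics",
    overall_accuracy_percent = acc$overall$percent
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, screening = scr, correlation = cm,
                 selection = sel, model = model, diagnostics = diag_,
                 estimates = est, accuracy = acc, roc = roc,
                 config = config, output_dir = output_dir))
}

#' Score the packaged reference estimates against the RC3 band
#'
#' Applies [assignment_accuracy()] to the packaged per-animal reference
#' estimates of one published algorithm.
#'
#' @param model `"CBC"` or `"CBC_SCHEM"`.
#' @param band_low,band_high Strict band bounds.
#' @return An `accuracy_summary`.
#' @examples
#' score_reference("CBC")$per_day  # day 7: 6/8 = 75%
#' @export
score_reference <- function(model = c("CBC", "CBC_SCHEM"),
                            band_low = 2.5, band_high = 3.5) {
  model <- match.arg(model)
  assignment_accuracy(reference_estimates(model), band_low, band_high)
}
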