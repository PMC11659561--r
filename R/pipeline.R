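#' End-to-end pipeline configuration
#'
#' A single global seed is split hierarchically across stages (generation,
#' each bootstrap endpoint, PAS interval, bias audit) so the full run is
#' reproducible and each stage can be re-run independently with identical
#' results.
#'
#' @param n_participants Participants to simulate (ignored when `dataset`
#'   is supplied).
#' @param seed Global integer seed.
#' @param dataset Optional [trial_dataset()] to analyse instead of
#'   simulating one.
#' @param sim Named list of [sim_config()] overrides.
#' @param settings A [bootstrap_settings()] template (seed is re-derived
#'   per endpoint).
#' @param hypothesis A [ni_hypothesis()].
#' @param predicate Reference-system parameters for the PAS comparison:
#'   participant-level sensitivity, its 95% CI, and diagnosability.
#' @param audits Attributes to audit for subgroup bias.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_participants = 567L, seed = 1L, dataset = NULL,
                       sim = list(),
                       settings = bootstrap_settings(n_replicates = 2000L),
                       hypothesis = ni_hypothesis(),
                       predicate = list(sensitivity = 0.872,
                                        ci = c(0.818, 0.912),
                                        diagnosability = 1),
                       audits = c("sex", "race", "ethnicity")) {
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), dataset = dataset, sim = sim,
                 settings = settings, hypothesis = hypothesis,
                 predicate = predicate, audits = audits),
            class = "run_config")
}

stage_settings <- function(config, stage) {
  s <- config$settings
  bootstrap_settings(n_replicates = s$n_replicates,
                     seed = derive_seed(config$seed, stage),
                     spectrum_target = s$spectrum_target,
                     expand_spectrum = s$expand_spectrum,
                     bound_level = s$bound_level)
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a trial dataset, then runs the complete analysis
#' sequence: disposition summary, accuracy at both units against both
#' reference standards (plus eye-level worst-case imputation), clustered
#' bootstrap non-inferiority for the co-primary endpoints at eye and
#' participant level, the study success verdict, the PAS break-even
#' comparison against a reference system, and the subgroup bias audit.
#' Identical configuration yields identical output.
#'
#' @param config A [run_config()].
#' @return A named list of class `report_bundle`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$dataset)) {
    if (config$n_participants < 1) {
      stop_df("generation stage: n_participants must be >= 1")
    }
    sim_args <- config$sim
    sim_args$n_participants <- config$n_participants
    sim_args$seed <- derive_seed(config$seed, "generate")
    ds <- generate_trial(do.call(sim_config, sim_args))
  } else {
    ds <- config$dataset
  }

  accuracy <- list(
    eye_level1 = accuracy_summary(ds, "eye", "level1"),
    eye_level2 = accuracy_summary(ds, "eye", "level2"),
    participant_level1 = accuracy_summary(ds, "participant", "level1"),
    eye_level1_worst_case = accuracy_summary(ds, "eye", "level1",
                                             worst_case = TRUE))

  boots <- list(
    sens_eye = bootstrap_metric(ds, "sensitivity", "eye", "level1",
                                stage_settings(config, "sens_eye"),
                                config$hypothesis),
    spec_eye = bootstrap_metric(ds, "specificity", "eye", "level1",
                                stage_settings(config, "spec_eye"),
                                config$hypothesis),
    sens_participant = bootstrap_metric(ds, "sensitivity", "participant",
                                        "level1",
                                        stage_settings(config, "sens_part"),
                                        config$hypothesis),
    spec_participant = bootstrap_metric(ds, "specificity", "participant",
                                        "level1",
                                        stage_settings(config, "spec_part"),
                                        config$hypothesis))
  success <- study_success(boots$sens_eye, boots$spec_eye, config$hypothesis)

  new_sens <- boots$sens_participant$point_estimate
  new_d <- diagnosability(ds, "participant")
  pred <- config$predicate
  ratio <- pas_break_even_ratio(
    pas_inputs(s_c = pred$sensitivity, d_c = pred$diagnosability %||% 1),
    pas_inputs(s_c = new_sens, d_c = new_d))
  interval <- pas_ratio_interval(
    pred$sensitivity, pred$ci, new_sens,
    quantile(boots$sens_participant$replicate_values, c(0.025, 0.975),
             names = FALSE),
    reference_d = pred$diagnosability %||% 1, new_d = new_d,
    n_draws = 20000L, seed = derive_seed(config$seed, "pas"))

  specs <- lapply(config$audits, subgroup_spec)
  bias <- if (length(specs) >= 2) {
    intersectional_audit(ds, specs, unit = "eye", reference = "level1",
                         settings = stage_settings(config, "bias"))
  } else if (length(specs) == 1) {
    list(bias_test(ds, specs[[1]], "sensitivity",
                   settings = stage_settings(config, "bias")))
  } else list()

  structure(list(config = config, dataset = ds,
                 waterfall = waterfall_summary(ds, ds, ds),
                 accuracy = accuracy, inference = boots,
                 study_success = success,
                 pas = list(break_even_ratio = ratio, interval = interval,
                            new_sensitivity = new_sens,
                            new_diagnosability = new_d,
                            predicate = pred),
                 bias = bias),
            class = "report_bundle")
}

bundle_sections <- function() {
  c("waterfall", "accuracy", "inference", "study_success", "pas", "bias")
}

bundle_flat <- function(bundle) {
  acc <- lapply(bundle$accuracy, function(a) {
    list(sensitivity = a$sensitivity, specificity = a$specificity,
         ppv = a$ppv, npv = a$npv, plr = a$plr, nlr = a$nlr,
         diagnosability = a$diagnosability, n_units = a$n_units)
  })
  inf <- lapply(bundle$inference, function(b) {
    list(point_estimate = b$point_estimate, lower_bound = b$lower_bound,
         ni_p_value = b$ni_p_value, p0 = b$p0)
  })
  bias <- lapply(bundle$bias, function(r) {
    if (!r$reported) return(list(reported = FALSE))
    list(reported = TRUE,
         estimates = as.list(r$group_estimates),
         difference = r$difference, p_value = r$p_value)
  })
  list(waterfall = as.data.frame(bundle$waterfall),
       accuracy = acc, inference = inf,
       study_success = bundle$study_success,
       pas = bundle$pas[c("break_even_ratio", "interval", "new_sensitivity",
                          "new_diagnosability")],
       bias = bias)
}

#' Render a pipeline report
#'
#' Renders the bundle as readable text (percentages to one decimal,
#' bounds labelled as one-sided lower bounds, suppressed subgroups shown
#' as "not reported") or as a machine-readable JSON document.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param format `"text"` or `"json"`.
#' @return Character scalar (the rendered document).
#' @export
render_report <- function(bundle, format = c("text", "json")) {
  format <- match.arg(format)
  missing <- setdiff(bundle_sections(), names(bundle))
  if (length(missing)) {
    stop_df("incomplete bundle; missing section(s): ",
            paste(missing, collapse = ", "))
  }
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_df("json rendering requires the jsonlite package")
    }
    return(jsonlite::toJSON(bundle_flat(bundle), auto_unbox = TRUE,
                            digits = NA, na = "null"))
  }
  lines <- c("== Trial analysis report ==", "",
             capture.output(print(bundle$waterfall)), "")
  for (nm in names(bundle$accuracy)) {
    lines <- c(lines, capture.output(print(bundle$accuracy[[nm]])), "")
  }
  for (nm in names(bundle$inference)) {
    lines <- c(lines, capture.output(print(bundle$inference[[nm]])))
  }
  lines <- c(lines, "",
             sprintf("Study success (both endpoints non-inferior): %s",
                     bundle$study_success), "",
             sprintf("PAS break-even ratio vs reference system: %.2fx (95%% CI %.2f-%.2f)",
                     bundle$pas$break_even_ratio, bundle$pas$interval[["lower"]],
                     bundle$pas$interval[["upper"]]),
             "")
  if (length(bundle$bias)) {
    lines <- c(lines, "Subgroup bias audit:")
    for (nm in names(bundle$bias)) {
      lines <- c(lines, paste0("  ",
                               capture.output(print(bundle$bias[[nm]]))))
    }
  } else {
    lines <- c(lines, "Subgroup bias audit: not run (no contrasts configured)")
  }
  paste(lines, collapse = "\n")
}

#' @importFrom utils capture.output
NULL
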