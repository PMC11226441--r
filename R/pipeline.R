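#' Pipeline configuration
#'
#' Bundles every stage's parameters — design, actor motion, mixing,
#' diversity-metric settings, rating-model parameters and the master
#' seed — into one object that round-trips losslessly through JSON, so a
#' whole analysis is reproducible from a single file.
#'
#' @param design An [experiment_design()].
#' @param self_params,other_params,experimenter_params
#'   [actor_motion_params()] for the three motion sources.
#' @param mixing A [mixing_config()].
#' @param metric_params A [diversity_params()].
#' @param curve_params Two-mode list as [default_curve_params()].
#' @param rating_noise_sd Rating noise SD.
#' @param id_coeffs Identification-model coefficients.
#' @param residual_discrepancy See [generate_experiment()].
#' @param seed Master seed (overrides `design$seed` when given).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = experiment_design(),
                            self_params = actor_motion_params(),
                            other_params = exploration_motion_params(),
                            experimenter_params = actor_motion_params(
                              exploration_multiplier = 1.2, switch_rate = 8
                            ),
                            mixing = mixing_config(),
                            metric_params = diversity_params(),
                            curve_params = default_curve_params(),
                            rating_noise_sd = 10,
                            id_coeffs = c(intercept = 20, beta_self = 45,
                                          beta_control = 12),
                            residual_discrepancy = 0.18,
                            seed = NULL) {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  structure(
    list(design = design, self_params = self_params,
         other_params = other_params,
         experimenter_params = experimenter_params, mixing = mixing,
         metric_params = metric_params, curve_params = curve_params,
         rating_noise_sd = rating_noise_sd, id_coeffs = id_coeffs,
         residual_discrepancy = residual_discrepancy),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a validated [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(x, strip)
    else if (!is.null(names(x))) as.list(x) # keep names as JSON keys
    else x
  }
  jsonlite::write_json(strip(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reconstruct <- function(constructor, args) do.call(constructor, as.list(args))
  pipeline_config(
    design = reconstruct(experiment_design, raw$design[
      c("n_participants", "reps", "trial_duration_s", "fps", "seed")]),
    self_params = reconstruct(actor_motion_params, raw$self_params),
    other_params = reconstruct(actor_motion_params, raw$other_params),
    experimenter_params = reconstruct(actor_motion_params, raw$experimenter_params),
    mixing = reconstruct(mixing_config, raw$mixing),
    metric_params = reconstruct(diversity_params, raw$metric_params),
    curve_params = lapply(raw$curve_params, function(p) {
      reconstruct(agency_curve_params, p[c("mode", "k", "c0", "A", "b")])
    }),
    rating_noise_sd = raw$rating_noise_sd,
    id_coeffs = unlist(raw$id_coeffs),
    residual_discrepancy = raw$residual_discrepancy
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> mix -> kinematics -> metrics -> rating model ->
#' statistics on one configuration: generates the synthetic experiment
#' (with per-trial motion metrics), runs the 2 x 2 repeated-measures
#' ANOVA on every dependent variable (agency and identification ratings,
#' the five moving distances, the diversity index), fits the two-mode
#' agency curves to the simulated ratings, and optionally writes the
#' trial table (CSV) and the effect and curve estimates (JSON) to
#' `output_dir`. Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for `trials.csv`,
#'   `anova_effects.json` and `curve_fits.json`.
#' @param fit_model Fit the agency curves (default `TRUE`).
#' @return A list of class `agencymix_results`: `trials`, `anovas` (one
#'   tidy tibble with a `dv` column), `fit` (an
#'   [agency_fit][fit_curves] or `NULL`), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         fit_model = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  exp <- generate_experiment(
    design = config$design, self_params = config$self_params,
    other_params = config$other_params, curve_params = config$curve_params,
    experimenter_params = config$experimenter_params, mixing = config$mixing,
    rating_noise_sd = config$rating_noise_sd, id_coeffs = config$id_coeffs,
    residual_discrepancy = config$residual_discrepancy,
    compute_metrics = TRUE, seed = config$design$seed
  )
  trials <- exp$trials
  dvs <- intersect(
    c("agency", "identification", "dist_overall", "dist_head",
      "dist_eye_l", "dist_eye_r", "dist_lip", "diversity"),
    names(trials)
  )
  anovas <- purrr::map_dfr(dvs, function(dv) {
    rm_anova_2x2(aggregate_cell_means(trials, dv)) |>
      tidy() |>
      dplyr::mutate(dv = dv, .before = 1)
  })
  fit <- NULL
  if (isTRUE(fit_model)) {
    fit <- fit_curves(trials, rating = "agency", consistency = "consistency",
                      face = "face", seed = config$design$seed)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(trials, file.path(output_dir, "trials.csv"))
    jsonlite::write_json(anovas, file.path(output_dir, "anova_effects.json"),
                         digits = NA, pretty = TRUE)
    if (!is.null(fit)) {
      jsonlite::write_json(tidy(fit), file.path(output_dir, "curve_fits.json"),
                           digits = NA, pretty = TRUE)
    }
  }
  structure(list(trials = trials, anovas = anovas, fit = fit, config = config),
            class = "agencymix_results")
}

#' @export
print.agencymix_results <- function(x, ...) {
  cat(sprintf("<agencymix_results> %d trials; ANOVA effects:\n", nrow(x$trials)))
  print(x$anovas, n = Inf)
  invisible(x)
}

trial_table_required <- c("participant", "face", "control", "repetition",
                          "agency", "identification")

#' Write / read a trial table as CSV
#'
#' The trial table is the long-format record of the experiment: one row
#' per trial with the design labels, both ratings and any derived motion
#' columns. Reading validates the schema (required columns, known
#' face/control labels, ratings within 0–100) and reports the offending
#' row on failure.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns a validated tibble.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  validate_trial_table(trials)
}

validate_trial_table <- function(trials) {
  missing_cols <- setdiff(trial_table_required, names(trials))
  if (length(missing_cols)) {
    stopf("trial table lacks column(s): %s", paste(missing_cols, collapse = ", "),
          class = "agencymix_schema_error")
  }
  bad_face <- which(!tolower(trials$face) %in% c("self", "other"))
  if (length(bad_face)) {
    stopf("row %d: unknown face label '%s'", bad_face[1], trials$face[bad_face[1]],
          class = "agencymix_schema_error")
  }
  bad_ctl <- which(!tolower(trials$control) %in% c("full", "partial"))
  if (length(bad_ctl)) {
    stopf("row %d: unknown control label '%s'", bad_ctl[1], trials$control[bad_ctl[1]],
          class = "agencymix_schema_error")
  }
  for (col in c("agency", "identification")) {
    bad <- which(!is.finite(trials[[col]]) | trials[[col]] < 0 | trials[[col]] > 100)
    if (length(bad)) {
      stopf("row %d: %s rating %s outside [0, 100]", bad[1], col,
            format(trials[[col]][bad[1]]), class = "agencymix_schema_error")
    }
  }
  tibble::as_tibble(trials)
}

#' Read an externally supplied ratings table
#'
#' Schema-driven adapter for rating tables deposited with arbitrary
#' column names (e.g. a public data repository export): `mapping` names
#' the file's columns for each canonical column, labels are normalized
#' to lower case, and the result is validated like any trial table.
#'
#' @param path CSV file path.
#' @param mapping Named character vector/list mapping canonical names
#'   (`participant`, `face`, `control`, `repetition`, `agency`,
#'   `identification`, optionally more) to the file's column names.
#' @return A validated trial tibble.
#' @export
read_external_ratings <- function(path, mapping) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mapping <- unlist(mapping)
  missing_map <- setdiff(trial_table_required, names(mapping))
  if (length(missing_map)) {
    stopf("mapping lacks canonical column(s): %s",
          paste(missing_map, collapse = ", "), class = "agencymix_schema_error")
  }
  missing_cols <- setdiff(unname(mapping), names(df))
  if (length(missing_cols)) {
    stopf("file '%s' lacks mapped column(s): %s", path,
          paste(missing_cols, collapse = ", "), class = "agencymix_schema_error")
  }
  out <- df[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out$face <- tolower(out$face)
  out$control <- tolower(out$control)
  validate_trial_table(out)
}
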