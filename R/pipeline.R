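#' Column schemas of the pipeline's tabular file formats
#'
#' All pipeline files are comma-delimited text with a header row. This
#' function documents (and is used to validate) the required columns of
#' each table kind.
#'
#' @param table one of `"participants"`, `"schedule"`, `"responses"`,
#'   `"parameters"`, `"pair_summaries"`, `"fsli"`.
#' @return character vector of required column names.
#' @export
laxity_schema <- function(table = c("participants", "schedule", "responses",
                                    "parameters", "pair_summaries", "fsli")) {
  table <- match.arg(table)
  switch(table,
    participants = c("id", "laxity_label", "apparent_age"),
    schedule = c("event_id", "group_id", "left_id", "right_id", "pair_key",
                 "order_flag"),
    responses = c("evaluator_id", "background", "event_id", "choice"),
    parameters = c("id", parameter_columns()),
    pair_summaries = c("pair_key", "target_id", "nontarget_id", "n_resp",
                       "k_t", "p_t", "logit_t", "binom_p"),
    fsli = c("id", "worth", "log_worth", "fsli", "separated"))
}

.read_table <- function(file, kind) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(laxity_schema(kind), names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' lacks required column(s): %s",
                 kind, file, paste(miss, collapse = ", ")))
  }
  df
}

#' Read a pipeline table, validating its schema
#'
#' @param file path to a comma-delimited text file with a header row.
#' @return data frame.
#' @name laxity-io
#' @export
read_participants <- function(file) .read_table(file, "participants")

#' @rdname laxity-io
#' @export
read_schedule <- function(file) .read_table(file, "schedule")

#' @rdname laxity-io
#' @export
read_responses <- function(file) .read_table(file, "responses")

#' @rdname laxity-io
#' @export
read_parameter_table <- function(file) .read_table(file, "parameters")

#' Full analysis configuration with study-faithful defaults
#'
#' One structure holding every tunable of the pipeline: the synthetic
#' generator ([generator_config()]), the logit boundary correction, the
#' Bradley-Terry mode/prior/separation policy, the collinearity screen, the
#' SVR settings, and the efficacy-test alphas.
#'
#' @param generator [generator_config()].
#' @param correction,eps logit boundary correction, see [choice_logit()].
#' @param bt_mode comparison-data mode, see [build_comparison_data()].
#' @param prior_strength Bradley-Terry ridge weight (`NULL` = default rule).
#' @param separation `"drop"` or `"shrink"`, see [laxity_scale()].
#' @param vif_threshold,a_priori_exclusions see [vif_screen()].
#' @param features,max_features,cost,epsilon,gamma see [fit_fsli_model()].
#' @param alpha,alpha_normality see [paired_change_test()].
#' @param run_efficacy logical; simulate and analyze the paired
#'   pre/post study as part of the pipeline run.
#' @return list of class `laxity_config`.
#' @export
laxity_config <- function(generator = generator_config(),
                          correction = "haldane", eps = 0.005,
                          bt_mode = "sigmoid", prior_strength = NULL,
                          separation = "drop", vif_threshold = 5,
                          a_priori_exclusions = c("F3", "R5"),
                          features = "auto", max_features = 8L, cost = 1,
                          epsilon = 0.1, gamma = NULL, alpha = 0.05,
                          alpha_normality = 0.05, run_efficacy = TRUE) {
  structure(
    list(generator = generator, correction = correction, eps = eps,
         bt_mode = bt_mode, prior_strength = prior_strength,
         separation = separation, vif_threshold = vif_threshold,
         a_priori_exclusions = a_priori_exclusions, features = features,
         max_features = as.integer(max_features), cost = cost,
         epsilon = epsilon, gamma = gamma, alpha = alpha,
         alpha_normality = alpha_normality, run_efficacy = run_efficacy),
    class = "laxity_config")
}

#' Run the full laxity-quantification pipeline on synthetic data
#'
#' Executes design, response simulation, perception quantification,
#' Bradley-Terry scaling, collinearity screening, FSLI regression modeling,
#' and (optionally) the paired efficacy study, end to end, and reconciles
#' the stage counts into a run manifest. Idempotent under a fixed seed.
#'
#' @param config [laxity_config()].
#' @param seed master integer seed; stage seeds are derived from it.
#' @param out_dir optional directory; when given, every stage output is
#'   written as comma-delimited text plus a JSON `manifest.json`.
#' @return object of class `laxity_run`: list with `participants`,
#'   `table`, `schedule`, `responses`, `summaries`, `concordance`, `scale`
#'   (the [laxity_scale()] frame), `vif`, `fit` (the `regression_fit`),
#'   `efficacy` (panel or `NULL`), and `manifest`.
#' @export
run_laxity_pipeline <- function(config = laxity_config(), seed = 1L,
                                out_dir = NULL) {
  stopifnot(inherits(config, "laxity_config"))
  seed <- as.integer(seed)
  seeds <- list(cohort = seed, groups = seed + 1L, schedule = seed + 2L,
                responses = seed + 3L, efficacy = seed + 4L)
  gen <- config$generator

  cohort <- generate_cohort(gen, seed = seeds$cohort)
  participants <- assign_groups(cohort$participants,
                                n_groups = gen$n_groups,
                                seed = seeds$groups)
  schedule <- presentation_schedule(participants, seed = seeds$schedule)
  latent <- stats::setNames(participants$latent_score, participants$id)
  responses <- simulate_responses(schedule, latent, gen,
                                  seed = seeds$responses)
  summaries <- collapse_orders(responses, schedule, participants,
                               correction = config$correction,
                               eps = config$eps)
  concordance <- evaluator_kappa(responses, schedule, participants)
  scale_df <- laxity_scale(summaries, mode = config$bt_mode,
                           prior_strength = config$prior_strength,
                           separation = config$separation)
  fsli <- stats::setNames(scale_df$fsli, scale_df$id)
  retained_ids <- scale_df$id[scale_df$retained]

  screen <- vif_screen(cohort$table, threshold = config$vif_threshold,
                       a_priori_exclusions = config$a_priori_exclusions)
  fit <- fit_fsli_model(
    cohort$table[cohort$table$id %in% retained_ids, , drop = FALSE],
    fsli[retained_ids], features = config$features,
    candidates = screen$retained, cost = config$cost,
    epsilon = config$epsilon, gamma = config$gamma,
    max_features = config$max_features)

  efficacy <- NULL
  if (isTRUE(config$run_efficacy)) {
    study <- simulate_efficacy_study(gen, seed = seeds$efficacy)
    efficacy <- efficacy_panel(study$baseline, study$followup,
                               alpha = config$alpha,
                               alpha_normality = config$alpha_normality)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("laxipair")),
    seed = seed, stage_seeds = seeds,
    counts = list(
      participants = nrow(participants),
      groups = gen$n_groups,
      pairs_per_group = nrow(schedule) / 2L / gen$n_groups,
      events = nrow(schedule),
      evaluators = gen$n_evaluators,
      responses = nrow(responses),
      pair_summaries = nrow(summaries),
      separated = sum(scale_df$separated),
      retained_for_modeling = length(retained_ids),
      features_selected = length(fit$feature_names),
      efficacy_pairs = if (is.null(efficacy)) 0L else gen$efficacy_n),
    config = config)
  with(manifest$counts, {
    stopifnot(responses == evaluators * events,
              pair_summaries == events / 2L,
              retained_for_modeling == participants - separated)
  })

  run <- structure(
    list(participants = participants, table = cohort$table,
         schedule = schedule, responses = responses, summaries = summaries,
         concordance = concordance, scale = scale_df, vif = screen,
         fit = fit, efficacy = efficacy, manifest = manifest),
    class = "laxity_run")
  if (!is.null(out_dir)) write_laxity_run(run, out_dir)
  run
}

#' Write every stage output of a pipeline run to a directory
#'
#' Emits the participant, schedule, response, pair-summary, FSLI, VIF, and
#' efficacy tables as comma-delimited text, the regression report and the
#' run manifest as JSON.
#'
#' @param run `laxity_run` object.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_laxity_run <- function(run, out_dir) {
  stopifnot(inherits(run, "laxity_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(run$participants, "participants.csv")
  wr(run$table, "parameters.csv")
  wr(run$schedule, "schedule.csv")
  wr(run$responses, "responses.csv")
  wr(run$summaries, "pair_summaries.csv")
  wr(run$scale, "fsli.csv")
  wr(data.frame(parameter = names(run$vif$vif), vif = unname(run$vif$vif)),
     "vif.csv")
  if (!is.null(run$efficacy)) wr(run$efficacy, "efficacy.csv")
  fit_report <- run$fit[c("feature_names", "hyperparameters", "r_squared",
                          "rmse", "pearson_r", "pearson_p",
                          "r_squared_train", "n")]
  fit_report$loo_predictions <- as.list(run$fit$loo_predictions)
  jsonlite::write_json(fit_report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.laxity_run <- function(x, ...) {
  ct <- x$manifest$counts
  cat("Facial skin laxity pipeline run\n")
  cat(sprintf("  %d participants in %d groups; %d events; %d evaluators; %d responses\n",
              ct$participants, ct$groups, ct$events, ct$evaluators,
              ct$responses))
  cat(sprintf("  %d pair summaries; %d separated participants; %d modeled\n",
              ct$pair_summaries, ct$separated, ct$retained_for_modeling))
  cat(sprintf("  consumer-expert mean kappa = %.3f\n",
              x$concordance$mean_kappa))
  cat(sprintf("  SVR: %d features, LOO R^2 = %.3f, RMSE = %.4f\n",
              length(x$fit$feature_names), x$fit$r_squared, x$fit$rmse))
  if (!is.null(x$efficacy)) {
    cat(sprintf("  efficacy: %d/%d endpoints improved significantly\n",
                sum(x$efficacy$improved), nrow(x$efficacy)))
  }
  invisible(x)
}
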