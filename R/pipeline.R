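#' Pipeline configuration
#'
#' Collects every tunable threshold and switch of the analysis pipeline
#' in one validated object. Defaults are the task's canonical values:
#' 275-px predictive threshold, 100-px correct-prediction threshold,
#' six-trial blocks, 750-ms inter-stimulus interval, awareness cutoff at
#' the 250 scale midpoint, Chebyshev distance-from-previous, diagonal
#' cross-recurrence match.
#'
#' @param n_per_sequence agents simulated per training sequence (13, so
#'   the 11 bundled sequences give a 143-participant cohort).
#' @param predictive_px,correct_px classification thresholds, px.
#' @param block_size trials per block.
#' @param isi_ms inter-stimulus interval, ms (informational; the
#'   simulator's timing contract).
#' @param awareness_cutoff low-awareness subset cutoff on the 100-400
#'   scale.
#' @param metric distance-from-previous metric.
#' @param match_variant cross-recurrence variant, see [match_score()].
#' @param params an [agent_params()] object.
#' @param layout a [task_layout()] object.
#' @param ... unknown keys are rejected with an error naming them.
#' @return A `swg_config` list.
#' @export
pipeline_config <- function(n_per_sequence = 13,
                            predictive_px = 275,
                            correct_px = 100,
                            block_size = 6,
                            isi_ms = 750,
                            awareness_cutoff = 250,
                            metric = "chebyshev",
                            match_variant = "diagonal",
                            params = agent_params(),
                            layout = task_layout(),
                            ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("config-error: unknown key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  structure(list(n_per_sequence = n_per_sequence,
                 predictive_px = predictive_px, correct_px = correct_px,
                 block_size = block_size, isi_ms = isi_ms,
                 awareness_cutoff = awareness_cutoff, metric = metric,
                 match_variant = match_variant, params = params,
                 layout = layout),
            class = "swg_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) the training sequences, simulates the cohort,
#' extracts trajectory features and block summaries, scores recall, and
#' runs the statistical stage: learning-curve mixed models for reaction
#' time and both distance measures, per-block uniformity chi-squares of
#' the predictive-proportion histograms, per-block excess-score t-tests
#' on the perfectly regular sequences, recall regressions, residual
#' mediation of awareness, and the low-awareness subset model.
#' Deterministic for a fixed seed and config.
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed.
#' @param sequences optional sequence table (defaults to
#'   [bundled_sequences()]).
#' @param out_dir if non-`NULL`, writes cohort CSVs, features/blocks/
#'   scores CSVs and a `results.json` summary there.
#' @return A list: `sequences`, `cohort`, `trial_data`, `features`,
#'   `blocks`, `scores`, and `results` (the statistical summaries).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 42L,
                         sequences = NULL, out_dir = NULL) {
  if (!inherits(config, "swg_config")) {
    stop("config-error: config must come from pipeline_config()",
         call. = FALSE)
  }
  if (is.null(sequences)) sequences <- bundled_sequences(warn = FALSE)

  cohort <- simulate_cohort(sequences,
                            n_per_sequence = config$n_per_sequence,
                            params = config$params, layout = config$layout,
                            seed = seed)
  events <- cohort_events(cohort)
  samples <- cohort_samples(cohort)
  participants <- cohort_participants(cohort)

  features <- trial_features(events, samples, layout = config$layout,
                             predictive_px = config$predictive_px,
                             correct_px = config$correct_px,
                             metric = config$metric)
  blocks <- block_summaries(features, block_size = config$block_size)
  scores <- score_cohort(participants, features,
                         match_variant = config$match_variant)

  # per-trial modelling table
  trial_data <- merge(events,
                      participants[, c("participant_id", "g")],
                      by = "participant_id")
  trial_data$rt <- trial_data$click_ms - trial_data$onset_ms
  trial_data <- merge(trial_data,
                      features[, c("participant_id", "trial",
                                   "dist_to_next", "dist_from_prev")],
                      by = c("participant_id", "trial"))
  trial_data <- trial_data[order(trial_data$participant_id,
                                 trial_data$trial), ]

  rt_fit <- fit_learning_model(trial_data, "rt")
  dtn_fit <- fit_learning_model(trial_data, "dist_to_next")
  dfp_fit <- fit_learning_model(
    trial_data[!is.na(trial_data$dist_from_prev), ], "dist_from_prev")

  # block histograms vs uniform
  chisq_by_block <- lapply(split(blocks, blocks$block), function(b) {
    uniformity_chisq(proportion_histogram(b$prop_predictive))
  })

  # excess scores on the fully regular sequences, block by block
  g1_ids <- scores$participant_id[abs(scores$train_g - 1) < 1e-9]
  excess_by_block <- NULL
  if (length(g1_ids) >= 2) {
    b1 <- blocks[blocks$participant_id %in% g1_ids, ]
    excess_by_block <- lapply(split(b1, b1$block), function(b) {
      excess_score_test(b$excess_score)
    })
  }

  recall_res <- recall_regressions(scores)
  med <- mediation_residuals(scores$train_g, scores$pred_prop,
                             scores$awareness)
  low_fit <- tryCatch(
    low_awareness_subset(trial_data, participants,
                         cutoff = config$awareness_cutoff),
    error = function(e) e$message)

  results <- list(rt_model = rt_fit, dist_to_next_model = dtn_fit,
                  dist_from_prev_model = dfp_fit,
                  chisq_by_block = chisq_by_block,
                  excess_by_block = excess_by_block,
                  recall = recall_res, mediation = med,
                  low_awareness = low_fit, seed = seed)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, out_dir)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(blocks, file.path(out_dir, "blocks.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summarise_results(results),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(sequences = sequences, cohort = cohort, trial_data = trial_data,
       features = features, blocks = blocks, scores = scores,
       results = results)
}

# JSON-friendly view of the statistical results
summarise_results <- function(results) {
  fit_sum <- function(f) {
    if (!inherits(f, "swg_model_fit")) return(f)
    list(coefficients = as.list(f$coefficients),
         anova = f$anova, backend = f$backend, singular = f$singular,
         n_obs = f$n_obs, n_subjects = f$n_subjects)
  }
  list(seed = results$seed,
       rt_model = fit_sum(results$rt_model),
       dist_to_next_model = fit_sum(results$dist_to_next_model),
       dist_from_prev_model = fit_sum(results$dist_from_prev_model),
       chisq_by_block = results$chisq_by_block,
       excess_by_block = results$excess_by_block,
       recall_correlations = results$recall$correlations,
       mediation = results$mediation,
       low_awareness = fit_sum(results$low_awareness))
}
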