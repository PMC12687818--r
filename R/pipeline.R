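#' Run the full survival-prediction pipeline
#'
#' Executes simulate (optional) -> label -> feature preparation -> SMOTE +
#' balanced-forest training with randomized hyperparameter search ->
#' threshold-tuned evaluation -> interpretation (Gini importance, pairwise
#' interaction screen, SHAP) -> trait network, writing each stage's output
#' under `outdir` along with the resolved configuration.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param traits,detections real input tables; if `NULL` a synthetic
#'   cohort is generated under the config's seed.
#' @return list with every stage artefact: `traits`, `detections`,
#'   `labels`, `features` (the prepared `feature_matrix`), `split`,
#'   `model` (bundle with forest, tuned config, threshold), `metrics`,
#'   `threshold_curve`, `importance`, `interactions`, `shap`, `network`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         traits = NULL, detections = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                     "] ", ...)
  if (is.null(traits)) {
    log_stage("simulate: n_birds=", config$n_birds,
              " seed=", stage_seed(config$seed, "simulate"))
    sim <- simulate_cohort(sim_config(n_birds = config$n_birds,
                                      seed = stage_seed(config$seed,
                                                        "simulate")))
    traits <- sim$traits
    detections <- sim$detections
  }
  log_stage("label: ", length(unique(detections$bird_id)), " birds, mode=",
            config$cjs_mode)
  labels_df <- label_detections(detections, mode = config$cjs_mode)
  idx <- match(traits$bird_id, labels_df$bird_id)
  if (anyNA(idx)) stop("birds without detection records: ",
                       paste(traits$bird_id[is.na(idx)], collapse = ", "))
  labels_df <- labels_df[idx, ]
  rownames(labels_df) <- NULL
  y <- labels_df$label

  log_stage("prep: assembling feature panel (mode=", config$mode, ")")
  raw <- assemble_features(traits, detections,
                           fall_window = config$fall_window)
  split <- stratified_split(y, config$test_frac,
                            seed = stage_seed(config$seed, "split"))
  fm <- prepare_features(raw, k = config$k_impute, mode = config$mode,
                         train_rows = split$train)
  log_stage("prep: ", length(fm$feature_names), " features retained (",
            length(fm$dropped_correlated), " pruned, ",
            length(fm$dropped_missing), " over-missing)")

  X_train <- fm$values[split$train, , drop = FALSE]
  y_train <- y[split$train]
  X_test <- fm$values[split$test, , drop = FALSE]
  y_test <- y[split$test]

  log_stage("train: randomized search, ", config$n_candidates,
            " candidates, 5-fold stratified CV")
  tuned <- tune_hyperparameters(X_train, y_train,
                                n_candidates = config$n_candidates,
                                seed = stage_seed(config$seed, "train"),
                                k_smote = config$k_smote)
  bal <- smote(X_train, y_train, config$k_smote)
  forest <- train_forest(bal$rows, bal$labels, tuned$config)

  probs_test <- predict_prob(forest, X_test)
  curve <- threshold_sweep(probs_test, y_test,
                           range = config$threshold_range,
                           n = config$threshold_n)
  tau <- curve$optimal
  metrics <- class_metrics(confusion(y_test,
                                     as.integer(probs_test >= tau)))
  metrics$brier <- brier(probs_test, y_test)
  metrics$threshold <- tau
  log_stage("evaluate: accuracy=", round(metrics$accuracy, 3),
            " macro_f1=", round(metrics$macro_f1, 3), " tau=", round(tau, 3))

  model <- list(forest = forest, config = tuned$config, tau = tau,
                cv_table = tuned$cv_table, seed = config$seed)

  log_stage("interpret: importance, ",
            choose(length(fm$feature_names), 2), " pairs, SHAP")
  importance <- gini_importance(forest)
  interactions <- interaction_screen(
    forest, X_test, y_test, tau = tau,
    n_repeats = config$interaction_repeats,
    cutoff = config$interaction_cutoff,
    seed = stage_seed(config$seed, "interact"))
  shap <- shap_dependence(forest, X_train)

  log_stage("network: bootstrap n_boot=", config$n_boot)
  net <- bootstrap_network(raw[fm$feature_names], n_boot = config$n_boot,
                           seed = stage_seed(config$seed, "network"))

  result <- list(traits = traits, detections = detections,
                 labels = labels_df, features = fm, split = split,
                 model = model, metrics = metrics, threshold_curve = curve,
                 importance = importance, interactions = interactions,
                 shap = shap, network = net, config = config)
  if (!is.null(outdir)) write_run(result, outdir)
  log_stage("done in ", round(as.numeric(Sys.time() - t0, units = "secs")),
            " s")
  invisible(result)
}

# Persist every stage artefact of a pipeline run as plain-text files.
write_run <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  write_traits(result$traits, out("cohort_traits.csv"))
  write_detections(result$detections, out("detections.csv"))
  utils::write.csv(result$labels, out("labels.csv"), row.names = FALSE)
  fmat <- cbind(bird_id = result$features$bird_ids, result$features$values)
  utils::write.csv(fmat, out("feature_matrix.csv"), row.names = FALSE)
  m <- result$metrics
  yaml::write_yaml(lapply(m, as.numeric), out("metrics.yml"))
  utils::write.csv(data.frame(threshold = result$threshold_curve$grid,
                              macro_f1 = result$threshold_curve$macro_f1),
                   out("threshold_curve.csv"), row.names = FALSE)
  imp <- result$importance
  utils::write.csv(data.frame(feature = names(imp$importance),
                              gini_importance = as.numeric(imp$importance),
                              null_line = imp$null_line),
                   out("importance.csv"), row.names = FALSE)
  utils::write.csv(result$interactions, out("interactions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$shap$shap), out("shap_values.csv"),
                   row.names = FALSE)
  utils::write.csv(result$network, out("trait_network.csv"),
                   row.names = FALSE)
  cfg <- result$config
  yaml::write_yaml(unclass(cfg), out("config_resolved.yml"))
  invisible(outdir)
}
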