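trait_columns <- c("bird_id", "release_year", "release_day", "release_lat",
                   "release_lon", "sex", "ancestry", "heterozygosity",
                   "wing_chord", "kipps", "distal", "p7", "p8", "p9", "p10",
                   "tail", "tarsus", "weight")

detection_columns <- c("bird_id", "station_id", "lat", "lon",
                       "days_since_tag")

#' Write / read a detection table
#'
#' CSV with columns `bird_id`, `station_id`, `lat`, `lon`,
#' `days_since_tag`; UTF-8, dot decimal separator, empty cell = missing.
#' Reading validates the schema: all columns present, coordinates within
#' range, no negative timestamps.
#'
#' @param detections detection data.frame.
#' @param path file path.
#' @export
write_detections <- function(detections, path) {
  stopifnot(all(detection_columns %in% names(detections)))
  utils::write.csv(detections[detection_columns], path,
                   row.names = FALSE, na = "")
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(detection_columns, names(d))
  if (length(missing_cols))
    stop("detection table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(d$days_since_tag < 0, na.rm = TRUE))
    stop("negative days_since_tag at line ",
         which(d$days_since_tag < 0)[1] + 1)
  if (any(abs(d$lat) > 90, na.rm = TRUE) || any(abs(d$lon) > 180, na.rm = TRUE))
    stop("coordinates out of range")
  d
}

#' Write / read a per-bird trait table
#'
#' CSV with one row per bird (`bird_id` unique) and the morphology,
#' release-metadata and ancestry columns. Empty cells are missing values.
#'
#' @param traits trait data.frame (extra columns are dropped on write).
#' @param path file path.
#' @export
write_traits <- function(traits, path) {
  stopifnot(all(trait_columns %in% names(traits)))
  utils::write.csv(traits[trait_columns], path, row.names = FALSE, na = "")
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trait_columns, names(d))
  if (length(missing_cols))
    stop("trait table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- d$bird_id[duplicated(d$bird_id)]
  if (length(dup))
    stop("duplicate bird_id: ", paste(unique(dup), collapse = ", "))
  numeric_cols <- setdiff(trait_columns, "bird_id")
  for (cl in numeric_cols)
    if (!is.numeric(d[[cl]]) && !all(is.na(d[[cl]])))
      stop("non-numeric values in column ", cl)
  d
}

#' Pipeline run configuration
#'
#' Collects every stage parameter with validated defaults. Unknown keys
#' are rejected. Per-stage seeds are derived from the global seed by
#' stage-name hashing (see [stage_seed()]) so stages can be rerun in
#' isolation reproducibly.
#'
#' @param seed global seed.
#' @param n_birds cohort size for the simulate stage.
#' @param mode preprocessing mode, `"pooled"` or `"strict"`.
#' @param cjs_mode `"cohort"` or `"per_bird"` survival labeling.
#' @param test_frac held-out fraction of the stratified split.
#' @param k_impute,k_smote neighbour counts.
#' @param n_candidates randomized-search candidates.
#' @param threshold_range,threshold_n macro-F1 threshold grid.
#' @param interaction_cutoff retention cutoff on the pairwise F1 drop.
#' @param interaction_repeats permutations averaged per pair.
#' @param n_boot bootstrap replicates of the trait network.
#' @param fall_window day-of-year limits for fall timing.
#' @return validated config list, class `run_config`.
#' @export
run_config <- function(seed = 42L, n_birds = 600L,
                       mode = c("pooled", "strict"),
                       cjs_mode = c("cohort", "per_bird"),
                       test_frac = 0.2, k_impute = 5, k_smote = 5,
                       n_candidates = 50,
                       threshold_range = c(0.40, 0.70), threshold_n = 100,
                       interaction_cutoff = 0.1, interaction_repeats = 1,
                       n_boot = 10000, fall_window = c(213, 304)) {
  mode <- match.arg(mode)
  cjs_mode <- match.arg(cjs_mode)
  if (test_frac <= 0 || test_frac >= 1)
    stop("test_frac must be in (0, 1)")
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  structure(list(seed = as.integer(seed), n_birds = as.integer(n_birds),
                 mode = mode, cjs_mode = cjs_mode, test_frac = test_frac,
                 k_impute = k_impute, k_smote = k_smote,
                 n_candidates = n_candidates,
                 threshold_range = threshold_range,
                 threshold_n = threshold_n,
                 interaction_cutoff = interaction_cutoff,
                 interaction_repeats = interaction_repeats,
                 n_boot = n_boot, fall_window = fall_window),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys must match [run_config()] arguments.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Deterministic per-stage seed derived from the global seed
#'
#' Hashes the stage name into a 31-bit offset so each pipeline stage gets
#' its own reproducible RNG stream.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483399 + 1)
}
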