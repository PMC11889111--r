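#' Build the per-window feature table for a set of recordings
#'
#' Runs matching-to-action segmentation and windowing on every recording,
#' then computes the 28 gaze statistics and the 99 IMU descriptors per
#' 3-second window. Each row carries `participant_id`, `recording_id`,
#' `window_id` and the familiarity `condition` label, so downstream splits
#' can be made participant-aware.
#'
#' @param recordings List of preprocessed `wayfam_recording`s (the unified
#'   IMU stream is created on the fly when absent).
#' @param window_s Window width (s).
#' @param radius_m Junction arrival radius (m); default per route.
#' @param dispersion_threshold,duration_threshold_ms I-DT parameters.
#' @param units_per_deg Saccade head-compensation calibration.
#' @return A tibble (the feature table); feature columns are tagged by
#'   modality in `attr(, "families")`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(2, effect_config(), seed = 1)
#' cohort <- lapply(cohort, preprocess_recording)
#' ft <- extract_features(cohort)
#' }
#' @export
extract_features <- function(recordings, window_s = 3, radius_m = NULL,
                             dispersion_threshold = 0.02,
                             duration_threshold_ms = 100,
                             units_per_deg = 1 / DEG_PER_SCENE_UNIT) {
  if (inherits(recordings, "wayfam_recording")) recordings <- list(recordings)
  rows <- purrr::map_dfr(recordings, function(rec) {
    if (is.null(rec$imu)) rec <- downsample_imu(rec)
    r <- radius_m %||% rec$route$decision_radius_m
    wins <- window_segments(extract_segments(rec, radius_m = r), width_s = window_s)
    if (nrow(wins) == 0) return(NULL)
    gz <- extract_gaze_features(rec, wins, dispersion_threshold,
                                duration_threshold_ms, units_per_deg)
    im <- extract_imu_features(rec, wins)
    meta <- tibble::tibble(
      participant_id = rec$participant_id,
      recording_id = rec$recording_id,
      condition = rec$condition,
      window_id = wins$window_id,
      t0 = wins$t0
    )
    dplyr::bind_cols(meta,
                     gz[, gaze_feature_names(), drop = FALSE],
                     im[, imu_feature_names(), drop = FALSE])
  })
  attr(rows, "families") <- feature_modalities()
  rows
}

# Modality tag (gaze | imu) per feature column.
feature_modalities <- function() {
  c(stats::setNames(rep("gaze", length(gaze_feature_names())), gaze_feature_names()),
    stats::setNames(rep("imu", length(imu_feature_names())), imu_feature_names()))
}

metadata_cols <- function() {
  c("participant_id", "recording_id", "condition", "window_id", "t0")
}

#' Scientific family tag of feature columns
#'
#' Maps a feature name to the behavioral family it describes: `fixation`,
#' `saccade`, `yaw`, `orientation` (roll/pitch) or `acceleration`.
#' Used to label SHAP importance ranks.
#'
#' @param feature Character vector of feature names.
#' @return Character vector of family tags.
#' @export
feature_family <- function(feature) {
  dplyr::case_when(
    startsWith(feature, "fix_") ~ "fixation",
    startsWith(feature, "sac_") | feature == "gl_ratio" ~ "saccade",
    startsWith(feature, "yaw") ~ "yaw",
    startsWith(feature, "roll") | startsWith(feature, "pitch") ~ "orientation",
    TRUE ~ "acceleration"
  )
}
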