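#' Simulate a cohort and classify familiarity end to end
#'
#' Convenience wrapper chaining the whole pipeline: cohort generation,
#' preprocessing, matching-to-action windowing, feature extraction and the
#' classification experiment. This is the entry point for calibration
#' studies on synthetic cohorts (e.g. a null-effect cohort should classify
#' at chance; a planted single-family contrast should be recovered and
#' attributed to that family by SHAP).
#'
#' @param effect An [effect_config()].
#' @param n_participants Cohort size (two recordings each).
#' @param route_pool Routes sampled per recording.
#' @param seed Integer seed driving generation, splits and training.
#' @param feature_sets,schemes,n_repeats,grid,n_search,n_cv_folds Passed to
#'   [run_experiment()].
#' @return List with `features` (the window feature table) and `experiment`
#'   (a `wayfam_experiment`).
#' @examples
#' \donttest{
#' out <- run_pipeline(null_effect_config(), n_participants = 6, seed = 1)
#' out$experiment
#' }
#' @export
run_pipeline <- function(effect, n_participants = 10,
                         route_pool = list(route_zigzag(4, 35)),
                         seed = 1, feature_sets = "gaze_imu",
                         schemes = "l5o4t", n_repeats = 1,
                         grid = default_model_grid(), n_search = NULL,
                         n_cv_folds = 10) {
  cohort <- generate_cohort(n_participants, effect, route_pool, seed = seed)
  cohort <- lapply(cohort, preprocess_recording)
  features <- extract_features(cohort)
  experiment <- run_experiment(features, feature_sets = feature_sets,
                               schemes = schemes, seed = derive_seed(seed, 997L),
                               n_repeats = n_repeats, grid = grid,
                               n_search = n_search, n_cv_folds = n_cv_folds)
  list(features = features, experiment = experiment)
}

#' Effect configuration with a contrast in yaw dynamics only
#'
#' All condition-dependent parameters are equalized except the yaw
#' head-scanning oscillation, whose familiar-condition amplitude (hence
#' SD) is `ratio` times the unfamiliar one. Used to test that the pipeline
#' recovers a class signal planted in a single feature family and
#' attributes it to yaw.
#'
#' @param ratio Familiar/unfamiliar yaw-oscillation amplitude ratio.
#' @param base_amplitude_deg Unfamiliar-condition amplitude (degrees).
#' @param ... Passed to [effect_config()].
#' @return A `wayfam_effect`.
#' @export
yaw_only_effect_config <- function(ratio = 2, base_amplitude_deg = 12, ...) {
  cfg <- null_effect_config(...)
  cfg$yaw_osc_amplitude_deg <- c(familiar = ratio * base_amplitude_deg,
                                 unfamiliar = base_amplitude_deg)
  cfg$yaw_osc_freq_hz[] <- 0.2
  validate_effect_config(cfg)
  cfg
}
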