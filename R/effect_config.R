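#' Condition-dependent effect configuration for the session generator
#'
#' Bundles every tunable of the synthetic wayfinding-session generator.
#' Parameters that carry the familiarity contrast (yaw scanning, fixation
#' dispersion, saccade amplitude) are given per condition; setting the two
#' conditions to identical values removes all class signal, which is the
#' null configuration used for calibration checks.
#'
#' @param yaw_osc_amplitude_deg Named numeric, amplitude (degrees) of the slow
#'   head-scanning yaw oscillation, one value per condition
#'   (`familiar`, `unfamiliar`).
#' @param yaw_osc_freq_hz Named numeric, frequency (Hz) of that oscillation
#'   per condition.
#' @param gait_step_freq_hz Step frequency of the walking-bounce component on
#'   the vertical acceleration channel (Hz).
#' @param acc_noise_sd Standard deviation of the additive accelerometer noise
#'   (m/s^2); scalar or named per condition to plant an
#'   acceleration-variance contrast.
#' @param fixation_duration_mean_ms,fixation_duration_sd_ms Mean and SD (ms)
#'   of the log-normal fixation-duration distribution.
#' @param fixation_dispersion_scale Named numeric per condition; half-width
#'   of the bounded within-fixation gaze jitter, in normalized scene units
#'   (per-axis dispersion of a long fixation approaches twice this value).
#' @param saccade_amplitude_shape Gamma shape of the saccade-amplitude
#'   distribution (shared across conditions).
#' @param saccade_amplitude_scale Named numeric per condition; gamma scale of
#'   the saccade-amplitude distribution, normalized scene units.
#' @param walking_speed_mps Walking speed along the route (m/s).
#' @param gnss_noise_sd_m Isotropic GNSS position noise SD (m).
#' @param gnss_inaccurate_rate Fraction of GNSS samples flagged `inaccurate`
#'   and displaced by a large jump, emulating loss of RTK correction.
#' @param anomaly_rate Expected number of cap-touch artifact bursts per
#'   minute (Poisson rate).
#' @param anomaly_peak_facc Peak free-acceleration magnitude of an injected
#'   artifact burst (m/s^2).
#' @param seed Default integer seed used when a generator call does not pass
#'   its own.
#'
#' @return An object of class `wayfam_effect` (a validated list).
#' @examples
#' cfg <- effect_config()
#' null_cfg <- null_effect_config() # both conditions identical
#' @export
effect_config <- function(yaw_osc_amplitude_deg = c(familiar = 10, unfamiliar = 20),
                          yaw_osc_freq_hz = c(familiar = 0.15, unfamiliar = 0.25),
                          gait_step_freq_hz = 1.8,
                          acc_noise_sd = 0.3,
                          fixation_duration_mean_ms = 250,
                          fixation_duration_sd_ms = 100,
                          fixation_dispersion_scale = c(familiar = 0.003, unfamiliar = 0.0045),
                          saccade_amplitude_shape = 2,
                          saccade_amplitude_scale = c(familiar = 0.04, unfamiliar = 0.07),
                          walking_speed_mps = 1.4,
                          gnss_noise_sd_m = 1.5,
                          gnss_inaccurate_rate = 0.02,
                          anomaly_rate = 1,
                          anomaly_peak_facc = 15,
                          seed = 1L) {
  cfg <- list(
    yaw_osc_amplitude_deg = as_condition_pair(yaw_osc_amplitude_deg),
    yaw_osc_freq_hz = as_condition_pair(yaw_osc_freq_hz),
    gait_step_freq_hz = gait_step_freq_hz,
    acc_noise_sd = as_condition_pair(acc_noise_sd),
    fixation_duration_mean_ms = fixation_duration_mean_ms,
    fixation_duration_sd_ms = fixation_duration_sd_ms,
    fixation_dispersion_scale = as_condition_pair(fixation_dispersion_scale),
    saccade_amplitude_shape = saccade_amplitude_shape,
    saccade_amplitude_scale = as_condition_pair(saccade_amplitude_scale),
    walking_speed_mps = walking_speed_mps,
    gnss_noise_sd_m = gnss_noise_sd_m,
    gnss_inaccurate_rate = gnss_inaccurate_rate,
    anomaly_rate = anomaly_rate,
    anomaly_peak_facc = anomaly_peak_facc,
    seed = as.integer(seed)
  )
  class(cfg) <- "wayfam_effect"
  validate_effect_config(cfg)
  cfg
}

#' @rdname effect_config
#' @param ... Passed on to [effect_config()].
#' @export
null_effect_config <- function(...) {
  cfg <- effect_config(...)
  for (f in condition_pair_fields()) {
    cfg[[f]][] <- mean(cfg[[f]])
  }
  cfg
}

condition_pair_fields <- function() {
  c("yaw_osc_amplitude_deg", "yaw_osc_freq_hz", "acc_noise_sd",
    "fixation_dispersion_scale", "saccade_amplitude_scale")
}

conditions <- function() c("familiar", "unfamiliar")

as_condition_pair <- function(x) {
  if (length(x) == 1L) x <- stats::setNames(rep(as.numeric(x), 2L), conditions())
  if (!all(conditions() %in% names(x))) {
    stop("per-condition parameter needs named values for 'familiar' and 'unfamiliar'",
         call. = FALSE)
  }
  as.numeric(x[conditions()]) |> stats::setNames(conditions())
}

validate_effect_config <- function(cfg) {
  stopifnot(inherits(cfg, "wayfam_effect"))
  nonneg <- c("gait_step_freq_hz", "fixation_duration_mean_ms",
              "fixation_duration_sd_ms", "saccade_amplitude_shape",
              "walking_speed_mps", "gnss_noise_sd_m", "gnss_inaccurate_rate",
              "anomaly_rate", "anomaly_peak_facc")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0) || any(!is.finite(cfg[[f]]))) {
      stop("effect_config field '", f, "' must be finite and >= 0", call. = FALSE)
    }
  }
  for (f in condition_pair_fields()) {
    if (any(cfg[[f]] < 0) || any(!is.finite(cfg[[f]]))) {
      stop("effect_config field '", f, "' must be finite and >= 0", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.wayfam_effect <- function(x, ...) {
  cat("<wayfam_effect>\n")
  for (f in setdiff(names(x), "seed")) {
    v <- x[[f]]
    if (length(v) == 2L) {
      cat(sprintf("  %-28s familiar=%g unfamiliar=%g\n", f, v[["familiar"]], v[["unfamiliar"]]))
    } else {
      cat(sprintf("  %-28s %g\n", f, v))
    }
  }
  cat(sprintf("  %-28s %d\n", "seed", x$seed))
  invisible(x)
}
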