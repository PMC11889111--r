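#' I-DT fixation detection
#'
#' Classical Identification by Dispersion-Threshold: a candidate window is
#' grown from the minimum-duration span while its dispersion
#' `(max x - min x) + (max y - min y)` stays at or below the threshold;
#' when it can grow no further a fixation is emitted with the mean point as
#' centroid, and the scan resumes after it (greedy left-to-right). At a
#' 200 Hz gaze rate velocity-based event detection is not viable, which is
#' why the dispersion criterion is used. Thresholds are in normalized scene
#' units: with a mobile tracker the stimulus distance is unknown, so
#' degrees are not meaningful.
#'
#' @param gaze Time-sorted tibble with `t` (s), `x`, `y` (normalized units).
#' @param dispersion_threshold Maximum within-fixation dispersion.
#' @param duration_threshold_ms Minimum fixation duration (ms).
#' @return Tibble of fixations: `t_start`, `t_end`, `duration_ms`, centroid
#'   `x`, `y`, `dispersion`, `dispersion_x`, `dispersion_y`.
#' @examples
#' g <- tibble::tibble(t = seq(0, 1, by = 0.005), x = 0.5, y = 0.5)
#' detect_fixations_idt(g)
#' @export
detect_fixations_idt <- function(gaze, dispersion_threshold = 0.02,
                                 duration_threshold_ms = 100) {
  empty <- tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          duration_ms = numeric(0), x = numeric(0), y = numeric(0),
                          dispersion = numeric(0), dispersion_x = numeric(0),
                          dispersion_y = numeric(0))
  n <- nrow(gaze)
  if (n == 0) return(empty)
  t <- gaze$t
  x <- gaze$x
  y <- gaze$y
  dur_s <- duration_threshold_ms / 1000
  out <- vector("list", 0)
  i <- 1L
  while (i <= n) {
    j <- i + findInterval(t[i] + dur_s - 1e-12, t[i:n])
    if (j > n) break # remaining span shorter than the minimum duration
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= dispersion_threshold) {
      while (j < n) {
        nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
        nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
        if ((nxmax - nxmin) + (nymax - nymin) > dispersion_threshold) break
        j <- j + 1L
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        t_start = t[i], t_end = t[j], duration_ms = (t[j] - t[i]) * 1000,
        x = mean(x[i:j]), y = mean(y[i:j]),
        dispersion = (xmax - xmin) + (ymax - ymin),
        dispersion_x = xmax - xmin, dispersion_y = ymax - ymin
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Head-rotation-compensated saccade between two fixations
#'
#' The raw inter-fixation centroid displacement confounds the eye's saccade
#' with the apparent scene shift caused by head rotation over the gap. The
#' head-induced shift is predicted from the IMU rotation delta
#' (yaw for x, pitch for y) mapped into normalized scene units by the
#' camera calibration, and subtracted before taking the Euclidean norm.
#' With `units_per_deg = 0` the compensation degenerates to the plain
#' centroid distance.
#'
#' @param fix_prev,fix_next Consecutive fixation rows (as returned by
#'   [detect_fixations_idt()]).
#' @param imu_window IMU tibble with `t`, `pitch`, `yaw` covering the
#'   inter-fixation gap; if it does not, the uncompensated amplitude is
#'   returned and flagged.
#' @param units_per_deg Normalized scene units per degree of head rotation;
#'   default from a nominal 82-degree horizontal field of view.
#' @return One-row tibble: `amplitude`, `duration_ms`, `compensated`.
#' @export
compensate_saccade <- function(fix_prev, fix_next, imu_window,
                               units_per_deg = 1 / DEG_PER_SCENE_UNIT) {
  g0 <- fix_prev$t_end
  g1 <- fix_next$t_start
  raw_dx <- fix_next$x - fix_prev$x
  raw_dy <- fix_next$y - fix_prev$y
  covered <- !is.null(imu_window) && nrow(imu_window) >= 2 &&
    min(imu_window$t) <= g0 + 1e-9 && max(imu_window$t) >= g1 - 1e-9
  if (covered && units_per_deg != 0) {
    yaw_at <- stats::approxfun(imu_window$t, imu_window$yaw, rule = 2)
    pitch_at <- stats::approxfun(imu_window$t, imu_window$pitch, rule = 2)
    head_dx <- -(yaw_at(g1) - yaw_at(g0)) * units_per_deg
    head_dy <- (pitch_at(g1) - pitch_at(g0)) * units_per_deg
    amp <- sqrt((raw_dx - head_dx)^2 + (raw_dy - head_dy)^2)
  } else {
    amp <- sqrt(raw_dx^2 + raw_dy^2)
  }
  tibble::tibble(amplitude = amp, duration_ms = (g1 - g0) * 1000,
                 compensated = covered && units_per_deg != 0)
}

# Adjusted Fisher-Pearson sample skewness; NA below 3 observations.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 == 0) return(NA_real_)
  g1 <- (sum((x - m)^3) / n) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

stat4 <- function(x, prefix) {
  if (length(x) == 0) {
    v <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  } else {
    v <- c(mean(x), min(x), max(x), if (length(x) >= 2) stats::var(x) else NA_real_)
  }
  stats::setNames(as.list(v), paste0(prefix, c("_mean", "_min", "_max", "_var")))
}

#' Names of the gaze feature bank
#'
#' 28 statistics: mean/min/max/var of fixation duration, dispersion and its
#' x/y components (16), fixation frequency, mean/min/max/var of saccade
#' amplitude and duration (8), saccade-amplitude skewness, saccade
#' frequency, and the g-l ratio (long-to-short saccade count ratio).
#'
#' @return Character vector of 28 column names.
#' @export
gaze_feature_names <- function() {
  c(paste0("fix_dur", c("_mean", "_min", "_max", "_var")),
    paste0("fix_disp", c("_mean", "_min", "_max", "_var")),
    paste0("fix_disp_x", c("_mean", "_min", "_max", "_var")),
    paste0("fix_disp_y", c("_mean", "_min", "_max", "_var")),
    "fix_freq",
    paste0("sac_ampl", c("_mean", "_min", "_max", "_var")),
    paste0("sac_dur", c("_mean", "_min", "_max", "_var")),
    "sac_ampl_skew", "sac_freq", "gl_ratio")
}

#' Gaze feature row for one window
#'
#' Computes the 28 gaze statistics (see [gaze_feature_names()]) from the
#' fixations and saccades detected inside one window. Frequencies are
#' events per second of window duration. The g-l ratio splits saccades into
#' long and short at `amplitude_split` (canonically the median saccade
#' amplitude of the whole recording); it is missing when no saccade falls
#' at or below the split. Variances and skewness are missing below two
#' (three) events.
#'
#' @param fixations,saccades Event tibbles clipped to the window.
#' @param duration_s Window duration (s).
#' @param amplitude_split Long/short amplitude split; defaults to the
#'   within-window median.
#' @return One-row tibble with 28 named features.
#' @export
gaze_feature_row <- function(fixations, saccades, duration_s = 3,
                             amplitude_split = NULL) {
  amps <- saccades$amplitude
  if (is.null(amplitude_split)) {
    amplitude_split <- if (length(amps)) stats::median(amps) else NA_real_
  }
  n_short <- sum(amps <= amplitude_split)
  gl <- if (length(amps) == 0 || is.na(amplitude_split) || n_short == 0) {
    NA_real_
  } else {
    sum(amps > amplitude_split) / n_short
  }
  tibble::as_tibble(c(
    stat4(fixations$duration_ms, "fix_dur"),
    stat4(fixations$dispersion, "fix_disp"),
    stat4(fixations$dispersion_x, "fix_disp_x"),
    stat4(fixations$dispersion_y, "fix_disp_y"),
    list(fix_freq = nrow(fixations) / duration_s),
    stat4(amps, "sac_ampl"),
    stat4(saccades$duration_ms, "sac_dur"),
    list(sac_ampl_skew = sample_skewness(amps),
         sac_freq = length(amps) / duration_s,
         gl_ratio = gl)
  ))[, gaze_feature_names()]
}

# Detect fixations/saccades for every window of one recording and return
# the per-window gaze feature rows (g-l split = recording-level median).
extract_gaze_features <- function(recording, windows,
                                  dispersion_threshold = 0.02,
                                  duration_threshold_ms = 100,
                                  units_per_deg = 1 / DEG_PER_SCENE_UNIT) {
  stopifnot(inherits(recording, "wayfam_recording"))
  imu <- recording$imu %||% recording$imu_rotation
  wins <- windows[windows$recording_id == recording$recording_id, , drop = FALSE]
  if (nrow(wins) == 0) return(NULL)
  events <- lapply(seq_len(nrow(wins)), function(i) {
    g <- recording$gaze
    g <- g[g$t >= wins$t0[i] & g$t < wins$t0[i] + wins$duration[i], , drop = FALSE]
    fx <- detect_fixations_idt(g, dispersion_threshold, duration_threshold_ms)
    sac <- NULL
    if (nrow(fx) >= 2) {
      sac <- purrr::map_dfr(seq_len(nrow(fx) - 1L), function(k) {
        compensate_saccade(fx[k, ], fx[k + 1L, ], imu, units_per_deg)
      })
    } else {
      sac <- tibble::tibble(amplitude = numeric(0), duration_ms = numeric(0),
                            compensated = logical(0))
    }
    list(fixations = fx, saccades = sac)
  })
  all_amps <- unlist(lapply(events, function(e) e$saccades$amplitude))
  split <- if (length(all_amps)) stats::median(all_amps) else NA_real_
  rows <- purrr::map_dfr(seq_along(events), function(i) {
    gaze_feature_row(events[[i]]$fixations, events[[i]]$saccades,
                     duration_s = wins$duration[i], amplitude_split = split)
  })
  dplyr::bind_cols(wins[, c("recording_id", "window_id", "t0")], rows)
}
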