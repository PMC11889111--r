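#' Generate one synthetic wayfinding recording
#'
#' Simulates the sensor streams of a single walk along a route under one
#' familiarity condition: a 200 Hz gaze stream driven by a fixation-saccade
#' renewal process, a multirate head-IMU (400 Hz inertial, 100 Hz
#' orientation) with a gait sinusoid, slow condition-scaled yaw scanning and
#' Poisson-placed cap-touch artifact bursts, and a 1 Hz GNSS track following
#' the route polyline with additive noise. One instruction-request event is
#' emitted per turn decision point.
#'
#' Ground truth needed by injection-recovery tests (artifact intervals,
#' per-junction arrival times) is attached under `$truth`; it is synthetic
#' bookkeeping, not a sensor product.
#'
#' @param participant_id Character or integer identifier.
#' @param condition `"familiar"` or `"unfamiliar"`.
#' @param effect An [effect_config()].
#' @param route A [make_route()] object.
#' @param seed Integer seed; the full recording is reproducible given
#'   (arguments, seed).
#' @param participant_effects Optional list with `yaw_offset` (deg) and
#'   `gait_freq_jitter` (Hz), the participant-level random effects shared
#'   across a participant's two recordings.
#'
#' @return A `wayfam_recording`: a list with `gaze`, `imu_inertial`,
#'   `imu_rotation`, `gnss`, `events`, `route`, `exclusion_intervals`,
#'   metadata and `truth`. The unified 100 Hz `imu` table is added by
#'   [downsample_imu()] / [preprocess_recording()].
#' @examples
#' rec <- generate_recording("p01", "familiar", effect_config(), route_zigzag(), seed = 1)
#' rec
#' @export
generate_recording <- function(participant_id, condition, effect, route,
                               seed = effect$seed,
                               participant_effects = NULL) {
  condition <- match.arg(condition, conditions())
  validate_effect_config(effect)
  stopifnot(inherits(route, "wayfam_route"))
  if (nrow(route$decision_points) < 1L) {
    stop("route has no decision points", call. = FALSE)
  }
  pe <- participant_effects %||% list(yaw_offset = 0, gait_freq_jitter = 0)

  with_seed(seed, {
    cl <- polyline_cumlen(route$polyline)
    total_len <- cl[length(cl)]
    speed <- effect$walking_speed_mps
    duration <- total_len / speed

    gnss <- simulate_gnss(route, duration, speed, effect)
    imu <- simulate_imu(duration, condition, effect, pe)
    gaze <- simulate_gaze(duration, condition, effect, imu$rotation)
    events <- simulate_events(route, speed)
    arrivals <- attr(events, "arrival_times")
    attr(events, "arrival_times") <- NULL

    structure(
      list(
        participant_id = as.character(participant_id),
        condition = condition,
        recording_id = paste(participant_id, condition, sep = "_"),
        gaze = gaze,
        imu_inertial = imu$inertial,
        imu_rotation = imu$rotation,
        imu = NULL,
        gnss = gnss,
        route = route,
        events = events,
        exclusion_intervals = tibble::tibble(t0 = numeric(0), t1 = numeric(0)),
        seed = as.integer(seed),
        effect = effect,
        truth = list(artifact_intervals = imu$artifact_intervals,
                     arrival_times = arrivals)
      ),
      class = "wayfam_recording"
    )
  })
}

#' @export
print.wayfam_recording <- function(x, ...) {
  cat(sprintf("<wayfam_recording> %s | %s\n", x$participant_id, x$condition))
  cat(sprintf("  gaze: %d samples @200 Hz | imu: %d inertial + %d rotation | gnss: %d fixes\n",
              nrow(x$gaze), nrow(x$imu_inertial), nrow(x$imu_rotation), nrow(x$gnss)))
  cat(sprintf("  events: %d | exclusions: %d | preprocessed imu: %s\n",
              nrow(x$events), nrow(x$exclusion_intervals),
              if (is.null(x$imu)) "no" else sprintf("%d rows", nrow(x$imu))))
  invisible(x)
}

simulate_gnss <- function(route, duration, speed, effect) {
  t <- seq(0, floor(duration))
  pos <- point_at_arclength(route$polyline, speed * t)
  east <- pos[, 1] + stats::rnorm(length(t), 0, effect$gnss_noise_sd_m)
  north <- pos[, 2] + stats::rnorm(length(t), 0, effect$gnss_noise_sd_m)
  quality <- rep("ok", length(t))
  # big flagged jumps away from the track ends so the 2+2 smoother applies
  n <- length(t)
  if (n > 5 && effect$gnss_inaccurate_rate > 0) {
    cand <- 3:(n - 2)
    bad <- cand[stats::runif(length(cand)) < effect$gnss_inaccurate_rate]
    if (length(bad)) {
      ang <- stats::runif(length(bad), 0, 2 * pi)
      r <- stats::runif(length(bad), 20, 50)
      east[bad] <- east[bad] + r * cos(ang)
      north[bad] <- north[bad] + r * sin(ang)
      quality[bad] <- "inaccurate"
    }
  }
  tibble::tibble(t = as.numeric(t), east = east, north = north, quality = quality)
}

simulate_imu <- function(duration, condition, effect, pe) {
  fs_rot <- 100
  fs_in <- 400
  t_rot <- seq(0, duration, by = 1 / fs_rot)
  t_in <- seq(0, duration, by = 1 / fs_in)

  amp <- effect$yaw_osc_amplitude_deg[[condition]]
  freq <- effect$yaw_osc_freq_hz[[condition]]
  phase <- stats::runif(3, 0, 2 * pi)
  ar_noise <- function(n, innov_sd) {
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), 0.95, "recursive"))
  }
  yaw <- wrap_angle_deg(pe$yaw_offset + amp * sin(2 * pi * freq * t_rot + phase[1]) +
                          ar_noise(length(t_rot), 0.3))
  roll <- 2 * sin(2 * pi * 0.5 * t_rot + phase[2]) + ar_noise(length(t_rot), 0.1)
  pitch <- 3 * sin(2 * pi * 0.4 * t_rot + phase[3]) + ar_noise(length(t_rot), 0.1)

  f_gait <- effect$gait_step_freq_hz + pe$gait_freq_jitter
  noise_sd <- effect$acc_noise_sd[[condition]]
  gphase <- stats::runif(2, 0, 2 * pi)
  facc_z <- 1.5 * sin(2 * pi * f_gait * t_in) +
    0.4 * sin(2 * pi * 2 * f_gait * t_in + gphase[1]) +
    stats::rnorm(length(t_in), 0, noise_sd)
  facc_y <- 0.6 * sin(2 * pi * f_gait / 2 * t_in + gphase[2]) +
    stats::rnorm(length(t_in), 0, noise_sd)
  facc_x <- stats::rnorm(length(t_in), 0, noise_sd)

  # Poisson cap-touch bursts: Gaussian envelope, dominant random axis pushed
  # above the configured peak so the 10 m/s^2 rule can find every burst.
  half_support <- 0.4
  env_sd <- 0.15
  n_burst <- stats::rpois(1, effect$anomaly_rate * duration / 60)
  intervals <- tibble::tibble(t0 = numeric(0), t1 = numeric(0))
  if (n_burst > 0 && duration > 2 * half_support + 1) {
    centers <- sort(stats::runif(n_burst, half_support + 0.5, duration - half_support - 0.5))
    # keep bursts separated so truth intervals stay disjoint
    keep <- c(TRUE, diff(centers) > 2 * half_support + 0.2)
    centers <- centers[keep]
    for (ct in centers) {
      d <- stats::rnorm(3)
      d <- d / max(abs(d))
      peak <- effect$anomaly_peak_facc * stats::runif(1, 1.15, 1.4)
      envl <- peak * exp(-(t_in - ct)^2 / (2 * env_sd^2))
      mask <- abs(t_in - ct) <= half_support
      facc_x[mask] <- facc_x[mask] + d[1] * envl[mask]
      facc_y[mask] <- facc_y[mask] + d[2] * envl[mask]
      facc_z[mask] <- facc_z[mask] + d[3] * envl[mask]
    }
    intervals <- tibble::tibble(t0 = centers - half_support, t1 = centers + half_support)
  }

  inertial <- tibble::tibble(
    t = t_in,
    acc_x = facc_x + 0.2, acc_y = facc_y - 0.3, acc_z = facc_z + 9.81,
    facc_x = facc_x, facc_y = facc_y, facc_z = facc_z
  )
  rotation <- tibble::tibble(t = t_rot, roll = roll, pitch = pitch, yaw = yaw)
  list(inertial = inertial, rotation = rotation, artifact_intervals = intervals)
}

simulate_gaze <- function(duration, condition, effect, rotation) {
  fs <- 200
  mean_ms <- effect$fixation_duration_mean_ms
  sd_ms <- effect$fixation_duration_sd_ms
  sdlog <- sqrt(log(1 + (sd_ms / mean_ms)^2))
  meanlog <- log(mean_ms) - sdlog^2 / 2
  disp_sd <- effect$fixation_dispersion_scale[[condition]]
  amp_shape <- effect$saccade_amplitude_shape
  amp_scale <- effect$saccade_amplitude_scale[[condition]]

  yaw_at <- stats::approxfun(rotation$t, rotation$yaw, rule = 2)
  pitch_at <- stats::approxfun(rotation$t, rotation$pitch, rule = 2)

  n_total <- floor(duration * fs) + 1L
  t <- (seq_len(n_total) - 1L) / fs
  x <- numeric(n_total)
  y <- numeric(n_total)

  cx <- 0.5
  cy <- 0.5
  now <- 0
  i <- 1L
  reflect <- function(v, lo = 0.1, hi = 0.9) {
    # reflect into [lo, hi]
    w <- hi - lo
    u <- (v - lo) %% (2 * w)
    lo + ifelse(u > w, 2 * w - u, u)
  }
  while (now < duration && i <= n_total) {
    fix_dur <- max(stats::rlnorm(1, meanlog, sdlog), 60) / 1000
    t_end <- min(now + fix_dur, duration)
    idx <- which(t >= now & t < t_end + 1e-12)
    if (length(idx)) {
      # bounded jitter: dispersion of a fixation stays below the I-DT
      # threshold instead of growing with its sample count
      x[idx] <- cx + stats::runif(length(idx), -disp_sd, disp_sd)
      y[idx] <- cy + stats::runif(length(idx), -disp_sd, disp_sd)
      i <- max(idx) + 1L
    }
    if (t_end >= duration) break
    # saccade: intrinsic eye jump plus apparent scene shift from head rotation
    amp <- stats::rgamma(1, shape = amp_shape, scale = amp_scale)
    ang <- stats::runif(1, 0, 2 * pi)
    sac_dur <- (20 + 2 * DEG_PER_SCENE_UNIT * amp) / 1000
    t_sac_end <- min(t_end + sac_dur, duration)
    head_dx <- -(yaw_at(t_sac_end) - yaw_at(t_end)) / DEG_PER_SCENE_UNIT
    head_dy <- (pitch_at(t_sac_end) - pitch_at(t_end)) / DEG_PER_SCENE_UNIT
    nx <- reflect(cx + amp * cos(ang) + head_dx)
    ny <- reflect(cy + amp * sin(ang) + head_dy)
    idx <- which(t >= t_end & t < t_sac_end + 1e-12)
    if (length(idx)) {
      frac <- (t[idx] - t_end) / max(t_sac_end - t_end, 1e-9)
      x[idx] <- cx + frac * (nx - cx)
      y[idx] <- cy + frac * (ny - cy)
    }
    cx <- nx
    cy <- ny
    now <- t_sac_end
  }
  tibble::tibble(t = t, x = x, y = y)
}

simulate_events <- function(route, speed) {
  cl <- polyline_cumlen(route$polyline)
  dp <- route$decision_points
  turn <- dp[dp$is_turn, , drop = FALSE]
  arrivals <- cl[dp$vertex] / speed
  names(arrivals) <- dp$junction_id
  t_req <- numeric(nrow(turn))
  prev_arrival <- 0
  for (i in seq_len(nrow(turn))) {
    arr <- cl[turn$vertex[i]] / speed
    lo <- prev_arrival + 0.5
    hi <- max(arr - 5, lo + 0.1)
    t_req[i] <- stats::runif(1, min(lo, hi), hi)
    prev_arrival <- arr
  }
  ev <- tibble::tibble(t_request = t_req, junction_id = turn$junction_id)
  attr(ev, "arrival_times") <- arrivals
  ev
}

#' Generate a paired-condition cohort
#'
#' Each participant contributes exactly two recordings, one per familiarity
#' condition, sharing that participant's random effects (baseline yaw offset
#' and gait-frequency jitter). This mirrors a within-subject walking study
#' in which every wayfinder covers one familiar and one unfamiliar route.
#'
#' @param n_participants Number of participants (>= 2).
#' @param effect An [effect_config()].
#' @param route_pool List of [make_route()] objects sampled per recording.
#' @param seed Integer seed.
#' @param yaw_offset_sd,gait_jitter_sd SDs of the participant-level random
#'   effects (degrees, Hz).
#'
#' @return A list of `wayfam_recording`s, length `2 * n_participants`.
#' @examples
#' cohort <- generate_cohort(3, effect_config(), list(route_zigzag()), seed = 1)
#' length(cohort)
#' @export
generate_cohort <- function(n_participants, effect, route_pool = list(route_zigzag()),
                            seed = effect$seed,
                            yaw_offset_sd = 15, gait_jitter_sd = 0.08) {
  if (n_participants < 2) stop("need at least 2 participants", call. = FALSE)
  if (length(route_pool) < 1) stop("route_pool must be non-empty", call. = FALSE)
  validate_effect_config(effect)

  pe_list <- with_seed(derive_seed(seed, 0L), {
    lapply(seq_len(n_participants), function(i) {
      list(yaw_offset = stats::rnorm(1, 0, yaw_offset_sd),
           gait_freq_jitter = stats::rnorm(1, 0, gait_jitter_sd))
    })
  })
  recs <- vector("list", 2L * n_participants)
  k <- 1L
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%03d", i)
    for (cond in conditions()) {
      s <- derive_seed(seed, k)
      route <- route_pool[[with_seed(s, sample.int(length(route_pool), 1))]]
      recs[[k]] <- generate_recording(pid, cond, effect, route,
                                      seed = s, participant_effects = pe_list[[i]])
      k <- k + 1L
    }
  }
  recs
}
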