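#' Zero-phase low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward
#' (zero phase distortion), the standard pre-step before change-point
#' scoring of free-acceleration channels.
#'
#' @param series Numeric vector.
#' @param cutoff_hz Cutoff frequency (Hz), must be below Nyquist.
#' @param fs_hz Sampling rate (Hz).
#' @param order Filter order (default 4).
#' @return Filtered series, same length.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 3, by = 0.01))
#' y <- lowpass_filter(x, cutoff_hz = 5, fs_hz = 100)
#' @export
lowpass_filter <- function(series, cutoff_hz, fs_hz, order = 4) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2)) {
    stop("cutoff_hz must lie in (0, fs_hz/2)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  n <- length(series)
  # mean removal plus odd-reflection padding suppress the start-up
  # transients of the forward-backward pass (unit DC gain restores the mean)
  mu <- mean(series)
  x <- series - mu
  np <- min(n - 1L, as.integer(ceiling(3 * fs_hz / cutoff_hz)))
  if (np > 0) {
    front <- 2 * x[1] - x[seq(np + 1L, 2L)]
    back <- 2 * x[n] - x[seq(n - 1L, n - np)]
    y <- signal::filtfilt(bf, c(front, x, back))[(np + 1L):(np + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  as.numeric(y) + mu
}

#' Singular spectrum transformation change scores
#'
#' Scores each evaluable time point by how much the principal subspace of
#' the past trajectory (Hankel) matrix differs from that of the future
#' trajectory matrix: `1 - mean squared principal-angle cosine` over the
#' leading `n_components` directions. Stationary signals score near 0;
#' abrupt changes in the local signal structure score near 1.
#'
#' Columns of each trajectory matrix are mean-centered, which makes the
#' score invariant to constant offsets of the series.
#'
#' @param series Numeric vector, length > `2 * window_len + lag`.
#' @param window_len Subseries (column) length of the trajectory matrices,
#'   in samples.
#' @param lag Gap between the past and future trajectory matrices, samples.
#' @param n_components Number of leading singular directions compared.
#' @param stride Evaluate every `stride`-th sample and linearly interpolate
#'   in between; 1 evaluates every sample.
#' @return Numeric vector of scores, same length as `series`; `NA` outside
#'   the evaluable range.
#' @examples
#' x <- c(rnorm(300), rnorm(300, mean = 5))
#' s <- sst_change_scores(x, window_len = 50, lag = 25)
#' which.max(s)
#' @export
sst_change_scores <- function(series, window_len = 50, lag = 25,
                              n_components = 2, stride = 1L) {
  n <- length(series)
  if (n <= 2 * window_len + lag) {
    stop("series too short for the requested window_len and lag", call. = FALSE)
  }
  w <- as.integer(window_len)
  q <- max(4L, min(16L, w %/% 2L)) # trajectory-matrix width; 16 suffices for subspace tracking
  k <- min(n_components, q, w)
  scale <- stats::sd(series)
  if (!is.finite(scale) || scale == 0) scale <- 1
  tiny <- 1e-10 * scale * sqrt(w)

  first <- lag + w + q
  last <- n - w - q + 1L
  if (first > last) stop("series too short for the requested window_len and lag", call. = FALSE)
  eval_at <- seq(first, last, by = max(1L, as.integer(stride)))

  col_off <- seq_len(q) - 1L
  row_off <- seq_len(w) - 1L
  # index template: w x q Hankel block starting at offset 0
  tmpl <- outer(row_off, col_off, `+`)

  principal_basis <- function(start) {
    H <- matrix(series[tmpl + start], nrow = w)
    H <- H - rep(.colMeans(H, w, q), each = w)
    if (sqrt(sum(H^2)) < tiny) return(NULL) # degenerate: constant block
    svd(H, nu = k, nv = 0L)$u
  }

  sc <- vapply(eval_at, function(i) {
    Up <- principal_basis(i - lag - w - q + 1L)
    Uf <- principal_basis(i + 1L)
    if (is.null(Up) && is.null(Uf)) return(0)
    if (is.null(Up) || is.null(Uf)) return(1)
    max(0, 1 - sum(crossprod(Up, Uf)^2) / k)
  }, numeric(1))

  out <- rep(NA_real_, n)
  if (length(eval_at) > 1L) {
    out[first:last] <- stats::approx(eval_at, sc, xout = first:last, rule = 2)$y
  } else {
    out[eval_at] <- sc
  }
  out
}

#' Classify IMU samples into desired and undesired parts
#'
#' Marks intervals around change-score peaks whose contemporaneous
#' free-acceleration magnitude (per-sample maximum over the three filtered
#' channels) exceeds `threshold_mps2` as undesired; the 10 m/s^2 default is
#' the empirical cap-touch artifact threshold. Intervals are dilated by
#' `dilate_s` on each side to cover burst shoulders.
#'
#' @param facc Data frame with columns `t`, `facc_x`, `facc_y`, `facc_z`
#'   (low-pass filtered free acceleration).
#' @param scores Change scores aligned with `facc` (same length), e.g. from
#'   [sst_change_scores()] on the free-acceleration magnitude.
#' @param threshold_mps2 Artifact amplitude threshold (m/s^2).
#' @param dilate_s Dilation of each undesired interval (s).
#' @param score_gate Minimum change score required near an
#'   amplitude exceedance for it to count as an artifact.
#' @return A `wayfam_anomaly_mask`: per-sample logical `undesired` plus a
#'   tibble of merged `[t0, t1]` intervals.
#' @export
classify_undesired <- function(facc, scores, threshold_mps2 = 10,
                               dilate_s = 0.25, score_gate = 0.02) {
  stopifnot(all(c("t", "facc_x", "facc_y", "facc_z") %in% names(facc)))
  if (length(scores) != nrow(facc)) {
    stop("scores and free-acceleration series are misaligned", call. = FALSE)
  }
  t <- facc$t
  mag <- pmax(abs(facc$facc_x), abs(facc$facc_y), abs(facc$facc_z))
  core <- is.finite(mag) & mag > threshold_mps2

  intervals <- tibble::tibble(t0 = numeric(0), t1 = numeric(0))
  if (any(core)) {
    r <- rle(core)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    t0 <- t1 <- numeric(0)
    for (j in keep) {
      i0 <- starts[j]
      i1 <- ends[j]
      # gate on a contemporaneous change-score peak (searched in a small
      # neighbourhood; absent scores near the series edges do not veto)
      lo <- t[i0] - dilate_s
      hi <- t[i1] + dilate_s
      s_near <- scores[t >= lo & t <= hi]
      gated <- if (all(is.na(s_near))) TRUE else max(s_near, na.rm = TRUE) >= score_gate
      if (gated) {
        t0 <- c(t0, t[i0] - dilate_s)
        t1 <- c(t1, t[i1] + dilate_s)
      }
    }
    intervals <- merge_intervals(tibble::tibble(t0 = t0, t1 = t1))
  }
  undesired <- in_any_interval(t, intervals)
  structure(list(t = t, undesired = undesired, intervals = intervals),
            class = "wayfam_anomaly_mask")
}

#' @export
print.wayfam_anomaly_mask <- function(x, ...) {
  cat(sprintf("<wayfam_anomaly_mask> %d/%d samples undesired, %d intervals\n",
              sum(x$undesired), length(x$undesired), nrow(x$intervals)))
  invisible(x)
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$t0), , drop = FALSE]
  t0 <- iv$t0[1]
  t1 <- iv$t1[1]
  out0 <- out1 <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$t0[i] <= t1) {
      t1 <- max(t1, iv$t1[i])
    } else {
      out0 <- c(out0, t0)
      out1 <- c(out1, t1)
      t0 <- iv$t0[i]
      t1 <- iv$t1[i]
    }
  }
  tibble::tibble(t0 = c(out0, t0), t1 = c(out1, t1))
}

in_any_interval <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    out <- out | (t >= iv$t0[i] & t <= iv$t1[i])
  }
  out
}

#' Drop undesired intervals from a recording
#'
#' Removes IMU and gaze samples inside the mask's undesired intervals and
#' extends the recording's exclusion intervals; the GNSS track is left
#' untouched (position fixes remain valid while the head sensor is
#' disturbed). Applying the same mask twice is a no-op.
#'
#' @param recording A `wayfam_recording`.
#' @param mask A `wayfam_anomaly_mask` built on this recording's IMU clock.
#' @return The recording with masked samples removed.
#' @export
drop_undesired <- function(recording, mask) {
  stopifnot(inherits(recording, "wayfam_recording"),
            inherits(mask, "wayfam_anomaly_mask"))
  iv <- mask$intervals
  if (nrow(iv) == 0) return(recording)
  for (stream in c("imu_inertial", "imu_rotation", "imu", "gaze")) {
    s <- recording[[stream]]
    if (is.null(s)) next
    recording[[stream]] <- s[!in_any_interval(s$t, iv), , drop = FALSE]
  }
  recording$exclusion_intervals <-
    merge_intervals(dplyr::bind_rows(recording$exclusion_intervals, iv))
  recording
}

#' Downsample multirate IMU streams onto the rotation clock
#'
#' Produces one row per rotation (roll/pitch/yaw, 100 Hz) timestamp; each
#' inertial channel takes the value of its nearest-in-time raw sample.
#' Rotational head measures are the anchor because head-motion analysis
#' rests on them, and they are the lowest-rate channels.
#'
#' @param x A `wayfam_recording` (its `$imu` slot is filled) or an inertial
#'   data frame (`t`, `acc_*`, `facc_*`).
#' @param rotation Rotation data frame (`t`, `roll`, `pitch`, `yaw`);
#'   ignored when `x` is a recording.
#' @return The recording, or the unified IMU tibble.
#' @export
downsample_imu <- function(x, rotation = NULL) {
  if (inherits(x, "wayfam_recording")) {
    x$imu <- downsample_imu(x$imu_inertial, x$imu_rotation)
    return(x)
  }
  inertial <- x
  if (is.null(rotation) || nrow(rotation) == 0) {
    stop("rotation channel is empty", call. = FALSE)
  }
  if (nrow(inertial) == 0) stop("inertial channel is empty", call. = FALSE)
  idx <- nearest_index(inertial$t, rotation$t)
  tibble::tibble(
    t = rotation$t,
    acc_x = inertial$acc_x[idx], acc_y = inertial$acc_y[idx], acc_z = inertial$acc_z[idx],
    facc_x = inertial$facc_x[idx], facc_y = inertial$facc_y[idx], facc_z = inertial$facc_z[idx],
    roll = rotation$roll, pitch = rotation$pitch, yaw = rotation$yaw
  )
}

# Index of the nearest value in sorted vector `x` for each query in `q`.
nearest_index <- function(x, q) {
  i <- findInterval(q, x, all.inside = TRUE)
  left <- abs(q - x[i]) <= abs(x[pmin(i + 1L, length(x))] - q)
  ifelse(left, i, pmin(i + 1L, length(x)))
}

#' Estimate a sub-second time offset from a yaw extremum
#'
#' Refines a coarse (1-second precision) event time `t_A` by locating the
#' extreme head movement in the yaw series within one second before and
#' after: `t_B` is the time of the largest absolute deviation of yaw from
#' the window median, and `delta_t = t_B - t_A`.
#'
#' @param yaw_series Data frame with `t` and `yaw` columns covering
#'   `[t_A - 1, t_A + 1]`.
#' @param t_A Coarse event time (s).
#' @param min_prominence_deg Deviation floor (degrees) below which the
#'   extremum is flagged unreliable (e.g. flat yaw).
#' @return A `wayfam_time_offset` with `delta_t`, `t_A`, `t_B`, `reliable`.
#' @export
estimate_time_offset <- function(yaw_series, t_A, min_prominence_deg = 2) {
  stopifnot(all(c("t", "yaw") %in% names(yaw_series)))
  dt <- stats::median(diff(yaw_series$t))
  tol <- 1.5 * dt
  if (min(yaw_series$t) > t_A - 1 + tol || max(yaw_series$t) < t_A + 1 - tol) {
    stop("yaw series does not cover [t_A - 1, t_A + 1]", call. = FALSE)
  }
  w <- yaw_series[yaw_series$t >= t_A - 1 & yaw_series$t <= t_A + 1, , drop = FALSE]
  dev <- abs(w$yaw - stats::median(w$yaw))
  i <- which.max(dev)
  structure(
    list(delta_t = w$t[i] - t_A, t_A = t_A, t_B = w$t[i],
         reliable = dev[i] >= min_prominence_deg),
    class = "wayfam_time_offset"
  )
}

#' @export
print.wayfam_time_offset <- function(x, ...) {
  cat(sprintf("<wayfam_time_offset> delta_t = %+.3f s (t_B = %.3f, t_A = %.3f)%s\n",
              x$delta_t, x$t_B, x$t_A, if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Repair flagged GNSS fixes by neighbour averaging
#'
#' Replaces each `inaccurate`-flagged fix by the weighted average of the two
#' fixes before and the two after, with the nearer neighbours weighted
#' double (`[1, 2, 2, 1] / 6`). Flagged fixes within two samples of the
#' track ends are left unchanged with a warning.
#'
#' @param track GNSS tibble (`t`, `east`, `north`, `quality`).
#' @return The repaired track.
#' @export
smooth_gnss <- function(track) {
  stopifnot(all(c("t", "east", "north", "quality") %in% names(track)))
  n <- nrow(track)
  flagged <- which(track$quality == "inaccurate")
  w <- c(1, 2, 2, 1) / 6
  east0 <- track$east
  north0 <- track$north
  for (i in flagged) {
    if (i <= 2 || i >= n - 1) {
      warning("flagged GNSS fix within 2 samples of the track end left unchanged",
              call. = FALSE)
      next
    }
    nb <- c(i - 2, i - 1, i + 1, i + 2)
    track$east[i] <- sum(w * east0[nb])
    track$north[i] <- sum(w * north0[nb])
  }
  track
}

#' Project GNSS fixes onto the route polyline
#'
#' Replaces every position by its nearest point on the route polyline,
#' the repair used when a trace is factually off the walked street.
#'
#' @param track GNSS tibble.
#' @param polyline A `wayfam_route` or a data frame with `east`, `north`.
#' @return Track with projected positions.
#' @export
project_to_route <- function(track, polyline) {
  if (inherits(polyline, "wayfam_route")) polyline <- polyline$polyline
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices", call. = FALSE)
  pr <- project_points_polyline(cbind(track$east, track$north), polyline)
  track$east <- pr$point[, 1]
  track$north <- pr$point[, 2]
  track
}

#' Run the full preprocessing chain on a recording
#'
#' Fixed order: low-pass filter the free acceleration, score change points
#' (singular spectrum transformation of the free-acceleration magnitude),
#' classify undesired intervals with the amplitude threshold, drop them
#' from the IMU and gaze streams, downsample the IMU onto the rotation
#' clock, then repair and route-project the GNSS track.
#'
#' @param recording A `wayfam_recording`.
#' @param cutoff_hz Low-pass cutoff for free acceleration (Hz).
#' @param threshold_mps2 Artifact amplitude threshold (m/s^2).
#' @param sst_window_len,sst_lag,sst_n_components,sst_stride Passed to
#'   [sst_change_scores()]; the stride trades score resolution for speed.
#' @param dilate_s Interval dilation in [classify_undesired()].
#' @param project_gnss Project the track onto the route polyline after
#'   smoothing.
#' @return The preprocessed recording (fields `imu`, `anomaly_mask` filled,
#'   exclusion intervals extended).
#' @examples
#' rec <- generate_recording("p01", "familiar", effect_config(),
#'                           route_zigzag(2, 30), seed = 1)
#' rec <- preprocess_recording(rec)
#' @export
preprocess_recording <- function(recording, cutoff_hz = 5, threshold_mps2 = 10,
                                 sst_window_len = 50, sst_lag = 25,
                                 sst_n_components = 2, sst_stride = 12L,
                                 dilate_s = 0.25, project_gnss = TRUE) {
  stopifnot(inherits(recording, "wayfam_recording"))
  inert <- recording$imu_inertial
  fs <- 1 / stats::median(diff(inert$t))
  facc_f <- tibble::tibble(
    t = inert$t,
    facc_x = lowpass_filter(inert$facc_x, cutoff_hz, fs),
    facc_y = lowpass_filter(inert$facc_y, cutoff_hz, fs),
    facc_z = lowpass_filter(inert$facc_z, cutoff_hz, fs)
  )
  mag <- sqrt(facc_f$facc_x^2 + facc_f$facc_y^2 + facc_f$facc_z^2)
  scores <- sst_change_scores(mag, window_len = sst_window_len, lag = sst_lag,
                              n_components = sst_n_components, stride = sst_stride)
  mask <- classify_undesired(facc_f, scores, threshold_mps2 = threshold_mps2,
                             dilate_s = dilate_s)
  recording <- drop_undesired(recording, mask)
  recording <- downsample_imu(recording)
  recording$gnss <- smooth_gnss(recording$gnss)
  if (project_gnss) recording$gnss <- project_to_route(recording$gnss, recording$route)
  recording$anomaly_mask <- mask
  recording
}
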