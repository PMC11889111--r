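#' Names of the IMU feature bank
#'
#' 99 per-window descriptors in six families: (a) 31 basic statistics
#' (min/max/mean/var of the relative -- per-trial mean-centered --
#' acceleration and orientation channels, yaw frequency change,
#' point-to-point amplitudes of acceleration and free acceleration),
#' (b) 50 cepstral coefficients of the acceleration magnitude, (c) 5
#' time-domain measures, (d) the fundamental period, (e) 8 movement
#' measures (movement intensity mean/var, signal magnitude area, per-axis
#' energy, entropy, movement variation), (f) 4 spectral/music measures
#' (zero-crossing rate, spectral centroid, spectral rolloff, chroma mean).
#'
#' @return Character vector of 99 column names, in canonical family order.
#' @export
imu_feature_names <- function() {
  chans <- c("acc_x", "acc_y", "acc_z", "roll", "pitch", "yaw")
  basic <- c(
    as.vector(t(outer(chans, c("_min", "_max", "_mean", "_var"), paste0))),
    "yaw_freq_change",
    paste0(c("acc_x", "acc_y", "acc_z", "facc_x", "facc_y", "facc_z"), "_p2p")
  )
  c(basic,
    sprintf("cep_%02d", seq_len(50)),
    c("tdm_std", "tdm_energy", "tdm_min_ampl", "tdm_max_ampl", "tdm_p2p_ampl"),
    "fundamental_period",
    c("mi_mean", "mi_var", "sma", "energy_x", "energy_y", "energy_z",
      "entropy", "mov_variation"),
    c("zero_crossing_rate", "spectral_centroid", "spectral_rolloff", "chroma_mean"))
}

# Sign changes of a series, zeros ignored.
count_sign_changes <- function(x) {
  x <- x[x != 0]
  if (length(x) < 2) return(0L)
  sum(x[-1] * x[-length(x)] < 0)
}

#' Basic IMU statistics (31 values)
#'
#' Channel statistics are computed on "relative" values: each channel is
#' centered on its per-trial mean (supplied via `center`), because the
#' sensor's position and alignment on the head are inconsistent between
#' trials and absolute levels are not comparable. Yaw frequency change is
#' the zero-crossing rate (crossings per second) of the centered yaw.
#' Point-to-point amplitude is `max - min` per listed channel.
#'
#' @param window_imu Unified IMU tibble (`t`, `acc_*`, `facc_*`, `roll`,
#'   `pitch`, `yaw`) restricted to one window.
#' @param center Optional named numeric of per-trial channel means
#'   (`acc_x` ... `yaw`); defaults to the window means.
#' @return Named list of 31 values (all `NA` below 2 samples).
#' @export
basic_stats <- function(window_imu, center = NULL) {
  chans <- c("acc_x", "acc_y", "acc_z", "roll", "pitch", "yaw")
  nm_basic <- as.vector(t(outer(chans, c("_min", "_max", "_mean", "_var"), paste0)))
  nms <- c(nm_basic, "yaw_freq_change",
           paste0(c("acc_x", "acc_y", "acc_z", "facc_x", "facc_y", "facc_z"), "_p2p"))
  if (nrow(window_imu) < 2) {
    return(stats::setNames(as.list(rep(NA_real_, length(nms))), nms))
  }
  out <- list()
  for (ch in chans) {
    mu <- if (!is.null(center) && ch %in% names(center)) center[[ch]] else mean(window_imu[[ch]])
    v <- window_imu[[ch]] - mu
    out[[paste0(ch, "_min")]] <- min(v)
    out[[paste0(ch, "_max")]] <- max(v)
    out[[paste0(ch, "_mean")]] <- mean(v)
    out[[paste0(ch, "_var")]] <- stats::var(v)
  }
  mu_yaw <- if (!is.null(center) && "yaw" %in% names(center)) center[["yaw"]] else mean(window_imu$yaw)
  span <- diff(range(window_imu$t))
  out$yaw_freq_change <- if (span > 0) {
    count_sign_changes(window_imu$yaw - mu_yaw) / span
  } else NA_real_
  for (ch in c("acc_x", "acc_y", "acc_z", "facc_x", "facc_y", "facc_z")) {
    out[[paste0(ch, "_p2p")]] <- diff(range(window_imu[[ch]]))
  }
  out[nms]
}

#' Real cepstral coefficients
#'
#' The cepstrum is the inverse Fourier transform of the log power spectrum
#' (`log(|X(f)|^2 + eps)`); its leading coefficients compactly encode the
#' spectral envelope of the signal. The first `n` coefficients (including
#' the zeroth, which carries overall signal scale) are returned.
#'
#' @param x Numeric signal (acceleration magnitude of one window), length
#'   at least `2 * n`.
#' @param n Number of leading coefficients.
#' @param eps Log floor preventing `-Inf` for empty spectral bins.
#' @return Numeric vector of `n` coefficients.
#' @examples
#' cepstral_coeffs(rnorm(300))[1:5]
#' @export
cepstral_coeffs <- function(x, n = 50, eps = 1e-12) {
  if (length(x) < 2 * n) stop("window too short for ", n, " cepstral coefficients", call. = FALSE)
  logspec <- log(Mod(stats::fft(x))^2 + eps)
  ceps <- Re(stats::fft(logspec, inverse = TRUE)) / length(x)
  ceps[seq_len(n)]
}

#' Time-domain measures of the acceleration magnitude (5 values)
#'
#' Standard deviation, energy (the integral of the squared signal,
#' `sum(x^2) / fs`), and the minimum, maximum and peak-to-peak amplitude.
#'
#' @param x Acceleration-magnitude window.
#' @param fs Sampling rate (Hz).
#' @return Named list of 5 values.
#' @export
time_domain_measures <- function(x, fs) {
  list(tdm_std = stats::sd(x),
       tdm_energy = sum(x^2) / fs,
       tdm_min_ampl = min(x),
       tdm_max_ampl = max(x),
       tdm_p2p_ampl = diff(range(x)))
}

# Local maxima with topographic prominence >= min_prominence.
find_prominent_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- x[i]
    j <- i
    left_min <- h
    while (j > 1) {
      j <- j - 1L
      if (x[j] > h) break
      left_min <- min(left_min, x[j])
    }
    if (j == 1 && x[j] <= h) left_min <- min(left_min, x[1])
    j <- i
    right_min <- h
    while (j < n) {
      j <- j + 1L
      if (x[j] > h) break
      right_min <- min(right_min, x[j])
    }
    keep[k] <- (h - max(left_min, right_min)) >= min_prominence
  }
  cand[keep]
}

#' Fundamental period of the acceleration magnitude
#'
#' Smallest time difference between two subsequent amplitude peaks; with a
#' gait-driven signal this reflects step cadence. Peaks are local maxima
#' with topographic prominence of at least `min_prominence` (default half
#' the window standard deviation). Missing when fewer than two peaks are
#' found.
#'
#' @param x Acceleration-magnitude window.
#' @param fs Sampling rate (Hz).
#' @param min_prominence Peak prominence floor; default `0.5 * sd(x)`.
#' @return Period in seconds, or `NA`.
#' @export
fundamental_period <- function(x, fs, min_prominence = NULL) {
  if (is.null(min_prominence)) min_prominence <- 0.5 * stats::sd(x)
  if (!is.finite(min_prominence) || min_prominence <= 0) return(NA_real_)
  pk <- find_prominent_peaks(x, min_prominence)
  if (length(pk) < 2) return(NA_real_)
  min(diff(pk)) / fs
}

#' Movement measures from tri-axial acceleration (8 values)
#'
#' Movement intensity (MI) is the per-sample Euclidean norm of the
#' acceleration vector, summarized by mean and variance. The signal
#' magnitude area (SMA) is the summed absolute tri-axial acceleration
#' normalized by window duration. Per-axis energy is the mean squared
#' acceleration. Entropy is the Shannon entropy (bits) of a 16-bin
#' histogram of MI, measuring signal uniformity. Movement variation (MV)
#' sums the absolute first differences over all axes, normalized by the
#' sample count.
#'
#' @param window_imu IMU window with `acc_x`, `acc_y`, `acc_z`.
#' @param n_bins Histogram bins for the entropy.
#' @return Named list of 8 values.
#' @export
movement_measures <- function(window_imu, n_bins = 16) {
  ax <- window_imu$acc_x
  ay <- window_imu$acc_y
  az <- window_imu$acc_z
  n <- length(ax)
  mi <- sqrt(ax^2 + ay^2 + az^2)
  list(
    mi_mean = mean(mi),
    mi_var = var0(mi),
    sma = mean(abs(ax) + abs(ay) + abs(az)),
    energy_x = sum(ax^2) / n,
    energy_y = sum(ay^2) / n,
    energy_z = sum(az^2) / n,
    entropy = shannon_entropy_bits(mi, n_bins),
    mov_variation = (sum(abs(diff(ax))) + sum(abs(diff(ay))) + sum(abs(diff(az)))) / n
  )
}

shannon_entropy_bits <- function(v, n_bins = 16) {
  if (diff(range(v)) == 0) return(0)
  counts <- tabulate(
    cut(v, breaks = seq(min(v), max(v), length.out = n_bins + 1L),
        include.lowest = TRUE, labels = FALSE),
    nbins = n_bins
  )
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Spectral and music-analysis measures (4 values)
#'
#' Zero-crossing rate of the mean-centered signal (crossings per sample
#' pair), spectral centroid (magnitude-weighted mean frequency), spectral
#' rolloff (smallest frequency below which `rolloff_frac` of the spectral
#' energy lies) and the chroma mean. Chroma bins here are 12
#' logarithmically spaced frequency bands spanning 0.5 Hz to Nyquist --
#' an adaptation of the musical semitone projection to the much lower
#' bandwidth of body-worn accelerometry.
#'
#' @param x Acceleration-magnitude window.
#' @param fs Sampling rate (Hz).
#' @param rolloff_frac Energy fraction for the rolloff.
#' @return Named list of 4 values.
#' @export
spectral_music_measures <- function(x, fs, rolloff_frac = 0.85) {
  n <- length(x)
  xc <- x - mean(x)
  zcr <- if (n > 1) count_sign_changes(xc) / (n - 1) else NA_real_
  nb <- n %/% 2 + 1L
  f <- (seq_len(nb) - 1L) * fs / n
  mag <- Mod(stats::fft(xc))[seq_len(nb)]
  total_mag <- sum(mag)
  centroid <- if (total_mag > 0) sum(f * mag) / total_mag else 0
  en <- mag^2
  rolloff <- if (sum(en) > 0) f[which(cumsum(en) >= rolloff_frac * sum(en))[1]] else 0
  edges <- exp(seq(log(0.5), log(fs / 2), length.out = 13L))
  bin <- findInterval(f, edges, rightmost.closed = TRUE)
  bins <- vapply(seq_len(12L), function(b) sum(mag[bin == b]), numeric(1))
  list(zero_crossing_rate = zcr, spectral_centroid = centroid,
       spectral_rolloff = rolloff, chroma_mean = mean(bins))
}

#' Full 99-feature IMU row for one window
#'
#' Concatenates the six feature families in canonical order. The cepstral,
#' time-domain, fundamental-period and spectral families are computed on
#' the acceleration magnitude `sqrt(acc_x^2 + acc_y^2 + acc_z^2)`; the
#' basic statistics use per-trial mean-centered channels (see
#' [basic_stats()]).
#'
#' @param window_imu Unified IMU tibble restricted to one window.
#' @param fs Sampling rate of the unified stream (Hz).
#' @param center Optional per-trial channel means for the relative
#'   statistics.
#' @return One-row tibble with the 99 columns of [imu_feature_names()];
#'   all-`NA` when the window is shorter than 1 s.
#' @examples
#' rec <- generate_recording("p01", "familiar", effect_config(),
#'                           route_zigzag(2, 30), seed = 1)
#' rec <- downsample_imu(rec)
#' w <- rec$imu[rec$imu$t < 3, ]
#' ncol(imu_feature_row(w))
#' @export
imu_feature_row <- function(window_imu, fs = 100, center = NULL) {
  nms <- imu_feature_names()
  span <- if (nrow(window_imu) > 1) diff(range(window_imu$t)) else 0
  if (span < 1) {
    return(tibble::as_tibble(stats::setNames(as.list(rep(NA_real_, length(nms))), nms)))
  }
  mag <- sqrt(window_imu$acc_x^2 + window_imu$acc_y^2 + window_imu$acc_z^2)
  row <- c(
    basic_stats(window_imu, center),
    stats::setNames(as.list(cepstral_coeffs(mag, 50)), sprintf("cep_%02d", 1:50)),
    time_domain_measures(mag, fs),
    list(fundamental_period = fundamental_period(mag, fs)),
    movement_measures(window_imu),
    spectral_music_measures(mag, fs)
  )
  tibble::as_tibble(row)[, nms]
}

# Per-window IMU feature rows for one preprocessed recording.
extract_imu_features <- function(recording, windows, fs = 100) {
  stopifnot(inherits(recording, "wayfam_recording"))
  imu <- recording$imu
  if (is.null(imu)) stop("recording has no unified IMU stream; run downsample_imu() first",
                         call. = FALSE)
  wins <- windows[windows$recording_id == recording$recording_id, , drop = FALSE]
  if (nrow(wins) == 0) return(NULL)
  center <- vapply(c("acc_x", "acc_y", "acc_z", "roll", "pitch", "yaw"),
                   function(ch) mean(imu[[ch]]), numeric(1))
  rows <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    w <- imu[imu$t >= wins$t0[i] & imu$t < wins$t0[i] + wins$duration[i], , drop = FALSE]
    imu_feature_row(w, fs = fs, center = center)
  })
  dplyr::bind_cols(wins[, c("recording_id", "window_id", "t0")], rows)
}
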