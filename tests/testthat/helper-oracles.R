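# Definition-level reference implementations, coded independently of the
# package internals, used to cross-check every feature family.

# --- I-DT: exhaustive maximal-window reference -------------------------------
# Scans left to right; at each anchor the minimum-duration window is located
# by explicit search and every candidate extension re-computes dispersion
# from scratch.
oracle_idt <- function(gaze, dispersion_threshold = 0.02, duration_threshold_ms = 100) {
  t <- gaze$t; x <- gaze$x; y <- gaze$y
  n <- length(t)
  mindur <- duration_threshold_ms / 1000
  disp <- function(i, j) {
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  }
  res <- NULL
  i <- 1L
  while (i <= n) {
    js <- which(t - t[i] >= mindur - 1e-12)
    js <- js[js >= i]
    if (length(js) == 0) break
    j <- js[1]
    if (disp(i, j) <= dispersion_threshold) {
      while (j < n && disp(i, j + 1L) <= dispersion_threshold) j <- j + 1L
      res <- rbind(res, data.frame(
        t_start = t[i], t_end = t[j], duration_ms = (t[j] - t[i]) * 1000,
        x = mean(x[i:j]), y = mean(y[i:j]),
        dispersion = disp(i, j),
        dispersion_x = max(x[i:j]) - min(x[i:j]),
        dispersion_y = max(y[i:j]) - min(y[i:j])
      ))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(res)) {
    res <- data.frame(t_start = numeric(0), t_end = numeric(0), duration_ms = numeric(0),
                      x = numeric(0), y = numeric(0), dispersion = numeric(0),
                      dispersion_x = numeric(0), dispersion_y = numeric(0))
  }
  res
}

# Random gaze snippet mixing stationary clusters and jumps.
random_gaze_snippet <- function(seed, n_max = 600, fs = 200) {
  set.seed(seed)
  n <- sample(50:n_max, 1)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n); y <- numeric(n)
  i <- 1
  cx <- runif(1); cy <- runif(1)
  while (i <= n) {
    len <- sample(5:80, 1)
    j <- min(n, i + len - 1)
    spread <- sample(c(0.002, 0.005, 0.012, 0.04), 1)
    x[i:j] <- cx + runif(j - i + 1, -spread, spread)
    y[i:j] <- cy + runif(j - i + 1, -spread, spread)
    cx <- runif(1); cy <- runif(1)
    i <- j + 1
  }
  tibble::tibble(t = t, x = x, y = y)
}

# --- direct statistic formulas ----------------------------------------------
oracle_mean <- function(v) sum(v) / length(v)
oracle_var <- function(v) {
  if (length(v) < 2) return(NA_real_)
  m <- oracle_mean(v)
  sum((v - m)^2) / (length(v) - 1)
}
oracle_skew <- function(v) {
  n <- length(v)
  if (n < 3) return(NA_real_)
  m <- oracle_mean(v)
  s <- sqrt(sum((v - m)^2) / n)
  if (s == 0) return(NA_real_)
  (sum(((v - m) / s)^3) / n) * sqrt(n * (n - 1)) / (n - 2)
}

oracle_gaze_row <- function(fix, sac, duration_s, split) {
  four <- function(v) c(mean = if (length(v)) oracle_mean(v) else NA_real_,
                        min = if (length(v)) min(v) else NA_real_,
                        max = if (length(v)) max(v) else NA_real_,
                        var = oracle_var(v))
  amps <- sac$amplitude
  n_short <- sum(amps <= split)
  c(four(fix$duration_ms), four(fix$dispersion), four(fix$dispersion_x),
    four(fix$dispersion_y), fix_freq = nrow(fix) / duration_s,
    four(amps), four(sac$duration_ms),
    sac_ampl_skew = oracle_skew(amps), sac_freq = length(amps) / duration_s,
    gl_ratio = if (length(amps) == 0 || n_short == 0) NA_real_ else sum(amps > split) / n_short)
}

# --- explicit DFT (naive O(n^2)) --------------------------------------------
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}
naive_idft <- function(X) {
  n <- length(X)
  k <- 0:(n - 1)
  W <- exp(2i * pi * outer(k, k) / n)
  as.vector(W %*% X) / n
}

oracle_cepstral <- function(x, n = 50, eps = 1e-12) {
  Re(naive_idft(log(abs(naive_dft(x))^2 + eps)))[seq_len(n)]
}

oracle_tdm <- function(x, fs) {
  m <- oracle_mean(x)
  c(tdm_std = sqrt(sum((x - m)^2) / (length(x) - 1)),
    tdm_energy = sum(x * x) / fs,
    tdm_min_ampl = min(x), tdm_max_ampl = max(x),
    tdm_p2p_ampl = max(x) - min(x))
}

# Independent prominence computation: brute-force over the whole series.
oracle_fundamental_period <- function(x, fs, min_prominence = NULL) {
  if (is.null(min_prominence)) min_prominence <- 0.5 * sqrt(oracle_var(x))
  if (!is.finite(min_prominence) || min_prominence <= 0) return(NA_real_)
  n <- length(x)
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] >= x[i + 1])) next
    left <- i - 1
    while (left >= 1 && x[left] <= x[i]) left <- left - 1
    lv <- if (left < 1) min(x[1:i]) else min(x[(left + 1):i])
    right <- i + 1
    while (right <= n && x[right] <= x[i]) right <- right + 1
    rv <- if (right > n) min(x[i:n]) else min(x[i:(right - 1)])
    if (x[i] - max(lv, rv) >= min_prominence) peaks <- c(peaks, i)
  }
  if (length(peaks) < 2) return(NA_real_)
  min(diff(peaks)) / fs
}

oracle_movement <- function(ax, ay, az, n_bins = 16) {
  n <- length(ax)
  mi <- sqrt(ax^2 + ay^2 + az^2)
  ent <- if (max(mi) == min(mi)) 0 else {
    edges <- seq(min(mi), max(mi), length.out = n_bins + 1)
    cnt <- numeric(n_bins)
    for (v in mi) {
      b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
      cnt[b] <- cnt[b] + 1
    }
    p <- cnt[cnt > 0] / n
    -sum(p * log(p)) / log(2)
  }
  c(mi_mean = oracle_mean(mi),
    mi_var = if (n < 2) 0 else oracle_var(mi),
    sma = oracle_mean(abs(ax) + abs(ay) + abs(az)),
    energy_x = sum(ax^2) / n, energy_y = sum(ay^2) / n, energy_z = sum(az^2) / n,
    entropy = ent,
    mov_variation = (sum(abs(ax[-1] - ax[-n])) + sum(abs(ay[-1] - ay[-n])) +
                       sum(abs(az[-1] - az[-n]))) / n)
}

oracle_spectral <- function(x, fs, rolloff_frac = 0.85) {
  n <- length(x)
  xc <- x - oracle_mean(x)
  xs <- xc[xc != 0]
  crossings <- sum(diff(sign(xs)) != 0)
  nb <- n %/% 2 + 1
  f <- (0:(nb - 1)) * fs / n
  mag <- abs(naive_dft(xc))[1:nb]
  centroid <- if (sum(mag) > 0) sum(f * mag) / sum(mag) else 0
  en <- mag^2
  roll <- if (sum(en) > 0) f[which(cumsum(en) / sum(en) >= rolloff_frac)[1]] else 0
  edges <- exp(seq(log(0.5), log(fs / 2), length.out = 13))
  bins <- numeric(12)
  for (i in seq_along(f)) {
    b <- findInterval(f[i], edges, rightmost.closed = TRUE)
    if (b >= 1 && b <= 12) bins[b] <- bins[b] + mag[i]
  }
  c(zero_crossing_rate = crossings / (n - 1), spectral_centroid = centroid,
    spectral_rolloff = roll, chroma_mean = mean(bins))
}

oracle_basic <- function(w, center) {
  out <- c()
  for (ch in c("acc_x", "acc_y", "acc_z", "roll", "pitch", "yaw")) {
    v <- w[[ch]] - center[[ch]]
    out <- c(out, stats::setNames(c(min(v), max(v), oracle_mean(v), oracle_var(v)),
                                  paste0(ch, c("_min", "_max", "_mean", "_var"))))
  }
  yv <- w$yaw - center[["yaw"]]
  yv <- yv[yv != 0]
  out <- c(out, yaw_freq_change = sum(diff(sign(yv)) != 0) / (max(w$t) - min(w$t)))
  for (ch in c("acc_x", "acc_y", "acc_z", "facc_x", "facc_y", "facc_z")) {
    out <- c(out, stats::setNames(max(w[[ch]]) - min(w[[ch]]), paste0(ch, "_p2p")))
  }
  out
}

# Random 3-s unified IMU window.
random_imu_window <- function(seed, fs = 100, duration = 3) {
  set.seed(seed)
  n <- fs * duration
  t <- (seq_len(n) - 1) / fs
  mk <- function(base) base + rnorm(n, 0, runif(1, 0.1, 1)) +
    runif(1, 0, 2) * sin(2 * pi * runif(1, 0.2, 5) * t + runif(1, 0, 2 * pi))
  tibble::tibble(
    t = t,
    acc_x = mk(0.2), acc_y = mk(-0.3), acc_z = mk(9.8),
    facc_x = mk(0), facc_y = mk(0), facc_z = mk(0),
    roll = mk(1), pitch = mk(2), yaw = mk(10)
  )
}
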