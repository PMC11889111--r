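test_that("I-DT handles canonical fixation patterns", {
  g <- tibble::tibble(t = seq(0, 1, by = 0.005), x = 0.5, y = 0.5)
  fx <- detect_fixations_idt(g)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 1000)
  expect_equal(fx$dispersion, 0)
  expect_equal(c(fx$x, fx$y), c(0.5, 0.5))

  # two stationary clusters separated by a jump -> exactly two fixations
  t <- seq(0, 0.3 - 0.005, by = 0.005)
  g2 <- tibble::tibble(t = t,
                       x = ifelse(t < 0.15, 0.1, 0.5),
                       y = ifelse(t < 0.15, 0.1, 0.5))
  fx2 <- detect_fixations_idt(g2)
  expect_equal(nrow(fx2), 2)
  expect_equal(fx2$x, c(0.1, 0.5))

  # 80 ms cluster stays below the 100 ms duration threshold
  t3 <- seq(0, 0.08, by = 0.005)
  g3 <- tibble::tibble(t = c(t3, 0.085 + t3), x = c(rep(0.1, length(t3)), rep(0.8, length(t3))),
                       y = 0.5)
  fx3 <- detect_fixations_idt(g3, dispersion_threshold = 0.02)
  expect_equal(nrow(fx3), 0)

  expect_equal(nrow(detect_fixations_idt(g[0, ])), 0)
})

test_that("greedy I-DT agrees with the exhaustive maximal-window reference", {
  for (seed in 1:25) {
    g <- random_gaze_snippet(seed)
    mine <- detect_fixations_idt(g)
    ref <- oracle_idt(g)
    expect_equal(nrow(mine), nrow(ref), info = paste("seed", seed))
    if (nrow(ref)) {
      expect_equal(as.data.frame(mine), ref, tolerance = 1e-12,
                   info = paste("seed", seed))
    }
  }
})

test_that("I-DT output is translation-invariant, time-shift equivariant, non-overlapping", {
  g <- random_gaze_snippet(99)
  fx <- detect_fixations_idt(g)
  shifted <- dplyr::mutate(g, x = x + 0.21, y = y - 0.13)
  fx2 <- detect_fixations_idt(shifted)
  expect_equal(fx2$duration_ms, fx$duration_ms)
  expect_equal(fx2$dispersion, fx$dispersion)
  expect_equal(fx2$x, fx$x + 0.21)

  lagged <- dplyr::mutate(g, t = t + 5)
  expect_equal(detect_fixations_idt(lagged)$t_start, fx$t_start + 5)

  if (nrow(fx) > 1) {
    expect_true(all(fx$t_start[-1] >= fx$t_end[-nrow(fx)]))
  }

  # lowering the dispersion threshold never increases total fixation time
  tot <- function(thr) sum(detect_fixations_idt(g, dispersion_threshold = thr)$duration_ms)
  thrs <- c(0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(vapply(thrs, tot, numeric(1))) >= 0))
})

test_that("saccade amplitudes are compensated by head rotation", {
  fixA <- tibble::tibble(t_start = 0, t_end = 0.2, x = 0.3, y = 0.5)
  fixB <- tibble::tibble(t_start = 0.25, t_end = 0.5, x = 0.5, y = 0.5)
  still <- tibble::tibble(t = seq(0, 0.6, by = 0.01), yaw = 0, pitch = 0)
  s <- compensate_saccade(fixA, fixB, still)
  expect_equal(s$amplitude, 0.2, tolerance = 1e-12)
  expect_equal(s$duration_ms, 50)

  # head yaw accounts exactly for the centroid shift -> amplitude ~ 0
  upd <- 1 / wayfam:::DEG_PER_SCENE_UNIT
  dyaw <- -0.2 / upd
  rot <- tibble::tibble(t = seq(0, 0.6, by = 0.01),
                        yaw = ifelse(t < 0.2, 0, ifelse(t > 0.25, dyaw, dyaw * (t - 0.2) / 0.05)),
                        pitch = 0)
  s2 <- compensate_saccade(fixA, fixB, rot)
  expect_lt(s2$amplitude, 1e-6)

  # zeroed calibration: falls back to the raw centroid distance
  s3 <- compensate_saccade(fixA, fixB, rot, units_per_deg = 0)
  expect_equal(s3$amplitude, 0.2)
  expect_false(s3$compensated)

  # missing IMU coverage: uncompensated and flagged
  s4 <- compensate_saccade(fixA, fixB, rot[rot$t > 0.22, ])
  expect_false(s4$compensated)
})

test_that("the gaze feature row matches direct formulas", {
  onefix <- tibble::tibble(t_start = 0, t_end = 0.3, duration_ms = 300,
                           x = 0.5, y = 0.5, dispersion = 0.01,
                           dispersion_x = 0.006, dispersion_y = 0.004)
  nosac <- tibble::tibble(amplitude = numeric(0), duration_ms = numeric(0))
  row <- gaze_feature_row(onefix, nosac, duration_s = 3)
  expect_equal(row$fix_freq, 1 / 3)
  expect_equal(row$fix_dur_mean, 300)
  expect_equal(row$fix_dur_min, 300)
  expect_equal(row$fix_dur_max, 300)
  expect_true(is.na(row$fix_dur_var))
  expect_true(is.na(row$gl_ratio))

  sac <- tibble::tibble(amplitude = c(1, 2, 3), duration_ms = c(30, 40, 50))
  row2 <- gaze_feature_row(onefix, sac, duration_s = 3, amplitude_split = 2)
  expect_equal(row2$sac_ampl_mean, 2)
  expect_equal(row2$sac_ampl_var, 1)
  expect_equal(row2$sac_ampl_skew, 0)
  expect_equal(row2$sac_freq, 1)
  expect_equal(row2$gl_ratio, 1 / 2)

  # randomized windows against the independent formula set
  for (seed in 1:20) {
    set.seed(seed)
    nf <- sample(0:8, 1)
    ns <- max(0, nf - 1)
    fix <- tibble::tibble(t_start = cumsum(runif(nf, 0.1, 0.3)),
                          duration_ms = runif(nf, 100, 400),
                          dispersion = runif(nf, 0, 0.02),
                          dispersion_x = runif(nf, 0, 0.01),
                          dispersion_y = runif(nf, 0, 0.01))
    fix$t_end <- fix$t_start + fix$duration_ms / 1000
    fix$x <- runif(nf); fix$y <- runif(nf)
    sacs <- tibble::tibble(amplitude = rgamma(ns, 2, 10), duration_ms = runif(ns, 20, 80))
    split <- if (ns) median(sacs$amplitude) else NA_real_
    mine <- gaze_feature_row(fix, sacs, duration_s = 3, amplitude_split = split)
    ref <- oracle_gaze_row(fix, sacs, 3, split)
    expect_equal(unname(unlist(mine)), unname(ref), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("per-window saccade count is fixation count minus one", {
  rec <- fixture_recording()
  wins <- window_segments(extract_segments(rec))
  gz <- wayfam:::extract_gaze_features(rec, wins)
  expect_equal(gz$sac_freq * 3, pmax(0, gz$fix_freq * 3 - 1))
})
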