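test_that("low-pass filter passes DC, kills far-out-of-band tones, keeps in-band ones", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  dc <- rep(2.5, length(t))
  expect_lt(max(abs(lowpass_filter(dc, 5, fs) - 2.5)), 1e-9)

  tone40 <- sin(2 * pi * 40 * t)
  out <- lowpass_filter(tone40, 5, fs)
  expect_lt(sqrt(mean(out^2)), 0.01 * sqrt(mean(tone40^2)))

  tone1 <- sin(2 * pi * 1 * t)
  mix <- tone1 + tone40
  expect_gt(cor(lowpass_filter(mix, 5, fs), tone1), 0.99)

  expect_error(lowpass_filter(tone1, 60, fs), "Nyquist|cutoff")
})

test_that("SST scores are low for stationary signals and localize a mean step", {
  t <- seq_len(1000)
  x <- sin(2 * pi * 0.02 * t)
  s <- sst_change_scores(x, window_len = 50, lag = 25)
  expect_true(all(s[!is.na(s)] >= 0))
  expect_lt(max(s, na.rm = TRUE), 0.1)

  set.seed(42)
  y <- c(rnorm(500, 0, 0.2), rnorm(500, 5, 0.2))
  sy <- sst_change_scores(y, window_len = 50, lag = 25)
  # the score forms a plateau while either trajectory block straddles the
  # step; its center localizes the change point
  hot <- which(sy >= 0.9 * max(sy, na.rm = TRUE))
  expect_lt(abs(mean(range(hot)) - 500), 50)

  expect_equal(sst_change_scores(y + 123.4, window_len = 50, lag = 25), sy)
  expect_error(sst_change_scores(rnorm(100), window_len = 50, lag = 25), "short")
})

test_that("undesired classification follows the amplitude threshold and is monotone", {
  set.seed(8)
  fs <- 400
  t <- seq(0, 20, by = 1 / fs)
  base <- function() rnorm(length(t), 0, 0.3)
  facc <- tibble::tibble(t = t, facc_x = base(), facc_y = base(), facc_z = base())
  scores <- rep(0.5, length(t))

  expect_equal(nrow(classify_undesired(facc, scores)$intervals), 0)

  burst <- 15 * exp(-(t - 10)^2 / (2 * 0.15^2))
  facc2 <- dplyr::mutate(facc, facc_y = facc_y + burst)
  mask <- classify_undesired(facc2, scores)
  expect_equal(nrow(mask$intervals), 1)
  expect_true(mask$intervals$t0[1] < 10 && mask$intervals$t1[1] > 10)

  expect_equal(nrow(classify_undesired(facc2, scores, threshold_mps2 = Inf)$intervals), 0)

  # monotone: raising the threshold never adds undesired samples
  m10 <- classify_undesired(facc2, scores, threshold_mps2 = 10)
  m14 <- classify_undesired(facc2, scores, threshold_mps2 = 14)
  expect_true(all(m10$undesired | !m14$undesired))

  expect_error(classify_undesired(facc2, scores[-1]), "misaligned")
})

test_that("dropping undesired intervals removes samples, keeps GNSS, and is idempotent", {
  rec <- generate_recording("p01", "familiar", effect_config(anomaly_rate = 0),
                            route_zigzag(2, 30), seed = 21)
  t <- rec$imu_inertial$t
  empty <- structure(list(t = t, undesired = rep(FALSE, length(t)),
                          intervals = tibble::tibble(t0 = numeric(0), t1 = numeric(0))),
                     class = "wayfam_anomaly_mask")
  expect_identical(drop_undesired(rec, empty), rec)

  iv <- tibble::tibble(t0 = 10, t1 = 12)
  mask <- structure(list(t = t, undesired = t >= 10 & t <= 12, intervals = iv),
                    class = "wayfam_anomaly_mask")
  dropped <- drop_undesired(rec, mask)
  for (stream in c("imu_inertial", "imu_rotation", "gaze")) {
    expect_false(any(dropped[[stream]]$t >= 10 & dropped[[stream]]$t <= 12))
  }
  expect_identical(dropped$gnss, rec$gnss)
  expect_equal(as.data.frame(dropped$exclusion_intervals), as.data.frame(iv))

  # duration bookkeeping (one-sample tolerance per interval edge)
  dt <- median(diff(t))
  retained <- nrow(dropped$imu_inertial) * dt
  expect_lt(abs(retained - (nrow(rec$imu_inertial) * dt - 2)), 3 * dt)

  expect_identical(drop_undesired(dropped, mask)$imu_inertial, dropped$imu_inertial)
})

test_that("IMU downsampling lands on rotation timestamps with nearest-sample values", {
  t100 <- seq(0, 3, by = 0.01)
  t400 <- seq(0, 3, by = 0.0025)
  rot <- tibble::tibble(t = t100, roll = 0, pitch = 0, yaw = sin(t100))
  inert <- tibble::tibble(t = t400, acc_x = 1.5, acc_y = 1.5, acc_z = 1.5,
                          facc_x = 0, facc_y = 0, facc_z = 0)
  ds <- downsample_imu(inert, rot)
  expect_equal(ds$t, t100)
  expect_true(all(ds$acc_x == 1.5))

  slope <- 2
  inert$acc_x <- slope * inert$t
  ds <- downsample_imu(inert, rot)
  expect_lte(max(abs(ds$acc_x - slope * ds$t)), slope * (1 / 800) + 1e-12)

  expect_error(downsample_imu(inert, rot[0, ]), "empty")
})

test_that("yaw-extremum time offsets are recovered to one sample", {
  t <- seq(0, 10, by = 0.01)
  mk_yaw <- function(peak_at) {
    tibble::tibble(t = t, yaw = 30 * exp(-(t - peak_at)^2 / (2 * 0.05^2)))
  }
  est <- estimate_time_offset(mk_yaw(5), t_A = 5)
  expect_equal(est$delta_t, 0, tolerance = 1e-9)

  est <- estimate_time_offset(mk_yaw(5.37), t_A = 5)
  expect_lte(abs(est$delta_t - 0.37), 0.01)
  expect_true(est$reliable)

  flat <- tibble::tibble(t = t, yaw = rep(1.0, length(t)))
  expect_false(estimate_time_offset(flat, t_A = 5)$reliable)
  expect_error(estimate_time_offset(mk_yaw(5), t_A = 9.99), "cover")
})

test_that("GNSS smoothing repairs flagged fixes with the 1-2-2-1 neighbour weights", {
  t <- 0:10
  track <- tibble::tibble(t = t, east = 1.4 * t, north = 0.7 * t,
                          quality = "ok")
  expect_identical(smooth_gnss(track), track)

  bad <- track
  bad$east[6] <- bad$east[6] + 50
  bad$quality[6] <- "inaccurate"
  sm <- smooth_gnss(bad)
  # collinear equally spaced neighbours: repaired point back on the line
  expect_equal(sm$east[6], 1.4 * 5, tolerance = 1e-12)
  expect_equal(sm$north[6], 0.7 * 5, tolerance = 1e-12)
  expect_identical(sm$east[-6], bad$east[-6])

  edge <- track
  edge$quality[1] <- "inaccurate"
  expect_warning(smooth_gnss(edge), "end")
})

test_that("route projection snaps to the polyline and preserves walk ordering", {
  poly <- tibble::tibble(east = c(0, 100, 100), north = c(0, 0, 80))
  on_line <- tibble::tibble(t = 0, east = 50, north = 0, quality = "ok")
  pr <- project_to_route(on_line, poly)
  expect_equal(c(pr$east, pr$north), c(50, 0))

  off <- tibble::tibble(t = 0, east = 50, north = 5, quality = "ok")
  pr <- project_to_route(off, poly)
  expect_equal(c(pr$east, pr$north), c(50, 0)) # foot of the perpendicular

  set.seed(3)
  tt <- 0:120
  s_true <- pmin(1.4 * tt, 180)
  true_pts <- wayfam:::point_at_arclength(poly, s_true)
  # high-precision receiver noise (dm-level) relative to 1.4 m steps
  walk <- tibble::tibble(t = tt, east = true_pts[, 1] + rnorm(length(tt), 0, 0.3),
                         north = true_pts[, 2] + rnorm(length(tt), 0, 0.3),
                         quality = "ok")
  prj <- project_to_route(walk, poly)
  s <- wayfam:::project_points_polyline(cbind(prj$east, prj$north), poly)$arclength
  expect_gte(mean(diff(s) >= -1e-9), 0.99)
})

test_that("the preprocessing chain removes injected artifacts end to end", {
  rec <- generate_recording("p01", "familiar", effect_config(anomaly_rate = 3),
                            route_zigzag(2, 30), seed = 33)
  truth <- rec$truth$artifact_intervals
  pre <- preprocess_recording(rec)
  expect_gt(nrow(truth), 0)
  expect_gte(nrow(pre$exclusion_intervals), 1)
  # no retained inertial sample still exceeds the threshold after filtering
  kept <- pre$imu_inertial
  fs <- 400
  mag <- pmax(abs(lowpass_filter(rec$imu_inertial$facc_x, 5, fs)),
              abs(lowpass_filter(rec$imu_inertial$facc_y, 5, fs)),
              abs(lowpass_filter(rec$imu_inertial$facc_z, 5, fs)))
  over <- rec$imu_inertial$t[mag > 10]
  expect_false(any(over %in% kept$t))
  expect_false(is.null(pre$imu))
})
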