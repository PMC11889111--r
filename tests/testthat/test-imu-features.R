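const_window <- function(ax = 3, ay = 4, az = 0, n = 300, fs = 100) {
  t <- (seq_len(n) - 1) / fs
  tibble::tibble(t = t, acc_x = ax, acc_y = ay, acc_z = az,
                 facc_x = 0, facc_y = 0, facc_z = 0,
                 roll = 1, pitch = 2, yaw = 3)
}

test_that("the feature bank has the contracted shape", {
  nms <- imu_feature_names()
  expect_length(nms, 99)
  expect_false(anyDuplicated(nms) > 0)
  expect_length(grep("^cep_", nms), 50)
  row <- imu_feature_row(random_imu_window(1))
  expect_equal(names(row), nms)
  expect_equal(ncol(row), 99)
})

test_that("basic statistics are mean-centered, offset-invariant, and count yaw crossings", {
  w <- const_window()
  b <- basic_stats(w)
  expect_equal(b$acc_x_var, 0)
  expect_equal(b$acc_x_p2p, 0)
  expect_equal(b$facc_z_p2p, 0)
  expect_equal(b$yaw_mean, 0) # centered on the window mean

  t <- (0:299) / 100
  w2 <- dplyr::mutate(w, yaw = sin(2 * pi * 0.5 * t + 0.3))
  b2 <- basic_stats(w2)
  expect_equal(b2$yaw_freq_change, 1.0, tolerance = 0.05)

  w3 <- dplyr::mutate(w2, yaw = yaw + 57)
  b3 <- basic_stats(w3)
  for (s in c("yaw_min", "yaw_max", "yaw_mean", "yaw_var", "yaw_freq_change")) {
    expect_equal(b3[[s]], b2[[s]], tolerance = 1e-12)
  }

  # per-trial centering reference shifts the window statistics
  b4 <- basic_stats(w2, center = c(yaw = 0.5))
  expect_equal(b4$yaw_mean, b2$yaw_mean + mean(w2$yaw) - 0.5, tolerance = 1e-12)
})

test_that("cepstral coefficients follow the log-spectrum definition", {
  set.seed(4)
  x <- rnorm(300)
  cc <- cepstral_coeffs(x)
  expect_length(cc, 50)
  expect_equal(cc, oracle_cepstral(x), tolerance = 1e-9)

  # scaling shifts only the zeroth coefficient, by 2 log k
  k <- 3.7
  cck <- cepstral_coeffs(k * x)
  expect_equal(cck[1] - cc[1], 2 * log(k), tolerance = 1e-9)
  expect_equal(cck[-1], cc[-1], tolerance = 1e-9)

  expect_true(all(is.finite(cepstral_coeffs(rep(0, 300)))))
  expect_error(cepstral_coeffs(rnorm(60)), "short")
})

test_that("time-domain measures integrate energy over time", {
  x <- rep(2, 300)
  tdm <- time_domain_measures(x, fs = 100)
  expect_equal(tdm$tdm_energy, 12)
  expect_equal(tdm$tdm_std, 0)
  expect_equal(tdm$tdm_p2p_ampl, 0)

  set.seed(5)
  y <- abs(rnorm(300, 9.8, 1))
  expect_equal(time_domain_measures(2 * y, 100)$tdm_energy,
               4 * time_domain_measures(y, 100)$tdm_energy, tolerance = 1e-12)
  expect_equal(unlist(time_domain_measures(y, 100)), oracle_tdm(y, 100),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fundamental period recovers oscillation cadence and rejects monotone input", {
  t <- (0:299) / 100
  x <- sin(2 * pi * 2 * t)
  expect_equal(fundamental_period(x, 100), 0.5, tolerance = 0.01)
  expect_true(is.na(fundamental_period(seq_len(300) * 0.01, 100)))

  # gait-like windows: cadence recovered across seeds
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    f <- runif(1, 1.4, 2.2)
    amp <- runif(1, 1, 2)
    ph <- runif(1, 0, 2 * pi)
    x <- amp * sin(2 * pi * f * t + ph) + rnorm(300, 0, 0.005)
    abs(fundamental_period(x, 100) - 1 / f)
  }, numeric(1))
  expect_true(all(errs <= 0.02))
})

test_that("movement measures match their definitions on the 3-4-5 window", {
  mm <- movement_measures(const_window())
  expect_equal(mm$mi_mean, 5)
  expect_equal(mm$mi_var, 0)
  expect_equal(mm$sma, 7)
  expect_equal(mm$mov_variation, 0)
  expect_equal(mm$entropy, 0)
  expect_equal(mm$energy_x, 9)

  # movement intensity spread uniformly over the 16 bins attains log2(16) bits
  w2 <- const_window(n = 288)
  w2$acc_x <- rep(seq(0, 15) + 0.5, each = 18)
  w2$acc_y <- 0
  w2$acc_z <- 0
  expect_equal(movement_measures(w2)$entropy, 4)
})

test_that("spectral measures locate a pure tone and count crossings", {
  t <- (0:299) / 100
  x <- sin(2 * pi * 10 * t) + 5 # strictly positive before centering
  sm <- spectral_music_measures(x, 100)
  expect_lte(abs(sm$spectral_centroid - 10), 100 / 300 + 0.2)
  expect_equal(sm$spectral_rolloff, 10, tolerance = 100 / 300)

  alt <- rep(c(1, -1), 150)
  expect_equal(spectral_music_measures(alt, 100)$zero_crossing_rate, 1)

  pos <- abs(rnorm(300)) + 1
  expect_equal(sum(pos < 0), 0) # strictly positive signal has no raw crossings
})

test_that("every family matches its independent recomputation on random windows", {
  for (seed in 1:30) {
    w <- random_imu_window(seed)
    mag <- sqrt(w$acc_x^2 + w$acc_y^2 + w$acc_z^2)
    center <- vapply(c("acc_x", "acc_y", "acc_z", "roll", "pitch", "yaw"),
                     function(ch) mean(w[[ch]]), numeric(1))
    rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1)
    expect_true(all(rel_err(unlist(basic_stats(w, center)), oracle_basic(w, center)) < 1e-9))
    expect_true(all(rel_err(cepstral_coeffs(mag), oracle_cepstral(mag)) < 1e-9))
    expect_true(all(rel_err(unlist(time_domain_measures(mag, 100)), oracle_tdm(mag, 100)) < 1e-9))
    fp <- fundamental_period(mag, 100)
    ofp <- oracle_fundamental_period(mag, 100)
    expect_true((is.na(fp) && is.na(ofp)) || rel_err(fp, ofp) < 1e-9)
    expect_true(all(rel_err(unlist(movement_measures(w)),
                            oracle_movement(w$acc_x, w$acc_y, w$acc_z)) < 1e-9))
    expect_true(all(rel_err(unlist(spectral_music_measures(mag, 100)),
                            oracle_spectral(mag, 100)) < 1e-9))
  }
})

test_that("feature rows are pure functions of the window", {
  w <- random_imu_window(77)
  expect_identical(imu_feature_row(w), imu_feature_row(w))
  short <- w[w$t < 0.9, ]
  expect_true(all(is.na(imu_feature_row(short))))
})
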