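test_that("the 3-SD outlier filter removes exactly the deviant rows", {
  ft <- fixture_separable_features()
  clamp1sd <- function(v) pmin(pmax(v, mean(v) - sd(v)), mean(v) + sd(v))
  within <- dplyr::mutate(ft, dplyr::across(c("signal", "noise1", "noise2"), clamp1sd))
  expect_equal(nrow(filter_outliers(within)), nrow(within))

  spiked <- within
  spiked$noise1[13] <- mean(within$noise1) + 4 * sd(within$noise1)
  filt <- filter_outliers(spiked)
  expect_equal(attr(filt, "n_removed"), 1)
  expect_false(spiked$window_id[13] %in% filt$window_id)

  # training-fitted stats applied to a second table
  stats <- attr(filter_outliers(ft), "stats")
  applied <- filter_outliers(ft, stats = stats)
  expect_s3_class(applied, "tbl_df")
})

test_that("Gaussian removal fraction matches the analytic expectation", {
  set.seed(12)
  k <- 4
  n <- 40000
  tab <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(n * k), n)), paste0("f", 1:k)))
  tab <- dplyr::mutate(tab,
                       participant_id = "p", recording_id = "r",
                       condition = "familiar", window_id = as.character(seq_len(n)))
  frac <- 1 - nrow(filter_outliers(tab)) / n
  expected <- 1 - (2 * pnorm(3) - 1)^k
  expect_equal(frac, expected, tolerance = 0.25) # 1.1% expected, wide MC slack
})

test_that("split plans respect their schemes and never leak", {
  ft <- fixture_separable_features(n_participants = 20)
  plans <- make_split(ft, "l5o4t", seed = 3, n_repeats = 3)
  for (plan in plans) {
    test <- ft[ft$window_id %in% plan$test_ids, ]
    train <- ft[ft$window_id %in% plan$train_ids, ]
    expect_equal(length(unique(test$recording_id)), 10)
    expect_equal(nrow(test) + nrow(train), nrow(ft))
    for (cond in c("familiar", "unfamiliar")) {
      expect_length(plan$holdout[[cond]], 5)
      expect_false(any(train$participant_id %in% plan$holdout[[cond]] &
                         train$condition == cond))
    }
  }
  # reproducibility
  plans2 <- make_split(ft, "l5o4t", seed = 3, n_repeats = 3)
  expect_identical(plans, plans2)

  p80 <- make_split(ft, "split_8020", seed = 3, n_repeats = 2)
  for (plan in p80) {
    expect_lte(abs(length(plan$test_ids) - 0.2 * nrow(ft)), 2)
  }
  expect_error(make_split(fixture_separable_features(n_participants = 4), "l5o4t"),
               "holdout")
})

test_that("tuning returns the single grid point and separates a linear signal", {
  ft <- fixture_separable_features()
  grid <- wayfam:::default_model_grid()
  model <- tune_and_train(ft, grid = grid, n_cv_folds = 4, seed = 5)
  expect_equal(model$config$n_estimators, grid$n_estimators)
  expect_equal(model$config$max_depth, grid$max_depth)

  p <- predict(model, ft)
  acc <- mean(ifelse(p >= 0.5, "familiar", "unfamiliar") == ft$condition)
  expect_gte(acc, 0.99)

  # determinism of the whole fit
  model2 <- tune_and_train(ft, grid = grid, n_cv_folds = 4, seed = 5)
  expect_equal(predict(model2, ft), p, tolerance = 1e-12)
})

test_that("cross-validation folds are disjoint from their scoring sets", {
  n <- 100
  folds <- wayfam:::with_seed(1, sample(rep(1:10, length.out = n)))
  for (f in 1:10) {
    expect_equal(sum(folds == f) + sum(folds != f), n)
    expect_length(intersect(which(folds == f), which(folds != f)), 0)
  }
})

test_that("evaluation reports accuracy, proportions and a decreasing train curve", {
  ft <- fixture_separable_features()
  model <- tune_and_train(ft, n_cv_folds = 4, seed = 5)
  ev <- evaluate_model(model, ft, train_rows = ft)
  expect_gte(ev$accuracy, 0.99)
  expect_equal(sum(ev$confusion), 1)
  expect_lte(ev$confusion["familiar", "unfamiliar"] + ev$confusion["unfamiliar", "familiar"],
             0.01)
  tr <- ev$logloss_curve[ev$logloss_curve$split == "train", ]
  expect_true(all(diff(tr$logloss) <= 1e-9))

  # permuted labels: held-out accuracy compatible with coin flipping
  set.seed(31)
  perm <- fixture_separable_features(n_participants = 12, seed = 31)
  perm$condition <- sample(perm$condition)
  plan <- make_split(perm, "split_8020", seed = 2, n_repeats = 1)[[1]]
  m <- tune_and_train(perm[perm$window_id %in% plan$train_ids, ], n_cv_folds = 4, seed = 2)
  ev2 <- evaluate_model(m, perm[perm$window_id %in% plan$test_ids, ])
  n_test <- ev2$n_test
  ci <- qnorm(0.975) * sqrt(0.25 / n_test)
  expect_gte(ev2$accuracy, 0.5 - ci - 0.05)
  expect_lte(ev2$accuracy, 0.5 + ci + 0.05)
})

test_that("SHAP attributions are additive and rank a planted signal first", {
  ft <- fixture_separable_features(n_participants = 12)
  model <- tune_and_train(ft, n_cv_folds = 4, seed = 9)
  imp <- shap_ranks(model, ft, k = 20)
  expect_equal(imp$ranks$feature[1], "signal")
  expect_equal(imp$ranks$rank, seq_len(nrow(imp$ranks)))

  contrib <- imp$contrib
  margins <- qlogis(predict(model, ft))
  expect_lt(max(abs(rowSums(contrib) - margins)), 1e-4) # single-precision margins

  # k above the feature count returns everything
  imp_all <- shap_ranks(model, ft, k = 100)
  expect_equal(nrow(imp_all$ranks), length(model$feature_cols))
})

test_that("the experiment matrix covers feature sets and schemes with tidy output", {
  ft <- fixture_cohort_features()
  ex <- run_experiment(ft, feature_sets = c("gaze", "imu", "gaze_imu"),
                       schemes = "split_8020", seed = 4, n_repeats = 2,
                       n_cv_folds = 3)
  expect_s3_class(ex, "wayfam_experiment")
  expect_equal(nrow(ex$summary), 3)
  expect_true(all(ex$summary$best_accuracy >= ex$summary$avg_accuracy - 1e-12))
  expect_true(all(ex$summary$avg_accuracy >= ex$summary$worst_accuracy - 1e-12))

  gi <- ex$evals[["gaze_imu|split_8020"]][[1]]$model
  expect_length(gi$feature_cols,
                length(gaze_feature_names()) + length(imu_feature_names()))

  td <- generics::tidy(ex)
  expect_equal(nrow(td), 6)
  gl <- generics::glance(ex)
  expect_named(gl, c("feature_set", "scheme", "avg_accuracy", "best_accuracy",
                     "worst_accuracy", "n_repeats"))
  ev <- ex$evals[["imu|split_8020"]][[1]]
  expect_s3_class(generics::tidy(ev), "tbl_df")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_logloss(ev), "ggplot")
  expect_s3_class(autoplot(ex$importance[["imu|split_8020"]]), "ggplot")
})
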