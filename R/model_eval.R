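#' Remove multivariate outlier windows
#'
#' Drops every row containing at least one feature value more than
#' `sd_limit` standard deviations from the column mean. The column means
#' and SDs are fit on the supplied table unless `stats` is given, which is
#' how the filter fit on the training partition is applied to a test
#' partition.
#'
#' @param features Feature tibble (metadata columns are ignored).
#' @param sd_limit Z-score limit (default 3).
#' @param stats Optional tibble (`feature`, `mean`, `sd`) from a previous
#'   call's `attr(, "stats")`.
#' @return Filtered tibble; `attr(, "stats")` holds the fitted column
#'   statistics and `attr(, "n_removed")` the removed-row count.
#' @export
filter_outliers <- function(features, sd_limit = 3, stats = NULL) {
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      metadata_cols())
  if (is.null(stats)) {
    stats <- tibble::tibble(
      feature = num_cols,
      mean = vapply(num_cols, function(c) mean(features[[c]], na.rm = TRUE), numeric(1)),
      sd = vapply(num_cols, function(c) stats::sd(features[[c]], na.rm = TRUE), numeric(1))
    )
  }
  bad <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(stats))) {
    cn <- stats$feature[i]
    if (!cn %in% names(features)) next
    s <- stats$sd[i]
    if (!is.finite(s) || s == 0) next
    z <- abs(features[[cn]] - stats$mean[i]) / s
    bad <- bad | (!is.na(z) & z > sd_limit)
  }
  out <- features[!bad, , drop = FALSE]
  attr(out, "families") <- attr(features, "families")
  attr(out, "stats") <- stats
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Train/test split plans
#'
#' Two validation schemes over the window-level feature table:
#' `split_8020` draws a condition-stratified 80/20 window split;
#' `l5o4t` ("leave five out for testing") holds out, per repeat, all
#' windows of `n_holdout_per_condition` randomly chosen participants'
#' familiar-condition recordings and of an independently drawn set of
#' participants' unfamiliar-condition recordings -- so test windows come
#' from (participant, condition) recordings never seen in training,
#' removing participant leakage.
#'
#' @param features Feature tibble.
#' @param scheme `"split_8020"` or `"l5o4t"`.
#' @param seed Integer seed.
#' @param n_holdout_per_condition Held-out participants per condition.
#' @param n_repeats Number of repeated draws.
#' @param test_fraction Test share for the 80/20 scheme.
#' @return List of split plans; each has `scheme`, `repeat_index`,
#'   `train_ids`, `test_ids` (window ids) and, for l5o4t, the held-out
#'   participants per condition.
#' @export
make_split <- function(features, scheme = c("split_8020", "l5o4t"), seed = 1,
                       n_holdout_per_condition = 5, n_repeats = 10,
                       test_fraction = 0.2) {
  scheme <- match.arg(scheme)
  stopifnot(!anyDuplicated(features$window_id))
  lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      if (scheme == "split_8020") {
        test_ids <- unlist(lapply(split(features$window_id, features$condition), function(ids) {
          sample(ids, round(test_fraction * length(ids)))
        }), use.names = FALSE)
        holdout <- NULL
      } else {
        parts <- sort(unique(features$participant_id))
        if (length(parts) <= n_holdout_per_condition) {
          stop("fewer participants than the l5o4t holdout size", call. = FALSE)
        }
        holdout <- list(familiar = sort(sample(parts, n_holdout_per_condition)),
                        unfamiliar = sort(sample(parts, n_holdout_per_condition)))
        test_ids <- features$window_id[
          (features$condition == "familiar" & features$participant_id %in% holdout$familiar) |
            (features$condition == "unfamiliar" & features$participant_id %in% holdout$unfamiliar)]
      }
      train_ids <- setdiff(features$window_id, test_ids)
      stopifnot(length(intersect(train_ids, test_ids)) == 0)
      list(scheme = scheme, repeat_index = r,
           train_ids = train_ids, test_ids = test_ids, holdout = holdout)
    })
  })
}

#' Hyperparameter search grid
#'
#' Cartesian grid over the gradient-boosted-tree hyperparameters that are
#' searched by cross-validation: subsample, number of estimators, minimum
#' child weight, maximum depth, learning rate, gamma and column subsample
#' per tree.
#'
#' @param subsample,n_estimators,min_child_weight,max_depth,learning_rate,gamma,colsample_bytree
#'   Candidate values.
#' @return Tibble, one row per configuration.
#' @export
search_grid <- function(subsample = c(0.1, 0.4, 0.5),
                        n_estimators = c(100, 500, 700, 1000),
                        min_child_weight = c(0.5, 0.6, 0.7),
                        max_depth = c(3, 6, 10),
                        learning_rate = c(0.001, 0.01, 0.05, 0.1),
                        gamma = c(0.6, 0.7, 1.0),
                        colsample_bytree = c(0.6, 0.7, 0.8, 1.0)) {
  tidyr::expand_grid(subsample = subsample, n_estimators = n_estimators,
                     min_child_weight = min_child_weight, max_depth = max_depth,
                     learning_rate = learning_rate, gamma = gamma,
                     colsample_bytree = colsample_bytree)
}

# A single fast configuration used as the default when no tuning is wanted.
default_model_grid <- function() {
  search_grid(subsample = 0.5, n_estimators = 150, min_child_weight = 0.5,
              max_depth = 6, learning_rate = 0.1, gamma = 0.6,
              colsample_bytree = 0.8)
}

feature_matrix <- function(features, feature_cols) {
  m <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

condition_label <- function(condition) as.numeric(condition == "familiar")

logloss <- function(y, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

fit_booster <- function(X, y, config, seed, nrounds = NULL) {
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 eta = config$learning_rate, max_depth = as.integer(config$max_depth),
                 subsample = config$subsample, gamma = config$gamma,
                 colsample_bytree = config$colsample_bytree,
                 min_child_weight = config$min_child_weight,
                 nthread = 1, seed = as.integer(seed))
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
                     nrounds = as.integer(nrounds %||% config$n_estimators),
                     verbose = 0)
}

#' Tune by cross-validation and train the familiarity classifier
#'
#' Searches the supplied hyperparameter grid (optionally a random subset)
#' by k-fold cross-validation on the training rows, scoring each
#' configuration by mean validation negative log-likelihood, then refits
#' the winning configuration on all training rows. Every fold prediction
#' is made on rows the fold's model never saw. Deterministic given
#' (data, grid, seed).
#'
#' @param train_rows Feature tibble (training partition).
#' @param grid Configuration tibble from [search_grid()]; defaults to a
#'   single fast configuration (no tuning).
#' @param feature_cols Feature columns to use; default every non-metadata
#'   numeric column.
#' @param n_cv_folds Cross-validation folds (10 canonical).
#' @param n_search Randomly subsample the grid to this many configurations
#'   (NULL = exhaustive).
#' @param seed Integer seed.
#' @return A `wayfam_model`: booster, chosen config, CV table, feature
#'   columns.
#' @export
tune_and_train <- function(train_rows, grid = default_model_grid(),
                           feature_cols = NULL, n_cv_folds = 10,
                           n_search = NULL, seed = 1) {
  feature_cols <- feature_cols %||%
    setdiff(names(train_rows)[vapply(train_rows, is.numeric, logical(1))], metadata_cols())
  X <- feature_matrix(train_rows, feature_cols)
  y <- condition_label(train_rows$condition)
  if (!is.null(n_search) && n_search < nrow(grid)) {
    grid <- with_seed(derive_seed(seed, 7L), grid[sample(nrow(grid), n_search), , drop = FALSE])
  }
  n <- nrow(X)
  folds <- with_seed(derive_seed(seed, 11L),
                     sample(rep(seq_len(n_cv_folds), length.out = n)))
  cv <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    config <- grid[g, ]
    fold_ll <- vapply(seq_len(n_cv_folds), function(f) {
      tr <- folds != f
      if (sum(!tr) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
      bst <- fit_booster(X[tr, , drop = FALSE], y[tr], config, derive_seed(seed, 100 + f))
      p <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1))
      logloss(y[!tr], p)
    }, numeric(1))
    dplyr::mutate(config, cv_logloss = mean(fold_ll, na.rm = TRUE))
  })
  best <- cv[which.min(cv$cv_logloss), ]
  booster <- fit_booster(X, y, best, derive_seed(seed, 13L))
  structure(
    list(booster = booster, config = best, cv = cv,
         feature_cols = feature_cols, n_train = n, seed = seed),
    class = "wayfam_model"
  )
}

#' @export
print.wayfam_model <- function(x, ...) {
  cat(sprintf("<wayfam_model> gradient-boosted trees on %d features, %d training windows\n",
              length(x$feature_cols), x$n_train))
  cat(sprintf("  chosen: n_estimators=%d depth=%d eta=%g subsample=%g gamma=%g colsample=%g min_chw=%g (cv logloss %.4f)\n",
              x$config$n_estimators, x$config$max_depth, x$config$learning_rate,
              x$config$subsample, x$config$gamma, x$config$colsample_bytree,
              x$config$min_child_weight, x$config$cv_logloss))
  invisible(x)
}

#' Predicted familiarity probability
#'
#' @param object A `wayfam_model`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @return Probability that each window belongs to the familiar condition.
#' @export
predict.wayfam_model <- function(object, newdata, ...) {
  predict(object$booster,
          xgboost::xgb.DMatrix(feature_matrix(newdata, object$feature_cols), nthread = 1))
}

#' Evaluate a fitted familiarity classifier
#'
#' Accuracy and the confusion matrix as proportions of all test windows,
#' plus train/test log-loss as a function of the number of boosting
#' rounds (the under/over-fitting diagnostic).
#'
#' @param model A `wayfam_model`.
#' @param test_rows Test partition.
#' @param train_rows Optional training partition for the train log-loss
#'   curve.
#' @param curve_points Number of boosting-round evaluations on the curve.
#' @return A `wayfam_eval` with `accuracy`, `confusion` (proportions),
#'   `logloss_curve`, `n_test`.
#' @export
evaluate_model <- function(model, test_rows, train_rows = NULL, curve_points = 25) {
  y <- condition_label(test_rows$condition)
  p <- predict(model, test_rows)
  pred <- ifelse(p >= 0.5, "familiar", "unfamiliar")
  conf <- matrix(0, 2, 2, dimnames = list(true = conditions(), predicted = conditions()))
  for (tc in conditions()) for (pc in conditions()) {
    conf[tc, pc] <- mean(test_rows$condition == tc & pred == pc)
  }
  nr <- model$config$n_estimators
  rounds <- unique(pmax(1L, round(seq(1L, nr, length.out = min(curve_points, nr)))))
  curve_for <- function(rows, split) {
    yy <- condition_label(rows$condition)
    dm <- xgboost::xgb.DMatrix(feature_matrix(rows, model$feature_cols), nthread = 1)
    tibble::tibble(
      round = rounds, split = split,
      logloss = vapply(rounds, function(r) {
        logloss(yy, predict(model$booster, dm, iterationrange = c(1, r)))
      }, numeric(1))
    )
  }
  curve <- curve_for(test_rows, "test")
  if (!is.null(train_rows)) curve <- dplyr::bind_rows(curve_for(train_rows, "train"), curve)
  structure(
    list(accuracy = mean(pred == test_rows$condition), confusion = conf,
         logloss_curve = curve, n_test = nrow(test_rows),
         config = model$config),
    class = "wayfam_eval"
  )
}

#' @export
print.wayfam_eval <- function(x, ...) {
  cat(sprintf("<wayfam_eval> accuracy %.3f on %d test windows\n", x$accuracy, x$n_test))
  print(round(x$confusion, 3))
  invisible(x)
}

#' SHAP feature-importance ranks
#'
#' Per-feature mean absolute SHAP value (TreeSHAP contributions on the
#' log-odds scale) over the supplied rows, ranked; the top `k` features
#' are returned with their behavioral family tag. SHAP attributions are
#' additive: per row they sum to the prediction margin minus the base
#' value.
#'
#' @param model A `wayfam_model`.
#' @param rows Feature tibble to explain.
#' @param k Number of top features (all if fewer).
#' @return A `wayfam_importance`: tibble `rank`, `feature`, `family`,
#'   `mean_abs_shap`.
#' @export
shap_ranks <- function(model, rows, k = 20) {
  contrib <- predict(model$booster,
                     xgboost::xgb.DMatrix(feature_matrix(rows, model$feature_cols), nthread = 1),
                     predcontrib = TRUE)
  shap <- contrib[, seq_len(ncol(contrib) - 1L), drop = FALSE] # last column is the bias term
  colnames(shap) <- model$feature_cols
  imp <- tibble::tibble(feature = colnames(shap),
                        mean_abs_shap = colMeans(abs(shap))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  family = feature_family(.data$feature)) |>
    dplyr::select("rank", "feature", "family", "mean_abs_shap")
  structure(list(ranks = utils::head(imp, k), contrib = contrib),
            class = "wayfam_importance")
}

#' @export
print.wayfam_importance <- function(x, ...) {
  cat("<wayfam_importance> top features by mean |SHAP|\n")
  print(as.data.frame(utils::head(x$ranks, 10)))
  invisible(x)
}

#' Run the full classification experiment matrix
#'
#' For every requested feature set (gaze only, IMU only, combined) and
#' validation scheme: repeat the split, fit the 3-SD outlier filter on the
#' training partition and apply it to both partitions, tune/train the
#' classifier, and evaluate on the held-out windows. Per cell the average,
#' best and worst accuracy over repeats are reported, together with the
#' SHAP importance ranks of the best repeat's model. An assertion at fit
#' time guarantees that no test window id ever reaches training.
#'
#' @param features Feature table from [extract_features()].
#' @param feature_sets Subset of `c("gaze", "imu", "gaze_imu")`.
#' @param schemes Subset of `c("split_8020", "l5o4t")`.
#' @param seed Integer seed.
#' @param n_repeats Repeats per scheme.
#' @param n_holdout_per_condition Held-out participants per condition
#'   (l5o4t).
#' @param grid,n_search,n_cv_folds Passed to [tune_and_train()].
#' @param sd_limit Outlier filter limit.
#' @param shap_k Top-k SHAP features reported.
#' @return A `wayfam_experiment`: `summary` tibble (one row per cell),
#'   `runs` (per-repeat accuracies), `evals` and `importance` per cell.
#' @export
run_experiment <- function(features,
                           feature_sets = c("gaze", "imu", "gaze_imu"),
                           schemes = c("l5o4t", "split_8020"),
                           seed = 1, n_repeats = 10,
                           n_holdout_per_condition = 5,
                           grid = default_model_grid(), n_search = NULL,
                           n_cv_folds = 10, sd_limit = 3, shap_k = 20) {
  feature_sets <- match.arg(feature_sets, c("gaze", "imu", "gaze_imu"), several.ok = TRUE)
  schemes <- match.arg(schemes, c("l5o4t", "split_8020"), several.ok = TRUE)
  cols_for <- function(set) switch(set,
    gaze = gaze_feature_names(),
    imu = imu_feature_names(),
    gaze_imu = c(gaze_feature_names(), imu_feature_names()))

  runs <- list()
  evals <- list()
  importance <- list()
  for (scheme in schemes) {
    plans <- make_split(features, scheme, seed = seed,
                        n_holdout_per_condition = n_holdout_per_condition,
                        n_repeats = n_repeats)
    for (set in feature_sets) {
      fcols <- intersect(cols_for(set), names(features))
      cell <- paste(set, scheme, sep = "|")
      cell_evals <- vector("list", length(plans))
      accs <- numeric(length(plans))
      for (i in seq_along(plans)) {
        plan <- plans[[i]]
        train <- features[features$window_id %in% plan$train_ids, , drop = FALSE]
        test <- features[features$window_id %in% plan$test_ids, , drop = FALSE]
        # leakage guard, enforced rather than assumed
        stopifnot(length(intersect(train$window_id, test$window_id)) == 0)
        if (plan$scheme == "l5o4t") {
          for (cond in conditions()) {
            stopifnot(!any(train$participant_id %in% plan$holdout[[cond]] &
                             train$condition == cond))
          }
        }
        train_f <- filter_outliers(train[, c(metadata_cols(), fcols)], sd_limit = sd_limit)
        test_f <- filter_outliers(test[, c(metadata_cols(), fcols)],
                                  sd_limit = sd_limit, stats = attr(train_f, "stats"))
        model <- tune_and_train(train_f, grid = grid, feature_cols = fcols,
                                n_cv_folds = n_cv_folds, n_search = n_search,
                                seed = derive_seed(seed, 1000 * i))
        cell_evals[[i]] <- evaluate_model(model, test_f, train_rows = train_f)
        cell_evals[[i]]$model <- model
        accs[i] <- cell_evals[[i]]$accuracy
      }
      best_i <- which.max(accs)
      best_plan <- plans[[best_i]]
      best_test <- features[features$window_id %in% best_plan$test_ids, , drop = FALSE]
      importance[[cell]] <- shap_ranks(cell_evals[[best_i]]$model, best_test, k = shap_k)
      evals[[cell]] <- cell_evals
      runs[[cell]] <- tibble::tibble(feature_set = set, scheme = scheme,
                                     repeat_index = seq_along(plans), accuracy = accs)
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$feature_set, .data$scheme) |>
    dplyr::summarise(avg_accuracy = mean(.data$accuracy),
                     best_accuracy = max(.data$accuracy),
                     worst_accuracy = min(.data$accuracy),
                     n_repeats = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, runs = runs, evals = evals,
                 importance = importance, seed = seed),
            class = "wayfam_experiment")
}

#' @export
print.wayfam_experiment <- function(x, ...) {
  cat("<wayfam_experiment>\n")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}
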