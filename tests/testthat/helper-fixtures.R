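# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# A short preprocessed recording used by segmentation / feature tests.
fixture_recording <- function() {
  memo("recording", function() {
    rec <- generate_recording("p01", "familiar", effect_config(),
                              route_zigzag(3, 35), seed = 101)
    preprocess_recording(rec)
  })
}

# A tiny paired cohort (4 participants) with default condition contrasts.
fixture_cohort <- function() {
  memo("cohort", function() {
    generate_cohort(4, effect_config(anomaly_rate = 0.5),
                    list(route_zigzag(3, 35)), seed = 202)
  })
}

fixture_cohort_pre <- function() {
  memo("cohort_pre", function() lapply(fixture_cohort(), preprocess_recording))
}

fixture_cohort_features <- function() {
  memo("cohort_features", function() extract_features(fixture_cohort_pre()))
}

# A feature table with a planted linear class signal, cheap to classify.
fixture_separable_features <- function(n_participants = 8, windows_each = 12, seed = 7) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    do.call(rbind, lapply(c("familiar", "unfamiliar"), function(cond) {
      shift <- if (cond == "familiar") 2.5 else -2.5
      data.frame(
        participant_id = sprintf("p%02d", i),
        recording_id = sprintf("p%02d_%s", i, cond),
        condition = cond,
        window_id = sprintf("p%02d_%s_w%02d", i, cond, seq_len(windows_each)),
        t0 = 3 * (seq_len(windows_each) - 1),
        signal = rnorm(windows_each, shift, 0.5),
        noise1 = rnorm(windows_each),
        noise2 = rnorm(windows_each)
      )
    }))
  }))
  tibble::as_tibble(rows)
}

interval_iou <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- (a1 - a0) + (b1 - b0) - inter
  inter / union
}
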