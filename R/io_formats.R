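#' Write / read a recording directory
#'
#' On-disk session layout, one directory per recording: `gaze.csv` (t,x,y),
#' `imu_inertial.csv` and `imu_rotation.csv` (raw multirate IMU),
#' optionally `imu.csv` (unified 100 Hz stream when preprocessed),
#' `gnss.csv` (t,east,north,quality), `events.csv` (t_request,junction_id),
#' `route.geojson` (LineString plus decision-point Point features) and
#' `manifest.json` (identity, seed, exclusion intervals, effect snapshot).
#' All distances are meters, times seconds, angles degrees and gaze
#' positions normalized scene units (origin top-left, x right, y down).
#'
#' `read_recording()` validates stream monotonicity and the condition label
#' on load; a missing file or a non-monotonic time column raises an error
#' naming the offending stream.
#'
#' @param recording A `wayfam_recording`.
#' @param dir Directory path (created if needed).
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns the `wayfam_recording`.
#' @examples
#' rec <- generate_recording("p01", "familiar", effect_config(),
#'                           route_zigzag(2, 30), seed = 1)
#' d <- file.path(tempdir(), "rec_p01")
#' write_recording(rec, d)
#' rec2 <- read_recording(d)
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "wayfam_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(recording$gaze, file.path(dir, "gaze.csv"), progress = FALSE)
  readr::write_csv(recording$imu_inertial, file.path(dir, "imu_inertial.csv"), progress = FALSE)
  readr::write_csv(recording$imu_rotation, file.path(dir, "imu_rotation.csv"), progress = FALSE)
  if (!is.null(recording$imu)) {
    readr::write_csv(recording$imu, file.path(dir, "imu.csv"), progress = FALSE)
  }
  readr::write_csv(recording$gnss, file.path(dir, "gnss.csv"), progress = FALSE)
  readr::write_csv(recording$events, file.path(dir, "events.csv"), progress = FALSE)
  write_route_geojson(recording$route, file.path(dir, "route.geojson"))
  manifest <- list(
    schema_version = 1L,
    participant_id = recording$participant_id,
    condition = recording$condition,
    recording_id = recording$recording_id,
    seed = recording$seed,
    exclusion_intervals = as.list(recording$exclusion_intervals),
    effect = effect_to_list(recording$effect)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  need <- c("gaze.csv", "imu_inertial.csv", "imu_rotation.csv", "gnss.csv",
            "events.csv", "route.geojson", "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("recording directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$condition, "familiar") &&
      !identical(manifest$condition, "unfamiliar")) {
    stop("manifest condition must be 'familiar' or 'unfamiliar', got '",
         manifest$condition, "'", call. = FALSE)
  }
  read_stream <- function(file, name) {
    s <- readr::read_csv(file.path(dir, file), show_col_types = FALSE, progress = FALSE)
    if (nrow(s) > 1 && any(diff(s$t) <= 0)) {
      stop("non-monotonic timestamps in stream '", name, "'", call. = FALSE)
    }
    s
  }
  excl <- manifest$exclusion_intervals
  excl <- tibble::tibble(t0 = as.numeric(unlist(excl$t0)), t1 = as.numeric(unlist(excl$t1)))
  imu <- if (file.exists(file.path(dir, "imu.csv"))) read_stream("imu.csv", "imu") else NULL
  structure(
    list(
      participant_id = manifest$participant_id,
      condition = manifest$condition,
      recording_id = manifest$recording_id,
      gaze = read_stream("gaze.csv", "gaze"),
      imu_inertial = read_stream("imu_inertial.csv", "imu_inertial"),
      imu_rotation = read_stream("imu_rotation.csv", "imu_rotation"),
      imu = imu,
      gnss = readr::read_csv(file.path(dir, "gnss.csv"), show_col_types = FALSE, progress = FALSE),
      route = read_route_geojson(file.path(dir, "route.geojson")),
      events = readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE, progress = FALSE),
      exclusion_intervals = excl,
      seed = manifest$seed,
      effect = effect_from_list(manifest$effect),
      truth = NULL
    ),
    class = "wayfam_recording"
  )
}

effect_to_list <- function(effect) {
  if (is.null(effect)) return(NULL)
  lapply(unclass(effect), function(v) if (length(v) > 1) as.list(v) else v)
}

effect_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  args <- lapply(lst, function(v) if (is.list(v)) unlist(v) else v)
  do.call(effect_config, args)
}

write_route_geojson <- function(route, path) {
  line <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = unname(apply(polyline_matrix(route$polyline), 1,
                                               function(p) as.list(unname(p)),
                                               simplify = FALSE))),
    properties = list(decision_radius_m = route$decision_radius_m)
  )
  pts <- lapply(seq_len(nrow(route$decision_points)), function(i) {
    v <- route$decision_points$vertex[i]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = list(route$polyline$east[v], route$polyline$north[v])),
      properties = list(junction_id = route$decision_points$junction_id[i],
                        is_turn = route$decision_points$is_turn[i],
                        vertex = v)
    )
  })
  gj <- list(type = "FeatureCollection", features = c(list(line), pts))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_route_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  types <- vapply(feats, function(f) f$geometry$type, character(1))
  line <- feats[[which(types == "LineString")[1]]]
  coords <- do.call(rbind, lapply(line$geometry$coordinates,
                                  function(c2) as.numeric(unlist(c2))))
  pts <- feats[types == "Point"]
  dp <- purrr::map_dfr(pts, function(f) {
    tibble::tibble(vertex = as.integer(f$properties$vertex),
                   junction_id = as.character(f$properties$junction_id),
                   is_turn = as.logical(f$properties$is_turn))
  })
  make_route(tibble::tibble(east = coords[, 1], north = coords[, 2]), dp,
             decision_radius_m = line$properties$decision_radius_m %||% 10)
}

#' Write / read a feature table
#'
#' Feature tables are CSV with a JSON column manifest alongside
#' (`<path>_manifest.json`) recording each feature column's modality tag.
#' Doubles round-trip exactly (shortest-representation encoding). Reading
#' validates the manifest against the file's columns and requires the
#' window metadata columns.
#'
#' @param table Non-empty feature tibble (from [extract_features()]).
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the tibble with the `families` attribute.
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0) stop("feature table is empty", call. = FALSE)
  if (anyDuplicated(names(table))) {
    stop("duplicate column names in feature table: ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "),
         call. = FALSE)
  }
  meta_needed <- setdiff(metadata_cols(), "t0")
  if (!all(meta_needed %in% names(table))) {
    stop("feature table must carry ", paste(meta_needed, collapse = ", "), call. = FALSE)
  }
  printable <- dplyr::mutate(table, dplyr::across(
    dplyr::where(is.double),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  ))
  readr::write_csv(printable, path, progress = FALSE, na = "NA")
  fams <- attr(table, "families") %||% feature_modalities()
  fams <- fams[names(fams) %in% names(table)]
  jsonlite::write_json(list(columns = names(table), families = as.list(fams)),
                       manifest_path(path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path) paste0(sub("\\.csv$", "", path), "_manifest.json")

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate column names in feature table file", call. = FALSE)
  }
  # base parser: correctly rounded doubles, so %.17g output round-trips exactly
  tab <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                           stringsAsFactors = FALSE))
  meta_needed <- setdiff(metadata_cols(), "t0")
  miss <- setdiff(meta_needed, names(tab))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (file.exists(manifest_path(path))) {
    man <- jsonlite::read_json(manifest_path(path))
    if (!identical(unlist(man$columns), names(tab))) {
      stop("column manifest does not match the feature table columns", call. = FALSE)
    }
    attr(tab, "families") <- unlist(man$families)
  }
  tab
}
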