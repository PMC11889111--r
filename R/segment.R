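#' Detect arrival at a junction from the GNSS track
#'
#' First GNSS time at which the distance between the position fix and the
#' junction's decision point drops to `radius_m` or below.
#'
#' @param gnss GNSS tibble (`t`, `east`, `north`).
#' @param route A `wayfam_route`.
#' @param junction_id Junction identifier in the route's decision points.
#' @param radius_m Arrival radius (m); defaults to the route's.
#' @return Arrival time (s), or `NA_real_` when the junction is never
#'   reached within the radius.
#' @export
detect_junction_arrival <- function(gnss, route, junction_id,
                                    radius_m = route$decision_radius_m) {
  xy <- route_junction_xy(route, junction_id)
  d <- sqrt((gnss$east - xy[["east"]])^2 + (gnss$north - xy[["north"]])^2)
  i <- which(d <= radius_m)
  if (length(i) == 0) return(NA_real_)
  gnss$t[min(i)]
}

#' Extract matching-to-action segments
#'
#' A segment spans from the moment a route instruction is requested to the
#' moment the wayfinder reaches the junction the instruction refers to --
#' the portion of the walk that carries the instruction-triggered
#' decision-making behavior. Repeated requests for the same junction are
#' merged into one segment starting at the earliest request. Segments are
#' clipped around the recording's exclusion intervals, so no downstream
#' window can overlap excluded data; requests whose junction is never
#' reached (or that arrive after the detected arrival) are skipped.
#'
#' @param recording A `wayfam_recording`.
#' @param radius_m Arrival radius (m).
#' @return Tibble of segments: `recording_id`, `junction_id`, `t_start`,
#'   `t_end`.
#' @export
extract_segments <- function(recording, radius_m = recording$route$decision_radius_m) {
  stopifnot(inherits(recording, "wayfam_recording"))
  ev <- recording$events
  if (nrow(ev) == 0) {
    return(tibble::tibble(recording_id = character(0), junction_id = character(0),
                          t_start = numeric(0), t_end = numeric(0)))
  }
  ev <- ev |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(t_request = min(.data$t_request), .groups = "drop")

  segs <- purrr::pmap_dfr(ev, function(t_request, junction_id) {
    t_arr <- detect_junction_arrival(recording$gnss, recording$route,
                                     junction_id, radius_m)
    if (is.na(t_arr) || t_arr <= t_request) {
      return(tibble::tibble(junction_id = character(0),
                            t_start = numeric(0), t_end = numeric(0)))
    }
    tibble::tibble(junction_id = junction_id, t_start = t_request, t_end = t_arr)
  })
  if (nrow(segs) == 0) {
    return(tibble::tibble(recording_id = character(0), junction_id = character(0),
                          t_start = numeric(0), t_end = numeric(0)))
  }
  segs <- clip_segments(segs, recording$exclusion_intervals)
  tibble::tibble(recording_id = recording$recording_id, segs) |>
    dplyr::arrange(.data$t_start)
}

# Split segments around exclusion intervals, keeping the clean pieces.
clip_segments <- function(segs, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(segs)
  exclusions <- merge_intervals(exclusions)
  purrr::pmap_dfr(segs, function(junction_id, t_start, t_end) {
    pieces <- tibble::tibble(t_start = t_start, t_end = t_end)
    for (i in seq_len(nrow(exclusions))) {
      e0 <- exclusions$t0[i]
      e1 <- exclusions$t1[i]
      pieces <- purrr::pmap_dfr(pieces, function(t_start, t_end) {
        if (e1 <= t_start || e0 >= t_end) {
          return(tibble::tibble(t_start = t_start, t_end = t_end))
        }
        out <- tibble::tibble(t_start = numeric(0), t_end = numeric(0))
        if (e0 > t_start) out <- dplyr::bind_rows(out, tibble::tibble(t_start = t_start, t_end = e0))
        if (e1 < t_end) out <- dplyr::bind_rows(out, tibble::tibble(t_start = e1, t_end = t_end))
        out
      })
    }
    if (nrow(pieces) == 0) return(tibble::tibble(junction_id = character(0), t_start = numeric(0), t_end = numeric(0)))
    tibble::tibble(junction_id = junction_id, pieces)
  })
}

#' Cut segments into fixed non-overlapping windows
#'
#' Each segment is tiled with contiguous windows of `width_s` seconds from
#' its start; the trailing remainder shorter than one window is discarded
#' so every window carries identical feature semantics.
#'
#' @param segments Tibble from [extract_segments()].
#' @param width_s Window width (s); the classification unit is 3 s.
#' @return Tibble of windows: segment columns plus `window_index` (0-based
#'   within segment), `t0`, `duration`, and a unique `window_id`.
#' @examples
#' segs <- tibble::tibble(recording_id = "r", junction_id = "J01",
#'                        t_start = 10, t_end = 40)
#' window_segments(segs)
#' @export
window_segments <- function(segments, width_s = 3) {
  if (width_s <= 0) stop("width_s must be positive", call. = FALSE)
  if (nrow(segments) == 0) {
    return(tibble::tibble(recording_id = character(0), junction_id = character(0),
                          t_start = numeric(0), t_end = numeric(0),
                          window_index = integer(0), t0 = numeric(0),
                          duration = numeric(0), window_id = character(0)))
  }
  out <- purrr::pmap_dfr(segments, function(recording_id, junction_id, t_start, t_end, ...) {
    n <- floor((t_end - t_start) / width_s + 1e-9)
    if (n < 1) return(NULL)
    tibble::tibble(
      recording_id = recording_id, junction_id = junction_id,
      t_start = t_start, t_end = t_end,
      window_index = seq_len(n) - 1L,
      t0 = t_start + (seq_len(n) - 1L) * width_s,
      duration = width_s
    )
  })
  if (is.null(out) || nrow(out) == 0) {
    return(window_segments(segments[0, , drop = FALSE], width_s))
  }
  out |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::mutate(window_id = sprintf("%s_w%03d", .data$recording_id,
                                      dplyr::row_number() - 1L)) |>
    dplyr::ungroup()
}
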