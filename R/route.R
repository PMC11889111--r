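#' Construct a walking-route geometry
#'
#' A route is an ordered planar polyline (meters, local east/north frame)
#' plus a set of decision points: junction vertices where the wayfinder may
#' have to act on an instruction. Turn junctions trigger instruction-request
#' events in the session generator.
#'
#' @param polyline Data frame with `east`, `north` columns (>= 2 vertices).
#' @param decision_points Data frame with `vertex` (1-based index into the
#'   polyline), `junction_id` (character) and `is_turn` (logical).
#' @param decision_radius_m Arrival radius around a decision point (m).
#'
#' @return A `wayfam_route` object.
#' @examples
#' route_zigzag(n_legs = 3)
#' @export
make_route <- function(polyline, decision_points, decision_radius_m = 10) {
  polyline <- tibble::as_tibble(polyline)[, c("east", "north")]
  if (nrow(polyline) < 2L) stop("route polyline needs at least 2 vertices", call. = FALSE)
  decision_points <- tibble::as_tibble(decision_points)
  stopifnot(all(c("vertex", "junction_id", "is_turn") %in% names(decision_points)))
  if (any(decision_points$vertex < 1L | decision_points$vertex > nrow(polyline))) {
    stop("decision point vertex index outside the polyline", call. = FALSE)
  }
  structure(
    list(polyline = polyline,
         decision_points = dplyr::mutate(decision_points,
                                         junction_id = as.character(.data$junction_id)),
         decision_radius_m = decision_radius_m),
    class = "wayfam_route"
  )
}

#' @rdname make_route
#' @param n_legs Number of straight legs; interior vertices become turn
#'   junctions.
#' @param leg_length_m Length of each leg (m).
#' @export
route_zigzag <- function(n_legs = 4, leg_length_m = 60, decision_radius_m = 10) {
  stopifnot(n_legs >= 1)
  # alternate east / north headings so every interior vertex is a 90-degree turn
  headings <- rep(c(0, 90), length.out = n_legs)
  pts <- matrix(0, n_legs + 1L, 2L)
  for (i in seq_len(n_legs)) {
    ang <- headings[i] * pi / 180
    pts[i + 1L, ] <- pts[i, ] + leg_length_m * c(cos(ang), sin(ang))
  }
  poly <- tibble::tibble(east = pts[, 1], north = pts[, 2])
  interior <- if (n_legs >= 2) seq(2L, n_legs) else integer(0)
  dp <- tibble::tibble(
    vertex = c(interior, n_legs + 1L),
    junction_id = c(sprintf("J%02d", seq_along(interior)), "DEST"),
    is_turn = c(rep(TRUE, length(interior)), FALSE)
  )
  make_route(poly, dp, decision_radius_m)
}

#' @export
print.wayfam_route <- function(x, ...) {
  cl <- polyline_cumlen(x$polyline)
  cat(sprintf("<wayfam_route> %d vertices, %.0f m, %d decision points (%d turns)\n",
              nrow(x$polyline), cl[length(cl)], nrow(x$decision_points),
              sum(x$decision_points$is_turn)))
  invisible(x)
}

route_junction_xy <- function(route, junction_id) {
  i <- match(junction_id, route$decision_points$junction_id)
  if (is.na(i)) stop("unknown junction_id: ", junction_id, call. = FALSE)
  v <- route$decision_points$vertex[i]
  c(east = route$polyline$east[v], north = route$polyline$north[v])
}

route_junction_arclength <- function(route, junction_id) {
  i <- match(junction_id, route$decision_points$junction_id)
  v <- route$decision_points$vertex[i]
  polyline_cumlen(route$polyline)[v]
}
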