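#' Fermat shortest-electrical-path travel time to an interior point
#'
#' The propagation path from an antenna to a hypothetical point inside the
#' head is decomposed into a free-space route to a signal entry point on the
#' skin and an interior segment from the entry point to the investigated
#' point, traversed at the effective permittivity evaluated at the segment
#' length. Following Fermat's principle, the one-way time is minimized over
#' candidate entry points, which are restricted to the antenna's line-of-sight
#' boundary vertices:
#'
#' \deqn{\tau = \tau_a + \min_e \left[ \frac{|A - e|}{c} +
#'   \frac{|e - p| \sqrt{\varepsilon_{eff}(|e - p|; a(e))}}{c} \right]}
#'
#' with `a(e)` the distance from entry vertex `e` to the head centroid.
#'
#' @param antenna antenna position (mm), outside the boundary.
#' @param point investigated point (mm), inside or on the boundary.
#' @param boundary a [head_boundary()].
#' @param model a [permittivity_model()].
#' @param antenna_delay antenna delay `tau_a` (seconds): the time to emit
#'   radiation from the antenna exterior from signal inception at the feed.
#' @param los optional precomputed [line_of_sight_points()] index set.
#' @return one-way propagation time (seconds).
#' @export
fermat_travel_time <- function(antenna, point, boundary, model,
                               antenna_delay = 0, los = NULL) {
  inside <- points_in_polygon(matrix(point, 1L), boundary$vertices) ||
    distance_to_boundary(point, boundary) < 1e-9
  if (!inside) stop("point must lie inside or on the head boundary")
  if (is.null(los)) los <- line_of_sight_points(antenna, boundary)
  if (length(los) == 0L) stop("empty line-of-sight set")
  e <- boundary$vertices[los, , drop = FALSE]
  d_air <- sqrt((e[, 1L] - antenna[1L])^2 + (e[, 2L] - antenna[2L])^2)
  d_int <- sqrt((e[, 1L] - point[1L])^2 + (e[, 2L] - point[2L])^2)
  a_e <- sqrt((e[, 1L] - boundary$centroid[1L])^2 +
                (e[, 2L] - boundary$centroid[2L])^2)
  eps <- if (model$kind == "fixed") {
    model$eps_fixed
  } else {
    model$eps_max * (1 - model$c1 * exp(-model$c2 * pmin(d_int, 2 * a_e) / a_e))
  }
  antenna_delay + mm_to_s(min(d_air + d_int * sqrt(eps)))
}

#' Round-trip travel-time table for a scan geometry and imaging grid
#'
#' For every antenna position and every in-head grid cell, the monostatic
#' round-trip time is twice the one-way Fermat propagation time. Cells outside
#' the head mask are `NA`.
#'
#' @param geometry a [scan_geometry()].
#' @param boundary a [head_boundary()].
#' @param grid an [imaging_grid()].
#' @param model a [permittivity_model()].
#' @param antenna_delay seconds; default 0 (synthetic data).
#' @param mask optional precomputed [head_mask()].
#' @return An object of class `travel_time_table`: `times` is an `N x P x Q`
#'   array of round-trip seconds, plus the `mask`, input references and a
#'   content `hash` for caching.
#' @export
build_travel_time_table <- function(geometry, boundary, grid, model,
                                    antenna_delay = 0, mask = NULL) {
  if (is.null(mask)) mask <- head_mask(grid, boundary)
  p <- grid$dims[1L]; q <- grid$dims[2L]
  n <- geometry$n_positions
  cx <- rep(grid$xs, times = q)[as.vector(mask)]
  cy <- rep(grid$ys, each = p)[as.vector(mask)]
  times <- array(NA_real_, c(n, p, q))
  flat <- which(as.vector(mask))
  cen <- boundary$centroid
  for (i in seq_len(n)) {
    ant <- geometry$positions[i, ]
    los <- line_of_sight_points(ant, boundary)
    e <- boundary$vertices[los, , drop = FALSE]
    d_air <- sqrt((e[, 1L] - ant[1L])^2 + (e[, 2L] - ant[2L])^2)
    a_e <- sqrt((e[, 1L] - cen[1L])^2 + (e[, 2L] - cen[2L])^2)
    best <- rep(Inf, length(cx))
    for (k in seq_along(los)) {
      d_int <- sqrt((cx - e[k, 1L])^2 + (cy - e[k, 2L])^2)
      eps <- if (model$kind == "fixed") {
        model$eps_fixed
      } else {
        model$eps_max *
          (1 - model$c1 * exp(-model$c2 * pmin(d_int, 2 * a_e[k]) / a_e[k]))
      }
      cand <- d_air[k] + d_int * sqrt(eps)
      best <- pmin(best, cand)
    }
    slab <- matrix(NA_real_, p, q)
    slab[flat] <- 2 * (antenna_delay + mm_to_s(best))
    times[i, , ] <- slab
  }
  structure(
    list(
      times = times, mask = mask, antenna_delay = antenna_delay,
      geometry = geometry, boundary = boundary, grid = grid, model = model,
      hash = travel_table_hash(geometry, boundary, grid, model, antenna_delay)
    ),
    class = "travel_time_table"
  )
}

#' Content hash identifying a travel-time table's inputs
#' @noRd
travel_table_hash <- function(geometry, boundary, grid, model, antenna_delay) {
  key <- c(
    as.vector(signif(geometry$positions, 12)),
    as.vector(signif(boundary$vertices, 12)),
    grid$dims, grid$cell_size, grid$center,
    model$eps_max, model$c1, model$c2,
    if (model$kind == "fixed") model$eps_fixed else -1,
    antenna_delay
  )
  # order-sensitive polynomial rolling hash; stable across sessions
  h <- 0
  for (v in key) h <- (h * 31 + sum(as.integer(
    charToRaw(sprintf("%.12g", v))))) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.travel_time_table <- function(x, ...) {
  cat(sprintf(
    "<travel_time_table> N = %d antennas, grid %d x %d (%.2f mm), %d in-head cells, hash %s\n",
    dim(x$times)[1L], x$grid$dims[1L], x$grid$dims[2L], x$grid$cell_size,
    sum(x$mask), x$hash
  ))
  invisible(x)
}
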