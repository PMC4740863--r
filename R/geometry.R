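# Speed of light in free space (m/s). All geometry is in millimetres;
# time computations convert mm -> m exactly once, here.
C0 <- 299792458

#' Seconds of one-way free-space travel per millimetre
#' @noRd
mm_to_s <- function(d_mm) d_mm * 1e-3 / C0

#' Construct a scan geometry from explicit antenna positions
#'
#' A scan geometry describes an equiangular monostatic acquisition: the same
#' antenna transmits and receives at `N` positions placed at equal angular
#' steps about the scan center. Positions must be ordered by increasing polar
#' angle about the center and the adjacent angular differences must be equal
#' (to within 1e-9 degrees).
#'
#' @param positions numeric N x 2 matrix of antenna coordinates (mm).
#' @param center length-2 numeric, scan center (mm).
#' @return An object of class `scan_geometry` with elements `positions`,
#'   `center`, `n_positions`, `angular_step` (degrees) and `boresights`
#'   (unit vectors pointing from each antenna toward the center).
#' @export
scan_geometry <- function(positions, center = c(0, 0)) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must be an N x 2 matrix")
  n <- nrow(positions)
  if (n < 3L) stop("a scan geometry needs at least 3 positions")
  rel <- sweep(positions, 2L, center)
  ang <- atan2(rel[, 2L], rel[, 1L])
  # unwrap so the sequence is strictly increasing
  ang_unwrapped <- ang
  if (n > 1L) {
    d <- diff(ang)
    d[d <= 0] <- d[d <= 0] + 2 * pi
    ang_unwrapped <- ang[1L] + c(0, cumsum(d))
  }
  steps_deg <- diff(ang_unwrapped) * 180 / pi
  step <- 360 / n
  if (any(abs(steps_deg - step) > 1e-9)) {
    stop("positions are not equiangular about the scan center")
  }
  bores <- -rel / sqrt(rowSums(rel^2))
  structure(
    list(
      positions = unname(positions), center = as.numeric(center),
      n_positions = n, angular_step = step, boresights = unname(bores)
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> N = %d positions, angular step %.4f deg, center (%.1f, %.1f) mm\n",
    x$n_positions, x$angular_step, x$center[1L], x$center[2L]
  ))
  invisible(x)
}

#' Parabolic scanning profile
#'
#' Places `n` antenna positions at equal angular steps about `center`, with
#' the radius varying parabolically in angle between the two profile radii:
#' within each quadrant the radius interpolates parabolically from `r1` on
#' the x axis to `r2` on the y axis,
#' `r(theta) = r2 + (r1 - r2) * (2 (theta mod pi) / pi - 1)^2`,
#' approximating a constant antenna-to-skin standoff around an elongated
#' (elliptical) head whose semi-axes differ. `r1 = r2` degenerates to a
#' circle.
#'
#' @param r1,r2 profile radii (mm), both positive.
#' @param n number of scan positions (>= 3).
#' @param center scan center (mm).
#' @param theta0 angular offset of the first position (degrees).
#' @return A [scan_geometry()].
#' @export
make_parabolic_scan <- function(r1, r2, n, center = c(0, 0), theta0 = 0) {
  if (!is.numeric(r1) || !is.numeric(r2) || r1 <= 0 || r2 <= 0) {
    stop("profile radii must be positive")
  }
  if (n < 3L) stop("n must be at least 3")
  theta <- (theta0 * pi / 180) + 2 * pi * (seq_len(n) - 1L) / n
  phase <- theta %% pi
  r <- r2 + (r1 - r2) * (2 * phase / pi - 1)^2
  pos <- cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
  scan_geometry(pos, center)
}

#' Circular scanning profile
#'
#' @param radius circle radius (mm).
#' @inheritParams make_parabolic_scan
#' @return A [scan_geometry()].
#' @export
make_circular_scan <- function(radius, n, center = c(0, 0), theta0 = 0) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  make_parabolic_scan(radius, radius, n, center, theta0)
}

#' Head boundary polygon
#'
#' The head outline at the imaged layer, stored as a closed simple polygon of
#' `I >= 16` vertices on the skin-air interface. Vertices are re-ordered
#' counter-clockwise if needed. The centroid is the area centroid of the
#' polygon and serves as the "center of the head" for the normal-depth
#' parameter of the permittivity model.
#'
#' @param vertices I x 2 numeric matrix of boundary points (mm), ordered along
#'   the outline (no repeated closing vertex).
#' @return An object of class `head_boundary` with `vertices`, `n_vertices`,
#'   `centroid`.
#' @export
head_boundary <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must be an I x 2 matrix")
  i <- nrow(v)
  if (i < 16L) stop("boundary needs at least 16 vertices")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  area2 <- sum(cross)
  if (abs(area2) < .Machine$double.eps) stop("degenerate boundary polygon")
  if (area2 < 0) { # make counter-clockwise
    v <- v[rev(seq_len(i)), , drop = FALSE]
    x <- v[, 1L]; y <- v[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cross <- x * yn - xn * y
    area2 <- sum(cross)
  }
  centroid <- c(sum((x + xn) * cross), sum((y + yn) * cross)) / (3 * area2)
  structure(
    list(vertices = unname(v), n_vertices = i, centroid = centroid,
         area = area2 / 2),
    class = "head_boundary"
  )
}

#' Elliptical head boundary sampled at I vertices
#'
#' @param a,b semi-axes along x and y (mm).
#' @param n number of boundary vertices (default 360).
#' @param center ellipse center (mm).
#' @return A [head_boundary()].
#' @export
ellipse_boundary <- function(a, b, n = 360L, center = c(0, 0)) {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  t <- 2 * pi * (seq_len(n) - 1L) / n
  head_boundary(cbind(center[1L] + a * cos(t), center[2L] + b * sin(t)))
}

#' Imaging grid of square cells
#'
#' The imaging area (default 300 x 300 mm) segmented into P x Q square cells
#' (default 0.5 mm) defined by their center points. Cells follow the half-open
#' convention `[x, x + cell)` with the center at `x + cell/2`.
#'
#' @param width,height grid extent (mm); must be integer multiples of
#'   `cell_size`.
#' @param cell_size cell edge (mm).
#' @param center grid center (mm).
#' @return An object of class `imaging_grid` with `xs` (P cell-center x
#'   coordinates), `ys` (Q cell-center y coordinates), `dims = c(P, Q)`,
#'   `cell_size`.
#' @export
imaging_grid <- function(width = 300, height = 300, cell_size = 0.5,
                         center = c(0, 0)) {
  p <- width / cell_size
  q <- height / cell_size
  if (abs(p - round(p)) > 1e-9 || abs(q - round(q)) > 1e-9) {
    stop("extent must be an integer number of cells")
  }
  p <- as.integer(round(p)); q <- as.integer(round(q))
  x0 <- center[1L] - width / 2
  y0 <- center[2L] - height / 2
  structure(
    list(
      xs = x0 + cell_size * (seq_len(p) - 0.5),
      ys = y0 + cell_size * (seq_len(q) - 0.5),
      dims = c(p, q), cell_size = cell_size,
      extent = c(width, height), center = as.numeric(center)
    ),
    class = "imaging_grid"
  )
}

#' Even-odd point-in-polygon test
#'
#' @param pts n x 2 matrix of query points.
#' @param poly I x 2 polygon vertex matrix.
#' @return logical vector; points on an edge count as inside.
#' @noRd
points_in_polygon <- function(pts, poly) {
  px <- pts[, 1L]; py <- pts[, 2L]
  n <- length(px)
  inside <- logical(n)
  xi <- poly[, 1L]; yi <- poly[, 2L]
  xj <- c(xi[-1L], xi[1L]); yj <- c(yi[-1L], yi[1L])
  for (k in seq_along(xi)) {
    x1 <- xi[k]; y1 <- yi[k]; x2 <- xj[k]; y2 <- yj[k]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- px[crosses] <= xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' Line-of-sight boundary vertices for an antenna
#'
#' Candidate signal entry points on the head boundary are restricted to the
#' arc the antenna can see: the tangent points of the head area as seen from
#' the antenna (the extremes of the maximum angular cone) and every boundary
#' vertex between them on the near side.
#'
#' @param antenna length-2 antenna position (mm), strictly outside the
#'   boundary.
#' @param boundary a [head_boundary()].
#' @return Integer vector of boundary vertex indices, ordered along the arc.
#' @export
line_of_sight_points <- function(antenna, boundary) {
  v <- boundary$vertices
  if (points_in_polygon(matrix(antenna, 1L), v)) {
    stop("antenna must lie strictly outside the head boundary")
  }
  rel <- sweep(v, 2L, antenna)
  phi <- atan2(rel[, 2L], rel[, 1L])
  phi0 <- atan2(boundary$centroid[2L] - antenna[2L],
                boundary$centroid[1L] - antenna[1L])
  dphi <- ((phi - phi0 + pi) %% (2 * pi)) - pi
  i_lo <- which.min(dphi)
  i_hi <- which.max(dphi)
  n <- nrow(v)
  arc1 <- if (i_lo <= i_hi) i_lo:i_hi else c(i_lo:n, 1L:i_hi)
  arc2 <- setdiff(seq_len(n), setdiff(arc1, c(i_lo, i_hi)))
  # near arc: the one containing the vertex closest to the antenna
  d2 <- rowSums(rel^2)
  nearest <- which.min(d2)
  if (nearest %in% arc1) arc1 else {
    if (i_lo <= i_hi) c(i_hi:n, 1L:i_lo) else i_hi:i_lo
  }
}

#' Boolean head mask on an imaging grid
#'
#' Marks each grid cell whose center lies inside the head boundary polygon
#' (even-odd rule; centers on the boundary count as inside).
#'
#' @param grid an [imaging_grid()].
#' @param boundary a [head_boundary()]; must fit inside the grid extent.
#' @return P x Q logical matrix (`[p, q]` indexes `(xs[p], ys[q])`).
#' @export
head_mask <- function(grid, boundary) {
  v <- boundary$vertices
  if (min(v[, 1L]) < min(grid$xs) - grid$cell_size ||
      max(v[, 1L]) > max(grid$xs) + grid$cell_size ||
      min(v[, 2L]) < min(grid$ys) - grid$cell_size ||
      max(v[, 2L]) > max(grid$ys) + grid$cell_size) {
    stop("boundary exceeds the imaging grid extent")
  }
  pts <- cbind(
    rep(grid$xs, times = grid$dims[2L]),
    rep(grid$ys, each = grid$dims[1L])
  )
  matrix(points_in_polygon(pts, v), grid$dims[1L], grid$dims[2L])
}

#' Shortest distance from a point to the boundary polyline
#' @noRd
distance_to_boundary <- function(point, boundary) {
  v <- boundary$vertices
  w <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  ex <- w[, 1L] - v[, 1L]; ey <- w[, 2L] - v[, 2L]
  px <- point[1L] - v[, 1L]; py <- point[2L] - v[, 2L]
  len2 <- ex^2 + ey^2
  t <- pmin(1, pmax(0, (px * ex + py * ey) / len2))
  dx <- px - t * ex; dy <- py - t * ey
  sqrt(min(dx^2 + dy^2))
}
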