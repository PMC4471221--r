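#' External cochlear length of a landmark path
#'
#' Sum of Euclidean distances between consecutive landmarks, in mm. With
#' landmarks placed at small intervals along the outer circumference of the
#' cochlea between the cupula (apex) and the origin of the basal turn, this
#' polyline length is the external cochlear length (ECL), a proxy for
#' basilar-membrane length. Full precision is returned; rounding to the
#' nearest tenth happens only in the reporting layer.
#'
#' @param path a [landmark_path] (or n x 3 matrix) with at least 2 points.
#' @return the polyline length (mm).
#' @export
polyline_length <- function(path) {
  pts <- .as_points(path)
  if (nrow(pts) < 2L)
    .stop2("invalid_input", "polyline_length needs at least 2 points")
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

.as_points <- function(path) {
  if (inherits(path, "landmark_path")) return(unclass(path))
  pts <- as.matrix(path)
  if (!is.numeric(pts) || ncol(pts) != 3L)
    .stop2("invalid_input", "expected a landmark_path or n x 3 matrix")
  pts
}

#' Locate the center of the cochlear spiral
#'
#' Estimates the spiral center "A" from the perpendicular bisectors of local
#' chords along the landmark path. All points are first projected
#' orthogonally onto their total-least-squares plane; chords are then formed
#' between landmarks a fixed index span apart (about one sixteenth of the
#' path, so chords stay local but long enough that landmark noise barely
#' tilts them), and A is the in-plane point minimising the squared distances
#' to all chord perpendicular bisectors. For points on a circular arc every
#' bisector passes through the true center, so the estimate is exact there.
#'
#' @param path a spiral [landmark_path] with at least 8 points, not all
#'   collinear.
#' @param span chord index span; default `max(1, round((n - 1)/16))`.
#' @return an object of class `spiral_geometry` with fields `center_A` (3D,
#'   mm), `center_2d` (in-plane coordinates), `plane` (center, normal,
#'   basis), and placeholders `R1`, `R2` filled by [fit_turn_circles()].
#' @export
spiral_center <- function(path, span = NULL) {
  pts <- .as_points(path)
  n <- nrow(pts)
  if (n < 8L)
    .stop2("invalid_input", "spiral center needs at least 8 landmarks")
  span <- if (is.null(span)) max(1L, round((n - 1L) / 16))
    else max(1L, min(as.integer(span), n - 1L))
  plane <- .fit_plane(pts)
  xy <- .project_2d(pts, plane)
  i1 <- seq_len(n - span)
  p1 <- xy[i1, , drop = FALSE]
  p2 <- xy[i1 + span, , drop = FALSE]
  A <- p2 - p1
  b <- rowSums(A * (p1 + p2) / 2)
  qr_A <- qr(A)
  if (qr_A$rank < 2L)
    .stop2("singular_geometry",
           "chord bisectors are parallel; spiral center is undetermined")
  c2d <- qr.coef(qr_A, b)
  center3d <- drop(plane$center + plane$basis %*% c2d)
  structure(list(center_A = center3d, center_2d = c2d, plane = plane,
                 R1 = NA_real_, R2 = NA_real_),
            class = "spiral_geometry")
}

#' @export
print.spiral_geometry <- function(x, ...) {
  cat(sprintf("<spiral_geometry: A = (%.3f, %.3f, %.3f)%s>\n",
              x$center_A[1], x$center_A[2], x$center_A[3],
              if (is.finite(x$R1))
                sprintf(", R1 = %.3f, R2 = %.3f", x$R1, x$R2) else ""))
  invisible(x)
}

# In-plane polar coordinates of a spiral path around a center, ordered from
# the basal end. Returns radii, the cumulative signed sweep (radians,
# monotone up to digitisation noise) and the total absolute sweep.
.spiral_polar <- function(path, center) {
  pts <- .as_points(path)
  start <- attr(path, "start")
  if (!is.null(start) && identical(start, "apex"))
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  geom <- if (inherits(center, "spiral_geometry")) center else NULL
  plane <- if (is.null(geom)) .fit_plane(pts) else geom$plane
  xy <- .project_2d(pts, plane)
  c2d <- if (is.null(geom)) {
    drop(crossprod(plane$basis, as.numeric(center) - plane$center))
  } else geom$center_2d
  rel <- sweep(xy, 2L, c2d)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-9))
    .stop2("undefined_angle",
           "landmark coincides with the spiral center; angle undefined")
  th <- atan2(rel[, 2L], rel[, 1L])
  dth <- diff(th)
  dth <- ((dth + pi) %% (2 * pi)) - pi   # wrap increments to (-pi, pi]
  sweep_cum <- c(0, cumsum(dth))
  list(r = r, sweep = abs(sweep_cum), total = abs(sweep_cum[length(sweep_cum)]))
}

#' Fit basal and apical turn circles
#'
#' Fits, with the common center "A" held fixed, circles to the landmarks of
#' the first (basal) and last (apical) spiral turns: the least-squares radius
#' for a fixed center is the mean in-plane distance of the turn's landmarks
#' to A. The basal turn covers the landmarks whose cumulative angular sweep
#' from the basal end is below one full rotation, the apical turn those
#' within one rotation of the apical end; on paths spanning less than two
#' full turns the two windows are truncated at the sweep midpoint so they do
#' not overlap.
#'
#' @param path a spiral [landmark_path] spanning at least one full turn.
#' @param center a `spiral_geometry` from [spiral_center()] or a 3D point.
#' @return the `spiral_geometry` with radii filled in: `R1` (apical, smaller)
#'   and `R2` (basal, larger), in mm.
#' @export
fit_turn_circles <- function(path, center) {
  pol <- .spiral_polar(path, center)
  if (pol$total < 2 * pi - 1e-6)
    .stop2("insufficient_turns",
           "path spans %.2f turns; at least one full turn is required",
           pol$total / (2 * pi))
  w <- min(2 * pi, pol$total / 2)
  basal <- pol$sweep < w - 1e-9
  apical <- pol$sweep > pol$total - w + 1e-9
  R2 <- mean(pol$r[basal])
  R1 <- mean(pol$r[apical])
  geom <- if (inherits(center, "spiral_geometry")) center else
    spiral_center(path)
  geom$R1 <- min(R1, R2)
  geom$R2 <- max(R1, R2)
  geom
}

#' Number of cochlear turns
#'
#' TUR is the absolute cumulative signed in-plane angular sweep of the
#' landmarks around the spiral center, divided by 360 degrees: the number of
#' full rotations plus the fractional angle between the center-to-apex and
#' center-to-base rays. Taking the absolute sweep makes the count independent
#' of the winding direction (left versus right cochlea).
#'
#' @inheritParams fit_turn_circles
#' @return number of turns (full rotations + fraction), full precision.
#' @export
count_turns <- function(path, center) {
  .spiral_polar(path, center)$total / (2 * pi)
}

#' Curvature gradient
#'
#' CUR is the dimensionless ratio R2/R1 between the radius of the larger
#' circle fitted to the first (basal) spiral turn and the radius of the
#' smaller circle fitted to the last (apical) turn.
#'
#' @param R1 apical (smaller) radius, mm; or a `spiral_geometry` with fitted
#'   radii, in which case `R2` is ignored.
#' @param R2 basal (larger) radius, mm.
#' @return CUR = R2/R1 (>= 1 under the caller contract R2 >= R1).
#' @export
curvature_gradient <- function(R1, R2) {
  if (inherits(R1, "spiral_geometry")) {
    R2 <- R1$R2; R1 <- R1$R1
  }
  .check_number(R1, "R1", positive = TRUE)
  .check_number(R2, "R2", positive = TRUE)
  R2 / R1
}

#' Oval window area
#'
#' Area (mm^2) of the oval-window outline: the outline points are projected
#' onto their total-least-squares plane (the analogue of the oblique slice
#' best fitting the complete outline) and the planar shoelace area of the
#' ordered projected polygon is returned. A self-intersecting projected
#' polygon is rejected.
#'
#' @param outline a window [landmark_path] with at least 5 points forming a
#'   simple closed loop (a duplicated closing point is tolerated).
#' @return the planar polygon area, mm^2.
#' @export
oval_window_area <- function(outline) {
  pts <- .as_points(outline)
  if (nrow(pts) >= 2L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 5L)
    .stop2("invalid_input", "an outline needs at least 5 distinct points")
  plane <- .fit_plane(pts)
  xy <- .project_2d(pts, plane)
  if (.polygon_self_intersects(xy))
    .stop2("invalid_outline", "projected outline polygon self-intersects")
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
}

# Proper-crossing test between all non-adjacent edge pairs of a closed
# polygon given as an n x 2 matrix of ordered vertices.
.polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  p <- xy
  q <- xy[c(2:n, 1L), , drop = FALSE]
  orient <- function(a, b, c)
    (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  for (i in seq_len(n - 2L)) {
    js <- seq.int(i + 2L, n)
    if (i == 1L) js <- js[js != n]        # edge n wraps to vertex 1
    if (!length(js)) next
    a <- p[rep(i, length(js)), , drop = FALSE]
    b <- q[rep(i, length(js)), , drop = FALSE]
    c_ <- p[js, , drop = FALSE]
    d <- q[js, , drop = FALSE]
    o1 <- orient(a, b, c_); o2 <- orient(a, b, d)
    o3 <- orient(c_, d, a); o4 <- orient(c_, d, b)
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(TRUE)
  }
  FALSE
}

#' Measure the five cochlear variables from landmark paths
#'
#' Combines [polyline_length()], [spiral_center()], [fit_turn_circles()],
#' [count_turns()], [curvature_gradient()] and [oval_window_area()] into the
#' standard five-variable description of a cochlea: ECL (mm), TUR (turns),
#' CUR (ratio), RECL = ECL/TUR (mm, computed on unrounded values) and OWA
#' (mm^2, `NA` when no outline is available, as for many fossils). All values
#' are kept at full precision; use [report_measurements()] for the rounded
#' reporting convention (one decimal for ECL/TUR/CUR/RECL, two for OWA).
#'
#' @param spiral a spiral [landmark_path].
#' @param outline an optional window [landmark_path].
#' @return an object of class `cochlear_measurements` (a list with elements
#'   `ecl`, `tur`, `cur`, `recl`, `owa`, `geometry`).
#' @export
measure_cochlea <- function(spiral, outline = NULL) {
  geom <- spiral_center(spiral)
  geom <- fit_turn_circles(spiral, geom)
  tur <- count_turns(spiral, geom)
  ecl <- polyline_length(spiral)
  out <- list(ecl = ecl,
              tur = tur,
              cur = curvature_gradient(geom),
              recl = ecl / tur,
              owa = if (is.null(outline)) NA_real_ else
                oval_window_area(outline),
              geometry = geom)
  class(out) <- "cochlear_measurements"
  out
}

#' @export
print.cochlear_measurements <- function(x, ...) {
  cat("Cochlear measurements (reported rounding):\n")
  print(report_measurements(x))
  invisible(x)
}

#' @export
as.data.frame.cochlear_measurements <- function(x, ...) {
  data.frame(ECL = x$ecl, TUR = x$tur, CUR = x$cur, RECL = x$recl,
             OWA = x$owa)
}

#' Reported (rounded) cochlear measurements
#'
#' Applies the reporting rounding rule - half away from zero, one decimal for
#' ECL, TUR, CUR and RECL, two decimals for OWA. Downstream statistics always
#' use the full-precision values.
#'
#' @param x a `cochlear_measurements` object or a data frame with columns
#'   ECL, TUR, CUR, RECL, OWA.
#' @return a one-row (or same-shape) data frame of rounded values.
#' @export
report_measurements <- function(x) {
  df <- if (inherits(x, "cochlear_measurements")) as.data.frame(x) else x
  for (v in intersect(c("ECL", "TUR", "CUR", "RECL"), names(df)))
    df[[v]] <- .round_half_up(df[[v]], 1L)
  if ("OWA" %in% names(df)) df$OWA <- .round_half_up(df$OWA, 2L)
  df
}
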