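#' Ordered 3D landmark paths
#'
#' A `landmark_path` is an ordered sequence of 3D coordinates (in mm) digitised
#' either along the outer circumference of the cochlear spiral (role
#' `"spiral"`) or around the oval-window outline (role `"window"`). Spiral
#' paths must declare at which anatomical end they start (`"base"`, the origin
#' of the basal turn, or `"apex"`, the cupula); the measurement code never
#' guesses the orientation.
#'
#' @param points numeric matrix (or data frame) with columns x, y, z in mm,
#'   one ordered landmark per row.
#' @param role `"spiral"` or `"window"`.
#' @param start for spiral paths, the declared first end: `"base"` or
#'   `"apex"`.
#' @return an object of class `landmark_path`: the coordinate matrix with
#'   attributes `role` and `start`.
#' @examples
#' th <- seq(0, 3 * pi, length.out = 200)
#' p <- landmark_path(cbind(cos(th), sin(th), 0), role = "spiral")
#' polyline_length(p)
#' @export
landmark_path <- function(points, role = c("spiral", "window"),
                          start = c("base", "apex")) {
  role <- match.arg(role)
  start <- match.arg(start)
  pts <- as.matrix(points)
  if (is.data.frame(points)) pts <- data.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 3L)
    .stop2("invalid_input", "landmark points must be an n x 3 numeric matrix")
  if (nrow(pts) < 2L)
    .stop2("invalid_input", "a landmark path needs at least 2 points")
  if (anyNA(pts) || any(!is.finite(pts)))
    .stop2("invalid_input", "landmark coordinates must be finite")
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d == 0))
    .stop2("invalid_input", "consecutive landmarks must be distinct (rows %s)",
           paste(which(d == 0), collapse = ", "))
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(pts, class = c("landmark_path", "matrix"),
            role = role, start = start)
}

#' @export
print.landmark_path <- function(x, ...) {
  cat(sprintf("<landmark_path: %d points, role = %s%s>\n", nrow(x),
              attr(x, "role"),
              if (attr(x, "role") == "spiral")
                paste0(", starts at ", attr(x, "start")) else ""))
  invisible(x)
}

#' Read / write landmark CSV files
#'
#' Landmark files are plain CSV with header `x,y,z` (units mm), one ordered
#' point per row. The path role and spiral orientation are supplied by the
#' caller, not guessed from the file.
#'
#' @param file path to a CSV file.
#' @inheritParams landmark_path
#' @return `read_landmarks()` returns a [landmark_path]; `write_landmarks()`
#'   returns `file` invisibly.
#' @export
read_landmarks <- function(file, role = c("spiral", "window"),
                           start = c("base", "apex")) {
  df <- read.csv(file)
  if (!all(c("x", "y", "z") %in% names(df)))
    .stop2("invalid_input", "landmark file '%s' must have header x,y,z", file)
  landmark_path(df[, c("x", "y", "z")], role = role, start = start)
}

#' @rdname read_landmarks
#' @param path a [landmark_path].
#' @export
write_landmarks <- function(path, file) {
  write.csv(as.data.frame(unclass(path)[, , drop = FALSE]), file,
            row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Total-least-squares plane through a point cloud. Returns the centroid, the
# unit normal (smallest principal axis) and an in-plane orthonormal basis.
.fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[2L] < max(sv$d[1L], 1) * 1e-10)
    .stop2("singular_geometry",
           "landmarks are (nearly) collinear; no unique best-fit plane")
  list(center = ctr, normal = sv$v[, 3L], basis = sv$v[, 1:2, drop = FALSE])
}

# Project to in-plane 2D coordinates (columns u, v) of a fitted plane.
.project_2d <- function(pts, plane) {
  sweep(pts, 2L, plane$center) %*% plane$basis
}
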