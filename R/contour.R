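#' Closed contour objects
#'
#' A contour is a closed, ordered polygon of vertices in image coordinates
#' (pixel centers at integer coordinates, origin top-left, x rightward,
#' y downward). Vertex order is normalized to counter-clockwise as seen on
#' screen. The contour is the state of the active-contour model and the
#' output of segmentation.
#'
#' @param vertices numeric n x 2 matrix of (x, y) vertex positions, n >= 8.
#' @return An object of class `contour`.
#' @export
contour <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 8) {
    stop_invalid("a contour needs an n x 2 vertex matrix with n >= 8")
  }
  if (!all(is.finite(vertices))) stop_invalid("contour vertices must be finite")
  colnames(vertices) <- c("x", "y")
  # normalize to counter-clockwise on screen: with y pointing down, CCW as
  # displayed corresponds to negative shoelace sign in (x, y)
  if (polygon_signed_area(vertices) > 0) {
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  }
  structure(list(vertices = vertices, closed = TRUE), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf(
    "<contour> %d vertices, area %.1f px^2, perimeter %.1f px\n",
    nrow(x$vertices), contour_area(x), contour_perimeter(x)
  ))
  invisible(x)
}

#' Regular polygon approximating a circle
#'
#' @param center numeric length-2 (x, y) center, pixels.
#' @param radius circle radius, pixels.
#' @param n number of vertices (default 64).
#' @return A [contour].
#' @export
circle_contour <- function(center, radius, n = 64) {
  if (!is_scalar_number(radius) || radius <= 0) stop_invalid("radius must be > 0")
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  contour(cbind(center[1] + radius * cos(t), center[2] + radius * sin(t)))
}

#' Polygon area, perimeter and centroid of a contour
#'
#' Area uses the shoelace formula on the vertex polygon.
#'
#' @param x a [contour].
#' @return `contour_area`: area in squared pixels; `contour_perimeter`:
#'   perimeter in pixels; `contour_centroid`: (x, y) centroid.
#' @export
contour_area <- function(x) polygon_area(x$vertices)

#' @rdname contour_area
#' @export
contour_perimeter <- function(x) polygon_perimeter(x$vertices)

#' @rdname contour_area
#' @export
contour_centroid <- function(x) polygon_centroid(x$vertices)

#' Resample a contour to uniformly spaced vertices
#'
#' Vertices are redistributed at uniform arc-length spacing along the closed
#' polygon, preserving the start vertex position and orientation.
#'
#' @param x a [contour].
#' @param n number of vertices in the result.
#' @return A [contour] with `n` vertices.
#' @export
resample_contour <- function(x, n = nrow(x$vertices)) {
  v <- x$vertices
  seg <- v[c(seq_len(nrow(v))[-1], 1), , drop = FALSE] - v
  d <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(d))
  per <- cs[length(cs)]
  if (per <= 0) stop_degenerate_contour("contour has zero perimeter")
  tt <- seq(0, per, length.out = n + 1)[seq_len(n)]
  vx <- stats::approx(cs, c(v[, 1], v[1, 1]), xout = tt)$y
  vy <- stats::approx(cs, c(v[, 2], v[1, 2]), xout = tt)$y
  contour(cbind(vx, vy))
}

# Vertices scaled from pixel units to mm, optionally recentered.
contour_to_mm <- function(x, pixel_spacing, center = c(0, 0)) {
  v <- sweep(x$vertices, 2, center) * pixel_spacing
  v
}
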