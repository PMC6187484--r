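# Internal helpers: classed conditions, bilinear sampling, polygon primitives.

stop_classed <- function(class, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "stenoscan_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_invalid <- function(msg, ...) {
  stop_classed("stenoscan_invalid_argument", msg, ...)
}

stop_out_of_range <- function(msg, ...) {
  stop_classed("stenoscan_out_of_range", msg, ...)
}

stop_degenerate_geometry <- function(msg, ...) {
  stop_classed("stenoscan_degenerate_geometry", msg, ...)
}

stop_inconsistent <- function(msg, ...) {
  stop_classed("stenoscan_segmentation_inconsistency", msg, ...)
}

stop_degenerate_contour <- function(msg, ...) {
  stop_classed("stenoscan_degenerate_contour", msg, ...)
}

# Bilinear interpolation of a matrix img (indexed [x, y], pixel centers at
# integer coordinates) at arbitrary positions; out-of-domain positions are
# clamped to the boundary. Returns list(values, clamped).
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img)
  ny <- ncol(img)
  clamped <- x < 1 | x > nx | y < 1 | y > ny
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L)
  y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0
  fy <- y - y0
  v <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
  list(values = v, clamped = clamped)
}

# Shoelace signed area of a closed polygon given as an n x 2 matrix.
# Positive for counter-clockwise order in a right-handed (x right, y up)
# frame; in image coordinates (y down) counter-clockwise appears negative,
# so callers use abs() for areas.
polygon_signed_area <- function(v) {
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(v) abs(polygon_signed_area(v))

polygon_perimeter <- function(v) {
  d <- v[c(seq_len(nrow(v))[-1], 1), , drop = FALSE] - v
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(v) {
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-12) return(colMeans(v))
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# TRUE for points inside the polygon (closed automatically by mgcv::in.out).
points_in_polygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, matrix(pts, ncol = 2))
}

# Circular (wrap-around) running median, ignoring NAs; window must be odd.
circular_median_filter <- function(x, window = 5) {
  n <- length(x)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    idx <- ((i - h - 1):(i + h - 1)) %% n + 1
    stats::median(x[idx], na.rm = TRUE)
  }, numeric(1))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
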