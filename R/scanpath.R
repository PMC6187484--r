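# Scan-path planning: acquisition poses for circle and linear scans computed
# from user-marked fistula sites (arterial anastomosis A, loop L, venous
# anastomosis V).

#' Mark a scan site
#'
#' @param site site label: `"A"`, `"L"`, `"V"` or `"other"`.
#' @param position numeric length-3 (x, y, z) position in the workspace
#'   frame, mm (z along the arm's rotation axis).
#' @return An object of class `scan_point`.
#' @export
scan_point <- function(site, position) {
  if (!site %in% c("A", "L", "V", "other")) {
    stop_invalid("site must be one of A, L, V, other")
  }
  position <- as.numeric(position)
  if (length(position) != 3 || !all(is.finite(position))) {
    stop_invalid("position must be a finite (x, y, z) triple in mm")
  }
  structure(list(site = site, position = position), class = "scan_point")
}

#' Circumscribed circle through three points
#'
#' The arc-like scan path is computed from the midpoints of two chords: the
#' perpendicular bisectors of the chords p1-p2 and p2-p3 intersect at the
#' unique circle center equidistant from all three points.
#'
#' @param p1,p2,p3 numeric length-2 (x, y) points, mm.
#' @return A list with `center` (x, y) and `radius`, mm.
#' @export
#' @examples
#' circle_from_points(c(0, 0), c(1, 1), c(2, 0))  # center (1, 0), radius 1
circle_from_points <- function(p1, p2, p3) {
  p1 <- as.numeric(p1)[1:2]; p2 <- as.numeric(p2)[1:2]; p3 <- as.numeric(p3)[1:2]
  if (!all(is.finite(c(p1, p2, p3)))) stop_invalid("points must be finite")
  a <- p2 - p1
  b <- p3 - p2
  # 2x2 system from |c - p1|^2 = |c - p2|^2 = |c - p3|^2
  det <- a[1] * b[2] - a[2] * b[1]
  scale <- max(sqrt(sum(a^2)), sqrt(sum(b^2)), 1e-12)
  if (abs(det) < 1e-9 * scale^2) {
    stop_degenerate_geometry(
      "the three points are (nearly) collinear: no circumscribed circle; use the linear scan method"
    )
  }
  m1 <- (p1 + p2) / 2
  m2 <- (p2 + p3) / 2
  rhs <- c(sum(a * m1), sum(b * m2))
  center <- solve(rbind(a, b), rhs)
  radius <- sqrt(sum((p1 - center)^2))
  list(center = as.numeric(center), radius = radius)
}

#' Build a scan plan from marked sites
#'
#' Circle method: waypoints are sampled at `slice_spacing` of arc length along
#' the circumscribed circle through the first, middle and last site, from the
#' first to the last site, in the direction that traverses the middle site;
#' `theta` is the polar angle of each waypoint about the circle center.
#' Linear method: waypoints are sampled along the polyline through the sites
#' with `theta = 0`.
#'
#' The native capture spacing `speed / frame_rate` is recorded; requesting a
#' `slice_spacing` larger than native flags the plan as requiring 3D
#' interpolation between captured slices.
#'
#' @param points list of at least three [scan_point()]s (or length-3 numeric
#'   vectors).
#' @param method `"circle"` or `"linear"`.
#' @param speed probe speed, cm/s.
#' @param frame_rate capture rate, Hz.
#' @param slice_spacing waypoint separation along the path, mm.
#' @param workspace half-extent of the arm workspace used for a validation
#'   warning (mm); scanning outside it warns but does not fail.
#' @return An object of class `scan_plan` with a `waypoints` data.frame
#'   (`x`, `y`, `z`, `theta`, `axial_position`), the geometry (`center`,
#'   `radius` for circle plans), `native_spacing` and `needs_interpolation`.
#' @export
build_plan <- function(points, method = c("circle", "linear"),
                       speed = 0.5, frame_rate = 1, slice_spacing = 5,
                       workspace = 300) {
  method <- match.arg(method)
  if (!is.list(points) || length(points) < 3) {
    stop_invalid("at least three scan points are required to compute a pathway")
  }
  pos <- t(vapply(points, function(p) {
    if (inherits(p, "scan_point")) p$position else {
      p <- as.numeric(p)
      if (length(p) == 2) p <- c(p, 0)
      p
    }
  }, numeric(3)))
  if (!all(is.finite(pos))) stop_invalid("scan point coordinates must be finite")
  if (speed <= 0 || frame_rate <= 0 || slice_spacing <= 0) {
    stop_invalid("speed, frame_rate and slice_spacing must be positive")
  }
  if (any(abs(pos) > workspace)) {
    warning("scan points lie outside the nominal arm workspace (",
            workspace, " mm half-extent)", call. = FALSE)
  }
  native_spacing <- speed * 10 / frame_rate  # cm/s * 10 / Hz = mm per frame

  if (method == "circle") {
    i_mid <- (nrow(pos) + 1) %/% 2
    p1 <- pos[1, 1:2]; pm <- pos[i_mid, 1:2]; pn <- pos[nrow(pos), 1:2]
    circ <- circle_from_points(p1, pm, pn)
    zlev <- mean(pos[, 3])
    th <- function(p) atan2(p[2] - circ$center[2], p[1] - circ$center[1])
    t1 <- th(p1); tm <- th(pm); tn <- th(pn)
    # direction chosen so the middle site lies on the traversed arc
    ccw_span <- (tn - t1) %% (2 * pi)
    ccw_mid <- (tm - t1) %% (2 * pi)
    if (ccw_mid <= ccw_span + 1e-12) {
      span <- ccw_span
      dir <- 1
    } else {
      span <- 2 * pi - ccw_span
      dir <- -1
    }
    arc_len <- span * circ$radius
    s <- seq(0, arc_len, by = slice_spacing)
    theta <- t1 + dir * s / circ$radius
    wp <- data.frame(
      x = circ$center[1] + circ$radius * cos(theta),
      y = circ$center[2] + circ$radius * sin(theta),
      z = zlev,
      theta = theta,
      axial_position = s
    )
    geom <- list(center = circ$center, radius = circ$radius)
  } else {
    seg <- diff(pos)
    seg_len <- sqrt(rowSums(seg^2))
    cs <- c(0, cumsum(seg_len))
    total <- cs[length(cs)]
    if (total <= 0) stop_invalid("scan points must span a non-zero path")
    s <- seq(0, total, by = slice_spacing)
    wx <- stats::approx(cs, pos[, 1], xout = s)$y
    wy <- stats::approx(cs, pos[, 2], xout = s)$y
    wz <- stats::approx(cs, pos[, 3], xout = s)$y
    wp <- data.frame(x = wx, y = wy, z = wz, theta = 0, axial_position = s)
    geom <- list(center = NULL, radius = NULL)
  }
  if (nrow(wp) < 2) {
    stop_invalid("slice_spacing larger than the path: plan needs >= 2 waypoints")
  }
  structure(list(
    method = method,
    waypoints = wp,
    speed = speed,
    frame_rate = frame_rate,
    slice_spacing = slice_spacing,
    native_spacing = native_spacing,
    needs_interpolation = slice_spacing > native_spacing + 1e-9,
    center = geom$center,
    radius = geom$radius
  ), class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "<scan_plan> %s scan: %d waypoints, %.1f mm spacing (native %.1f mm%s)\n",
    x$method, nrow(x$waypoints), x$slice_spacing, x$native_spacing,
    if (x$needs_interpolation) ", interpolation required" else ""
  ))
  if (x$method == "circle") {
    cat(sprintf("  arc radius %.1f mm about (%.1f, %.1f)\n",
                x$radius, x$center[1], x$center[2]))
  }
  invisible(x)
}

#' Rotation angle of a frame in a scan plan
#'
#' Returns the rotation angle about the z-axis of frame `k` (0-based). For
#' circle plans, consecutive frames differ by `slice_spacing / radius`
#' radians; linear plans have constant angle 0.
#'
#' @param plan a [build_plan()] scan plan.
#' @param k 0-based frame index.
#' @return Angle in radians.
#' @export
frame_angle <- function(plan, k) {
  n <- nrow(plan$waypoints)
  if (any(k < 0 | k >= n)) {
    stop_out_of_range(sprintf("frame index must lie in [0, %d)", n))
  }
  plan$waypoints$theta[k + 1]
}
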