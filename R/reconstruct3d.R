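# 3D reconstruction: rotate per-frame contours into a common frame,
# interpolate between captured slices, and mesh the contour stack.

#' Rotate a contour about the z-axis
#'
#' Applies the frame rotation `x' = x cos(theta) + y sin(theta)`,
#' `y' = y cos(theta) - x sin(theta)` (a clockwise rotation for positive
#' `theta`; z is unchanged) to every vertex. The rotation is rigid: vertex
#' count, pairwise distances, area and perimeter are preserved.
#'
#' @param contour a [contour()] (vertices in mm).
#' @param theta rotation angle about the z-axis, radians.
#' @return The rotated [contour()].
#' @export
rotate_contour <- function(contour, theta) {
  stopifnot(inherits(contour, "contour"))
  v <- contour$vertices
  ct <- cos(theta)
  st <- sin(theta)
  out <- contour
  out$vertices <- cbind(
    x = v[, 1] * ct + v[, 2] * st,
    y = v[, 2] * ct - v[, 1] * st
  )
  out
}

#' An oriented contour in the reconstruction stack
#'
#' @param contour a [contour()] with vertices in mm (in-plane coordinates).
#' @param theta rotation angle of the frame about the z-axis, radians.
#' @param z axial position along the scan path, mm.
#' @param source `"captured"` or `"interpolated"`.
#' @param frame_index index of the captured frame, if any.
#' @return An object of class `oriented_contour`.
#' @export
oriented_contour <- function(contour, theta, z, source = "captured",
                             frame_index = NA_integer_) {
  stopifnot(inherits(contour, "contour"))
  if (!is.finite(theta)) stop_invalid("theta must be finite")
  structure(list(contour = contour, theta = theta, z = z, source = source,
                 frame_index = frame_index), class = "oriented_contour")
}

# Resample b to the vertex count of a and cyclically shift it to minimize the
# summed squared vertex distance (correspondence for interpolation/meshing).
align_contours <- function(a, b) {
  n <- nrow(a$vertices)
  b <- resample_contour(b, n)
  vb <- b$vertices
  best_s <- 0
  best <- Inf
  for (s in 0:(n - 1)) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    val <- sum((a$vertices - vb[idx, ])^2)
    if (val < best) {
      best <- val
      best_s <- s
    }
  }
  idx <- ((seq_len(n) - 1 + best_s) %% n) + 1
  b$vertices <- vb[idx, , drop = FALSE]
  class(b) <- "contour"
  b
}

#' Linearly interpolate between two oriented contours
#'
#' After correspondence resampling (equal vertex counts, cyclic alignment),
#' vertices, `theta` and `z` are interpolated at `n_intermediate` uniform
#' fractions strictly between the endpoints (endpoints are not duplicated).
#'
#' @param a,b [oriented_contour()]s with `a$z < b$z`.
#' @param n_intermediate number of intermediate contours (>= 0).
#' @return List of `n_intermediate` oriented contours tagged `"interpolated"`.
#' @export
interpolate_contours <- function(a, b, n_intermediate) {
  stopifnot(inherits(a, "oriented_contour"), inherits(b, "oriented_contour"))
  if (n_intermediate < 0) stop_invalid("n_intermediate must be >= 0")
  if (!(a$z < b$z)) stop_invalid("a must precede b along the path (a$z < b$z)")
  if (n_intermediate == 0) return(list())
  vb <- align_contours(a$contour, b$contour)
  va <- a$contour$vertices
  lapply(seq_len(n_intermediate), function(k) {
    f <- k / (n_intermediate + 1)
    oriented_contour(
      contour(va * (1 - f) + vb$vertices * f),
      theta = a$theta * (1 - f) + b$theta * f,
      z = a$z * (1 - f) + b$z * f,
      source = "interpolated"
    )
  })
}

# World (x, y, z) vertices of an oriented contour. Linear plans stack frames
# perpendicular to the path (in-plane x, y map to world x, y; z = axial).
# Circle plans sweep about the arm's z-axis: in-plane x is radial (offset by
# the arc radius), in-plane y is depth (world -z), and the frame rotation
# carries the section to its angular position.
world_vertices <- function(oc, plan) {
  v <- oc$contour$vertices
  if (!is.null(plan) && plan$method == "circle") {
    pre <- cbind(plan$radius + v[, 1], 0 * v[, 1])
    rot <- cbind(
      pre[, 1] * cos(oc$theta) + pre[, 2] * sin(oc$theta),
      pre[, 2] * cos(oc$theta) - pre[, 1] * sin(oc$theta)
    )
    cbind(x = rot[, 1] + plan$center[1], y = rot[, 2] + plan$center[2],
          z = -v[, 2])
  } else {
    rot <- rotate_contour(oc$contour, oc$theta)$vertices
    cbind(x = rot[, 1], y = rot[, 2], z = oc$z)
  }
}

# Triangulate a stack of rings (list of m x 3 vertex matrices with equal m)
# into a closed surface mesh with centroid-fan end caps.
mesh_from_rings <- function(rings) {
  n <- nrow(rings[[1]])
  verts <- do.call(rbind, rings)
  faces <- list()
  for (k in seq_len(length(rings) - 1)) {
    o1 <- (k - 1) * n
    o2 <- k * n
    j <- seq_len(n)
    jn <- c(2:n, 1)
    faces[[length(faces) + 1]] <- cbind(o1 + j, o1 + jn, o2 + jn)
    faces[[length(faces) + 1]] <- cbind(o1 + j, o2 + jn, o2 + j)
  }
  c1 <- colMeans(rings[[1]])
  c2 <- colMeans(rings[[length(rings)]])
  verts <- rbind(verts, c1, c2)
  i1 <- nrow(verts) - 1L
  i2 <- nrow(verts)
  j <- seq_len(n)
  jn <- c(2:n, 1)
  o2 <- (length(rings) - 1) * n
  faces[[length(faces) + 1]] <- cbind(i1, jn, j)
  faces[[length(faces) + 1]] <- cbind(i2, o2 + j, o2 + jn)
  list(vertices = unname(verts), faces = do.call(rbind, faces))
}

#' Signed volume enclosed by a triangulated surface
#'
#' Divergence-theorem sum of signed tetrahedron volumes; the absolute value
#' is the enclosed volume for a closed, consistently oriented mesh.
#'
#' @param mesh list with `vertices` (m x 3) and `faces` (t x 3 indices).
#' @return Volume in the cube of the vertex unit.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  abs(sum(
    a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  ) / 6)
}

#' Build a 3D vessel model from segmented frames
#'
#' Converts per-frame lumen and vessel contours to mm about the frame center,
#' orients each by its frame's rotation angle and axial position, inserts
#' linearly interpolated contours so that no axial gap exceeds
#' `interpolation_spacing`, and triangulates both contour stacks into closed
#' surface meshes.
#'
#' @param segs a `segmentation_series` (or list of [segment_frame()] results).
#' @param frames the corresponding list of `bmode_frame`s.
#' @param plan the [build_plan()] scan plan used for acquisition (may be
#'   `NULL` for a plain linear stack).
#' @param interpolation_spacing maximal axial gap between consecutive
#'   contours, mm.
#' @return An object of class `vessel_model`: oriented contour stacks
#'   (`lumen`, `vessel`), meshes (`lumen_mesh`, `vessel_mesh`),
#'   `interpolated_count` and bookkeeping.
#' @export
build_model <- function(segs, frames, plan = NULL, interpolation_spacing = 20) {
  if (length(segs) < 2) {
    stop_classed("stenoscan_insufficient_data",
                 "3D reconstruction needs at least two captured frames")
  }
  if (interpolation_spacing <= 0) {
    stop_invalid("interpolation_spacing must be positive")
  }
  make_stack <- function(role) {
    lapply(seq_along(segs), function(k) {
      fr <- frames[[k]]
      ctr <- c((nrow(fr$intensity) + 1) / 2, (ncol(fr$intensity) + 1) / 2)
      v_mm <- contour_to_mm(segs[[k]][[role]], fr$pixel_spacing, ctr)
      oriented_contour(contour(v_mm), theta = fr$theta,
                       z = fr$axial_position, source = "captured",
                       frame_index = fr$frame_index)
    })
  }
  interpolate_stack <- function(stack) {
    out <- list()
    n_interp <- 0L
    for (k in seq_len(length(stack) - 1)) {
      out[[length(out) + 1]] <- stack[[k]]
      gap <- stack[[k + 1]]$z - stack[[k]]$z
      if (gap > interpolation_spacing + 1e-9) {
        mids <- interpolate_contours(stack[[k]], stack[[k + 1]],
                                     ceiling(gap / interpolation_spacing) - 1L)
        out <- c(out, mids)
        n_interp <- n_interp + length(mids)
      }
    }
    out[[length(out) + 1]] <- stack[[length(stack)]]
    list(stack = out, n_interp = n_interp)
  }
  mesh_stack <- function(stack) {
    n <- nrow(stack[[1]]$contour$vertices)
    rings <- vector("list", length(stack))
    prev <- stack[[1]]$contour
    rings[[1]] <- world_vertices(stack[[1]], plan)
    for (k in seq_along(stack)[-1]) {
      aligned <- align_contours(prev, stack[[k]]$contour)
      oc <- stack[[k]]
      oc$contour <- aligned
      rings[[k]] <- world_vertices(oc, plan)
      prev <- aligned
    }
    mesh_from_rings(rings)
  }
  lm_st <- interpolate_stack(make_stack("lumen"))
  vs_st <- interpolate_stack(make_stack("vessel"))
  structure(list(
    lumen = lm_st$stack,
    vessel = vs_st$stack,
    lumen_mesh = mesh_stack(lm_st$stack),
    vessel_mesh = mesh_stack(vs_st$stack),
    interpolated_count = lm_st$n_interp,
    interpolation_spacing = interpolation_spacing,
    method = if (is.null(plan)) "linear" else plan$method,
    frames_used = length(segs)
  ), class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf(
    "<vessel_model> %d captured + %d interpolated sections (%s scan); lumen volume %.0f mm^3\n",
    x$frames_used, x$interpolated_count, x$method, mesh_volume(x$lumen_mesh)
  ))
  invisible(x)
}

#' In-plane cross-section of a vessel model at an axial position
#'
#' Linearly interpolates the lumen and vessel contour stacks at axial
#' position `z` (mm along the scan path).
#'
#' @param model a [build_model()] result.
#' @param z axial position, mm, within the stack extent.
#' @return List with `lumen` and `vessel` [contour()]s in mm.
#' @export
slice_model <- function(model, z) {
  slice_one <- function(stack) {
    zs <- vapply(stack, function(s) s$z, numeric(1))
    if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9) {
      stop_out_of_range("z outside the reconstructed extent")
    }
    k <- findInterval(z, zs, rightmost.closed = TRUE)
    k <- max(min(k, length(stack) - 1L), 1L)
    a <- stack[[k]]
    b <- stack[[k + 1]]
    f <- if (b$z > a$z) (z - a$z) / (b$z - a$z) else 0
    if (f <= 1e-9) return(a$contour)
    if (f >= 1 - 1e-9) return(b$contour)
    vb <- align_contours(a$contour, b$contour)
    contour(a$contour$vertices * (1 - f) + vb$vertices * f)
  }
  list(lumen = slice_one(model$lumen), vessel = slice_one(model$vessel))
}

## ---- mesh / point export ---------------------------------------------------

#' Export meshes and contour point clouds
#'
#' `write_stl` writes an ASCII STL surface, `write_ply` an ASCII PLY, and
#' `write_contour_cloud_csv` the stacked world coordinates of a model's
#' contours as CSV. `read_stl` and `read_ply` read files written by these
#' functions back into vertex/face lists.
#'
#' @param mesh list with `vertices` (m x 3) and `faces` (t x 3).
#' @param file output path.
#' @param name solid name recorded in the STL header.
#' @return The file path, invisibly (readers: a mesh list).
#' @export
write_stl <- function(mesh, file, name = "stenoscan") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    nrm <- c(
      (b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
      (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
      (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
    )
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeLines(c(
      sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
      sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
      sprintf("      vertex %g %g %g", c3[1], c3[2], c3[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(file)
}

#' @rdname write_stl
#' @export
read_stl <- function(file) {
  lines <- readLines(file)
  vx <- grep("^\\s*vertex ", lines, value = TRUE)
  nums <- t(vapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }, numeric(3)))
  n_tri <- nrow(nums) / 3
  list(vertices = nums,
       faces = matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}

#' @rdname write_stl
#' @export
write_ply <- function(mesh, file) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(file)
}

#' @rdname write_stl
#' @export
read_ply <- function(file) {
  lines <- readLines(file)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  start <- which(lines == "end_header")
  vdat <- do.call(rbind, lapply(strsplit(lines[start + seq_len(nv)], " "), as.numeric))
  fdat <- do.call(rbind, lapply(strsplit(lines[start + nv + seq_len(nf)], " "),
                                function(p) as.integer(p[2:4]) + 1L))
  list(vertices = vdat, faces = fdat)
}

#' @rdname write_stl
#' @param model a [build_model()] result.
#' @param plan the scan plan used (for world coordinates), or `NULL`.
#' @export
write_contour_cloud_csv <- function(model, file, plan = NULL) {
  rows <- do.call(rbind, lapply(c("lumen", "vessel"), function(role) {
    do.call(rbind, lapply(model[[role]], function(oc) {
      w <- world_vertices(oc, plan)
      data.frame(role = role, source = oc$source, z_path = oc$z,
                 x = w[, 1], y = w[, 2], z = w[, 3])
    }))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
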