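# Contour rotation, interpolation, model building and mesh export.

test_that("frame rotation is the printed clockwise map and is rigid", {
  oct <- circle_contour(c(0, 0), 1, 8)
  expect_equal(rotate_contour(oct, 0)$vertices, oct$vertices)
  rot <- rotate_contour(oct, pi / 2)
  # the vertex at (1, 0) maps to (0, -1) under the clockwise convention
  i0 <- which.min(rowSums(sweep(oct$vertices, 2, c(1, 0))^2))
  expect_equal(unname(rot$vertices[i0, ]), c(0, -1), tolerance = 1e-12)

  shape <- contour(cbind(c(3, 5, 6, 5.5, 4, 2.5, 2, 2.2),
                         c(1, 1.2, 3, 4.5, 5, 4.2, 3, 1.8)))
  for (th in c(0.3, 1.7, -2.4)) {
    r <- rotate_contour(shape, th)
    expect_equal(contour_area(r), contour_area(shape), tolerance = 1e-9)
    expect_equal(contour_perimeter(r), contour_perimeter(shape),
                 tolerance = 1e-9)
    d0 <- as.matrix(stats::dist(shape$vertices))
    d1 <- as.matrix(stats::dist(r$vertices))
    expect_equal(d1, d0, tolerance = 1e-9)
    back <- rotate_contour(r, -th)
    expect_lt(max(abs(back$vertices - shape$vertices)), 1e-9)
  }
})

test_that("contour interpolation is linear in shape, angle and position", {
  a <- oriented_contour(circle_contour(c(0, 0), 5, 32), theta = 0, z = 0)
  b <- oriented_contour(circle_contour(c(0, 0), 5, 32), theta = 0.4, z = 20)
  expect_length(interpolate_contours(a, b, 0), 0)
  mid <- interpolate_contours(a, b, 1)[[1]]
  expect_equal(mid$z, 10)
  expect_equal(mid$theta, 0.2)
  expect_identical(mid$source, "interpolated")
  expect_equal(contour_area(mid$contour), contour_area(a$contour),
               tolerance = 1e-6)

  small <- oriented_contour(circle_contour(c(0, 0), 2.25, 32), theta = 0, z = 20)
  m2 <- interpolate_contours(a, small, 1)[[1]]
  d_mid <- 2 * sqrt(contour_area(m2$contour) / pi)
  expect_equal(d_mid, 7.25, tolerance = 0.02)  # linear radius interpolation

  expect_error(interpolate_contours(a, b, -1),
               class = "stenoscan_invalid_argument")
  expect_error(interpolate_contours(b, a, 1),
               class = "stenoscan_invalid_argument")
})

# truth-based segmentation stub: circular contours at the design radii
truth_segs <- function(spec, zs, pixel_spacing = 0.1, size = 160) {
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  lapply(zs, function(z) {
    list(lumen = circle_contour(ctr, lumen_profile(spec, z) / 2 / pixel_spacing),
         vessel = circle_contour(ctr, spec$D / 2 / pixel_spacing))
  })
}
truth_frames <- function(zs, theta = 0, pixel_spacing = 0.1, size = 160) {
  lapply(seq_along(zs), function(k) {
    frame_of(matrix(0, size, size), pixel_spacing, axial = zs[k] - zs[1],
             theta = if (length(theta) > 1) theta[k] else theta,
             index = k - 1L)
  })
}

test_that("straight stacks reconstruct the design geometry", {
  spec <- make_phantom_spec("A", "III")
  zs <- seq(30, 70, by = 5)
  segs <- truth_segs(spec, zs)
  frames <- truth_frames(zs)
  model <- build_model(segs, frames, plan = NULL, interpolation_spacing = 20)
  expect_s3_class(model, "vessel_model")

  # cross-section at the stenosis center recovers the residual diameter
  sl <- slice_model(model, 50 - 30)
  d_slice <- 2 * sqrt(contour_area(sl$lumen) / pi)
  expect_equal(d_slice, 4.5, tolerance = 0.1)

  # with theta = 0 the world stack equals the unrotated contours
  w <- stenoscan:::world_vertices(model$lumen[[1]], NULL)
  v_mm <- stenoscan:::contour_to_mm(segs[[1]]$lumen, 0.1, c(80.5, 80.5))
  expect_equal(w[, 1:2], v_mm, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(w[, 3] == frames[[1]]$axial_position))

  expect_error(build_model(segs[1], frames[1]),
               class = "stenoscan_insufficient_data")
})

test_that("coarse captures are densified to the interpolation spacing", {
  spec <- make_phantom_spec("B", "I")
  zs <- c(10, 50, 90)  # 40 mm gaps, native capture decimated
  model <- build_model(truth_segs(spec, zs), truth_frames(zs), NULL,
                       interpolation_spacing = 20)
  gaps <- diff(vapply(model$lumen, `[[`, numeric(1), "z"))
  expect_true(all(gaps <= 20 + 1e-9))
  expect_gt(model$interpolated_count, 0)
  expect_setequal(unique(vapply(model$lumen, `[[`, character(1), "source")),
                  c("captured", "interpolated"))
})

test_that("circle-plan sections sweep an arc of the plan radius", {
  plan <- build_plan(list(c(60, 0, 0), c(0, 60, 0), c(-60, 0, 0)), "circle",
                     slice_spacing = 10)
  spec <- make_phantom_spec("C", "II")
  n_use <- min(8, nrow(plan$waypoints))
  zs <- plan$waypoints$axial_position[seq_len(n_use)] + 30
  frames <- truth_frames(zs, theta = plan$waypoints$theta[seq_len(n_use)])
  for (k in seq_len(n_use)) {
    frames[[k]]$axial_position <- plan$waypoints$axial_position[k]
  }
  model <- build_model(truth_segs(spec, zs), frames, plan,
                       interpolation_spacing = 20)
  cent <- t(vapply(model$vessel, function(oc) {
    colMeans(stenoscan:::world_vertices(oc, plan))
  }, numeric(3)))
  r_cent <- sqrt((cent[, 1] - plan$center[1])^2 +
                   (cent[, 2] - plan$center[2])^2)
  expect_equal(r_cent, rep(plan$radius, nrow(cent)), tolerance = 0.05)
})

test_that("lumen volume shrinks as the design stenosis grows", {
  zs <- seq(35, 65, by = 5)
  vols <- vapply(c("I", "II", "III"), function(cl) {
    spec <- make_phantom_spec("A", cl)
    mesh_volume(build_model(truth_segs(spec, zs), truth_frames(zs),
                            NULL, 20)$lumen_mesh)
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("meshes are closed and survive STL/PLY round-trips", {
  spec <- make_phantom_spec("C", "III")
  zs <- seq(40, 60, by = 10)
  model <- build_model(truth_segs(spec, zs), truth_frames(zs), NULL, 20)
  mesh <- model$lumen_mesh
  # closed orientable surface: V - E + F = 2 with E = 3F/2
  expect_equal(nrow(mesh$vertices) - nrow(mesh$faces) / 2, 2)
  vol <- mesh_volume(mesh)
  expect_gt(vol, 0)

  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, stl)
  back <- read_stl(stl)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  expect_equal(mesh_volume(back), vol, tolerance = 1e-5)

  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  back2 <- read_ply(ply)
  expect_equal(back2$faces, mesh$faces, ignore_attr = TRUE)
  expect_equal(back2$vertices, mesh$vertices, tolerance = 1e-5,
               ignore_attr = TRUE)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_contour_cloud_csv(model, csv)
  cloud <- utils::read.csv(csv)
  expect_true(all(c("role", "source", "x", "y", "z") %in% names(cloud)))
  expect_setequal(unique(cloud$role), c("lumen", "vessel"))
})
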