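# Snake energies, greedy evolution and frame segmentation.

test_that("frame smoothing is an identity at sigma 0 and reduces variance", {
  fr <- disk_frame(blur = 0)
  expect_identical(smooth_frame(fr, 0), fr)
  const <- frame_of(matrix(0.5, 32, 32))
  expect_equal(smooth_frame(const, 0.5)$intensity, const$intensity,
               tolerance = 1e-6)
  spec <- make_phantom_spec("B", "II")
  noisy <- render_bmode(render_truth(spec, 50), noise_params(seed = 9))
  smoothed <- smooth_frame(noisy, 0.3)
  expect_lt(stats::var(as.numeric(smoothed$intensity)),
            stats::var(as.numeric(noisy$intensity)))
  expect_gte(min(smoothed$intensity), min(noisy$intensity))
  expect_lte(max(smoothed$intensity), max(noisy$intensity))
  expect_error(smooth_frame(noisy, -1), class = "stenoscan_invalid_argument")
})

test_that("image energy fields follow their definitions", {
  const <- frame_of(matrix(0.4, 32, 32))
  f <- image_energy_field(const)
  expect_true(all(f$e_edge == 0))
  expect_true(all(is.finite(f$e_term)))

  # vertical step edge: most negative edge energy on the edge line
  img <- matrix(0.1, 48, 48)
  img[25:48, ] <- 0.9
  step <- smooth_frame(frame_of(img), 0.15)
  fs <- image_energy_field(step)
  col_energy <- rowMeans(fs$e_edge)  # x-profile (edge runs along y)
  expect_equal(which.min(col_energy), 24, tolerance = 1)

  # raw weight selection: (0, 1, 0) reproduces E_edge exactly
  p <- acm_params(w_line = 0, w_edge = 1, w_term = 0, normalize = FALSE)
  fr <- disk_frame()
  f2 <- image_energy_field(fr, p)
  expect_identical(f2$combined, f2$e_edge)
})

test_that("internal energy matches the regular-polygon closed form", {
  r <- 10
  n <- 32
  poly <- circle_contour(c(0, 0), r, n)
  p <- acm_params(alpha = 0.3, beta = 0)
  ie <- internal_energy(poly, p)
  chord2 <- (2 * r * sin(pi / n))^2  # exact first-difference oracle
  expect_equal(ie$per_vertex, rep(0.3 * chord2, n), tolerance = 1e-9)
  expect_equal(ie$total, 0.3 * chord2, tolerance = 1e-9)
  # and approximately alpha * (2 pi r / n)^2 for fine sampling
  expect_equal(ie$total, 0.3 * (2 * pi * r / n)^2, tolerance = 1e-2)

  expect_equal(internal_energy(poly, acm_params(alpha = 0, beta = 0))$total, 0)

  # straight-line runs carry no curvature term; a corner does
  vs <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(3, 1), c(3, 2),
              c(0, 2), c(0, 1))
  bend <- internal_energy(contour(vs), acm_params(alpha = 0, beta = 1))
  i_straight <- which(apply(contour(vs)$vertices, 1,
                            function(v) all(v == c(2, 0))))
  i_corner <- which(apply(contour(vs)$vertices, 1,
                          function(v) all(v == c(3, 0))))
  expect_equal(bend$per_vertex[i_straight], 0)
  expect_gt(bend$per_vertex[i_corner], 0)
})

test_that("snake energy decomposes as internal plus image, constraint zero", {
  fr <- disk_frame(radius = 15, size = 48)
  p <- acm_params()
  fields <- image_energy_field(fr, p)
  ctr <- circle_contour(frame_center(fr), 15, 32)
  br <- snake_energy(ctr, fields, p)
  expect_equal(br$e_con, 0)
  expect_equal(br$e_ext, br$e_image)
  expect_equal(br$e_snake, br$e_int + br$e_image, tolerance = 1e-12)

  # a contour on the disk edge beats the same contour displaced by 3 px
  off <- ctr
  off$vertices <- off$vertices + 3
  expect_lt(snake_energy(ctr, fields, p)$e_snake,
            snake_energy(off, fields, p)$e_snake)

  p0 <- acm_params(alpha = 0, beta = 0, w_line = 0, w_edge = 0, w_term = 0)
  f0 <- image_energy_field(fr, p0)
  expect_equal(snake_energy(ctr, f0, p0)$e_snake, 0)

  # out-of-domain vertices are clamped and flagged
  wide <- circle_contour(frame_center(fr), 40, 16)
  expect_true(any(snake_energy(wide, fields, p)$clamped))
})

test_that("greedy evolution converges on a noise-free disk", {
  fr <- disk_frame(radius = 20, size = 64, blur = 1.5)
  p <- acm_params(n_vertices = 32)
  ctr0 <- frame_center(fr)

  # start on the boundary: immediate fixed point
  on_edge <- evolve_snake(circle_contour(ctr0, 20, 32), fr, p)
  expect_lte(on_edge$iterations, 2)
  r_conv <- sqrt(rowSums(sweep(on_edge$contour$vertices, 2, ctr0)^2))
  expect_lt(max(abs(r_conv - 20)), 1.5)

  # start 5 px outside: beyond the blurred edge's capture range, so the
  # elastic term must deflate the contour onto the boundary (stiffness off:
  # single-vertex greedy moves cannot deform a circle against beta)
  p_deflate <- acm_params(alpha = 0.2, beta = 0, n_vertices = 32)
  out5 <- evolve_snake(circle_contour(ctr0, 25, 32), fr, p_deflate)
  r5 <- sqrt(rowSums(sweep(out5$contour$vertices, 2, ctr0)^2))
  expect_lt(abs(mean(r5) - 20), 1)

  expect_error(evolve_snake(circle_contour(c(100, 100), 20, 32), fr, p),
               class = "stenoscan_invalid_argument")
})

test_that("evolution is monotone and locally optimal at convergence", {
  spec <- make_phantom_spec("C", "III")
  fr <- render_bmode(render_truth(spec, 50, pixel_spacing = 0.2, size = 64),
                     noise_params(seed = 21))
  fr <- smooth_frame(fr, 0.1)
  p <- acm_params(n_vertices = 24, move_tolerance = 0)
  fields <- image_energy_field(fr, p)
  ev <- evolve_snake(circle_contour(frame_center(fr), 9, 24), fr, p, fields)
  expect_true(all(diff(ev$trace) <= 1e-9))

  # brute-force oracle: no single-vertex move in the search neighborhood
  # lowers the independently computed total energy
  v <- ev$contour$vertices
  e0 <- oracle_snake_energy(v, fields$combined, p$alpha, p$beta)
  for (i in seq_len(nrow(v))) {
    for (dx in -p$search_radius:p$search_radius) {
      for (dy in -p$search_radius:p$search_radius) {
        vv <- v
        vv[i, ] <- vv[i, ] + c(dx, dy)
        expect_gte(oracle_snake_energy(vv, fields$combined, p$alpha, p$beta),
                   e0 - 1e-9)
      }
    }
  }
})

test_that("larger stiffness yields smoother converged contours", {
  # speckled disk with a clear edge: a floppy snake chases speckle minima,
  # a stiff one stays smooth
  img <- withr::with_seed(31, {
    base <- ifelse(outer((1:96 - 48.5)^2, (1:96 - 48.5)^2, "+") <= 18^2,
                   0.85, 0.15)
    base * matrix(stats::rgamma(96^2, shape = 8, rate = 8), 96, 96)
  })
  fr <- frame_of(as.matrix(EBImage::gblur(img, sigma = 1)))
  sum_sq_second_diff <- function(v) {
    n <- nrow(v)
    vm <- v[c(n, 1:(n - 1)), ]
    vp <- v[c(2:n, 1), ]
    sum((vm - 2 * v + vp)^2)
  }
  run_beta <- function(beta) {
    p <- acm_params(alpha = 0.05, beta = beta, n_vertices = 32,
                    max_iterations = 60)
    ev <- evolve_snake(circle_contour(c(48.5, 48.5), 20, 32), fr, p)
    sum_sq_second_diff(ev$contour$vertices)
  }
  expect_lt(run_beta(2), run_beta(0.01))
})

test_that("segment_frame recovers design diameters", {
  # noise-free severe-vs-mild contrast: type A class I center frame
  spec <- make_phantom_spec("A", "I")
  tr <- render_truth(spec, 50)
  clean <- render_bmode(tr, noise_params(speckle_scale = 0, blur_sigma = 0.1,
                                         seed = 1))
  sg <- segment_frame(clean, frame_center(clean))
  dd <- equivalent_diameters(sg$lumen, sg$vessel, 0.1)
  expect_equal(dd[["d"]], 9, tolerance = 0.1)
  expect_equal(dd[["D"]], 10, tolerance = 0.1)

  expect_error(segment_frame(clean, c(-5, 10)),
               class = "stenoscan_invalid_argument")

  # default-noise C-III center frame: DOS within 3 percentage points
  spec3 <- make_phantom_spec("C", "III")
  noisy <- render_bmode(render_truth(spec3, 50), noise_params(seed = 8))
  sg3 <- segment_frame(noisy, frame_center(noisy))
  dd3 <- equivalent_diameters(sg3$lumen, sg3$vessel, 0.1)
  expect_lt(abs(dos(dd3[["d"]], dd3[["D"]]) - dos(2.2, 5)), 3)
})

test_that("equivalent diameters follow the shoelace oracle", {
  circ <- circle_contour(c(60, 60), 50, 64)
  dd <- equivalent_diameters(circ, circ, 0.1)
  expect_equal(dd[["D"]], 10, tolerance = 0.02)  # polygon-discretization tol
  expect_equal(dd[["d"]], dd[["D"]])
  a <- 10
  sq <- resample_contour(contour(rbind(c(0, 0), c(a, 0), c(a, a), c(0, a),
                                       c(0, 7.5), c(0, 5), c(0, 2.5),
                                       c(0, 1))), 32)
  dsq <- equivalent_diameters(sq, sq, 1)
  expect_equal(dsq[["D"]], 2 * a / sqrt(pi), tolerance = 0.02)
  far <- circle_contour(c(300, 300), 20, 32)
  expect_error(equivalent_diameters(far, circ, 0.1),
               class = "stenoscan_segmentation_inconsistency")
})

test_that("series propagation matches per-frame truth and is symmetric", {
  spec <- make_phantom_spec("B", "II")
  plan <- build_plan(list(c(0, 0, 25), c(0, 0, 50), c(0, 0, 75)), "linear",
                     slice_spacing = 5)
  ser <- generate_series(spec, plan, noise_params(seed = 17))
  ctr <- frame_center(ser$frames[[1]])

  single <- propagate_series(ser$frames[1], ctr)
  direct <- segment_frame(ser$frames[[1]], ctr)
  expect_equal(equivalent_diameters(single[[1]]$lumen, single[[1]]$vessel, 0.1),
               equivalent_diameters(direct$lumen, direct$vessel, 0.1))

  segs <- propagate_series(ser$frames, ctr)
  d_rec <- vapply(segs, function(s) {
    equivalent_diameters(s$lumen, s$vessel, 0.1)[["d"]]
  }, numeric(1))
  zs <- vapply(ser$truths, `[[`, numeric(1), "axial_position")
  expect_lt(max(abs(d_rec - lumen_profile(spec, zs))), 0.1)

  rev_segs <- propagate_series(rev(ser$frames), ctr)
  d_rev <- rev(vapply(rev_segs, function(s) {
    equivalent_diameters(s$lumen, s$vessel, 0.1)[["d"]]
  }, numeric(1)))
  expect_lt(max(abs(d_rev - d_rec)), 0.1)
})

test_that("propagation failures name the frame and return earlier results", {
  spec <- make_phantom_spec("A", "II")
  good <- render_bmode(render_truth(spec, 50), noise_params(seed = 3))
  flat <- frame_of(matrix(0.5, 256, 256))
  err <- tryCatch(
    propagate_series(list(good, flat), frame_center(good)),
    error = identity
  )
  expect_s3_class(err, "stenoscan_propagation_error")
  expect_equal(err$frame, 2)
  expect_length(err$partial, 1)
  expect_match(conditionMessage(err), "frame 2")
})

test_that("contour serialization round-trips", {
  spec <- make_phantom_spec("C", "III")
  fr <- render_bmode(render_truth(spec, 50), noise_params(seed = 5))
  sg <- segment_frame(fr, frame_center(fr))
  file <- withr::local_tempfile(fileext = ".json")
  write_contours(list(sg), list(fr), file)
  back <- read_contours(file)
  expect_length(back, 2)
  roles <- vapply(back, `[[`, character(1), "role")
  expect_setequal(roles, c("lumen", "vessel"))
  expect_equal(back[[which(roles == "lumen")]]$contour$vertices,
               sg$lumen$vertices, tolerance = 1e-9, ignore_attr = TRUE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_diameters_csv(list(sg), list(fr), csv)
  tab <- utils::read.csv(csv)
  expect_named(tab, c("frame_index", "d_mm", "D_mm"))
})
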