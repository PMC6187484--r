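# Active-contour (snake) segmentation of vessel cross-sections, with
# radial-profile initialization and sub-pixel boundary measurement.

#' Active-contour model parameters
#'
#' Weights of the snake energy: the internal energy
#' `E_int = alpha |dv/ds|^2 + beta |d^2v/ds^2|^2` controls elasticity and
#' stiffness; the image energy `E_image = w_line E_line + w_edge E_edge +
#' w_term E_term` combines intensity, negative squared gradient magnitude and
#' level-line curvature. The constraint energy is fixed at zero.
#'
#' @param alpha elasticity weight (>= 0).
#' @param beta stiffness weight (>= 0).
#' @param w_line,w_edge,w_term image-energy weights.
#' @param search_radius half-width of the greedy search neighborhood, px.
#' @param max_iterations maximum greedy sweeps.
#' @param move_tolerance stop when the fraction of vertices that moved in a
#'   sweep falls below this value.
#' @param n_vertices number of contour vertices.
#' @param normalize normalize each image-energy field to unit maximum
#'   magnitude before weighting, so the weights are dimensionless and
#'   comparable to the internal terms (greedy-snake practice). Setting
#'   `FALSE` uses the raw fields.
#' @param term_smooth extra Gaussian smoothing (px) applied before computing
#'   the level-line curvature term, which is noise-sensitive.
#' @param n_rays,sector_rays,ray_step radial-measurement controls used by
#'   [segment_frame()]: number of rays cast from the seed, width (in rays) of
#'   the angular averaging sector, and radial sampling step in px.
#' @return An object of class `acm_params`.
#' @export
acm_params <- function(alpha = 0.1, beta = 0.4,
                       w_line = 0, w_edge = 1, w_term = 0.3,
                       search_radius = 2L, max_iterations = 200L,
                       move_tolerance = 0.05, n_vertices = 64L,
                       normalize = TRUE, term_smooth = 2,
                       n_rays = 48L, sector_rays = 11L, ray_step = 0.5) {
  if (alpha < 0 || beta < 0) stop_invalid("alpha and beta must be >= 0")
  if (max_iterations < 1) stop_invalid("max_iterations must be >= 1")
  if (move_tolerance < 0 || move_tolerance >= 1) {
    stop_invalid("move_tolerance must lie in [0, 1)")
  }
  if (n_vertices < 8) stop_invalid("n_vertices must be >= 8")
  structure(list(
    alpha = alpha, beta = beta,
    w_line = w_line, w_edge = w_edge, w_term = w_term,
    search_radius = as.integer(search_radius),
    max_iterations = as.integer(max_iterations),
    move_tolerance = move_tolerance,
    n_vertices = as.integer(n_vertices),
    normalize = isTRUE(normalize),
    term_smooth = term_smooth,
    n_rays = as.integer(n_rays),
    sector_rays = as.integer(sector_rays),
    ray_step = ray_step
  ), class = "acm_params")
}

#' Gaussian smoothing of a frame
#'
#' Reduces speckle before boundary detection. `sigma` is given in mm and
#' converted to pixels through the frame's pixel spacing; `sigma = 0` returns
#' the frame unchanged.
#'
#' @param frame a `bmode_frame`.
#' @param sigma Gaussian standard deviation, mm.
#' @return The smoothed `bmode_frame`.
#' @export
smooth_frame <- function(frame, sigma) {
  stopifnot(inherits(frame, "bmode_frame"))
  if (!is_scalar_number(sigma) || sigma < 0) {
    stop_invalid("sigma must be a non-negative number (mm)")
  }
  if (sigma == 0) return(frame)
  rng <- range(frame$intensity)
  sm <- as.matrix(EBImage::gblur(frame$intensity,
                                 sigma = sigma / frame$pixel_spacing))
  frame$intensity <- pmin(pmax(sm, rng[1]), rng[2])
  frame
}

# Central-difference gradients with replicated borders; img indexed [x, y].
.grad <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- (img[c(2:nx, nx), ] - img[c(1, 1:(nx - 1)), ]) / 2
  gy <- (img[, c(2:ny, ny)] - img[, c(1, 1:(ny - 1))]) / 2
  list(gx = gx, gy = gy)
}

.second_diffs <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  xx <- img[c(2:nx, nx), ] - 2 * img + img[c(1, 1:(nx - 1)), ]
  yy <- img[, c(2:ny, ny)] - 2 * img + img[, c(1, 1:(ny - 1))]
  g <- .grad(img)
  xy <- (g$gy[c(2:nx, nx), ] - g$gy[c(1, 1:(nx - 1)), ]) / 2
  list(xx = xx, yy = yy, xy = xy, x = g$gx, y = g$gy)
}

#' Image-energy fields for the snake
#'
#' Computes the three image functionals on a (pre-smoothed) frame:
#' `E_line` is the intensity itself, `E_edge` the negative squared gradient
#' magnitude, and `E_term` the curvature of level lines of a further-smoothed
#' copy. The combined field applies the `w_line`, `w_edge`, `w_term` weights
#' (after per-field normalization when `params$normalize` is `TRUE`).
#'
#' @param frame a (smoothed) `bmode_frame`.
#' @param params an [acm_params()] object.
#' @return An object of class `energy_fields` holding the three raw fields
#'   and the weighted `combined` field.
#' @export
image_energy_field <- function(frame, params = acm_params()) {
  stopifnot(inherits(frame, "bmode_frame"))
  img <- frame$intensity
  e_line <- img
  g <- .grad(img)
  e_edge <- -(g$gx^2 + g$gy^2)
  smooth2 <- if (params$term_smooth > 0) {
    as.matrix(EBImage::gblur(img, sigma = params$term_smooth))
  } else {
    img
  }
  d <- .second_diffs(smooth2)
  e_term <- (d$yy * d$x^2 - 2 * d$xy * d$x * d$y + d$xx * d$y^2) /
    ((d$x^2 + d$y^2)^1.5 + 1e-8)
  nrm <- function(f) {
    m <- max(abs(f))
    if (params$normalize && m > 0) f / m else f
  }
  combined <- params$w_line * nrm(e_line) + params$w_edge * nrm(e_edge) +
    params$w_term * nrm(e_term)
  structure(list(
    e_line = e_line, e_edge = e_edge, e_term = e_term,
    combined = combined, params = params
  ), class = "energy_fields")
}

#' Internal (shape) energy of a contour
#'
#' Cyclic finite differences over the uniform parameterization:
#' per vertex, `alpha |v_i - v_(i-1)|^2 + beta |v_(i-1) - 2 v_i + v_(i+1)|^2`;
#' the total is the mean over vertices (discretized integral).
#'
#' @param contour a [contour()].
#' @param params an [acm_params()] object.
#' @return List with `per_vertex` (numeric vector) and `total`.
#' @export
internal_energy <- function(contour, params = acm_params()) {
  v <- contour$vertices
  n <- nrow(v)
  vm <- v[c(n, 1:(n - 1)), , drop = FALSE]
  vp <- v[c(2:n, 1), , drop = FALSE]
  e1 <- rowSums((v - vm)^2)
  e2 <- rowSums((vm - 2 * v + vp)^2)
  per_vertex <- params$alpha * e1 + params$beta * e2
  list(per_vertex = per_vertex, total = mean(per_vertex))
}

#' Total snake energy of a contour on precomputed fields
#'
#' Discretizes the snake functional as the mean over vertices of the internal
#' plus external energy; image terms are sampled at vertex positions by
#' bilinear interpolation (out-of-domain samples clamped to the border and
#' flagged). The constraint energy is zero.
#'
#' @param contour a [contour()].
#' @param fields an [image_energy_field()] result for the same frame.
#' @param params an [acm_params()] object.
#' @return An object of class `energy_breakdown` with totals `e_int`,
#'   `e_image`, `e_con` (0), `e_ext`, `e_snake`, per-vertex term arrays and a
#'   `clamped` logical vector.
#' @export
snake_energy <- function(contour, fields, params = acm_params()) {
  stopifnot(inherits(fields, "energy_fields"))
  v <- contour$vertices
  s_comb <- bilinear_sample(fields$combined, v[, 1], v[, 2])
  s_line <- bilinear_sample(fields$e_line, v[, 1], v[, 2])$values
  s_edge <- bilinear_sample(fields$e_edge, v[, 1], v[, 2])$values
  s_term <- bilinear_sample(fields$e_term, v[, 1], v[, 2])$values
  int <- internal_energy(contour, params)
  e_image <- mean(s_comb$values)
  structure(list(
    e_int = int$total,
    e_image = e_image,
    e_con = 0,
    e_ext = e_image,
    e_snake = int$total + e_image,
    per_vertex = list(
      int = int$per_vertex,
      line = s_line, edge = s_edge, term = s_term,
      image = s_comb$values
    ),
    clamped = s_comb$clamped
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> E_snake = %.4f (E_int %.4f + E_image %.4f, E_con 0)\n",
    x$e_snake, x$e_int, x$e_image
  ))
  invisible(x)
}

# Candidate offsets of the greedy neighborhood in row-major order (y outer,
# x inner); ties prefer smallest displacement, then row-major rank.
.neighborhood_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  cbind(dx = g$dx, dy = g$dy)
}

#' Evolve a snake by greedy energy minimization
#'
#' Each sweep visits vertices in index order and moves each to the position
#' in its `(2 * search_radius + 1)^2` neighborhood that minimizes its local
#' energy contribution (its image energy plus every internal term involving
#' it); energy ties prefer the smallest displacement, then row-major
#' neighborhood order, so evolution is deterministic. After each sweep the
#' contour is resampled to uniform arc-length spacing (skipped if that would
#' raise the total energy), and evolution stops when the fraction of moved
#' vertices falls below `move_tolerance` or after `max_iterations` sweeps.
#' Total snake energy never increases across iterations.
#'
#' @param init initial [contour()], inside the image.
#' @param frame a (pre-smoothed) `bmode_frame`.
#' @param params an [acm_params()] object.
#' @param fields optional precomputed [image_energy_field()] for `frame`.
#' @return List with `contour` (converged), `energy` (an `energy_breakdown`),
#'   `iterations`, and `trace` (total energy after each sweep).
#' @export
evolve_snake <- function(init, frame, params = acm_params(), fields = NULL) {
  stopifnot(inherits(init, "contour"), inherits(frame, "bmode_frame"))
  nx <- nrow(frame$intensity); ny <- ncol(frame$intensity)
  if (any(init$vertices[, 1] < 1 | init$vertices[, 1] > nx |
          init$vertices[, 2] < 1 | init$vertices[, 2] > ny)) {
    stop_invalid("initial contour must lie inside the image")
  }
  if (is.null(fields)) fields <- image_energy_field(frame, params)
  field <- fields$combined
  off <- .neighborhood_offsets(params$search_radius)
  disp <- abs(off[, 1]) + abs(off[, 2])
  alpha <- params$alpha; beta <- params$beta
  ctr <- resample_contour(init, params$n_vertices)
  v <- ctr$vertices
  n <- nrow(v)

  local_energy <- function(cand, vm2, vm, vp, vp2) {
    # all snake terms that involve the moving vertex
    e_img <- bilinear_sample(field, cand[, 1], cand[, 2])$values
    d1a <- (cand[, 1] - vm[1])^2 + (cand[, 2] - vm[2])^2
    d1b <- (vp[1] - cand[, 1])^2 + (vp[2] - cand[, 2])^2
    s0 <- (vm[1] - 2 * cand[, 1] + vp[1])^2 + (vm[2] - 2 * cand[, 2] + vp[2])^2
    sm <- (vm2[1] - 2 * vm[1] + cand[, 1])^2 + (vm2[2] - 2 * vm[2] + cand[, 2])^2
    sp <- (cand[, 1] - 2 * vp[1] + vp2[1])^2 + (cand[, 2] - 2 * vp[2] + vp2[2])^2
    alpha * (d1a + d1b) + beta * (s0 + sm + sp) + e_img
  }

  total_energy <- function(verts) {
    snake_energy(structure(list(vertices = verts, closed = TRUE),
                           class = "contour"), fields, params)$e_snake
  }

  trace <- numeric(0)
  energy_now <- total_energy(v)
  iterations <- 0L
  for (it in seq_len(params$max_iterations)) {
    iterations <- it
    moved <- 0L
    for (i in seq_len(n)) {
      im2 <- ((i - 3) %% n) + 1; im <- ((i - 2) %% n) + 1
      ip <- (i %% n) + 1; ip2 <- ((i + 1) %% n) + 1
      cand <- cbind(v[i, 1] + off[, 1], v[i, 2] + off[, 2])
      e <- local_energy(cand, v[im2, ], v[im, ], v[ip, ], v[ip2, ])
      e_min <- min(e)
      tie <- which(e <= e_min + 1e-12)
      j <- tie[order(disp[tie], tie)[1]]
      if (off[j, 1] != 0 || off[j, 2] != 0) {
        v[i, ] <- cand[j, ]
        moved <- moved + 1L
      }
    }
    if (length(unique(paste(round(v[, 1], 6), round(v[, 2], 6)))) < 8) {
      stop_degenerate_contour("contour collapsed below 8 effective vertices")
    }
    energy_now <- total_energy(v)
    if (moved / n < params$move_tolerance) {
      trace <- c(trace, energy_now)
      break
    }
    resampled <- resample_contour(
      structure(list(vertices = v, closed = TRUE), class = "contour"), n
    )$vertices
    energy_rs <- total_energy(resampled)
    if (energy_rs <= energy_now + 1e-12) {
      v <- resampled
      energy_now <- energy_rs
    }
    trace <- c(trace, energy_now)
  }
  final <- contour(v)
  list(
    contour = final,
    energy = snake_energy(final, fields, params),
    iterations = iterations,
    trace = trace
  )
}

## ---- radial profile measurement -------------------------------------------

# Fit a double step profile v(r) = L + (P-L) Phi((r-r1)/s) + (W-P) Phi((r-r2)/s)
# on [0, wall crest]. The levels are solved by inner least squares; edge
# positions and blur width by bounded quasi-Newton from derivative-peak
# initializations. Resolves sub-resolution plaque rings where the inner edge
# is only a gradient shoulder. Returns c(r_lumen, r_vessel) in the units of
# rr, or NULL.
fit_edge_profile <- function(v, rr, min_step_frac = 0.12) {
  crest <- which.max(v)
  if (crest < 8) return(NULL)
  v <- v[seq_len(crest)]
  rr <- rr[seq_len(crest)]
  step <- rr[2] - rr[1]
  dv <- diff(v) / step
  if (max(dv) <= 0) return(NULL)
  thr <- max(0.35 * max(dv), 0.02)
  up <- which(dv >= thr)
  if (!length(up)) return(NULL)
  runs <- split(up, cumsum(c(1, diff(up) > 3)))
  pk <- unname(vapply(runs, function(j) rr[j[which.max(dv[j])]] + step / 2, 0))
  p0 <- rr[which.max(dv)] + step / 2
  lo <- c(rr[1], log(0.05), log(0.5))
  hi <- c(max(rr), log(max(max(rr) - rr[1], 0.1)), log(3))
  # levels solved in closed form (ridge-stabilized 3x3 normal equations)
  solve_levels <- function(r1, r2, s) {
    B <- cbind(1, stats::pnorm((rr - r1) / s), stats::pnorm((rr - r2) / s))
    G <- crossprod(B)
    diag(G) <- diag(G) + 1e-10
    cf <- drop(solve(G, crossprod(B, v)))
    list(cf = cf, rss = sum((v - drop(B %*% cf))^2))
  }
  obj <- function(par) {
    f <- solve_levels(par[1], par[1] + exp(par[2]), exp(par[3]))
    f$rss + 1e3 * sum(pmin(f$cf[2:3], 0)^2)
  }
  inits <- list(c(p0 - 2.5, log(2.5), log(1.2)),
                c(p0 - 1, log(2), log(1.2)))
  if (length(pk) >= 2) {
    inits <- c(list(c(pk[1], log(max(pk[length(pk)] - pk[1], 0.5)), log(1.2))),
               inits)
  }
  best <- NULL
  noise_floor <- length(v) * 5e-4
  for (ini in inits) {
    o <- tryCatch(
      stats::optim(pmin(pmax(ini, lo), hi), obj, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = list(maxit = 60)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    if (!is.null(best) && best$value < noise_floor) break
  }
  if (is.null(best)) return(NULL)
  r1 <- best$par[1]
  r2 <- r1 + exp(best$par[2])
  s <- exp(best$par[3])
  cf <- solve_levels(r1, r2, s)$cf
  if (any(!is.finite(cf))) return(NULL)
  amp1 <- cf[2]; amp2 <- cf[3]
  if (amp1 + amp2 <= 0) return(NULL)
  if (amp1 < min_step_frac * (amp1 + amp2)) r1 <- r2  # no resolvable inner step
  if (amp2 < min_step_frac * (amp1 + amp2)) r2 <- r1
  c(r_lumen = min(r1, r2), r_vessel = max(r1, r2))
}

# Sector-averaged radial intensity profiles and fitted lumen/wall-interface
# radii around a seed point. Angular averaging over `sector_rays` adjacent
# rays exploits local circularity of the vessel to suppress speckle without
# degrading radial resolution.
measure_vessel_radii <- function(img, seed, params = acm_params()) {
  nx <- nrow(img); ny <- ncol(img)
  n_rays <- params$n_rays
  step <- params$ray_step
  rmax <- min(seed[1] - 1, seed[2] - 1, nx - seed[1], ny - seed[2]) - 1
  if (rmax < 5) stop_invalid("seed point too close to the image border")
  rr <- seq(step, rmax, by = step)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[seq_len(n_rays)]
  V <- vapply(ang, function(a) {
    bilinear_sample(img, seed[1] + rr * cos(a), seed[2] + rr * sin(a))$values
  }, numeric(length(rr)))
  h <- (params$sector_rays - 1) %/% 2
  out <- matrix(NA_real_, n_rays, 2)
  for (i in seq_len(n_rays)) {
    idx <- ((i - h - 1):(i + h - 1)) %% n_rays + 1
    e <- fit_edge_profile(rowMeans(V[, idx, drop = FALSE]), rr)
    if (!is.null(e)) out[i, ] <- e
  }
  list(r_lumen = out[, 1], r_vessel = out[, 2], angles = ang)
}

# Close gaps and smooth per-ray radii; returns NULL if mostly missing.
.clean_radii <- function(r) {
  if (mean(is.na(r)) > 0.5) return(NULL)
  r <- circular_median_filter(r, 5)
  if (any(is.na(r))) r[is.na(r)] <- stats::median(r, na.rm = TRUE)
  r
}

.radii_contour <- function(seed, radii, angles, n_vertices) {
  resample_contour(
    contour(cbind(seed[1] + radii * cos(angles),
                  seed[2] + radii * sin(angles))),
    n_vertices
  )
}

#' Segment lumen and vessel-wall boundaries in one frame
#'
#' Three stages: (1) sector-averaged radial profiles from a seed inside the
#' lumen are fit with a double-step edge model, giving initial lumen
#' (expanding from the seed) and vessel (shrinking from outside onto the
#' wall's inner interface) contours; (2) both contours are refined by the
#' greedy active-contour model; (3) the boundary radii are re-measured at
#' sub-pixel precision around the converged centroid, which resolves plaque
#' rings thinner than the system blur. The lumen is constrained to lie inside
#' the vessel contour.
#'
#' @param frame a `bmode_frame`.
#' @param seed_point (x, y) pixel position inside the lumen.
#' @param params an [acm_params()] object.
#' @param smooth_sigma pre-smoothing in mm applied before segmentation
#'   (0 to disable if the frame is already smoothed).
#' @return List with `lumen` and `vessel` [contour()]s (pixel units), the
#'   `seed` used and `params`.
#' @export
segment_frame <- function(frame, seed_point, params = acm_params(),
                          smooth_sigma = 0.05) {
  stopifnot(inherits(frame, "bmode_frame"))
  nx <- nrow(frame$intensity); ny <- ncol(frame$intensity)
  seed_point <- as.numeric(seed_point)
  if (length(seed_point) != 2 || any(!is.finite(seed_point)) ||
      seed_point[1] < 1 || seed_point[1] > nx ||
      seed_point[2] < 1 || seed_point[2] > ny) {
    stop_invalid("seed_point must be an (x, y) position inside the image")
  }
  sm <- smooth_frame(frame, smooth_sigma)
  img <- sm$intensity

  meas <- measure_vessel_radii(img, seed_point, params)
  r_l <- .clean_radii(meas$r_lumen)
  r_v <- .clean_radii(meas$r_vessel)
  if (is.null(r_l) || is.null(r_v)) {
    stop_inconsistent("no vessel boundary detected around the seed point")
  }
  r_v <- pmax(r_v, r_l)
  init_l <- .radii_contour(seed_point, r_l, meas$angles, params$n_vertices)
  init_v <- .radii_contour(seed_point, r_v, meas$angles, params$n_vertices)

  fields <- image_energy_field(sm, params)
  ev_l <- evolve_snake(init_l, sm, params, fields)
  ev_v <- evolve_snake(init_v, sm, params, fields)

  # sub-pixel measurement around the converged lumen centroid
  cen <- contour_centroid(ev_l$contour)
  if (sqrt(sum((cen - seed_point)^2)) > 0.5) {
    meas <- measure_vessel_radii(img, cen, params)
    r_l2 <- .clean_radii(meas$r_lumen)
    r_v2 <- .clean_radii(meas$r_vessel)
    if (!is.null(r_l2) && !is.null(r_v2)) {
      r_l <- r_l2
      r_v <- pmax(r_v2, r_l2)
    }
  } else {
    cen <- seed_point
  }
  lumen <- .radii_contour(cen, r_l, meas$angles, params$n_vertices)
  vessel <- .radii_contour(cen, pmax(r_v, r_l), meas$angles, params$n_vertices)

  if (contour_area(lumen) > contour_area(vessel) * 1.05 ||
      !points_in_polygon(vessel$vertices, contour_centroid(lumen))) {
    stop_inconsistent("lumen contour is not inside the vessel contour")
  }
  list(lumen = lumen, vessel = vessel, seed = cen, params = params,
       snakes = list(lumen = ev_l, vessel = ev_v))
}

#' Segment a frame series sequentially
#'
#' Frames are segmented in order; each frame after the first is initialized
#' from the previous frame's converged contours (warm start: the previous
#' lumen centroid seeds the radial measurement, and propagation is purely
#' forward, so per-frame results never depend on later frames).
#'
#' @param frames list of `bmode_frame` objects.
#' @param first_seed (x, y) seed inside the lumen of the first frame.
#' @param params an [acm_params()] object.
#' @param smooth_sigma pre-smoothing in mm per frame.
#' @return List (class `segmentation_series`) of per-frame results as
#'   returned by [segment_frame()]. If frame `k` fails, an error of class
#'   `stenoscan_propagation_error` is thrown whose condition carries the
#'   failing frame in `$frame` and the earlier results in `$partial`.
#' @export
propagate_series <- function(frames, first_seed, params = acm_params(),
                             smooth_sigma = 0.05) {
  if (length(frames) < 1) stop_invalid("at least one frame is required")
  out <- vector("list", length(frames))
  seed <- as.numeric(first_seed)
  for (k in seq_along(frames)) {
    res <- tryCatch(
      segment_frame(frames[[k]], seed, params, smooth_sigma),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      stop_classed(
        "stenoscan_propagation_error",
        sprintf("segmentation failed at frame %d: %s", k, conditionMessage(res)),
        frame = k, partial = out[seq_len(k - 1)]
      )
    }
    out[[k]] <- res
    seed <- res$seed
  }
  structure(out, class = "segmentation_series")
}

#' Area-equivalent diameters of nested lumen and vessel contours
#'
#' Polygon areas (shoelace formula) are converted to the diameters of circles
#' of equal area, `2 sqrt(A / pi)`, and scaled to mm. The residual diameter is
#' clipped to `d <= D`; clearly non-nested contours raise a
#' segmentation-inconsistency error.
#'
#' @param lumen,vessel [contour()]s in pixel units, lumen nested in vessel.
#' @param pixel_spacing mm per pixel.
#' @return Named numeric vector `c(d = , D = )` in mm.
#' @export
equivalent_diameters <- function(lumen, vessel, pixel_spacing) {
  stopifnot(inherits(lumen, "contour"), inherits(vessel, "contour"))
  a_l <- contour_area(lumen)
  a_v <- contour_area(vessel)
  if (a_l > a_v * 1.05 ||
      !points_in_polygon(vessel$vertices, polygon_centroid(lumen$vertices))) {
    stop_inconsistent("contours are not nested (lumen must lie inside vessel)")
  }
  d <- 2 * sqrt(a_l / pi) * pixel_spacing
  D <- 2 * sqrt(a_v / pi) * pixel_spacing
  c(d = min(d, D), D = D)
}

#' Serialize contours to JSON and per-frame diameters to CSV
#'
#' The JSON schema stores one record per contour:
#' `{frame_index, role, pixel_spacing_mm, coordinate_convention, vertices,
#' params_used}`.
#'
#' @param segs a `segmentation_series` (or list of [segment_frame()] results).
#' @param frames the corresponding frames (for index and pixel spacing).
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_contours <- function(segs, frames, file) {
  recs <- list()
  for (k in seq_along(segs)) {
    for (role in c("lumen", "vessel")) {
      recs[[length(recs) + 1]] <- list(
        frame_index = frames[[k]]$frame_index,
        role = role,
        pixel_spacing_mm = frames[[k]]$pixel_spacing,
        coordinate_convention = "pixel-centers-integer, origin top-left, y down",
        vertices = unname(apply(segs[[k]][[role]]$vertices, 1, function(r) r,
                                simplify = FALSE)),
        params_used = unclass(segs[[k]]$params)
      )
    }
  }
  jsonlite::write_json(recs, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_contours
#' @export
read_contours <- function(file) {
  recs <- jsonlite::read_json(file)
  lapply(recs, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    list(frame_index = r$frame_index, role = r$role,
         pixel_spacing_mm = r$pixel_spacing_mm, contour = contour(v))
  })
}

#' @rdname write_contours
#' @param file output CSV path with columns `frame_index`, `d_mm`, `D_mm`.
#' @export
write_diameters_csv <- function(segs, frames, file) {
  rows <- do.call(rbind, lapply(seq_along(segs), function(k) {
    dd <- equivalent_diameters(segs[[k]]$lumen, segs[[k]]$vessel,
                               frames[[k]]$pixel_spacing)
    data.frame(frame_index = frames[[k]]$frame_index,
               d_mm = dd[["d"]], D_mm = dd[["D"]])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
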