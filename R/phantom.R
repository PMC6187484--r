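# Phantom simulation: ground-truthed stenosed-vessel geometry and
# B-mode-like rendering of cross-section frames.

# Design grid of the validation phantoms: three vessel calibers crossed with
# three stenosis severities. d = residual patent diameter at the plaque,
# D = vessel diameter, both mm.
.phantom_presets <- data.frame(
  vessel_type    = rep(c("A", "B", "C"), each = 3),
  stenosis_class = rep(c("I", "II", "III"), times = 3),
  d = c(9, 7.8, 4.5, 7, 6.2, 3.5, 4.5, 3.9, 2.2),
  D = c(10, 10, 10, 8, 8, 8, 5, 5, 5),
  stringsAsFactors = FALSE
)

#' Phantom design presets
#'
#' The nine stenosed-vessel phantom designs used for validation: vessel types
#' A (D = 10 mm), B (D = 8 mm) and C (D = 5 mm), each with stenosis classes
#' I (mild, DOS about 20\%), II (moderate, about 40\%) and III (severe,
#' about 80\%).
#'
#' @return A data.frame with columns `vessel_type`, `stenosis_class`, `d`, `D`
#'   and the design `dos` (percent) computed from them.
#' @export
phantom_presets <- function() {
  out <- .phantom_presets
  out$dos <- dos(out$d, out$D)
  out
}

#' Create a stenosed-vessel phantom specification
#'
#' Builds the parametric description of a vessel phantom with a focal,
#' cosine-tapered concentric stenosis. Presets reproduce the design grid of
#' [phantom_presets()]; all other geometry comes from documented defaults and
#' can be overridden.
#'
#' @param vessel_type one of `"A"`, `"B"`, `"C"`.
#' @param stenosis_class one of `"I"`, `"II"`, `"III"`.
#' @param length centerline extent, mm.
#' @param stenosis_center axial position of maximal stenosis, mm.
#' @param stenosis_length axial extent of the plaque taper, mm.
#' @param wall_thickness vessel wall thickness (rendering contrast only), mm.
#' @param path_kind centerline shape, `"straight"` or `"arc"`.
#' @param path_params for `"straight"`, a list with `from` and `to` 3D points
#'   (mm); for `"arc"`, a list with `center` (3D), `radius` (mm). Defaults to
#'   a straight segment of `length` mm along z.
#' @param eccentricity lumen center offset as a fraction of (D - d)/2;
#'   0 (default) keeps the residual lumen concentric.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' make_phantom_spec("A", "I")$d  # 9 mm
make_phantom_spec <- function(vessel_type, stenosis_class,
                              length = 100,
                              stenosis_center = length / 2,
                              stenosis_length = 10,
                              wall_thickness = 1.5,
                              path_kind = c("straight", "arc"),
                              path_params = NULL,
                              eccentricity = 0) {
  types <- unique(.phantom_presets$vessel_type)
  classes <- unique(.phantom_presets$stenosis_class)
  if (!is.character(vessel_type) || length(vessel_type) != 1 ||
      !(vessel_type %in% types)) {
    stop_invalid(sprintf(
      "unknown vessel_type %s; valid types: %s",
      deparse(vessel_type), paste(types, collapse = ", ")
    ))
  }
  if (!is.character(stenosis_class) || length(stenosis_class) != 1 ||
      !(stenosis_class %in% classes)) {
    stop_invalid(sprintf(
      "unknown stenosis_class %s; valid classes: %s",
      deparse(stenosis_class), paste(classes, collapse = ", ")
    ))
  }
  row <- .phantom_presets[.phantom_presets$vessel_type == vessel_type &
                            .phantom_presets$stenosis_class == stenosis_class, ]
  path_kind <- match.arg(path_kind)
  if (is.null(path_params)) {
    path_params <- list(from = c(0, 0, 0), to = c(0, 0, length))
  }
  spec <- structure(list(
    vessel_type = vessel_type,
    stenosis_class = stenosis_class,
    d = row$d,
    D = row$D,
    length = length,
    stenosis_center = stenosis_center,
    stenosis_length = stenosis_length,
    wall_thickness = wall_thickness,
    path_kind = path_kind,
    path_params = path_params,
    eccentricity = eccentricity
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(d > 0 && d <= D)) stop_invalid("phantom requires 0 < d <= D")
    if (stenosis_length <= 0) stop_invalid("stenosis_length must be > 0")
    if (stenosis_center < 0 || stenosis_center > length) {
      stop_invalid("stenosis_center must lie within the centerline extent")
    }
    if (wall_thickness <= 0) stop_invalid("wall_thickness must be > 0")
    if (eccentricity < 0 || eccentricity > 1) {
      stop_invalid("eccentricity must be in [0, 1]")
    }
  })
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> type %s class %s: d = %.1f mm, D = %.1f mm (design DOS %.1f%%)\n",
    x$vessel_type, x$stenosis_class, x$d, x$D, dos(x$d, x$D)
  ))
  cat(sprintf(
    "  %s centerline, length %.0f mm; plaque %.0f mm long at z = %.0f mm\n",
    x$path_kind, x$length, x$stenosis_length, x$stenosis_center
  ))
  invisible(x)
}

#' Patent lumen diameter along the centerline
#'
#' The plaque narrows the lumen smoothly from the vessel diameter `D` far from
#' the stenosis to the residual diameter `d` at its center, following a cosine
#' taper over `stenosis_length` (symmetric about `stenosis_center`).
#'
#' @param spec a [make_phantom_spec()] specification.
#' @param z axial position(s) along the centerline, mm.
#' @return Patent diameter(s) in mm.
#' @export
lumen_profile <- function(spec, z) {
  if (any(z < 0 | z > spec$length)) {
    stop_out_of_range(sprintf(
      "z outside centerline extent [0, %g] mm", spec$length
    ))
  }
  u <- abs(z - spec$stenosis_center)
  half <- spec$stenosis_length / 2
  taper <- ifelse(u >= half, 0,
                  (1 + cos(2 * pi * (z - spec$stenosis_center) /
                             spec$stenosis_length)) / 2)
  spec$D - (spec$D - spec$d) * taper
}

#' Rasterize the ground-truth cross-section at an axial position
#'
#' Produces binary masks of the patent lumen and of the vessel (diameter `D`)
#' on a pixel grid, plus the bright wall annulus used for rendering. Masks are
#' centered in the frame; with `eccentricity > 0` the lumen disk is offset
#' toward +x while staying inside the vessel.
#'
#' @param spec a [make_phantom_spec()] specification.
#' @param z axial position, mm.
#' @param pixel_spacing pixel size, mm/px. Must resolve `D` with >= 20 px.
#' @param size frame side length, pixels.
#' @return An object of class `cross_section_truth` with fields `lumen_mask`,
#'   `vessel_mask`, `wall_mask` (logical `size` x `size` matrices, indexed
#'   `[x, y]`), `pixel_spacing` and `axial_position`.
#' @export
render_truth <- function(spec, z, pixel_spacing = 0.1, size = 256) {
  if (!is_scalar_number(pixel_spacing) || pixel_spacing <= 0) {
    stop_invalid("pixel_spacing must be a positive number")
  }
  if (spec$D / pixel_spacing < 20) {
    stop_invalid("pixel_spacing too coarse: D must span at least 20 pixels")
  }
  outer_d <- spec$D + 2 * spec$wall_thickness
  if (outer_d / pixel_spacing + 4 > size) {
    stop_invalid(sprintf(
      "frame size %d too small: vessel plus wall spans %.0f px",
      size, outer_d / pixel_spacing
    ))
  }
  ld <- lumen_profile(spec, z)
  cx <- (size + 1) / 2
  xs <- (seq_len(size) - cx) * pixel_spacing
  # lumen offset for eccentric plaque: keep lumen inside the vessel
  off <- spec$eccentricity * (spec$D - ld) / 2
  r2_center <- outer(xs^2, xs^2, "+")
  r2_lumen <- outer((xs - off)^2, xs^2, "+")
  structure(list(
    lumen_mask = r2_lumen <= (ld / 2)^2,
    vessel_mask = r2_center <= (spec$D / 2)^2,
    wall_mask = r2_center <= (outer_d / 2)^2 & r2_center > (spec$D / 2)^2,
    pixel_spacing = pixel_spacing,
    axial_position = z
  ), class = "cross_section_truth")
}

#' Speckle and contrast parameters for B-mode rendering
#'
#' Echo levels follow B-mode appearance: anechoic lumen, echogenic soft
#' tissue/plaque, hyperechoic wall. Speckle is multiplicative unit-mean
#' gamma noise (relative standard deviation `speckle_scale`) applied before a
#' Gaussian system blur of `blur_sigma` mm, a first-order approximation of
#' the imaging point-spread function.
#'
#' @param speckle_scale relative standard deviation of the multiplicative
#'   speckle (0 disables it).
#' @param blur_sigma standard deviation of the system blur, mm (0 disables).
#' @param lumen_level,wall_level,background_level grayscale levels in `[0, 1]`
#'   with `wall_level > background_level > lumen_level`.
#' @param seed integer; fully determines the rendered noise.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(speckle_scale = 0.3, blur_sigma = 0.1,
                         lumen_level = 0.05, wall_level = 0.85,
                         background_level = 0.35, seed = 1L) {
  if (speckle_scale < 0 || blur_sigma < 0) {
    stop_invalid("speckle_scale and blur_sigma must be >= 0")
  }
  if (!(wall_level > background_level && background_level > lumen_level)) {
    stop_invalid("levels must satisfy wall_level > background_level > lumen_level")
  }
  if (any(c(lumen_level, wall_level, background_level) < 0) ||
      any(c(lumen_level, wall_level, background_level) > 1)) {
    stop_invalid("levels must lie in [0, 1]")
  }
  structure(list(
    speckle_scale = speckle_scale, blur_sigma = blur_sigma,
    lumen_level = lumen_level, wall_level = wall_level,
    background_level = background_level, seed = as.integer(seed)
  ), class = "noise_params")
}

new_bmode_frame <- function(intensity, pixel_spacing, frame_index = 0L,
                            axial_position = 0, theta = 0) {
  structure(list(
    intensity = intensity,
    pixel_spacing = pixel_spacing,
    frame_index = as.integer(frame_index),
    axial_position = axial_position,
    theta = theta
  ), class = "bmode_frame")
}

#' @export
print.bmode_frame <- function(x, ...) {
  cat(sprintf(
    "<bmode_frame> #%d: %d x %d px at %.3g mm/px, z = %.1f mm, theta = %.3f rad\n",
    x$frame_index, nrow(x$intensity), ncol(x$intensity), x$pixel_spacing,
    x$axial_position, x$theta
  ))
  invisible(x)
}

#' Render a B-mode-like frame from a ground-truth cross-section
#'
#' Assigns echo levels by region (lumen, plaque/tissue, wall annulus,
#' background), multiplies by seeded unit-mean gamma speckle, applies the
#' Gaussian system blur and clips to `[0, 1]`. The render is a pure function
#' of its arguments including the seed.
#'
#' @param truth a [render_truth()] cross-section.
#' @param noise a [noise_params()] object.
#' @return A `bmode_frame` whose `intensity` is a `[x, y]` matrix in `[0, 1]`.
#' @export
render_bmode <- function(truth, noise = noise_params()) {
  stopifnot(inherits(truth, "cross_section_truth"))
  n <- nrow(truth$lumen_mask)
  img <- matrix(noise$background_level, n, ncol(truth$lumen_mask))
  img[truth$wall_mask] <- noise$wall_level
  # plaque / intraluminal tissue renders at soft-tissue level
  img[truth$vessel_mask] <- noise$background_level
  img[truth$lumen_mask] <- noise$lumen_level
  if (noise$speckle_scale > 0) {
    shape <- 1 / noise$speckle_scale^2
    img <- img * withr::with_seed(
      noise$seed,
      matrix(stats::rgamma(length(img), shape = shape, rate = shape),
             nrow(img), ncol(img))
    )
  }
  if (noise$blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = noise$blur_sigma /
                                      truth$pixel_spacing))
  }
  img <- pmin(pmax(img, 0), 1)
  new_bmode_frame(img, truth$pixel_spacing,
                  axial_position = truth$axial_position)
}

# Axial coordinate (arc length along the phantom centerline) of a scan-plan
# waypoint. Straight phantoms project onto the centerline direction; arc
# phantoms use the plan's own axial_position (the plan is assumed to follow
# the centerline).
phantom_axial_coordinate <- function(spec, waypoint_position, axial_position) {
  if (spec$path_kind == "straight") {
    p0 <- spec$path_params$from
    u <- spec$path_params$to - p0
    u <- u / sqrt(sum(u^2))
    sum((waypoint_position - p0) * u)
  } else {
    axial_position
  }
}

#' Render a frame series along a scan plan
#'
#' One frame is rendered per plan waypoint, at the phantom axial coordinate of
#' that waypoint, with `axial_position` and rotation angle `theta` copied from
#' the plan. Ground-truth cross-sections are attached for testing. Each frame
#' draws its speckle from `noise$seed + frame_index`, so a series is fully
#' reproducible.
#'
#' @param spec a [make_phantom_spec()] specification.
#' @param plan a [build_plan()] scan plan whose waypoints lie on the phantom
#'   centerline.
#' @param noise a [noise_params()] object.
#' @param pixel_spacing,size frame raster parameters (see [render_truth()]).
#' @return An object of class `phantom_series`: list with `frames` (list of
#'   `bmode_frame`) and `truths` (list of `cross_section_truth`).
#' @export
generate_series <- function(spec, plan, noise = noise_params(),
                            pixel_spacing = 0.1, size = 256) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(plan, "scan_plan"))
  wp <- plan$waypoints
  zs <- vapply(seq_len(nrow(wp)), function(i) {
    phantom_axial_coordinate(spec, c(wp$x[i], wp$y[i], wp$z[i]),
                             wp$axial_position[i])
  }, numeric(1))
  if (any(zs < 0 - 1e-9 | zs > spec$length + 1e-9)) {
    stop_out_of_range(sprintf(
      "scan plan leaves the phantom extent [0, %g] mm (waypoints span %.1f..%.1f)",
      spec$length, min(zs), max(zs)
    ))
  }
  zs <- pmin(pmax(zs, 0), spec$length)
  frames <- vector("list", nrow(wp))
  truths <- vector("list", nrow(wp))
  for (i in seq_len(nrow(wp))) {
    tr <- render_truth(spec, zs[i], pixel_spacing, size)
    ni <- noise
    ni$seed <- noise$seed + i - 1L
    fr <- render_bmode(tr, ni)
    fr$frame_index <- i - 1L
    fr$axial_position <- wp$axial_position[i]
    fr$theta <- wp$theta[i]
    frames[[i]] <- fr
    truths[[i]] <- tr
  }
  structure(list(frames = frames, truths = truths, spec = spec, plan = plan),
            class = "phantom_series")
}

#' Write and read a frame series as PNG files plus a JSON manifest
#'
#' Frames are stored as 8-bit grayscale PNGs next to a `manifest.json` listing
#' per-frame `frame_index`, `axial_position_mm`, `theta_rad` and
#' `pixel_spacing_mm`. The manifest schema is the hand-off point for real
#' ultrasound captures.
#'
#' @param frames list of `bmode_frame` objects (or a `phantom_series`).
#' @param dir output directory (created if needed).
#' @return `write_frame_series`: the directory, invisibly;
#'   `read_frame_series`: a list of `bmode_frame` objects.
#' @export
write_frame_series <- function(frames, dir) {
  if (inherits(frames, "phantom_series")) frames <- frames$frames
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(frames, function(fr) {
    file <- sprintf("frame_%04d.png", fr$frame_index)
    # intensity is [x, y]; PNG rows are y
    png::writePNG(t(fr$intensity), file.path(dir, file))
    list(file = file, frame_index = fr$frame_index,
         axial_position_mm = fr$axial_position, theta_rad = fr$theta,
         pixel_spacing_mm = fr$pixel_spacing)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest, function(m) {
    img <- png::readPNG(file.path(dir, m$file))
    if (length(dim(img)) == 3) img <- img[, , 1]
    new_bmode_frame(t(img), m$pixel_spacing_mm, m$frame_index,
                    m$axial_position_mm, m$theta_rad)
  })
}
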