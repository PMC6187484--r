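# Shared fixtures: small synthetic frames and a memoised phantom study.

# Noise-free bright disk on a dark background, optionally Gaussian-blurred;
# intensity indexed [x, y] like bmode frames.
disk_frame <- function(radius = 20, size = 64, blur = 1.5,
                       inside = 0.9, outside = 0.1, pixel_spacing = 0.1) {
  ctr <- (size + 1) / 2
  xs <- seq_len(size) - ctr
  img <- ifelse(outer(xs^2, xs^2, "+") <= radius^2, inside, outside)
  if (blur > 0) img <- as.matrix(EBImage::gblur(img, sigma = blur))
  stenoscan:::new_bmode_frame(img, pixel_spacing)
}

# Plain frame stub around an intensity matrix.
frame_of <- function(img, pixel_spacing = 0.1, axial = 0, theta = 0,
                     index = 0L) {
  stenoscan:::new_bmode_frame(img, pixel_spacing, index, axial, theta)
}

frame_center <- function(frame) {
  c((nrow(frame$intensity) + 1) / 2, (ncol(frame$intensity) + 1) / 2)
}

# Independent total snake energy oracle (mean internal + mean sampled field),
# written against the published energy decomposition, not the package's
# snake_energy() path.
oracle_snake_energy <- function(vertices, field, alpha, beta) {
  n <- nrow(vertices)
  vm <- vertices[c(n, 1:(n - 1)), , drop = FALSE]
  vp <- vertices[c(2:n, 1), , drop = FALSE]
  e_int <- alpha * rowSums((vertices - vm)^2) +
    beta * rowSums((vm - 2 * vertices + vp)^2)
  x <- pmin(pmax(vertices[, 1], 1), nrow(field))
  y <- pmin(pmax(vertices[, 2], 1), ncol(field))
  x0 <- pmin(floor(x), nrow(field) - 1)
  y0 <- pmin(floor(y), ncol(field) - 1)
  fx <- x - x0
  fy <- y - y0
  e_img <- field[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    field[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    field[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    field[cbind(x0 + 1, y0 + 1)] * fx * fy
  mean(e_int) + mean(e_img)
}

# The nine-preset recovery study is expensive; compute it once per seed and
# share across test files.
.study_cache <- new.env(parent = emptyenv())
cached_phantom_study <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- run_phantom_study(seed = seed)
  }
  .study_cache[[key]]
}
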