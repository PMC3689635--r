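# Circular LBP-style neighborhoods and the global texture-variance score.
#
# The i-th of N neighbors of a center (c_x, c_y) sits at
#   x = c_x + R * cos(2*pi*i/N),  y = c_y + R * sin(2*pi*i/N),  i = 1..N,
# in (x right, y down) image coordinates. Off-grid positions are bilinearly
# interpolated from the 4 surrounding pixel centers; positions within
# .grid_snap of a grid point are read directly.

.grid_snap <- 1e-9

#' Circular neighborhood specification
#'
#' @param R Sampling radius in pixels (positive, may be fractional).
#' @param N Number of equally spaced neighbors on the circle (integer >= 2).
#' @return Object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(R, N = 8L) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("radius R must be a positive scalar", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("neighbor count N must be an integer >= 2", call. = FALSE)
  }
  structure(list(R = R, N = N), class = "neighborhood_spec")
}

# snap a fractional offset to the grid; returns c(offset0, offset1, frac)
.snap_offset <- function(d) {
  o0 <- floor(d)
  f <- d - o0
  if (f < .grid_snap) {
    c(o0, o0, 0)
  } else if (f > 1 - .grid_snap) {
    c(o0 + 1, o0 + 1, 0)
  } else {
    c(o0, o0 + 1, f)
  }
}

# bilinear read at real-valued (x, y), 0-based
.bilinear_at <- function(img, x, y) {
  v <- nrow(img); h <- ncol(img)
  if (x < -.grid_snap || x > h - 1 + .grid_snap ||
      y < -.grid_snap || y > v - 1 + .grid_snap) {
    stop("sampling position outside image bounds", call. = FALSE)
  }
  sx <- .snap_offset(min(max(x, 0), h - 1))
  sy <- .snap_offset(min(max(y, 0), v - 1))
  fx <- sx[3]; fy <- sy[3]
  (1 - fy) * ((1 - fx) * img[sy[1] + 1, sx[1] + 1] +
              fx * img[sy[1] + 1, sx[2] + 1]) +
    fy * ((1 - fx) * img[sy[2] + 1, sx[1] + 1] +
          fx * img[sy[2] + 1, sx[2] + 1])
}

#' Sample intensities on a circle around a center pixel
#'
#' Returns the N neighbor intensities used by the LBP pattern and the
#' local texture variance, in order i = 1..N.
#'
#' @param img Grayscale image matrix.
#' @param center 0-based `(c_x, c_y)` center coordinates.
#' @param spec A [neighborhood_spec()].
#' @return Numeric vector of N intensities.
#' @examples
#' m <- matrix(1:9, 3, 3, byrow = TRUE)
#' sample_neighbors(m, c(1, 1), neighborhood_spec(1, 4))  # 8 4 2 6
#' @export
sample_neighbors <- function(img, center, spec) {
  validate_gray_image(img)
  stopifnot(inherits(spec, "neighborhood_spec"))
  cx <- center[1]; cy <- center[2]
  v <- nrow(img); h <- ncol(img)
  if (cx - spec$R < -.grid_snap || cx + spec$R > h - 1 + .grid_snap ||
      cy - spec$R < -.grid_snap || cy + spec$R > v - 1 + .grid_snap) {
    stop(sprintf(
      "circle of radius %g around center (%g, %g) exits image bounds",
      spec$R, cx, cy), call. = FALSE)
  }
  i <- seq_len(spec$N)
  ang <- 2 * pi * i / spec$N
  vapply(i, function(k) {
    .bilinear_at(img, cx + spec$R * cos(ang[k]), cy + spec$R * sin(ang[k]))
  }, numeric(1))
}

#' Local binary pattern at a center pixel
#'
#' Each neighbor is thresholded against the center intensity: bit i is 1
#' when the neighbor is at least as bright as the center (the threshold
#' function maps 0 to 1), else 0. The bit sequence is also packed into a
#' decimal code with weight `2^(i-1)` on bit i.
#'
#' @inheritParams sample_neighbors
#' @return Object of class `lbp_pattern`: list with integer vector `bits`
#'   (length N), `code` (decimal pattern code), `center`, and the
#'   sampled `neighbors`.
#' @export
lbp_pattern <- function(img, center, spec) {
  p_n <- sample_neighbors(img, center, spec)
  p_c <- img[center[2] + 1, center[1] + 1]
  bits <- as.integer(p_n - p_c >= 0)
  structure(
    list(bits = bits,
         code = sum(bits * 2^(seq_along(bits) - 1)),
         center = center,
         neighbors = p_n),
    class = "lbp_pattern"
  )
}

#' Local texture variance at a center pixel
#'
#' Population variance (divisor N) of the N circularly sampled neighbor
#' intensities around their own mean; the center pixel itself does not
#' enter the mean.
#'
#' @inheritParams sample_neighbors
#' @return Non-negative scalar, in squared intensity units.
#' @export
local_variance <- function(img, center, spec) {
  p_n <- sample_neighbors(img, center, spec)
  mu <- mean(p_n)
  mean((p_n - mu)^2)
}

#' Global texture variance of an image
#'
#' Averages the local neighbor variance over every center whose full
#' sampling circle lies inside the image (centers at distance >= R from
#' all borders). Restricting to valid centers and dividing by their count
#' avoids the padding artifacts that including border pixels would
#' introduce; for images much larger than R the difference from averaging
#' over all h x v pixels is negligible.
#'
#' @inheritParams sample_neighbors
#' @return Non-negative scalar with attribute `valid_center_count`.
#' @export
global_texture_variance <- function(img, spec) {
  validate_gray_image(img)
  stopifnot(inherits(spec, "neighborhood_spec"))
  v <- nrow(img); h <- ncol(img)
  R <- spec$R; N <- spec$N
  lo_x <- ceiling(R - .grid_snap); hi_x <- floor(h - 1 - R + .grid_snap)
  lo_y <- ceiling(R - .grid_snap); hi_y <- floor(v - 1 - R + .grid_snap)
  if (lo_x > hi_x || lo_y > hi_y) {
    stop(sprintf(
      "no valid centers for radius %g: image must be at least %d x %d",
      R, 2 * ceiling(R) + 1, 2 * ceiling(R) + 1), call. = FALSE)
  }

  # The fractional part of each neighbor offset is the same for every
  # center, so the whole sampling plane for neighbor i is a fixed blend of
  # four shifted submatrices of the image.
  i <- seq_len(N)
  ang <- 2 * pi * i / N
  dx <- R * cos(ang)
  dy <- R * sin(ang)
  rows0 <- (lo_y + 1):(hi_y + 1)
  cols0 <- (lo_x + 1):(hi_x + 1)
  planes <- vector("list", N)
  for (k in i) {
    sx <- .snap_offset(dx[k])
    sy <- .snap_offset(dy[k])
    fx <- sx[3]; fy <- sy[3]
    r0 <- rows0 + sy[1]; r1 <- rows0 + sy[2]
    c0 <- cols0 + sx[1]; c1 <- cols0 + sx[2]
    planes[[k]] <-
      (1 - fy) * ((1 - fx) * img[r0, c0, drop = FALSE] +
                  fx * img[r0, c1, drop = FALSE]) +
      fy * ((1 - fx) * img[r1, c0, drop = FALSE] +
            fx * img[r1, c1, drop = FALSE])
  }
  mu <- Reduce(`+`, planes) / N
  acc <- 0
  for (k in i) {
    acc <- acc + (planes[[k]] - mu)^2
  }
  loc <- acc / N
  structure(mean(loc), valid_center_count = length(loc))
}

#' Multi-radius texture-variance score
#'
#' The mucosa-visibility score: the global texture variance computed at
#' several sampling radii and averaged, so that both fine and coarse
#' texture frequencies contribute. Defaults to radii 10, 20, ..., 50
#' pixels with 8 neighbors.
#'
#' @param img Grayscale image matrix; RGB arrays are converted via
#'   [to_grayscale()].
#' @param radii Numeric vector of sampling radii in pixels.
#' @param N Neighbors per circle.
#' @param weights Grayscale conversion weights, used only for RGB input.
#' @return Object of class `texture_variance`: list with `per_radius`
#'   (named numeric vector), `averaged` (their arithmetic mean), `radii`,
#'   `N`, and `valid_center_count` per radius.
#' @export
multi_radius_score <- function(img, radii = c(10, 20, 30, 40, 50), N = 8L,
                               weights = c(0.299, 0.587, 0.114)) {
  if (!is.matrix(img)) {
    img <- to_grayscale(img, weights)
  }
  validate_gray_image(img)
  if (length(radii) < 1L) {
    stop("need at least one radius", call. = FALSE)
  }
  mn <- min(dim(img))
  bad <- radii[2 * radii >= mn]
  if (length(bad) > 0L) {
    stop(sprintf(
      "image of size %d x %d is too small for radius %g (needs min dimension > %g)",
      nrow(img), ncol(img), max(bad), 2 * max(bad)), call. = FALSE)
  }
  per <- numeric(length(radii))
  counts <- integer(length(radii))
  for (j in seq_along(radii)) {
    g <- global_texture_variance(img, neighborhood_spec(radii[j], N))
    per[j] <- as.numeric(g)
    counts[j] <- attr(g, "valid_center_count")
  }
  names(per) <- as.character(radii)
  names(counts) <- as.character(radii)
  structure(
    list(per_radius = per,
         averaged = mean(per),
         radii = radii,
         N = as.integer(N),
         valid_center_count = counts),
    class = "texture_variance"
  )
}

#' @export
print.texture_variance <- function(x, ...) {
  cat(sprintf("Global texture variance (N = %d):\n", x$N))
  for (r in names(x$per_radius)) {
    cat(sprintf("  R = %s: %.4f\n", r, x$per_radius[[r]]))
  }
  cat(sprintf("  averaged over %d radii: %.4f\n",
              length(x$per_radius), x$averaged))
  invisible(x)
}
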