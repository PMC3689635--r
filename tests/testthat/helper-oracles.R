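# Independent reference implementations used to cross-check the package:
# plain scalar loops written directly from the defining formulas, sharing
# no code with the vectorized implementation under test.

# bilinear read at real (x, y), 0-based coordinates
oracle_bilinear <- function(img, x, y) {
  eps <- 1e-9
  x <- min(max(x, 0), ncol(img) - 1)
  y <- min(max(y, 0), nrow(img) - 1)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  if (fx < eps) { fx <- 0 } else if (fx > 1 - eps) { x0 <- x0 + 1; fx <- 0 }
  if (fy < eps) { fy <- 0 } else if (fy > 1 - eps) { y0 <- y0 + 1; fy <- 0 }
  x1 <- min(x0 + 1, ncol(img) - 1)
  y1 <- min(y0 + 1, nrow(img) - 1)
  (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
    fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
}

oracle_neighbors <- function(img, cx, cy, R, N) {
  vals <- numeric(N)
  for (i in seq_len(N)) {
    ang <- 2 * pi * i / N
    vals[i] <- oracle_bilinear(img, cx + R * cos(ang), cy + R * sin(ang))
  }
  vals
}

oracle_local_variance <- function(img, cx, cy, R, N) {
  p <- oracle_neighbors(img, cx, cy, R, N)
  mu <- sum(p) / N
  sum((p - mu)^2) / N
}

# exhaustive double loop over every center whose circle stays in bounds
oracle_global_variance <- function(img, R, N) {
  v <- nrow(img); h <- ncol(img)
  lo <- ceiling(R); acc <- 0; cnt <- 0
  for (cy in lo:(v - 1 - lo)) {
    for (cx in lo:(h - 1 - lo)) {
      acc <- acc + oracle_local_variance(img, cx, cy, R, N)
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# point-in-polygon by winding angle (interior) plus distance-to-segment
# boundary test; a different algorithm than the ray-crossing rasterizer
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  eps <- 1e-9
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[e %% n + 1, 1]; y2 <- poly[e %% n + 1, 2]
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (len2 == 0) 0 else
      max(0, min(1, ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / len2))
    d2 <- (px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2
    if (d2 < eps) return(TRUE)
  }
  total <- 0
  for (e in seq_len(n)) {
    x1 <- poly[e, 1] - px; y1 <- poly[e, 2] - py
    x2 <- poly[e %% n + 1, 1] - px; y2 <- poly[e %% n + 1, 2] - py
    total <- total + atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2)
  }
  abs(total) > pi
}

oracle_rasterize <- function(poly, shape) {
  v <- shape[1]; h <- shape[2]
  m <- matrix(FALSE, v, h)
  for (yy in 0:(v - 1)) {
    for (xx in 0:(h - 1)) {
      m[yy + 1, xx + 1] <- oracle_in_polygon(xx, yy, poly)
    }
  }
  m
}

# small uniform-random 8-bit test image
random_image <- function(v, h, seed) {
  set.seed(seed)
  matrix(sample(0:255, v * h, replace = TRUE), v, h)
}

# small, fast generator settings for design-level tests
quick_params <- function(kind = c("contrast", "texture")) {
  kind <- match.arg(kind)
  function(stain, region, score) {
    synthetic_params(
      image_size = c(96, 96),
      lesion_type = if (kind == "contrast") "flat_depressed" else "none")
  }
}
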