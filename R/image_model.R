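# Coordinate convention used throughout: pixels are addressed as (x, y) with
# x the 0-based column index increasing rightward and y the 0-based row index
# increasing downward.  A GrayImage is stored as a plain numeric matrix with
# v rows and h columns, so pixel (x, y) lives at img[y + 1, x + 1].

#' Validate a grayscale image matrix
#'
#' A grayscale image is a numeric matrix on the 0-255 intensity scale
#' (real-valued; conversion from color is not re-quantized). Dimensions are
#' rows = image height `v`, columns = image width `h`.
#'
#' @param img Numeric matrix.
#' @return The matrix, invisibly, after validation.
#' @export
validate_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("grayscale image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("grayscale intensities must lie in [0, 255] and contain no NA",
         call. = FALSE)
  }
  invisible(img)
}

#' Convert an RGB image to grayscale
#'
#' Applies a per-pixel luma weighting of the three color channels. The
#' default weights are the ITU-R BT.601 luma coefficients
#' (0.299, 0.587, 0.114). The result is kept real-valued: no rounding or
#' re-quantization is applied, so downstream scores operate on the exact
#' weighted intensities.
#'
#' @param img Numeric array `v x h x 3` with channel values in \[0, 255\],
#'   or a numeric matrix (already grayscale), which is validated and
#'   returned unchanged.
#' @param weights Length-3 numeric vector of channel weights summing to 1.
#' @return Numeric matrix `v x h` of intensities in \[0, 255\].
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(px)  # 0.299 * 255 = 76.245
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(img)) {
    return(validate_gray_image(img))
  }
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("color image must be a v x h x 3 array", call. = FALSE)
  }
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-9) {
    stop("grayscale weights must be three values summing to 1", call. = FALSE)
  }
  rng <- range(img[, , 1:3])
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  out <- weights[1] * img[, , 1] + weights[2] * img[, , 2] +
    weights[3] * img[, , 3]
  matrix(out, nrow = dim(img)[1], ncol = dim(img)[2])
}

#' Rasterize a polygon region to a pixel mask
#'
#' Converts an annotation polygon into the set of pixel centers it covers.
#' A pixel belongs to the mask when its center is strictly inside the
#' polygon under the even-odd rule, or lies on the polygon boundary
#' (inclusive rasterization, which keeps small hand-drawn regions stable).
#'
#' @param polygon Numeric matrix with columns (x, y): ordered vertices in
#'   0-based pixel coordinates. At least three vertices, all inside the
#'   image bounds.
#' @param image_shape Integer vector `c(v, h)`: image rows and columns.
#' @return Logical matrix `v x h`; `TRUE` marks pixels in the region.
#' @export
rasterize_region <- function(polygon, image_shape) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("polygon needs at least 3 (x, y) vertices", call. = FALSE)
  }
  v <- image_shape[1]
  h <- image_shape[2]
  px <- polygon[, 1]
  py <- polygon[, 2]
  if (any(px < 0 | px > h - 1 | py < 0 | py > v - 1)) {
    stop("polygon vertex outside image bounds", call. = FALSE)
  }
  # shoelace area; a degenerate (zero-area) polygon cannot be rasterized
  nv <- nrow(polygon)
  nxt <- c(2:nv, 1L)
  area <- abs(sum(px * py[nxt] - px[nxt] * py)) / 2
  if (area < 1e-12) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }

  X <- matrix(rep(0:(h - 1), each = v), nrow = v)
  Y <- matrix(rep(0:(v - 1), times = h), nrow = v)
  x <- as.vector(X)
  y <- as.vector(Y)
  inside <- logical(length(x))
  boundary <- logical(length(x))
  eps <- 1e-9
  for (e in seq_len(nv)) {
    x1 <- px[e]; y1 <- py[e]
    x2 <- px[nxt[e]]; y2 <- py[nxt[e]]
    # even-odd ray crossing (half-open in y so shared vertices count once)
    crosses <- (y1 > y) != (y2 > y)
    if (any(crosses)) {
      xi <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- inside[crosses]
      flip <- x[crosses] < xi - eps
      inside[crosses] <- xor(hit, flip)
    }
    # on-segment test: zero cross product and within the segment bbox
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on <- abs(cross) <= eps * max(seg_len, 1) &
      x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
      y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
    boundary <- boundary | on
  }
  matrix(inside | boundary, nrow = v, ncol = h)
}

#' Mean intensity over a pixel mask
#'
#' Summarizes the gray values of a region by its arithmetic mean (the
#' default) or its median.
#'
#' @param img Grayscale image matrix.
#' @param mask Logical matrix of the same dimensions, or a two-column
#'   matrix of 0-based (x, y) pixel coordinates.
#' @param stat Region summary: "mean" (default) or "median".
#' @return Scalar summary intensity in \[0, 255\].
#' @export
region_mean <- function(img, mask, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  validate_gray_image(img)
  if (is.logical(mask)) {
    if (!all(dim(mask) == dim(img))) {
      stop("mask dimensions must match the image", call. = FALSE)
    }
    vals <- img[mask]
  } else {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L) {
      stop("coordinate mask must have two columns (x, y)", call. = FALSE)
    }
    if (any(mask[, 1] < 0 | mask[, 1] > ncol(img) - 1 |
            mask[, 2] < 0 | mask[, 2] > nrow(img) - 1)) {
      stop("mask coordinates outside image bounds", call. = FALSE)
    }
    vals <- img[cbind(mask[, 2] + 1L, mask[, 1] + 1L)]
  }
  if (length(vals) == 0L) {
    stop("empty region mask", call. = FALSE)
  }
  if (stat == "mean") mean(vals) else stats::median(vals)
}

#' Build a lesion/healthy region pair
#'
#' Bundles the two annotated regions every contrast score needs: the lesion
#' region and a disjoint healthy-tissue region, each given as a polygon in
#' 0-based (x, y) pixel coordinates and rasterized to pixel masks.
#'
#' @param lesion_polygon,healthy_polygon Two-column (x, y) vertex matrices.
#' @param image_shape `c(v, h)` rows and columns of the annotated image.
#' @return Object of class `region_pair`: list with logical matrices
#'   `lesion_mask` and `healthy_mask` plus the source polygons.
#' @export
region_pair <- function(lesion_polygon, healthy_polygon, image_shape) {
  lm <- rasterize_region(lesion_polygon, image_shape)
  hm <- rasterize_region(healthy_polygon, image_shape)
  if (!any(lm) || !any(hm)) {
    stop("lesion and healthy regions must each be nonempty", call. = FALSE)
  }
  if (any(lm & hm)) {
    stop("lesion and healthy regions must be disjoint", call. = FALSE)
  }
  structure(
    list(lesion_mask = lm, healthy_mask = hm,
         lesion_polygon = as.matrix(lesion_polygon),
         healthy_polygon = as.matrix(healthy_polygon)),
    class = "region_pair"
  )
}

#' Read an image file as 0-255 intensities
#'
#' Reads 8-bit PNG or TIFF, grayscale or RGB. Grayscale files come back as
#' a `v x h` matrix, RGB files as a `v x h x 3` array, both on the 0-255
#' scale expected by the scoring functions.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or `v x h x 3` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  raw <- raw * 255
  if (length(dim(raw)) == 2L) {
    return(raw)
  }
  nchan <- dim(raw)[3]
  if (nchan == 1L) {
    return(raw[, , 1])
  }
  raw[, , 1:3, drop = FALSE]
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are rounded to the nearest 8-bit level on write; scoring on
#' files therefore sees quantized values, while in-memory workflows keep
#' full precision.
#'
#' @param img Grayscale image matrix (0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_gray_image(img)
  png::writePNG(round(img) / 255, path)
  invisible(path)
}

#' Read a region-annotation JSON file
#'
#' Annotation files carry one polygon per region:
#' `{"lesion": [[x, y], ...], "healthy": [[x, y], ...]}` in 0-based pixel
#' coordinates.
#'
#' @param path Path to the JSON annotation file.
#' @param image_shape `c(v, h)` of the annotated image.
#' @return A [region_pair()] object.
#' @export
read_regions <- function(path, image_shape) {
  ann <- jsonlite::fromJSON(path)
  if (is.null(ann$lesion) || is.null(ann$healthy)) {
    stop("annotation file must contain 'lesion' and 'healthy' polygons",
         call. = FALSE)
  }
  region_pair(ann$lesion, ann$healthy, image_shape)
}

#' Write a region-annotation JSON file
#'
#' @param regions A [region_pair()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_pair"))
  obj <- list(lesion = unname(regions$lesion_polygon),
              healthy = unname(regions$healthy_polygon))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
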