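# Synthetic stained-mucosa patch generator.
#
# Real stained-patch photographs were never deposited, so the pipeline is
# exercised on generated images: a correlated Gaussian texture field on a
# uniform mucosa background, an elliptical lesion with its own dye uptake,
# additive sensor noise, and a dose-response model in which both the
# lesion/background contrast and the texture amplitude respond unimodally
# to dye concentration with a configurable planted optimum.

#' Unimodal dose-response curve
#'
#' A gamma-shaped bump `((c/c_star) * exp(1 - c/c_star))^shape`: zero at
#' concentration 0, unique maximum of 1 at `c_star`, decaying beyond it.
#' The `shape` exponent controls how fast the response collapses once the
#' tissue oversaturates past the optimum.
#'
#' @param conc Concentration(s), in percent.
#' @param c_star Optimal concentration (percent).
#' @param shape Oversaturation shape exponent (> 0).
#' @return Response value(s) in \[0, 1\].
#' @export
dose_response <- function(conc, c_star, shape = 2) {
  stopifnot(c_star > 0, shape > 0)
  r <- conc / c_star
  ifelse(conc <= 0, 0, (r * exp(1 - r))^shape)
}

#' Stain dose-response model
#'
#' Describes how a dye changes the synthetic image as a function of
#' concentration: a saturating darkening of healthy mucosa, an additional
#' unimodal darkening of lesion tissue peaking at the planted optimum
#' `c_star`, and a unimodal gain on the texture-field amplitude also
#' peaking at `c_star`. At concentration 0 the texture gain is 1 and the
#' only lesion/healthy difference is the dye-free baseline offset.
#'
#' The planted effect sizes are expressed as relative increases, so the
#' expected contrast score at `c_star` is `(1 + contrast_gain)` times the
#' unstained baseline, and the expected texture-variance score is roughly
#' `(1 + texture_var_gain)` times the unstained score.
#'
#' @param c_star Planted optimal concentration (percent).
#' @param contrast_gain Relative contrast increase at the optimum (e.g.
#'   2.05 plants a ~205 percent increase over unstained).
#' @param texture_var_gain Relative texture-variance increase at the
#'   optimum (applied to the squared texture amplitude).
#' @param oversaturation_shape Shape exponent of [dose_response()];
#'   larger values collapse the response faster past `c_star`.
#' @param lesion_baseline Gray-level offset of unstained lesion tissue
#'   below healthy tissue (the contrast baseline; must be > 0 for percent
#'   increases to be defined).
#' @param healthy_max_shift Maximum darkening of healthy mucosa at high
#'   concentration (gray levels).
#' @param healthy_half_sat Concentration at which healthy darkening
#'   reaches half its maximum.
#' @return Object of class `stain_response_model`.
#' @export
stain_response_model <- function(c_star = 0.4,
                                 contrast_gain = 2.05,
                                 texture_var_gain = 1.25,
                                 oversaturation_shape = 2,
                                 lesion_baseline = 12,
                                 healthy_max_shift = 30,
                                 healthy_half_sat = 0.3) {
  stopifnot(c_star > 0, lesion_baseline > 0, healthy_max_shift >= 0)
  structure(
    list(c_star = c_star,
         contrast_gain = contrast_gain,
         texture_var_gain = texture_var_gain,
         oversaturation_shape = oversaturation_shape,
         lesion_baseline = lesion_baseline,
         healthy_max_shift = healthy_max_shift,
         healthy_half_sat = healthy_half_sat),
    class = "stain_response_model"
  )
}

#' Healthy-mucosa intensity shift at a concentration
#' @param model A [stain_response_model()].
#' @param conc Concentration(s) in percent.
#' @return Signed gray-level shift(s) (negative = darkening).
#' @export
healthy_uptake <- function(model, conc) {
  -model$healthy_max_shift * conc / (conc + model$healthy_half_sat)
}

#' Lesion-tissue intensity shift at a concentration
#' @inheritParams healthy_uptake
#' @return Signed gray-level shift(s).
#' @export
lesion_uptake <- function(model, conc) {
  healthy_uptake(model, conc) - model$lesion_baseline -
    model$lesion_baseline * model$contrast_gain *
      dose_response(conc, model$c_star, model$oversaturation_shape)
}

#' Texture-amplitude gain at a concentration
#'
#' Multiplier on the texture-field amplitude; its square is the planted
#' gain on the texture-variance score, `1 + texture_var_gain * f(c)`.
#'
#' @inheritParams healthy_uptake
#' @return Gain(s) >= 1, equal to 1 at concentration 0.
#' @export
texture_gain <- function(model, conc) {
  sqrt(1 + model$texture_var_gain *
         dose_response(conc, model$c_star, model$oversaturation_shape))
}

#' Default stain model for a dye and stomach region
#'
#' Encodes the study conditions the generator emulates: an absorptive
#' (methylene-blue-like) dye whose texture enhancement peaks at 0.4
#' percent in both regions, and a contrast (indigo-carmine-like) dye
#' whose lesion contrast peaks at 0.2 percent in the fundus and 0.6
#' percent in the pylorus, with planted relative increases of 105/120
#' percent (texture, fundus/pylorus) and 469/205 percent (contrast,
#' fundus/pylorus). These are generator settings defining the synthetic
#' ground truth, not measurements.
#'
#' @param stain `"methylene_blue"` or `"indigo_carmine"`.
#' @param region `"fundus"` or `"pylorus"`.
#' @return A [stain_response_model()].
#' @export
default_stain_model <- function(stain = c("methylene_blue", "indigo_carmine"),
                                region = c("fundus", "pylorus")) {
  stain <- match.arg(stain)
  region <- match.arg(region)
  if (stain == "methylene_blue") {
    stain_response_model(
      c_star = 0.4,
      contrast_gain = 0,
      texture_var_gain = if (region == "pylorus") 1.25 else 1.10
    )
  } else {
    stain_response_model(
      c_star = if (region == "fundus") 0.2 else 0.6,
      contrast_gain = if (region == "fundus") 4.69 else 2.05,
      texture_var_gain = 0
    )
  }
}

#' Synthetic-patch generator parameters
#'
#' @param image_size `c(v, h)` rows and columns; default 256 x 256, large
#'   enough for the default texture radii up to 50 px.
#' @param base_intensity Background mucosa gray level.
#' @param texture_correlation_length Gaussian smoothing length (pixels) of
#'   the mucosal texture field.
#' @param texture_amplitude Standard deviation (gray levels) of the
#'   texture field at concentration 0.
#' @param lesion_type `"none"` (plain mucosa), `"flat_depressed"`
#'   (0-IIc-like uniform depressed patch) or `"raised"` (0-Ip-like dome
#'   profile).
#' @param lesion_center 0-based `(x, y)` ellipse center; default scales
#'   with the image.
#' @param lesion_axes Ellipse semi-axes `(a_x, a_y)` in pixels; default
#'   scales with the image.
#' @param noise_sd Additive Gaussian sensor-noise standard deviation.
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size = c(256L, 256L),
                             base_intensity = 170,
                             texture_correlation_length = 3,
                             texture_amplitude = 10,
                             lesion_type = c("none", "flat_depressed",
                                             "raised"),
                             lesion_center = NULL,
                             lesion_axes = NULL,
                             noise_sd = 2) {
  lesion_type <- match.arg(lesion_type)
  v <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  stopifnot(v >= 8L, h >= 8L, noise_sd >= 0, texture_amplitude >= 0,
            texture_correlation_length > 0)
  if (is.null(lesion_center)) lesion_center <- c(0.375 * (h - 1), 0.5 * (v - 1))
  if (is.null(lesion_axes)) lesion_axes <- c(0.175 * h, 0.115 * v)
  if (lesion_type != "none") {
    if (lesion_center[1] - lesion_axes[1] < 0 ||
        lesion_center[1] + lesion_axes[1] > h - 1 ||
        lesion_center[2] - lesion_axes[2] < 0 ||
        lesion_center[2] + lesion_axes[2] > v - 1) {
      stop("lesion geometry extends outside image bounds", call. = FALSE)
    }
  }
  structure(
    list(image_size = c(v, h),
         base_intensity = base_intensity,
         texture_correlation_length = texture_correlation_length,
         texture_amplitude = texture_amplitude,
         lesion_type = lesion_type,
         lesion_center = lesion_center,
         lesion_axes = lesion_axes,
         noise_sd = noise_sd),
    class = "synthetic_params"
  )
}

# banded row-normalized Gaussian smoothing matrix (n x n), memoized
.smooth_cache <- new.env(parent = emptyenv())

.smoothing_matrix <- function(n, ell) {
  key <- paste(n, ell, sep = "_")
  if (!is.null(.smooth_cache[[key]])) {
    return(.smooth_cache[[key]])
  }
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * ell^2)))
  K[K < 1e-12] <- 0
  K <- K / rowSums(K)
  .smooth_cache[[key]] <- K
  K
}

# correlated zero-mean texture field with unit standard deviation
.texture_field <- function(v, h, ell) {
  Z <- matrix(stats::rnorm(v * h), v, h)
  Kv <- .smoothing_matrix(v, ell)
  Kh <- .smoothing_matrix(h, ell)
  F <- Kv %*% Z %*% t(Kh)
  # interior variance of smoothed unit noise under a separable kernel
  s <- sqrt(sum(Kv[ceiling(v / 2), ]^2) * sum(Kh[ceiling(h / 2), ]^2))
  F <- F / s
  F - mean(F)
}

# 32-gon approximation of the lesion ellipse, kept inside image bounds
.lesion_polygon <- function(params) {
  th <- 2 * pi * (0:31) / 32
  cx <- params$lesion_center[1]; cy <- params$lesion_center[2]
  x <- cx + params$lesion_axes[1] * cos(th)
  y <- cy + params$lesion_axes[2] * sin(th)
  h <- params$image_size[2]; v <- params$image_size[1]
  cbind(pmin(pmax(x, 0), h - 1), pmin(pmax(y, 0), v - 1))
}

# healthy-reference rectangle on the right side of the patch, away from
# the lesion ellipse
.healthy_polygon <- function(params) {
  v <- params$image_size[1]; h <- params$image_size[2]
  x0 <- params$lesion_center[1] + params$lesion_axes[1] + 0.05 * h
  x1 <- h - 1 - 0.04 * h
  y0 <- 0.15 * v
  y1 <- v - 1 - 0.15 * v
  if (x1 - x0 < 4) {
    stop("image too small to place a healthy reference region", call. = FALSE)
  }
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

#' Deterministic per-patch seed from a master seed
#'
#' Folds the master seed with the design-cell labels (stain, region,
#' concentration, replicate) so every patch gets a reproducible,
#' order-independent RNG seed below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param stain,region Character labels.
#' @param conc Concentration in percent.
#' @param replicate Replicate id.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, stain, region, conc, replicate) {
  key <- paste(master_seed, stain, region, format(conc, nsmall = 4),
               replicate, sep = "|")
  bytes <- utf8ToInt(key)
  m <- 2147483647
  hsh <- 0
  for (b in bytes) {
    hsh <- (hsh * 31 + b) %% m
  }
  as.integer(hsh)
}

#' Generate one synthetic stained-mucosa patch
#'
#' Builds the image as base intensity + correlated texture field scaled by
#' the concentration-dependent texture gain + region-specific dye uptake
#' (healthy shift everywhere, lesion shift inside the planted ellipse) +
#' Gaussian sensor noise, clipped to \[0, 255\]. Ground-truth lesion and
#' healthy annotation regions are returned alongside the image. Output is
#' fully determined by the seed and the arguments.
#'
#' @param params A [synthetic_params()].
#' @param model A [stain_response_model()].
#' @param stain Stain label stored in the record.
#' @param concentration Dye concentration in percent (>= 0).
#' @param region Anatomical region label (`"fundus"` or `"pylorus"`).
#' @param replicate_id Replicate identifier.
#' @param seed Integer RNG seed for this patch.
#' @return Object of class `patch_record`: list with `image` (grayscale
#'   matrix), `regions` (a [region_pair()], or `NULL` when
#'   `lesion_type = "none"`), and the metadata fields.
#' @export
generate_patch <- function(params, model, stain = "methylene_blue",
                           concentration = 0, region = "fundus",
                           replicate_id = 1L, seed = 1L) {
  stopifnot(inherits(params, "synthetic_params"),
            inherits(model, "stain_response_model"),
            concentration >= 0)
  v <- params$image_size[1]; h <- params$image_size[2]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  img <- matrix(params$base_intensity, v, h)
  if (params$texture_amplitude > 0) {
    amp <- params$texture_amplitude * texture_gain(model, concentration)
    img <- img + amp * .texture_field(v, h, params$texture_correlation_length)
  }
  img <- img + healthy_uptake(model, concentration)

  regions <- NULL
  if (params$lesion_type != "none") {
    lp <- .lesion_polygon(params)
    hp <- .healthy_polygon(params)
    regions <- region_pair(lp, hp, c(v, h))
    delta <- lesion_uptake(model, concentration) -
      healthy_uptake(model, concentration)
    if (params$lesion_type == "flat_depressed") {
      img[regions$lesion_mask] <- img[regions$lesion_mask] + delta
    } else {
      # raised dome: offset strongest at the lesion center, zero at the rim
      X <- matrix(rep(0:(h - 1), each = v), v, h)
      Y <- matrix(rep(0:(v - 1), times = h), v, h)
      r2 <- ((X - params$lesion_center[1]) / params$lesion_axes[1])^2 +
        ((Y - params$lesion_center[2]) / params$lesion_axes[2])^2
      prof <- pmax(1 - r2, 0)
      img <- img + delta * prof
    }
  }
  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(v * h, sd = params$noise_sd), v, h)
  }
  img <- pmin(pmax(img, 0), 255)

  structure(
    list(image = img,
         regions = regions,
         stain = stain,
         concentration = concentration,
         region = region,
         replicate_id = replicate_id,
         seed = as.integer(seed),
         params = params,
         model = model),
    class = "patch_record"
  )
}

#' @export
print.patch_record <- function(x, ...) {
  cat(sprintf(
    "Synthetic patch: %s %.1f%% (%s, replicate %s), %d x %d px, %s lesion\n",
    x$stain, x$concentration, x$region, x$replicate_id,
    nrow(x$image), ncol(x$image), x$params$lesion_type))
  invisible(x)
}
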