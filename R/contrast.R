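#' Lesion-to-background contrast score
#'
#' The contrast score is the difference between the summary gray value of
#' the lesion region and that of the healthy region,
#' `I_c = g(R_l) - g(R_h)`, where `g` of a region is its mean gray value
#' (median available as an option). On an 8-bit image the score magnitude
#' lies between 0 and 255: small values mean the lesion barely stands out
#' from the surrounding mucosa, large values mean high contrast. By default
#' the absolute value is reported, so dark-on-light and light-on-dark
#' lesions score alike; the signed difference is always retained in the
#' result.
#'
#' @param img Grayscale image matrix (0-255); RGB arrays are converted via
#'   [to_grayscale()].
#' @param regions A [region_pair()] with disjoint lesion and healthy masks.
#' @param absolute Report `|I_c|` (default `TRUE`) or the signed value.
#' @param stat Region summary passed to [region_mean()]: "mean" or "median".
#' @param weights Grayscale conversion weights, used only for RGB input.
#' @return Object of class `contrast_result`: list with elements `I_c`
#'   (the reported score), `signed` (lesion mean minus healthy mean),
#'   `lesion_mean`, `healthy_mean`, and `absolute` (whether `|.|` was
#'   applied).
#' @examples
#' img <- matrix(40, 8, 8)
#' img[2:4, 2:4] <- 100
#' rp <- region_pair(rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3)),
#'                   rbind(c(5, 5), c(7, 5), c(7, 7), c(5, 7)),
#'                   c(8, 8))
#' contrast_score(img, rp)$I_c  # 60
#' @export
contrast_score <- function(img, regions, absolute = TRUE,
                           stat = c("mean", "median"),
                           weights = c(0.299, 0.587, 0.114)) {
  stat <- match.arg(stat)
  if (!is.matrix(img)) {
    img <- to_grayscale(img, weights)
  }
  if (!inherits(regions, "region_pair")) {
    stop("'regions' must be a region_pair object", call. = FALSE)
  }
  lm <- region_mean(img, regions$lesion_mask, stat)
  hm <- region_mean(img, regions$healthy_mask, stat)
  signed <- lm - hm
  structure(
    list(I_c = if (absolute) abs(signed) else signed,
         signed = signed,
         lesion_mean = lm,
         healthy_mean = hm,
         absolute = absolute),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "Lesion-to-background contrast I_c = %.3f (lesion %.3f, healthy %.3f%s)\n",
    x$I_c, x$lesion_mean, x$healthy_mean,
    if (x$absolute) ", absolute" else ", signed"))
  invisible(x)
}
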