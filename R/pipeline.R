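# Concentration-series analysis: score each patch with the arm's score,
# average replicates per concentration, locate the peak of the series, and
# report the percent increase of the peak over unstained tissue.

#' Average scores per concentration
#'
#' @param scores Data frame with columns `concentration` and `score` (one
#'   row per replicate patch).
#' @return Data frame with one row per concentration, in increasing grid
#'   order: concentration, mean_score, sd_score, n.
#' @export
aggregate_scores <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("no scores to aggregate", call. = FALSE)
  }
  conc <- sort(unique(scores$concentration))
  out <- data.frame(
    concentration = conc,
    mean_score = vapply(conc, function(cc) {
      mean(scores$score[scores$concentration == cc])
    }, numeric(1)),
    sd_score = vapply(conc, function(cc) {
      stats::sd(scores$score[scores$concentration == cc])
    }, numeric(1)),
    n = vapply(conc, function(cc) {
      sum(scores$concentration == cc)
    }, integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Locate the optimal concentration of a series
#'
#' The optimum is the grid point with the maximal mean score - the series
#' is discrete and no interpolation between grid points is attempted. Ties
#' are broken toward the lowest concentration (the least dye that achieves
#' the maximal score) and flagged.
#'
#' @param summary Data frame from [aggregate_scores()], or a named numeric
#'   vector of per-concentration means.
#' @return List with `concentration`, `mean_score`, and `tie` (TRUE when
#'   the maximum is not unique).
#' @export
find_optimal_concentration <- function(summary) {
  if (is.numeric(summary) && !is.null(names(summary))) {
    summary <- data.frame(concentration = as.numeric(names(summary)),
                          mean_score = as.numeric(summary))
  }
  if (nrow(summary) < 2L) {
    stop("need at least two concentrations to locate an optimum",
         call. = FALSE)
  }
  o <- order(summary$concentration)
  conc <- summary$concentration[o]
  ms <- summary$mean_score[o]
  top <- max(ms)
  hits <- which(ms >= top)
  list(concentration = conc[hits[1]],
       mean_score = top,
       tie = length(hits) > 1L)
}

#' Percent increase of the peak score over unstained tissue
#'
#' @param optimal_mean Mean score at the optimal concentration.
#' @param unstained_mean Mean score of the unstained (concentration 0)
#'   patches; must be positive.
#' @return `100 * (optimal_mean - unstained_mean) / unstained_mean`.
#' @examples
#' percent_increase(22, 10)  # 120
#' @export
percent_increase <- function(optimal_mean, unstained_mean) {
  if (!is.finite(unstained_mean) || unstained_mean <= 0) {
    stop("unstained baseline score must be positive", call. = FALSE)
  }
  100 * (optimal_mean - unstained_mean) / unstained_mean
}

#' Score one patch
#'
#' Applies the requested staining-quality score to a patch: the
#' lesion-to-background contrast (needs region annotations) or the
#' multi-radius texture variance.
#'
#' @param image Grayscale matrix or RGB array.
#' @param score `"contrast"` or `"texture"`.
#' @param regions A [region_pair()]; required for the contrast score.
#' @param radii,N Texture-score neighborhood settings.
#' @param absolute,stat Contrast-score settings (see [contrast_score()]).
#' @param weights Grayscale conversion weights for RGB input.
#' @return Scalar score.
#' @export
score_patch <- function(image, score = c("contrast", "texture"),
                        regions = NULL, radii = c(10, 20, 30, 40, 50),
                        N = 8L, absolute = TRUE, stat = "mean",
                        weights = c(0.299, 0.587, 0.114)) {
  score <- match.arg(score)
  if (score == "contrast") {
    if (is.null(regions)) {
      stop("the contrast score needs lesion/healthy region annotations",
           call. = FALSE)
    }
    contrast_score(image, regions, absolute = absolute, stat = stat,
                   weights = weights)$I_c
  } else {
    multi_radius_score(image, radii = radii, N = N, weights = weights)$averaged
  }
}

# turn a manifest row into an in-memory record
.load_manifest_row <- function(row) {
  if (!file.exists(row$image)) {
    stop("cannot read image file: ", row$image, call. = FALSE)
  }
  img <- read_image(row$image)
  if (!is.matrix(img)) img <- to_grayscale(img)
  regions <- NULL
  if (!is.na(row$annotation) && nzchar(row$annotation)) {
    regions <- read_regions(row$annotation, dim(img))
  }
  list(image = img, regions = regions, stain = row$stain,
       concentration = row$concentration, region = row$region,
       replicate_id = row$replicate)
}

#' Score every patch of a design and analyze the concentration series
#'
#' The end-to-end analysis: each patch is scored with its arm's score
#' (contrast for lesion/contrast-dye arms, texture variance for
#' mucosa/absorptive-dye arms), replicate scores are averaged per
#' concentration, the peak of each series is located, and the percent
#' increase of the peak over the unstained baseline (concentration 0 of
#' the same arm) is computed.
#'
#' @param records List of `patch_record` objects from [generate_design()],
#'   or the path to a manifest CSV whose images and annotations are read
#'   from disk.
#' @param design The [experiment_design()] the records instantiate.
#' @param radii,N,absolute,stat,weights Scoring settings, see
#'   [score_patch()].
#' @return Object of class `concentration_analysis`: list with
#'   * `scores`: long data frame (stain, region, concentration,
#'     replicate, score), one row per patch;
#'   * `arms`: per-arm list with the aggregated summary table, the
#'     optimum (`concentration`, `mean_score`, `tie`), the unstained mean
#'     and `percent_increase` (NA, flagged, when the arm has a single
#'     concentration or no unstained baseline).
#' @export
run_pipeline <- function(records, design, radii = c(10, 20, 30, 40, 50),
                         N = 8L, absolute = TRUE, stat = "mean",
                         weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.character(records) && length(records) == 1L) {
    man <- read_manifest(records)
    records <- lapply(seq_len(nrow(man)),
                      function(i) .load_manifest_row(man[i, ]))
  }

  cells <- design_cells(design)
  have <- vapply(records, function(r) {
    paste(r$stain, r$region, r$concentration, r$replicate_id)
  }, character(1))
  want <- with(cells, paste(stain, region, concentration, replicate))
  absent <- setdiff(want, have)
  if (length(absent) > 0L) {
    stop("design cells missing from the records: ",
         paste(utils::head(absent, 5L), collapse = "; "),
         if (length(absent) > 5L) sprintf(" (and %d more)",
                                          length(absent) - 5L),
         call. = FALSE)
  }

  score_of <- stats::setNames(
    cells$score, paste(cells$stain, cells$region))
  long <- data.frame(
    stain = vapply(records, `[[`, character(1), "stain"),
    region = vapply(records, `[[`, character(1), "region"),
    concentration = vapply(records, `[[`, numeric(1), "concentration"),
    replicate = vapply(records, function(r) as.integer(r$replicate_id),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  long$score <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    sc <- score_of[[paste(r$stain, r$region)]]
    score_patch(r$image, sc, regions = r$regions, radii = radii, N = N,
                absolute = absolute, stat = stat, weights = weights)
  }, numeric(1))

  arms <- list()
  for (arm in design) {
    key <- paste(arm$stain, arm$region, sep = ".")
    sub <- long[long$stain == arm$stain & long$region == arm$region, ]
    summ <- aggregate_scores(sub)
    single <- nrow(summ) < 2L
    opt <- if (single) {
      list(concentration = summ$concentration[1],
           mean_score = summ$mean_score[1], tie = FALSE)
    } else {
      find_optimal_concentration(summ)
    }
    has_baseline <- any(summ$concentration == 0)
    unstained <- if (has_baseline) {
      summ$mean_score[summ$concentration == 0]
    } else NA_real_
    pct <- if (!single && has_baseline && is.finite(unstained) &&
               unstained > 0) {
      percent_increase(opt$mean_score, unstained)
    } else NA_real_
    arms[[key]] <- list(
      stain = arm$stain, region = arm$region, score = arm$score,
      summary = summ,
      optimum = opt,
      no_optimum = single,
      unstained_mean = unstained,
      percent_increase = pct
    )
  }
  structure(list(scores = long, arms = arms),
            class = "concentration_analysis")
}

#' @export
print.concentration_analysis <- function(x, ...) {
  cat(sprintf("Concentration analysis: %d patches, %d arms\n",
              nrow(x$scores), length(x$arms)))
  for (a in x$arms) {
    if (a$no_optimum) {
      cat(sprintf("  %s / %s (%s): single concentration, no optimum\n",
                  a$stain, a$region, a$score))
    } else {
      cat(sprintf(
        "  %s / %s (%s): optimum %.1f%% (mean score %.3f%s)%s\n",
        a$stain, a$region, a$score, a$optimum$concentration,
        a$optimum$mean_score,
        if (a$optimum$tie) ", tied" else "",
        if (is.finite(a$percent_increase))
          sprintf(", +%.1f%% over unstained", a$percent_increase) else ""))
    }
  }
  invisible(x)
}

#' Write the analysis report
#'
#' Emits the long per-patch score table as CSV and the per-arm summary
#' (per-concentration means, optimum, percent increase) as JSON.
#'
#' @param analysis A `concentration_analysis` from [run_pipeline()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `analysis`, invisibly.
#' @export
write_report <- function(analysis, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(analysis, "concentration_analysis"))
  if (!is.null(csv_path)) {
    utils::write.csv(analysis$scores, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- lapply(analysis$arms, function(a) {
      list(stain = a$stain, region = a$region, score = a$score,
           concentrations = a$summary$concentration,
           mean_scores = a$summary$mean_score,
           sd_scores = a$summary$sd_score,
           n = a$summary$n,
           optimal_concentration =
             if (a$no_optimum) NULL else a$optimum$concentration,
           optimal_mean_score =
             if (a$no_optimum) NULL else a$optimum$mean_score,
           tie = isTRUE(a$optimum$tie),
           no_optimum = a$no_optimum,
           unstained_mean = a$unstained_mean,
           percent_increase = a$percent_increase)
    })
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(analysis)
}

#' Read a generator/scoring configuration file
#'
#' Configurations are plain YAML or JSON mappings; recognized keys mirror
#' the arguments of [synthetic_params()], [stain_response_model()] and the
#' scoring functions (`radii`, `N`, `grayscale_weights`, ...). Unknown
#' keys are kept so callers can carry their own settings.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be YAML or JSON", call. = FALSE)
  }
}
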