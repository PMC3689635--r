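# Experimental designs: which dye, which stomach region, which
# concentration grid, how many replicate patches per grid point, and which
# score judges that arm (contrast for the lesion dye, texture variance for
# the mucosa dye).

#' One arm of a staining experiment
#'
#' An arm fixes the dye, the anatomical region, the concentration grid
#' (including 0 for unstained tissue when a percent increase over
#' unstained is wanted), the replicate count per concentration, and the
#' score used to judge staining quality in that arm.
#'
#' @param stain Stain label, e.g. `"indigo_carmine"`.
#' @param region Anatomical region, `"fundus"` or `"pylorus"`.
#' @param concentrations Strictly increasing concentration grid (percent).
#' @param replicates Patches per concentration (>= 1).
#' @param score `"contrast"` or `"texture"`.
#' @return Object of class `design_arm`.
#' @export
design_arm <- function(stain, region, concentrations, replicates = 5L,
                       score = c("contrast", "texture")) {
  score <- match.arg(score)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (length(concentrations) < 1L || any(concentrations < 0) ||
      is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentration grid must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(stain = stain, region = region,
         concentrations = concentrations,
         replicates = replicates, score = score),
    class = "design_arm"
  )
}

#' Experiment design: a set of arms
#'
#' @param ... [design_arm()] objects.
#' @return Object of class `experiment_design` (list of arms).
#' @export
experiment_design <- function(...) {
  arms <- list(...)
  if (length(arms) == 1L && is.list(arms[[1]]) &&
      !inherits(arms[[1]], "design_arm")) {
    arms <- arms[[1]]
  }
  if (!all(vapply(arms, inherits, logical(1), "design_arm"))) {
    stop("all components must be design_arm objects", call. = FALSE)
  }
  keys <- vapply(arms, function(a) paste(a$stain, a$region), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (stain, region) arm", call. = FALSE)
  }
  structure(arms, class = "experiment_design")
}

#' Lesion-contrast design: indigo-carmine concentration series
#'
#' Both stomach regions, concentrations 0 (unstained) and 0.2 to 1.6
#' percent in steps of 0.2, five replicate lesion-bearing patches per
#' concentration and region: 9 concentrations x 2 regions x 5 = 90
#' patches, scored by lesion-to-background contrast.
#'
#' @param replicates Patches per concentration and region.
#' @return An [experiment_design()].
#' @export
indigo_design <- function(replicates = 5L) {
  grid <- c(0, seq(0.2, 1.6, by = 0.2))
  experiment_design(
    design_arm("indigo_carmine", "fundus", grid, replicates, "contrast"),
    design_arm("indigo_carmine", "pylorus", grid, replicates, "contrast")
  )
}

#' Mucosa-texture design: methylene-blue concentration series
#'
#' Plain-mucosa patches (no lesion imitations), five replicates per
#' concentration: fundus concentrations 0 and 0.2 to 2.0 percent, pylorus
#' 0 and 0.2 to 1.6 percent, in steps of 0.2 - (11 + 9) x 5 = 100
#' patches, scored by the multi-radius texture variance.
#'
#' @param replicates Patches per concentration and region.
#' @return An [experiment_design()].
#' @export
methylene_design <- function(replicates = 5L) {
  experiment_design(
    design_arm("methylene_blue", "fundus",
               c(0, seq(0.2, 2.0, by = 0.2)), replicates, "texture"),
    design_arm("methylene_blue", "pylorus",
               c(0, seq(0.2, 1.6, by = 0.2)), replicates, "texture")
  )
}

#' Combined staining study design
#'
#' The indigo-carmine contrast series plus the methylene-blue texture
#' series: 90 + 100 = 190 patches in total.
#'
#' @param replicates Patches per concentration and region.
#' @return An [experiment_design()].
#' @export
full_design <- function(replicates = 5L) {
  experiment_design(c(unclass(indigo_design(replicates)),
                      unclass(methylene_design(replicates))))
}

#' Enumerate the patches of a design
#'
#' @param design An [experiment_design()].
#' @return Data frame with one row per patch: stain, region, score,
#'   concentration, replicate.
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  rows <- lapply(design, function(arm) {
    expand.grid(replicate = seq_len(arm$replicates),
                concentration = arm$concentrations,
                KEEP.OUT.ATTRS = FALSE)[, 2:1]
  })
  out <- do.call(rbind, Map(function(arm, df) {
    data.frame(stain = arm$stain, region = arm$region, score = arm$score,
               concentration = df$concentration, replicate = df$replicate,
               stringsAsFactors = FALSE)
  }, design, rows))
  rownames(out) <- NULL
  key <- with(out, paste(stain, region, concentration, replicate))
  if (anyDuplicated(key)) {
    stop("duplicate (cell, replicate) in design", call. = FALSE)
  }
  out
}

#' Generate every patch of a design
#'
#' Instantiates the synthetic patches of a full design, one per
#' (stain, region, concentration, replicate) cell, with per-patch seeds
#' derived deterministically from a master seed. Optionally writes the
#' images (PNG), annotation JSONs and a manifest CSV to a directory.
#'
#' @param design An [experiment_design()].
#' @param params A [synthetic_params()], or a function
#'   `function(stain, region, score)` returning one per arm. By default,
#'   contrast-scored arms get flat-depressed lesion patches and
#'   texture-scored arms plain mucosa.
#' @param model A [stain_response_model()], or a function
#'   `function(stain, region)` returning one per arm; defaults to
#'   [default_stain_model()].
#' @param master_seed Master seed for [derive_seed()].
#' @param dir Optional output directory for PNGs, annotation JSONs and
#'   `manifest.csv`.
#' @return List of [generate_patch()] records; if `dir` is given, the
#'   manifest data frame is attached as attribute `manifest`.
#' @export
generate_design <- function(design, params = NULL, model = NULL,
                            master_seed = 1L, dir = NULL) {
  cells <- design_cells(design)
  if (is.null(params)) {
    params <- function(stain, region, score) {
      synthetic_params(lesion_type =
                         if (score == "contrast") "flat_depressed" else "none")
    }
  }
  if (inherits(params, "synthetic_params")) {
    p_fixed <- params
    params <- function(stain, region, score) p_fixed
  }
  if (is.null(model)) {
    model <- function(stain, region) default_stain_model(stain, region)
  }
  if (inherits(model, "stain_response_model")) {
    m_fixed <- model
    model <- function(stain, region) m_fixed
  }

  records <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    records[[i]] <- generate_patch(
      params(cl$stain, cl$region, cl$score),
      model(cl$stain, cl$region),
      stain = cl$stain,
      concentration = cl$concentration,
      region = cl$region,
      replicate_id = cl$replicate,
      seed = derive_seed(master_seed, cl$stain, cl$region,
                         cl$concentration, cl$replicate)
    )
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- write_design(records, dir)
    attr(records, "manifest") <- manifest
  }
  records
}

#' Write generated patches to disk with a manifest
#'
#' @param records List of `patch_record` objects.
#' @param dir Output directory.
#' @return The manifest data frame (also written as `manifest.csv`).
#' @export
write_design <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(records)
  img_path <- character(n)
  ann_path <- character(n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    stem <- sprintf("%s_%s_c%04.1f_r%02d", r$stain, r$region,
                    r$concentration, as.integer(r$replicate_id))
    img_path[i] <- file.path(dir, paste0(stem, ".png"))
    write_image(r$image, img_path[i])
    if (!is.null(r$regions)) {
      ann_path[i] <- file.path(dir, paste0(stem, ".json"))
      write_regions(r$regions, ann_path[i])
    } else {
      ann_path[i] <- ""
    }
  }
  manifest <- data.frame(
    image = img_path,
    annotation = ann_path,
    stain = vapply(records, `[[`, character(1), "stain"),
    concentration = vapply(records, `[[`, numeric(1), "concentration"),
    region = vapply(records, `[[`, character(1), "region"),
    replicate = vapply(records, function(r) as.integer(r$replicate_id),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a manifest CSV
#'
#' @param path Path to a manifest CSV with columns image, annotation,
#'   stain, concentration, region, replicate.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image", "annotation", "stain", "concentration", "region",
              "replicate")
  missing <- setdiff(needed, names(man))
  if (length(missing) > 0L) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  man
}
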