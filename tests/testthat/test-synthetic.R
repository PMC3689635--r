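small_params <- function(lesion = "flat_depressed", ...) {
  synthetic_params(image_size = c(96, 96), lesion_type = lesion, ...)
}

test_that("dose-response curve is zero at 0, peaks at c_star, then decays", {
  grid <- seq(0, 2, by = 0.2)
  f <- dose_response(grid, c_star = 0.4)
  expect_equal(f[1], 0)
  expect_equal(max(f), 1)
  expect_equal(grid[which.max(f)], 0.4)
  after <- f[grid >= 0.4]
  expect_true(all(diff(after) < 0))
  before <- f[grid <= 0.4]
  expect_true(all(diff(before) > 0))
})

test_that("stain model honors its boundary conditions", {
  m <- stain_response_model(c_star = 0.6, contrast_gain = 2.05,
                            texture_var_gain = 1.25)
  expect_equal(texture_gain(m, 0), 1)
  expect_equal(healthy_uptake(m, 0), 0)
  expect_equal(lesion_uptake(m, 0), -m$lesion_baseline)
  grid <- seq(0, 2, by = 0.2)
  sep <- abs(lesion_uptake(m, grid) - healthy_uptake(m, grid))
  expect_equal(grid[which.max(sep)], 0.6)
  tg <- texture_gain(m, grid)
  expect_equal(grid[which.max(tg)], 0.6)
  # planted relative contrast increase at the optimum
  expect_equal(max(sep) / sep[1] - 1, 2.05)
})

test_that("patch generation is deterministic for a fixed seed", {
  p1 <- generate_patch(small_params(), default_stain_model("indigo_carmine"),
                       "indigo_carmine", 0.4, "fundus", 1, seed = 123)
  p2 <- generate_patch(small_params(), default_stain_model("indigo_carmine"),
                       "indigo_carmine", 0.4, "fundus", 1, seed = 123)
  expect_identical(p1$image, p2$image)
  p3 <- generate_patch(small_params(), default_stain_model("indigo_carmine"),
                       "indigo_carmine", 0.4, "fundus", 1, seed = 124)
  expect_false(identical(p1$image, p3$image))
})

test_that("patch generation does not disturb the session RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_patch(small_params(), default_stain_model(),
                           seed = 5L))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("degenerate generator settings give a flat image plus lesion offset", {
  params <- small_params(noise_sd = 0)
  params$texture_amplitude <- 0
  model <- default_stain_model("indigo_carmine", "fundus")
  p <- generate_patch(params, model, "indigo_carmine", 0, "fundus", 1, 1)
  healthy_vals <- unique(p$image[!p$regions$lesion_mask])
  expect_equal(healthy_vals, params$base_intensity)
  lesion_vals <- unique(p$image[p$regions$lesion_mask])
  expect_equal(lesion_vals, params$base_intensity - model$lesion_baseline)
})

test_that("with zero uptake the image mean stays at the base intensity", {
  model <- stain_response_model(contrast_gain = 0, texture_var_gain = 0,
                                healthy_max_shift = 0, lesion_baseline = 1e-9)
  params <- small_params("none")
  params$texture_amplitude <- 0
  for (s in 1:5) {
    p <- generate_patch(params, model, "none_stain", 0.4, "fundus", 1, s)
    tol <- 3 * params$noise_sd / sqrt(prod(params$image_size))
    expect_lt(abs(mean(p$image) - params$base_intensity), tol)
  }
})

test_that("contrast at the planted optimum beats unstained across seeds", {
  model <- default_stain_model("indigo_carmine", "fundus")
  wins <- 0L
  for (s in 1:20) {
    p_star <- generate_patch(small_params(), model, "indigo_carmine",
                             model$c_star, "fundus", 1, seed = s)
    p_0 <- generate_patch(small_params(), model, "indigo_carmine",
                          0, "fundus", 1, seed = s)
    c_star <- contrast_score(p_star$image, p_star$regions)$I_c
    c_0 <- contrast_score(p_0$image, p_0$regions)$I_c
    wins <- wins + (c_star > c_0)
  }
  expect_equal(wins, 20L)
})

test_that("lesion geometry outside the image is rejected", {
  expect_error(
    synthetic_params(image_size = c(64, 64), lesion_type = "flat_depressed",
                     lesion_center = c(60, 32), lesion_axes = c(10, 5)),
    "bounds")
})

test_that("raised lesions get a dome profile, strongest at the center", {
  params <- small_params("raised", noise_sd = 0)
  params$texture_amplitude <- 0
  model <- default_stain_model("indigo_carmine", "fundus")
  p <- generate_patch(params, model, "indigo_carmine", 0.2, "fundus", 1, 2)
  cx <- round(params$lesion_center[1]); cy <- round(params$lesion_center[2])
  center_val <- p$image[cy + 1, cx + 1]
  rim_val <- p$image[cy + 1, cx + 1 + params$lesion_axes[1] + 2]
  expect_lt(center_val, rim_val)  # dye-darkened dome center
})

test_that("derived per-patch seeds are reproducible and spread out", {
  s1 <- derive_seed(7, "indigo_carmine", "fundus", 0.4, 3)
  s2 <- derive_seed(7, "indigo_carmine", "fundus", 0.4, 3)
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
  cells <- design_cells(full_design())
  seeds <- mapply(derive_seed, 7, cells$stain, cells$region,
                  cells$concentration, cells$replicate)
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("design generation enumerates the printed patch counts", {
  expect_equal(length(generate_design(indigo_design(),
                                      params = quick_params("contrast"),
                                      master_seed = 1)), 90L)
  expect_equal(length(generate_design(methylene_design(),
                                      params = quick_params("texture"),
                                      master_seed = 1)), 100L)
  expect_equal(nrow(design_cells(full_design())), 190L)
})

test_that("design regeneration with one master seed is fully reproducible", {
  d <- indigo_design(replicates = 1L)
  r1 <- generate_design(d, params = quick_params("contrast"), master_seed = 5)
  r2 <- generate_design(d, params = quick_params("contrast"), master_seed = 5)
  expect_identical(lapply(r1, `[[`, "image"), lapply(r2, `[[`, "image"))
  r3 <- generate_design(d, params = quick_params("contrast"), master_seed = 6)
  expect_false(identical(r1[[1]]$image, r3[[1]]$image))
})

test_that("written designs round-trip through the manifest", {
  dir <- withr::local_tempdir()
  d <- experiment_design(
    design_arm("indigo_carmine", "fundus", c(0, 0.2), 2L, "contrast"))
  recs <- generate_design(d, params = quick_params("contrast"),
                          master_seed = 3, dir = dir)
  man <- attr(recs, "manifest")
  expect_equal(nrow(man), 4L)
  expect_true(all(file.exists(man$image)))
  expect_true(all(file.exists(man$annotation)))
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$concentration, man$concentration)
})
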