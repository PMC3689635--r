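spec14 <- neighborhood_spec(1, 4)

test_that("circular sampling reproduces the hand-worked 3x3 example", {
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  # neighbors of the center at R = 1: i=1 below (8), i=2 left (4),
  # i=3 above (2), i=4 right (6) in (x right, y down) coordinates
  expect_equal(sample_neighbors(m, c(1, 1), spec14), c(8, 4, 2, 6))
  p <- lbp_pattern(m, c(1, 1), spec14)
  expect_equal(p$bits, c(1L, 0L, 0L, 1L))
  expect_equal(p$code, 1 + 8)  # weights 2^(i-1)
  expect_equal(local_variance(m, c(1, 1), spec14), 5.0)
})

test_that("constant images give all-ones patterns and zero variance", {
  m <- matrix(42, 7, 7)
  expect_equal(sample_neighbors(m, c(3, 3), neighborhood_spec(2, 8)),
               rep(42, 8))
  expect_equal(lbp_pattern(m, c(3, 3), neighborhood_spec(2, 8))$bits,
               rep(1L, 8))  # threshold maps a zero difference to 1
  expect_equal(local_variance(m, c(3, 3), neighborhood_spec(2, 8)), 0)
  expect_equal(as.numeric(global_texture_variance(m, neighborhood_spec(2, 8))),
               0)
  ms <- multi_radius_score(matrix(9, 128, 128))
  expect_equal(unname(ms$per_radius), rep(0, 5))
  expect_equal(ms$averaged, 0)
})

test_that("off-grid samples are bilinear blends of the 4 surrounding pixels", {
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  got <- sample_neighbors(m, c(1, 1), neighborhood_spec(1, 8))
  d <- 1 / sqrt(2)
  # i = 1: angle pi/4, position (1 + d, 1 + d) inside the lower-right cell
  expect_equal(got[1],
               (1 - d)^2 * 5 + d * (1 - d) * 6 + (1 - d) * d * 8 + d^2 * 9)
  expect_equal(got, oracle_neighbors(m, 1, 1, 1, 8))
})

test_that("sampling refuses circles that exit the image", {
  m <- matrix(0, 5, 5)
  expect_error(sample_neighbors(m, c(1, 2), neighborhood_spec(2, 8)),
               "bounds")
  expect_error(local_variance(m, c(2, 2), neighborhood_spec(3, 8)),
               "bounds")
  expect_error(global_texture_variance(matrix(0, 4, 4),
                                       neighborhood_spec(2, 8)),
               "at least")
})

test_that("negating the image flips every strict-inequality bit", {
  for (s in 1:5) {
    img <- random_image(8, 8, seed = 200 + s)
    spec <- neighborhood_spec(2, 8)
    a <- lbp_pattern(img, c(4, 4), spec)
    b <- lbp_pattern(255 - img, c(4, 4), spec)
    strict <- abs(a$neighbors - img[5, 5]) > 1e-12
    expect_equal(b$bits[strict], 1L - a$bits[strict])
  }
})

test_that("local variance is shift invariant", {
  img <- random_image(9, 9, seed = 31)
  img[img > 200] <- 200
  spec <- neighborhood_spec(2.5, 8)
  v0 <- local_variance(img, c(4, 4), spec)
  expect_equal(local_variance(img + 55, c(4, 4), spec), v0)
})

test_that("global texture variance matches the exhaustive oracle", {
  cases <- expand.grid(R = c(1, 2, 3.5), N = c(4, 8))
  for (i in seq_len(nrow(cases))) {
    img <- random_image(20, 24, seed = 300 + i)
    got <- as.numeric(global_texture_variance(
      img, neighborhood_spec(cases$R[i], cases$N[i])))
    want <- oracle_global_variance(img, cases$R[i], cases$N[i])
    expect_equal(got, want, tolerance = 1e-12,
                 info = sprintf("R=%g N=%d", cases$R[i], cases$N[i]))
  }
})

test_that("global texture variance is shift invariant and a^2-scaling", {
  img <- random_image(24, 24, seed = 9)
  img[img > 120] <- 120
  spec <- neighborhood_spec(3, 8)
  v0 <- as.numeric(global_texture_variance(img, spec))
  expect_equal(as.numeric(global_texture_variance(img + 100, spec)), v0)
  expect_equal(as.numeric(global_texture_variance(2 * img, spec)), 4 * v0)
  expect_equal(as.numeric(global_texture_variance(0.5 * img, spec)), 0.25 * v0)
})

test_that("an edge image has higher texture variance than its blurred copy", {
  step <- cbind(matrix(0, 20, 10), matrix(255, 20, 10))
  spec <- neighborhood_spec(2, 8)
  v_step <- as.numeric(global_texture_variance(step, spec))
  expect_gt(v_step, 0)
  blurred <- t(apply(step, 1, function(r) stats::filter(r, rep(1 / 5, 5),
                                                        circular = TRUE)))
  v_blur <- as.numeric(global_texture_variance(blurred, spec))
  expect_gt(v_step, v_blur)
})

test_that("a radially symmetric pattern scores alike under 90-degree rotation", {
  n <- 64
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  r <- sqrt((xy$x - (n - 1) / 2)^2 + (xy$y - (n - 1) / 2)^2)
  img <- matrix(127.5 + 100 * sin(r / 2), n, n)
  spec <- neighborhood_spec(5, 8)
  v1 <- as.numeric(global_texture_variance(img, spec))
  v2 <- as.numeric(global_texture_variance(t(img[n:1, ]), spec))
  expect_lt(abs(v1 - v2) / v1, 0.01)
})

test_that("multi-radius score averages its per-radius components", {
  img <- random_image(128, 128, seed = 55)
  ms <- multi_radius_score(img)
  expect_equal(ms$averaged, mean(ms$per_radius))
  expect_equal(names(ms$per_radius), c("10", "20", "30", "40", "50"))
  expect_true(all(ms$per_radius >= 0))
  # per-radius values agree with the single-radius entry point
  expect_equal(unname(ms$per_radius["20"]),
               as.numeric(global_texture_variance(img,
                                                  neighborhood_spec(20, 8))))
  expect_error(multi_radius_score(matrix(0, 64, 64)), "50")
})

test_that("multi-radius score matches the oracle on a smooth blob texture", {
  set.seed(21)
  base <- matrix(runif(16 * 16, 60, 190), 16, 16)
  big <- base[rep(1:16, each = 4), rep(1:16, each = 4)]  # 64x64 blocky blobs
  radii <- c(2, 4)
  ms <- multi_radius_score(big, radii = radii, N = 8)
  for (j in seq_along(radii)) {
    want <- oracle_global_variance(big, radii[j], 8)
    expect_equal(unname(ms$per_radius[j]), want, tolerance = 1e-12)
  }
})

test_that("higher planted texture amplitude raises the score monotonically", {
  set.seed(4)
  field <- matrix(rnorm(64 * 64), 64, 64)
  amps <- c(2, 5, 10, 20, 40)
  scores <- vapply(amps, function(a) {
    img <- pmin(pmax(127.5 + a * field, 0), 255)
    multi_radius_score(img, radii = c(4, 8), N = 8)$averaged
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
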