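test_that("separable two-block image segments exactly", {
  m <- matrix(50L, 8, 8); m[, 5:8] <- 200L
  img <- gray_image(m)
  seeds <- seed_set(rbind(c(2, 6), c(5, 7)), rbind(c(2, 2), c(6, 3)),
                    dim(img))
  res <- segment(img, seeds, mode = "static")
  expect_identical(unclass(res$mask), matrix(as.integer(m == 200L), 8, 8))
  expect_s3_class(res$mask, "binary_mask")
})

test_that("result energy is consistent and flow equals min-cut energy", {
  s <- ring_fixture(11)
  res <- segment(s$image, s$seeds, mode = "static")
  model <- build_model(s$image, s$seeds)
  field <- build_lambda_field(NULL, lambda1 = 20, dim = dim(s$image))
  expect_equal(res$energy,
               energy(res$mask, s$image, model, field,
                      sigma = res$config$sigma),
               tolerance = 1e-6)
  expect_equal(res$flow, res$energy, tolerance = 1e-6)
})

test_that("random 3x3 segmentations attain the exhaustive energy minimum", {
  set.seed(61)
  for (i in 1:10) {
    img <- rand_gray(3, 3)
    seeds <- seed_set(rbind(c(1, 1)), rbind(c(3, 3)), dim(img))
    res <- segment(img, seeds, mode = "static", sigma = 15)
    model <- build_model(img, seeds)
    field <- build_lambda_field(NULL, lambda1 = 20, dim = c(3, 3))
    e_min <- bf_min_energy(img, model, field, 15)
    expect_equal(res$energy, e_min, tolerance = 1e-9)
  }
})

test_that("adaptive with an empty boundary set is bit-identical to static", {
  s <- ring_fixture(12)
  static <- segment(s$image, s$seeds, mode = "static")
  # force an empty boundary map through the extraction knobs: a threshold
  # no gradient can exceed
  adaptive <- segment(s$image, s$seeds, mode = "adaptive",
                      boundary_args = list(method = "gradient-threshold",
                                           threshold = 1e9))
  expect_identical(unclass(adaptive$mask), unclass(static$mask))
  expect_equal(adaptive$energy, static$energy, tolerance = 1e-12)
})

test_that("segmentation is deterministic", {
  s <- ring_fixture(13)
  r1 <- segment(s$image, s$seeds, mode = "adaptive")
  r2 <- segment(s$image, s$seeds, mode = "adaptive")
  expect_identical(unclass(r1$mask), unclass(r2$mask))
  expect_identical(r1$energy, r2$energy)
})

test_that("segment_auto equals segment with the same Otsu seed sets", {
  s <- synth_generate(synth_params(), seed = 14)
  auto <- segment_auto(s$image, mode = "static")
  manual <- segment(s$image, auto_seeds(s$image), mode = "static")
  expect_identical(unclass(auto$mask), unclass(manual$mask))
  expect_error(segment_auto(gray_image(matrix(9L, 4, 4))), "degenerate")
})

test_that("auto seeding covers every cell mode of a heterogeneous image", {
  p <- synth_params(cell_jitter = 40, noise_sd = 3, height = 96L,
                    width = 96L)
  s <- synth_generate(p, seed = 15)
  seeds <- auto_seeds(s$image)
  model <- build_model(s$image, seeds)
  interior <- cellcut:::erode3x3(cellcut:::erode3x3(unclass(s$truth) == 1L))
  cell_px <- unique(as.integer(unclass(s$image)[interior]))
  # every interior intensity has non-trivial support in the fg histogram
  expect_true(all(model$fg_hist[cell_px + 1] > 1e-4))
})

test_that("hard seeds pin their own pixels", {
  m <- matrix(120L, 6, 6)
  img <- gray_image(m + matrix(sample(-3:3, 36, TRUE), 6, 6))
  seeds <- seed_set(rbind(c(1, 1)), rbind(c(6, 6)), dim(img))
  res <- segment(img, seeds, mode = "static", hard_seeds = TRUE)
  expect_equal(unclass(res$mask)[1, 1], 1L)
  expect_equal(unclass(res$mask)[6, 6], 0L)
})

test_that("lambda_sweep returns one scored row per lambda", {
  s <- ring_fixture(16)
  one <- lambda_sweep(s$image, s$seeds, mode = "static", grid = 20,
                      truth = s$truth)
  base <- segment(s$image, s$seeds, mode = "static")
  expect_equal(one$f1,
               metrics_report(confusion(base$mask, s$truth))$f1)

  expect_error(lambda_sweep(s$image, s$seeds, grid = numeric(0),
                            truth = s$truth), "empty")
  expect_error(lambda_sweep(s$image, s$seeds, grid = c(10, -1),
                            truth = s$truth), "positive")
})

test_that("lambda matters more for sparse scribbles than for auto seeds", {
  s <- synth_generate(synth_params(), seed = 17)
  grid <- c(1, 50, 150, 400)
  scr <- generate_scribbles(s$truth, coverage = 0.15, seed = 17,
                            erosion = 3)
  inter <- lambda_sweep(s$image, scribble_seeds(scr, s$image),
                        mode = "static", grid = grid, truth = s$truth)
  auto <- lambda_sweep(s$image, auto_seeds(s$image), mode = "static",
                       grid = grid, truth = s$truth)
  expect_lt(diff(range(auto$f1)), 0.02)
  expect_gt(diff(range(inter$f1)), diff(range(auto$f1)))
})

test_that("noise_experiment scores each density against the clean truth", {
  s <- ring_fixture(18)
  tab <- noise_experiment(s$image, s$seeds, mode = "static",
                          densities = c(0, 0.1), truth = s$truth,
                          seed = 5)
  clean <- metrics_report(confusion(
    segment(s$image, s$seeds, mode = "static")$mask, s$truth))
  expect_equal(tab$f1[1], clean$f1)       # density 0 = clean image
  expect_equal(nrow(tab), 2)
  expect_error(noise_experiment(s$image, s$seeds, densities = 0.7,
                                truth = s$truth), "0, 0.5")
  # robustness smoke at the maximum allowed density
  tab5 <- noise_experiment(s$image, s$seeds, mode = "static",
                           densities = 0.5, truth = s$truth, seed = 6)
  expect_gt(tab5$f1, 0)
})
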