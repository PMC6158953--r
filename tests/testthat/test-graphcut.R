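test_that("smoothness_weight evaluates the Gaussian penalty", {
  expect_equal(smoothness_weight(50, 50, 10), 1)
  expect_equal(smoothness_weight(10, 20, 10), exp(-0.5))
  expect_lt(smoothness_weight(0, 255, 1), 1e-30)
  expect_error(smoothness_weight(1, 2, 0), "positive")
  expect_error(smoothness_weight(1, 2, -3), "positive")
})

test_that("the toy 4-node network gives flow 60 with `a` on the source side", {
  # weights O-a=50, a-B=20, b-B=70, a-b=18, O-b=22; nodes a=1, b=2,
  # O=3 (source), B=4 (sink)
  g <- seg_graph(4, from = c(3, 1, 2, 1, 3), to = c(1, 4, 4, 2, 2),
                 cap = c(50, 20, 70, 18, 22), source = 3, sink = 4,
                 undirected = TRUE)
  oracle <- bf_min_cut(g)
  expect_equal(oracle$capacity, 60)   # enumerated: cuts are 72, 60, 138, 90
  expect_true(oracle$source_side[1])  # a with O
  expect_false(oracle$source_side[2]) # b with B

  res <- max_flow(g)
  expect_equal(res$flow, oracle$capacity, tolerance = 1e-9)
  expect_identical(res$source_side, oracle$source_side)
})

test_that("max-flow equals brute-force min cut on 100 random graphs", {
  set.seed(31)
  for (i in 1:100) {
    n_px <- sample(2:8, 1)
    n <- n_px + 2L
    src <- n_px + 1L
    snk <- n_px + 2L
    # random t-links plus random sparse inner edges
    from <- c(rep(src, n_px), seq_len(n_px))
    to <- c(seq_len(n_px), rep(snk, n_px))
    cap <- round(runif(2 * n_px, 0, 50), 2)
    n_extra <- sample(0:(n_px * 2), 1)
    if (n_extra > 0) {
      eu <- sample(n_px, n_extra, replace = TRUE)
      ev <- sample(n_px, n_extra, replace = TRUE)
      keep <- eu != ev
      from <- c(from, eu[keep]); to <- c(to, ev[keep])
      cap <- c(cap, round(runif(sum(keep), 0, 20), 2))
    }
    g <- seg_graph(n, from, to, cap, src, snk, undirected = TRUE)
    res <- max_flow(g)
    oracle <- bf_min_cut(g)
    expect_equal(res$flow, oracle$capacity, tolerance = 1e-9)
    # returned cut must itself attain the max-flow value
    expect_equal(cut_capacity(g, res$source_side), res$flow,
                 tolerance = 1e-9)
  }
})

test_that("degenerate graphs behave", {
  # chain bottleneck
  g <- seg_graph(3, from = c(2, 1), to = c(1, 3), cap = c(5, 3),
                 source = 2, sink = 3)
  expect_equal(max_flow(g)$flow, 3)
  # all-zero capacities
  g0 <- seg_graph(3, from = c(2, 1), to = c(1, 3), cap = c(0, 0),
                  source = 2, sink = 3)
  res <- max_flow(g0)
  expect_equal(res$flow, 0)
  expect_error(seg_graph(3, 1, 2, -1, 1, 3), "0")
  expect_error(seg_graph(3, 1, 2, Inf, 1, 3), "finite")
})

test_that("build_graph produces the expected structure", {
  img <- gray_image(matrix(c(10L, 200L), 1, 2))
  s <- seed_set(rbind(c(1, 2)), rbind(c(1, 1)), dim(img))
  model <- build_model(img, s)
  field <- build_lambda_field(NULL, dim = dim(img))
  g <- build_graph(img, model, field, sigma = 10)
  expect_equal(g$n_nodes, 4)                 # 2 pixels + 2 terminals
  expect_equal(length(g$from), 2 + 2 + 2)    # 4 t-links + n-link both ways

  img3 <- rand_gray(3, 3)
  s3 <- seed_set(rbind(c(1, 1)), rbind(c(3, 3)), dim(img3))
  g3 <- build_graph(img3, build_model(img3, s3),
                    build_lambda_field(NULL, dim = c(3, 3)), sigma = 10)
  expect_equal(g3$n_nodes, 11)               # 9 + terminals
  expect_equal(length(g3$from), 18 + 2 * 12) # 18 t-links, 12 n-links
})

test_that("boundary pixels get a zero B t-link under an adaptive field", {
  img <- rand_gray(3, 3)
  s <- seed_set(rbind(c(1, 1)), rbind(c(3, 3)), dim(img))
  b <- matrix(FALSE, 3, 3); b[2, 2] <- TRUE
  g <- build_graph(img, build_model(img, s),
                   build_lambda_field(b, lambda1 = 20, c_p = 20),
                   sigma = 10)
  # pixel (2,2) is node 5 (row-major); its B t-link is arc 9 + 5
  n <- 9
  b_arc <- which(g$from == 5 & g$to == n + 2)
  expect_equal(g$cap[b_arc], 0)
  o_arc <- which(g$from == n + 1 & g$to == 5)
  expect_gt(g$cap[o_arc], 0)
})

test_that("min-cut labeling minimizes the energy exhaustively (3x3)", {
  set.seed(32)
  for (i in 1:20) {
    img <- rand_gray(3, 3)
    model <- rand_model()
    sigma <- runif(1, 5, 60)
    # alternate static and adaptive fields
    b <- matrix(runif(9) < 0.3, 3, 3)
    field <- if (i %% 2 == 0)
      build_lambda_field(b, lambda1 = runif(1, 1, 30), c_p = 20)
    else
      build_lambda_field(NULL, lambda1 = runif(1, 1, 30), dim = c(3, 3))
    g <- build_graph(img, model, field, sigma = sigma)
    cut <- max_flow(g)
    lab <- labeling_from_cut(cut, g)
    e_cut <- energy(lab, img, model, field, sigma = sigma)
    e_min <- bf_min_energy(img, model, field, sigma)
    expect_equal(e_cut, e_min, tolerance = 1e-9)
    # flow value equals the optimal energy: the graph encodes the energy
    expect_equal(cut$flow, e_min, tolerance = 1e-9)
  }
})

test_that("energy accounts data and smoothness terms correctly", {
  img <- gray_image(matrix(50L, 3, 3))
  model <- structure(list(fg_hist = rep(1 / 256, 256),
                          bg_hist = rep(1 / 256, 256), smoothing = 0),
                     class = "appearance_model")
  field <- build_lambda_field(NULL, lambda1 = 20, dim = c(3, 3))
  # constant labeling on a uniform model: x * lambda * log 256
  e0 <- energy(binary_mask(matrix(0L, 3, 3)), img, model, field, sigma = 10)
  expect_equal(e0, 9 * 20 * log(256), tolerance = 1e-9)
  # flipping the center pixel adds exactly 4 smoothness penalties
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 1L
  e1 <- energy(binary_mask(lab), img, model, field, sigma = 10)
  expect_equal(e1, e0 + 4 * smoothness_weight(50, 50, 10),
               tolerance = 1e-9)
})

test_that("labeling_from_cut maps sides to labels", {
  img <- gray_image(matrix(c(10L, 10L, 240L, 240L), 2, 2))
  s <- seed_set(rbind(c(1, 2)), rbind(c(1, 1)), dim(img))
  g <- build_graph(img, build_model(img, s),
                   build_lambda_field(NULL, dim = dim(img)), sigma = 10)
  cut <- max_flow(g)
  lab <- labeling_from_cut(cut, g)
  expect_identical(unclass(lab), matrix(c(0L, 0L, 1L, 1L), 2, 2))
})

test_that("DIMACS dump is well-formed", {
  g <- seg_graph(3, from = c(2, 1), to = c(1, 3), cap = c(5, 3),
                 source = 2, sink = 3)
  f <- withr::local_tempfile(fileext = ".dimacs")
  write_dimacs(g, f)
  lines <- readLines(f)
  expect_equal(lines[1], "p max 3 2")
  expect_equal(sum(startsWith(lines, "a ")), 2)
})

test_that("raising lambda1 never increases the smoothness share", {
  s <- ring_fixture(3)
  shares <- vapply(c(2, 20, 200), function(l) {
    res <- segment(s$image, s$seeds, mode = "static", lambda1 = l)
    model <- build_model(s$image, s$seeds)
    field <- build_lambda_field(NULL, lambda1 = l, dim = dim(s$image))
    e_tot <- energy(res$mask, s$image, model, field)
    field1 <- build_lambda_field(NULL, lambda1 = l, dim = dim(s$image))
    # smoothness part: energy with data term removed
    m0 <- structure(list(fg_hist = rep(1, 256), bg_hist = rep(1, 256),
                         smoothing = 0), class = "appearance_model")
    e_smooth <- energy(res$mask, s$image, m0, field1)
    e_smooth / max(e_tot, 1e-12)
  }, numeric(1))
  expect_true(all(diff(shares) <= 1e-9))
})
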