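#' Smoothness (n-link) weight between two intensities
#'
#' The pairwise penalty paid when 4-neighbors `a`, `b` receive different
#' labels: \eqn{\exp(-(I_a-I_b)^2 / (2\sigma^2))}, in (0, 1]. Similar
#' neighbors are expensive to separate; a strong edge (large intensity
#' difference relative to `sigma`) is nearly free to cut.
#'
#' @param ia,ib grey levels (vectorized).
#' @param sigma similarity scale in grey levels, must be positive.
#' @return Numeric weight(s) in (0, 1].
#' @examples
#' smoothness_weight(10, 20, 10)  # exp(-0.5)
#' @export
smoothness_weight <- function(ia, ib, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  exp(-((ia - ib)^2) / (2 * sigma^2))
}

#' Estimate the similarity scale sigma from an image
#'
#' Standard deviation of all 4-neighbor intensity differences. Constant
#' images (zero spread) fall back to 1 grey level.
#'
#' @param image a [gray_image()].
#' @return Positive scalar.
#' @export
estimate_sigma <- function(image) {
  m <- unclass(as_gray_image(image))
  h <- nrow(m); w <- ncol(m)
  d <- c(if (w > 1) m[, -1] - m[, -w], if (h > 1) m[-1, ] - m[-h, ])
  s <- if (length(d) > 1) stats::sd(d) else 0
  if (is.na(s) || s <= 0) 1 else s
}

#' Construct an s/t graph from an arc list
#'
#' Low-level constructor used by [build_graph()] and directly for toy
#' networks. Arcs are directed; pass `undirected = TRUE` to insert the
#' antiparallel partner of every arc (the usual encoding of undirected
#' capacities for max-flow).
#'
#' @param n_nodes total node count including terminals.
#' @param from,to 1-based node ids.
#' @param cap non-negative finite capacities.
#' @param source,sink terminal node ids.
#' @param undirected insert reverse arcs with equal capacity.
#' @param dim optional image dimensions when pixel nodes map to a grid.
#' @return A `seg_graph` object.
#' @export
seg_graph <- function(n_nodes, from, to, cap, source, sink,
                      undirected = FALSE, dim = NULL) {
  stopifnot(length(from) == length(to), length(from) == length(cap))
  if (any(!is.finite(cap)) || any(cap < 0))
    stop("capacities must be finite and >= 0", call. = FALSE)
  if (undirected) {
    from2 <- c(from, to); to2 <- c(to, from); cap2 <- c(cap, cap)
    from <- from2; to <- to2; cap <- cap2
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 from = as.integer(from), to = as.integer(to),
                 cap = as.numeric(cap),
                 source = as.integer(source), sink = as.integer(sink),
                 dim = if (is.null(dim)) NULL else as.integer(dim)),
            class = "seg_graph")
}

#' @export
print.seg_graph <- function(x, ...) {
  cat(sprintf("<seg_graph: %d nodes, %d arcs, source %d, sink %d>\n",
              x$n_nodes, length(x$from), x$source, x$sink))
  invisible(x)
}

pixel_index <- function(dim) {
  # id of pixel (r, c) is (r-1)*width + c; terminals come last
  function(r, c) (r - 1L) * dim[2] + c
}

#' Build the segmentation graph for an image
#'
#' Every pixel gets one t-link to the object terminal O (source) and one
#' to the background terminal B (sink); 4-neighbor pairs get n-links.
#' Convention: the O-link of pixel `a` carries the *background* data cost
#' `lambda1 * o_mult[a] * (-log P(I_a | bg))` and the B-link the
#' *foreground* cost `lambda1 * b_mult[a] * (-log P(I_a | fg))`, so a
#' pixel ending on the source (foreground) side pays its foreground data
#' cost through the severed B-link. n-links carry
#' [smoothness_weight()] and are *not* scaled by lambda.
#'
#' @param image a [gray_image()].
#' @param model an `appearance_model` from [build_model()].
#' @param field a `lambda_field` from [build_lambda_field()].
#' @param sigma similarity scale; default [estimate_sigma()] of the image.
#' @param hard_seeds optional [seed_set()]; its pixels get an extra
#'   `1e6`-capacity link to their own terminal (Boykov-Jolly style hard
#'   constraints). Default `NULL`: seeds act only through the histograms.
#' @return A `seg_graph` whose nodes are pixels `1..n` (row-major) plus
#'   source `n+1` and sink `n+2`.
#' @export
build_graph <- function(image, model, field, sigma = NULL,
                        hard_seeds = NULL) {
  image <- as_gray_image(image)
  stopifnot(inherits(model, "appearance_model"),
            inherits(field, "lambda_field"))
  check_same_shape(image, field$o_mult, "image and lambda field")
  if (is.null(sigma)) sigma <- estimate_sigma(image)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  n <- h * w
  src <- n + 1L; snk <- n + 2L
  idx <- pixel_index(c(h, w))

  px <- as.vector(t(unclass(image)))            # row-major pixel order
  costs <- data_cost(model, px)
  o_cap <- field$lambda1 * as.vector(t(field$o_mult)) * costs$cost_bg
  b_cap <- field$lambda1 * as.vector(t(field$b_mult)) * costs$cost_fg
  if (!is.null(hard_seeds)) {
    BIG <- 1e6
    fg_id <- idx(hard_seeds$foreground[, 1], hard_seeds$foreground[, 2])
    bg_id <- idx(hard_seeds$background[, 1], hard_seeds$background[, 2])
    o_cap[fg_id] <- o_cap[fg_id] + BIG
    b_cap[bg_id] <- b_cap[bg_id] + BIG
  }

  # n-links: right and down neighbors, undirected
  m <- unclass(image)
  efrom <- integer(0); eto <- integer(0); ecap <- numeric(0)
  if (w > 1) {
    r <- rep(seq_len(h), each = w - 1); c1 <- rep(seq_len(w - 1), h)
    wgt <- smoothness_weight(m[cbind(r, c1)], m[cbind(r, c1 + 1)], sigma)
    efrom <- c(efrom, idx(r, c1)); eto <- c(eto, idx(r, c1 + 1))
    ecap <- c(ecap, wgt)
  }
  if (h > 1) {
    r1 <- rep(seq_len(h - 1), each = w); cc <- rep(seq_len(w), h - 1)
    wgt <- smoothness_weight(m[cbind(r1, cc)], m[cbind(r1 + 1, cc)], sigma)
    efrom <- c(efrom, idx(r1, cc)); eto <- c(eto, idx(r1 + 1, cc))
    ecap <- c(ecap, wgt)
  }

  from <- c(rep(src, n), seq_len(n), efrom, eto)
  to <- c(seq_len(n), rep(snk, n), eto, efrom)
  cap <- c(o_cap, b_cap, ecap, ecap)
  g <- seg_graph(n + 2L, from, to, cap, src, snk, dim = c(h, w))
  g$sigma <- sigma
  g
}

#' Solve max-flow/min-cut on a segmentation graph
#'
#' Edmonds-Karp (shortest augmenting paths by BFS) on the arc list, with
#' a fixed node ordering, so the result is deterministic for a fixed
#' graph. The cut side is the set of nodes reachable from the source in
#' the final residual graph.
#'
#' @param graph a `seg_graph`.
#' @return List with `flow` (the max-flow = min-cut value) and
#'   `source_side` (logical per node, `TRUE` = object/source side).
#' @export
max_flow <- function(graph) {
  stopifnot(inherits(graph, "seg_graph"))
  res <- maxflow_cpp(graph$n_nodes, graph$from, graph$to, graph$cap,
                     graph$source, graph$sink)
  list(flow = res$flow, source_side = res$source_side)
}

#' Binary labeling from a cut
#'
#' @param cut result of [max_flow()].
#' @param graph the `seg_graph` it was computed on (needs grid `dim`).
#' @return A [binary_mask()]: 1 on the object (source) side, 0 on the
#'   background side.
#' @export
labeling_from_cut <- function(cut, graph) {
  stopifnot(inherits(graph, "seg_graph"))
  if (is.null(graph$dim))
    stop("graph has no pixel-grid dimensions", call. = FALSE)
  n <- prod(graph$dim)
  binary_mask(matrix(as.integer(cut$source_side[seq_len(n)]),
                     nrow = graph$dim[1], ncol = graph$dim[2],
                     byrow = TRUE))
}

#' Segmentation energy of a labeling
#'
#' The lambda-weighted sum of per-pixel data costs plus the smoothness
#' penalty of every 4-neighbor pair with unequal labels. With the t-link
#' convention of [build_graph()], foreground pixels contribute
#' `lambda1 * b_mult * cost_fg` and background pixels
#' `lambda1 * o_mult * cost_bg`, which is exactly the total capacity of
#' the corresponding minimum cut.
#'
#' @param labeling a [binary_mask()].
#' @param image a [gray_image()].
#' @param model an `appearance_model`.
#' @param field a `lambda_field`.
#' @param sigma similarity scale (default [estimate_sigma()]).
#' @return Scalar energy.
#' @export
energy <- function(labeling, image, model, field, sigma = NULL) {
  labeling <- as_binary_mask(labeling)
  image <- as_gray_image(image)
  check_same_shape(labeling, image, "labeling and image")
  check_same_shape(image, field$o_mult, "image and lambda field")
  if (is.null(sigma)) sigma <- estimate_sigma(image)
  costs <- data_cost(model, as.integer(image))
  fg <- unclass(labeling) == 1L
  data_term <- sum(field$lambda1 * field$b_mult[fg] *
                     matrix(costs$cost_fg, nrow(image))[fg]) +
    sum(field$lambda1 * field$o_mult[!fg] *
          matrix(costs$cost_bg, nrow(image))[!fg])
  m <- unclass(image)
  h <- nrow(m); w <- ncol(m)
  smooth <- 0
  if (w > 1) {
    diffc <- unclass(labeling)[, -w] != unclass(labeling)[, -1]
    smooth <- smooth +
      sum(smoothness_weight(m[, -w][diffc], m[, -1][diffc], sigma))
  }
  if (h > 1) {
    diffr <- unclass(labeling)[-h, ] != unclass(labeling)[-1, ]
    smooth <- smooth +
      sum(smoothness_weight(m[-h, ][diffr], m[-1, ][diffr], sigma))
  }
  data_term + smooth
}

#' Dump a graph in DIMACS max-flow format
#'
#' @param graph a `seg_graph`.
#' @param path output path.
#' @export
write_dimacs <- function(graph, path) {
  stopifnot(inherits(graph, "seg_graph"))
  lines <- c(sprintf("p max %d %d", graph$n_nodes, length(graph$from)),
             sprintf("n %d s", graph$source),
             sprintf("n %d t", graph$sink),
             sprintf("a %d %d %.17g", graph$from, graph$to, graph$cap))
  writeLines(lines, path)
  invisible(path)
}
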