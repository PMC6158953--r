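# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration instead of max-flow,
# direct class-variance computation instead of the histogram recursion.

# Capacity of the cut induced by a source-side indicator (logical per
# node): total capacity of arcs leaving the source side.
cut_capacity <- function(graph, source_side) {
  sum(graph$cap[source_side[graph$from] & !source_side[graph$to]])
}

# Minimum s/t cut by enumerating all 2^k partitions of the non-terminal
# nodes. Returns the minimum capacity and one minimizing source side.
bf_min_cut <- function(graph) {
  inner <- setdiff(seq_len(graph$n_nodes), c(graph$source, graph$sink))
  k <- length(inner)
  best <- Inf
  best_side <- NULL
  for (bits in 0:(2^k - 1)) {
    side <- rep(FALSE, graph$n_nodes)
    side[graph$source] <- TRUE
    side[inner[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]] <- TRUE
    cc <- cut_capacity(graph, side)
    if (cc < best - 1e-12) {
      best <- cc
      best_side <- side
    }
  }
  list(capacity = best, source_side = best_side)
}

# Otsu threshold by direct evaluation: for every candidate t compute the
# two class means from the raw pixel vector and the between-class
# variance w0*w1*(mu0-mu1)^2; lowest maximizer wins.
otsu_bruteforce <- function(pixels) {
  px <- as.integer(pixels)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    lo <- px[px <= t]
    hi <- px[px > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(px)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Exhaustive minimum of the segmentation energy over all 2^n labelings.
bf_min_energy <- function(image, model, field, sigma) {
  n <- length(image)
  best <- Inf
  for (bits in 0:(2^n - 1)) {
    lab <- matrix(as.integer(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0),
                  nrow(image), ncol(image))
    e <- energy(binary_mask(lab), image, model, field, sigma = sigma)
    if (e < best) best <- e
  }
  best
}

rand_gray <- function(h, w) {
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

rand_model <- function() {
  fg <- runif(256) + 1e-3
  bg <- runif(256) + 1e-3
  structure(list(fg_hist = fg / sum(fg), bg_hist = bg / sum(bg),
                 smoothing = 1e-6),
            class = "appearance_model")
}

# Standard ring fixture: the stated synthetic world for the shrink-bias
# experiments (defaults of synth_params()), with conservative
# interior-only scribbles that never touch the boundary ring.
ring_fixture <- function(seed) {
  s <- synth_generate(synth_params(), seed = seed)
  scr <- generate_scribbles(s$truth, coverage = 0.15, seed = 1000 + seed,
                            erosion = 3)
  s$seeds <- scribble_seeds(scr, s$image)
  s
}
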