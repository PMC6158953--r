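#' Graph-cut segmentation of a grayscale image
#'
#' Orchestrates the full pipeline: build the appearance model from the
#' seeds, build the lambda field (static: identically `lambda1`;
#' adaptive: boosted toward the object terminal and zeroed toward the
#' background terminal on the extracted cell-boundary set), assemble the
#' s/t graph and take the minimum cut.
#'
#' @param image a [gray_image()] (or 0-255 integer matrix).
#' @param seeds a [seed_set()] valid for the image.
#' @param mode `"static"` (one global lambda) or `"adaptive"`
#'   (boundary-adaptive lambda).
#' @param lambda1 base graph-cut parameter (default 20).
#' @param c_p boundary boost constant for adaptive mode (default 20; the
#'   effective object-link lambda on boundary pixels is
#'   `lambda1 * c_p`).
#' @param sigma smoothness similarity scale; default estimated from the
#'   image ([estimate_sigma()]).
#' @param smoothing histogram pseudo-count (see [build_model()]).
#' @param hard_seeds if `TRUE`, seed pixels additionally get
#'   large-capacity t-links to their own terminal; default `FALSE`
#'   (seeds act only through the histograms).
#' @param boundary_args list of extra arguments to
#'   [extract_boundaries()] in adaptive mode.
#' @return A `seg_result`: list with `mask` (a [binary_mask()]), `energy`,
#'   `flow` (the min-cut value) and `config` echoing all effective
#'   parameters.
#' @examples
#' img <- gray_image(matrix(c(rep(50L, 8), rep(200L, 8)), 4, 4))
#' s <- seed_set(rbind(c(1, 3)), rbind(c(1, 1)), dim(img))
#' segment(img, s, mode = "static")$mask
#' @export
segment <- function(image, seeds, mode = c("static", "adaptive"),
                    lambda1 = 20, c_p = 20, sigma = NULL,
                    smoothing = 1e-6, hard_seeds = FALSE,
                    boundary_args = list()) {
  image <- as_gray_image(image)
  mode <- match.arg(mode)
  if (lambda1 <= 0) stop("lambda1 must be positive", call. = FALSE)
  model <- build_model(image, seeds, smoothing = smoothing)
  if (is.null(sigma)) sigma <- estimate_sigma(image)

  boundaries <- NULL
  if (mode == "adaptive") {
    boundaries <- tryCatch(
      do.call(extract_boundaries, c(list(image), boundary_args)),
      error = function(e) {
        warning("boundary extraction failed (", conditionMessage(e),
                "); falling back to static lambda")
        NULL
      })
    if (!is.null(boundaries) && !any(boundaries)) boundaries <- NULL
  }
  field <- build_lambda_field(boundaries, lambda1 = lambda1,
                              c_p = if (is.null(boundaries)) 1 else c_p,
                              dim = dim(image))

  g <- build_graph(image, model, field, sigma = sigma,
                   hard_seeds = if (hard_seeds) seeds else NULL)
  cut <- max_flow(g)
  mask <- labeling_from_cut(cut, g)
  structure(list(
    mask = mask,
    energy = energy(mask, image, model, field, sigma = sigma),
    flow = cut$flow,
    config = list(mode = mode, lambda1 = lambda1,
                  c_p = if (is.null(boundaries)) NA_real_ else c_p,
                  sigma = sigma, smoothing = smoothing,
                  hard_seeds = hard_seeds,
                  n_boundary = if (is.null(boundaries)) 0L
                               else sum(boundaries),
                  n_fg_seeds = nrow(seeds$foreground),
                  n_bg_seeds = nrow(seeds$background))),
    class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf(
    "<seg_result: %s lambda, %d fg px, energy %.3f, flow %.3f>\n",
    x$config$mode, sum(x$mask), x$energy, x$flow))
  invisible(x)
}

#' Fully automatic segmentation (Otsu-derived seeds)
#'
#' Equivalent to `segment(image, auto_seeds(image), ...)`: sample
#' foreground pixels are every pixel above the Otsu threshold, background
#' samples every pixel at or below it.
#'
#' @inheritParams segment
#' @param ... passed to [segment()].
#' @param erosion optional erosion of the Otsu classes before sampling
#'   (see [auto_seeds()]).
#' @return A `seg_result`.
#' @export
segment_auto <- function(image, mode = c("static", "adaptive"),
                         erosion = 0L, ...) {
  image <- as_gray_image(image)
  segment(image, auto_seeds(image, erosion = erosion), mode = mode, ...)
}

#' Sweep the graph-cut parameter and score each segmentation
#'
#' @inheritParams segment
#' @param grid non-empty vector of positive lambda values.
#' @param truth ground-truth [binary_mask()].
#' @param ... passed to [segment()].
#' @return Data frame with columns `lambda`, `ai`, `f1`.
#' @export
lambda_sweep <- function(image, seeds, mode = c("static", "adaptive"),
                         grid, truth, ...) {
  mode <- match.arg(mode)
  if (length(grid) == 0) stop("lambda grid is empty", call. = FALSE)
  if (any(grid <= 0)) stop("lambda values must be positive", call. = FALSE)
  truth <- as_binary_mask(truth)
  rows <- lapply(grid, function(l) {
    rep <- metrics_report(confusion(
      segment(image, seeds, mode = mode, lambda1 = l, ...)$mask, truth))
    data.frame(lambda = l, ai = rep$ai, f1 = rep$f1)
  })
  do.call(rbind, rows)
}

#' Noise-robustness experiment at constant lambda
#'
#' Applies salt-and-pepper noise at each density, re-segments and scores
#' against ground truth. In interactive use the seed *coordinates* are
#' held fixed (histograms are rebuilt from the noisy image, as a user's
#' scribbles would be); pass `seeds = NULL` to re-derive automatic Otsu
#' seeds from each noisy image instead.
#'
#' @inheritParams segment
#' @param seeds a [seed_set()], or `NULL` for automatic seeding per
#'   noisy image.
#' @param densities noise densities, each in `[0, 0.5]`.
#' @param truth ground-truth [binary_mask()].
#' @param seed RNG seed for the noise (private stream; density 0 always
#'   reproduces the clean image).
#' @param ... passed to [segment()].
#' @return Data frame with columns `density`, `ai`, `f1`.
#' @export
noise_experiment <- function(image, seeds, mode = c("static", "adaptive"),
                             densities, truth, lambda1 = 20, seed = 1L,
                             ...) {
  mode <- match.arg(mode)
  if (any(densities < 0 | densities > 0.5))
    stop("densities must lie in [0, 0.5]", call. = FALSE)
  truth <- as_binary_mask(truth)
  rows <- lapply(seq_along(densities), function(i) {
    noisy <- add_salt_pepper(image, densities[i], seed = seed + i - 1L)
    res <- if (is.null(seeds))
      segment_auto(noisy, mode = mode, lambda1 = lambda1, ...)
    else
      segment(noisy, seeds, mode = mode, lambda1 = lambda1, ...)
    rep <- metrics_report(confusion(res$mask, truth))
    data.frame(density = densities[i], ai = rep$ai, f1 = rep$f1)
  })
  do.call(rbind, rows)
}
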