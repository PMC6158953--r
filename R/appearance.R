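#' Intensity appearance model from seed pixels
#'
#' Builds smoothed 256-bin probability histograms of foreground and
#' background seed intensities. These give the data term of the
#' segmentation energy: the cost of labeling pixel `a` with intensity
#' \eqn{I_a} as foreground (background) is \eqn{-\log P(I_a \mid fg)}
#' (\eqn{-\log P(I_a \mid bg)}), natural log.
#'
#' Each bin receives a pseudo-count `smoothing` before normalization, so
#' unseen intensities get a large but finite cost rather than an infinite
#' one (seeds stay soft evidence, not hard constraints).
#'
#' @param image a [gray_image()].
#' @param seeds a [seed_set()] with both classes non-empty.
#' @param smoothing pseudo-count added to every bin (default `1e-6`).
#' @return An `appearance_model`: list with `fg_hist`, `bg_hist`
#'   (length-256 probability vectors) and `smoothing`.
#' @examples
#' img <- gray_image(matrix(c(10L, 10L, 20L, 200L), 2, 2))
#' s <- seed_set(rbind(c(1, 1), c(2, 1), c(1, 2)), rbind(c(2, 2)), dim(img))
#' m <- build_model(img, s, smoothing = 0)
#' m$fg_hist[c(11, 21)]  # P(10|fg) = 2/3, P(20|fg) = 1/3
#' @export
build_model <- function(image, seeds, smoothing = 1e-6) {
  image <- as_gray_image(image)
  if (!inherits(seeds, "seed_set")) stop("seeds must be a seed_set",
                                         call. = FALSE)
  if (nrow(seeds$foreground) == 0 || nrow(seeds$background) == 0)
    stop("empty seed class: both foreground and background samples required",
         call. = FALSE)
  if (smoothing < 0) stop("smoothing must be >= 0", call. = FALSE)
  hist_of <- function(coords) {
    v <- unclass(image)[coords]
    counts <- tabulate(v + 1L, nbins = 256L) + smoothing
    counts / sum(counts)
  }
  structure(list(fg_hist = hist_of(seeds$foreground),
                 bg_hist = hist_of(seeds$background),
                 smoothing = smoothing),
            class = "appearance_model")
}

#' @export
print.appearance_model <- function(x, ...) {
  cat(sprintf("<appearance_model: 256 bins, smoothing %g>\n", x$smoothing))
  invisible(x)
}

#' Data-term costs of an intensity under an appearance model
#'
#' @param model an `appearance_model` from [build_model()].
#' @param intensity grey level(s) in 0..255 (vectorized).
#' @return List with numeric vectors `cost_fg` and `cost_bg`, the negative
#'   natural log-probabilities of `intensity` under the foreground and
#'   background histograms. `Inf` is possible only with `smoothing = 0`.
#' @export
data_cost <- function(model, intensity) {
  stopifnot(inherits(model, "appearance_model"))
  if (any(intensity < 0 | intensity > 255 | intensity != floor(intensity)))
    stop("intensity must be an integer grey level in 0..255", call. = FALSE)
  idx <- as.integer(intensity) + 1L
  list(cost_fg = -log(model$fg_hist[idx]),
       cost_bg = -log(model$bg_hist[idx]))
}

#' Export/import an appearance model as JSON
#'
#' @param model an `appearance_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the reconstructed `appearance_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "appearance_model"))
  jsonlite::write_json(list(fg_hist = model$fg_hist,
                            bg_hist = model$bg_hist,
                            smoothing = model$smoothing),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$fg_hist) != 256 || length(x$bg_hist) != 256)
    stop("model file must contain two 256-bin histograms", call. = FALSE)
  structure(list(fg_hist = as.numeric(x$fg_hist),
                 bg_hist = as.numeric(x$bg_hist),
                 smoothing = as.numeric(x$smoothing)),
            class = "appearance_model")
}
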