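#' Parameters of the synthetic cell-image generator
#'
#' The generator emulates fluorescence-microscopy-like images: bright,
#' roundish, non-overlapping cells on a darker background, each cell
#' optionally wearing an intermediate-intensity boundary ring (the
#' regime in which graph cut shaves off boundary pixels, i.e. shrink
#' bias) and optional per-cell brightness jitter (emulating heterogeneous
#' datasets). Gaussian pixel noise is added last and intensities clamped
#' to 0-255.
#'
#' @param height,width image size in pixels.
#' @param n_cells number of cells to place (rejection sampling, no
#'   overlap; cells keep 2 px clearance from each other and the border).
#' @param radius_range inclusive range of cell radii in pixels.
#' @param cell_intensity mean interior grey level.
#' @param cell_jitter half-range of per-cell brightness offsets
#'   (0 = homogeneous dataset, larger = heterogeneous).
#' @param bg_intensity background grey level.
#' @param bg_speckle fraction of background pixels replaced by
#'   intermediate-intensity speckle (out-of-focus debris / uneven
#'   illumination). Real fluorescence backgrounds are heavy-tailed, not
#'   Gaussian; this is what makes background histograms put mass on
#'   intermediate grey levels, the precondition for shrink bias when
#'   foreground scribbles miss boundary intensities. 0 disables.
#' @param speckle_range inclusive grey-level range of speckle pixels.
#' @param ring_width boundary-ring width in pixels (0 disables the ring).
#' @param ring_intensity grey level of the ring; must lie between
#'   background and cell means when `ring_width > 0`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @return A `synth_params` list.
#' @export
synth_params <- function(height = 64L, width = 64L, n_cells = 4L,
                         radius_range = c(7L, 11L),
                         cell_intensity = 180, cell_jitter = 0,
                         bg_intensity = 50, bg_speckle = 0.03,
                         speckle_range = c(90, 150), ring_width = 2L,
                         ring_intensity = 120, noise_sd = 6) {
  if (cell_intensity == bg_intensity)
    stop("cell and background intensities must differ", call. = FALSE)
  if (ring_width > 0 &&
      (ring_intensity - bg_intensity) * (cell_intensity - ring_intensity) < 0)
    stop("ring intensity must lie between background and cell means",
         call. = FALSE)
  if (bg_speckle < 0 || bg_speckle > 1)
    stop("bg_speckle must lie in [0, 1]", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 radius_range = as.integer(radius_range),
                 cell_intensity = cell_intensity, cell_jitter = cell_jitter,
                 bg_intensity = bg_intensity,
                 bg_speckle = bg_speckle,
                 speckle_range = as.numeric(speckle_range),
                 ring_width = as.integer(ring_width),
                 ring_intensity = ring_intensity, noise_sd = noise_sd),
            class = "synth_params")
}

#' Generate a synthetic cell image with ground truth
#'
#' @param params a [synth_params()].
#' @param seed RNG seed; every run with the same seed and parameters is
#'   bit-identical. The generator uses a private RNG stream and leaves
#'   the caller's `.Random.seed` untouched.
#' @return List with `image` (a [gray_image()]), `truth` (a
#'   [binary_mask()] marking the full cell support, ring included) and
#'   `cells` (data frame of sub-pixel centers and radii).
#' @examples
#' s <- synth_generate(synth_params(n_cells = 2), seed = 1)
#' sum(s$truth)
#' @export
synth_generate <- function(params = synth_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(seed, {
    h <- params$height; w <- params$width
    img <- matrix(params$bg_intensity, h, w)
    truth <- matrix(0L, h, w)
    centers <- matrix(numeric(0), 0, 3)  # row, col, radius
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * max(params$n_cells, 1L)
    while (placed < params$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", params$n_cells,
             " non-overlapping cells; reduce n_cells or radii",
             call. = FALSE)
      r <- if (params$radius_range[1] == params$radius_range[2])
        params$radius_range[1] else
          sample(params$radius_range[1]:params$radius_range[2], 1)
      cy <- runif(1, r + 2, h - r - 1)
      cx <- runif(1, r + 2, w - r - 1)
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(d < centers[, 3] + r + 2)) next
      }
      centers <- rbind(centers, c(cy, cx, r))
      placed <- placed + 1L

      jitter <- if (params$cell_jitter > 0)
        runif(1, -params$cell_jitter, params$cell_jitter) else 0
      dist <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
      inside <- dist <= r
      interior <- dist <= r - params$ring_width
      truth[inside] <- 1L
      img[interior] <- params$cell_intensity + jitter
      if (params$ring_width > 0)
        img[inside & !interior] <- params$ring_intensity
    }
    if (params$bg_speckle > 0) {
      bg_idx <- which(truth == 0L)
      k <- round(params$bg_speckle * length(bg_idx))
      if (k > 0) {
        hit <- sample(bg_idx, k)
        img[hit] <- runif(k, params$speckle_range[1],
                          params$speckle_range[2])
      }
    }
    if (params$noise_sd > 0)
      img <- img + rnorm(h * w, sd = params$noise_sd)
    img <- pmin(pmax(round_half_up(img), 0), 255)
    cells <- as.data.frame(centers)
    names(cells) <- c("row", "col", "radius")
    list(image = gray_image(matrix(as.integer(img), h, w)),
         truth = binary_mask(truth),
         cells = cells)
  })
}

#' Add salt-and-pepper noise to an image
#'
#' A fraction `density` of pixels, chosen uniformly without replacement,
#' is replaced: half by 0 (pepper) and half by 255 (salt); the odd pixel
#' of an odd draw goes to pepper. Remaining pixels are untouched.
#'
#' @param image a [gray_image()].
#' @param density fraction of pixels to corrupt, in `[0, 1]`.
#' @param seed RNG seed (private stream).
#' @return A [gray_image()].
#' @export
add_salt_pepper <- function(image, density, seed = 1L) {
  image <- as_gray_image(image)
  if (!is.numeric(density) || density < 0 || density > 1)
    stop("density must lie in [0, 1]", call. = FALSE)
  n <- length(image)
  k <- round(density * n)
  if (k == 0) return(image)
  with_seed(seed, {
    hit <- sample.int(n, k)
    out <- unclass(image)
    n_pepper <- ceiling(k / 2)
    out[hit[seq_len(n_pepper)]] <- 0L
    if (k > n_pepper) out[hit[(n_pepper + 1):k]] <- 255L
    gray_image(out)
  })
}

#' Simulate conservative interior scribbles from a ground-truth mask
#'
#' Each class is eroded `erosion` times with a 3x3 element (so scribbles
#' never touch class boundaries, mimicking a careful human who avoids
#' ambiguous boundary pixels and therefore under-samples boundary
#' intensities — the condition under which boundary-adaptive lambda
#' matters), then a fraction `coverage` of each eroded class is sampled.
#' If erosion empties a class, un-eroded sampling is used with a warning.
#'
#' @param truth a [binary_mask()] containing both classes.
#' @param coverage fraction of each (eroded) class to sample, in (0, 1].
#' @param seed RNG seed (private stream).
#' @param erosion erosion iterations applied to each class first.
#' @return Integer scribble matrix over {0 unlabeled, 1 fg, 2 bg}.
#' @export
generate_scribbles <- function(truth, coverage, seed = 1L, erosion = 1L) {
  truth <- as_binary_mask(truth)
  if (coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]", call. = FALSE)
  fg <- unclass(truth) == 1L
  bg <- !fg
  if (!any(fg) || !any(bg))
    stop("truth must contain both classes", call. = FALSE)
  fg_e <- fg; bg_e <- bg
  for (i in seq_len(erosion)) {
    fg_e <- erode3x3(fg_e)
    bg_e <- erode3x3(bg_e)
  }
  if (!any(fg_e)) { warning("foreground emptied by erosion; sampling un-eroded")
    fg_e <- fg }
  if (!any(bg_e)) { warning("background emptied by erosion; sampling un-eroded")
    bg_e <- bg }
  with_seed(seed, {
    scr <- matrix(0L, nrow(truth), ncol(truth))
    pick <- function(mask_idx) {
      k <- max(1L, round(coverage * length(mask_idx)))
      if (k >= length(mask_idx)) mask_idx else sample(mask_idx, k)
    }
    scr[pick(which(fg_e))] <- 1L
    scr[pick(which(bg_e))] <- 2L
    scr
  })
}
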