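#' Seed sets: foreground/background sample pixels
#'
#' A `seed_set` holds the coordinates of sample foreground pixels (the
#' observed set \eqn{M_O}) and sample background pixels (\eqn{M_B}) used
#' to build the intensity appearance model. Coordinates are (row, col)
#' matrices, 1-based.
#'
#' @param foreground,background two-column integer matrices of (row, col)
#'   coordinates.
#' @param dim image dimensions `c(height, width)` used for bounds checks.
#' @return A `seed_set` object.
#' @export
seed_set <- function(foreground, background, dim) {
  fg <- coord_matrix(foreground)
  bg <- coord_matrix(background)
  for (m in list(fg, bg)) {
    if (nrow(m) > 0 &&
        (min(m) < 1L || max(m[, 1]) > dim[1] || max(m[, 2]) > dim[2]))
      stop("seed coordinates out of image bounds", call. = FALSE)
  }
  key <- function(m) (m[, 1] - 1) * dim[2] + m[, 2]
  if (nrow(fg) > 0 && nrow(bg) > 0 && length(intersect(key(fg), key(bg))))
    stop("foreground and background seeds must be disjoint", call. = FALSE)
  structure(list(foreground = fg, background = bg, dim = as.integer(dim)),
            class = "seed_set")
}

coord_matrix <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) return(matrix(integer(0), 0, 2))
  if (ncol(m) != 2) stop("coordinates must be (row, col) pairs",
                         call. = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set: %d foreground, %d background px on %dx%d>\n",
              nrow(x$foreground), nrow(x$background), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Otsu threshold of an 8-bit image
#'
#' Returns the grey level `t` maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the 256-bin histogram,
#' where the "black" class is every pixel with intensity `<= t` and the
#' "white" class every pixel with intensity `> t`. Ties are broken by the
#' lowest optimal threshold, so the result is deterministic.
#'
#' @param image a [gray_image()] or intensity matrix.
#' @return Integer threshold in 0..254.
#' @examples
#' img <- gray_image(matrix(c(rep(50L, 60), rep(200L, 40)), 10, 10))
#' otsu_threshold(img)
#' @export
otsu_threshold <- function(image) {
  image <- as_gray_image(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  omega0 <- cumsum(p)                    # mass of class {<= t}
  mu_t <- cumsum(p * levels)
  mu_total <- mu_t[256]
  # between-class variance at t = 0..254 (index 1..255)
  w0 <- omega0[1:255]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_total * w0[valid] - mu_t[1:255][valid])^2 /
    (w0[valid] * w1[valid])
  which.max(bcv) - 1L                    # which.max takes the first (lowest)
}

#' Automatic seed selection from an Otsu pre-segmentation
#'
#' All pixels above the Otsu threshold become foreground samples and all
#' pixels at or below it become background samples, so the two sets
#' partition the image. An optional erosion shrinks each class away from
#' the Otsu boundary for robustness experiments (default 0: use every
#' labeled pixel).
#'
#' @inheritParams otsu_threshold
#' @param erosion non-negative integer; radius of a square-element erosion
#'   applied to each class before sampling.
#' @return A [seed_set()].
#' @export
auto_seeds <- function(image, erosion = 0L) {
  image <- as_gray_image(image)
  t <- otsu_threshold(image)
  fg <- unclass(image) > t
  bg <- !fg
  if (erosion > 0L) {
    for (i in seq_len(erosion)) {
      fg <- erode3x3(fg)
      bg <- erode3x3(bg)
    }
    if (!any(fg) || !any(bg)) {
      warning("erosion emptied a seed class; using un-eroded Otsu classes")
      fg <- unclass(image) > t
      bg <- !fg
    }
  }
  seed_set(which(fg, arr.ind = TRUE), which(bg, arr.ind = TRUE), dim(image))
}

#' Seeds from a scribble label mask
#'
#' The scribble mask uses 0 for unlabeled, 1 for foreground and 2 for
#' background pixels (the file-based stand-in for interactive painting).
#'
#' @param scribble integer matrix over {0, 1, 2}, same shape as `image`.
#' @inheritParams otsu_threshold
#' @return A [seed_set()].
#' @export
scribble_seeds <- function(scribble, image) {
  image <- as_gray_image(image)
  scribble <- as.matrix(scribble)
  storage.mode(scribble) <- "integer"
  check_same_shape(scribble, image, "scribble and image")
  if (!all(scribble %in% 0:2))
    stop("scribble labels must be 0 (unlabeled), 1 (fg) or 2 (bg)",
         call. = FALSE)
  fg <- which(scribble == 1L, arr.ind = TRUE)
  bg <- which(scribble == 2L, arr.ind = TRUE)
  if (nrow(fg) == 0 || nrow(bg) == 0)
    stop("empty seed class: scribble must mark both foreground and background",
         call. = FALSE)
  seed_set(fg, bg, dim(image))
}

#' Read scribbles from a PNG mask or a row,col,label CSV
#'
#' @param path PNG whose pixel values are 0/1/2, or a CSV with columns
#'   `row`, `col`, `label` (1-based coordinates).
#' @inheritParams otsu_threshold
#' @return A [seed_set()].
#' @export
read_scribbles <- function(path, image) {
  image <- as_gray_image(image)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path)
    scr <- matrix(0L, nrow(image), ncol(image))
    scr[cbind(df$row, df$col)] <- as.integer(df$label)
  } else {
    scr <- unclass(read_gray_image(path))
  }
  scribble_seeds(scr, image)
}

# binary erosion / dilation with a 3x3 square element, edge-padded with
# FALSE (erosion treats out-of-image as background)
erode3x3 <- function(m) {
  shift_all(m, all = TRUE)
}

dilate3x3 <- function(m) {
  shift_all(m, all = FALSE)
}

shift_all <- function(m, all) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- if (all) matrix(TRUE, h, w) else matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    s <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    out <- if (all) out & s else out | s
  }
  out
}
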