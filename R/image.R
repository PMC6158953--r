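#' Grayscale image and binary mask containers
#'
#' A `gray_image` is an integer matrix of 8-bit intensities (0-255) with
#' class `"gray_image"`; a `binary_mask` is a 0/1 integer matrix with class
#' `"binary_mask"`. Coordinates are row-major, (row, col), top-left origin.
#'
#' @param pixels integer matrix of intensities in 0-255.
#' @return A validated `gray_image` object.
#' @examples
#' img <- gray_image(matrix(128L, 3, 3))
#' dim(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  p <- pixels
  storage.mode(p) <- "integer"
  if (anyNA(p)) stop("image contains missing values", call. = FALSE)
  if (min(p) < 0L || max(p) > 255L)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(p, class = c("gray_image", class(matrix())))
}

#' @rdname gray_image
#' @param labels integer matrix over {0, 1}.
#' @export
binary_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  m <- labels
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop("mask values must be 0 or 1", call. = FALSE)
  structure(m, class = c("binary_mask", class(matrix())))
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) x else gray_image(x)
}

as_binary_mask <- function(x) {
  if (inherits(x, "binary_mask")) x else binary_mask(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop(sprintf("%s must share the same shape (%dx%d vs %dx%d)",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, intensities %d..%d>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read a grayscale image from PNG, TIFF or PGM
#'
#' Multi-channel input is converted to luminance (0.299 R + 0.587 G +
#' 0.114 B, rounded half-up). 16-bit input is rescaled to 0-255 by
#' dividing by the image maximum (not 65535) and rounding half-up:
#' microscopy images rarely use the full 16-bit range and the segmentation
#' model operates on 256-bin histograms.
#'
#' @param path path to a `.png`, `.tif`/`.tiff` or `.pgm` file.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8 && identical(magic, png_signature())) {
    px <- read_png_raw(path)
  } else if (length(magic) >= 4 &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    px <- read_tiff_raw(path)
  } else if (length(magic) >= 2 && magic[1] == as.raw(0x50) &&
             magic[2] %in% as.raw(c(0x32, 0x35))) {
    px <- read_pgm_raw(path)
  } else {
    stop("unrecognized image format: ", path, call. = FALSE)
  }
  gray_image(px)
}

# Collapse a height x width x channels array to 8-bit luminance,
# rescaling by the image max when the sample depth exceeds 8 bits.
channels_to_gray <- function(arr, bitdepth) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      y <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      y <- arr[, , 1]  # gray (+ alpha): drop alpha
    }
  } else {
    y <- arr
  }
  if (bitdepth > 8L) {
    mx <- max(y)
    if (mx > 0) y <- y / mx * 255
  }
  matrix(as.integer(round_half_up(y)), nrow = nrow(y), ncol = ncol(y))
}

#' Write a binary mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_png_raw(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @inheritParams write_mask
#' @param image a [gray_image()] or 0-255 integer matrix.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  write_png_raw(unclass(image), path)
  invisible(path)
}

# --- PGM (plain/raw) ------------------------------------------------------
# Text P2 and binary P5, maxval <= 65535. Kept for plain-text fixtures.

read_pgm_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  tok <- pgm_token_reader(con)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (is.na(w) || is.na(h) || w < 1 || h < 1 || is.na(maxv) || maxv < 1)
    stop("malformed PGM header", call. = FALSE)
  if (identical(magic, "P2")) {
    vals <- integer(w * h)
    for (i in seq_len(w * h)) vals[i] <- as.integer(tok())
  } else if (identical(magic, "P5")) {
    if (maxv > 255) {
      vals <- readBin(con, "integer", n = w * h, size = 2L,
                      signed = FALSE, endian = "big")
    } else {
      vals <- as.integer(readBin(con, "raw", n = w * h))
    }
  } else stop("not a PGM file", call. = FALSE)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  channels_to_gray(m, bitdepth = if (maxv > 255) 16L else 8L)
}

pgm_token_reader <- function(con) {
  function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || !nzchar(ch)) stop("truncated PGM", call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!nzchar(ch) || ch == "\n") break
        }
      } else if (!grepl("^[[:space:]]$", ch)) break
    }
    tokv <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!nzchar(ch) || grepl("^[[:space:]]$", ch)) break
      tokv <- paste0(tokv, ch)
    }
    tokv
  }
}

write_pgm <- function(image, path) {
  image <- as_gray_image(image)
  lines <- c("P2", paste(ncol(image), nrow(image)), "255",
             apply(unclass(image), 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
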