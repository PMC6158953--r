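# Minimal PNG codec (grayscale-oriented).
#
# Reading supports non-interlaced PNGs with bit depth 8 or 16 and color
# types 0 (gray), 2 (RGB), 3 (8-bit palette), 4 (gray+alpha) and
# 6 (RGBA); writing emits non-interlaced images with filter type 0.
# Deflate is delegated to zlib; CRCs likewise. Hand-rolled because no
# raster-image package is available in the deployment environment.

png_signature <- function() as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a,
                                     0x1a, 0x0a))

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

read_u32be <- function(r, off) {
  sum(as.integer(r[off + 0:3]) * c(16777216, 65536, 256, 1))
}

read_png_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 33 || !identical(raw[1:8], png_signature()))
    stop("not a PNG file: ", path, call. = FALSE)
  pos <- 9L
  width <- height <- bitdepth <- coltype <- interlace <- NA_integer_
  idat <- list()
  plte <- NULL
  while (pos + 7 <= length(raw)) {
    len <- read_u32be(raw, pos)
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    dstart <- pos + 8L
    data <- if (len > 0) raw[dstart:(dstart + len - 1)] else raw(0)
    if (type == "IHDR") {
      width <- read_u32be(data, 1)
      height <- read_u32be(data, 5)
      bitdepth <- as.integer(data[9])
      coltype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "PLTE") {
      plte <- matrix(as.integer(data), ncol = 3, byrow = TRUE)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- dstart + len + 4L  # skip CRC
  }
  if (is.na(width) || width < 1 || height < 1)
    stop("PNG has zero or missing dimensions", call. = FALSE)
  if (interlace != 0L)
    stop("interlaced PNG is not supported", call. = FALSE)
  if (!bitdepth %in% c(8L, 16L))
    stop("unsupported PNG bit depth: ", bitdepth, call. = FALSE)
  channels <- switch(as.character(coltype),
                     "0" = 1L, "2" = 3L, "3" = 1L, "4" = 2L, "6" = 4L,
                     stop("unsupported PNG color type: ", coltype,
                          call. = FALSE))
  if (coltype == 3L && (bitdepth != 8L || is.null(plte)))
    stop("only 8-bit palette PNGs with a PLTE chunk are supported",
         call. = FALSE)
  bpp <- channels * bitdepth %/% 8L
  stride <- width * bpp
  flt <- zlib_inflate(do.call(c, idat), height * (stride + 1))
  bytes <- as.integer(png_unfilter(flt, height, stride, bpp))

  if (bitdepth == 16L) {
    vals <- bytes[seq(1, length(bytes), 2)] * 256L +
      bytes[seq(2, length(bytes), 2)]
  } else vals <- bytes
  # vals: scanline-major, channel-interleaved
  arr <- aperm(array(vals, dim = c(channels, width, height)), c(3, 2, 1))
  if (coltype == 3L) {
    idx <- arr[, , 1] + 1L
    arr <- array(c(matrix(plte[idx, 1], nrow(arr)),
                   matrix(plte[idx, 2], nrow(arr)),
                   matrix(plte[idx, 3], nrow(arr))),
                 dim = c(dim(arr)[1:2], 3))
  }
  channels_to_gray(arr, bitdepth)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32_bytes(body)))
}

# image: integer matrix (gray) or height x width x 3 array (RGB);
# bitdepth 8 or 16. Scanlines use filter type 0.
write_png_raw <- function(image, path, bitdepth = 8L) {
  if (length(dim(image)) == 3L) {
    coltype <- 2L
    h <- dim(image)[1]; w <- dim(image)[2]
    vals <- as.vector(aperm(image, c(3, 2, 1)))  # interleave channels
  } else {
    coltype <- 0L
    h <- nrow(image); w <- ncol(image)
    vals <- as.vector(t(image))
  }
  channels <- if (coltype == 2L) 3L else 1L
  if (bitdepth == 16L) {
    bytes <- as.raw(rbind(vals %/% 256L, vals %% 256L))
  } else {
    if (max(vals) > 255L) stop("8-bit PNG cannot hold values > 255",
                               call. = FALSE)
    bytes <- as.raw(vals)
  }
  stride <- w * channels * bitdepth %/% 8L
  sl <- matrix(bytes, nrow = stride, ncol = h)
  flt <- as.raw(rbind(raw(h), sl))  # prepend filter byte 0 per scanline
  ihdr <- c(u32be(w), u32be(h), as.raw(c(bitdepth, coltype, 0, 0, 0)))
  out <- c(png_signature(),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_deflate(as.vector(flt))),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
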