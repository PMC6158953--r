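# Minimal baseline TIFF reader/writer (uncompressed grayscale or RGB,
# 8 or 16 bits per sample, both byte orders, first IFD only). Microscopy
# TIFFs exported as plain uncompressed rasters fit this profile; anything
# fancier (LZW, tiles, planar config 2) is rejected with a clear error.

read_tiff_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  le <- identical(raw[1:2], as.raw(c(0x49, 0x49)))
  be <- identical(raw[1:2], as.raw(c(0x4d, 0x4d)))
  if (!le && !be) stop("not a TIFF file: ", path, call. = FALSE)
  rd <- function(off, n) tiff_uint(raw, off, n, le)
  if (rd(3, 2) != 42L) stop("bad TIFF magic", call. = FALSE)
  ifd <- rd(5, 4)
  nent <- rd(ifd + 1, 2)
  tags <- list()
  for (i in seq_len(nent)) {
    e <- ifd + 3 + (i - 1) * 12
    tag <- rd(e, 2); typ <- rd(e + 2, 2); cnt <- rd(e + 4, 4)
    size <- c(1, 1, 2, 4, 8)[typ]
    if (is.na(size)) next
    nbytes <- size * cnt
    voff <- if (nbytes <= 4) e + 8 else rd(e + 8, 4) + 1
    vals <- vapply(seq_len(cnt), function(k)
      rd(voff + (k - 1) * size, size), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing tag ", tag, call. = FALSE)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8)[1]
  comp <- need(259, 1)
  spp <- need(277, 1)
  offsets <- need(273)
  rps <- need(278, h)
  counts <- need(279, NULL)
  if (comp != 1) stop("only uncompressed TIFF is supported", call. = FALSE)
  if (!bits %in% c(8, 16))
    stop("only 8/16-bit TIFF is supported", call. = FALSE)
  if (!is.null(tags[["284"]]) && tags[["284"]] != 1)
    stop("planar TIFF is not supported", call. = FALSE)
  if (w < 1 || h < 1) stop("TIFF has zero dimensions", call. = FALSE)
  bytes_per_px <- spp * bits / 8
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    rows <- min(rps, h - (s - 1) * rps)
    n_px <- rows * w * spp
    off <- offsets[s] + 1
    if (bits == 16) {
      chunk <- readBin(raw[off:(off + 2 * n_px - 1)], "integer",
                       n = n_px, size = 2L, signed = FALSE,
                       endian = if (le) "little" else "big")
    } else {
      chunk <- as.integer(raw[off:(off + n_px - 1)])
    }
    vals <- c(vals, chunk)
  }
  arr <- aperm(array(vals, dim = c(spp, w, h)), c(3, 2, 1))
  if (spp == 1L) arr <- arr[, , 1, drop = TRUE]
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = h, ncol = w)
  channels_to_gray(if (spp > 1L) arr else arr, bitdepth = bits)
}

tiff_uint <- function(raw, off, n, le) {
  b <- as.integer(raw[off:(off + n - 1)])
  if (le) sum(b * 256^(seq_len(n) - 1)) else sum(b * 256^rev(seq_len(n) - 1))
}

# Single-strip little-endian grayscale writer (8 or 16 bits), used to
# build round-trip fixtures in code rather than shipping binaries.
write_tiff_gray <- function(image, path, bitdepth = 8L) {
  h <- nrow(image); w <- ncol(image)
  vals <- as.vector(t(image))
  px <- if (bitdepth == 16L) {
    writeBin(as.integer(vals), raw(), size = 2L, endian = "little")
  } else as.raw(vals)
  le16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  le32 <- function(x) as.raw(c(x, x %/% 256, x %/% 65536, x %/% 16777216) %% 256)
  entry <- function(tag, typ, cnt, val)
    c(le16(tag), le16(typ), le32(cnt), le32(val))
  data_off <- 8L
  ifd_off <- data_off + length(px)
  entries <- list(
    entry(256, 3, 1, w), entry(257, 3, 1, h),
    entry(258, 3, 1, bitdepth), entry(259, 3, 1, 1),
    entry(262, 3, 1, 1),                      # BlackIsZero
    entry(273, 4, 1, data_off), entry(277, 3, 1, 1),
    entry(278, 3, 1, h), entry(279, 4, 1, length(px)))
  ifd <- c(le16(length(entries)), do.call(c, entries), le32(0))
  out <- c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), le32(ifd_off), px, ifd)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
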