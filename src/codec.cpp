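#include <Rcpp.h>
#include <zlib.h>
#include <vector>

using namespace Rcpp;

// zlib (RFC 1950) stream helpers for the PNG codec.

// [[Rcpp::export]]
RawVector zlib_deflate(RawVector data) {
  uLong srclen = data.size();
  uLong bound = compressBound(srclen);
  std::vector<Bytef> out(bound);
  uLongf outlen = bound;
  int rc = compress2(out.data(), &outlen,
                     (const Bytef*) RAW(data), srclen, 9);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector res(outlen);
  std::copy(out.begin(), out.begin() + outlen, res.begin());
  return res;
}

// [[Rcpp::export]]
RawVector zlib_inflate(RawVector data, double expected_size) {
  uLongf outlen = (uLongf) expected_size;
  RawVector res(outlen);
  int rc = uncompress((Bytef*) RAW(res), &outlen,
                      (const Bytef*) RAW(data), (uLong) data.size());
  if (rc != Z_OK) stop("zlib decompression failed (code %d)", rc);
  if (outlen != (uLongf) expected_size)
    stop("decompressed size %lu != expected %lu",
         (unsigned long) outlen, (unsigned long) expected_size);
  return res;
}

// [[Rcpp::export]]
double crc32_bytes(RawVector data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*) RAW(data), data.size());
  return (double) crc;
}

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// Reverse PNG scanline filtering. `data` holds height scanlines of
// (1 filter byte + stride bytes); bpp is bytes per pixel.
// [[Rcpp::export]]
RawVector png_unfilter(RawVector data, int height, int stride, int bpp) {
  if ((R_xlen_t)(height) * (stride + 1) != data.size())
    stop("filtered data has wrong length");
  RawVector out((R_xlen_t) height * stride);
  std::vector<unsigned char> prev(stride, 0), cur(stride, 0);
  R_xlen_t pos = 0;
  for (int y = 0; y < height; ++y) {
    int ft = data[pos++];
    for (int x = 0; x < stride; ++x) cur[x] = data[pos++];
    switch (ft) {
    case 0: break;
    case 1:
      for (int x = bpp; x < stride; ++x) cur[x] += cur[x - bpp];
      break;
    case 2:
      for (int x = 0; x < stride; ++x) cur[x] += prev[x];
      break;
    case 3:
      for (int x = 0; x < stride; ++x) {
        int left = x >= bpp ? cur[x - bpp] : 0;
        cur[x] += (unsigned char) ((left + prev[x]) / 2);
      }
      break;
    case 4:
      for (int x = 0; x < stride; ++x) {
        int left = x >= bpp ? cur[x - bpp] : 0;
        int ul = x >= bpp ? prev[x - bpp] : 0;
        cur[x] += (unsigned char) paeth(left, prev[x], ul);
      }
      break;
    default:
      stop("unsupported PNG filter type %d", ft);
    }
    std::copy(cur.begin(), cur.end(), out.begin() + (R_xlen_t) y * stride);
    prev = cur;
  }
  return out;
}
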