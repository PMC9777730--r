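// Minimal 8-bit PNG codec (zlib-backed) and nearest-neighbour colour decoding.
//
// The codec covers what this package reads and writes: bit depth 8, colour
// types 0 (gray), 2 (RGB), 3 (palette), 4 (gray+alpha), 6 (RGBA), filters
// 0-4, no Adam7 interlacing. Alpha is dropped on read; writing always uses
// filter 0 rows and one IDAT chunk, so output bytes are deterministic for a
// given pixel array.

#include <Rcpp.h>
#include <zlib.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

uint32_t read_be32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

void push_be32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

void push_chunk(std::vector<unsigned char>& out, const char* type,
                const unsigned char* data, size_t len) {
  push_be32(out, (uint32_t)len);
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (len) out.insert(out.end(), data, data + len);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(len + 4));
  push_be32(out, (uint32_t)crc);
}

int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

} // namespace

// Decode a PNG byte stream to an H x W x 3 integer array (RGB, 0-255).
// [[Rcpp::export(name = ".png_decode")]]
IntegerVector png_decode_(RawVector data) {
  const unsigned char* p = RAW(data);
  size_t n = data.size();
  if (n < 8 || std::memcmp(p, PNG_SIG, 8) != 0)
    stop("not a PNG file (bad signature)");

  uint32_t width = 0, height = 0;
  int bitdepth = 0, colortype = -1, interlace = 0;
  bool seen_ihdr = false;
  std::vector<unsigned char> idat, plte;

  size_t pos = 8;
  while (pos + 12 <= n) {
    uint32_t len = read_be32(p + pos);
    const char* type = (const char*)(p + pos + 4);
    if (pos + 12 + (size_t)len > n) stop("corrupt PNG: truncated chunk");
    const unsigned char* cdata = p + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      if (len != 13) stop("corrupt PNG: bad IHDR");
      width = read_be32(cdata);
      height = read_be32(cdata + 4);
      bitdepth = cdata[8];
      colortype = cdata[9];
      interlace = cdata[12];
      seen_ihdr = true;
    } else if (std::memcmp(type, "PLTE", 4) == 0) {
      plte.assign(cdata, cdata + len);
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), cdata, cdata + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + (size_t)len;
  }
  if (!seen_ihdr || idat.empty()) stop("corrupt PNG: missing IHDR or IDAT");
  if (bitdepth != 8) stop("unsupported PNG: only bit depth 8 is handled");
  if (interlace != 0) stop("unsupported PNG: interlaced images are not handled");
  if (width == 0 || height == 0) stop("corrupt PNG: zero dimension");

  int channels;
  switch (colortype) {
    case 0: channels = 1; break; // gray
    case 2: channels = 3; break; // RGB
    case 3: channels = 1; break; // palette index
    case 4: channels = 2; break; // gray + alpha
    case 6: channels = 4; break; // RGBA
    default: stop("unsupported PNG colour type %d", colortype);
  }
  if (colortype == 3 && plte.size() < 3) stop("corrupt PNG: palette missing");

  size_t stride = (size_t)width * channels;
  size_t rawlen = (stride + 1) * height;
  std::vector<unsigned char> rawbuf(rawlen);
  uLongf destLen = (uLongf)rawlen;
  int zret = uncompress(rawbuf.data(), &destLen, idat.data(), (uLong)idat.size());
  if (zret != Z_OK || destLen != rawlen)
    stop("PNG inflate failed (zlib code %d)", zret);

  // un-filter in place into a contiguous scanline buffer
  std::vector<unsigned char> img((size_t)width * height * channels);
  int bpp = channels;
  for (uint32_t r = 0; r < height; ++r) {
    unsigned char f = rawbuf[r * (stride + 1)];
    const unsigned char* cur = rawbuf.data() + r * (stride + 1) + 1;
    unsigned char* dst = img.data() + (size_t)r * stride;
    const unsigned char* up = r ? img.data() + (size_t)(r - 1) * stride : 0;
    for (size_t i = 0; i < stride; ++i) {
      int a = (i >= (size_t)bpp) ? dst[i - bpp] : 0;
      int b = up ? up[i] : 0;
      int c = (up && i >= (size_t)bpp) ? up[i - bpp] : 0;
      int x = cur[i], val;
      switch (f) {
        case 0: val = x; break;
        case 1: val = x + a; break;
        case 2: val = x + b; break;
        case 3: val = x + ((a + b) >> 1); break;
        case 4: val = x + paeth(a, b, c); break;
        default: stop("corrupt PNG: filter type %d", (int)f);
      }
      dst[i] = (unsigned char)(val & 0xff);
    }
  }

  // expand to RGB, column-major R array dim (H, W, 3)
  IntegerVector out((R_xlen_t)height * width * 3);
  size_t plane = (size_t)height * width;
  for (uint32_t r = 0; r < height; ++r) {
    for (uint32_t c = 0; c < width; ++c) {
      const unsigned char* px = img.data() + ((size_t)r * width + c) * channels;
      int R8, G8, B8;
      switch (colortype) {
        case 0: case 4: R8 = G8 = B8 = px[0]; break;
        case 2: case 6: R8 = px[0]; G8 = px[1]; B8 = px[2]; break;
        default: { // palette
          size_t idx = (size_t)px[0] * 3;
          if (idx + 2 >= plte.size()) stop("corrupt PNG: palette index out of range");
          R8 = plte[idx]; G8 = plte[idx + 1]; B8 = plte[idx + 2];
        }
      }
      size_t base = (size_t)r + (size_t)c * height;
      out[base] = R8;
      out[base + plane] = G8;
      out[base + 2 * plane] = B8;
    }
  }
  out.attr("dim") = IntegerVector::create(height, width, 3);
  return out;
}

// Encode an H x W x 3 integer array (RGB, 0-255) as PNG bytes.
// [[Rcpp::export(name = ".png_encode")]]
RawVector png_encode_(IntegerVector pixels, int height, int width) {
  if (height <= 0 || width <= 0) stop("image dimensions must be positive");
  if ((R_xlen_t)height * width * 3 != pixels.size())
    stop("pixel array does not match dimensions");

  size_t plane = (size_t)height * width;
  size_t stride = (size_t)width * 3;
  std::vector<unsigned char> raw((stride + 1) * height);
  for (int r = 0; r < height; ++r) {
    unsigned char* row = raw.data() + (size_t)r * (stride + 1);
    row[0] = 0; // filter: none
    for (int c = 0; c < width; ++c) {
      size_t base = (size_t)r + (size_t)c * height;
      for (int k = 0; k < 3; ++k) {
        int v = pixels[base + (size_t)k * plane];
        if (v < 0 || v > 255) stop("pixel values must be in 0..255");
        row[1 + (size_t)c * 3 + k] = (unsigned char)v;
      }
    }
  }

  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  int zret = compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(), 6);
  if (zret != Z_OK) stop("PNG deflate failed (zlib code %d)", zret);

  std::vector<unsigned char> out;
  out.reserve(bound + 128);
  out.insert(out.end(), PNG_SIG, PNG_SIG + 8);
  unsigned char ihdr[13];
  ihdr[0] = (width >> 24) & 0xff; ihdr[1] = (width >> 16) & 0xff;
  ihdr[2] = (width >> 8) & 0xff;  ihdr[3] = width & 0xff;
  ihdr[4] = (height >> 24) & 0xff; ihdr[5] = (height >> 16) & 0xff;
  ihdr[6] = (height >> 8) & 0xff;  ihdr[7] = height & 0xff;
  ihdr[8] = 8;  // bit depth
  ihdr[9] = 2;  // colour type: RGB
  ihdr[10] = 0; ihdr[11] = 0; ihdr[12] = 0;
  push_chunk(out, "IHDR", ihdr, 13);
  push_chunk(out, "IDAT", comp.data(), bound);
  push_chunk(out, "IEND", 0, 0);
  return RawVector(out.begin(), out.end());
}

// Nearest LUT level per pixel, squared-Euclidean RGB distance, ties to the
// lowest index (lowest stiffness). rgb: n x 3, lut: L x 3. Returns 1-based
// level indices.
// [[Rcpp::export(name = ".nn_level")]]
IntegerVector nn_level_(IntegerMatrix rgb, IntegerMatrix lut) {
  int n = rgb.nrow(), L = lut.nrow();
  if (rgb.ncol() != 3 || lut.ncol() != 3) stop("rgb and lut must have 3 columns");
  IntegerVector out(n);
  std::vector<int> lr(L), lg(L), lb(L);
  for (int l = 0; l < L; ++l) { lr[l] = lut(l, 0); lg[l] = lut(l, 1); lb[l] = lut(l, 2); }
  for (int i = 0; i < n; ++i) {
    int r = rgb(i, 0), g = rgb(i, 1), b = rgb(i, 2);
    int best = 0; long bestd = 1L << 30;
    for (int l = 0; l < L; ++l) {
      int dr = r - lr[l], dg = g - lg[l], db = b - lb[l];
      long d = (long)dr * dr + (long)dg * dg + (long)db * db;
      if (d < bestd) { bestd = d; best = l; }
    }
    out[i] = best + 1;
  }
  return out;
}
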