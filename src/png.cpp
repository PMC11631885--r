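// Minimal PNG codec for label masks, backed by zlib.
//
// The environment provides no PNG-capable R package, so the package carries
// its own small codec. Scope is deliberately narrow: 8-bit, non-interlaced,
// colour type 3 (indexed, our writer's format) or 0 (greyscale) images, which
// covers the segmentation masks this package reads and writes. Pixel values
// are returned as integer labels; the palette is cosmetic.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::RawVector;

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

uint32_t get_u32(const unsigned char* p) {
  return (uint32_t(p[0]) << 24) | (uint32_t(p[1]) << 16) | (uint32_t(p[2]) << 8) |
         uint32_t(p[3]);
}

void put_chunk(std::vector<unsigned char>& out, const char type[5],
               const std::vector<unsigned char>& data) {
  put_u32(out, static_cast<uint32_t>(data.size()));
  std::vector<unsigned char> td(type, type + 4);
  td.insert(td.end(), data.begin(), data.end());
  out.insert(out.end(), td.begin(), td.end());
  put_u32(out, static_cast<uint32_t>(crc32(0L, td.data(), td.size())));
}

}  // namespace

// mask: integer matrix (values 0..255); palette: n x 3 integer RGB.
// [[Rcpp::export]]
void cpp_png_write_indexed(const std::string& path, const IntegerMatrix& mask,
                           const IntegerMatrix& palette) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<unsigned char> raw(static_cast<size_t>(H) * (W + 1));
  for (int r = 0; r < H; ++r) {
    raw[static_cast<size_t>(r) * (W + 1)] = 0;  // filter type 0
    for (int c = 0; c < W; ++c) {
      const int v = mask(r, c);
      if (v < 0 || v > 255) Rcpp::stop("mask values must be in 0..255");
      raw[static_cast<size_t>(r) * (W + 1) + 1 + c] = static_cast<unsigned char>(v);
    }
  }
  uLongf bound = compressBound(raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), raw.size(), 6) != Z_OK)
    Rcpp::stop("zlib compression failed");
  comp.resize(bound);

  std::vector<unsigned char> out = {0x89, 'P', 'N', 'G', 0x0d, 0x0a, 0x1a, 0x0a};
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, W);
  put_u32(ihdr, H);
  ihdr.push_back(8);   // bit depth
  ihdr.push_back(3);   // colour type: indexed
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter method
  ihdr.push_back(0);   // no interlace
  put_chunk(out, "IHDR", ihdr);
  std::vector<unsigned char> plte;
  for (int i = 0; i < palette.nrow(); ++i)
    for (int j = 0; j < 3; ++j)
      plte.push_back(static_cast<unsigned char>(palette(i, j) & 0xff));
  put_chunk(out, "PLTE", plte);
  put_chunk(out, "IDAT", comp);
  put_chunk(out, "IEND", {});

  std::FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) Rcpp::stop("cannot open '%s' for writing", path.c_str());
  std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
}

// [[Rcpp::export]]
IntegerMatrix cpp_png_read(const std::string& path) {
  std::FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) Rcpp::stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long sz = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf(sz > 0 ? sz : 0);
  if (sz > 0 && std::fread(buf.data(), 1, sz, f) != static_cast<size_t>(sz)) {
    std::fclose(f);
    Rcpp::stop("short read on '%s'", path.c_str());
  }
  std::fclose(f);
  static const unsigned char sig[8] = {0x89, 'P', 'N', 'G', 0x0d, 0x0a, 0x1a, 0x0a};
  if (buf.size() < 8 || std::memcmp(buf.data(), sig, 8) != 0)
    Rcpp::stop("'%s' is not a PNG file", path.c_str());

  uint32_t W = 0, H = 0;
  int depth = 0, ctype = -1, interlace = 0;
  std::vector<unsigned char> idat;
  size_t pos = 8;
  while (pos + 8 <= buf.size()) {
    const uint32_t len = get_u32(&buf[pos]);
    if (pos + 12 + len > buf.size()) Rcpp::stop("truncated PNG chunk");
    const char* type = reinterpret_cast<const char*>(&buf[pos + 4]);
    const unsigned char* data = &buf[pos + 8];
    if (std::memcmp(type, "IHDR", 4) == 0) {
      W = get_u32(data);
      H = get_u32(data + 4);
      depth = data[8];
      ctype = data[9];
      interlace = data[12];
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (W == 0 || H == 0) Rcpp::stop("PNG missing IHDR");
  if (depth != 8 || (ctype != 3 && ctype != 0) || interlace != 0)
    Rcpp::stop(
        "unsupported PNG variant (need 8-bit indexed or greyscale, "
        "non-interlaced); got depth %d colour type %d",
        depth, ctype);

  const size_t stride = static_cast<size_t>(W) + 1;
  std::vector<unsigned char> raw(static_cast<size_t>(H) * stride);
  uLongf destlen = raw.size();
  int zrc = uncompress(raw.data(), &destlen, idat.data(), idat.size());
  if (zrc != Z_OK || destlen != raw.size()) Rcpp::stop("PNG inflate failed");

  // undo scanline filters (bytes-per-pixel = 1)
  std::vector<unsigned char> img(static_cast<size_t>(H) * W);
  for (uint32_t r = 0; r < H; ++r) {
    const unsigned char ft = raw[r * stride];
    for (uint32_t c = 0; c < W; ++c) {
      const int x = raw[r * stride + 1 + c];
      const int a = c > 0 ? img[static_cast<size_t>(r) * W + c - 1] : 0;
      const int b = r > 0 ? img[static_cast<size_t>(r - 1) * W + c] : 0;
      const int cc = (r > 0 && c > 0) ? img[static_cast<size_t>(r - 1) * W + c - 1] : 0;
      int v = 0;
      switch (ft) {
        case 0: v = x; break;
        case 1: v = x + a; break;
        case 2: v = x + b; break;
        case 3: v = x + (a + b) / 2; break;
        case 4: {
          const int p = a + b - cc;
          const int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - cc);
          v = x + ((pa <= pb && pa <= pc) ? a : (pb <= pc ? b : cc));
          break;
        }
        default: Rcpp::stop("unsupported PNG filter type %d", ft);
      }
      img[static_cast<size_t>(r) * W + c] = static_cast<unsigned char>(v & 0xff);
    }
  }
  IntegerMatrix out(H, W);
  for (uint32_t r = 0; r < H; ++r)
    for (uint32_t c = 0; c < W; ++c) out(r, c) = img[static_cast<size_t>(r) * W + c];
  return out;
}
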