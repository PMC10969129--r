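// Minimal 8-bit PNG reader/writer over zlib, sufficient for the package's
// on-disk dataset format. Writer emits non-interlaced RGB (color type 2)
// with filter 0 on every scanline; reader accepts bit-depth-8 grayscale,
// gray+alpha, RGB and RGBA, any of the five standard scanline filters,
// no interlacing. Intensities are exchanged with R as doubles in [0, 1].
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

void write_chunk(std::vector<unsigned char>& out, const char* type,
                 const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, (uint32_t)crc);
}

int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

}  // namespace

// pixels: H x W x 3 array of doubles in [0, 1]; values are clamped then
// quantized with round(v * 255).
// [[Rcpp::export]]
void png_write_rgb8(std::string path, NumericVector pixels) {
  IntegerVector d = pixels.attr("dim");
  if (d.size() != 3 || d[2] != 3)
    stop("png_write_rgb8: pixels must be an H x W x 3 array");
  int H = d[0], W = d[1];
  // raw stream: per row, filter byte 0 then RGB triples
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * 3));
  size_t pos = 0;
  for (int i = 0; i < H; ++i) {
    raw[pos++] = 0;
    for (int j = 0; j < W; ++j) {
      for (int c = 0; c < 3; ++c) {
        double v = pixels[i + (size_t)H * j + (size_t)H * W * c];
        if (v < 0) v = 0;
        if (v > 1) v = 1;
        raw[pos++] = (unsigned char)std::lround(v * 255.0);
      }
    }
  }
  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("png_write_rgb8: zlib compression failed");
  comp.resize(bound);

  std::vector<unsigned char> out(PNG_SIG, PNG_SIG + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(8);   // bit depth
  ihdr.push_back(2);   // color type RGB
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter method
  ihdr.push_back(0);   // no interlace
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", comp);
  write_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("png_write_rgb8: cannot open '%s' for writing", path.c_str());
  size_t n = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (n != out.size()) stop("png_write_rgb8: short write to '%s'", path.c_str());
}

// Returns an H x W x C array (C = 1 or 3) of doubles in [0, 1]; alpha
// channels are dropped.
// [[Rcpp::export]]
NumericVector png_read_cpp(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("png_read: cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long sz = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)sz);
  size_t got = std::fread(buf.data(), 1, (size_t)sz, f);
  std::fclose(f);
  if (got != (size_t)sz || sz < 8 || std::memcmp(buf.data(), PNG_SIG, 8) != 0)
    stop("png_read: '%s' is not a PNG file", path.c_str());

  uint32_t W = 0, H = 0;
  int bit_depth = 0, color_type = -1, interlace = 0;
  std::vector<unsigned char> idat;
  size_t pos = 8;
  while (pos + 12 <= (size_t)sz) {
    uint32_t len = get_u32(&buf[pos]);
    const char* type = (const char*)&buf[pos + 4];
    const unsigned char* data = &buf[pos + 8];
    if (pos + 12 + len > (size_t)sz) stop("png_read: truncated chunk");
    if (std::memcmp(type, "IHDR", 4) == 0) {
      W = get_u32(data);
      H = get_u32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      interlace = data[12];
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (W == 0 || H == 0) stop("png_read: missing IHDR");
  if (bit_depth != 8) stop("png_read: only bit depth 8 is supported");
  if (interlace != 0) stop("png_read: interlaced PNG is not supported");
  int nch;
  switch (color_type) {
    case 0: nch = 1; break;  // gray
    case 2: nch = 3; break;  // RGB
    case 4: nch = 2; break;  // gray + alpha
    case 6: nch = 4; break;  // RGBA
    default: stop("png_read: unsupported color type %d", color_type);
  }
  size_t stride = (size_t)W * nch;
  size_t raw_len = H * (stride + 1);
  std::vector<unsigned char> raw(raw_len);
  uLongf dest_len = (uLongf)raw_len;
  int zrc = uncompress(raw.data(), &dest_len, idat.data(), (uLong)idat.size());
  if (zrc != Z_OK || dest_len != raw_len)
    stop("png_read: zlib inflate failed (%d)", zrc);

  // undo scanline filters in place (result stored row-major per row)
  std::vector<unsigned char> img((size_t)H * stride);
  for (uint32_t i = 0; i < H; ++i) {
    unsigned char ft = raw[i * (stride + 1)];
    const unsigned char* src = &raw[i * (stride + 1) + 1];
    unsigned char* cur = &img[i * stride];
    const unsigned char* up = i > 0 ? &img[(i - 1) * stride] : nullptr;
    for (size_t x = 0; x < stride; ++x) {
      int A = x >= (size_t)nch ? cur[x - nch] : 0;
      int B = up ? up[x] : 0;
      int C = (up && x >= (size_t)nch) ? up[x - nch] : 0;
      int v = src[x];
      switch (ft) {
        case 0: break;
        case 1: v += A; break;
        case 2: v += B; break;
        case 3: v += (A + B) / 2; break;
        case 4: v += paeth(A, B, C); break;
        default: stop("png_read: unknown filter type %d", ft);
      }
      cur[x] = (unsigned char)(v & 0xff);
    }
  }

  int out_ch = (nch >= 3) ? 3 : 1;
  NumericVector out((size_t)H * W * out_ch);
  out.attr("dim") = IntegerVector::create((int)H, (int)W, out_ch);
  for (uint32_t i = 0; i < H; ++i)
    for (uint32_t j = 0; j < W; ++j)
      for (int c = 0; c < out_ch; ++c)
        out[i + (size_t)H * j + (size_t)H * W * c] =
            img[i * stride + (size_t)j * nch + c] / 255.0;
  return out;
}
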