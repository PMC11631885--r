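// Binary image utilities: 8-connected component labelling and Zhang-Suen
// morphological thinning (medial-axis style skeletonization).

#include <Rcpp.h>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::LogicalMatrix;

// Label 8-connected components of fg (non-zero = foreground). Labels 1..n.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& fg) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (fg(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int k = 0; k < 8; ++k) {
          const int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (fg(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  return lab;
}

// Zhang-Suen thinning of a binary image. Returns the 1-px-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_skeletonize(const LogicalMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<unsigned char> a(static_cast<size_t>(H) * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) a[r + static_cast<size_t>(c) * H] = img(r, c) ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return a[r + static_cast<size_t>(c) * H];
  };
  std::vector<size_t> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (!a[r + static_cast<size_t>(c) * H]) continue;
          // neighbours clockwise from north: p2..p9
          const int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
                    p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
                    p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                        (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                        (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                        (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + static_cast<size_t>(c) * H);
        }
      if (!kill.empty()) changed = true;
      for (size_t k : kill) a[k] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) out(r, c) = a[r + static_cast<size_t>(c) * H] != 0;
  return out;
}
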