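#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive integer-shift block matching by Euclidean distance between
// intensity patches.  Candidate shifts are visited in order of increasing
// displacement magnitude (then row offset, then col offset), so accepting
// only strict improvements realizes the tie-break rule: smallest |d|,
// then lexicographic (drow, dcol).  Partial sums abandon a candidate as
// soon as it exceeds the current best, which keeps the scan cheap.
//
// origins: 1-based top-left corners of each tile in the reference frame.
// pred:    integer predicted shift per tile, added to the tile origin to
//          center the search window (zero for the coarse stage).
// Shifts whose window would leave the moving frame are skipped; a tile
// with no in-bounds candidate is flagged invalid rather than erroring.
//
// Returns an n x 4 matrix: drow, dcol (residual shift relative to the
// prediction), score (Euclidean distance = sqrt(SSD)), valid (0/1).
// [[Rcpp::export]]
NumericMatrix match_tiles_cpp(NumericMatrix ref, NumericMatrix mov,
                              IntegerMatrix origins, IntegerMatrix pred,
                              int tile, int radius) {
  const int H = mov.nrow(), W = mov.ncol();
  if (ref.nrow() != H || ref.ncol() != W)
    stop("reference and moving frames must share one shape");
  if (tile < 1 || tile > H || tile > W)
    stop("tile size must be positive and fit inside the frame");
  if (radius < 0)
    stop("search radius must be non-negative");
  const int n = origins.nrow();

  std::vector<std::array<int, 2> > cand;
  cand.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc) {
      std::array<int, 2> s = {{dr, dc}};
      cand.push_back(s);
    }
  std::sort(cand.begin(), cand.end(),
            [](const std::array<int, 2>& a, const std::array<int, 2>& b) {
              const int ma = a[0] * a[0] + a[1] * a[1];
              const int mb = b[0] * b[0] + b[1] * b[1];
              if (ma != mb) return ma < mb;
              if (a[0] != b[0]) return a[0] < b[0];
              return a[1] < b[1];
            });

  const double* R0 = ref.begin();
  const double* M0 = mov.begin();
  NumericMatrix out(n, 4);

  for (int i = 0; i < n; ++i) {
    const int r0 = origins(i, 0) - 1, c0 = origins(i, 1) - 1;
    if (r0 < 0 || c0 < 0 || r0 + tile > H || c0 + tile > W)
      stop("tile origin places the tile outside the reference frame");
    const int pr = pred(i, 0), pc = pred(i, 1);

    double best = R_PosInf;
    int bdr = 0, bdc = 0;
    bool found = false;

    for (std::size_t k = 0; k < cand.size(); ++k) {
      const int dr = cand[k][0], dc = cand[k][1];
      const int rr = r0 + pr + dr, cc = c0 + pc + dc;
      if (rr < 0 || cc < 0 || rr + tile > H || cc + tile > W) continue;
      double ssd = 0.0;
      for (int c = 0; c < tile; ++c) {
        const double* pm = M0 + static_cast<std::size_t>(cc + c) * H + rr;
        const double* pf = R0 + static_cast<std::size_t>(c0 + c) * H + r0;
        for (int r = 0; r < tile; ++r) {
          const double d = pm[r] - pf[r];
          ssd += d * d;
        }
        if (ssd >= best) break;
      }
      if (ssd < best) {
        best = ssd;
        bdr = dr;
        bdc = dc;
        found = true;
      }
    }

    out(i, 0) = bdr;
    out(i, 1) = bdc;
    out(i, 2) = found ? std::sqrt(best) : NA_REAL;
    out(i, 3) = found ? 1.0 : 0.0;
  }
  return out;
}
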