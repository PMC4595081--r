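#include <Rcpp.h>
using namespace Rcpp;

// Chain-structured dynamic program for the fine boundary model.
//
// The boundary is a sequence of points eta_0 .. eta_2n; the log-posterior is
// a sum over consecutive pairs of g_i(eta_{i-1}, eta_i), where g_i adds the
// per-pixel edge log-likelihood ratios of the segment's expected edge type
// along the rasterized segment, plus the orientation prior
// -B * circdist45(alpha_i, beta_i). The global maximizer over the product
// of admissible sets is found by the standard forward pass + backtrack.
//
// Pixel accounting matches the R reference (fine_objective): the first
// segment includes both endpoints; later segments exclude their start
// pixel, so join pixels are counted once.

static inline int dir_code8(int dr, int dc) {
  if (dr == 0 && dc == 0) return -1;
  double ang = std::atan2((double)dr, (double)dc);
  int code = (int)std::lround(ang / (M_PI / 4.0));
  return ((code % 8) + 8) % 8;
}

static inline int circ_dist8(int a, int b) {
  int d = std::abs(a - b) % 8;
  return std::min(d, 8 - d);
}

// sum of L over the Bresenham line from (r0,c0) to (r1,c1); when
// include_start is false the first pixel is skipped
static double line_sum(const double* L, int nr, int nc, int r0, int c0,
                       int r1, int c1, bool include_start) {
  int dr = std::abs(r1 - r0), dc = std::abs(c1 - c0);
  int sr = r0 < r1 ? 1 : -1, sc = c0 < c1 ? 1 : -1;
  int err = dc - dr;
  double total = 0.0;
  bool first = true;
  for (;;) {
    if (!first || include_start) {
      if (r0 >= 1 && r0 <= nr && c0 >= 1 && c0 <= nc)
        total += L[(r0 - 1) + (c0 - 1) * nr];
    }
    first = false;
    if (r0 == r1 && c0 == c1) break;
    int e2 = 2 * err;
    if (e2 > -dr) { err -= dr; c0 += sc; }
    if (e2 < dc) { err += dc; r0 += sr; }
  }
  return total;
}

// [[Rcpp::export]]
List dp_solve_cpp(List corridors, NumericVector lmaps, IntegerVector edge_types,
                  IntegerVector beta, double B) {
  IntegerVector ldim = lmaps.attr("dim");
  int nr = ldim[0], nc = ldim[1];
  const double* lm = REAL(lmaps);
  int m = corridors.size();          // number of boundary points (2n + 1)
  if (m < 2) stop("need at least two admissible sets");
  if (edge_types.size() != m - 1 || beta.size() != m - 1)
    stop("edge_types and beta must have one entry per segment");

  std::vector<IntegerMatrix> G(m);
  for (int i = 0; i < m; ++i) {
    G[i] = as<IntegerMatrix>(corridors[i]);
    if (G[i].nrow() == 0) stop("empty admissible set");
  }

  std::vector<std::vector<double>> val(m);
  std::vector<std::vector<int>> back(m);
  val[0].assign(G[0].nrow(), 0.0);
  back[0].assign(G[0].nrow(), -1);

  for (int i = 1; i < m; ++i) {
    int ncur = G[i].nrow(), nprev = G[i - 1].nrow();
    val[i].assign(ncur, R_NegInf);
    back[i].assign(ncur, -1);
    const double* L = lm + (size_t)(edge_types[i - 1] - 1) * nr * nc;
    bool include_start = (i == 1);
    for (int j = 0; j < ncur; ++j) {
      int rc = G[i](j, 0), cc = G[i](j, 1);
      double bestv = R_NegInf;
      int bestk = -1;
      for (int k = 0; k < nprev; ++k) {
        int rp = G[i - 1](k, 0), cp = G[i - 1](k, 1);
        double g = line_sum(L, nr, nc, rp, cp, rc, cc, include_start);
        int code = dir_code8(rc - rp, cc - cp);
        if (code >= 0) g -= B * circ_dist8(code, beta[i - 1]);
        double v = val[i - 1][k] + g;
        if (v > bestv) { bestv = v; bestk = k; }
      }
      val[i][j] = bestv;
      back[i][j] = bestk;
    }
  }

  int last = 0;
  double bestv = val[m - 1][0];
  for (int j = 1; j < (int)val[m - 1].size(); ++j)
    if (val[m - 1][j] > bestv) { bestv = val[m - 1][j]; last = j; }

  IntegerMatrix path(m, 2);
  int cur = last;
  for (int i = m - 1; i >= 0; --i) {
    path(i, 0) = G[i](cur, 0);
    path(i, 1) = G[i](cur, 1);
    cur = back[i][cur];
  }
  return List::create(_["boundary"] = path, _["log_post"] = bestv);
}
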