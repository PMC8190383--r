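#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// A gap of length k costs gap_open + k * gap_ext.

// [[Rcpp::export(name = ".sw_score_matrix")]]
NumericMatrix sw_score_matrix(CharacterVector reads, CharacterVector refs,
                              double match, double mismatch,
                              double gap_open, double gap_ext) {
  const int nr = reads.size(), nf = refs.size();
  NumericMatrix out(nr, nf);
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_ext;
  for (int f = 0; f < nf; ++f) {
    const std::string b = as<std::string>(refs[f]);
    const int m = (int) b.size();
    std::vector<double> H(m + 1), Fv(m + 1);
    for (int r = 0; r < nr; ++r) {
      const std::string a = as<std::string>(reads[r]);
      const int n = (int) a.size();
      std::fill(H.begin(), H.end(), 0.0);
      std::fill(Fv.begin(), Fv.end(), NEG);
      double best = 0.0;
      for (int i = 1; i <= n; ++i) {
        double diag = 0.0;   // H[i-1][j-1]
        double E = NEG;
        double Hleft = 0.0;  // H[i][j-1]
        const char ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
          E = std::max(Hleft - open_cost, E - gap_ext);
          Fv[j] = std::max(H[j] - open_cost, Fv[j] - gap_ext);
          const double s = (ai == b[j - 1]) ? match : mismatch;
          double h = diag + s;
          if (E > h) h = E;
          if (Fv[j] > h) h = Fv[j];
          if (h < 0.0) h = 0.0;
          diag = H[j];
          H[j] = h;
          Hleft = h;
          if (h > best) best = h;
        }
      }
      out(r, f) = best;
    }
  }
  return out;
}

// Full traceback for one read/ref pair. Returns the optimal local alignment
// with deterministic tie-breaking (first best cell in row-major scan;
// diagonal preferred over gaps during traceback). Positions are 1-based.
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int) a.size(), m = (int) b.size();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_ext;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> Fv((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double e = std::max(H[at(i, j - 1)] - open_cost,
                                E[at(i, j - 1)] - gap_ext);
      const double f = std::max(H[at(i - 1, j)] - open_cost,
                                Fv[at(i - 1, j)] - gap_ext);
      const double s = (ai == b[j - 1]) ? match : mismatch;
      double h = H[at(i - 1, j - 1)] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      E[at(i, j)] = e; Fv[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> rpos, spos;  // aligned (non-gap) columns
  int mism = 0;
  int i = bi, j = bj;
  int read_start = bi + 1, seg_start = bj + 1;
  // state 0 = H, 1 = E (gap in read axis: consumes ref), 2 = F (consumes read)
  int state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      const double h = H[at(i, j)];
      if (h <= 0.0) break;
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (h == H[at(i - 1, j - 1)] + s) {
        rpos.push_back(i); spos.push_back(j);
        if (a[i - 1] != b[j - 1]) ++mism;
        read_start = i; seg_start = j;
        --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      const double e = E[at(i, j)];
      seg_start = j;
      if (e == H[at(i, j - 1)] - open_cost) { --j; state = 0; }
      else { --j; }
    } else {
      const double f = Fv[at(i, j)];
      read_start = i;
      if (f == H[at(i - 1, j)] - open_cost) { --i; state = 0; }
      else { --i; }
    }
  }
  std::reverse(rpos.begin(), rpos.end());
  std::reverse(spos.begin(), spos.end());
  return List::create(
    _["score"] = best,
    _["read_start"] = read_start, _["read_end"] = bi,
    _["seg_start"] = seg_start, _["seg_end"] = bj,
    _["mismatches"] = mism,
    _["read_pos"] = IntegerVector(rpos.begin(), rpos.end()),
    _["seg_pos"] = IntegerVector(spos.begin(), spos.end()));
}
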