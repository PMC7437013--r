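#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Synchronization likelihood over all channel pairs of one segment.
//
// Each channel is time-delay embedded (dimension m, lag L). For a reference
// index k, candidate indices j satisfy w1 < |k - j| <= w2 within the valid
// embedding range (a Theiler corridor that excludes autocorrelated
// neighbours while bounding the search horizon). The critical distance
// eps_c(k) is the ceil(pref * n_cand)-th smallest Euclidean distance to the
// candidates; recurrences are candidates within eps_c(k) (ties at eps
// included). For a pair (a, b),
//   SL_ab(k) = sum_j R_a(k,j) R_b(k,j) / sum_j R_a(k,j)
// and the reported value is the mean over retained k of the symmetrised
// (SL_ab + SL_ba) / 2. Recurrence rows are held as 64-bit masks so the pair
// accumulation is popcount work.
// [[Rcpp::export(name = ".sl_pairwise")]]
NumericMatrix sl_pairwise(NumericMatrix segment, int L, int m, int w1, int w2,
                          double pref, int nrec) {
  const int n = segment.nrow();
  const int nc = segment.ncol();
  const int span = (m - 1) * L;
  const int nk = n - span;
  if (nk < 2) stop("segment too short for the requested embedding");

  // embeddings: emb[c][k*m + d]
  std::vector<std::vector<double> > emb(nc);
  for (int c = 0; c < nc; ++c) {
    emb[c].resize((size_t)nk * m);
    for (int k = 0; k < nk; ++k)
      for (int d = 0; d < m; ++d)
        emb[c][(size_t)k * m + d] = segment(k + d * L, c);
  }

  const int win = 2 * w2 + 1;           // max candidate window width
  const int nwords = (win + 63) / 64;
  std::vector<std::vector<uint64_t> > rows(nc,
      std::vector<uint64_t>(nwords, 0));
  std::vector<double> den(nc);
  std::vector<double> d2(win), tmp(win);
  std::vector<int> cand(win);

  NumericMatrix acc(nc, nc);            // acc(a,b): sum over k of num/den_a
  long retained = 0;

  for (int k = 0; k < nk; ++k) {
    const int jlo = std::max(0, k - w2);
    const int jhi = std::min(nk - 1, k + w2);
    int ncand = 0;
    for (int j = jlo; j <= jhi; ++j) {
      const int gap = j > k ? j - k : k - j;
      if (gap > w1) cand[ncand++] = j;
    }
    if (ncand < nrec) continue;
    int ncrit = (int)std::ceil(pref * ncand);
    if (ncrit < 1) ncrit = 1;

    for (int c = 0; c < nc; ++c) {
      const double *E = emb[c].data();
      const double *ek = E + (size_t)k * m;
      for (int t = 0; t < ncand; ++t) {
        const double *ej = E + (size_t)cand[t] * m;
        double s = 0.0;
        for (int d = 0; d < m; ++d) {
          const double diff = ek[d] - ej[d];
          s += diff * diff;
        }
        d2[t] = s;
      }
      std::copy(d2.begin(), d2.begin() + ncand, tmp.begin());
      std::nth_element(tmp.begin(), tmp.begin() + (ncrit - 1),
                       tmp.begin() + ncand);
      const double eps2 = tmp[ncrit - 1];

      std::fill(rows[c].begin(), rows[c].end(), 0);
      int dc = 0;
      for (int t = 0; t < ncand; ++t) {
        if (d2[t] <= eps2) {
          const int bit = cand[t] - jlo;
          rows[c][bit >> 6] |= (uint64_t)1 << (bit & 63);
          ++dc;
        }
      }
      den[c] = (double)dc;
    }

    for (int a = 0; a < nc - 1; ++a) {
      const uint64_t *ra = rows[a].data();
      for (int b = a + 1; b < nc; ++b) {
        const uint64_t *rb = rows[b].data();
        long num = 0;
        for (int w = 0; w < nwords; ++w) {
#if defined(__GNUC__) || defined(__clang__)
          num += __builtin_popcountll(ra[w] & rb[w]);
#else
          uint64_t v = ra[w] & rb[w];
          while (v) { v &= v - 1; ++num; }
#endif
        }
        acc(a, b) += num / den[a];
        acc(b, a) += num / den[b];
      }
    }
    ++retained;
  }

  if (retained == 0)
    stop("no reference index has enough recurrence candidates");

  NumericMatrix out(nc, nc);
  for (int a = 0; a < nc; ++a) {
    out(a, a) = 1.0;
    for (int b = a + 1; b < nc; ++b) {
      const double v = (acc(a, b) + acc(b, a)) / (2.0 * retained);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}
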