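#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev-distance template counting for sample entropy (Richman-Moorman).
// B = # ordered pairs i < j (both in 1..N-m) whose length-m templates match,
// A = # of those pairs whose length-(m+1) templates also match.
// Match criterion is strict: max |x_i+k - x_j+k| < r. Self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nm = n - m; // number of templates with an (m+1)-extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Approximate entropy phi_m (Pincus): self-matches included, criterion <= r.
// ApEn(m, r) = phi(m) - phi(m+1).
// [[Rcpp::export(name = ".apen_phi")]]
double apen_phi(NumericVector x, int m, double r) {
  int n = x.size();
  int nm = n - m + 1;
  if (nm <= 0) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) ++cnt;
    }
    acc += std::log((double)cnt / (double)nm);
  }
  return acc / (double)nm;
}

// LZ76 exhaustive-history parsing of a 0/1 sequence; returns the phrase count.
// A phrase starting at i extends while s[i..j] occurs as a substring of
// s[0..j-1] beginning at some position < i (overlap with the phrase allowed);
// the first non-reproducible symbol closes the phrase. Candidate start
// positions are filtered incrementally, so typical sequences parse in near
// linear time.
// [[Rcpp::export(name = ".lz76_phrases")]]
int lz76_phrases(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 0;
  int i = 0;
  std::vector<int> cand, keep;
  while (i < n) {
    // l = longest reproducible prefix of the phrase starting at i;
    // cand = history start positions matching that prefix
    cand.clear();
    for (int start = 0; start < i; ++start) if (s[start] == s[i]) cand.push_back(start);
    int l = cand.empty() ? 0 : 1;
    while (l > 0 && i + l < n) {
      keep.clear();
      for (size_t q = 0; q < cand.size(); ++q) {
        if (s[cand[q] + l] == s[i + l]) keep.push_back(cand[q]);
      }
      if (keep.empty()) break;
      cand.swap(keep);
      ++l;
    }
    // phrase = reproducible prefix + one innovative symbol, unless the
    // reproducible prefix runs to the end of the sequence
    int phrase_len = (i + l < n) ? (l + 1) : (n - i);
    ++c;
    i += phrase_len;
  }
  return c;
}

// Natural visibility graph edges under the strict criterion (collinear
// intermediate points block visibility). times strictly increasing.
// Returns a 2-column 1-based integer matrix of node pairs (a < b).
// [[Rcpp::export(name = ".nvg_edges")]]
IntegerMatrix nvg_edges(NumericVector t, NumericVector y) {
  int n = t.size();
  std::vector<int> from, to;
  for (int a = 0; a < n - 1; ++a) {
    double maxslope = R_NegInf;
    for (int b = a + 1; b < n; ++b) {
      double slope = (y[b] - y[a]) / (t[b] - t[a]);
      if (b == a + 1 || slope > maxslope) {
        from.push_back(a + 1);
        to.push_back(b + 1);
      }
      if (slope > maxslope) maxslope = slope;
    }
  }
  int m = from.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = from[e]; out(e, 1) = to[e]; }
  return out;
}
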