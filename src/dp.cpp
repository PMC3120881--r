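#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Rolling 2-bit k-mer codes over an uppercase DNA string. Codes are exact in
// a double for k <= 25 (4^25 < 2^53); windows containing any non-ACGT base
// yield NA. Position i holds the code of the k-mer starting at i (1-based in
// the returned vector).
// [[Rcpp::export]]
NumericVector kmer_codes_cpp(std::string seq, int k) {
  int n = (int)seq.size();
  if (k < 1 || k > 25) stop("k must be in 1..25");
  int m = n - k + 1;
  if (m < 1) return NumericVector(0);
  NumericVector out(m, NA_REAL);
  double code = 0.0;
  const double top = std::pow(4.0, k - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0.0; continue; }
    if (valid >= k) {
      code = (code - base_code(seq[i - k]) * top) * 4.0 + b;
    } else {
      code = code * 4.0 + b;
      ++valid;
    }
    if (valid >= k) out[i - k + 1] = code;
  }
  return out;
}

// Global alignment of two short segments under unit costs (match 0,
// mismatch 1, indel 1), diagonal preferred on ties. Returns integer counts
// c(matches, mismatches, ins, del) where ins = bases of `a` aligned to a gap
// and del = bases of `b` aligned to a gap. Used to close small inter-anchor
// gaps inside an exon block; segment sizes are bounded by the caller.
// [[Rcpp::export]]
IntegerVector nw_counts_cpp(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return IntegerVector::create(0, 0, n, m);
  if ((double)(n + 1) * (double)(m + 1) > 2.6e7)
    stop("nw_counts_cpp: segments too long (%d x %d)", n, m);
  int W = m + 1;
  std::vector<int> D((size_t)(n + 1) * W);
  std::vector<unsigned char> T((size_t)(n + 1) * W); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int j = 0; j <= m; ++j) { D[j] = j; T[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * W] = i;
    T[(size_t)i * W] = 1;
    for (int j = 1; j <= m; ++j) {
      int sub = D[(size_t)(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = D[(size_t)(i - 1) * W + j] + 1;
      int left = D[(size_t)i * W + (j - 1)] + 1;
      int best = sub; unsigned char t = 0;
      if (up < best) { best = up; t = 1; }
      if (left < best) { best = left; t = 2; }
      D[(size_t)i * W + j] = best;
      T[(size_t)i * W + j] = t;
    }
  }
  int i = n, j = m, matches = 0, mismatches = 0, ins = 0, del = 0;
  while (i > 0 || j > 0) {
    unsigned char t = T[(size_t)i * W + j];
    if (i > 0 && j > 0 && t == 0) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      ++ins; --i;
    } else {
      ++del; --j;
    }
  }
  return IntegerVector::create(matches, mismatches, ins, del);
}
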