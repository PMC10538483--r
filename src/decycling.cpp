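// Core numeric kernels: Mykkeltveit embedding, O(k) decycling-set membership,
// sliding-window minimizer selection and Miniception membership.
// k-mers are exact base-4 digit vectors (A=0, C=1, G=2, T=3), big-endian:
// digit i is character i. No integer-width ceiling on k.
#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

namespace {

std::vector<double> sin_table(int k) {
  std::vector<double> s(k);
  for (int i = 0; i < k; ++i) s[i] = std::sin(2.0 * M_PI * i / k);
  return s;
}

// I(x) and I(x') for the one-letter clockwise rotation x' = x_{k-1} x_0 .. x_{k-2}.
// Digit x_i of x sits at position i+1 of x', so I(x') reuses a shifted table.
inline void imag_pair(const int* x, int k, const double* s,
                      double& Ix, double& Ixp) {
  Ix = 0.0; Ixp = 0.0;
  for (int i = 0; i < k; ++i) {
    double xi = x[i];
    Ix  += s[i] * xi;
    Ixp += s[(i + 1) % k] * xi;
  }
}

// True iff no cyclic rotation of x is lexicographically smaller than x
// (equal rotations allowed). Single scan of at most 2k-1 comparisons;
// i tracks the length of the current match against the prefix of x.
bool smallest_rotation(const int* x, int k) {
  if (k == 1) return true;
  int i = 0;
  for (int j = 1; j <= 2 * k - 1; ++j) {
    int c = x[j % k];
    int p = x[i % k];
    if (c < p) return false;
    if (c > p) i = 0; else ++i;
    if (j >= k - 1 && i % k == 0) return true;
  }
  return false;
}

// Membership in the Mykkeltveit decycling set D_k (symmetric = false) or its
// mirror set (symmetric = true): first positive (negative) counterclockwise
// rotation of the conjugacy class; all-zero-embedding classes contribute
// their lexicographically smallest rotation (shared by both variants).
// |I| <= eps is treated as zero.
bool mds_member(const int* x, int k, const double* s, double eps,
                bool symmetric) {
  double Ix, Ixp;
  imag_pair(x, k, s, Ix, Ixp);
  if (!symmetric) {
    if (Ix > eps) return Ixp <= eps;
  } else {
    if (Ix < -eps) return Ixp >= -eps;
  }
  if (std::fabs(Ix) <= eps && std::fabs(Ixp) <= eps)
    return smallest_rotation(x, k);
  return false;
}

// Strict "smaller under the order" test between the k-mers starting at
// positions p1 and p2 of a digit sequence: partition rank first, then the
// XOR-hashed value compared digit-by-digit (lazy XOR, no materialization).
struct KeyCmp {
  const int* seq;
  const int* ranks;
  const int* mask;
  int k;
  bool less(int p1, int p2) const {
    if (ranks[p1] != ranks[p2]) return ranks[p1] < ranks[p2];
    const int* a = seq + p1;
    const int* b = seq + p2;
    for (int j = 0; j < k; ++j) {
      int da = a[j] ^ mask[j];
      int db = b[j] ^ mask[j];
      if (da != db) return da < db;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector embed_kmer_cpp(IntegerVector x) {
  int k = x.size();
  double R = 0.0, I = 0.0;
  for (int i = 0; i < k; ++i) {
    double a = 2.0 * M_PI * i / k;
    R += x[i] * std::cos(a);
    I += x[i] * std::sin(a);
  }
  return NumericVector::create(Named("R") = R, Named("I") = I);
}

// [[Rcpp::export]]
bool smallest_rotation_cpp(IntegerVector x) {
  return smallest_rotation(INTEGER(x), x.size());
}

// [[Rcpp::export]]
bool mds_member_cpp(IntegerVector x, double eps, bool symmetric) {
  int k = x.size();
  std::vector<double> s = sin_table(k);
  return mds_member(INTEGER(x), k, s.data(), eps, symmetric);
}

// Partition rank of every k-mer position of a digit sequence.
// double_decycling = false: 0 if in D_k else 1.
// double_decycling = true:  0 if in D_k, 1 if in the symmetric set only, else 2.
// [[Rcpp::export]]
IntegerVector seq_partition_ranks_cpp(IntegerVector seq, int k, double eps,
                                      bool double_decycling) {
  int n = seq.size() - k + 1;
  if (n < 1) return IntegerVector(0);
  std::vector<double> s = sin_table(k);
  IntegerVector out(n);
  const int* sq = INTEGER(seq);
  int rest = double_decycling ? 2 : 1;
  for (int p = 0; p < n; ++p) {
    const int* x = sq + p;
    if (mds_member(x, k, s.data(), eps, false)) out[p] = 0;
    else if (double_decycling && mds_member(x, k, s.data(), eps, true)) out[p] = 1;
    else out[p] = rest;
  }
  return out;
}

// Miniception membership for every k-mer position: true iff the minimum
// k0-mer of the k-mer (XOR-hash order `mask`, leftmost tie) sits at offset 0
// or offset k - k0.
// [[Rcpp::export]]
LogicalVector miniception_flags_cpp(IntegerVector seq, int k, int k0,
                                    IntegerVector mask) {
  int n = seq.size() - k + 1;
  if (n < 1) return LogicalVector(0);
  LogicalVector out(n);
  const int* sq = INTEGER(seq);
  const int* m = INTEGER(mask);
  int last = k - k0;
  for (int p = 0; p < n; ++p) {
    int best = 0;
    for (int o = 1; o <= last; ++o) {
      const int* a = sq + p + o;
      const int* b = sq + p + best;
      for (int j = 0; j < k0; ++j) {
        int da = a[j] ^ m[j];
        int db = b[j] ^ m[j];
        if (da != db) {
          if (da < db) best = o;
          break;
        }
      }
    }
    out[p] = (best == 0 || best == last);
  }
  return out;
}

// Distinct, sorted 0-based minimizer positions of a digit sequence under the
// scheme (k, w, partition ranks, XOR mask). Monotone deque; ties within a
// window resolve to the leftmost position (equal keys are never popped).
// Contract: bit-exact equality with the naive per-window argmin.
// [[Rcpp::export]]
IntegerVector select_minimizers_cpp(IntegerVector seq, int k, int w,
                                    IntegerVector ranks, IntegerVector mask) {
  int nk = seq.size() - k + 1;
  int nw = nk - w + 1;
  if (nw < 1) return IntegerVector(0);
  KeyCmp cmp{INTEGER(seq), INTEGER(ranks), INTEGER(mask), k};
  std::deque<int> dq;
  std::vector<int> sel;
  int lastsel = -1;
  for (int p = 0; p < nk; ++p) {
    while (!dq.empty() && cmp.less(p, dq.back())) dq.pop_back();
    dq.push_back(p);
    int j = p - w + 1;  // window whose last k-mer is p
    if (j >= 0) {
      while (dq.front() < j) dq.pop_front();
      if (dq.front() != lastsel) {
        sel.push_back(dq.front());
        lastsel = dq.front();
      }
    }
  }
  return wrap(sel);
}

// All members of D_k (or the symmetric set) among the 4^k k-mers, in
// lexicographic (code) order. Small-k only; guarded at the R level.
// [[Rcpp::export]]
CharacterVector enumerate_mds_cpp(int k, double eps, bool symmetric) {
  std::vector<double> s = sin_table(k);
  std::vector<int> d(k, 0);
  std::vector<std::string> out;
  static const char alpha[] = "ACGT";
  double n = std::pow(4.0, k);
  std::string buf(k, 'A');
  for (double c = 0; c < n; ++c) {
    if (mds_member(d.data(), k, s.data(), eps, symmetric)) {
      for (int i = 0; i < k; ++i) buf[i] = alpha[d[i]];
      out.push_back(buf);
    }
    int i = k - 1;
    while (i >= 0 && ++d[i] == 4) { d[i] = 0; --i; }
  }
  return wrap(out);
}

// Tolerance audit over all 4^k k-mers: largest |I| at or below eps (the
// computed "zeros") and smallest |I| above eps (the genuine non-zeros).
// [[Rcpp::export]]
NumericVector imag_gap_cpp(int k, double eps) {
  std::vector<double> s = sin_table(k);
  std::vector<int> d(k, 0);
  double below = 0.0;
  double above = R_PosInf;
  double n = std::pow(4.0, k);
  for (double c = 0; c < n; ++c) {
    double I = 0.0;
    for (int i = 0; i < k; ++i) I += s[i] * d[i];
    double a = std::fabs(I);
    if (a <= eps) {
      if (a > below) below = a;
    } else if (a < above) {
      above = a;
    }
    int i = k - 1;
    while (i >= 0 && ++d[i] == 4) { d[i] = 0; --i; }
  }
  return NumericVector::create(Named("max_below") = below,
                               Named("min_above") = above);
}
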