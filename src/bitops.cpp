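#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// Packed layout: W = ceil(K/64) little-endian 64-bit words per signature,
// columns stored consecutively in one raw vector (8*W*N bytes).
// Bit position = feature index mod 64, LSB first, so serialized bytes are
// portable across platforms.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

static inline const uint64_t* word_ptr(const RawVector& v) {
  return reinterpret_cast<const uint64_t*>(RAW(const_cast<RawVector&>(v)));
}

// [[Rcpp::export]]
RawVector cpp_pack(IntegerMatrix x) {
  const int K = x.nrow(), N = x.ncol();
  const R_xlen_t W = (K + 63) / 64;
  RawVector out(8 * W * (R_xlen_t)N);
  std::memset(RAW(out), 0, (size_t)out.size());
  uint64_t* w = reinterpret_cast<uint64_t*>(RAW(out));
  for (int j = 0; j < N; ++j) {
    uint64_t* col = w + (R_xlen_t)j * W;
    for (int k = 0; k < K; ++k) {
      const int v = x(k, j);
      if (v == 1) {
        col[k >> 6] |= (uint64_t)1 << (k & 63);
      } else if (v != 0) {
        if (v == NA_INTEGER)
          stop("non-binary entry NA at row %d, column %d", k + 1, j + 1);
        stop("non-binary entry %d at row %d, column %d", v, k + 1, j + 1);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(RawVector words, int K, int N) {
  const R_xlen_t W = (K + 63) / 64;
  if (words.size() != 8 * W * (R_xlen_t)N)
    stop("word buffer has %lld bytes, expected %lld",
         (long long)words.size(), (long long)(8 * W * N));
  IntegerMatrix out(K, N);
  const uint64_t* w = word_ptr(words);
  for (int j = 0; j < N; ++j) {
    const uint64_t* col = w + (R_xlen_t)j * W;
    for (int k = 0; k < K; ++k)
      out(k, j) = (int)((col[k >> 6] >> (k & 63)) & 1);
  }
  return out;
}

// TRUE when every bit at position >= K in each column's last word is zero.
// [[Rcpp::export]]
bool cpp_padding_clean(RawVector words, int K, int N) {
  const R_xlen_t W = (K + 63) / 64;
  const int used = K & 63;          // bits used in the last word (0 = all 64)
  if (used == 0) return true;
  const uint64_t pad_mask = ~(((uint64_t)1 << used) - 1);
  const uint64_t* w = word_ptr(words);
  for (int j = 0; j < N; ++j)
    if (w[(R_xlen_t)j * W + (W - 1)] & pad_mask) return false;
  return true;
}

// [[Rcpp::export]]
double cpp_popcount(RawVector words) {
  if (words.size() % 8 != 0)
    stop("word buffer length must be a multiple of 8 bytes");
  const uint64_t* w = word_ptr(words);
  const R_xlen_t n = words.size() / 8;
  double total = 0;
  for (R_xlen_t i = 0; i < n; ++i) total += popcount64(w[i]);
  return total;
}

// [[Rcpp::export]]
IntegerVector cpp_col_popcounts(RawVector words, int K, int N) {
  const R_xlen_t W = (K + 63) / 64;
  const uint64_t* w = word_ptr(words);
  IntegerVector out(N);
  for (int j = 0; j < N; ++j) {
    const uint64_t* col = w + (R_xlen_t)j * W;
    int c = 0;
    for (R_xlen_t i = 0; i < W; ++i) c += popcount64(col[i]);
    out[j] = c;
  }
  return out;
}

// op: 1 = AND, 2 = XOR, 3 = OR
// [[Rcpp::export]]
IntegerMatrix cpp_compare(RawVector qwords, int nq, RawVector lwords, int nl,
                          int W, int op) {
  const uint64_t* q = word_ptr(qwords);
  const uint64_t* l = word_ptr(lwords);
  IntegerMatrix out(nq, nl);
  for (int j = 0; j < nl; ++j) {
    const uint64_t* lj = l + (R_xlen_t)j * W;
    for (int i = 0; i < nq; ++i) {
      const uint64_t* qi = q + (R_xlen_t)i * W;
      int c = 0;
      switch (op) {
      case 1: for (int w = 0; w < W; ++w) c += popcount64(qi[w] & lj[w]); break;
      case 2: for (int w = 0; w < W; ++w) c += popcount64(qi[w] ^ lj[w]); break;
      default: for (int w = 0; w < W; ++w) c += popcount64(qi[w] | lj[w]);
      }
      out(i, j) = c;
    }
  }
  return out;
}

// Strictly upper triangular self-comparison: cells with i >= j stay zero.
// [[Rcpp::export]]
IntegerMatrix cpp_compare_self(RawVector words, int n, int W, int op) {
  const uint64_t* m = word_ptr(words);
  IntegerMatrix out(n, n);
  for (int j = 1; j < n; ++j) {
    const uint64_t* cj = m + (R_xlen_t)j * W;
    for (int i = 0; i < j; ++i) {
      const uint64_t* ci = m + (R_xlen_t)i * W;
      int c = 0;
      switch (op) {
      case 1: for (int w = 0; w < W; ++w) c += popcount64(ci[w] & cj[w]); break;
      case 2: for (int w = 0; w < W; ++w) c += popcount64(ci[w] ^ cj[w]); break;
      default: for (int w = 0; w < W; ++w) c += popcount64(ci[w] | cj[w]);
      }
      out(i, j) = c;
    }
  }
  return out;
}
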