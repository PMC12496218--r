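#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sobol low-discrepancy sequence with Matousek linear-matrix scrambling and
// a digital shift.  Direction numbers follow the standard Joe-Kuo table
// (first 16 dimensions embedded below); 32 bits of precision.
//
// Scrambling randomness (lower-triangular GF(2) matrices and shift vectors)
// is supplied from R so that all randomness flows through R's RNG.

namespace {

// Joe-Kuo primitive polynomial degrees, coefficients, and initial m values
// for dimensions 2..16 (dimension 1 is the van der Corput sequence).
const int JK_S[15] = {1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 5, 5, 6, 6, 6};
const int JK_A[15] = {0, 1, 1, 2, 1, 4, 2, 4, 7, 11, 13, 14, 1, 13, 16};
const int JK_M[15][6] = {
    {1, 0, 0, 0, 0, 0},   // d = 2
    {1, 3, 0, 0, 0, 0},   // d = 3
    {1, 3, 1, 0, 0, 0},   // d = 4
    {1, 1, 1, 0, 0, 0},   // d = 5
    {1, 1, 3, 3, 0, 0},   // d = 6
    {1, 3, 5, 13, 0, 0},  // d = 7
    {1, 1, 5, 5, 17, 0},  // d = 8
    {1, 1, 5, 5, 5, 0},   // d = 9
    {1, 1, 7, 11, 19, 0}, // d = 10
    {1, 1, 5, 1, 1, 0},   // d = 11
    {1, 1, 1, 3, 11, 0},  // d = 12
    {1, 3, 5, 5, 31, 0},  // d = 13
    {1, 3, 3, 9, 7, 49},  // d = 14
    {1, 1, 1, 15, 21, 21},// d = 15
    {1, 3, 1, 13, 27, 49} // d = 16
};

const int NBITS = 32;

// direction numbers v[k] (k = 0..31) for one dimension, as uint32 with the
// most significant bit corresponding to the first binary digit
void direction_numbers(int dim0, uint32_t v[]) {
  uint32_t m[NBITS];
  if (dim0 == 0) {
    for (int k = 0; k < NBITS; ++k) m[k] = 1u;
  } else {
    int s = JK_S[dim0 - 1];
    int a = JK_A[dim0 - 1];
    for (int k = 0; k < s; ++k) m[k] = (uint32_t) JK_M[dim0 - 1][k];
    for (int k = s; k < NBITS; ++k) {
      uint32_t mk = m[k - s] ^ (m[k - s] << s);
      for (int i = 1; i < s; ++i)
        if ((a >> (s - 1 - i)) & 1) mk ^= (m[k - i] << i);
      m[k] = mk;
    }
  }
  for (int k = 0; k < NBITS; ++k)
    v[k] = m[k] << (NBITS - 1 - k);
}

// apply a lower-triangular GF(2) scrambling matrix (columns packed as
// uint32, column j has its diagonal bit set) to a direction number
inline uint32_t lms_apply(const uint32_t Lcol[], uint32_t x) {
  uint32_t y = 0;
  for (int j = 0; j < NBITS; ++j)
    if ((x >> (NBITS - 1 - j)) & 1) y ^= Lcol[j];
  return y;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_sobol(int n, int dim, NumericMatrix Lcols, NumericVector shift,
                        bool scramble) {
  if (dim < 1 || dim > 16)
    stop("Sobol dimension must be between 1 and 16 (got %d)", dim);
  if (n < 1) stop("number of points must be positive");
  NumericMatrix out(n, dim);
  std::vector<uint32_t> L(NBITS);
  uint32_t v[NBITS], vs[NBITS];
  const double denom = 4294967296.0; // 2^32
  for (int d = 0; d < dim; ++d) {
    direction_numbers(d, v);
    if (scramble) {
      for (int j = 0; j < NBITS; ++j)
        L[j] = (uint32_t) Lcols(j, d);
      for (int k = 0; k < NBITS; ++k) vs[k] = lms_apply(L.data(), v[k]);
    } else {
      for (int k = 0; k < NBITS; ++k) vs[k] = v[k];
    }
    uint32_t sh = scramble ? (uint32_t) shift[d] : 0u;
    uint32_t x = 0;
    out(0, d) = ((double) (x ^ sh)) / denom;
    for (int i = 1; i < n; ++i) {
      // Gray-code order: flip the direction number of the lowest zero bit
      int c = 0;
      int ii = i - 1;
      while (ii & 1) { ii >>= 1; ++c; }
      x ^= vs[c];
      out(i, d) = ((double) (x ^ sh)) / denom;
    }
  }
  return out;
}
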