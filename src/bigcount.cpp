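// Exact (arbitrary-precision) integer arithmetic for structure counting.
// Counts overflow 64-bit integers near n ~ 60 for pairable sequences and the
// asymptotic-growth utility needs exact counts up to length 501, so a minimal
// big-unsigned-integer type (little-endian base 2^32 limbs) is kept here.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cstdio>

using namespace Rcpp;

typedef std::vector<uint32_t> Big; // little-endian limbs, no leading zeros; empty == 0

static Big big_one() { return Big(1, 1u); }

static Big big_add(const Big &a, const Big &b) {
  const size_t n = std::max(a.size(), b.size());
  Big r;
  r.reserve(n + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r.push_back(static_cast<uint32_t>(s & 0xffffffffULL));
    carry = s >> 32;
  }
  if (carry) r.push_back(static_cast<uint32_t>(carry));
  return r;
}

static Big big_mul(const Big &a, const Big &b) {
  if (a.empty() || b.empty()) return Big();
  std::vector<uint64_t> acc(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      unsigned __int128 cur =
          (unsigned __int128)a[i] * b[j] + acc[i + j] + carry;
      acc[i + j] = static_cast<uint64_t>(cur & 0xffffffffULL);
      carry = static_cast<uint64_t>(cur >> 32);
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t cur = acc[k] + (carry & 0xffffffffULL);
      acc[k] = cur & 0xffffffffULL;
      carry = (carry >> 32) + (cur >> 32);
      ++k;
    }
  }
  Big r(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) r[i] = static_cast<uint32_t>(acc[i]);
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

static double big_to_double(const Big &a) {
  double r = 0.0;
  for (size_t i = a.size(); i-- > 0;) r = r * 4294967296.0 + a[i];
  return r;
}

static std::string big_to_string(Big a) {
  if (a.empty()) return "0";
  std::string out;
  while (!a.empty()) {
    uint64_t rem = 0;
    for (size_t i = a.size(); i-- > 0;) {
      uint64_t cur = (rem << 32) | a[i];
      a[i] = static_cast<uint32_t>(cur / 1000000000ULL);
      rem = cur % 1000000000ULL;
    }
    while (!a.empty() && a.back() == 0) a.pop_back();
    char buf[16];
    if (a.empty())
      std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)rem);
    else
      std::snprintf(buf, sizeof(buf), "%09llu", (unsigned long long)rem);
    out = std::string(buf) + out;
  }
  return out;
}

// Fill the structure-counting table C for a sequence whose pairability is
// given as a logical matrix (pairable[i,j] true iff residues i and j may pair,
// minimal-loop constraint NOT yet applied).  Empty intervals count 1.
// [[Rcpp::export]]
List count_matrix_bigint(LogicalMatrix pairable, int min_loop) {
  const int n = pairable.nrow();
  CharacterMatrix exact(n, n);
  NumericMatrix num(n, n);
  std::fill(exact.begin(), exact.end(), NA_STRING);
  std::fill(num.begin(), num.end(), NA_REAL);
  if (n == 0) return List::create(_["exact"] = exact, _["counts"] = num);

  // C stored per interval; index (i,j) 0-based with i <= j
  std::vector<std::vector<Big> > C(n, std::vector<Big>(n));
  for (int i = 0; i < n; ++i) C[i][i] = big_one();
  // value of C over [i, j] treating i > j (empty interval) as 1
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      Big v = C[i][j - 1]; // case: j unpaired (j-1 >= i here)
      for (int k = i; k < j - min_loop; ++k) {
        if (!pairable(k, j)) continue;
        Big left = (k - 1 >= i) ? C[i][k - 1] : big_one();
        Big inner = (k + 1 <= j - 1) ? C[k + 1][j - 1] : big_one();
        v = big_add(v, big_mul(left, inner));
      }
      C[i][j] = v;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      exact(i, j) = big_to_string(C[i][j]);
      num(i, j) = big_to_double(C[i][j]);
    }
  return List::create(_["exact"] = exact, _["counts"] = num);
}

// Length-only specialization of the counting recursion (all position pairs
// treated as pairable): f(m) = f(m-1) + sum_{k=1..m-l-1} f(k-1) * f(m-k-1),
// f(0) = ... = f(l+1) = 1.  Returns f(n+1)/f(n) as a double plus the exact
// decimal strings of the two counts.
// [[Rcpp::export]]
List growth_sequence_bigint(int n, int min_loop) {
  if (n < 1) stop("n must be >= 1");
  const int top = n + 1;
  std::vector<Big> f(top + 1);
  for (int m = 0; m <= std::min(top, min_loop + 1); ++m) f[m] = big_one();
  for (int m = min_loop + 2; m <= top; ++m) {
    Big v = f[m - 1];
    for (int k = 1; k <= m - min_loop - 1; ++k)
      v = big_add(v, big_mul(f[k - 1], f[m - k - 1]));
    f[m] = v;
  }
  double ratio = big_to_double(f[top]) / big_to_double(f[n]);
  return List::create(_["ratio"] = ratio,
                      _["f_n"] = big_to_string(f[n]),
                      _["f_n1"] = big_to_string(f[top]));
}
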