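// Arbitrary-precision non-negative integers ("big naturals") for exact
// weighted counting and unranking.  Representation on the R side: an
// integer vector of limbs in base 2^15, little-endian, no trailing zero
// limbs; the empty vector is zero.  Base 2^15 keeps every limb product
// within int64 range even when accumulating millions of partial products.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int64_t BASE = 32768;  // 2^15
static const int SHIFT = 15;
static const int64_t MASK = BASE - 1;

typedef std::vector<int64_t> limbs;

static limbs from_iv(const IntegerVector& x) {
  limbs v(x.begin(), x.end());
  while (!v.empty() && v.back() == 0) v.pop_back();
  return v;
}

static IntegerVector to_iv(const limbs& v) {
  size_t n = v.size();
  while (n > 0 && v[n - 1] == 0) --n;
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (int)v[i];
  return out;
}

static int cmp_limbs(const limbs& a, const limbs& b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static limbs add_limbs(const limbs& a, const limbs& b) {
  limbs r(std::max(a.size(), b.size()) + 1, 0);
  int64_t carry = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    int64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r[i] = s & MASK;
    carry = s >> SHIFT;
  }
  return r;
}

// requires a >= b
static limbs sub_limbs(const limbs& a, const limbs& b) {
  limbs r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = a[i] - borrow - (i < b.size() ? b[i] : 0);
    if (s < 0) { s += BASE; borrow = 1; } else borrow = 0;
    r[i] = s;
  }
  return r;
}

static limbs mul_limbs(const limbs& a, const limbs& b) {
  if (a.empty() || b.empty()) return limbs();
  limbs acc(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] == 0) continue;
    for (size_t j = 0; j < b.size(); ++j) acc[i + j] += a[i] * b[j];
    // partial carry pass to keep accumulators far from overflow
    if ((i & 1023) == 1023) {
      int64_t carry = 0;
      for (size_t k = 0; k < acc.size(); ++k) {
        int64_t s = acc[k] + carry;
        acc[k] = s & MASK;
        carry = s >> SHIFT;
      }
    }
  }
  int64_t carry = 0;
  for (size_t k = 0; k < acc.size(); ++k) {
    int64_t s = acc[k] + carry;
    acc[k] = s & MASK;
    carry = s >> SHIFT;
  }
  while (carry > 0) { acc.push_back(carry & MASK); carry >>= SHIFT; }
  return acc;
}

static limbs mul_small(const limbs& a, int64_t m) {
  if (a.empty() || m == 0) return limbs();
  limbs r(a.size() + 5, 0);
  int64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = a[i] * m + carry;
    r[i] = s & MASK;
    carry = s >> SHIFT;
  }
  size_t i = a.size();
  while (carry > 0) { r[i++] = carry & MASK; carry >>= SHIFT; }
  r.resize(i > a.size() ? i : a.size());
  return r;
}

// schoolbook long division; quotient and remainder
static void divmod_limbs(const limbs& a, const limbs& b, limbs& q, limbs& r) {
  if (b.empty()) stop("division by zero big natural");
  if (cmp_limbs(a, b) < 0) { q = limbs(); r = a; return; }
  if (b.size() == 1) {
    int64_t d = b[0], rem = 0;
    q.assign(a.size(), 0);
    for (size_t i = a.size(); i-- > 0;) {
      int64_t cur = (rem << SHIFT) + a[i];
      q[i] = cur / d;
      rem = cur % d;
    }
    while (!q.empty() && q.back() == 0) q.pop_back();
    r = rem ? limbs(1, rem) : limbs();
    return;
  }
  // Knuth algorithm D, normalized so the divisor's top limb >= BASE/2
  int shift = 0;
  int64_t top = b.back();
  while ((top << shift) < BASE / 2) ++shift;
  limbs u = mul_small(a, (int64_t)1 << shift);
  limbs v = mul_small(b, (int64_t)1 << shift);
  size_t n = v.size(), m = u.size() >= n ? u.size() - n : 0;
  u.resize(u.size() + 1, 0);
  q.assign(m + 1, 0);
  for (size_t j = m + 1; j-- > 0;) {
    int64_t num = (u[j + n] << SHIFT) + u[j + n - 1];
    int64_t qhat = num / v[n - 1];
    int64_t rhat = num % v[n - 1];
    while (qhat >= BASE || qhat * v[n - 2] > ((rhat << SHIFT) + u[j + n - 2])) {
      --qhat;
      rhat += v[n - 1];
      if (rhat >= BASE) break;
    }
    // multiply-subtract
    int64_t borrow = 0, carry = 0;
    for (size_t i = 0; i < n; ++i) {
      int64_t p = qhat * v[i] + carry;
      carry = p >> SHIFT;
      int64_t sub = u[i + j] - (p & MASK) - borrow;
      if (sub < 0) { sub += BASE; borrow = 1; } else borrow = 0;
      u[i + j] = sub;
    }
    int64_t sub = u[j + n] - carry - borrow;
    if (sub < 0) { sub += BASE; borrow = 1; } else borrow = 0;
    u[j + n] = sub;
    if (borrow) {  // qhat was one too large; add back
      --qhat;
      int64_t c = 0;
      for (size_t i = 0; i < n; ++i) {
        int64_t s = u[i + j] + v[i] + c;
        u[i + j] = s & MASK;
        c = s >> SHIFT;
      }
      u[j + n] = (u[j + n] + c) & MASK;
    }
    q[j] = qhat;
  }
  while (!q.empty() && q.back() == 0) q.pop_back();
  // remainder = u[0..n-1] >> shift
  limbs rr(u.begin(), u.begin() + n);
  while (!rr.empty() && rr.back() == 0) rr.pop_back();
  if (shift > 0) {
    int64_t carry = 0;
    for (size_t i = rr.size(); i-- > 0;) {
      int64_t cur = (carry << SHIFT) + rr[i];
      rr[i] = cur >> shift;
      carry = cur & (((int64_t)1 << shift) - 1);
    }
    while (!rr.empty() && rr.back() == 0) rr.pop_back();
  }
  r = rr;
}

// [[Rcpp::export]]
IntegerVector bn_add_(IntegerVector a, IntegerVector b) {
  return to_iv(add_limbs(from_iv(a), from_iv(b)));
}

// [[Rcpp::export]]
IntegerVector bn_sub_(IntegerVector a, IntegerVector b) {
  limbs la = from_iv(a), lb = from_iv(b);
  if (cmp_limbs(la, lb) < 0) stop("big natural subtraction would be negative");
  return to_iv(sub_limbs(la, lb));
}

// [[Rcpp::export]]
IntegerVector bn_mul_(IntegerVector a, IntegerVector b) {
  return to_iv(mul_limbs(from_iv(a), from_iv(b)));
}

// [[Rcpp::export]]
List bn_divmod_(IntegerVector a, IntegerVector b) {
  limbs q, r;
  divmod_limbs(from_iv(a), from_iv(b), q, r);
  return List::create(_["q"] = to_iv(q), _["r"] = to_iv(r));
}

// [[Rcpp::export]]
int bn_cmp_(IntegerVector a, IntegerVector b) {
  return cmp_limbs(from_iv(a), from_iv(b));
}

// [[Rcpp::export]]
IntegerVector bn_gcd_(IntegerVector a, IntegerVector b) {
  limbs x = from_iv(a), y = from_iv(b), q, r;
  while (!y.empty()) {
    divmod_limbs(x, y, q, r);
    x = y;
    y = r;
  }
  return to_iv(x);
}

// [[Rcpp::export]]
IntegerVector bn_from_string_(std::string s) {
  limbs v;
  for (char ch : s) {
    if (ch < '0' || ch > '9') stop("invalid decimal digit in big natural string");
    v = mul_small(v, 10);
    if (ch != '0') v = add_limbs(v, limbs(1, ch - '0'));
  }
  while (!v.empty() && v.back() == 0) v.pop_back();
  return to_iv(v);
}

// [[Rcpp::export]]
std::string bn_to_string_(IntegerVector a) {
  limbs v = from_iv(a);
  if (v.empty()) return "0";
  std::string out;
  limbs ten(1, 10), q, r;
  while (!v.empty()) {
    divmod_limbs(v, ten, q, r);
    out.push_back('0' + (char)(r.empty() ? 0 : r[0]));
    v = q;
  }
  std::reverse(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
IntegerVector bn_from_double_(double x) {
  if (x < 0 || x != std::floor(x) || x > 9007199254740992.0)
    stop("value not representable as an exact big natural");
  limbs v;
  while (x > 0) {
    double hi = std::floor(x / (double)BASE);
    v.push_back((int64_t)(x - hi * (double)BASE));
    x = hi;
  }
  return to_iv(v);
}

// [[Rcpp::export]]
double bn_to_double_(IntegerVector a) {
  limbs v = from_iv(a);
  double out = 0;
  for (size_t i = v.size(); i-- > 0;) out = out * (double)BASE + (double)v[i];
  return out;
}

// [[Rcpp::export]]
int bn_bitlen_(IntegerVector a) {
  limbs v = from_iv(a);
  if (v.empty()) return 0;
  int bits = (int)(v.size() - 1) * SHIFT;
  int64_t t = v.back();
  while (t > 0) { ++bits; t >>= 1; }
  return bits;
}

// bits: 0/1 integer vector, most significant bit first
// [[Rcpp::export]]
IntegerVector bn_from_bits_(IntegerVector bits) {
  limbs v;
  int64_t cur = 0;
  int ncur = 0;
  // build from least significant end
  for (int i = bits.size() - 1; i >= 0; --i) {
    if (bits[i]) cur |= ((int64_t)1 << ncur);
    if (++ncur == SHIFT) { v.push_back(cur); cur = 0; ncur = 0; }
  }
  if (ncur > 0) v.push_back(cur);
  while (!v.empty() && v.back() == 0) v.pop_back();
  return to_iv(v);
}

// sum over i of xs[[i]] * ys[[i]]  (the convolution inner loop)
// [[Rcpp::export]]
IntegerVector bn_dot_(List xs, List ys) {
  if (xs.size() != ys.size()) stop("bn_dot: length mismatch");
  limbs acc;
  for (int i = 0; i < xs.size(); ++i) {
    limbs a = from_iv(xs[i]), b = from_iv(ys[i]);
    if (a.empty() || b.empty()) continue;
    acc = add_limbs(acc, mul_limbs(a, b));
  }
  return to_iv(acc);
}
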