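// Ring arithmetic over Z_{2^n} with n <= 64, fixed-point codec, deterministic
// splitmix64 randomness streams, and the Z_67 private-compare kernel.
//
// Ring elements travel through R as numeric vectors whose 8-byte patterns are
// reinterpreted as uint64 (the bit64 storage technique). R never performs
// arithmetic on them; every operation lands here.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static inline uint64_t d2u(double x) {
  uint64_t u;
  std::memcpy(&u, &x, 8);
  return u;
}
static inline double u2d(uint64_t u) {
  double x;
  std::memcpy(&x, &u, 8);
  return x;
}
static inline uint64_t mask_of(int nbits) {
  return (nbits >= 64) ? ~0ULL : ((1ULL << nbits) - 1ULL);
}

// ---- element construction / inspection ------------------------------------

// [[Rcpp::export]]
NumericVector rg_from_dbl(NumericVector x, int nbits) {
  // exact for |x| < 2^53; negatives wrap (two's complement)
  uint64_t m = mask_of(nbits);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (!R_FINITE(v) || v != std::floor(v))
      stop("rg_from_dbl: non-integer input");
    int64_t s = (int64_t)v;
    out[i] = u2d(((uint64_t)s) & m);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rg_to_dbl(NumericVector x) {
  // unsigned value as double (exact only below 2^53; callers know)
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (double)d2u(x[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector rg_as_char(NumericVector x) {
  CharacterVector out(x.size());
  char buf[24];
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)d2u(x[i]));
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector rg_eq(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("rg_eq: length mismatch");
  LogicalVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = d2u(a[i]) == d2u(b[i]);
  return out;
}

// ---- modular arithmetic ----------------------------------------------------

// b recycled if scalar
// [[Rcpp::export]]
NumericVector rg_add(NumericVector a, NumericVector b, int nbits) {
  uint64_t m = mask_of(nbits);
  R_xlen_t n = a.size(), nb = b.size();
  if (nb != n && nb != 1) stop("rg_add: length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = u2d((d2u(a[i]) + d2u(b[nb == 1 ? 0 : i])) & m);
  return out;
}

// [[Rcpp::export]]
NumericVector rg_sub(NumericVector a, NumericVector b, int nbits) {
  uint64_t m = mask_of(nbits);
  R_xlen_t n = a.size(), nb = b.size();
  if (nb != n && nb != 1) stop("rg_sub: length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = u2d((d2u(a[i]) - d2u(b[nb == 1 ? 0 : i])) & m);
  return out;
}

// [[Rcpp::export]]
NumericVector rg_neg(NumericVector a, int nbits) {
  uint64_t m = mask_of(nbits);
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = u2d((0ULL - d2u(a[i])) & m);
  return out;
}

// [[Rcpp::export]]
NumericVector rg_mul(NumericVector a, NumericVector b, int nbits) {
  uint64_t m = mask_of(nbits);
  R_xlen_t n = a.size(), nb = b.size();
  if (nb != n && nb != 1) stop("rg_mul: length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = u2d((d2u(a[i]) * d2u(b[nb == 1 ? 0 : i])) & m);
  return out;
}

// x * 2^k mod 2^nbits (left shift)
// [[Rcpp::export]]
NumericVector rg_shl(NumericVector a, int k, int nbits) {
  uint64_t m = mask_of(nbits);
  NumericVector out(a.size());
  if (k >= 64) {
    for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = u2d(0ULL);
    return out;
  }
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = u2d((d2u(a[i]) << k) & m);
  return out;
}

// x mod 2^mbits (keep low bits) -- used for d = x mod K with mbits = n-1
// [[Rcpp::export]]
NumericVector rg_mod2m(NumericVector a, int mbits) {
  uint64_t m = mask_of(mbits);
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = u2d(d2u(a[i]) & m);
  return out;
}

// Local share truncation by f bits (SecureML-style probabilistic truncation).
// party 0: z >> f ; party 1: -((-z) >> f). Reconstructs to floor(v / 2^f)
// plus a Bernoulli carry with success probability equal to the dropped
// fraction -- stochastic rounding, unbiased in expectation. (A deterministic
// rounding offset on one share was tried and rejected: it adds a +0.5 ULP
// systematic bias per product.)
// [[Rcpp::export]]
NumericVector rg_trunc_share(NumericVector a, int f, int party, int nbits) {
  uint64_t m = mask_of(nbits);
  NumericVector out(a.size());
  if (f == 0) {
    for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = a[i];
    return out;
  }
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    uint64_t u = d2u(a[i]) & m;
    if (party == 0) {
      out[i] = u2d((u >> f) & m);
    } else {
      uint64_t negu = (0ULL - u) & m;
      out[i] = u2d((0ULL - (negu >> f)) & m);
    }
  }
  return out;
}

// ---- fixed-point codec -----------------------------------------------------

// [[Rcpp::export]]
NumericVector rg_encode(NumericVector x, int nbits, int f) {
  uint64_t m = mask_of(nbits);
  double lim = std::ldexp(1.0, nbits - 1 - f);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (!R_FINITE(v)) stop("rg_encode: non-finite input");
    if (std::fabs(v) >= lim)
      stop("rg_encode: value %g outside representable range (|x| < 2^%d)",
           v, nbits - 1 - f);
    double scaled = std::ldexp(v, f);       // exact: power-of-two scaling
    double r = std::round(scaled);          // round half away from zero
    int64_t s = (int64_t)r;
    out[i] = u2d(((uint64_t)s) & m);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rg_decode(NumericVector x, int nbits, int f) {
  uint64_t m = mask_of(nbits);
  uint64_t sign = 1ULL << (nbits - 1);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint64_t u = d2u(x[i]) & m;
    double v;
    if (u & sign) {
      // two's complement negative
      uint64_t negu = (0ULL - u) & m;
      v = -std::ldexp((double)negu, -f);
    } else {
      v = std::ldexp((double)u, -f);
    }
    out[i] = v;
  }
  return out;
}

// ---- bit decomposition -----------------------------------------------------

// nbits x m matrix of 0/1, most-significant bit first
// [[Rcpp::export]]
IntegerMatrix rg_bits(NumericVector x, int nbits) {
  R_xlen_t mcol = x.size();
  IntegerMatrix out(nbits, mcol);
  int* op = INTEGER(out);
  const double* xp = REAL(x);
  for (R_xlen_t j = 0; j < mcol; ++j) {
    uint64_t u = d2u(xp[j]) & mask_of(nbits);
    int* oj = op + (size_t)j * nbits;
    for (int i = 0; i < nbits; ++i)
      oj[i] = (int)((u >> (nbits - 1 - i)) & 1ULL);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rg_from_bits(IntegerMatrix bits) {
  int nbits = bits.nrow();
  NumericVector out(bits.ncol());
  for (int j = 0; j < bits.ncol(); ++j) {
    uint64_t u = 0;
    for (int i = 0; i < nbits; ++i)
      u = (u << 1) | (uint64_t)(bits(i, j) & 1);
    out[j] = u2d(u);
  }
  return out;
}

// ---- matrix product mod 2^nbits -------------------------------------------

// [[Rcpp::export]]
NumericVector rg_matmul(NumericVector a, NumericVector b,
                        int p, int q, int s, int nbits) {
  // a is p x q (column-major), b is q x s; returns p x s column-major
  if ((R_xlen_t)p * q != a.size() || (R_xlen_t)q * s != b.size())
    stop("rg_matmul: dimension mismatch");
  uint64_t m = mask_of(nbits);
  NumericVector out((R_xlen_t)p * s);
  std::vector<uint64_t> au(a.size()), bu(b.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) au[i] = d2u(a[i]);
  for (R_xlen_t i = 0; i < b.size(); ++i) bu[i] = d2u(b[i]);
  for (int col = 0; col < s; ++col) {
    for (int row = 0; row < p; ++row) {
      uint64_t acc = 0;
      const uint64_t* bcol = &bu[(size_t)col * q];
      for (int kk = 0; kk < q; ++kk)
        acc += au[(size_t)kk * p + row] * bcol[kk];
      out[(R_xlen_t)col * p + row] = u2d(acc & m);
    }
  }
  return out;
}

// ---- splitmix64 streams ----------------------------------------------------

static inline uint64_t sm64_next(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
NumericVector rng_seed_state(double seed) {
  // derive an initial 64-bit state from an R double seed
  uint64_t s = (uint64_t)(int64_t)seed;
  s ^= 0xD1B54A32D192ED03ULL;
  uint64_t st = s;
  (void)sm64_next(st);  // scramble once
  return NumericVector::create(u2d(st));
}

// draw `count` ring elements; modulus given as bit-cast uint64 (0 => 2^64)
// [[Rcpp::export]]
List rng_draw(NumericVector state, int count, NumericVector modulus) {
  uint64_t st = d2u(state[0]);
  uint64_t mod = d2u(modulus[0]);
  NumericVector out(count);
  for (int i = 0; i < count; ++i) {
    uint64_t v = sm64_next(st);
    if (mod != 0ULL) v %= mod;
    out[i] = u2d(v);
  }
  return List::create(_["values"] = out, _["state"] = NumericVector::create(u2d(st)));
}

// draw `count` small integers in [0, modulus)
// [[Rcpp::export]]
List rng_draw_int(NumericVector state, int count, int modulus) {
  uint64_t st = d2u(state[0]);
  IntegerVector out(count);
  int* op = INTEGER(out);
  const uint64_t mod = (uint64_t)modulus;
  for (int i = 0; i < count; ++i)
    op[i] = (int)(sm64_next(st) % mod);
  return List::create(_["values"] = out, _["state"] = NumericVector::create(u2d(st)));
}

// m independent permutations of 0..(nbits-1), one per column (Fisher-Yates)
// [[Rcpp::export]]
List rng_perm(NumericVector state, int nbits, int m) {
  uint64_t st = d2u(state[0]);
  IntegerMatrix out(nbits, m);
  int* op = INTEGER(out);
  for (int j = 0; j < m; ++j) {
    int* oj = op + (size_t)j * nbits;
    for (int i = 0; i < nbits; ++i) oj[i] = i;
    for (int i = nbits - 1; i > 0; --i) {
      int k = (int)(sm64_next(st) % (uint64_t)(i + 1));
      int tmp = oj[i]; oj[i] = oj[k]; oj[k] = tmp;
    }
  }
  return List::create(_["values"] = out, _["state"] = NumericVector::create(u2d(st)));
}

// ---- Z_67 private compare kernel ------------------------------------------

// Per-party message of the SecureNN-style private compare over Z_V.
// rbits: nbits x m additive shares (mod V) of the bits of secret r (MSB first)
// ybits: nbits x m public bits of y (and the comparison is r >? y)
// beta:  m common random bits; when beta=1 the complementary test (y+1 >? r)
//        is encoded instead (y < K fits in nbits, so y+1 never overflows)
// scal:  nbits x m common random non-zero scalars (1..V-1)
// perm:  nbits x m common random permutations of the bit positions
// [[Rcpp::export]]
IntegerMatrix pc_party_msg(IntegerMatrix rbits, IntegerMatrix ybits, int party,
                           IntegerVector beta, IntegerMatrix scal,
                           IntegerMatrix perm, int V) {
  constexpr int PV = 67;            // compile-time modulus (fast % / bounds)
  if (V != PV) stop("pc_party_msg: V must be 67");
  const int nb = rbits.nrow();
  const int m = rbits.ncol();
  IntegerMatrix out(nb, m);
  const int* rb = INTEGER(rbits);
  const int* yb = INTEGER(ybits);
  const int* sc = INTEGER(scal);
  const int* pm = INTEGER(perm);
  const int* bt = INTEGER(beta);
  int* op = INTEGER(out);
  std::vector<int> tb(nb), c(nb);
  const bool p1 = (party == 1);
  for (int j = 0; j < m; ++j) {
    const int* rbj = rb + (size_t)j * nb;
    const int* ybj = yb + (size_t)j * nb;
    const int* scj = sc + (size_t)j * nb;
    const int* pmj = pm + (size_t)j * nb;
    int* opj = op + (size_t)j * nb;
    // bits of the public comparand: y when beta=0, y+1 when beta=1
    int carry = bt[j];
    for (int i = nb - 1; i >= 0; --i) {
      int s = ybj[i] + carry;
      tb[i] = s & 1;
      carry = s >> 1;
    }
    // prefix sums of shared XOR terms w_k for k more significant than i
    int wsum = 0;
    if (bt[j] == 0) {
      for (int i = 0; i < nb; ++i) {
        const int r_i = rbj[i];     // this party's share of bit i (0..66)
        const int t_i = tb[i];
        // c_i = t_i + 1 - r_i + wsum (public terms held by party 1)
        int c_i = (p1 ? (t_i + 1) : 0) - r_i + wsum;
        if (c_i < 0) c_i += PV; else if (c_i >= PV) c_i -= PV;
        c[i] = c_i;
        int w_i = r_i + (p1 ? t_i : 0) - 2 * t_i * r_i;   // in [-66, 66]
        wsum += w_i;
        if (wsum < 0) wsum += PV; else if (wsum >= PV) wsum -= PV;
      }
    } else {
      for (int i = 0; i < nb; ++i) {
        const int r_i = rbj[i];
        const int t_i = tb[i];
        // c_i = r_i - t_i + 1 + wsum
        int c_i = r_i + (p1 ? (1 - t_i) : 0) + wsum;
        if (c_i >= PV) c_i -= PV;
        c[i] = c_i;
        int w_i = r_i + (p1 ? t_i : 0) - 2 * t_i * r_i;
        wsum += w_i;
        if (wsum < 0) wsum += PV; else if (wsum >= PV) wsum -= PV;
      }
    }
    // scale by common non-zero randoms, then permute positions
    for (int i = 0; i < nb; ++i)
      opj[pmj[i]] = (c[i] * scj[i]) % PV;
  }
  return out;
}

// Helper combines the two messages: u' = 1 iff some position reconstructs to 0
// [[Rcpp::export]]
IntegerVector pc_helper(IntegerMatrix d0, IntegerMatrix d1, int V) {
  constexpr int PV = 67;
  if (V != PV) stop("pc_helper: V must be 67");
  const int nb = d0.nrow(), m = d0.ncol();
  if (d1.nrow() != nb || d1.ncol() != m) stop("pc_helper: shape mismatch");
  const int* a = INTEGER(d0);
  const int* b = INTEGER(d1);
  IntegerVector out(m);
  int* op = INTEGER(out);
  for (int j = 0; j < m; ++j) {
    const int* aj = a + (size_t)j * nb;
    const int* bj = b + (size_t)j * nb;
    int found = 0;
    for (int i = 0; i < nb; ++i)
      if ((aj[i] + bj[i]) % PV == 0) { found = 1; break; }
    op[j] = found;
  }
  return out;
}

// unsigned a < b, elementwise (used for public wrap detection)
// [[Rcpp::export]]
LogicalVector rg_lt(NumericVector a, NumericVector b) {
  R_xlen_t n = a.size(), nb = b.size();
  if (nb != n && nb != 1) stop("rg_lt: length mismatch");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = d2u(a[i]) < d2u(b[nb == 1 ? 0 : i]);
  return out;
}

// Fused MOC dealing step for the helper: draws r over K, its K-sharing, the
// Z_67 bit shares of r and Boolean shares of the sharing's wrap flag, in one
// pass (draw order: r, r0, bit shares, wrap share -- matching the unfused
// sequence). Purely P2-local computation.
// [[Rcpp::export]]
List moc_deal(NumericVector state, int m, int nbits) {
  constexpr int PV = 67;
  uint64_t st = d2u(state[0]);
  const uint64_t Kmask = (1ULL << (nbits - 1)) - 1ULL;
  NumericVector r0(m), r1(m);
  IntegerMatrix rb0(nbits, m), rb1(nbits, m);
  IntegerVector w0(m), w1(m);
  std::vector<uint64_t> r(m);
  for (int j = 0; j < m; ++j) r[j] = sm64_next(st) & Kmask;
  int* b0 = INTEGER(rb0);
  int* b1 = INTEGER(rb1);
  for (int j = 0; j < m; ++j) {
    uint64_t r0j = sm64_next(st) & Kmask;
    uint64_t r1j = (r[j] - r0j) & Kmask;
    r0[j] = u2d(r0j);
    r1[j] = u2d(r1j);
    w0[j] = (int)(sm64_next(st) & 1ULL);           // Boolean share
    w1[j] = w0[j] ^ (int)(r0j > r[j]);             // wrap iff r0 > r
    int* c0 = b0 + (size_t)j * nbits;
    int* c1 = b1 + (size_t)j * nbits;
    for (int i = 0; i < nbits; ++i) {
      int bit = (int)((r[j] >> (nbits - 1 - i)) & 1ULL);
      int s0 = (int)(sm64_next(st) % PV);
      c0[i] = s0;
      int s1 = bit - s0;
      if (s1 < 0) s1 += PV;
      c1[i] = s1;
    }
  }
  return List::create(_["r0"] = r0, _["r1"] = r1, _["rb0"] = rb0,
                      _["rb1"] = rb1, _["w0"] = w0, _["w1"] = w1,
                      _["state"] = NumericVector::create(u2d(st)));
}

// Danger-zone flags for wrap-safe truncation. Plain local truncation is off
// by the full ring modulus when P0's (uniform) share lies within |v * 2^f|
// of the ring boundary. P0's share alone -- uniform and independent of the
// secret -- reveals whether that can happen for any |v| below the public
// magnitude bound 2^(nbits-12), so P0 flags it (+1: bottom zone, -1: top
// zone) and both proxies shift by the public constant 2^(nbits-10) before
// shifting. The flag is a function of a uniform value only, hence
// simulatable; the correction makes the off-by-one error contract hold with
// certainty instead of with high probability.
// [[Rcpp::export]]
IntegerVector trunc_flags(NumericVector z0, int nbits) {
  const uint64_t m = mask_of(nbits);
  const uint64_t zone = (nbits >= 12) ? (1ULL << (nbits - 11)) : 1ULL;
  IntegerVector out(z0.size());
  for (R_xlen_t i = 0; i < z0.size(); ++i) {
    uint64_t u = d2u(z0[i]) & m;
    if (u < zone) out[i] = 1;
    else if ((m - u) < zone) out[i] = -1;
    else out[i] = 0;
  }
  return out;
}

// apply z += sign * flag * 2^(nbits-10)
// [[Rcpp::export]]
NumericVector trunc_apply(NumericVector z, IntegerVector flags, int sign,
                          int nbits) {
  const uint64_t m = mask_of(nbits);
  const uint64_t delta = (nbits >= 10) ? (1ULL << (nbits - 10)) : 1ULL;
  NumericVector out(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    uint64_t u = d2u(z[i]) & m;
    int64_t s = (int64_t)sign * flags[i];
    if (s > 0) u += delta; else if (s < 0) u -= delta;
    out[i] = u2d(u & m);
  }
  return out;
}

// Fused local algebra helpers: one pass instead of chains of rg_* calls on
// large vectors (the protocols are unchanged; these only collapse party-local
// expression trees).

// MUX completion for one proxy: x - b*d + t1*b + t2*d + t3 - H  (mod 2^nbits)
// with t1, t2, t3 per-element tape vectors (t3 already a product).
// [[Rcpp::export]]
NumericVector mux_local(NumericVector x, NumericVector b, NumericVector d,
                        NumericVector t1, NumericVector t2, NumericVector t3,
                        NumericVector H, int nbits) {
  const uint64_t m = mask_of(nbits);
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double *xp = REAL(x), *bp = REAL(b), *dp = REAL(d), *t1p = REAL(t1),
               *t2p = REAL(t2), *t3p = REAL(t3), *Hp = REAL(H);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t bu = d2u(bp[i]), du = d2u(dp[i]);
    uint64_t acc = d2u(xp[i]) - bu * du + d2u(t1p[i]) * bu +
                   d2u(t2p[i]) * du + d2u(t3p[i]) - d2u(Hp[i]);
    op[i] = u2d(acc & m);
  }
  return out;
}

// MOC output assembly for one proxy: yh + K*(wy + c + w) - r  (mod 2^nbits),
// wy/c/w small integer vectors (public wrap flag, PC share, wrap share).
// [[Rcpp::export]]
NumericVector moc_local(NumericVector yh, IntegerVector wy, IntegerVector c,
                        IntegerVector w, NumericVector r, int nbits) {
  const uint64_t m = mask_of(nbits);
  const uint64_t K = 1ULL << (nbits - 1);
  R_xlen_t n = yh.size();
  NumericVector out(n);
  const double *yp = REAL(yh), *rp = REAL(r);
  const int *wyp = INTEGER(wy), *cp = INTEGER(c), *wp = INTEGER(w);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t acc = d2u(yp[i]) + K * (uint64_t)(wyp[i] + cp[i] + wp[i]) -
                   d2u(rp[i]);
    op[i] = u2d(acc & m);
  }
  return out;
}
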