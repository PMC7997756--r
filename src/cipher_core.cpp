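#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iterate three independent logistic maps x <- r*x*(1-x).
// The first m iterates are discarded (transient); the last discarded
// triple is returned so initial-value bytes for the diffusion chains can
// be derived from it. Series rows are the n post-transient iterates.
// [[Rcpp::export]]
List chaos_iterate_cpp(NumericVector x0, NumericVector r, int n, int m) {
  NumericMatrix series(n, 3);
  double x[3] = {x0[0], x0[1], x0[2]};
  NumericVector last(3, NA_REAL);
  for (int t = 0; t < m; ++t) {
    for (int k = 0; k < 3; ++k) x[k] = r[k] * x[k] * (1.0 - x[k]);
  }
  if (m > 0) { last[0] = x[0]; last[1] = x[1]; last[2] = x[2]; }
  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < 3; ++k) {
      x[k] = r[k] * x[k] * (1.0 - x[k]);
      series(t, k) = x[k];
    }
  }
  return List::create(_["series"] = series, _["last_transient"] = last);
}

// b = floor(u * scale) mod 256; u in [0,1), scale <= 1e10 so the product
// stays exactly representable in a double.
// [[Rcpp::export]]
IntegerVector quantize_bytes_cpp(NumericVector u, double scale) {
  int n = u.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    long long q = (long long)std::floor(u[i] * scale);
    out[i] = (int)(((q % 256) + 256) % 256);
  }
  return out;
}

// Mix the previous ciphertext byte with the keystream byte. Plain
// addition mod 256 is linear in the top bit (x + 128 == x ^ 128), which
// leaves an absorbing difference state; the left-rotation moves the top
// bit down so no fixed bit position is absorbing (an ARX step).
static inline int mix_arx(int prev, int r) {
  int t = (prev + r) & 255;
  return ((t << 3) | (t >> 5)) & 255;
}

// Chained diffusion. arx = false (plain XOR chain):
//   forward:  E[i] = E[i-1] ^ R[i] ^ Q[i], boundary E[-1] = iv;
//   reverse:  E[i] = E[i+1] ^ R[i] ^ Q[i], boundary E[n] = iv.
// arx = true (carry-propagating chain, breaks GF(2) linearity):
//   forward:  E[i] = Q[i] ^ rotl8((R[i] + E[i-1]) mod 256, 3);
//   reverse:  E[i] = Q[i] ^ rotl8((R[i] + E[i+1]) mod 256, 3).
// [[Rcpp::export]]
IntegerVector xor_diffuse_cpp(IntegerVector q, IntegerVector r, int iv,
                              bool forward, bool arx) {
  int n = q.size();
  IntegerVector e(n);
  int acc = iv;
  if (forward) {
    for (int i = 0; i < n; ++i) {
      e[i] = arx ? (q[i] ^ mix_arx(acc, r[i])) : (acc ^ r[i] ^ q[i]);
      acc = e[i];
    }
  } else {
    for (int i = n - 1; i >= 0; --i) {
      e[i] = arx ? (q[i] ^ mix_arx(acc, r[i])) : (acc ^ r[i] ^ q[i]);
      acc = e[i];
    }
  }
  return e;
}

// Inverse of xor_diffuse_cpp. Plain chain: P[i] = C[prev] ^ C[i] ^ S[i];
// arx chain: P[i] = C[i] ^ rotl8((S[i] + C[prev]) mod 256, 3);
// boundary = iv. The mixing function never needs inverting because it
// only consumes already-known ciphertext bytes.
// [[Rcpp::export]]
IntegerVector xor_undiffuse_cpp(IntegerVector e, IntegerVector s, int iv,
                                bool forward, bool arx) {
  int n = e.size();
  IntegerVector p(n);
  int acc = iv;
  if (forward) {
    for (int i = 0; i < n; ++i) {
      p[i] = arx ? (e[i] ^ mix_arx(acc, s[i])) : (acc ^ e[i] ^ s[i]);
      acc = e[i];
    }
  } else {
    for (int i = n - 1; i >= 0; --i) {
      p[i] = arx ? (e[i] ^ mix_arx(acc, s[i])) : (acc ^ e[i] ^ s[i]);
      acc = e[i];
    }
  }
  return p;
}
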