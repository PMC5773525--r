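#pragma once
#include <Rcpp.h>

// Site / cell state codes shared by all models:
//   0 empty, 1 A+ (PCD+, phenotype A), 2 B+ , 3 A- (PCD-), 4 B-
inline bool st_alive(int s) { return s > 0; }
inline bool st_plus(int s) { return s == 1 || s == 2; }
inline int st_pheno(int s) { return (s == 1 || s == 3) ? 0 : 1; } // 0 = A, 1 = B
inline int st_flip(int s) {
  switch (s) {
  case 1: return 2;
  case 2: return 1;
  case 3: return 4;
  default: return 3;
  }
}

inline int ribinom(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int) R::rbinom((double) n, p);
}

// uniform integer in [0, n)
inline int runif_int(int n) {
  int k = (int) (R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}
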