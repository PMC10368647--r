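#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Forward-simulator inner loops. Genotype draws use a xoshiro256++ stream
// whose state is seeded from R's RNG on every call, so set.seed() in R
// fully determines every draw while keeping the per-entry cost low enough
// for multi-generation cohorts with ~10^8 genotype entries.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() { return (next() >> 11) * 0x1.0p-53; }
};

// Seed the stream from R's RNG so all randomness descends from set.seed().
Xoshiro256pp seeded_stream() {
  const uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
  const uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
  return Xoshiro256pp((a << 32) ^ b ^ 0x8f1bbcdcbfa53e0bULL);
}

} // namespace

// Founder genotypes: one column per SNP, entries ~ Binomial(2, p[j]),
// realized with a single uniform per entry against precomputed thresholds.
// [[Rcpp::export(name = ".founder_geno_cpp")]]
IntegerMatrix founder_geno_cpp(int n, NumericVector p) {
  const int m = p.size();
  IntegerMatrix g(n, m);
  Xoshiro256pp rng = seeded_stream();
  for (int j = 0; j < m; ++j) {
    const double pj = p[j];
    const double t2 = pj * pj;              // P(geno = 2)
    const double t1 = t2 + 2.0 * pj * (1.0 - pj); // P(geno >= 1)
    int *col = &g(0, j);
    for (int i = 0; i < n; ++i) {
      const double u = rng.uniform();
      col[i] = (u < t2) + (u < t1); // branchless: 2, 1, or 0
    }
  }
  return g;
}

// Mendelian transmission without linkage: each parent passes one allele per
// SNP, drawn uniformly from their two (a fair random bit decides what a
// heterozygote transmits; homozygotes transmit deterministically). Couples
// are processed jointly so each parent genotype is fetched once for both
// children; sibling draws stay independent.
// [[Rcpp::export(name = ".transmit_cpp")]]
IntegerMatrix transmit_cpp(IntegerMatrix geno, IntegerVector father,
                           IntegerVector mother) {
  const int ncpl = father.size();
  const int m = geno.ncol();
  IntegerMatrix child(2 * ncpl, m);
  Xoshiro256pp rng = seeded_stream();
  uint64_t bits = 0;
  int bits_left = 0;
  for (int j = 0; j < m; ++j) {
    const int *col = &geno(0, j);
    int *out = &child(0, j);
    for (int i = 0; i < ncpl; ++i) {
      const int gf = col[father[i] - 1];
      const int gm = col[mother[i] - 1];
      if (bits_left < 4) { bits = rng.next(); bits_left = 64; }
      const int hf = gf & 1, hm = gm & 1, base = (gf >> 1) + (gm >> 1);
      out[2 * i] = base + (hf & (int)(bits & 1)) + (hm & (int)((bits >> 1) & 1));
      out[2 * i + 1] = base + (hf & (int)((bits >> 2) & 1)) + (hm & (int)((bits >> 3) & 1));
      bits >>= 4;
      bits_left -= 4;
    }
  }
  return child;
}

// Per-SNP simple regression of y on allele count: slope, classical SE, and
// effect-allele frequency, in one pass per column. Monomorphic SNPs get
// beta = 0 and se = Inf.
// [[Rcpp::export(name = ".gwas_cpp")]]
List gwas_cpp(IntegerMatrix geno, NumericVector y) {
  const int n = geno.nrow();
  const int m = geno.ncol();
  NumericVector beta(m), se(m), eaf(m);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double syy = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = y[i] - ybar;
    syy += d * d;
  }
  for (int j = 0; j < m; ++j) {
    const int *col = &geno(0, j);
    double sg = 0.0, sgg = 0.0, sgy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double g = col[i];
      sg += g;
      sgg += g * g;
      sgy += g * y[i];
    }
    const double gbar = sg / n;
    const double sxx = sgg - n * gbar * gbar;
    const double sxy = sgy - n * gbar * ybar;
    eaf[j] = gbar / 2.0;
    if (sxx <= 0.0) {
      beta[j] = 0.0;
      se[j] = R_PosInf;
    } else {
      const double b = sxy / sxx;
      beta[j] = b;
      double rss = syy - b * sxy;
      if (rss < 0.0) rss = 0.0;
      se[j] = sqrt(rss / (n - 2.0) / sxx);
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["eaf"] = eaf);
}

// Genotype-matrix-times-weights without coercing the integer matrix to double.
// [[Rcpp::export(name = ".geno_score_cpp")]]
NumericVector geno_score_cpp(IntegerMatrix geno, NumericVector w) {
  const int n = geno.nrow();
  const int m = geno.ncol();
  if (w.size() != m) stop("weight vector length does not match SNP count");
  NumericVector s(n);
  for (int j = 0; j < m; ++j) {
    const double wj = w[j];
    if (wj == 0.0) continue;
    const int *col = &geno(0, j);
    for (int i = 0; i < n; ++i) s[i] += wj * col[i];
  }
  return s;
}
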