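// Generation loop for the sexual-conflict-with-decoy simulator.
//
// Alleles are small integers (0..allele_max); a pair's mating rate depends
// only on the integer allele sums at the male, female and decoy loci, so all
// rates are precomputed into a lookup table once per run (parameters are
// constant).  The RNG is a self-contained xoshiro256++ seeded per replicate
// from (seed, stream) via splitmix64, so trajectories are bit-reproducible
// across platforms and independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro256pp(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer on [0, n); Lemire multiply-shift (n << 2^64 so the
  // bias is negligible and draws stay deterministic)
  uint32_t below(uint32_t n) {
    return (uint32_t)(((__uint128_t)next() * n) >> 64);
  }
};

struct ModelPars {
  double Popt, Bmax, sw, xw, sp, xp, si, xi, sd, xd, c0, Dopt;
  int allele_max;
  bool normalize;
};

ModelPars readPars(const List &params) {
  ModelPars p;
  p.Popt = as<double>(params["P_opt"]);
  p.Bmax = as<double>(params["B_max"]);
  p.sw = as<double>(params["s_w"]);  p.xw = as<double>(params["x_w"]);
  p.sp = as<double>(params["s_p"]);  p.xp = as<double>(params["x_p"]);
  p.si = as<double>(params["si"]);   p.xi = as<double>(params["xi"]);
  p.sd = as<double>(params["sd"]);   p.xd = as<double>(params["xd"]);
  p.c0 = as<double>(params["c0"]);   p.Dopt = as<double>(params["D_opt"]);
  p.allele_max = as<int>(params["allele_max"]);
  p.normalize = as<bool>(params["normalize"]);
  return p;
}

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// Mating rate of one male-female pair from integer allele sums at the
// male (ms), female (fs) and decoy (ds) loci.  Mirrors the R-level model
// functions exactly; cross-checked against them in the test suite.
double pairRate(int ms, int fs, int ds, const ModelPars &p, bool decoy_on) {
  double denom = p.normalize ? 2.0 * p.allele_max : 2.0;
  double zm = ms / denom, zf = fs / denom, zd = ds / denom;
  double D = std::fabs(zm - zf);
  double P = std::exp(-std::pow(D / p.sp, p.xp));
  if (decoy_on) {
    double lo = std::min(zm, zf), hi = std::max(zm, zf);
    if (zd > lo && zd < hi) {  // theta = 1, strict
      double dev = std::fabs(D - p.Dopt);
      double dmd = std::fabs(zd - zm);
      double Pt = p.Popt * std::min(1.0, std::pow(dev / p.sd, p.xd));
      double Pi = p.Popt * p.c0 * std::min(1.0, std::pow(dmd / p.si, p.xi));
      P = clamp01(p.Popt - Pt - Pi);
    }
  }
  return P;
}

}  // namespace

// Full mating-rate lookup table indexed [male_sum+1, female_sum+1,
// decoy_sum+1] (allele sums 0..2*allele_max).  Exposed so tests can verify
// the engine's table against the pure-R model functions.
// [[Rcpp::export(name = ".rate_table_cpp")]]
NumericVector rate_table_cpp(List params, bool decoy_on) {
  ModelPars p = readPars(params);
  int S = 2 * p.allele_max + 1;
  NumericVector out((R_xlen_t)S * S * S);
  for (int ds = 0; ds < S; ++ds)
    for (int fs = 0; fs < S; ++fs)
      for (int ms = 0; ms < S; ++ms)
        out[(R_xlen_t)ms + (R_xlen_t)S * (fs + (R_xlen_t)S * ds)] =
            pairRate(ms, fs, ds, p, decoy_on);
  out.attr("dim") = IntegerVector::create(S, S, S);
  return out;
}

// One replicate.  init = initial allele values (male, female, decoy,
// neutral); returns a (generations+1) x 6 matrix: generation, per-locus mean
// allelic values, and the population mean realized mating rate during the
// generation's mating round (NaN on row 0).
// [[Rcpp::export(name = ".sim_engine_cpp")]]
NumericMatrix sim_engine_cpp(int N, int generations, int n_enc, double mu,
                             IntegerVector init, List params, bool decoy_on,
                             double seed, double stream) {
  ModelPars p = readPars(params);
  const int amax = p.allele_max;
  const int S = 2 * amax + 1;

  if (N <= 0 || N % 2 != 0) stop("population size N must be even and positive");
  if (init.size() != 4) stop("init must hold 4 initial allele values");
  for (int l = 0; l < 4; ++l)
    if (init[l] < 0 || init[l] > amax)
      stop("initial allele value outside allele space [0, allele_max]");

  Xoshiro256pp rng((uint64_t)seed, (uint64_t)stream);

  // rate table laid out [fs][ds][ms]: one female's row is contiguous
  std::vector<double> P3((size_t)S * S * S);
  for (int fs = 0; fs < S; ++fs)
    for (int ds = 0; ds < S; ++ds)
      for (int ms = 0; ms < S; ++ms)
        P3[((size_t)fs * S + ds) * S + ms] = pairRate(ms, fs, ds, p, decoy_on);

  // fecundity by number of matings k out of n_enc
  std::vector<double> Wtab(n_enc + 1);
  for (int k = 0; k <= n_enc; ++k) {
    double P = (double)k / n_enc;
    Wtab[k] = p.Bmax * std::exp(-std::pow(std::fabs(P - p.Popt) / p.sw, p.xw));
  }

  // alleles: individual i, locus l (0=m,1=f,2=d,3=n), copy c
  std::vector<uint8_t> all((size_t)N * 8), nxt((size_t)N * 8);
  std::vector<uint8_t> sex(N), nsex(N);  // 1 = male
  for (int i = 0; i < N; ++i) {
    sex[i] = (i < N / 2) ? 1 : 0;
    for (int l = 0; l < 4; ++l) {
      all[(size_t)i * 8 + 2 * l] = (uint8_t)init[l];
      all[(size_t)i * 8 + 2 * l + 1] = (uint8_t)init[l];
    }
  }

  NumericMatrix traj(generations + 1, 6);
  auto record = [&](int g, double mrate) {
    double sums[4] = {0, 0, 0, 0};
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < 4; ++l)
        sums[l] += all[(size_t)i * 8 + 2 * l] + all[(size_t)i * 8 + 2 * l + 1];
    traj(g, 0) = g;
    for (int l = 0; l < 4; ++l) traj(g, l + 1) = sums[l] / (2.0 * N);
    traj(g, 5) = mrate;
  };
  record(0, NA_REAL);

  std::vector<int> males, females;
  std::vector<int> msum;            // male-locus allele sum per male
  std::vector<int> mates;           // flat mate list (indices into males[])
  std::vector<int> mate_off;        // offsets per mated female
  std::vector<int> mother_id;       // individual index of each mated female
  std::vector<double> cumW;

  for (int g = 1; g <= generations; ++g) {
    males.clear(); females.clear();
    for (int i = 0; i < N; ++i) (sex[i] ? males : females).push_back(i);
    if (males.empty()) stop("no males in generation %d", g);
    if (females.empty()) stop("no females in generation %d", g);

    const int nm = (int)males.size();
    msum.resize(nm);
    for (int j = 0; j < nm; ++j)
      msum[j] = all[(size_t)males[j] * 8 + 0] + all[(size_t)males[j] * 8 + 1];

    mates.clear(); mate_off.clear(); mother_id.clear(); cumW.clear();
    mate_off.push_back(0);
    double totW = 0.0;
    long total_matings = 0;

    for (size_t fi = 0; fi < females.size(); ++fi) {
      int i = females[fi];
      int fs = all[(size_t)i * 8 + 2] + all[(size_t)i * 8 + 3];
      int ds = all[(size_t)i * 8 + 4] + all[(size_t)i * 8 + 5];
      const double *row = &P3[((size_t)fs * S + ds) * S];
      int k = 0;
      size_t first = mates.size();
      for (int e = 0; e < n_enc; ++e) {
        uint32_t j = rng.below((uint32_t)nm);
        double pr = row[msum[j]];
        double u = rng.unif();
        if (u < pr) { mates.push_back((int)j); ++k; }
      }
      total_matings += k;
      if (k > 0) {
        mother_id.push_back(i);
        mate_off.push_back((int)mates.size());
        totW += Wtab[k];
        cumW.push_back(totW);
      } else {
        mates.resize(first);
      }
    }
    if (mother_id.empty())
      stop("no females mated in generation %d; cannot form the next generation", g);

    // next generation: mother ~ fecundity-weighted among mated females,
    // sire uniform over the mother's mates, Mendelian gametes + mutation
    for (int c = 0; c < N; ++c) {
      double u = rng.unif() * totW;
      int m = (int)(std::lower_bound(cumW.begin(), cumW.end(), u) - cumW.begin());
      if (m >= (int)mother_id.size()) m = (int)mother_id.size() - 1;
      int mom = mother_id[m];
      int nmates = mate_off[m + 1] - mate_off[m];
      int dad = males[mates[mate_off[m] + (int)rng.below((uint32_t)nmates)]];
      for (int l = 0; l < 4; ++l) {
        for (int par = 0; par < 2; ++par) {
          int src = par == 0 ? mom : dad;
          int a = all[(size_t)src * 8 + 2 * l + (rng.next() & 1)];
          if (mu > 0.0 && rng.unif() < mu) {
            int step = (rng.next() & 1) ? 1 : -1;
            a += step;
            if (a < 0) a = 1;              // reflect at 0
            else if (a > amax) a = amax - 1;  // reflect at allele_max
          }
          nxt[(size_t)c * 8 + 2 * l + par] = (uint8_t)a;
        }
      }
      nsex[c] = (uint8_t)(rng.next() & 1);
    }
    all.swap(nxt);
    sex.swap(nsex);

    double mean_rate =
        (double)total_matings / ((double)females.size() * n_enc);
    record(g, mean_rate);
    if (g % 512 == 0) Rcpp::checkUserInterrupt();
  }

  colnames(traj) = CharacterVector::create(
      "generation", "mean_male", "mean_female", "mean_decoy", "mean_neutral",
      "mean_mating");
  return traj;
}
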