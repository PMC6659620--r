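#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained counter-seeded RNG so that ensembles are bit-reproducible
// from (params, init, path seeds, grid) independently of R's RNG state.
// Path seeds are 64-bit integers passed as doubles (exact below 2^53).

static inline uint64_t splitmix64_next(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1); offset keeps log() finite
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) *
           (1.0 / 9007199254740992.0);
  }
};

// Direct-method Gillespie simulation of the six-channel two-phenotype model:
// birth E (kE*E), birth M (kM*M), death E (muE*E), death M (muM*M),
// switch E->M (kEM*E), switch M->E (kME*M). State is recorded at each grid
// time as the value of the right-continuous jump process.
// [[Rcpp::export]]
List ssa_ensemble_cpp(double kE, double kM, double muE, double muM,
                      double kEM, double kME,
                      IntegerVector E0, IntegerVector M0,
                      NumericVector tgrid, NumericVector seeds,
                      double max_events) {
  const int nrep = E0.size();
  const int nt = tgrid.size();
  if (M0.size() != nrep || seeds.size() != nrep)
    stop("E0, M0 and seeds must have equal length");
  IntegerMatrix Eout(nrep, nt), Mout(nrep, nt);

  for (int r = 0; r < nrep; ++r) {
    Xoshiro256pp rng(static_cast<uint64_t>(seeds[r]));
    double t = 0.0;
    long long E = E0[r], M = M0[r];
    if (E < 0 || M < 0) stop("negative initial counts");
    int gi = 0;
    double nev = 0.0;
    while (gi < nt) {
      const double aE = kE * E, aM = kM * M;
      const double dE = muE * E, dM = muM * M;
      const double sEM = kEM * E, sME = kME * M;
      const double atot = aE + aM + dE + dM + sEM + sME;
      if (atot <= 0.0) {  // extinct or frozen: constant from here on
        for (; gi < nt; ++gi) {
          Eout(r, gi) = static_cast<int>(E);
          Mout(r, gi) = static_cast<int>(M);
        }
        break;
      }
      const double tnext = t - std::log(rng.unif()) / atot;
      while (gi < nt && tgrid[gi] < tnext) {
        Eout(r, gi) = static_cast<int>(E);
        Mout(r, gi) = static_cast<int>(M);
        ++gi;
      }
      if (gi >= nt) break;
      const double u = rng.unif() * atot;
      if (u < aE) ++E;
      else if (u < aE + aM) ++M;
      else if (u < aE + aM + dE) --E;
      else if (u < aE + aM + dE + dM) --M;
      else if (u < aE + aM + dE + dM + sEM) { --E; ++M; }
      else { --M; ++E; }
      t = tnext;
      if (++nev > max_events)
        stop("SSA exceeded max_events; population may be super-critical");
    }
  }
  return List::create(_["E"] = Eout, _["M"] = Mout);
}
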