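// Stochastic lattice sweep kernel.
//
// Grid codes: 0 vacant; 1..K species-1 strain k (production rate a_vals[k-1],
// a = 0 is the non-producer); 100 sensitive; 101 resistant.
//
// One sweep visits every site exactly once in a fresh uniform random order
// (single-pass Fisher-Yates: at step i the visited site is drawn uniformly
// from the not-yet-visited set). At an occupied site the cell reproduces
// with probability max(0, r_i)*dt into a uniformly chosen Moore neighbour
// (birth discarded if the target is occupied), then independently dies with
// probability v*dt; one 32-bit uniform decides the joint (birth, death)
// event through the product partition. Updates are applied immediately
// (asynchronous), so newborns landing on not-yet-visited sites act later in
// the same sweep.
//
// The antibiotic enters through per-site Moore-neighbourhood production
// sums, maintained incrementally on every producer birth/death and rebuilt
// from the grid at each kernel entry; this equals recomputing the local
// field from the instantaneous configuration at every birth attempt.
//
// Performance notes (the acceptance-scale runs need ~1e10 site visits):
//  - xoshiro256++ seeded through splitmix64, kept in register-resident
//    locals: writes through the grid's char pointer may alias anything, so
//    state held in an addressable struct would be spilled every visit.
//  - a visit whose event uniform exceeds the largest possible event
//    probability (max birth prob + death prob, a few percent) is resolved
//    without touching the grid at all; only the permutation swap remains.
//  - permutation indices are 16-bit when the lattice has <= 65536 sites
//    (L <= 256), halving the hot random-access footprint.
//
// Determinism: the RNG state is threaded through R between kernel calls,
// so identical (seed, config) gives bit-identical trajectories.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro256 {
  uint64_t s[4];
};

static uint64_t splitmix64(uint64_t &z) {
  z += 0x9e3779b97f4a7c15ULL;
  uint64_t t = z;
  t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
  t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
  return t ^ (t >> 31);
}

static IntegerVector pack_state(const Xoshiro256 &rng) {
  IntegerVector st(8);
  std::memcpy(INTEGER(st), rng.s, 32);
  return st;
}

// [[Rcpp::export]]
IntegerVector cpp_rng_state(int seed) {
  Xoshiro256 rng;
  uint64_t z = (uint64_t)(uint32_t)seed;
  for (int i = 0; i < 4; ++i) rng.s[i] = splitmix64(z);
  return pack_state(rng);
}

static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

#define U01_32 2.3283064365386963e-10   /* 2^-32 */

struct SweepParams {
  int L, n, K, m_act;
  double r2, dt, pd, inv9b, u;
  bool mut1, mut2, global_dispersal;
  const double *pb;          // birth probability per code (1..101)
  const double *a_vals;      // production rate per species-1 code
  const int *active_codes;
  const int *pos_active;
  const int *xp, *xm;
  uint64_t skip_thresh;      // 32-bit threshold: uniform above => no event
};

template <typename IDX>
static void run_sweeps(uint8_t *__restrict__ g, float *__restrict__ asum,
                       IDX *__restrict__ perm, const SweepParams &sp,
                       int nsweeps, Xoshiro256 &rng,
                       long long &births, long long &deaths) {
  const int L = sp.L, n = sp.n;
  const double r2 = sp.r2, dt = sp.dt, pd = sp.pd, inv9b = sp.inv9b, u = sp.u;
  const double *__restrict__ pb = sp.pb;
  const double *__restrict__ av = sp.a_vals;
  const int *__restrict__ xp = sp.xp;
  const int *__restrict__ xm = sp.xm;
  const uint64_t skip_thresh = sp.skip_thresh;
  uint64_t s0 = rng.s[0], s1 = rng.s[1], s2 = rng.s[2], s3 = rng.s[3];
#define NEXT_RAND(res) do { \
    (res) = rotl64(s0 + s3, 23) + s0; \
    const uint64_t t_ = s1 << 17; \
    s2 ^= s0; s3 ^= s1; s1 ^= s2; s0 ^= s3; \
    s2 ^= t_; s3 = rotl64(s3, 45); } while (0)

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int i = n - 1; i >= 0; --i) {
      uint64_t r; NEXT_RAND(r);
      const int j = (int)(((uint64_t)(uint32_t)r * (uint64_t)(i + 1)) >> 32);
      const IDX site = perm[j];
      perm[j] = perm[i];
      perm[i] = site;

      // no event is possible above the global probability bound: resolve
      // the visit without reading the grid
      const uint64_t hi = r >> 32;
      if (hi >= skip_thresh) continue;

      const int code = g[site];
      if (!code) continue;

      double p_birth;
      if (code == 100) {
        const double rs = r2 - asum[site] * inv9b;
        p_birth = rs > 0 ? rs * dt : 0.0;
      } else {
        p_birth = pb[code];
      }

      const double uu = (double)(uint32_t)hi * U01_32;
      const double pbd = p_birth * pd;
      bool do_birth, do_death;
      if (uu < pbd) { do_birth = true; do_death = true; }
      else if (uu < p_birth) { do_birth = true; do_death = false; }
      else if (uu < p_birth + pd - pbd) { do_birth = false; do_death = true; }
      else continue;

      if (do_birth) {
        uint64_t r2bits; NEXT_RAND(r2bits);
        int target;
        if (sp.global_dispersal) {
          target = (int)(((uint64_t)(uint32_t)r2bits * (uint64_t)n) >> 32);
        } else {
          const int dir = (int)(r2bits & 7ULL);
          const int y = (int)site / L, x = (int)site - y * L;
          int nx = x + DX[dir], ny = y + DY[dir];
          if (nx < 0) nx += L; else if (nx >= L) nx -= L;
          if (ny < 0) ny += L; else if (ny >= L) ny -= L;
          target = ny * L + nx;
        }
        if (g[target] == 0) {
          int oc = code;
          if (u > 0.0) {
            const double um = (double)(uint32_t)(r2bits >> 32) * U01_32;
            if (um < u) {
              if (code < 100) {
                if (sp.mut1 && sp.m_act > 1) {
                  const int p = sp.pos_active[code];
                  const int nother = (p >= 0) ? sp.m_act - 1 : sp.m_act;
                  if (nother > 0) {
                    uint64_t rm; NEXT_RAND(rm);
                    int idx = (int)(((uint64_t)(uint32_t)rm *
                                     (uint64_t)nother) >> 32);
                    if (p >= 0 && idx >= p) ++idx;
                    oc = sp.active_codes[idx];
                  }
                }
              } else if (sp.mut2) {
                oc = (code == 100) ? 101 : 100;
              }
            }
          }
          g[target] = (uint8_t)oc;
          ++births;
          if (oc < 100) {
            const float a = (float)av[oc - 1];
            if (a != 0.0f) {
              const int ty = target / L, tx = target - ty * L;
              const int xs[3] = {xm[tx], tx, xp[tx]};
              const int ys[3] = {xm[ty], ty, xp[ty]};
              for (int iy = 0; iy < 3; ++iy)
                for (int ix = 0; ix < 3; ++ix)
                  asum[ys[iy] * L + xs[ix]] += a;
            }
          }
        }
      }

      if (do_death) {
        g[site] = 0;
        ++deaths;
        if (code < 100) {
          const float a = (float)av[code - 1];
          if (a != 0.0f) {
            const int sy = (int)site / L, sx = (int)site - sy * L;
            const int xs[3] = {xm[sx], sx, xp[sx]};
            const int ys[3] = {xm[sy], sy, xp[sy]};
            for (int iy = 0; iy < 3; ++iy)
              for (int ix = 0; ix < 3; ++ix)
                asum[ys[iy] * L + xs[ix]] -= a;
          }
        }
      }
    }
  }
#undef NEXT_RAND
  rng.s[0] = s0; rng.s[1] = s1; rng.s[2] = s2; rng.s[3] = s3;
}

// [[Rcpp::export]]
List cpp_advance(RawVector grid_in, int L, NumericVector a_vals,
                 IntegerVector active_codes,
                 double r1, double r2, double b, double c, double v,
                 double cR, double dt, double u,
                 bool mut1, bool mut2, bool global_dispersal,
                 int nsweeps, IntegerVector rng_state) {
  const int n = L * L;
  if ((int)grid_in.size() != n) stop("grid size does not match L");
  const int K = a_vals.size();
  if (K > 99) stop("at most 99 species-1 strains supported");

  RawVector grid = clone(grid_in);
  uint8_t *g = (uint8_t *)RAW(grid);

  Xoshiro256 rng;
  if (rng_state.size() != 8) stop("rng state must have 8 integers");
  std::memcpy(rng.s, INTEGER(rng_state), 32);

  // birth probabilities per code (S computed per site from the field)
  std::vector<double> pb(102, 0.0);
  for (int k = 1; k <= K; ++k) {
    double r = r1 - a_vals[k - 1] * c;
    pb[k] = r > 0 ? r * dt : 0.0;
  }
  {
    double rR = r2 - cR;
    pb[101] = rR > 0 ? rR * dt : 0.0;
  }
  const double pd = v * dt;

  // Any cell's birth probability is bounded by max(r1, r2)*dt; above
  // pb_max + pd no (birth, death) combination can fire.
  double pb_max = r2 > r1 ? r2 * dt : r1 * dt;
  uint64_t skip_thresh = (uint64_t)std::ceil((pb_max + pd) * 4294967296.0);
  if (skip_thresh > 4294967296ULL) skip_thresh = 4294967296ULL;

  // torus wrap tables
  std::vector<int> xp(L), xm(L);
  for (int i = 0; i < L; ++i) {
    xp[i] = (i + 1 == L) ? 0 : i + 1;
    xm[i] = (i == 0) ? L - 1 : i - 1;
  }

  // Moore-neighbourhood production sums (includes the centre site).
  // float is exact here for integer-valued production rates; rebuilt from
  // the grid on every kernel entry regardless.
  std::vector<float> asum(n, 0.0f);
  for (int y = 0; y < L; ++y) {
    for (int x = 0; x < L; ++x) {
      int code = g[y * L + x];
      if (code == 0 || code >= 100) continue;
      float a = (float)a_vals[code - 1];
      if (a == 0.0f) continue;
      const int xs[3] = {xm[x], x, xp[x]};
      const int ys[3] = {xm[y], y, xp[y]};
      for (int iy = 0; iy < 3; ++iy)
        for (int ix = 0; ix < 3; ++ix)
          asum[ys[iy] * L + xs[ix]] += a;
    }
  }

  // position of each active code inside active_codes (codes are 1..K)
  const int m_act = active_codes.size();
  std::vector<int> pos_active(K + 1, -1);
  for (int i = 0; i < m_act; ++i) {
    int cde = active_codes[i];
    if (cde < 1 || cde > K) stop("active code out of range");
    pos_active[cde] = i;
  }

  SweepParams sp;
  sp.L = L; sp.n = n; sp.K = K; sp.m_act = m_act;
  sp.r2 = r2; sp.dt = dt; sp.pd = pd; sp.inv9b = 1.0 / (9.0 * b); sp.u = u;
  sp.mut1 = mut1; sp.mut2 = mut2; sp.global_dispersal = global_dispersal;
  sp.pb = pb.data(); sp.a_vals = REAL(a_vals);
  sp.active_codes = INTEGER(active_codes); sp.pos_active = pos_active.data();
  sp.xp = xp.data(); sp.xm = xm.data();
  sp.skip_thresh = skip_thresh;

  long long births = 0, deaths = 0;
  if (n <= 65536) {
    std::vector<uint16_t> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = (uint16_t)i;
    run_sweeps<uint16_t>(g, asum.data(), perm.data(), sp, nsweeps, rng,
                         births, deaths);
  } else {
    std::vector<int32_t> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    run_sweeps<int32_t>(g, asum.data(), perm.data(), sp, nsweeps, rng,
                        births, deaths);
  }

  IntegerVector counts(102);
  std::vector<int> cnt(102, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]] += 1;
  for (int k = 0; k < 102; ++k) counts[k] = cnt[k];

  return List::create(_["grid"] = grid,
                      _["counts"] = counts,
                      _["rng_state"] = pack_state(rng),
                      _["births"] = (double)births,
                      _["deaths"] = (double)deaths);
}
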