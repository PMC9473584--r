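// Coarse-grained Langevin dynamics core: bead-spring chains with
// harmonic bonds, a cosine sticker attraction (Tyr-Arg, ATP-Arg) and a
// softened truncated Lennard-Jones repulsion, in a fully periodic box.
// O(N^2) minimum-image pair loop; system sizes here are a few hundred
// beads, where this beats a cell list.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// deterministic, platform-independent RNG (xoshiro256++) with
// Box-Muller normals
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
};

struct ForceField {
  double rb, kbond, r0, U0_YR, U0_AR, lambda, sigma, rc;
  double eps[4];       // per-type repulsion strength: N, Y, R, ATP
  double shift;        // additive shift so the repulsion vanishes at rc
  double repulsion_raw(double r) const {
    double A = (1.0 - lambda) * (1.0 - lambda);
    double s6 = std::pow(r / sigma, 6.0);
    double d = A + s6;
    return 4.0 * lambda * (1.0 / (d * d) - 1.0 / d);
  }
};

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// energy and |dU/dr|-style radial derivative for one pair; returns
// dU/dr (the force on bead i along r_ij is -dUdr * rhat)
inline void pair_eval(const ForceField& ff, int ti, int tj, double r,
                      bool bonded, double& U, double& dUdr) {
  U = 0.0; dUdr = 0.0;
  if (bonded) {
    double dr = r - ff.rb;
    U += ff.kbond * dr * dr;
    dUdr += 2.0 * ff.kbond * dr;
    return;  // bonded neighbours feel only the spring
  }
  // soft repulsion between beads of the same type only (it exists to
  // prevent same-type aggregation; cross-type pairs would otherwise
  // have their sticker attraction swamped, sigma > r0)
  if (ti == tj && r < ff.rc) {
    double e = ff.eps[ti];
    double A = (1.0 - ff.lambda) * (1.0 - ff.lambda);
    double s2 = (r / ff.sigma) * (r / ff.sigma);
    double s6 = s2 * s2 * s2;
    double d = A + s6;
    U += e * (4.0 * ff.lambda * (1.0 / (d * d) - 1.0 / d) - ff.shift);
    double ds6dr = (r > 0) ? 6.0 * s6 / r : 0.0;
    dUdr += e * 4.0 * ff.lambda * (-2.0 / (d * d * d) + 1.0 / (d * d)) * ds6dr;
  }
  // sticker attraction: Tyr-Arg and ATP-Arg
  double U0 = 0.0;
  if ((ti == 1 && tj == 2) || (ti == 2 && tj == 1)) U0 = ff.U0_YR;
  else if ((ti == 3 && tj == 2) || (ti == 2 && tj == 3)) U0 = ff.U0_AR;
  if (U0 != 0.0 && r < ff.r0) {
    U += U0 * (1.0 + std::cos(M_PI * r / ff.r0));
    dUdr += -U0 * (M_PI / ff.r0) * std::sin(M_PI * r / ff.r0);
  }
}

ForceField make_ff(const List& ffl) {
  ForceField ff;
  ff.rb = ffl["r_b"]; ff.kbond = ffl["k_bond"]; ff.r0 = ffl["r0"];
  ff.U0_YR = ffl["U0_YR"]; ff.U0_AR = ffl["U0_AR"];
  ff.lambda = ffl["lambda_lj"]; ff.sigma = ffl["sigma"]; ff.rc = ffl["r_c"];
  NumericVector eps = ffl["eps_type"];
  for (int i = 0; i < 4; ++i) ff.eps[i] = eps[i];
  ff.shift = ff.repulsion_raw(ff.rc);
  return ff;
}

// accumulate one interacting pair (distance already inside cutoff or bonded)
inline void accumulate_pair(const ForceField& ff, int i, int j,
                            int ti, int tj, bool bonded,
                            double dx, double dy, double dz, double r2,
                            NumericMatrix& f, double& U) {
  double r = std::sqrt(r2);
  double u, dudr;
  pair_eval(ff, ti, tj, r, bonded, u, dudr);
  U += u;
  if (r > 1e-12) {
    double fac = -dudr / r;
    f(i, 0) += fac * dx; f(i, 1) += fac * dy; f(i, 2) += fac * dz;
    f(j, 0) -= fac * dx; f(j, 1) -= fac * dy; f(j, 2) -= fac * dz;
  }
}

// cell-list nonbonded loop plus explicit bond loop
void compute_forces(const ForceField& ff, const NumericMatrix& x,
                    const IntegerVector& type, const IntegerVector& chain,
                    const NumericVector& box, NumericMatrix& f,
                    double* Utot) {
  int n = x.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  double U = 0.0;
  double rc2 = ff.rc * ff.rc;

  // bonds: consecutive beads of the same chain
  for (int i = 0; i + 1 < n; ++i) {
    if (chain[i] != chain[i + 1]) continue;
    double dx = min_image(x(i, 0) - x(i + 1, 0), box[0]);
    double dy = min_image(x(i, 1) - x(i + 1, 1), box[1]);
    double dz = min_image(x(i, 2) - x(i + 1, 2), box[2]);
    accumulate_pair(ff, i, i + 1, type[i], type[i + 1], true,
                    dx, dy, dz, dx * dx + dy * dy + dz * dz, f, U);
  }

  // cell list on wrapped coordinates
  int ncx = std::max(1, (int)(box[0] / ff.rc));
  int ncy = std::max(1, (int)(box[1] / ff.rc));
  int ncz = std::max(1, (int)(box[2] / ff.rc));
  int ncells = ncx * ncy * ncz;
  std::vector<int> head(ncells, -1), nxt(n, -1), cellof(n);
  std::vector<double> wx(n), wy(n), wz(n);
  for (int i = 0; i < n; ++i) {
    wx[i] = x(i, 0) - box[0] * std::floor(x(i, 0) / box[0]);
    wy[i] = x(i, 1) - box[1] * std::floor(x(i, 1) / box[1]);
    wz[i] = x(i, 2) - box[2] * std::floor(x(i, 2) / box[2]);
    int cx = std::min(ncx - 1, (int)(wx[i] / box[0] * ncx));
    int cy = std::min(ncy - 1, (int)(wy[i] / box[1] * ncy));
    int cz = std::min(ncz - 1, (int)(wz[i] / box[2] * ncz));
    int c = (cz * ncy + cy) * ncx + cx;
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  bool few_cells = (ncx < 3 || ncy < 3 || ncz < 3);
  if (few_cells) {
    // box too small for a safe cell decomposition: plain O(N^2)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (chain[i] == chain[j] && std::abs(i - j) == 1) continue;
        double dx = min_image(x(i, 0) - x(j, 0), box[0]);
        double dy = min_image(x(i, 1) - x(j, 1), box[1]);
        double dz = min_image(x(i, 2) - x(j, 2), box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= rc2)
          accumulate_pair(ff, i, j, type[i], type[j], false,
                          dx, dy, dz, r2, f, U);
      }
  } else {
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          for (int i = head[c]; i >= 0; i = nxt[i]) {
            for (int ddz = -1; ddz <= 1; ++ddz)
              for (int ddy = -1; ddy <= 1; ++ddy)
                for (int ddx = -1; ddx <= 1; ++ddx) {
                  int c2 = (((cz + ddz + ncz) % ncz) * ncy +
                            (cy + ddy + ncy) % ncy) * ncx +
                           (cx + ddx + ncx) % ncx;
                  for (int j = head[c2]; j >= 0; j = nxt[j]) {
                    if (j <= i) continue;
                    if (chain[i] == chain[j] && std::abs(i - j) == 1)
                      continue;
                    double dx = min_image(wx[i] - wx[j], box[0]);
                    double dy = min_image(wy[i] - wy[j], box[1]);
                    double dz = min_image(wz[i] - wz[j], box[2]);
                    double r2 = dx * dx + dy * dy + dz * dz;
                    if (r2 <= rc2)
                      accumulate_pair(ff, i, j, type[i], type[j], false,
                                      dx, dy, dz, r2, f, U);
                  }
                }
          }
        }
  }
  if (Utot) *Utot = U;
}

}  // namespace

// [[Rcpp::export]]
double cg_total_energy(NumericMatrix coords, IntegerVector type,
                       IntegerVector chain, NumericVector box, List ffl) {
  ForceField ff = make_ff(ffl);
  NumericMatrix f(coords.nrow(), 3);
  double U = 0.0;
  compute_forces(ff, coords, type, chain, box, f, &U);
  return U;
}

// [[Rcpp::export]]
NumericMatrix cg_forces(NumericMatrix coords, IntegerVector type,
                        IntegerVector chain, NumericVector box, List ffl) {
  ForceField ff = make_ff(ffl);
  NumericMatrix f(coords.nrow(), 3);
  compute_forces(ff, coords, type, chain, box, f, nullptr);
  return f;
}

// BAOAB Langevin integrator.  Positions are kept unwrapped; the
// minimum-image convention handles periodicity.
// [[Rcpp::export]]
List cg_run_langevin(NumericMatrix coords, IntegerVector type,
                     IntegerVector chain, NumericVector box, List ffl,
                     int n_steps, double dt, double kT, double gamma,
                     double mass, int seed, int sample_every) {
  ForceField ff = make_ff(ffl);
  int n = coords.nrow();
  NumericMatrix x = clone(coords);
  NumericMatrix v(n, 3), f(n, 3);
  Rng rng(static_cast<uint64_t>(seed));
  double U = 0.0;
  compute_forces(ff, x, type, chain, box, f, &U);
  // Maxwell-Boltzmann start (zero for kT = 0)
  double vsig0 = std::sqrt(kT / mass);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) v(i, d) = vsig0 * rng.norm();

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(kT * (1.0 - c1 * c1) / mass);
  int n_frames = n_steps / sample_every + 1;
  List frames(n_frames);
  NumericVector times(n_frames), energies(n_frames);
  frames[0] = clone(x); times[0] = 0.0; energies[0] = U;
  int fi = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        v(i, d) += 0.5 * dt * f(i, d) / mass;
        x(i, d) += 0.5 * dt * v(i, d);
      }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) = c1 * v(i, d) + c2 * rng.norm();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        x(i, d) += 0.5 * dt * v(i, d);
    compute_forces(ff, x, type, chain, box, f, &U);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v(i, d) += 0.5 * dt * f(i, d) / mass;
    if (s % sample_every == 0 && fi < n_frames) {
      for (int i = 0; i < n * 3; ++i)
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate at step %d", s);
      frames[fi] = clone(x);
      times[fi] = s * dt;
      energies[fi] = U;
      ++fi;
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["energies"] = energies, _["velocities"] = v);
}
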