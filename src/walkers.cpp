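#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Counter-free xorshift128+ stream, seeded through splitmix64 so that any
// 64-bit seed yields a well-mixed state. All walker randomness comes from
// this stream: results are bitwise reproducible for a given seed and are
// independent of R's RNG state.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s0, s1;
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t nextu() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() {  // in [0, 1)
    return (nextu() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Random walk of spins through a labelled voxel grid under a PGSE encoding.
//
// Spins take per-axis Bernoulli steps of length sqrt(2 * D * dt) (D of the
// compartment they started in; membranes are impermeable so the compartment
// never changes). A per-axis move that would land in a voxel of a different
// label is rejected (zero flux); the other axes are unaffected, so diffusion
// parallel to a wall is not suppressed. Label lookup wraps periodically on
// all axes; positions used for phase are never wrapped, so the accrued phase
// is that of an infinite periodic medium.
//
// Rather than accumulating a phase per gradient direction, the walk
// accumulates the time integral of position over each gradient lobe
// (midpoint rule, with fractional weights where a step straddles a lobe
// edge). For a constant-amplitude PGSE pair with the refocusing flip between
// the lobes, the phase along unit direction g is
//   phi = gamma * G * dot(g, I1 - I2),
// a linear functional of the returned per-walker vector F = I1 - I2, so one
// set of trajectories serves every direction and the b0 measurement.
//
// [[Rcpp::export]]
List cpp_walk_pgse(IntegerVector labels, IntegerVector dims, double dx,
                   NumericVector diffusivity, int n_walkers, double dt,
                   double delta, double Delta, double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * dx, Ly = ny * dx, Lz = nz * dx;
  const double inv_dx = 1.0 / dx;
  const int *lab = INTEGER(labels);
  const int nlab = diffusivity.size();

  RNG rng(static_cast<uint64_t>(seed));

  const double t_end = Delta + delta;
  const int nt = static_cast<int>(std::ceil(t_end / dt - 1e-12));

  // per-step lobe weight: +overlap with lobe 1, -overlap with lobe 2
  std::vector<double> w(nt);
  for (int k = 0; k < nt; ++k) {
    double t0 = k * dt, t1 = t0 + dt;
    double o1 = std::max(0.0, std::min(t1, delta) - t0);
    double o2 = std::max(0.0, std::min(t1, t_end) - std::max(t0, Delta));
    w[k] = o1 - o2;
  }

  std::vector<double> step(nlab);
  for (int c = 0; c < nlab; ++c) step[c] = std::sqrt(2.0 * diffusivity[c] * dt);

  NumericMatrix F(n_walkers, 3);
  IntegerVector comp(n_walkers);

  for (int j = 0; j < n_walkers; ++j) {
    // wrapped coordinates for lookup, unwrapped for phase
    double wx = rng.unif() * Lx, wy = rng.unif() * Ly, wz = rng.unif() * Lz;
    double x = wx, y = wy, z = wz;
    int ix = static_cast<int>(wx * inv_dx); if (ix >= nx) ix = nx - 1;
    int iy = static_cast<int>(wy * inv_dx); if (iy >= ny) iy = ny - 1;
    int iz = static_cast<int>(wz * inv_dx); if (iz >= nz) iz = nz - 1;
    const int c = lab[ix + nx * (iy + ny * iz)];
    comp[j] = c;
    const double h = step[c];

    double Fx = 0.0, Fy = 0.0, Fz = 0.0;
    for (int k = 0; k < nt; ++k) {
      const uint64_t bits = rng.nextu();
      const double px = x, py = y, pz = z;

      // x axis
      {
        double s = (bits & 1ULL) ? h : -h;
        double c1 = wx + s;
        if (c1 < 0) c1 += Lx; else if (c1 >= Lx) c1 -= Lx;
        int i1 = static_cast<int>(c1 * inv_dx); if (i1 >= nx) i1 = nx - 1;
        if (lab[i1 + nx * (iy + ny * iz)] == c) { wx = c1; ix = i1; x += s; }
      }
      // y axis
      {
        double s = (bits & 2ULL) ? h : -h;
        double c1 = wy + s;
        if (c1 < 0) c1 += Ly; else if (c1 >= Ly) c1 -= Ly;
        int i1 = static_cast<int>(c1 * inv_dx); if (i1 >= ny) i1 = ny - 1;
        if (lab[ix + nx * (i1 + ny * iz)] == c) { wy = c1; iy = i1; y += s; }
      }
      // z axis
      {
        double s = (bits & 4ULL) ? h : -h;
        double c1 = wz + s;
        if (c1 < 0) c1 += Lz; else if (c1 >= Lz) c1 -= Lz;
        int i1 = static_cast<int>(c1 * inv_dx); if (i1 >= nz) i1 = nz - 1;
        if (lab[ix + nx * (iy + ny * i1)] == c) { wz = c1; iz = i1; z += s; }
      }

      const double wk = w[k];
      if (wk != 0.0) {
        Fx += wk * 0.5 * (px + x);
        Fy += wk * 0.5 * (py + y);
        Fz += wk * 0.5 * (pz + z);
      }
    }
    F(j, 0) = Fx; F(j, 1) = Fy; F(j, 2) = Fz;
  }

  return List::create(_["F"] = F, _["comp"] = comp);
}

// Count voxels newly covered by a cylinder of given radius around the
// infinite line through p0 with unit direction ax; optionally commit them
// (label = 1). Voxel rule: a voxel belongs to the fiber if its centre lies
// within the cylinder.
//
// [[Rcpp::export]]
int cpp_cylinder_coverage(IntegerVector labels, IntegerVector dims, double dx,
                          NumericVector p0, NumericVector ax, double radius,
                          bool apply) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int *lab = INTEGER(labels);
  const double r2 = radius * radius;
  const double ax0 = ax[0], ax1 = ax[1], ax2 = ax[2];
  const double p00 = p0[0], p01 = p0[1], p02 = p0[2];
  int count = 0;
  for (int k = 0; k < nz; ++k) {
    const double vz = (k + 0.5) * dx - p02;
    for (int jj = 0; jj < ny; ++jj) {
      const double vy = (jj + 0.5) * dx - p01;
      const double byz = vy * ax1 + vz * ax2;
      const double qyz = vy * vy + vz * vz;
      int *row = lab + nx * (jj + ny * k);
      for (int i = 0; i < nx; ++i) {
        const double vx = (i + 0.5) * dx - p00;
        const double t = vx * ax0 + byz;
        const double d2 = vx * vx + qyz - t * t;
        if (d2 <= r2 && row[i] == 0) {
          ++count;
          if (apply) row[i] = 1;
        }
      }
    }
  }
  return count;
}
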