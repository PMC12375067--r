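#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Overdamped Langevin propagator for the synthetic channel generator.
//
// Reduced units: length nm, time ps, energy kT (300 K).  Forces are
// force/kT in 1/nm; the update is
//   x += D * f * dt + sqrt(2 D dt) * eta
// Ion z-forces: Gaussian binding wells + uniform field + screened-Coulomb
// pair repulsion; x/y: harmonic wall outside the pore-radius function and an
// optional off-axis Gaussian side pocket (full 3D).  Waters diffuse freely
// inside the wall.  Coordinates are wrapped to the centered box for output;
// the true (unwrapped) axial coordinate of every ion is retained and a
// ground-truth traversal log is kept at step resolution.

// Deterministic normal deviates independent of the C++ standard library's
// distributions: xoshiro256++ uniforms (seeded via splitmix64) fed through
// the Marsaglia polar transform.
struct NormGen {
  uint64_t s[4];
  double spare;
  bool has_spare;
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit NormGen(uint64_t seed) : spare(0.0), has_spare(false) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double m = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

static inline double wrap1(double x, double L) {
  return x - L * std::floor(x / L + 0.5);
}

// Axial segment index on the boundary-tiled axis: segments alternate
// OUTSIDE/INSIDE; odd index = inside the pore interval [z_lower, z_upper]
// (mod Lz).  Used for the ground-truth traversal state machine.
static inline long axial_seg(double z, double zlo, double zup, double Lz) {
  return static_cast<long>(std::floor((z - zlo) / Lz)) +
         static_cast<long>(std::floor((z - zup) / Lz)) + 2L;
}

// wall-radius lookup on the (uniform) z grid supplied by the R wrapper
struct WallGrid {
  std::vector<double> r;
  double z0, inv_dz;
  int n;
  WallGrid(const NumericVector& gz, const NumericVector& gr)
    : r(gr.begin(), gr.end()), z0(gz[0]),
      inv_dz((gz.size() - 1) / (gz[gz.size() - 1] - gz[0])),
      n(gz.size()) {}
  inline double at(double z) const {
    double p = (z - z0) * inv_dz;
    if (p <= 0) return r[0];
    if (p >= n - 1) return r[n - 1];
    int i = static_cast<int>(p);
    double t = p - i;
    return r[i] + t * (r[i + 1] - r[i]);
  }
};

// [[Rcpp::export(name = ".langevin_core")]]
List langevin_core(int n_steps, int save_stride, double dt,
                   NumericVector box,
                   NumericMatrix ion_init,      // n_ions x 3, centered coords
                   NumericVector ion_D,
                   NumericVector ion_field_f,   // per-ion q*E/kT, 1/nm
                   NumericVector well_center, NumericVector well_width,
                   NumericMatrix well_depth,    // n_ions x n_wells, kT
                   bool pocket_on, NumericVector pocket_center,
                   double pocket_width, NumericVector pocket_depth,
                   double pocket_radius,        // sphere radius for visit log
                   double rep_amp, double rep_lambda,
                   NumericVector wall_z, NumericVector wall_r, double wall_k,
                   NumericMatrix water_init,    // n_waters x 3
                   double water_D,
                   double z_upper, double z_lower,
                   double sf_low, double sf_high,
                   double pathway_memory,
                   bool deterministic, double seed) {
  const int n_ions = ion_init.nrow(), n_wat = water_init.nrow();
  const int n_part = n_ions + n_wat;
  const int n_wells = well_center.size();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const int n_saved = n_steps / save_stride + 1;
  const double rep_cut = 4.0 * rep_lambda;
  WallGrid wall(wall_z, wall_r);
  std::vector<double> well_cut(n_wells);
  for (int j = 0; j < n_wells; ++j) well_cut[j] = 6.0 * well_width[j];
  const double pocket_cut2 = 36.0 * pocket_width * pocket_width;

  // Per-particle RNG streams with fixed offsets: changing the particle count
  // never reshuffles another particle's noise.
  std::vector<NormGen> rng;
  rng.reserve(n_part);
  uint64_t base = static_cast<uint64_t>(seed);
  for (int i = 0; i < n_part; ++i)
    rng.emplace_back(base * 0x9E3779B97F4A7C15ULL + 0x100000001B3ULL * (i + 1));

  std::vector<double> x(n_part), y(n_part), zw(n_part);  // wrapped
  std::vector<double> zu(n_ions);                        // unwrapped ion z
  for (int i = 0; i < n_ions; ++i) {
    x[i] = ion_init(i, 0); y[i] = ion_init(i, 1); zw[i] = ion_init(i, 2);
    zu[i] = ion_init(i, 2);
  }
  for (int w = 0; w < n_wat; ++w) {
    x[n_ions + w] = water_init(w, 0); y[n_ions + w] = water_init(w, 1);
    zw[n_ions + w] = water_init(w, 2);
  }

  NumericVector positions(Dimension(n_part, 3, n_saved));
  NumericMatrix unwrapped(n_ions, n_saved);   // ion-major: contiguous per frame
  NumericVector times(n_saved);

  // Ground-truth traversal state machine (step resolution).
  std::vector<long> last_out_seg(n_ions), entry_seg(n_ions, 0);
  std::vector<char> pending(n_ions, 0), sf_entered(n_ions, 0), via(n_ions, 0);
  std::vector<double> t_enter(n_ions, 0.0);
  std::vector<double> last_pocket_t(n_ions, -1e30);
  std::vector<double> ev;  // rows: ion, dir(+1 out/-1 in), t_enter, t_exit, via
  for (int i = 0; i < n_ions; ++i) {
    long s = axial_seg(zu[i], z_lower, z_upper, Lz);
    if (s % 2L == 0L) last_out_seg[i] = s;
    else { last_out_seg[i] = s - 1; pending[i] = 0; }  // initial inside ignored
  }

  std::vector<double> fx(n_ions), fy(n_ions), fz(n_ions);
  int save_at = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    if (step % save_stride == 0) {
      for (int i = 0; i < n_part; ++i) {
        positions[save_at * 3 * n_part + 0 * n_part + i] = x[i];
        positions[save_at * 3 * n_part + 1 * n_part + i] = y[i];
        positions[save_at * 3 * n_part + 2 * n_part + i] = zw[i];
      }
      for (int i = 0; i < n_ions; ++i) unwrapped(i, save_at) = zu[i];
      times[save_at] = t;
      ++save_at;
    }
    if (step == n_steps) break;

    // ---- ion forces (per kT)
    for (int i = 0; i < n_ions; ++i) {
      double fzi = ion_field_f[i], fxi = 0.0, fyi = 0.0;
      for (int j = 0; j < n_wells; ++j) {
        double d = zw[i] - well_center[j];
        if (std::fabs(d) > well_cut[j]) continue;   // negligible tail
        double w2 = well_width[j] * well_width[j];
        fzi += -well_depth(i, j) * d / w2 * std::exp(-0.5 * d * d / w2);
      }
      if (pocket_on) {
        double dx = wrap1(x[i] - pocket_center[0], Lx);
        double dy = wrap1(y[i] - pocket_center[1], Ly);
        double dz = wrap1(zw[i] - pocket_center[2], Lz);
        double q2 = dx * dx + dy * dy + dz * dz;
        if (q2 < pocket_cut2) {
          double w2 = pocket_width * pocket_width;
          double c = -pocket_depth[i] / w2 * std::exp(-0.5 * q2 / w2);
          fxi += c * dx; fyi += c * dy; fzi += c * dz;
          if (q2 <= pocket_radius * pocket_radius) last_pocket_t[i] = t;
        }
      }
      double rw = wall.at(zw[i]);
      double r2 = x[i] * x[i] + y[i] * y[i];
      if (r2 > rw * rw && r2 > 1e-24) {
        double r = std::sqrt(r2);
        double fr = -wall_k * (r - rw);
        fxi += fr * x[i] / r; fyi += fr * y[i] / r;
      }
      fx[i] = fxi; fy[i] = fyi; fz[i] = fzi;
    }
    if (rep_amp > 0.0) {
      for (int i = 0; i < n_ions; ++i) {
        for (int j = i + 1; j < n_ions; ++j) {
          double dx = wrap1(x[i] - x[j], Lx), dy = wrap1(y[i] - y[j], Ly);
          double dz = wrap1(zw[i] - zw[j], Lz);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > rep_cut) continue;
          if (d < 0.05) d = 0.05;
          double fmag = rep_amp * std::exp(-d / rep_lambda) *
                        (1.0 / (d * d) + 1.0 / (rep_lambda * d));
          double c = fmag / d;
          fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
          fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
        }
      }
    }
    for (int i = 0; i < n_ions; ++i) {
      double D = ion_D[i], amp = deterministic ? 0.0 : std::sqrt(2.0 * D * dt);
      double ddx = D * fx[i] * dt, ddy = D * fy[i] * dt, ddz = D * fz[i] * dt;
      if (!deterministic) {
        ddx += amp * rng[i].norm(); ddy += amp * rng[i].norm();
        ddz += amp * rng[i].norm();
      }
      x[i] = wrap1(x[i] + ddx, Lx); y[i] = wrap1(y[i] + ddy, Ly);
      zu[i] += ddz; zw[i] = wrap1(zw[i] + ddz, Lz);
    }
    // ---- waters: free diffusion inside the wall
    for (int w = 0; w < n_wat; ++w) {
      int i = n_ions + w;
      double fxi = 0.0, fyi = 0.0;
      double rw = wall.at(zw[i]);
      double r2w = x[i] * x[i] + y[i] * y[i];
      if (r2w > rw * rw && r2w > 1e-24) {
        double r = std::sqrt(r2w);
        double fr = -wall_k * (r - rw);
        fxi = fr * x[i] / r; fyi = fr * y[i] / r;
      }
      double amp = deterministic ? 0.0 : std::sqrt(2.0 * water_D * dt);
      double ddx = water_D * fxi * dt, ddy = water_D * fyi * dt, ddz = 0.0;
      if (!deterministic) {
        ddx += amp * rng[i].norm(); ddy += amp * rng[i].norm();
        ddz += amp * rng[i].norm();
      }
      x[i] = wrap1(x[i] + ddx, Lx); y[i] = wrap1(y[i] + ddy, Ly);
      zw[i] = wrap1(zw[i] + ddz, Lz);
    }
    // ---- ground-truth state machine
    double tn = (step + 1) * dt;
    for (int i = 0; i < n_ions; ++i) {
      long s = axial_seg(zu[i], z_lower, z_upper, Lz);
      if (s % 2L != 0L) {  // inside
        if (!pending[i]) {
          pending[i] = 1; t_enter[i] = tn; entry_seg[i] = last_out_seg[i];
          sf_entered[i] = 0; via[i] = 0;
        }
        if (!sf_entered[i] && zw[i] >= sf_low && zw[i] <= sf_high) {
          sf_entered[i] = 1;
          via[i] = (tn - last_pocket_t[i]) <= pathway_memory ? 1 : 0;
        }
      } else {             // outside
        if (pending[i]) {
          if (s != entry_seg[i]) {
            double dir = (s > entry_seg[i]) ? 1.0 : -1.0;
            ev.push_back(i + 1); ev.push_back(dir);
            ev.push_back(t_enter[i]); ev.push_back(tn);
            ev.push_back(via[i] ? 1.0 : 0.0);
          }
          pending[i] = 0;
        }
        last_out_seg[i] = s;
      }
    }
  }

  int n_ev = ev.size() / 5;
  NumericMatrix events(n_ev, 5);
  for (int k = 0; k < n_ev; ++k)
    for (int c = 0; c < 5; ++c) events(k, c) = ev[5 * k + c];
  colnames(events) = CharacterVector::create("ion", "direction", "t_enter_ps",
                                             "t_exit_ps", "via_side_pocket");
  return List::create(_["times"] = times, _["positions"] = positions,
                      _["unwrapped_z"] = unwrapped, _["events"] = events);
}
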