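// Voxel Monte Carlo photon-packet transport: hop-drop-spin with
// voxel-boundary clipping, continuous absorption, Henyey-Greenstein
// scattering and Russian roulette. Per-photon PCG32 substreams keyed by
// (run seed, photon index) make runs reproducible under any execution
// order and give common-random-numbers pairing across scenarios.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform on the open interval (0, 1)
  double uniform() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// exp(-x) for small non-negative x; exact call above the Taylor window
// (5th-order truncation error < 1e-12 relative at the 0.01 cutoff)
inline double exp_neg(double x) {
  if (x < 1e-2) {
    return 1.0 - x * (1.0 - 0.5 * x * (1.0 - x * (1.0 - 0.25 * x) / 3.0));
  }
  return std::exp(-x);
}

// unpolarized Fresnel reflectance for internal incidence, relative index
// n_rel = n_medium / n_outside > 1; cos_i = |cosine of incidence angle|
inline double fresnel_R(double n_rel, double cos_i) {
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = n_rel * n_rel * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (cos_i - n_rel * cos_t) / (cos_i + n_rel * cos_t);
  return 0.5 * (rs * rs + rp * rp);
}

struct Grid {
  int nx, ny, nz;
  double v;             // voxel edge (mm)
  const double* mus;    // per-voxel scattering coefficient
  double mua;           // uniform absorption coefficient
  double g;             // uniform anisotropy
};

struct Ledger {
  double absorbed = 0.0;
  double escaped = 0.0;
  double roulette_net = 0.0;  // killed weight minus roulette boosts
  double capped = 0.0;
  double capped_count = 0.0;
};

inline double hg_cos(double g, double u) {
  double ct;
  if (g != 0.0) {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  } else {
    ct = 2.0 * u - 1.0;
  }
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// sin/cos pair for an azimuth in [0, 2pi): one transcendental + one sqrt
inline void sincos_azimuth(double phi, double& sp, double& cp) {
  cp = std::cos(phi);
  double s2 = 1.0 - cp * cp;
  sp = (phi < 3.141592653589793238) ? std::sqrt(s2 > 0.0 ? s2 : 0.0)
                                    : -std::sqrt(s2 > 0.0 ? s2 : 0.0);
}

inline void spin_dir(double& ux, double& uy, double& uz,
                     double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double sp, cp;
  sincos_azimuth(phi, sp, cp);
  double nux, nuy, nuz;
  if (std::fabs(uz) > 0.99999) {
    nux = st * cp;
    nuy = st * sp;
    nuz = ct * (uz >= 0.0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nuz = -den * st * cp + uz * ct;
  }
  double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
  ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
}

// Transport a single packet. Deposits the pathlength integral (weight x
// length, with continuous-absorption decay folded in) into `fluence`;
// voxels in z-layer `det_layer` additionally accumulate into `det_tally`
// (nx*ny, may be null). Returns termination status: 1 escaped,
// 2 roulette-killed, 3 step-capped.
int transport_one(const Grid& G, Pcg32& rng,
                  double x, double y, double z,
                  double ux, double uy, double uz, double w,
                  double weight_threshold, double survival_prob,
                  double max_steps, double n_rel,
                  double* fluence, double* det_tally, int det_layer,
                  double* plane_tally, int plane_iz,
                  Ledger& led,
                  double* exit_state /* len 7: x y z ux uy uz w, or null */) {
  const double v = G.v;
  const double INF = std::numeric_limits<double>::infinity();
  int ix = (int)std::floor(x / v);
  int iy = (int)std::floor(y / v);
  int iz = (int)std::floor(z / v);
  if (ix < 0) ix = 0; if (ix >= G.nx) ix = G.nx - 1;
  if (iy < 0) iy = 0; if (iy >= G.ny) iy = G.ny - 1;
  if (iz < 0) iz = 0; if (iz >= G.nz) iz = G.nz - 1;

  double tau = -std::log(rng.uniform());  // optical depth to next scatter
  double steps = 0.0;
  int status = 0;
  const double inv_mua = G.mua > 0.0 ? 1.0 / G.mua : 0.0;
  // reciprocal direction components, refreshed on every direction change
  double inv_ux = ux != 0.0 ? 1.0 / ux : INF;
  double inv_uy = uy != 0.0 ? 1.0 / uy : INF;
  double inv_uz = uz != 0.0 ? 1.0 / uz : INF;

  while (true) {
    steps += 1.0;
    if (steps > max_steps) {
      led.capped += w;
      led.capped_count += 1.0;
      status = 3;
      break;
    }
    const int idx = ix + G.nx * (iy + G.ny * iz);
    const double musv = G.mus[idx];

    // distance to the nearest voxel face along the flight direction
    double tx = INF, ty = INF, tz = INF;
    if (ux > 0.0)      tx = ((ix + 1) * v - x) * inv_ux;
    else if (ux < 0.0) tx = (ix * v - x) * inv_ux;
    if (uy > 0.0)      ty = ((iy + 1) * v - y) * inv_uy;
    else if (uy < 0.0) ty = (iy * v - y) * inv_uy;
    if (uz > 0.0)      tz = ((iz + 1) * v - z) * inv_uz;
    else if (uz < 0.0) tz = (iz * v - z) * inv_uz;
    double db = tx < ty ? (tx < tz ? tx : tz) : (ty < tz ? ty : tz);
    if (db < 0.0) db = 0.0;

    bool scatter = musv > 0.0 && tau <= musv * db;  // no division on crossings
    double step = scatter ? tau / musv : db;

    // drop: continuous absorption over the traversed length
    double dep;
    if (G.mua > 0.0) {
      double att = exp_neg(G.mua * step);
      dep = w * (1.0 - att) * inv_mua;
      led.absorbed += w * (1.0 - att);
      w *= att;
    } else {
      dep = w * step;
    }
    fluence[idx] += dep;
    if (det_tally && iz == det_layer) det_tally[ix + G.nx * iy] += dep;

    x += ux * step; y += uy * step; z += uz * step;

    if (scatter) {
      tau = -std::log(rng.uniform());
      double ct = hg_cos(G.g, rng.uniform());
      double phi = 6.283185307179586477 * rng.uniform();
      spin_dir(ux, uy, uz, ct, phi);
      inv_ux = ux != 0.0 ? 1.0 / ux : INF;
      inv_uy = uy != 0.0 ? 1.0 / uy : INF;
      inv_uz = uz != 0.0 ? 1.0 / uz : INF;
      if (w < weight_threshold) {
        if (rng.uniform() < survival_prob) {
          double boost = w / survival_prob - w;
          led.roulette_net -= boost;
          w += boost;
        } else {
          led.roulette_net += w;
          status = 2;
          break;
        }
      }
    } else {
      tau -= musv * db;
      if (tau < 0.0) tau = 0.0;
      // cross into the neighbouring voxel; snap to the shared face
      int axis = (db == tx) ? 0 : (db == ty ? 1 : 2);
      double uc = axis == 0 ? ux : (axis == 1 ? uy : uz);
      int step_dir = uc > 0.0 ? 1 : -1;
      int* ic = axis == 0 ? &ix : (axis == 1 ? &iy : &iz);
      int nvox = axis == 0 ? G.nx : (axis == 1 ? G.ny : G.nz);
      int face = *ic + (step_dir > 0 ? 1 : 0);
      double fcoord = face * v;
      if (axis == 0) x = fcoord; else if (axis == 1) y = fcoord; else z = fcoord;
      int nidx = *ic + step_dir;
      if (nidx < 0 || nidx >= nvox) {
        // outer boundary: matched media escape, or Fresnel reflection when
        // the phantom is optically denser than its surroundings
        bool reflect = false;
        if (n_rel > 1.0) {
          reflect = rng.uniform() < fresnel_R(n_rel, std::fabs(uc));
        }
        if (!reflect) {
          led.escaped += w;
          status = 1;
          break;
        }
        if (axis == 0)      { ux = -ux; inv_ux = -inv_ux; }
        else if (axis == 1) { uy = -uy; inv_uy = -inv_uy; }
        else                { uz = -uz; inv_uz = -inv_uz; }
      } else {
        *ic = nidx;
        if (plane_tally && axis == 2 && step_dir == 1 && iz == plane_iz) {
          plane_tally[ix + G.nx * iy] += w;  // downward crossing at z = plane
        }
      }
    }
  }
  if (exit_state) {
    exit_state[0] = x; exit_state[1] = y; exit_state[2] = z;
    exit_state[3] = ux; exit_state[4] = uy; exit_state[5] = uz;
    exit_state[6] = w;
  }
  return status;
}

// Sample a launch state for photon `i` (stream already seeded).
// src_type: 0 = collimated Gaussian beam entering the z = 0 face along +z
//           1 = isotropic point source at src_pos
inline void launch(const Grid& G, Pcg32& rng, int src_type,
                   double cx, double cy, double sigma,
                   const double* src_pos,
                   double& x, double& y, double& z,
                   double& ux, double& uy, double& uz) {
  if (src_type == 0) {
    double ex = G.nx * G.v, ey = G.ny * G.v;
    do {
      double u1 = rng.uniform(), u2 = rng.uniform();
      double r = sigma * std::sqrt(-2.0 * std::log(u1));
      x = cx + r * std::cos(6.283185307179586477 * u2);
      y = cy + r * std::sin(6.283185307179586477 * u2);
    } while (x <= 0.0 || x >= ex || y <= 0.0 || y >= ey);
    z = 0.0;
    ux = 0.0; uy = 0.0; uz = 1.0;
  } else {
    x = src_pos[0]; y = src_pos[1]; z = src_pos[2];
    double ct = 2.0 * rng.uniform() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = 6.283185307179586477 * rng.uniform();
    ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
  }
}

}  // namespace

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector dims, double voxel,
                double mu_a, NumericVector mu_s, double g,
                int src_type, NumericVector src_pos, double sigma,
                double n_photons, int seed,
                double weight_threshold, double survival_prob,
                double max_steps, int n_batches, int det_layer,
                double n_rel, int plane_iz) {
  Grid G{dims[0], dims[1], dims[2], voxel, mu_s.begin(), mu_a, g};
  if ((R_xlen_t)G.nx * G.ny * G.nz != mu_s.size())
    stop("mu_s length does not match grid dimensions");
  NumericVector fluence((R_xlen_t)G.nx * G.ny * G.nz);
  const int nb = n_batches;
  NumericVector det_batches(det_layer >= 0 ?
                            (R_xlen_t)G.nx * G.ny * nb : 0);
  NumericVector plane(plane_iz >= 0 ? (R_xlen_t)G.nx * G.ny : 0);
  NumericVector batch_n(nb);
  Ledger led;
  const double cx = 0.5 * G.nx * voxel, cy = 0.5 * G.ny * voxel;
  const uint64_t run_key = splitmix64((uint64_t)(uint32_t)seed);
  const double N = n_photons;

  double* flu = fluence.begin();
  double* dbat = det_batches.size() ? det_batches.begin() : nullptr;
  double* pln = plane.size() ? plane.begin() : nullptr;

  for (double i = 0.0; i < N; i += 1.0) {
    uint64_t pid = (uint64_t)i;
    Pcg32 rng;
    rng.seed(run_key, pid);
    int batch = (int)(pid % (uint64_t)nb);
    batch_n[batch] += 1.0;
    double x, y, z, ux, uy, uz;
    launch(G, rng, src_type, cx, cy, sigma, src_pos.begin(),
           x, y, z, ux, uy, uz);
    double* tally = dbat ? dbat + (R_xlen_t)batch * G.nx * G.ny : nullptr;
    transport_one(G, rng, x, y, z, ux, uy, uz, 1.0,
                  weight_threshold, survival_prob, max_steps, n_rel,
                  flu, tally, det_layer, pln, plane_iz, led, nullptr);
    if (((uint64_t)i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["fluence_raw"] = fluence,
    _["det_batches"] = det_batches.size() ? (SEXP)det_batches : R_NilValue,
    _["plane_raw"] = plane.size() ? (SEXP)plane : R_NilValue,
    _["batch_n"] = batch_n,
    _["launched"] = N,
    _["absorbed"] = led.absorbed,
    _["escaped"] = led.escaped,
    _["roulette_net"] = led.roulette_net,
    _["capped"] = led.capped,
    _["capped_count"] = led.capped_count);
}

// [[Rcpp::export]]
List propagate_photon_cpp(IntegerVector dims, double voxel,
                          double mu_a, NumericVector mu_s, double g,
                          NumericVector pos, NumericVector dir,
                          double weight, int seed, double stream,
                          double weight_threshold, double survival_prob,
                          double max_steps, double n_rel) {
  Grid G{dims[0], dims[1], dims[2], voxel, mu_s.begin(), mu_a, g};
  if ((R_xlen_t)G.nx * G.ny * G.nz != mu_s.size())
    stop("mu_s length does not match grid dimensions");
  NumericVector deposit((R_xlen_t)G.nx * G.ny * G.nz);
  Ledger led;
  Pcg32 rng;
  rng.seed(splitmix64((uint64_t)(uint32_t)seed), (uint64_t)stream);
  double exit_state[7];
  int status = transport_one(G, rng, pos[0], pos[1], pos[2],
                             dir[0], dir[1], dir[2], weight,
                             weight_threshold, survival_prob, max_steps,
                             n_rel, deposit.begin(), nullptr, -1,
                             nullptr, -1, led, exit_state);
  return List::create(
    _["deposit_raw"] = deposit,
    _["status"] = CharacterVector::create(
        status == 1 ? "escaped" : (status == 2 ? "roulette" : "capped")),
    _["position"] = NumericVector::create(exit_state[0], exit_state[1],
                                          exit_state[2]),
    _["direction"] = NumericVector::create(exit_state[3], exit_state[4],
                                           exit_state[5]),
    _["weight"] = exit_state[6],
    _["absorbed"] = led.absorbed,
    _["escaped"] = led.escaped,
    _["roulette_net"] = led.roulette_net,
    _["capped"] = led.capped);
}

// [[Rcpp::export]]
NumericVector launch_positions_cpp(double n_photons, int seed,
                                   double cx, double cy, double sigma,
                                   double ex, double ey) {
  // replays the launch-stage draws of mc_run_cpp's Gaussian source
  const double N = n_photons;
  NumericMatrix out((int)N, 2);
  const uint64_t run_key = splitmix64((uint64_t)(uint32_t)seed);
  for (double i = 0.0; i < N; i += 1.0) {
    Pcg32 rng;
    rng.seed(run_key, (uint64_t)i);
    double x, y;
    do {
      double u1 = rng.uniform(), u2 = rng.uniform();
      double r = sigma * std::sqrt(-2.0 * std::log(u1));
      x = cx + r * std::cos(6.283185307179586477 * u2);
      y = cy + r * std::sin(6.283185307179586477 * u2);
    } while (x <= 0.0 || x >= ex || y <= 0.0 || y >= ey);
    out((int)i, 0) = x;
    out((int)i, 1) = y;
  }
  return out;
}
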