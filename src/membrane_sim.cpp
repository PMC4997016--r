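// Sub-stepped Monte-Carlo core for lateral diffusion in a phase-separated
// membrane with a field of reflecting nano-traps (Poisson escape, release at
// the rim). Uses R's RNG so set.seed() in R governs determinism.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TrapGrid {
  double cell;
  std::unordered_map<long long, std::vector<int>> buckets;
  const NumericVector *x, *y, *r;

  static long long key(long kx, long ky) {
    return (static_cast<long long>(kx) << 32) ^ (ky & 0xffffffffLL);
  }

  void build(const NumericVector &tx, const NumericVector &ty,
             const NumericVector &tr) {
    x = &tx; y = &ty; r = &tr;
    double rmax = 0.0;
    for (int i = 0; i < tr.size(); ++i) rmax = std::max(rmax, tr[i]);
    cell = std::max(2.0 * rmax, 0.05);
    for (int i = 0; i < tx.size(); ++i) {
      long kx = (long)std::floor(tx[i] / cell);
      long ky = (long)std::floor(ty[i] / cell);
      buckets[key(kx, ky)].push_back(i);
    }
  }

  // index of the trap containing (px, py), or -1
  int find(double px, double py) const {
    if (buckets.empty()) return -1;
    long kx = (long)std::floor(px / cell);
    long ky = (long)std::floor(py / cell);
    for (long dx = -1; dx <= 1; ++dx) {
      for (long dy = -1; dy <= 1; ++dy) {
        auto it = buckets.find(key(kx + dx, ky + dy));
        if (it == buckets.end()) continue;
        for (int i : it->second) {
          double ddx = px - (*x)[i], ddy = py - (*y)[i];
          if (ddx * ddx + ddy * ddy <= (*r)[i] * (*r)[i]) return i;
        }
      }
    }
    return -1;
  }
};

inline bool in_lo(const LogicalMatrix &mask, double px_um, double ox,
                  double oy, double x, double y) {
  int j = (int)std::lround((x - ox) / px_um);
  int i = (int)std::lround((y - oy) / px_um);
  if (i < 0 || j < 0 || i >= mask.nrow() || j >= mask.ncol()) return false;
  return mask(i, j);
}

} // namespace

// [[Rcpp::export(name = ".sim_membrane_cpp")]]
List sim_membrane_cpp(int n_frames, int substeps, double dt,
                      double d_out, double d_lo,
                      NumericVector trap_x, NumericVector trap_y,
                      NumericVector trap_r, double escape_rate,
                      LogicalMatrix lo_mask, double mask_px_um,
                      double mask_ox, double mask_oy,
                      double x0, double y0) {
  const double dt_sub = dt / substeps;
  const double sd_out = std::sqrt(2.0 * d_out * dt_sub);
  const double sd_lo = std::sqrt(2.0 * d_lo * dt_sub);
  const double p_esc = 1.0 - std::exp(-escape_rate * dt_sub);
  const double rim_eps = 5e-4; // 0.5 nm beyond the rim on release

  TrapGrid grid;
  grid.build(trap_x, trap_y, trap_r);

  NumericVector true_x(n_frames), true_y(n_frames);
  NumericVector obs_x(n_frames), obs_y(n_frames);
  IntegerVector state(n_frames); // 0 = LD, 1 = LO_FREE, 2 = LO_TRAPPED

  std::vector<double> dw_start, dw_end;
  std::vector<int> dw_trap, dw_complete;

  double x = x0, y = y0;
  int trap = grid.find(x, y);
  if (trap >= 0) { dw_start.push_back(0.0); dw_trap.push_back(trap); }

  true_x[0] = x; true_y[0] = y;
  obs_x[0] = x; obs_y[0] = y;
  state[0] = trap >= 0 ? 2
             : (in_lo(lo_mask, mask_px_um, mask_ox, mask_oy, x, y) ? 1 : 0);

  long sub = 0;
  for (int f = 1; f < n_frames; ++f) {
    double ax = 0.0, ay = 0.0; // exposure accumulators
    for (int s = 0; s < substeps; ++s) {
      ++sub;
      if (trap >= 0) {
        if (unif_rand() < p_esc) {
          // release just outside the rim, radially outward through the
          // particle's current position (escape = boundary permeation; a
          // random-angle release would inject a spurious in-disk jump into
          // the short-lag MSD)
          double dx = x - trap_x[trap], dy = y - trap_y[trap];
          double d = std::sqrt(dx * dx + dy * dy);
          double ux, uy;
          if (d > 1e-12) { ux = dx / d; uy = dy / d; }
          else { double th = 2.0 * M_PI * unif_rand(); ux = std::cos(th); uy = std::sin(th); }
          x = trap_x[trap] + (trap_r[trap] + rim_eps) * ux;
          y = trap_y[trap] + (trap_r[trap] + rim_eps) * uy;
          dw_end.push_back((double)sub * dt_sub);
          dw_complete.push_back(1);
          trap = grid.find(x, y); // may drop straight into a neighbour
          if (trap >= 0) {
            dw_start.push_back((double)sub * dt_sub);
            dw_trap.push_back(trap);
          }
        } else {
          double nx = x + sd_lo * norm_rand();
          double ny = y + sd_lo * norm_rand();
          // radial fold at the reflecting trap boundary
          double cx = trap_x[trap], cy = trap_y[trap], R = trap_r[trap];
          double dx = nx - cx, dy = ny - cy;
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > R && d > 0.0) {
            double d2 = 2.0 * R - d;
            if (d2 < 0.0) d2 = R * unif_rand(); // pathological huge step
            nx = cx + dx / d * d2;
            ny = cy + dy / d * d2;
          }
          x = nx; y = ny;
        }
      } else {
        bool lo = in_lo(lo_mask, mask_px_um, mask_ox, mask_oy, x, y);
        double sd = lo ? sd_lo : sd_out;
        x += sd * norm_rand();
        y += sd * norm_rand();
        trap = grid.find(x, y);
        if (trap >= 0) {
          dw_start.push_back((double)sub * dt_sub);
          dw_trap.push_back(trap);
        }
      }
      ax += x; ay += y;
    }
    true_x[f] = x; true_y[f] = y;
    obs_x[f] = ax / substeps; obs_y[f] = ay / substeps;
    state[f] = trap >= 0 ? 2
               : (in_lo(lo_mask, mask_px_um, mask_ox, mask_oy, x, y) ? 1 : 0);
  }
  if (dw_start.size() > dw_end.size()) { // trajectory ends while trapped
    dw_end.push_back((double)sub * dt_sub);
    dw_complete.push_back(0);
  }

  return List::create(
      _["true_x"] = true_x, _["true_y"] = true_y,
      _["obs_x"] = obs_x, _["obs_y"] = obs_y,
      _["state"] = state,
      _["dwell_start_s"] = wrap(dw_start),
      _["dwell_end_s"] = wrap(dw_end),
      _["dwell_trap"] = wrap(dw_trap),
      _["dwell_complete"] = wrap(dw_complete));
}
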