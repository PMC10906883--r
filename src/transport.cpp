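// Photon transport through the dual-panel LYSO scanner.
//
// Physics: photoelectric absorption + free-electron Klein-Nishina Compton
// scattering only; energy is deposited at the interaction point (no secondary
// electron transport).  Crystal reflector gaps and everything outside the
// crystals are vacuum for 511 keV photons.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static const double MEC2 = 510.99895;   // electron rest energy, keV
static const double CLIGHT = 299.792458; // mm / ns
static const double EPS_STEP = 1e-9;    // mm, boundary nudging

// ---------------------------------------------------------------------------
// log-log interpolated attenuation table (linear coefficients in 1/cm)
struct XSTable {
  std::vector<double> logE, logpe, logcs;
  double emin, emax;

  void init(const NumericVector& E, const NumericVector& mupe,
            const NumericVector& mucs) {
    int n = E.size();
    logE.resize(n); logpe.resize(n); logcs.resize(n);
    for (int i = 0; i < n; ++i) {
      logE[i] = std::log(E[i]);
      logpe[i] = std::log(std::max(mupe[i], 1e-300));
      logcs[i] = std::log(std::max(mucs[i], 1e-300));
    }
    emin = E[0]; emax = E[n - 1];
  }
  // clamped log-log interpolation
  inline void mu(double E, double& pe, double& cs) const {
    double le = std::log(std::min(std::max(E, emin), emax));
    size_t hi = std::upper_bound(logE.begin(), logE.end(), le) - logE.begin();
    if (hi == 0) hi = 1;
    if (hi >= logE.size()) hi = logE.size() - 1;
    size_t lo = hi - 1;
    double w = (le - logE[lo]) / (logE[hi] - logE[lo]);
    pe = std::exp(logpe[lo] + w * (logpe[hi] - logpe[lo]));
    cs = std::exp(logcs[lo] + w * (logcs[hi] - logcs[lo]));
  }
};

// ---------------------------------------------------------------------------
// scanner geometry: two slabs zin<=|z|<zout, lateral periodic cell structure.
// A point is inside a crystal iff |x|,|y| < half_span and the in-cell
// fractional coordinate along both axes falls in [c_lo, c_hi).
struct Geom {
  double zin, zout, half_span, cell_pitch, c_lo, c_hi, block_pitch;
  int nblocks, cells_per_block;

  inline bool lateral_crystal(double u) const {
    double v = u + half_span;
    if (v < 0 || v >= 2 * half_span) return false;
    double f = v - cell_pitch * std::floor(v / cell_pitch);
    return f >= c_lo && f < c_hi;
  }
  inline bool in_crystal(double x, double y, double z) const {
    double az = std::fabs(z);
    if (az < zin || az >= zout) return false;
    return lateral_crystal(x) && lateral_crystal(y);
  }
  // distance to the next lateral material-change plane along one axis
  inline double lateral_dist(double u, double du) const {
    if (du == 0.0) return R_PosInf;
    double v = u + half_span;
    if (v < 0 || v > 2 * half_span) {
      // outside the panel span: next plane is the span edge, if approached
      double target = (du > 0.0) ? 0.0 : 2 * half_span;
      double t = (target - v) / du;
      return (t > 0) ? t : R_PosInf;
    }
    double cell = std::floor(v / cell_pitch);
    double best = R_PosInf;
    const double offs[3] = {0.0, c_lo, c_hi};
    for (int cc = -1; cc <= 1; ++cc) {
      double base = (cell + cc) * cell_pitch;
      for (int oi = 0; oi < 3; ++oi) {
        double t = (base + offs[oi] - v) / du;
        if (t > EPS_STEP && t < best) best = t;
      }
    }
    return best;
  }
  inline double zplane_dist(double z, double dz) const {
    if (dz == 0.0) return R_PosInf;
    double best = R_PosInf;
    const double planes[4] = {-zout, -zin, zin, zout};
    for (int i = 0; i < 4; ++i) {
      double t = (planes[i] - z) / dz;
      if (t > EPS_STEP && t < best) best = t;
    }
    return best;
  }
  inline int block_index(double u) const {  // 0..nblocks-1
    int b = (int)std::floor((u + half_span) / block_pitch);
    if (b < 0) b = 0;
    if (b >= nblocks) b = nblocks - 1;
    return b;
  }
  inline int cell_index(double u) const {   // global cell index along one axis
    int c = (int)std::floor((u + half_span) / cell_pitch);
    int n = nblocks * cells_per_block;
    if (c < 0) c = 0;
    if (c >= n) c = n - 1;
    return c;
  }
};

static Geom geom_from_list(const List& g) {
  Geom G;
  G.zin = as<double>(g["zin"]);
  G.zout = as<double>(g["zout"]);
  G.half_span = as<double>(g["half_span"]);
  G.cell_pitch = as<double>(g["cell_pitch"]);
  G.c_lo = as<double>(g["c_lo"]);
  G.c_hi = as<double>(g["c_hi"]);
  G.block_pitch = as<double>(g["block_pitch"]);
  G.nblocks = as<int>(g["nblocks"]);
  G.cells_per_block = as<int>(g["cells_per_block"]);
  return G;
}

// ---------------------------------------------------------------------------
// Klein-Nishina sampling of the scattered-photon energy fraction
// (composition-rejection scheme; exact for a free electron at rest).
template <class RNG>
static double sample_kn_eps(double E, RNG& rng,
                            std::uniform_real_distribution<double>& U) {
  double k = E / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(eps0);
  double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, greject;
  do {
    if (U(rng) * (a1 + a2) < a1)
      eps = std::exp(-a1 * U(rng));
    else
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * U(rng));
    double t = (1.0 - eps) / (k * eps);
    double sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (U(rng) < 1.0 - greject);
  return eps;
}

// rotate direction d by polar angle (cost) about itself with azimuth phi
static void rotate_direction(double* d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  // orthonormal basis (e1, e2) perpendicular to d
  double e1[3];
  if (std::fabs(d[2]) < 0.999) {
    e1[0] = -d[1]; e1[1] = d[0]; e1[2] = 0.0;
  } else {
    e1[0] = 0.0; e1[1] = -d[2]; e1[2] = d[1];
  }
  double n = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  e1[0] /= n; e1[1] /= n; e1[2] /= n;
  double e2[3] = {d[1]*e1[2] - d[2]*e1[1],
                  d[2]*e1[0] - d[0]*e1[2],
                  d[0]*e1[1] - d[1]*e1[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    d[i] = cost * d[i] + sint * (cp * e1[i] + sp * e2[i]);
  n = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

struct HitRec {
  double x, y, z, edep, time;
  int type;     // 1 = photoelectric, 2 = Compton
  int order;    // 1-based along the photon chain
};

// track one photon; returns hits, sets escaped energy
template <class RNG>
static void track_one(double* pos, double* dir, double t0, const Geom& G,
                      const XSTable& XS, RNG& rng,
                      std::uniform_real_distribution<double>& U,
                      std::vector<HitRec>& hits, double& e_escape) {
  double E = 511.0;             // annihilation photon energy, keV
  double path = 0.0;
  int order = 0;
  const double WORLD_XY = 250.0, WORLD_Z = 60.0;
  for (int guard = 0; guard < 100000; ++guard) {
    if (std::fabs(pos[0]) > WORLD_XY || std::fabs(pos[1]) > WORLD_XY ||
        std::fabs(pos[2]) > WORLD_Z) {
      e_escape = E;
      return;
    }
    bool in_slab = std::fabs(pos[2]) >= G.zin && std::fabs(pos[2]) < G.zout;
    double tb = G.zplane_dist(pos[2], dir[2]);
    if (in_slab) {
      tb = std::min(tb, G.lateral_dist(pos[0], dir[0]));
      tb = std::min(tb, G.lateral_dist(pos[1], dir[1]));
    }
    if (!std::isfinite(tb)) { e_escape = E; return; }
    bool crystal = in_slab && G.lateral_crystal(pos[0]) && G.lateral_crystal(pos[1]);
    if (crystal) {
      double pe, cs;
      XS.mu(E, pe, cs);
      double mutot = pe + cs;                    // 1/cm
      double s = -std::log(U(rng)) * 10.0 / mutot;  // mm
      if (s < tb) {
        pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
        path += s;
        ++order;
        if (U(rng) < pe / mutot) {               // photoelectric: absorb
          hits.push_back({pos[0], pos[1], pos[2], E, t0 + path / CLIGHT, 1, order});
          e_escape = 0.0;
          return;
        }
        // Compton scatter
        double eps = sample_kn_eps(E, rng, U);
        double k = E / MEC2;
        double cost = 1.0 - (1.0 / eps - 1.0) / k;
        double phi = 2.0 * M_PI * U(rng);
        double edep = E * (1.0 - eps);
        hits.push_back({pos[0], pos[1], pos[2], edep, t0 + path / CLIGHT, 2, order});
        rotate_direction(dir, cost, phi);
        E *= eps;
        continue;
      }
    }
    double adv = tb + EPS_STEP;
    pos[0] += adv * dir[0]; pos[1] += adv * dir[1]; pos[2] += adv * dir[2];
    path += adv;
  }
  e_escape = E;  // pathological guard exit
}

// ---------------------------------------------------------------------------
// Track back-to-back photon pairs.  origins/dirs: one row per emission event;
// photon 0 flies along +dir, photon 1 along -dir.  Returns per-photon,
// per-panel singles (detector-level aggregation of the hit chain) and,
// optionally, the full hit list.
// [[Rcpp::export]]
List cpp_track_pairs(NumericMatrix origins, NumericMatrix dirs,
                     NumericVector times, List geom, List xs,
                     double seed, bool return_hits) {
  const int n = origins.nrow();
  Geom G = geom_from_list(geom);
  XSTable XS;
  XS.init(as<NumericVector>(xs["energy"]), as<NumericVector>(xs["mu_pe"]),
          as<NumericVector>(xs["mu_cs"]));
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(std::nextafter(0.0, 1.0), 1.0);

  // singles accumulators
  std::vector<double> s_event, s_photon, s_panel, s_block, s_sipm, s_element,
      s_nhits, s_ncompton, s_terminal, s_etrue, s_ewx, s_ewy, s_ewz,
      s_fhx, s_fhy, s_fhz, s_time, s_escape, s_eblock, s_bewx, s_bewy,
      s_bewz, s_blockwin;
  // optional hits accumulators
  std::vector<double> h_event, h_photon, h_order, h_x, h_y, h_z, h_edep,
      h_type, h_time;

  std::vector<HitRec> hits;
  hits.reserve(32);

  for (int i = 0; i < n; ++i) {
    for (int q = 0; q < 2; ++q) {
      double pos[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
      double dir[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
      if (q == 1) { dir[0] = -dir[0]; dir[1] = -dir[1]; dir[2] = -dir[2]; }
      hits.clear();
      double e_escape = 0.0;
      track_one(pos, dir, times[i], G, XS, rng, U, hits, e_escape);
      if (hits.empty()) continue;
      if (return_hits) {
        for (const HitRec& h : hits) {
          h_event.push_back(i + 1); h_photon.push_back(q);
          h_order.push_back(h.order);
          h_x.push_back(h.x); h_y.push_back(h.y); h_z.push_back(h.z);
          h_edep.push_back(h.edep); h_type.push_back(h.type);
          h_time.push_back(h.time);
        }
      }
      // aggregate singles per panel (a backscattered photon can deposit in
      // both panels; each panel yields its own single)
      for (int pan = -1; pan <= 1; pan += 2) {
        double esum = 0, ewx = 0, ewy = 0, ewz = 0;
        int nh = 0, ncs = 0, first = -1, last_global = (int)hits.size() - 1;
        // per-block accumulation for the block-level readout
        double be[9] = {0}, bex[9] = {0}, bey[9] = {0}, bez[9] = {0};
        for (size_t hIdx = 0; hIdx < hits.size(); ++hIdx) {
          const HitRec& h = hits[hIdx];
          int hp = h.z > 0 ? 1 : -1;
          if (hp != pan) continue;
          if (first < 0) first = (int)hIdx;
          esum += h.edep;
          ewx += h.edep * h.x; ewy += h.edep * h.y; ewz += h.edep * h.z;
          ++nh;
          if (h.type == 2) ++ncs;
          int hb = G.block_index(h.x) * 3 + G.block_index(h.y);
          be[hb] += h.edep;
          bex[hb] += h.edep * h.x; bey[hb] += h.edep * h.y;
          bez[hb] += h.edep * h.z;
        }
        if (nh == 0 || esum <= 0) continue;
        int bwin = 0;
        for (int b = 1; b < 9; ++b) if (be[b] > be[bwin]) bwin = b;
        const HitRec& fh = hits[first];
        const HitRec& lh = hits[last_global];
        int terminal = (lh.type == 1 && (lh.z > 0 ? 1 : -1) == pan) ? 1 : 0;
        int bi = G.block_index(fh.x), bj = G.block_index(fh.y);
        int block = (pan > 0 ? 9 : 0) + bi * 3 + bj;
        // SiPM cell (8x8 of 7.2 mm per block) of the first hit
        double ub = (fh.x + G.half_span) - G.block_pitch * bi;
        double vb = (fh.y + G.half_span) - G.block_pitch * bj;
        int si = std::min(7, std::max(0, (int)(ub / 7.2)));
        int sj = std::min(7, std::max(0, (int)(vb / 7.2)));
        int sipm = block * 64 + si * 8 + sj;
        int element = block * G.cells_per_block * G.cells_per_block +
            (G.cell_index(fh.x) % G.cells_per_block) * G.cells_per_block +
            (G.cell_index(fh.y) % G.cells_per_block);
        s_event.push_back(i + 1); s_photon.push_back(q); s_panel.push_back(pan);
        s_block.push_back(block); s_sipm.push_back(sipm);
        s_element.push_back(element);
        s_nhits.push_back(nh); s_ncompton.push_back(ncs);
        s_terminal.push_back(terminal); s_etrue.push_back(esum);
        if (nh == 1) {   // a one-hit single has EWP = FHP exactly
          s_ewx.push_back(fh.x); s_ewy.push_back(fh.y); s_ewz.push_back(fh.z);
        } else {
          s_ewx.push_back(ewx / esum); s_ewy.push_back(ewy / esum);
          s_ewz.push_back(ewz / esum);
        }
        s_fhx.push_back(fh.x); s_fhy.push_back(fh.y); s_fhz.push_back(fh.z);
        s_time.push_back(fh.time);
        s_escape.push_back(e_escape);
        s_eblock.push_back(be[bwin]);
        s_bewx.push_back(bex[bwin] / be[bwin]);
        s_bewy.push_back(bey[bwin] / be[bwin]);
        s_bewz.push_back(bez[bwin] / be[bwin]);
        s_blockwin.push_back((pan > 0 ? 9 : 0) + bwin);
      }
    }
  }

  List singles = List::create(
      _["event"] = wrap(s_event), _["photon"] = wrap(s_photon),
      _["panel"] = wrap(s_panel), _["block"] = wrap(s_block),
      _["sipm"] = wrap(s_sipm), _["element"] = wrap(s_element),
      _["n_hits"] = wrap(s_nhits), _["n_compton"] = wrap(s_ncompton),
      _["terminal_pe"] = wrap(s_terminal), _["energy_true"] = wrap(s_etrue),
      _["ewx"] = wrap(s_ewx), _["ewy"] = wrap(s_ewy), _["ewz"] = wrap(s_ewz),
      _["fhx"] = wrap(s_fhx), _["fhy"] = wrap(s_fhy), _["fhz"] = wrap(s_fhz),
      _["time"] = wrap(s_time), _["energy_escaped"] = wrap(s_escape));
  List blockro = List::create(
      _["energy_block"] = wrap(s_eblock), _["bewx"] = wrap(s_bewx),
      _["bewy"] = wrap(s_bewy), _["bewz"] = wrap(s_bewz),
      _["block_win"] = wrap(s_blockwin));
  if (!return_hits)
    return List::create(_["singles"] = singles, _["block"] = blockro);
  List hl = List::create(
      _["event"] = wrap(h_event), _["photon"] = wrap(h_photon),
      _["hit_order"] = wrap(h_order), _["x"] = wrap(h_x), _["y"] = wrap(h_y),
      _["z"] = wrap(h_z), _["energy_deposited"] = wrap(h_edep),
      _["interaction"] = wrap(h_type), _["time"] = wrap(h_time));
  return List::create(_["singles"] = singles, _["block"] = blockro,
                      _["hits"] = hl);
}

// [[Rcpp::export]]
NumericVector cpp_sample_kn(int n, double E, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(std::nextafter(0.0, 1.0), 1.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_kn_eps(E, rng, U);
  return out;
}
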