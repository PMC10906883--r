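// Siddon ray-voxel projector and list-mode OSEM for the limited-angle
// dual-panel geometry.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct VoxGrid {
  int n[3];
  double vox[3], org[3];   // org = world coordinate of the grid corner
  int nvox() const { return n[0] * n[1] * n[2]; }
  inline int lin(int i, int j, int k) const { return i + n[0] * (j + n[1] * k); }
};

static VoxGrid grid_from_list(const List& g) {
  VoxGrid G;
  IntegerVector n = g["n"];
  NumericVector v = g["voxel"], o = g["origin"];
  for (int a = 0; a < 3; ++a) { G.n[a] = n[a]; G.vox[a] = v[a]; G.org[a] = o[a]; }
  return G;
}

// Exact ray-voxel intersection lengths (Siddon).  Appends (linear index,
// length in mm) pairs for the segment of the ray p0 -> p1 inside the grid.
static void siddon_row(const double* p0, const double* p1, const VoxGrid& G,
                       std::vector<int>& idx, std::vector<double>& len) {
  double d[3], L = 0;
  for (int a = 0; a < 3; ++a) { d[a] = p1[a] - p0[a]; L += d[a] * d[a]; }
  L = std::sqrt(L);
  if (L <= 0) return;
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    double lo = G.org[a], hi = G.org[a] + G.n[a] * G.vox[a];
    if (d[a] == 0.0) {
      if (p0[a] < lo || p0[a] >= hi) return;
    } else {
      double ta = (lo - p0[a]) / d[a], tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return;
  int iv[3];
  double tnext[3], dt[3];
  double tm = t0 + 1e-12 * (t1 - t0);
  for (int a = 0; a < 3; ++a) {
    double x = p0[a] + tm * d[a];
    int i = (int)std::floor((x - G.org[a]) / G.vox[a]);
    if (i < 0) i = 0;
    if (i >= G.n[a]) i = G.n[a] - 1;
    iv[a] = i;
    if (d[a] == 0.0) {
      tnext[a] = R_PosInf; dt[a] = R_PosInf;
    } else {
      int step = d[a] > 0 ? 1 : 0;
      double plane = G.org[a] + (i + step) * G.vox[a];
      tnext[a] = (plane - p0[a]) / d[a];
      dt[a] = G.vox[a] / std::fabs(d[a]);
    }
  }
  double t = t0;
  for (int guard = 0; guard < G.n[0] + G.n[1] + G.n[2] + 4; ++guard) {
    int am = 0;
    if (tnext[1] < tnext[am]) am = 1;
    if (tnext[2] < tnext[am]) am = 2;
    double te = std::min(tnext[am], t1);
    double seg = (te - t) * L;
    if (seg > 0) {
      idx.push_back(G.lin(iv[0], iv[1], iv[2]));
      len.push_back(seg);
    }
    if (te >= t1) break;
    t = te;
    iv[am] += d[am] > 0 ? 1 : -1;
    if (iv[am] < 0 || iv[am] >= G.n[am]) break;
    tnext[am] += dt[am];
  }
}

// [[Rcpp::export]]
List cpp_siddon(NumericVector p0, NumericVector p1, List grid) {
  VoxGrid G = grid_from_list(grid);
  std::vector<int> idx; std::vector<double> len;
  idx.reserve(512); len.reserve(512);
  siddon_row(&p0[0], &p1[0], G, idx, len);
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len));
}

// Sum of intersection lengths per voxel over a set of LORs (used for the
// planar-source normalization / sensitivity image).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix A, NumericMatrix B, List grid) {
  VoxGrid G = grid_from_list(grid);
  NumericVector img(G.nvox());
  std::vector<int> idx; std::vector<double> len;
  idx.reserve(512); len.reserve(512);
  for (int i = 0; i < A.nrow(); ++i) {
    double p0[3] = {A(i, 0), A(i, 1), A(i, 2)};
    double p1[3] = {B(i, 0), B(i, 1), B(i, 2)};
    idx.clear(); len.clear();
    siddon_row(p0, p1, G, idx, len);
    for (size_t k = 0; k < idx.size(); ++k) img[idx[k]] += len[k];
  }
  return img;
}

// List-mode OSEM.  Events are assigned to subsets round-robin by list order.
// Update: f_j <- (f_j / S_j) * sum_{i in subset} a_ij / (sum_k a_ik f_k).
// Voxels with S_j = 0 stay 0.  Events with non-positive forward projection
// are skipped and counted.
// [[Rcpp::export]]
NumericVector cpp_lm_osem(NumericMatrix A, NumericMatrix B,
                          NumericVector sens, List grid, int n_iter,
                          int n_subsets) {
  VoxGrid G = grid_from_list(grid);
  const int nv = G.nvox(), n = A.nrow();
  if (sens.size() != nv) stop("sensitivity image does not match the grid");
  NumericVector f(nv);
  for (int j = 0; j < nv; ++j) f[j] = sens[j] > 0 ? 1.0 : 0.0;
  std::vector<double> acc(nv);
  std::vector<int> idx; std::vector<double> len;
  idx.reserve(512); len.reserve(512);
  int skipped = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < n_subsets; ++s) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int i = s; i < n; i += n_subsets) {
        double p0[3] = {A(i, 0), A(i, 1), A(i, 2)};
        double p1[3] = {B(i, 0), B(i, 1), B(i, 2)};
        idx.clear(); len.clear();
        siddon_row(p0, p1, G, idx, len);
        double fwd = 0;
        for (size_t k = 0; k < idx.size(); ++k) fwd += len[k] * f[idx[k]];
        if (fwd <= 0) { ++skipped; continue; }
        double w = 1.0 / fwd;
        for (size_t k = 0; k < idx.size(); ++k) acc[idx[k]] += len[k] * w;
      }
      for (int j = 0; j < nv; ++j)
        if (sens[j] > 0) f[j] *= acc[j] / sens[j];
    }
  }
  f.attr("skipped") = skipped;
  return f;
}

// List-mode Poisson log-likelihood up to a constant:
// sum_i log(sum_j a_ij f_j) - sum_j S_j f_j   (skips zero-forward events)
// [[Rcpp::export]]
double cpp_lm_loglik(NumericMatrix A, NumericMatrix B, NumericVector sens,
                     List grid, NumericVector f) {
  VoxGrid G = grid_from_list(grid);
  std::vector<int> idx; std::vector<double> len;
  double ll = 0;
  for (int i = 0; i < A.nrow(); ++i) {
    double p0[3] = {A(i, 0), A(i, 1), A(i, 2)};
    double p1[3] = {B(i, 0), B(i, 1), B(i, 2)};
    idx.clear(); len.clear();
    siddon_row(p0, p1, G, idx, len);
    double fwd = 0;
    for (size_t k = 0; k < idx.size(); ++k) fwd += len[k] * f[idx[k]];
    if (fwd > 0) ll += std::log(fwd);
  }
  for (int j = 0; j < G.nvox(); ++j) ll -= sens[j] * f[j];
  return ll;
}
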