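#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Voxel grid convention: voxel (i,j,k) (0-based) is centred at
// origin + index * spacing and spans the half-open box
// [origin + (index-0.5)*spacing, origin + (index+0.5)*spacing) per axis.
// Rays are parameterised p(t) = p0 + t * d with unit d, t in mm.

static inline bool clip_ray(const double* p0, const double* d,
                            const double* lo, const double* hi,
                            double tmax, double& t0, double& t1) {
  t0 = 0.0;
  t1 = tmax;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      // parallel to the slab: inside test with half-open upper bound
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return false;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// Siddon-style exact traversal: breakpoints are the parametric values of all
// voxel-boundary plane crossings in (t0, t1); each interval's voxel is read
// off at its midpoint, which is strictly interior so boundary ties cannot
// arise. Chord lengths are differences of consecutive breakpoints, so their
// sum telescopes to t1 - t0 up to rounding.
static void trace_core(const double* p0, const double* d, double tmax,
                       const int* dim, const double* sp, const double* org,
                       std::vector<int>& idx, std::vector<double>& len,
                       double& t0, double& t1) {
  idx.clear();
  len.clear();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = org[a] - 0.5 * sp[a];
    hi[a] = org[a] + (dim[a] - 0.5) * sp[a];
  }
  t0 = 0.0;
  t1 = 0.0;
  if (tmax <= 0.0 || !clip_ray(p0, d, lo, hi, tmax, t0, t1)) return;

  std::vector<double> ts;
  ts.reserve(dim[0] + dim[1] + dim[2] + 2);
  ts.push_back(t0);
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-14) continue;
    double inv = 1.0 / d[a];
    // plane index range intersecting (t0, t1)
    double xa = p0[a] + t0 * d[a];
    double xb = p0[a] + t1 * d[a];
    if (xa > xb) std::swap(xa, xb);
    int kmin = (int)std::floor((xa - lo[a]) / sp[a]) - 1;
    int kmax = (int)std::ceil((xb - lo[a]) / sp[a]) + 1;
    if (kmin < 0) kmin = 0;
    if (kmax > dim[a]) kmax = dim[a];
    for (int k = kmin; k <= kmax; ++k) {
      double t = (lo[a] + k * sp[a] - p0[a]) * inv;
      if (t > t0 && t < t1) ts.push_back(t);
    }
  }
  ts.push_back(t1);
  std::sort(ts.begin(), ts.end());

  const int nx = dim[0], ny = dim[1];
  int prev = -1;
  for (size_t s = 0; s + 1 < ts.size(); ++s) {
    double dt = ts[s + 1] - ts[s];
    if (dt <= 0.0) continue;
    double tm = 0.5 * (ts[s] + ts[s + 1]);
    int iv[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      double pm = p0[a] + tm * d[a];
      int i = (int)std::floor((pm - lo[a]) / sp[a]);
      if (i < 0) i = 0;
      if (i >= dim[a]) i = dim[a] - 1;
      iv[a] = i;
      if (!ok) break;
    }
    if (!ok) continue;
    int lin = iv[0] + nx * (iv[1] + ny * iv[2]);
    if (lin == prev && !len.empty()) {
      len.back() += dt;  // corner-grazing duplicate interval
    } else {
      idx.push_back(lin);
      len.push_back(dt);
      prev = lin;
    }
  }
}

// [[Rcpp::export]]
List cpp_trace_ray(NumericVector p0, NumericVector d, double tmax,
                   IntegerVector dim, NumericVector spacing,
                   NumericVector origin) {
  std::vector<int> idx;
  std::vector<double> len;
  double t0, t1;
  trace_core(p0.begin(), d.begin(), tmax, dim.begin(), spacing.begin(),
             origin.begin(), idx, len, t0, t1);
  IntegerVector ridx(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) ridx[i] = idx[i] + 1;  // 1-based
  return List::create(_["idx"] = ridx, _["length"] = NumericVector(len.begin(), len.end()),
                      _["t_entry"] = t0, _["t_exit"] = t1);
}

// WEPL of every ray through every volume: each ray is traversed once and its
// chords dotted with each volume's RSP values. vols is a list of numeric
// arrays sharing dim.
// [[Rcpp::export]]
NumericMatrix cpp_bundle_wepl(NumericMatrix p0, NumericVector d,
                              NumericVector tmax, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              List vols) {
  const int nray = p0.nrow();
  const int nvol = vols.size();
  std::vector<const double*> vp(nvol);
  const R_xlen_t nvox = (R_xlen_t)dim[0] * dim[1] * dim[2];
  for (int v = 0; v < nvol; ++v) {
    NumericVector vol = vols[v];
    if (vol.size() != nvox) stop("volume %d has wrong size", v + 1);
    vp[v] = REAL(vol);
  }
  NumericMatrix out(nray, nvol);
  std::vector<int> idx;
  std::vector<double> len;
  double t0, t1;
  for (int r = 0; r < nray; ++r) {
    double q[3] = {p0(r, 0), p0(r, 1), p0(r, 2)};
    trace_core(q, d.begin(), tmax[r], dim.begin(), spacing.begin(),
               origin.begin(), idx, len, t0, t1);
    for (int v = 0; v < nvol; ++v) {
      double w = 0.0;
      const double* vol = vp[v];
      for (size_t s = 0; s < idx.size(); ++s) w += len[s] * vol[idx[s]];
      out(r, v) = w;
    }
  }
  return out;
}

// Union of voxels traversed (with positive chord) by any ray of a bundle.
// [[Rcpp::export]]
LogicalVector cpp_bundle_mark(NumericMatrix p0, NumericVector d,
                              NumericVector tmax, IntegerVector dim,
                              NumericVector spacing, NumericVector origin) {
  const int nray = p0.nrow();
  const R_xlen_t nvox = (R_xlen_t)dim[0] * dim[1] * dim[2];
  LogicalVector mark(nvox, false);
  std::vector<int> idx;
  std::vector<double> len;
  double t0, t1;
  for (int r = 0; r < nray; ++r) {
    double q[3] = {p0(r, 0), p0(r, 1), p0(r, 2)};
    trace_core(q, d.begin(), tmax[r], dim.begin(), spacing.begin(),
               origin.begin(), idx, len, t0, t1);
    for (size_t s = 0; s < idx.size(); ++s)
      if (len[s] > 0.0) mark[idx[s]] = true;
  }
  return mark;
}

// For each ray, parametric t of the distal (last) exit from the mask along
// the full in-grid path; NA if the ray never traverses a mask voxel.
// [[Rcpp::export]]
NumericVector cpp_mask_stop(NumericMatrix p0, NumericVector d,
                            IntegerVector dim, NumericVector spacing,
                            NumericVector origin, LogicalVector mask) {
  const int nray = p0.nrow();
  const R_xlen_t nvox = (R_xlen_t)dim[0] * dim[1] * dim[2];
  if (mask.size() != nvox) stop("mask has wrong size");
  NumericVector out(nray, NA_REAL);
  std::vector<int> idx;
  std::vector<double> len;
  double t0, t1;
  const double big = 1e12;
  for (int r = 0; r < nray; ++r) {
    double q[3] = {p0(r, 0), p0(r, 1), p0(r, 2)};
    trace_core(q, d.begin(), big, dim.begin(), spacing.begin(), origin.begin(),
               idx, len, t0, t1);
    double t = t0;
    double stop_t = NA_REAL;
    for (size_t s = 0; s < idx.size(); ++s) {
      t += len[s];
      if (mask[idx[s]] && len[s] > 0.0) stop_t = t;
    }
    out[r] = stop_t;
  }
  return out;
}
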