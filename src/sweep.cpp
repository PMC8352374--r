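#include <Rcpp.h>
using namespace Rcpp;

// Nearest-voxel rule shared with the R side: floor(x + 0.5), 0-based in,
// 1-based out handled by the caller keeping everything 0-based here.
static inline int nearest_index(double frac) {
  return (int)std::floor(frac + 0.5);
}

// Exhaustive pose sweep: for each pose, test every sampled beam point
// against the obstruction array (early exit on the first hit); for clear
// poses, mark target grid points inside the posed treatment cell.
//
// base_vox: list (one per tilt) of n_pts x 3 matrices of fractional voxel
//           coordinates (0-based) of the beam cloud at zero translation.
// tilt_idx: 1-based index into base_vox per pose.
// trans_vox: n_pose x 3 translation in voxel units.
// obst: logical array (dim dm) of obstruction voxels.
// grid_pts: m x 3 world coordinates of target grid points.
// foci/axes: n_pose x 3 focus position / unit beam axis per pose.
// a2, c2: squared transverse / long semi-axes of the cell.
// [[Rcpp::export(name = ".sweep_poses")]]
List sweep_poses(List base_vox, IntegerVector tilt_idx,
                 NumericMatrix trans_vox, LogicalVector obst,
                 IntegerVector dm, NumericMatrix grid_pts,
                 NumericMatrix foci, NumericMatrix axes,
                 double a2, double c2) {
  const int n_pose = tilt_idx.size();
  const int m = grid_pts.nrow();
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const int *ob = LOGICAL(obst);
  LogicalVector clear(n_pose);
  LogicalVector covered(m);
  int n_clear = 0;

  std::vector<NumericMatrix> clouds;
  clouds.reserve(base_vox.size());
  for (int t = 0; t < base_vox.size(); ++t)
    clouds.push_back(as<NumericMatrix>(base_vox[t]));

  for (int p = 0; p < n_pose; ++p) {
    const NumericMatrix &bv = clouds[tilt_idx[p] - 1];
    const int n_pts = bv.nrow();
    const double tx = trans_vox(p, 0), ty = trans_vox(p, 1),
                 tz = trans_vox(p, 2);
    const double *c0 = &bv(0, 0), *c1 = &bv(0, 1), *c2v = &bv(0, 2);
    bool blocked = false;
    for (int q = 0; q < n_pts; ++q) {
      int i = nearest_index(c0[q] + tx);
      if (i < 0 || i >= nx) continue;
      int j = nearest_index(c1[q] + ty);
      if (j < 0 || j >= ny) continue;
      int k = nearest_index(c2v[q] + tz);
      if (k < 0 || k >= nz) continue;
      if (ob[i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny]) {
        blocked = true;
        break;
      }
    }
    clear[p] = !blocked;
    if (blocked) continue;
    ++n_clear;
    const double fx = foci(p, 0), fy = foci(p, 1), fz = foci(p, 2);
    const double ax = axes(p, 0), ay = axes(p, 1), az = axes(p, 2);
    for (int g = 0; g < m; ++g) {
      if (covered[g]) continue;
      double dx = grid_pts(g, 0) - fx;
      double dy = grid_pts(g, 1) - fy;
      double dz = grid_pts(g, 2) - fz;
      double w = dx * ax + dy * ay + dz * az;
      double r2 = dx * dx + dy * dy + dz * dz - w * w;
      if (r2 < 0) r2 = 0;
      if (r2 / a2 + (w * w) / c2 <= 1.0) covered[g] = TRUE;
    }
  }
  return List::create(_["covered"] = covered, _["clear"] = clear,
                      _["n_clear"] = n_clear);
}
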