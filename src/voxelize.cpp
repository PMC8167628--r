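#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate per-voxel occupancy (fraction of voxel inside any sphere) by
// regular sub-voxel sampling: each voxel is probed at ss^3 points placed on a
// regular grid strictly inside the voxel. Spheres are assumed non-overlapping
// (packer contract); occupancy from tangent spheres can exceed 1 by a sliver
// at shared sub-samples, the R wrapper clamps to 1.
//
// Voxel (i, j, k), 0-based here, has its centre at origin + (i + 0.5) * dx
// etc.; only voxels intersecting a sphere's bounding box are visited.
// [[Rcpp::export]]
NumericVector cpp_sphere_occupancy(IntegerVector dims, NumericVector spacing,
                                   NumericVector origin,
                                   NumericMatrix centers, NumericVector radii,
                                   int ss) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector occ((R_xlen_t)nx * ny * nz);

  std::vector<double> offx(ss), offy(ss), offz(ss);
  for (int s = 0; s < ss; ++s) {
    double u = (s + 0.5) / ss - 0.5;
    offx[s] = u * dx; offy[s] = u * dy; offz[s] = u * dz;
  }
  const double w = 1.0 / ((double)ss * ss * ss);

  for (int b = 0; b < centers.nrow(); ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double r = radii[b], r2 = r * r;
    int i0 = (int)std::floor((cx - r - ox) / dx - 0.5);
    int i1 = (int)std::ceil((cx + r - ox) / dx - 0.5);
    int j0 = (int)std::floor((cy - r - oy) / dy - 0.5);
    int j1 = (int)std::ceil((cy + r - oy) / dy - 0.5);
    int k0 = (int)std::floor((cz - r - oz) / dz - 0.5);
    int k1 = (int)std::ceil((cz + r - oz) / dz - 0.5);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;

    for (int k = k0; k <= k1; ++k) {
      const double vz = oz + (k + 0.5) * dz - cz;
      for (int j = j0; j <= j1; ++j) {
        const double vy = oy + (j + 0.5) * dy - cy;
        for (int i = i0; i <= i1; ++i) {
          const double vx = ox + (i + 0.5) * dx - cx;
          // quick accept/reject on the voxel's circumscribed sphere
          const double cdist2 = vx * vx + vy * vy + vz * vz;
          const double half =
            0.5 * std::sqrt(dx * dx + dy * dy + dz * dz);
          if (cdist2 > (r + half) * (r + half)) continue;
          int cnt = 0;
          if (cdist2 < (r - half) * (r - half)) {
            cnt = ss * ss * ss;  // voxel fully inside
          } else {
            for (int sz_ = 0; sz_ < ss; ++sz_) {
              const double pz = vz + offz[sz_];
              const double z2 = pz * pz;
              if (z2 > r2) continue;
              for (int sy_ = 0; sy_ < ss; ++sy_) {
                const double py = vy + offy[sy_];
                const double yz2 = z2 + py * py;
                if (yz2 > r2) continue;
                for (int sx_ = 0; sx_ < ss; ++sx_) {
                  const double px = vx + offx[sx_];
                  if (yz2 + px * px <= r2) ++cnt;
                }
              }
            }
          }
          if (cnt > 0)
            occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] +=
              cnt * w;
        }
      }
    }
  }
  return occ;
}
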