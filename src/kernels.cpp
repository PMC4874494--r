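#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window matched filter over a 3-D volume.
//
// vol      : volume values, column-major, dims = dim (nx, ny, nz)
// offsets  : m x 3 integer matrix of 0-based voxel offsets relative to the
//            anchor voxel (template voxels with value 1)
// statistic: 0 = sum of covered voxels, 1 = mean over non-excluded voxels
// exclude  : optional logical array (same dims as vol); TRUE voxels are left
//            out of the mean (air compensation)
//
// Values are recorded at the anchor voxel.  Placements where the template
// would leave the volume are not populated (NA).  The argmax is the first
// strict maximum in lexicographic (z, y, x) scan order; ties with the
// maximum are counted so the caller can warn on multiple maxima.
// [[Rcpp::export]]
List cpp_matched_scan(NumericVector vol, IntegerVector dim,
                      IntegerMatrix offsets, int statistic,
                      Nullable<LogicalVector> exclude) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = offsets.nrow();
  if (m == 0) stop("empty template");
  const double *v = REAL(vol);
  const int *excl = nullptr;
  LogicalVector exclv;
  if (exclude.isNotNull()) {
    exclv = exclude.get();
    excl = LOGICAL(exclv);
  }

  int omin[3] = {offsets(0, 0), offsets(0, 1), offsets(0, 2)};
  int omax[3] = {offsets(0, 0), offsets(0, 1), offsets(0, 2)};
  for (int i = 1; i < m; ++i)
    for (int a = 0; a < 3; ++a) {
      int o = offsets(i, a);
      if (o < omin[a]) omin[a] = o;
      if (o > omax[a]) omax[a] = o;
    }
  // valid anchor range per axis (0-based, inclusive)
  int lo[3], hi[3];
  const int dims[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = -omin[a];
    hi[a] = dims[a] - 1 - omax[a];
    if (lo[a] > hi[a]) stop("template larger than volume");
  }

  // precompute linear offsets
  std::vector<long long> loff(m);
  for (int i = 0; i < m; ++i)
    loff[i] = (long long)offsets(i, 0) +
              (long long)nx * (offsets(i, 1) + (long long)ny * offsets(i, 2));

  NumericVector out((R_xlen_t)nx * ny * nz, NA_REAL);
  double *o = REAL(out);
  bool haveBest = false;
  double best = 0.0;
  int bestIdx[3] = {0, 0, 0};
  int nties = 0;
  long long nvalid = 0;

  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x) {
        long long base = (long long)x + (long long)nx * (y + (long long)ny * z);
        double val;
        if (statistic == 0 && !excl) {
          double s = 0.0;
          for (int i = 0; i < m; ++i) s += v[base + loff[i]];
          val = s;
        } else if (statistic == 0) {
          double s = 0.0;
          for (int i = 0; i < m; ++i)
            if (!excl[base + loff[i]]) s += v[base + loff[i]];
          val = s;
        } else {
          double s = 0.0;
          long long n = 0;
          for (int i = 0; i < m; ++i) {
            long long j = base + loff[i];
            if (!excl || !excl[j]) { s += v[j]; ++n; }
          }
          if (n == 0) continue;  // all covered voxels excluded: invalid
          val = s / (double)n;
        }
        o[base] = val;
        ++nvalid;
        if (!haveBest || val > best) {
          haveBest = true;
          best = val;
          bestIdx[0] = x; bestIdx[1] = y; bestIdx[2] = z;
          nties = 1;
        } else if (val == best) {
          ++nties;
        }
      }

  if (!haveBest) stop("template larger than volume");
  return List::create(_["values"] = out,
                      _["argmax"] = IntegerVector::create(bestIdx[0], bestIdx[1], bestIdx[2]),
                      _["max"] = best,
                      _["nmaxima"] = nties,
                      _["nvalid"] = (double)nvalid,
                      _["lo"] = IntegerVector::create(lo[0], lo[1], lo[2]),
                      _["hi"] = IntegerVector::create(hi[0], hi[1], hi[2]));
}

// Six-degree-of-freedom perturbation search.
//
// For every combination of a rotation node (nr nodes; the mapped sphere
// centers, already rotated, are supplied as fractional PET voxel anchors)
// and a translation node (nt nodes; supplied as voxel-space offsets), the
// six filled spheres are rasterized with the Binary Center Inclusion rule
// (voxel center within or on the sphere boundary, distances in mm) and the
// sum of covered PET voxels is recorded.
//
// rotCenters : (nr*ns) x 3, fractional 0-based voxel anchors; sphere index
//              varies fastest (row = s + ns*r)
// transVox   : nt x 3 voxel-space translation offsets
// radii      : ns sphere radii in mm
// spacing    : voxel size in mm
//
// Nodes where any sphere extends beyond the volume are invalid (NA).
// Output is length nr*nt with rotation index varying fastest.
// [[Rcpp::export]]
NumericVector cpp_perturb_search(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing,
                                 NumericMatrix rotCenters,
                                 NumericMatrix transVox,
                                 NumericVector radii) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ns = radii.size();
  const int nr = rotCenters.nrow() / ns;
  const int nt = transVox.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *v = REAL(vol);

  NumericVector out((R_xlen_t)nr * nt, NA_REAL);
  double *o = REAL(out);

  std::vector<double> rvox(ns * 3), r2(ns);
  for (int s = 0; s < ns; ++s) {
    r2[s] = radii[s] * radii[s];
    rvox[3 * s + 0] = radii[s] / sx;
    rvox[3 * s + 1] = radii[s] / sy;
    rvox[3 * s + 2] = radii[s] / sz;
  }

  for (int r = 0; r < nr; ++r) {
    for (int t = 0; t < nt; ++t) {
      double total = 0.0;
      bool ok = true;
      for (int s = 0; s < ns && ok; ++s) {
        const double ax = rotCenters(s + ns * r, 0) + transVox(t, 0);
        const double ay = rotCenters(s + ns * r, 1) + transVox(t, 1);
        const double az = rotCenters(s + ns * r, 2) + transVox(t, 2);
        const int x0 = (int)std::ceil(ax - rvox[3 * s]);
        const int x1 = (int)std::floor(ax + rvox[3 * s]);
        const int y0 = (int)std::ceil(ay - rvox[3 * s + 1]);
        const int y1 = (int)std::floor(ay + rvox[3 * s + 1]);
        const int z0 = (int)std::ceil(az - rvox[3 * s + 2]);
        const int z1 = (int)std::floor(az + rvox[3 * s + 2]);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x1 >= nx || y1 >= ny || z1 >= nz) {
          ok = false;
          break;
        }
        const double rr = r2[s];
        for (int z = z0; z <= z1; ++z) {
          const double dz = (z - az) * sz, dz2 = dz * dz;
          if (dz2 > rr) continue;
          for (int y = y0; y <= y1; ++y) {
            const double dy = (y - ay) * sy, d2 = dz2 + dy * dy;
            if (d2 > rr) continue;
            const long long base = (long long)nx * (y + (long long)ny * z);
            for (int x = x0; x <= x1; ++x) {
              const double dx = (x - ax) * sx;
              if (d2 + dx * dx <= rr) total += v[base + x];
            }
          }
        }
      }
      if (ok) o[r + (long long)nr * t] = total;
    }
  }
  return out;
}
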