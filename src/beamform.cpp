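#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-way delay-and-sum accumulation over a regular voxel grid.
//
// re, im: real/imaginary parts of the analytic compressed traces
//         (n_samples x n_elements); elem: n_elements x 3 positions (mm);
// gx/gy/gz: voxel-centre coordinates (mm); c: sound speed (mm/us);
// fs: sampling rate (MHz); lag0: lag of the first sample (us);
// coherent: complex sum then modulus if true, magnitude sum otherwise.
// Voxels whose delay falls outside the trace support get no contribution.
// Returns intensity as a gx-fastest flattened array plus the count of
// out-of-support voxel-element pairs.
// [[Rcpp::export(name = ".das_accumulate_cpp")]]
List das_accumulate_cpp(NumericMatrix re, NumericMatrix im, NumericMatrix elem,
                        NumericVector gx, NumericVector gy, NumericVector gz,
                        double c, double fs, double lag0, bool coherent) {
  const R_xlen_t nx = gx.size(), ny = gy.size(), nz = gz.size();
  const int ne = elem.nrow();
  const int ns = re.nrow();
  const R_xlen_t nvox = nx * ny * nz;
  std::vector<double> acc_re(nvox, 0.0), acc_im(nvox, 0.0), acc_mag;
  if (!coherent) acc_mag.assign(nvox, 0.0);
  long long misses = 0;
  const double inv_c_fs = fs / c;
  // element-outer loop keeps one trace hot in cache and hoists its pointers
  for (int e = 0; e < ne; ++e) {
    const double ex = elem(e, 0), ey = elem(e, 1), ez = elem(e, 2);
    const double *tr = &re(0, e);
    const double *ti = &im(0, e);
    R_xlen_t v = 0;
    for (R_xlen_t iz = 0; iz < nz; ++iz) {
      const double dz = gz[iz] - ez;
      const double dz2 = dz * dz;
      for (R_xlen_t iy = 0; iy < ny; ++iy) {
        const double dy = gy[iy] - ey;
        const double dyz2 = dz2 + dy * dy;
        for (R_xlen_t ix = 0; ix < nx; ++ix, ++v) {
          const double dx = gx[ix] - ex;
          const double sidx = std::sqrt(dyz2 + dx * dx) * inv_c_fs - lag0 * fs;
          const int i0 = (int)sidx;   // sidx >= 0 in-support; negatives handled below
          if (sidx < 0.0 || i0 + 1 >= ns) { ++misses; continue; }
          const double w = sidx - i0;
          const double vr = tr[i0] + w * (tr[i0 + 1] - tr[i0]);
          const double vi = ti[i0] + w * (ti[i0 + 1] - ti[i0]);
          if (coherent) {
            acc_re[v] += vr;
            acc_im[v] += vi;
          } else {
            acc_mag[v] += std::sqrt(vr * vr + vi * vi);
          }
        }
      }
    }
  }
  NumericVector out(nvox);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    out[v] = coherent ? std::sqrt(acc_re[v] * acc_re[v] + acc_im[v] * acc_im[v])
                      : acc_mag[v];
  }
  return List::create(_["intensity"] = out, _["misses"] = (double)misses);
}

// Exhaustive minimizer of the multilateration objective
// sum_i (||p - s_i|| - d_i)^2 over a regular grid of candidate positions.
// Independent reference solver for cross-checking the iterative path.
// [[Rcpp::export(name = ".grid_search_cpp")]]
List grid_search_cpp(NumericMatrix elem, NumericVector d,
                     NumericVector ax, NumericVector ay, NumericVector az) {
  const int ne = elem.nrow();
  double best = R_PosInf;
  double bx = ax[0], by = ay[0], bz = az[0];
  for (int iz = 0; iz < az.size(); ++iz) {
    const double z = az[iz];
    for (int iy = 0; iy < ay.size(); ++iy) {
      const double y = ay[iy];
      for (int ix = 0; ix < ax.size(); ++ix) {
        const double x = ax[ix];
        double f = 0.0;
        for (int e = 0; e < ne; ++e) {
          const double dx = x - elem(e, 0);
          const double dy = y - elem(e, 1);
          const double dz = z - elem(e, 2);
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz) - d[e];
          f += r * r;
        }
        if (f < best) {
          best = f; bx = x; by = y; bz = z;
        }
      }
    }
  }
  return List::create(
    _["position"] = NumericVector::create(bx, by, bz),
    _["objective"] = best
  );
}
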