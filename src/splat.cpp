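#include <Rcpp.h>
using namespace Rcpp;

// Forward-splatting accumulator: each pixel deposits (w*value, w) into all
// voxels whose centers lie within trunc_radius of the pixel position, with
// Gaussian weight w = base_w * exp(-d^2 / (2 sigma^2)). Arrays are column
// major with x fastest: idx = ix + nx*(iy + ny*iz). Accumulates in place
// into wv_sum / w_sum (passed as pre-allocated numeric vectors).
// [[Rcpp::export(name = ".splat_accumulate")]]
void splat_accumulate(NumericMatrix pos, NumericVector values,
                      NumericVector base_weights, NumericVector origin,
                      NumericVector spacing, IntegerVector dims,
                      double sigma, double trunc_radius,
                      NumericVector wv_sum, NumericVector w_sum) {
  const int n = pos.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r2 = trunc_radius * trunc_radius;
  for (int i = 0; i < n; ++i) {
    const double v = values[i];
    if (!R_finite(v)) continue;  // invalid pixels carry no weight
    const double bw = base_weights[i];
    if (bw <= 0.0) continue;
    const double px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
    int lo[3], hi[3];
    const double p[3] = {px, py, pz};
    const int nd[3] = {nx, ny, nz};
    bool empty = false;
    for (int a = 0; a < 3; ++a) {
      lo[a] = (int)std::ceil((p[a] - trunc_radius - origin[a]) / spacing[a]);
      hi[a] = (int)std::floor((p[a] + trunc_radius - origin[a]) / spacing[a]);
      if (lo[a] < 0) lo[a] = 0;
      if (hi[a] > nd[a] - 1) hi[a] = nd[a] - 1;
      if (lo[a] > hi[a]) { empty = true; break; }
    }
    if (empty) continue;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = origin[2] + iz * spacing[2] - pz;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = origin[1] + iy * spacing[1] - py;
        const double dzy2 = dz * dz + dy * dy;
        if (dzy2 > r2) continue;
        const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = origin[0] + ix * spacing[0] - px;
          const double d2 = dzy2 + dx * dx;
          if (d2 > r2) continue;
          const double w = bw * std::exp(-d2 * inv2s2);
          wv_sum[base + ix] += w * v;
          w_sum[base + ix] += w;
        }
      }
    }
  }
}
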