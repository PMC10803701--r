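// Rotation-based parallel-beam SPECT projector.
//
// Geometry: volume array dim (nx, ny, nz), column-major; z is the axial
// (rotation) axis.  For a projection at angle theta the volume is resampled
// (bilinear, in-plane) into a frame where the detector sits at +y; depth
// slabs (fixed y index) are then attenuated, blurred with the
// distance-dependent collimator response, and summed toward the detector.
// The backprojector is the exact algebraic transpose of every step
// (gather-rotation <-> scatter-rotation, symmetric blur kernels, diagonal
// attenuation), which OS-EM requires.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline double deg2rad(double d) { return d * M_PI / 180.0; }

// Bilinear in-plane rotation, gather form: out(t) = vol(R(theta) t).
static void rotate_gather(const double* vol, double* out,
                          int nx, int ny, int nz, double theta) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c = std::cos(theta), s = std::sin(theta);
  const int nxy = nx * ny;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const double dx = ix - cx, dy = iy - cy;
      const double sx = c * dx - s * dy + cx;
      const double sy = s * dx + c * dy + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
                   w01 = (1 - fx) * fy,       w11 = fx * fy;
      const bool i00 = x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny;
      const bool i10 = x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny;
      const bool i01 = x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      const bool i11 = x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      const int o = ix + nx * iy;
      const int b00 = x0 + nx * y0, b10 = b00 + 1, b01 = b00 + nx, b11 = b01 + 1;
      for (int iz = 0; iz < nz; ++iz) {
        const int zo = iz * nxy;
        double v = 0.0;
        if (i00) v += w00 * vol[b00 + zo];
        if (i10) v += w10 * vol[b10 + zo];
        if (i01) v += w01 * vol[b01 + zo];
        if (i11) v += w11 * vol[b11 + zo];
        out[o + zo] = v;
      }
    }
  }
}

// Transpose of rotate_gather: scatter with identical weights.
static void rotate_scatter(const double* vol, double* out,
                           int nx, int ny, int nz, double theta) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c = std::cos(theta), s = std::sin(theta);
  const int nxy = nx * ny;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const double dx = ix - cx, dy = iy - cy;
      const double sx = c * dx - s * dy + cx;
      const double sy = s * dx + c * dy + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
                   w01 = (1 - fx) * fy,       w11 = fx * fy;
      const bool i00 = x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny;
      const bool i10 = x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny;
      const bool i01 = x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      const bool i11 = x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      const int o = ix + nx * iy;
      const int b00 = x0 + nx * y0, b10 = b00 + 1, b01 = b00 + nx, b11 = b01 + 1;
      for (int iz = 0; iz < nz; ++iz) {
        const int zo = iz * nxy;
        const double v = vol[o + zo];
        if (v == 0.0) continue;
        if (i00) out[b00 + zo] += w00 * v;
        if (i10) out[b10 + zo] += w10 * v;
        if (i01) out[b01 + zo] += w01 * v;
        if (i11) out[b11 + zo] += w11 * v;
      }
    }
  }
}

// Symmetric truncated-Gaussian kernel, normalized to unit sum; radius 3 sigma.
static std::vector<double> gauss_kernel(double sigma_px) {
  if (sigma_px < 0.05) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma_px);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double sum = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (i * i) / (sigma_px * sigma_px));
    k[i + r] = v; sum += v;
  }
  for (double& v : k) v /= sum;
  return k;
}

// In-place separable blur of an nx-by-nz plane (zero padding).
static void blur_plane(double* p, int nx, int nz, const std::vector<double>& k,
                       std::vector<double>& scratch) {
  const int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  scratch.assign((size_t)nx * nz, 0.0);
  // along x
  for (int iz = 0; iz < nz; ++iz) {
    const int off = iz * nx;
    for (int ix = 0; ix < nx; ++ix) {
      const double v = p[off + ix];
      if (v == 0.0) continue;
      const int lo = std::max(-r, -ix), hi = std::min(r, nx - 1 - ix);
      for (int d = lo; d <= hi; ++d) scratch[off + ix + d] += v * k[d + r];
    }
  }
  // along z
  std::fill(p, p + (size_t)nx * nz, 0.0);
  for (int iz = 0; iz < nz; ++iz) {
    const int off = iz * nx;
    const int lo = std::max(-r, -iz), hi = std::min(r, nz - 1 - iz);
    for (int ix = 0; ix < nx; ++ix) {
      const double v = scratch[off + ix];
      if (v == 0.0) continue;
      for (int d = lo; d <= hi; ++d) p[(iz + d) * nx + ix] += v * k[d + r];
    }
  }
}

struct AngleModel {
  std::vector<double> sig2_px;  // total PSF variance (px^2) per depth index
  double vox_cm;
};

static AngleModel depth_model(int ny, double vox_mm, double orbit_mm,
                              double sigma_int_mm, double sigma_slope,
                              bool use_psf) {
  AngleModel m;
  m.vox_cm = vox_mm / 10.0;
  m.sig2_px.assign(ny, 0.0);
  if (!use_psf) return m;
  const double cy = 0.5 * (ny - 1);
  for (int j = 0; j < ny; ++j) {
    double dist = orbit_mm - (j - cy) * vox_mm;  // detector beyond +y face
    if (dist < 0) dist = 0;
    const double sig_mm2 = sigma_int_mm * sigma_int_mm +
                           sigma_slope * sigma_slope * dist * dist;
    m.sig2_px[j] = sig_mm2 / (vox_mm * vox_mm);
  }
  return m;
}

// Attenuation factor per rotated voxel: exp(-vox_cm * (sum mu above + mu/2)).
static void atten_factors(const double* rotmu, double* att,
                          int nx, int ny, int nz, double vox_cm) {
  const int nxy = nx * ny;
  for (int iz = 0; iz < nz; ++iz) {
    for (int ix = 0; ix < nx; ++ix) {
      double cum = 0.0;
      for (int j = ny - 1; j >= 0; --j) {
        const int idx = ix + nx * j + nxy * iz;
        const double mu = rotmu[idx];
        att[idx] = std::exp(-vox_cm * (cum + 0.5 * mu));
        cum += mu;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_fp_angle(NumericVector act, NumericVector mu,
                           IntegerVector dims, double theta_deg,
                           double vox_mm, double orbit_mm,
                           double sigma_int_mm, double sigma_slope,
                           bool use_psf, bool use_atten) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const double th = deg2rad(theta_deg);
  std::vector<double> rotA((size_t)nx * ny * nz), rotM, att;
  rotate_gather(REAL(act), rotA.data(), nx, ny, nz, th);
  if (use_atten) {
    rotM.resize((size_t)nx * ny * nz);
    att.resize((size_t)nx * ny * nz);
    rotate_gather(REAL(mu), rotM.data(), nx, ny, nz, th);
    atten_factors(rotM.data(), att.data(), nx, ny, nz, vox_mm / 10.0);
  }
  AngleModel m = depth_model(ny, vox_mm, orbit_mm, sigma_int_mm, sigma_slope, use_psf);
  std::vector<double> acc((size_t)nx * nz, 0.0), scratch;
  for (int j = 0; j < ny; ++j) {
    if (use_psf && j > 0) {
      const double d2 = m.sig2_px[j - 1] - m.sig2_px[j];
      if (d2 > 1e-12) {
        std::vector<double> k = gauss_kernel(std::sqrt(d2));
        blur_plane(acc.data(), nx, nz, k, scratch);
      }
    }
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix) {
        const int idx = ix + nx * j + nxy * iz;
        double v = rotA[idx];
        if (use_atten) v *= att[idx];
        acc[iz * nx + ix] += v;
      }
  }
  if (use_psf && m.sig2_px[ny - 1] > 1e-12) {
    std::vector<double> k = gauss_kernel(std::sqrt(m.sig2_px[ny - 1]));
    blur_plane(acc.data(), nx, nz, k, scratch);
  }
  NumericMatrix out(nx, nz);
  std::copy(acc.begin(), acc.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bp_angle(NumericMatrix proj, NumericVector mu,
                           IntegerVector dims, double theta_deg,
                           double vox_mm, double orbit_mm,
                           double sigma_int_mm, double sigma_slope,
                           bool use_psf, bool use_atten) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const double th = deg2rad(theta_deg);
  std::vector<double> rotM, att;
  if (use_atten) {
    rotM.resize((size_t)nx * ny * nz);
    att.resize((size_t)nx * ny * nz);
    rotate_gather(REAL(mu), rotM.data(), nx, ny, nz, th);
    atten_factors(rotM.data(), att.data(), nx, ny, nz, vox_mm / 10.0);
  }
  AngleModel m = depth_model(ny, vox_mm, orbit_mm, sigma_int_mm, sigma_slope, use_psf);
  std::vector<double> tmp((size_t)nx * nz), scratch;
  std::copy(proj.begin(), proj.end(), tmp.begin());
  if (use_psf && m.sig2_px[ny - 1] > 1e-12) {
    std::vector<double> k = gauss_kernel(std::sqrt(m.sig2_px[ny - 1]));
    blur_plane(tmp.data(), nx, nz, k, scratch);
  }
  std::vector<double> rotOut((size_t)nx * ny * nz, 0.0);
  for (int j = ny - 1; j >= 0; --j) {
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix) {
        const int idx = ix + nx * j + nxy * iz;
        double v = tmp[iz * nx + ix];
        if (use_atten) v *= att[idx];
        rotOut[idx] = v;
      }
    if (use_psf && j > 0) {
      const double d2 = m.sig2_px[j - 1] - m.sig2_px[j];
      if (d2 > 1e-12) {
        std::vector<double> k = gauss_kernel(std::sqrt(d2));
        blur_plane(tmp.data(), nx, nz, k, scratch);
      }
    }
  }
  NumericVector out((size_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), 0.0);
  rotate_scatter(rotOut.data(), REAL(out), nx, ny, nz, th);
  out.attr("dim") = dims;
  return out;
}

// Separable 3D Gaussian blur (zero padding, unit-sum kernel) used by the
// post-reconstruction filter and the synthetic micro-CT scanner PSF.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims,
                         NumericVector sigma_px) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size(), 0.0);
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> k = gauss_kernel(sigma_px[axis]);
    const int r = ((int)k.size() - 1) / 2;
    if (r == 0) continue;
    std::fill(b.begin(), b.end(), 0.0);
    const int n = sizes[axis], st = strides[axis];
    // iterate over all lines along `axis`
    const int n0 = sizes[(axis + 1) % 3], st0 = strides[(axis + 1) % 3];
    const int n1 = sizes[(axis + 2) % 3], st1 = strides[(axis + 2) % 3];
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        const size_t base = (size_t)i0 * st0 + (size_t)i1 * st1;
        for (int i = 0; i < n; ++i) {
          const double v = a[base + (size_t)i * st];
          if (v == 0.0) continue;
          const int lo = std::max(-r, -i), hi = std::min(r, n - 1 - i);
          for (int d = lo; d <= hi; ++d)
            b[base + (size_t)(i + d) * st] += v * k[d + r];
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// 3x3x3 box erosion/dilation of a 0/1 mask.
// [[Rcpp::export]]
IntegerVector cpp_morph3(IntegerVector mask, IntegerVector dims, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  IntegerVector out((size_t)nx * ny * nz);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int hit = dilate ? 0 : 1;
        for (int dz = -1; dz <= 1 && (dilate ? !hit : hit); ++dz) {
          const int z = iz + dz;
          if (z < 0 || z >= nz) { if (!dilate) hit = 0; continue; }
          for (int dy = -1; dy <= 1 && (dilate ? !hit : hit); ++dy) {
            const int y = iy + dy;
            if (y < 0 || y >= ny) { if (!dilate) hit = 0; continue; }
            for (int dx = -1; dx <= 1; ++dx) {
              const int x = ix + dx;
              if (x < 0 || x >= nx) { if (!dilate) hit = 0; continue; }
              const int v = mask[x + nx * y + nxy * z];
              if (dilate && v) { hit = 1; break; }
              if (!dilate && !v) { hit = 0; break; }
            }
          }
        }
        out[ix + nx * iy + nxy * iz] = hit;
      }
  out.attr("dim") = dims;
  return out;
}

// 6-connected flood fill of the complement of `mask`, seeded from all volume
// faces; returns 1 where background air connects to the outside.
// [[Rcpp::export]]
IntegerVector cpp_outside_air(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector out(n);
  std::queue<int> q;
  auto push = [&](int ix, int iy, int iz) {
    const int idx = ix + nx * iy + nxy * iz;
    if (!mask[idx] && !out[idx]) { out[idx] = 1; q.push(idx); }
  };
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) { push(0, iy, iz); push(nx - 1, iy, iz); }
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) { push(ix, 0, iz); push(ix, ny - 1, iz); }
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) { push(ix, iy, 0); push(ix, iy, nz - 1); }
  while (!q.empty()) {
    const int idx = q.front(); q.pop();
    const int iz = idx / nxy, rem = idx % nxy, iy = rem / nx, ix = rem % nx;
    if (ix > 0) push(ix - 1, iy, iz);
    if (ix < nx - 1) push(ix + 1, iy, iz);
    if (iy > 0) push(ix, iy - 1, iz);
    if (iy < ny - 1) push(ix, iy + 1, iz);
    if (iz > 0) push(ix, iy, iz - 1);
    if (iz < nz - 1) push(ix, iy, iz + 1);
  }
  out.attr("dim") = dims;
  return out;
}

// Fused OS-EM angle update: forward-project the current estimate, form the
// count ratio y / max(yhat, eps), and backproject it, reusing the rotated
// attenuation volume between the two passes.  The global count scale
// (sensitivity x time x voxel volume) enters only the ratio; the outer
// backprojection scale cancels against the sensitivity image.
// [[Rcpp::export]]
NumericVector cpp_osem_angle(NumericVector x, NumericMatrix y,
                             NumericVector mu, IntegerVector dims,
                             double theta_deg, double vox_mm, double orbit_mm,
                             double sigma_int_mm, double sigma_slope,
                             bool use_psf, double scale) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const double th = deg2rad(theta_deg);
  std::vector<double> rotA((size_t)nx * ny * nz), rotM((size_t)nx * ny * nz),
      att((size_t)nx * ny * nz);
  rotate_gather(REAL(x), rotA.data(), nx, ny, nz, th);
  rotate_gather(REAL(mu), rotM.data(), nx, ny, nz, th);
  atten_factors(rotM.data(), att.data(), nx, ny, nz, vox_mm / 10.0);
  AngleModel m = depth_model(ny, vox_mm, orbit_mm, sigma_int_mm, sigma_slope, use_psf);
  std::vector<double> acc((size_t)nx * nz, 0.0), scratch;
  std::vector<std::vector<double>> kstep(ny);
  for (int j = 0; j < ny; ++j) {
    if (use_psf && j > 0) {
      const double d2 = m.sig2_px[j - 1] - m.sig2_px[j];
      if (d2 > 1e-12) {
        kstep[j] = gauss_kernel(std::sqrt(d2));
        blur_plane(acc.data(), nx, nz, kstep[j], scratch);
      }
    }
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix) {
        const int idx = ix + nx * j + nxy * iz;
        acc[iz * nx + ix] += rotA[idx] * att[idx];
      }
  }
  std::vector<double> kend;
  if (use_psf && m.sig2_px[ny - 1] > 1e-12) {
    kend = gauss_kernel(std::sqrt(m.sig2_px[ny - 1]));
    blur_plane(acc.data(), nx, nz, kend, scratch);
  }
  // ratio in count units
  std::vector<double> tmp((size_t)nx * nz);
  for (int i = 0; i < nx * nz; ++i) {
    const double yi = y[i];
    tmp[i] = (yi == 0.0) ? 0.0 : yi / std::max(acc[i] * scale, 1e-10);
  }
  // backprojection (transpose chain)
  if (!kend.empty()) blur_plane(tmp.data(), nx, nz, kend, scratch);
  std::vector<double> rotOut((size_t)nx * ny * nz, 0.0);
  for (int j = ny - 1; j >= 0; --j) {
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix) {
        const int idx = ix + nx * j + nxy * iz;
        rotOut[idx] = tmp[iz * nx + ix] * att[idx];
      }
    if (use_psf && j > 0 && !kstep[j].empty())
      blur_plane(tmp.data(), nx, nz, kstep[j], scratch);
  }
  NumericVector out((size_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), 0.0);
  rotate_scatter(rotOut.data(), REAL(out), nx, ny, nz, th);
  out.attr("dim") = dims;
  return out;
}
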