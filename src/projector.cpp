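// SPECT parallel-beam projector core.
//
// Geometry convention: volume axes are (x = LR, y = AP, z = CC); the camera
// rotates about z. For a projection at angle `ang` (radians) the volume is
// rotated by -ang so that the detector lies on the +y side; detector axes are
// then u = x, v = z with one detector bin per voxel column (bin size = in-plane
// voxel spacing, which must be isotropic in x/y).
//
// The backprojector is the exact algebraic transpose of the forward projector
// (same bilinear weights, same attenuation factors, same symmetric normalized
// Gaussian kernels), so <Ax, y> == <x, A^T y> up to float rounding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double FWHM_TO_SIGMA = 2.354820045030949; // 2*sqrt(2*log(2))

// ---------------------------------------------------------------- rotation --

// Pull-back bilinear rotation about the z axis by angle `a` (counterclockwise
// in the xy plane), zero outside the grid. Rotation center is the grid center.
static cube rotate_z_pull(const cube& v, double a) {
  const uword nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  cube out(nx, ny, nz, fill::zeros);
  const double cx = 0.5 * (double)(nx - 1), cy = 0.5 * (double)(ny - 1);
  const double ca = std::cos(a), sa = std::sin(a);
  for (uword j = 0; j < ny; ++j) {
    for (uword i = 0; i < nx; ++i) {
      // sample source at R(-a) * (xc, yc)
      const double xc = (double)i - cx, yc = (double)j - cy;
      const double xs = ca * xc + sa * yc + cx;
      const double ys = -sa * xc + ca * yc + cy;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      const double w01 = (1 - fx) * fy, w11 = fx * fy;
      for (uword k = 0; k < nz; ++k) {
        double acc = 0.0;
        if (x0 >= 0 && x0 < (int)nx && y0 >= 0 && y0 < (int)ny)
          acc += w00 * v((uword)x0, (uword)y0, k);
        if (x0 + 1 >= 0 && x0 + 1 < (int)nx && y0 >= 0 && y0 < (int)ny)
          acc += w10 * v((uword)(x0 + 1), (uword)y0, k);
        if (x0 >= 0 && x0 < (int)nx && y0 + 1 >= 0 && y0 + 1 < (int)ny)
          acc += w01 * v((uword)x0, (uword)(y0 + 1), k);
        if (x0 + 1 >= 0 && x0 + 1 < (int)nx && y0 + 1 >= 0 && y0 + 1 < (int)ny)
          acc += w11 * v((uword)(x0 + 1), (uword)(y0 + 1), k);
        out(i, j, k) = acc;
      }
    }
  }
  return out;
}

// Transpose of rotate_z_pull(., a): splat each rotated-grid value back into
// the source grid with the same bilinear weights.
static cube rotate_z_push(const cube& v, double a) {
  const uword nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  cube out(nx, ny, nz, fill::zeros);
  const double cx = 0.5 * (double)(nx - 1), cy = 0.5 * (double)(ny - 1);
  const double ca = std::cos(a), sa = std::sin(a);
  for (uword j = 0; j < ny; ++j) {
    for (uword i = 0; i < nx; ++i) {
      const double xc = (double)i - cx, yc = (double)j - cy;
      const double xs = ca * xc + sa * yc + cx;
      const double ys = -sa * xc + ca * yc + cy;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const double fx = xs - x0, fy = ys - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      const double w01 = (1 - fx) * fy, w11 = fx * fy;
      for (uword k = 0; k < nz; ++k) {
        const double val = v(i, j, k);
        if (val == 0.0) continue;
        if (x0 >= 0 && x0 < (int)nx && y0 >= 0 && y0 < (int)ny)
          out((uword)x0, (uword)y0, k) += w00 * val;
        if (x0 + 1 >= 0 && x0 + 1 < (int)nx && y0 >= 0 && y0 < (int)ny)
          out((uword)(x0 + 1), (uword)y0, k) += w10 * val;
        if (x0 >= 0 && x0 < (int)nx && y0 + 1 >= 0 && y0 + 1 < (int)ny)
          out((uword)x0, (uword)(y0 + 1), k) += w01 * val;
        if (x0 + 1 >= 0 && x0 + 1 < (int)nx && y0 + 1 >= 0 && y0 + 1 < (int)ny)
          out((uword)(x0 + 1), (uword)(y0 + 1), k) += w11 * val;
      }
    }
  }
  return out;
}

// ------------------------------------------------------------------ blur ----

static vec gauss_kernel(double sigma) {
  if (sigma <= 1e-8) return vec(1, fill::ones);
  int r = (int)std::ceil(3.0 * sigma);
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
  k /= accu(k); // normalized, symmetric -> self-adjoint with zero padding
  return k;
}

// separable blur of a (nu x nv) plane, zero padded
static mat blur_plane(const mat& p, double sig_u, double sig_v) {
  const uword nu = p.n_rows, nv = p.n_cols;
  mat tmp = p;
  if (sig_u > 1e-8) {
    vec k = gauss_kernel(sig_u);
    const int r = ((int)k.n_elem - 1) / 2;
    mat t2(nu, nv, fill::zeros);
    for (uword v2 = 0; v2 < nv; ++v2)
      for (uword u = 0; u < nu; ++u) {
        const double val = tmp(u, v2);
        if (val == 0.0) continue;
        const int lo = std::max(0, (int)u - r), hi = std::min((int)nu - 1, (int)u + r);
        for (int uu = lo; uu <= hi; ++uu) t2((uword)uu, v2) += val * k(uu - (int)u + r);
      }
    tmp = t2;
  }
  if (sig_v > 1e-8) {
    vec k = gauss_kernel(sig_v);
    const int r = ((int)k.n_elem - 1) / 2;
    mat t2(nu, nv, fill::zeros);
    for (uword v2 = 0; v2 < nv; ++v2)
      for (uword u = 0; u < nu; ++u) {
        const double val = tmp(u, v2);
        if (val == 0.0) continue;
        const int lo = std::max(0, (int)v2 - r), hi = std::min((int)nv - 1, (int)v2 + r);
        for (int vv = lo; vv <= hi; ++vv) t2(u, (uword)vv) += val * k(vv - (int)v2 + r);
      }
    tmp = t2;
  }
  return tmp;
}

// [[Rcpp::export]]
arma::mat blur2_cpp(const arma::mat& p, double sig_u, double sig_v) {
  return blur_plane(p, sig_u, sig_v);
}

// ------------------------------------------------------- attenuation weights -

// w(i,j,k) = exp(-(sum_{j'>j} mu*dy + 0.5*mu(i,j,k)*dy)) in the rotated frame
// (detector on the +y side).
static cube atten_weights(const cube& rmu, double dy) {
  const uword nx = rmu.n_rows, ny = rmu.n_cols, nz = rmu.n_slices;
  cube w(nx, ny, nz);
  for (uword k = 0; k < nz; ++k)
    for (uword i = 0; i < nx; ++i) {
      double cum = 0.0;
      for (int j = (int)ny - 1; j >= 0; --j) {
        const double m = rmu(i, (uword)j, k) * dy;
        w(i, (uword)j, k) = std::exp(-(cum + 0.5 * m));
        cum += m;
      }
    }
  return w;
}

// --------------------------------------------------------------- projector --

// [[Rcpp::export]]
arma::mat forward_project_cpp(const arma::cube& act, const arma::cube& mu,
                              double ang, double dx, double dy, double dz,
                              double det_dist, double fwhm0, double fwhm_slope,
                              bool use_att, bool use_psf) {
  const uword nx = act.n_rows, ny = act.n_cols, nz = act.n_slices;
  cube ra = rotate_z_pull(act, -ang);
  cube w;
  if (use_att) w = atten_weights(rotate_z_pull(mu, -ang), dy);
  const double cy = 0.5 * (double)(ny - 1);
  mat proj(nx, nz, fill::zeros);
  mat plane(nx, nz);
  for (uword j = 0; j < ny; ++j) {
    for (uword k = 0; k < nz; ++k)
      for (uword i = 0; i < nx; ++i)
        plane(i, k) = use_att ? ra(i, j, k) * w(i, j, k) : ra(i, j, k);
    if (use_psf) {
      const double d = det_dist - ((double)j - cy) * dy;
      double fw = fwhm0 + fwhm_slope * d;
      if (fw < 0.1) fw = 0.1;
      plane = blur_plane(plane, fw / FWHM_TO_SIGMA / dx, fw / FWHM_TO_SIGMA / dz);
    }
    proj += plane;
  }
  return proj;
}

// [[Rcpp::export]]
arma::cube back_project_cpp(const arma::mat& proj, const arma::cube& mu,
                            double ang, double dx, double dy, double dz,
                            double det_dist, double fwhm0, double fwhm_slope,
                            bool use_att, bool use_psf, int nx_, int ny_, int nz_) {
  const uword nx = (uword)nx_, ny = (uword)ny_, nz = (uword)nz_;
  cube w;
  if (use_att) w = atten_weights(rotate_z_pull(mu, -ang), dy);
  const double cy = 0.5 * (double)(ny - 1);
  cube vol(nx, ny, nz, fill::zeros);
  for (uword j = 0; j < ny; ++j) {
    mat plane = proj;
    if (use_psf) {
      const double d = det_dist - ((double)j - cy) * dy;
      double fw = fwhm0 + fwhm_slope * d;
      if (fw < 0.1) fw = 0.1;
      plane = blur_plane(plane, fw / FWHM_TO_SIGMA / dx, fw / FWHM_TO_SIGMA / dz);
    }
    for (uword k = 0; k < nz; ++k)
      for (uword i = 0; i < nx; ++i)
        vol(i, j, k) = use_att ? plane(i, k) * w(i, j, k) : plane(i, k);
  }
  return rotate_z_push(vol, -ang);
}

// -------------------------------------------------------------- 2D affine ---

// Pull-back bilinear affine resampling of a plane about its center:
// out(u,v) = in(m11*uc + m12*vc + tu + cu, m21*uc + m22*vc + tv + cv),
// p = (m11, m12, m21, m22, tu, tv) in bin units.
// [[Rcpp::export]]
arma::mat affine_resample2_cpp(const arma::mat& img, const arma::vec& p) {
  const uword nu = img.n_rows, nv = img.n_cols;
  const double cu = 0.5 * (double)(nu - 1), cv = 0.5 * (double)(nv - 1);
  mat out(nu, nv, fill::zeros);
  for (uword v2 = 0; v2 < nv; ++v2)
    for (uword u = 0; u < nu; ++u) {
      const double uc = (double)u - cu, vc = (double)v2 - cv;
      const double us = p(0) * uc + p(1) * vc + p(4) + cu;
      const double vs = p(2) * uc + p(3) * vc + p(5) + cv;
      const int u0 = (int)std::floor(us), v0 = (int)std::floor(vs);
      const double fu = us - u0, fv = vs - v0;
      double acc = 0.0;
      if (u0 >= 0 && u0 < (int)nu && v0 >= 0 && v0 < (int)nv)
        acc += (1 - fu) * (1 - fv) * img((uword)u0, (uword)v0);
      if (u0 + 1 < (int)nu && u0 + 1 >= 0 && v0 >= 0 && v0 < (int)nv)
        acc += fu * (1 - fv) * img((uword)(u0 + 1), (uword)v0);
      if (u0 >= 0 && u0 < (int)nu && v0 + 1 < (int)nv && v0 + 1 >= 0)
        acc += (1 - fu) * fv * img((uword)u0, (uword)(v0 + 1));
      if (u0 + 1 < (int)nu && u0 + 1 >= 0 && v0 + 1 < (int)nv && v0 + 1 >= 0)
        acc += fu * fv * img((uword)(u0 + 1), (uword)(v0 + 1));
      out(u, v2) = acc;
    }
  return out;
}

// Bilinear splatting of unit-weight events at continuous 0-based detector
// coordinates; events falling fully outside the detector are dropped.
// [[Rcpp::export]]
Rcpp::List splat_events_cpp(const arma::vec& u, const arma::vec& v,
                            int nu_, int nv_) {
  const int nu = nu_, nv = nv_;
  mat out(nu, nv, fill::zeros);
  int dropped = 0;
  double placed = 0.0;
  for (uword e = 0; e < u.n_elem; ++e) {
    const int u0 = (int)std::floor(u(e)), v0 = (int)std::floor(v(e));
    const double fu = u(e) - u0, fv = v(e) - v0;
    bool any = false;
    if (u0 >= 0 && u0 < nu && v0 >= 0 && v0 < nv) { out(u0, v0) += (1 - fu) * (1 - fv); placed += (1 - fu) * (1 - fv); any = true; }
    if (u0 + 1 >= 0 && u0 + 1 < nu && v0 >= 0 && v0 < nv) { out(u0 + 1, v0) += fu * (1 - fv); placed += fu * (1 - fv); any = true; }
    if (u0 >= 0 && u0 < nu && v0 + 1 >= 0 && v0 + 1 < nv) { out(u0, v0 + 1) += (1 - fu) * fv; placed += (1 - fu) * fv; any = true; }
    if (u0 + 1 >= 0 && u0 + 1 < nu && v0 + 1 >= 0 && v0 + 1 < nv) { out(u0 + 1, v0 + 1) += fu * fv; placed += fu * fv; any = true; }
    if (!any) ++dropped;
  }
  return Rcpp::List::create(Rcpp::Named("counts") = out,
                            Rcpp::Named("dropped") = dropped,
                            Rcpp::Named("placed") = placed);
}

// ----------------------------------------------------------- 3D translate ---

// Pull-back trilinear translation: out(x) = v(x + t), t in voxel units.
// [[Rcpp::export]]
arma::cube translate3_cpp(const arma::cube& v, double tx, double ty, double tz) {
  const uword nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  cube out(nx, ny, nz, fill::zeros);
  for (uword k = 0; k < nz; ++k) {
    const double zs = (double)k + tz;
    const int z0 = (int)std::floor(zs);
    const double fz = zs - z0;
    if (z0 < -1 || z0 > (int)nz - 1) continue;
    for (uword j = 0; j < ny; ++j) {
      const double ys = (double)j + ty;
      const int y0 = (int)std::floor(ys);
      const double fy = ys - y0;
      if (y0 < -1 || y0 > (int)ny - 1) continue;
      for (uword i = 0; i < nx; ++i) {
        const double xs = (double)i + tx;
        const int x0 = (int)std::floor(xs);
        const double fx = xs - x0;
        if (x0 < -1 || x0 > (int)nx - 1) continue;
        double acc = 0.0;
        for (int dz2 = 0; dz2 <= 1; ++dz2) {
          const int zz = z0 + dz2;
          if (zz < 0 || zz >= (int)nz) continue;
          const double wz = dz2 ? fz : 1 - fz;
          for (int dy2 = 0; dy2 <= 1; ++dy2) {
            const int yy = y0 + dy2;
            if (yy < 0 || yy >= (int)ny) continue;
            const double wy = dy2 ? fy : 1 - fy;
            for (int dx2 = 0; dx2 <= 1; ++dx2) {
              const int xx = x0 + dx2;
              if (xx < 0 || xx >= (int)nx) continue;
              const double wx = dx2 ? fx : 1 - fx;
              acc += wx * wy * wz * v((uword)xx, (uword)yy, (uword)zz);
            }
          }
        }
        out(i, j, k) = acc;
      }
    }
  }
  return out;
}

// ------------------------------------------------------------- distances ----

// Minimum Euclidean distance from each row of A to the point set B (both in mm).
// [[Rcpp::export]]
arma::vec min_dist_to_set_cpp(const arma::mat& A, const arma::mat& B) {
  vec out(A.n_rows);
  for (uword i = 0; i < A.n_rows; ++i) {
    double best = datum::inf;
    for (uword j = 0; j < B.n_rows; ++j) {
      const double d0 = A(i, 0) - B(j, 0), d1 = A(i, 1) - B(j, 1), d2 = A(i, 2) - B(j, 2);
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}

// ------------------------------------------------------------ convolution ---

// Direct 3D convolution with a small kernel (odd dims), zero padded.
// [[Rcpp::export]]
arma::cube conv3_cpp(const arma::cube& v, const arma::cube& k) {
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  const int rx = ((int)k.n_rows - 1) / 2, ry = ((int)k.n_cols - 1) / 2,
            rz = ((int)k.n_slices - 1) / 2;
  cube out(nx, ny, nz, fill::zeros);
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii) {
        const double val = v(ii, jj, kk);
        if (val == 0.0) continue;
        const int xlo = std::max(0, ii - rx), xhi = std::min(nx - 1, ii + rx);
        const int ylo = std::max(0, jj - ry), yhi = std::min(ny - 1, jj + ry);
        const int zlo = std::max(0, kk - rz), zhi = std::min(nz - 1, kk + rz);
        for (int z2 = zlo; z2 <= zhi; ++z2)
          for (int y2 = ylo; y2 <= yhi; ++y2)
            for (int x2 = xlo; x2 <= xhi; ++x2)
              out(x2, y2, z2) += val * k(x2 - ii + rx, y2 - jj + ry, z2 - kk + rz);
      }
  return out;
}
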