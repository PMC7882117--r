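#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Siddon / Amanatides-Woo traversal of a 2-D pixel grid by an infinite line
// through (ox, oy) with unit direction (dx, dy). Grid: nx x ny pixels of size
// (sx, sy) mm, lower corner (x0, y0). Appends 0-based linear pixel indices
// (ix + iy*nx) and intersection lengths (mm) to idx/len.
static void trace_ray(double ox, double oy, double dx, double dy,
                      int nx, int ny, double sx, double sy,
                      double x0, double y0,
                      std::vector<int> &idx, std::vector<double> &len) {
  const double xmin = x0, xmax = x0 + nx * sx;
  const double ymin = y0, ymax = y0 + ny * sy;
  double t0 = -1e30, t1 = 1e30;
  if (std::fabs(dx) < 1e-14) {
    if (ox <= xmin || ox >= xmax) return;
  } else {
    double ta = (xmin - ox) / dx, tb = (xmax - ox) / dx;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(dy) < 1e-14) {
    if (oy <= ymin || oy >= ymax) return;
  } else {
    double ta = (ymin - oy) / dy, tb = (ymax - oy) / dy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (t0 >= t1) return;

  const double eps = 1e-12 * (t1 - t0 + 1.0);
  double px = ox + (t0 + eps) * dx, py = oy + (t0 + eps) * dy;
  int ix = (int)std::floor((px - x0) / sx);
  int iy = (int)std::floor((py - y0) / sy);
  if (ix < 0) ix = 0;
  if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0;
  if (iy > ny - 1) iy = ny - 1;

  int stepx = (dx > 1e-14) ? 1 : ((dx < -1e-14) ? -1 : 0);
  int stepy = (dy > 1e-14) ? 1 : ((dy < -1e-14) ? -1 : 0);
  double tMaxX = 1e30, tMaxY = 1e30, tDX = 1e30, tDY = 1e30;
  if (stepx != 0) {
    double bound = x0 + (stepx > 0 ? (ix + 1) : ix) * sx;
    tMaxX = (bound - ox) / dx;
    tDX = sx / std::fabs(dx);
  }
  if (stepy != 0) {
    double bound = y0 + (stepy > 0 ? (iy + 1) : iy) * sy;
    tMaxY = (bound - oy) / dy;
    tDY = sy / std::fabs(dy);
  }

  double t = t0;
  while (t < t1 - 1e-12) {
    double tnext = std::min(std::min(tMaxX, tMaxY), t1);
    double seg = tnext - t;
    if (seg > 0) {
      idx.push_back(ix + iy * nx);
      len.push_back(seg);
    }
    bool stepX = (tMaxX <= tMaxY) && (tMaxX <= t1 + 1e-12);
    bool stepY = (tMaxY <= tMaxX) && (tMaxY <= t1 + 1e-12);
    if (stepX) { ix += stepx; tMaxX += tDX; }
    if (stepY) { iy += stepy; tMaxY += tDY; }
    t = tnext;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
}

// [[Rcpp::export]]
List cpp_siddon_trace(double ox, double oy, double dx, double dy,
                      int nx, int ny, double sx, double sy,
                      double x0, double y0) {
  double norm = std::sqrt(dx * dx + dy * dy);
  if (norm < 1e-300) stop("ray direction must be non-zero");
  std::vector<int> idx; std::vector<double> len;
  trace_ray(ox, oy, dx / norm, dy / norm, nx, ny, sx, sy, x0, y0, idx, len);
  IntegerVector out_i(idx.size());
  NumericVector out_l(len.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    out_i[k] = idx[k] + 1;  // 1-based linear index into the R matrix
    out_l[k] = len[k];
  }
  return List::create(_["index"] = out_i, _["length"] = out_l);
}

// Parallel-beam geometry: view angle theta, detector bin j (0-based) at
// signed offset s = (j - (nbins-1)/2) * pitch; ray through (s cos, s sin)
// with direction (-sin, cos).

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles,
                                  int nbins, double pitch, double spacing) {
  int nx = img.nrow(), ny = img.ncol(), nv = angles.size();
  double x0 = -nx * spacing / 2.0, y0 = -ny * spacing / 2.0;
  NumericMatrix sino(nv, nbins);
  std::vector<int> idx; std::vector<double> len;
  for (int v = 0; v < nv; ++v) {
    double c = std::cos(angles[v]), s = std::sin(angles[v]);
    for (int j = 0; j < nbins; ++j) {
      double off = (j - (nbins - 1) / 2.0) * pitch;
      idx.clear(); len.clear();
      trace_ray(off * c, off * s, -s, c, nx, ny, spacing, spacing,
                x0, y0, idx, len);
      double acc = 0;
      for (size_t k = 0; k < idx.size(); ++k) acc += img[idx[k]] * len[k];
      sino(v, j) = acc;
    }
  }
  return sino;
}

// Exact transpose of cpp_forward_project (ray-driven backprojection):
// used for adjoint-consistency and as A^T in algebraic checks.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_ray(NumericMatrix sino, NumericVector angles,
                                  double pitch, int nx, int ny,
                                  double spacing) {
  int nv = angles.size(), nbins = sino.ncol();
  double x0 = -nx * spacing / 2.0, y0 = -ny * spacing / 2.0;
  NumericMatrix img(nx, ny);
  std::vector<int> idx; std::vector<double> len;
  for (int v = 0; v < nv; ++v) {
    double c = std::cos(angles[v]), s = std::sin(angles[v]);
    for (int j = 0; j < nbins; ++j) {
      double val = sino(v, j);
      if (val == 0) continue;
      double off = (j - (nbins - 1) / 2.0) * pitch;
      idx.clear(); len.clear();
      trace_ray(off * c, off * s, -s, c, nx, ny, spacing, spacing,
                x0, y0, idx, len);
      for (size_t k = 0; k < idx.size(); ++k) img[idx[k]] += val * len[k];
    }
  }
  return img;
}

// Pixel-driven backprojection with linear detector interpolation: the
// textbook backprojection operator used inside filtered backprojection.
// Returns the plain sum over views; the caller applies the d_theta scaling.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_pixel(NumericMatrix q, NumericVector angles,
                                    double pitch, int nx, int ny,
                                    double spacing) {
  int nv = angles.size(), nbins = q.ncol();
  NumericMatrix img(nx, ny);
  double cx = (nx + 1) / 2.0, cy = (ny + 1) / 2.0;
  double det_c = (nbins - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    double c = std::cos(angles[v]), s = std::sin(angles[v]);
    for (int iy = 0; iy < ny; ++iy) {
      double y = (iy + 1 - cy) * spacing;
      for (int ix = 0; ix < nx; ++ix) {
        double x = (ix + 1 - cx) * spacing;
        double u = (x * c + y * s) / pitch + det_c;  // fractional bin
        int j0 = (int)std::floor(u);
        if (j0 < 0 || j0 >= nbins - 1) continue;
        double w = u - j0;
        img(ix, iy) += (1 - w) * q(v, j0) + w * q(v, j0 + 1);
      }
    }
  }
  return img;
}
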