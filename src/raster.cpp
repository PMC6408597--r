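#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimal z-buffer triangle rasterizer with Gouraud (per-vertex)
// Lambertian shading and an optional per-pixel cast-shadow test done by
// ray-marching a height field along the light's horizontal direction.
//
// World units are cm. The image plane is z = 0; the eye sits at
// `eye` (ez > 0) looking towards -z. A world point projects through the
// eye onto the plane, and plane coordinates map linearly to pixels:
// the plane window spans [-half_w, half_w] x [-half_h, half_h].
// Depth is distance from the eye along the viewing axis (ez - z), so
// smaller depth = nearer. Triangles are assumed small relative to the
// scene depth range; attributes (incl. depth) are interpolated affinely
// in screen space.

static inline bool shadow_free(const NumericMatrix& hf, double x0, double y0,
                               double cell, double hfmax, double x, double y,
                               double z, double lhx, double lhy,
                               double tan_elev, double bias) {
  int nx = hf.nrow(), ny = hf.ncol();
  double t = cell;
  while (true) {
    double h = z + t * tan_elev + bias;
    if (h > hfmax) return true;
    double sx = x + t * lhx, sy = y + t * lhy;
    int ix = (int)std::floor((sx - x0) / cell);
    int iy = (int)std::floor((sy - y0) / cell);
    if (ix < 0 || iy < 0 || ix >= nx || iy >= ny) return true;
    if (hf(ix, iy) > h) return false;
    t += cell;
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_render(const NumericMatrix& V, const IntegerMatrix& F,
                const NumericMatrix& C, const NumericMatrix& Nrm,
                const IntegerVector& obj, const NumericVector& eye,
                double half_w, double half_h, int wpx, int hpx,
                int light_kind, const NumericVector& ldir,
                double ambient_floor, bool shadows, const NumericMatrix& hf,
                double hf_x0, double hf_y0, double hf_cell, double tan_elev,
                double lhx, double lhy, double shadow_bias) {
  const int nv = V.nrow(), nf = F.nrow();
  const double ex = eye[0], ey = eye[1], ez = eye[2];

  // project vertices to continuous pixel coordinates
  std::vector<double> sx(nv), sy(nv), dep(nv), inten(nv);
  for (int i = 0; i < nv; ++i) {
    double z = V(i, 2);
    double t = ez / (ez - z);
    double px = ex + (V(i, 0) - ex) * t;
    double py = ey + (V(i, 1) - ey) * t;
    sx[i] = (px + half_w) / (2.0 * half_w) * wpx;
    sy[i] = (half_h - py) / (2.0 * half_h) * hpx;
    dep[i] = ez - z;
    if (light_kind == 0) {
      inten[i] = 0.5 * (1.0 + Nrm(i, 2));  // uniform upper-hemisphere light
    } else {
      double d = Nrm(i, 0) * ldir[0] + Nrm(i, 1) * ldir[1] +
                 Nrm(i, 2) * ldir[2];
      inten[i] = d > 0.0 ? d : 0.0;
    }
  }

  NumericMatrix zbuf(hpx, wpx), ar(hpx, wpx), ag(hpx, wpx), ab(hpx, wpx),
      sh(hpx, wpx);
  IntegerMatrix ob(hpx, wpx);
  std::fill(zbuf.begin(), zbuf.end(), R_PosInf);

  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double x0 = sx[a], y0 = sy[a], x1 = sx[b], y1 = sy[b], x2 = sx[c],
           y2 = sy[c];
    double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    int jmin = std::max(0, (int)std::floor(std::min({x0, x1, x2}) - 0.5));
    int jmax = std::min(wpx - 1, (int)std::ceil(std::max({x0, x1, x2}) - 0.5));
    int imin = std::max(0, (int)std::floor(std::min({y0, y1, y2}) - 0.5));
    int imax = std::min(hpx - 1, (int)std::ceil(std::max({y0, y1, y2}) - 0.5));
    if (jmin > jmax || imin > imax) continue;
    double inv = 1.0 / area;
    const double eps = -1e-9;  // tolerate shared-edge roundoff (no cracks)
    for (int j = jmin; j <= jmax; ++j) {  // column-outer: matrices are
      double pxc = j + 0.5;               // column-major
      for (int i = imin; i <= imax; ++i) {
        double pyc = i + 0.5;
        double w0 = ((x1 - pxc) * (y2 - pyc) - (x2 - pxc) * (y1 - pyc)) * inv;
        double w1 = ((x2 - pxc) * (y0 - pyc) - (x0 - pxc) * (y2 - pyc)) * inv;
        double w2 = 1.0 - w0 - w1;
        if (w0 < eps || w1 < eps || w2 < eps) continue;
        double d = w0 * dep[a] + w1 * dep[b] + w2 * dep[c];
        if (d >= zbuf(i, j)) continue;
        zbuf(i, j) = d;
        ar(i, j) = w0 * C(a, 0) + w1 * C(b, 0) + w2 * C(c, 0);
        ag(i, j) = w0 * C(a, 1) + w1 * C(b, 1) + w2 * C(c, 1);
        ab(i, j) = w0 * C(a, 2) + w1 * C(b, 2) + w2 * C(c, 2);
        sh(i, j) = w0 * inten[a] + w1 * inten[b] + w2 * inten[c];
        ob(i, j) = obj[f];
      }
    }
  }

  // combine shading; reconstruct world position from depth for shadows
  double hfmax = 0.0;
  if (shadows) {
    for (int k = 0; k < hf.size(); ++k)
      if (hf[k] > hfmax) hfmax = hf[k];
  }
  NumericMatrix R(hpx, wpx), G(hpx, wpx), B(hpx, wpx);
  for (int j = 0; j < wpx; ++j) {
    for (int i = 0; i < hpx; ++i) {
      if (ob(i, j) == 0) {
        zbuf(i, j) = NA_REAL;
        continue;
      }
      double gain;
      if (light_kind == 0) {
        gain = sh(i, j);
      } else {
        double vis = 1.0;
        if (shadows) {
          double z = ez - zbuf(i, j);
          double t = ez / (ez - z);
          double px = (j + 0.5) / (double)wpx * 2.0 * half_w - half_w;
          double py = half_h - (i + 0.5) / (double)hpx * 2.0 * half_h;
          double x = ex + (px - ex) / t;
          double y = ey + (py - ey) / t;
          vis = shadow_free(hf, hf_x0, hf_y0, hf_cell, hfmax, x, y, z, lhx,
                            lhy, tan_elev, shadow_bias)
                    ? 1.0
                    : 0.0;
        }
        gain = ambient_floor + (1.0 - ambient_floor) * sh(i, j) * vis;
      }
      R(i, j) = std::min(1.0, ar(i, j) * gain);
      G(i, j) = std::min(1.0, ag(i, j) * gain);
      B(i, j) = std::min(1.0, ab(i, j) * gain);
    }
  }
  return List::create(_["r"] = R, _["g"] = G, _["b"] = B, _["depth"] = zbuf,
                      _["obj"] = ob);
}
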