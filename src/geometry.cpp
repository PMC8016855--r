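#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, ch. 5.1.5). Returns squared distance; closest point in out[3].
static double closest_pt_tri(const double *p, const double *a,
                             const double *b, const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
  } else {
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) out[i] = b[i];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
      } else {
        double cp[3];
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
        double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) out[i] = c[i];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i)
                out[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i)
                out[i] = a[i] + ab[i] * v + ac[i] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - out[0], dy = p[1] - out[1], dz = p[2] - out[2];
  return dx * dx + dy * dy + dz * dz;
}

// For each query point, closest point on the triangulated surface (V, F).
// F is 1-based. Brute force over triangles with bounding-sphere pruning.
// [[Rcpp::export]]
List cpp_closest_on_surface(NumericMatrix P, NumericMatrix V,
                            IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector face(np);

  // triangle centroids and circumscribed bound radius for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), cr(nf);
  std::vector<double> tri(9 * nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double *t = &tri[9 * f];
    t[0] = V(i0, 0); t[1] = V(i0, 1); t[2] = V(i0, 2);
    t[3] = V(i1, 0); t[4] = V(i1, 1); t[5] = V(i1, 2);
    t[6] = V(i2, 0); t[7] = V(i2, 1); t[8] = V(i2, 2);
    cx[f] = (t[0] + t[3] + t[6]) / 3.0;
    cy[f] = (t[1] + t[4] + t[7]) / 3.0;
    cz[f] = (t[2] + t[5] + t[8]) / 3.0;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dx = t[3 * k] - cx[f], dy = t[3 * k + 1] - cy[f],
             dz = t[3 * k + 2] - cz[f];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    cr[f] = std::sqrt(r2);
  }

  double out[3];
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    double best = R_PosInf;
    int bestf = -1;
    double bx = 0, by = 0, bz = 0;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - cr[f];
      if (dc > 0 && dc * dc >= best) continue;
      const double *t = &tri[9 * f];
      double d2 = closest_pt_tri(p, t, t + 3, t + 6, out);
      if (d2 < best) {
        best = d2;
        bestf = f;
        bx = out[0]; by = out[1]; bz = out[2];
      }
    }
    dist[ip] = std::sqrt(best);
    closest(ip, 0) = bx; closest(ip, 1) = by; closest(ip, 2) = bz;
    face[ip] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}

// Moller-Trumbore ray/triangle intersection. For each origin+direction,
// does the ray hit any listed face within max_len? Returns hit flag and
// the parametric distance of the nearest hit (Inf when none). With
// cull_backfaces, only front-side hits count: the triangle's outward
// normal must oppose the ray direction (mated surfaces face each other).
// [[Rcpp::export]]
List cpp_ray_hits(NumericMatrix O, NumericMatrix D, NumericMatrix V,
                  IntegerMatrix F, double max_len,
                  bool cull_backfaces = true) {
  const double EPS = 1e-12;
  int no = O.nrow(), nf = F.nrow();
  LogicalVector hit(no);
  NumericVector tmin(no);
  std::vector<double> tri(9 * nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double *t = &tri[9 * f];
    t[0] = V(i0, 0); t[1] = V(i0, 1); t[2] = V(i0, 2);
    t[3] = V(i1, 0); t[4] = V(i1, 1); t[5] = V(i1, 2);
    t[6] = V(i2, 0); t[7] = V(i2, 1); t[8] = V(i2, 2);
  }
  for (int io = 0; io < no; ++io) {
    double o[3] = {O(io, 0), O(io, 1), O(io, 2)};
    double d[3] = {D(io, 0), D(io, 1), D(io, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double *t = &tri[9 * f];
      double e1[3], e2[3];
      for (int k = 0; k < 3; ++k) {
        e1[k] = t[3 + k] - t[k];
        e2[k] = t[6 + k] - t[k];
      }
      double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                      d[2] * e2[0] - d[0] * e2[2],
                      d[0] * e2[1] - d[1] * e2[0]};
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      // det = e1.(d x e2) = -d.n, so front-side hits (ray opposing the
      // face normal, d.n < 0) have det > 0
      if (cull_backfaces ? (det < EPS) : (std::fabs(det) < EPS))
        continue;
      double inv = 1.0 / det;
      double tv[3] = {o[0] - t[0], o[1] - t[1], o[2] - t[2]};
      double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                      tv[2] * e1[0] - tv[0] * e1[2],
                      tv[0] * e1[1] - tv[1] * e1[0]};
      double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double tt = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
      if (tt > 1e-9 && tt <= max_len && tt < best) best = tt;
    }
    hit[io] = R_finite(best);
    tmin[io] = best;
  }
  return List::create(_["hit"] = hit, _["t"] = tmin);
}
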