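#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a, b, c) to p. Ericson, Real-Time Collision
// Detection, 5.1.5.
static inline void closestOnTri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// [[Rcpp::export(name = ".closest_point_on_mesh")]]
List closest_point_on_mesh(NumericMatrix query, NumericMatrix verts,
                           IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  NumericMatrix out(nq, 3);
  NumericVector dist(nq);
  std::vector<double> vx(verts.nrow()), vy(verts.nrow()), vz(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    double best = R_PosInf, bestPt[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      double a[3] = {vx[ia], vy[ia], vz[ia]};
      double b[3] = {vx[ib], vy[ib], vz[ib]};
      double c[3] = {vx[ic], vy[ic], vz[ic]};
      // cheap reject: squared distance to triangle's bounding sphere center
      double cx = (a[0] + b[0] + c[0]) / 3.0, cy = (a[1] + b[1] + c[1]) / 3.0,
             cz = (a[2] + b[2] + c[2]) / 3.0;
      double dc = (p[0] - cx) * (p[0] - cx) + (p[1] - cy) * (p[1] - cy) +
                  (p[2] - cz) * (p[2] - cz);
      double ra = (a[0] - cx) * (a[0] - cx) + (a[1] - cy) * (a[1] - cy) +
                  (a[2] - cz) * (a[2] - cz);
      double rb = (b[0] - cx) * (b[0] - cx) + (b[1] - cy) * (b[1] - cy) +
                  (b[2] - cz) * (b[2] - cz);
      double rc = (c[0] - cx) * (c[0] - cx) + (c[1] - cy) * (c[1] - cy) +
                  (c[2] - cz) * (c[2] - cz);
      double rmax = std::sqrt(std::max(ra, std::max(rb, rc)));
      double lower = std::sqrt(dc) - rmax;
      if (lower > 0 && lower * lower >= best) continue;
      double pt[3];
      closestOnTri(p, a, b, c, pt);
      double d = (p[0] - pt[0]) * (p[0] - pt[0]) +
                 (p[1] - pt[1]) * (p[1] - pt[1]) +
                 (p[2] - pt[2]) * (p[2] - pt[2]);
      if (d < best) {
        best = d;
        bestPt[0] = pt[0]; bestPt[1] = pt[1]; bestPt[2] = pt[2];
      }
    }
    out(q, 0) = bestPt[0]; out(q, 1) = bestPt[1]; out(q, 2) = bestPt[2];
    dist[q] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["distance"] = dist);
}
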