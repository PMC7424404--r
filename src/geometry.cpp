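#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// closest point on triangle (a,b,c) to p -- Ericson, Real-Time Collision Detection
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export]]
List cpp_closest_mesh(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericVector dist(nq);
  NumericMatrix pts(nq, 3);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) { vx[i] = V(i,0); vy[i] = V(i,1); vz[i] = V(i,2); }
  // per-triangle bounding spheres for cheap pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int t = 0; t < nf; ++t) {
    int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
    cx[t] = (vx[i0]+vx[i1]+vx[i2])/3.0;
    cy[t] = (vy[i0]+vy[i1]+vy[i2])/3.0;
    cz[t] = (vz[i0]+vz[i1]+vz[i2])/3.0;
    double r2 = 0.0;
    const int ii[3] = {i0, i1, i2};
    for (int k = 0; k < 3; ++k) {
      double dx = vx[ii[k]]-cx[t], dy = vy[ii[k]]-cy[t], dz = vz[ii[k]]-cz[t];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  for (int qi = 0; qi < nq; ++qi) {
    double p[3] = {Q(qi,0), Q(qi,1), Q(qi,2)};
    double best = DBL_MAX, bestpt[3] = {0,0,0};
    for (int t = 0; t < nf; ++t) {
      double dx = p[0]-cx[t], dy = p[1]-cy[t], dz = p[2]-cz[t];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[t];
      if (dc > 0 && dc*dc >= best) continue;
      int i0 = F(t,0)-1, i1 = F(t,1)-1, i2 = F(t,2)-1;
      double a[3] = {vx[i0], vy[i0], vz[i0]};
      double b[3] = {vx[i1], vy[i1], vz[i1]};
      double c[3] = {vx[i2], vy[i2], vz[i2]};
      double cp[3];
      closest_on_tri(p, a, b, c, cp);
      double d2 = (p[0]-cp[0])*(p[0]-cp[0]) + (p[1]-cp[1])*(p[1]-cp[1]) +
                  (p[2]-cp[2])*(p[2]-cp[2]);
      if (d2 < best) { best = d2; bestpt[0]=cp[0]; bestpt[1]=cp[1]; bestpt[2]=cp[2]; }
    }
    dist[qi] = std::sqrt(best);
    pts(qi,0) = bestpt[0]; pts(qi,1) = bestpt[1]; pts(qi,2) = bestpt[2];
  }
  return List::create(_["dist"] = dist, _["points"] = pts);
}

// [[Rcpp::export]]
List cpp_nn(NumericMatrix Q, NumericMatrix R) {
  const int nq = Q.nrow(), nr = R.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int qi = 0; qi < nq; ++qi) {
    double best = DBL_MAX; int bi = 0;
    const double x = Q(qi,0), y = Q(qi,1), z = Q(qi,2);
    for (int ri = 0; ri < nr; ++ri) {
      double dx = x - R(ri,0), dy = y - R(ri,1), dz = z - R(ri,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = ri; }
    }
    idx[qi] = bi + 1;
    dist[qi] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
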