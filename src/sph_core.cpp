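#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic spline kernel, support radius 2h.
// 3D normalization 1/(pi h^3), 2D normalization 10/(7 pi h^2).
static inline double ksigma(double h, int dim) {
  if (dim == 3) return 1.0 / (M_PI * h * h * h);
  return 10.0 / (7.0 * M_PI * h * h);
}

static inline double kf(double q) {
  if (q < 1.0) return 1.0 - 1.5 * q * q + 0.75 * q * q * q;
  if (q < 2.0) { double s = 2.0 - q; return 0.25 * s * s * s; }
  return 0.0;
}

static inline double kdf(double q) {
  if (q < 1.0) return -3.0 * q + 2.25 * q * q;
  if (q < 2.0) { double s = 2.0 - q; return -0.75 * s * s; }
  return 0.0;
}

// [[Rcpp::export]]
List cpp_cubic_kernel(NumericMatrix dx, double h, int dim) {
  int n = dx.nrow(), d = dx.ncol();
  NumericVector W(n);
  NumericMatrix gradW(n, d);
  double sig = ksigma(h, dim);
  for (int i = 0; i < n; ++i) {
    double r2 = 0.0;
    for (int k = 0; k < d; ++k) r2 += dx(i, k) * dx(i, k);
    double r = std::sqrt(r2);
    double q = r / h;
    W[i] = sig * kf(q);
    if (r > 0.0 && q < 2.0) {
      double c = sig * kdf(q) / (h * r);
      for (int k = 0; k < d; ++k) gradW(i, k) = c * dx(i, k);
    }
  }
  return List::create(_["W"] = W, _["gradW"] = gradW);
}

// Neighbor pairs within `cutoff`.  `period` has one entry per coordinate:
// 0 means non-periodic, L > 0 means periodic with box length L (minimal
// image).  Periodic boxes use an O(n^2) scan (benchmark scenes are small);
// non-periodic uses a cell-linked list.
// Returns unordered pairs i < j (1-based), the displacement dx = x_i - x_j
// (minimal image), and the distance r.
// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix pos, double cutoff, NumericVector period) {
  int n = pos.nrow(), d = pos.ncol();
  std::vector<int> pi, pj;
  std::vector<double> pdx, pr;
  bool periodic = false;
  for (int k = 0; k < d; ++k) if (period[k] > 0) periodic = true;
  double c2 = cutoff * cutoff;

  if (periodic || n <= 300) {
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b) {
        double r2 = 0.0, dxk[3];
        for (int k = 0; k < d; ++k) {
          double dd = pos(a, k) - pos(b, k);
          if (period[k] > 0) {
            double L = period[k];
            dd -= L * std::round(dd / L);
          }
          dxk[k] = dd;
          r2 += dd * dd;
        }
        if (r2 < c2 && r2 > 0.0) {
          pi.push_back(a + 1); pj.push_back(b + 1);
          for (int k = 0; k < d; ++k) pdx.push_back(dxk[k]);
          pr.push_back(std::sqrt(r2));
        }
      }
    }
  } else {
    // cell-linked list
    double mn[3] = {0, 0, 0};
    int nc[3] = {1, 1, 1};
    for (int k = 0; k < d; ++k) {
      double lo = pos(0, k), hi = pos(0, k);
      for (int a = 1; a < n; ++a) {
        if (pos(a, k) < lo) lo = pos(a, k);
        if (pos(a, k) > hi) hi = pos(a, k);
      }
      mn[k] = lo;
      nc[k] = std::max(1, (int)std::floor((hi - lo) / cutoff) + 1);
    }
    long ncell = (long)nc[0] * nc[1] * (d == 3 ? nc[2] : 1);
    std::vector<int> head(ncell, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n, 0);
    for (int a = 0; a < n; ++a) {
      int ix = std::min(nc[0] - 1, (int)std::floor((pos(a, 0) - mn[0]) / cutoff));
      int iy = std::min(nc[1] - 1, (int)std::floor((pos(a, 1) - mn[1]) / cutoff));
      int iz = 0;
      if (d == 3) iz = std::min(nc[2] - 1, (int)std::floor((pos(a, 2) - mn[2]) / cutoff));
      ci[a] = ix; cj[a] = iy; ck[a] = iz;
      long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
      nxt[a] = head[cell]; head[cell] = a;
    }
    int zlo = (d == 3) ? -1 : 0, zhi = (d == 3) ? 1 : 0;
    for (int a = 0; a < n; ++a) {
      for (int oz = zlo; oz <= zhi; ++oz) {
        int iz = ck[a] + oz;
        if (iz < 0 || iz >= (d == 3 ? nc[2] : 1)) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int iy = cj[a] + oy;
          if (iy < 0 || iy >= nc[1]) continue;
          for (int ox = -1; ox <= 1; ++ox) {
            int ix = ci[a] + ox;
            if (ix < 0 || ix >= nc[0]) continue;
            long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
            for (int b = head[cell]; b >= 0; b = nxt[b]) {
              if (b <= a) continue;
              double r2 = 0.0, dxk[3];
              for (int k = 0; k < d; ++k) {
                double dd = pos(a, k) - pos(b, k);
                dxk[k] = dd;
                r2 += dd * dd;
              }
              if (r2 < c2 && r2 > 0.0) {
                pi.push_back(a + 1); pj.push_back(b + 1);
                for (int k = 0; k < d; ++k) pdx.push_back(dxk[k]);
                pr.push_back(std::sqrt(r2));
              }
            }
          }
        }
      }
    }
  }
  int m = (int)pi.size();
  NumericMatrix dxm(m, d);
  for (int e = 0; e < m; ++e)
    for (int k = 0; k < d; ++k) dxm(e, k) = pdx[(size_t)e * d + k];
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["dx"] = dxm, _["r"] = wrap(pr));
}

// Continuity and momentum rates over a pair list.
// drho_a/dt = sum_b m_b (v_a - v_b) . gradW_a
// dv_a/dt   = -sum_b m_b (P_a + P_b)/(rho_a rho_b) gradW_a
//           +  sum_b m_b (mu_a + mu_b) v_ab / (rho_a rho_b r^2) (r_ab . gradW_a)
// Optional Monaghan artificial viscosity (alpha > 0) and delta-SPH
// density diffusion (delta > 0), both off by default so the verbatim
// equations are testable.
// Coincident pairs (r == 0) contribute nothing; their count is returned.
// [[Rcpp::export]]
List cpp_sph_rates(IntegerVector pi, IntegerVector pj, NumericMatrix dx,
                   NumericVector r, NumericMatrix vel, NumericVector rho,
                   NumericVector P, NumericVector m, NumericVector mu,
                   double h, int dim, double alpha, double c0,
                   double delta = 0.0,
                   Nullable<NumericMatrix> vel_visc = R_NilValue) {
  NumericMatrix velv = vel_visc.isNotNull() ? NumericMatrix(vel_visc)
                                            : vel;
  int n = rho.size(), d = dx.ncol(), np = pi.size();
  NumericVector drho(n);
  NumericMatrix acc(n, d);
  double sig = ksigma(h, dim);
  int ncoinc = 0;
  for (int e = 0; e < np; ++e) {
    int a = pi[e] - 1, b = pj[e] - 1;
    double re = r[e];
    if (re <= 0.0) { ++ncoinc; continue; }
    double q = re / h;
    if (q >= 2.0) continue;
    double gw = sig * kdf(q) / (h * re); // gradW = gw * dx
    double vab[3], vabv[3], rdotg = 0.0, vdotr = 0.0;
    for (int k = 0; k < d; ++k) {
      vab[k] = vel(a, k) - vel(b, k);
      vabv[k] = velv(a, k) - velv(b, k);
      rdotg += dx(e, k) * gw * dx(e, k);
      vdotr += vab[k] * dx(e, k);
    }
    // continuity
    double ca = 0.0;
    for (int k = 0; k < d; ++k) ca += vab[k] * gw * dx(e, k);
    drho[a] += m[b] * ca;
    drho[b] += m[a] * ca;
    if (delta > 0.0) {
      double dcoef = 2.0 * delta * h * c0 * (-gw);
      drho[a] += dcoef * (m[b] / rho[b]) * (rho[b] - rho[a]);
      drho[b] += dcoef * (m[a] / rho[a]) * (rho[a] - rho[b]);
    }
    // pressure term
    double pc = (P[a] + P[b]) / (rho[a] * rho[b]);
    if (alpha > 0.0 && vdotr < 0.0) {
      double mu_ab = h * vdotr / (re * re + 0.01 * h * h);
      pc += -alpha * c0 * mu_ab / (0.5 * (rho[a] + rho[b]));
    }
    // viscous term (Morris-type as printed)
    double vc = (mu[a] + mu[b]) * rdotg / (rho[a] * rho[b] * re * re);
    for (int k = 0; k < d; ++k) {
      double gk = gw * dx(e, k);
      acc(a, k) += -m[b] * pc * gk + m[b] * vc * vabv[k];
      acc(b, k) += m[a] * pc * gk - m[a] * vc * vabv[k];
    }
  }
  return List::create(_["drho"] = drho, _["acc"] = acc,
                      _["n_coincident"] = ncoinc);
}

// Summation density: rho_a = sum_b m_b W_ab including the self term.
// [[Rcpp::export]]
NumericVector cpp_summation_density(IntegerVector pi, IntegerVector pj,
                                    NumericVector r, NumericVector m,
                                    double h, int dim, int n) {
  NumericVector rho(n);
  double sig = ksigma(h, dim);
  for (int a = 0; a < n; ++a) rho[a] = m[a] * sig; // W(0) = sigma * f(0), f(0)=1
  int np = pi.size();
  for (int e = 0; e < np; ++e) {
    int a = pi[e] - 1, b = pj[e] - 1;
    double w = sig * kf(r[e] / h);
    rho[a] += m[b] * w;
    rho[b] += m[a] * w;
  }
  return rho;
}

// Kernel interpolation of one or more fields at arbitrary points.
// vals is n x k; returns q x k.  If shepard, normalize by sum m_b/rho_b W.
// [[Rcpp::export]]
NumericMatrix cpp_interpolate(NumericMatrix at, NumericMatrix pos,
                              NumericMatrix vals, NumericVector rho,
                              NumericVector m, double h, int dim,
                              bool shepard) {
  int q = at.nrow(), n = pos.nrow(), d = pos.ncol(), nf = vals.ncol();
  NumericMatrix out(q, nf);
  double sig = ksigma(h, dim);
  double cut2 = 4.0 * h * h;
  for (int p = 0; p < q; ++p) {
    double wsum = 0.0;
    for (int b = 0; b < n; ++b) {
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = at(p, k) - pos(b, k);
        r2 += dd * dd;
      }
      if (r2 >= cut2) continue;
      double w = sig * kf(std::sqrt(r2) / h) * m[b] / rho[b];
      wsum += w;
      for (int f = 0; f < nf; ++f) out(p, f) += w * vals(b, f);
    }
    if (shepard && wsum > 1e-12)
      for (int f = 0; f < nf; ++f) out(p, f) /= wsum;
  }
  return out;
}

// Node-to-surface contact detection: particles within `thickness` of a
// triangle face (projection inside the face).  Returns one contact per
// (particle, face); duplicate contacts arising from projections that fall
// exactly on a shared edge keep only the lowest element index.
// Degenerate faces are skipped (count returned).
// [[Rcpp::export]]
List cpp_detect_contacts(NumericMatrix ppos, NumericMatrix nodes,
                         IntegerMatrix tris, double thickness) {
  int np = ppos.nrow(), nt = tris.nrow();
  std::vector<int> cp, ce;
  std::vector<double> cdepth, cnx, cny, cnz, cw1, cw2, cw3, cd;
  int ndegen = 0;
  // particle grid
  double cs = std::max(thickness, 1e-9) * 2.0;
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) { mn[k] = 1e300; mx[k] = -1e300; }
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < 3; ++k) {
      if (ppos(p, k) < mn[k]) mn[k] = ppos(p, k);
      if (ppos(p, k) > mx[k]) mx[k] = ppos(p, k);
    }
  int nc[3];
  for (int k = 0; k < 3; ++k)
    nc[k] = np > 0 ? std::max(1, (int)std::floor((mx[k] - mn[k]) / cs) + 1) : 1;
  long ncell = (long)nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(np, -1);
  for (int p = 0; p < np; ++p) {
    int ix = std::min(nc[0] - 1, std::max(0, (int)std::floor((ppos(p, 0) - mn[0]) / cs)));
    int iy = std::min(nc[1] - 1, std::max(0, (int)std::floor((ppos(p, 1) - mn[1]) / cs)));
    int iz = std::min(nc[2] - 1, std::max(0, (int)std::floor((ppos(p, 2) - mn[2]) / cs)));
    long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
    nxt[p] = head[cell]; head[cell] = p;
  }
  for (int t = 0; t < nt; ++t) {
    int i1 = tris(t, 0) - 1, i2 = tris(t, 1) - 1, i3 = tris(t, 2) - 1;
    double v1[3], e1[3], e2[3], nrm[3];
    for (int k = 0; k < 3; ++k) {
      v1[k] = nodes(i1, k);
      e1[k] = nodes(i2, k) - v1[k];
      e2[k] = nodes(i3, k) - v1[k];
    }
    nrm[0] = e1[1] * e2[2] - e1[2] * e2[1];
    nrm[1] = e1[2] * e2[0] - e1[0] * e2[2];
    nrm[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double a2 = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    if (a2 < 1e-16) { ++ndegen; continue; }
    for (int k = 0; k < 3; ++k) nrm[k] /= a2;
    double d11 = 0, d12 = 0, d22 = 0;
    for (int k = 0; k < 3; ++k) {
      d11 += e1[k] * e1[k]; d12 += e1[k] * e2[k]; d22 += e2[k] * e2[k];
    }
    double det = d11 * d22 - d12 * d12;
    if (det <= 0) { ++ndegen; continue; }
    // AABB of triangle expanded by thickness -> cell range
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(v1[k], std::min(nodes(i2, k), nodes(i3, k))) - thickness;
      hi[k] = std::max(v1[k], std::max(nodes(i2, k), nodes(i3, k))) + thickness;
    }
    int clo[3], chi[3];
    bool empty = false;
    for (int k = 0; k < 3; ++k) {
      clo[k] = (int)std::floor((lo[k] - mn[k]) / cs);
      chi[k] = (int)std::floor((hi[k] - mn[k]) / cs);
      if (chi[k] < 0 || clo[k] >= nc[k]) empty = true;
      clo[k] = std::max(0, clo[k]); chi[k] = std::min(nc[k] - 1, chi[k]);
    }
    if (empty) continue;
    for (int iz = clo[2]; iz <= chi[2]; ++iz)
      for (int iy = clo[1]; iy <= chi[1]; ++iy)
        for (int ix = clo[0]; ix <= chi[0]; ++ix) {
          long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
          for (int p = head[cell]; p >= 0; p = nxt[p]) {
            double dvec[3], dist = 0.0;
            for (int k = 0; k < 3; ++k) dvec[k] = ppos(p, k) - v1[k];
            for (int k = 0; k < 3; ++k) dist += dvec[k] * nrm[k];
            if (std::fabs(dist) > thickness) continue;
            // projection barycentric
            double q1 = 0, q2 = 0;
            for (int k = 0; k < 3; ++k) {
              double qk = dvec[k] - dist * nrm[k];
              q1 += qk * e1[k]; q2 += qk * e2[k];
            }
            double wb = (d22 * q1 - d12 * q2) / det;
            double wc = (d11 * q2 - d12 * q1) / det;
            double wa = 1.0 - wb - wc;
            if (wa < -1e-12 || wb < -1e-12 || wc < -1e-12) continue;
            double sgn = dist >= 0.0 ? 1.0 : -1.0;
            cp.push_back(p + 1); ce.push_back(t + 1);
            cdepth.push_back(thickness - std::fabs(dist));
            cnx.push_back(sgn * nrm[0]); cny.push_back(sgn * nrm[1]);
            cnz.push_back(sgn * nrm[2]);
            cw1.push_back(wa < 0 ? 0 : wa);
            cw2.push_back(wb < 0 ? 0 : wb);
            cw3.push_back(wc < 0 ? 0 : wc);
            cd.push_back(dist);
          }
        }
  }
  // edge dedup: same particle, same signed distance & depth from two faces
  // sharing the projection point -> keep lowest element index
  int m = (int)cp.size();
  std::vector<bool> keep(m, true);
  std::vector<std::vector<int> > byp(np);
  for (int e = 0; e < m; ++e) byp[cp[e] - 1].push_back(e);
  for (int p = 0; p < np; ++p) {
    std::vector<int>& v = byp[p];
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y) {
        int ex = v[x], ey = v[y];
        if (!keep[ex] || !keep[ey]) continue;
        if (std::fabs(cd[ex] - cd[ey]) < 1e-12 &&
            std::fabs(cdepth[ex] - cdepth[ey]) < 1e-12 &&
            std::fabs(cnx[ex] - cnx[ey]) < 1e-9 &&
            std::fabs(cny[ex] - cny[ey]) < 1e-9 &&
            std::fabs(cnz[ex] - cnz[ey]) < 1e-9) {
          if (ce[ex] <= ce[ey]) keep[ey] = false; else keep[ex] = false;
        }
      }
  }
  std::vector<int> fp, fe;
  std::vector<double> fd, fnx, fny, fnz, fw1, fw2, fw3;
  for (int e = 0; e < m; ++e) {
    if (!keep[e]) continue;
    fp.push_back(cp[e]); fe.push_back(ce[e]); fd.push_back(cdepth[e]);
    fnx.push_back(cnx[e]); fny.push_back(cny[e]); fnz.push_back(cnz[e]);
    fw1.push_back(cw1[e]); fw2.push_back(cw2[e]); fw3.push_back(cw3[e]);
  }
  int mf = (int)fp.size();
  NumericMatrix nrm(mf, 3), wts(mf, 3);
  for (int e = 0; e < mf; ++e) {
    nrm(e, 0) = fnx[e]; nrm(e, 1) = fny[e]; nrm(e, 2) = fnz[e];
    wts(e, 0) = fw1[e]; wts(e, 1) = fw2[e]; wts(e, 2) = fw3[e];
  }
  return List::create(_["particle"] = wrap(fp), _["element"] = wrap(fe),
                      _["depth"] = wrap(fd), _["normal"] = nrm,
                      _["weights"] = wts, _["n_degenerate"] = ndegen);
}

// Shepard-filtered density reinitialization:
// rho_a <- sum_b m_b W_ab / sum_b (m_b/rho_b) W_ab (sums include self).
// [[Rcpp::export]]
NumericVector cpp_shepard_density(IntegerVector pi, IntegerVector pj,
                                  NumericVector r, NumericVector m,
                                  NumericVector rho, double h, int dim,
                                  int n) {
  NumericVector num(n), den(n);
  double sig = ksigma(h, dim);
  for (int a = 0; a < n; ++a) {
    num[a] = m[a] * sig;
    den[a] = m[a] / rho[a] * sig;
  }
  int np = pi.size();
  for (int e = 0; e < np; ++e) {
    int a = pi[e] - 1, b = pj[e] - 1;
    double w = sig * kf(r[e] / h);
    num[a] += m[b] * w; den[a] += m[b] / rho[b] * w;
    num[b] += m[a] * w; den[b] += m[a] / rho[a] * w;
  }
  NumericVector out(n);
  for (int a = 0; a < n; ++a) out[a] = num[a] / den[a];
  return out;
}

// Fused per-step rate evaluation: builds the neighbor structure
// internally (no pair arrays returned to R) and accumulates continuity
// and momentum rates.  Same physics as cpp_sph_rates.
// [[Rcpp::export]]
List cpp_fluid_rates_full(NumericMatrix pos, NumericMatrix vel,
                          NumericVector rho, NumericVector P,
                          NumericVector m, NumericVector mu, double h,
                          int dim, double alpha, double c0, double delta,
                          NumericVector period,
                          Nullable<NumericMatrix> vel_visc = R_NilValue,
                          Nullable<IntegerVector> type = R_NilValue,
                          double rep_r0 = 0.0, double rep_k = 0.0) {
  // optional short-range wall repulsion: a one-sided linear penalty
  // spring between fluid and boundary particles closer than rep_r0,
  // preventing creep through the wall lattice under sustained load
  IntegerVector typ = type.isNotNull() ? IntegerVector(type)
                                       : IntegerVector(0);
  bool has_rep = rep_r0 > 0.0 && rep_k > 0.0 && typ.size() > 0;
  NumericMatrix velv = vel_visc.isNotNull() ? NumericMatrix(vel_visc)
                                            : vel;
  int n = pos.nrow(), d = pos.ncol();
  NumericVector drho(n);
  NumericMatrix acc(n, d);
  double cutoff = 2.0 * h, c2 = cutoff * cutoff;
  double sig = ksigma(h, dim);
  bool periodic = false;
  for (int k = 0; k < d; ++k) if (period[k] > 0) periodic = true;
  // raw column pointers (hot loop)
  const double* Xp = REAL(pos);
  const double* Vp = REAL(vel);
  const double* VVp = REAL(velv);
  const double* Rp = REAL(rho);
  const double* Pp = REAL(P);
  const double* Mp = REAL(m);
  const double* MUp = REAL(mu);
  double* DRp = REAL(drho);
  double* ACp = REAL(acc);

  // process one interacting pair (a < b implied by caller)
  auto do_pair = [&](int a, int b, const double* dxk, double r2) {
    double re = std::sqrt(r2);
    if (re <= 0.0) return;
    double q = re / h;
    double gw = sig * kdf(q) / (h * re);
    double vab[3], vabv[3], rdotg = 0.0, vdotr = 0.0, ca = 0.0;
    for (int k = 0; k < d; ++k) {
      long o = (long)k * n;
      vab[k] = Vp[a + o] - Vp[b + o];
      vabv[k] = VVp[a + o] - VVp[b + o];
      rdotg += dxk[k] * gw * dxk[k];
      vdotr += vab[k] * dxk[k];
      ca += vab[k] * gw * dxk[k];
    }
    DRp[a] += Mp[b] * ca;
    DRp[b] += Mp[a] * ca;
    if (delta > 0.0) {
      double dcoef = 2.0 * delta * h * c0 * (-gw);
      DRp[a] += dcoef * (Mp[b] / Rp[b]) * (Rp[b] - Rp[a]);
      DRp[b] += dcoef * (Mp[a] / Rp[a]) * (Rp[a] - Rp[b]);
    }
    double pc = (Pp[a] + Pp[b]) / (Rp[a] * Rp[b]);
    if (alpha > 0.0 && vdotr < 0.0) {
      double mu_ab = h * vdotr / (re * re + 0.01 * h * h);
      pc += -alpha * c0 * mu_ab / (0.5 * (Rp[a] + Rp[b]));
    }
    double vc = (MUp[a] + MUp[b]) * rdotg / (Rp[a] * Rp[b] * re * re);
    for (int k = 0; k < d; ++k) {
      long o = (long)k * n;
      double gk = gw * dxk[k];
      ACp[a + o] += -Mp[b] * pc * gk + Mp[b] * vc * vabv[k];
      ACp[b + o] += Mp[a] * pc * gk - Mp[a] * vc * vabv[k];
    }
    if (has_rep && re < rep_r0) {
      bool wa = typ[a] != 0, wb = typ[b] != 0;
      if (wa != wb) {
        double fr = rep_k * (rep_r0 - re) / re; // spring along dx
        if (wb) { // fluid a pushed away from wall b (dx = x_a - x_b)
          for (int k = 0; k < d; ++k)
            ACp[a + (long)k * n] += fr * dxk[k] / Mp[a];
        } else {
          for (int k = 0; k < d; ++k)
            ACp[b + (long)k * n] -= fr * dxk[k] / Mp[b];
        }
      }
    }
  };

  if (periodic || n <= 300) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double r2 = 0.0, dxk[3];
        for (int k = 0; k < d; ++k) {
          double dd = pos(a, k) - pos(b, k);
          if (period[k] > 0) dd -= period[k] * std::round(dd / period[k]);
          dxk[k] = dd; r2 += dd * dd;
        }
        if (r2 < c2 && r2 > 0.0) do_pair(a, b, dxk, r2);
      }
  } else {
    double mn[3] = {0, 0, 0};
    int nc[3] = {1, 1, 1};
    for (int k = 0; k < d; ++k) {
      double lo = pos(0, k), hi = pos(0, k);
      for (int a = 1; a < n; ++a) {
        if (pos(a, k) < lo) lo = pos(a, k);
        if (pos(a, k) > hi) hi = pos(a, k);
      }
      mn[k] = lo;
      nc[k] = std::max(1, (int)std::floor((hi - lo) / cutoff) + 1);
    }
    long ncell = (long)nc[0] * nc[1] * (d == 3 ? nc[2] : 1);
    std::vector<int> head(ncell, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n, 0);
    for (int a = 0; a < n; ++a) {
      int ix = std::min(nc[0] - 1, (int)std::floor((pos(a, 0) - mn[0]) / cutoff));
      int iy = std::min(nc[1] - 1, (int)std::floor((pos(a, 1) - mn[1]) / cutoff));
      int iz = 0;
      if (d == 3) iz = std::min(nc[2] - 1, (int)std::floor((pos(a, 2) - mn[2]) / cutoff));
      ci[a] = ix; cj[a] = iy; ck[a] = iz;
      long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
      nxt[a] = head[cell]; head[cell] = a;
    }
    int zlo = (d == 3) ? -1 : 0, zhi = (d == 3) ? 1 : 0;
    for (int a = 0; a < n; ++a) {
      for (int oz = zlo; oz <= zhi; ++oz) {
        int iz = ck[a] + oz;
        if (iz < 0 || iz >= (d == 3 ? nc[2] : 1)) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int iy = cj[a] + oy;
          if (iy < 0 || iy >= nc[1]) continue;
          for (int ox = -1; ox <= 1; ++ox) {
            int ix = ci[a] + ox;
            if (ix < 0 || ix >= nc[0]) continue;
            long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
            for (int b = head[cell]; b >= 0; b = nxt[b]) {
              if (b <= a) continue;
              double r2 = 0.0, dxk[3];
              for (int k = 0; k < d; ++k) {
                double dd = Xp[a + (long)k * n] - Xp[b + (long)k * n];
                dxk[k] = dd; r2 += dd * dd;
              }
              if (r2 < c2 && r2 > 0.0) do_pair(a, b, dxk, r2);
            }
          }
        }
      }
    }
  }
  return List::create(_["drho"] = drho, _["acc"] = acc);
}

// Generalized wall boundary pressure (Adami et al. style): wall-particle
// pressure extrapolated from adjacent fluid with a hydrostatic
// correction,
//   P_w = [sum_f (P_f + rho_f g.(r_w - r_f)) V_f W] / [sum_f V_f W],
// walls with no fluid in range get P = 0.  Returns the wall pressures
// (vector over all particles; fluid entries untouched copies of P).
// [[Rcpp::export]]
NumericVector cpp_wall_pressure(NumericMatrix pos, NumericVector P,
                                NumericVector rho, NumericVector m,
                                IntegerVector type, double h, int dim,
                                NumericVector gravity,
                                NumericVector period) {
  int n = pos.nrow(), d = pos.ncol();
  double cutoff = 2.0 * h, c2 = cutoff * cutoff;
  double sig = ksigma(h, dim);
  NumericVector num(n), den(n);
  const double* Xp = REAL(pos);
  bool periodic = false;
  for (int k = 0; k < d; ++k) if (period[k] > 0) periodic = true;

  auto do_pair = [&](int a, int b, const double* dxk, double r2) {
    // dxk = x_a - x_b
    bool wa = type[a] != 0, wb = type[b] != 0;
    if (wa == wb) return; // only wall-fluid pairs contribute
    double w = sig * kf(std::sqrt(r2) / h);
    if (wa) { // a wall, b fluid
      double hyd = 0.0;
      for (int k = 0; k < d; ++k) hyd += rho[b] * gravity[k] * dxk[k];
      double vf = m[b] / rho[b];
      num[a] += (P[b] + hyd) * vf * w;
      den[a] += vf * w;
    } else { // b wall, a fluid
      double hyd = 0.0;
      for (int k = 0; k < d; ++k) hyd += rho[a] * gravity[k] * (-dxk[k]);
      double vf = m[a] / rho[a];
      num[b] += (P[a] + hyd) * vf * w;
      den[b] += vf * w;
    }
  };

  if (periodic || n <= 300) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        if ((type[a] != 0) == (type[b] != 0)) continue;
        double r2 = 0.0, dxk[3];
        for (int k = 0; k < d; ++k) {
          double dd = Xp[a + (long)k * n] - Xp[b + (long)k * n];
          if (period[k] > 0) dd -= period[k] * std::round(dd / period[k]);
          dxk[k] = dd; r2 += dd * dd;
        }
        if (r2 < c2 && r2 > 0.0) do_pair(a, b, dxk, r2);
      }
  } else {
    double mn[3] = {0, 0, 0};
    int nc[3] = {1, 1, 1};
    for (int k = 0; k < d; ++k) {
      double lo = Xp[(long)k * n], hi = lo;
      for (int a = 1; a < n; ++a) {
        double x = Xp[a + (long)k * n];
        if (x < lo) lo = x;
        if (x > hi) hi = x;
      }
      mn[k] = lo;
      nc[k] = std::max(1, (int)std::floor((hi - lo) / cutoff) + 1);
    }
    long ncell = (long)nc[0] * nc[1] * (d == 3 ? nc[2] : 1);
    std::vector<int> head(ncell, -1), nxt(n, -1);
    std::vector<int> ci(n), cj(n), ck(n, 0);
    for (int a = 0; a < n; ++a) {
      int ix = std::min(nc[0] - 1, (int)std::floor((Xp[a] - mn[0]) / cutoff));
      int iy = std::min(nc[1] - 1, (int)std::floor((Xp[a + (long)n] - mn[1]) / cutoff));
      int iz = 0;
      if (d == 3) iz = std::min(nc[2] - 1, (int)std::floor((Xp[a + 2L * n] - mn[2]) / cutoff));
      ci[a] = ix; cj[a] = iy; ck[a] = iz;
      long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
      nxt[a] = head[cell]; head[cell] = a;
    }
    int zlo = (d == 3) ? -1 : 0, zhi = (d == 3) ? 1 : 0;
    for (int a = 0; a < n; ++a) {
      for (int oz = zlo; oz <= zhi; ++oz) {
        int iz = ck[a] + oz;
        if (iz < 0 || iz >= (d == 3 ? nc[2] : 1)) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int iy = cj[a] + oy;
          if (iy < 0 || iy >= nc[1]) continue;
          for (int ox = -1; ox <= 1; ++ox) {
            int ix = ci[a] + ox;
            if (ix < 0 || ix >= nc[0]) continue;
            long cell = ((long)iz * nc[1] + iy) * nc[0] + ix;
            for (int b = head[cell]; b >= 0; b = nxt[b]) {
              if (b <= a) continue;
              if ((type[a] != 0) == (type[b] != 0)) continue;
              double r2 = 0.0, dxk[3];
              for (int k = 0; k < d; ++k) {
                double dd = Xp[a + (long)k * n] - Xp[b + (long)k * n];
                dxk[k] = dd; r2 += dd * dd;
              }
              if (r2 < c2 && r2 > 0.0) do_pair(a, b, dxk, r2);
            }
          }
        }
      }
    }
  }
  NumericVector out = clone(P);
  for (int a = 0; a < n; ++a) {
    if (type[a] != 0) out[a] = den[a] > 1e-12 ? num[a] / den[a] : 0.0;
  }
  return out;
}
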