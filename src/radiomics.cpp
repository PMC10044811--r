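// Low-level kernels for the 3D radiomic feature engine.
//
// All voxel arrays arrive as R column-major vectors cropped to the ROI
// bounding box; gray levels are 1..ng with NA_INTEGER outside the ROI.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique direction vectors covering the 26-neighbourhood up to sign
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *m = &out[d * ng * ng];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = lv[idx3(i, j, k, nx, ny)];
          if (a == NA_INTEGER) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue;
          int b = lv[idx3(i2, j2, k2, nx, ny)];
          if (b == NA_INTEGER) continue;
          // symmetric: count the pair in both orientations
          m[(a - 1) + ng * (b - 1)] += 1.0;
          m[(b - 1) + ng * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lv, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *m = &out[d * ng * maxlen];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = lv[idx3(i, j, k, nx, ny)];
          if (a == NA_INTEGER) continue;
          // run starts here iff predecessor is absent or differs
          int ip = i - dx, jp = j - dy, kp = k - dz;
          if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz) {
            int p = lv[idx3(ip, jp, kp, nx, ny)];
            if (p == a) continue;
          }
          int len = 1;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          while (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny && k2 >= 0 &&
                 k2 < nz && lv[idx3(i2, j2, k2, nx, ny)] == a) {
            ++len;
            i2 += dx; j2 += dy; k2 += dz;
          }
          m[(a - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// 26-connected zones of equal gray level; rows are (level, size)
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lv, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || lv[s] == NA_INTEGER) continue;
    int lev = lv[s], size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      ++size;
      int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            int t = idx3(i2, j2, k2, nx, ny);
            if (!seen[t] && lv[t] == lev) { seen[t] = 1; stack.push_back(t); }
          }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) { out(r, 0) = zl[r]; out(r, 1) = zs[r]; }
  return out;
}

// 26-connected component labels of a logical mask (0 outside)
// [[Rcpp::export]]
IntegerVector cpp_label_mask(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            int t = idx3(i2, j2, k2, nx, ny);
            if (mask[t] && !lab[t]) { lab[t] = next; stack.push_back(t); }
          }
    }
  }
  return lab;
}

// counts[level, d + 1] where d = number of 26-neighbours within alpha
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, IntegerVector dims, int ng,
                       int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = lv[idx3(i, j, k, nx, ny)];
        if (a == NA_INTEGER) continue;
        int d = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 ||
                  k2 >= nz)
                continue;
              int b = lv[idx3(i2, j2, k2, nx, ny)];
              if (b != NA_INTEGER && std::abs(b - a) <= alpha) ++d;
            }
        out(a - 1, d) += 1.0;
      }
  return out;
}

// columns: s_i (summed |level - neighbourhood mean|), n_i (voxel count);
// voxels with no in-ROI neighbour are excluded
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lv, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = lv[idx3(i, j, k, nx, ny)];
        if (a == NA_INTEGER) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 ||
                  k2 >= nz)
                continue;
              int b = lv[idx3(i2, j2, k2, nx, ny)];
              if (b != NA_INTEGER) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += std::fabs(a - sum / cnt);
        out(a - 1, 1) += 1.0;
      }
  return out;
}

// minimum Euclidean distance between two point sets (rows = points, mm)
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  int nb = b.nrow();
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) { bx[j] = b(j,0); by[j] = b(j,1); bz[j] = b(j,2); }
  for (int i = 0; i < a.nrow(); ++i) {
    double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = x - bx[j];
      double d2 = dx * dx;
      if (d2 >= best) continue;
      double dy = y - by[j];
      d2 += dy * dy;
      if (d2 >= best) continue;
      double dz = z - bz[j];
      d2 += dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// largest pairwise distance within one point set
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix a) {
  double best = 0.0;
  int n = a.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = a(i, 0) - a(j, 0), dy = a(i, 1) - a(j, 1),
             dz = a(i, 2) - a(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// ---- marching tetrahedra over a scalar field ---------------------------
// Field is sampled at voxel centres (node coords = index * spacing); each
// grid cell is split into six tetrahedra around the 0-7 diagonal.  Returns
// c(surface area, enclosed volume) of the iso-surface, volume by the
// divergence theorem over the consistently outward-oriented triangles.

static const int TETS[6][4] = {
  {0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
  {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}
};

static inline void cross3(const double *u, const double *v, double *w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

static void add_tri(const double *q1, const double *q2, const double *q3,
                    const double *inref, double &area, double &vol) {
  double e1[3] = {q2[0] - q1[0], q2[1] - q1[1], q2[2] - q1[2]};
  double e2[3] = {q3[0] - q1[0], q3[1] - q1[1], q3[2] - q1[2]};
  double nrm[3];
  cross3(e1, e2, nrm);
  double cen[3] = {(q1[0] + q2[0] + q3[0]) / 3.0 - inref[0],
                   (q1[1] + q2[1] + q3[1]) / 3.0 - inref[1],
                   (q1[2] + q2[2] + q3[2]) / 3.0 - inref[2]};
  double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
  const double *a = q2, *b = q3;
  if (dot < 0) { a = q3; b = q2; }   // flip to outward orientation
  cross3(e1, e2, nrm);               // area from either orientation
  area += 0.5 * std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                          nrm[2] * nrm[2]);
  double c1[3];
  double bb[3] = {b[0], b[1], b[2]};
  cross3(a, bb, c1);
  vol += (q1[0] * c1[0] + q1[1] * c1[1] + q1[2] * c1[2]) / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_mesh(NumericVector field, IntegerVector dims,
                       NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol = 0.0;
  double vc[8][3];
  double fv[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any = false, all = true;
        for (int v = 0; v < 8; ++v) {
          int oi = v & 1, oj = (v >> 1) & 1, ok = (v >> 2) & 1;
          fv[v] = field[idx3(i + oi, j + oj, k + ok, nx, ny)];
          vc[v][0] = (i + oi) * sx;
          vc[v][1] = (j + oj) * sy;
          vc[v][2] = (k + ok) * sz;
          if (fv[v] > iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (fv[tv[v]] > iso) in[nin++] = tv[v];
            else out[nout++] = tv[v];
          }
          if (nin == 0 || nin == 4) continue;
          // intersection point on edge inside->outside
          auto ipt = [&](int vi, int vo, double *p) {
            double tt = (iso - fv[vi]) / (fv[vo] - fv[vi]);
            p[0] = vc[vi][0] + tt * (vc[vo][0] - vc[vi][0]);
            p[1] = vc[vi][1] + tt * (vc[vo][1] - vc[vi][1]);
            p[2] = vc[vi][2] + tt * (vc[vo][2] - vc[vi][2]);
          };
          if (nin == 1) {
            double p1[3], p2[3], p3[3];
            ipt(in[0], out[0], p1); ipt(in[0], out[1], p2);
            ipt(in[0], out[2], p3);
            add_tri(p1, p2, p3, vc[in[0]], area, vol);
          } else if (nin == 3) {
            double p1[3], p2[3], p3[3];
            ipt(in[0], out[0], p1); ipt(in[1], out[0], p2);
            ipt(in[2], out[0], p3);
            double cen[3] = {(vc[in[0]][0] + vc[in[1]][0] + vc[in[2]][0]) / 3.0,
                             (vc[in[0]][1] + vc[in[1]][1] + vc[in[2]][1]) / 3.0,
                             (vc[in[0]][2] + vc[in[1]][2] + vc[in[2]][2]) / 3.0};
            add_tri(p1, p2, p3, cen, area, vol);
          } else { // nin == 2: quad AC, AD, BD, BC split in two
            double pac[3], pad[3], pbd[3], pbc[3];
            ipt(in[0], out[0], pac); ipt(in[0], out[1], pad);
            ipt(in[1], out[1], pbd); ipt(in[1], out[0], pbc);
            double cen[3] = {(vc[in[0]][0] + vc[in[1]][0]) / 2.0,
                             (vc[in[0]][1] + vc[in[1]][1]) / 2.0,
                             (vc[in[0]][2] + vc[in[1]][2]) / 2.0};
            add_tri(pac, pad, pbd, cen, area, vol);
            add_tri(pac, pbd, pbc, cen, area, vol);
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol));
}

// voxels of mask with at least one 6-neighbour outside the mask
// [[Rcpp::export]]
LogicalVector cpp_boundary(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size());
  static const int N6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idx3(i, j, k, nx, ny);
        if (!mask[c]) continue;
        bool bnd = false;
        for (int t = 0; t < 6 && !bnd; ++t) {
          int i2 = i + N6[t][0], j2 = j + N6[t][1], k2 = k + N6[t][2];
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            bnd = true;
          else if (!mask[idx3(i2, j2, k2, nx, ny)])
            bnd = true;
        }
        out[c] = bnd;
      }
  return out;
}

// L1-penalized logistic regression path by IRLS + cyclic coordinate
// descent with an active-set strategy, warm-started along a decreasing
// lambda sequence.  x must be standardized column-wise; the intercept is
// unpenalized.  Objective:
// (1/n) sum log(1 + exp(-(2y-1) eta)) + lambda * sum |beta_j|.
// [[Rcpp::export]]
List cpp_lasso_path(NumericMatrix x, NumericVector y, NumericVector lambdas,
                    double tol, int max_iter) {
  int n = x.nrow(), p = x.ncol(), nl = lambdas.size();
  NumericMatrix betas(p, nl);
  NumericVector b0s(nl);
  IntegerVector iters(nl);
  LogicalVector conv(nl);
  std::vector<double> beta(p, 0.0), eta(n), mu(n), w(n), r(n), v(p);
  std::vector<char> active(p, 0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = (ybar > 0 && ybar < 1) ? std::log(ybar / (1 - ybar)) : 0.0;
  for (int i = 0; i < n; ++i) eta[i] = b0;

  for (int li = 0; li < nl; ++li) {
    double lam = lambdas[li];
    bool ok = false;
    int it = 0;
    for (int outer = 0; outer < max_iter; ++outer) {
      it = outer + 1;
      double wsum = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = std::max(std::min(eta[i], 30.0), -30.0);
        mu[i] = 1.0 / (1.0 + std::exp(-e));
        w[i] = std::max(mu[i] * (1.0 - mu[i]), 1e-6);
        r[i] = (y[i] - mu[i]) / w[i];
        wsum += w[i];
      }
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * x(i, j) * x(i, j);
        v[j] = s / n;
      }
      // one coordinate update; returns the absolute change
      auto upd = [&](int j) {
        if (v[j] <= 0) return 0.0;
        double u = 0.0;
        for (int i = 0; i < n; ++i) u += w[i] * x(i, j) * r[i];
        u = u / n + v[j] * beta[j];
        double bn = 0.0;
        if (u > lam) bn = (u - lam) / v[j];
        else if (u < -lam) bn = (u + lam) / v[j];
        double d = bn - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= x(i, j) * d;
          beta[j] = bn;
          active[j] = 1;
        }
        return std::fabs(d);
      };
      auto upd0 = [&]() {
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += w[i] * r[i];
        double del0 = num / wsum;
        if (del0 != 0.0) {
          b0 += del0;
          for (int i = 0; i < n; ++i) r[i] -= del0;
        }
        return std::fabs(del0);
      };
      double outer_del = 0.0;
      for (int cycle = 0; cycle < 50; ++cycle) {
        // full sweep over all coordinates
        double maxdel = upd0();
        for (int j = 0; j < p; ++j) maxdel = std::max(maxdel, upd(j));
        outer_del = std::max(outer_del, maxdel);
        if (maxdel < tol) break;
        // iterate the active set to convergence
        for (int sweep = 0; sweep < 1000; ++sweep) {
          double d2 = upd0();
          for (int j = 0; j < p; ++j)
            if (active[j]) d2 = std::max(d2, upd(j));
          outer_del = std::max(outer_del, d2);
          if (d2 < tol) break;
        }
      }
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0) e += x(i, j) * beta[j];
        eta[i] = e;
      }
      if (outer_del < tol) { ok = true; break; }
    }
    for (int j = 0; j < p; ++j) betas(j, li) = beta[j];
    b0s[li] = b0;
    iters[li] = it;
    conv[li] = ok;
  }
  return List::create(_["beta"] = betas, _["intercept"] = b0s,
                      _["iterations"] = iters, _["converged"] = conv);
}

// index ranges (1-based) of the TRUE region: c(ilo,ihi,jlo,jhi,klo,khi)
// [[Rcpp::export]]
IntegerVector cpp_bbox(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ilo = nx, ihi = -1, jlo = ny, jhi = -1, klo = nz, khi = -1;
  int c = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++c)
        if (mask[c]) {
          if (i < ilo) ilo = i;
          if (i > ihi) ihi = i;
          if (j < jlo) jlo = j;
          if (j > jhi) jhi = j;
          if (k < klo) klo = k;
          if (k > khi) khi = k;
        }
  if (ihi < 0) return IntegerVector(0);
  return IntegerVector::create(ilo + 1, ihi + 1, jlo + 1, jhi + 1,
                               klo + 1, khi + 1);
}
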