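#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Domain topology: periodic on x (gut tube seam), reflective on y.

static inline double wrap_x(double x, double w) {
  x -= w * std::floor(x / w);
  if (x >= w) x = 0.0;  // guard fp edge when x/w rounds down
  return x;
}

static inline double reflect_y(double y, double h) {
  double p = 2.0 * h;
  y -= p * std::floor(y / p);
  if (y > h) y = p - y;
  return y;
}

static inline double wdist2(double x1, double y1, double x2, double y2,
                            double w) {
  double dx = std::fabs(x1 - x2);
  if (dx > 0.5 * w) dx = w - dx;
  double dy = y1 - y2;
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
NumericVector cpp_wrap_point(double x, double y, double width, double height) {
  return NumericVector::create(wrap_x(x, width), reflect_y(y, height));
}

// [[Rcpp::export]]
NumericVector cpp_wrapped_distance(NumericVector x1, NumericVector y1,
                                   NumericVector x2, NumericVector y2,
                                   double width) {
  R_xlen_t n = x1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::sqrt(wdist2(x1[i], y1[i], x2[i], y2[i], width));
  return out;
}

// Chemokine field: additive radial linear-decay kernel over active sources
// (differentiated LTo with expression >= threshold), cutoff r_chem.
struct ChemField {
  const double *lx, *ly, *expr;
  const std::vector<int> *src;
  double rchem, w, h;

  double level(double px, double py) const {
    px = wrap_x(px, w);
    py = reflect_y(py, h);
    double c = 0.0, r2 = rchem * rchem;
    for (size_t k = 0; k < src->size(); ++k) {
      int j = (*src)[k];
      double d2 = wdist2(px, py, lx[j], ly[j], w);
      if (d2 < r2) c += expr[j] * (1.0 - std::sqrt(d2) / rchem);
    }
    return c;
  }

  void gradient(double px, double py, double fd, double *gx, double *gy) const {
    *gx = (level(px + fd, py) - level(px - fd, py)) / (2.0 * fd);
    *gy = (level(px, py + fd) - level(px, py - fd)) / (2.0 * fd);
  }
};

static std::vector<int> active_sources(const LogicalVector &diff,
                                       const NumericVector &expr,
                                       double threshold) {
  std::vector<int> src;
  for (int j = 0; j < diff.size(); ++j)
    if (diff[j] && expr[j] >= threshold) src.push_back(j);
  return src;
}

// [[Rcpp::export]]
double cpp_chem_level(double px, double py, NumericVector lto_x,
                      NumericVector lto_y, LogicalVector diff,
                      NumericVector expr, double threshold, double r_chem,
                      double width, double height) {
  std::vector<int> src = active_sources(diff, expr, threshold);
  ChemField f = {lto_x.begin(), lto_y.begin(), expr.begin(),
                 &src,          r_chem,        width,
                 height};
  return f.level(px, py);
}

// [[Rcpp::export]]
NumericVector cpp_chem_gradient(double px, double py, NumericVector lto_x,
                                NumericVector lto_y, LogicalVector diff,
                                NumericVector expr, double threshold,
                                double r_chem, double fd_step, double width,
                                double height) {
  std::vector<int> src = active_sources(diff, expr, threshold);
  ChemField f = {lto_x.begin(), lto_y.begin(), expr.begin(),
                 &src,          r_chem,        width,
                 height};
  double gx, gy;
  f.gradient(px, py, fd_step, &gx, &gy);
  return NumericVector::create(gx, gy);
}

// Single-linkage components under wrapped distance <= linking (union-find).
// [[Rcpp::export]]
IntegerVector cpp_single_linkage(NumericVector x, NumericVector y, double width,
                                 double linking) {
  int n = x.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  // find with path halving
  struct UF {
    std::vector<int> &p;
    int find(int i) {
      while (p[i] != i) {
        p[i] = p[p[i]];
        i = p[i];
      }
      return i;
    }
  } uf = {parent};
  double l2 = linking * linking;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (wdist2(x[i], y[i], x[j], y[j], width) <= l2) {
        int ri = uf.find(i), rj = uf.find(j);
        if (ri != rj) parent[ri] = rj;
      }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// The 72-hour simulation loop. RNG is R's stream (seeded by the caller), so a
// run is bitwise reproducible given (config, seed). Per step: inject new
// cells, snapshot LTo state, update motile cells in a freshly shuffled order
// (move, emit contact events, arrest check against the nearest differentiated
// LTo), then apply the step's contact events to the LTo synchronously.
// [[Rcpp::export]]
List cpp_run(NumericVector lto_x, NumericVector lto_y, IntegerVector inj_ltin,
             IntegerVector inj_lti, double width, double height, double dt_min,
             double speed, double r_motile, double r_lto, double r_adh,
             double l0, double dl, double r_chem, double chem_thr,
             double fd_step, bool record) {
  int nL = lto_x.size();
  int n_steps = inj_ltin.size();
  int cap = 0;
  for (int s = 0; s < n_steps; ++s) cap += inj_ltin[s] + inj_lti[s];

  std::vector<double> mx(cap), my(cap), entry(cap);
  std::vector<int> kind(cap), state(cap);  // kind: 0 LTin, 1 LTi; state: 0/1
  std::vector<int> ldiff(nL, 0), lcont(nL, 0);
  std::vector<double> lexpr(nL, 0.0);

  int n = 0, n_arr = 0, n_diff = 0;
  double step_len = speed * dt_min;
  double contact_r2 = (r_motile + r_lto) * (r_motile + r_lto);

  std::vector<int> ord, src, diffed, ev_l, ev_k;
  ord.reserve(cap);
  src.reserve(nL);
  diffed.reserve(nL);
  NumericMatrix diag(record ? n_steps : 0, 5);

  for (int s = 0; s < n_steps; ++s) {
    double t0 = s * dt_min / 60.0;  // hours at step start
    for (int i = 0; i < inj_ltin[s]; ++i, ++n) {
      mx[n] = unif_rand() * width;
      my[n] = unif_rand() * height;
      kind[n] = 0;
      state[n] = 0;
      entry[n] = t0;
    }
    for (int i = 0; i < inj_lti[s]; ++i, ++n) {
      mx[n] = unif_rand() * width;
      my[n] = unif_rand() * height;
      kind[n] = 1;
      state[n] = 0;
      entry[n] = t0;
    }

    src.clear();
    diffed.clear();
    for (int j = 0; j < nL; ++j)
      if (ldiff[j]) {
        diffed.push_back(j);
        if (lexpr[j] >= chem_thr) src.push_back(j);
      }
    ChemField f = {lto_x.begin(), lto_y.begin(), lexpr.data(),
                   &src,          r_chem,        width,
                   height};

    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }

    ev_l.clear();
    ev_k.clear();
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      if (state[i] == 1) continue;  // arrest is absorbing

      double theta = 2.0 * M_PI * unif_rand();
      double ux = std::cos(theta), uy = std::sin(theta);
      double dx = ux, dy = uy;
      if (kind[i] == 1) {
        double c = f.level(mx[i], my[i]);
        double b = c < 1.0 ? c : 1.0;
        if (b > 0.0) {
          double gx, gy;
          f.gradient(mx[i], my[i], fd_step, &gx, &gy);
          double gn = std::sqrt(gx * gx + gy * gy);
          if (gn > 0.0) {
            gx /= gn;
            gy /= gn;
          } else {
            gx = gy = 0.0;
          }
          double vx = (1.0 - b) * ux + b * gx;
          double vy = (1.0 - b) * uy + b * gy;
          double vn = std::sqrt(vx * vx + vy * vy);
          if (vn > 0.0) {
            dx = vx / vn;
            dy = vy / vn;
          }
        }
      }
      mx[i] = wrap_x(mx[i] + step_len * dx, width);
      my[i] = reflect_y(my[i] + step_len * dy, height);

      double best_d2 = -1.0;
      int best_j = -1;
      for (int j = 0; j < nL; ++j) {
        double d2 = wdist2(mx[i], my[i], lto_x[j], lto_y[j], width);
        if (d2 <= contact_r2) {
          ev_l.push_back(j);
          ev_k.push_back(kind[i]);
        }
        if (ldiff[j] && (best_j < 0 || d2 < best_d2)) {
          best_d2 = d2;
          best_j = j;
        }
      }
      if (best_j >= 0) {
        double d = std::sqrt(best_d2);
        double p = d < r_adh ? lexpr[best_j] * (1.0 - d / r_adh) : 0.0;
        if (p > 0.0 && unif_rand() < p) {
          state[i] = 1;
          ++n_arr;
        }
      }
    }

    for (size_t e = 0; e < ev_l.size(); ++e) {
      int j = ev_l[e];
      if (ev_k[e] == 0) {
        if (!ldiff[j]) {  // LTin contact differentiates an LTo
          ldiff[j] = 1;
          lexpr[j] = l0;
          ++n_diff;
        }
      } else if (ldiff[j]) {  // LTi contact matures a differentiated LTo
        lcont[j] += 1;
        lexpr[j] = std::min(1.0, lexpr[j] + dl);
      }
    }

    if (record) {
      diag(s, 0) = (s + 1) * dt_min / 60.0;
      diag(s, 1) = n;
      diag(s, 2) = n_arr;
      diag(s, 3) = n_diff;
      diag(s, 4) = (double)src.size();
    }
  }

  return List::create(
      _["x"] = NumericVector(mx.begin(), mx.begin() + n),
      _["y"] = NumericVector(my.begin(), my.begin() + n),
      _["kind"] = IntegerVector(kind.begin(), kind.begin() + n),
      _["state"] = IntegerVector(state.begin(), state.begin() + n),
      _["entry_time"] = NumericVector(entry.begin(), entry.begin() + n),
      _["lto_differentiated"] = LogicalVector(ldiff.begin(), ldiff.end()),
      _["lto_expression"] = NumericVector(lexpr.begin(), lexpr.end()),
      _["lto_contacts"] = IntegerVector(lcont.begin(), lcont.end()),
      _["diagnostics"] = diag);
}
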