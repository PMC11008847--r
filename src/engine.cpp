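// Fast per-step engine core. Implements exactly the step orchestration of
// the R reference `step()`: (0) stop when a division is due (handled in R);
// (1) cortical remodeling; (2) division program (growth ramp, adhesion
// cessation); (3) bond matching and contact flags; (4) effective adhesion
// parameters (new contacts, previous N_sub); (5) force summation;
// (6) explicit Euler move. Tie-breaking and iteration orders mirror the R
// implementations so that single steps agree to floating-point accuracy.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct Par {
  double A0, k_A, k_L, gamma_cc, R_cc, gamma_cs, d_cc, d_cs, l_cc, l_cs,
      C_s, C_G, beta, dt, steps_per_hour, activation_fraction,
      fb_cc_per_bond, fb_cs_factor, fb_dcc_factor;
};

struct CellS {
  std::vector<double> x, z;
  double A0, ref, age;
  double cycle;   // < 0 means no division
  bool dividing;
  // per-step program state
  double A0_target;
  bool gamma_on;
  // carried history
  bool contact, left, right;
  int nsub_prev;
};

struct SubBond { int cell, node, sub; double dist; };
struct CellBond { int ci, nj, cl, nk; double dist; bool attractive; };

static inline int ipn(int j, int n) { return j + 1 < n ? j + 1 : 0; }
static inline int imn(int j, int n) { return j > 0 ? j - 1 : n - 1; }

// one remodeling pass; mirrors remodel_cortex()
static void remodel(CellS &c) {
  int n = (int)c.x.size();
  std::vector<double> elen(n);
  for (int j = 0; j < n; ++j) {
    double dx = c.x[ipn(j, n)] - c.x[j], dz = c.z[ipn(j, n)] - c.z[j];
    elen[j] = std::sqrt(dx * dx + dz * dz);
  }
  std::vector<bool> ins(n, false), rem(n, false);
  int n_ins = 0, n_rem = 0;
  for (int j = 0; j < n; ++j)
    if (elen[j] > 2.0 * c.ref) { ins[j] = true; ++n_ins; }
  for (int j = 0; j < n; ++j) {
    if (elen[j] < 0.5 * c.ref) {
      int a = j, b = ipn(j, n);
      double dax = c.x[a] - c.x[imn(a, n)], daz = c.z[a] - c.z[imn(a, n)];
      double dbx = c.x[b] - c.x[ipn(b, n)], dbz = c.z[b] - c.z[ipn(b, n)];
      double da = std::sqrt(dax * dax + daz * daz);
      double db = std::sqrt(dbx * dbx + dbz * dbz);
      int victim = (da <= db) ? a : b;
      if (!rem[victim]) { rem[victim] = true; ++n_rem; }
    }
  }
  if (n_rem > 0 && n - n_rem + n_ins < 8) {
    Rf_warning("cortex remodeling skipped removals to keep >= 8 nodes");
    std::fill(rem.begin(), rem.end(), false);
    n_rem = 0;
  }
  if (n_rem == 0 && n_ins == 0) return;
  std::vector<double> nx, nz;
  nx.reserve(n + n_ins); nz.reserve(n + n_ins);
  for (int j = 0; j < n; ++j) {
    if (!rem[j]) { nx.push_back(c.x[j]); nz.push_back(c.z[j]); }
    if (ins[j]) {
      nx.push_back((c.x[j] + c.x[ipn(j, n)]) / 2.0);
      nz.push_back((c.z[j] + c.z[ipn(j, n)]) / 2.0);
    }
  }
  c.x.swap(nx); c.z.swap(nz);
}

// internal forces; mirrors internal_forces()
static void add_internal(const CellS &c, const Par &p,
                         std::vector<double> &fx, std::vector<double> &fz) {
  int n = (int)c.x.size();
  double S = 0.0;
  for (int j = 0; j < n; ++j)
    S += c.x[j] * c.z[ipn(j, n)] - c.x[ipn(j, n)] * c.z[j];
  double A = std::fabs(S) / 2.0;
  double sgn = (S >= 0) ? 1.0 : -1.0;
  std::vector<double> tx(n), tz(n);
  double L = 0.0;
  bool warned = false;
  for (int j = 0; j < n; ++j) {
    double ex = c.x[ipn(j, n)] - c.x[j], ez = c.z[ipn(j, n)] - c.z[j];
    double el = std::sqrt(ex * ex + ez * ez);
    if (el == 0.0) {
      if (!warned) {
        Rf_warning("degenerate (zero-length) cortex edge; tangent treated as zero");
        warned = true;
      }
      tx[j] = 0.0; tz[j] = 0.0;
    } else {
      tx[j] = ex / el; tz[j] = ez / el;
      L += el;
    }
  }
  double coefA = p.k_A * (A - c.A0_target) * sgn / 2.0;
  for (int j = 0; j < n; ++j) {
    int jp = ipn(j, n), jm = imn(j, n);
    fx[j] += -coefA * (c.z[jp] - c.z[jm]) - p.k_L * L * (tx[jm] - tx[j]);
    fz[j] += coefA * (c.x[jp] - c.x[jm]) - p.k_L * L * (tz[jm] - tz[j]);
  }
}

// R findInterval(x, v): number of v[i] <= x (1-based count), 0 if below v[0]
static inline int find_interval(double xv, const std::vector<double> &v) {
  int lo = 0, hi = (int)v.size(); // count of elements <= xv
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (v[mid] <= xv) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List cpp_advance(List cells_in, NumericVector ref_spacing, NumericVector A0,
                 NumericVector age, NumericVector cycle,
                 LogicalVector dividing, NumericMatrix substrate,
                 List params, double spread_scale, int n_steps, int stride,
                 int start_step, LogicalVector contact,
                 LogicalVector contact_left, LogicalVector contact_right,
                 IntegerVector nsub_prev) {
  Par p;
  p.A0 = params["A0"]; p.k_A = params["k_A"]; p.k_L = params["k_L"];
  p.gamma_cc = params["gamma_cc"]; p.R_cc = params["R_cc"];
  p.gamma_cs = params["gamma_cs"]; p.d_cc = params["d_cc"];
  p.d_cs = params["d_cs"]; p.l_cc = params["l_cc"]; p.l_cs = params["l_cs"];
  p.C_s = params["C_s"]; p.C_G = params["C_G"]; p.beta = params["beta"];
  p.dt = params["dt"]; p.steps_per_hour = params["steps_per_hour"];
  p.activation_fraction = params["activation_fraction"];
  p.fb_cc_per_bond = params["fb_cc_per_bond"];
  p.fb_cs_factor = params["fb_cs_factor"];
  p.fb_dcc_factor = params["fb_dcc_factor"];

  int nc = cells_in.size();
  std::vector<CellS> cells(nc);
  for (int i = 0; i < nc; ++i) {
    NumericMatrix M = cells_in[i];
    int n = M.nrow();
    cells[i].x.resize(n); cells[i].z.resize(n);
    for (int j = 0; j < n; ++j) {
      cells[i].x[j] = M(j, 0); cells[i].z[j] = M(j, 1);
    }
    cells[i].A0 = A0[i];
    cells[i].ref = ref_spacing[i];
    cells[i].age = age[i];
    cells[i].cycle = cycle[i];
    cells[i].dividing = dividing[i];
    cells[i].contact = contact[i];
    cells[i].left = contact_left[i];
    cells[i].right = contact_right[i];
    cells[i].nsub_prev = nsub_prev[i];
  }
  int m = substrate.nrow();
  std::vector<double> sx(m);
  for (int k = 0; k < m; ++k) sx[k] = substrate(k, 0);

  List frames;
  int steps_done = 0;

  for (int s = 0; s < n_steps; ++s) {
    // (0) stop if a division is due; R performs it
    bool due = false;
    for (int i = 0; i < nc; ++i)
      if (cells[i].dividing && cells[i].cycle >= 0.0 &&
          cells[i].age >= cells[i].cycle) due = true;
    if (due) break;

    // (1) remodeling
    for (int i = 0; i < nc; ++i) remodel(cells[i]);

    // (2) division program
    for (int i = 0; i < nc; ++i) {
      CellS &c = cells[i];
      c.A0_target = c.A0;
      c.gamma_on = true;
      if (c.dividing && c.cycle >= 0.0) {
        double start = c.cycle - 1.0;
        if (c.age >= start) {
          double tau = (c.age - start) / 1.0;
          if (tau > 1.0) tau = 1.0;
          if (tau < 0.0) tau = 0.0;
          c.A0_target = c.A0 * (1.0 + tau);
          c.gamma_on = false;
        }
      }
    }

    // (3) bonds --------------------------------------------------------
    // substrate bonds, mutual-nearest (global over all cells)
    std::vector<int> gcell, gnode;
    std::vector<double> gx, gz;
    for (int i = 0; i < nc; ++i)
      for (int j = 0; j < (int)cells[i].x.size(); ++j) {
        gcell.push_back(i); gnode.push_back(j);
        gx.push_back(cells[i].x[j]); gz.push_back(cells[i].z[j]);
      }
    int ng = (int)gx.size();
    std::vector<int> near_k(ng);
    std::vector<double> near_d(ng);
    for (int j = 0; j < ng; ++j) {
      int k = find_interval(gx[j], sx);
      if (k < 1) k = 1;
      if (k > m - 1) k = m - 1; // all.inside, 1-based
      int k0 = k - 1;           // 0-based left node
      int k1 = (k0 + 1 < m) ? k0 + 1 : m - 1;
      int kk = (std::fabs(gx[j] - sx[k0]) <= std::fabs(sx[k1] - gx[j]))
                   ? k0 : k1;
      near_k[j] = kk;
      near_d[j] = std::sqrt((gx[j] - sx[kk]) * (gx[j] - sx[kk]) +
                            gz[j] * gz[j]);
    }
    std::vector<double> best_d(m, std::numeric_limits<double>::infinity());
    std::vector<int> best_j(m, -1);
    for (int j = 0; j < ng; ++j) {
      int lo = find_interval(gx[j] - p.d_cs, sx); // 0-based first index
      int hi = find_interval(gx[j] + p.d_cs, sx) - 1;
      if (hi >= m) hi = m - 1;
      for (int k = lo; k <= hi; ++k) {
        double dd = std::sqrt((gx[j] - sx[k]) * (gx[j] - sx[k]) +
                              gz[j] * gz[j]);
        if (dd < best_d[k]) { best_d[k] = dd; best_j[k] = j; }
      }
    }
    std::vector<SubBond> sbonds;
    std::vector<int> nsub_now(nc, 0);
    for (int j = 0; j < ng; ++j) {
      if (near_d[j] < p.d_cs && best_j[near_k[j]] == j) {
        SubBond b; b.cell = gcell[j]; b.node = gnode[j];
        b.sub = near_k[j]; b.dist = near_d[j];
        sbonds.push_back(b);
        ++nsub_now[b.cell];
      }
    }

    // cell-cell bonds; matching range from previous contact flags
    std::vector<double> d_eff(nc);
    for (int i = 0; i < nc; ++i)
      d_eff[i] = cells[i].contact ? p.fb_dcc_factor * p.d_cc : p.d_cc;
    std::vector<double> xmin(nc), xmax(nc), cx(nc);
    for (int i = 0; i < nc; ++i) {
      double mn = cells[i].x[0], mx = cells[i].x[0], sum = 0.0;
      for (double v : cells[i].x) {
        if (v < mn) mn = v;
        if (v > mx) mx = v;
        sum += v;
      }
      xmin[i] = mn; xmax[i] = mx;
      cx[i] = sum / cells[i].x.size();
    }
    std::vector<CellBond> cbonds;
    std::vector<bool> has(nc, false), lft(nc, false), rgt(nc, false);
    for (int i = 0; i + 1 < nc; ++i) {
      for (int l = i + 1; l < nc; ++l) {
        double d = std::max(d_eff[i], d_eff[l]);
        if (xmin[i] > xmax[l] + d || xmin[l] > xmax[i] + d) continue;
        int ni = (int)cells[i].x.size(), nl = (int)cells[l].x.size();
        // column-major over (node of i, node of l), matching R's which()
        for (int k = 0; k < nl; ++k) {
          double qx = cells[l].x[k], qz = cells[l].z[k];
          for (int j = 0; j < ni; ++j) {
            double dx = cells[i].x[j] - qx;
            if (dx > d || dx < -d) continue;
            double dz = cells[i].z[j] - qz;
            double dist = std::sqrt(dx * dx + dz * dz);
            if (dist < d) {
              CellBond b; b.ci = i; b.nj = j; b.cl = l; b.nk = k;
              b.dist = dist; b.attractive = dist > p.l_cc;
              cbonds.push_back(b);
              if (b.attractive) { has[i] = true; has[l] = true; }
              if (cx[l] < cx[i]) lft[i] = true; else rgt[i] = true;
              if (cx[i] < cx[l]) lft[l] = true; else rgt[l] = true;
            }
          }
        }
      }
    }

    // (4) effective parameters (new contacts, previous N_sub)
    std::vector<double> gcc_eff(nc), gcs_eff(nc);
    for (int i = 0; i < nc; ++i) {
      double base = cells[i].gamma_on ? p.gamma_cc : 0.0;
      gcc_eff[i] = has[i]
          ? base * (1.0 + p.fb_cc_per_bond * cells[i].nsub_prev) : base;
      gcs_eff[i] = has[i] ? p.fb_cs_factor * p.gamma_cs : p.gamma_cs;
    }

    // (5) forces -------------------------------------------------------
    std::vector<std::vector<double> > fx(nc), fz(nc);
    std::vector<std::vector<bool> > bonded(nc);
    for (int i = 0; i < nc; ++i) {
      fx[i].assign(cells[i].x.size(), 0.0);
      fz[i].assign(cells[i].x.size(), 0.0);
      bonded[i].assign(cells[i].x.size(), false);
      add_internal(cells[i], p, fx[i], fz[i]);
    }
    bool warned_coincident = false;
    for (const SubBond &b : sbonds) {
      bonded[b.cell][b.node] = true;
      if (b.dist == 0.0) continue;
      double ux = (cells[b.cell].x[b.node] - sx[b.sub]) / b.dist;
      double uz = cells[b.cell].z[b.node] / b.dist;
      double f = -gcs_eff[b.cell] * (b.dist - p.l_cs);
      fx[b.cell][b.node] += f * ux;
      fz[b.cell][b.node] += f * uz;
    }
    for (const CellBond &b : cbonds) {
      if (b.dist == 0.0) {
        if (!warned_coincident) {
          Rf_warning("coincident nodes in a cell-cell bond; force set to zero");
          warned_coincident = true;
        }
        continue;
      }
      double ux = (cells[b.ci].x[b.nj] - cells[b.cl].x[b.nk]) / b.dist;
      double uz = (cells[b.ci].z[b.nj] - cells[b.cl].z[b.nk]) / b.dist;
      double g = b.attractive ? std::min(gcc_eff[b.ci], gcc_eff[b.cl])
                              : p.R_cc;
      double f = -g * (b.dist - p.l_cc);
      fx[b.ci][b.nj] += f * ux;
      fz[b.ci][b.nj] += f * uz;
      fx[b.cl][b.nk] -= f * ux;
      fz[b.cl][b.nk] -= f * uz;
    }
    // gravity: cells without a path to the substrate
    std::vector<bool> grounded(nc, false);
    for (const SubBond &b : sbonds) grounded[b.cell] = true;
    bool changed = true;
    while (changed) {
      changed = false;
      for (const CellBond &b : cbonds) {
        if (grounded[b.ci] != grounded[b.cl]) {
          grounded[b.ci] = grounded[b.cl] = true;
          changed = true;
        }
      }
    }
    for (int i = 0; i < nc; ++i) {
      if (!grounded[i])
        for (size_t j = 0; j < fz[i].size(); ++j) fz[i][j] -= p.C_G;
    }
    // active spreading with per-side contact inhibition
    const double s2 = std::sqrt(2.0) / 2.0;
    for (int i = 0; i < nc; ++i) {
      int n = (int)cells[i].x.size();
      int nb = nsub_now[i];
      if (nb == 0 || (double)nb / n < p.activation_fraction) continue;
      int leftmost = -1, rightmost = -1;
      for (int j = 0; j < n; ++j) {
        if (!bonded[i][j]) continue;
        if (leftmost < 0 || cells[i].x[j] < cells[i].x[leftmost])
          leftmost = j;
        if (rightmost < 0 || cells[i].x[j] > cells[i].x[rightmost])
          rightmost = j;
      }
      // neighbour outside the bonded run, preferring the outward side
      auto flank = [&](int j, bool left_side) -> int {
        int jm = imn(j, n), jp = ipn(j, n);
        int cand[2]; int ncand = 0;
        if (!bonded[i][jm]) cand[ncand++] = jm;
        if (!bonded[i][jp]) cand[ncand++] = jp;
        if (ncand == 0) return -1;
        if (ncand == 1) return cand[0];
        if (left_side)
          return (cells[i].x[cand[0]] <= cells[i].x[cand[1]]) ? cand[0]
                                                              : cand[1];
        return (cells[i].x[cand[0]] >= cells[i].x[cand[1]]) ? cand[0]
                                                            : cand[1];
      };
      if (!lft[i]) {
        int j = flank(leftmost, true);
        if (j >= 0) {
          fx[i][j] += spread_scale * (-s2);
          fz[i][j] += spread_scale * (-s2);
        }
      }
      if (!rgt[i]) {
        int j = flank(rightmost, false);
        if (j >= 0) {
          fx[i][j] += spread_scale * s2;
          fz[i][j] += spread_scale * (-s2);
        }
      }
    }

    // (6) explicit Euler move
    double scale = p.dt / p.beta;
    for (int i = 0; i < nc; ++i) {
      for (size_t j = 0; j < cells[i].x.size(); ++j) {
        if (!std::isfinite(fx[i][j]) || !std::isfinite(fz[i][j]))
          stop("non-finite force at step %d (cell %d)",
               start_step + s + 1, i + 1);
        cells[i].x[j] += scale * fx[i][j];
        cells[i].z[j] += scale * fz[i][j];
      }
      cells[i].age += 1.0 / p.steps_per_hour;
      cells[i].contact = has[i];
      cells[i].left = lft[i];
      cells[i].right = rgt[i];
      cells[i].nsub_prev = nsub_now[i];
    }
    ++steps_done;

    int global = start_step + s + 1;
    if (stride > 0 && global % stride == 0) {
      List nodes(nc);
      NumericVector fage(nc);
      LogicalVector fc(nc), fl(nc), fr(nc), fg(nc);
      IntegerVector fn(nc);
      for (int i = 0; i < nc; ++i) {
        int n = (int)cells[i].x.size();
        NumericMatrix M(n, 2);
        for (int j = 0; j < n; ++j) {
          M(j, 0) = cells[i].x[j]; M(j, 1) = cells[i].z[j];
        }
        nodes[i] = M;
        fage[i] = cells[i].age;
        fc[i] = cells[i].contact; fl[i] = cells[i].left;
        fr[i] = cells[i].right;
        fn[i] = cells[i].nsub_prev;
        fg[i] = cells[i].gamma_on;
      }
      frames.push_back(List::create(
          _["step"] = global, _["nodes"] = nodes, _["age"] = fage,
          _["contact"] = fc, _["contact_left"] = fl,
          _["contact_right"] = fr, _["nsub"] = fn,
          _["gamma_cc_on"] = fg));
    }
  }

  List out_cells(nc);
  NumericVector out_age(nc);
  LogicalVector out_c(nc), out_l(nc), out_r(nc);
  IntegerVector out_n(nc);
  for (int i = 0; i < nc; ++i) {
    int n = (int)cells[i].x.size();
    NumericMatrix M(n, 2);
    for (int j = 0; j < n; ++j) {
      M(j, 0) = cells[i].x[j]; M(j, 1) = cells[i].z[j];
    }
    out_cells[i] = M;
    out_age[i] = cells[i].age;
    out_c[i] = cells[i].contact;
    out_l[i] = cells[i].left;
    out_r[i] = cells[i].right;
    out_n[i] = cells[i].nsub_prev;
  }
  return List::create(
      _["cells"] = out_cells, _["age"] = out_age, _["contact"] = out_c,
      _["contact_left"] = out_l, _["contact_right"] = out_r,
      _["nsub"] = out_n, _["steps_done"] = steps_done,
      _["frames"] = frames);
}
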