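#include "pcd_common.h"
using namespace Rcpp;

// 2D lattice model.  Sites hold one of the four cell types or are empty.
// Moore (8-site) neighbourhood, non-periodic edges.  The lattice is stored
// column-major (R matrix layout): site (i, j) -> index i + j * nr.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Per-cell assortment of one PCD+ site: same-genotype living neighbours over
// living neighbours.  Returns -1 when the site is not PCD+ or has no living
// neighbour.
static double site_r(const int *g, int nr, int nc, int i, int j) {
  int s = g[i + j * nr];
  if (!st_plus(s)) return -1.0;
  int living = 0, same = 0;
  for (int k = 0; k < 8; ++k) {
    int ii = i + DR[k], jj = j + DC[k];
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    int sn = g[ii + jj * nr];
    if (st_alive(sn)) {
      ++living;
      if (st_plus(sn)) ++same;
    }
  }
  if (living == 0) return -1.0;
  return (double) same / (double) living;
}

static double measure_r(const int *g, int nr, int nc, int *ncount) {
  double sum = 0.0;
  int n = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double ri = site_r(g, nr, nc, i, j);
      if (ri >= 0.0) {
        sum += ri;
        ++n;
      }
    }
  }
  *ncount = n;
  return n > 0 ? sum / n : NA_REAL;
}

// Pass-based repopulation: in each pass the empty sites (visited in random
// order) with at least one living neighbour *at the start of the pass* are
// filled by an offspring of a uniformly chosen such neighbour; offspring
// switch phenotype with their genotype's switch probability and only become
// available as parents in the next pass.  Returns false when no living cell
// exists (nothing to fill from).
static bool repopulate(int *g, int nr, int nc, double p_plus, double p_minus) {
  int n = nr * nc;
  std::vector<int> snapshot(n);
  std::vector<int> empties;
  for (;;) {
    empties.clear();
    bool any_living = false;
    for (int k = 0; k < n; ++k) {
      if (g[k] == 0) empties.push_back(k);
      else any_living = true;
    }
    if (empties.empty()) return true;
    if (!any_living) return false;
    std::copy(g, g + n, snapshot.begin());
    for (int k = (int) empties.size() - 1; k > 0; --k) {
      int j = runif_int(k + 1);
      std::swap(empties[k], empties[j]);
    }
    bool filled = false;
    for (size_t e = 0; e < empties.size(); ++e) {
      int idx = empties[e];
      int i = idx % nr, j = idx / nr;
      int nbr[8];
      int cnt = 0;
      for (int k = 0; k < 8; ++k) {
        int ii = i + DR[k], jj = j + DC[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int sn = snapshot[ii + jj * nr];
        if (st_alive(sn)) nbr[cnt++] = sn;
      }
      if (cnt > 0) {
        int parent = nbr[runif_int(cnt)];
        double p = st_plus(parent) ? p_plus : p_minus;
        int child = parent;
        if (p > 0 && R::unif_rand() < p) child = st_flip(parent);
        g[idx] = child;
        filled = true;
      }
    }
    if (!filled) return false; // unreachable on a connected grid with a living cell
  }
}

static void lat_counts(const int *g, int n, int *cnt) {
  cnt[0] = cnt[1] = cnt[2] = cnt[3] = 0;
  for (int k = 0; k < n; ++k)
    if (g[k] > 0) ++cnt[g[k] - 1];
}

// [[Rcpp::export]]
List lat_measure_r_cpp(IntegerMatrix grid, bool per_cell) {
  int nr = grid.nrow(), nc = grid.ncol();
  const int *g = INTEGER(grid);
  double sum = 0.0;
  int n = 0;
  std::vector<double> vals;
  std::vector<int> rows, cols;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double ri = site_r(g, nr, nc, i, j);
      if (ri >= 0.0) {
        sum += ri;
        ++n;
        if (per_cell) {
          vals.push_back(ri);
          rows.push_back(i + 1);
          cols.push_back(j + 1);
        }
      }
    }
  }
  List out = List::create(
    _["mean_r"] = n > 0 ? sum / n : NA_REAL,
    _["n_cells"] = n);
  if (per_cell) {
    out["r_values"] = wrap(vals);
    out["row"] = wrap(rows);
    out["col"] = wrap(cols);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix lat_repopulate_cpp(IntegerMatrix grid, double p_plus,
                                 double p_minus) {
  IntegerMatrix g = clone(grid);
  bool ok = repopulate(INTEGER(g), g.nrow(), g.ncol(), p_plus, p_minus);
  if (!ok) stop("cannot repopulate a lattice with no living cells");
  return g;
}

// One lattice round: disaster with probability d (uniform phenotype target,
// lattice-wide annihilation), then simultaneous PCD deaths at probability c,
// then repopulation.  prev_target: -1 none yet, 0 A, 1 B.
// [[Rcpp::export]]
List lat_round_cpp(IntegerMatrix grid, double c, double d, double p_plus,
                   double p_minus, int prev_target) {
  IntegerMatrix gm = clone(grid);
  int nr = gm.nrow(), nc = gm.ncol(), n = nr * nc;
  int *g = INTEGER(gm);
  int ncell;
  double r_before = measure_r(g, nr, nc, &ncell);
  bool disaster = (d > 0) && (R::unif_rand() < d);
  int target = -1;
  if (disaster) {
    target = (R::unif_rand() < 0.5) ? 0 : 1;
    for (int k = 0; k < n; ++k)
      if (g[k] > 0 && st_pheno(g[k]) == target) g[k] = 0;
  }
  for (int k = 0; k < n; ++k)
    if (st_plus(g[k]) && R::unif_rand() < c) g[k] = 0;
  bool alive = repopulate(g, nr, nc, p_plus, p_minus);
  double r_after = NA_REAL;
  int cnt[4] = {0, 0, 0, 0};
  if (alive) {
    r_after = measure_r(g, nr, nc, &ncell);
    lat_counts(g, n, cnt);
  }
  int switched = NA_INTEGER;
  if (disaster && prev_target >= 0) switched = (target != prev_target) ? 1 : 0;
  return List::create(
    _["grid"] = gm,
    _["extinct_all"] = !alive,
    _["disaster"] = disaster,
    _["target"] = target,
    _["switched"] = switched,
    _["mean_r_before"] = r_before,
    _["mean_r_after"] = r_after,
    _["counts"] = IntegerVector::create(cnt[0], cnt[1], cnt[2], cnt[3]));
}

// Full lattice competition.  Winner codes as in the well-mixed model.
// [[Rcpp::export]]
List lat_run_cpp(IntegerMatrix init, double c, double d, double p_plus,
                 double p_minus, int max_rounds) {
  IntegerMatrix gm = clone(init);
  int nr = gm.nrow(), nc = gm.ncol(), n = nr * nc;
  int *g = INTEGER(gm);
  std::vector<int> v_round, v1, v2, v3, v4, v_dis, v_tgt, v_sw;
  std::vector<double> v_rb, v_ra;
  int winner = 0, rounds = 0, prev_target = -1;
  int ncell;
  for (int round = 1; round <= max_rounds; ++round) {
    double r_before = measure_r(g, nr, nc, &ncell);
    bool disaster = (d > 0) && (R::unif_rand() < d);
    int target = -1;
    if (disaster) {
      target = (R::unif_rand() < 0.5) ? 0 : 1;
      for (int k = 0; k < n; ++k)
        if (g[k] > 0 && st_pheno(g[k]) == target) g[k] = 0;
    }
    for (int k = 0; k < n; ++k)
      if (st_plus(g[k]) && R::unif_rand() < c) g[k] = 0;
    bool alive = repopulate(g, nr, nc, p_plus, p_minus);
    int cnt[4] = {0, 0, 0, 0};
    double r_after = NA_REAL;
    if (alive) {
      r_after = measure_r(g, nr, nc, &ncell);
      lat_counts(g, n, cnt);
    }
    int switched = NA_INTEGER;
    if (disaster && prev_target >= 0)
      switched = (target != prev_target) ? 1 : 0;
    if (disaster) prev_target = target;
    v_round.push_back(round);
    v1.push_back(cnt[0]);
    v2.push_back(cnt[1]);
    v3.push_back(cnt[2]);
    v4.push_back(cnt[3]);
    v_dis.push_back(disaster ? 1 : 0);
    v_tgt.push_back(target);
    v_sw.push_back(switched);
    v_rb.push_back(r_before);
    v_ra.push_back(r_after);
    rounds = round;
    long Gp = (long) cnt[0] + cnt[1], Gn = (long) cnt[2] + cnt[3];
    if (!alive) { winner = 3; break; }
    if (Gn == 0) { winner = 1; break; }
    if (Gp == 0) { winner = 2; break; }
  }
  if (winner == 0) {
    int cnt[4];
    lat_counts(g, n, cnt);
    long Gp = (long) cnt[0] + cnt[1], Gn = (long) cnt[2] + cnt[3];
    winner = (Gp > Gn) ? 4 : (Gn > Gp) ? 5 : 6;
    rounds = max_rounds;
  }
  return List::create(
    _["winner"] = winner,
    _["rounds"] = rounds,
    _["grid"] = gm,
    _["trajectory"] = List::create(
      _["round"] = wrap(v_round), _["a_plus"] = wrap(v1),
      _["b_plus"] = wrap(v2), _["a_minus"] = wrap(v3),
      _["b_minus"] = wrap(v4), _["disaster"] = wrap(v_dis),
      _["target"] = wrap(v_tgt), _["switched"] = wrap(v_sw),
      _["mean_r_before"] = wrap(v_rb), _["mean_r_after"] = wrap(v_ra)));
}

// Initial configuration at a target mean assortment: equal genotype numbers
// (+/- 1), phenotypes assigned A/B with probability 0.5, then random
// same-phenotype genotype swaps accepted whenever they move the measured
// mean r towards the target.  High targets start from two half-grid
// genotype blocks, others from a uniform random mix.
// [[Rcpp::export]]
List lat_init_cpp(double target_r, int nr, int nc, int max_iter,
                  double tol_stop) {
  int n = nr * nc;
  IntegerMatrix gm(nr, nc);
  int *g = INTEGER(gm);
  int nplus = n / 2;
  std::vector<int> plus_flag(n, 0);
  if (target_r >= 0.8) {
    // left-half columns PCD+ (column-major indices 0 .. nplus-1)
    for (int k = 0; k < nplus; ++k) plus_flag[k] = 1;
  } else {
    for (int k = 0; k < nplus; ++k) plus_flag[k] = 1;
    for (int k = n - 1; k > 0; --k) {
      int j = runif_int(k + 1);
      std::swap(plus_flag[k], plus_flag[j]);
    }
  }
  for (int k = 0; k < n; ++k) {
    int pheno = (R::unif_rand() < 0.5) ? 0 : 1; // 0 = A, 1 = B
    g[k] = plus_flag[k] ? (pheno == 0 ? 1 : 2) : (pheno == 0 ? 3 : 4);
  }
  int ncell;
  double mean = measure_r(g, nr, nc, &ncell);
  double sum = mean * ncell; // full lattice: ncell == nplus, constant
  int iter = 0;
  std::vector<int> affected;
  affected.reserve(20);
  while (std::fabs(mean - target_r) > tol_stop && iter < max_iter) {
    ++iter;
    int i1 = runif_int(n);
    int i2 = runif_int(n);
    int s1 = g[i1], s2 = g[i2];
    if (st_pheno(s1) != st_pheno(s2) || st_plus(s1) == st_plus(s2)) continue;
    // affected sites: the two swapped sites and their neighbourhoods
    affected.clear();
    int both[2] = {i1, i2};
    for (int b = 0; b < 2; ++b) {
      int idx = both[b];
      int ri = idx % nr, cj = idx / nr;
      affected.push_back(idx);
      for (int k = 0; k < 8; ++k) {
        int ii = ri + DR[k], jj = cj + DC[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        affected.push_back(ii + jj * nr);
      }
    }
    std::sort(affected.begin(), affected.end());
    affected.erase(std::unique(affected.begin(), affected.end()),
                   affected.end());
    double before = 0.0;
    for (size_t a = 0; a < affected.size(); ++a) {
      double ri = site_r(g, nr, nc, affected[a] % nr, affected[a] / nr);
      if (ri >= 0.0) before += ri;
    }
    g[i1] = s2;
    g[i2] = s1;
    double after = 0.0;
    for (size_t a = 0; a < affected.size(); ++a) {
      double ri = site_r(g, nr, nc, affected[a] % nr, affected[a] / nr);
      if (ri >= 0.0) after += ri;
    }
    double new_sum = sum - before + after;
    double new_mean = new_sum / ncell;
    if (std::fabs(new_mean - target_r) < std::fabs(mean - target_r)) {
      sum = new_sum;
      mean = new_mean;
    } else {
      g[i1] = s1;
      g[i2] = s2;
    }
  }
  // recompute exactly to shed accumulated float error
  mean = measure_r(g, nr, nc, &ncell);
  return List::create(
    _["grid"] = gm,
    _["achieved_r"] = mean,
    _["iterations"] = iter);
}
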