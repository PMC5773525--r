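#include "pcd_common.h"
using namespace Rcpp;

// 3D patch-structured agent-based model.  The world is a grid of patches,
// each holding at most K cells; within a patch cells are exchangeable so a
// patch is represented by its counts of the four types (columns: A+, B+,
// A-, B-).  Patch index: x + nx * (y + ny * z), zero based.

static int n_neighbors(int k, int nx, int ny, int nz, bool moore, int *out) {
  int x = k % nx, y = (k / nx) % ny, z = k / (nx * ny);
  int cnt = 0;
  if (!moore) {
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int i = 0; i < 6; ++i) {
      int xx = x + dx[i], yy = y + dy[i], zz = z + dz[i];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      out[cnt++] = xx + nx * (yy + ny * zz);
    }
  } else {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          out[cnt++] = xx + nx * (yy + ny * zz);
        }
  }
  return cnt;
}

static int patch_total(const int *C, int P, int k) {
  return C[k] + C[k + P] + C[k + 2 * P] + C[k + 3 * P];
}

// One time step, phases in order: disaster (prob d, kills 1 - kill_fraction
// survivors of the target phenotype in every patch), reproduction (each
// pre-existing cell produces one offspring into its own patch while space
// remains; the reproducing cells are a uniform subset when space is short),
// migration (each cell moves with probability mig to a uniformly chosen
// adjacent patch, blocked if the destination is full), then PCD deaths.
static void abm_step_internal(int *C, int P, int nx, int ny, int nz, int K,
                              double d, double kill_fraction, double p_switch,
                              double mig, double c_pcd, bool moore,
                              int *disaster_out, int *target_out) {
  *disaster_out = 0;
  *target_out = -1;
  if (d > 0 && R::unif_rand() < d) {
    *disaster_out = 1;
    int target = (R::unif_rand() < 0.5) ? 0 : 1;
    *target_out = target;
    int c1 = (target == 0) ? 0 : 1; // A: columns 0 (A+) and 2 (A-)
    int c2 = (target == 0) ? 2 : 3;
    for (int k = 0; k < P; ++k) {
      C[k + c1 * P] = ribinom(C[k + c1 * P], 1.0 - kill_fraction);
      C[k + c2 * P] = ribinom(C[k + c2 * P], 1.0 - kill_fraction);
    }
  }
  // reproduction
  for (int k = 0; k < P; ++k) {
    int n = patch_total(C, P, k);
    int f = K - n;
    if (n <= 0 || f <= 0) continue;
    int births = n < f ? n : f;
    // parents: multivariate hypergeometric draw of `births` cells
    int rem = n, need = births;
    int par[4];
    for (int t = 0; t < 4; ++t) {
      int ct = C[k + t * P];
      if (need <= 0) {
        par[t] = 0;
      } else if (rem == ct) {
        par[t] = need;
        need = 0;
      } else {
        par[t] = (int) R::rhyper((double) ct, (double) (rem - ct),
                                 (double) need);
        need -= par[t];
      }
      rem -= ct;
    }
    for (int t = 0; t < 4; ++t) {
      if (par[t] == 0) continue;
      int sw = ribinom(par[t], p_switch);
      int flip = (t == 0) ? 1 : (t == 1) ? 0 : (t == 2) ? 3 : 2;
      C[k + t * P] += par[t] - sw;
      C[k + flip * P] += sw;
    }
  }
  // migration
  if (mig > 0) {
    std::vector<int> src, typ;
    for (int k = 0; k < P; ++k)
      for (int t = 0; t < 4; ++t) {
        int mv = ribinom(C[k + t * P], mig);
        for (int q = 0; q < mv; ++q) {
          src.push_back(k);
          typ.push_back(t);
        }
      }
    for (int k = (int) src.size() - 1; k > 0; --k) {
      int j = runif_int(k + 1);
      std::swap(src[k], src[j]);
      std::swap(typ[k], typ[j]);
    }
    int nbr[26];
    for (size_t q = 0; q < src.size(); ++q) {
      int cnt = n_neighbors(src[q], nx, ny, nz, moore, nbr);
      if (cnt == 0) continue;
      int dst = nbr[runif_int(cnt)];
      if (patch_total(C, P, dst) < K) {
        C[src[q] + typ[q] * P] -= 1;
        C[dst + typ[q] * P] += 1;
      }
    }
  }
  // PCD deaths (PCD+ genotype only)
  if (c_pcd > 0) {
    for (int k = 0; k < P; ++k) {
      C[k] -= ribinom(C[k], c_pcd);
      C[k + P] -= ribinom(C[k + P], c_pcd);
    }
  }
}

// snapshot metrics: global counts, per-genotype phenotypic diversity
// (normalised Shannon entropy of the A/B split) and patch-level assortment
// (mean over PCD+ cells with at least one patch-mate of the same-genotype
// fraction among patch-mates).
static void abm_metrics_internal(const int *C, int P, long *tot,
                                 double *div_p, double *div_n,
                                 double *r_mean) {
  tot[0] = tot[1] = tot[2] = tot[3] = 0;
  double num = 0.0;
  long den = 0;
  for (int k = 0; k < P; ++k) {
    int c0 = C[k], c1 = C[k + P], c2 = C[k + 2 * P], c3 = C[k + 3 * P];
    tot[0] += c0; tot[1] += c1; tot[2] += c2; tot[3] += c3;
    int n = c0 + c1 + c2 + c3;
    int gp = c0 + c1;
    if (n >= 2 && gp >= 1) {
      num += (double) gp * (double) (gp - 1) / (double) (n - 1);
      den += gp;
    }
  }
  *r_mean = den > 0 ? num / (double) den : NA_REAL;
  long ap = tot[0], bp = tot[1], an = tot[2], bn = tot[3];
  if (ap + bp == 0) {
    *div_p = NA_REAL;
  } else {
    double fa = (double) ap / (double) (ap + bp);
    *div_p = (fa <= 0.0 || fa >= 1.0)
      ? 0.0 : -(fa * std::log(fa) + (1 - fa) * std::log(1 - fa)) / std::log(2.0);
  }
  if (an + bn == 0) {
    *div_n = NA_REAL;
  } else {
    double fa = (double) an / (double) (an + bn);
    *div_n = (fa <= 0.0 || fa >= 1.0)
      ? 0.0 : -(fa * std::log(fa) + (1 - fa) * std::log(1 - fa)) / std::log(2.0);
  }
}

// [[Rcpp::export]]
List abm_step_cpp(IntegerMatrix counts, IntegerVector dims, int K, double d,
                  double kill_fraction, double p_switch, double mig,
                  double c_pcd, bool moore) {
  IntegerMatrix C = clone(counts);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int P = nx * ny * nz;
  int dis, tgt;
  abm_step_internal(INTEGER(C), P, nx, ny, nz, K, d, kill_fraction, p_switch,
                    mig, c_pcd, moore, &dis, &tgt);
  return List::create(_["counts"] = C, _["disaster"] = dis == 1,
                      _["target"] = tgt);
}

// [[Rcpp::export]]
List abm_metrics_cpp(IntegerMatrix counts) {
  int P = counts.nrow();
  long tot[4];
  double dp, dn, rm;
  abm_metrics_internal(INTEGER(counts), P, tot, &dp, &dn, &rm);
  return List::create(
    _["counts"] = IntegerVector::create((int) tot[0], (int) tot[1],
                                        (int) tot[2], (int) tot[3]),
    _["diversity_plus"] = dp, _["diversity_minus"] = dn,
    _["assortment"] = rm);
}

// Run until a genotype present at initialisation goes extinct (total
// extinction for monocultures) or max_steps.  Winner codes as elsewhere.
// [[Rcpp::export]]
List abm_run_cpp(IntegerMatrix counts, IntegerVector dims, int K, double d,
                 double kill_fraction, double p_switch, double mig,
                 double c_pcd, bool moore, int max_steps, int record_every,
                 bool check_capacity) {
  IntegerMatrix Cm = clone(counts);
  int *C = INTEGER(Cm);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int P = nx * ny * nz;
  long tot[4];
  double dp, dn, rm;
  abm_metrics_internal(C, P, tot, &dp, &dn, &rm);
  bool had_plus = (tot[0] + tot[1]) > 0;
  bool had_minus = (tot[2] + tot[3]) > 0;
  std::vector<int> v_step, v1, v2, v3, v4, v_dis, v_tgt;
  std::vector<double> v_dp, v_dn, v_r;
  v_step.push_back(0); v1.push_back((int) tot[0]); v2.push_back((int) tot[1]);
  v3.push_back((int) tot[2]); v4.push_back((int) tot[3]);
  v_dis.push_back(0); v_tgt.push_back(-1);
  v_dp.push_back(dp); v_dn.push_back(dn); v_r.push_back(rm);
  int winner = 0, steps = 0;
  for (int step = 1; step <= max_steps; ++step) {
    int dis, tgt;
    abm_step_internal(C, P, nx, ny, nz, K, d, kill_fraction, p_switch, mig,
                      c_pcd, moore, &dis, &tgt);
    if (check_capacity) {
      for (int k = 0; k < P; ++k)
        if (patch_total(C, P, k) > K)
          stop("patch capacity exceeded (internal error)");
    }
    abm_metrics_internal(C, P, tot, &dp, &dn, &rm);
    steps = step;
    long Gp = tot[0] + tot[1], Gn = tot[2] + tot[3];
    bool ext_p = had_plus && Gp == 0;
    bool ext_n = had_minus && Gn == 0;
    bool terminal = ext_p || ext_n;
    if (terminal || step % record_every == 0) {
      v_step.push_back(step);
      v1.push_back((int) tot[0]); v2.push_back((int) tot[1]);
      v3.push_back((int) tot[2]); v4.push_back((int) tot[3]);
      v_dis.push_back(dis); v_tgt.push_back(tgt);
      v_dp.push_back(dp); v_dn.push_back(dn); v_r.push_back(rm);
    }
    if (terminal) {
      if (ext_p && ext_n) winner = 3;
      else if (ext_n && had_plus) winner = 1;
      else if (ext_p && had_minus) winner = 2;
      else winner = 3; // monoculture extinction
      break;
    }
  }
  if (winner == 0) {
    long Gp = tot[0] + tot[1], Gn = tot[2] + tot[3];
    winner = (Gp > Gn) ? 4 : (Gn > Gp) ? 5 : 6;
    steps = max_steps;
  }
  return List::create(
    _["winner"] = winner,
    _["steps"] = steps,
    _["counts"] = Cm,
    _["trajectory"] = List::create(
      _["step"] = wrap(v_step), _["a_plus"] = wrap(v1),
      _["b_plus"] = wrap(v2), _["a_minus"] = wrap(v3),
      _["b_minus"] = wrap(v4), _["diversity_plus"] = wrap(v_dp),
      _["diversity_minus"] = wrap(v_dn), _["assortment"] = wrap(v_r),
      _["disaster"] = wrap(v_dis), _["target"] = wrap(v_tgt)));
}
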