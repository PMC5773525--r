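#include "pcd_common.h"
using namespace Rcpp;

// Spatially-implicit model: the population is four counts (A+, B+, A-, B-)
// at carrying capacity N, with a fixed assortment probability r.

// One PCD/replacement round.  Deaths are binomial per PCD+ phenotype; each
// dying cell is replaced with probability r by an own-genotype offspring of
// the same phenotype (which switches with probability p_plus), otherwise by
// a competitor offspring whose phenotype is drawn from the competitor's
// phenotype frequencies at the start of the round and then switched with
// probability p_minus.  Total population is conserved.  When the competitor
// is extinct, replacement falls back to the own genotype (r effectively 1):
// only living cells can regrow.
static void pcd_round_counts(int *s, double c, double r,
                             double p_plus, double p_minus) {
  int Ap = s[0], Bp = s[1], An = s[2], Bn = s[3];
  long Gn = (long) An + Bn;
  int dA = ribinom(Ap, c);
  int dB = ribinom(Bp, c);
  double r_eff = (Gn == 0) ? 1.0 : r;
  int ownA = ribinom(dA, r_eff);
  int ownB = ribinom(dB, r_eff);
  int swA = ribinom(ownA, p_plus); // A-parent own replacements switched to B
  int swB = ribinom(ownB, p_plus);
  int comp = (dA - ownA) + (dB - ownB);
  int gainAn = 0, gainBn = 0;
  if (comp > 0) {
    double fA = (double) An / (double) Gn;
    double probA = fA * (1.0 - p_minus) + (1.0 - fA) * p_minus;
    gainAn = ribinom(comp, probA);
    gainBn = comp - gainAn;
  }
  s[0] = Ap - dA + (ownA - swA) + swB;
  s[1] = Bp - dB + (ownB - swB) + swA;
  s[2] = An + gainAn;
  s[3] = Bn + gainBn;
}

// Sequential birth urn: each birth picks a parent uniformly from the current
// (growing) population; offspring inherits genotype and phenotype, switching
// phenotype with the genotype's switch probability.
static void regrow_counts(int *s, double p_plus, double p_minus, int N) {
  long total = (long) s[0] + s[1] + s[2] + s[3];
  if (total <= 0) return;
  while (total < N) {
    double u = R::unif_rand() * (double) total;
    int t = 0;
    double acc = 0.0;
    for (t = 0; t < 4; ++t) {
      acc += s[t];
      if (u < acc) break;
    }
    if (t > 3) t = 3;
    double p = (t < 2) ? p_plus : p_minus;
    int child = t;
    if (p > 0 && R::unif_rand() < p)
      child = (t == 0) ? 1 : (t == 1) ? 0 : (t == 2) ? 3 : 2;
    s[child] += 1;
    ++total;
  }
}

// target: 0 = phenotype A (counts 0 and 2), 1 = phenotype B (counts 1 and 3)
static void disaster_counts(int *s, int target, double kill_fraction) {
  int i1 = (target == 0) ? 0 : 1;
  int i2 = (target == 0) ? 2 : 3;
  if (kill_fraction >= 1.0) {
    s[i1] = 0;
    s[i2] = 0;
  } else {
    s[i1] = ribinom(s[i1], 1.0 - kill_fraction);
    s[i2] = ribinom(s[i2], 1.0 - kill_fraction);
  }
}

// [[Rcpp::export]]
IntegerVector wm_pcd_round_cpp(IntegerVector state, double c, double r,
                               double p_plus, double p_minus) {
  int s[4] = {state[0], state[1], state[2], state[3]};
  pcd_round_counts(s, c, r, p_plus, p_minus);
  return IntegerVector::create(s[0], s[1], s[2], s[3]);
}

// [[Rcpp::export]]
IntegerVector wm_regrow_cpp(IntegerVector state, double p_plus,
                            double p_minus, int N) {
  int s[4] = {state[0], state[1], state[2], state[3]};
  regrow_counts(s, p_plus, p_minus, N);
  return IntegerVector::create(s[0], s[1], s[2], s[3]);
}

// [[Rcpp::export]]
IntegerVector wm_disaster_cpp(IntegerVector state, int target,
                              double kill_fraction) {
  int s[4] = {state[0], state[1], state[2], state[3]};
  disaster_counts(s, target, kill_fraction);
  return IntegerVector::create(s[0], s[1], s[2], s[3]);
}

// Full competition: each round is (disaster with prob d, regrowth to N,
// one PCD/replacement step), until a genotype goes extinct or max_rounds.
// Winner codes: 1 PCD+, 2 PCD-, 3 both extinct, 4/5 timeout majority
// (PCD+/PCD-), 6 timeout tie.
// [[Rcpp::export]]
List wm_run_competition_cpp(IntegerVector init, double p_plus, double p_minus,
                            double c, double r, double d, double kill_fraction,
                            int N, int max_rounds, bool record) {
  int s[4] = {init[0], init[1], init[2], init[3]};
  std::vector<int> v_round, v1, v2, v3, v4, v_dis, v_tgt;
  if (record) {
    v_round.reserve(1024);
  }
  int winner = 0, rounds = 0;
  for (int round = 1; round <= max_rounds; ++round) {
    bool disaster = (d > 0) && (R::unif_rand() < d);
    int target = -1;
    if (disaster) {
      target = (R::unif_rand() < 0.5) ? 0 : 1;
      disaster_counts(s, target, kill_fraction);
    }
    long total = (long) s[0] + s[1] + s[2] + s[3];
    if (total > 0) {
      regrow_counts(s, p_plus, p_minus, N);
      pcd_round_counts(s, c, r, p_plus, p_minus);
    }
    if (record) {
      v_round.push_back(round);
      v1.push_back(s[0]);
      v2.push_back(s[1]);
      v3.push_back(s[2]);
      v4.push_back(s[3]);
      v_dis.push_back(disaster ? 1 : 0);
      v_tgt.push_back(target);
    }
    rounds = round;
    long Gp = (long) s[0] + s[1], Gn = (long) s[2] + s[3];
    if (Gp == 0 && Gn == 0) { winner = 3; break; }
    if (Gn == 0) { winner = 1; break; }
    if (Gp == 0) { winner = 2; break; }
  }
  if (winner == 0) {
    long Gp = (long) s[0] + s[1], Gn = (long) s[2] + s[3];
    winner = (Gp > Gn) ? 4 : (Gn > Gp) ? 5 : 6;
    rounds = max_rounds;
  }
  List out = List::create(
    _["winner"] = winner,
    _["rounds"] = rounds,
    _["state"] = IntegerVector::create(s[0], s[1], s[2], s[3]));
  if (record) {
    out["trajectory"] = List::create(
      _["round"] = wrap(v_round), _["a_plus"] = wrap(v1),
      _["b_plus"] = wrap(v2), _["a_minus"] = wrap(v3),
      _["b_minus"] = wrap(v4), _["disaster"] = wrap(v_dis),
      _["target"] = wrap(v_tgt));
  }
  return out;
}
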