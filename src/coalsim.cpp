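#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Model codes shared with the R layer:
//   0 = SNM, 1 = EXP, 2 = BOT, 3 = BOT_EXP, 4 = IM2
// Time is measured in units of 4*N0 generations; coalescence among k
// lineages in a deme of relative size rho occurs at total rate k*(k-1)/rho.

static double next_coal_time_single(int k, double t, int model, double g,
                                    double t_b, double severity) {
  const double rate0 = (double)k * ((double)k - 1.0);
  for (;;) {
    const bool has_bneck = (model == 2 || model == 3);
    const bool growing = (model == 1 || model == 3) && (!has_bneck || t < t_b);
    const double epoch_end = (has_bneck && t < t_b) ? t_b : R_PosInf;
    const double E = R::exp_rand();
    double tau;
    if (growing && g != 0.0) {
      // rho(s) = exp(-g*s): cumulative hazard rate0*(exp(g(t+tau))-exp(g t))/g
      if (g * t > 700.0) return t + 1e-12; // size already vanishing; merge now
      tau = std::log(std::exp(g * t) + g * E / rate0) / g - t;
    } else {
      const double rho = (has_bneck && t >= t_b) ? 1.0 / severity : 1.0;
      tau = E * rho / rate0;
    }
    if (t + tau <= epoch_end) return t + tau;
    t = epoch_end;
  }
}

static inline int pick_index(int k) {
  int i = (int)(unif_rand() * k);
  return (i >= k) ? k - 1 : i;
}

// Merge two random members of `act`; returns time-stamped new node id.
static void merge_pair(std::vector<int> &act, int node, double t,
                       IntegerVector &parent, NumericVector &node_time) {
  int ia = pick_index((int)act.size());
  int a = act[ia];
  act[ia] = act.back();
  act.pop_back();
  int ib = pick_index((int)act.size());
  int b = act[ib];
  act[ib] = act.back();
  act.pop_back();
  parent[a] = node;
  parent[b] = node;
  node_time[node] = t;
  act.push_back(node);
}

static void sim_single_pop(int n, int model, double g, double t_b,
                           double severity, IntegerVector &parent,
                           NumericVector &node_time) {
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) act.push_back(i);
  int next_node = n;
  double t = 0.0;
  int k = n;
  while (k > 1) {
    t = next_coal_time_single(k, t, model, g, t_b, severity);
    merge_pair(act, next_node, t, parent, node_time);
    ++next_node;
    --k;
  }
}

static void sim_im2(int n1, int n2, double rho2, double rhoA, double t_split,
                    double m12, double m21, IntegerVector &parent,
                    NumericVector &node_time) {
  std::vector<int> act1, act2;
  act1.reserve(2 * (n1 + n2));
  act2.reserve(n2);
  for (int i = 0; i < n1; ++i) act1.push_back(i);
  for (int i = 0; i < n2; ++i) act2.push_back(n1 + i);
  int next_node = n1 + n2;
  double t = 0.0;
  while ((int)(act1.size() + act2.size()) > 1) {
    int k1 = (int)act1.size(), k2 = (int)act2.size();
    if (t < t_split) {
      const double rc1 = (double)k1 * (k1 - 1);            // rho1 = 1
      const double rc2 = (double)k2 * (k2 - 1) / rho2;
      const double rm1 = (double)k1 * m12;
      const double rm2 = (double)k2 * m21;
      const double R = rc1 + rc2 + rm1 + rm2;
      double tau = (R > 0.0) ? R::exp_rand() / R : R_PosInf;
      if (t + tau >= t_split) {
        // lineages merge into the ancestral deme
        t = t_split;
        act1.insert(act1.end(), act2.begin(), act2.end());
        act2.clear();
        continue;
      }
      t += tau;
      double u = unif_rand() * R;
      if (u < rc1) {
        merge_pair(act1, next_node++, t, parent, node_time);
      } else if (u < rc1 + rc2) {
        merge_pair(act2, next_node++, t, parent, node_time);
      } else if (u < rc1 + rc2 + rm1) {
        int ia = pick_index(k1);                           // deme 1 -> deme 2
        act2.push_back(act1[ia]);
        act1[ia] = act1.back();
        act1.pop_back();
      } else {
        int ib = pick_index(k2);                           // deme 2 -> deme 1
        act1.push_back(act2[ib]);
        act2[ib] = act2.back();
        act2.pop_back();
      }
    } else {
      int k = k1 + k2;
      if (!act2.empty()) {
        act1.insert(act1.end(), act2.begin(), act2.end());
        act2.clear();
      }
      const double R = (double)k * (k - 1) / rhoA;
      t += R::exp_rand() / R;
      merge_pair(act1, next_node++, t, parent, node_time);
    }
  }
}

// [[Rcpp::export]]
List sim_genealogy_cpp(int n1, int n2, int model, double g, double t_b,
                       double severity, double rho2, double rhoA,
                       double t_split, double m12, double m21) {
  const int n = n1 + n2;
  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes, 0.0);
  if (model == 4) {
    sim_im2(n1, n2, rho2, rhoA, t_split, m12, m21, parent, node_time);
  } else {
    sim_single_pop(n, model, g, t_b, severity, parent, node_time);
  }
  double total = 0.0;
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] >= 0) total += node_time[parent[i]] - node_time[i];
  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["n"] = n, _["total_length"] = total,
                      _["tmrca"] = node_time[n_nodes - 1]);
}

// Place mutations on a genealogy under the infinite-sites model.
// fixed_s < 0 -> Poisson(theta * total branch length); else exactly fixed_s.
// Returns a polarized n x S 0/1 matrix (1 = derived) with sorted positions
// in (0,1).
// [[Rcpp::export]]
List drop_mutations_cpp(IntegerVector parent, NumericVector node_time,
                        int n, double theta, int fixed_s) {
  const int n_nodes = parent.size();
  std::vector<double> blen(n_nodes, 0.0);
  double total = 0.0;
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] >= 0) {
      blen[i] = node_time[parent[i]] - node_time[i];
      total += blen[i];
    }
  int S = (fixed_s >= 0) ? fixed_s : (int)R::rpois(theta * total);
  NumericVector pos(S);
  for (int j = 0; j < S; ++j) pos[j] = unif_rand();
  std::sort(pos.begin(), pos.end());
  // infinite sites: positions must be unique; redraw the rare RNG ties
  for (int guard = 0; guard < 100; ++guard) {
    bool tied = false;
    for (int j = 1; j < S; ++j)
      if (pos[j] == pos[j - 1]) {
        pos[j] = unif_rand();
        tied = true;
      }
    if (!tied) break;
    std::sort(pos.begin(), pos.end());
  }
  // leaf sets: children always have smaller index than their parent
  std::vector<std::vector<int> > leaves(n_nodes);
  for (int i = 0; i < n; ++i) leaves[i].push_back(i);
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] >= 0) {
      std::vector<int> &p = leaves[parent[i]];
      p.insert(p.end(), leaves[i].begin(), leaves[i].end());
    }
  std::vector<double> cum(n_nodes);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += blen[i];
    cum[i] = acc;
  }
  IntegerMatrix mat(n, S);
  for (int j = 0; j < S; ++j) {
    const double u = unif_rand() * total;
    int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (b >= n_nodes) b = n_nodes - 1;
    const std::vector<int> &lv = leaves[b];
    for (size_t q = 0; q < lv.size(); ++q) mat(lv[q], j) = 1;
  }
  return List::create(_["matrix"] = mat, _["positions"] = pos,
                      _["total_length"] = total);
}

// Fast batch sampler of (S, tmrca, total_length) for single-population models.
// [[Rcpp::export]]
NumericMatrix sim_s_tmrca_cpp(int n, int model, double g, double t_b,
                              double severity, double theta, int n_reps) {
  const int n_nodes = 2 * n - 1;
  NumericMatrix out(n_reps, 3);
  for (int r = 0; r < n_reps; ++r) {
    IntegerVector parent(n_nodes, -1);
    NumericVector node_time(n_nodes, 0.0);
    sim_single_pop(n, model, g, t_b, severity, parent, node_time);
    double total = 0.0;
    for (int i = 0; i < n_nodes; ++i)
      if (parent[i] >= 0) total += node_time[parent[i]] - node_time[i];
    out(r, 0) = (theta > 0.0) ? R::rpois(theta * total) : 0.0;
    out(r, 1) = node_time[n_nodes - 1];
    out(r, 2) = total;
  }
  return out;
}

// Null distribution machinery for the fixed-S neutrality tests: for each
// replicate simulate a standard-neutral genealogy, place exactly S mutations
// (multinomially by branch length, ancestral state known), and return the
// per-replicate mean pairwise diversity (theta_pi) and theta_H.
// [[Rcpp::export]]
NumericMatrix fixed_s_null_cpp(int n, int S, int n_reps) {
  const int n_nodes = 2 * n - 1;
  NumericMatrix out(n_reps, 2);
  const double denom = (double)n * (n - 1);
  for (int r = 0; r < n_reps; ++r) {
    IntegerVector parent(n_nodes, -1);
    NumericVector node_time(n_nodes, 0.0);
    sim_single_pop(n, 0, 0.0, 0.0, 1.0, parent, node_time);
    std::vector<double> blen(n_nodes, 0.0);
    std::vector<int> nleaf(n_nodes, 0);
    for (int i = 0; i < n; ++i) nleaf[i] = 1;
    double total = 0.0;
    for (int i = 0; i < n_nodes; ++i)
      if (parent[i] >= 0) {
        blen[i] = node_time[parent[i]] - node_time[i];
        total += blen[i];
        nleaf[parent[i]] += nleaf[i];
      }
    std::vector<double> cum(n_nodes);
    double acc = 0.0;
    for (int i = 0; i < n_nodes; ++i) {
      acc += blen[i];
      cum[i] = acc;
    }
    double pi_sum = 0.0, th_sum = 0.0;
    for (int j = 0; j < S; ++j) {
      const double u = unif_rand() * total;
      int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (b >= n_nodes) b = n_nodes - 1;
      const double c = (double)nleaf[b];
      pi_sum += 2.0 * c * (n - c);
      th_sum += 2.0 * c * c;
    }
    out(r, 0) = pi_sum / denom;
    out(r, 1) = th_sum / denom;
  }
  return out;
}
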