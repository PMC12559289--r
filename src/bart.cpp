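// Probit BART: sum-of-trees sampler with truncated-normal data augmentation.
//
// Model: y_i ~ Bernoulli(Phi(f(x_i))), f = sum_j g(x; T_j, M_j), latent
// z_i ~ N(f(x_i), 1) truncated by the observed class.  Tree structures carry
// the depth-penalising split prior P(split | depth d) = alpha * (1+d)^-beta,
// leaf values are N(0, sigma_mu^2) with sigma_mu = 3 / (k * sqrt(m)), and the
// residual variance is fixed at 1 (probit identifiability).
//
// Trees are updated one at a time by Metropolis-Hastings on the structure
// (grow / prune / change / swap) with the leaf marginal likelihood
// integrated out, followed by conjugate-normal leaf draws.  All randomness
// comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Node {
  int var;      // -1 for a leaf, else 0-based covariate index
  double cut;   // x[var] <= cut descends left
  int left;     // child indices within the tree vector, -1 for a leaf
  int right;
  double value; // leaf value (ignored on interior nodes)
};

typedef std::vector<Node> Tree;

inline Tree stump() {
  Tree t(1);
  t[0].var = -1; t[0].cut = 0.0; t[0].left = -1; t[0].right = -1; t[0].value = 0.0;
  return t;
}

inline double psplit(int depth, double alpha, double beta) {
  return alpha * std::pow(1.0 + depth, -beta);
}

// Depth of every node, root = 0.  Assumes a compact tree (no orphans).
void compute_depths(const Tree& tr, std::vector<int>& depth) {
  depth.assign(tr.size(), 0);
  for (size_t i = 0; i < tr.size(); ++i) {
    if (tr[i].var >= 0) {
      depth[tr[i].left]  = depth[i] + 1;
      depth[tr[i].right] = depth[i] + 1;
    }
  }
}

// Rebuild a tree in depth-first preorder, dropping orphaned nodes.
int compact_rec(const Tree& tr, int idx, Tree& out) {
  int my = (int) out.size();
  out.push_back(tr[idx]);
  if (tr[idx].var >= 0) {
    int l = compact_rec(tr, tr[idx].left, out);
    int r = compact_rec(tr, tr[idx].right, out);
    out[my].left = l;
    out[my].right = r;
  } else {
    out[my].left = -1;
    out[my].right = -1;
  }
  return my;
}

Tree compact(const Tree& tr) {
  Tree out;
  out.reserve(tr.size());
  compact_rec(tr, 0, out);
  return out;
}

inline int leaf_of(const Tree& tr, const double* Xp, int n, int i) {
  int nd = 0;
  while (tr[nd].var >= 0)
    nd = (Xp[(size_t) tr[nd].var * n + i] <= tr[nd].cut) ? tr[nd].left : tr[nd].right;
  return nd;
}

// Per-leaf counts and residual sums; returns false if any leaf is empty
// (such proposals are rejected: the prior is restricted to trees whose
// leaves all contain training data).
bool leaf_suff(const Tree& tr, const double* Xp, int n,
               const std::vector<double>& r,
               std::vector<int>& cnt, std::vector<double>& sum) {
  cnt.assign(tr.size(), 0);
  sum.assign(tr.size(), 0.0);
  for (int i = 0; i < n; ++i) {
    int nd = leaf_of(tr, Xp, n, i);
    cnt[nd]++;
    sum[nd] += r[i];
  }
  for (size_t j = 0; j < tr.size(); ++j)
    if (tr[j].var < 0 && cnt[j] == 0) return false;
  return true;
}

// Log marginal likelihood of the residuals with leaf values integrated out
// (terms not depending on the partition cancel in MH ratios and are dropped).
double marg_loglik(const Tree& tr, const std::vector<int>& cnt,
                   const std::vector<double>& sum, double s2mu) {
  double ll = 0.0;
  for (size_t j = 0; j < tr.size(); ++j) {
    if (tr[j].var < 0) {
      double denom = 1.0 + cnt[j] * s2mu;
      ll += -0.5 * std::log(denom) + 0.5 * s2mu * sum[j] * sum[j] / denom;
    }
  }
  return ll;
}

void list_leaves(const Tree& tr, std::vector<int>& out) {
  out.clear();
  for (size_t j = 0; j < tr.size(); ++j) if (tr[j].var < 0) out.push_back((int) j);
}

void list_internal(const Tree& tr, std::vector<int>& out) {
  out.clear();
  for (size_t j = 0; j < tr.size(); ++j) if (tr[j].var >= 0) out.push_back((int) j);
}

// Interior nodes whose both children are leaves (prunable).
void list_prunable(const Tree& tr, std::vector<int>& out) {
  out.clear();
  for (size_t j = 0; j < tr.size(); ++j)
    if (tr[j].var >= 0 && tr[tr[j].left].var < 0 && tr[tr[j].right].var < 0)
      out.push_back((int) j);
}

inline int runif_int(int k) {          // uniform on 0..k-1
  int v = (int) std::floor(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

// Serialize a tree depth-first into the flat posterior arrays, returning the
// absolute index of its root.
int serialize_rec(const Tree& tr, int idx,
                  std::vector<int>& o_var, std::vector<double>& o_cut,
                  std::vector<double>& o_val,
                  std::vector<int>& o_left, std::vector<int>& o_right) {
  int my = (int) o_var.size();
  o_var.push_back(tr[idx].var);
  o_cut.push_back(tr[idx].cut);
  o_val.push_back(tr[idx].value);
  o_left.push_back(-1);
  o_right.push_back(-1);
  if (tr[idx].var >= 0) {
    int l = serialize_rec(tr, tr[idx].left, o_var, o_cut, o_val, o_left, o_right);
    int r = serialize_rec(tr, tr[idx].right, o_var, o_cut, o_val, o_left, o_right);
    o_left[my] = l;
    o_right[my] = r;
  }
  return my;
}

} // namespace

// [[Rcpp::export]]
List bart_probit_fit_cpp(NumericMatrix X, IntegerVector y, int m, double k,
                         double alpha, double beta, int n_burn, int n_draws,
                         double clip = 10.0,
                         double p_grow = 0.25, double p_prune = 0.25,
                         double p_change = 0.40, double p_swap = 0.10) {
  const int n = X.nrow();
  const int p = X.ncol();
  const double* Xp = &X[0];
  const double sigma_mu = 3.0 / (k * std::sqrt((double) m));
  const double s2mu = sigma_mu * sigma_mu;

  // Candidate cutpoints: observed unique values per covariate, excluding the
  // maximum (the rule x <= cut must send at least one value right).
  std::vector< std::vector<double> > cuts(p);
  for (int v = 0; v < p; ++v) {
    std::vector<double> col(n);
    for (int i = 0; i < n; ++i) col[i] = Xp[(size_t) v * n + i];
    std::sort(col.begin(), col.end());
    col.erase(std::unique(col.begin(), col.end()), col.end());
    if (!col.empty()) col.pop_back();
    cuts[v] = col;
  }

  std::vector<Tree> trees(m, stump());
  std::vector< std::vector<double> > tfit(m, std::vector<double>(n, 0.0));
  std::vector<double> total(n, 0.0), z(n, 0.0), r(n, 0.0);
  std::vector<int> cnt, cnt_new, depth;
  std::vector<double> sum, sum_new;
  std::vector<int> leaves, internal, prunable, pairs_parent, pairs_child;

  std::vector<int> o_var, o_left, o_right, roots;
  std::vector<double> o_cut, o_val;
  roots.reserve((size_t) n_draws * m);

  int accepted = 0, proposed = 0;
  const int total_iter = n_burn + n_draws;

  for (int iter = 0; iter < total_iter; ++iter) {
    // --- latent truncated-normal draws, unit error variance ---
    for (int i = 0; i < n; ++i) {
      double mu = total[i];
      double u = unif_rand();
      double zi;
      if (y[i] == 1) {
        double p0 = R::pnorm(0.0, mu, 1.0, 1, 0);  // P(z <= 0)
        zi = R::qnorm(p0 + u * (1.0 - p0), mu, 1.0, 1, 0);
        if (!R_finite(zi) || zi > clip) zi = clip;
        if (zi <= 0.0) zi = 1e-8;
      } else {
        double p0 = R::pnorm(0.0, mu, 1.0, 1, 0);
        zi = R::qnorm(u * p0, mu, 1.0, 1, 0);
        if (!R_finite(zi) || zi < -clip) zi = -clip;
        if (zi >= 0.0) zi = -1e-8;
      }
      z[i] = zi;
    }

    // --- one MH structural move + conjugate leaf draw per tree ---
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) r[i] = z[i] - (total[i] - tfit[j][i]);

      Tree& tr = trees[j];
      leaf_suff(tr, Xp, n, r, cnt, sum);
      double ll_cur = marg_loglik(tr, cnt, sum, s2mu);

      Tree prop;
      bool have_prop = false;
      double log_ratio = 0.0;   // structure-prior and proposal correction
      double u = unif_rand();
      ++proposed;

      if (u < p_grow) {
        // ---- GROW ----
        list_leaves(tr, leaves);
        int L = leaves[runif_int((int) leaves.size())];
        int v = runif_int(p);
        if (!cuts[v].empty()) {
          double c = cuts[v][runif_int((int) cuts[v].size())];
          prop = tr;
          prop[L].var = v; prop[L].cut = c;
          prop[L].left = (int) prop.size();
          prop[L].right = (int) prop.size() + 1;
          Node leaf; leaf.var = -1; leaf.cut = 0.0; leaf.left = -1; leaf.right = -1; leaf.value = 0.0;
          prop.push_back(leaf);
          prop.push_back(leaf);
          compute_depths(tr, depth);
          int d = depth[L];
          list_prunable(prop, prunable);
          double ps = psplit(d, alpha, beta), ps1 = psplit(d + 1, alpha, beta);
          log_ratio = std::log(ps) + 2.0 * std::log(1.0 - ps1) - std::log(1.0 - ps)
                    + std::log(p_prune) - std::log(p_grow)
                    + std::log((double) leaves.size())
                    - std::log((double) prunable.size());
          have_prop = true;
        }
      } else if (u < p_grow + p_prune) {
        // ---- PRUNE ----
        list_prunable(tr, prunable);
        if (!prunable.empty()) {
          int P = prunable[runif_int((int) prunable.size())];
          compute_depths(tr, depth);
          int d = depth[P];
          Tree tmp = tr;
          tmp[P].var = -1; tmp[P].left = -1; tmp[P].right = -1; tmp[P].value = 0.0;
          prop = compact(tmp);
          list_leaves(prop, leaves);
          double ps = psplit(d, alpha, beta), ps1 = psplit(d + 1, alpha, beta);
          log_ratio = -std::log(ps) - 2.0 * std::log(1.0 - ps1) + std::log(1.0 - ps)
                    + std::log(p_grow) - std::log(p_prune)
                    + std::log((double) prunable.size())
                    - std::log((double) leaves.size());
          have_prop = true;
        }
      } else if (u < p_grow + p_prune + p_change) {
        // ---- CHANGE ---- (symmetric: rule-prior and proposal terms cancel)
        list_internal(tr, internal);
        if (!internal.empty()) {
          int C = internal[runif_int((int) internal.size())];
          int v = runif_int(p);
          if (!cuts[v].empty()) {
            double c = cuts[v][runif_int((int) cuts[v].size())];
            prop = tr;
            prop[C].var = v; prop[C].cut = c;
            have_prop = true;
          }
        }
      } else {
        // ---- SWAP ---- (symmetric: structure unchanged)
        pairs_parent.clear(); pairs_child.clear();
        for (size_t a = 0; a < tr.size(); ++a) {
          if (tr[a].var < 0) continue;
          if (tr[tr[a].left].var >= 0)  { pairs_parent.push_back((int) a); pairs_child.push_back(tr[a].left); }
          if (tr[tr[a].right].var >= 0) { pairs_parent.push_back((int) a); pairs_child.push_back(tr[a].right); }
        }
        if (!pairs_parent.empty()) {
          int s = runif_int((int) pairs_parent.size());
          prop = tr;
          std::swap(prop[pairs_parent[s]].var, prop[pairs_child[s]].var);
          std::swap(prop[pairs_parent[s]].cut, prop[pairs_child[s]].cut);
          have_prop = true;
        }
      }

      bool use_prop = false;
      if (have_prop && leaf_suff(prop, Xp, n, r, cnt_new, sum_new)) {
        double ll_new = marg_loglik(prop, cnt_new, sum_new, s2mu);
        double logA = ll_new - ll_cur + log_ratio;
        if (std::log(unif_rand()) < logA) use_prop = true;
      }
      if (use_prop) {
        tr = prop;
        cnt = cnt_new;
        sum = sum_new;
        ++accepted;
      }

      // Conjugate leaf-value draws given the partial residuals.
      for (size_t nd = 0; nd < tr.size(); ++nd) {
        if (tr[nd].var < 0) {
          double denom = 1.0 + cnt[nd] * s2mu;
          double post_mean = s2mu * sum[nd] / denom;
          double post_sd = std::sqrt(s2mu / denom);
          tr[nd].value = post_mean + post_sd * norm_rand();
        }
      }

      // Refresh this tree's fit and the running total.
      for (int i = 0; i < n; ++i) {
        double nf = tr[leaf_of(tr, Xp, n, i)].value;
        total[i] += nf - tfit[j][i];
        tfit[j][i] = nf;
      }
    }

    if (iter >= n_burn) {
      for (int j = 0; j < m; ++j)
        roots.push_back(serialize_rec(trees[j], 0, o_var, o_cut, o_val, o_left, o_right));
    }
  }

  return List::create(
    _["var"] = wrap(o_var), _["cut"] = wrap(o_cut), _["value"] = wrap(o_val),
    _["left"] = wrap(o_left), _["right"] = wrap(o_right),
    _["roots"] = wrap(roots),
    _["m"] = m, _["n_draws"] = n_draws,
    _["sigma_mu"] = sigma_mu,
    _["acceptance_rate"] = proposed > 0 ? (double) accepted / proposed : NA_REAL);
}

// [[Rcpp::export]]
List bart_predict_cpp(IntegerVector var, NumericVector cut, NumericVector value,
                      IntegerVector left, IntegerVector right, IntegerVector roots,
                      int m, NumericMatrix Xnew, IntegerVector draw_ids,
                      bool return_draws, double lower_q, double upper_q) {
  const int n = Xnew.nrow();
  const int nd = draw_ids.size();
  const double* Xp = &Xnew[0];
  const int* vp = INTEGER(var);
  const double* cp = REAL(cut);
  const double* valp = REAL(value);
  const int* lp = INTEGER(left);
  const int* rp = INTEGER(right);
  const int* rootp = INTEGER(roots);

  NumericMatrix draws(n, nd);
  double* dp = &draws[0];
  for (int di = 0; di < nd; ++di) {
    int d = draw_ids[di];
    double* col = dp + (size_t) di * n;
    for (int j = 0; j < m; ++j) {
      int root = rootp[(size_t) d * m + j];
      for (int i = 0; i < n; ++i) {
        int nod = root;
        while (vp[nod] >= 0)
          nod = (Xp[(size_t) vp[nod] * n + i] <= cp[nod]) ? lp[nod] : rp[nod];
        col[i] += valp[nod];
      }
    }
    for (int i = 0; i < n; ++i) col[i] = R::pnorm(col[i], 0.0, 1.0, 1, 0);
  }

  NumericVector mean(n), lower(n), upper(n);
  std::vector<double> row(nd);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int di = 0; di < nd; ++di) { row[di] = dp[(size_t) di * n + i]; s += row[di]; }
    mean[i] = s / nd;
    std::sort(row.begin(), row.end());
    // type-7 quantiles, matching stats::quantile defaults
    double hl = (nd - 1) * lower_q, hu = (nd - 1) * upper_q;
    int fl = (int) std::floor(hl), fu = (int) std::floor(hu);
    int cl = std::min(fl + 1, nd - 1), cu = std::min(fu + 1, nd - 1);
    lower[i] = row[fl] + (hl - fl) * (row[cl] - row[fl]);
    upper[i] = row[fu] + (hu - fu) * (row[cu] - row[fu]);
  }

  if (return_draws)
    return List::create(_["mean"] = mean, _["lower"] = lower, _["upper"] = upper,
                        _["draws"] = draws);
  return List::create(_["mean"] = mean, _["lower"] = lower, _["upper"] = upper);
}
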