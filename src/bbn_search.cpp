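// Discrete Bayesian network structure search scored by minimum description
// length.  Data arrive as an integer matrix (1..arity[j], NA = missing);
// family scores use complete cases on the child-plus-parents subset only.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

static const double LOG2E = 1.4426950408889634;

// data_bits + model_bits for one node given a parent set.
// out[0] = data bits, out[1] = model bits, out[2] = records used.
static void family_bits(const IntegerMatrix& X, const IntegerVector& arity,
                        int child, const std::vector<int>& parents,
                        double* out) {
  const int n = X.nrow();
  const int r = arity[child];
  long long q = 1;
  std::vector<long long> stride(parents.size());
  for (size_t k = 0; k < parents.size(); ++k) {
    stride[k] = q;
    q *= arity[parents[k]];
    if (q > 2000000LL) stop("parent state space too large");
  }
  std::vector<double> counts(static_cast<size_t>(q) * r, 0.0);
  long long used = 0;
  for (int i = 0; i < n; ++i) {
    int c = X(i, child);
    if (c == NA_INTEGER) continue;
    long long idx = 0;
    bool ok = true;
    for (size_t k = 0; k < parents.size(); ++k) {
      int v = X(i, parents[k]);
      if (v == NA_INTEGER) { ok = false; break; }
      idx += stride[k] * (v - 1);
    }
    if (!ok) continue;
    counts[idx * r + (c - 1)] += 1.0;
    ++used;
  }
  double ll = 0.0;  // sum of log2 P(child | parents) over used records
  for (long long s = 0; s < q; ++s) {
    double tot = 0.0;
    for (int c = 0; c < r; ++c) tot += counts[s * r + c];
    if (tot == 0.0) continue;
    for (int c = 0; c < r; ++c) {
      double m = counts[s * r + c];
      if (m > 0.0) ll += m * std::log(m / tot) * LOG2E;
    }
  }
  out[0] = -ll;
  out[1] = (used > 0) ? 0.5 * std::log((double)used) * LOG2E * (r - 1) * (double)q
                      : 0.0;
  out[2] = (double)used;
}

// [[Rcpp::export]]
NumericVector cpp_family_bits(IntegerMatrix X, IntegerVector arity,
                              int child, IntegerVector parents) {
  std::vector<int> par(parents.begin(), parents.end());
  double out[3];
  family_bits(X, arity, child, par, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

typedef std::vector<std::vector<bool> > Adj;

// is there a directed path from a to b?
static bool has_path(const Adj& adj, int a, int b, int p) {
  if (a == b) return true;
  std::vector<bool> seen(p, false);
  std::vector<int> stack(1, a);
  seen[a] = true;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int v = 0; v < p; ++v) {
      if (adj[u][v] && !seen[v]) {
        if (v == b) return true;
        seen[v] = true;
        stack.push_back(v);
      }
    }
  }
  return false;
}

struct ScoreCache {
  const IntegerMatrix& X;
  const IntegerVector& arity;
  bool use_memo;
  std::map<std::pair<int, uint64_t>, double> memo;
  ScoreCache(const IntegerMatrix& X_, const IntegerVector& a_)
      : X(X_), arity(a_), use_memo(X_.ncol() <= 64) {}
  double score(int child, const std::vector<int>& parents) {
    uint64_t mask = 0;
    if (use_memo) {
      for (size_t k = 0; k < parents.size(); ++k)
        mask |= (uint64_t)1 << parents[k];
      std::pair<int, uint64_t> key(child, mask);
      std::map<std::pair<int, uint64_t>, double>::iterator it = memo.find(key);
      if (it != memo.end()) return it->second;
      double out[3];
      family_bits(X, arity, child, parents, out);
      double s = out[0] + out[1];
      memo[key] = s;
      return s;
    }
    double out[3];
    family_bits(X, arity, child, parents, out);
    return out[0] + out[1];
  }
};

static std::vector<int> parents_of(const Adj& adj, int j, int p) {
  std::vector<int> par;
  for (int i = 0; i < p; ++i)
    if (adj[i][j]) par.push_back(i);
  return par;
}

static std::vector<int> with_parent(const std::vector<int>& par, int add) {
  std::vector<int> out(par);
  out.push_back(add);
  // keep sorted so memo masks and count strides are canonical
  for (size_t k = out.size() - 1; k > 0 && out[k] < out[k - 1]; --k)
    std::swap(out[k], out[k - 1]);
  return out;
}

static std::vector<int> without_parent(const std::vector<int>& par, int drop) {
  std::vector<int> out;
  for (size_t k = 0; k < par.size(); ++k)
    if (par[k] != drop) out.push_back(par[k]);
  return out;
}

// Greedy hill climbing from the required-arcs graph over {add, delete,
// reverse}.  A move is accepted only when it lowers the description length
// by more than lambda times the current description length of the families
// it modifies (the changed child's family; both endpoint families for a
// reversal) — a scale-free sparsity gate: lambda = 0 recovers plain MDL
// hill climbing, larger lambda demands proportionally stronger evidence
// per arc regardless of how many other variables are in the table.  Ties
// between equally good moves break by enumeration order (add, then delete,
// then reverse; within an operator by (from, to) column index), so the
// search is deterministic.
// [[Rcpp::export]]
List cpp_hc(IntegerMatrix X, IntegerVector arity, double lambda,
            int max_parents, LogicalMatrix forbidden, LogicalMatrix required) {
  const int p = X.ncol();
  ScoreCache cache(X, arity);
  Adj adj(p, std::vector<bool>(p, false));
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (required(i, j)) adj[i][j] = true;
  // cycle check on the required skeleton
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (adj[i][j]) {
        adj[i][j] = false;
        if (has_path(adj, j, i, p)) stop("required arcs form a cycle");
        adj[i][j] = true;
      }

  std::vector<double> fam(p);
  double total = 0.0;
  for (int j = 0; j < p; ++j) {
    fam[j] = cache.score(j, parents_of(adj, j, p));
    total += fam[j];
  }

  const int max_iter = 4 * p * p + 16;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    double best_gain = 0.0;
    int best_op = -1, best_i = -1, best_j = -1;
    double best_new_j = 0.0, best_new_i = 0.0;

    // operator 1: add i -> j
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (i == j || adj[i][j] || adj[j][i] || forbidden(i, j)) continue;
        std::vector<int> par = parents_of(adj, j, p);
        if ((int)par.size() >= max_parents) continue;
        if (has_path(adj, j, i, p)) continue;  // would create a cycle
        double s = cache.score(j, with_parent(par, i));
        double gain = fam[j] - s;
        if (gain > lambda * fam[j] && gain > best_gain + 1e-12) {
          best_gain = gain; best_op = 0; best_i = i; best_j = j;
          best_new_j = s;
        }
      }
    }
    // operator 2: delete i -> j
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (!adj[i][j] || required(i, j)) continue;
        std::vector<int> par = parents_of(adj, j, p);
        double s = cache.score(j, without_parent(par, i));
        double gain = fam[j] - s;
        if (gain > lambda * fam[j] && gain > best_gain + 1e-12) {
          best_gain = gain; best_op = 1; best_i = i; best_j = j;
          best_new_j = s;
        }
      }
    }
    // operator 3: reverse i -> j (becomes j -> i)
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (!adj[i][j] || required(i, j) || forbidden(j, i)) continue;
        std::vector<int> par_i = parents_of(adj, i, p);
        if ((int)par_i.size() >= max_parents) continue;
        adj[i][j] = false;
        bool cyc = has_path(adj, i, j, p);
        adj[i][j] = true;
        if (cyc) continue;
        std::vector<int> par_j = parents_of(adj, j, p);
        double s_j = cache.score(j, without_parent(par_j, i));
        double s_i = cache.score(i, with_parent(par_i, j));
        double gain = (fam[j] - s_j) + (fam[i] - s_i);
        if (gain > lambda * (fam[i] + fam[j]) && gain > best_gain + 1e-12) {
          best_gain = gain; best_op = 2; best_i = i; best_j = j;
          best_new_j = s_j; best_new_i = s_i;
        }
      }
    }

    if (best_op < 0) break;
    if (best_op == 0) {
      adj[best_i][best_j] = true;
      fam[best_j] = best_new_j;
    } else if (best_op == 1) {
      adj[best_i][best_j] = false;
      fam[best_j] = best_new_j;
    } else {
      adj[best_i][best_j] = false;
      adj[best_j][best_i] = true;
      fam[best_j] = best_new_j;
      fam[best_i] = best_new_i;
    }
    total -= best_gain;
  }

  LogicalMatrix out(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) out(i, j) = adj[i][j];
  return List::create(_["adjacency"] = out, _["total"] = total,
                      _["iterations"] = iter);
}
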