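// Bayesian structure-learning internals: an exact posterior oracle that
// sums the score over every DAG exactly once (inclusion-exclusion over
// sink sets), a single-edge Metropolis-Hastings sampler over DAG space,
// and a parent-set sampler used when drawing a DAG conditional on an
// ordered node partition.
//
// Score tables are per-node vectors of log local scores indexed by a
// compressed bitmask over the remaining p-1 nodes in increasing order.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int compress_mask(int m, int j) {
  int low = m & ((1 << j) - 1);
  int high = (m >> (j + 1)) << j;
  return low | high;
}

// expand per-node compressed score table into linear-space alpha over
// full p-bit masks: A[j][U] = sum_{pa subset of U\{j}} exp(s_j(pa) - M_j)
static void build_alpha(const List& tables, int p,
                        std::vector<std::vector<double>>& A,
                        std::vector<double>& M) {
  int full = 1 << p;
  A.assign(p, std::vector<double>(full));
  M.assign(p, 0.0);
  int csize = 1 << (p - 1);
  for (int j = 0; j < p; ++j) {
    NumericVector tab = tables[j];
    if (tab.size() != csize) stop("score table has wrong length");
    double m = tab[0];
    for (int k = 1; k < csize; ++k) if (tab[k] > m) m = tab[k];
    M[j] = m;
    std::vector<double> z(csize);
    for (int k = 0; k < csize; ++k) z[k] = std::exp(tab[k] - m);
    // zeta transform (subset sums) over p-1 bits
    for (int b = 0; b < p - 1; ++b)
      for (int k = 0; k < csize; ++k)
        if (k & (1 << b)) z[k] += z[k ^ (1 << b)];
    for (int U = 0; U < full; ++U)
      A[j][U] = z[compress_mask(U & ~(1 << j), j)];
  }
}

// Z = sum over DAGs on the node set `full` of prod_j alpha-normalised
// scores, by the sink-set inclusion-exclusion recurrence.
// If mod_node >= 0, that node's alpha is restricted to parent sets
// containing mod_req: alpha~(U) = A(U) - A(U \ {mod_req}).
static double dag_sum(const std::vector<std::vector<double>>& A, int p,
                      int mod_node, int mod_req) {
  int full = (1 << p) - 1;
  std::vector<double> f(full + 1, 0.0);
  f[0] = 1.0;
  int reqbit = (mod_req >= 0) ? (1 << mod_req) : 0;
  for (int S = 1; S <= full; ++S) {
    double acc = 0.0;
    // iterate non-empty subsets T of S (candidate sink sets)
    for (int T = S; T > 0; T = (T - 1) & S) {
      int U = S ^ T;  // remaining nodes; parents drawn from U
      double prod = f[U];
      int nT = 0;
      for (int j = 0; j < p && prod != 0.0; ++j) {
        if (!(T & (1 << j))) continue;
        ++nT;
        double a;
        if (j == mod_node)
          a = A[j][U] - A[j][U & ~reqbit];
        else
          a = A[j][U];
        prod *= a;
      }
      acc += ((nT & 1) ? prod : -prod);
    }
    f[S] = acc;
  }
  return f[full];
}

// [[Rcpp::export]]
Rcpp::List cpp_exact_posterior(const Rcpp::List& tables, int p) {
  if (p < 1 || p > 16) stop("exact posterior supports 1 <= p <= 16");
  std::vector<std::vector<double>> A;
  std::vector<double> M;
  build_alpha(tables, p, A, M);
  double Z = dag_sum(A, p, -1, -1);
  if (!(Z > 0.0)) stop("exact posterior: evidence underflowed or is non-positive");
  NumericMatrix prob(p, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      double Zij = dag_sum(A, p, j, i);
      double pr = Zij / Z;
      if (pr < 0.0) pr = 0.0;
      if (pr > 1.0) pr = 1.0;
      prob(i, j) = pr;  // P(i -> j)
    }
  }
  double logZ = std::log(Z);
  for (int j = 0; j < p; ++j) logZ += M[j];
  return Rcpp::List::create(Rcpp::Named("edge_prob") = prob,
                            Rcpp::Named("log_evidence") = logZ);
}

static inline double table_score(const NumericVector& tab, int pa_mask, int j) {
  return tab[compress_mask(pa_mask, j)];
}

// is `target` reachable from `from` following child pointers?
static bool reachable(const std::vector<int>& children, int from, int target, int p) {
  int visited = 1 << from;
  std::vector<int> stack{from};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int ch = children[v];
    if (ch & (1 << target)) return true;
    for (int u = 0; u < p; ++u)
      if ((ch & (1 << u)) && !(visited & (1 << u))) {
        visited |= (1 << u);
        stack.push_back(u);
      }
  }
  return false;
}

// Single-edge add/delete/reverse Metropolis-Hastings over DAGs with a
// uniform structure prior times an optional per-edge log penalty.
// Proposal: pick an ordered pair (i,j) uniformly; if i->j exists, flip a
// coin between delete and reverse; if neither orientation exists,
// propose adding i->j; otherwise the move is null.  The resulting
// Hastings correction is 1/2 for additions and 2 for deletions.
// [[Rcpp::export]]
Rcpp::List cpp_edge_mh(const Rcpp::List& tables, int p, double n_iter,
                       double burn_in, double thin, double edge_logprior,
                       Rcpp::IntegerVector init_parents) {
  if (p < 1 || p > 16) stop("edge sampler supports 1 <= p <= 16");
  std::vector<int> parents(p, 0), children(p, 0);
  std::vector<NumericVector> tabs(p);
  for (int j = 0; j < p; ++j) tabs[j] = as<NumericVector>(tables[j]);
  double logscore = 0.0;
  int n_edges = 0;
  if (init_parents.size() == p)
    for (int j = 0; j < p; ++j) parents[j] = init_parents[j];
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < p; ++i)
      if (parents[j] & (1 << i)) { children[i] |= (1 << j); ++n_edges; }
    logscore += table_score(tabs[j], parents[j], j);
  }
  logscore += edge_logprior * n_edges;

  long long keep = (long long)std::floor((n_iter - burn_in) / thin);
  if (keep < 0) keep = 0;
  IntegerMatrix out(keep, p);
  NumericVector trace(keep);
  long long stored = 0, accepted = 0, proposed = 0;
  long long iters = (long long)n_iter, burn = (long long)burn_in,
            th = (long long)thin;

  for (long long it = 1; it <= iters; ++it) {
    int i = (int)(unif_rand() * p); if (i >= p) i = p - 1;
    int j = (int)(unif_rand() * (p - 1)); if (j >= p - 1) j = p - 2;
    if (p > 1 && j >= i) ++j;
    if (p > 1) {
      if (parents[j] & (1 << i)) {
        ++proposed;
        if (unif_rand() < 0.5) {
          // delete i -> j
          double delta = table_score(tabs[j], parents[j] & ~(1 << i), j)
                       - table_score(tabs[j], parents[j], j) - edge_logprior;
          if (std::log(unif_rand()) < delta + std::log(2.0)) {
            parents[j] &= ~(1 << i);
            children[i] &= ~(1 << j);
            --n_edges;
            logscore += delta;
            ++accepted;
          }
        } else {
          // reverse i -> j to j -> i
          children[i] &= ~(1 << j);  // temporarily drop the edge
          bool cyc = reachable(children, i, j, p);
          if (!cyc) {
            double delta = table_score(tabs[j], parents[j] & ~(1 << i), j)
                         - table_score(tabs[j], parents[j], j)
                         + table_score(tabs[i], parents[i] | (1 << j), i)
                         - table_score(tabs[i], parents[i], i);
            if (std::log(unif_rand()) < delta) {
              parents[j] &= ~(1 << i);
              parents[i] |= (1 << j);
              children[j] |= (1 << i);
              logscore += delta;
              ++accepted;
            } else children[i] |= (1 << j);
          } else children[i] |= (1 << j);
        }
      } else if (!(parents[i] & (1 << j))) {
        ++proposed;
        // add i -> j unless it would create a cycle
        if (!reachable(children, j, i, p)) {
          double delta = table_score(tabs[j], parents[j] | (1 << i), j)
                       - table_score(tabs[j], parents[j], j) + edge_logprior;
          if (std::log(unif_rand()) < delta - std::log(2.0)) {
            parents[j] |= (1 << i);
            children[i] |= (1 << j);
            ++n_edges;
            logscore += delta;
            ++accepted;
          }
        }
      }
    }
    if (it > burn && ((it - burn) % th == 0) && stored < keep) {
      for (int v = 0; v < p; ++v) out(stored, v) = parents[v];
      trace[stored] = logscore;
      ++stored;
    }
  }
  return Rcpp::List::create(Rcpp::Named("parent_masks") = out,
                            Rcpp::Named("score_trace") = trace,
                            Rcpp::Named("acceptance_rate") =
                              proposed > 0 ? (double)accepted / proposed : 0.0);
}

// Sample a parent set for one node, proportional to exp(log score),
// among subsets of P_comp that intersect Q_comp (compressed masks).
// Q_comp == 0 means the node sits in the first block: empty parent set.
// [[Rcpp::export]]
int cpp_sample_parent_set(const Rcpp::NumericVector& table_comp, int P_comp,
                          int Q_comp) {
  if (Q_comp == 0) return 0;
  double mx = -INFINITY;
  for (int s = P_comp; ; s = (s - 1) & P_comp) {
    if (s & Q_comp) { double v = table_comp[s]; if (v > mx) mx = v; }
    if (s == 0) break;
  }
  if (!std::isfinite(mx)) stop("no admissible parent set has positive weight");
  double total = 0.0;
  for (int s = P_comp; ; s = (s - 1) & P_comp) {
    if (s & Q_comp) total += std::exp(table_comp[s] - mx);
    if (s == 0) break;
  }
  double u = unif_rand() * total, acc = 0.0;
  int last = -1;
  for (int s = P_comp; ; s = (s - 1) & P_comp) {
    if (s & Q_comp) {
      acc += std::exp(table_comp[s] - mx);
      last = s;
      if (acc >= u) return s;
    }
    if (s == 0) break;
  }
  return last;
}

// [[Rcpp::export]]
int cpp_compress_mask(int m, int j) { return compress_mask(m, j); }
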