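// Structured-coalescent simulation with infinite-sites mutation.
//
// Scaling contract (pinned by the test battery in test-coalsim.R):
//   * internal time unit = 2 N_ref generations;
//   * pair-coalescence rate within deme i = C(k_i, 2) / x_i, where
//     x_i = theta_i / theta_ref is the relative deme size;
//   * backward migration rate per lineage from deme i to j = M_ij / 2,
//     with M_ij = 4 N_e m the effective-migrant rate;
//   * a merge event scheduled at internal time t moves every lineage of the
//     child deme into the parent deme (input split times in 4Ne units are
//     doubled by the R layer before they reach this file);
//   * mutation count ~ Poisson((theta_locus / 2) * total branch length),
//     each mutation a new segregating column (infinite sites).
// Under this contract E[pi] = theta, E[S] = theta * a1(n) and, for an
// isolated pair of demes split at tau (4Ne units), E[dxy] = theta (1 + 2 tau).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Genealogy {
  int n;                        // number of leaves
  std::vector<double> time;     // node times, length 2n-1
  std::vector<int> parent;      // parent id or -1 for root
  double total_length;
  double tmrca;
};

// Exact exponential-race simulation of the genealogy. Group labels of the
// leaves (used for summary statistics) are decoupled from the demes that
// drive the dynamics so that collapsed models can still be scored against
// the original sampling groups.
Genealogy simulate_genealogy(const IntegerVector& group_sizes,
                             const IntegerVector& group_deme,
                             NumericVector x_in,
                             NumericMatrix mig_in,
                             const NumericVector& ev_time,
                             const IntegerVector& ev_from,
                             const IntegerVector& ev_to,
                             const NumericVector& ev_x) {
  const int d = x_in.size();
  const int G = group_sizes.size();
  std::vector<double> x(x_in.begin(), x_in.end());
  std::vector<std::vector<double> > mig(d, std::vector<double>(d, 0.0));
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j)
      if (i != j) mig[i][j] = mig_in(i, j) / 2.0;  // per-lineage rate

  int n = 0;
  for (int g = 0; g < G; ++g) n += group_sizes[g];
  if (n < 2) stop("need at least 2 sampled lineages");

  Genealogy gen;
  gen.n = n;
  gen.time.assign(2 * n - 1, 0.0);
  gen.parent.assign(2 * n - 1, -1);

  std::vector<std::vector<int> > by_deme(d);
  {
    int id = 0;
    for (int g = 0; g < G; ++g)
      for (int r = 0; r < group_sizes[g]; ++r)
        by_deme[group_deme[g]].push_back(id++);
  }

  std::vector<double> row_rate(d, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) row_rate[i] += mig[i][j];

  double t = 0.0;
  int next_node = n;
  int k_total = n;
  int ev = 0;
  const int n_ev = ev_time.size();
  const long max_steps = 100000000L;  // hard guard against mis-specified models
  long steps = 0;

  while (k_total > 1) {
    if (++steps > max_steps) stop("simulation did not terminate (check migration routes / root cap)");
    double coal_tot = 0.0, mig_tot = 0.0;
    for (int i = 0; i < d; ++i) {
      const double k = (double)by_deme[i].size();
      if (k > 1) coal_tot += k * (k - 1.0) / (2.0 * x[i]);
      mig_tot += k * row_rate[i];
    }
    const double r_tot = coal_tot + mig_tot;

    double t_next;
    if (r_tot <= 0.0) {
      if (ev >= n_ev)
        stop("no coalescence possible and no further merge events: non-terminating configuration");
      t_next = R_PosInf;
    } else {
      t_next = t + exp_rand() / r_tot;
    }

    if (ev < n_ev && t_next >= ev_time[ev]) {
      // apply the scheduled deme merge
      t = ev_time[ev];
      const int from = ev_from[ev], into = ev_to[ev];
      for (size_t u = 0; u < by_deme[from].size(); ++u)
        by_deme[into].push_back(by_deme[from][u]);
      by_deme[from].clear();
      x[into] = ev_x[ev];
      x[from] = 1.0;  // dead deme, rates zeroed below
      for (int j = 0; j < d; ++j) { mig[from][j] = 0.0; mig[j][from] = 0.0; }
      for (int i = 0; i < d; ++i) {
        row_rate[i] = 0.0;
        for (int j = 0; j < d; ++j) row_rate[i] += mig[i][j];
      }
      ++ev;
      continue;
    }

    t = t_next;
    double u = unif_rand() * r_tot;
    bool done = false;
    for (int i = 0; i < d && !done; ++i) {
      const double k = (double)by_deme[i].size();
      const double ci = (k > 1) ? k * (k - 1.0) / (2.0 * x[i]) : 0.0;
      if (u < ci) {
        // coalescence in deme i: pick an unordered pair uniformly
        const int ki = by_deme[i].size();
        int a = (int)(unif_rand() * ki); if (a == ki) a = ki - 1;
        int b = (int)(unif_rand() * (ki - 1)); if (b == ki - 1) b = ki - 2;
        if (b >= a) ++b;
        const int na = by_deme[i][a], nb = by_deme[i][b];
        const int id = next_node++;
        gen.time[id] = t;
        gen.parent[na] = id;
        gen.parent[nb] = id;
        // replace a by the new node, drop b (swap-with-last)
        by_deme[i][a] = id;
        by_deme[i][b] = by_deme[i].back();
        by_deme[i].pop_back();
        --k_total;
        done = true;
        break;
      }
      u -= ci;
    }
    if (done) continue;
    for (int i = 0; i < d; ++i) {
      const double mi = by_deme[i].size() * row_rate[i];
      if (u < mi) {
        const int ki = by_deme[i].size();
        int a = (int)(unif_rand() * ki); if (a == ki) a = ki - 1;
        double v = unif_rand() * row_rate[i];
        int target = -1;
        for (int j = 0; j < d; ++j) {
          if (i == j) continue;
          if (v < mig[i][j]) { target = j; break; }
          v -= mig[i][j];
        }
        if (target < 0) {  // numerical edge: take the last open route
          for (int j = d - 1; j >= 0; --j)
            if (j != i && mig[i][j] > 0) { target = j; break; }
        }
        const int node = by_deme[i][a];
        by_deme[i][a] = by_deme[i].back();
        by_deme[i].pop_back();
        by_deme[target].push_back(node);
        break;
      }
      u -= mi;
    }
  }

  gen.tmrca = gen.time[2 * n - 2];
  gen.total_length = 0.0;
  for (int v = 0; v < 2 * n - 2; ++v)
    gen.total_length += gen.time[gen.parent[v]] - gen.time[v];
  return gen;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_sim_locus(IntegerVector group_sizes,
                   IntegerVector group_deme,
                   NumericVector x,
                   NumericMatrix mig,
                   NumericVector ev_time,
                   IntegerVector ev_from,
                   IntegerVector ev_to,
                   NumericVector ev_x,
                   double theta_locus,
                   bool want_matrix,
                   bool want_tree) {
  Genealogy gen = simulate_genealogy(group_sizes, group_deme, x, mig,
                                     ev_time, ev_from, ev_to, ev_x);
  const int n = gen.n;
  const int G = group_sizes.size();

  // leaf-group counts under every node (node ids are a topological order:
  // parents are created after, and numbered above, their children)
  std::vector<std::vector<int> > below(2 * n - 1, std::vector<int>(G, 0));
  {
    int id = 0;
    for (int g = 0; g < G; ++g)
      for (int r = 0; r < group_sizes[g]; ++r) below[id++][g] = 1;
  }
  for (int v = 0; v < 2 * n - 2; ++v)
    for (int g = 0; g < G; ++g) below[gen.parent[v]][g] += below[v][g];

  // mutations: Poisson on total length, uniform placement on branches
  const int n_mut = (theta_locus > 0 && gen.total_length > 0)
                        ? (int)R::rpois(theta_locus / 2.0 * gen.total_length)
                        : 0;
  std::vector<double> cum(2 * n - 2);
  double acc = 0.0;
  for (int v = 0; v < 2 * n - 2; ++v) {
    acc += gen.time[gen.parent[v]] - gen.time[v];
    cum[v] = acc;
  }
  std::vector<int> mut_node(n_mut);
  for (int m = 0; m < n_mut; ++m) {
    const double u = unif_rand() * gen.total_length;
    int lo = 0, hi = 2 * n - 3;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    mut_node[m] = lo;
  }

  // summary statistics from derived-allele counts
  double pi_num = 0.0;
  NumericVector pi_g_num(G), nG(G);
  for (int g = 0; g < G; ++g) nG[g] = group_sizes[g];
  const int n_pairs = G * (G - 1) / 2;
  NumericVector dxy_num(n_pairs);
  int S = 0;
  for (int m = 0; m < n_mut; ++m) {
    const std::vector<int>& cg = below[mut_node[m]];
    int c = 0;
    for (int g = 0; g < G; ++g) c += cg[g];
    if (c <= 0 || c >= n) continue;  // cannot happen below the root, kept as a guard
    ++S;
    pi_num += (double)c * (n - c);
    int p = 0;
    for (int g = 0; g < G; ++g) {
      pi_g_num[g] += (double)cg[g] * (group_sizes[g] - cg[g]);
      for (int h = g + 1; h < G; ++h, ++p)
        dxy_num[p] += (double)cg[g] * (group_sizes[h] - cg[h]) +
                      (double)cg[h] * (group_sizes[g] - cg[g]);
    }
  }

  NumericVector pi_within(G), dxy(n_pairs);
  for (int g = 0; g < G; ++g)
    pi_within[g] = (group_sizes[g] > 1)
                       ? pi_g_num[g] / (group_sizes[g] * (group_sizes[g] - 1.0) / 2.0)
                       : NA_REAL;
  {
    int p = 0;
    for (int g = 0; g < G; ++g)
      for (int h = g + 1; h < G; ++h, ++p)
        dxy[p] = dxy_num[p] / ((double)group_sizes[g] * group_sizes[h]);
  }

  List out = List::create(
      _["S"] = S,
      _["pi"] = pi_num / (n * (n - 1.0) / 2.0),
      _["pi_within"] = pi_within,
      _["dxy"] = dxy,
      _["n"] = n,
      _["tmrca"] = gen.tmrca,
      _["total_length"] = gen.total_length);

  if (want_matrix) {
    // materialise the 0/1 haplotype matrix (segregating columns only)
    std::vector<std::vector<int> > children(2 * n - 1);
    for (int v = 0; v < 2 * n - 2; ++v) children[gen.parent[v]].push_back(v);
    IntegerMatrix geno(n, S);
    int col = 0;
    for (int m = 0; m < n_mut; ++m) {
      const std::vector<int>& cg = below[mut_node[m]];
      int c = 0;
      for (int g = 0; g < G; ++g) c += cg[g];
      if (c <= 0 || c >= n) continue;
      std::vector<int> stack(1, mut_node[m]);
      while (!stack.empty()) {
        const int v = stack.back();
        stack.pop_back();
        if (v < n) geno(v, col) = 1;
        else for (size_t u = 0; u < children[v].size(); ++u) stack.push_back(children[v][u]);
      }
      ++col;
    }
    IntegerVector leaf_group(n);
    {
      int id = 0;
      for (int g = 0; g < G; ++g)
        for (int r = 0; r < group_sizes[g]; ++r) leaf_group[id++] = g + 1;
    }
    out["genotypes"] = geno;
    out["leaf_group"] = leaf_group;
  }
  if (want_tree) {
    out["parent"] = IntegerVector(gen.parent.begin(), gen.parent.end());
    out["node_time"] = NumericVector(gen.time.begin(), gen.time.end());
  }
  return out;
}
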