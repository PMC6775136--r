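#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Uniform draw on 0..n-1 from R's RNG (RNGScope handled by the wrapper).
static inline int sample_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Randomized greedy agglomerative clustering.
//
// Edges come 1-based with ei <= ej; a self-loop (ei == ej) of weight w
// contributes w to total weight and 2w to its node's strength.  Starting from
// singleton communities, each step samples `sample_size` communities that
// still have neighbours, scans all merges between a sampled community and one
// of its neighbours, and applies the merge with maximal modularity gain
//   dQ = 2 * ( w_ab/(2m) - s_a*s_b/(2m)^2 ),
// ties broken by the lexicographically smallest (min id, max id) pair.
// Q is recorded at every dendrogram level; the membership at the level with
// maximal Q (earliest on ties) is returned.  Merging stops when no
// inter-community edge remains, so disconnected components are never joined
// (joining them can only lower Q).
// [[Rcpp::export(name = ".rg_run")]]
List rg_run(int n, IntegerVector ei, IntegerVector ej, NumericVector ew,
            double m, int sample_size) {
  if (sample_size < 1) stop("sample_size must be >= 1");
  std::vector< std::map<int, double> > nbr(n);
  std::vector<double> strength(n, 0.0), within(n, 0.0);
  int ne = ei.size();
  for (int e = 0; e < ne; ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    double w = ew[e];
    if (a == b) {
      within[a] += w;
      strength[a] += 2.0 * w;
    } else {
      nbr[a][b] += w;
      nbr[b][a] += w;
      strength[a] += w;
      strength[b] += w;
    }
  }
  const double two_m = 2.0 * m;
  double q = 0.0;
  for (int v = 0; v < n; ++v)
    q += within[v] / m - (strength[v] / two_m) * (strength[v] / two_m);

  std::vector<double> qlevel;
  qlevel.reserve(n);
  qlevel.push_back(q);

  // communities that still have at least one neighbour
  std::vector<int> active;
  active.reserve(n);
  std::vector<int> pos(n, -1);
  for (int v = 0; v < n; ++v)
    if (!nbr[v].empty()) {
      pos[v] = (int)active.size();
      active.push_back(v);
    }

  std::vector<int> win_log, lose_log;
  win_log.reserve(n);
  lose_log.reserve(n);

  std::vector<int> sampled;
  while (!active.empty()) {
    int navail = (int)active.size();
    int s = sample_size < navail ? sample_size : navail;
    sampled.clear();
    for (int t = 0; t < s; ++t) {  // partial Fisher-Yates over `active`
      int j = t + sample_int(navail - t);
      int cu = active[t], cv = active[j];
      active[t] = cv; active[j] = cu;
      pos[cv] = t; pos[cu] = j;
      sampled.push_back(active[t]);
    }
    double best_dq = R_NegInf;
    int best_a = -1, best_b = -1;
    for (size_t si = 0; si < sampled.size(); ++si) {
      int c = sampled[si];
      for (std::map<int, double>::const_iterator it = nbr[c].begin();
           it != nbr[c].end(); ++it) {
        int d = it->first;
        double dq = 2.0 * (it->second / two_m -
                           strength[c] * strength[d] / (two_m * two_m));
        int a = c < d ? c : d, b = c < d ? d : c;
        if (dq > best_dq ||
            (dq == best_dq && (a < best_a || (a == best_a && b < best_b)))) {
          best_dq = dq;
          best_a = a;
          best_b = b;
        }
      }
    }
    if (best_a < 0) break;  // defensive; active communities always have neighbours
    int a = best_a, b = best_b;
    double w_ab = nbr[a][b];
    nbr[a].erase(b);
    nbr[b].erase(a);
    for (std::map<int, double>::const_iterator it = nbr[b].begin();
         it != nbr[b].end(); ++it) {
      int k = it->first;
      nbr[a][k] += it->second;
      nbr[k].erase(b);
      nbr[k][a] += it->second;
    }
    nbr[b].clear();
    within[a] += within[b] + w_ab;
    strength[a] += strength[b];
    within[b] = 0.0;
    strength[b] = 0.0;
    // deactivate b, and a if it ran out of neighbours
    for (int c = 0; c < 2; ++c) {
      int x = c == 0 ? b : a;
      if (pos[x] >= 0 && (x == b || nbr[x].empty())) {
        int p = pos[x];
        int last = active.back();
        active[p] = last;
        pos[last] = p;
        active.pop_back();
        pos[x] = -1;
      }
    }
    q += best_dq;
    qlevel.push_back(q);
    win_log.push_back(a);
    lose_log.push_back(b);
  }

  int best_level = 0;
  double best_q = qlevel[0];
  for (size_t t = 1; t < qlevel.size(); ++t)
    if (qlevel[t] > best_q) {
      best_q = qlevel[t];
      best_level = (int)t;
    }

  // replay the first best_level merges with union-find
  std::vector<int> parent(n);
  for (int v = 0; v < n; ++v) parent[v] = v;
  for (int t = 0; t < best_level; ++t) {
    int w = win_log[t];
    while (parent[w] != w) w = parent[w];
    int l = lose_log[t];
    while (parent[l] != l) l = parent[l];
    parent[l] = w;
  }
  IntegerVector memb(n);
  std::vector<int> relab(n, 0);
  int next_id = 0;
  for (int v = 0; v < n; ++v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    parent[v] = r;  // path compression for later nodes
    if (relab[r] == 0) relab[r] = ++next_id;
    memb[v] = relab[r];
  }
  return List::create(_["membership"] = memb, _["q"] = best_q,
                      _["n_communities"] = next_id,
                      _["n_levels"] = (int)qlevel.size());
}

// Simulated-annealing seriation of a co-clustering matrix.
//
// Minimizes H = sum_{i<j} s_ij * d_ij^alpha where d_ij is the circular
// distance between the positions of i and j.  Moves are random pair swaps
// (optionally restricted to pairs inside the same group); Metropolis
// acceptance with Boltzmann factor exp(-dH/T); geometric cooling.  The
// best-seen order is returned, so the result never costs more than the
// starting (identity) order.  A stage with no accepted cost-changing move
// counts toward the stall criterion; zero-cost swaps are still applied for
// mixing but do not reset it.
// [[Rcpp::export(name = ".anneal_run")]]
List anneal_run(NumericMatrix s, double alpha, double t_start, double cooling,
                int sweeps, int stall_stages, int max_stages,
                IntegerVector groups) {
  int n = s.nrow();
  if (n < 2) stop("need at least two nodes");
  std::vector<int> posv(n);
  for (int v = 0; v < n; ++v) posv[v] = v;

  int dmax = n / 2;
  std::vector<double> dpow(dmax + 1, 0.0);
  for (int d = 1; d <= dmax; ++d) dpow[d] = std::pow((double)d, alpha);

  // restricted move set: nodes eligible for swapping, per group
  bool restricted = groups.size() == n;
  std::vector< std::vector<int> > members;
  std::vector<int> eligible;
  if (restricted) {
    int gmax = 0;
    for (int v = 0; v < n; ++v) gmax = std::max(gmax, groups[v]);
    members.resize(gmax + 1);
    for (int v = 0; v < n; ++v) members[groups[v]].push_back(v);
    for (int v = 0; v < n; ++v)
      if ((int)members[groups[v]].size() > 1) eligible.push_back(v);
    if (eligible.empty())
      stop("no group has two or more members; nothing to swap");
  }

  double h = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int a = posv[i] - posv[j];
      if (a < 0) a = -a;
      h += s(i, j) * dpow[a < n - a ? a : n - a];
    }
  double h_start = h;

  auto circ = [n](int pi, int pj) -> int {
    int a = pi - pj;
    if (a < 0) a = -a;
    return a < n - a ? a : n - a;
  };
  // dH of swapping the positions of nodes u and v
  auto delta_swap = [&](int u, int v) -> double {
    int pu = posv[u], pv = posv[v];
    double dh = 0.0;
    for (int k = 0; k < n; ++k) {
      if (k == u || k == v) continue;
      int pk = posv[k];
      double su = s(u, k), sv = s(v, k);
      if (su != 0.0) dh += su * (dpow[circ(pv, pk)] - dpow[circ(pu, pk)]);
      if (sv != 0.0) dh += sv * (dpow[circ(pu, pk)] - dpow[circ(pv, pk)]);
    }
    return dh;
  };
  auto propose = [&](int &u, int &v) {
    if (restricted) {
      u = eligible[sample_int((int)eligible.size())];
      const std::vector<int> &g = members[groups[u]];
      int j = sample_int((int)g.size() - 1);
      v = g[j] == u ? g[g.size() - 1] : g[j];
    } else {
      u = sample_int(n);
      v = sample_int(n - 1);
      if (v >= u) ++v;
    }
  };

  if (t_start <= 0.0) {
    // heuristic: 10 x sd of dH over 100 random proposals from the start order
    const int tries = 100;
    double sum = 0.0, sum2 = 0.0;
    for (int t = 0; t < tries; ++t) {
      int u, v;
      propose(u, v);
      double dh = delta_swap(u, v);
      sum += dh;
      sum2 += dh * dh;
    }
    double var = sum2 / tries - (sum / tries) * (sum / tries);
    t_start = 10.0 * std::sqrt(var > 0.0 ? var : 0.0);
    if (t_start <= 0.0) t_start = 1.0;
  }

  double T = t_start;
  std::vector<int> best_pos = posv;
  double best_h = h;
  int stall = 0, stage = 0;
  while (stall < stall_stages && stage < max_stages) {
    int changed = 0;
    for (int t = 0; t < sweeps; ++t) {
      int u, v;
      propose(u, v);
      double dh = delta_swap(u, v);
      if (dh <= 0.0 || unif_rand() < std::exp(-dh / T)) {
        int tmp = posv[u];
        posv[u] = posv[v];
        posv[v] = tmp;
        h += dh;
        if (dh != 0.0) ++changed;
        if (h < best_h) {
          best_h = h;
          best_pos = posv;
        }
      }
    }
    stall = changed == 0 ? stall + 1 : 0;
    T *= cooling;
    ++stage;
  }

  IntegerVector order(n);
  for (int v = 0; v < n; ++v) order[best_pos[v]] = v + 1;
  return List::create(_["order"] = order, _["h"] = best_h,
                      _["h_start"] = h_start, _["t_start"] = t_start,
                      _["stages"] = stage);
}
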