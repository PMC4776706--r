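// Backward structured coalescent conditioned on a recorded forward
// demography.  Each generation backward, a lineage in deme d at generation
// g moves to source s with probability immigrants(s -> d, g) / N_g(d)
// (residual mass stays); co-resident lineages in a deme of haploid size N
// then coalesce pairwise with probability 1/N, at most one merger per deme
// per generation.  At the start of the expansion all remaining lineages sit
// in the origin deme and coalesce in a single Wright-Fisher deme of
// 2*Ne_ANC genes.
//
// The LDD arrival ledger comes CSR-indexed: ldd_off[g] .. ldd_off[g+1]
// bounds generation g's slice, sorted by target deme.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static const int DROW[4] = {-1, 1, 0, 0};
static const int DCOL[4] = {0, 0, -1, 1};

// [[Rcpp::export]]
List simulate_genealogy_cpp(NumericMatrix dens, IntegerMatrix adj,
                            IntegerVector ldd_target,
                            IntegerVector ldd_source,
                            IntegerVector ldd_count,
                            IntegerVector ldd_off,
                            int n_rows, int n_cols, int origin0,
                            double ne_anc_genes, int t_start,
                            IntegerVector sample_deme0) {
  const int n_tips = sample_deme0.size();
  const int n_nodes = 2 * n_tips - 1;
  IntegerVector parent(n_nodes, NA_INTEGER);
  NumericVector node_time(n_nodes, 0.0);

  std::vector<int> act_node(n_tips), act_deme(n_tips);
  for (int i = 0; i < n_tips; ++i) {
    act_node[i] = i;
    act_deme[i] = sample_deme0[i];
    if (dens(0, sample_deme0[i]) < 1.0)
      stop("sampled deme %d is unoccupied at present", sample_deme0[i] + 1);
  }
  int next_node = n_tips;
  int n_act = n_tips;

  std::unordered_map<int, std::vector<int>> by_deme;
  const int *lt = INTEGER(ldd_target), *ls = INTEGER(ldd_source),
            *lc = INTEGER(ldd_count);

  for (int g = 0; g < t_start && n_act > 1; ++g) {
    const int lo = ldd_off[g], hi = ldd_off[g + 1];

    // migration backward: g -> g+1
    for (int i = 0; i < n_act; ++i) {
      int d = act_deme[i];
      double N = dens(g, d);
      if (N <= 0.0)
        stop("record corruption: lineage in deme %d with zero density at generation %d",
             d + 1, g);
      double u = R::unif_rand() * N;
      double cum = 0.0;
      int row = d % n_rows, col = d / n_rows;
      int moved = -1;
      for (int dir = 0; dir < 4 && moved < 0; ++dir) {
        int cnt = adj(g, 4 * d + dir);
        if (cnt == 0) continue;
        cum += cnt;
        if (u < cum) {
          int r2 = row + DROW[dir], c2 = col + DCOL[dir];
          moved = c2 * n_rows + r2;
        }
      }
      if (moved < 0 && lo < hi) {
        const int *first = std::lower_bound(lt + lo, lt + hi, d);
        for (const int *p = first; p < lt + hi && *p == d && moved < 0; ++p) {
          long long e = p - lt;
          cum += lc[e];
          if (u < cum) moved = ls[e];
        }
      }
      if (moved >= 0) act_deme[i] = moved;
    }

    // coalescence at generation g+1 within demes
    by_deme.clear();
    for (int i = 0; i < n_act; ++i) by_deme[act_deme[i]].push_back(i);
    std::vector<int> drop;
    for (auto &kv : by_deme) {
      int k = kv.second.size();
      if (k < 2) continue;
      double N1 = dens(g + 1, kv.first);
      if (N1 < 1.0) N1 = 1.0;
      double p_pair = (double) k * (k - 1) / 2.0 / N1;
      if (p_pair > 1.0) p_pair = 1.0;
      if (R::unif_rand() < p_pair) {
        int a = (int) (R::unif_rand() * k);
        int b = (int) (R::unif_rand() * (k - 1));
        if (b >= a) ++b;
        int ia = kv.second[a], ib = kv.second[b];
        int anc = next_node++;
        parent[act_node[ia]] = anc;
        parent[act_node[ib]] = anc;
        node_time[anc] = g + 1;
        act_node[ia] = anc;
        drop.push_back(ib);
      }
    }
    std::sort(drop.begin(), drop.end(), std::greater<int>());
    for (int ib : drop) {
      act_node[ib] = act_node[n_act - 1];
      act_deme[ib] = act_deme[n_act - 1];
      --n_act;
    }
  }

  // ancestral panmictic phase: at the expansion start every remaining
  // lineage joins the single ancestral Wright-Fisher deme
  double t = t_start;
  while (n_act > 1) {
    double rate = (double) n_act * (n_act - 1) / 2.0 / ne_anc_genes;
    t += R::exp_rand() / rate;
    int a = (int) (R::unif_rand() * n_act);
    int b = (int) (R::unif_rand() * (n_act - 1));
    if (b >= a) ++b;
    int anc = next_node++;
    parent[act_node[a]] = anc;
    parent[act_node[b]] = anc;
    node_time[anc] = t;
    act_node[a] = anc;
    act_node[b] = act_node[n_act - 1];
    --n_act;
  }

  return List::create(_["parent"] = parent, _["node_time"] = node_time,
                      _["n_tips"] = n_tips);
}
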