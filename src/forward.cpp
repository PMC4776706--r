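// Forward lattice demography: logistic regulation, nearest-neighbour
// migration, long-distance dispersal with a truncated-rounded gamma kernel,
// and full recording of densities and immigrant ledgers for the backward
// coalescent pass.
//
// Units: deme densities and all migrant counts are GENE copies (haploid
// counts, 2x diploid individuals).  Densities are real-valued (deterministic
// growth); migrant counts are integer random variates.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// direction encoding: source deme relative to the receiving deme
// 0 = north (row-1), 1 = south (row+1), 2 = west (col-1), 3 = east (col+1)
static const int DROW[4] = {-1, 1, 0, 0};
static const int DCOL[4] = {0, 0, -1, 1};

// Gamma(shape alpha, rate alpha/mu_bar) distance, rounded to the nearest
// integer, resampled until it lies in [dmin, dmax].
static int ldd_distance_one(double alpha, double mu_bar, int dmin, int dmax) {
  for (int iter = 0; iter < 100000; ++iter) {
    double x = R::rgamma(alpha, mu_bar / alpha);  // R uses scale = 1/rate
    int k = (int) std::lround(x);
    if (k >= dmin && k <= dmax) return k;
  }
  Rcpp::stop("LDD kernel rejection sampling failed to converge");
}

// [[Rcpp::export]]
IntegerVector sample_ldd_distance_cpp(int n, double alpha, double mu_bar,
                                      int dmin, int dmax) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ldd_distance_one(alpha, mu_bar, dmin, dmax);
  return out;
}

// probabilities of the truncated-rounded kernel over dmin..dmax
// (identical in law to round-and-resample rejection sampling)
static std::vector<double> kernel_pmf(double alpha, double mu_bar,
                                      int dmin, int dmax) {
  std::vector<double> pmf;
  double rate = alpha / mu_bar, tot = 0.0;
  for (int k = dmin; k <= dmax; ++k) {
    double p = R::pgamma(k + 0.5, alpha, 1.0 / rate, 1, 0) -
               R::pgamma(k - 0.5, alpha, 1.0 / rate, 1, 0);
    tot += p;
    pmf.push_back(p);
  }
  for (double &p : pmf) p /= tot;
  return pmf;
}

// lattice displacement distribution at integer distance k: the measure of
// uniform angles theta for which (round(k sin), round(k cos)) hits each
// offset, integrated on a fine fixed grid (cached per k; error < 1e-6)
struct Offset { int dr, dc; double p; };

static const std::vector<Offset> &offset_table(int k) {
  static std::map<int, std::vector<Offset>> cache;
  auto it = cache.find(k);
  if (it != cache.end()) return it->second;
  const int G = 1 << 21;
  std::map<std::pair<int, int>, long> tally;
  for (int j = 0; j < G; ++j) {
    double th = (j + 0.5) * (2.0 * M_PI / G);
    int dr = (int) std::lround(k * std::sin(th));
    int dc = (int) std::lround(k * std::cos(th));
    ++tally[{dr, dc}];
  }
  std::vector<Offset> tab;
  for (auto &kv : tally)
    tab.push_back({kv.first.first, kv.first.second,
                   (double) kv.second / G});
  return cache.emplace(k, std::move(tab)).first->second;
}

// combined (distance x direction) cumulative displacement table
struct Jump { int dr, dc; double cum; };

static std::vector<Jump> jump_table(double alpha, double mu_bar,
                                    int dmin, int dmax) {
  std::vector<double> pmf = kernel_pmf(alpha, mu_bar, dmin, dmax);
  std::vector<Jump> out;
  double cum = 0.0;
  for (int k = dmin; k <= dmax; ++k)
    for (const Offset &o : offset_table(k)) {
      cum += pmf[k - dmin] * o.p;
      out.push_back({o.dr, o.dc, cum});
    }
  if (!out.empty()) out.back().cum = 1.0;
  return out;
}

// [[Rcpp::export]]
List run_forward_cpp(int n_rows, int n_cols, List epochs, int origin0,
                     double ne_anc_genes, double r, double m, double ldd_prop,
                     double alpha, double mu_bar, int regime, int t_start,
                     int ldd_min, int ldd_max) {
  const int nd = n_rows * n_cols;
  const int ng = t_start + 1;  // generations t_start .. 0 BP
  NumericMatrix dens(ng, nd);  // row index = generation BP
  IntegerMatrix adj(ng, 4 * nd);
  // LDD arrival ledger: flat arrays, one contiguous target-sorted block per
  // generation (the generation loop runs monotonically, so blocks come out
  // contiguous by construction)
  std::vector<int> ldd_flat_gen, ldd_flat_target, ldd_flat_source;
  std::vector<long long> blk_start(ng + 1, 0);
  std::vector<std::pair<int, int>> ldd_tmp;

  std::vector<double> N(nd, 0.0), Npre(nd);
  N[origin0] = ne_anc_genes;
  dens(t_start, origin0) = ne_anc_genes;

  std::vector<Jump> jumps;
  if (regime > 0 && ldd_prop > 0.0)
    jumps = jump_table(alpha, mu_bar, ldd_min, ldd_max);

  // epoch bookkeeping: epochs ordered by decreasing time, epoch covers
  // (t_lo, t_hi]; the final epoch also covers generation 0.
  int ep = 0, n_ep = epochs.size();
  List cur = epochs[ep];
  NumericVector K = cur["K"];
  double t_lo = cur["t_lo"];

  double tot_emig = 0, tot_lost = 0, tot_disc = 0, tot_imm = 0;
  std::vector<double> arrivals(nd);
  std::vector<int> arr_dir(4 * nd);

  for (int g = t_start - 1; g >= 0; --g) {
    while (g <= t_lo && ep + 1 < n_ep) {
      ++ep;
      cur = epochs[ep];
      K = cur["K"];
      t_lo = (double) cur["t_lo"];
    }
    // capacity update + logistic growth; an overfull deme declines towards
    // K but never below it (the raw discrete logistic would crash it)
    for (int d = 0; d < nd; ++d) {
      if (K[d] <= 0.0) { N[d] = 0.0; continue; }
      double n0 = N[d];
      if (n0 > 0.0) {
        double n1 = n0 + r * n0 * (1.0 - n0 / K[d]);
        double fl = std::min(n0, (double) K[d]);
        N[d] = std::max(fl, n1);
      }
    }
    std::copy(N.begin(), N.end(), Npre.begin());
    std::fill(arrivals.begin(), arrivals.end(), 0.0);
    std::fill(arr_dir.begin(), arr_dir.end(), 0);
    ldd_tmp.clear();

    for (int d = 0; d < nd; ++d) {
      double n0 = Npre[d];
      if (n0 < 1.0) continue;
      int M = (int) std::lround(n0 * m);  // migrant pool: 2*N_t*m gene copies
      if (M <= 0) continue;
      int ldd = 0;
      if (regime > 0 && ldd_prop > 0.0)
        ldd = (int) R::rbinom((double) M, ldd_prop);
      int rem = M - ldd;
      tot_emig += M;
      N[d] -= M;
      int row = d % n_rows, col = d / n_rows;
      // equal multinomial split of the adjacent pool over four directions
      for (int dir = 0; dir < 4; ++dir) {
        int cnt;
        if (dir < 3) {
          cnt = (int) R::rbinom((double) rem, 1.0 / (4 - dir));
          rem -= cnt;
        } else cnt = rem;
        if (cnt == 0) continue;
        int r2 = row + DROW[dir], c2 = col + DCOL[dir];
        if (r2 < 0 || r2 >= n_rows || c2 < 0 || c2 >= n_cols) {
          tot_lost += cnt; continue;
        }
        int t2 = c2 * n_rows + r2;
        if (K[t2] <= 0.0) { tot_lost += cnt; continue; }
        arrivals[t2] += cnt;
        // source direction seen from the target is the opposite one
        int opp = (dir < 2) ? (1 - dir) : (5 - dir);
        arr_dir[4 * t2 + opp] += cnt;
        tot_imm += cnt;
      }
      // long-distance dispersers, one by one: a single uniform draw maps
      // to a (distance x direction) lattice displacement
      for (int k = 0; k < ldd; ++k) {
        double u = R::unif_rand();
        size_t lo2 = 0, hi2 = jumps.size() - 1;
        while (lo2 < hi2) {
          size_t mid = (lo2 + hi2) / 2;
          if (jumps[mid].cum < u) lo2 = mid + 1; else hi2 = mid;
        }
        int r2 = row + jumps[lo2].dr;
        int c2 = col + jumps[lo2].dc;
        if (r2 < 0 || r2 >= n_rows || c2 < 0 || c2 >= n_cols) {
          tot_disc += 1; continue;
        }
        int t2 = c2 * n_rows + r2;
        bool occupied = Npre[t2] >= 1.0;
        bool ok = K[t2] > 0.0;
        if (regime == 2 && occupied) ok = false;   // empty places only
        if (regime == 3 && !occupied) ok = false;  // occupied places only
        if (!ok) { tot_disc += 1; continue; }
        arrivals[t2] += 1;
        tot_imm += 1;
        ldd_tmp.push_back({t2, d});
      }
    }
    std::sort(ldd_tmp.begin(), ldd_tmp.end());  // by target, for lookup
    for (auto &ts : ldd_tmp) {
      ldd_flat_gen.push_back(g);
      ldd_flat_target.push_back(ts.first);
      ldd_flat_source.push_back(ts.second);
    }
    blk_start[g] = (long long) ldd_flat_gen.size();  // end of g's block
    for (int d = 0; d < nd; ++d) {
      N[d] += arrivals[d];
      dens(g, d) = N[d];
      for (int dir = 0; dir < 4; ++dir)
        adj(g, 4 * d + dir) = arr_dir[4 * d + dir];
    }
  }

  // re-emit the ledger in ascending-generation order with CSR offsets
  // (generation g's block sits at [blk_start[g+1], blk_start[g]) above)
  const long long n_ldd_total = (long long) ldd_flat_gen.size();
  blk_start[ng] = 0;
  IntegerVector ldd_gen(n_ldd_total), ldd_target(n_ldd_total),
      ldd_source(n_ldd_total), ldd_off(ng + 1);
  long long pos = 0;
  for (int g = 0; g < ng; ++g) {
    ldd_off[g] = (int) pos;
    for (long long e = blk_start[g + 1]; e < blk_start[g]; ++e) {
      ldd_gen[pos] = g;
      ldd_target[pos] = ldd_flat_target[e];
      ldd_source[pos] = ldd_flat_source[e];
      ++pos;
    }
  }
  ldd_off[ng] = (int) pos;

  double total = 0;
  for (int d = 0; d < nd; ++d) total += N[d];

  return List::create(
    _["densities"] = dens,
    _["adj"] = adj,
    _["ldd_gen"] = ldd_gen,
    _["ldd_target"] = ldd_target,
    _["ldd_source"] = ldd_source,
    _["ldd_off"] = ldd_off,
    _["diagnostics"] = List::create(
      _["emigrants"] = tot_emig, _["immigrants"] = tot_imm,
      _["lost_at_sea"] = tot_lost, _["ldd_discarded"] = tot_disc),
    _["extinct"] = total < 1.0);
}
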