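// Structured coalescent with admixture pulses, SMC recombination along the
// chromosome, HKY sequence evolution, and byte-level allele counting.
//
// Time is measured in units of 4N generations; a pair of lineages in the same
// population (all of relative size 1) coalesces at rate 2.  Recombination
// breakpoints arrive along the sequence at rate (4Nr per bp) x (total tree
// branch length in 4N units).
//
// All randomness comes from std::mt19937_64 through inverse-CDF draws only,
// so identical seeds give identical output on any platform.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <random>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

class Rng {
  std::mt19937_64 eng;
public:
  explicit Rng(uint64_t s) : eng(s) {}
  // uniform in (0,1)
  double unif() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double rexp(double rate) { return -std::log(unif()) / rate; }
  int pick(int n) { int k = (int)(unif() * n); return k >= n ? n - 1 : k; }
};

// population codes: 0 = I1, 1 = I2, 2 = O; after the ingroup split I1/I2
// lineages carry 0, after the root everything carries 0.
struct Events {
  // sorted by time: pulses first (times < t_in), then split_in, split_root
  std::vector<double> time;
  std::vector<int> type;       // 0 pulse, 1 split_in, 2 split_root
  std::vector<int> src, dst;   // pulse only: dst relabels to src (backwards)
  std::vector<double> frac;
  int n() const { return (int)time.size(); }
};

struct Tree {
  int ntips, nnodes, nep;
  std::vector<int> parent;          // -1 root, -2 freed
  std::vector<double> ntime;
  std::vector<int8_t> lab;          // nnodes x nep, label of branch above node
  int root;
  const Events* ev;

  void init(int ntips_, const Events* ev_) {
    ntips = ntips_; nnodes = 2 * ntips - 1; ev = ev_; nep = ev->n() + 1;
    parent.assign(nnodes, -1);
    ntime.assign(nnodes, 0.0);
    lab.assign((size_t)nnodes * nep, -1);
  }
  int epoch_of(double t) const {
    int e = 0;
    while (e < ev->n() && ev->time[e] <= t) ++e;
    return e;
  }
  double ptime(int v) const { return parent[v] < 0 ? INF : ntime[parent[v]]; }
  int8_t& L(int v, int e) { return lab[(size_t)v * nep + e]; }
  int8_t  L(int v, int e) const { return lab[(size_t)v * nep + e]; }

  // apply event j to a single label, drawing pulse outcomes from rng
  void apply_event(int j, int8_t& l, Rng& rng) const {
    if (ev->type[j] == 0) {
      if (l == ev->dst[j] && rng.unif() < ev->frac[j]) l = (int8_t)ev->src[j];
    } else if (ev->type[j] == 1) {
      if (l == 1) l = 0;
    } else {
      if (l == 2) l = 0;
    }
  }
  // fill label row of v from epoch e0 (where it is `l`) up to the last epoch
  void fill_labels_up(int v, int e0, int8_t l, Rng& rng) {
    L(v, e0) = l;
    for (int j = e0; j < ev->n(); ++j) {
      apply_event(j, l, rng);
      L(v, j + 1) = l;
    }
  }
};

// sample a full structured-coalescent tree over ntips = 3n tips
void simulate_tree(Tree& tr, int n, Rng& rng) {
  int ntips = 3 * n;
  std::vector<int> active;      // node ids
  std::vector<int8_t> cur;      // current labels
  for (int i = 0; i < ntips; ++i) {
    active.push_back(i);
    cur.push_back((int8_t)(i / n));
    tr.L(i, 0) = (int8_t)(i / n);
  }
  int nxt = ntips;
  double t = 0.0;
  int e = 0;
  const Events* ev = tr.ev;
  while ((int)active.size() > 1) {
    int k[3] = {0, 0, 0};
    for (size_t i = 0; i < active.size(); ++i) k[cur[i]]++;
    double rate = 0.0;
    for (int p = 0; p < 3; ++p) rate += (double)k[p] * (k[p] - 1);
    double tb = e < ev->n() ? ev->time[e] : INF;
    double w = rate > 0 ? rng.rexp(rate) : INF;
    if (t + w < tb) {
      t += w;
      // choose population proportional to k(k-1), then a uniform pair
      double u = rng.unif() * rate, acc = 0.0;
      int pop = 2;
      for (int p = 0; p < 3; ++p) {
        acc += (double)k[p] * (k[p] - 1);
        if (u < acc) { pop = p; break; }
      }
      std::vector<int> idx;
      for (size_t i = 0; i < active.size(); ++i)
        if (cur[i] == pop) idx.push_back((int)i);
      int ia = rng.pick((int)idx.size());
      int ib = rng.pick((int)idx.size() - 1);
      if (ib >= ia) ++ib;
      int a = idx[ia], b = idx[ib];
      int m = nxt++;
      tr.parent[active[a]] = m;
      tr.parent[active[b]] = m;
      tr.ntime[m] = t;
      tr.L(m, e) = (int8_t)pop;
      // replace slot min(a,b) with m, drop the other
      int lo = std::min(a, b), hi = std::max(a, b);
      active[lo] = m; cur[lo] = (int8_t)pop;
      active.erase(active.begin() + hi);
      cur.erase(cur.begin() + hi);
    } else {
      t = tb;
      for (size_t i = 0; i < active.size(); ++i) tr.apply_event(e, cur[i], rng);
      ++e;
      for (size_t i = 0; i < active.size(); ++i) tr.L(active[i], e) = cur[i];
    }
  }
  tr.root = active[0];
  // extend the root lineage's labels through all remaining epochs
  int er = tr.epoch_of(tr.ntime[tr.root]);
  tr.fill_labels_up(tr.root, er, tr.L(tr.root, er), rng);
}

double total_length(const Tree& tr) {
  double s = 0.0;
  for (int v = 0; v < tr.nnodes; ++v)
    if (tr.parent[v] >= 0) s += tr.ntime[tr.parent[v]] - tr.ntime[v];
  return s;
}

// one SMC update: detach a uniformly chosen branch point, re-coalesce the
// floating lineage through the same structured process
void smc_update(Tree& tr, Rng& rng) {
  const Events* ev = tr.ev;
  // 1. branch point uniform on total branch length
  double LT = total_length(tr);
  double r = rng.unif() * LT, acc = 0.0;
  int v = -1; double u = 0.0;
  for (int w = 0; w < tr.nnodes; ++w) {
    if (tr.parent[w] < 0) continue;
    double bl = tr.ntime[tr.parent[w]] - tr.ntime[w];
    if (r < acc + bl) { v = w; u = tr.ntime[w] + (r - acc); break; }
    acc += bl;
  }
  if (v < 0) { // numerical edge: last branch
    for (int w = tr.nnodes - 1; w >= 0; --w)
      if (tr.parent[w] >= 0) { v = w; u = tr.ntime[w]; break; }
  }
  // 2. detach: splice sibling s to grandparent, free p
  int p = tr.parent[v], g = tr.parent[p], s = -1;
  for (int w = 0; w < tr.nnodes; ++w)
    if (w != v && tr.parent[w] == p) { s = w; break; }
  int e0 = tr.epoch_of(tr.ntime[p]);
  int e1 = (g == -1) ? tr.nep - 1 : tr.epoch_of(tr.ntime[g]);
  for (int e = e0; e <= e1; ++e) tr.L(s, e) = tr.L(p, e);
  tr.parent[s] = g;
  if (g == -1) tr.root = s;
  tr.parent[p] = -2;
  // 3. float lineage v upward from u
  double t = u;
  int e = tr.epoch_of(u);
  int8_t fl = tr.L(v, e);
  int target = -1;
  for (;;) {
    // next change point: standing node time or epoch boundary above t
    double tc = (e < ev->n()) ? ev->time[e] : INF;
    bool is_boundary = true;
    for (int w = 0; w < tr.nnodes; ++w) {
      if (w == v || tr.parent[w] == -2) continue;
      if (tr.ntime[w] > t && tr.ntime[w] < tc) { tc = tr.ntime[w]; is_boundary = false; }
    }
    // hazard within (t, tc): 2 per standing same-label branch
    int k = 0;
    for (int w = 0; w < tr.nnodes; ++w) {
      if (w == v || tr.parent[w] == -2) continue;
      if (tr.ntime[w] <= t && t < tr.ptime(w) && tr.L(w, e) == fl) ++k;
    }
    if (k > 0) {
      double wt = rng.rexp(2.0 * k);
      if (t + wt < tc) {
        double t0 = t;  // segment start: the standing set is evaluated here
        t += wt;
        int j = rng.pick(k), c = 0;
        for (int w = 0; w < tr.nnodes; ++w) {
          if (w == v || tr.parent[w] == -2) continue;
          if (tr.ntime[w] <= t0 && t0 < tr.ptime(w) && tr.L(w, e) == fl) {
            if (c == j) { target = w; break; }
            ++c;
          }
        }
        break;
      }
    }
    if (tc == INF) break; // cannot happen: root branch always stands
    t = tc;
    if (is_boundary) {
      tr.apply_event(e, fl, rng);
      ++e;
      tr.L(v, e) = fl;
    }
  }
  // 4. insert: reuse p as the new coalescent node at time t on branch `target`
  int gp = tr.parent[target];
  tr.ntime[p] = t;
  tr.parent[p] = gp;
  tr.parent[target] = p;
  tr.parent[v] = p;
  int ec = tr.epoch_of(t);
  int ee = (gp == -1) ? tr.nep - 1 : tr.epoch_of(tr.ntime[gp]);
  for (int i = ec; i <= ee; ++i) tr.L(p, i) = tr.L(target, i);
  if (gp == -1) tr.root = p;
}

} // namespace

// [[Rcpp::export(name = ".sim_genealogies_cpp")]]
List sim_genealogies_cpp(int n_per_pop, double t_in, double t_root,
                         NumericVector pulse_time, IntegerVector pulse_src,
                         IntegerVector pulse_dst, NumericVector pulse_frac,
                         double rho_bp, double chrom_length, double seed,
                         std::string mode, double block_size) {
  Events ev;
  // assemble sorted event list: pulses (ascending time), then the two splits
  std::vector<int> ord(pulse_time.size());
  for (int i = 0; i < (int)ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return pulse_time[a] < pulse_time[b];
  });
  for (int i : ord) {
    ev.time.push_back(pulse_time[i]); ev.type.push_back(0);
    ev.src.push_back(pulse_src[i]); ev.dst.push_back(pulse_dst[i]);
    ev.frac.push_back(pulse_frac[i]);
  }
  ev.time.push_back(t_in);  ev.type.push_back(1);
  ev.src.push_back(-1); ev.dst.push_back(-1); ev.frac.push_back(0);
  ev.time.push_back(t_root); ev.type.push_back(2);
  ev.src.push_back(-1); ev.dst.push_back(-1); ev.frac.push_back(0);

  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x1234567ULL);
  int ntips = 3 * n_per_pop, nnodes = 2 * ntips - 1;

  std::vector<double> breaks;
  std::vector<int> all_parent;
  std::vector<double> all_time;
  all_parent.reserve((size_t)nnodes * 64);
  all_time.reserve((size_t)nnodes * 64);

  Tree tr;
  auto record = [&](double end) {
    breaks.push_back(end);
    for (int v = 0; v < nnodes; ++v) {
      all_parent.push_back(tr.parent[v] + 1); // 1-based, 0 = root
      all_time.push_back(tr.ntime[v]);
    }
  };

  if (mode == "blocks") {
    double x = 0.0;
    while (x < chrom_length) {
      double end = std::min(x + block_size, chrom_length);
      tr.init(ntips, &ev);
      simulate_tree(tr, n_per_pop, rng);
      record(end);
      x = end;
    }
  } else { // smc
    tr.init(ntips, &ev);
    simulate_tree(tr, n_per_pop, rng);
    double x = 0.0;
    for (;;) {
      double LT = total_length(tr);
      double step = rho_bp > 0 ? rng.rexp(rho_bp * LT) : INF;
      if (x + step >= chrom_length) { record(chrom_length); break; }
      x += step;
      record(x);
      smc_update(tr, rng);
      if (breaks.size() % 4096 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int T = (int)breaks.size();
  IntegerMatrix pm(nnodes, T);
  NumericMatrix tm(nnodes, T);
  for (int t = 0; t < T; ++t)
    for (int v = 0; v < nnodes; ++v) {
      pm(v, t) = all_parent[(size_t)t * nnodes + v];
      tm(v, t) = all_time[(size_t)t * nnodes + v];
    }
  return List::create(_["breaks"] = NumericVector(breaks.begin(), breaks.end()),
                      _["parent"] = pm, _["time"] = tm);
}

namespace {

// 4x4 matrix exponential via scaled Taylor series (rate matrices are tiny)
void expm4(const double Q[4][4], double t, double P[4][4]) {
  double A[4][4], M[4][4], term[4][4];
  double m = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      A[i][j] = Q[i][j] * t;
      m = std::max(m, std::fabs(A[i][j]));
    }
  int s = 0;
  while (m > 0.5) { m /= 2; ++s; }
  double sc = std::pow(2.0, -s);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) A[i][j] *= sc;
  // P = I + A + A^2/2! + ...
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) { P[i][j] = (i == j) + A[i][j]; term[i][j] = A[i][j]; }
  for (int k = 2; k <= 14; ++k) {
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double v = 0.0;
        for (int l = 0; l < 4; ++l) v += term[i][l] * A[l][j];
        M[i][j] = v / k;
      }
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) { term[i][j] = M[i][j]; P[i][j] += M[i][j]; }
  }
  while (s-- > 0) {
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double v = 0.0;
        for (int l = 0; l < 4; ++l) v += P[i][l] * P[l][j];
        M[i][j] = v;
      }
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) P[i][j] = M[i][j];
  }
}

} // namespace

// [[Rcpp::export(name = ".evolve_seq_cpp")]]
RawMatrix evolve_seq_cpp(NumericVector breaks, IntegerMatrix parent,
                         NumericMatrix ntime, int chrom_length,
                         NumericVector freqs, double kappa, double scale,
                         double seed) {
  int nnodes = parent.nrow(), T = parent.ncol();
  int ntips = (nnodes + 1) / 2;
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0xABCDEFULL);

  // HKY rate matrix, normalised to mean rate 1
  double pi[4] = {freqs[0], freqs[1], freqs[2], freqs[3]};
  double Q[4][4];
  auto is_transition = [](int i, int j) {
    return (i == 0 && j == 2) || (i == 2 && j == 0) ||
           (i == 1 && j == 3) || (i == 3 && j == 1);
  };
  double mean_rate = 0.0;
  for (int i = 0; i < 4; ++i) {
    double rs = 0.0;
    for (int j = 0; j < 4; ++j) {
      if (i == j) continue;
      Q[i][j] = (is_transition(i, j) ? kappa : 1.0) * pi[j];
      rs += Q[i][j];
    }
    Q[i][i] = -rs;
    mean_rate += pi[i] * rs;
  }
  if (mean_rate > 0)
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) Q[i][j] /= mean_rate;

  double cumpi[4] = {pi[0], pi[0] + pi[1], pi[0] + pi[1] + pi[2], 1.0};
  const unsigned char BASE[4] = {'A', 'C', 'G', 'T'};

  RawMatrix out(chrom_length, ntips);
  std::vector<int> ord(nnodes);
  std::vector<double> cum((size_t)nnodes * 16);
  std::vector<int> st(nnodes);

  int site0 = 0; // 0-based first site of current interval
  double prev_break = 0.0;
  for (int t = 0; t < T; ++t) {
    // integer sites in this interval: site index s (1-based) belongs here if
    // s - 0.5 lies in [prev_break, breaks[t])
    int s_from = (int)std::ceil(prev_break + 0.5);
    int s_to = (int)std::ceil(breaks[t] + 0.5) - 1;
    if (s_to > chrom_length) s_to = chrom_length;
    prev_break = breaks[t];
    if (s_to < s_from) continue;

    // node processing order: decreasing time (parents before children)
    for (int v = 0; v < nnodes; ++v) ord[v] = v;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return ntime(a, t) > ntime(b, t);
    });
    // per-branch cumulative transition rows
    for (int v = 0; v < nnodes; ++v) {
      int p = parent(v, t) - 1;
      if (p < 0) continue;
      double bl = (ntime(p, t) - ntime(v, t)) * scale;
      double P[4][4];
      expm4(Q, bl, P);
      for (int i = 0; i < 4; ++i) {
        double c = 0.0;
        for (int j = 0; j < 4; ++j) {
          c += P[i][j];
          cum[(size_t)v * 16 + i * 4 + j] = c;
        }
        cum[(size_t)v * 16 + i * 4 + 3] = 1.0; // guard rounding
      }
    }
    for (int s = s_from - 1; s < s_to; ++s) {
      for (int oi = 0; oi < nnodes; ++oi) {
        int v = ord[oi];
        int p = parent(v, t) - 1;
        if (p < 0) { // root: stationary draw
          double u = rng.unif();
          int b = 0;
          while (b < 3 && u > cumpi[b]) ++b;
          st[v] = b;
        } else {
          double u = rng.unif();
          const double* row = &cum[(size_t)v * 16 + st[p] * 4];
          int b = 0;
          while (b < 3 && u > row[b]) ++b;
          st[v] = b;
        }
      }
      for (int k = 0; k < ntips; ++k) out(s, k) = BASE[st[k]];
    }
    site0 = s_to;
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  (void)site0;
  return out;
}

namespace {

// IUPAC nucleotide -> bitmask (A=1, C=2, G=4, T=8); 0 = missing
int iupac_mask(unsigned char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;
    case 'Y': case 'y': return 10;
    case 'S': case 's': return 6;
    case 'W': case 'w': return 9;
    case 'K': case 'k': return 12;
    case 'M': case 'm': return 3;
    default: return 0; // N, -, ., B/D/H/V treated as missing
  }
}
int popcount4(int m) {
  return ((m & 1) != 0) + ((m & 2) != 0) + ((m & 4) != 0) + ((m & 8) != 0);
}

} // namespace

// Per-site allele counts over a set of samples.  Haploid samples contribute
// one allele; diploid samples two (IUPAC heterozygotes one of each base).
// Returns nsites x 5: counts of A, C, G, T and of heterozygous calls.
// [[Rcpp::export(name = ".site_counts_cpp")]]
IntegerMatrix site_counts_cpp(RawMatrix calls, IntegerVector cols, int ploidy) {
  int S = calls.nrow();
  IntegerMatrix out(S, 5);
  for (int ci = 0; ci < cols.size(); ++ci) {
    int j = cols[ci] - 1;
    for (int s = 0; s < S; ++s) {
      int m = iupac_mask(calls(s, j));
      int pc = popcount4(m);
      if (pc == 0) continue;
      if (ploidy == 1) {
        if (pc != 1) continue;
        for (int b = 0; b < 4; ++b) if (m & (1 << b)) out(s, b) += 1;
      } else {
        if (pc == 1) {
          for (int b = 0; b < 4; ++b) if (m & (1 << b)) out(s, b) += 2;
        } else if (pc == 2) {
          for (int b = 0; b < 4; ++b) if (m & (1 << b)) out(s, b) += 1;
          out(s, 4) += 1;
        }
      }
    }
  }
  return out;
}

// Expected mismatch (IUPAC codes averaged over compatible resolutions) and
// jointly callable site count between two samples over site-index ranges
// [from, to] (1-based).  Returns k x 2 (mismatch sum, n callable).
// [[Rcpp::export(name = ".pair_mismatch_cpp")]]
NumericMatrix pair_mismatch_cpp(RawMatrix calls, int i, int j,
                                IntegerVector from, IntegerVector to) {
  int k = from.size();
  NumericMatrix out(k, 2);
  int ci = i - 1, cj = j - 1;
  for (int w = 0; w < k; ++w) {
    double mm = 0.0; double n = 0.0;
    int s0 = from[w] - 1, s1 = to[w] - 1;
    for (int s = s0; s <= s1; ++s) {
      int m1 = iupac_mask(calls(s, ci));
      int m2 = iupac_mask(calls(s, cj));
      int p1 = popcount4(m1), p2 = popcount4(m2);
      if (p1 == 0 || p2 == 0 || p1 > 2 || p2 > 2) continue;
      n += 1.0;
      if (m1 == m2 && p1 == 1) continue;
      mm += 1.0 - (double)popcount4(m1 & m2) / ((double)p1 * p2);
    }
    out(w, 0) = mm;
    out(w, 1) = n;
  }
  return out;
}

// Non-missing call count per sample over site-index ranges (1-based, inclusive)
// [[Rcpp::export(name = ".callable_counts_cpp")]]
IntegerMatrix callable_counts_cpp(RawMatrix calls, IntegerVector cols,
                                  IntegerVector from, IntegerVector to) {
  int k = from.size(), nc = cols.size();
  IntegerMatrix out(k, nc);
  for (int c = 0; c < nc; ++c) {
    int j = cols[c] - 1;
    for (int w = 0; w < k; ++w) {
      int n = 0;
      for (int s = from[w] - 1; s <= to[w] - 1; ++s) {
        int m = iupac_mask(calls(s, j));
        int pc = popcount4(m);
        if (pc >= 1 && pc <= 2) ++n;
      }
      out(w, c) = n;
    }
  }
  return out;
}
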