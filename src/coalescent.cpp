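// Continuous-time coalescent for multi-deme divergence scenarios with
// piecewise-constant deme sizes, plus generalized stepwise (GSM)
// microsatellite mutation and the summary statistics consumed by the ABC
// layer. Time is measured backward in generations; a diploid deme of size N
// holds 2N gene copies, so a pair of lineages coalesces at rate 1/(2N) per
// generation.

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Events: matrix with columns (time, kind, a, b); kind 0 = merge of deme a
// into deme b, kind 1 = deme a size becomes b. Rows must be sorted by time
// ascending; equal-time rows apply in row order.

struct Genealogy {
  std::vector<int> parent;      // -1 for root
  std::vector<double> time;     // node times (leaves at 0)
  int n_leaves;
};

static Genealogy sim_genealogy(const IntegerVector& sample_genes,
                               NumericVector deme_sizes,
                               const NumericMatrix& events) {
  int D = deme_sizes.size();
  std::vector<double> N(D);
  for (int d = 0; d < D; ++d) N[d] = deme_sizes[d];
  int n = 0;
  for (int d = 0; d < D; ++d) n += sample_genes[d];
  Genealogy g;
  g.n_leaves = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);
  std::vector<std::vector<int> > act(D);  // active lineage ids per deme
  int id = 0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < sample_genes[d]; ++k) act[d].push_back(id++);
  int next_node = n;
  int alive = n;
  double t = 0.0;
  int ev = 0, n_ev = events.nrow();
  while (alive > 1) {
    double tot = 0.0;
    for (int d = 0; d < D; ++d) {
      double k = (double)act[d].size();
      if (k > 1.5) tot += k * (k - 1.0) / (4.0 * N[d]);
    }
    double t_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;
    if (tot <= 0.0 && !R_finite(t_ev))
      stop("non-coalescing event structure: lineages remain in disconnected demes");
    double dt = (tot > 0.0) ? ::exp_rand() / tot : R_PosInf;
    if (t + dt >= t_ev) {
      t = t_ev;
      while (ev < n_ev && events(ev, 0) <= t) {
        int kind = (int)events(ev, 1);
        int a = (int)events(ev, 2) - 1;
        if (kind == 0) {
          int b = (int)events(ev, 3) - 1;
          for (size_t k = 0; k < act[a].size(); ++k) act[b].push_back(act[a][k]);
          act[a].clear();
        } else {
          N[a] = events(ev, 3);
        }
        ++ev;
      }
      continue;
    }
    t += dt;
    // choose deme proportional to its coalescence rate
    double u = unif_rand() * tot, acc = 0.0;
    int dsel = -1;
    for (int d = 0; d < D; ++d) {
      double k = (double)act[d].size();
      if (k > 1.5) {
        acc += k * (k - 1.0) / (4.0 * N[d]);
        if (u <= acc) { dsel = d; break; }
      }
    }
    if (dsel < 0) { for (int d = D - 1; d >= 0; --d) if (act[d].size() > 1) { dsel = d; break; } }
    std::vector<int>& v = act[dsel];
    int i = (int)(unif_rand() * v.size()); if (i >= (int)v.size()) i = v.size() - 1;
    int j = (int)(unif_rand() * (v.size() - 1)); if (j >= (int)v.size() - 1) j = v.size() - 2;
    if (j >= i) ++j;
    int li = v[i], lj = v[j];
    int node = next_node++;
    g.parent[li] = node; g.parent[lj] = node;
    g.time[node] = t;
    v[i] = node;            // replace one lineage by the parent,
    v[j] = v.back();        // swap-remove the other (all cases safe)
    v.pop_back();
    --alive;
  }
  return g;
}

static int mutate_allele(int val, int nmut, double pgsm, int lo, int hi) {
  for (int m = 0; m < nmut; ++m) {
    int step = 1;
    if (pgsm > 0.0) step += (int)::Rf_rgeom(1.0 - pgsm);
    if (unif_rand() < 0.5) step = -step;
    val += step;
    while (val < lo || val > hi) {
      if (val > hi) val = 2 * hi - val;
      if (val < lo) val = 2 * lo - val;
    }
  }
  return val;
}

// [[Rcpp::export]]
IntegerVector cpp_sim_locus(IntegerVector sample_genes, NumericVector deme_sizes,
                            NumericMatrix events, double mu, double pgsm,
                            int lo, int hi, int root_allele) {
  Genealogy g = sim_genealogy(sample_genes, deme_sizes, events);
  int nn = 2 * g.n_leaves - 1;
  std::vector<int> allele(nn, root_allele);
  // order nodes by decreasing time so parents are resolved before children
  std::vector<int> ord(nn);
  for (int i = 0; i < nn; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&g](int a, int b) { return g.time[a] > g.time[b]; });
  for (int k = 0; k < nn; ++k) {
    int node = ord[k];
    int par = g.parent[node];
    if (par < 0) { allele[node] = root_allele; continue; }
    double bl = g.time[par] - g.time[node];
    int nmut = (mu > 0.0 && bl > 0.0) ? (int)::Rf_rpois(mu * bl) : 0;
    allele[node] = mutate_allele(allele[par], nmut, pgsm, lo, hi);
  }
  IntegerVector out(g.n_leaves);
  for (int i = 0; i < g.n_leaves; ++i) out[i] = allele[i];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_sim_dataset(IntegerVector sample_genes, NumericVector deme_sizes,
                              NumericMatrix events, NumericVector mu,
                              NumericVector pgsm, int lo, int hi,
                              int root_allele) {
  int L = mu.size();
  int n = 0;
  for (int d = 0; d < sample_genes.size(); ++d) n += sample_genes[d];
  IntegerMatrix out(n, L);
  for (int l = 0; l < L; ++l) {
    IntegerVector col = cpp_sim_locus(sample_genes, deme_sizes, events,
                                      mu[l], pgsm[l], lo, hi, root_allele);
    for (int i = 0; i < n; ++i) out(i, l) = col[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sim_tmrca(IntegerVector sample_genes, NumericVector deme_sizes,
                            NumericMatrix events, int reps) {
  NumericMatrix out(reps, 2);  // columns: tree height, total branch length
  for (int r = 0; r < reps; ++r) {
    Genealogy g = sim_genealogy(sample_genes, deme_sizes, events);
    int nn = 2 * g.n_leaves - 1;
    double h = 0.0, tl = 0.0;
    for (int i = 0; i < nn; ++i) {
      if (g.time[i] > h) h = g.time[i];
      if (g.parent[i] >= 0) tl += g.time[g.parent[i]] - g.time[i];
    }
    out(r, 0) = h;
    out(r, 1) = tl;
  }
  return out;
}

// ---- summary statistics ------------------------------------------------
// genes: (2 * n_ind) x L matrix of allele sizes in repeat units, gene
// copies 2i, 2i+1 (0-based) belonging to diploid individual i; pop: 1-based
// population index per individual; npop populations. Ordering contract:
// per-pop mean allele count, per-pop mean unbiased H_E, per-pop mean
// allele-size variance, then pairwise (lexicographic i<j) WC F_ST and
// delta-mu^2. With holdout = true, appends: global mean Garza-Williamson M,
// then pairwise pooled mean allele count, pooled mean size variance, and
// shared-allele distance. One scan of the gene matrix per locus; allele
// states are binned on the observed size range.

// [[Rcpp::export]]
NumericVector cpp_dataset_stats(IntegerMatrix genes, IntegerVector pop,
                                int npop, bool holdout) {
  int n_ind = pop.size();
  int L = genes.ncol();
  int npair = npop * (npop - 1) / 2;
  int base = 3 * npop + 2 * npair;
  int extra = holdout ? (1 + 3 * npair) : 0;
  NumericVector out(base + extra);
  std::vector<double> kA(npop, 0.0), He(npop, 0.0), Va(npop, 0.0);
  std::vector<std::vector<double> > msize(npop, std::vector<double>(L, 0.0));
  std::vector<double> fst_a(npair, 0.0), fst_abc(npair, 0.0), dmu(npair, 0.0);
  std::vector<double> kpool(npair, 0.0), vpool(npair, 0.0), das(npair, 0.0);
  double gw_sum = 0.0; int gw_cnt = 0;
  std::vector<int> ni(npop, 0);
  for (int q = 0; q < n_ind; ++q) ++ni[pop[q] - 1];
  for (int l = 0; l < L; ++l) {
    int mn = genes(0, l), mx = genes(0, l);
    for (int r = 0; r < 2 * n_ind; ++r) {
      int v = genes(r, l);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    int S = mx - mn + 1;
    std::vector<int> cnt(npop * S, 0), hetc(npop * S, 0);
    std::vector<double> sum(npop, 0.0), sum2(npop, 0.0);
    // genotype-class tallies for the shared-allele distance
    std::vector<std::map<std::pair<int, int>, int> > gclass;
    if (holdout) gclass.resize(npop);
    for (int q = 0; q < n_ind; ++q) {
      int p = pop[q] - 1;
      int a1 = genes(2 * q, l) - mn, a2 = genes(2 * q + 1, l) - mn;
      ++cnt[p * S + a1]; ++cnt[p * S + a2];
      if (a1 != a2) { ++hetc[p * S + a1]; ++hetc[p * S + a2]; }
      double v1 = a1, v2 = a2;
      sum[p] += v1 + v2; sum2[p] += v1 * v1 + v2 * v2;
      if (holdout) {
        std::pair<int, int> key(std::min(a1, a2), std::max(a1, a2));
        ++gclass[p][key];
      }
    }
    for (int p = 0; p < npop; ++p) {
      int m = 2 * ni[p];
      int k = 0, smin = -1, smax = -1;
      double sump2 = 0.0;
      for (int s = 0; s < S; ++s) {
        int c = cnt[p * S + s];
        if (c > 0) {
          ++k;
          if (smin < 0) smin = s;
          smax = s;
          double f = c / (double)m;
          sump2 += f * f;
        }
      }
      kA[p] += k;
      He[p] += (m > 1) ? (m / (m - 1.0)) * (1.0 - sump2) : 0.0;
      double mnl = sum[p] / m;
      msize[p][l] = mnl + mn;
      Va[p] += (m > 1) ? (sum2[p] - m * mnl * mnl) / (m - 1.0) : 0.0;
      if (holdout && k > 0) {
        gw_sum += k / (double)(smax - smin + 1);
        ++gw_cnt;
      }
    }
    int ix = 0;
    for (int i = 0; i < npop; ++i) {
      for (int j = i + 1; j < npop; ++j, ++ix) {
        double d = msize[i][l] - msize[j][l];
        dmu[ix] += d * d;
        if (ni[i] >= 2 && ni[j] >= 2) {
          double r = 2.0, N = ni[i] + ni[j];
          double nbar = N / r;
          double nc = (N - (ni[i] * (double)ni[i] + ni[j] * (double)ni[j]) / N) /
            (r - 1.0);
          int k_tot = 0;
          for (int s = 0; s < S; ++s)
            if (cnt[i * S + s] + cnt[j * S + s] > 0) ++k_tot;
          if (k_tot >= 2) {
            for (int s = 0; s < S; ++s) {
              int ci = cnt[i * S + s], cj = cnt[j * S + s];
              if (ci + cj == 0) continue;
              double pi = ci / (2.0 * ni[i]), pj = cj / (2.0 * ni[j]);
              double hi = hetc[i * S + s] / (double)ni[i];
              double hj = hetc[j * S + s] / (double)ni[j];
              double pbar = (ni[i] * pi + ni[j] * pj) / N;
              double s2 = (ni[i] * (pi - pbar) * (pi - pbar) +
                           ni[j] * (pj - pbar) * (pj - pbar)) / ((r - 1.0) * nbar);
              double hbar = (ni[i] * hi + ni[j] * hj) / N;
              double a = (nbar / nc) *
                (s2 - (pbar * (1 - pbar) - s2 * (r - 1.0) / r - hbar / 4.0) /
                 (nbar - 1.0));
              double b = (nbar / (nbar - 1.0)) *
                (pbar * (1 - pbar) - s2 * (r - 1.0) / r -
                 hbar * (2.0 * nbar - 1.0) / (4.0 * nbar));
              double c_ = hbar / 2.0;
              fst_a[ix] += a;
              fst_abc[ix] += a + b + c_;
            }
          }
        }
        if (holdout) {
          int m12 = 2 * (ni[i] + ni[j]);
          int kp = 0;
          double sp = sum[i] + sum[j], sp2 = sum2[i] + sum2[j];
          for (int s = 0; s < S; ++s)
            if (cnt[i * S + s] + cnt[j * S + s] > 0) ++kp;
          kpool[ix] += kp;
          double mnl = sp / m12;
          vpool[ix] += (sp2 - m12 * mnl * mnl) / (m12 - 1.0);
          double ps = 0.0;
          for (std::map<std::pair<int, int>, int>::iterator it1 = gclass[i].begin();
               it1 != gclass[i].end(); ++it1) {
            for (std::map<std::pair<int, int>, int>::iterator it2 = gclass[j].begin();
                 it2 != gclass[j].end(); ++it2) {
              int a = it1->first.first, b = it1->first.second;
              int c = it2->first.first, d = it2->first.second;
              int shared;
              if (a == b) shared = (c == a) + (d == a);
              else if (c == d) shared = (a == c) + (b == c);
              else shared = (a == c || a == d) + (b == c || b == d);
              ps += (it1->second / (double)ni[i]) * (it2->second / (double)ni[j]) *
                (shared / 2.0);
            }
          }
          das[ix] += ps;
        }
      }
    }
  }
  for (int p = 0; p < npop; ++p) {
    out[p] = kA[p] / L;
    out[npop + p] = He[p] / L;
    out[2 * npop + p] = Va[p] / L;
  }
  for (int ix = 0; ix < npair; ++ix) {
    out[3 * npop + ix] = (fst_abc[ix] > 0.0) ? fst_a[ix] / fst_abc[ix] : 0.0;
    out[3 * npop + npair + ix] = dmu[ix] / L;
  }
  if (holdout) {
    int hx = base;
    out[hx] = gw_sum / gw_cnt;
    for (int ix = 0; ix < npair; ++ix) {
      out[hx + 1 + ix] = kpool[ix] / L;
      out[hx + 1 + npair + ix] = vpool[ix] / L;
      out[hx + 1 + 2 * npair + ix] = 1.0 - das[ix] / L;
    }
  }
  return out;
}
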