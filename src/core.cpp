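// Core numerical engine: structured coalescent over a 3-species
// isolation-with-migration model space, finite/infinite-sites mutation,
// and count-based per-locus summary statistics.  All randomness goes
// through R's RNG so set.seed() in R controls everything.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// log-space unsigned Stirling numbers of the first kind (for Fu's Fs)
// ---------------------------------------------------------------------------
static std::vector< std::vector<double> > stirling_cache;

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  double s = (a > b) ? b : a;
  return m + std::log1p(std::exp(s - m));
}

static void ensure_stirling(int n) {
  if ((int)stirling_cache.size() > n) return;
  if (stirling_cache.empty()) {
    stirling_cache.push_back(std::vector<double>(1, 0.0));       // |s(0,0)| = 1
    std::vector<double> r1(2, R_NegInf); r1[1] = 0.0;            // |s(1,1)| = 1
    stirling_cache.push_back(r1);
  }
  for (int m = (int)stirling_cache.size(); m <= n; ++m) {
    const std::vector<double>& prev = stirling_cache[m - 1];
    std::vector<double> row(m + 1, R_NegInf);
    double lm = std::log((double)(m - 1));
    for (int k = 1; k <= m; ++k) {
      double a = (k <= m - 1) ? lm + prev[k] : R_NegInf;
      double b = prev[k - 1];
      row[k] = logadd(a, b);
    }
    stirling_cache.push_back(row);
  }
}

// P(K >= h | theta) under the Ewens sampling formula, then logit.
static double fu_fs_stat(int n, int h, double theta) {
  if (n < 2 || theta <= 0.0) return NA_REAL;
  ensure_stirling(n);
  double lpoch = 0.0;
  for (int i = 0; i < n; ++i) lpoch += std::log(theta + i);
  double lth = std::log(theta);
  double lsp = R_NegInf;
  for (int j = h; j <= n; ++j)
    lsp = logadd(lsp, stirling_cache[n][j] + j * lth - lpoch);
  double sp = std::exp(lsp);
  const double eps = 1e-12;                 // saturation clip
  if (sp < eps) sp = eps;
  if (sp > 1.0 - eps) sp = 1.0 - eps;
  return std::log(sp / (1.0 - sp));
}

static double tajima_d_stat(int n, int S, double k) {
  if (n < 2 || S < 1) return NA_REAL;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * ((double)n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double den = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));
  if (den <= 0.0) return NA_REAL;
  return (k - S / a1) / den;
}

// [[Rcpp::export]]
double cpp_fu_fs(int n, int h, double theta) { return fu_fs_stat(n, h, theta); }

// [[Rcpp::export]]
double cpp_tajima_d(int n, int S, double k) { return tajima_d_stat(n, S, k); }

// ---------------------------------------------------------------------------
// per-locus statistics from an integer alignment (rows = sequences, 0..3)
// ---------------------------------------------------------------------------
// Output layout (G species, P = G*(G-1)/2 pairs in order (1,2),(1,3),(2,3)...):
//   per species: S, Eta, h, Hd, k, thetaW_site, TajD, Fs          (8 each)
//   per pair:    PhiST, dxy_count, s1, s2, Sp, Fp                 (6 each)
static const int SP_NST = 8, PR_NST = 6;

static void locus_stats_internal(const IntegerMatrix& seqs,
                                 const std::vector<int>& grp, int G,
                                 std::vector<double>& out) {
  const int n = seqs.nrow(), L = seqs.ncol();
  const int P = G * (G - 1) / 2;
  out.assign(G * SP_NST + P * PR_NST, NA_REAL);
  std::vector<int> ng(G, 0);
  for (int i = 0; i < n; ++i) ng[grp[i]]++;

  std::vector< std::array<int, 2> > pairs;
  for (int i = 0; i < G; ++i)
    for (int j = i + 1; j < G; ++j) pairs.push_back({{i, j}});

  std::vector<int> S(G, 0), Eta(G, 0);
  std::vector<double> sumdiff(G, 0.0);             // sum over unordered within pairs
  std::vector<double> Tx(P, 0.0);                  // sum over cross pairs
  std::vector<int> s1(P, 0), s2(P, 0), Sp(P, 0), Fp(P, 0);
  std::vector<int> segsites; segsites.reserve(128);

  std::vector<int> cnt(G * 4);
  for (int s = 0; s < L; ++s) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int tot[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int b = seqs(i, s);
      cnt[grp[i] * 4 + b]++;
      tot[b]++;
    }
    int nbt = 0;
    for (int b = 0; b < 4; ++b) if (tot[b]) nbt++;
    if (nbt > 1) segsites.push_back(s);
    for (int g = 0; g < G; ++g) {
      if (ng[g] < 2) continue;
      int nb = 0; double homo = 0.0;
      for (int b = 0; b < 4; ++b) {
        int c = cnt[g * 4 + b];
        if (c) nb++;
        homo += (double)c * (c - 1) / 2.0;
      }
      if (nb > 1) { S[g]++; Eta[g] += nb - 1; }
      sumdiff[g] += (double)ng[g] * (ng[g] - 1) / 2.0 - homo;
    }
    for (int p = 0; p < P; ++p) {
      int g1 = pairs[p][0], g2 = pairs[p][1];
      if (ng[g1] == 0 || ng[g2] == 0) continue;
      int nb1 = 0, nb2 = 0, b1 = -1, b2 = -1;
      double cross = 0.0;
      for (int b = 0; b < 4; ++b) {
        int c1 = cnt[g1 * 4 + b], c2 = cnt[g2 * 4 + b];
        if (c1) { nb1++; b1 = b; }
        if (c2) { nb2++; b2 = b; }
        cross += (double)c1 * c2;
      }
      Tx[p] += (double)ng[g1] * ng[g2] - cross;
      bool p1 = nb1 > 1, p2 = nb2 > 1;
      if (p1 && p2) Sp[p]++;
      else if (p1) s1[p]++;
      else if (p2) s2[p]++;
      else if (b1 != b2) Fp[p]++;
    }
  }

  const int nseg = (int)segsites.size();
  for (int g = 0; g < G; ++g) {
    double* o = &out[g * SP_NST];
    int m = ng[g];
    if (m < 2) continue;
    // haplotype grouping over segregating columns (identical elsewhere)
    std::vector<int> rows; rows.reserve(m);
    for (int i = 0; i < n; ++i) if (grp[i] == g) rows.push_back(i);
    std::sort(rows.begin(), rows.end(), [&](int a, int b) {
      for (int t = 0; t < nseg; ++t) {
        int sidx = segsites[t];
        int va = seqs(a, sidx), vb = seqs(b, sidx);
        if (va != vb) return va < vb;
      }
      return false;
    });
    int h = 1, run = 1;
    double sump2 = 0.0;
    for (int i = 1; i < m; ++i) {
      bool eq = true;
      for (int t = 0; t < nseg; ++t) {
        int sidx = segsites[t];
        if (seqs(rows[i], sidx) != seqs(rows[i - 1], sidx)) { eq = false; break; }
      }
      if (eq) run++;
      else { sump2 += (double)run * run; run = 1; h++; }
    }
    sump2 += (double)run * run;
    double hd = ((double)m / (m - 1.0)) * (1.0 - sump2 / ((double)m * m));
    double k = sumdiff[g] / ((double)m * (m - 1) / 2.0);
    double am = 0.0;
    for (int i = 1; i < m; ++i) am += 1.0 / i;
    o[0] = S[g];
    o[1] = Eta[g];
    o[2] = h;
    o[3] = hd;
    o[4] = k;
    o[5] = (L > 0) ? S[g] / (am * L) : NA_REAL;
    o[6] = tajima_d_stat(m, S[g], k);
    o[7] = fu_fs_stat(m, h, k);
  }
  for (int p = 0; p < P; ++p) {
    double* o = &out[G * SP_NST + p * PR_NST];
    int g1 = pairs[p][0], g2 = pairs[p][1];
    int n1 = ng[g1], n2 = ng[g2];
    if (n1 == 0 || n2 == 0) continue;
    double dxy = Tx[p] / ((double)n1 * n2);
    double phi = NA_REAL;
    if (n1 >= 2 && n2 >= 2) {
      double N = n1 + n2;
      double ssd_w = sumdiff[g1] / n1 + sumdiff[g2] / n2;
      double ssd_t = (sumdiff[g1] + sumdiff[g2] + Tx[p]) / N;
      double ssd_a = ssd_t - ssd_w;
      double s2w = ssd_w / (N - 2.0);
      double nc = N - ((double)n1 * n1 + (double)n2 * n2) / N;
      double s2a = (ssd_a - s2w) / nc;     // df among = 1
      double den = s2a + s2w;
      if (den != 0.0) phi = s2a / den;
    }
    o[0] = phi;
    o[1] = dxy;
    o[2] = s1[p];
    o[3] = s2[p];
    o[4] = Sp[p];
    o[5] = Fp[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_locus_stats(const IntegerMatrix& seqs, const IntegerVector& grp,
                              int G) {
  std::vector<int> g(grp.begin(), grp.end());
  std::vector<double> out;
  locus_stats_internal(seqs, g, G, out);
  return NumericVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// AMOVA PhiST (any number of groups) + permutation p-value
// ---------------------------------------------------------------------------
static double phist_from_counts(const std::vector<int>& grp, int G,
                                const IntegerMatrix& seg) {
  const int n = seg.nrow(), S = seg.ncol();
  std::vector<int> ng(G, 0);
  for (int i = 0; i < n; ++i) ng[grp[i]]++;
  std::vector<double> within(G, 0.0);
  double txall = 0.0;
  std::vector<int> cnt(G * 4);
  for (int s = 0; s < S; ++s) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int tot[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) { int b = seg(i, s); cnt[grp[i] * 4 + b]++; tot[b]++; }
    double allpairs = (double)n * (n - 1) / 2.0;
    for (int b = 0; b < 4; ++b) allpairs -= (double)tot[b] * (tot[b] - 1) / 2.0;
    double wsum = 0.0;
    for (int g = 0; g < G; ++g) {
      double homo = 0.0;
      for (int b = 0; b < 4; ++b) {
        int c = cnt[g * 4 + b];
        homo += (double)c * (c - 1) / 2.0;
      }
      double w = (double)ng[g] * (ng[g] - 1) / 2.0 - homo;
      within[g] += w;
      wsum += w;
    }
    txall += allpairs - wsum;
  }
  double N = n;
  double ssd_w = 0.0, sum_within = 0.0, sumsq = 0.0;
  for (int g = 0; g < G; ++g) {
    if (ng[g] > 0) ssd_w += within[g] / ng[g];
    sum_within += within[g];
    sumsq += (double)ng[g] * ng[g];
  }
  double ssd_t = (sum_within + txall) / N;
  double ssd_a = ssd_t - ssd_w;
  double s2w = ssd_w / (N - G);
  double nc = (N - sumsq / N) / (G - 1.0);
  double s2a = (ssd_a / (G - 1.0) - s2w) / nc;
  double den = s2a + s2w;
  if (den == 0.0) return NA_REAL;
  return s2a / den;
}

// [[Rcpp::export]]
NumericVector cpp_phist_perm(const IntegerMatrix& seqs, const IntegerVector& grp,
                             int n_perm) {
  const int n = seqs.nrow(), L = seqs.ncol();
  int G = 0;
  for (int i = 0; i < n; ++i) if (grp[i] + 1 > G) G = grp[i] + 1;
  // restrict to segregating columns
  std::vector<int> segidx;
  for (int s = 0; s < L; ++s) {
    int first = seqs(0, s);
    for (int i = 1; i < n; ++i)
      if (seqs(i, s) != first) { segidx.push_back(s); break; }
  }
  IntegerMatrix seg(n, (int)segidx.size());
  for (size_t t = 0; t < segidx.size(); ++t)
    for (int i = 0; i < n; ++i) seg(i, (int)t) = seqs(i, segidx[t]);

  std::vector<int> g(grp.begin(), grp.end());
  double obs = phist_from_counts(g, G, seg);
  double p = NA_REAL;
  if (n_perm > 0 && !ISNAN(obs)) {
    int ge = 0;
    std::vector<int> gp = g;
    for (int r = 0; r < n_perm; ++r) {
      for (int i = n - 1; i > 0; --i) {           // Fisher-Yates with R RNG
        int j = (int)(R::unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(gp[i], gp[j]);
      }
      double ph = phist_from_counts(gp, G, seg);
      if (!ISNAN(ph) && ph >= obs - 1e-12) ge++;
    }
    p = (1.0 + ge) / (double)(n_perm + 1);        // observed included
  }
  return NumericVector::create(obs, p);
}

// ---------------------------------------------------------------------------
// structured coalescent
// ---------------------------------------------------------------------------
struct SimCfg {
  int nsamp[3];
  double N[3], Npair, Nroot;
  int sis1, sis2;             // 0-based sister pair merging at t0
  double t0, t1;
  double Mb[3][3];            // backward migration rate, lineage in i -> j
  bool mig_on;
  bool rmig; double tmig;     // migration only more recently than tmig
  bool rexp; double texp;     // sizes ratio*N more anciently than texp
  double ratio;
};

struct Genealogy {
  std::vector<double> time;   // node times, generations
  std::vector<int> parent;    // -1 for root
  std::vector<int> left, right;
  std::vector<double> mig_t;  // migration events (time, node carried, from, to)
  std::vector<int> mig_node, mig_from, mig_to;
  int n_leaves;
};

static inline double popsize_at(const SimCfg& c, int p, double t) {
  if (p == 3) return c.Npair;
  if (p == 4) return c.Nroot;
  if (c.rexp && t >= c.texp) return c.N[p] * c.ratio;
  return c.N[p];
}

static void sim_genealogy_internal(const SimCfg& c, Genealogy& gen) {
  const int ntot = c.nsamp[0] + c.nsamp[1] + c.nsamp[2];
  const int nn = 2 * ntot - 1;
  gen.n_leaves = ntot;
  gen.time.assign(nn, 0.0);
  gen.parent.assign(nn, -1);
  gen.left.assign(nn, -1);
  gen.right.assign(nn, -1);
  gen.mig_t.clear(); gen.mig_node.clear(); gen.mig_from.clear(); gen.mig_to.clear();

  std::vector< std::vector<int> > pool(5);
  {
    int id = 0;
    for (int sp = 0; sp < 3; ++sp)
      for (int i = 0; i < c.nsamp[sp]; ++i) pool[sp].push_back(id++);
  }
  int next_node = ntot;
  int alive = ntot;

  std::vector<double> bps;
  if (c.mig_on && c.rmig) bps.push_back(c.tmig);
  if (c.rexp) bps.push_back(c.texp);
  bps.push_back(c.t0);
  bps.push_back(c.t1);
  std::sort(bps.begin(), bps.end());

  double t = 0.0;
  size_t bi = 0;
  long guard = 0;
  while (alive > 1) {
    if (++guard > 100000000L) stop("coalescent simulation failed to terminate");
    bool mig = c.mig_on && t < c.t0 && (!c.rmig || t < c.tmig);
    double tot = 0.0;
    double crate[5];
    for (int p = 0; p < 5; ++p) {
      double kp = (double)pool[p].size();
      crate[p] = (kp >= 2.0) ? kp * (kp - 1.0) / 2.0 / (2.0 * popsize_at(c, p, t)) : 0.0;
      tot += crate[p];
    }
    double mrate[3][3] = {{0}};
    if (mig) {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          if (i != j && !pool[i].empty()) {
            mrate[i][j] = pool[i].size() * c.Mb[i][j];
            tot += mrate[i][j];
          }
    }
    double tnext = (bi < bps.size()) ? bps[bi] : R_PosInf;
    bool jump = true;
    double tev = R_PosInf;
    if (tot > 0.0) {
      tev = t + R::exp_rand() / tot;
      jump = (tev >= tnext);
    }
    if (jump) {
      if (!R_FINITE(tnext)) stop("no events possible and no epoch boundary left");
      t = tnext;
      // apply all transitions scheduled exactly here
      while (bi < bps.size() && bps[bi] <= t) {
        if (bps[bi] == c.t0) {
          for (int id : pool[c.sis1]) pool[3].push_back(id);
          for (int id : pool[c.sis2]) pool[3].push_back(id);
          pool[c.sis1].clear(); pool[c.sis2].clear();
        }
        if (bps[bi] == c.t1) {
          for (int p = 0; p < 4; ++p) {
            for (int id : pool[p]) pool[4].push_back(id);
            pool[p].clear();
          }
        }
        ++bi;
      }
      continue;
    }
    t = tev;
    double u = R::unif_rand() * tot;
    int done = 0;
    for (int p = 0; p < 5 && !done; ++p) {
      if (u < crate[p]) {
        int kp = (int)pool[p].size();
        int a = (int)(R::unif_rand() * kp); if (a >= kp) a = kp - 1;
        int b = (int)(R::unif_rand() * (kp - 1)); if (b >= kp - 1) b = kp - 2;
        if (b >= a) b++;
        int na = pool[p][a], nb = pool[p][b];
        int nid = next_node++;
        gen.time[nid] = t;
        gen.left[nid] = na; gen.right[nid] = nb;
        gen.parent[na] = nid; gen.parent[nb] = nid;
        if (a > b) std::swap(a, b);
        pool[p].erase(pool[p].begin() + b);
        pool[p].erase(pool[p].begin() + a);
        pool[p].push_back(nid);
        alive--;
        done = 1;
        break;
      }
      u -= crate[p];
    }
    if (done) continue;
    for (int i = 0; i < 3 && !done; ++i)
      for (int j = 0; j < 3 && !done; ++j)
        if (i != j && mrate[i][j] > 0.0) {
          if (u < mrate[i][j]) {
            int kp = (int)pool[i].size();
            int a = (int)(R::unif_rand() * kp); if (a >= kp) a = kp - 1;
            int id = pool[i][a];
            pool[i].erase(pool[i].begin() + a);
            pool[j].push_back(id);
            gen.mig_t.push_back(t);
            gen.mig_node.push_back(id);
            gen.mig_from.push_back(i);
            gen.mig_to.push_back(j);
            done = 1;
          } else u -= mrate[i][j];
        }
    if (!done) {
      // numerical leftover: treat as no-op
    }
  }
}

static SimCfg parse_cfg(const List& cfg) {
  SimCfg c;
  IntegerVector ns = cfg["samples"];
  NumericVector N = cfg["N"];
  for (int i = 0; i < 3; ++i) { c.nsamp[i] = ns[i]; c.N[i] = N[i]; }
  c.Npair = as<double>(cfg["N_pair"]);
  c.Nroot = as<double>(cfg["N_root"]);
  c.sis1 = as<int>(cfg["sis1"]);
  c.sis2 = as<int>(cfg["sis2"]);
  c.t0 = as<double>(cfg["t0"]);
  c.t1 = as<double>(cfg["t1"]);
  NumericMatrix Mb = cfg["Mb"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) c.Mb[i][j] = Mb(i, j);
  c.mig_on = as<bool>(cfg["mig_on"]);
  c.rmig = as<bool>(cfg["rmig"]);
  c.tmig = as<double>(cfg["t_mig"]);
  c.rexp = as<bool>(cfg["rexp"]);
  c.texp = as<double>(cfg["t_exp"]);
  c.ratio = as<double>(cfg["ratio"]);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (!R_FINITE(c.Mb[i][j]) || c.Mb[i][j] < 0) stop("non-finite migration rate");
  if (!(c.t0 < c.t1)) stop("t0 must be < t1");
  return c;
}

// [[Rcpp::export]]
List cpp_sim_genealogy(const List& cfg) {
  SimCfg c = parse_cfg(cfg);
  Genealogy g;
  sim_genealogy_internal(c, g);
  return List::create(
    _["time"] = NumericVector(g.time.begin(), g.time.end()),
    _["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
    _["left"] = IntegerVector(g.left.begin(), g.left.end()),
    _["right"] = IntegerVector(g.right.begin(), g.right.end()),
    _["n_leaves"] = g.n_leaves,
    _["mig_time"] = NumericVector(g.mig_t.begin(), g.mig_t.end()),
    _["mig_node"] = IntegerVector(g.mig_node.begin(), g.mig_node.end()),
    _["mig_from"] = IntegerVector(g.mig_from.begin(), g.mig_from.end()),
    _["mig_to"] = IntegerVector(g.mig_to.begin(), g.mig_to.end()));
}

// ---------------------------------------------------------------------------
// mutation: drop Poisson mutations on branches, build leaf alignment
// ---------------------------------------------------------------------------
static IntegerMatrix mutate_internal(const std::vector<double>& time,
                                     const std::vector<int>& parent,
                                     int n_leaves, int L, double mu_site,
                                     bool finite_sites) {
  const int nn = (int)time.size();
  // topological order from the root (robust to tied node times)
  std::vector<int> ord; ord.reserve(nn);
  {
    std::vector< std::vector<int> > children(nn);
    int root = -1;
    for (int i = 0; i < nn; ++i) {
      if (parent[i] < 0) root = i;
      else children[parent[i]].push_back(i);
    }
    if (root < 0) stop("genealogy has no root");
    ord.push_back(root);
    for (size_t q = 0; q < ord.size(); ++q)
      for (int ch : children[ord[q]]) ord.push_back(ch);
    if ((int)ord.size() != nn) stop("genealogy is not a tree");
  }

  // per-node mutation site lists; mutation-dense branches (expected hits
  // comparable to the locus length) are instead sampled site-wise from the
  // exact Jukes-Cantor transition, which has the same end-state distribution
  // as explicit mutation placement at a fraction of the cost
  std::vector< std::vector<int> > msites(nn);
  std::vector<char> bulk(nn, 0);
  long total = 0;
  for (int i = 0; i < nn; ++i) {
    if (parent[i] < 0) continue;
    double blen = time[parent[i]] - time[i];
    double lam = blen * mu_site * L;
    if (finite_sites && lam > 0.5 * L) { bulk[i] = 1; continue; }
    int nm = (int)R::rpois(lam);
    if (nm > 0) {
      msites[i].reserve(nm);
      total += nm;
      for (int m = 0; m < nm; ++m) msites[i].push_back(-1); // placeholder
    }
  }
  if (finite_sites) {
    for (int i = 0; i < nn; ++i)
      for (size_t m = 0; m < msites[i].size(); ++m) {
        int s = (int)(R::unif_rand() * L); if (s >= L) s = L - 1;
        msites[i][m] = s;
      }
  } else {
    if (total > (long)L)
      stop("infinite-sites model exhausted the locus (%ld mutations, %d sites); use finite_sites_JC", total, L);
    // sample `total` distinct sites via partial Fisher-Yates
    std::vector<int> sites(L);
    for (int s = 0; s < L; ++s) sites[s] = s;
    long drawn = 0;
    for (int i = 0; i < nn; ++i)
      for (size_t m = 0; m < msites[i].size(); ++m) {
        long j = drawn + (long)(R::unif_rand() * (L - drawn));
        if (j >= (long)L) j = L - 1;
        std::swap(sites[drawn], sites[j]);
        msites[i][m] = sites[drawn];
        drawn++;
      }
  }

  std::vector<int> seq(nn * L);
  int root = ord[0];
  for (int s = 0; s < L; ++s) {
    int b = (int)(R::unif_rand() * 4); if (b >= 4) b = 3;
    seq[root * L + s] = b;
  }
  for (int oi = 1; oi < nn; ++oi) {
    int i = ord[oi];
    int p = parent[i];
    std::copy(seq.begin() + p * L, seq.begin() + (p + 1) * L, seq.begin() + i * L);
    if (bulk[i]) {
      double blen = time[p] - time[i];
      double p_same = 0.25 + 0.75 * std::exp(-(4.0 / 3.0) * mu_site * blen);
      for (int s = 0; s < L; ++s) {
        if (R::unif_rand() > p_same) {
          int shift = 1 + (int)(R::unif_rand() * 3); if (shift > 3) shift = 3;
          seq[i * L + s] = (seq[i * L + s] + shift) % 4;
        }
      }
    } else {
      for (int s : msites[i]) {
        int shift = 1 + (int)(R::unif_rand() * 3); if (shift > 3) shift = 3;
        seq[i * L + s] = (seq[i * L + s] + shift) % 4;
      }
    }
  }
  IntegerMatrix out(n_leaves, L);
  for (int i = 0; i < n_leaves; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = seq[i * L + s];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_mutate(const NumericVector& time, const IntegerVector& parent,
                         int n_leaves, int L, double mu_site, bool finite_sites) {
  std::vector<double> tt(time.begin(), time.end());
  std::vector<int> pp(parent.begin(), parent.end());
  return mutate_internal(tt, pp, n_leaves, L, mu_site, finite_sites);
}

// ---------------------------------------------------------------------------
// whole multilocus dataset in one call: per-locus stats (and optionally the
// simulated alignments themselves)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_sim_dataset(const List& cfg, int n_loci, int L,
                     const NumericVector& mu_loc, bool finite_sites,
                     bool return_aligns) {
  SimCfg c = parse_cfg(cfg);
  const int ntot = c.nsamp[0] + c.nsamp[1] + c.nsamp[2];
  std::vector<int> grp(ntot);
  {
    int id = 0;
    for (int sp = 0; sp < 3; ++sp)
      for (int i = 0; i < c.nsamp[sp]; ++i) grp[id++] = sp;
  }
  int G = 3;
  const int ncol = G * SP_NST + 3 * PR_NST;
  NumericMatrix stats(n_loci, ncol);
  List aligns(return_aligns ? n_loci : 0);
  Genealogy g;
  std::vector<double> row;
  for (int l = 0; l < n_loci; ++l) {
    sim_genealogy_internal(c, g);
    IntegerMatrix al = mutate_internal(g.time, g.parent, g.n_leaves, L,
                                       mu_loc[l], finite_sites);
    locus_stats_internal(al, grp, G, row);
    for (int j = 0; j < ncol; ++j) stats(l, j) = row[j];
    if (return_aligns) aligns[l] = al;
  }
  if (return_aligns)
    return List::create(_["stats"] = stats, _["aligns"] = aligns);
  return List::create(_["stats"] = stats);
}
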