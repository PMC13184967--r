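#include <Rcpp.h>
using namespace Rcpp;

// betaMNTD for a set of sample pairs.
//
// rel:   taxa x samples relative-abundance matrix (columns sum to 1)
// D:     taxa x taxa patristic distance matrix
// pairs: npairs x 2, 0-based sample indices
// perm:  0-based taxa permutation applied to D (taxa-label shuffle null);
//        identity permutation gives the observed statistic.
//
// betaMNTD(a,b) = 0.5 * [ sum_{i in a} f_ai * min_{j in b} D[i,j]
//                       + sum_{j in b} f_bj * min_{i in a} D[i,j] ]
// Shared taxa contribute distance 0 (conspecifics included).
// [[Rcpp::export]]
NumericVector cpp_bmntd_pairs(const NumericMatrix& rel,
                              const NumericMatrix& D,
                              const IntegerMatrix& pairs,
                              const IntegerVector& perm) {
  const int nt = rel.nrow();
  const int np = pairs.nrow();

  // samples actually needed
  std::vector<int> need;
  std::vector<int> slot(rel.ncol(), -1);
  for (int p = 0; p < np; ++p) {
    for (int k = 0; k < 2; ++k) {
      int s = pairs(p, k);
      if (slot[s] < 0) { slot[s] = need.size(); need.push_back(s); }
    }
  }
  const int ns = need.size();

  // supports
  std::vector< std::vector<int> > supp(ns);
  for (int q = 0; q < ns; ++q) {
    int s = need[q];
    for (int i = 0; i < nt; ++i)
      if (rel(i, s) > 0.0) supp[q].push_back(i);
    if (supp[q].empty()) stop("empty community in betaMNTD");
  }

  // minD(i, q) = min over j in support of sample need[q] of D[perm i, perm j]
  NumericMatrix minD(nt, ns);
  for (int q = 0; q < ns; ++q) {
    const std::vector<int>& sp = supp[q];
    for (int i = 0; i < nt; ++i) {
      const int pi = perm[i];
      double m = R_PosInf;
      for (size_t u = 0; u < sp.size(); ++u) {
        double d = D(pi, perm[sp[u]]);
        if (d < m) m = d;
      }
      minD(i, q) = m;
    }
  }

  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    int qa = slot[pairs(p, 0)], qb = slot[pairs(p, 1)];
    int sa = need[qa], sb = need[qb];
    double acc = 0.0;
    const std::vector<int>& A = supp[qa];
    for (size_t u = 0; u < A.size(); ++u)
      acc += rel(A[u], sa) * minD(A[u], qb);
    const std::vector<int>& B = supp[qb];
    for (size_t u = 0; u < B.size(); ++u)
      acc += rel(B[u], sb) * minD(B[u], qa);
    out[p] = 0.5 * acc;
  }
  return out;
}

// Local similarity DP for one pair of standardized series.
//
// For each alignment offset d in -D..D (scanned in order of |d|, positive
// first, keeping strictly better scores so small delays win ties), form the
// products x[t] * y[t + d] and find the maximal-magnitude contiguous partial
// sum (max-subarray for positive runs, min-subarray for negative runs).
// score = signed best sum / n. Reported delay d means the best alignment
// pairs x[t] with y[t + d] (a follower y lagging x by L is found at d = L);
// start/end are 1-based indices of the aligned window in x coordinates.
// [[Rcpp::export]]
List cpp_local_similarity(const NumericVector& zx, const NumericVector& zy,
                          const int D) {
  const int n = zx.size();
  double best = 0.0; int bestd = 0, bests = 1, beste = 1;

  for (int ad = 0; ad <= D; ++ad) {
    for (int sgn = 0; sgn < (ad == 0 ? 1 : 2); ++sgn) {
      int d = (sgn == 0) ? ad : -ad;
      int t0 = std::max(0, -d);          // 0-based x start
      int t1 = std::min(n - 1, n - 1 - d); // 0-based x end
      // Kadane, both signs, tracking intervals
      double maxcur = 0.0, maxbest = 0.0; int maxs = t0, maxcs = t0, maxe = t0 - 1;
      double mincur = 0.0, minbest = 0.0; int mins = t0, mincs = t0, mine = t0 - 1;
      for (int t = t0; t <= t1; ++t) {
        double p = zx[t] * zy[t + d];
        if (maxcur <= 0.0) { maxcur = p; maxcs = t; } else maxcur += p;
        if (maxcur > maxbest) { maxbest = maxcur; maxs = maxcs; maxe = t; }
        if (mincur >= 0.0) { mincur = p; mincs = t; } else mincur += p;
        if (mincur < minbest) { minbest = mincur; mins = mincs; mine = t; }
      }
      if (maxbest > std::abs(best)) {
        best = maxbest; bestd = d; bests = maxs + 1; beste = maxe + 1;
      }
      if (-minbest > std::abs(best)) {
        best = minbest; bestd = d; bests = mins + 1; beste = mine + 1;
      }
    }
  }
  return List::create(_["score"] = best / n, _["delay"] = bestd,
                      _["start"] = bests, _["end"] = beste);
}

static double ls_abs_score(const double* zx, const double* zy,
                           const int n, const int D) {
  double best = 0.0;
  for (int d = -D; d <= D; ++d) {
    int t0 = std::max(0, -d);
    int t1 = std::min(n - 1, n - 1 - d);
    double maxcur = 0.0, maxbest = 0.0, mincur = 0.0, minbest = 0.0;
    for (int t = t0; t <= t1; ++t) {
      double p = zx[t] * zy[t + d];
      maxcur = (maxcur <= 0.0) ? p : maxcur + p;
      if (maxcur > maxbest) maxbest = maxcur;
      mincur = (mincur >= 0.0) ? p : mincur + p;
      if (mincur < minbest) minbest = mincur;
    }
    if (maxbest > best) best = maxbest;
    if (-minbest > best) best = -minbest;
  }
  return best / n;
}

// Permutation p-value for |LS|: permute the time order of y with
// Fisher-Yates driven by R's RNG (so set.seed() controls it exactly).
// p = (1 + #{ |LS_perm| >= |LS_obs| }) / (1 + n_perm)
// [[Rcpp::export]]
double cpp_lsa_pvalue(const NumericVector& zx, const NumericVector& zy,
                      const int D, const int n_perm) {
  const int n = zx.size();
  const double obs = ls_abs_score(zx.begin(), zy.begin(), n, D);
  std::vector<double> y(zy.begin(), zy.end());
  RNGScope scope;
  int count = 0;
  for (int k = 0; k < n_perm; ++k) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    if (ls_abs_score(zx.begin(), y.data(), n, D) >= obs) ++count;
  }
  return (1.0 + count) / (1.0 + n_perm);
}
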