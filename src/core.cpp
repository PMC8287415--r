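#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Byte-wise (C locale) string comparison, used for canonical gene-pair
// ordering.  Locale-dependent R string comparison must never leak into
// pair canonicalization.
// [[Rcpp::export]]
LogicalVector str_gt_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = std::strcmp(CHAR(STRING_ELT(a, i)), CHAR(STRING_ELT(b, i))) > 0;
  }
  return out;
}

// Welch t of CILP products for every pair under one labeling.
// Xt is samples x genes (column per gene, cache-friendly); ia/ib are 0-based
// gene column indices.  The labeling is given as index lists (case samples
// then control samples) so every inner loop is branch-free; zbuf holds the
// group-wise standardized matrix in group-blocked sample order (the order
// is irrelevant to the Welch statistic).  scores receives one t per pair.
static void dysgps_core(const double* X, int ns, int ng,
                        const int* idx1, int n1, const int* idx0, int n0,
                        const int* ia, const int* ib, int np,
                        double* zbuf, double* scores) {
  for (int g = 0; g < ng; ++g) {
    const double* x = X + (size_t)g * ns;
    double* z = zbuf + (size_t)g * ns;
    double s1 = 0.0, s0 = 0.0;
    for (int k = 0; k < n1; ++k) s1 += x[idx1[k]];
    for (int k = 0; k < n0; ++k) s0 += x[idx0[k]];
    const double m1 = s1 / n1, m0 = s0 / n0;
    double q1 = 0.0, q0 = 0.0;
    for (int k = 0; k < n1; ++k) {
      const double c = x[idx1[k]] - m1;
      z[k] = c;
      q1 += c * c;
    }
    for (int k = 0; k < n0; ++k) {
      const double c = x[idx0[k]] - m0;
      z[n1 + k] = c;
      q0 += c * c;
    }
    const double sd1 = std::sqrt(q1 / (n1 - 1));
    const double sd0 = std::sqrt(q0 / (n0 - 1));
    if (sd1 <= 0.0 || sd0 <= 0.0) {
      for (int k = 0; k < ns; ++k) z[k] = NA_REAL;
    } else {
      const double i1 = 1.0 / sd1, i0 = 1.0 / sd0;
      for (int k = 0; k < n1; ++k) z[k] *= i1;
      for (int k = n1; k < ns; ++k) z[k] *= i0;
    }
  }
  for (int p = 0; p < np; ++p) {
    const double* za = zbuf + (size_t)ia[p] * ns;
    const double* zb = zbuf + (size_t)ib[p] * ns;
    double s1 = 0.0, q1 = 0.0, s0 = 0.0, q0 = 0.0;
    for (int k = 0; k < n1; ++k) {
      const double y = za[k] * zb[k];
      s1 += y; q1 += y * y;
    }
    for (int k = n1; k < ns; ++k) {
      const double y = za[k] * zb[k];
      s0 += y; q0 += y * y;
    }
    const double m1 = s1 / n1, m0 = s0 / n0;
    const double v1 = (q1 - n1 * m1 * m1) / (n1 - 1);
    const double v0 = (q0 - n0 * m0 * m0) / (n0 - 1);
    const double den = std::sqrt(v1 / n1 + v0 / n0);
    scores[p] = (m1 - m0) / den;
  }
}

// Split a 0/1 group vector into case / control sample index lists.
static void split_groups(const int* grp, int ns,
                         std::vector<int>& idx1, std::vector<int>& idx0) {
  idx1.clear(); idx0.clear();
  for (int k = 0; k < ns; ++k) {
    if (grp[k]) idx1.push_back(k); else idx0.push_back(k);
  }
}

// [[Rcpp::export]]
NumericVector dysgps_cpp(NumericMatrix Xt, IntegerVector ia, IntegerVector ib,
                         IntegerVector grp) {
  const int ns = Xt.nrow(), ng = Xt.ncol(), np = ia.size();
  if (ib.size() != np) stop("pair index length mismatch");
  if (grp.size() != ns) stop("group vector length mismatch");
  std::vector<int> idx1, idx0;
  split_groups(INTEGER(grp), ns, idx1, idx0);
  if (idx1.size() < 2 || idx0.size() < 2)
    stop("need at least 2 samples per group");
  std::vector<double> zbuf((size_t)ns * ng);
  NumericVector out(np);
  dysgps_core(REAL(Xt), ns, ng, idx1.data(), idx1.size(),
              idx0.data(), idx0.size(),
              INTEGER(ia), INTEGER(ib), np, zbuf.data(), REAL(out));
  return out;
}

// Running-sum extrema for one ranked list and a set of pathways.
// Candidate extrema of S_hit - S_miss occur only at hit positions (maxima)
// and immediately before them (minima); 0 (the start/end value) is always a
// candidate.  sorted_hits holds 1-based ranks ascending, w aligned weights.
static double dysps_one(const int* ranks, const double* w, int m,
                        int N, double NR) {
  const double nmiss = (double)(N - m);
  double cum = 0.0, smax = 0.0, smin = 0.0;
  for (int j = 0; j < m; ++j) {
    const double missterm = (double)(ranks[j] - 1 - j) / nmiss;
    const double before = cum / NR - missterm;
    cum += w[j];
    const double after = cum / NR - missterm;
    if (before < smin) smin = before;
    if (after > smax) smax = after;
  }
  if (std::fabs(smax) > std::fabs(smin)) return smax;
  if (std::fabs(smax) < std::fabs(smin)) return smin;
  return smax;
}

struct PathwaySet {
  std::vector<std::vector<int>> idx;  // 0-based pair indices per pathway
};

static void build_pathways(const List& pathways, int np, PathwaySet& ps) {
  const int K = pathways.size();
  ps.idx.resize(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector v = pathways[k];
    std::vector<int>& dst = ps.idx[k];
    dst.resize(v.size());
    for (int j = 0; j < v.size(); ++j) {
      const int i = v[j] - 1;
      if (i < 0 || i >= np) stop("pathway pair index out of range");
      dst[j] = i;
    }
    if ((int)dst.size() >= np)
      stop("pathway must be a strict subset of the ranked list");
    if (dst.empty()) stop("empty pathway");
  }
}

// Score all pathways for one score vector.  idxbuf/rankof are reused
// workspaces of length np.
static void dysps_all(const double* scores, const int* tiekey, int np,
                      const PathwaySet& ps, double p_exp,
                      std::vector<int>& idxbuf, std::vector<int>& rankof,
                      double* out) {
  for (int i = 0; i < np; ++i) idxbuf[i] = i;
  std::sort(idxbuf.begin(), idxbuf.end(), [&](int a, int b) {
    if (scores[a] != scores[b]) return scores[a] > scores[b];
    return tiekey[a] < tiekey[b];
  });
  for (int r = 0; r < np; ++r) rankof[idxbuf[r]] = r + 1;
  const int K = ps.idx.size();
  std::vector<std::pair<int, double>> hits;
  for (int k = 0; k < K; ++k) {
    const std::vector<int>& members = ps.idx[k];
    const int m = members.size();
    hits.clear();
    double NR = 0.0;
    for (int j = 0; j < m; ++j) {
      const int i = members[j];
      double w;
      if (p_exp == 1.0) w = std::fabs(scores[i]);
      else if (p_exp == 0.0) w = 1.0;
      else w = std::pow(std::fabs(scores[i]), p_exp);
      NR += w;
      hits.emplace_back(rankof[i], w);
    }
    if (NR <= 0.0) stop("all pathway pair weights are zero (N_R = 0)");
    std::sort(hits.begin(), hits.end());
    std::vector<int> rr(m);
    std::vector<double> ww(m);
    for (int j = 0; j < m; ++j) { rr[j] = hits[j].first; ww[j] = hits[j].second; }
    out[k] = dysps_one(rr.data(), ww.data(), m, np, NR);
  }
}

// [[Rcpp::export]]
NumericVector dysps_cpp(NumericVector scores, IntegerVector tiekey,
                        List pathways, double p_exp) {
  const int np = scores.size();
  if (tiekey.size() != np) stop("tiekey length mismatch");
  for (int i = 0; i < np; ++i)
    if (!R_finite(scores[i])) stop("non-finite pair score at index %d", i + 1);
  PathwaySet ps;
  build_pathways(pathways, np, ps);
  NumericVector out(pathways.size());
  std::vector<int> idxbuf(np), rankof(np);
  dysps_all(REAL(scores), INTEGER(tiekey), np, ps, p_exp,
            idxbuf, rankof, REAL(out));
  return out;
}

// Shared-permutation null: one label shuffle scores every pathway.
// grp_perms is samples x n_perm with 0/1 entries; returns n_perm x K.
// [[Rcpp::export]]
NumericMatrix perm_null_cpp(NumericMatrix Xt, IntegerVector ia, IntegerVector ib,
                            IntegerMatrix grp_perms, IntegerVector tiekey,
                            List pathways, double p_exp) {
  const int ns = Xt.nrow(), ng = Xt.ncol(), np = ia.size();
  const int nperm = grp_perms.ncol();
  if (grp_perms.nrow() != ns) stop("permutation matrix row count != samples");
  if (tiekey.size() != np) stop("tiekey length mismatch");
  PathwaySet ps;
  build_pathways(pathways, np, ps);
  const int K = pathways.size();
  NumericMatrix out(nperm, K);
  std::vector<double> zbuf((size_t)ns * ng), scores(np), es(K);
  std::vector<int> idxbuf(np), rankof(np), idx1, idx0;
  for (int t = 0; t < nperm; ++t) {
    split_groups(&grp_perms(0, t), ns, idx1, idx0);
    if (idx1.size() < 2 || idx0.size() < 2)
      stop("permutation %d leaves a group with < 2 samples", t + 1);
    dysgps_core(REAL(Xt), ns, ng, idx1.data(), idx1.size(),
                idx0.data(), idx0.size(),
                INTEGER(ia), INTEGER(ib), np, zbuf.data(), scores.data());
    for (int i = 0; i < np; ++i)
      if (!R_finite(scores[i]))
        stop("non-finite pair score in permutation %d", t + 1);
    dysps_all(scores.data(), INTEGER(tiekey), np, ps, p_exp,
              idxbuf, rankof, es.data());
    for (int k = 0; k < K; ++k) out(t, k) = es[k];
    if ((t & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
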