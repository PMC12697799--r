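#include <RcppArmadillo.h>
#include <algorithm>
#include <limits>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// k smallest code-distance candidates per query, excluding candidates whose
// window overlaps the query in time (|start difference| < excl). Ties at the
// k-th distance are resolved by seeded uniform sampling among the tied set.
// Returns 1-based indices into the candidate rows, sorted by distance.
// [[Rcpp::export]]
List cpp_topk_neighbors(const arma::mat& Q, const arma::mat& C,
                        const arma::vec& qstart, const arma::vec& cstart,
                        double excl, int k, int tieSeed) {
  const int nq = Q.n_rows, nc = C.n_rows;
  if (nq == 0) stop("no query windows");
  if (nc < k) stop("neighbor capacity: only %d candidates for k = %d", nc, k);
  for (int i = 1; i < nc; ++i)
    if (cstart(i) < cstart(i - 1))
      stop("candidate window starts must be non-decreasing");
  arma::vec c2 = arma::sum(arma::square(C), 1);
  arma::vec q2 = arma::sum(arma::square(Q), 1);
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  const int block = 128;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> buf(nc);
  std::vector<int> keep, tied;
  const double* cs = cstart.memptr();
  for (int b0 = 0; b0 < nq; b0 += block) {
    const int b1 = std::min(b0 + block, nq);
    arma::mat G = C * Q.rows(b0, b1 - 1).t();  // nc x nb
    for (int j = b0; j < b1; ++j) {
      arma::vec d2 = c2 + q2(j) - 2.0 * G.col(j - b0);
      double* pd = d2.memptr();
      // overlap exclusion: candidates with |start - qstart| < excl form a
      // contiguous index range because starts are sorted
      const int exLo = (int)(std::lower_bound(cs, cs + nc,
                             qstart(j) - excl + 1e-9) - cs);
      const int exHi = (int)(std::upper_bound(cs, cs + nc,
                             qstart(j) + excl - 1e-9) - cs);
      for (int i = exLo; i < exHi; ++i) pd[i] = inf;
      const int navail = nc - (exHi - exLo);
      if (navail < k)
        stop("neighbor capacity: query %d (start %.3f s) has only %d non-excluded candidates for k = %d; reduce k or the stride",
             j + 1, qstart(j), navail, k);
      for (int i = 0; i < nc; ++i) if (pd[i] < 0) pd[i] = 0;
      std::copy(pd, pd + nc, buf.begin());
      std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
      const double dk = buf[k - 1];
      // purely relative tolerance: tie membership is then invariant under
      // a uniform rescaling of all distances (e.g. a duplicated unit)
      const double eps = 1e-9 * dk;
      keep.clear(); tied.clear();
      for (int i = 0; i < nc; ++i) {
        if (pd[i] < dk - eps) keep.push_back(i);
        else if (pd[i] <= dk + eps) tied.push_back(i);  // index order
      }
      int need = k - (int)keep.size();
      if (need > 0) {
        std::mt19937 rng(2654435761u * (unsigned)tieSeed + (unsigned)j);
        for (int t = 0; t < need; ++t) {
          std::uniform_int_distribution<int> u(t, (int)tied.size() - 1);
          std::swap(tied[t], tied[u(rng)]);
          keep.push_back(tied[t]);
        }
      }
      std::vector<std::pair<double, int> > out;
      out.reserve(k);
      for (size_t m = 0; m < keep.size(); ++m)
        out.push_back(std::make_pair(std::sqrt(pd[keep[m]]), keep[m]));
      std::sort(out.begin(), out.end());
      for (int t = 0; t < k; ++t) {
        idx(j, t) = out[t].second + 1;
        dist(j, t) = out[t].first;
      }
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Average the k neighbor stimulus segments per query at each lag and place
// the per-query prediction at (query column + lag), accumulating pixel sums
// and per-column placement counts. Neighbor segments (or placement columns)
// falling outside the stimulus are dropped. All columns 0-based.
// [[Rcpp::export]]
List cpp_reconstruct(const arma::mat& S, const IntegerMatrix& neigh,
                     const IntegerVector& candCol,
                     const IntegerVector& queryCol,
                     const IntegerVector& lagCol, int L) {
  const int nf = S.n_rows, nt = S.n_cols;
  const int nq = neigh.nrow(), k = neigh.ncol(), nl = lagCol.size();
  if (nl == 0) stop("at least one lag is required");
  if (L < 1 || L > nt) stop("segment length out of range");
  arma::mat acc(nf, nt, arma::fill::zeros);
  arma::vec cnt(nt, arma::fill::zeros);
  int minLag = lagCol[0], maxLag = lagCol[0];
  for (int l = 1; l < nl; ++l) {
    minLag = std::min(minLag, lagCol[l]);
    maxLag = std::max(maxLag, lagCol[l]);
  }
  const int extL = L + (maxLag - minLag);
  arma::mat seg(nf, L), ext(nf, extL);
  int dropped = 0;
  // accumulate in candidate-index order so the floating-point sum does not
  // depend on how distance ties happened to be ordered
  std::vector<int> nidx(k);
  for (int q = 0; q < nq; ++q) {
    for (int m = 0; m < k; ++m) nidx[m] = neigh(q, m) - 1;
    std::sort(nidx.begin(), nidx.end());
    // fast path: every neighbor's extended segment (all lags) in range --
    // average once and reuse shifted views per lag
    bool allIn = true;
    for (int m = 0; m < k && allIn; ++m) {
      const int s0 = candCol[nidx[m]] + minLag;
      if (s0 < 0 || s0 + extL > nt) allIn = false;
    }
    if (allIn) {
      ext.zeros();
      for (int m = 0; m < k; ++m) {
        const int s0 = candCol[nidx[m]] + minLag;
        ext += S.cols(s0, s0 + extL - 1);
      }
      ext /= (double)k;
      for (int l = 0; l < nl; ++l) {
        const int off = lagCol[l] - minLag;
        const int t0 = queryCol[q] + lagCol[l];
        for (int c = 0; c < L; ++c) {
          const int tc = t0 + c;
          if (tc < 0 || tc >= nt) continue;
          acc.col(tc) += ext.col(off + c);
          cnt(tc) += 1.0;
        }
      }
      continue;
    }
    for (int l = 0; l < nl; ++l) {
      const int lag = lagCol[l];
      seg.zeros();
      int used = 0;
      for (int m = 0; m < k; ++m) {
        const int s = candCol[nidx[m]] + lag;
        if (s < 0 || s + L > nt) { ++dropped; continue; }
        seg += S.cols(s, s + L - 1);
        ++used;
      }
      if (used == 0) continue;
      seg /= (double)used;
      const int t0 = queryCol[q] + lag;
      for (int c = 0; c < L; ++c) {
        const int tc = t0 + c;
        if (tc < 0 || tc >= nt) continue;
        acc.col(tc) += seg.col(c);
        cnt(tc) += 1.0;
      }
    }
  }
  return List::create(_["sum"] = acc, _["count"] = cnt,
                      _["dropped"] = dropped);
}

// Correlation profiles between two grids over selected columns:
// per-column correlation across rows, and per-row correlation across the
// selected columns. Degenerate (zero-variance) entries are NA.
// [[Rcpp::export]]
List cpp_corr_profiles(const arma::mat& A, const arma::mat& P,
                       const IntegerVector& cols) {
  const int nf = A.n_rows;
  const int ncov = cols.size();
  NumericVector corrT(A.n_cols, NA_REAL);
  NumericVector corrF(nf, NA_REAL);
  // per-column correlations, vectorized over columns
  {
    const arma::rowvec mA = arma::mean(A, 0), mP = arma::mean(P, 0);
    const arma::rowvec sA = arma::stddev(A, 0, 0),
                       sP = arma::stddev(P, 0, 0);
    const arma::rowvec cv =
      (arma::sum(A % P, 0) - (double)nf * (mA % mP)) / (double)(nf - 1);
    for (int jj = 0; jj < ncov; ++jj) {
      const int j = cols[jj];
      if (sA(j) > 1e-14 && sP(j) > 1e-14)
        corrT[j] = cv(j) / (sA(j) * sP(j));
    }
  }
  arma::uvec uc(ncov);
  for (int jj = 0; jj < ncov; ++jj) uc(jj) = (arma::uword)cols[jj];
  for (int f = 0; f < nf; ++f) {
    const arma::rowvec a = A.row(f), p = P.row(f);
    const arma::vec av = a.cols(uc).t(), pv = p.cols(uc).t();
    const double sa = arma::stddev(av), sp = arma::stddev(pv);
    if (sa > 1e-14 && sp > 1e-14)
      corrF[f] = arma::as_scalar(arma::cor(av, pv));
  }
  return List::create(_["corrT"] = corrT, _["corrF"] = corrF);
}
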