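#include <Rcpp.h>
using namespace Rcpp;

// Greedy farthest-point sampling (max-min). Ties broken by lowest index
// (strict > comparison keeps the first maximiser). 1-based start index.
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix X, int m, int start) {
  const int n = X.nrow();
  IntegerVector sel(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  for (int j = 0; j < m; ++j) {
    sel[j] = cur + 1;
    const double cx = X(cur, 0), cy = X(cur, 1), cz = X(cur, 2);
    double best = -1.0;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = X(i, 0) - cx, dy = X(i, 1) - cy, dz = X(i, 2) - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind[i]) mind[i] = d2;
      if (mind[i] > best) { best = mind[i]; bi = i; }
    }
    cur = bi;
  }
  return sel;
}

// Brute-force k nearest neighbours (self excluded), indices sorted by
// increasing distance; ties by lowest index (stable sort on (d2, index)).
// [[Rcpp::export]]
List knn_cpp(NumericMatrix X, int k) {
  const int n = X.nrow();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    int nc = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
      cand[nc++] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + nc);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;
      dist(i, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Ball query: for each center, points of X within `radius`, nearest-first,
// capped at nsample; a center with no point in range falls back to its
// single nearest point so no group is empty.
// [[Rcpp::export]]
List ball_query_cpp(NumericMatrix centers, NumericMatrix X, double radius,
                    int nsample) {
  const int m = centers.nrow(), n = X.nrow();
  const double r2 = radius * radius;
  std::vector<int> idx;
  idx.reserve((size_t)m * std::min(n, nsample));
  IntegerVector counts(m);
  std::vector<std::pair<double, int> > inr;
  for (int c = 0; c < m; ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    inr.clear();
    double bestd = R_PosInf;
    int besti = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = X(i, 0) - cx, dy = X(i, 1) - cy, dz = X(i, 2) - cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) inr.push_back(std::make_pair(d2, i));
      if (d2 < bestd) { bestd = d2; besti = i; }
    }
    if (inr.empty()) inr.push_back(std::make_pair(bestd, besti));
    const int take = std::min((int)inr.size(), nsample);
    std::partial_sort(inr.begin(), inr.begin() + take, inr.end());
    for (int j = 0; j < take; ++j) idx.push_back(inr[j].second + 1);
    counts[c] = take;
  }
  return List::create(_["idx"] = wrap(idx), _["counts"] = counts);
}

// Column-wise max over contiguous row groups. ptr is 0-based offsets of
// length G+1; group g owns rows [ptr[g], ptr[g+1]). Returns per-group max
// and the (1-based) row index in H attaining it (first occurrence).
// [[Rcpp::export]]
List group_max_cpp(NumericMatrix H, IntegerVector ptr) {
  const int g = ptr.size() - 1, c = H.ncol();
  NumericMatrix mx(g, c);
  IntegerMatrix am(g, c);
  for (int i = 0; i < g; ++i) {
    const int lo = ptr[i], hi = ptr[i + 1];
    for (int j = 0; j < c; ++j) {
      double best = H(lo, j);
      int bi = lo;
      for (int r = lo + 1; r < hi; ++r)
        if (H(r, j) > best) { best = H(r, j); bi = r; }
      mx(i, j) = best;
      am(i, j) = bi + 1;
    }
  }
  return List::create(_["max"] = mx, _["argmax"] = am);
}

// k nearest rows of X for each row of Q (self not excluded), nearest-first.
// [[Rcpp::export]]
List nearestk_cpp(NumericMatrix Q, NumericMatrix X, int k) {
  const int nq = Q.nrow(), n = X.nrow();
  if (k > n) k = n;
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < nq; ++i) {
    const double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = X(j, 0) - qx, dy = X(j, 1) - qy, dz = X(j, 2) - qz;
      cand[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = cand[j].second + 1;
      dist(i, j) = std::sqrt(cand[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Squared Euclidean cross-distance matrix (A rows x B rows).
// [[Rcpp::export]]
NumericMatrix cross_dist2_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = B(j, 0) - ax, dy = B(j, 1) - ay, dz = B(j, 2) - az;
      D(i, j) = dx * dx + dy * dy + dz * dz;
    }
  }
  return D;
}
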