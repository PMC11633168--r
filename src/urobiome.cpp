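// Compiled kernels: pairwise root-JSD, PAM (BUILD + SWAP), a small
// classification random forest, and an IRLS logistic scan with a
// Firth-penalized fallback. All randomness goes through R's RNG so a
// set.seed() in R fixes every result.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- JSD

// rows of X must be strictly positive and sum to 1
// [[Rcpp::export(name = ".jsd_pairwise_cpp")]]
NumericMatrix jsd_pairwise_cpp(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector H(n);
  for (int i = 0; i < n; ++i) {
    double h = 0.0;
    for (int j = 0; j < p; ++j) h -= X(i, j) * std::log(X(i, j));
    H[i] = h;
  }
  NumericMatrix D(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double hm = 0.0;
      for (int j = 0; j < p; ++j) {
        double m = 0.5 * (X(a, j) + X(b, j));
        hm -= m * std::log(m);
      }
      double jsd = hm - 0.5 * (H[a] + H[b]);
      if (jsd < 0) jsd = 0;
      double d = std::sqrt(jsd);
      D(a, b) = d;
      D(b, a) = d;
    }
  }
  return D;
}

// ---------------------------------------------------------------- PAM

static double pam_cost(const NumericMatrix& D,
                       const std::vector<int>& med,
                       std::vector<int>& assign) {
  const int n = D.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int who = -1;
    for (size_t m = 0; m < med.size(); ++m) {
      double d = D(i, med[m]);
      if (d < best) { best = d; who = (int)m; }
    }
    assign[i] = who;
    total += best;
  }
  return total;
}

// BUILD initialization then best-improvement SWAP to convergence.
// Ties break toward the lowest sample index.
// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(const NumericMatrix& D, const int k) {
  const int n = D.nrow();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  std::vector<int> med;
  std::vector<bool> is_med(n, false);
  // BUILD: first medoid minimizes the total distance
  {
    double best = R_PosInf; int who = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += D(i, j);
      if (s < best - 1e-12) { best = s; who = i; }
    }
    med.push_back(who); is_med[who] = true;
  }
  std::vector<double> nearest(n);
  for (int i = 0; i < n; ++i) nearest[i] = D(i, med[0]);
  while ((int)med.size() < k) {
    double best_gain = -1.0; int who = -1;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double delta = nearest[i] - D(i, c);
        if (delta > 0) gain += delta;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; who = c; }
    }
    med.push_back(who); is_med[who] = true;
    for (int i = 0; i < n; ++i)
      if (D(i, who) < nearest[i]) nearest[i] = D(i, who);
  }
  std::vector<int> assign(n);
  double cost = pam_cost(D, med, assign);
  // SWAP: best-improvement local search
  bool improved = true;
  while (improved) {
    improved = false;
    double best_cost = cost;
    int bm = -1, bh = -1;
    for (size_t m = 0; m < med.size(); ++m) {
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        std::vector<int> trial = med;
        trial[m] = h;
        std::vector<int> tmp(n);
        double c2 = pam_cost(D, trial, tmp);
        if (c2 < best_cost - 1e-12) { best_cost = c2; bm = (int)m; bh = h; }
      }
    }
    if (bm >= 0) {
      is_med[med[bm]] = false;
      med[bm] = bh;
      is_med[bh] = true;
      cost = pam_cost(D, med, assign);
      improved = true;
    }
  }
  // stable cluster numbering: order medoids by sample index
  std::vector<int> ord(med.size());
  for (size_t i = 0; i < med.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return med[a] < med[b]; });
  std::vector<int> rank(med.size());
  for (size_t i = 0; i < ord.size(); ++i) rank[ord[i]] = (int)i;
  IntegerVector assignment(n), medoids(k);
  for (size_t i = 0; i < ord.size(); ++i) medoids[i] = med[ord[i]] + 1;
  for (int i = 0; i < n; ++i) assignment[i] = rank[assign[i]] + 1;
  return List::create(_["assignments"] = assignment,
                      _["medoids"] = medoids,
                      _["cost"] = cost);
}

// ------------------------------------------------------- random forest

struct RfState {
  const arma::mat* X;
  const arma::mat* Xtest;
  const IntegerVector* y;
  int mtry, min_node;
  arma::vec* test_score;   // summed leaf class-1 fractions
  arma::vec* importance;   // Gini decrease per feature
  int n_train;
};

static double gini_imp(const double n1, const double n) {
  if (n <= 0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

static void rf_grow(RfState& st, std::vector<int>& idx,
                    std::vector<int>& tidx) {
  const int n = (int)idx.size();
  double n1 = 0;
  for (int i : idx) n1 += (*st.y)[i];
  const double g_node = gini_imp(n1, n);
  bool leaf = (n < st.min_node * 2) || n1 == 0 || n1 == n;
  int best_f = -1; double best_thr = 0, best_dec = 1e-12;
  double bl = 0, bl1 = 0;
  if (!leaf) {
    const int p = (int)st.X->n_cols;
    // sample mtry distinct feature indices via R's RNG
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < st.mtry; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }
    std::vector<std::pair<double, int>> vals(n);
    for (int f = 0; f < st.mtry; ++f) {
      const int j = feats[f];
      for (int i = 0; i < n; ++i)
        vals[i] = { (*st.X)(idx[i], j), (*st.y)[idx[i]] };
      std::sort(vals.begin(), vals.end());
      double l = 0, l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l += 1; l1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue;
        double r = n - l, r1 = n1 - l1;
        double dec = g_node - (l / n) * gini_imp(l1, l)
                            - (r / n) * gini_imp(r1, r);
        if (dec > best_dec) {
          best_dec = dec; best_f = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          bl = l; bl1 = l1;
        }
      }
    }
  }
  if (best_f < 0) {  // leaf
    double frac = n > 0 ? n1 / n : 0.5;
    for (int t : tidx) (*st.test_score)[t] += frac;
    return;
  }
  (*st.importance)[best_f] += ((double)n / st.n_train) * best_dec;
  std::vector<int> li, ri, lt, rt;
  li.reserve((size_t)bl); ri.reserve(n - (size_t)bl);
  for (int i : idx)
    ((*st.X)(i, best_f) <= best_thr ? li : ri).push_back(i);
  for (int t : tidx)
    ((*st.Xtest)(t, best_f) <= best_thr ? lt : rt).push_back(t);
  rf_grow(st, li, lt);
  rf_grow(st, ri, rt);
}

// [[Rcpp::export(name = ".rf_cpp")]]
List rf_cpp(const arma::mat& X, const IntegerVector& y,
            const arma::mat& Xtest, const int n_trees,
            const int mtry, const int min_node) {
  const int n = (int)X.n_rows, p = (int)X.n_cols;
  const int nt = (int)Xtest.n_rows;
  arma::vec score(nt, arma::fill::zeros);
  arma::vec imp(p, arma::fill::zeros);
  RfState st{ &X, &Xtest, &y, mtry, min_node, &score, &imp, n };
  GetRNGstate();
  std::vector<int> tidx(nt);
  for (int t = 0; t < nt; ++t) tidx[t] = t;
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    std::vector<int> tloc = tidx;
    rf_grow(st, idx, tloc);
  }
  PutRNGstate();
  score /= n_trees;
  double tot = arma::accu(imp);
  if (tot > 0) imp /= tot;
  return List::create(_["prob"] = score, _["importance"] = imp);
}

// ------------------------------------------------- logistic regression

static bool irls_fit(const arma::mat& X, const arma::vec& y,
                     arma::vec& beta, arma::mat& cov, bool firth) {
  const int maxit = firth ? 200 : 50;
  beta.zeros(X.n_cols);
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    eta = arma::clamp(eta, -30.0, 30.0);
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = p % (1.0 - p);
    w = arma::clamp(w, 1e-10, 0.25);
    arma::mat XtW = X.t() * arma::diagmat(w);
    arma::mat I = XtW * X;
    arma::vec resid = y - p;
    if (firth) {
      arma::mat Iinv;
      if (!arma::inv_sympd(Iinv, I)) return false;
      arma::vec h(X.n_rows);
      for (arma::uword i = 0; i < X.n_rows; ++i)
        h(i) = w(i) * arma::as_scalar(X.row(i) * Iinv * X.row(i).t());
      resid += h % (0.5 - p);
    }
    arma::vec step;
    if (!arma::solve(step, I, X.t() * resid,
                     arma::solve_opts::no_approx)) return false;
    // damp large Newton steps (Firth under separation oscillates
    // without this)
    double ms = arma::max(arma::abs(step));
    if (ms > 2.0) step *= 2.0 / ms;
    beta += step;
    if (arma::max(arma::abs(step)) < 1e-8) {
      if (!arma::inv_sympd(cov, I)) return false;
      return true;
    }
  }
  return false;
}

// per-variant logistic fit of y ~ covariates + dosage; Wald test on the
// dosage term, Firth fallback on separation / non-convergence.
// G may contain NaN (missing dosage); covariates C must include the
// intercept column and be complete.
// [[Rcpp::export(name = ".logistic_scan_cpp")]]
List logistic_scan_cpp(const arma::mat& G, const arma::vec& y,
                       const arma::mat& C) {
  const int m = (int)G.n_cols;
  const int pc = (int)C.n_cols;
  NumericVector beta(m), se(m), pval(m), nn(m);
  LogicalVector firth_used(m);
  for (int v = 0; v < m; ++v) {
    arma::uvec ok = arma::find_finite(G.col(v));
    const int n = (int)ok.n_elem;
    nn[v] = n;
    arma::mat X(n, pc + 1);
    X.cols(0, pc - 1) = C.rows(ok);
    arma::vec g = G.col(v);
    X.col(pc) = g.elem(ok);
    arma::vec yy = y.elem(ok);
    if (arma::var(X.col(pc)) < 1e-12) {
      beta[v] = NA_REAL; se[v] = NA_REAL; pval[v] = NA_REAL;
      continue;
    }
    arma::vec b; arma::mat cov;
    bool ok_fit = irls_fit(X, yy, b, cov, false);
    bool flag = !ok_fit || std::abs(b(pc)) > 15 ||
      (ok_fit && std::sqrt(cov(pc, pc)) > 100);
    if (flag) {
      ok_fit = irls_fit(X, yy, b, cov, true);
      firth_used[v] = true;
    }
    if (!ok_fit) {
      beta[v] = NA_REAL; se[v] = NA_REAL; pval[v] = NA_REAL;
      continue;
    }
    beta[v] = b(pc);
    se[v] = std::sqrt(cov(pc, pc));
    double z = beta[v] / se[v];
    pval[v] = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["p"] = pval,
                      _["n"] = nn, _["firth"] = firth_used);
}
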