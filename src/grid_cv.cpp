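// Inner-loop cross-validated grid evaluation for SO-CovSel-LDA.
//
// For one block order and one fold partition, computes the pooled
// misclassification count of every complexity tuple (0..cmax per block)
// in a single pass per fold, exploiting the prefix property of greedy
// CovSel: the selection for c variables is the first c picks of the
// selection for cmax variables, so the stage tree needs only
// 1 + (cmax+1) + (cmax+1)^2 + ... CovSel runs instead of one per tuple.
//
// Projections (block orthogonalization against the accumulated selected
// variables, and the per-stage least-squares fit on the train-centered
// selected columns) are carried out with incrementally maintained
// orthonormal bases (modified Gram-Schmidt, tolerance-guarded), which is
// the same projection the R implementation computes via a pseudo-inverse
// whenever the selected columns are full rank — the generic case for
// continuous concentration data. A test asserts equality of the error
// counts against an R reference composed from the public fit/classify
// functions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double VAR_TOL = 1e-12;

// Greedy CovSel on (X, y), up to nvar picks; returns number achieved.
// Ties break to the lowest column index; zero-variance columns (under the
// running deflation) are skipped.
static int covsel_greedy(mat X, vec y, int nvar, uvec& out) {
  const double n1 = (double)X.n_rows - 1.0;
  int got = 0;
  for (int s = 0; s < nvar; ++s) {
    rowvec ss = sum(square(X), 0);
    vec cv = X.t() * y / n1;
    double best = -1.0;
    int bj = -1;
    for (uword j = 0; j < X.n_cols; ++j) {
      if (ss(j) <= VAR_TOL) continue;
      double sc = cv(j) * cv(j);
      if (sc > best) { best = sc; bj = (int)j; }
    }
    if (bj < 0) break;
    out(s) = (uword)bj;
    vec v = X.col(bj) / std::sqrt(ss(bj));
    X -= v * (v.t() * X);
    y -= v * dot(v, y);
    ++got;
  }
  return got;
}

struct FoldCtx {
  std::vector<mat> Xtr, Xte;  // per stage (order applied, scaled)
  vec ytr;                    // raw 0/1 labels, train
  ivec yte;                   // test labels
  double ybar;
  double n1tr, n0tr;
  bool equal_priors;
  ivec* err;                  // output: per-tuple error counts
  std::vector<int> strides;   // tuple index strides per stage
  ivec cmax;
};

static void mark_infeasible(FoldCtx& C, int k, int cidx) {
  const int K = (int)C.Xtr.size();
  int later = 1;
  for (int kk = k + 1; kk < K; ++kk) later *= (C.cmax(kk) + 1);
  for (int t = 0; t < later; ++t) {
    int off = 0, tt = t;
    for (int kk = k + 1; kk < K; ++kk) {
      off += (tt % (C.cmax(kk) + 1)) * C.strides[kk];
      tt /= (C.cmax(kk) + 1);
    }
    (*C.err)(cidx + off) = -1;
  }
}

// Recursive enumeration over stages. Q/Qte: orthonormal basis of the
// variables selected so far (train) and the same transformation applied
// to the test rows; yo: current orthogonalized response; ptr/pte:
// accumulated prediction contributions.
static void recurse(FoldCtx& C, int k, int idx,
                    const mat& Q, const mat& Qte,
                    const vec& yo, const vec& ptr, const vec& pte) {
  const int K = (int)C.Xtr.size();
  if (k == K) {
    vec yhat_tr = ptr + C.ybar;
    vec yhat_te = pte + C.ybar;
    double m1 = 0, m0 = 0, ss1 = 0, ss0 = 0;
    for (uword i = 0; i < C.ytr.n_elem; ++i) {
      if (C.ytr(i) > 0.5) m1 += yhat_tr(i); else m0 += yhat_tr(i);
    }
    m1 /= C.n1tr;
    m0 /= C.n0tr;
    for (uword i = 0; i < C.ytr.n_elem; ++i) {
      double d = yhat_tr(i) - (C.ytr(i) > 0.5 ? m1 : m0);
      if (C.ytr(i) > 0.5) ss1 += d * d; else ss0 += d * d;
    }
    double s2 = (ss1 + ss0) / (C.n1tr + C.n0tr - 2.0);
    double p1 = C.equal_priors ? 0.5 : C.n1tr / (C.n1tr + C.n0tr);
    int miss = 0;
    if (s2 <= 0.0 || m1 == m0) {
      // degenerate: a constant prediction carries no class information;
      // fall back to the larger-prior class (ties -> class 1)
      int lab = (p1 >= 0.5) ? 1 : 0;
      for (uword i = 0; i < C.yte.n_elem; ++i)
        if (C.yte(i) != lab) ++miss;
    } else {
      double thr = 0.5 * (m1 + m0) +
        s2 * std::log((1.0 - p1) / p1) / (m1 - m0);
      double dir = (m1 > m0) ? 1.0 : -1.0;
      for (uword i = 0; i < C.yte.n_elem; ++i) {
        int lab = (dir * (yhat_te(i) - thr) >= 0.0) ? 1 : 0;
        if (C.yte(i) != lab) ++miss;
      }
    }
    if ((*C.err)(idx) >= 0) (*C.err)(idx) += miss;
    return;
  }

  const mat& Xk = C.Xtr[k];
  const mat& Xk_te = C.Xte[k];
  mat Xo = Xk, Xo_te = Xk_te;
  if (Q.n_cols > 0) {
    mat Cf = Q.t() * Xk;
    Xo -= Q * Cf;
    Xo_te -= Qte * Cf;
  }
  const int cm = C.cmax(k);

  // c = 0: stage skipped
  recurse(C, k + 1, idx, Q, Qte, yo, ptr, pte);

  uvec seq(std::max(cm, 1));
  int avail = covsel_greedy(Xo, yo, cm, seq);

  // incremental bases over the prefix: U for the train-centered selected
  // columns (regression), V for the uncentered ones (accumulation)
  mat U(Xo.n_rows, 0), Ute(Xo_te.n_rows, 0);
  mat V(Xo.n_rows, 0), Vte(Xo_te.n_rows, 0);
  vec fitted(Xo.n_rows, fill::zeros), fitted_te(Xo_te.n_rows, fill::zeros);

  for (int c = 1; c <= cm; ++c) {
    int cidx = idx + c * C.strides[k];
    if (c > avail) { mark_infeasible(C, k, cidx); continue; }
    uword j = seq(c - 1);

    // regression direction: center on the training mean, orthonormalize
    double mu = mean(Xo.col(j));
    vec xc = Xo.col(j) - mu;
    vec xc_te = Xo_te.col(j) - mu;
    for (uword q = 0; q < U.n_cols; ++q) {
      double r = dot(U.col(q), xc);
      xc -= r * U.col(q);
      xc_te -= r * Ute.col(q);
    }
    double nrm = norm(xc);
    if (nrm > 1e-10) {
      xc /= nrm;
      xc_te /= nrm;
      double g = dot(xc, yo);
      fitted += g * xc;
      fitted_te += g * xc_te;
      U = join_rows(U, xc);
      Ute = join_rows(Ute, xc_te);
    }

    // accumulation direction: uncentered original-scale selected column
    vec xv = Xo.col(j), xv_te = Xo_te.col(j);
    for (uword q = 0; q < V.n_cols; ++q) {
      double r = dot(V.col(q), xv);
      xv -= r * V.col(q);
      xv_te -= r * Vte.col(q);
    }
    double nrm2 = norm(xv);
    if (nrm2 > 1e-10) {
      V = join_rows(V, xv / nrm2);
      Vte = join_rows(Vte, xv_te / nrm2);
    }

    recurse(C, k + 1, cidx, join_rows(Q, V), join_rows(Qte, Vte),
            yo - fitted, ptr + fitted, pte + fitted_te);
  }
}

// blocks: list of n x p_k numeric matrices, already in STAGE order.
// y: 0/1 labels (length n). fold: 1-based fold ids (length n).
// cmax: per-stage maximum complexity. scale_folds: autoscale per fold on
// the training rows (guarded: sd < 1e-12 treated as 1). Returns per-tuple
// pooled misclassification counts, index = sum_k c_k * prod_{j<k}(cmax_j+1);
// NA marks tuples infeasible in at least one fold.
// [[Rcpp::export]]
Rcpp::IntegerVector grid_cv_misclass(Rcpp::List blocks,
                                     Rcpp::IntegerVector y,
                                     Rcpp::IntegerVector fold,
                                     Rcpp::IntegerVector cmax,
                                     bool scale_folds,
                                     bool equal_priors) {
  const int K = blocks.size();
  const int n = y.size();
  std::vector<mat> X(K);
  for (int k = 0; k < K; ++k) {
    X[k] = Rcpp::as<mat>(blocks[k]);
    if ((int)X[k].n_rows != n) Rcpp::stop("block row count mismatch");
  }
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i]);

  int ntup = 1;
  std::vector<int> strides(K);
  for (int k = 0; k < K; ++k) { strides[k] = ntup; ntup *= (cmax[k] + 1); }

  ivec err(ntup, fill::zeros);
  ivec cm(K);
  for (int k = 0; k < K; ++k) cm(k) = cmax[k];

  for (int f = 1; f <= nfold; ++f) {
    std::vector<uword> tr, te;
    for (int i = 0; i < n; ++i) {
      if (fold[i] == f) te.push_back(i); else tr.push_back(i);
    }
    if (te.empty()) continue;
    uvec tri(tr), tei(te);
    FoldCtx C;
    C.cmax = cm;
    C.strides = strides;
    C.err = &err;
    C.equal_priors = equal_priors;
    C.Xtr.resize(K);
    C.Xte.resize(K);
    vec yall(n);
    for (int i = 0; i < n; ++i) yall(i) = y[i];
    C.ytr = yall(tri);
    C.yte = ivec(te.size());
    for (size_t i = 0; i < te.size(); ++i) C.yte(i) = y[te[i]];
    C.n1tr = accu(C.ytr);
    C.n0tr = (double)tri.n_elem - C.n1tr;
    if (C.n1tr < 1.0 || C.n0tr < 1.0)
      Rcpp::stop("a training fold lost a class");
    C.ybar = mean(C.ytr);
    for (int k = 0; k < K; ++k) {
      mat tr_m = X[k].rows(tri);
      mat te_m = X[k].rows(tei);
      if (scale_folds) {
        rowvec mu = mean(tr_m, 0);
        rowvec s = stddev(tr_m, 0, 0);  // n-1 denominator
        s.transform([](double v) { return v < 1e-12 ? 1.0 : v; });
        tr_m.each_row() -= mu; tr_m.each_row() /= s;
        te_m.each_row() -= mu; te_m.each_row() /= s;
      }
      C.Xtr[k] = std::move(tr_m);
      C.Xte[k] = std::move(te_m);
    }
    vec yo = C.ytr - C.ybar;
    vec ptr(tri.n_elem, fill::zeros), pte(tei.n_elem, fill::zeros);
    mat Q0(tri.n_elem, 0), Q0te(tei.n_elem, 0);
    recurse(C, 0, 0, Q0, Q0te, yo, ptr, pte);
  }

  Rcpp::IntegerVector out(ntup);
  for (int t = 0; t < ntup; ++t) out[t] = err(t) < 0 ? NA_INTEGER : err(t);
  return out;
}
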