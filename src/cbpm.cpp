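// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Partial correlation of every column of X with y given the covariate
// columns Zcov plus an implicit intercept. Computed from cross-products of
// the projection onto [1 | centered Zcov] (mathematically identical to
// correlating the OLS residuals of X_e and y on the covariates); centering
// the covariates keeps the small normal-equation system well conditioned.
// Zero-variance residual columns return NaN (unselectable).
static arma::vec partial_cor_core(const arma::mat& X, const arma::vec& y,
                                  const arma::mat& Zcov) {
  const arma::uword n = X.n_rows, c = Zcov.n_cols;
  arma::mat Z(n, c + 1);
  Z.col(0).ones();
  if (c > 0) {
    arma::rowvec zm = arma::mean(Zcov, 0);
    Z.cols(1, c) = Zcov.each_row() - zm;
  }
  arma::mat S = Z.t() * Z;            // (c+1) x (c+1)
  arma::mat C = Z.t() * X;            // (c+1) x E
  arma::vec zy = Z.t() * y;
  arma::vec w = arma::solve(S, zy, arma::solve_opts::likely_sympd);
  arma::mat M = arma::solve(S, C, arma::solve_opts::likely_sympd);
  arma::vec num = X.t() * y - C.t() * w;
  arma::vec xss = arma::sum(X % X, 0).t() - arma::sum(C % M, 0).t();
  double yss = arma::dot(y, y) - arma::dot(zy, w);
  arma::vec r(X.n_cols);
  const double tol = 1e-12;
  for (arma::uword e = 0; e < X.n_cols; ++e) {
    double den2 = xss(e) * yss;
    r(e) = (xss(e) > tol && den2 > 0.0) ? num(e) / std::sqrt(den2)
                                        : arma::datum::nan;
  }
  return r;
}

// [[Rcpp::export]]
arma::vec cpp_partial_cor(const arma::mat& X, const arma::vec& y,
                          const arma::mat& Zcov) {
  if (X.n_rows != y.n_elem || (Zcov.n_cols > 0 && Zcov.n_rows != y.n_elem))
    stop("row mismatch between X, y and covariates");
  return partial_cor_core(X, y, Zcov);
}

// Full leave-one-out CBPM: per fold, select edges on the n-1 training rows by
// partial correlation with the (possibly permuted) behavior at threshold
// p < alpha, sum selected edges into positive/negative strengths, fit the
// strength model by OLS on the training rows only, and predict the held-out
// subject. model_form: 0 = intercept + pos + neg, 1 = pos only, 2 = neg only.
// A fold with no usable strength term predicts the training mean (fallback).
// Only training rows ever enter selection or fitting, so the held-out row
// cannot leak into its own fold.
// [[Rcpp::export]]
List cpp_cbpm_loocv(const arma::mat& X, const arma::vec& y,
                    const arma::mat& Zcov, double alpha, int model_form,
                    bool keep_masks) {
  const arma::uword n = X.n_rows, E = X.n_cols, c = Zcov.n_cols;
  if (y.n_elem != n) stop("length of y must match rows of X");
  if (c > 0 && Zcov.n_rows != n) stop("covariate rows must match rows of X");
  if (!(alpha > 0.0 && alpha <= 1.0)) stop("alpha must lie in (0, 1]");

  const int dfree = static_cast<int>(n) - 3 - static_cast<int>(c);
  if (dfree < 1) stop("too few subjects for the selection degrees of freedom");
  const double tcrit = R::qt(1.0 - alpha / 2.0, dfree, 1, 0);
  // p < alpha  <=>  |t| > tcrit  <=>  |r| > rcrit (strict)
  const double rcrit = tcrit / std::sqrt(dfree + tcrit * tcrit);

  arma::vec pred(n);
  LogicalVector fallback(n);
  arma::umat pos_masks, neg_masks;
  if (keep_masks) {
    pos_masks.zeros(E, n);
    neg_masks.zeros(E, n);
  }
  NumericMatrix coefs(static_cast<int>(n), 3);
  std::fill(coefs.begin(), coefs.end(), NA_REAL);

  arma::uvec tr(n - 1);
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword k = 0;
    for (arma::uword s = 0; s < n; ++s)
      if (s != i) tr(k++) = s;

    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    arma::mat Ztr = (c > 0) ? arma::mat(Zcov.rows(tr)) : arma::mat(n - 1, 0);

    arma::vec r = partial_cor_core(Xtr, ytr, Ztr);
    arma::vec posv(E, arma::fill::zeros), negv(E, arma::fill::zeros);
    for (arma::uword e = 0; e < E; ++e) {
      const double re = r(e);
      if (!std::isfinite(re)) continue;
      if (re > rcrit) posv(e) = 1.0;
      else if (-re > rcrit) negv(e) = 1.0;
    }
    if (model_form == 1) negv.zeros();
    if (model_form == 2) posv.zeros();

    arma::vec ps = Xtr * posv, ns = Xtr * negv;
    const bool use_pos = arma::any(posv > 0.5) && (ps.max() - ps.min() > 0.0);
    const bool use_neg = arma::any(negv > 0.5) && (ns.max() - ns.min() > 0.0);

    double yhat;
    if (!use_pos && !use_neg) {
      yhat = arma::mean(ytr);
      fallback[static_cast<int>(i)] = true;
      coefs(static_cast<int>(i), 0) = yhat;
    } else {
      const arma::uword p = 1 + (use_pos ? 1 : 0) + (use_neg ? 1 : 0);
      arma::mat D(n - 1, p);
      D.col(0).ones();
      arma::uword col = 1;
      if (use_pos) D.col(col++) = ps;
      if (use_neg) D.col(col++) = ns;
      arma::vec coef = arma::solve(D, ytr);
      const double psi = arma::dot(X.row(i).t(), posv);
      const double nsi = arma::dot(X.row(i).t(), negv);
      yhat = coef(0);
      col = 1;
      coefs(static_cast<int>(i), 0) = coef(0);
      if (use_pos) {
        coefs(static_cast<int>(i), 1) = coef(col);
        yhat += coef(col++) * psi;
      }
      if (use_neg) {
        coefs(static_cast<int>(i), 2) = coef(col);
        yhat += coef(col++) * nsi;
      }
    }
    pred(i) = yhat;
    if (keep_masks) {
      pos_masks.col(i) = arma::conv_to<arma::uvec>::from(posv > 0.5);
      neg_masks.col(i) = arma::conv_to<arma::uvec>::from(negv > 0.5);
    }
  }

  List out = List::create(Named("predicted") = pred,
                          Named("fallback") = fallback,
                          Named("coefficients") = coefs);
  if (keep_masks) {
    out["pos_masks"] = wrap(pos_masks);
    out["neg_masks"] = wrap(neg_masks);
  }
  return out;
}
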