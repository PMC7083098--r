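#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// REML sufficient statistics for a multi-response random-intercept model.
//
// Individuals are grouped into design classes that share the same stacked
// fixed-effect matrix X (m x p) and number of trials; Y holds one column of
// stacked observations per individual in the class (trial-major, trait
// fastest). The marginal covariance of one individual's stacked record is
//   V = I_n (x) R + J_n (x) G
// with G the among-individual and R the within-trial residual covariance,
// so V, its Cholesky factor and the triangular solves are computed once per
// class rather than once per individual.
// [[Rcpp::export]]
List reml_pieces(List Xs, List Ys, const arma::mat& G, const arma::mat& R) {
  const int q = G.n_rows;
  const int p = as<arma::mat>(Xs[0]).n_cols;
  arma::mat XtVX(p, p, arma::fill::zeros);
  arma::vec XtVy(p, arma::fill::zeros);
  double yty = 0.0, logdet = 0.0, nobs = 0.0;
  for (int c = 0; c < Xs.size(); ++c) {
    arma::mat X = Xs[c];
    arma::mat Y = Ys[c];
    const int m = X.n_rows;
    const int n_i = m / q;
    const int nc = Y.n_cols;
    arma::mat V(m, m);
    for (int a = 0; a < n_i; ++a)
      for (int b = 0; b < n_i; ++b)
        V.submat(a * q, b * q, a * q + q - 1, b * q + q - 1) =
          (a == b) ? R + G : G;
    arma::mat L;
    if (!arma::chol(L, V, "lower"))
      stop("marginal covariance is not positive definite");
    arma::mat A = arma::solve(arma::trimatl(L), arma::join_rows(X, Y));
    arma::mat AX = A.cols(0, p - 1);
    arma::mat AY = A.cols(p, p + nc - 1);
    XtVX += nc * (AX.t() * AX);
    XtVy += AX.t() * arma::sum(AY, 1);
    yty += arma::accu(AY % AY);
    logdet += nc * 2.0 * arma::accu(arma::log(L.diag()));
    nobs += static_cast<double>(nc) * m;
  }
  return List::create(_["XtVX"] = XtVX, _["XtVy"] = XtVy, _["yty"] = yty,
                      _["logdet"] = logdet, _["nobs"] = nobs);
}

// Negative restricted log-likelihood and its matrix gradients with respect
// to G and R. Writing V-dot for the derivative of V along a covariance
// direction S,
//   d NLL = 0.5 [ tr(V^-1 Vdot) - tr(C^-1 X'V^-1 Vdot V^-1 X) - y'P Vdot P y ]
// with C = X'V^-1 X and P y = V^-1 (y - X beta). For S acting on G,
// Vdot = J (x) S; for S acting on R, Vdot = I (x) S. Collecting terms gives
// q x q matrices GammaG, GammaR such that d NLL = 0.5 tr(GammaG dG) +
// 0.5 tr(GammaR dR); the Cholesky-parameter chain rule is applied in R.
// [[Rcpp::export]]
List reml_nll_grad(List Xs, List Ys, const arma::mat& G, const arma::mat& R) {
  const int q = G.n_rows;
  const int p = as<arma::mat>(Xs[0]).n_cols;
  const int ncls = Xs.size();
  arma::mat XtVX(p, p, arma::fill::zeros);
  arma::vec XtVy(p, arma::fill::zeros);
  double yty = 0.0, logdet = 0.0, nobs = 0.0;
  std::vector<arma::mat> Winv(ncls);
  bool ok = true;
  for (int c = 0; c < ncls && ok; ++c) {
    arma::mat X = Xs[c];
    arma::mat Y = Ys[c];
    const int m = X.n_rows;
    const int n_i = m / q;
    const int nc = Y.n_cols;
    arma::mat V(m, m);
    for (int a = 0; a < n_i; ++a)
      for (int b = 0; b < n_i; ++b)
        V.submat(a * q, b * q, a * q + q - 1, b * q + q - 1) =
          (a == b) ? R + G : G;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) { ok = false; break; }
    arma::mat A = arma::solve(arma::trimatl(L), arma::join_rows(X, Y));
    arma::mat AX = A.cols(0, p - 1);
    arma::mat AY = A.cols(p, p + nc - 1);
    XtVX += nc * (AX.t() * AX);
    XtVy += AX.t() * arma::sum(AY, 1);
    yty += arma::accu(AY % AY);
    logdet += nc * 2.0 * arma::accu(arma::log(L.diag()));
    nobs += static_cast<double>(nc) * m;
    arma::mat Linv = arma::inv(arma::trimatl(L));
    Winv[c] = Linv.t() * Linv;
  }
  if (!ok)
    return List::create(_["ok"] = false);
  arma::mat Cch;
  if (!arma::chol(Cch, XtVX))
    return List::create(_["ok"] = false);
  arma::vec beta = arma::solve(arma::trimatu(Cch),
                   arma::solve(arma::trimatl(Cch.t()), XtVy));
  double yPy = yty - arma::dot(XtVy, beta);
  double ldC = 2.0 * arma::accu(arma::log(Cch.diag()));
  double nll = 0.5 * (logdet + ldC + yPy +
                      (nobs - p) * std::log(2.0 * M_PI));
  arma::mat Cinv = arma::inv_sympd(XtVX);
  arma::mat GammaG(q, q, arma::fill::zeros);
  arma::mat GammaR(q, q, arma::fill::zeros);
  for (int c = 0; c < ncls; ++c) {
    arma::mat X = Xs[c];
    arma::mat Y = Ys[c];
    const int m = X.n_rows;
    const int n_i = m / q;
    const int nc = Y.n_cols;
    const arma::mat& W = Winv[c];
    arma::mat T = W * X;                       // V^-1 X
    arma::mat Q = W * Y;                       // columns: V^-1 (y_i - X beta)
    Q.each_col() -= T * beta;
    arma::mat Wsum(q, q, arma::fill::zeros), Wdsum(q, q, arma::fill::zeros);
    arma::mat U1(q, p, arma::fill::zeros);     // summed block rows of T
    arma::mat Qt(q, nc, arma::fill::zeros);    // summed block rows of Q
    arma::mat AI(q, q, arma::fill::zeros);     // sum_a Q_a Q_a'
    arma::mat TR(q, q, arma::fill::zeros);     // sum_a T_a Cinv T_a'
    for (int a = 0; a < n_i; ++a)
      for (int b = 0; b < n_i; ++b)
        Wsum += W.submat(a * q, b * q, a * q + q - 1, b * q + q - 1);
    for (int a = 0; a < n_i; ++a) {
      arma::mat Ta = T.rows(a * q, a * q + q - 1);
      arma::mat Qa = Q.rows(a * q, a * q + q - 1);
      Wdsum += W.submat(a * q, a * q, a * q + q - 1, a * q + q - 1);
      U1 += Ta;
      Qt += Qa;
      AI += Qa * Qa.t();
      TR += Ta * Cinv * Ta.t();
    }
    GammaG += nc * (Wsum - U1 * Cinv * U1.t()) - Qt * Qt.t();
    GammaR += nc * (Wdsum - TR) - AI;
  }
  return List::create(_["ok"] = true, _["nll"] = nll, _["beta"] = beta,
                      _["GammaG"] = GammaG, _["GammaR"] = GammaR);
}
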