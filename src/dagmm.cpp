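// Numeric kernels for DAG-MM: coordinate-descent solvers for the two
// penalized moment objectives of the skeleton stage, and the per-node
// weighted-least-squares / Newton-Raphson estimator for the marginal
// negative log-likelihood of the mixed-effects SEM.

#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Lasso path for one node of the first moment objective:
//   minimise  sum_i (y_i - Z_i' b)^2 + lambda * ||b||_1
// over a decreasing lambda sequence with warm starts. Convergence is
// declared when the KKT stationarity violation falls below kkt_tol
// (absolute, on the gradient scale 2 Z'r). Zero-variance columns are
// left at zero.
// [[Rcpp::export]]
arma::mat lasso_path_cpp(const arma::mat& Z, const arma::vec& y,
                         const arma::vec& lambdas, double kkt_tol,
                         int max_sweeps, const arma::vec& b_init) {
  const uword nf = Z.n_cols, nl = lambdas.n_elem;
  vec cn(nf);
  for (uword j = 0; j < nf; ++j) cn(j) = dot(Z.col(j), Z.col(j));
  mat B(nf, nl, fill::zeros);
  vec b = b_init.n_elem == nf ? b_init : vec(nf, fill::zeros);
  vec r = y - Z * b;
  std::vector<uword> active;
  for (uword li = 0; li < nl; ++li) {
    const double lam = lambdas(li);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      // full sweep
      for (uword j = 0; j < nf; ++j) {
        if (cn(j) <= 0.0) continue;
        const double num = dot(Z.col(j), r) + cn(j) * b(j);
        const double bn = soft_threshold(num, lam / 2.0) / cn(j);
        const double d = bn - b(j);
        if (d != 0.0) { r -= Z.col(j) * d; b(j) = bn; }
      }
      // inner active-set sweeps until the active coordinates stabilise
      active.clear();
      for (uword j = 0; j < nf; ++j)
        if (b(j) != 0.0) active.push_back(j);
      for (int inner = 0; inner < max_sweeps; ++inner) {
        double dmax = 0.0;
        for (uword a = 0; a < active.size(); ++a) {
          const uword j = active[a];
          const double num = dot(Z.col(j), r) + cn(j) * b(j);
          const double bn = soft_threshold(num, lam / 2.0) / cn(j);
          const double d = bn - b(j);
          if (d != 0.0) {
            r -= Z.col(j) * d;
            b(j) = bn;
            dmax = std::max(dmax, 2.0 * cn(j) * std::fabs(d));
          }
        }
        if (dmax <= 0.5 * kkt_tol) break;
      }
      // KKT check over all coordinates
      vec g = 2.0 * (Z.t() * r);
      double viol = 0.0;
      for (uword j = 0; j < nf; ++j) {
        if (cn(j) <= 0.0) continue;
        if (b(j) == 0.0)
          viol = std::max(viol, std::fabs(g(j)) - lam);
        else
          viol = std::max(viol, std::fabs(g(j) - lam * (b(j) > 0 ? 1.0 : -1.0)));
      }
      if (viol <= kkt_tol) break;
    }
    B.col(li) = b;
  }
  return B;
}

// Non-negative penalized least squares path for the second moment
// objective of one node:
//   minimise sum_i (b_i - c0 - A_i' c)^2 + lambda * sum_k c_k
//   subject to c >= 0 (random-effect variances), c0 >= floor (error
//   variance). Because c >= 0 the l1 penalty is linear; projected
//   coordinate descent yields exact zeros at the boundary.
// [[Rcpp::export]]
Rcpp::List nn_path_cpp(const arma::mat& A, const arma::vec& b,
                       const arma::vec& lambdas, double floor_,
                       double kkt_tol, int max_sweeps) {
  const uword nf = A.n_cols, nl = lambdas.n_elem;
  const double n = static_cast<double>(A.n_rows);
  vec cn(nf);
  for (uword j = 0; j < nf; ++j) cn(j) = dot(A.col(j), A.col(j));
  mat C(nf, nl, fill::zeros);
  vec c0v(nl);
  vec c(nf, fill::zeros);
  double c0 = std::max(floor_, mean(b));
  vec r = b - c0;  // residual b - c0 - A c
  for (uword li = 0; li < nl; ++li) {
    const double lam = lambdas(li);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      const double c0n = std::max(floor_, c0 + accu(r) / n);
      if (c0n != c0) { r -= (c0n - c0); c0 = c0n; }
      for (uword j = 0; j < nf; ++j) {
        if (cn(j) <= 0.0) continue;
        const double num = dot(A.col(j), r) + cn(j) * c(j) - lam / 2.0;
        const double cnew = std::max(0.0, num / cn(j));
        const double d = cnew - c(j);
        if (d != 0.0) { r -= A.col(j) * d; c(j) = cnew; }
      }
      // KKT stationarity: gradient of the smooth part is -2 A'r (+lam).
      vec g = -2.0 * (A.t() * r);
      const double gi = -2.0 * accu(r);
      double viol = (c0 > floor_) ? std::fabs(gi) : std::max(0.0, -gi);
      for (uword j = 0; j < nf; ++j) {
        if (cn(j) <= 0.0) continue;
        const double kk = g(j) + lam;
        if (c(j) > 0.0)
          viol = std::max(viol, std::fabs(kk));
        else
          viol = std::max(viol, std::max(0.0, -kk));
      }
      if (viol <= kkt_tol) break;
    }
    C.col(li) = c;
    c0v(li) = c0;
  }
  return Rcpp::List::create(Rcpp::Named("coef") = C,
                            Rcpp::Named("intercept") = c0v);
}

// Per-node minimiser of the marginal negative log-likelihood term
//   sum_i [ (y_i - Z_i' b)^2 / w_i + log w_i ],
//   w_i = sum_k sigma2_k m_ik^2 + sigma2_eps,
// alternating weighted least squares for the stacked fixed effects b with
// Newton-Raphson on log-variances (backtracking line search, variances
// floored at var_floor). Mp holds the parent columns, X the covariates;
// the stacked design has column (t*d + l) = X[,l] * Mp[,t].
// [[Rcpp::export]]
Rcpp::List fit_node_cpp(const arma::vec& y, const arma::mat& Mp,
                        const arma::mat& X, arma::vec beta_init,
                        arma::vec logv_init, double var_floor,
                        double rel_tol, int max_iter) {
  const uword n = y.n_elem, k = Mp.n_cols, d = X.n_cols;
  const double lfloor = std::log(var_floor), lceil = std::log(1e8);

  if (k == 0) {
    const double v = std::max(var_floor, mean(square(y)));
    const double nll = n * std::log(v) + accu(square(y)) / v;
    return Rcpp::List::create(
        Rcpp::Named("beta") = arma::mat(d, 0),
        Rcpp::Named("sigma2") = arma::vec(),
        Rcpp::Named("error_var") = v, Rcpp::Named("nll") = nll,
        Rcpp::Named("converged") = true, Rcpp::Named("iterations") = 0);
  }

  mat Z(n, k * d);
  for (uword t = 0; t < k; ++t)
    for (uword l = 0; l < d; ++l) Z.col(t * d + l) = X.col(l) % Mp.col(t);
  mat A(n, k + 1);
  if (k > 0) A.cols(0, k - 1) = square(Mp);
  A.col(k).ones();

  vec b = beta_init;
  vec u = clamp(logv_init, lfloor, lceil);
  vec w = A * exp(u);
  vec r = y - Z * b;
  double obj = accu(square(r) / w + log(w));
  bool converged = false;
  int it;
  for (it = 1; it <= max_iter; ++it) {
    // (a) weighted least squares for the fixed effects
    mat Zw = Z.each_col() / w;
    mat G = Z.t() * Zw;
    const double ridge0 = 1e-10 * (trace(G) / (k * d) + 1.0);
    G.diag() += ridge0;
    vec rhs = Zw.t() * y;
    vec bn;
    if (!solve(bn, G, rhs, solve_opts::no_approx)) {
      G.diag() += 1e4 * ridge0;
      solve(bn, G, rhs);
    }
    b = bn;
    r = y - Z * b;

    // (b) Newton-Raphson on log-variances
    vec rr = square(r);
    for (int nr = 0; nr < 25; ++nr) {
      vec ev = exp(u);
      w = A * ev;
      vec w2 = square(w);
      vec s = 1.0 / w - rr / w2;                   // d obj / d w
      vec t2 = -1.0 / w2 + 2.0 * rr / (w2 % w);    // d s / d w
      mat Ae = A.each_row() % ev.t();
      vec grad = Ae.t() * s;
      const double gn = norm(grad, "inf");
      const double cur = accu(rr / w + log(w));
      if (gn < 1e-10 * (std::fabs(cur) + 1.0)) break;
      mat H = Ae.t() * (Ae.each_col() % t2);
      H.diag() += grad;
      vec step;
      double ridge = 0.0;
      bool oks = solve(step, H, -grad, solve_opts::no_approx);
      int tries = 0;
      while ((!oks || dot(step, grad) >= 0.0) && tries < 6) {
        ridge = (ridge == 0.0)
                    ? 1e-6 * (std::fabs(trace(H)) / (k + 1) + 1.0)
                    : ridge * 100.0;
        mat Hr = H;
        Hr.diag() += ridge;
        oks = solve(step, Hr, -grad, solve_opts::no_approx);
        ++tries;
      }
      if (!oks || dot(step, grad) >= 0.0) step = -grad / (gn + 1.0);
      double alpha = 1.0;
      bool improved = false;
      for (int h = 0; h < 30; ++h) {
        vec un = clamp(u + alpha * step, lfloor, lceil);
        vec wn = A * exp(un);
        const double on = accu(rr / wn + log(wn));
        if (on < cur - 1e-14 * std::fabs(cur)) {
          u = un;
          improved = true;
          break;
        }
        alpha *= 0.5;
      }
      if (!improved) break;
    }
    w = A * exp(u);
    const double obj_new = accu(square(r) / w + log(w));
    if (std::fabs(obj - obj_new) <= rel_tol * (std::fabs(obj) + 1e-8)) {
      obj = obj_new;
      converged = true;
      break;
    }
    obj = obj_new;
  }
  vec ev = exp(u);
  mat beta(d, k);
  for (uword t = 0; t < k; ++t) beta.col(t) = b.subvec(t * d, t * d + d - 1);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("sigma2") = arma::vec(ev.subvec(0, k - 1)),
      Rcpp::Named("error_var") = ev(k), Rcpp::Named("nll") = obj,
      Rcpp::Named("converged") = converged, Rcpp::Named("iterations") = it);
}
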