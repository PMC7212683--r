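// EM core for Gaussian mixtures with eigendecomposed covariance
// constraints (volume / shape / orientation equal or variable per
// component). Mirrors the reference R implementation in R/mixture.R; the
// two engines are cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int EII = 0, VII = 1, EEI = 2, VEI = 3, EVI = 4, VVI = 5,
                 EEE = 6, EVE = 7, VEE = 8, VVE = 9, EEV = 10, VEV = 11,
                 EVV = 12, VVV = 13;

// log N(x; mu, Sigma) for all rows of X
static vec ldmvnorm_cpp(const mat& X, const vec& mu, const mat& Sigma) {
  const uword d = X.n_cols;
  mat R;
  if (!chol(R, Sigma)) throw std::runtime_error("covariance not positive definite");
  mat Xc = X.each_row() - mu.t();
  mat Y = solve(trimatl(R.t()), Xc.t());
  double ldet = accu(log(R.diag()));
  return -0.5 * d * std::log(2.0 * M_PI) - ldet -
         0.5 * sum(square(Y), 0).t();
}

struct EStep { mat z; double loglik; };

static EStep estep_cpp(const mat& X, const vec& pi_k, const mat& mu,
                       const cube& Sigma) {
  const uword n = X.n_rows, G = pi_k.n_elem;
  mat lp(n, G);
  for (uword k = 0; k < G; ++k)
    lp.col(k) = ldmvnorm_cpp(X, mu.col(k), Sigma.slice(k)) +
                std::log(pi_k(k));
  vec m = max(lp, 1);
  vec lse = m + log(sum(exp(lp.each_col() - m), 1));
  EStep out;
  out.z = exp(lp.each_col() - lse);
  out.loglik = accu(lse);
  return out;
}

// minimise sum_k tr(D M_k D' W_k) over orthogonal D by cyclic Givens
// sweeps; closed-form optimal angle per coordinate plane
static mat givens_orientation_cpp(mat D, const cube& W, const mat& M,
                                  int max_sweeps = 50, double tol = 1e-10) {
  const uword d = D.n_rows, G = W.n_slices;
  for (int s = 0; s < max_sweeps; ++s) {
    double max_theta = 0.0;
    for (uword i = 0; i + 1 < d; ++i) for (uword j = i + 1; j < d; ++j) {
      double P = 0.0, Q = 0.0;
      for (uword k = 0; k < G; ++k) {
        mat S = D.t() * W.slice(k) * D;
        double w = M(i, k) - M(j, k);
        P += w * (S(i, i) - S(j, j)) / 2.0;
        Q += w * S(i, j);
      }
      double theta = 0.5 * std::atan2(-Q, -P);
      if (std::fabs(theta) > tol) {
        double cs = std::cos(theta), sn = std::sin(theta);
        vec di = D.col(i), dj = D.col(j);
        D.col(i) = cs * di + sn * dj;
        D.col(j) = -sn * di + cs * dj;
      }
      max_theta = std::max(max_theta, std::fabs(theta));
    }
    if (max_theta < tol) break;
  }
  return D;
}

static double geo_det(const vec& v) {
  return std::exp(accu(log(v)) / v.n_elem);
}

// EVE / VVE: alternate shape(+volume) with common-orientation update
static cube common_orientation_cpp(const cube& W, const vec& nk, double n,
                                   bool equal_volume, double inner_tol) {
  const uword d = W.n_rows, G = W.n_slices;
  mat Wsum(d, d, fill::zeros);
  for (uword k = 0; k < G; ++k) Wsum += W.slice(k);
  vec eval; mat D;
  eig_sym(eval, D, symmatu(Wsum));
  mat A(d, G, fill::ones);
  vec lam(G, fill::ones);
  double obj_prev = datum::inf;
  for (int it = 0; it < 100; ++it) {
    vec dets(G);
    mat diags(d, G);
    for (uword k = 0; k < G; ++k)
      diags.col(k) = diagvec(D.t() * W.slice(k) * D);
    if (equal_volume) {
      for (uword k = 0; k < G; ++k) dets(k) = geo_det(diags.col(k));
      double lam_c = accu(dets) / n;
      lam.fill(lam_c);
      for (uword k = 0; k < G; ++k) A.col(k) = diags.col(k) / dets(k);
    } else {
      for (uword k = 0; k < G; ++k) {
        vec full = diags.col(k) / nk(k);
        lam(k) = geo_det(full);
        A.col(k) = full / lam(k);
      }
    }
    mat M = 1.0 / A;
    M.each_row() /= lam.t();
    D = givens_orientation_cpp(D, W, M);
    // objective: sum_k tr(Sigma_k^{-1} W_k) + nk (d log lam + sum log A)
    double obj = 0.0;
    for (uword k = 0; k < G; ++k) {
      mat Sig_inv = D * diagmat(1.0 / (lam(k) * A.col(k))) * D.t();
      obj += accu(Sig_inv % W.slice(k)) +
             nk(k) * (d * std::log(lam(k)) + accu(log(A.col(k))));
    }
    if (std::isfinite(obj_prev) &&
        std::fabs(obj_prev - obj) < inner_tol * (1.0 + std::fabs(obj)))
      break;
    obj_prev = obj;
  }
  cube Sigma(d, d, G);
  for (uword k = 0; k < G; ++k)
    Sigma.slice(k) = D * diagmat(lam(k) * A.col(k)) * D.t();
  return Sigma;
}

static cube sigma_mstep_cpp(int family, const cube& W, const vec& nk,
                            double n, double inner_tol) {
  const uword d = W.n_rows, G = W.n_slices;
  cube Sigma(d, d, G);
  mat Wsum(d, d, fill::zeros);
  for (uword k = 0; k < G; ++k) Wsum += W.slice(k);
  switch (family) {
  case EII: {
    double lam = 0.0;
    for (uword k = 0; k < G; ++k) lam += trace(W.slice(k));
    lam /= n * d;
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = lam * eye(d, d);
    break; }
  case VII: {
    for (uword k = 0; k < G; ++k)
      Sigma.slice(k) = (trace(W.slice(k)) / (nk(k) * d)) * eye(d, d);
    break; }
  case EEI: {
    vec dg = diagvec(Wsum) / n;
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = diagmat(dg);
    break; }
  case VEI: {
    vec a = diagvec(Wsum);
    a /= geo_det(a);
    vec lam(G);
    for (int it = 0; it < 100; ++it) {
      for (uword k = 0; k < G; ++k)
        lam(k) = accu(diagvec(W.slice(k)) / a) / (nk(k) * d);
      vec b(d, fill::zeros);
      for (uword k = 0; k < G; ++k) b += diagvec(W.slice(k)) / lam(k);
      vec a_new = b / geo_det(b);
      bool done = max(abs(a_new - a)) < inner_tol * max(abs(a));
      a = a_new;
      if (done) break;
    }
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = diagmat(lam(k) * a);
    break; }
  case EVI: {
    vec dets(G);
    for (uword k = 0; k < G; ++k) dets(k) = geo_det(diagvec(W.slice(k)));
    double lam = accu(dets) / n;
    for (uword k = 0; k < G; ++k)
      Sigma.slice(k) = diagmat(lam * diagvec(W.slice(k)) / dets(k));
    break; }
  case VVI: {
    for (uword k = 0; k < G; ++k)
      Sigma.slice(k) = diagmat(diagvec(W.slice(k)) / nk(k));
    break; }
  case EEE: {
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = Wsum / n;
    break; }
  case VVV: {
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = W.slice(k) / nk(k);
    break; }
  case EEV: case VEV: {
    cube L(d, d, G);
    mat om(d, G);
    for (uword k = 0; k < G; ++k) {
      vec ev; mat V;
      eig_sym(ev, V, symmatu(W.slice(k)));
      om.col(k) = ev;
      L.slice(k) = V;
    }
    if (family == EEV) {
      vec osum = sum(om, 1);
      vec shape = osum / geo_det(osum);
      double lam = geo_det(osum) / n;
      for (uword k = 0; k < G; ++k)
        Sigma.slice(k) = L.slice(k) * diagmat(lam * shape) * L.slice(k).t();
    } else {
      vec a = sum(om, 1);
      a /= geo_det(a);
      vec lam(G);
      for (int it = 0; it < 100; ++it) {
        for (uword k = 0; k < G; ++k)
          lam(k) = accu(om.col(k) / a) / (nk(k) * d);
        vec b(d, fill::zeros);
        for (uword k = 0; k < G; ++k) b += om.col(k) / lam(k);
        vec a_new = b / geo_det(b);
        bool done = max(abs(a_new - a)) < inner_tol * max(abs(a));
        a = a_new;
        if (done) break;
      }
      for (uword k = 0; k < G; ++k)
        Sigma.slice(k) = L.slice(k) * diagmat(lam(k) * a) * L.slice(k).t();
    }
    break; }
  case EVV: {
    vec dets(G);
    for (uword k = 0; k < G; ++k) {
      double dt = det(W.slice(k));
      dets(k) = std::pow(std::max(dt, 1e-300), 1.0 / d);
    }
    double lam = accu(dets) / n;
    for (uword k = 0; k < G; ++k)
      Sigma.slice(k) = lam * W.slice(k) / dets(k);
    break; }
  case VEE: {
    mat C = Wsum / n;
    C /= std::pow(det(C), 1.0 / d);
    vec lam(G, fill::ones);
    for (int it = 0; it < 100; ++it) {
      for (uword k = 0; k < G; ++k)
        lam(k) = trace(solve(C, W.slice(k))) / (nk(k) * d);
      mat Wt(d, d, fill::zeros);
      for (uword k = 0; k < G; ++k) Wt += W.slice(k) / lam(k);
      mat C_new = Wt / std::pow(det(Wt), 1.0 / d);
      bool done = abs(C_new - C).max() < inner_tol * abs(C).max();
      C = C_new;
      if (done) break;
    }
    for (uword k = 0; k < G; ++k) Sigma.slice(k) = lam(k) * C;
    break; }
  case EVE:
    Sigma = common_orientation_cpp(W, nk, n, true, inner_tol);
    break;
  case VVE:
    Sigma = common_orientation_cpp(W, nk, n, false, inner_tol);
    break;
  default:
    throw std::runtime_error("unknown family code");
  }
  return Sigma;
}

// [[Rcpp::export(name = ".em_core_cpp")]]
Rcpp::List em_core_cpp(const arma::mat& X, arma::mat Z, int family,
                       double tol, int max_iter, double floor_val,
                       double inner_tol) {
  const uword n = X.n_rows, d = X.n_cols, G = Z.n_cols;
  std::vector<double> ll_trace;
  double ll_prev = -datum::inf;
  bool converged = false, regularized = false;
  vec pi_k(G);
  mat mu(d, G);
  cube Sigma(d, d, G);
  for (int it = 0; it < max_iter; ++it) {
    // M-step
    vec nk = sum(Z, 0).t();
    if (nk.min() < 1e-8) throw std::runtime_error("component collapsed");
    pi_k = nk / double(n);
    cube W(d, d, G);
    for (uword k = 0; k < G; ++k) {
      mu.col(k) = (X.t() * Z.col(k)) / nk(k);
      mat Xc = X.each_row() - mu.col(k).t();
      Xc.each_col() %= sqrt(Z.col(k));
      W.slice(k) = Xc.t() * Xc;
    }
    Sigma = sigma_mstep_cpp(family, W, nk, double(n), inner_tol);
    for (uword k = 0; k < G; ++k) {
      if (!Sigma.slice(k).is_finite())
        throw std::runtime_error("covariance update diverged");
      vec ev; mat V;
      eig_sym(ev, V, symmatu(Sigma.slice(k)));
      if (ev.min() < floor_val) {
        regularized = true;
        ev = clamp(ev, floor_val, datum::inf);
        Sigma.slice(k) = V * diagmat(ev) * V.t();
      }
    }
    // E-step
    EStep es = estep_cpp(X, pi_k, mu, Sigma);
    Z = es.z;
    ll_trace.push_back(es.loglik);
    if (std::isfinite(ll_prev) &&
        std::fabs(es.loglik - ll_prev) < tol * (1.0 + std::fabs(es.loglik))) {
      converged = true;
      break;
    }
    ll_prev = es.loglik;
  }
  Rcpp::List sig_list(G);
  for (uword k = 0; k < G; ++k) sig_list[k] = Sigma.slice(k);
  return Rcpp::List::create(
    Rcpp::Named("pi") = pi_k,
    Rcpp::Named("mu") = mu,
    Rcpp::Named("Sigma") = sig_list,
    Rcpp::Named("z") = Z,
    Rcpp::Named("loglik") = ll_trace.back(),
    Rcpp::Named("loglik_trace") = ll_trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = int(ll_trace.size()),
    Rcpp::Named("regularized") = regularized);
}
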