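// L1-regularized maximum-entropy solver for presence-background niche
// models. Minimizes
//   F(lambda) = -pbar'lambda + log sum_bg exp(B lambda) + sum_j w_j |lambda_j|
// (pbar = presence feature means, B = background feature matrix, w = per-
// feature penalty weights). Two phases:
//   1. monotone FISTA (proximal gradient + Nesterov momentum with adaptive
//      restart and backtracking) to a coarse tolerance;
//   2. active-set coordinate descent: 1-D prox-Newton updates with an
//      objective-decrease safeguard over the working set (nonzero features
//      plus the worst KKT violators), repeated until the full KKT residual
//      of the L1 subdifferential meets the requested tolerance.
// The accepted objective sequence is non-increasing throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double log_sum_exp(const vec& s) {
  double m = s.max();
  return m + std::log(accu(exp(s - m)));
}

static double penalty(const vec& lambda, const vec& w) {
  return dot(w, abs(lambda));
}

static vec soft_threshold(const vec& x, const vec& t) {
  return sign(x) % max(abs(x) - t, zeros<vec>(x.n_elem));
}

static double soft1(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static double kkt_residual(const vec& grad, const vec& lambda, const vec& w) {
  double r = 0.0;
  for (uword j = 0; j < lambda.n_elem; ++j) {
    double rj;
    if (lambda[j] > 0)       rj = std::fabs(grad[j] + w[j]);
    else if (lambda[j] < 0)  rj = std::fabs(grad[j] - w[j]);
    else                     rj = std::max(0.0, std::fabs(grad[j]) - w[j]);
    if (rj > r) r = rj;
  }
  return r;
}

// [[Rcpp::export]]
Rcpp::List maxent_solve_cpp(const arma::mat& B, const arma::vec& pbar,
                            const arma::vec& w, double tol, int max_iter,
                            int check_every) {
  const uword m = B.n_cols;
  vec lambda(m, fill::zeros);
  vec s = B * lambda;
  double lse = log_sum_exp(s);
  double f_best = lse - dot(pbar, lambda) + penalty(lambda, w);
  std::vector<double> obj_path;
  obj_path.push_back(f_best);
  bool converged = false;
  long total_iter = 0;

  // ---- phase 1: monotone FISTA to a coarse tolerance -------------------
  {
    vec y = lambda, lambda_prev = lambda, grad_y(m);
    double t = 1.0, L = 1.0;
    const double coarse_tol = std::max(tol, 1e-3);
    int fista_cap = 2000;
    for (int iter = 1; iter <= fista_cap; ++iter) {
      ++total_iter;
      vec sy = B * y;
      double lse_y = log_sum_exp(sy);
      vec q = exp(sy - lse_y);
      grad_y = B.t() * q - pbar;
      double f_y = lse_y - dot(pbar, y);
      vec cand, sc;
      double f_cand;
      for (int bt = 0; bt < 60; ++bt) {
        cand = soft_threshold(y - grad_y / L, w / L);
        sc = B * cand;
        f_cand = log_sum_exp(sc) - dot(pbar, cand);
        vec d = cand - y;
        double quad = f_y + dot(grad_y, d) + 0.5 * L * dot(d, d);
        if (f_cand <= quad + 1e-12 * std::fabs(quad)) break;
        L *= 2.0;
      }
      double F_cand = f_cand + penalty(cand, w);
      lambda_prev = lambda;
      if (F_cand <= f_best) { lambda = cand; s = sc; f_best = F_cand; }
      obj_path.push_back(f_best);
      if (dot(y - cand, cand - lambda_prev) > 0) {
        t = 1.0; y = lambda;
      } else {
        double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
        y = cand + ((t - 1.0) / t_new) * (cand - lambda_prev);
        t = t_new;
      }
      L = std::max(L * 0.95, 1e-3);
      if (iter % check_every == 0) {
        vec sl = B * lambda;
        double lsel = log_sum_exp(sl);
        vec ql = exp(sl - lsel);
        vec grad = B.t() * ql - pbar;
        if (kkt_residual(grad, lambda, w) <= coarse_tol) break;
      }
    }
  }

  // ---- phase 2: active-set coordinate descent + damped orthant Newton --
  s = B * lambda;
  lse = log_sum_exp(s);
  double kkt = datum::inf;
  for (int outer = 0; outer < 500 && total_iter < max_iter; ++outer) {
    vec q = exp(s - lse);
    vec grad = B.t() * q - pbar;
    kkt = kkt_residual(grad, lambda, w);
    if (kkt <= tol) { converged = true; break; }

    uvec nz = find(abs(lambda) > 0);
    vec viol = abs(grad) - w;
    viol(nz).zeros();
    uvec order = sort_index(viol, "descend");
    std::vector<uword> act(nz.begin(), nz.end());
    for (uword i = 0; i < std::min<uword>(50, order.n_elem); ++i) {
      if (viol(order[i]) > 0) act.push_back(order[i]);
    }
    if (act.empty()) break;
    uvec active = conv_to<uvec>::from(act);

    // sweeps of safeguarded 1-D prox-Newton updates over the working set
    for (int sweep = 0; sweep < 20 && total_iter < max_iter; ++sweep) {
      ++total_iter;
      double max_delta = 0.0;
      for (uword k = 0; k < active.n_elem; ++k) {
        uword j = active[k];
        vec bj = B.col(j);
        q = exp(s - lse);
        double ej = dot(bj, q);
        double gj = ej - pbar[j];
        double hj = dot(square(bj), q) - ej * ej;
        if (hj < 1e-10) hj = 1e-10;
        double old = lambda[j];
        double prop = soft1(old - gj / hj, w[j] / hj);
        double delta = prop - old;
        if (delta == 0.0) continue;
        double F0 = lse - dot(pbar, lambda) + penalty(lambda, w);
        // halving safeguard: local curvature can undershoot globally
        for (int ls = 0; ls < 30; ++ls) {
          vec s_new = s + delta * bj;
          double lse_new = log_sum_exp(s_new);
          double lam_j_new = old + delta;
          double lin_new = dot(pbar, lambda) - pbar[j] * old + pbar[j] * lam_j_new;
          double pen_new = penalty(lambda, w) - w[j] * std::fabs(old) +
            w[j] * std::fabs(lam_j_new);
          double F_new = lse_new - lin_new + pen_new;
          if (F_new <= F0 + 1e-14 * std::fabs(F0)) {
            lambda[j] = lam_j_new;
            s = s_new;
            lse = lse_new;
            f_best = F_new;
            max_delta = std::max(max_delta, std::fabs(delta));
            break;
          }
          delta *= 0.5;
          if (std::fabs(delta) < 1e-15) break;
        }
      }
      obj_path.push_back(f_best);
      if (max_delta < 1e-12) break;
    }

    // damped orthant Newton polish on the nonzero set: coordinate descent
    // zigzags on strongly correlated hinge features, a second-order step
    // does not
    for (int nit = 0; nit < 40 && total_iter < max_iter; ++nit) {
      ++total_iter;
      uvec nzn = find(abs(lambda) > 0);
      if (nzn.is_empty()) break;
      mat Ba = B.cols(nzn);
      vec q2 = exp(s - lse);
      vec ga = Ba.t() * q2 - pbar(nzn);
      vec wa = w(nzn);
      vec la = lambda(nzn);
      vec sigma = sign(la);
      vec g_or = ga + wa % sigma;
      if (norm(g_or, "inf") <= 0.2 * tol) break;
      vec u = Ba.t() * q2;
      mat Bq = Ba.each_col() % sqrt(q2);
      mat H = Bq.t() * Bq - u * u.t();
      double hscale = H.diag().max();
      bool accepted = false;
      double damp = 1e-9;
      double F0 = lse - dot(pbar, lambda) + penalty(lambda, w);
      for (int lm = 0; lm < 25; ++lm) {
        mat Hd = H;
        Hd.diag() += damp * hscale + 1e-12;
        vec d;
        if (!solve(d, Hd, -g_or, solve_opts::likely_sympd + solve_opts::no_approx)) {
          damp = std::max(damp * 10, 1e-6);
          continue;
        }
        vec la_new = la + d;
        for (uword k = 0; k < la_new.n_elem; ++k) {
          if (sigma[k] * la_new[k] < 0) la_new[k] = 0;   // leave the orthant -> drop
        }
        vec lam_new = lambda;
        lam_new(nzn) = la_new;
        vec s_new = s + Ba * (la_new - la);
        double lse_new = log_sum_exp(s_new);
        double F_new = lse_new - dot(pbar, lam_new) + penalty(lam_new, w);
        if (F_new < F0) {
          lambda = lam_new; s = s_new; lse = lse_new; f_best = F_new;
          obj_path.push_back(f_best);
          accepted = true;
          break;
        }
        damp = std::max(damp * 10, 1e-6);
      }
      if (!accepted) break;
    }
  }

  {
    vec sl = B * lambda;
    double lsel = log_sum_exp(sl);
    vec ql = exp(sl - lsel);
    vec grad = B.t() * ql - pbar;
    kkt = kkt_residual(grad, lambda, w);
    if (kkt <= tol) converged = true;
  }

  return Rcpp::List::create(
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("objective") = f_best,
    Rcpp::Named("objective_path") = obj_path,
    Rcpp::Named("kkt_residual") = kkt,
    Rcpp::Named("iterations") = (int) total_iter,
    Rcpp::Named("converged") = converged
  );
}
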