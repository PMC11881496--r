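// Gibbs samplers for whole-genome regression models.
// All randomness goes through R's RNG so chains are bit-reproducible
// under set.seed() at the R level.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double rinvchisq(double df, double scale_sum) {
  // draw from scaled inverse chi-square given df and nu*S (sum form)
  return scale_sum / R::rchisq(df);
}

static inline void check_finite(double se2, int iter) {
  if (!std::isfinite(se2) || se2 <= 0.0) {
    stop("residual variance diverged at iteration %d", iter + 1);
  }
}

// Spike-and-slab regression with a single slab variance (BayesCpi).
// pi_fixed / sb2_fixed / se2_fixed < 0 mean "estimate from the data".
// [[Rcpp::export]]
List cpp_bayescpi(const arma::vec& y, const arma::mat& X,
                  int n_iter, int burn_in, int thin,
                  double nu0, double s0_beta, double s0_e,
                  double pi_fixed, double sb2_fixed, double se2_fixed,
                  bool sample_mu) {
  const int n = X.n_rows, M = X.n_cols;
  arma::vec xx(M);
  for (int j = 0; j < M; ++j) xx[j] = arma::dot(X.col(j), X.col(j));
  double vy = arma::var(y);
  double mu = sample_mu ? arma::mean(y) : 0.0;
  double pi = (pi_fixed >= 0.0) ? pi_fixed : 0.5;   // P(null effect)
  double sb2 = (sb2_fixed > 0.0) ? sb2_fixed : s0_beta;
  double se2 = (se2_fixed > 0.0) ? se2_fixed : 0.5 * vy;
  if (se2 <= 0.0) se2 = 1.0;
  arma::vec beta(M, arma::fill::zeros);
  arma::ivec delta(M, arma::fill::zeros);
  arma::vec resid = y - mu;

  arma::vec beta_acc(M, arma::fill::zeros), pip_acc(M, arma::fill::zeros);
  int n_kept = 0;
  std::vector<double> tr_mu, tr_pi, tr_sb2, tr_se2, tr_h2, tr_m;

  for (int it = 0; it < n_iter; ++it) {
    if (sample_mu) {
      double mold = mu;
      mu = R::rnorm(mold + arma::mean(resid), std::sqrt(se2 / n));
      resid += (mold - mu);
    }
    int m_in = 0;
    double ssq_beta = 0.0;
    for (int j = 0; j < M; ++j) {
      double bold = beta[j];
      double rhs = arma::dot(X.col(j), resid) + xx[j] * bold;
      double C = xx[j] + se2 / sb2;
      double logL1 = -0.5 * std::log(sb2 * C / se2) +
                     rhs * rhs / (2.0 * se2 * C);
      double p1;
      if (pi <= 0.0) p1 = 1.0;
      else if (pi >= 1.0) p1 = 0.0;
      else p1 = 1.0 / (1.0 + (pi / (1.0 - pi)) * std::exp(-logL1));
      double bnew = 0.0;
      int dnew = 0;
      if (R::unif_rand() < p1) {
        bnew = R::rnorm(rhs / C, std::sqrt(se2 / C));
        dnew = 1;
        ++m_in;
        ssq_beta += bnew * bnew;
      }
      if (bnew != bold) resid += X.col(j) * (bold - bnew);
      beta[j] = bnew;
      delta[j] = dnew;
    }
    if (pi_fixed < 0.0) pi = R::rbeta(1.0 + (M - m_in), 1.0 + m_in);
    if (sb2_fixed <= 0.0) {
      sb2 = rinvchisq(nu0 + m_in, ssq_beta + nu0 * s0_beta);
    }
    if (se2_fixed <= 0.0) {
      se2 = rinvchisq(nu0 + n, arma::dot(resid, resid) + nu0 * s0_e);
    }
    check_finite(se2, it);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      beta_acc += beta;
      for (int j = 0; j < M; ++j) pip_acc[j] += delta[j];
      arma::vec g = y - resid - mu;
      double vg = arma::var(g);
      tr_mu.push_back(mu); tr_pi.push_back(pi);
      tr_sb2.push_back(sb2); tr_se2.push_back(se2);
      tr_h2.push_back(vg / (vg + se2)); tr_m.push_back((double)m_in);
    }
  }
  return List::create(
    _["beta_mean"] = beta_acc / n_kept,
    _["pip"] = pip_acc / n_kept,
    _["trace_mu"] = tr_mu, _["trace_pi"] = tr_pi,
    _["trace_sigma2_beta"] = tr_sb2, _["trace_sigma2_e"] = tr_se2,
    _["trace_h2"] = tr_h2, _["trace_n_included"] = tr_m);
}

// Grouped spike + L-Gaussian mixture regression (BayesRR-RC; a single
// group gives BayesR). Component variances are rel_var[l] * sigma2_s.
// [[Rcpp::export]]
List cpp_bayesrrrc(const arma::vec& y, const arma::mat& X,
                   const arma::ivec& group, int S,
                   const arma::vec& rel_var,
                   int n_iter, int burn_in, int thin,
                   double nu0, const arma::vec& s0_s, double s0_e) {
  const int n = X.n_rows, M = X.n_cols, L = rel_var.n_elem;
  arma::vec xx(M);
  for (int j = 0; j < M; ++j) xx[j] = arma::dot(X.col(j), X.col(j));
  double vy = arma::var(y);
  double mu = arma::mean(y);
  double se2 = 0.5 * vy;
  if (se2 <= 0.0) se2 = 1.0;
  arma::vec sig_s(S);
  for (int s = 0; s < S; ++s) sig_s[s] = s0_s[s];
  arma::mat pi_s(S, L + 1);
  pi_s.col(0).fill(0.95);
  for (int l = 1; l <= L; ++l) pi_s.col(l).fill(0.05 / L);
  arma::vec beta(M, arma::fill::zeros);
  arma::ivec comp(M, arma::fill::zeros);
  arma::vec resid = y - mu;
  arma::mat gmat(n, S, arma::fill::zeros);     // per-group genetic values

  arma::vec beta_acc(M, arma::fill::zeros), pip_acc(M, arma::fill::zeros);
  arma::mat pi_acc(S, L + 1, arma::fill::zeros);
  arma::vec vexp_acc(S, arma::fill::zeros), sig_acc(S, arma::fill::zeros);
  int n_kept = 0;
  std::vector<double> tr_se2, tr_h2, tr_nmed, tr_nlarge, tr_mu;
  arma::vec logw(L + 1);

  for (int it = 0; it < n_iter; ++it) {
    double mold = mu;
    mu = R::rnorm(mold + arma::mean(resid), std::sqrt(se2 / n));
    resid += (mold - mu);

    arma::imat counts(S, L + 1, arma::fill::zeros);
    arma::vec ssq_s(S, arma::fill::zeros);
    arma::ivec m_s(S, arma::fill::zeros);
    for (int j = 0; j < M; ++j) {
      int s = group[j];
      double bold = beta[j];
      double rhs = arma::dot(X.col(j), resid) + xx[j] * bold;
      logw[0] = std::log(std::max(pi_s(s, 0), 1e-300));
      for (int l = 1; l <= L; ++l) {
        double vl = rel_var[l - 1] * sig_s[s];
        double C = xx[j] + se2 / vl;
        logw[l] = std::log(std::max(pi_s(s, l), 1e-300)) -
                  0.5 * std::log(vl * C / se2) + rhs * rhs / (2.0 * se2 * C);
      }
      double wmax = logw.max();
      double tot = 0.0;
      for (int l = 0; l <= L; ++l) { logw[l] = std::exp(logw[l] - wmax); tot += logw[l]; }
      double u = R::unif_rand() * tot;
      int pick = 0;
      double cum = 0.0;
      for (int l = 0; l <= L; ++l) { cum += logw[l]; if (u <= cum) { pick = l; break; } }
      double bnew = 0.0;
      if (pick > 0) {
        double vl = rel_var[pick - 1] * sig_s[s];
        double C = xx[j] + se2 / vl;
        bnew = R::rnorm(rhs / C, std::sqrt(se2 / C));
        ssq_s[s] += bnew * bnew / rel_var[pick - 1];
        ++m_s[s];
      }
      ++counts(s, pick);
      if (bnew != bold) {
        arma::vec dx = X.col(j) * (bold - bnew);
        resid += dx;
        gmat.col(s) -= dx;
      }
      beta[j] = bnew;
      comp[j] = pick;
    }
    // Dirichlet(1 + counts) per group
    for (int s = 0; s < S; ++s) {
      double tot = 0.0;
      for (int l = 0; l <= L; ++l) {
        double g = R::rgamma(1.0 + counts(s, l), 1.0);
        pi_s(s, l) = g;
        tot += g;
      }
      pi_s.row(s) /= tot;
      sig_s[s] = rinvchisq(nu0 + m_s[s], ssq_s[s] + nu0 * s0_s[s]);
      if (sig_s[s] < 1e-12 * vy) sig_s[s] = 1e-12 * vy;
    }
    se2 = rinvchisq(nu0 + n, arma::dot(resid, resid) + nu0 * s0_e);
    check_finite(se2, it);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      beta_acc += beta;
      int nmed = 0, nlarge = 0;
      for (int j = 0; j < M; ++j) {
        if (comp[j] > 0) pip_acc[j] += 1.0;
        if (L >= 2 && comp[j] == L - 1) ++nmed;
        if (comp[j] == L) ++nlarge;
      }
      pi_acc += pi_s;
      sig_acc += sig_s;
      arma::vec gtot(n, arma::fill::zeros);
      for (int s = 0; s < S; ++s) {
        vexp_acc[s] += arma::var(gmat.col(s));
        gtot += gmat.col(s);
      }
      double vg = arma::var(gtot);
      tr_se2.push_back(se2);
      tr_h2.push_back(vg / (vg + se2));
      tr_nmed.push_back((double)nmed);
      tr_nlarge.push_back((double)nlarge);
      tr_mu.push_back(mu);
    }
  }
  return List::create(
    _["beta_mean"] = beta_acc / n_kept,
    _["pip"] = pip_acc / n_kept,
    _["pi_est"] = pi_acc / n_kept,
    _["var_explained"] = vexp_acc / n_kept,
    _["sigma2_s"] = sig_acc / n_kept,
    _["trace_sigma2_e"] = tr_se2, _["trace_h2"] = tr_h2,
    _["trace_n_medium"] = tr_nmed, _["trace_n_large"] = tr_nlarge,
    _["trace_mu"] = tr_mu);
}

// BSLMM: polygenic term (via the GRM eigendecomposition, supplied rotated)
// plus a sparse set of additional effects. Inputs are already rotated by
// the GRM eigenvectors U: yt = U'y, Xt = U'X, onest = U'1.
// pi is updated by random-walk Metropolis on log(pi) with a log-uniform
// prior on [pi_min, 1]; variances by conjugate Gibbs.
// [[Rcpp::export]]
List cpp_bslmm(const arma::vec& yt, const arma::mat& Xt,
               const arma::vec& d, const arma::vec& onest,
               int n_iter, int burn_in, int thin,
               double nu0, double s0_a, double s0_p, double s0_e,
               double pi_init, double pi_min, double rw_sd,
               bool sparse_on) {
  const int n = Xt.n_rows, M = Xt.n_cols;
  arma::vec xx(M);
  for (int j = 0; j < M; ++j) xx[j] = arma::dot(Xt.col(j), Xt.col(j));
  const double dtol = 1e-10;
  int n_pos = 0;
  for (int i = 0; i < n; ++i) if (d[i] > dtol) ++n_pos;
  double vy = arma::var(yt);  // rotation is orthogonal: var differs only via mean
  double mu = arma::dot(onest, yt) / n;
  double se2 = 0.5 * arma::var(yt - onest * mu);
  if (se2 <= 0.0) se2 = 1.0;
  double sa2 = s0_a, sp2 = s0_p, pi = pi_init;
  arma::vec beta(M, arma::fill::zeros), u(n, arma::fill::zeros);
  arma::ivec delta(M, arma::fill::zeros);
  arma::vec resid = yt - onest * mu;

  arma::vec beta_acc(M, arma::fill::zeros), pip_acc(M, arma::fill::zeros);
  arma::vec u_acc(n, arma::fill::zeros);
  double mu_acc = 0.0;
  int n_kept = 0;
  std::vector<double> tr_pi, tr_sa2, tr_sp2, tr_se2, tr_h2, tr_m;

  for (int it = 0; it < n_iter; ++it) {
    // intercept (design vector onest, |onest|^2 = n)
    {
      double rhs = arma::dot(onest, resid) + n * mu;
      double mnew = R::rnorm(rhs / n, std::sqrt(se2 / n));
      resid += onest * (mu - mnew);
      mu = mnew;
    }
    int m_in = 0;
    double ssq_beta = 0.0;
    if (sparse_on) {
      for (int j = 0; j < M; ++j) {
        double bold = beta[j];
        double rhs = arma::dot(Xt.col(j), resid) + xx[j] * bold;
        double C = xx[j] + se2 / sa2;
        double logL1 = -0.5 * std::log(sa2 * C / se2) +
                       rhs * rhs / (2.0 * se2 * C);
        double p1 = 1.0 / (1.0 + ((1.0 - pi) / pi) * std::exp(-logL1));
        double bnew = 0.0;
        int dnew = 0;
        if (R::unif_rand() < p1) {
          bnew = R::rnorm(rhs / C, std::sqrt(se2 / C));
          dnew = 1; ++m_in; ssq_beta += bnew * bnew;
        }
        if (bnew != bold) resid += Xt.col(j) * (bold - bnew);
        beta[j] = bnew;
        delta[j] = dnew;
      }
    }
    // polygenic values: independent conditionals in the rotated basis
    double uqf = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = resid[i] + u[i];
      double unew = 0.0;
      if (d[i] > dtol) {
        double prec = 1.0 / se2 + 1.0 / (d[i] * sp2);
        unew = R::rnorm((r / se2) / prec, std::sqrt(1.0 / prec));
        uqf += unew * unew / d[i];
      }
      resid[i] = r - unew;
      u[i] = unew;
    }
    if (sparse_on) {
      sa2 = rinvchisq(nu0 + m_in, ssq_beta + nu0 * s0_a);
      // RW Metropolis on log(pi), log-uniform prior on [pi_min, 1]
      double lpi = std::log(pi) + R::rnorm(0.0, rw_sd);
      double pin = std::exp(lpi);
      if (pin >= pi_min && pin <= 1.0 && pin < 1.0) {
        double la = (m_in - 1.0) * (std::log(pin) - std::log(pi)) +
                    (M - m_in) * (std::log(1.0 - pin) - std::log(1.0 - pi));
        if (std::log(R::unif_rand()) < la) pi = pin;
      }
    }
    sp2 = rinvchisq(nu0 + n_pos, uqf + nu0 * s0_p);
    se2 = rinvchisq(nu0 + n, arma::dot(resid, resid) + nu0 * s0_e);
    check_finite(se2, it);
    (void)vy;

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      beta_acc += beta;
      for (int j = 0; j < M; ++j) pip_acc[j] += delta[j];
      u_acc += u;
      mu_acc += mu;
      arma::vec g = yt - resid - onest * mu;   // Xb + u, rotated
      double gbar = arma::dot(onest, g) / n;
      double vg = (arma::dot(g, g) - n * gbar * gbar) / (n - 1.0);
      tr_pi.push_back(pi); tr_sa2.push_back(sa2); tr_sp2.push_back(sp2);
      tr_se2.push_back(se2); tr_h2.push_back(vg / (vg + se2));
      tr_m.push_back((double)m_in);
    }
  }
  return List::create(
    _["beta_mean"] = beta_acc / n_kept,
    _["pip"] = pip_acc / n_kept,
    _["u_mean_rot"] = u_acc / n_kept,
    _["mu_mean"] = mu_acc / n_kept,
    _["trace_pi"] = tr_pi, _["trace_sigma2_a"] = tr_sa2,
    _["trace_sigma2_poly"] = tr_sp2, _["trace_sigma2_e"] = tr_se2,
    _["trace_h2"] = tr_h2, _["trace_n_additional"] = tr_m);
}
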