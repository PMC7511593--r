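// Marginal log-likelihood of the latent moderated structural equations model.
//
// Conditional on the latent moderator Z = z the model is linear-Gaussian:
// X | z is normal, M = a X + zeta_M, Y = c X + (b1 + b3 z) M + b2 z + zeta_Y,
// and the 14 indicators are jointly normal with node-specific mean mu(z) and
// covariance L Psi(z) L' + Theta. The marginal per-case likelihood is the
// 1-D integral over z, evaluated by Gauss-Hermite quadrature whose nodes are
// recentred per case on the posterior of z computed under the b3 = 0
// linearisation of the current parameter point (adaptive quadrature; exact
// for every K when b3 = 0).
//
// Parameter vector layout (length 48), fixed across the package:
//   0:1   lambda_x2, lambda_x3
//   2:4   lambda_m2, lambda_m3, lambda_m4
//   5:6   lambda_z2, lambda_z3
//   7:9   lambda_y2, lambda_y3, lambda_y4
//   10:23 tau  (x1..x3, m1..m4, z1..z3, y1..y4)
//   24:37 theta (same order)
//   38:42 a, b1, b2, b3, c
//   43:45 phi_x, phi_z, phi_xz
//   46:47 psi_m, psi_y

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double LOG2PI = 1.8378770664093454836;

// Fills out[i] with the per-case log-likelihood; returns false when the
// parameter point is infeasible (non-positive variances).
static bool lms_casewise(const arma::vec& par, const arma::mat& X,
                         const arma::vec& gh_t, const arma::vec& gh_logw,
                         arma::vec& out) {
  const int n = X.n_rows;
  const int K = gh_t.n_elem;

  double lamx[3] = {1.0, par[0], par[1]};
  double lamm[4] = {1.0, par[2], par[3], par[4]};
  double lamz[3] = {1.0, par[5], par[6]};
  double lamy[4] = {1.0, par[7], par[8], par[9]};
  arma::vec tau = par.subvec(10, 23);
  arma::vec theta = par.subvec(24, 37);
  const double a = par[38], b1 = par[39], b2 = par[40], b3 = par[41],
               c = par[42];
  const double phx = par[43], phz = par[44], phxz = par[45];
  const double psm = par[46], psy = par[47];

  if (theta.min() <= 0.0 || phz <= 0.0 || psm <= 0.0 || psy <= 0.0)
    return false;
  const double v = phx - phxz * phxz / phz; // Var(X | Z = z)
  if (v <= 0.0) return false;
  const double gamma = phxz / phz;

  arma::vec thinv = 1.0 / theta;
  double sumlogtheta = arma::accu(arma::log(theta));
  double logdetpsi = std::log(v) + std::log(psm) + std::log(psy);

  // diagonal of L' Theta^-1 L (columns of L have disjoint support)
  double g1 = 0, g2 = 0, g3 = 0, ddt = 0;
  for (int j = 0; j < 3; ++j) g1 += lamx[j] * lamx[j] * thinv[j];
  for (int j = 0; j < 4; ++j) g2 += lamm[j] * lamm[j] * thinv[3 + j];
  for (int j = 0; j < 4; ++j) g3 += lamy[j] * lamy[j] * thinv[10 + j];
  for (int j = 0; j < 3; ++j) ddt += lamz[j] * lamz[j] * thinv[7 + j];

  // ---- adaptation: joint Gaussian of (x, Z) under the b3 = 0 linearisation
  arma::mat Lam4(14, 4, arma::fill::zeros);
  for (int j = 0; j < 3; ++j) Lam4(j, 0) = lamx[j];
  for (int j = 0; j < 4; ++j) Lam4(3 + j, 1) = lamm[j];
  for (int j = 0; j < 3; ++j) Lam4(7 + j, 2) = lamz[j];
  for (int j = 0; j < 4; ++j) Lam4(10 + j, 3) = lamy[j];
  arma::mat P4(4, 4);
  const double varm0 = a * a * phx + psm;
  P4(0, 0) = phx;
  P4(0, 1) = P4(1, 0) = a * phx;
  P4(0, 2) = P4(2, 0) = phxz;
  P4(1, 1) = varm0;
  P4(1, 2) = P4(2, 1) = a * phxz;
  P4(2, 2) = phz;
  const double cyx = c * phx + b1 * a * phx + b2 * phxz;
  const double cym = c * a * phx + b1 * varm0 + b2 * a * phxz;
  const double cyz = c * phxz + b1 * a * phxz + b2 * phz;
  P4(0, 3) = P4(3, 0) = cyx;
  P4(1, 3) = P4(3, 1) = cym;
  P4(2, 3) = P4(3, 2) = cyz;
  P4(3, 3) = c * cyx + b1 * cym + b2 * cyz + psy;
  arma::mat Sxx = Lam4 * P4 * Lam4.t();
  Sxx.diag() += theta;
  arma::vec covlatz = {phxz, a * phxz, phz, cyz};
  arma::vec sxz = Lam4 * covlatz;
  arma::vec kvec;
  double s2;
  if (arma::solve(kvec, Sxx, sxz, arma::solve_opts::likely_sympd)) {
    s2 = phz - arma::dot(sxz, kvec);
    if (!(s2 > 1e-12)) { s2 = phz; kvec.zeros(); }
  } else {
    s2 = phz;
    kvec = arma::zeros(14);
  }
  const double s_ad = std::sqrt(s2);
  const double log_sqrt2s = 0.5 * std::log(2.0 * s2);

  // ---- per-case precomputations
  arma::mat Xc = X.each_row() - tau.t();      // n x 14
  arma::vec m_ad = Xc * kvec;                 // adapted posterior means
  arma::vec q0 = (arma::square(Xc) * thinv);  // x' Theta^-1 x
  arma::vec w1(n), w2(n), w3(n), e(n, arma::fill::zeros);
  w1.zeros(); w2.zeros(); w3.zeros();
  for (int j = 0; j < 3; ++j) w1 += (lamx[j] * thinv[j]) * Xc.col(j);
  for (int j = 0; j < 4; ++j) w2 += (lamm[j] * thinv[3 + j]) * Xc.col(3 + j);
  for (int j = 0; j < 4; ++j) w3 += (lamy[j] * thinv[10 + j]) * Xc.col(10 + j);
  for (int j = 0; j < 3; ++j) e += (lamz[j] * thinv[7 + j]) * Xc.col(7 + j);

  const double iv = 1.0 / v, im = 1.0 / psm, iy = 1.0 / psy;
  const double logprior_const = -0.5 * (std::log(2.0 * M_PI * phz));
  const double dens_const = -0.5 * (14.0 * LOG2PI + sumlogtheta + logdetpsi);
  const double sqrt2 = std::sqrt(2.0);
  const double node_const = log_sqrt2s + logprior_const + dens_const;

  // z-independent pieces of C = Psi(z)^-1 + diag(g)
  const double C11 = iv + a * a * im + c * c * iy + g1;
  const double C13 = -c * iy;
  const double C33 = iy + g3;
  const double ihz = 0.5 / phz;

  std::vector<double> buf(K);
  for (int i = 0; i < n; ++i) {
    const double mi = m_ad[i], w1i = w1[i], w2i = w2[i], w3i = w3[i],
                 q0i = q0[i], ei = e[i];
    double mx = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < K; ++k) {
      const double z = mi + sqrt2 * s_ad * gh_t[k];
      const double beta = b1 + b3 * z;
      const double mu1 = gamma * z;
      const double mu2 = a * mu1;
      const double mu3 = (c + beta * a) * mu1 + b2 * z;
      const double C12 = -a * im + c * beta * iy;
      const double C22 = im + beta * beta * iy + g2;
      const double C23 = -beta * iy;
      const double A11 = C22 * C33 - C23 * C23;
      const double A12 = C13 * C23 - C12 * C33;
      const double A13 = C12 * C23 - C13 * C22;
      const double A22 = C11 * C33 - C13 * C13;
      const double A23 = C12 * C13 - C11 * C23;
      const double A33 = C11 * C22 - C12 * C12;
      const double detC = C11 * A11 + C12 * A12 + C13 * A13;
      if (!(detC > 0.0)) return false;
      const double h1 = w1i - g1 * mu1;
      const double h2 = w2i - g2 * mu2;
      const double h3 = w3i - g3 * mu3;
      const double hCh = (h1 * (A11 * h1 + A12 * h2 + A13 * h3) +
                          h2 * (A12 * h1 + A22 * h2 + A23 * h3) +
                          h3 * (A13 * h1 + A23 * h2 + A33 * h3)) / detC;
      const double uTu = q0i -
        2.0 * (w1i * mu1 + w2i * mu2 + w3i * mu3) - 2.0 * ei * z +
        (g1 * mu1 * mu1 + g2 * mu2 * mu2 + g3 * mu3 * mu3) + z * z * ddt;
      const double lt = gh_logw[k] + node_const -
        0.5 * (std::log(detC) + uTu - hCh) - z * z * ihz;
      buf[k] = lt;
      if (lt > mx) mx = lt;
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(buf[k] - mx);
    out[i] = mx + std::log(sum);
  }
  return true;
}

// [[Rcpp::export]]
double cpp_lms_loglik_total(const arma::vec& par, const arma::mat& X,
                            const arma::vec& gh_t, const arma::vec& gh_logw) {
  arma::vec out(X.n_rows);
  if (!lms_casewise(par, X, gh_t, gh_logw, out)) return -1e12;
  double tot = arma::accu(out);
  if (!std::isfinite(tot)) return -1e12;
  return tot;
}

// [[Rcpp::export]]
arma::vec cpp_lms_loglik_casewise(const arma::vec& par, const arma::mat& X,
                                  const arma::vec& gh_t,
                                  const arma::vec& gh_logw) {
  arma::vec out(X.n_rows);
  if (!lms_casewise(par, X, gh_t, gh_logw, out)) out.fill(-1e12 / X.n_rows);
  return out;
}
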