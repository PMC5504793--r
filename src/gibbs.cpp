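// Single-site Gibbs samplers for whole-genome regression.
//
// One engine drives the five marker-effect priors:
//   0 BRR      m_j ~ N(0, s2m), common variance, scaled-inv-chi2 update
//   1 Bayes A  m_j ~ N(0, s2_j), per-marker scaled-inv-chi2 variances
//   2 Bayes B  as Bayes A plus a point mass at zero with inclusion
//              indicators and (optionally) a Beta-updated inclusion rate
//   3 Bayes C  common variance plus indicators and Beta-updated pi
//   4 BL       double-exponential prior via the exponential-mixture
//              representation (m_j ~ N(0, s2e * tau2_j))
// Fixed effects get the flat-Gaussian prior N(0, 1e6); the residual
// variance is scaled-inv-chi2(nuE, Se). All draws use R's RNG so results
// are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rchisq1(double df) { return R::rchisq(df); }

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_wgr_cpp")]]
List gibbs_wgr_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                   int method, int nIter, int burnIn, int thin,
                   double nuE, double Se, double nuM, double Sm,
                   double piIncl, bool updatePi,
                   double blShape, double blRate,
                   bool fixVar, double s2eFix, double s2mFix) {
  const int n = y.n_elem, q = X.n_cols, p = Z.n_cols;
  const double priorPrecB = 1e-6;  // fixed effects ~ N(0, 1e6)

  arma::vec b(q, arma::fill::zeros), m(p, arma::fill::zeros);
  arma::vec e = y;
  arma::vec xtx(q), ztz(p);
  for (int j = 0; j < q; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));
  for (int j = 0; j < p; ++j) ztz[j] = arma::dot(Z.col(j), Z.col(j));

  double s2e = fixVar ? s2eFix : arma::var(y) * 0.5;
  double s2m = fixVar ? s2mFix : std::max(Sm, 1e-10);
  arma::vec s2j(p); s2j.fill(std::max(Sm, 1e-10));     // Bayes A/B
  arma::vec tau2(p, arma::fill::ones);                 // BL
  double lambda2 = blShape / blRate;                   // BL regularization
  arma::uvec delta(p, arma::fill::ones);               // B / C indicators
  if (method == 2 || method == 3) {
    delta.zeros();
    m.zeros();
  }

  const int nSave = (nIter - burnIn) / thin;
  arma::vec mSum(p, arma::fill::zeros), bSum(q, arma::fill::zeros);
  NumericVector h2s(nSave), s2es(nSave), s2ms(nSave), pis(nSave), lam2s(nSave);
  int saved = 0;

  for (int it = 1; it <= nIter; ++it) {
    // fixed effects
    for (int j = 0; j < q; ++j) {
      e += X.col(j) * b[j];
      double cj = arma::dot(X.col(j), e);
      double prec = xtx[j] / s2e + priorPrecB;
      double mean = (cj / s2e) / prec;
      b[j] = mean + R::norm_rand() / std::sqrt(prec);
      e -= X.col(j) * b[j];
    }

    if (method == 0 || method == 1 || method == 4) {
      // always-in priors: BRR / Bayes A / BL
      for (int j = 0; j < p; ++j) {
        if (ztz[j] <= 0.0) { m[j] = 0.0; continue; }
        e += Z.col(j) * m[j];
        double cj = arma::dot(Z.col(j), e);
        double priorVar = (method == 0) ? s2m
                          : (method == 1) ? s2j[j]
                          : s2e * tau2[j];
        double prec = ztz[j] / s2e + 1.0 / priorVar;
        double mean = (cj / s2e) / prec;
        m[j] = mean + R::norm_rand() / std::sqrt(prec);
        e -= Z.col(j) * m[j];
      }
      if (method == 0 && !fixVar)
        s2m = (arma::dot(m, m) + nuM * Sm) / rchisq1(p + nuM);
      if (method == 1)
        for (int j = 0; j < p; ++j)
          s2j[j] = (m[j] * m[j] + nuM * Sm) / rchisq1(nuM + 1.0);
      if (method == 4) {
        for (int j = 0; j < p; ++j) {
          double mj2 = std::max(m[j] * m[j], 1e-12);
          double itau = rinvgauss(std::sqrt(lambda2 * s2e / mj2), lambda2);
          tau2[j] = 1.0 / itau;
        }
        lambda2 = R::rgamma(blShape + p, 1.0 / (blRate + arma::accu(tau2) / 2.0));
      }
    } else {
      // spike-and-slab priors: Bayes B / Bayes C
      int nIn = 0;
      for (int j = 0; j < p; ++j) {
        if (ztz[j] <= 0.0) { m[j] = 0.0; delta[j] = 0; continue; }
        if (delta[j] == 1) e += Z.col(j) * m[j];
        double cj = arma::dot(Z.col(j), e);
        double sv = (method == 2) ? s2j[j] : s2m;
        double v1 = s2e + ztz[j] * sv;
        double logBF = 0.5 * std::log(s2e / v1) +
                       0.5 * cj * cj * sv / (s2e * v1);
        double lo = logBF + std::log(piIncl) - std::log1p(-piIncl);
        double pIn = 1.0 / (1.0 + std::exp(-lo));
        if (R::unif_rand() < pIn) {
          delta[j] = 1;
          double prec = ztz[j] / s2e + 1.0 / sv;
          double mean = (cj / s2e) / prec;
          m[j] = mean + R::norm_rand() / std::sqrt(prec);
          e -= Z.col(j) * m[j];
          ++nIn;
        } else {
          delta[j] = 0;
          m[j] = 0.0;
        }
        if (method == 2)
          s2j[j] = (delta[j] ? (m[j] * m[j] + nuM * Sm) / rchisq1(nuM + 1.0)
                             : nuM * Sm / rchisq1(nuM));
      }
      if (method == 3) {
        double ssm = 0.0;
        for (int j = 0; j < p; ++j) ssm += m[j] * m[j];
        s2m = (ssm + nuM * Sm) / rchisq1(nIn + nuM);
      }
      if (updatePi)
        piIncl = R::rbeta(1.0 + nIn, 1.0 + p - nIn);
      piIncl = std::min(std::max(piIncl, 1e-6), 1.0 - 1e-6);
    }

    if (!fixVar) {
      double ss = arma::dot(e, e);
      double df = n;
      if (method == 4) {  // BL: marker scale shares the residual variance
        for (int j = 0; j < p; ++j) ss += m[j] * m[j] / tau2[j];
        df += p;
      }
      s2e = (ss + nuE * Se) / rchisq1(df + nuE);
    }
    if (!std::isfinite(s2e) || s2e > 1e12)
      stop("divergent residual variance at iteration %d", it);

    if (it > burnIn && (it - burnIn) % thin == 0 && saved < nSave) {
      mSum += m;
      bSum += b;
      arma::vec g = y - X * b - e;
      double vg = arma::var(g);
      h2s[saved] = vg / (vg + s2e);
      s2es[saved] = s2e;
      s2ms[saved] = (method == 1 || method == 2) ? arma::mean(s2j) : s2m;
      pis[saved] = piIncl;
      lam2s[saved] = lambda2;
      ++saved;
    }
  }

  return List::create(
      _["m_mean"] = mSum / std::max(saved, 1),
      _["b_mean"] = bSum / std::max(saved, 1),
      _["h2_samples"] = h2s, _["s2e_samples"] = s2es,
      _["s2m_samples"] = s2ms, _["pi_samples"] = pis,
      _["lambda2_samples"] = lam2s, _["n_saved"] = saved);
}
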