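// Single-site Gibbs samplers for threshold / linear animal models.
// All randomness comes from R's RNG so set.seed() in R makes runs
// bit-reproducible.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;

// Truncated-normal draw by inverse CDF in log space: exact in the far tails
// where naive rejection or plain inverse CDF would stall or return Inf.
static double rtnorm_one(double mean, double sd, double t, bool upper) {
  const double alpha = (t - mean) / sd;
  const double u = ::unif_rand();
  double x;
  if (upper) { // (t, Inf)
    const double logp = R::pnorm(alpha, 0.0, 1.0, 0, 1);
    x = R::qnorm(std::log(u) + logp, 0.0, 1.0, 0, 1);
  } else {     // (-Inf, t]
    const double logp = R::pnorm(alpha, 0.0, 1.0, 1, 1);
    x = R::qnorm(std::log(u) + logp, 0.0, 1.0, 1, 1);
  }
  return mean + sd * x;
}

// [[Rcpp::export]]
NumericVector rtnorm_cpp(int n, double mean, double sd, double t, bool upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_one(mean, sd, t, upper);
  return out;
}

// scaled inverse chi-square draw: (ss + nu*S) / chisq(df0 + nu)
static double rsclinv(double ss, double df0, double nu, double S) {
  const double df = df0 + nu;
  if (df <= 0.0) Rcpp::stop("variance full conditional has non-positive df");
  return (ss + nu * S) / R::rchisq(df);
}

struct RecIndex {
  std::vector<int> start;  // q+1 offsets
  std::vector<int> idx;    // record indices grouped by animal
  std::vector<int> nrec;   // records per animal
  RecIndex(const IntegerVector& animal, int q, int n) {
    start.assign(q + 1, 0);
    nrec.assign(q, 0);
    for (int i = 0; i < n; ++i) nrec[animal[i] - 1]++;
    for (int k = 0; k < q; ++k) start[k + 1] = start[k] + nrec[k];
    idx.assign(n, 0);
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[pos[animal[i] - 1]++] = i;
  }
};

// one Gauss-Seidel-with-noise pass over fixed effects (CSC sparse X)
static void update_fixed(const arma::sp_mat& X, arma::vec& beta, arma::vec& e,
                         double s2e) {
  const int p = X.n_cols;
  for (int j = 0; j < p; ++j) {
    double xtx = 0.0, xte = 0.0;
    for (arma::sp_mat::const_col_iterator it = X.begin_col(j);
         it != X.end_col(j); ++it) {
      xtx += (*it) * (*it);
      xte += (*it) * e[it.row()];
    }
    if (xtx == 0.0) continue;
    const double mean = beta[j] + xte / xtx;
    const double bnew = mean + std::sqrt(s2e / xtx) * ::norm_rand();
    const double delta = bnew - beta[j];
    for (arma::sp_mat::const_col_iterator it = X.begin_col(j);
         it != X.end_col(j); ++it)
      e[it.row()] -= (*it) * delta;
    beta[j] = bnew;
  }
}

// one pass over breeding values; lambda = s2e/s2a weights Ainv
static void update_animals(const arma::sp_mat& Ainv, const RecIndex& ri,
                           arma::vec& a, arma::vec& e, double s2a, double s2e) {
  const int q = Ainv.n_cols;
  const double lambda = s2e / s2a;
  for (int k = 0; k < q; ++k) {
    double akk = 0.0, arow = 0.0;
    for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k);
         it != Ainv.end_col(k); ++it) {
      if ((int)it.row() == k) akk = *it;
      else arow += (*it) * a[it.row()];
    }
    double zte = 0.0;
    const int zz = ri.nrec[k];
    for (int m = ri.start[k]; m < ri.start[k + 1]; ++m) zte += e[ri.idx[m]];
    const double d = zz + lambda * akk;
    const double mean = (zte + zz * a[k] - lambda * arow) / d;
    const double anew = mean + std::sqrt(s2e / d) * ::norm_rand();
    const double delta = anew - a[k];
    for (int m = ri.start[k]; m < ri.start[k + 1]; ++m)
      e[ri.idx[m]] -= delta;
    a[k] = anew;
  }
}

static double quad_ainv(const arma::sp_mat& Ainv, const arma::vec& a) {
  return arma::as_scalar(a.t() * (Ainv * a));
}

// Draw from log p(s) = -(s - m)^2/(2 v) - (nu + 1) log s - ssp/(2 s^2),
// s > 0, by inverse CDF on a grid over the region holding the mass.
static double sample_scale_conditional(double m, double v, double nu,
                                       double ssp, double fallback) {
  const double sv = std::sqrt(v);
  // the conditional is a truncated Gaussian around m tilted by the prior;
  // grid the support where its mass lives
  double lo = std::max(1e-8, m - 10.0 * sv);
  double hi = std::max(m + 10.0 * sv, 20.0 * sv);
  const int K = 512;
  std::vector<double> logd(K), grid(K);
  const double step = (hi - lo) / K;
  double mx = -1e300;
  for (int k = 0; k < K; ++k) {
    const double s = lo + step * (k + 0.5);
    grid[k] = s;
    double ld = -(s - m) * (s - m) / (2.0 * v) - (nu + 1.0) * std::log(s);
    if (ssp > 0.0) ld -= ssp / (2.0 * s * s);
    logd[k] = ld;
    if (ld > mx) mx = ld;
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    logd[k] = std::exp(logd[k] - mx);
    tot += logd[k];
  }
  if (!std::isfinite(tot) || tot <= 0.0) return fallback;
  const double u = ::unif_rand() * tot;
  double acc = 0.0, snew = grid[K - 1];
  for (int k = 0; k < K; ++k) {
    acc += logd[k];
    if (acc >= u) { snew = grid[k]; break; }
  }
  return snew;
}

// Ancillarity-sufficiency interweaving move for the genetic scale.
// In the non-centered parameterization a = sigma_a * a_tilde with
// a_tilde ~ N(0, A), the full conditional of sigma_a given a_tilde and the
// data is the scale conditional above with m, v from the Gaussian data
// term and the prior terms from the scaled-inverse-chi-square prior
// transformed to the standard-deviation scale. a and the residuals are
// rescaled afterwards. Dramatically improves mixing of sigma2_a when
// individual records carry little information.
static double asis_rescale(arma::vec& a, arma::vec& e,
                           double s2a, double s2e, double nu, double S,
                           const IntegerVector& animal) {
  const int n = e.n_elem;
  const double sa = std::sqrt(s2a);
  double rw = 0.0, ww = 0.0;
  // r_i = l_i - x_i' beta = e_i + a_(anim i); w_i = a_(anim i) / sa
  for (int i = 0; i < n; ++i) {
    const double ai = a[animal[i] - 1];
    rw += (e[i] + ai) * ai;
    ww += ai * ai;
  }
  if (ww <= 0.0) return s2a;  // all breeding values zero: nothing to do
  rw /= sa;
  ww /= s2a;
  const double m = rw / ww, v = s2e / ww;
  const double snew = sample_scale_conditional(m, v, nu, nu * S, sa);
  const double c = snew / sa;
  // e_new = (l - Xb) - c * Za_old = e_old + (1 - c) * Za_old
  for (int i = 0; i < n; ++i)
    e[i] += (1.0 - c) * a[animal[i] - 1];
  a *= c;
  return snew * snew;
}

// [[Rcpp::export]]
List gibbs_uni_cpp(const arma::vec& y, bool threshold, const arma::sp_mat& X,
                   const IntegerVector& animal, int q,
                   const arma::sp_mat& Ainv, double nu_a, double S_a,
                   double nu_e, double S_e, double s2a0, double s2e0,
                   int n_iter, int burn_in, int thin,
                   bool update_s2a, bool update_s2e) {
  const int n = y.n_elem, p = X.n_cols;
  if (burn_in >= n_iter) Rcpp::stop("burn_in must be smaller than chain length");
  RecIndex ri(animal, q, n);

  arma::vec beta(p, arma::fill::zeros), a(q, arma::fill::zeros);
  arma::vec l(n), e(n);
  double s2a = s2a0, s2e = threshold ? 1.0 : s2e0;
  if (threshold) {
    for (int i = 0; i < n; ++i) {
      if (y[i] != 0.0 && y[i] != 1.0)
        Rcpp::stop("threshold trait scores must be 0 or 1");
      l[i] = rtnorm_one(0.0, 1.0, 0.0, y[i] == 1.0);
    }
  } else l = y;
  e = l;  // beta = a = 0 at start

  const int n_store = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_store, 3);
  arma::vec ebv_sum(q, arma::fill::zeros), beta_sum(p, arma::fill::zeros);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    if (threshold) {
      for (int i = 0; i < n; ++i) {
        const double mu = l[i] - e[i];
        const double lnew = rtnorm_one(mu, 1.0, 0.0, y[i] == 1.0);
        e[i] += lnew - l[i];
        l[i] = lnew;
      }
    }
    update_fixed(X, beta, e, s2e);
    update_animals(Ainv, ri, a, e, s2a, s2e);
    if (update_s2a) {
      s2a = rsclinv(quad_ainv(Ainv, a), (double)q, nu_a, S_a);
      s2a = asis_rescale(a, e, s2a, s2e, nu_a, S_a, animal);
    }
    if (!threshold && update_s2e)
      s2e = rsclinv(arma::dot(e, e), (double)n, nu_e, S_e);

    if (it % 1000 == 0) {  // refresh residuals against numeric drift
      arma::vec mu = X * beta;
      for (int i = 0; i < n; ++i) mu[i] += a[animal[i] - 1];
      e = l - mu;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_store) {
      samples(stored, 0) = s2a;
      samples(stored, 1) = s2e;
      samples(stored, 2) = s2a / (s2a + s2e);
      ebv_sum += a;
      beta_sum += beta;
      ++stored;
    }
  }

  return List::create(
    Rcpp::Named("samples") = samples,
    Rcpp::Named("ebv_mean") = NumericVector(ebv_sum.begin(), ebv_sum.end()) /
                              std::max(stored, 1),
    Rcpp::Named("beta_mean") = NumericVector(beta_sum.begin(), beta_sum.end()) /
                               std::max(stored, 1),
    Rcpp::Named("final_liability") = NumericVector(l.begin(), l.end()),
    Rcpp::Named("final_a") = NumericVector(a.begin(), a.end()),
    Rcpp::Named("final_beta") = NumericVector(beta.begin(), beta.end()),
    Rcpp::Named("n_stored") = stored);
}

// 2x2 Wishart via Bartlett decomposition
static arma::mat rwish2(double df, const arma::mat& V) {
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = ::norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Bivariate linear(2)-threshold(1) sampler. One row per animal record pair;
// miss flags mark unobserved channels (data augmentation fills them).
// Residual covariance is identified through the conditional-regression
// parameterization with R[1,1] fixed at 1.
// [[Rcpp::export]]
List gibbs_biv_cpp(const arma::vec& y1, const IntegerVector& miss1,
                   const arma::vec& y2, const IntegerVector& miss2,
                   const arma::sp_mat& X1, const arma::sp_mat& X2,
                   const IntegerVector& animal, int q,
                   const arma::sp_mat& Ainv,
                   const arma::mat& G_start, double nu_G, const arma::mat& S_G,
                   double r22_start, double nu_r, double S_r,
                   int n_iter, int burn_in, int thin, bool zero_cov) {
  const int n = y1.n_elem;
  if (burn_in >= n_iter) Rcpp::stop("burn_in must be smaller than chain length");
  RecIndex ri(animal, q, n);

  const int p1 = X1.n_cols, p2 = X2.n_cols;
  arma::vec b1(p1, arma::fill::zeros), b2(p2, arma::fill::zeros);
  arma::vec a1(q, arma::fill::zeros), a2(q, arma::fill::zeros);
  arma::mat G = G_start;
  double r12 = 0.0, r22 = r22_start;

  arma::vec l1(n), y2a(n);
  for (int i = 0; i < n; ++i) {
    if (miss1[i]) l1[i] = ::norm_rand();
    else {
      if (y1[i] != 0.0 && y1[i] != 1.0)
        Rcpp::stop("threshold trait scores must be 0 or 1");
      l1[i] = rtnorm_one(0.0, 1.0, 0.0, y1[i] == 1.0);
    }
    y2a[i] = miss2[i] ? 0.0 : y2[i];
  }
  arma::vec e1 = l1, e2 = y2a;

  const int n_store = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_store, 9);
  arma::vec ebv1_sum(q, arma::fill::zeros), ebv2_sum(q, arma::fill::zeros);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // residual precision of current R = [[1, r12], [r12, r22]]
    const double det = r22 - r12 * r12;
    const double r11i = r22 / det, r12i = -r12 / det, r22i = 1.0 / det;

    // latent liabilities (channel 1), conditional on channel-2 residual
    const double cv = 1.0 - r12 * r12 / r22;  // Var(e1 | e2)
    for (int i = 0; i < n; ++i) {
      const double mu = (l1[i] - e1[i]) + (r12 / r22) * e2[i];
      const double lnew = miss1[i]
        ? mu + std::sqrt(cv) * ::norm_rand()
        : rtnorm_one(mu, std::sqrt(cv), 0.0, y1[i] == 1.0);
      e1[i] += lnew - l1[i];
      l1[i] = lnew;
    }
    // augmented channel-2 records, conditional on channel-1 residual
    const double cv2 = r22 - r12 * r12;  // Var(e2 | e1), Var(e1) = 1
    for (int i = 0; i < n; ++i) {
      if (!miss2[i]) continue;
      const double mu = (y2a[i] - e2[i]) + r12 * e1[i];
      const double ynew = mu + std::sqrt(cv2) * ::norm_rand();
      e2[i] += ynew - y2a[i];
      y2a[i] = ynew;
    }

    // fixed effects, trait 1 then trait 2
    for (int j = 0; j < p1; ++j) {
      double xtx = 0.0, grad = 0.0;
      for (arma::sp_mat::const_col_iterator itc = X1.begin_col(j);
           itc != X1.end_col(j); ++itc) {
        xtx += (*itc) * (*itc);
        grad += (*itc) * (r11i * e1[itc.row()] + r12i * e2[itc.row()]);
      }
      if (xtx == 0.0) continue;
      const double d = xtx * r11i;
      const double bnew = b1[j] + grad / d + std::sqrt(1.0 / d) * ::norm_rand();
      const double delta = bnew - b1[j];
      for (arma::sp_mat::const_col_iterator itc = X1.begin_col(j);
           itc != X1.end_col(j); ++itc)
        e1[itc.row()] -= (*itc) * delta;
      b1[j] = bnew;
    }
    for (int j = 0; j < p2; ++j) {
      double xtx = 0.0, grad = 0.0;
      for (arma::sp_mat::const_col_iterator itc = X2.begin_col(j);
           itc != X2.end_col(j); ++itc) {
        xtx += (*itc) * (*itc);
        grad += (*itc) * (r12i * e1[itc.row()] + r22i * e2[itc.row()]);
      }
      if (xtx == 0.0) continue;
      const double d = xtx * r22i;
      const double bnew = b2[j] + grad / d + std::sqrt(1.0 / d) * ::norm_rand();
      const double delta = bnew - b2[j];
      for (arma::sp_mat::const_col_iterator itc = X2.begin_col(j);
           itc != X2.end_col(j); ++itc)
        e2[itc.row()] -= (*itc) * delta;
      b2[j] = bnew;
    }

    // breeding values under G^-1 (x) A^-1 prior
    arma::mat Gi = arma::inv_sympd(G);
    for (int k = 0; k < q; ++k) {
      double akk = 0.0, arow1 = 0.0, arow2 = 0.0;
      for (arma::sp_mat::const_col_iterator itc = Ainv.begin_col(k);
           itc != Ainv.end_col(k); ++itc) {
        if ((int)itc.row() == k) akk = *itc;
        arow1 += (*itc) * a1[itc.row()];
        arow2 += (*itc) * a2[itc.row()];
      }
      const int zz = ri.nrec[k];
      double ge1 = 0.0, ge2 = 0.0;
      for (int m = ri.start[k]; m < ri.start[k + 1]; ++m) {
        const int i = ri.idx[m];
        ge1 += r11i * e1[i] + r12i * e2[i];
        ge2 += r12i * e1[i] + r22i * e2[i];
      }
      // trait 1
      {
        const double d = zz * r11i + Gi(0, 0) * akk;
        const double grad = ge1 - Gi(0, 0) * arow1 - Gi(0, 1) * arow2;
        const double anew = a1[k] + grad / d + std::sqrt(1.0 / d) * ::norm_rand();
        const double delta = anew - a1[k];
        for (int m = ri.start[k]; m < ri.start[k + 1]; ++m)
          e1[ri.idx[m]] -= delta;
        arow1 += akk * delta;
        ge1 -= zz * r11i * delta;
        ge2 -= zz * r12i * delta;
        a1[k] = anew;
      }
      // trait 2
      {
        const double d = zz * r22i + Gi(1, 1) * akk;
        const double grad = ge2 - Gi(1, 0) * arow1 - Gi(1, 1) * arow2;
        const double anew = a2[k] + grad / d + std::sqrt(1.0 / d) * ::norm_rand();
        const double delta = anew - a2[k];
        for (int m = ri.start[k]; m < ri.start[k + 1]; ++m)
          e2[ri.idx[m]] -= delta;
        a2[k] = anew;
      }
    }

    // genetic covariance matrix
    arma::mat U(q, 2);
    U.col(0) = a1; U.col(1) = a2;
    arma::mat S = U.t() * (Ainv * U);
    S = 0.5 * (S + S.t());  // guard against round-off asymmetry
    if (zero_cov) {
      G(0, 0) = rsclinv(S(0, 0), (double)q, nu_G, S_G(0, 0));
      G(1, 1) = rsclinv(S(1, 1), (double)q, nu_G, S_G(1, 1));
      G(0, 1) = G(1, 0) = 0.0;
    } else {
      arma::mat W = rwish2((double)q + nu_G, arma::inv_sympd(S + S_G));
      G = arma::inv_sympd(W);
    }

    // residual components under R[1,1] = 1: regression of e2 on e1
    if (zero_cov) {
      r12 = 0.0;
      r22 = rsclinv(arma::dot(e2, e2), (double)n, nu_r, S_r);
    } else {
      const double sxx = arma::dot(e1, e1);
      const double sxy = arma::dot(e1, e2);
      const double bhat = sxy / sxx;
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        const double r = e2[i] - bhat * e1[i];
        sse += r * r;
      }
      const double psi = rsclinv(sse, (double)(n - 1), nu_r, S_r);
      const double b = bhat + std::sqrt(psi / sxx) * ::norm_rand();
      r12 = b;
      r22 = psi + b * b;
    }

    // interweaving move for the threshold channel's genetic scale
    // (non-centered redraw of sigma_1 given a1/sigma_1; see asis_rescale)
    {
      const double det2 = r22 - r12 * r12;
      const double w11 = r22 / det2, w12 = -r12 / det2;
      const double s1 = std::sqrt(G(0, 0));
      const double rho = G(0, 1) / std::sqrt(G(0, 0) * G(1, 1));
      double num = 0.0, ww = 0.0;
      for (int i = 0; i < n; ++i) {
        const double w = a1[animal[i] - 1] / s1;
        const double r1 = e1[i] + a1[animal[i] - 1];
        num += w * (w11 * r1 + w12 * e2[i]);
        ww += w * w;
      }
      if (ww > 0.0) {
        const double v = 1.0 / (w11 * ww);
        const double m = num / (w11 * ww);
        const double ssp = zero_cov ? nu_G * S_G(0, 0)
                                    : S_G(0, 0) / (1.0 - rho * rho);
        const double s1new = sample_scale_conditional(m, v, nu_G, ssp, s1);
        const double c = s1new / s1;
        for (int i = 0; i < n; ++i)
          e1[i] += (1.0 - c) * a1[animal[i] - 1];
        a1 *= c;
        G(0, 0) = s1new * s1new;
        if (!zero_cov) {
          const double g12new = rho * s1new * std::sqrt(G(1, 1));
          G(0, 1) = G(1, 0) = g12new;
        }
      }
    }

    if (it % 1000 == 0) {
      arma::vec mu1 = X1 * b1, mu2 = X2 * b2;
      for (int i = 0; i < n; ++i) {
        mu1[i] += a1[animal[i] - 1];
        mu2[i] += a2[animal[i] - 1];
      }
      e1 = l1 - mu1;
      e2 = y2a - mu2;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_store) {
      samples(stored, 0) = G(0, 0);
      samples(stored, 1) = G(0, 1);
      samples(stored, 2) = G(1, 1);
      samples(stored, 3) = 1.0;   // R[threshold, threshold], fixed
      samples(stored, 4) = r12;
      samples(stored, 5) = r22;
      samples(stored, 6) = G(0, 1) / std::sqrt(G(0, 0) * G(1, 1));
      samples(stored, 7) = G(0, 0) / (G(0, 0) + 1.0);
      samples(stored, 8) = G(1, 1) / (G(1, 1) + r22);
      ebv1_sum += a1;
      ebv2_sum += a2;
      ++stored;
    }
  }

  return List::create(
    Rcpp::Named("samples") = samples,
    Rcpp::Named("ebv1_mean") = NumericVector(ebv1_sum.begin(), ebv1_sum.end()) /
                               std::max(stored, 1),
    Rcpp::Named("ebv2_mean") = NumericVector(ebv2_sum.begin(), ebv2_sum.end()) /
                               std::max(stored, 1),
    Rcpp::Named("final_liability") = NumericVector(l1.begin(), l1.end()),
    Rcpp::Named("n_stored") = stored);
}
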