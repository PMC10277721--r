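// Metropolis-within-Gibbs sampler for the multilevel (bivariate) AR(1)
// dynamic structural equation model with random means, lag coefficients,
// log innovation variances and linear slopes, covariate effects on all
// random effects, and data augmentation for missing weeks.
//
// Observation model (person i, process j, week t = 1..T, tbar = (T+1)/2):
//   Y_ijt = mu_ij + s_ij (t - tbar) + y_ijt
//   y_ijt = sum_k Phi_i(j,k) y_ik,t-1 + e_ijt,  e_ijt ~ N(0, pi_ij)
//   y_i0 ~ N(0, stationary covariance of (Phi_i, diag(pi_i)))
//   eta_i = gamma + B x_i + u_i,  u_i ~ N(0, Omega)
//
// All random draws use R's RNG so results are reproducible from set.seed().

#include <RcppArmadillo.h>
using namespace arma;

// parameter layout within eta: mu (p), phi row-major (p*p), lnpi (p),
// slope (p, when trend)
struct Layout {
  int p, d;
  bool trend;
  uvec mu, phi, lnpi, slope, ms;  // ms = mu and slope block
  Layout(int p_, bool trend_) : p(p_), trend(trend_) {
    int p2 = p * p;
    d = 2 * p + p2 + (trend ? p : 0);
    mu = regspace<uvec>(0, p - 1);
    phi = regspace<uvec>(p, p + p2 - 1);
    lnpi = regspace<uvec>(p + p2, p + p2 + p - 1);
    if (trend) {
      slope = regspace<uvec>(2 * p + p2, 2 * p + p2 + p - 1);
      ms = join_cols(mu, slope);
    } else {
      ms = mu;
    }
  }
};

static double rnorm1() { return R::rnorm(0.0, 1.0); }

static vec rnorm_vec(int k) {
  vec z(k);
  for (int i = 0; i < k; ++i) z[i] = rnorm1();
  return z;
}

// spectral radius of a 1x1 or 2x2 matrix
static double spec_radius(const mat& A) {
  if (A.n_rows == 1) return std::abs(A(0, 0));
  double tr = 0.5 * (A(0, 0) + A(1, 1));
  double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
  double disc = tr * tr - det;
  if (disc >= 0.0) {
    double r = std::sqrt(disc);
    return std::max(std::abs(tr + r), std::abs(tr - r));
  }
  return std::sqrt(det);  // complex pair, |lambda| = sqrt(det)
}

// stationary covariance (closed forms for p <= 2): solves S = Phi S Phi' + Psi
static bool stat_cov(const mat& Phi, const vec& pi, mat& S) {
  if (spec_radius(Phi) >= 0.999) return false;
  if (Phi.n_rows == 1) {
    S.set_size(1, 1);
    S(0, 0) = pi[0] / (1.0 - Phi(0, 0) * Phi(0, 0));
    return S(0, 0) > 0.0;
  }
  // Cramer solve of the 3x3 vectorised Lyapunov system, rhs (pi1, 0, pi2)
  double a = Phi(0, 0), b = Phi(0, 1), c = Phi(1, 0), d = Phi(1, 1);
  double m11 = 1 - a * a, m12 = -2 * a * b, m13 = -b * b;
  double m21 = -a * c, m22 = 1 - (a * d + b * c), m23 = -b * d;
  double m31 = -c * c, m32 = -2 * c * d, m33 = 1 - d * d;
  double det = m11 * (m22 * m33 - m23 * m32) - m12 * (m21 * m33 - m23 * m31) +
               m13 * (m21 * m32 - m22 * m31);
  if (std::abs(det) < 1e-14) return false;
  double p1 = pi[0], p2 = pi[1];
  double s11 = (p1 * (m22 * m33 - m23 * m32) + m12 * m23 * p2 -
                m13 * m22 * p2) / det;
  double s12 = (-m11 * m23 * p2 - p1 * (m21 * m33 - m23 * m31) +
                m13 * m21 * p2) / det;
  double s22 = (m11 * m22 * p2 - m12 * m21 * p2 +
                p1 * (m21 * m32 - m22 * m31)) / det;
  S.set_size(2, 2);
  S(0, 0) = s11; S(0, 1) = S(1, 0) = s12; S(1, 1) = s22;
  return s11 > 0.0 && s22 > 0.0 && s11 * s22 - s12 * s12 > 0.0;
}

// log N(y; 0, S) up to the additive constant, p <= 2
static double ldmvnorm0(const vec& y, const mat& S) {
  if (S.n_rows == 1)
    return -0.5 * std::log(S(0, 0)) - 0.5 * y[0] * y[0] / S(0, 0);
  double det = S(0, 0) * S(1, 1) - S(0, 1) * S(0, 1);
  if (det <= 0.0) return -datum::inf;
  double q = (y[0] * y[0] * S(1, 1) - 2.0 * y[0] * y[1] * S(0, 1) +
              y[1] * y[1] * S(0, 0)) / det;
  return -0.5 * std::log(det) - 0.5 * q;
}

// draw from N(mean, Prec^{-1}) given the precision matrix
static vec draw_mvn_prec(const vec& rhs, mat Prec) {
  Prec = symmatu(Prec);
  mat R;
  if (!chol(R, Prec)) {
    Prec.diag() += 1e-8 * (1.0 + Prec.diag().max());
    R = chol(Prec);
  }
  vec mean = solve(trimatu(R), solve(trimatl(R.t()), rhs));
  return mean + solve(trimatu(R), rnorm_vec(rhs.n_elem));
}

// inverse-Wishart(S, df) via the Bartlett decomposition
static mat draw_invwish(const mat& S, double df) {
  int d = S.n_rows;
  mat Sinv = inv_sympd(symmatu(S));
  mat L = chol(Sinv, "lower");
  mat A(d, d, fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  mat W = L * A;
  return inv_sympd(symmatu(W * W.t()));
}

// conditional N(mean, C) of block b given the rest, from N(m, Omega)
struct CondBlock {
  uvec b, r;
  mat G;      // Omega_br Omega_rr^{-1}
  mat Prec;   // (Omega_bb - G Omega_rb)^{-1}
  void compute(const mat& Omega, const uvec& b_, int d) {
    b = b_;
    uvec all = regspace<uvec>(0, d - 1);
    std::vector<unsigned int> rv;
    for (int i = 0; i < d; ++i)
      if (!any(b == (unsigned int)i)) rv.push_back(i);
    r = uvec(rv);
    mat Orr = symmatu(Omega.submat(r, r));
    G = Omega.submat(b, r) * inv_sympd(Orr);
    mat C = symmatu(Omega.submat(b, b) - G * Omega.submat(r, b));
    C.diag() += 1e-12;
    Prec = inv_sympd(C);
  }
  vec condMean(const vec& m, const vec& eta) const {
    return m(b) + G * (eta(r) - m(r));
  }
};

// [[Rcpp::export]]
Rcpp::List dsem_mcmc(const arma::cube& Yin,       // p x T x n, NaN = missing
                     const arma::mat& X,          // q x n covariates
                     bool trend,
                     int niter, int nburn,
                     arma::mat eta,               // d x n initial values
                     arma::vec gamma,
                     arma::mat B,                 // d x q
                     arma::mat Omega,
                     double gammaPriorVar, double lnpiPriorVar,
                     double bPriorVar,
                     const arma::vec& iwS0diag, double iwDf,
                     bool storePerson) {
  const int p = Yin.n_rows, T = Yin.n_cols, n = Yin.n_slices;
  const int q = X.n_rows;
  Layout L(p, trend);
  const int d = L.d;
  const double tbar = (T + 1.0) / 2.0;
  vec cvec(T + 1);
  for (int t = 0; t <= T; ++t) cvec[t] = t - tbar;
  // sums over weeks 2..T of the centring weights, used by the closed-form
  // accumulation in the (mu, slope) update
  struct { double n2 = 0, sC = 0, sC1 = 0, sCC = 0, sC11 = 0, sCC1 = 0; } cs;
  for (int t = 2; t <= T; ++t) {
    cs.n2 += 1.0;
    cs.sC += cvec[t];
    cs.sC1 += cvec[t - 1];
    cs.sCC += cvec[t] * cvec[t];
    cs.sC11 += cvec[t - 1] * cvec[t - 1];
    cs.sCC1 += cvec[t] * cvec[t - 1];
  }

  // missing-data bookkeeping and initial imputations (person mean = 0 dev)
  cube Y = Yin;
  std::vector<std::vector<int>> missW(n);  // weeks (1-based) with any missing
  cube missMask(p, T, n, fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) {
      bool any = false;
      for (int j = 0; j < p; ++j)
        if (!std::isfinite(Y(j, t, i))) {
          missMask(j, t, i) = 1.0;
          Y(j, t, i) = eta(L.mu[j], i);  // start at the individual mean
          any = true;
        }
      if (any) missW[i].push_back(t + 1);
    }

  mat y0(p, n, fill::zeros);
  mat lsig(p, n);
  lsig.fill(std::log(0.5));
  mat accN(p, n, fill::zeros), attN(p, n, fill::zeros);
  long phiReject = 0, phiTries = 0, phiMhAcc = 0;

  // prior precisions for theta = [gamma, B] (column-major over d x (1+q))
  int m = 1 + q;
  vec thetaPriorPrec(d * m, fill::value(1.0 / bPriorVar));
  for (int j = 0; j < d; ++j) thetaPriorPrec[j] = 1.0 / gammaPriorVar;
  for (int j = 0; j < p; ++j) thetaPriorPrec[L.lnpi[j]] = 1.0 / lnpiPriorVar;
  mat S0 = diagmat(iwS0diag);
  double nu0 = iwDf;

  mat gammaDraws(niter, d), OmegaDraws(niter, d * d);
  mat BDraws(niter, std::max(d * q, 1));
  cube personDraws;
  if (storePerson) personDraws.set_size(d, n, niter);
  vec nonstatCount(niter, fill::zeros);

  CondBlock cMS, cPHI;
  std::vector<CondBlock> cLNPI(p);

  for (int iter = 0; iter < nburn + niter; ++iter) {
    bool burn = iter < nburn;
    // per-sweep conditional-prior pieces (depend on Omega only)
    cMS.compute(Omega, L.ms, d);
    cPHI.compute(Omega, L.phi, d);
    for (int j = 0; j < p; ++j)
      cLNPI[j].compute(Omega, uvec{L.lnpi[j]}, d);
    mat M = repmat(gamma, 1, n);
    if (q > 0) M += B * X;

    int sweepNonstat = 0;
    for (int i = 0; i < n; ++i) {
      vec mi = M.col(i);
      vec mu = eta(L.mu, uvec{(unsigned int)i});
      vec s = trend ? vec(eta(L.slope, uvec{(unsigned int)i}))
                    : vec(p, fill::zeros);
      mat Phi(p, p);
      for (int j = 0; j < p; ++j)
        for (int k = 0; k < p; ++k) Phi(j, k) = eta(L.phi[j * p + k], i);
      vec pivec(p);
      for (int j = 0; j < p; ++j) pivec[j] = std::exp(eta(L.lnpi[j], i));
      vec pinv = 1.0 / pivec;
      mat P = diagmat(pinv);

      // deviations, col 0 = latent pre-study deviation
      mat devs(p, T + 1);
      devs.col(0) = y0.col(i);
      for (int t = 1; t <= T; ++t)
        devs.col(t) = Y.slice(i).col(t - 1) - mu - s * cvec[t];

      // (1) impute missing weeks in deviation space
      for (int w : missW[i]) {
        mat Q;
        vec bv;
        if (w < T) {
          Q = P + Phi.t() * P * Phi;
          bv = P * (Phi * devs.col(w - 1)) + Phi.t() * (P * devs.col(w + 1));
        } else {
          Q = P;
          bv = P * (Phi * devs.col(w - 1));
        }
        std::vector<unsigned int> mIdx, oIdx;
        for (int j = 0; j < p; ++j)
          (missMask(j, w - 1, i) > 0 ? mIdx : oIdx).push_back(j);
        uvec mm(mIdx);
        vec pot = bv(mm);
        if (!oIdx.empty()) {
          uvec oo(oIdx);
          pot -= Q.submat(mm, uvec(oIdx)) * devs.submat(oo, uvec{(unsigned int)w});
        }
        vec newdev = draw_mvn_prec(pot, mat(Q.submat(mm, mm)));
        for (size_t a = 0; a < mIdx.size(); ++a) {
          int j = mIdx[a];
          devs(j, w) = newdev[a];
          Y(j, w - 1, i) = newdev[a] + mu[j] + s[j] * cvec[w];
        }
      }

      // (2) latent initial deviation from its full conditional
      mat Sig;
      stat_cov(Phi, pivec, Sig);
      mat Prec0 = inv_sympd(symmatu(Sig)) + Phi.t() * P * Phi;
      vec rhs0 = Phi.t() * (P * devs.col(1));
      vec y0new = draw_mvn_prec(rhs0, Prec0);
      y0.col(i) = y0new;
      devs.col(0) = y0new;

      // (3) conjugate joint update of (mu, slope); the per-week design
      // [I - Phi, c_t I - c_{t-1} Phi] is accumulated in closed form using
      // the precomputed sums over the week-centring weights
      {
        int pb = L.ms.n_elem;
        mat XtPX(pb, pb, fill::zeros);
        vec XtPr(pb, fill::zeros);
        mat D = eye(p, p) - Phi;
        mat PD = D.each_col() % pinv;
        mat PPhi = Phi.each_col() % pinv;
        // residual sums over weeks 2..T: r_t = Y_t - Phi Y_{t-1}
        vec sY(p, fill::zeros), sY1(p, fill::zeros);
        vec sCY(p, fill::zeros), sCY1(p, fill::zeros);
        vec sC1Y(p, fill::zeros), sC1Y1(p, fill::zeros);
        for (int t = 2; t <= T; ++t) {
          vec yt = Y.slice(i).col(t - 1), y1 = Y.slice(i).col(t - 2);
          sY += yt;  sY1 += y1;
          sCY += cvec[t] * yt;  sCY1 += cvec[t] * y1;
          sC1Y += cvec[t - 1] * yt;  sC1Y1 += cvec[t - 1] * y1;
        }
        vec sR = sY - Phi * sY1;
        vec r1 = Y.slice(i).col(0) - Phi * devs.col(0);
        XtPX.submat(0, 0, p - 1, p - 1) = P + cs.n2 * D.t() * PD;
        XtPr.head(p) = pinv % r1 + D.t() * (pinv % sR);
        if (trend) {
          vec sCR = sCY - Phi * sCY1;
          vec sC1R = sC1Y - Phi * sC1Y1;
          mat ms = cvec[1] * P + cs.sC * D.t() * P - cs.sC1 * D.t() * PPhi;
          XtPX.submat(0, p, p - 1, 2 * p - 1) = ms;
          XtPX.submat(p, 0, 2 * p - 1, p - 1) = ms.t();
          XtPX.submat(p, p, 2 * p - 1, 2 * p - 1) =
            (cvec[1] * cvec[1] + cs.sCC) * P -
            cs.sCC1 * (PPhi + PPhi.t()) + cs.sC11 * Phi.t() * PPhi;
          XtPr.tail(p) = cvec[1] * (pinv % r1) + pinv % sCR -
            Phi.t() * (pinv % sC1R);
        }
        vec mprior = cMS.condMean(mi, eta.col(i));
        vec msNew = draw_mvn_prec(cMS.Prec * mprior + XtPr,
                                  mat(cMS.Prec + XtPX));
        eta(L.ms, uvec{(unsigned int)i}) = msNew;
        mu = msNew.head(p);
        if (trend) s = msNew.tail(p);
        for (int t = 1; t <= T; ++t)
          devs.col(t) = Y.slice(i).col(t - 1) - mu - s * cvec[t];
      }

      // (4) conjugate proposal for the lag block, Metropolis-corrected for
      // the initial-condition prior; non-stationary proposals are discarded
      {
        mat W = devs.cols(0, T - 1);
        mat Z = devs.cols(1, T);
        mat XtX = W * W.t();
        int p2 = p * p;
        mat lik(p2, p2, fill::zeros);
        vec rhs(p2);
        for (int j = 0; j < p; ++j) {
          lik.submat(j * p, j * p, j * p + p - 1, j * p + p - 1) =
            XtX * pinv[j];
          rhs.subvec(j * p, j * p + p - 1) = (W * Z.row(j).t()) * pinv[j];
        }
        vec mprior = cPHI.condMean(mi, eta.col(i));
        vec fNew = draw_mvn_prec(cPHI.Prec * mprior + rhs,
                                 mat(cPHI.Prec + lik));
        mat PhiNew(p, p);
        for (int j = 0; j < p; ++j)
          for (int k = 0; k < p; ++k) PhiNew(j, k) = fNew[j * p + k];
        ++phiTries;
        mat SigNew;
        if (!stat_cov(PhiNew, pivec, SigNew)) {
          ++phiReject;
          ++sweepNonstat;
        } else {
          double la = ldmvnorm0(devs.col(0), SigNew) -
                      ldmvnorm0(devs.col(0), Sig);
          if (std::log(R::runif(0.0, 1.0)) < la) {
            Phi = PhiNew;
            Sig = SigNew;
            for (int j = 0; j < p2; ++j) eta(L.phi[j], i) = fNew[j];
            ++phiMhAcc;
          }
        }
      }

      // (5) adaptive random-walk Metropolis on each log innovation variance
      {
        mat W = devs.cols(0, T - 1);
        mat E = devs.cols(1, T) - Phi * W;
        for (int j = 0; j < p; ++j) {
          double cur = eta(L.lnpi[j], i);
          double sse = dot(E.row(j), E.row(j));
          double prop = cur + std::exp(lsig(j, i)) * rnorm1();
          vec mpr = cLNPI[j].condMean(mi, eta.col(i));
          double cprec = cLNPI[j].Prec(0, 0);
          vec piProp = pivec;
          piProp[j] = std::exp(prop);
          mat SigProp;
          double la = -datum::inf;
          if (stat_cov(Phi, piProp, SigProp)) {
            double llCur = -0.5 * T * cur - 0.5 * sse / pivec[j] -
                           0.5 * cprec * std::pow(cur - mpr[0], 2) +
                           ldmvnorm0(devs.col(0), Sig);
            double llProp = -0.5 * T * prop - 0.5 * sse / piProp[j] -
                            0.5 * cprec * std::pow(prop - mpr[0], 2) +
                            ldmvnorm0(devs.col(0), SigProp);
            la = llProp - llCur;
          }
          bool acc = std::log(R::runif(0.0, 1.0)) < la;
          if (acc) {
            eta(L.lnpi[j], i) = prop;
            pivec[j] = std::exp(prop);
            pinv[j] = 1.0 / pivec[j];
            P(j, j) = pinv[j];
            Sig = SigProp;
          }
          if (burn) {
            double step = std::pow(iter + 1.0, -0.6);
            lsig(j, i) += step * ((acc ? 1.0 : 0.0) - 0.35);
          } else {
            attN(j, i) += 1.0;
            if (acc) accN(j, i) += 1.0;
          }
        }
      }
    }

    // (6) joint conjugate update of theta = [gamma, B]
    {
      mat Wm(m, n);
      Wm.row(0).ones();
      if (q > 0) Wm.rows(1, m - 1) = X;
      mat Oinv = inv_sympd(symmatu(Omega));
      mat Prec = kron(Wm * Wm.t(), Oinv);
      Prec.diag() += thetaPriorPrec;
      vec rhs = vectorise(Oinv * eta * Wm.t());
      vec th = draw_mvn_prec(rhs, Prec);
      mat theta = reshape(th, d, m);
      gamma = theta.col(0);
      if (q > 0) B = theta.cols(1, m - 1);
    }

    // (7) conjugate inverse-Wishart update of Omega
    {
      mat U = eta - repmat(gamma, 1, n);
      if (q > 0) U -= B * X;
      Omega = draw_invwish(S0 + U * U.t(), nu0 + n);
    }

    if (!burn) {
      int it = iter - nburn;
      gammaDraws.row(it) = gamma.t();
      OmegaDraws.row(it) = vectorise(Omega).t();
      if (q > 0) BDraws.row(it) = vectorise(B).t();
      if (storePerson) personDraws.slice(it) = eta;
      nonstatCount[it] = sweepNonstat;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  double lnpiAcc = attN.max() > 0 ? accu(accN) / accu(attN) : NA_REAL;
  return Rcpp::List::create(
    Rcpp::Named("gamma") = gammaDraws,
    Rcpp::Named("B") = BDraws,
    Rcpp::Named("Omega") = OmegaDraws,
    Rcpp::Named("person") = personDraws,
    Rcpp::Named("nonstat") = nonstatCount,
    Rcpp::Named("acceptLnpi") = lnpiAcc,
    Rcpp::Named("phiRejectRate") = phiTries ? (double)phiReject / phiTries : 0.0,
    Rcpp::Named("phiAcceptRate") = phiTries ? (double)phiMhAcc / phiTries : 0.0);
}

// Per-draw average individually standardised lag matrices from stored
// person-level draws. Returns one row per draw with the p*p averaged
// standardised coefficients (row-major) plus the count of person-draws
// excluded as non-stationary.
// [[Rcpp::export]]
Rcpp::List avg_std_draws(const arma::cube& person, int p, bool trend) {
  int n = person.n_cols, niter = person.n_slices;
  Layout L(p, trend);
  mat out(niter, p * p, fill::zeros);
  ivec excl(niter, fill::zeros);
  for (int it = 0; it < niter; ++it) {
    mat acc(p, p, fill::zeros);
    int used = 0;
    for (int i = 0; i < n; ++i) {
      mat Phi(p, p);
      for (int j = 0; j < p; ++j)
        for (int k = 0; k < p; ++k) Phi(j, k) = person(L.phi[j * p + k], i, it);
      vec pivec(p);
      for (int j = 0; j < p; ++j)
        pivec[j] = std::exp(person(L.lnpi[j], i, it));
      mat S;
      if (!stat_cov(Phi, pivec, S)) {
        excl[it] += 1;
        continue;
      }
      vec sdv = sqrt(S.diag());
      for (int j = 0; j < p; ++j)
        for (int k = 0; k < p; ++k)
          acc(j, k) += Phi(j, k) * sdv[k] / sdv[j];
      ++used;
    }
    if (used > 0) out.row(it) = vectorise(acc.t() / used).t();
  }
  return Rcpp::List::create(Rcpp::Named("draws") = out,
                            Rcpp::Named("excluded") = excl);
}
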