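// Blocked Gibbs sampler for the linear growth curve model with
// Dirichlet-process-mixture (truncated stick-breaking) measurement errors.
//
// Model:  y_i = Lambda b_i + e_i,  b_i = beta + u_i,  u_i ~ N(0, Psi),
//         e_i | z_i ~ N(0, Phi^(z_i)),  P(z_i = j) = p_j,
//         p from sticks q_j ~ Beta(1, alpha), j < C, q_C = 1,
//         beta ~ N(0, beta_var I),  Psi ~ IW(psi_df, psi_scale),
//         alpha ~ Gamma(a1, a2).
//
// Two base-measure structures for the component covariances:
//   isotropic: Phi^(j) = phi_j I,  phi_j ~ IG(n0/2, w0/2),
//              w0 ~ Gamma(w_df/2, 1/(2 w_scale))      [identified]
//   full:      Phi^(j) ~ IW(n0, W0),  W0 ~ Wishart(w_df, w_scale)
//
// All randomness goes through R's RNG so set.seed() governs every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int jitter_events = 0;

// Cholesky (lower) with escalating diagonal jitter; throws after 8 tries.
static arma::mat safe_chol_lower(const arma::mat& S) {
  arma::mat L;
  arma::mat A = arma::symmatu(S);
  double scale = arma::trace(A) / A.n_rows;
  if (!(scale > 0)) scale = 1.0;
  double jit = 0.0;
  for (int k = 0; k < 8; ++k) {
    if (arma::chol(L, A + jit * arma::eye(A.n_rows, A.n_cols), "lower")) {
      if (k > 0) ++jitter_events;
      return L;
    }
    jit = (jit == 0.0) ? 1e-8 * scale : jit * 10.0;
  }
  throw std::runtime_error("Cholesky failed despite jitter");
}

static arma::mat inv_from_chol(const arma::mat& L) {
  arma::mat Linv = arma::inv(arma::trimatl(L));
  return Linv.t() * Linv;
}

static arma::mat safe_inv_sympd(const arma::mat& S) {
  return inv_from_chol(safe_chol_lower(S));
}

// Wishart(df, scale) via the Bartlett decomposition.
static arma::mat rwishart(double df, const arma::mat& scale) {
  const int p = scale.n_rows;
  arma::mat L = safe_chol_lower(scale);
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(Rf_rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverse-Wishart(df, scale): inverse of Wishart(df, scale^{-1}).
static arma::mat rinvwishart(double df, const arma::mat& scale) {
  return safe_inv_sympd(rwishart(df, safe_inv_sympd(scale)));
}

// Inverse-gamma(shape, rate) draw.
static double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

static arma::vec rmvnorm_chol(const arma::vec& mean, const arma::mat& L) {
  arma::vec z(mean.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mean + L * z;
}

struct ChainState {
  arma::vec beta;
  arma::mat B;        // N x q subject effects
  arma::mat Psi;
  arma::cube Phi;     // T x T x C (full structure)
  arma::vec phis;     // C       (isotropic structure)
  arma::mat W0;       // T x T (full) or 1 x 1 (isotropic scalar w0)
  arma::ivec z;
  arma::vec q, p;
  double alpha;
};

struct Priors {
  double a1, a2, n0, w_df, beta_var, psi_df;
  arma::mat w_scale, w_scale_inv, psi_scale;
  int alpha_update;   // 0 stick-conjugate, 1 Escobar-West augmentation
  bool iso;
};

// One full Gibbs sweep over all blocks; state is modified in place.
static void gibbs_sweep(const arma::mat& Y, const arma::mat& Lambda,
                        ChainState& st, const Priors& pr) {
  const int N = Y.n_rows;
  const int T = Lambda.n_rows;
  const int qdim = Lambda.n_cols;
  const int C = pr.iso ? st.phis.n_elem : st.Phi.n_slices;

  arma::mat Psi_inv = safe_inv_sympd(st.Psi);
  arma::mat LtL = Lambda.t() * Lambda;

  // --- subject effects b_i | z_i, beta, Psi, Phi ---------------------
  if (N > 0) {
    arma::ivec nj(C, arma::fill::zeros);
    for (int i = 0; i < N; ++i) nj(st.z(i))++;
    std::vector<arma::mat> Vj(C), Lvj(C), Bmatj(C);
    for (int j = 0; j < C; ++j) {
      if (nj(j) == 0) continue;
      arma::mat A;
      if (pr.iso) {
        Bmatj[j] = Lambda.t() / st.phis(j);
        A = LtL / st.phis(j);
      } else {
        arma::mat Phi_inv = safe_inv_sympd(st.Phi.slice(j));
        Bmatj[j] = Lambda.t() * Phi_inv;
        A = Bmatj[j] * Lambda;
      }
      Vj[j] = safe_inv_sympd(A + Psi_inv);
      Lvj[j] = safe_chol_lower(Vj[j]);
    }
    arma::vec prior_part = Psi_inv * st.beta;
    for (int i = 0; i < N; ++i) {
      int j = st.z(i);
      arma::vec m = Vj[j] * (Bmatj[j] * Y.row(i).t() + prior_part);
      st.B.row(i) = rmvnorm_chol(m, Lvj[j]).t();
    }
  }

  // --- fixed effects beta | {b_i}, Psi -------------------------------
  {
    arma::mat prec = (1.0 / pr.beta_var) * arma::eye(qdim, qdim);
    arma::vec lin(qdim, arma::fill::zeros);
    if (N > 0) {
      prec += N * Psi_inv;
      lin = Psi_inv * arma::sum(st.B, 0).t();
    }
    arma::mat V = safe_inv_sympd(prec);
    st.beta = rmvnorm_chol(V * lin, safe_chol_lower(V));
  }

  // --- random-effect covariance Psi | {u_i} --------------------------
  {
    arma::mat S = pr.psi_scale;
    if (N > 0) {
      arma::mat U = st.B.each_row() - st.beta.t();
      S += U.t() * U;
    }
    st.Psi = rinvwishart(pr.psi_df + N, S);
  }

  // --- allocations z_i | p, {Phi}, residuals -------------------------
  arma::mat E;
  arma::ivec nj(C, arma::fill::zeros);
  if (N > 0) {
    E = Y - st.B * Lambda.t();                    // N x T residuals
    arma::mat loglik(N, C);
    arma::vec ss;
    if (pr.iso) ss = arma::sum(E % E, 1);
    for (int j = 0; j < C; ++j) {
      double lp = (st.p(j) > 0) ? std::log(st.p(j)) :
        -std::numeric_limits<double>::infinity();
      if (pr.iso) {
        loglik.col(j) = lp - 0.5 * T * std::log(st.phis(j)) -
          0.5 * ss / st.phis(j);
      } else {
        arma::mat L = safe_chol_lower(st.Phi.slice(j));
        double logdet = 2.0 * arma::sum(arma::log(L.diag()));
        arma::mat X = arma::solve(arma::trimatl(L), E.t());  // T x N
        arma::rowvec quad = arma::sum(X % X, 0);
        loglik.col(j) = lp - 0.5 * logdet - 0.5 * quad.t();
      }
    }
    for (int i = 0; i < N; ++i) {
      arma::rowvec ll = loglik.row(i);
      double m = ll.max();
      arma::rowvec w = arma::exp(ll - m);         // log-space renormalization
      double tot = arma::accu(w);
      double u = unif_rand() * tot;
      double cum = 0.0;
      int pick = C - 1;
      for (int j = 0; j < C; ++j) {
        cum += w(j);
        if (u <= cum) { pick = j; break; }
      }
      st.z(i) = pick;
      nj(pick)++;
    }
  }

  // --- component covariances and base scale --------------------------
  if (pr.iso) {
    double w0 = st.W0(0, 0);
    arma::vec ssr(C, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      ssr(st.z(i)) += arma::dot(E.row(i), E.row(i));
    }
    double inv_sum = 0.0;
    for (int j = 0; j < C; ++j) {
      st.phis(j) = rinvgamma(0.5 * pr.n0 + 0.5 * nj(j) * T,
                             0.5 * w0 + 0.5 * ssr(j));
      inv_sum += 1.0 / st.phis(j);
    }
    // w0 | {phi_j}: conjugate gamma (prior Gamma(w_df/2, 1/(2 w_scale)))
    double hs = 0.5 * pr.w_df + 0.5 * C * pr.n0;
    double hr = 1.0 / (2.0 * pr.w_scale(0, 0)) + 0.5 * inv_sum;
    st.W0(0, 0) = R::rgamma(hs, 1.0 / hr);
  } else {
    arma::mat sumPhiInv(T, T, arma::fill::zeros);
    std::vector<arma::mat> Sj(C);
    for (int j = 0; j < C; ++j) Sj[j] = st.W0;
    for (int i = 0; i < N; ++i) {
      Sj[st.z(i)] += E.row(i).t() * E.row(i);
    }
    for (int j = 0; j < C; ++j) {
      st.Phi.slice(j) = rinvwishart(pr.n0 + nj(j), Sj[j]);
      sumPhiInv += safe_inv_sympd(st.Phi.slice(j));
    }
    // W0 | {Phi^(j)}: conjugate Wishart update
    st.W0 = rwishart(pr.w_df + C * pr.n0,
                     safe_inv_sympd(pr.w_scale_inv + sumPhiInv));
  }

  // --- sticks q | allocations, alpha; weights by stick-breaking ------
  {
    int tail = 0;
    for (int j = 0; j < C; ++j) tail += nj(j);
    double remain = 1.0;
    for (int j = 0; j < C; ++j) {
      tail -= nj(j);                               // subjects beyond j
      double qj;
      if (j < C - 1) {
        qj = R::rbeta(1.0 + nj(j), st.alpha + tail);
        if (qj < 1e-300) qj = 1e-300;
        if (qj > 1.0 - 1e-12) qj = 1.0 - 1e-12;
      } else {
        qj = 1.0;                                  // final stick closes off
      }
      st.q(j) = qj;
      st.p(j) = qj * remain;
      remain *= (1.0 - qj);
    }
  }

  // --- precision parameter alpha -------------------------------------
  if (pr.alpha_update == 1 && N > 0) {
    // Escobar-West augmentation using the occupied-cluster count
    int K = 0;
    for (int j = 0; j < C; ++j) if (nj(j) > 0) ++K;
    double x = R::rbeta(st.alpha + 1.0, (double) N);
    double rate = pr.a2 - std::log(x);
    double odds = (pr.a1 + K - 1.0) / (N * rate);
    double shape = (unif_rand() < odds / (1.0 + odds)) ? pr.a1 + K
                                                       : pr.a1 + K - 1.0;
    st.alpha = R::rgamma(shape, 1.0 / rate);
  } else {
    // conjugate update under the truncated stick-breaking likelihood
    double s = 0.0;
    for (int j = 0; j < C - 1; ++j) s += std::log1p(-st.q(j));
    st.alpha = R::rgamma(pr.a1 + C - 1.0, 1.0 / (pr.a2 - s));
  }
  if (st.alpha < 1e-300) st.alpha = 1e-300;
}

// [[Rcpp::export]]
List gibbs_bnp_gcm_cpp(const arma::mat& Y, const arma::mat& Lambda,
                       arma::vec beta, arma::mat B, arma::mat Psi,
                       arma::cube Phi, arma::vec phis, arma::mat W0,
                       arma::ivec z, double alpha,
                       double a1, double a2, double n0,
                       double w_df, const arma::mat& w_scale,
                       double beta_var, double psi_df,
                       const arma::mat& psi_scale,
                       int n_iter, int burn_in, int alpha_update,
                       bool isotropic, int truncation, int thin = 1) {
  const int C = truncation;
  const int N = Y.n_rows;
  const int T = Lambda.n_rows;
  jitter_events = 0;

  ChainState st;
  st.beta = beta; st.B = B; st.Psi = Psi; st.Phi = Phi; st.phis = phis;
  st.W0 = W0; st.z = z; st.alpha = alpha;
  st.q.set_size(C); st.p.set_size(C);
  st.q.fill(0.5); st.q(C - 1) = 1.0;
  {
    double remain = 1.0;
    for (int j = 0; j < C; ++j) {
      st.p(j) = st.q(j) * remain;
      remain *= 1 - st.q(j);
    }
  }

  Priors pr;
  pr.a1 = a1; pr.a2 = a2; pr.n0 = n0; pr.w_df = w_df;
  pr.beta_var = beta_var; pr.psi_df = psi_df;
  pr.w_scale = w_scale; pr.psi_scale = psi_scale;
  pr.w_scale_inv = isotropic ? w_scale : safe_inv_sympd(w_scale);
  pr.alpha_update = alpha_update;
  pr.iso = isotropic;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat draws(n_keep, 8);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    bool ok = false;
    for (int attempt = 0; attempt < 2 && !ok; ++attempt) {
      try {
        gibbs_sweep(Y, Lambda, st, pr);
        ok = true;
      } catch (const std::exception& e) {
        if (attempt == 1) {
          stop("Gibbs iteration %d failed twice: %s", it, e.what());
        }
      }
    }
    if (it > burn_in && (it - burn_in - 1) % thin == 0) {
      int K = 0;
      arma::ivec nj(C, arma::fill::zeros);
      for (int i = 0; i < N; ++i) nj(st.z(i))++;
      for (int j = 0; j < C; ++j) if (nj(j) > 0) ++K;
      double s2e = 0.0;
      for (int j = 0; j < C; ++j) {
        s2e += st.p(j) * (isotropic ? st.phis(j)
                                    : arma::trace(st.Phi.slice(j)) / T);
      }
      draws(kept, 0) = st.beta(0);
      draws(kept, 1) = st.beta.n_elem > 1 ? st.beta(1) : NA_REAL;
      draws(kept, 2) = st.Psi(0, 0);
      draws(kept, 3) = st.Psi.n_rows > 1 ? st.Psi(1, 1) : NA_REAL;
      draws(kept, 4) = st.Psi.n_rows > 1 ? st.Psi(0, 1) : NA_REAL;
      draws(kept, 5) = s2e;
      draws(kept, 6) = st.alpha;
      draws(kept, 7) = K;
      ++kept;
    }
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws.rows(0, kept - 1),
    _["n_jitter"] = jitter_events,
    _["final"] = List::create(
      _["beta"] = st.beta, _["psi"] = st.Psi, _["alpha"] = st.alpha,
      _["allocations"] = st.z + 1, _["weights"] = st.p,
      _["W0"] = st.W0,
      _["phi"] = isotropic ? wrap(st.phis) : wrap(st.Phi))
  );
}
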