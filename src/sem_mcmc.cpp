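// Metropolis-Hastings-within-Gibbs core for the recursive SEM / MTM
// sire-herd-permanent-environment mixed model.
//
// Model (per record i, T traits):
//   (I - Lambda) y_i = B' x_i + h_{herd(i)} + p_{cow(i)} + s_{sire(i)} + e_i
//   e_i ~ N(0, R); R diagonal when the structure has edges (SEM), full
//   inverse-Wishart otherwise (MTM). s ~ N(0, G (x) A), p ~ N(0, P (x) I),
//   h ~ N(0, H (x) I). Structural coefficients get independent N(lambda0,
//   tau2) priors and are updated by scalar random-walk MH on the reduced
//   residuals; det(I - Lambda) = 1 for acyclic structures so no Jacobian
//   enters the ratio.
//
// All randomness comes from R's RNG (R::*), so chains are bit-reproducible
// under set.seed().

#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec mvn_from_precision(const mat& Prec, const vec& lin) {
  // draw from N(Prec^{-1} lin, Prec^{-1}) via Cholesky of the precision
  mat U = chol(Prec); // upper: Prec = U' U
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), lin));
  vec z(lin.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + solve(trimatu(U), z);
}

static mat rinvwishart(double df, const mat& S) {
  // X ~ Wishart(df, S^{-1}) by Bartlett; return X^{-1}
  const uword d = S.n_rows;
  mat L = chol(inv_sympd(symmatu(S)), "lower");
  mat A(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  mat W = LA * LA.t();
  return inv_sympd(symmatu(W));
}

// Gibbs update for an i.i.d.-prior random-effect block (herd or cow PE):
// effect_j | rest ~ N((n_j Rinv + Cinv)^{-1} Rinv sum_d_j, (n_j Rinv + Cinv)^{-1})
static void iid_level_update(mat& Eff, const mat& D, const uvec& level,
                             const std::vector<std::vector<uword>>& rows,
                             const mat& Rinv, const mat& Cinv) {
  const uword nl = rows.size(), T = Eff.n_cols, n = D.n_rows;
  mat SumD(nl, T, fill::zeros);
  for (uword i = 0; i < n; ++i) SumD.row(level(i)) += D.row(i);
  std::map<uword, std::vector<uword>> by_count;
  for (uword j = 0; j < nl; ++j) by_count[rows[j].size()].push_back(j);
  for (const auto& grp : by_count) {
    mat Prec = (double)grp.first * Rinv + Cinv;
    mat Cov = inv_sympd(symmatu(Prec));
    mat Lc = chol(Cov, "lower");
    mat MeanMap = (Cov * Rinv).t(); // sum_d -> conditional mean (row form)
    for (uword j : grp.second) {
      rowvec z(T);
      for (uword t = 0; t < T; ++t) z(t) = R::norm_rand();
      Eff.row(j) = SumD.row(j) * MeanMap + z * Lc.t();
    }
  }
}

// [[Rcpp::export]]
Rcpp::List sem_mcmc_cpp(const arma::mat& Y, const arma::mat& X,
                        const arma::uvec& herd, const arma::uvec& cow,
                        const arma::uvec& sire,
                        bool use_herd, bool use_cow, bool use_sire,
                        const arma::mat& Ainv,
                        const arma::umat& edges, // E x 2: (to, from) 0-based
                        double nu, const arma::mat& Sg, const arma::mat& Sp,
                        const arma::mat& Sh, const arma::mat& Sr,
                        const arma::vec& r_scale, // per-trait invChisq scale
                        double tau2, double lambda0, double b_var,
                        arma::vec lambda, arma::vec step,
                        int n_iter, int burn_in, int thin,
                        int adapt_every, double target_accept,
                        bool verbose) {
  const uword n = Y.n_rows, T = Y.n_cols, p = X.n_cols;
  const uword E = edges.n_rows;
  const bool r_diag = E > 0;
  const uword nh = use_herd ? herd.max() + 1 : 0;
  const uword nc = use_cow ? cow.max() + 1 : 0;
  const uword m = use_sire ? Ainv.n_rows : 0;

  // record groups per level
  std::vector<std::vector<uword>> herd_rows(nh), cow_rows(nc), sire_rows(m);
  if (use_herd) for (uword i = 0; i < n; ++i) herd_rows[herd(i)].push_back(i);
  if (use_cow)  for (uword i = 0; i < n; ++i) cow_rows[cow(i)].push_back(i);
  if (use_sire) for (uword i = 0; i < n; ++i) sire_rows[sire(i)].push_back(i);

  const mat XtX = X.t() * X;

  // state
  mat B(p, T, fill::zeros);
  mat Hmat(std::max(nh, (uword)1), T, fill::zeros);
  mat Pmat(std::max(nc, (uword)1), T, fill::zeros);
  mat Smat(std::max(m, (uword)1), T, fill::zeros);
  mat G = Sg / std::max(nu - T - 1.0, 1.0);
  mat Pc = Sp / std::max(nu - T - 1.0, 1.0);
  mat Hc = Sh / std::max(nu - T - 1.0, 1.0);
  mat R;
  if (r_diag) R = diagmat(r_scale / std::max(nu - 2.0, 1.0));
  else        R = Sr / std::max(nu - T - 1.0, 1.0);

  // structural scale responses
  mat Ystar = Y;
  for (uword e = 0; e < E; ++e)
    Ystar.col(edges(e, 0)) -= lambda(e) * Y.col(edges(e, 1));

  const int n_store = (n_iter - burn_in) / thin;
  mat B_draws(n_store, p * T);
  mat G_draws(n_store, T * T), P_draws(n_store, T * T),
      H_draws(n_store, T * T), R_draws(n_store, T * T);
  mat L_draws(n_store, std::max(E, (uword)1), fill::zeros);
  vec acc_post(std::max(E, (uword)1), fill::zeros);
  vec acc_batch(std::max(E, (uword)1), fill::zeros);
  int batch_count = 0, post_count = 0;
  mat H_mean(Hmat.n_rows, T, fill::zeros), P_mean(Pmat.n_rows, T, fill::zeros),
      S_mean(Smat.n_rows, T, fill::zeros);

  mat Hpart(n, T, fill::zeros), Ppart(n, T, fill::zeros),
      Spart(n, T, fill::zeros);

  int stored = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    mat Rinv = r_diag ? mat(diagmat(1.0 / R.diag()))
                      : mat(inv_sympd(symmatu(R)));

    if (use_herd) Hpart = Hmat.rows(herd);
    if (use_cow)  Ppart = Pmat.rows(cow);
    if (use_sire) Spart = Smat.rows(sire);

    // ---- fixed effects -------------------------------------------------
    {
      mat D = Ystar - Hpart - Ppart - Spart;
      mat Prec = kron(Rinv, XtX);
      Prec.diag() += 1.0 / b_var;
      vec lin = vectorise(X.t() * D * Rinv);
      vec beta = mvn_from_precision(Prec, lin);
      B = reshape(beta, p, T);
    }
    mat XB = X * B;

    // ---- herd effects --------------------------------------------------
    // Levels are exchangeable given their record count, so the conditional
    // precision n_j * Rinv + Hinv is shared within count groups; factor it
    // once per group and draw all levels of the group together.
    if (use_herd) {
      mat D = Ystar - XB - Ppart - Spart;
      iid_level_update(Hmat, D, herd, herd_rows, Rinv,
                       inv_sympd(symmatu(Hc)));
      Hpart = Hmat.rows(herd);
    }

    // ---- cow permanent environment ------------------------------------
    if (use_cow) {
      mat D = Ystar - XB - Hpart - Spart;
      iid_level_update(Pmat, D, cow, cow_rows, Rinv,
                       inv_sympd(symmatu(Pc)));
      Ppart = Pmat.rows(cow);
    }

    // ---- sire effects (single-site, shrunk through G^{-1} (x) A^{-1}) --
    if (use_sire) {
      mat D = Ystar - XB - Hpart - Ppart;
      mat Rsum(m, T, fill::zeros);
      for (uword i = 0; i < n; ++i) Rsum.row(sire(i)) += D.row(i);
      mat Ginv = inv_sympd(symmatu(G));
      for (uword q = 0; q < m; ++q) {
        rowvec aS = Ainv.row(q) * Smat; // 1 x T
        vec prior_lin = Ginv * (aS.t() - Ainv(q, q) * Smat.row(q).t());
        vec lin = Rinv * Rsum.row(q).t() - prior_lin;
        mat Prec = (double)sire_rows[q].size() * Rinv + Ainv(q, q) * Ginv;
        Smat.row(q) = mvn_from_precision(Prec, lin).t();
      }
      Spart = Smat.rows(sire);
    }

    // ---- covariance components ----------------------------------------
    if (use_sire) {
      mat Sc = Sg + Smat.t() * Ainv * Smat;
      G = rinvwishart(nu + (double)m, Sc);
    }
    if (use_cow)  Pc = rinvwishart(nu + (double)nc, Sp + Pmat.t() * Pmat);
    if (use_herd) Hc = rinvwishart(nu + (double)nh, Sh + Hmat.t() * Hmat);

    mat Emat = Ystar - XB - Hpart - Ppart - Spart;
    if (r_diag) {
      for (uword t = 0; t < T; ++t) {
        double sse = dot(Emat.col(t), Emat.col(t));
        R(t, t) = (r_scale(t) + sse) / R::rchisq(nu + (double)n);
      }
    } else {
      R = rinvwishart(nu + (double)n, Sr + Emat.t() * Emat);
    }

    // ---- structural coefficients (random-walk MH) ----------------------
    if (E > 0) {
      for (uword e = 0; e < E; ++e) {
        const uword t = edges(e, 0), x = edges(e, 1);
        const double prop = lambda(e) + step(e) * R::norm_rand();
        const double delta = prop - lambda(e);
        vec e_new = Emat.col(t) - delta * Y.col(x);
        const double sse_new = dot(e_new, e_new);
        const double sse_old = dot(Emat.col(t), Emat.col(t));
        double logr = -(sse_new - sse_old) / (2.0 * R(t, t))
          - ((prop - lambda0) * (prop - lambda0)
             - (lambda(e) - lambda0) * (lambda(e) - lambda0)) / (2.0 * tau2);
        if (std::log(unif_rand()) < logr) {
          lambda(e) = prop;
          Ystar.col(t) -= delta * Y.col(x);
          Emat.col(t) = e_new;
          acc_batch(e) += 1.0;
          if (iter > burn_in) acc_post(e) += 1.0;
        }
      }
      // Robbins-Monro step adaptation, burn-in only
      if (iter <= burn_in && (iter % adapt_every) == 0) {
        ++batch_count;
        const double gain = 1.0 / std::sqrt((double)batch_count);
        for (uword e = 0; e < E; ++e) {
          const double rate = acc_batch(e) / adapt_every;
          step(e) *= std::exp(gain * (rate - target_accept));
          step(e) = std::min(std::max(step(e), 1e-8), 1e3);
        }
        acc_batch.zeros();
      }
    }

    if (iter > burn_in) {
      ++post_count;
      if (use_herd) H_mean += Hmat;
      if (use_cow)  P_mean += Pmat;
      if (use_sire) S_mean += Smat;
      if ((iter - burn_in) % thin == 0 && stored < n_store) {
        B_draws.row(stored) = vectorise(B).t();
        G_draws.row(stored) = vectorise(G).t();
        P_draws.row(stored) = vectorise(Pc).t();
        H_draws.row(stored) = vectorise(Hc).t();
        R_draws.row(stored) = vectorise(R).t();
        if (E > 0) L_draws.row(stored) = lambda.t();
        ++stored;
      }
    }
    if (verbose && (iter % 1000) == 0) {
      Rcpp::Rcout << "iteration " << iter << "/" << n_iter;
      if (E > 0)
        Rcpp::Rcout << "  lambda[0] = " << lambda(0)
                    << "  step[0] = " << step(0);
      Rcpp::Rcout << std::endl;
    }
    if ((iter % 200) == 0) Rcpp::checkUserInterrupt();
  }

  if (post_count > 0) {
    H_mean /= post_count; P_mean /= post_count; S_mean /= post_count;
  }
  return Rcpp::List::create(
    Rcpp::Named("B") = B_draws,
    Rcpp::Named("G") = G_draws,
    Rcpp::Named("P") = P_draws,
    Rcpp::Named("H") = H_draws,
    Rcpp::Named("R") = R_draws,
    Rcpp::Named("lambda") = L_draws,
    Rcpp::Named("n_stored") = stored,
    Rcpp::Named("accept_rate") = E > 0
      ? Rcpp::wrap(vec(acc_post / std::max(n_iter - burn_in, 1)))
      : Rcpp::wrap(vec()),
    Rcpp::Named("step_final") = step,
    Rcpp::Named("herd_mean") = H_mean,
    Rcpp::Named("cow_mean") = P_mean,
    Rcpp::Named("sire_mean") = S_mean
  );
}
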