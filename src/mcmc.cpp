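// MCMC engine for the grid-based Bayesian mixed model.
//
// Model: y_ij = mu + x_ij' beta + p_ij' Delta Psi b_i + e_ij,
// e ~ N(0, sigma2), b_i ~ N(0, I_k). Latent binary indicators select which
// candidate genetic effects (main / epistatic / SNP-covariate products) are
// active; their positions move over the SNP catalog by Metropolis-Hastings.
// All continuous blocks are conjugate Gibbs updates. Every random draw goes
// through R's RNG so that set.seed() makes chains bit-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Effect {
  int type;     // 0 main, 1 epistatic, 2 SNP-covariate
  int s1;       // SNP index (0-based)
  int s2;       // second SNP (epi) or covariate index (gt), else -1
  double beta;
  double sb2;   // prior scale s_beta2 for this term's slab variance
  double sigb2; // current slab variance sigma_beta2
  arma::vec col;
};

double rinvchisq(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

// exact half-line truncated normal via inverse CDF (lower bound 0)
double rtnorm_pos(double mean, double sd) {
  double plo = R::pnorm(0.0, mean, sd, 1, 0);
  if (plo >= 1.0 - 1e-15) return 0.0;
  double u = plo + R::unif_rand() * (1.0 - plo);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (!std::isfinite(x) || x < 0.0) x = 0.0;
  return x;
}

double col_var(const arma::vec& x) {
  double n = (double)x.n_elem;
  if (n < 2) return 0.0;
  double m = arma::mean(x);
  return arma::dot(x - m, x - m) / (n - 1.0);
}

} // namespace

// [[Rcpp::export]]
List mcmc_run(const arma::vec& y, const arma::ivec& subj,
              const arma::mat& A, const arma::mat& G, const arma::mat& Cov,
              const List& priors, const List& control, const List& init) {
  const int N = y.n_elem;
  const int k = A.n_cols;
  const int n = G.n_rows;
  const int p = G.n_cols;
  const int q = Cov.n_cols;
  const int npsi = k * (k - 1) / 2;

  // priors
  const arma::vec w = priors["w"];                 // (main, epi, gt)
  const double nu_beta = priors["nu_beta"];
  const double Eh = priors["expected_h"];
  const double V = priors["V"];
  const double eta0 = priors["eta0"];
  const double tau02 = priors["tau02"];
  const double nu_sigma = priors["nu_sigma"];
  const double s_sigma2 = priors["s_sigma2"];
  const double m_d0 = priors["m_delta0"];
  const double s_d02 = priors["s_delta02"];
  const double psi_prior_mean = priors["psi0"];
  const double psi_prior_var = priors["r0"];
  const double cov_beta_var = priors["cov_beta_var"];

  // control
  const int n_iter = control["n_iter"];
  const int burn_in = control["burn_in"];
  const int thin = control["thin"];
  const int mh_sweeps = control["mh_sweeps"];
  const arma::vec move_probs = control["move_probs"]; // add, drop, swap, refresh
  const int cap = control["effect_cap"];
  const bool upd_gamma = control["upd_gamma"];
  const bool upd_beta = control["upd_beta"];
  const bool upd_cov_beta = control["upd_cov_beta"];
  const bool upd_b = control["upd_b"];
  const bool upd_delta = control["upd_delta"];
  const bool upd_psi = control["upd_psi"];
  const bool upd_mu = control["upd_mu"];
  const bool upd_sigma2 = control["upd_sigma2"];
  const bool upd_sigma_beta2 = control["upd_sigma_beta2"];
  const double fix_sb2 = control["fix_sigma_beta2"]; // NaN if unset
  const bool store_b = control["store_b"];

  // state init
  double mu = init["mu"];
  double sigma2 = init["sigma2"];
  arma::vec delta = init["delta"];
  arma::vec psi = init["psi"];
  arma::mat b = as<arma::mat>(init["b"]); // n x k
  arma::vec cov_beta = as<arma::vec>(init["cov_beta"]);

  // subject row offsets (rows assumed sorted by subject)
  std::vector<int> off(n + 1, 0);
  for (int o = 0; o < N; ++o) off[subj[o] + 1]++;
  for (int i = 0; i < n; ++i) off[i + 1] += off[i];

  const double d_type[3] = {(double)p, (double)p * (p - 1) / 2.0, (double)p * q};
  arma::vec type_prob(3);
  for (int t = 0; t < 3; ++t) type_prob[t] = w[t] * d_type[t];
  double tp_sum = arma::accu(type_prob);
  if (tp_sum > 0) type_prob /= tp_sum;

  auto psi_mat = [&](const arma::vec& ps) {
    arma::mat P = arma::eye(k, k);
    int pos = 0;
    for (int m = 1; m < k; ++m)
      for (int l = 0; l < m; ++l) P(m, l) = ps[pos++];
    return P;
  };

  arma::mat Psi = psi_mat(psi);
  arma::mat Lm = arma::diagmat(delta) * Psi;
  arma::mat Z = A * Lm; // N x k

  auto term_col = [&](int type, int s1, int s2) {
    arma::vec out(N);
    if (type == 0) {
      for (int o = 0; o < N; ++o) out[o] = G(subj[o], s1);
    } else if (type == 1) {
      for (int o = 0; o < N; ++o) out[o] = G(subj[o], s1) * G(subj[o], s2);
    } else {
      for (int o = 0; o < N; ++o) out[o] = G(subj[o], s1) * Cov(o, s2);
    }
    return out;
  };

  std::vector<Effect> eff;
  {
    List act = init["active"];
    IntegerVector at = act["type"], a1 = act["snp1"], a2 = act["snp2"];
    NumericVector ab = act["beta"], av = act["sigb2"];
    for (int j = 0; j < at.size(); ++j) {
      Effect e;
      e.type = at[j]; e.s1 = a1[j] - 1; e.s2 = a2[j] == NA_INTEGER ? -1 : a2[j] - 1;
      e.beta = ab[j];
      e.col = term_col(e.type, e.s1, e.s2);
      double Va = col_var(e.col);
      e.sb2 = Va > 0 ? (nu_beta - 2.0) * Eh * V / (nu_beta * Va) : V;
      e.sigb2 = av[j];
      eff.push_back(e);
    }
  }

  // residual
  arma::vec re_part(N, arma::fill::zeros);
  for (int o = 0; o < N; ++o) re_part[o] = arma::dot(Z.row(o), b.row(subj[o]));
  arma::vec r = y - mu - Cov * cov_beta - re_part;
  for (size_t j = 0; j < eff.size(); ++j) r -= eff[j].beta * eff[j].col;

  auto refresh_re = [&]() {
    Psi = psi_mat(psi);
    Lm = arma::diagmat(delta) * Psi;
    Z = A * Lm;
  };

  auto same_term = [](const Effect& e, int type, int s1, int s2) {
    return e.type == type && e.s1 == s1 && e.s2 == s2;
  };
  auto find_term = [&](int type, int s1, int s2, int skip) {
    for (int j = 0; j < (int)eff.size(); ++j)
      if (j != skip && same_term(eff[j], type, s1, s2)) return j;
    return -1;
  };

  auto gibbs_beta_one = [&](Effect& e, double prior_var) {
    arma::vec ra = r + e.beta * e.col;
    double prec = arma::dot(e.col, e.col) / sigma2 + 1.0 / prior_var;
    double mean = (arma::dot(e.col, ra) / sigma2) / prec;
    e.beta = mean + R::norm_rand() / std::sqrt(prec);
    r = ra - e.beta * e.col;
  };

  auto mh_move = [&]() {
    double u = R::unif_rand();
    int m = (int)eff.size();
    if (u < move_probs[0]) { // add
      if (m >= cap || tp_sum <= 0) return;
      double ut = R::unif_rand();
      int type = ut < type_prob[0] ? 0 : (ut < type_prob[0] + type_prob[1] ? 1 : 2);
      int s1, s2 = -1;
      if (type == 0) {
        s1 = (int)(R::unif_rand() * p); if (s1 >= p) s1 = p - 1;
      } else if (type == 1) {
        if (p < 2) return;
        double idx = std::floor(R::unif_rand() * d_type[1]);
        int i = 0; double rem = idx;
        while (rem >= p - 1 - i) { rem -= p - 1 - i; ++i; }
        s1 = i; s2 = i + 1 + (int)rem;
      } else {
        s1 = (int)(R::unif_rand() * p); if (s1 >= p) s1 = p - 1;
        s2 = (int)(R::unif_rand() * q); if (s2 >= q) s2 = q - 1;
      }
      if (find_term(type, s1, s2, -1) >= 0) return;
      arma::vec col = term_col(type, s1, s2);
      double Va = col_var(col);
      if (Va <= 0) return;
      double sb2 = (nu_beta - 2.0) * Eh * V / (nu_beta * Va);
      double sigb2 = std::isnan(fix_sb2) ? rinvchisq(nu_beta, sb2) : fix_sb2;
      double beta = R::norm_rand() * std::sqrt(sigb2);
      arma::vec rn = r - beta * col;
      double dll = (arma::dot(r, r) - arma::dot(rn, rn)) / (2.0 * sigma2);
      double la = dll + std::log(w[type]) - std::log1p(-w[type]) +
        std::log(move_probs[1] / (m + 1.0)) -
        std::log(move_probs[0] * type_prob[type] / d_type[type]);
      if (std::log(R::unif_rand()) < la) {
        Effect e{type, s1, s2, beta, sb2, sigb2, col};
        eff.push_back(e);
        r = rn;
      }
    } else if (u < move_probs[0] + move_probs[1]) { // drop
      if (m == 0) return;
      int j = (int)(R::unif_rand() * m); if (j >= m) j = m - 1;
      const Effect& e = eff[j];
      arma::vec rn = r + e.beta * e.col;
      double dll = (arma::dot(r, r) - arma::dot(rn, rn)) / (2.0 * sigma2);
      double la = dll + std::log1p(-w[e.type]) - std::log(w[e.type]) +
        std::log(move_probs[0] * type_prob[e.type] / d_type[e.type]) -
        std::log(move_probs[1] / (double)m);
      if (std::log(R::unif_rand()) < la) {
        r = rn;
        eff.erase(eff.begin() + j);
      }
    } else if (u < move_probs[0] + move_probs[1] + move_probs[2]) { // swap position
      if (m == 0) return;
      int j = (int)(R::unif_rand() * m); if (j >= m) j = m - 1;
      Effect e = eff[j];
      int s1 = e.s1, s2 = e.s2;
      if (e.type == 0) {
        s1 = (int)(R::unif_rand() * p); if (s1 >= p) s1 = p - 1;
      } else if (e.type == 1) {
        int nw = (int)(R::unif_rand() * p); if (nw >= p) nw = p - 1;
        if (R::unif_rand() < 0.5) s1 = nw; else s2 = nw;
        if (s1 == s2) return;
        if (s1 > s2) std::swap(s1, s2);
      } else {
        s1 = (int)(R::unif_rand() * p); if (s1 >= p) s1 = p - 1;
      }
      if (find_term(e.type, s1, s2, j) >= 0) return;
      arma::vec col = term_col(e.type, s1, s2);
      double Va = col_var(col);
      if (Va <= 0) return;
      double sb2 = (nu_beta - 2.0) * Eh * V / (nu_beta * Va);
      double sigb2 = std::isnan(fix_sb2) ? rinvchisq(nu_beta, sb2) : fix_sb2;
      double beta = R::norm_rand() * std::sqrt(sigb2);
      arma::vec rn = r + e.beta * e.col - beta * col;
      double dll = (arma::dot(r, r) - arma::dot(rn, rn)) / (2.0 * sigma2);
      if (std::log(R::unif_rand()) < dll) {
        eff[j].s1 = s1; eff[j].s2 = s2; eff[j].beta = beta;
        eff[j].sb2 = sb2; eff[j].sigb2 = sigb2; eff[j].col = col;
        r = rn;
      }
    } else { // within-model refresh
      if (m == 0) return;
      int j = (int)(R::unif_rand() * m); if (j >= m) j = m - 1;
      gibbs_beta_one(eff[j], eff[j].sigb2);
    }
  };

  // sample storage
  const int n_keep = n_iter / thin;
  arma::vec out_mu(n_keep), out_sigma2(n_keep), out_llm(n_keep), out_llc(n_keep);
  arma::mat out_delta(n_keep, k), out_psi(n_keep, npsi), out_covb(n_keep, q);
  arma::ivec out_nact(n_keep);
  arma::vec fit_accum(N, arma::fill::zeros);
  arma::mat b_accum(n, k, arma::fill::zeros);
  arma::mat out_b(store_b ? n_keep : 0, store_b ? n * k : 0);
  std::vector<int> es, et, e1, e2;
  std::vector<double> eb;

  arma::mat R0inv = arma::eye(npsi > 0 ? npsi : 1, npsi > 0 ? npsi : 1) / psi_prior_var;

  int kept = 0;
  for (int iter = 0; iter < burn_in + n_iter; ++iter) {
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();

    if (upd_gamma) {
      for (int s = 0; s < mh_sweeps; ++s) mh_move();
    }
    if (upd_cov_beta) {
      for (int c = 0; c < q; ++c) {
        arma::vec col = Cov.col(c);
        arma::vec ra = r + cov_beta[c] * col;
        double prec = arma::dot(col, col) / sigma2 + 1.0 / cov_beta_var;
        double mean = (arma::dot(col, ra) / sigma2) / prec;
        cov_beta[c] = mean + R::norm_rand() / std::sqrt(prec);
        r = ra - cov_beta[c] * col;
      }
    }
    if (upd_beta) {
      for (size_t j = 0; j < eff.size(); ++j) gibbs_beta_one(eff[j], eff[j].sigb2);
    }
    if (upd_sigma_beta2 && std::isnan(fix_sb2)) {
      for (size_t j = 0; j < eff.size(); ++j) {
        eff[j].sigb2 = rinvchisq(nu_beta + 1.0,
          (eff[j].beta * eff[j].beta + nu_beta * eff[j].sb2) / (nu_beta + 1.0));
      }
    }
    if (upd_b) {
      for (int i = 0; i < n; ++i) {
        int a = off[i], bnd = off[i + 1], ni = bnd - a;
        arma::mat Zi = Z.rows(a, bnd - 1);
        arma::vec ri = r.subvec(a, bnd - 1) + Zi * b.row(i).t();
        arma::mat M = arma::eye(k, k) + Zi.t() * Zi / sigma2;
        arma::mat Mc = arma::chol(M); // upper: M = Mc' Mc
        arma::vec rhs = Zi.t() * ri / sigma2;
        arma::vec mean = arma::solve(arma::trimatu(Mc),
                          arma::solve(arma::trimatl(Mc.t()), rhs));
        arma::vec zdraw(k);
        for (int l = 0; l < k; ++l) zdraw[l] = R::norm_rand();
        arma::vec bnew = mean + arma::solve(arma::trimatu(Mc), zdraw);
        b.row(i) = bnew.t();
        r.subvec(a, bnd - 1) = ri - Zi * bnew;
        (void)ni;
      }
    }
    if (upd_delta) {
      arma::mat U = b * Psi.t(); // row i = (Psi b_i)'
      for (int l = 0; l < k; ++l) {
        arma::vec cl(N);
        for (int o = 0; o < N; ++o) cl[o] = A(o, l) * U(subj[o], l);
        arma::vec rno = r + delta[l] * cl;
        double prec = 1.0 / s_d02 + arma::dot(cl, cl) / sigma2;
        double mean = (m_d0 / s_d02 + arma::dot(cl, rno) / sigma2) / prec;
        delta[l] = rtnorm_pos(mean, 1.0 / std::sqrt(prec));
        r = rno - delta[l] * cl;
      }
      refresh_re();
    }
    if (upd_psi && npsi > 0) {
      arma::mat Gm(N, npsi);
      int pos = 0;
      for (int mrow = 1; mrow < k; ++mrow) {
        for (int l = 0; l < mrow; ++l) {
          for (int o = 0; o < N; ++o)
            Gm(o, pos) = A(o, mrow) * delta[mrow] * b(subj[o], l);
          ++pos;
        }
      }
      arma::vec rno = r + Gm * psi;
      arma::mat Mp = R0inv + Gm.t() * Gm / sigma2;
      arma::mat Mc = arma::chol(Mp);
      arma::vec rhs = R0inv * arma::vec(npsi, arma::fill::value(psi_prior_mean)) +
        Gm.t() * rno / sigma2;
      arma::vec mean = arma::solve(arma::trimatu(Mc),
                        arma::solve(arma::trimatl(Mc.t()), rhs));
      arma::vec zdraw(npsi);
      for (int l = 0; l < npsi; ++l) zdraw[l] = R::norm_rand();
      psi = mean + arma::solve(arma::trimatu(Mc), zdraw);
      r = rno - Gm * psi;
      refresh_re();
    }
    if (upd_mu) {
      arma::vec rm = r + mu;
      double prec = N / sigma2 + 1.0 / tau02;
      double mean = (arma::accu(rm) / sigma2 + eta0 / tau02) / prec;
      mu = mean + R::norm_rand() / std::sqrt(prec);
      r = rm - mu;
    }
    if (upd_sigma2) {
      double rss = arma::dot(r, r);
      sigma2 = (nu_sigma * s_sigma2 + rss) / R::rchisq(nu_sigma + N);
    }

    int it_post = iter - burn_in + 1;
    if (it_post >= 1 && it_post % thin == 0 && kept < n_keep) {
      out_mu[kept] = mu;
      out_sigma2[kept] = sigma2;
      out_delta.row(kept) = delta.t();
      if (npsi > 0) out_psi.row(kept) = psi.t();
      out_covb.row(kept) = cov_beta.t();
      out_nact[kept] = (int)eff.size();

      // conditional log-likelihood
      double rss = arma::dot(r, r);
      out_llc[kept] = -0.5 * N * std::log(2.0 * M_PI * sigma2) - rss / (2.0 * sigma2);

      // marginal log-likelihood (b integrated out), per subject
      double llm = 0.0;
      for (int i = 0; i < n; ++i) {
        int a = off[i], bnd = off[i + 1], ni = bnd - a;
        arma::mat Zi = Z.rows(a, bnd - 1);
        arma::vec rm = r.subvec(a, bnd - 1) + Zi * b.row(i).t();
        arma::mat Si = Zi * Zi.t() + sigma2 * arma::eye(ni, ni);
        arma::mat Sc = arma::chol(Si);
        arma::vec zi = arma::solve(arma::trimatl(Sc.t()), rm);
        llm += -0.5 * (ni * std::log(2.0 * M_PI) + arma::dot(zi, zi)) -
          arma::accu(arma::log(Sc.diag()));
      }
      out_llm[kept] = llm;

      arma::vec rep(N);
      for (int o = 0; o < N; ++o) rep[o] = arma::dot(Z.row(o), b.row(subj[o]));
      fit_accum += y - r - mu - rep; // covariate + genetic linear predictor
      b_accum += b;
      if (store_b) out_b.row(kept) = arma::vectorise(b).t(); // column-major: subject fastest

      for (size_t j = 0; j < eff.size(); ++j) {
        es.push_back(kept + 1);
        et.push_back(eff[j].type);
        e1.push_back(eff[j].s1 + 1);
        e2.push_back(eff[j].s2 + 1);
        eb.push_back(eff[j].beta);
      }
      ++kept;
    }
  }

  return List::create(
    _["mu"] = out_mu, _["sigma2"] = out_sigma2,
    _["delta"] = out_delta, _["psi"] = out_psi,
    _["cov_beta"] = out_covb, _["n_active"] = out_nact,
    _["loglik_marg"] = out_llm, _["loglik_cond"] = out_llc,
    _["fit_mean"] = fit_accum / std::max(kept, 1),
    _["b_mean"] = b_accum / std::max(kept, 1),
    _["b_samples"] = out_b,
    _["effects"] = DataFrame::create(
      _["sample"] = wrap(es), _["type"] = wrap(et),
      _["snp1"] = wrap(e1), _["snp2"] = wrap(e2), _["beta"] = wrap(eb)),
    _["n_samples"] = kept
  );
}
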