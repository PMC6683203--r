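// Blockwise adaptive random-walk Metropolis sampler for the joint
// two-generation model. One block per submodel: its regression
// coefficients plus (for normal/beta families) the log of its scale
// parameter, updated jointly with a Haario-style adaptive multivariate
// normal proposal during burn-in. Missing maternal-mass covariates are
// imputed each sweep by an independence Metropolis step whose proposal is
// the gen-1 predictive for the dam, so the acceptance ratio reduces to the
// offspring likelihood ratio. Uses R's RNG throughout so runs are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;

enum Family { FAM_BERN = 0, FAM_NORMAL = 1, FAM_BETA = 2 };
enum ScalePrior { SCALE_NONE = 0, SCALE_HALFNORMAL = 1, SCALE_GAMMA = 2 };

struct Block {
  std::string name;
  int family;
  arma::mat X;
  arma::vec y;
  arma::vec pm, ps;          // coefficient prior mean / sd
  int scale_prior;           // prior family for the scale parameter
  double sp1, sp2;
  bool has_scale;
  // state
  arma::vec coef;
  double lscale;             // log sigma / log phi
  double ll;                 // cached log-likelihood
  // adaptation
  int dim;
  arma::vec amu;             // running mean of theta
  arma::mat am2;             // running sum of squares (Welford)
  long acount;
  arma::mat prop_chol;
  double log_lambda;
  long n_prop, n_acc;        // sampling-phase acceptance bookkeeping
};

static inline double row_ll(int family, double y, double eta, double scale) {
  switch (family) {
  case FAM_BERN: {
    double l1pe = (eta > 0.0) ? eta + std::log1p(std::exp(-eta))
                              : std::log1p(std::exp(eta));
    return y * eta - l1pe;
  }
  case FAM_NORMAL: {
    double z = (y - eta) / scale;
    return -LOG_SQRT_2PI - std::log(scale) - 0.5 * z * z;
  }
  default: {  // FAM_BETA
    double mu = 1.0 / (1.0 + std::exp(-eta));
    if (mu < 1e-12) mu = 1e-12;
    if (mu > 1.0 - 1e-12) mu = 1.0 - 1e-12;
    double a = mu * scale, b = (1.0 - mu) * scale;
    return std::lgamma(scale) - std::lgamma(a) - std::lgamma(b) +
      (a - 1.0) * std::log(y) + (b - 1.0) * std::log1p(-y);
  }
  }
}

static double block_loglik(const Block &b, const arma::vec &coef,
                           double lscale) {
  const arma::uword n = b.X.n_rows;
  if (n == 0) return 0.0;
  double scale = std::exp(lscale);
  arma::vec eta = b.X * coef;
  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    ll += row_ll(b.family, b.y[i], eta[i], scale);
  }
  return ll;
}

static double block_logprior(const Block &b, const arma::vec &coef,
                             double lscale) {
  double lp = 0.0;
  for (arma::uword i = 0; i < coef.n_elem; ++i) {
    double z = (coef[i] - b.pm[i]) / b.ps[i];
    lp += -LOG_SQRT_2PI - std::log(b.ps[i]) - 0.5 * z * z;
  }
  if (b.has_scale) {
    double s = std::exp(lscale);
    if (b.scale_prior == SCALE_HALFNORMAL) {
      double z = s / b.sp1;
      lp += std::log(2.0) - LOG_SQRT_2PI - std::log(b.sp1) - 0.5 * z * z;
    } else {  // gamma(shape sp1, rate sp2)
      lp += R::dgamma(s, b.sp1, 1.0 / b.sp2, 1);
    }
    lp += lscale;  // Jacobian of the log parameterization
  }
  return lp;
}

struct ImputeTarget {
  int block;
  int col;
  arma::uvec rows;
};

struct ImputeEntry {
  arma::vec prior_x;                // dam covariate row in the mass model
  int pseudo_row;                   // dam's latent row in the mass model
  std::vector<ImputeTarget> targets;
};

// [[Rcpp::export(name = ".mcmc_run")]]
List mcmc_run(List blocks_in, List impute_in, List config) {
  const int n_burn = as<int>(config["burn_in"]);
  const int n_keep = as<int>(config["keep"]);
  const int thin = as<int>(config["thin"]);
  const bool adapt = as<bool>(config["adapt"]);
  const bool update_blocks = as<bool>(config["update_blocks"]);
  const bool update_impute = as<bool>(config["update_impute"]);
  const double target_accept = as<double>(config["target_accept"]);
  const int prior_block = as<int>(config["prior_block"]);  // 0-based, -1 none
  const int recompute_every = 2000;

  const int nb = blocks_in.size();
  std::vector<Block> blocks(nb);
  int n_par = 0;
  for (int b = 0; b < nb; ++b) {
    List bl = blocks_in[b];
    Block &B = blocks[b];
    B.name = as<std::string>(bl["name"]);
    B.family = as<int>(bl["family"]);
    B.X = as<arma::mat>(bl["X"]);
    B.y = as<arma::vec>(bl["y"]);
    B.pm = as<arma::vec>(bl["prior_mean"]);
    B.ps = as<arma::vec>(bl["prior_sd"]);
    B.scale_prior = as<int>(bl["scale_prior"]);
    B.has_scale = B.scale_prior != SCALE_NONE;
    B.sp1 = as<double>(bl["scale_par1"]);
    B.sp2 = as<double>(bl["scale_par2"]);
    B.coef = as<arma::vec>(bl["init_coef"]);
    B.lscale = B.has_scale ? std::log(as<double>(bl["init_scale"])) : 0.0;
    B.ll = block_loglik(B, B.coef, B.lscale);
    if (!std::isfinite(B.ll)) {
      stop("non-finite log-likelihood at initialization in submodel '" +
           B.name + "'");
    }
    B.dim = B.coef.n_elem + (B.has_scale ? 1 : 0);
    arma::vec psd = as<arma::vec>(bl["init_prop_sd"]);
    B.prop_chol = arma::diagmat(psd);
    B.amu = arma::zeros(B.dim);
    B.am2 = arma::zeros(B.dim, B.dim);
    B.acount = 0;
    B.log_lambda = 0.0;
    B.n_prop = 0;
    B.n_acc = 0;
    n_par += B.dim;
  }

  // imputation setup
  arma::vec imp = as<arma::vec>(impute_in["init"]);
  const int n_imp = imp.n_elem;
  std::vector<ImputeEntry> entries(n_imp);
  if (n_imp > 0) {
    List ents = impute_in["entries"];
    for (int j = 0; j < n_imp; ++j) {
      List e = ents[j];
      ImputeEntry &E = entries[j];
      E.prior_x = as<arma::vec>(e["prior_x"]);
      E.pseudo_row = as<int>(e["pseudo_row"]);  // 0-based, -1 if absent
      List tg = e["targets"];
      for (int t = 0; t < tg.size(); ++t) {
        List ti = tg[t];
        ImputeTarget T;
        T.block = as<int>(ti["block"]);   // 0-based
        T.col = as<int>(ti["col"]);       // 0-based
        T.rows = as<arma::uvec>(ti["rows"]);  // 0-based
        E.targets.push_back(T);
      }
    }
  }

  const long n_total = (long)n_burn + (long)n_keep * thin;
  arma::mat draws(n_keep, n_par);
  arma::mat imp_draws(n_keep, std::max(n_imp, 0));
  long imp_prop = 0, imp_acc = 0;
  int stored = 0;

  for (long iter = 0; iter < n_total; ++iter) {
    const bool burn = iter < n_burn;

    if (update_blocks) {
      for (int b = 0; b < nb; ++b) {
        Block &B = blocks[b];
        const int d = B.dim;
        arma::vec z(d);
        for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
        arma::vec step = std::exp(B.log_lambda) * (B.prop_chol * z);
        arma::vec coef_new = B.coef + step.head(B.coef.n_elem);
        double lscale_new = B.has_scale ? B.lscale + step[d - 1] : 0.0;
        double ll_new = block_loglik(B, coef_new, lscale_new);
        double logr = ll_new + block_logprior(B, coef_new, lscale_new) -
          B.ll - block_logprior(B, B.coef, B.lscale);
        double alpha = std::isfinite(logr)
          ? std::min(1.0, std::exp(std::min(logr, 0.0))) : 0.0;
        bool accept = std::isfinite(logr) &&
          std::log(R::unif_rand()) < logr;
        if (accept) {
          B.coef = coef_new;
          B.lscale = lscale_new;
          B.ll = ll_new;
        }
        if (!burn) {
          B.n_prop++;
          if (accept) B.n_acc++;
        }
        if (burn && adapt) {
          // Robbins-Monro global scale toward the target acceptance rate
          double gamma = std::pow((double)(iter + 1), -0.6);
          B.log_lambda += gamma * (alpha - target_accept);
          // Welford update of the empirical covariance
          arma::vec theta(d);
          theta.head(B.coef.n_elem) = B.coef;
          if (B.has_scale) theta[d - 1] = B.lscale;
          B.acount++;
          arma::vec delta = theta - B.amu;
          B.amu += delta / (double)B.acount;
          B.am2 += delta * (theta - B.amu).t();
          if (B.acount > 100 && B.acount % 200 == 0) {
            arma::mat cov = B.am2 / (double)(B.acount - 1);
            cov.diag() += 1e-9;
            arma::mat L;
            if (arma::chol(L, cov, "lower")) {
              B.prop_chol = (2.38 / std::sqrt((double)d)) * L;
            }
          }
        }
      }
    }

    if (update_impute && n_imp > 0 && prior_block >= 0) {
      Block &PB = blocks[prior_block];
      double psd = std::exp(PB.lscale);
      for (int j = 0; j < n_imp; ++j) {
        ImputeEntry &E = entries[j];
        double eta0 = arma::dot(E.prior_x, PB.coef);
        double m_old = imp[j];
        double m_new = R::rnorm(eta0, psd);
        // independence proposal from the dam's predictive: the acceptance
        // ratio is the offspring likelihood ratio alone
        double logr = 0.0;
        std::vector<double> deltas(E.targets.size(), 0.0);
        for (size_t t = 0; t < E.targets.size(); ++t) {
          ImputeTarget &T = E.targets[t];
          Block &TB = blocks[T.block];
          double c = TB.coef[T.col];
          double sc = std::exp(TB.lscale);
          double d_t = 0.0;
          for (arma::uword r = 0; r < T.rows.n_elem; ++r) {
            arma::uword row = T.rows[r];
            double eta_old = arma::dot(TB.X.row(row), TB.coef);
            double eta_new = eta_old + (m_new - m_old) * c;
            d_t += row_ll(TB.family, TB.y[row], eta_new, sc) -
              row_ll(TB.family, TB.y[row], eta_old, sc);
          }
          deltas[t] = d_t;
          logr += d_t;
        }
        imp_prop++;
        if (std::isfinite(logr) && std::log(R::unif_rand()) < logr) {
          imp_acc++;
          imp[j] = m_new;
          for (size_t t = 0; t < E.targets.size(); ++t) {
            ImputeTarget &T = E.targets[t];
            Block &TB = blocks[T.block];
            for (arma::uword r = 0; r < T.rows.n_elem; ++r) {
              TB.X(T.rows[r], T.col) = m_new;
            }
            TB.ll += deltas[t];
          }
          if (E.pseudo_row >= 0) {
            PB.y[E.pseudo_row] = m_new;
            PB.ll += row_ll(FAM_NORMAL, m_new, eta0, psd) -
              row_ll(FAM_NORMAL, m_old, eta0, psd);
          }
        }
      }
    }

    // guard against numerical drift from incremental cache updates
    if (n_imp > 0 && (iter + 1) % recompute_every == 0) {
      for (int b = 0; b < nb; ++b) {
        blocks[b].ll = block_loglik(blocks[b], blocks[b].coef,
                                    blocks[b].lscale);
      }
    }

    if (!burn && ((iter - n_burn + 1) % thin == 0)) {
      int pos = 0;
      for (int b = 0; b < nb; ++b) {
        Block &B = blocks[b];
        for (arma::uword i = 0; i < B.coef.n_elem; ++i) {
          draws(stored, pos++) = B.coef[i];
        }
        if (B.has_scale) draws(stored, pos++) = std::exp(B.lscale);
      }
      for (int j = 0; j < n_imp; ++j) imp_draws(stored, j) = imp[j];
      stored++;
    }

    if (iter % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector accept(nb);
  CharacterVector bnames(nb);
  List final_coef(nb);
  NumericVector final_scale(nb);
  for (int b = 0; b < nb; ++b) {
    Block &B = blocks[b];
    accept[b] = B.n_prop > 0 ? (double)B.n_acc / (double)B.n_prop
                             : NA_REAL;
    bnames[b] = B.name;
    final_coef[b] = wrap(B.coef);
    final_scale[b] = B.has_scale ? std::exp(B.lscale) : NA_REAL;
  }
  accept.names() = bnames;
  final_coef.names() = bnames;
  final_scale.names() = bnames;

  return List::create(
    _["draws"] = draws,
    _["imputed"] = imp_draws,
    _["accept"] = accept,
    _["impute_accept"] = imp_prop > 0 ? (double)imp_acc / (double)imp_prop
                                      : NA_REAL,
    _["final_coef"] = final_coef,
    _["final_scale"] = final_scale,
    _["final_imputed"] = wrap(imp));
}
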