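#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log-likelihood term, stable for large |eta|:
// y*eta - log(1 + exp(eta))
static inline double loglik_term(int y, double eta) {
  double lse = (eta > 0.0) ? eta + log1p(std::exp(-eta)) : log1p(std::exp(eta));
  return y * eta - lse;
}

static double loglik_all(const IntegerVector& y, const std::vector<double>& eta) {
  double ll = 0.0;
  int n = y.size();
  for (int i = 0; i < n; ++i) ll += loglik_term(y[i], eta[i]);
  return ll;
}

// log-likelihood after shifting eta by d * x (without mutating eta)
static double loglik_shift(const IntegerVector& y, const std::vector<double>& eta,
                           const NumericMatrix& X, int col, double d) {
  double ll = 0.0;
  int n = y.size();
  for (int i = 0; i < n; ++i) ll += loglik_term(y[i], eta[i] + d * X(i, col));
  return ll;
}

// One-component adaptive random-walk Metropolis sampler for the
// use-availability logistic RSF with Laplace (Lasso) shrinkage priors,
// exact conjugate Gibbs lambda update, optional per-individual random
// intercepts (Uniform(0, re_upper) prior on the SD), and categorical Gibbs
// latent-indicator scale selection for multi-scale covariates.
//
// X holds every covariate column (single-scale columns plus one column per
// candidate radius of each multi-scale variable). single_cols / ms_cols are
// 1-based column indices into X. Coefficients are ordered single-scale
// variables first, then one shared coefficient per multi-scale variable.
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List rsf_mcmc_cpp(NumericMatrix X, IntegerVector y, IntegerVector ind,
                  IntegerVector single_cols, List ms_cols,
                  int n_iter, int burn, int thin,
                  double a, double b,
                  bool use_re, double re_upper, double beta0_sd,
                  bool sample_scales, IntegerVector scale_init,
                  double lambda_init) {
  const int n = X.nrow();
  const int n_single = single_cols.size();
  const int n_ms = ms_cols.size();
  const int K = n_single + n_ms;          // coefficients under the Lasso prior
  const int J = use_re ? max(ind) : 0;    // individuals (ind is 1-based, 0 = none)

  if (burn >= n_iter) stop("burn-in must be smaller than the iteration count");
  const int n_keep = (n_iter - burn) / thin;

  // column index in X used by each coefficient; ms coefficients point at the
  // currently selected candidate column
  std::vector<int> coef_col(K);
  std::vector<std::vector<int>> cand(n_ms);
  std::vector<int> sel(n_ms);
  for (int k = 0; k < n_single; ++k) coef_col[k] = single_cols[k] - 1;
  for (int v = 0; v < n_ms; ++v) {
    IntegerVector cc = ms_cols[v];
    cand[v].resize(cc.size());
    for (int r = 0; r < cc.size(); ++r) cand[v][r] = cc[r] - 1;
    sel[v] = scale_init[v] - 1;
    if (sel[v] < 0 || sel[v] >= (int)cand[v].size())
      stop("scale_init out of range");
    coef_col[n_single + v] = cand[v][sel[v]];
  }

  // rows per individual for random-intercept updates
  std::vector<std::vector<int>> rows_of(J);
  if (use_re)
    for (int i = 0; i < n; ++i) rows_of[ind[i] - 1].push_back(i);

  // state
  double beta0 = 0.0, lambda = lambda_init, sigma_g = use_re ? 0.5 : 0.0;
  std::vector<double> beta(K, 0.0), gam(J, 0.0), eta(n, 0.0);

  // adaptive step sizes (log scale), acceptance bookkeeping per batch of 50
  const double target = 0.44, adapt_step = 0.1;
  std::vector<double> step_b(K + 1, 0.2), acc_b(K + 1, 0.0);
  std::vector<double> step_g(J, 0.3), acc_g(J, 0.0);
  double step_s = 0.2, acc_s = 0.0;
  int batch_n = 0;

  // storage
  NumericVector out_b0(n_keep), out_lam(n_keep), out_sig(use_re ? n_keep : 0);
  NumericMatrix out_beta(n_keep, K);
  NumericMatrix out_gam(use_re ? n_keep : 0, J);
  IntegerMatrix out_sel(n_keep, n_ms);

  RNGScope scope;
  int keep_i = 0;

  for (int it = 1; it <= n_iter; ++it) {
    bool adapting = it <= burn;

    // --- intercept (diffuse Normal prior, outside the Lasso) ---
    {
      double d = R::rnorm(0.0, step_b[0]);
      double cur = loglik_all(y, eta);
      double prop = cur; // recompute with constant shift
      prop = 0.0;
      for (int i = 0; i < n; ++i) prop += loglik_term(y[i], eta[i] + d);
      double lr = prop - cur
        + R::dnorm(beta0 + d, 0.0, beta0_sd, 1) - R::dnorm(beta0, 0.0, beta0_sd, 1);
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        beta0 += d;
        for (int i = 0; i < n; ++i) eta[i] += d;
        acc_b[0] += 1.0;
      }
    }

    // --- Lasso coefficients ---
    for (int k = 0; k < K; ++k) {
      int col = coef_col[k];
      double d = R::rnorm(0.0, step_b[k + 1]);
      double cur = loglik_all(y, eta);
      double prop = loglik_shift(y, eta, X, col, d);
      double lr = prop - cur
        - lambda * std::fabs(beta[k] + d) + lambda * std::fabs(beta[k]);
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        beta[k] += d;
        for (int i = 0; i < n; ++i) eta[i] += d * X(i, col);
        acc_b[k + 1] += 1.0;
      }
    }

    // --- lambda: exact Gamma(a + K, b + sum |beta|) full conditional ---
    {
      double sab = 0.0;
      for (int k = 0; k < K; ++k) sab += std::fabs(beta[k]);
      lambda = R::rgamma(a + K, 1.0 / (b + sab)); // R::rgamma takes scale
    }

    // --- random intercepts ---
    if (use_re) {
      for (int j = 0; j < J; ++j) {
        double d = R::rnorm(0.0, step_g[j]);
        double cur = 0.0, prop = 0.0;
        for (int i : rows_of[j]) {
          cur += loglik_term(y[i], eta[i]);
          prop += loglik_term(y[i], eta[i] + d);
        }
        double lr = prop - cur
          + R::dnorm(gam[j] + d, 0.0, sigma_g, 1) - R::dnorm(gam[j], 0.0, sigma_g, 1);
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          gam[j] += d;
          for (int i : rows_of[j]) eta[i] += d;
          acc_g[j] += 1.0;
        }
      }
      // sigma_gamma: Metropolis under Uniform(0, re_upper)
      double sp = sigma_g + R::rnorm(0.0, step_s);
      if (sp > 0.0 && sp < re_upper) {
        double lr = 0.0;
        for (int j = 0; j < J; ++j)
          lr += R::dnorm(gam[j], 0.0, sp, 1) - R::dnorm(gam[j], 0.0, sigma_g, 1);
        if (std::log(R::runif(0.0, 1.0)) < lr) { sigma_g = sp; acc_s += 1.0; }
      }
    }

    // --- latent scale indicators: categorical Gibbs, uniform prior ---
    if (sample_scales) {
      for (int v = 0; v < n_ms; ++v) {
        int kc = n_single + v;
        int cur_col = coef_col[kc];
        int C = cand[v].size();
        std::vector<double> ll(C);
        double mx = R_NegInf;
        for (int r = 0; r < C; ++r) {
          if (cand[v][r] == cur_col) ll[r] = loglik_all(y, eta);
          else {
            double llr = 0.0;
            for (int i = 0; i < n; ++i) {
              double e = eta[i] + beta[kc] * (X(i, cand[v][r]) - X(i, cur_col));
              llr += loglik_term(y[i], e);
            }
            ll[r] = llr;
          }
          if (ll[r] > mx) mx = ll[r];
        }
        double tot = 0.0;
        for (int r = 0; r < C; ++r) { ll[r] = std::exp(ll[r] - mx); tot += ll[r]; }
        double u = R::runif(0.0, 1.0) * tot, cum = 0.0;
        int pick = C - 1;
        for (int r = 0; r < C; ++r) { cum += ll[r]; if (u <= cum) { pick = r; break; } }
        if (cand[v][pick] != cur_col) {
          for (int i = 0; i < n; ++i)
            eta[i] += beta[kc] * (X(i, cand[v][pick]) - X(i, cur_col));
          sel[v] = pick;
          coef_col[kc] = cand[v][pick];
        } else sel[v] = pick;
      }
    }

    // --- step-size adaptation, burn-in only ---
    ++batch_n;
    if (batch_n == 50) {
      if (adapting) {
        for (int k = 0; k <= K; ++k) {
          step_b[k] *= std::exp((acc_b[k] / 50.0 > target) ? adapt_step : -adapt_step);
          step_b[k] = std::min(std::max(step_b[k], 1e-4), 10.0);
        }
        for (int j = 0; j < J; ++j) {
          step_g[j] *= std::exp((acc_g[j] / 50.0 > target) ? adapt_step : -adapt_step);
          step_g[j] = std::min(std::max(step_g[j], 1e-4), 10.0);
        }
        step_s *= std::exp((acc_s / 50.0 > target) ? adapt_step : -adapt_step);
        step_s = std::min(std::max(step_s, 1e-4), 10.0);
      }
      std::fill(acc_b.begin(), acc_b.end(), 0.0);
      std::fill(acc_g.begin(), acc_g.end(), 0.0);
      acc_s = 0.0;
      batch_n = 0;
    }

    // --- retain ---
    if (it > burn && (it - burn) % thin == 0) {
      out_b0[keep_i] = beta0;
      out_lam[keep_i] = lambda;
      for (int k = 0; k < K; ++k) out_beta(keep_i, k) = beta[k];
      for (int v = 0; v < n_ms; ++v) out_sel(keep_i, v) = sel[v] + 1;
      if (use_re) {
        out_sig[keep_i] = sigma_g;
        for (int j = 0; j < J; ++j) out_gam(keep_i, j) = gam[j];
      }
      ++keep_i;
    }
  }

  return List::create(
    _["beta0"] = out_b0, _["beta"] = out_beta, _["lambda"] = out_lam,
    _["sigma_gamma"] = out_sig, _["gamma"] = out_gam, _["scale"] = out_sel,
    _["n_keep"] = n_keep);
}

// Circular-window focal mean over a raster matrix. offs holds the (row, col)
// cell offsets of window members (centre included); NA cells and out-of-bounds
// cells are excluded, so the window shrinks at edges and around nodata.
// [[Rcpp::export]]
NumericMatrix focal_mean_cpp(NumericMatrix v, IntegerMatrix offs) {
  int nr = v.nrow(), nc = v.ncol(), m = offs.nrow();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0; int cnt = 0;
      for (int k = 0; k < m; ++k) {
        int rr = r + offs(k, 0), cc = c + offs(k, 1);
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double val = v(rr, cc);
        if (NumericMatrix::is_na(val)) continue;
        s += val; ++cnt;
      }
      out(r, c) = (cnt > 0) ? s / cnt : NA_REAL;
    }
  }
  return out;
}
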