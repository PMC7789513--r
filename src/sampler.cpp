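#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the binomial logit spatio-temporal
// BYM model:
//   logit(mu_it) = alpha + s_i + u_i + d0 t*_t + v_t + d1_i t*_t + eps_it
// Single-site random-walk Metropolis on every latent block, with the
// sum-to-zero constraints on s, d1, v re-imposed after each sweep by
// transferring the block mean into alpha (s, v) or d0 (d1), which leaves
// the linear predictor unchanged.  Variances: random-walk on log sigma
// under the half-Gaussian SD prior, exact conjugate Gibbs under the
// Gamma precision prior.  Uses R's RNG so results are reproducible from
// set.seed() on the R side.

// binomial cell log-likelihood, constant term dropped
static inline double cell_ll(double y, double n, double eta) {
  double lse = (eta > 0.0) ? eta + log1p(std::exp(-eta))
                           : log1p(std::exp(eta));
  return y * eta - n * lse;
}

struct AdaptScale {
  double scale;
  int acc, att;          // window counters (adaptation)
  long acc_post, att_post; // post-adaptation counters (reporting)
  AdaptScale() : scale(0.1), acc(0), att(0), acc_post(0), att_post(0) {}
  void tally(bool accepted, bool adapting) {
    if (adapting) { att++; if (accepted) acc++; }
    else { att_post++; if (accepted) acc_post++; }
  }
  void maybe_adapt(bool adapting) {
    if (!adapting || att < 100) return;
    double rate = (double)acc / att;
    if (rate < 0.20) scale *= 0.7;
    else if (rate > 0.50) scale *= 1.4;
    acc = 0; att = 0;
  }
  double rate_post() const {
    return att_post > 0 ? (double)acc_post / att_post : NA_REAL;
  }
};

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericMatrix y, NumericMatrix nn, NumericVector tstar,
                  IntegerVector nb_num, IntegerVector nb_adj,
                  List init, List prior, List control) {
  const int N = y.nrow(), T = y.ncol();

  // neighbour offsets into nb_adj (0-based area indices)
  std::vector<int> nb_off(N + 1, 0);
  for (int i = 0; i < N; i++) nb_off[i + 1] = nb_off[i] + nb_num[i];

  // state
  double alpha = as<double>(init["alpha"]);
  double d0 = as<double>(init["d0"]);
  std::vector<double> s = as<std::vector<double> >(init["s"]);
  std::vector<double> u = as<std::vector<double> >(init["u"]);
  std::vector<double> d1 = as<std::vector<double> >(init["d1"]);
  std::vector<double> v = as<std::vector<double> >(init["v"]);
  NumericMatrix eps0 = init["eps"];
  std::vector<double> eps(N * T);
  for (int t = 0; t < T; t++)
    for (int i = 0; i < N; i++) eps[i + N * t] = eps0(i, t);
  NumericVector sig2 = clone(as<NumericVector>(init["sigma2"])); // s,u,v,d,eps

  // prior config
  const int fam = as<int>(prior["family"]); // 0 half-gaussian SD, 1 gamma prec
  const double hg_scale2 = as<double>(prior["scale2"]);
  const double g_shape = as<double>(prior["shape"]);
  const double g_rate = as<double>(prior["rate"]);

  // control
  const int n_iter = as<int>(control["n_iter"]);
  const int burnin = as<int>(control["burnin"]);
  const int thin = as<int>(control["thin"]);
  const int adapt_until = as<int>(control["adapt_until"]);
  const bool use_lik = as<bool>(control["use_likelihood"]);
  const LogicalVector upd = control["update"]; // alpha,d0,s,u,d1,v,eps,sigma
  const int progress_every = as<int>(control["progress_every"]);

  // impose the identification constraints at the start, transferring any
  // mean into the fixed effects so the linear predictor is unchanged
  {
    double ms = 0, md = 0, mv = 0;
    for (int i = 0; i < N; i++) { ms += s[i]; md += d1[i]; }
    for (int t = 0; t < T; t++) mv += v[t];
    ms /= N; md /= N; mv /= T;
    for (int i = 0; i < N; i++) { s[i] -= ms; d1[i] -= md; }
    for (int t = 0; t < T; t++) v[t] -= mv;
    alpha += ms + mv;
    d0 += md;
  }

  // cached linear predictor and per-cell log-likelihood
  std::vector<double> eta(N * T), ll(N * T, 0.0);
  for (int t = 0; t < T; t++)
    for (int i = 0; i < N; i++) {
      int k = i + N * t;
      eta[k] = alpha + s[i] + u[i] + d0 * tstar[t] + v[t] +
               d1[i] * tstar[t] + eps[k];
      if (use_lik) ll[k] = cell_ll(y(i, t), nn(i, t), eta[k]);
    }
  for (int k = 0; k < N * T; k++)
    if (!std::isfinite(ll[k]))
      stop("non-finite log-likelihood at initial state (cell %d)", k + 1);

  // proposal scales: alpha,d0,s,u,d1,v,eps + 5 log-sigma blocks
  NumericVector prop0 = init["prop"];
  std::vector<AdaptScale> ad(13);
  for (int b = 0; b < 12; b++) ad[b].scale = prop0[b];
  ad[12].scale = prop0.size() > 12 ? prop0[12] : 0.3; // s/u balancing move

  const int P = 2 + 3 * N + T + 5 + N * T;
  const int n_keep = (n_iter - burnin) / thin;
  NumericMatrix draws(n_keep, P);

  RNGScope scope;
  std::vector<double> ll_prop(N * T);

  // ICAR pairwise quadratic form sum_{i<j, i~j} (x_i - x_j)^2 == x'Qx
  auto icar_quad = [&](const std::vector<double>& x) {
    double q = 0.0;
    for (int i = 0; i < N; i++)
      for (int k = nb_off[i]; k < nb_off[i + 1]; k++) {
        int j = nb_adj[k];
        if (j > i) { double d = x[i] - x[j]; q += d * d; }
      }
    return q;
  };

  // log hyperprior on sigma2 plus component log-density terms that depend
  // on sigma (used by the log-sigma random walk under the half-Gaussian)
  auto sigma_logtarget = [&](double lsig, double quad, double rank) {
    double sigma = std::exp(lsig), s2 = sigma * sigma;
    double lp = -sigma * sigma / (2.0 * hg_scale2); // half-Gaussian kernel
    lp += -rank * lsig - quad / (2.0 * s2);         // component terms
    lp += lsig;                                     // Jacobian d sigma/d lsig
    return lp;
  };

  int keep_row = 0;
  for (int iter = 1; iter <= n_iter; iter++) {
    const bool adapting = iter <= adapt_until;

    // ---- alpha (flat prior) ----
    if (upd[0]) {
      double delta = R::rnorm(0.0, ad[0].scale);
      double lr = 0.0;
      if (use_lik) {
        for (int k = 0; k < N * T; k++) {
          int i = k % N, t = k / N;
          ll_prop[k] = cell_ll(y(i, t), nn(i, t), eta[k] + delta);
          lr += ll_prop[k] - ll[k];
        }
      }
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        alpha += delta;
        for (int k = 0; k < N * T; k++) eta[k] += delta;
        if (use_lik) std::swap(ll, ll_prop);
      }
      ad[0].tally(acc, adapting); ad[0].maybe_adapt(adapting);
    }

    // ---- d0 (flat prior) ----
    if (upd[1]) {
      double delta = R::rnorm(0.0, ad[1].scale);
      double lr = 0.0;
      if (use_lik) {
        for (int k = 0; k < N * T; k++) {
          int i = k % N, t = k / N;
          ll_prop[k] = cell_ll(y(i, t), nn(i, t), eta[k] + delta * tstar[t]);
          lr += ll_prop[k] - ll[k];
        }
      }
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) {
        d0 += delta;
        for (int t = 0; t < T; t++)
          for (int i = 0; i < N; i++) eta[i + N * t] += delta * tstar[t];
        if (use_lik) std::swap(ll, ll_prop);
      }
      ad[1].tally(acc, adapting); ad[1].maybe_adapt(adapting);
    }

    // ---- s_i single-site (ICAR prior) ----
    if (upd[2]) {
      double s2s = sig2[0];
      for (int i = 0; i < N; i++) {
        double delta = R::rnorm(0.0, ad[2].scale);
        double lr = 0.0;
        double lp_new[64]; // per-row proposed cell ll (T <= 64 assumed)
        if (use_lik) {
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            lp_new[t] = cell_ll(y(i, t), nn(i, t), eta[k] + delta);
            lr += lp_new[t] - ll[k];
          }
        }
        // ICAR prior ratio: pairs (i, j) over neighbours of i
        double dp = 0.0;
        for (int k = nb_off[i]; k < nb_off[i + 1]; k++) {
          int j = nb_adj[k];
          double o = s[i] - s[j], nw = s[i] + delta - s[j];
          dp += nw * nw - o * o;
        }
        lr += -dp / (2.0 * s2s);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          s[i] += delta;
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            eta[k] += delta;
            if (use_lik) ll[k] = lp_new[t];
          }
        }
        ad[2].tally(acc, adapting);
      }
      ad[2].maybe_adapt(adapting);
      // re-center: transfer mean into alpha (eta unchanged)
      double m = 0.0; for (int i = 0; i < N; i++) m += s[i];
      m /= N;
      for (int i = 0; i < N; i++) s[i] -= m;
      alpha += m;
    }

    // ---- u_i single-site (iid Gaussian prior) ----
    if (upd[3]) {
      double s2u = sig2[1];
      for (int i = 0; i < N; i++) {
        double delta = R::rnorm(0.0, ad[3].scale);
        double lr = 0.0;
        double lp_new[64];
        if (use_lik) {
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            lp_new[t] = cell_ll(y(i, t), nn(i, t), eta[k] + delta);
            lr += lp_new[t] - ll[k];
          }
        }
        double nw = u[i] + delta;
        lr += -(nw * nw - u[i] * u[i]) / (2.0 * s2u);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          u[i] = nw;
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            eta[k] += delta;
            if (use_lik) ll[k] = lp_new[t];
          }
        }
        ad[3].tally(acc, adapting);
      }
      ad[3].maybe_adapt(adapting);
    }

    // ---- balancing move: (s_i, u_i) -> (s_i + c, u_i - c) ----
    // s_i + u_i (all the likelihood sees) is untouched, so this costs no
    // likelihood evaluation while it decorrelates the structured /
    // unstructured split, whose single-site mixing is notoriously slow
    if (upd[2] && upd[3]) {
      double s2s = sig2[0], s2u = sig2[1];
      for (int i = 0; i < N; i++) {
        double c = R::rnorm(0.0, ad[12].scale);
        double dp = 0.0;
        for (int k = nb_off[i]; k < nb_off[i + 1]; k++) {
          int j = nb_adj[k];
          double o = s[i] - s[j], nw = s[i] + c - s[j];
          dp += nw * nw - o * o;
        }
        double un = u[i] - c;
        double lr = -dp / (2.0 * s2s) -
                    (un * un - u[i] * u[i]) / (2.0 * s2u);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) { s[i] += c; u[i] = un; }
        ad[12].tally(acc, adapting);
      }
      ad[12].maybe_adapt(adapting);
      double m = 0.0; for (int i = 0; i < N; i++) m += s[i];
      m /= N;
      // re-center s into the (flat-prior) intercept, as after the s sweep
      for (int i = 0; i < N; i++) s[i] -= m;
      alpha += m;
    }

    // ---- d1_i single-site (ICAR prior) ----
    if (upd[4]) {
      double s2d = sig2[3];
      for (int i = 0; i < N; i++) {
        double delta = R::rnorm(0.0, ad[4].scale);
        double lr = 0.0;
        double lp_new[64];
        if (use_lik) {
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            lp_new[t] = cell_ll(y(i, t), nn(i, t), eta[k] + delta * tstar[t]);
            lr += lp_new[t] - ll[k];
          }
        }
        double dp = 0.0;
        for (int k = nb_off[i]; k < nb_off[i + 1]; k++) {
          int j = nb_adj[k];
          double o = d1[i] - d1[j], nw = d1[i] + delta - d1[j];
          dp += nw * nw - o * o;
        }
        lr += -dp / (2.0 * s2d);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          d1[i] += delta;
          for (int t = 0; t < T; t++) {
            int k = i + N * t;
            eta[k] += delta * tstar[t];
            if (use_lik) ll[k] = lp_new[t];
          }
        }
        ad[4].tally(acc, adapting);
      }
      ad[4].maybe_adapt(adapting);
      double m = 0.0; for (int i = 0; i < N; i++) m += d1[i];
      m /= N;
      for (int i = 0; i < N; i++) d1[i] -= m;
      d0 += m;
    }

    // ---- v_t: in-subspace moves v' = v + delta (e_t - 1/T) ----
    // the proposal never leaves the sum-to-zero subspace, so the target is
    // exactly the centered Gaussian (per-coordinate variance
    // sigma_v^2 (1 - 1/T)); the move shifts every year's column of eta
    if (upd[5]) {
      double s2v = sig2[2];
      for (int t = 0; t < T; t++) {
        double delta = R::rnorm(0.0, ad[5].scale);
        double lr = 0.0;
        if (use_lik) {
          for (int tt = 0; tt < T; tt++) {
            double shift = (tt == t) ? delta * (1.0 - 1.0 / T)
                                     : -delta / T;
            for (int i = 0; i < N; i++) {
              int k = i + N * tt;
              ll_prop[k] = cell_ll(y(i, tt), nn(i, tt), eta[k] + shift);
              lr += ll_prop[k] - ll[k];
            }
          }
        }
        // |v'|^2 - |v|^2 with sum(v) = 0
        double dquad = 2.0 * delta * v[t] +
                       delta * delta * (1.0 - 1.0 / T);
        lr += -dquad / (2.0 * s2v);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          for (int tt = 0; tt < T; tt++) {
            double shift = (tt == t) ? delta * (1.0 - 1.0 / T)
                                     : -delta / T;
            v[tt] += shift;
            for (int i = 0; i < N; i++) {
              int k = i + N * tt;
              eta[k] += shift;
              if (use_lik) ll[k] = ll_prop[k];
            }
          }
        }
        ad[5].tally(acc, adapting);
      }
      ad[5].maybe_adapt(adapting);
    }

    // ---- eps_it single-site ----
    if (upd[6]) {
      double s2e = sig2[4];
      for (int k = 0; k < N * T; k++) {
        int i = k % N, t = k / N;
        double delta = R::rnorm(0.0, ad[6].scale);
        double lr = 0.0, lnew = 0.0;
        if (use_lik) {
          lnew = cell_ll(y(i, t), nn(i, t), eta[k] + delta);
          lr += lnew - ll[k];
        }
        double nw = eps[k] + delta;
        lr += -(nw * nw - eps[k] * eps[k]) / (2.0 * s2e);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) {
          eps[k] = nw;
          eta[k] += delta;
          if (use_lik) ll[k] = lnew;
        }
        ad[6].tally(acc, adapting);
      }
      ad[6].maybe_adapt(adapting);
    }

    // ---- variance components ----
    if (upd[7]) {
      double quad[5], rank[5];
      quad[0] = icar_quad(s);          rank[0] = N - 1;
      { double q = 0; for (int i = 0; i < N; i++) q += u[i] * u[i];
        quad[1] = q; } rank[1] = N;
      { double q = 0; for (int t = 0; t < T; t++) q += v[t] * v[t];
        quad[2] = q; } rank[2] = T - 1;  // v lives on the centered subspace
      quad[3] = icar_quad(d1);         rank[3] = N - 1;
      { double q = 0; for (int k = 0; k < N * T; k++) q += eps[k] * eps[k];
        quad[4] = q; } rank[4] = N * T;
      for (int c = 0; c < 5; c++) {
        if (fam == 1) { // conjugate Gibbs on the precision
          double tau = R::rgamma(g_shape + rank[c] / 2.0,
                                 1.0 / (g_rate + quad[c] / 2.0));
          sig2[c] = 1.0 / tau;
        } else {        // random walk on log sigma
          AdaptScale& a = ad[7 + c];
          double lsig = 0.5 * std::log(sig2[c]);
          double lprop = lsig + R::rnorm(0.0, a.scale);
          double lr = sigma_logtarget(lprop, quad[c], rank[c]) -
                      sigma_logtarget(lsig, quad[c], rank[c]);
          bool acc = std::log(R::runif(0.0, 1.0)) < lr;
          if (acc) sig2[c] = std::exp(2.0 * lprop);
          a.tally(acc, adapting); a.maybe_adapt(adapting);
        }
      }
    }

    if (progress_every > 0 && iter % progress_every == 0) {
      double lsum = 0.0;
      for (int k = 0; k < N * T; k++) lsum += ll[k];
      Rprintf("iter %d / %d  log-lik %.2f\n", iter, n_iter, lsum);
    }

    // ---- store ----
    if (iter > burnin && (iter - burnin) % thin == 0) {
      int r = keep_row++;
      int c = 0;
      draws(r, c++) = alpha;
      draws(r, c++) = d0;
      for (int i = 0; i < N; i++) draws(r, c++) = s[i];
      for (int i = 0; i < N; i++) draws(r, c++) = u[i];
      for (int i = 0; i < N; i++) draws(r, c++) = d1[i];
      for (int t = 0; t < T; t++) draws(r, c++) = v[t];
      for (int j = 0; j < 5; j++) draws(r, c++) = sig2[j];
      for (int k = 0; k < N * T; k++) draws(r, c++) = eps[k];
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rates(13), scales(13);
  for (int b = 0; b < 13; b++) {
    acc_rates[b] = ad[b].rate_post();
    scales[b] = ad[b].scale;
  }
  return List::create(_["draws"] = draws,
                      _["acceptance"] = acc_rates,
                      _["prop_scales"] = scales);
}
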