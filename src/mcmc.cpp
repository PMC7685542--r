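// Metropolis-within-Gibbs core for the negative binomial BYM + AR(1) +
// iid-interaction model. One call runs one chain; all randomness comes from
// R's RNG so seeding with set.seed() on the R side gives bit-identical
// chains.
//
// Update order per sweep: u (site-wise, ICAR full-conditional proposal with
// NB likelihood Metropolis correction), sum-to-zero recentring of u with
// compensation absorbed into alpha, v, xi, nu, alpha, rho (logit-scale RW),
// precisions (conjugate Gibbs), r (RW on log r). Blocks with no likelihood
// contribution (areas/quarters/cells with no observed data) are drawn
// exactly from their prior full conditionals, so an all-missing panel
// samples the joint prior.

#include <Rcpp.h>
using namespace Rcpp;

// NB log pmf terms that depend on mu only (size k held fixed)
static inline double nb_mu_kernel(double y, double mu, double k) {
  return k * std::log(k / (k + mu)) + y * std::log(mu / (k + mu));
}

// NB log pmf terms depending on mu and k (lgamma(y+1) dropped)
static inline double nb_rk_kernel(double y, double mu, double k) {
  return R::lgammafn(y + k) - R::lgammafn(k) +
         k * std::log(k / (k + mu)) + y * std::log(mu / (k + mu));
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericMatrix y, NumericMatrix E, LogicalMatrix obs,
                   IntegerVector nb, IntegerVector nb_ptr, IntegerVector comp,
                   int n_comp, List init, List prior, List ctrl) {
  const int I = y.nrow(), T = y.ncol();

  // --- state ---------------------------------------------------------------
  double alpha = as<double>(init["alpha"]);
  NumericVector u = clone(as<NumericVector>(init["u"]));
  NumericVector v = clone(as<NumericVector>(init["v"]));
  NumericVector xi = clone(as<NumericVector>(init["xi"]));
  NumericMatrix nu = clone(as<NumericMatrix>(init["nu"]));
  double rho = as<double>(init["rho"]);
  double r = as<double>(init["r"]);
  double tau_u = as<double>(init["tau_u"]);
  double tau_v = as<double>(init["tau_v"]);
  double tau_xi = as<double>(init["tau_xi"]);
  double tau_nu = as<double>(init["tau_nu"]);

  const double a_tau = as<double>(prior["gamma_shape"]);
  const double b_tau = as<double>(prior["gamma_rate"]);
  const double a_r = as<double>(prior["shape_r"]);
  const double b_r = as<double>(prior["rate_r"]);

  const int n_iter = as<int>(ctrl["n_iter"]);
  const int n_burnin = as<int>(ctrl["n_burnin"]);
  const int thin = as<int>(ctrl["thin"]);
  const int adapt_interval = as<int>(ctrl["adapt_interval"]);
  const double target = as<double>(ctrl["target_accept"]);
  NumericVector sds = clone(as<NumericVector>(ctrl["sds"]));
  double s_v = sds["s_v"], s_xi = sds["s_xi"], s_nu = sds["s_nu"];
  double s_alpha = sds["s_alpha"], s_rho = sds["s_rho"], s_r = sds["s_r"];
  // scales of the likelihood-invariant reparameterisation moves
  double s_uv = sds["s_uv"], s_nv = sds["s_nv"], s_nx = sds["s_nx"],
         s_xa = sds["s_xa"];

  // --- bookkeeping ---------------------------------------------------------
  std::vector<int> deg(I);
  for (int i = 0; i < I; ++i) deg[i] = nb_ptr[i + 1] - nb_ptr[i];

  std::vector<bool> row_obs(I, false), col_obs(T, false);
  bool any_obs = false;
  for (int i = 0; i < I; ++i)
    for (int t = 0; t < T; ++t)
      if (obs(i, t)) { row_obs[i] = true; col_obs[t] = true; any_obs = true; }

  // per-component sizes for recentring
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < I; ++i) comp_size[comp[i]]++;

  // rank of the ICAR precision: non-islands minus their components;
  // counting islands as components gives the same number I - n_comp
  const double rank_u = (double)(I - n_comp);

  NumericMatrix mu(I, T);
  auto refresh_mu = [&]() {
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < I; ++i)
        mu(i, t) = E(i, t) * std::exp(alpha + u[i] + v[i] + xi[t] + nu(i, t));
  };

  const int n_keep = (n_iter - n_burnin) / thin;
  const int P = 7 + 2 * I + T + I * T;
  NumericMatrix draws(n_keep, P);

  // acceptance counters: windows (for adaptation) and totals (post burn-in)
  double accw_v = 0, attw_v = 0, accw_xi = 0, attw_xi = 0, accw_nu = 0, attw_nu = 0;
  double accw_a = 0, attw_a = 0, accw_rho = 0, attw_rho = 0, accw_r = 0, attw_r = 0;
  double acc_u = 0, att_u = 0, acc_v = 0, att_v = 0, acc_xi = 0, att_xi = 0;
  double acc_nu = 0, att_nu = 0, acc_a = 0, att_a = 0, acc_rho = 0, att_rho = 0;
  double acc_r = 0, att_r = 0;
  double accw_uv = 0, attw_uv = 0, accw_nv = 0, attw_nv = 0;
  double accw_nx = 0, attw_nx = 0, accw_xa = 0, attw_xa = 0;

  refresh_mu();
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const double k = 1.0 / r;
    const bool post = it > n_burnin;

    // ---- u: site-wise ICAR full-conditional proposals ---------------------
    for (int i = 0; i < I; ++i) {
      if (deg[i] == 0) { u[i] = 0.0; continue; }  // island policy
      double nbsum = 0.0;
      for (int e = nb_ptr[i]; e < nb_ptr[i + 1]; ++e) nbsum += u[nb[e]];
      const double m = nbsum / deg[i];
      const double prop = R::rnorm(m, 1.0 / std::sqrt(tau_u * deg[i]));
      double dll = 0.0;
      if (row_obs[i]) {
        const double f = std::exp(prop - u[i]);
        for (int t = 0; t < T; ++t)
          if (obs(i, t))
            dll += nb_mu_kernel(y(i, t), mu(i, t) * f, k) -
                   nb_mu_kernel(y(i, t), mu(i, t), k);
      }
      if (post) att_u += 1;
      if (dll >= 0 || R::unif_rand() < std::exp(dll)) {
        const double f = std::exp(prop - u[i]);
        u[i] = prop;
        for (int t = 0; t < T; ++t) mu(i, t) *= f;
        if (post) acc_u += 1;
      }
    }

    // ---- sum-to-zero recentring, compensation into alpha ------------------
    {
      double gm = 0.0;
      for (int i = 0; i < I; ++i) gm += u[i];
      gm /= I;
      std::vector<double> cm(n_comp, 0.0);
      for (int i = 0; i < I; ++i) cm[comp[i]] += u[i];
      for (int c = 0; c < n_comp; ++c) cm[c] /= comp_size[c];
      for (int i = 0; i < I; ++i) u[i] -= cm[comp[i]];
      alpha += gm;
      refresh_mu();
    }

    // ---- v: unstructured spatial effects ----------------------------------
    for (int i = 0; i < I; ++i) {
      if (!row_obs[i]) {  // prior Gibbs draw
        const double newv = R::rnorm(0.0, 1.0 / std::sqrt(tau_v));
        const double f = std::exp(newv - v[i]);
        v[i] = newv;
        for (int t = 0; t < T; ++t) mu(i, t) *= f;
        continue;
      }
      const double prop = v[i] + s_v * R::norm_rand();
      double d = -0.5 * tau_v * (prop * prop - v[i] * v[i]);
      const double f = std::exp(prop - v[i]);
      for (int t = 0; t < T; ++t)
        if (obs(i, t))
          d += nb_mu_kernel(y(i, t), mu(i, t) * f, k) -
               nb_mu_kernel(y(i, t), mu(i, t), k);
      attw_v += 1;
      if (post) att_v += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        v[i] = prop;
        for (int t = 0; t < T; ++t) mu(i, t) *= f;
        accw_v += 1;
        if (post) acc_v += 1;
      }
    }

    // ---- xi: temporal AR(1) effects ---------------------------------------
    for (int t = 0; t < T; ++t) {
      // AR(1) full-conditional mean/precision given the other time points
      double fc_mean, fc_prec;
      if (T == 1) { fc_mean = 0.0; fc_prec = tau_xi; }
      else if (t == 0) { fc_mean = rho * xi[1]; fc_prec = tau_xi; }
      else if (t == T - 1) { fc_mean = rho * xi[T - 2]; fc_prec = tau_xi; }
      else {
        fc_prec = tau_xi * (1.0 + rho * rho);
        fc_mean = rho * (xi[t - 1] + xi[t + 1]) / (1.0 + rho * rho);
      }
      if (!col_obs[t]) {  // prior Gibbs draw
        const double newxi = R::rnorm(fc_mean, 1.0 / std::sqrt(fc_prec));
        const double f = std::exp(newxi - xi[t]);
        xi[t] = newxi;
        for (int i = 0; i < I; ++i) mu(i, t) *= f;
        continue;
      }
      const double prop = xi[t] + s_xi * R::norm_rand();
      double d = -0.5 * fc_prec * ((prop - fc_mean) * (prop - fc_mean) -
                                   (xi[t] - fc_mean) * (xi[t] - fc_mean));
      const double f = std::exp(prop - xi[t]);
      for (int i = 0; i < I; ++i)
        if (obs(i, t))
          d += nb_mu_kernel(y(i, t), mu(i, t) * f, k) -
               nb_mu_kernel(y(i, t), mu(i, t), k);
      attw_xi += 1;
      if (post) att_xi += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        xi[t] = prop;
        for (int i = 0; i < I; ++i) mu(i, t) *= f;
        accw_xi += 1;
        if (post) acc_xi += 1;
      }
    }

    // ---- nu: space-time interaction ---------------------------------------
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < I; ++i) {
        if (!obs(i, t)) {  // prior Gibbs draw
          nu(i, t) = R::rnorm(0.0, 1.0 / std::sqrt(tau_nu));
          mu(i, t) = E(i, t) * std::exp(alpha + u[i] + v[i] + xi[t] + nu(i, t));
          continue;
        }
        const double prop = nu(i, t) + s_nu * R::norm_rand();
        const double f = std::exp(prop - nu(i, t));
        double d = -0.5 * tau_nu * (prop * prop - nu(i, t) * nu(i, t)) +
                   nb_mu_kernel(y(i, t), mu(i, t) * f, k) -
                   nb_mu_kernel(y(i, t), mu(i, t), k);
        attw_nu += 1;
        if (post) att_nu += 1;
        if (d >= 0 || R::unif_rand() < std::exp(d)) {
          nu(i, t) = prop;
          mu(i, t) *= f;
          accw_nu += 1;
          if (post) acc_nu += 1;
        }
      }
    }

    // ---- reparameterisation moves -----------------------------------------
    // All four proposals leave the linear predictor (hence the likelihood)
    // unchanged and are accepted on prior ratios alone. They let variance
    // flow between nested explanations of the same signal (interaction vs
    // main effects, structured vs unstructured, temporal mean vs intercept),
    // which single-site sweeps exchange only geometrically slowly.

    // (a) u[i] <- u[i] + c, v[i] <- v[i] - c : BYM split
    for (int i = 0; i < I; ++i) {
      if (deg[i] == 0) continue;
      const double c = s_uv * R::norm_rand();
      double dS = 0.0;
      for (int e = nb_ptr[i]; e < nb_ptr[i + 1]; ++e) {
        const double d0 = u[i] - u[nb[e]];
        dS += (d0 + c) * (d0 + c) - d0 * d0;
      }
      const double vn = v[i] - c;
      const double d = -0.5 * tau_u * dS - 0.5 * tau_v * (vn * vn - v[i] * v[i]);
      attw_uv += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        u[i] += c;
        v[i] = vn;
        accw_uv += 1;
      }
    }

    // (b) v[i] <- v[i] + c, nu[i, .] <- nu[i, .] - c : area-persistent
    //     content of the interaction moves into the unstructured effect
    for (int i = 0; i < I; ++i) {
      const double c = s_nv * R::norm_rand();
      const double vn = v[i] + c;
      double d = -0.5 * tau_v * (vn * vn - v[i] * v[i]);
      double dn = 0.0;
      for (int t = 0; t < T; ++t) {
        const double n0 = nu(i, t), n1 = n0 - c;
        dn += n1 * n1 - n0 * n0;
      }
      d += -0.5 * tau_nu * dn;
      attw_nv += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        v[i] = vn;
        for (int t = 0; t < T; ++t) nu(i, t) -= c;
        accw_nv += 1;
      }
    }

    // (c) xi[t] <- xi[t] + c, nu[., t] <- nu[., t] - c : time-persistent
    //     content of the interaction moves into the temporal effect
    for (int t = 0; t < T; ++t) {
      const double c = s_nx * R::norm_rand();
      const double xn = xi[t] + c;
      double Q0, Q1;
      if (t == 0) {
        Q0 = (1.0 - rho * rho) * xi[0] * xi[0];
        Q1 = (1.0 - rho * rho) * xn * xn;
        if (T > 1) {
          const double e0 = xi[1] - rho * xi[0], e1 = xi[1] - rho * xn;
          Q0 += e0 * e0; Q1 += e1 * e1;
        }
      } else {
        const double e0 = xi[t] - rho * xi[t - 1], e1 = xn - rho * xi[t - 1];
        Q0 = e0 * e0; Q1 = e1 * e1;
        if (t < T - 1) {
          const double f0 = xi[t + 1] - rho * xi[t], f1 = xi[t + 1] - rho * xn;
          Q0 += f0 * f0; Q1 += f1 * f1;
        }
      }
      double d = -0.5 * tau_xi * (Q1 - Q0);
      double dn = 0.0;
      for (int i = 0; i < I; ++i) {
        const double n0 = nu(i, t), n1 = n0 - c;
        dn += n1 * n1 - n0 * n0;
      }
      d += -0.5 * tau_nu * dn;
      attw_nx += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        xi[t] = xn;
        for (int i = 0; i < I; ++i) nu(i, t) -= c;
        accw_nx += 1;
      }
    }

    // (d) xi <- xi + c, alpha <- alpha - c : temporal level vs intercept
    if (any_obs) {
      const double c = s_xa * R::norm_rand();
      double Q0 = (1.0 - rho * rho) * xi[0] * xi[0];
      double Q1 = (1.0 - rho * rho) * (xi[0] + c) * (xi[0] + c);
      for (int t = 1; t < T; ++t) {
        const double e0 = xi[t] - rho * xi[t - 1];
        const double e1 = e0 + c * (1.0 - rho);
        Q0 += e0 * e0; Q1 += e1 * e1;
      }
      const double d = -0.5 * tau_xi * (Q1 - Q0);
      attw_xa += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        for (int t = 0; t < T; ++t) xi[t] += c;
        alpha -= c;
        accw_xa += 1;
      }
    }

    // the moves shifted components of the linear predictor jointly; mu is
    // unchanged in exact arithmetic but refresh to prevent drift
    refresh_mu();

    // ---- alpha: flat prior, likelihood-only RW (skipped with no data) -----
    if (any_obs) {
      const double da = s_alpha * R::norm_rand();
      const double f = std::exp(da);
      double d = 0.0;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < I; ++i)
          if (obs(i, t))
            d += nb_mu_kernel(y(i, t), mu(i, t) * f, k) -
                 nb_mu_kernel(y(i, t), mu(i, t), k);
      attw_a += 1;
      if (post) att_a += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        alpha += da;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < I; ++i) mu(i, t) *= f;
        accw_a += 1;
        if (post) acc_a += 1;
      }
    }

    // ---- rho: RW on z = log((1+rho)/(1-rho)), Uniform(-1,1) prior ---------
    if (T >= 2) {
      const double z = std::log((1.0 + rho) / (1.0 - rho));
      const double zp = z + s_rho * R::norm_rand();
      const double rp = (std::exp(zp) - 1.0) / (std::exp(zp) + 1.0);
      auto ar1_rho_terms = [&](double rh) {
        double Q = (1.0 - rh * rh) * xi[0] * xi[0];
        for (int t = 1; t < T; ++t) {
          const double e = xi[t] - rh * xi[t - 1];
          Q += e * e;
        }
        return 0.5 * std::log(1.0 - rh * rh) - 0.5 * tau_xi * Q;
      };
      // Jacobian of rho -> z: (1 - rho^2)/2
      double d = ar1_rho_terms(rp) - ar1_rho_terms(rho) +
                 std::log(1.0 - rp * rp) - std::log(1.0 - rho * rho);
      attw_rho += 1;
      if (post) att_rho += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        rho = rp;
        accw_rho += 1;
        if (post) acc_rho += 1;
      }
    }

    // ---- precisions: conjugate Gibbs --------------------------------------
    {
      double S = 0.0;
      for (int i = 0; i < I; ++i)
        for (int e = nb_ptr[i]; e < nb_ptr[i + 1]; ++e)
          if (nb[e] > i) {
            const double dd = u[i] - u[nb[e]];
            S += dd * dd;
          }
      tau_u = R::rgamma(a_tau + 0.5 * rank_u, 1.0 / (b_tau + 0.5 * S));

      double sv = 0.0;
      for (int i = 0; i < I; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a_tau + 0.5 * I, 1.0 / (b_tau + 0.5 * sv));

      double Q = (1.0 - rho * rho) * xi[0] * xi[0];
      for (int t = 1; t < T; ++t) {
        const double e = xi[t] - rho * xi[t - 1];
        Q += e * e;
      }
      tau_xi = R::rgamma(a_tau + 0.5 * T, 1.0 / (b_tau + 0.5 * Q));

      double sn = 0.0;
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < I; ++i) sn += nu(i, t) * nu(i, t);
      tau_nu = R::rgamma(a_tau + 0.5 * I * T, 1.0 / (b_tau + 0.5 * sn));
    }

    // ---- r: RW on log r; prior p(theta) = exp(-a_r*theta - b_r*exp(-theta))
    {
      const double th = std::log(r);
      const double thp = th + s_r * R::norm_rand();
      const double rp = std::exp(thp);
      double d = -a_r * (thp - th) - b_r * (std::exp(-thp) - std::exp(-th));
      if (any_obs) {
        const double kp = 1.0 / rp;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < I; ++i)
            if (obs(i, t))
              d += nb_rk_kernel(y(i, t), mu(i, t), kp) -
                   nb_rk_kernel(y(i, t), mu(i, t), k);
      }
      attw_r += 1;
      if (post) att_r += 1;
      if (d >= 0 || R::unif_rand() < std::exp(d)) {
        r = rp;
        accw_r += 1;
        if (post) acc_r += 1;
      }
    }

    // ---- adaptation: burn-in only, so the post-burn-in kernel is fixed ----
    if (!post && adapt_interval > 0 && it % adapt_interval == 0) {
      auto tune = [&](double& s, double acc, double att) {
        if (att < 1) return;
        double f = std::exp((acc / att) - target);
        s *= f;
        if (s < 1e-6) s = 1e-6;
        if (s > 100.0) s = 100.0;
      };
      tune(s_v, accw_v, attw_v);
      tune(s_xi, accw_xi, attw_xi);
      tune(s_nu, accw_nu, attw_nu);
      tune(s_alpha, accw_a, attw_a);
      tune(s_rho, accw_rho, attw_rho);
      tune(s_r, accw_r, attw_r);
      tune(s_uv, accw_uv, attw_uv);
      tune(s_nv, accw_nv, attw_nv);
      tune(s_nx, accw_nx, attw_nx);
      tune(s_xa, accw_xa, attw_xa);
      accw_v = attw_v = accw_xi = attw_xi = accw_nu = attw_nu = 0;
      accw_a = attw_a = accw_rho = attw_rho = accw_r = attw_r = 0;
      accw_uv = attw_uv = accw_nv = attw_nv = 0;
      accw_nx = attw_nx = accw_xa = attw_xa = 0;
    }

    // ---- storage ----------------------------------------------------------
    if (post && ((it - n_burnin) % thin == 0) && keep < n_keep) {
      int c = 0;
      draws(keep, c++) = alpha;
      draws(keep, c++) = rho;
      draws(keep, c++) = r;
      draws(keep, c++) = tau_u;
      draws(keep, c++) = tau_v;
      draws(keep, c++) = tau_xi;
      draws(keep, c++) = tau_nu;
      for (int i = 0; i < I; ++i) draws(keep, c++) = u[i];
      for (int i = 0; i < I; ++i) draws(keep, c++) = v[i];
      for (int t = 0; t < T; ++t) draws(keep, c++) = xi[t];
      for (int t = 0; t < T; ++t)
        for (int i = 0; i < I; ++i) draws(keep, c++) = nu(i, t);
      keep++;
    }

    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc = NumericVector::create(
      _["u"] = att_u > 0 ? acc_u / att_u : NA_REAL,
      _["v"] = att_v > 0 ? acc_v / att_v : NA_REAL,
      _["xi"] = att_xi > 0 ? acc_xi / att_xi : NA_REAL,
      _["nu"] = att_nu > 0 ? acc_nu / att_nu : NA_REAL,
      _["alpha"] = att_a > 0 ? acc_a / att_a : NA_REAL,
      _["rho"] = att_rho > 0 ? acc_rho / att_rho : NA_REAL,
      _["r"] = att_r > 0 ? acc_r / att_r : NA_REAL);
  NumericVector sds_out = NumericVector::create(
      _["s_v"] = s_v, _["s_xi"] = s_xi, _["s_nu"] = s_nu,
      _["s_alpha"] = s_alpha, _["s_rho"] = s_rho, _["s_r"] = s_r,
      _["s_uv"] = s_uv, _["s_nv"] = s_nv, _["s_nx"] = s_nx,
      _["s_xa"] = s_xa);

  return List::create(_["draws"] = draws, _["acceptance"] = acc,
                      _["proposal_sds"] = sds_out);
}
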