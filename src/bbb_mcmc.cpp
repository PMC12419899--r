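// Metropolis-Hastings sampler for the Brownian-bridge clade-age model.
//
// Parameter space: root age t0, extinction age te (extinct clades only),
// random-walk variance s2, preservation parameters q0 and beta, and the
// latent log-diversity trajectory y over the 1-Myr lifespan bins.  Bin k
// covers [k, k+1) Ma; it is inside the lifespan when its midpoint k+0.5
// lies strictly inside (te, t0) — a midpoint exactly on an anchor age
// would give a degenerate increment.  Anchors: y = 0 at t0 (one founding
// species) and, at
// the young end, y = log(extant richness) at age 0 (extant) or y = 0 at te
// (extinct).  The trajectory prior is the bridge conditioned on both
// anchors with a floor y >= 0 inside the lifespan.
//
// When t0 or te moves change the number of lifespan bins, new trajectory
// values are proposed from the conditional bridge prior, so the proposal
// density cancels against the prior in the acceptance ratio (unit
// Jacobian).  Block trajectory updates redraw a sub-segment from the
// bridge conditional on its flanking values; only the observation term
// and the floor survive in the ratio.
//
// All randomness comes from R's RNG, so set.seed() makes runs bit-exact.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double dnorm_log(double x, double mean, double sd) {
  return R::dnorm(x, mean, sd, 1);
}

struct SegDraw {
  std::vector<double> v;  // values in draw order (descending age)
  double logq;
};

// Exact sequential draw of a Brownian bridge at descending interior ages,
// conditioned on (aL, vL) older and (aR, vR) younger.
SegDraw draw_segment(double aL, double vL, double aR, double vR,
                     const std::vector<double>& ages, double s2) {
  SegDraw d;
  d.v.resize(ages.size());
  d.logq = 0.0;
  double ap = aL, vp = vL;
  for (size_t i = 0; i < ages.size(); ++i) {
    double m = ages[i];
    double A = ap - m, B = m - aR;
    double mean = vp + (vR - vp) * A / (A + B);
    double sd = std::sqrt(s2 * A * B / (A + B));
    double y = mean + sd * norm_rand();
    d.logq += dnorm_log(y, mean, sd);
    d.v[i] = y;
    ap = m;
    vp = y;
  }
  return d;
}

// Density of an existing segment under the same conditional construction.
double segment_logdens(double aL, double vL, double aR, double vR,
                       const std::vector<double>& ages,
                       const std::vector<double>& vals, double s2) {
  double lq = 0.0, ap = aL, vp = vL;
  for (size_t i = 0; i < ages.size(); ++i) {
    double m = ages[i];
    double A = ap - m, B = m - aR;
    double mean = vp + (vR - vp) * A / (A + B);
    double sd = std::sqrt(s2 * A * B / (A + B));
    lq += dnorm_log(vals[i], mean, sd);
    ap = m;
    vp = vals[i];
  }
  return lq;
}

} // namespace

// [[Rcpp::export]]
List bbb_mcmc_cpp(IntegerVector counts, double extant_richness,
                  bool is_extinct, double max_age, double min_t0,
                  double te_max, int iterations, int sampling_freq,
                  double burnin_frac, int q_var, double s2_rate,
                  double q0_rate, double beta_rate, double init_t0,
                  double init_te, double init_s2, double init_q0,
                  double init_beta, bool update_t0, bool update_te,
                  bool update_s2, bool update_q0, bool update_beta,
                  bool prior_only, bool adapt) {
  const int nbin_data = counts.size();
  const bool floor_on = !prior_only;

  // --- state ---
  double t0 = init_t0, te = init_te, s2 = init_s2, q0 = init_q0,
         beta = init_beta;
  double yend = is_extinct ? 0.0 : std::log(extant_richness);
  double young_age = is_extinct ? te : 0.0;
  int klo = (int)std::floor(young_age - 0.5) + 1;
  int khi = (int)std::ceil(t0 - 0.5) - 1;
  std::vector<double> y(khi - klo + 1);
  for (int k = klo; k <= khi; ++k) {  // linear interpolation of the anchors
    double m = k + 0.5;
    y[k - klo] = 0.0 + (yend - 0.0) * (t0 - m) / (t0 - young_age);
  }

  auto bridge_lp = [&](const std::vector<double>& yy, int lo, int hi,
                       double root, double ya, double s2v) -> double {
    if (floor_on)
      for (double v : yy)
        if (v < 0) return R_NegInf;
    double lp = 0.0, ap = root, vp = 0.0;
    for (int k = hi; k >= lo; --k) {
      double m = k + 0.5;
      lp += dnorm_log(yy[k - lo], vp, std::sqrt(s2v * (ap - m)));
      ap = m;
      vp = yy[k - lo];
    }
    lp += dnorm_log(yend, vp, std::sqrt(s2v * (ap - ya)));
    lp -= dnorm_log(yend, 0.0, std::sqrt(s2v * (root - ya)));
    return lp;
  };

  auto obs_ll = [&](const std::vector<double>& yy, int lo, int hi,
                    double root, double q0v, double betav) -> double {
    if (prior_only) return 0.0;
    double ll = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double lam = q0v * std::exp(betav * (root - (k + 0.5))) *
                   std::exp(yy[k - lo]);
      double x = (k < nbin_data) ? (double)counts[k] : 0.0;
      ll += x * std::log(lam) - lam - std::lgamma(x + 1.0);
    }
    return ll;
  };

  auto hyper_lp = [&](double s2v, double q0v, double betav) -> double {
    double h = std::log(s2_rate) - s2_rate * s2v + std::log(q0_rate) -
               q0_rate * q0v;
    if (q_var == 1) h += std::log(beta_rate) - beta_rate * betav;
    return h;
  };

  double cur_B = bridge_lp(y, klo, khi, t0, young_age, s2);
  double cur_obs = obs_ll(y, klo, khi, t0, q0, beta);
  double cur_H = hyper_lp(s2, q0, beta);

  // --- moves ---
  enum { M_T0 = 0, M_TE, M_TRAJ, M_S2, M_Q0, M_BETA, M_SHIFT, M_TILT,
         N_MOVES };
  double weight[N_MOVES] = {0.18, 0.13, 0.29, 0.07, 0.08, 0.07, 0.10, 0.08};
  if (!update_t0) weight[M_T0] = 0;
  if (!is_extinct || !update_te) weight[M_TE] = 0;
  if (!update_s2) weight[M_S2] = 0;
  if (!update_q0) { weight[M_Q0] = 0; weight[M_SHIFT] = 0; }
  if (q_var != 1 || !update_beta) { weight[M_BETA] = 0; weight[M_TILT] = 0; }
  double wsum = 0;
  for (int i = 0; i < N_MOVES; ++i) wsum += weight[i];

  // windows / log-multipliers / shear slope
  double scale[N_MOVES] = {8.0, 4.0, 0.0, 0.8, 0.8, 0.8, 0.5, 0.004};
  int n_prop[N_MOVES] = {0}, n_acc[N_MOVES] = {0};
  int win_prop[N_MOVES] = {0}, win_acc[N_MOVES] = {0};
  const int block_max = 15;
  const int burn_iters = (int)(burnin_frac * iterations);

  const int nsamp =
      iterations / sampling_freq - burn_iters / sampling_freq;
  NumericMatrix samples(nsamp, 7);
  int row = 0;

  for (int it = 1; it <= iterations; ++it) {
    // pick a move
    double u = unif_rand() * wsum;
    int mv = 0;
    for (; mv < N_MOVES - 1; ++mv) {
      if (u < weight[mv]) break;
      u -= weight[mv];
    }
    ++n_prop[mv];
    ++win_prop[mv];
    bool accepted = false;

    if (mv == M_T0) {
      double t0p = t0 + scale[M_T0] * (unif_rand() - 0.5) * 2.0;
      if (t0p >= min_t0 && t0p <= max_age && t0p > young_age + 1e-8) {
        int khip = (int)std::ceil(t0p - 0.5) - 1;
        std::vector<double> yp;
        double Sq_new = 0.0, Sq_old = 0.0;
        bool ok = true;
        if (khip >= khi) {
          yp = y;
          if (khip > khi) {
            std::vector<double> ages(khip - khi);
            for (int k = khip; k > khi; --k) ages[khip - k] = k + 0.5;
            SegDraw d = draw_segment(t0p, 0.0, khi + 0.5, y[khi - klo],
                                     ages, s2);
            Sq_new = d.logq;
            yp.resize(khip - klo + 1);
            for (int k = khi + 1; k <= khip; ++k)
              yp[k - klo] = d.v[khip - k];
          }
        } else {
          if (khip < klo) {
            ok = false;  // lifespan would lose all bins
          } else {
            yp.assign(y.begin(), y.begin() + (khip - klo + 1));
            std::vector<double> ages(khi - khip), vals(khi - khip);
            for (int k = khi; k > khip; --k) {
              ages[khi - k] = k + 0.5;
              vals[khi - k] = y[k - klo];
            }
            Sq_old = segment_logdens(t0, 0.0, khip + 0.5, y[khip - klo],
                                     ages, vals, s2);
          }
        }
        if (ok) {
          double Bp = bridge_lp(yp, klo, khip, t0p, young_age, s2);
          double obsp = obs_ll(yp, klo, khip, t0p, q0, beta);
          double logA = (obsp + Bp - Sq_new) - (cur_obs + cur_B - Sq_old);
          if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
            t0 = t0p;
            khi = khip;
            y.swap(yp);
            cur_B = Bp;
            cur_obs = obsp;
            accepted = true;
          }
        }
      }
    } else if (mv == M_TE) {
      double tep = te + scale[M_TE] * (unif_rand() - 0.5) * 2.0;
      if (tep >= 0.0 && tep <= te_max && tep < t0 - 1e-8) {
        int klop = (int)std::floor(tep - 0.5) + 1;
        std::vector<double> yp;
        double Sq_new = 0.0, Sq_old = 0.0;
        bool ok = (klop <= khi);
        if (ok) {
          if (klop <= klo) {
            yp.assign(khi - klop + 1, 0.0);
            for (int k = klo; k <= khi; ++k) yp[k - klop] = y[k - klo];
            if (klop < klo) {
              std::vector<double> ages(klo - klop);
              for (int k = klo - 1; k >= klop; --k)
                ages[klo - 1 - k] = k + 0.5;
              SegDraw d = draw_segment(klo + 0.5, y[0], tep, yend, ages, s2);
              Sq_new = d.logq;
              for (int k = klop; k < klo; ++k)
                yp[k - klop] = d.v[klo - 1 - k];
            }
          } else {  // klop > klo: drop young bins
            yp.assign(y.begin() + (klop - klo), y.end());
            std::vector<double> ages(klop - klo), vals(klop - klo);
            for (int k = klop - 1; k >= klo; --k) {
              ages[klop - 1 - k] = k + 0.5;
              vals[klop - 1 - k] = y[k - klo];
            }
            Sq_old = segment_logdens(klop + 0.5, y[klop - klo], te, yend,
                                     ages, vals, s2);
          }
          double Bp = bridge_lp(yp, klop, khi, t0, tep, s2);
          double obsp = obs_ll(yp, klop, khi, t0, q0, beta);
          double logA = (obsp + Bp - Sq_new) - (cur_obs + cur_B - Sq_old);
          if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
            te = tep;
            young_age = tep;
            klo = klop;
            y.swap(yp);
            cur_B = Bp;
            cur_obs = obsp;
            accepted = true;
          }
        }
      }
    } else if (mv == M_TRAJ) {
      int L = khi - klo + 1;
      int s = (int)(unif_rand() * L);
      if (s >= L) s = L - 1;
      int maxlen = std::min(L - s, block_max);
      int len = 1 + (int)(unif_rand() * maxlen);
      if (len > maxlen) len = maxlen;
      int j = s + len - 1;  // indices s..j of y (ascending bin)
      double aL = (j == L - 1) ? t0 : (klo + j + 1 + 0.5);
      double vL = (j == L - 1) ? 0.0 : y[j + 1];
      double aR = (s == 0) ? young_age : (klo + s - 1 + 0.5);
      double vR = (s == 0) ? yend : y[s - 1];
      std::vector<double> ages(len);
      for (int i = 0; i < len; ++i) ages[i] = klo + (j - i) + 0.5;
      SegDraw d = draw_segment(aL, vL, aR, vR, ages, s2);
      bool ok = true;
      if (floor_on)
        for (double v : d.v)
          if (v < 0) { ok = false; break; }
      if (ok) {
        double dobs = 0.0;
        if (!prior_only) {
          for (int i = 0; i < len; ++i) {
            int k = klo + (j - i);
            double q = q0 * std::exp(beta * (t0 - (k + 0.5)));
            double x = (k < nbin_data) ? (double)counts[k] : 0.0;
            double lam_new = q * std::exp(d.v[i]);
            double lam_old = q * std::exp(y[k - klo]);
            dobs += x * (d.v[i] - y[k - klo]) - (lam_new - lam_old);
          }
        }
        if (std::log(unif_rand()) < dobs) {
          for (int i = 0; i < len; ++i) y[(j - i)] = d.v[i];
          cur_obs += dobs;
          cur_B = bridge_lp(y, klo, khi, t0, young_age, s2);
          accepted = true;
        }
      }
    } else if (mv == M_S2) {
      double s2p = s2 * std::exp(scale[M_S2] * (unif_rand() - 0.5));
      double Bp = bridge_lp(y, klo, khi, t0, young_age, s2p);
      double logA = Bp - cur_B - s2_rate * (s2p - s2) + std::log(s2p / s2);
      if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
        s2 = s2p;
        cur_B = Bp;
        cur_H = hyper_lp(s2, q0, beta);
        accepted = true;
      }
    } else if (mv == M_Q0) {
      double q0p = q0 * std::exp(scale[M_Q0] * (unif_rand() - 0.5));
      double obsp = obs_ll(y, klo, khi, t0, q0p, beta);
      double logA =
          obsp - cur_obs - q0_rate * (q0p - q0) + std::log(q0p / q0);
      if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
        q0 = q0p;
        cur_obs = obsp;
        cur_H = hyper_lp(s2, q0, beta);
        accepted = true;
      }
    } else if (mv == M_BETA) {
      double betap = beta * std::exp(scale[M_BETA] * (unif_rand() - 0.5));
      double obsp = obs_ll(y, klo, khi, t0, q0, betap);
      double logA = obsp - cur_obs - beta_rate * (betap - beta) +
                    std::log(betap / beta);
      if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
        beta = betap;
        cur_obs = obsp;
        cur_H = hyper_lp(s2, q0, beta);
        accepted = true;
      }
    } else if (mv == M_TILT) {
      // joint shear along the (beta, trajectory-slope) ridge:
      // y_k -> y_k + g * (t0 - m_k), beta -> beta - g.  Every Poisson mean
      // is unchanged (unit Jacobian shear), so only the bridge prior and
      // the beta hyperprior enter the ratio.
      double g = scale[M_TILT] * (unif_rand() - 0.5) * 2.0;
      double betap = beta - g;
      if (betap > 0) {
        std::vector<double> yp(y);
        for (int k = klo; k <= khi; ++k)
          yp[k - klo] += g * (t0 - (k + 0.5));
        double Bp = bridge_lp(yp, klo, khi, t0, young_age, s2);
        double logA = Bp - cur_B - beta_rate * (betap - beta);
        if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
          y.swap(yp);
          beta = betap;
          cur_B = Bp;
          cur_H = hyper_lp(s2, q0, beta);
          accepted = true;
        }
      }
    } else {  // M_SHIFT: joint level shift along the (q0, trajectory) ridge
      // y -> y + c, q0 -> q0 * exp(-c): every Poisson mean q(t) * N_t is
      // unchanged, so only the bridge prior (anchor increments), the q0
      // hyperprior and the log |Jacobian| = -c enter the ratio.
      double c = scale[M_SHIFT] * (unif_rand() - 0.5) * 2.0;
      double q0p = q0 * std::exp(-c);
      std::vector<double> yp(y);
      for (double& v : yp) v += c;
      double Bp = bridge_lp(yp, klo, khi, t0, young_age, s2);
      double logA = Bp - cur_B - q0_rate * (q0p - q0) - c;
      if (std::isfinite(logA) && std::log(unif_rand()) < logA) {
        y.swap(yp);
        q0 = q0p;
        cur_B = Bp;
        cur_H = hyper_lp(s2, q0, beta);
        accepted = true;
      }
    }

    if (accepted) {
      ++n_acc[mv];
      ++win_acc[mv];
    }

    // proposal-scale tuning, burn-in only (target acceptance 0.2-0.5)
    if (adapt && it <= burn_iters && mv != M_TRAJ && win_prop[mv] >= 50) {
      double rate = (double)win_acc[mv] / win_prop[mv];
      if (rate > 0.5) scale[mv] *= 1.25;
      else if (rate < 0.2) scale[mv] /= 1.25;
      if (mv == M_T0 || mv == M_TE) {
        if (scale[mv] < 0.05) scale[mv] = 0.05;
        if (scale[mv] > 200.0) scale[mv] = 200.0;
      } else if (mv == M_TILT) {
        if (scale[mv] < 2e-4) scale[mv] = 2e-4;
        if (scale[mv] > 0.05) scale[mv] = 0.05;
      } else {
        if (scale[mv] < 0.01) scale[mv] = 0.01;
        if (scale[mv] > 6.0) scale[mv] = 6.0;
      }
      win_prop[mv] = 0;
      win_acc[mv] = 0;
    }

    if (it > burn_iters && it % sampling_freq == 0 && row < nsamp) {
      samples(row, 0) = it;
      samples(row, 1) = cur_B + cur_obs + cur_H;
      samples(row, 2) = t0;
      samples(row, 3) = te;
      samples(row, 4) = s2;
      samples(row, 5) = q0;
      samples(row, 6) = beta;
      ++row;
    }
  }

  NumericVector yout(y.begin(), y.end());
  NumericVector acc(N_MOVES), prop(N_MOVES);
  for (int i = 0; i < N_MOVES; ++i) {
    acc[i] = n_acc[i];
    prop[i] = n_prop[i];
  }
  return List::create(
      _["samples"] = samples, _["final_y"] = yout, _["final_klo"] = klo,
      _["final_khi"] = khi, _["final_t0"] = t0, _["final_te"] = te,
      _["final_sigma2"] = s2, _["final_q0"] = q0, _["final_beta"] = beta,
      _["accepts"] = acc, _["proposals"] = prop,
      _["logpost"] = cur_B + cur_obs + cur_H);
}
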