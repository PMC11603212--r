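// Daily-timestep individual-based engine for the kill-trapping model.
//
// One call simulates the whole trapping window night by night:
//   1. on reproduction-season onset, re-record the adult count N*
//   2. births  ~ Binomial(adults, B(t) * dt), newborns placed uniformly
//   3. deaths  ~ per-individual Bernoulli(M / 365 * dt)
//   4. captures: per-individual Bernoulli(p_encTOT), then a lure draw,
//      then Bernoulli(p_int for that lure); kill-traps remove the animal
// sigma, g0 and the trap-inclusion radius are recomputed from the current
// density whenever the composition of the population (or the set of active
// traps) has changed. All randomness comes from R's RNG so results are
// reproducible with set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_engine_cpp")]]
List sim_engine_cpp(NumericVector hx0, NumericVector hy0, NumericMatrix pint0,
                    IntegerVector age0,
                    NumericVector trap_x, NumericVector trap_y,
                    IntegerVector trap_active_night,
                    int n_days, NumericVector fvals, LogicalVector repro_onset,
                    List par,
                    int mode,            // 0 single, 1 simultaneous, 2 switch
                    double rc, int trigger_window, double share_new,
                    NumericVector beta_a, NumericVector beta_b,
                    double rect_w, double rect_h, bool copy_lures) {
  const int n0 = hx0.size();
  const int J = trap_x.size();
  const int L = pint0.ncol();

  const double area       = as<double>(par["area_ha"]);
  const double alpha      = as<double>(par["birth_rate_max"]);
  const double c_dd       = as<double>(par["density_coeff"]);
  const double m_annual   = as<double>(par["mortality_rate"]);
  const double mu0        = as<double>(par["mu0"]);
  const double s_coeff    = as<double>(par["sigma_coeff"]);
  const double s_exp      = as<double>(par["sigma_exp"]);
  const double s_max      = as<double>(par["sigma_max_m"]);
  const double g_coeff    = as<double>(par["g0_coeff"]);
  const double g_exp      = as<double>(par["g0_exp"]);
  const double hr_mult    = as<double>(par["hr_mult"]);
  const double perception = as<double>(par["perception_distance_m"]);
  const double dt         = as<double>(par["dt_days"]);
  const int adult_age     = as<int>(par["adult_age_days"]);

  std::vector<double> Hx(hx0.begin(), hx0.end());
  std::vector<double> Hy(hy0.begin(), hy0.end());
  std::vector< std::vector<double> > P(L);
  for (int l = 0; l < L; ++l) {
    P[l].assign(pint0.column(l).begin(), pint0.column(l).end());
  }
  std::vector<int> age(age0.begin(), age0.end());
  std::vector<char> alive(n0, 1);
  std::vector<int> capn(n0, NA_INTEGER);

  // neighbour lists: traps within the largest possible inclusion radius
  const double max_r = hr_mult * s_max + perception;
  const double max_r2 = max_r * max_r;
  std::vector< std::vector<int> > nb_idx(n0);
  std::vector< std::vector<double> > nb_d2(n0);
  auto build_nb = [&](int i) {
    // sorted by squared distance so the nightly loop can stop at the
    // current (density-dependent, usually much smaller) inclusion radius
    std::vector< std::pair<double, int> > tmp;
    for (int j = 0; j < J; ++j) {
      double dx = Hx[i] - trap_x[j], dy = Hy[i] - trap_y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 <= max_r2) tmp.push_back(std::make_pair(d2, j));
    }
    std::sort(tmp.begin(), tmp.end());
    nb_idx[i].resize(tmp.size());
    nb_d2[i].resize(tmp.size());
    for (size_t k = 0; k < tmp.size(); ++k) {
      nb_d2[i][k] = tmp[k].first;
      nb_idx[i][k] = tmp[k].second;
    }
  };
  for (int i = 0; i < n0; ++i) build_nb(i);

  // nights on which a trap becomes active (forces a probability refresh)
  std::vector<char> act_change(n_days + 2, 0);
  for (int j = 0; j < J; ++j) {
    int a = trap_active_night[j];
    if (a >= 1 && a <= n_days) act_change[a] = 1;
  }

  IntegerVector out_capt(n_days), out_birth(n_days), out_death(n_days),
      out_nalive(n_days), out_nadult(n_days);
  std::vector<double> pTot;
  bool dirty = true;
  int last_nalive = -1;
  const double md = m_annual / 365.0 * dt;

  int n_star = 0;
  for (int i = 0; i < n0; ++i) {
    if (alive[i] && age[i] >= adult_age) ++n_star;
  }
  bool switched = false;
  int switch_day = NA_INTEGER;
  double init_rate = -1.0;

  for (int day = 1; day <= n_days; ++day) {
    int N = (int) Hx.size();

    // adult census at reproduction-season onset
    if (repro_onset[day - 1]) {
      int na = 0;
      for (int i = 0; i < N; ++i) {
        if (alive[i] && age[i] >= adult_age) ++na;
      }
      n_star = na;
    }

    // births
    int n_adults = 0, n_alive_now = 0;
    for (int i = 0; i < N; ++i) {
      if (alive[i]) {
        ++n_alive_now;
        if (age[i] >= adult_age) ++n_adults;
      }
    }
    double B = (alpha - c_dd * n_star) * fvals[day - 1] * dt;
    if (B < 0) B = 0;
    if (B > 1) B = 1;
    int nb = (n_adults > 0 && B > 0) ? (int) R::rbinom(n_adults, B) : 0;
    for (int k = 0; k < nb; ++k) {
      Hx.push_back(R::runif(0.0, rect_w));
      Hy.push_back(R::runif(0.0, rect_h));
      for (int l = 0; l < L; ++l) {
        double v = (copy_lures && l > 0)
            ? P[0].back()
            : R::rbeta(beta_a[l], beta_b[l]);
        P[l].push_back(v);
      }
      age.push_back(0);
      alive.push_back(1);
      capn.push_back(NA_INTEGER);
      nb_idx.push_back(std::vector<int>());
      nb_d2.push_back(std::vector<double>());
      build_nb((int) Hx.size() - 1);
    }
    if (nb > 0) { dirty = true; n_alive_now += nb; N += nb; }
    out_birth[day - 1] = nb;

    // natural deaths (newborns die at the adult rate)
    int nd = 0;
    for (int i = 0; i < N; ++i) {
      if (alive[i] && unif_rand() < md) { alive[i] = 0; ++nd; }
    }
    if (nd > 0) { dirty = true; n_alive_now -= nd; }
    out_death[day - 1] = nd;

    // captures
    int ncap = 0;
    if (act_change[day]) dirty = true;
    if (J > 0 && n_alive_now > 0) {
      if (dirty || n_alive_now != last_nalive) {
        double D = n_alive_now / area;
        double sigma = (D <= 0) ? s_max
                                : std::min(s_max, s_coeff * std::pow(D, s_exp));
        double g0 = std::min(1.0, g_coeff * std::pow(sigma, g_exp));
        double radius = hr_mult * sigma + perception;
        double r2 = radius * radius;
        double ge = g0 / mu0;
        double inv2s2 = 1.0 / (2.0 * sigma * sigma);
        pTot.assign(N, 0.0);
        for (int i = 0; i < N; ++i) {
          if (!alive[i]) continue;
          double q = 1.0;
          const std::vector<int>& idx = nb_idx[i];
          const std::vector<double>& dd2 = nb_d2[i];
          for (size_t k = 0; k < idx.size(); ++k) {
            if (dd2[k] > r2) break;  // lists are distance-sorted
            if (trap_active_night[idx[k]] > day) continue;
            double pe = ge * std::exp(-dd2[k] * inv2s2);
            if (pe > 1.0) pe = 1.0;
            q *= (1.0 - pe);
          }
          pTot[i] = 1.0 - q;
        }
        last_nalive = n_alive_now;
        dirty = false;
      }
      for (int i = 0; i < N; ++i) {
        if (!alive[i] || pTot[i] <= 0) continue;
        if (unif_rand() < pTot[i]) {
          int lure = 0;
          if (mode == 1) {
            if (L > 1 && unif_rand() < share_new) lure = 1;
          } else if (mode == 2 && switched && L > 1) {
            lure = 1;
          }
          double pi = P[lure][i];
          if (pi > 0 && unif_rand() < pi) {
            alive[i] = 0;
            capn[i] = day;
            ++ncap;
          }
        }
      }
      n_alive_now -= ncap;
    }
    out_capt[day - 1] = ncap;
    out_nalive[day - 1] = n_alive_now;

    for (int i = 0; i < N; ++i) age[i] += (int) dt;
    {
      int na = 0;
      for (int i = 0; i < N; ++i) {
        if (alive[i] && age[i] >= adult_age) ++na;
      }
      out_nadult[day - 1] = na;
    }

    // catch-rate trigger for lure-switch scenarios (7-night trailing mean
    // over the initial rate; evaluated after tonight's captures, switch
    // takes effect from the next night)
    if (mode == 2 && !switched && day >= trigger_window + 1) {
      if (init_rate < 0) {
        double s = 0;
        for (int k = 0; k < trigger_window; ++k) s += out_capt[k];
        init_rate = s / trigger_window;
      }
      if (init_rate == 0) {
        switched = true;
        switch_day = day;
      } else {
        double s = 0;
        for (int k = day - trigger_window; k < day; ++k) s += out_capt[k];
        double trailing = s / trigger_window;
        if (trailing / init_rate <= 1.0 - rc + 1e-12) {
          switched = true;
          switch_day = day;
        }
      }
    }
  }

  const int N = (int) Hx.size();
  NumericMatrix pint_out(N, L);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < N; ++i) pint_out(i, l) = P[l][i];
  }
  LogicalVector alive_out(N);
  IntegerVector capn_out(N), age_out(N);
  NumericVector hx_out(N), hy_out(N);
  for (int i = 0; i < N; ++i) {
    alive_out[i] = alive[i] != 0;
    capn_out[i] = capn[i];
    age_out[i] = age[i];
    hx_out[i] = Hx[i];
    hy_out[i] = Hy[i];
  }

  return List::create(
      _["captures"] = out_capt, _["births"] = out_birth,
      _["deaths"] = out_death, _["n_alive"] = out_nalive,
      _["n_adults"] = out_nadult,
      _["alive"] = alive_out, _["capture_night"] = capn_out,
      _["age_days"] = age_out, _["pint"] = pint_out,
      _["hx"] = hx_out, _["hy"] = hy_out,
      _["switch_night"] = switch_day, _["n_star_final"] = n_star);
}
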