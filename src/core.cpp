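// Compiled core of the reindeer-lichen simulator.
//
// One year of the model (winter energy budget -> condition-dependent
// survival -> harmonic-mean reproduction -> lichen grazing and regrowth ->
// autumn slaughter -> cash flow) exactly mirrors the R reference
// implementation in R/simulate.R; the tests assert numerical identity.
// On top of the stepper: trajectory simulation and present-value objectives
// with forward-difference gradients, used by the L-BFGS-B optimizers.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  int n_f, n_m;
  std::vector<double> mass_f, mass_m, need_f, need_m, smass_f, smass_m;
  std::vector<double> fec_max, s_base_f, s_base_m, male_weight;
  double carcass_frac, s_summer, harem, sex_ratio;
  double fec_scale, fec_shape, surv_rho0, surv_b;
  double need_ref, winter_days, me_lichen, me_supp;
  int winter_periods;
  double c_lichen, k_u, omega, tau, eta_over, over_cap;
  double gamma, loss_lin, loss_max, cov_smooth, smooth_w;
  double area_ha, r_growth, K, w_max, k_w, wastage_area_exp;
  double areas[3], mults[3];
  double price_calf, price_adult, subsidy, herding_cost, slaughter_cost, feed_price;
};

std::vector<double> as_vec(const List& L, const char* nm) {
  NumericVector v = L[nm];
  return std::vector<double>(v.begin(), v.end());
}

Pars parse_pars(const List& L) {
  Pars p;
  p.n_f = as<int>(L["n_f"]); p.n_m = as<int>(L["n_m"]);
  p.mass_f = as_vec(L, "mass_f"); p.mass_m = as_vec(L, "mass_m");
  p.need_f = as_vec(L, "need_f"); p.need_m = as_vec(L, "need_m");
  p.smass_f = as_vec(L, "smass_f"); p.smass_m = as_vec(L, "smass_m");
  p.fec_max = as_vec(L, "fec_max");
  p.s_base_f = as_vec(L, "s_base_f"); p.s_base_m = as_vec(L, "s_base_m");
  p.male_weight = as_vec(L, "male_weight");
  p.carcass_frac = as<double>(L["carcass_frac"]);
  p.s_summer = as<double>(L["s_summer"]);
  p.harem = as<double>(L["harem"]);
  p.sex_ratio = as<double>(L["sex_ratio"]);
  p.fec_scale = as<double>(L["fec_scale"]);
  p.fec_shape = as<double>(L["fec_shape"]);
  p.surv_rho0 = as<double>(L["surv_rho0"]); p.surv_b = as<double>(L["surv_b"]);
  p.need_ref = as<double>(L["need_ref"]);
  p.winter_days = as<double>(L["winter_days"]);
  p.winter_periods = as<int>(L["winter_periods"]);
  p.me_lichen = as<double>(L["me_lichen"]); p.me_supp = as<double>(L["me_supp"]);
  p.c_lichen = as<double>(L["c_lichen"]); p.k_u = as<double>(L["k_u"]);
  p.omega = as<double>(L["omega"]); p.tau = as<double>(L["tau"]);
  p.eta_over = as<double>(L["eta_over"]); p.over_cap = as<double>(L["over_cap"]);
  p.gamma = as<double>(L["gamma"]);
  p.loss_lin = as<double>(L["loss_lin"]); p.loss_max = as<double>(L["loss_max"]);
  p.cov_smooth = as<double>(L["cov_smooth"]);
  p.smooth_w = as<double>(L["smooth_w"]);
  p.area_ha = as<double>(L["area_ha"]); p.r_growth = as<double>(L["r_growth"]);
  p.K = as<double>(L["K"]);
  p.w_max = as<double>(L["w_max"]); p.k_w = as<double>(L["k_w"]);
  p.wastage_area_exp = as<double>(L["wastage_area_exp"]);
  NumericVector a = L["areas"], m = L["mults"];
  for (int i = 0; i < 3; ++i) { p.areas[i] = a[i]; p.mults[i] = m[i]; }
  p.price_calf = as<double>(L["price_calf"]);
  p.price_adult = as<double>(L["price_adult"]);
  p.subsidy = as<double>(L["subsidy"]);
  p.herding_cost = as<double>(L["herding_cost"]);
  p.slaughter_cost = as<double>(L["slaughter_cost"]);
  p.feed_price = as<double>(L["feed_price"]);
  return p;
}

inline double softplus_w(double z, double w) {
  double q = z / w;
  if (q > 30.0) return z;
  return w * std::log1p(std::exp(q));
}

inline double smin1(double v, double w) { return 1.0 - softplus_w(1.0 - v, w); }

inline double plogis(double q) { return 1.0 / (1.0 + std::exp(-q)); }

inline double surv_resp(double rho, double rho0, double b) {
  return plogis((rho0 - rho) / b) / plogis(rho0 / b);
}

inline double fec_resp(double rho, double scale, double shape) {
  if (rho <= 0.0) return 1.0;
  return std::exp(-std::pow(rho / scale, shape));
}

inline double loss_cap(double raw, double lin, double mx) {
  if (raw <= lin) return raw;
  double span = mx - lin;
  return mx - span * std::exp(-(raw - lin) / span);
}

inline double clamp01(double v) { return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v); }

// smooth min(a, b) on the animal-count scale, overflow-safe
inline double smin_ab(double a, double b, double w) {
  double mn = a < b ? a : b;
  double d = a > b ? a - b : b - a;
  double v = mn - w * std::log1p(std::exp(-d / w));
  return v > 0.0 ? v : 0.0;
}

struct StepOut {
  double net_revenue, revenue, feeding_cost, other_costs;
  double calf_pct, removal, meat_kg, herd_pre, calves;
};

// advance (f, m, x) by one model year.
// dec = [sf(n_f), sm(n_m), feed_kg]; the first n_f+n_m entries are slaughter
// fractions in [0,1] (escapement = false) or kept-animal targets per class
// (escapement = true: everything above the target is slaughtered)
StepOut step(const Pars& p, std::vector<double>& f, std::vector<double>& m,
             double& x, const double* dec, int wint, bool escapement,
             double esc_w) {
  const double area = p.areas[wint], mult = p.mults[wint];
  const double W = p.winter_days;
  const double feed_kg = dec[p.n_f + p.n_m] > 0.0 ? dec[p.n_f + p.n_m] : 0.0;

  // winter energy budget, sub-period by sub-period: the herd's grazing
  // depletes the lichen within the winter, so late-winter coverage falls
  // below early-winter coverage (coverage is shared across classes)
  const int S = p.winter_periods;
  const double days_s = W / S;
  double need_ref_w = p.need_ref * mult;
  double wintered = 0.0, eff_need = 0.0;
  for (int i = 0; i < p.n_f; ++i) {
    wintered += f[i];
    eff_need += f[i] * p.need_f[i] * mult;
  }
  for (int j = 0; j < p.n_m; ++j) {
    wintered += m[j];
    eff_need += m[j] * p.need_m[j] * mult;
  }
  double offered_period = feed_kg * p.me_supp / S;
  double x_s = x, deficit_units = 0.0, removal = 0.0;
  for (int s = 0; s < S; ++s) {
    double lam = p.c_lichen * x_s * x_s / (x_s + p.k_u);
    double pot = (lam + p.omega) * area * p.tau;
    double cov = smin1(pot / need_ref_w, p.cov_smooth);
    if (cov < 0.0) cov = 0.0;
    double share_l = pot > 0.0 ? lam / (lam + p.omega) : 0.0;
    double period_deficit = eff_need * (1.0 - cov) * days_s;
    double relief = 0.0;
    if (period_deficit > 0.0) {
      double sw = p.smooth_w * (period_deficit > 1.0 ? period_deficit : 1.0);
      double consumed = period_deficit -
          softplus_w(period_deficit - offered_period, sw);
      if (consumed < 0.0) consumed = 0.0;
      relief = consumed / period_deficit;
    }
    deficit_units += (1.0 - cov) * (1.0 - relief) * days_s;
    double povr = pot / need_ref_w - 1.0;
    if (povr < 0.0) povr = 0.0;
    if (povr > p.over_cap) povr = p.over_cap;
    double eat_rel = share_l * cov + p.eta_over * povr * share_l;
    double wastage = p.w_max * x_s / (x_s + p.k_w) *
        std::pow(area / 30.0, p.wastage_area_exp);
    double removal_s = eff_need * eat_rel / p.me_lichen * (1.0 + wastage) *
        days_s;
    removal += removal_s;
    x_s -= removal_s / p.area_ha;
    if (x_s < 0.0) x_s = 0.0;
  }
  x = x_s + p.r_growth * x_s * (1.0 - x_s / p.K);

  // per-class condition, survival
  std::vector<double> surv_f(p.n_f), surv_m(p.n_m), phi_f(p.n_f);
  for (int i = 0; i < p.n_f; ++i) {
    double need = p.need_f[i] * mult;
    double raw = need * deficit_units / (p.gamma * p.smass_f[i]);
    double rho = loss_cap(raw, p.loss_lin, p.loss_max);
    surv_f[i] = f[i] * p.s_base_f[i] * surv_resp(rho, p.surv_rho0, p.surv_b);
    phi_f[i] = fec_resp(rho, p.fec_scale, p.fec_shape);
  }
  for (int j = 0; j < p.n_m; ++j) {
    double need = p.need_m[j] * mult;
    double raw = need * deficit_units / (p.gamma * p.smass_m[j]);
    double rho = loss_cap(raw, p.loss_lin, p.loss_max);
    surv_m[j] = m[j] * p.s_base_m[j] * surv_resp(rho, p.surv_rho0, p.surv_b);
  }

  // reproduction (surviving females calve; harmonic-mean mating)
  double breeding = 0.0, births_raw = 0.0, eff_males = 0.0;
  for (int i = 0; i < p.n_f; ++i) {
    if (p.fec_max[i] > 0.0) breeding += surv_f[i];
    births_raw += surv_f[i] * p.fec_max[i] * phi_f[i];
  }
  for (int j = 0; j < p.n_m; ++j) eff_males += surv_m[j] * p.male_weight[j];
  double pmate = 0.0;
  if (breeding > 0.0) {
    double z = p.harem * eff_males / breeding;
    pmate = smin1(2.0 * z / (1.0 + z), p.smooth_w);
    if (pmate < 0.0) pmate = 0.0;
  }
  double births = births_raw * pmate;

  // aging to the autumn round-up (terminal classes exit)
  std::vector<double> Ff(p.n_f), Mm(p.n_m);
  Ff[0] = births * p.sex_ratio * p.s_summer;
  Mm[0] = births * (1.0 - p.sex_ratio) * p.s_summer;
  for (int i = p.n_f - 1; i >= 1; --i) Ff[i] = surv_f[i - 1];
  for (int j = p.n_m - 1; j >= 1; --j) Mm[j] = surv_m[j - 1];

  double fem_adult = 0.0, herd_pre = 0.0;
  for (int i = 1; i < p.n_f; ++i) fem_adult += Ff[i];
  for (int i = 0; i < p.n_f; ++i) herd_pre += Ff[i];
  for (int j = 0; j < p.n_m; ++j) herd_pre += Mm[j];

  // slaughter and cash flow
  double meat = 0.0, rev_meat = 0.0, n_sl = 0.0, herd_post = 0.0;
  for (int i = 0; i < p.n_f; ++i) {
    double kept = escapement ? smin_ab(Ff[i], dec[i] < 0.0 ? 0.0 : dec[i],
                                       esc_w)
                             : (1.0 - clamp01(dec[i])) * Ff[i];
    double sl = Ff[i] - kept;
    meat += sl * p.carcass_frac * p.mass_f[i];
    rev_meat += sl * p.carcass_frac * p.mass_f[i] *
        (i == 0 ? p.price_calf : p.price_adult);
    n_sl += sl;
    f[i] = kept;
    herd_post += kept;
  }
  for (int j = 0; j < p.n_m; ++j) {
    double dj = dec[p.n_f + j];
    double kept = escapement ? smin_ab(Mm[j], dj < 0.0 ? 0.0 : dj, esc_w)
                             : (1.0 - clamp01(dj)) * Mm[j];
    double sl = Mm[j] - kept;
    meat += sl * p.carcass_frac * p.mass_m[j];
    rev_meat += sl * p.carcass_frac * p.mass_m[j] *
        (j == 0 ? p.price_calf : p.price_adult);
    n_sl += sl;
    m[j] = kept;
    herd_post += kept;
  }

  StepOut o;
  o.revenue = rev_meat + p.subsidy * herd_post;
  o.feeding_cost = feed_kg * p.feed_price;
  o.other_costs = p.herding_cost * wintered + p.slaughter_cost * n_sl;
  o.net_revenue = o.revenue - o.feeding_cost - o.other_costs;
  o.calf_pct = fem_adult > 0.0 ? 100.0 * (Ff[0] + Mm[0]) / fem_adult : NA_REAL;
  o.removal = removal;
  o.meat_kg = meat;
  o.herd_pre = herd_pre;
  o.calves = Ff[0] + Mm[0];
  return o;
}

// present value of a decision schedule: rows 0..n_free-1 of `free_dec` for
// the first years, then `d_ss` up to horizon + ext years, under per-year
// winter types (years beyond the winters vector reuse its last entry).
// The stationary tail beyond the simulated span is valued from the MEAN net
// revenue of the final `tail_avg` simulated years: an unstable or collapsing
// stationary policy thus shows up inside the objective instead of being
// hidden behind the truncation.
double pv_schedule(const Pars& p, std::vector<double> f, std::vector<double> m,
                   double x, const double* free_dec, int n_free,
                   const double* d_ss, int horizon, int ext, int tail_avg,
                   double r, double tail_years, const int* wint,
                   int n_wint, bool escapement, double esc_w) {
  const int nd = p.n_f + p.n_m + 1;
  const int H = horizon + ext;
  if (tail_avg > H) tail_avg = H;
  double disc = 1.0 / (1.0 + r);
  double w = 1.0, pv = 0.0, tail_sum = 0.0;
  for (int t = 0; t < H; ++t) {
    const double* dec = t < n_free ? free_dec + (size_t)t * nd : d_ss;
    int wt = t < n_wint ? wint[t] : wint[n_wint - 1];
    StepOut o = step(p, f, m, x, dec, wt, escapement, esc_w);
    pv += w * o.net_revenue;
    if (t >= H - tail_avg) tail_sum += o.net_revenue;
    w *= disc;
  }
  double tail_nr = tail_sum / tail_avg;
  if (r > 0.0) pv += tail_nr * w * (1.0 + r) / r;  // w = disc^H here
  else pv += tail_nr * tail_years;
  return pv;
}

// pv_schedule plus a stationarity terminal condition: lichen drift over the
// final `tail_avg` years of the extension is penalized quadratically, so
// the stationary decision must actually rest the system (no slow mining
// hidden beyond the truncation)
double pv_schedule_stat(const Pars& p, std::vector<double> f,
                        std::vector<double> m, double x,
                        const double* free_dec, int n_free,
                        const double* d_ss, int horizon, int ext,
                        int tail_avg, double r, double tail_years,
                        const int* wint, int n_wint, bool escapement,
                        double esc_w, double stat_penalty) {
  const int nd = p.n_f + p.n_m + 1;
  const int H = horizon + ext;
  int ta = tail_avg > H ? H : tail_avg;
  double disc = 1.0 / (1.0 + r);
  double w = 1.0, pv = 0.0, tail_sum = 0.0, x_mark = 0.0;
  for (int t = 0; t < H; ++t) {
    const double* dec = t < n_free ? free_dec + (size_t)t * nd : d_ss;
    int wt = t < n_wint ? wint[t] : wint[n_wint - 1];
    StepOut o = step(p, f, m, x, dec, wt, escapement, esc_w);
    pv += w * o.net_revenue;
    if (t == H - ta) x_mark = x;
    if (t >= H - ta) tail_sum += o.net_revenue;
    w *= disc;
  }
  double tail_nr = tail_sum / ta;
  if (r > 0.0) pv += tail_nr * w * (1.0 + r) / r;
  else pv += tail_nr * tail_years;
  double drift = x - x_mark;
  pv -= stat_penalty * drift * drift;
  return pv;
}

// objective on a parsed parameter set; theta holds n_free decision rows
// (fractions in [0,1], feed column scaled by feed_max) plus, if opt_dss, a
// final stationary row; otherwise d_ss supplies the stationary decision
double obj_impl(const Pars& p, const std::vector<double>& f0,
                const std::vector<double>& m0, double x0,
                const double* theta, int n_theta, int n_free, bool opt_dss,
                const double* d_ss_fixed, int horizon, int ext, int tail_avg,
                double r, double tail_years, double feed_max,
                const int* wint, int n_wint, bool escapement,
                double dec_scale, double esc_w, double stat_penalty) {
  const int nd = p.n_f + p.n_m + 1;
  std::vector<double> free_dec((size_t)n_free * nd), dss(nd);
  for (int t = 0; t < n_free; ++t)
    for (int k = 0; k < nd; ++k) {
      double v = theta[(size_t)t * nd + k];
      free_dec[(size_t)t * nd + k] = (k == nd - 1) ? v * feed_max
                                                   : v * dec_scale;
    }
  if (opt_dss) {
    for (int k = 0; k < nd; ++k) {
      double v = theta[(size_t)n_free * nd + k];
      dss[k] = (k == nd - 1) ? v * feed_max : v * dec_scale;
    }
  } else {
    for (int k = 0; k < nd; ++k) dss[k] = d_ss_fixed[k];
  }
  std::vector<double> f(f0), m(m0);
  return pv_schedule_stat(p, f, m, x0, free_dec.data(), n_free, dss.data(),
                          horizon, ext, tail_avg, r, tail_years, wint,
                          n_wint, escapement, esc_w, stat_penalty);
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List pars, NumericVector f0, NumericVector m0, double x0,
                  NumericMatrix decisions, IntegerVector winters,
                  bool escapement = false, double esc_w = 0.1) {
  Pars p = parse_pars(pars);
  int H = winters.size();
  if (decisions.nrow() != H || decisions.ncol() != p.n_f + p.n_m + 1)
    stop("decision matrix has wrong shape");
  std::vector<double> f(f0.begin(), f0.end()), m(m0.begin(), m0.end());
  double x = x0;
  NumericVector lichen(H), herd(H), calves(H), meat(H), revenue(H),
      feeding(H), other(H), net(H), calfpct(H), removal(H), herd_pre(H);
  std::vector<double> dec(p.n_f + p.n_m + 1);
  for (int t = 0; t < H; ++t) {
    for (int k = 0; k < (int)dec.size(); ++k) dec[k] = decisions(t, k);
    StepOut o = step(p, f, m, x, dec.data(), winters[t], escapement, esc_w);
    lichen[t] = x;
    double hs = 0.0;
    for (double v : f) hs += v;
    for (double v : m) hs += v;
    herd[t] = hs;
    calves[t] = o.calves; meat[t] = o.meat_kg;
    revenue[t] = o.revenue; feeding[t] = o.feeding_cost;
    other[t] = o.other_costs; net[t] = o.net_revenue;
    calfpct[t] = o.calf_pct; removal[t] = o.removal;
    herd_pre[t] = o.herd_pre;
  }
  return List::create(
      _["years"] = List::create(
          _["year"] = seq_len(H), _["lichen"] = lichen, _["herd"] = herd,
          _["herd_pre_slaughter"] = herd_pre, _["calves"] = calves,
          _["meat_kg"] = meat, _["revenue"] = revenue,
          _["feeding_cost"] = feeding, _["other_costs"] = other,
          _["net_revenue"] = net, _["calf_pct"] = calfpct,
          _["lichen_removed_kg"] = removal),
      _["f_final"] = NumericVector(f.begin(), f.end()),
      _["m_final"] = NumericVector(m.begin(), m.end()), _["x_final"] = x);
}

// objective for the deterministic dynamic solve: theta holds n_free rows of
// per-class decisions plus (if opt_dss) a final stationary row; fractions in
// [0,1], feed column scaled by feed_max
// [[Rcpp::export]]
double cpp_objective(List pars, NumericVector f0, NumericVector m0, double x0,
                     NumericVector theta, int n_free, bool opt_dss,
                     NumericVector d_ss_fixed, int horizon, int ext,
                     int tail_avg, double r, double tail_years,
                     double feed_max, IntegerVector winters,
                     bool escapement = false, double dec_scale = 1.0,
                     double esc_w = 0.1, double stat_penalty = 0.0) {
  Pars p = parse_pars(pars);
  const int nd = p.n_f + p.n_m + 1;
  int need = n_free * nd + (opt_dss ? nd : 0);
  if (theta.size() != need) stop("theta has wrong length");
  if (winters.size() < 1) stop("winters must be non-empty");
  if (!opt_dss && d_ss_fixed.size() != nd) stop("d_ss has wrong length");
  std::vector<double> f(f0.begin(), f0.end()), m(m0.begin(), m0.end());
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> dsf(d_ss_fixed.begin(), d_ss_fixed.end());
  std::vector<int> wv(winters.begin(), winters.end());
  return obj_impl(p, f, m, x0, th.data(), th.size(), n_free, opt_dss,
                  dsf.data(), horizon, ext, tail_avg, r, tail_years,
                  feed_max, wv.data(), wv.size(), escapement, dec_scale,
                  esc_w, stat_penalty);
}

// finite-difference gradient of cpp_objective over theta (forward steps,
// switching to backward in the upper half of the box)
// [[Rcpp::export]]
NumericVector cpp_gradient(List pars, NumericVector f0, NumericVector m0,
                           double x0, NumericVector theta, int n_free,
                           bool opt_dss, NumericVector d_ss_fixed, int horizon,
                           int ext, int tail_avg, double r, double tail_years,
                           double feed_max, IntegerVector winters,
                           bool escapement, double dec_scale, double esc_w,
                           double stat_penalty, double h) {
  Pars p = parse_pars(pars);
  int n = theta.size();
  NumericVector g(n);
  std::vector<double> f(f0.begin(), f0.end()), m(m0.begin(), m0.end());
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> dsf(d_ss_fixed.begin(), d_ss_fixed.end());
  std::vector<int> wv(winters.begin(), winters.end());
  double base = obj_impl(p, f, m, x0, th.data(), n, n_free, opt_dss,
                         dsf.data(), horizon, ext, tail_avg, r, tail_years,
                         feed_max, wv.data(), wv.size(), escapement,
                         dec_scale, esc_w, stat_penalty);
  for (int i = 0; i < n; ++i) {
    double step_h = th[i] > 0.5 ? -h : h;
    double old = th[i];
    th[i] = old + step_h;
    double val = obj_impl(p, f, m, x0, th.data(), n, n_free, opt_dss,
                          dsf.data(), horizon, ext, tail_avg, r, tail_years,
                          feed_max, wv.data(), wv.size(), escapement,
                          dec_scale, esc_w, stat_penalty);
    g[i] = (val - base) / step_h;
    th[i] = old;
  }
  return g;
}
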