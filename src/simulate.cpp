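#include <Rcpp.h>
using namespace Rcpp;

// f-I curve with series expansion across the removable singularity at x = 0
static inline double phi(double I, double a, double b, double d) {
  double x = a * I - b;
  double r;
  if (std::fabs(x) < 1e-6) {
    r = 1.0 / d + x / 2.0 + d * x * x / 12.0;
  } else {
    r = x / (1.0 - std::exp(-d * x));
  }
  return r > 0.0 ? r : 0.0;
}

// Fixed-step Euler integration of the coupled E/I gating equations with
// sample-and-hold injection of the drive. Records every `record_every`-th
// step (state at step start, currents/rates computed from it) and
// accumulates per-node mean excitatory rates over all steps.
// [[Rcpp::export]]
List simulate_core_cpp(NumericMatrix C, NumericMatrix drive, NumericVector J,
                       List p, double dt, int steps_per_sample,
                       int record_every, int n_steps,
                       NumericVector SE0, NumericVector SI0,
                       LogicalVector record_flags) {
  const int n = C.nrow();
  const int n_drive = drive.ncol();

  const double W_E = p["W_E"], W_I = p["W_I"], I0 = p["I0"];
  const double a_E = p["a_E"], b_E = p["b_E"], d_E = p["d_E"];
  const double a_I = p["a_I"], b_I = p["b_I"], d_I = p["d_I"];
  const double tau_E = p["tau_E"], tau_I = p["tau_I"];
  const double gamma_E = p["gamma_E"], gamma_I = p["gamma_I"];
  const double w_plus = p["w_plus"], J_NMDA = p["J_NMDA"];
  const double G = p["G"], w_BG_E = p["w_BG_E"], w_BG_I = p["w_BG_I"];
  const double sigma = p["noise_sigma"];
  const bool recurrence = p["recurrence_enabled"];

  std::vector<double> SE(SE0.begin(), SE0.end());
  std::vector<double> SI(SI0.begin(), SI0.end());
  std::vector<double> IE(n), II(n), rE(n), rI(n), LR(n), INJ(n);
  std::vector<double> rate_sum(n, 0.0);
  std::vector<double> Cv(C.begin(), C.end());  // column-major n x n
  const double *drv = drive.begin();           // column-major n x n_drive

  const int n_rec = (n_steps + record_every - 1) / record_every;
  // record_flags order: S_E, S_I, r_E, r_I, I_E, I_I, long_range, injected
  NumericMatrix recSE, recSI, recRE, recRI, recIE, recII, recLR, recINJ;
  if (record_flags[0]) recSE = NumericMatrix(n, n_rec);
  if (record_flags[1]) recSI = NumericMatrix(n, n_rec);
  if (record_flags[2]) recRE = NumericMatrix(n, n_rec);
  if (record_flags[3]) recRI = NumericMatrix(n, n_rec);
  if (record_flags[4]) recIE = NumericMatrix(n, n_rec);
  if (record_flags[5]) recII = NumericMatrix(n, n_rec);
  if (record_flags[6]) recLR = NumericMatrix(n, n_rec);
  if (record_flags[7]) recINJ = NumericMatrix(n, n_rec);
  NumericVector rec_time(n_rec);

  int rec_idx = 0;
  for (int t = 0; t < n_steps; ++t) {
    int di = t / steps_per_sample;
    if (di >= n_drive) di = n_drive - 1;

    const double *dcol = drv + (size_t)di * n;
    for (int i = 0; i < n; ++i) {
      double lr = 0.0;
      for (int j = 0; j < n; ++j) lr += Cv[i + (size_t)j * n] * SE[j];
      lr *= G;
      double inj = dcol[i];
      double ie = W_E * I0 + lr - J[i] * SI[i] + w_BG_E * inj;
      double ii = W_I * I0 - SI[i] + w_BG_I * inj;
      if (recurrence) {
        ie += w_plus * J_NMDA * SE[i];
        ii += J_NMDA * SE[i];
      }
      if (sigma > 0.0) {
        ie += sigma * R::norm_rand();
        ii += sigma * R::norm_rand();
      }
      IE[i] = ie; II[i] = ii;
      LR[i] = lr; INJ[i] = inj;
      rE[i] = phi(ie, a_E, b_E, d_E);
      rI[i] = phi(ii, a_I, b_I, d_I);
      rate_sum[i] += rE[i];
    }

    if (t % record_every == 0) {
      rec_time[rec_idx] = t * dt;
      for (int i = 0; i < n; ++i) {
        if (record_flags[0]) recSE(i, rec_idx) = SE[i];
        if (record_flags[1]) recSI(i, rec_idx) = SI[i];
        if (record_flags[2]) recRE(i, rec_idx) = rE[i];
        if (record_flags[3]) recRI(i, rec_idx) = rI[i];
        if (record_flags[4]) recIE(i, rec_idx) = IE[i];
        if (record_flags[5]) recII(i, rec_idx) = II[i];
        if (record_flags[6]) recLR(i, rec_idx) = LR[i];
        if (record_flags[7]) recINJ(i, rec_idx) = INJ[i];
      }
      ++rec_idx;
    }

    for (int i = 0; i < n; ++i) {
      double se = SE[i] + dt * (-SE[i] / tau_E + (1.0 - SE[i]) * gamma_E * rE[i]);
      double si = SI[i] + dt * (-SI[i] / tau_I + gamma_I * rI[i]);
      if (!std::isfinite(se) || !std::isfinite(si))
        stop("integration diverged (non-finite state) in region %d", i + 1);
      SE[i] = se < 0.0 ? 0.0 : (se > 1.0 ? 1.0 : se);
      SI[i] = si < 0.0 ? 0.0 : si;
    }
  }

  NumericVector mean_rE(n);
  for (int i = 0; i < n; ++i) mean_rE[i] = rate_sum[i] / n_steps;

  List out = List::create(_["time"] = rec_time, _["mean_r_E"] = mean_rE);
  if (record_flags[0]) out["S_E"] = recSE;
  if (record_flags[1]) out["S_I"] = recSI;
  if (record_flags[2]) out["r_E"] = recRE;
  if (record_flags[3]) out["r_I"] = recRI;
  if (record_flags[4]) out["I_E"] = recIE;
  if (record_flags[5]) out["I_I"] = recII;
  if (record_flags[6]) out["long_range"] = recLR;
  if (record_flags[7]) out["injected"] = recINJ;
  return out;
}

// Balloon-Windkessel hemodynamic model: four states per region
// (vasodilatory signal s, inflow f, volume v, deoxyhemoglobin q) driven by
// excitatory synaptic gating, Euler-integrated at the input sampling rate,
// followed by the static nonlinear BOLD readout.
// [[Rcpp::export]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix SE, List hp, double dt_s) {
  const int n = SE.nrow(), T = SE.ncol();
  const double kappa = hp["kappa"], gamma_h = hp["gamma_h"];
  const double tau_h = hp["tau_h"], alpha_h = hp["alpha_h"];
  const double rho = hp["rho"], V0 = hp["V0"];
  const double k1 = hp["k1"], k2 = hp["k2"], k3 = hp["k3"];
  const double ialpha = 1.0 / alpha_h;

  NumericMatrix bold(n, T);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double x = SE(i, t);
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double ds = x - kappa * s - gamma_h * (f - 1.0);
      double df = s;
      double dv = (f - std::pow(v, ialpha)) / tau_h;
      double dq = (f * E / rho - q * std::pow(v, ialpha) / v) / tau_h;
      s += dt_s * ds;
      f += dt_s * df;
      v += dt_s * dv;
      q += dt_s * dq;
      if (f <= 0.0 || v <= 0.0 || q <= 0.0 || !std::isfinite(v))
        stop("hemodynamic integration produced non-positive state in region %d",
             i + 1);
      bold(i, t) = 100.0 * V0 *
        (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return bold;
}
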