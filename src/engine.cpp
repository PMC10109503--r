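// Fixed-step co-simulation of the three-compartment WDR neuron, its
// dual-exponential synaptic inputs, the per-C-synapse buffered proton
// clefts and the pH-gated ASIC populations.
//
// Units: mV, ms, nS, pA (nS*mV = pA), pF, uM, mM (protons).
// Integration: exponential Euler for voltages (total conductance form) and
// gating variables; exact exponential update for ASIC inactivation; the
// cleft total-proton ODE is sub-stepped explicitly at <= 0.005 ms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Traub-Miles spike kinetics
inline double vtrap(double x, double y) {
  // x/(1-exp(-x/y)) with the removable singularity handled
  return (std::fabs(x / y) < 1e-6) ? y * (1.0 + x / (2.0 * y)) :
         x / (1.0 - std::exp(-x / y));
}
inline double alpha_m(double v) { return 0.32 * vtrap(v + 54.0, 4.0); }
inline double beta_m(double v)  { return 0.28 * vtrap(-(v + 27.0), 5.0); }
inline double alpha_h(double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); }
inline double beta_h(double v)  { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); }
inline double alpha_n(double v) { return 0.032 * vtrap(v + 52.0, 5.0); }
inline double beta_n(double v)  { return 0.5 * std::exp(-(v + 57.0) / 40.0); }

inline void gate_step(double &x, double a, double b, double dt) {
  double tau = 1.0 / (a + b);
  double xinf = a * tau;
  x = xinf + (x - xinf) * std::exp(-dt / tau);
}
inline void gate_step_inf(double &x, double xinf, double tau, double dt) {
  x = xinf + (x - xinf) * std::exp(-dt / tau);
}

inline double hilln(double ca, double kd, double n) {
  double r = std::pow(ca / kd, n);
  return r / (1.0 + r);
}

inline double mg_block(double v) {
  return 1.0 / (1.0 + (1.0 / 3.57) * std::exp(-0.062 * v));
}

inline double asic_tauh_ms(double ph, int form, const double *cf) {
  double tau_s;
  switch (form) {
  case 0: // biased gaussian: a1 e^{-a2 (pH-b2)^2} + a3 pH - b3
    tau_s = cf[0] * std::exp(-cf[1] * (ph - cf[2]) * (ph - cf[2])) +
            cf[3] * ph - cf[4];
    break;
  case 1: // symmetrized exponential: amp e^{-rate |pH-c|} + offset
    tau_s = cf[0] * std::exp(-cf[1] * std::fabs(ph - cf[2])) + cf[3];
    break;
  case 2: // affine: max(0, -a pH + b)
    tau_s = std::max(0.0, -cf[0] * ph + cf[1]);
    break;
  default: // piecewise affine
    tau_s = (ph <= cf[4]) ? std::max(0.0, cf[0] * ph - cf[1])
                          : std::max(0.0, cf[2] * ph + cf[3]);
  }
  if (tau_s < 1e-3) tau_s = 1e-3; // 1 ms positivity floor
  return tau_s * 1000.0;
}

// free protons from buffered total: positive root of
// H^2 + H (Kd + B0 - T) - Kd T = 0, cancellation-safe
inline double free_from_total(double htot, double b0, double kd) {
  double b = kd + b0 - htot;
  double c0 = -kd * htot;
  double disc = std::sqrt(b * b - 4.0 * c0);
  return (b >= 0.0) ? -2.0 * c0 / (b + disc) : (-b + disc) / 2.0;
}

} // namespace

// [[Rcpp::export]]
List cleft_run_cpp(double b0, double kd, double h0, double q_amp,
                   double pulse_dur, double tau, NumericVector events,
                   double duration, double dt, double record_dt,
                   double ph0) {
  double hfree = std::pow(10.0, -ph0) * 1e3;
  double htot = hfree * (1.0 + b0 / (hfree + kd));
  long nstep = (long)std::ceil(duration / dt);
  int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  std::vector<double> rt, rph, rfree, rtot;
  size_t iev = 0;
  double pulse_until = -1.0;
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    if (s % rec_every == 0) {
      rt.push_back(t); rph.push_back(-std::log10(hfree * 1e-3));
      rfree.push_back(hfree); rtot.push_back(htot);
    }
    while (iev < (size_t)events.size() && events[iev] <= t) {
      if (events[iev] + pulse_dur > pulse_until)
        pulse_until = events[iev] + pulse_dur;
      ++iev;
    }
    double q = (t < pulse_until) ? q_amp : 0.0;
    htot += dt * (q - (hfree - h0) / tau);
    if (htot < 0.0) htot = 0.0;
    hfree = free_from_total(htot, b0, kd);
  }
  rt.push_back(nstep * dt); rph.push_back(-std::log10(hfree * 1e-3));
  rfree.push_back(hfree); rtot.push_back(htot);
  return List::create(_["time"] = rt, _["ph"] = rph, _["h_free"] = rfree,
                      _["h_total"] = rtot);
}

// [[Rcpp::export]]
List engine_run_cpp(double dt, double duration, double record_dt,
                    NumericVector cap_pf, NumericVector g_axial,
                    double e_leak, double e_na, double e_k, double e_ca,
                    double e_can,
                    NumericVector g_leak, NumericVector g_na,
                    NumericVector g_kdr, NumericVector g_kca,
                    NumericVector g_cal, NumericVector g_can,
                    double cal_vhalf, double cal_k, double cal_tau,
                    double kd_kca, double n_kca, double tau_kca, double kd_can,
                    double n_can, double tau_can, double ca_rest, NumericVector tau_ca,
                    NumericVector ca_gain, double v_init,
                    IntegerVector syn_comp_id, IntegerVector syn_is_nmda,
                    NumericVector syn_gmax, NumericVector syn_norm,
                    NumericVector syn_tau_r, NumericVector syn_tau_d,
                    NumericVector syn_erev, NumericVector syn_cafrac,
                    IntegerVector syn_rec_kind,
                    NumericVector ev_time, IntegerVector ev_synapse,
                    IntegerVector c_synapse_ids, int shared_cleft,
                    double cleft_b0, double cleft_kd, double cleft_h0,
                    double cleft_q, double cleft_pulse_dur,
                    double cleft_tau,
                    int has_asic, int asic_mittx, double asic_g,
                    double asic_nm, double asic_ph05m, double asic_nh,
                    double asic_ph05h, double asic_alpha,
                    int asic_tau_form, NumericVector asic_tau_coeffs,
                    double asic_erev, double asic_cafrac,
                    double i_inj, double inj_start, double inj_end) {
  const int DEND = 0, SOMA = 1, AXON = 2;
  const int n_rec_inst = syn_gmax.size();
  const int n_c = c_synapse_ids.size();
  const int n_cleft = shared_cleft ? (n_c > 0 ? 1 : 0) : n_c;

  // map synapse id -> cleft index (C synapses only)
  std::vector<int> cleft_of; // indexed by synapse id
  int max_syn = 0;
  for (int i = 0; i < n_rec_inst; ++i)
    if (syn_comp_id[i] + 1 > max_syn) max_syn = syn_comp_id[i] + 1;
  cleft_of.assign(max_syn, -1);
  for (int j = 0; j < n_c; ++j)
    cleft_of[c_synapse_ids[j]] = shared_cleft ? 0 : j;

  // neuron state
  double V[3] = {v_init, v_init, v_init};
  double mna[3], hna[3], nk[3], mcal[3], wkca[3], mcan[3];
  for (int c = 0; c < 3; ++c) {
    double a = alpha_m(V[c]), b = beta_m(V[c]);
    mna[c] = a / (a + b);
    a = alpha_h(V[c]); b = beta_h(V[c]);
    hna[c] = a / (a + b);
    a = alpha_n(V[c]); b = beta_n(V[c]);
    nk[c] = a / (a + b);
    mcal[c] = 1.0 / (1.0 + std::exp(-(V[c] - cal_vhalf) / cal_k));
    wkca[c] = hilln(ca_rest, kd_kca, n_kca);
    mcan[c] = hilln(ca_rest, kd_can, n_can);
  }
  double Ca[2] = {ca_rest, ca_rest}; // dend, soma

  // synaptic kernel accumulators: g = a_slow - b_fast
  std::vector<double> acc_a(n_rec_inst, 0.0), acc_b(n_rec_inst, 0.0);
  std::vector<double> dec_d(n_rec_inst), dec_r(n_rec_inst);
  for (int i = 0; i < n_rec_inst; ++i) {
    dec_d[i] = std::exp(-dt / syn_tau_d[i]);
    dec_r[i] = std::exp(-dt / syn_tau_r[i]);
  }

  // clefts
  std::vector<double> cl_htot(n_cleft), cl_hfree(n_cleft), cl_ph(n_cleft);
  std::vector<double> cl_pulse_until(n_cleft, -1.0);
  std::vector<double> cl_last_event(n_cleft, -1e9);
  double hfree0 = cleft_h0;
  double htot0 = hfree0 * (1.0 + cleft_b0 / (hfree0 + cleft_kd));
  for (int j = 0; j < n_cleft; ++j) {
    cl_htot[j] = htot0; cl_hfree[j] = hfree0;
    cl_ph[j] = -std::log10(hfree0 * 1e-3);
  }
  int n_sub = std::max(1, (int)std::ceil(dt / 0.005));
  double h_sub = dt / n_sub;

  // ASIC populations, one per C synapse
  const double *atc = asic_tau_coeffs.begin();
  double h_rest = asic_alpha /
    (1.0 + std::pow(10.0, -asic_nh * (7.4 - asic_ph05h)));
  std::vector<double> asic_h(n_c, h_rest);

  // recording
  long nstep = (long)std::ceil(duration / dt);
  int rec_every = std::max(1, (int)std::lround(record_dt / dt));
  long nrec = nstep / rec_every + 1;
  NumericVector r_time(nrec), r_vd(nrec), r_vs(nrec), r_va(nrec),
      r_cad(nrec), r_cas(nrec), r_open(nrec),
      r_ikca(nrec), r_ican(nrec), r_ical(nrec), r_iasic(nrec),
      r_iampa(nrec), r_inmda(nrec), r_igaba(nrec), r_ink1(nrec);
  NumericMatrix r_ph(nrec, n_cleft);
  long irec = 0;

  std::vector<double> spikes;
  double last_spike = -1e9;
  double v_axon_prev = V[AXON];
  size_t iev = 0;
  const int n_ev = ev_time.size();

  // record the initial state in slot 0
  r_time[0] = 0.0; r_vd[0] = V[DEND]; r_vs[0] = V[SOMA]; r_va[0] = V[AXON];
  r_cad[0] = Ca[0]; r_cas[0] = Ca[1];
  for (int j = 0; j < n_cleft; ++j) r_ph(0, j) = cl_ph[j];
  if (has_asic) {
    double ph74 = -std::log10(cleft_h0 * 1e-3);
    r_open[0] = asic_mittx ? 1.0 :
      h_rest / (1.0 + std::pow(10.0, asic_nm * (ph74 - asic_ph05m)));
  }

  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;

    // deliver events due in [t, t+dt)
    while (iev < (size_t)n_ev && ev_time[iev] < t + dt) {
      int sid = ev_synapse[iev];
      // receptor kernels of this synapse
      for (int i = 0; i < n_rec_inst; ++i)
        if (syn_comp_id[i] == sid) {
          acc_a[i] += syn_gmax[i] * syn_norm[i];
          acc_b[i] += syn_gmax[i] * syn_norm[i];
        }
      // proton pulse if this is a C synapse (1 ms refractory coalescing)
      int cj = (sid < (int)cleft_of.size()) ? cleft_of[sid] : -1;
      if (cj >= 0 && ev_time[iev] - cl_last_event[cj] >= 1.0) {
        double until = ev_time[iev] + cleft_pulse_dur;
        if (until > cl_pulse_until[cj]) cl_pulse_until[cj] = until;
        cl_last_event[cj] = ev_time[iev];
      }
      ++iev;
    }

    // clefts: explicit sub-steps
    for (int j = 0; j < n_cleft; ++j) {
      double htot = cl_htot[j], hfree = cl_hfree[j];
      for (int k = 0; k < n_sub; ++k) {
        double tk = t + k * h_sub;
        double q = (tk < cl_pulse_until[j] &&
                    tk >= cl_last_event[j]) ? cleft_q : 0.0;
        htot += h_sub * (q - (hfree - cleft_h0) / cleft_tau);
        if (htot < 0.0) htot = 0.0;
        hfree = free_from_total(htot, cleft_b0, cleft_kd);
      }
      cl_htot[j] = htot; cl_hfree[j] = hfree;
      cl_ph[j] = -std::log10(hfree * 1e-3);
    }

    // ASIC gating: m instantaneous, h exact exponential
    double open1 = 0.0;
    if (has_asic) {
      for (int j = 0; j < n_c; ++j) {
        int cj = shared_cleft ? 0 : j;
        double ph = cl_ph[cj];
        if (!asic_mittx) {
          double hinf = asic_alpha /
            (1.0 + std::pow(10.0, -asic_nh * (ph - asic_ph05h)));
          double tauh = asic_tauh_ms(ph, asic_tau_form, atc);
          asic_h[j] = hinf + (asic_h[j] - hinf) * std::exp(-dt / tauh);
        }
      }
      int cj0 = 0;
      double ph1 = (n_cleft > 0) ? cl_ph[cj0] : 7.4;
      open1 = asic_mittx ? 1.0 :
        asic_h[0] / (1.0 + std::pow(10.0, asic_nm * (ph1 - asic_ph05m)));
    }

    // synaptic + ASIC conductances on the dendrite (folded into the
    // exponential-Euler update as conductance * reversal terms; trace
    // currents evaluated at the pre-step voltage)
    double g_syn_tot = 0.0, g_syn_E = 0.0, i_ca_syn = 0.0;
    double i_ampa = 0.0, i_nmda = 0.0, i_gaba = 0.0, i_nk1 = 0.0;
    double vd = V[DEND];
    double B = mg_block(vd);
    for (int i = 0; i < n_rec_inst; ++i) {
      double g = acc_a[i] - acc_b[i];
      acc_a[i] *= dec_d[i]; acc_b[i] *= dec_r[i];
      if (g <= 0.0) continue;
      if (syn_is_nmda[i]) g *= B;
      g_syn_tot += g; g_syn_E += g * syn_erev[i];
      double cur = g * (vd - syn_erev[i]);
      if (syn_cafrac[i] > 0.0 && cur < 0.0)
        i_ca_syn += syn_cafrac[i] * cur;
      switch (syn_rec_kind[i]) {
      case 0: i_ampa += cur; break;
      case 1: i_nmda += cur; break;
      case 2: i_gaba += cur; break;
      default: i_nk1 += cur;
      }
    }
    double i_asic = 0.0, i_ca_asic = 0.0;
    if (has_asic) {
      for (int j = 0; j < n_c; ++j) {
        int cj = shared_cleft ? 0 : j;
        double open;
        if (asic_mittx) open = 1.0;
        else {
          double m = 1.0 /
            (1.0 + std::pow(10.0, asic_nm * (cl_ph[cj] - asic_ph05m)));
          open = m * asic_h[j];
        }
        double g = asic_g * open;
        g_syn_tot += g; g_syn_E += g * asic_erev;
        double cur = g * (vd - asic_erev);
        i_asic += cur;
        if (cur < 0.0) i_ca_asic += asic_cafrac * cur;
      }
    }

    // intrinsic currents and voltage update (exponential Euler per
    // compartment, neighbours at previous-step values)
    double i_kca_d = 0, i_can_d = 0, i_cal_d = 0;
    double Vnew[3];
    for (int c = 0; c < 3; ++c) {
      double gtot = g_leak[c];
      double gE = g_leak[c] * e_leak;
      double gna_c = g_na[c] * mna[c] * mna[c] * mna[c] * hna[c];
      gtot += gna_c; gE += gna_c * e_na;
      double gk_c = g_kdr[c] * nk[c] * nk[c] * nk[c] * nk[c];
      gtot += gk_c; gE += gk_c * e_k;
      double gkca_c = g_kca[c] * wkca[c];
      gtot += gkca_c; gE += gkca_c * e_k;
      double gcal_c = g_cal[c] * mcal[c];
      gtot += gcal_c; gE += gcal_c * e_ca;
      double gcan_c = g_can[c] * mcan[c];
      gtot += gcan_c; gE += gcan_c * e_can;
      double i_ext = 0.0; // external/source currents, positive outward
      if (c == DEND) {
        gtot += g_syn_tot; gE += g_syn_E;
        i_kca_d = gkca_c * (V[c] - e_k);
        i_can_d = gcan_c * (V[c] - e_can);
        i_cal_d = gcal_c * (V[c] - e_ca);
      }
      if (c == SOMA && i_inj != 0.0 && t >= inj_start && t < inj_end)
        i_ext -= i_inj; // positive i_inj depolarizes
      // axial coupling
      if (c == DEND) { gtot += g_axial[0]; gE += g_axial[0] * V[SOMA]; }
      if (c == SOMA) {
        gtot += g_axial[0] + g_axial[1];
        gE += g_axial[0] * V[DEND] + g_axial[1] * V[AXON];
      }
      if (c == AXON) { gtot += g_axial[1]; gE += g_axial[1] * V[SOMA]; }
      double vinf = (gE - i_ext) / gtot;
      Vnew[c] = vinf + (V[c] - vinf) * std::exp(-dt * gtot / cap_pf[c]);
    }

    // gating updates at midpoint voltages (halves the splitting error of
    // the voltage/gating coupling)
    for (int c = 0; c < 3; ++c) {
      double vm = 0.5 * (V[c] + Vnew[c]);
      if (g_na[c] > 0.0) {
        gate_step(mna[c], alpha_m(vm), beta_m(vm), dt);
        gate_step(hna[c], alpha_h(vm), beta_h(vm), dt);
      }
      if (g_kdr[c] > 0.0)
        gate_step(nk[c], alpha_n(vm), beta_n(vm), dt);
      double minf = 1.0 / (1.0 + std::exp(-(vm - cal_vhalf) / cal_k));
      gate_step_inf(mcal[c], minf, cal_tau, dt);
      double ca_here = (c == DEND) ? Ca[0] : (c == SOMA ? Ca[1] : ca_rest);
      gate_step_inf(wkca[c], hilln(ca_here, kd_kca, n_kca), tau_kca, dt);
      gate_step_inf(mcan[c], hilln(ca_here, kd_can, n_can), tau_can, dt);
    }

    // calcium pools (dend = 0, soma = 1); influx from Ca-carrying currents
    {
      double i_ca_dend = i_cal_d + i_ca_syn + i_ca_asic; // pA, inward < 0
      double influx_d = (i_ca_dend < 0.0) ? -ca_gain[0] * i_ca_dend : 0.0;
      double target = ca_rest + influx_d * tau_ca[0];
      Ca[0] = target + (Ca[0] - target) * std::exp(-dt / tau_ca[0]);
      double gcal_s = g_cal[SOMA] * mcal[SOMA];
      double i_cal_s = gcal_s * (V[SOMA] - e_ca);
      double influx_s = (i_cal_s < 0.0) ? -ca_gain[1] * i_cal_s : 0.0;
      target = ca_rest + influx_s * tau_ca[1];
      Ca[1] = target + (Ca[1] - target) * std::exp(-dt / tau_ca[1]);
    }

    for (int c = 0; c < 3; ++c) V[c] = Vnew[c];

    if (std::fabs(V[DEND]) > 200.0 || std::fabs(V[SOMA]) > 200.0 ||
        std::fabs(V[AXON]) > 200.0)
      stop("numerical divergence (|V| > 200 mV) at t = %f ms", t);

    // spike detection on the axonal compartment
    if (v_axon_prev < 0.0 && V[AXON] >= 0.0 &&
        (t + dt) - last_spike >= 2.0) {
      spikes.push_back(t + dt);
      last_spike = t + dt;
    }
    v_axon_prev = V[AXON];

    if ((s + 1) % rec_every == 0 || s == nstep - 1) {
      long k = (s + 1) / rec_every;
      if (k >= nrec) k = nrec - 1;
      r_time[k] = t + dt; r_vd[k] = V[DEND]; r_vs[k] = V[SOMA];
      r_va[k] = V[AXON]; r_cad[k] = Ca[0]; r_cas[k] = Ca[1];
      r_open[k] = open1;
      r_ikca[k] = i_kca_d; r_ican[k] = i_can_d; r_ical[k] = i_cal_d;
      r_iasic[k] = i_asic; r_iampa[k] = i_ampa; r_inmda[k] = i_nmda;
      r_igaba[k] = i_gaba; r_ink1[k] = i_nk1;
      for (int j = 0; j < n_cleft; ++j) r_ph(k, j) = cl_ph[j];
    }
  }
  return List::create(
      _["spike_times"] = spikes, _["time"] = r_time,
      _["v_dend"] = r_vd, _["v_soma"] = r_vs, _["v_axon"] = r_va,
      _["ca_dend"] = r_cad, _["ca_soma"] = r_cas,
      _["ph"] = r_ph, _["asic_open"] = r_open,
      _["i_kca"] = r_ikca, _["i_can"] = r_ican, _["i_cal"] = r_ical,
      _["i_asic"] = r_iasic, _["i_ampa"] = r_iampa,
      _["i_nmda"] = r_inmda, _["i_gaba"] = r_igaba, _["i_nk1"] = r_ink1);
}
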