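#include <Rcpp.h>
using namespace Rcpp;

// Conductance-based point-neuron integrator (1 or 2 compartments).
//
// Units throughout: time ms, voltage mV, current pA, conductance nS,
// capacitance pF (so C dV/dt is in pA and g*V in pA with no scale factors).
//
// Gating uses exponential Euler (exact for the locally-linear gating ODE),
// voltage a forward update; synaptic conductances are sums of analytically
// decaying exponentials so their updates are exact.
//
// mode: 0 = current clamp (stim is injected current, pA),
//       1 = voltage clamp (stim is the command voltage, mV; the somatic
//           membrane follows it exactly and the pipette current is recorded).

static inline double hcn_minf(double v, double v12, double k) {
  return 1.0 / (1.0 + std::exp((v - v12) / k));
}

static inline double hcn_tau(double v, double tmin, double tmax,
                             double tv12, double tk) {
  // depolarized -> tau_max (slow), hyperpolarized -> tau_min (fast)
  return tmin + (tmax - tmin) / (1.0 + std::exp(-(v - tv12) / tk));
}

// [[Rcpp::export]]
List sim_core(double dt, int decim, int mode, NumericVector stim,
              List prm, List syn, List spk) {
  const int n = stim.size();
  const int n_out = n / decim;

  // --- membrane parameters ---
  const double Cs   = as<double>(prm["C_m"]);
  const double gL   = as<double>(prm["g_leak"]);
  const double EL   = as<double>(prm["E_leak"]);
  const double gh   = as<double>(prm["g_hcn_max"]);
  const double v12  = as<double>(prm["hcn_V12"]);
  const double hk   = as<double>(prm["hcn_k"]);
  const double Eh   = as<double>(prm["E_hcn"]);
  const double tmin = as<double>(prm["hcn_tau_min"]);
  const double tmax = as<double>(prm["hcn_tau_max"]);
  const double tv12 = as<double>(prm["hcn_tau_V12"]);
  const double tk   = as<double>(prm["hcn_tau_k"]);
  const bool   two  = as<bool>(prm["two_comp"]);
  const double Cd   = as<double>(prm["C_dend"]);
  const double gLd  = as<double>(prm["g_leak_dend"]);
  const double gc   = as<double>(prm["g_c"]);
  const double fhd  = as<double>(prm["hcn_dend_frac"]); // fraction of gh on dendrite
  const double v0   = as<double>(prm["v_init"]);
  const double ibias= as<double>(prm["i_bias"]);

  // phenomenological inductive branch (linearized resonant membrane)
  const bool   use_w = as<bool>(prm["use_ind"]);
  const double r_w   = as<double>(prm["ind_r"]);   // GOhm (mV per pA)
  const double L_w   = as<double>(prm["ind_L"]);   // GOhm * ms

  // Mg block of NMDA receptors: B(V) = 1 / (1 + [Mg] * scale * exp(-slope*V))
  const double mg       = as<double>(prm["mg_mM"]);
  const double mg_scale = as<double>(prm["mg_scale"]);
  const double mg_slope = as<double>(prm["mg_slope"]);

  // --- synapses: one row per receptor ---
  NumericVector sg    = syn["gbar"];     // nS (or pA peak if current-based)
  NumericVector staur = syn["tau_rise"]; // ms
  NumericVector staud = syn["tau_decay"];
  NumericVector sE    = syn["E_rev"];
  IntegerVector snmda = syn["is_nmda"];  // 0/1
  IntegerVector scur  = syn["current_based"];
  IntegerVector scomp = syn["comp"];     // 0 soma, 1 dendrite
  NumericVector snorm = syn["peak_norm"];// peak of (e^-t/td - e^-t/tr), precomputed
  IntegerVector ev_r  = syn["ev_receptor"]; // 0-based, sorted by time
  NumericVector ev_t  = syn["ev_time"];     // ms
  NumericVector ev_w  = syn["ev_weight"];   // per-event amplitude scale
  const int n_rec = sg.size();
  const int n_ev  = ev_r.size();

  // --- spiking (stylized action potential pasted on threshold crossing) ---
  const bool   spike_en = as<bool>(spk["enabled"]);
  const double v_th     = as<double>(spk["v_th"]);
  const double v_reset  = as<double>(spk["v_reset"]);
  const double refrac   = as<double>(spk["refrac"]); // ms
  NumericVector wave    = spk["wave"];               // mV at sim dt
  const int n_wave = wave.size();

  NumericVector rec(n_out);      // recorded channel (V in cc, I in vc)
  NumericVector rec_dend(two ? n_out : 0);
  NumericVector rec_m(n_out);    // somatic HCN gating
  NumericVector rec_ih(n_out);   // somatic HCN current, pA
  std::vector<double> spikes;

  double Vs = v0, Vd = v0;
  double ms_ = hcn_minf(v0, v12, hk), md_ = ms_;
  double Iw = 0.0;               // inductive-branch current, pA
  const double Vw0 = v0;         // branch equilibrium potential

  // synaptic state: decay and rise exponentials per receptor
  std::vector<double> xd(n_rec, 0.0), xr(n_rec, 0.0);
  std::vector<double> kd(n_rec), kr(n_rec);
  for (int r = 0; r < n_rec; ++r) {
    kd[r] = std::exp(-dt / staud[r]);
    kr[r] = std::exp(-dt / staur[r]);
  }

  const double gh_s = two ? gh * (1.0 - fhd) : gh;
  const double gh_d = two ? gh * fhd : 0.0;

  int ev_i = 0;
  int wave_pos = -1;             // >=0 while pasting the AP waveform
  double refrac_until = -1.0;
  double Vs_prev = v0;

  for (int i = 0; i < n; ++i) {
    const double t = i * dt;

    // deliver synaptic events scheduled at or before t
    while (ev_i < n_ev && ev_t[ev_i] <= t + 1e-9) {
      int r = ev_r[ev_i];
      xd[r] += ev_w[ev_i]; xr[r] += ev_w[ev_i];
      ++ev_i;
    }

    // synaptic currents per compartment (pA, inward negative in cc)
    double Isyn_s = 0.0, Isyn_d = 0.0;
    for (int r = 0; r < n_rec; ++r) {
      xd[r] *= kd[r]; xr[r] *= kr[r];
      double shape = (xd[r] - xr[r]) / snorm[r];
      if (shape < 0) shape = 0;
      double Vloc = (scomp[r] == 1 && two) ? Vd : Vs;
      double I;
      if (scur[r]) {
        I = -sg[r] * shape;                 // fixed inward current waveform (pA)
      } else {
        double g = sg[r] * shape;
        if (snmda[r]) g *= 1.0 / (1.0 + mg * mg_scale * std::exp(-mg_slope * Vloc));
        I = g * (Vloc - sE[r]);             // outward-positive membrane current
      }
      if (scomp[r] == 1 && two) Isyn_d += I;
      else                      Isyn_s += I;
    }

    if (mode == 0) {
      // ---- current clamp ----
      double tau_s = hcn_tau(Vs, tmin, tmax, tv12, tk);
      ms_ += (hcn_minf(Vs, v12, hk) - ms_) * (1.0 - std::exp(-dt / tau_s));
      double Ih_s = gh_s * ms_ * (Vs - Eh);
      double Ih_d = 0.0;
      if (two) {
        double tau_d = hcn_tau(Vd, tmin, tmax, tv12, tk);
        md_ += (hcn_minf(Vd, v12, hk) - md_) * (1.0 - std::exp(-dt / tau_d));
        Ih_d = gh_d * md_ * (Vd - Eh);
      }
      if (use_w) {
        Iw += dt * ((Vs - Vw0) - r_w * Iw) / L_w;
      }

      if (wave_pos >= 0) {
        // stylized AP overrides the membrane equation
        Vs = wave[wave_pos];
        if (++wave_pos >= n_wave) { wave_pos = -1; Vs = v_reset; }
      } else if (t < refrac_until) {
        Vs = v_reset;
      } else {
        double dVs;
        if (two) {
          dVs = (-gL * (Vs - EL) - Ih_s - Isyn_s
                 + gc * (Vd - Vs) + stim[i] + ibias - Iw) / Cs;
        } else {
          dVs = (-gL * (Vs - EL) - Ih_s - Isyn_s + stim[i] + ibias - Iw) / Cs;
        }
        Vs += dt * dVs;
      }
      if (two) {
        double dVd = (-gLd * (Vd - EL) - Ih_d - Isyn_d + gc * (Vs - Vd)) / Cd;
        Vd += dt * dVd;
      }

      // threshold crossing -> record spike, start waveform
      if (spike_en && wave_pos < 0 && t >= refrac_until &&
          Vs >= v_th && Vs_prev < v_th) {
        spikes.push_back(t);
        wave_pos = 0;
        refrac_until = t + refrac;
      }
      Vs_prev = Vs;

      if (std::abs(Vs) > 200.0 || (two && std::abs(Vd) > 200.0))
        stop("unstable integration: |V| exceeded 200 mV at t = %f ms", t);

      if (i % decim == 0 && i / decim < n_out) {
        int j = i / decim;
        rec[j] = Vs;
        if (two) rec_dend[j] = Vd;
        rec_m[j] = ms_;
        rec_ih[j] = Ih_s + (two ? Ih_d : 0.0);
      }
    } else {
      // ---- voltage clamp: soma held at the command potential ----
      Vs = stim[i];
      double tau_s = hcn_tau(Vs, tmin, tmax, tv12, tk);
      ms_ += (hcn_minf(Vs, v12, hk) - ms_) * (1.0 - std::exp(-dt / tau_s));
      double Ih_s = gh_s * ms_ * (Vs - Eh);
      double Icap = (i > 0) ? Cs * (stim[i] - stim[i - 1]) / dt : 0.0;
      double Ipip = gL * (Vs - EL) + Ih_s + Isyn_s + Icap;
      if (two) {
        double tau_d = hcn_tau(Vd, tmin, tmax, tv12, tk);
        md_ += (hcn_minf(Vd, v12, hk) - md_) * (1.0 - std::exp(-dt / tau_d));
        double Ih_d = gh_d * md_ * (Vd - Eh);
        double dVd = (-gLd * (Vd - EL) - Ih_d - Isyn_d + gc * (Vs - Vd)) / Cd;
        Ipip += gc * (Vs - Vd);
        Vd += dt * dVd;
        if (std::abs(Vd) > 200.0)
          stop("unstable integration: |V| exceeded 200 mV at t = %f ms", t);
      }
      if (i % decim == 0 && i / decim < n_out) {
        int j = i / decim;
        rec[j] = Ipip;
        if (two) rec_dend[j] = Vd;
        rec_m[j] = ms_;
        rec_ih[j] = Ih_s;
      }
    }
  }

  return List::create(_["rec"] = rec, _["dend"] = rec_dend,
                      _["m"] = rec_m, _["ih"] = rec_ih,
                      _["spikes"] = wrap(spikes));
}
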