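// Clock-driven simulation engine for the balanced two-compartment network.
//
// Per-step order of operations:
//   1. exact exponential decay of synaptic conductances
//   2. delivery of queued recurrent spikes (previous step) and external
//      Poisson spikes falling in the current step
//   3. forward-Euler integration of membrane voltages and adaptation
//   4. threshold detection, reset to E_l, refractory clamp
//   5. bAP detection (dendritic voltage + recent somatic spike + bAP
//      refractoriness)
//   6. exact exponential decay of plasticity traces and the rate filter
//      to the current spike time, then plasticity updates reading the
//      pre-increment trace values (t - epsilon convention)
//   7. trace and rate-filter increments for this step's events
//
// Units: mV, nS, pA, pF, ms. Conductance times voltage is pA; pA over pF
// is mV/ms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Csr {
  std::vector<int> off, tgt;
  void load(const List& p) {
    IntegerVector o = p["off"], t = p["tgt"];
    off.assign(o.begin(), o.end());
    tgt.assign(t.begin(), t.end());
  }
};

struct Csc {
  std::vector<int> off, src, widx;
  void load(const List& p) {
    IntegerVector o = p["csc_off"], s = p["csc_src"], w = p["csc_widx"];
    off.assign(o.begin(), o.end());
    src.assign(s.begin(), s.end());
    widx.assign(w.begin(), w.end());
  }
};

inline double clipw(double w, double wmax) {
  if (w < 0.0) return 0.0;
  if (w > wmax) return wmax;
  return w;
}

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(List neuron, List plast, List gates, List conn,
                 List input, List init, List sim) {
  const double dt = as<double>(sim["dt"]);
  const double warmup_ms = as<double>(sim["warmup_ms"]);
  const double main_ms = as<double>(sim["main_ms"]);
  const double bin_ms = as<double>(sim["bin_ms"]);
  const int baseline_bins = as<int>(sim["baseline_bins"]);
  const double snapshot_ms = as<double>(sim["snapshot_ms"]);
  const bool rec_currents = as<bool>(sim["record_currents"]);
  const bool rec_bap = as<bool>(sim["record_bAP"]);
  const bool stop_expl = as<bool>(sim["stop_on_explosion"]);
  const double stop_factor = as<double>(sim["stop_factor"]);
  const bool plast_enabled = as<bool>(sim["plasticity_on"]);
  IntegerVector rec_idx_r = sim["record_voltages"]; // 0-based

  // --- neuron parameters ---
  const double C_s = as<double>(neuron["C_s"]), C_d = as<double>(neuron["C_d"]);
  const double g_l = as<double>(neuron["g_l"]), g_l_d = as<double>(neuron["g_l_d"]);
  const double E_l = as<double>(neuron["E_l"]), E_I = as<double>(neuron["E_I"]);
  const double v_reset = as<double>(neuron["v_reset"]);
  const double v_th = as<double>(neuron["v_theta"]);
  const double v_th_I = as<double>(neuron["v_theta_I"]);
  const double tau_m_I = as<double>(neuron["tau_m_I"]);
  const double C_I = g_l * tau_m_I;
  const double c_d = as<double>(neuron["c_d"]);
  const double a_wd = as<double>(neuron["a_omega_d"]);
  const double b_ws = as<double>(neuron["b_omega_s"]);
  const double tau_ws = as<double>(neuron["tau_omega_s"]);
  const double tau_wd = as<double>(neuron["tau_omega_d"]);
  const double g_s = as<double>(neuron["g_s"]);
  const double g_d = as<double>(neuron["g_d"]);
  const double E_d = as<double>(neuron["E_d"]);
  const double D_d = as<double>(neuron["D_d"]);
  const double lam = as<double>(neuron["lambda_scale"]);
  const double t_ref = as<double>(neuron["t_ref"]);
  const double bap_delay = as<double>(neuron["bAP_delay"]);
  const double bap_dur = as<double>(neuron["bAP_duration"]);

  // --- plasticity parameters ---
  const double A_plus = as<double>(plast["A_plus"]);
  const double A_Ca = as<double>(plast["A_Ca"]);
  const double alpha = as<double>(plast["alpha"]);
  const double th_bap = as<double>(plast["theta_bAP"]);
  const double th_Ca = as<double>(plast["theta_Ca"]);
  const double tau_p = as<double>(plast["tau_plus"]);
  const double tau_mn = as<double>(plast["tau_minus"]);
  const double tau_sl = as<double>(plast["tau_slow"]);
  const double w_max = as<double>(plast["w_max"]);
  const double eta = as<double>(plast["eta"]);
  double kappa = as<double>(plast["kappa"]); // NA -> calibrate
  const double tau_homeo_ms = as<double>(plast["tau_homeo"]) * 1000.0;
  const double bap_refr = as<double>(plast["bAP_refractory"]);
  const double bap_win = as<double>(plast["bAP_window"]);

  // --- gates (per E neuron) ---
  NumericVector gam_s = gates["gamma_soma"], gam_d = gates["gamma_dend"];
  NumericVector inh_s = gates["inh_scale_soma"], inh_d = gates["inh_scale_dend"];
  NumericVector vshift = gates["v_theta_shift"];
  NumericVector eta_s = gates["eta_soma"], eta_d = gates["eta_dend"];

  // --- connectivity ---
  List c_pe = conn["pe"], c_pi = conn["pi"], c_ees = conn["ee_soma"],
       c_eed = conn["ee_dend"], c_ei = conn["ei"], c_ies = conn["ie_soma"],
       c_ied = conn["ie_dend"], c_ii = conn["ii"];
  Csr pe, pi, ees, eed, ei, ies, ied, ii;
  pe.load(c_pe); pi.load(c_pi); ees.load(c_ees); eed.load(c_eed);
  ei.load(c_ei); ies.load(c_ies); ied.load(c_ied); ii.load(c_ii);
  Csc ees_in, eed_in;
  ees_in.load(c_ees); eed_in.load(c_eed);
  const double w_EP = as<double>(c_pe["w"]), w_IP = as<double>(c_pi["w"]);
  const double w_IE = as<double>(c_ei["w"]), w_EI = as<double>(c_ies["w"]);
  const double w_EI_d = as<double>(c_ied["w"]), w_II = as<double>(c_ii["w"]);
  const double w0_s = as<double>(c_ees["w"]), w0_d = as<double>(c_eed["w"]);
  NumericVector Ws = clone(as<NumericVector>(c_ees["w_init"]));
  NumericVector Wd = clone(as<NumericVector>(c_eed["w_init"]));

  // --- input spikes ---
  NumericVector ptime = input["time"];
  IntegerVector psrc = input["source"]; // 0-based
  const int np = ptime.size();

  // --- state ---
  NumericVector Vs0 = init["V_s"], Vd0 = init["V_d"], VI0 = init["V_I"];
  const int NE = Vs0.size(), NI = VI0.size();
  std::vector<double> Vs(Vs0.begin(), Vs0.end());
  std::vector<double> Vd(Vd0.begin(), Vd0.end());
  std::vector<double> VI(VI0.begin(), VI0.end());
  std::vector<double> ws(NE, 0.0), wd(NE, 0.0);
  std::vector<double> gEs(NE, 0.0), gIs(NE, 0.0), gEd(NE, 0.0), gId(NE, 0.0);
  std::vector<double> gEI(NI, 0.0), gII(NI, 0.0);
  std::vector<double> zp(NE, 0.0), zm_s(NE, 0.0), zsl_s(NE, 0.0);
  std::vector<double> zm_d(NE, 0.0), zsl_d(NE, 0.0), sbar(NE, 0.0);
  std::vector<double> refE(NE, -1e18), refI(NI, -1e18);
  std::vector<double> last_sp(NE, -1e18), last_bap(NE, -1e18);

  // four decay factors: E/I conductance per compartment; inhibitory cells
  // use the somatic-compartment constants
  const double tau_E_soma = as<double>(sim["tau_E_soma"]);
  const double tau_I_soma = as<double>(sim["tau_I_soma"]);
  const double tau_E_dend = as<double>(sim["tau_E_dend"]);
  const double tau_I_dend = as<double>(sim["tau_I_dend"]);
  const double f_Es = std::exp(-dt / tau_E_soma);
  const double f_Is = std::exp(-dt / tau_I_soma);
  const double f_Ed = std::exp(-dt / tau_E_dend);
  const double f_Id = std::exp(-dt / tau_I_dend);
  const double f_zp = std::exp(-dt / tau_p);
  const double f_zm = std::exp(-dt / tau_mn);
  const double f_zsl = std::exp(-dt / tau_sl);
  const double f_sbar = std::exp(-dt / tau_homeo_ms);
  const double sbar_jump = 1000.0 / tau_homeo_ms; // Hz per spike

  const double total_ms = warmup_ms + main_ms;
  const long n_steps = (long)std::llround(total_ms / dt);
  const long warm_steps = (long)std::llround(warmup_ms / dt);
  const double eps = 1e-9;

  // recording
  std::vector<double> spE_t, spI_t, bap_t;
  std::vector<int> spE_i, spI_i, bap_i;
  spE_t.reserve(1 << 16); spI_t.reserve(1 << 14);
  const int n_bins = (int)std::ceil(main_ms / bin_ms - eps);
  std::vector<double> bin_cnt(n_bins, 0.0);
  int bins_done = 0;
  bool early = false;
  double warm_cnt = 0.0; // E spikes in last 2 s of warm-up

  double cum_abs_s = 0.0, cum_net_s = 0.0, cum_abs_d = 0.0, cum_net_d = 0.0;
  std::vector<double> snap_t, snap_abs_s, snap_net_s, snap_abs_d, snap_net_d;
  long next_snap = 1;

  std::vector<double> exc_sum(rec_currents ? NE : 0, 0.0);
  std::vector<double> inh_sum(rec_currents ? NE : 0, 0.0);
  long cur_samples = 0;

  std::vector<int> rec_idx(rec_idx_r.begin(), rec_idx_r.end());
  const int nrec = rec_idx.size();
  std::vector<double> rec_t, rec_vs, rec_vd, rec_ws, rec_wd;

  std::vector<int> pendE, pendI, spk_now, bap_now;
  pendE.reserve(NE); pendI.reserve(NI);
  spk_now.reserve(NE); bap_now.reserve(NE);

  int pp = 0; // poisson pointer
  bool plast_on = false;
  double homeo_k = 0.0; // A_plus tau_p tau_sl / (tau_mn kappa), taus in s
  if (R_finite(kappa) && kappa > 0.0) {
    homeo_k = A_plus * (tau_p / 1000.0) * (tau_sl / 1000.0) /
              ((tau_mn / 1000.0) * kappa);
  }

  long step = 0;
  double t_end = 0.0;
  for (step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double t_next = t + dt;

    // switch on plasticity at the warm-up boundary
    if (step == warm_steps && plast_enabled && eta != 0.0) {
      if (!R_finite(kappa) || kappa <= 0.0) {
        kappa = warm_cnt / (2.0 * NE);
        if (kappa <= 0.0)
          stop("warm-up produced no spikes; cannot calibrate kappa");
        homeo_k = A_plus * (tau_p / 1000.0) * (tau_sl / 1000.0) /
                  ((tau_mn / 1000.0) * kappa);
      }
      plast_on = true;
    }

    // 1. conductance decay
    for (int i = 0; i < NE; ++i) {
      gEs[i] *= f_Es; gIs[i] *= f_Is;
      gEd[i] *= f_Ed; gId[i] *= f_Id;
    }
    for (int i = 0; i < NI; ++i) { gEI[i] *= f_Es; gII[i] *= f_Is; }

    // 2. delivery: queued recurrent spikes, then Poisson in [t, t + dt)
    for (size_t q = 0; q < pendE.size(); ++q) {
      const int j = pendE[q];
      for (int k = ees.off[j]; k < ees.off[j + 1]; ++k)
        gEs[ees.tgt[k]] += Ws[k];
      for (int k = eed.off[j]; k < eed.off[j + 1]; ++k)
        gEd[eed.tgt[k]] += Wd[k];
      for (int k = ei.off[j]; k < ei.off[j + 1]; ++k)
        gEI[ei.tgt[k]] += w_IE;
    }
    for (size_t q = 0; q < pendI.size(); ++q) {
      const int j = pendI[q];
      for (int k = ies.off[j]; k < ies.off[j + 1]; ++k) {
        const int i = ies.tgt[k];
        gIs[i] += w_EI * inh_s[i];
      }
      for (int k = ied.off[j]; k < ied.off[j + 1]; ++k) {
        const int i = ied.tgt[k];
        gId[i] += w_EI_d * inh_d[i];
      }
      for (int k = ii.off[j]; k < ii.off[j + 1]; ++k)
        gII[ii.tgt[k]] += w_II;
    }
    pendE.clear(); pendI.clear();
    while (pp < np && ptime[pp] < t_next - eps) {
      const int s = psrc[pp];
      for (int k = pe.off[s]; k < pe.off[s + 1]; ++k) gEs[pe.tgt[k]] += w_EP;
      for (int k = pi.off[s]; k < pi.off[s + 1]; ++k) gEI[pi.tgt[k]] += w_IP;
      ++pp;
    }

    // 3.-4. integration, thresholding, resets
    spk_now.clear();
    for (int i = 0; i < NE; ++i) {
      const double vs = Vs[i], vd = Vd[i];
      const double sig = 1.0 / (1.0 + std::exp(-(vd - E_d) / D_d));
      const double since = t - last_sp[i];
      const double K = (since >= bap_delay - eps &&
                        since <= bap_delay + bap_dur + eps) ? 1.0 : 0.0;
      const double Is = -g_l * (vs - E_l) - gam_s[i] * gEs[i] * vs -
                        gIs[i] * (vs - E_I) + lam * (g_s * sig + ws[i]);
      const double Id = -g_l_d * (vd - E_l) - gam_d[i] * gEd[i] * vd -
                        gId[i] * (vd - E_I) + g_d * sig + c_d * K + wd[i];
      double vs_n = vs + dt * Is / C_s;
      const double vd_n = vd + dt * Id / C_d;
      ws[i] += -dt * ws[i] / tau_ws;
      wd[i] += dt * (-wd[i] + a_wd * (vd - E_l)) / tau_wd;
      if (!R_finite(vs_n) || !R_finite(vd_n))
        stop("non-finite voltage at t = %f ms (neuron %d)", t_next, i + 1);
      if (t_next < refE[i] - eps) {
        vs_n = v_reset; // refractory clamp
      } else if (vs_n > v_th + vshift[i]) {
        vs_n = v_reset;
        ws[i] += b_ws;
        refE[i] = t_next + t_ref;
        last_sp[i] = t_next;
        spk_now.push_back(i);
      }
      Vs[i] = vs_n; Vd[i] = vd_n;
    }
    for (size_t q = 0; q < spk_now.size(); ++q) {
      const int i = spk_now[q];
      spE_t.push_back(t_next); spE_i.push_back(i + 1);
      pendE.push_back(i);
      if (t_next > warmup_ms + eps) {
        const int b = (int)((t_next - warmup_ms - eps) / bin_ms);
        if (b >= 0 && b < n_bins) bin_cnt[b] += 1.0;
      } else if (t_next > warmup_ms - 2000.0 + eps) {
        warm_cnt += 1.0;
      }
    }
    for (int i = 0; i < NI; ++i) {
      const double v = VI[i];
      const double Ii = -g_l * (v - E_l) - gEI[i] * v - gII[i] * (v - E_I);
      double v_n = v + dt * Ii / C_I;
      if (!R_finite(v_n))
        stop("non-finite inhibitory voltage at t = %f ms", t_next);
      if (t_next < refI[i] - eps) {
        v_n = v_reset;
      } else if (v_n > v_th_I) {
        v_n = v_reset;
        refI[i] = t_next + t_ref;
        spI_t.push_back(t_next); spI_i.push_back(i + 1);
        pendI.push_back(i);
      }
      VI[i] = v_n;
    }

    // 5. bAP detection at t_next
    bap_now.clear();
    for (int i = 0; i < NE; ++i) {
      if (Vd[i] > th_bap &&
          t_next - last_sp[i] <= bap_win + eps &&
          t_next - last_bap[i] >= bap_refr - eps) {
        last_bap[i] = t_next;
        bap_now.push_back(i);
        if (rec_bap) { bap_t.push_back(t_next); bap_i.push_back(i + 1); }
      }
    }

    // 6. decay traces / rate filter to t_next, then plasticity on
    //    pre-increment values
    for (int i = 0; i < NE; ++i) {
      zp[i] *= f_zp;
      zm_s[i] *= f_zm; zsl_s[i] *= f_zsl;
      zm_d[i] *= f_zm; zsl_d[i] *= f_zsl;
      sbar[i] *= f_sbar;
    }
    if (plast_on) {
      for (size_t q = 0; q < spk_now.size(); ++q) {
        const int i = spk_now[q]; // postsynaptic somatic spike
        const double pot = eta_s[i] * eta * w0_s * A_plus * zsl_s[i];
        if (pot != 0.0) {
          for (int k = ees_in.off[i]; k < ees_in.off[i + 1]; ++k) {
            const int widx = ees_in.widx[k];
            const double dw = pot * zp[ees_in.src[k]];
            const double wn = clipw(Ws[widx] + dw, w_max);
            const double ap = wn - Ws[widx];
            Ws[widx] = wn;
            cum_abs_s += std::fabs(ap); cum_net_s += ap;
          }
        }
      }
      for (size_t q = 0; q < bap_now.size(); ++q) {
        const int i = bap_now[q]; // postsynaptic bAP event
        const double pot = eta_d[i] * eta * w0_d * A_plus * zsl_d[i];
        if (pot != 0.0) {
          for (int k = eed_in.off[i]; k < eed_in.off[i + 1]; ++k) {
            const int widx = eed_in.widx[k];
            const double dw = pot * zp[eed_in.src[k]];
            const double wn = clipw(Wd[widx] + dw, w_max);
            const double ap = wn - Wd[widx];
            Wd[widx] = wn;
            cum_abs_d += std::fabs(ap); cum_net_d += ap;
          }
        }
      }
      for (size_t q = 0; q < spk_now.size(); ++q) {
        const int j = spk_now[q]; // presynaptic spike
        for (int k = ees.off[j]; k < ees.off[j + 1]; ++k) {
          const int i = ees.tgt[k];
          const double Am = homeo_k * sbar[i] * sbar[i];
          const double dw = -eta_s[i] * eta * w0_s * Am * zm_s[i];
          if (dw != 0.0) {
            const double wn = clipw(Ws[k] + dw, w_max);
            const double ap = wn - Ws[k];
            Ws[k] = wn;
            cum_abs_s += std::fabs(ap); cum_net_s += ap;
          }
        }
        for (int k = eed.off[j]; k < eed.off[j + 1]; ++k) {
          const int i = eed.tgt[k];
          if (eta_d[i] == 0.0) continue; // closed gate freezes the synapse
          const double Am = homeo_k * sbar[i] * sbar[i];
          const double ca = (Vd[i] > th_Ca) ? A_Ca : 0.0;
          const double dw = eta_d[i] *
            (eta * w0_d * (-Am * zm_d[i] + ca) - alpha);
          const double wn = clipw(Wd[k] + dw, w_max);
          const double ap = wn - Wd[k];
          Wd[k] = wn;
          cum_abs_d += std::fabs(ap); cum_net_d += ap;
        }
      }
    }

    // 7. trace / rate-filter increments
    for (size_t q = 0; q < spk_now.size(); ++q) {
      const int i = spk_now[q];
      zp[i] += 1.0; zm_s[i] += 1.0; zsl_s[i] += 1.0;
      sbar[i] += sbar_jump;
    }
    for (size_t q = 0; q < bap_now.size(); ++q) {
      const int i = bap_now[q];
      zm_d[i] += 1.0; zsl_d[i] += 1.0;
    }

    // recording
    if (rec_currents && t_next > warmup_ms + eps && step % 10 == 0) {
      for (int i = 0; i < NE; ++i) {
        exc_sum[i] += -gam_s[i] * gEs[i] * Vs[i];
        inh_sum[i] += -gIs[i] * (Vs[i] - E_I);
      }
      ++cur_samples;
    }
    if (nrec > 0) {
      rec_t.push_back(t_next);
      for (int q = 0; q < nrec; ++q) {
        const int i = rec_idx[q];
        rec_vs.push_back(Vs[i]); rec_vd.push_back(Vd[i]);
        rec_ws.push_back(ws[i]); rec_wd.push_back(wd[i]);
      }
    }

    t_end = t_next;

    // bin completion, snapshots and early stop (main phase only)
    if (t_next > warmup_ms + eps) {
      const double tm = t_next - warmup_ms;
      const int done = (int)((tm + eps) / bin_ms);
      if (done > bins_done) {
        bins_done = done;
        if (stop_expl && bins_done > baseline_bins) {
          double rb = 0.0;
          for (int b = 0; b < baseline_bins; ++b) rb += bin_cnt[b];
          rb /= (baseline_bins * NE * (bin_ms / 1000.0));
          const double last = bin_cnt[bins_done - 1] /
                              (NE * (bin_ms / 1000.0));
          if (rb > 0.0 && last > stop_factor * rb) { early = true; }
        }
      }
      if ((long)std::floor((tm + eps) / snapshot_ms) >= next_snap) {
        snap_t.push_back(tm / 1000.0);
        snap_abs_s.push_back(cum_abs_s); snap_net_s.push_back(cum_net_s);
        snap_abs_d.push_back(cum_abs_d); snap_net_d.push_back(cum_net_d);
        ++next_snap;
      }
      if (early) break;
    }
  }

  List vrec = R_NilValue;
  if (nrec > 0) {
    const long ns = rec_t.size();
    NumericMatrix mvs(nrec, ns), mvd(nrec, ns), mws(nrec, ns), mwd(nrec, ns);
    for (long s = 0; s < ns; ++s)
      for (int q = 0; q < nrec; ++q) {
        mvs(q, s) = rec_vs[s * nrec + q]; mvd(q, s) = rec_vd[s * nrec + q];
        mws(q, s) = rec_ws[s * nrec + q]; mwd(q, s) = rec_wd[s * nrec + q];
      }
    vrec = List::create(_["t"] = NumericVector(rec_t.begin(), rec_t.end()),
                        _["V_s"] = mvs, _["V_d"] = mvd,
                        _["omega_s"] = mws, _["omega_d"] = mwd);
  }

  List currents = R_NilValue;
  if (rec_currents && cur_samples > 0) {
    NumericVector em(NE), im(NE);
    for (int i = 0; i < NE; ++i) {
      em[i] = exc_sum[i] / cur_samples;
      im[i] = inh_sum[i] / cur_samples;
    }
    currents = List::create(_["exc_mean"] = em, _["inh_mean"] = im);
  }

  return List::create(
    _["spike_E_time"] = NumericVector(spE_t.begin(), spE_t.end()),
    _["spike_E_id"] = IntegerVector(spE_i.begin(), spE_i.end()),
    _["spike_I_time"] = NumericVector(spI_t.begin(), spI_t.end()),
    _["spike_I_id"] = IntegerVector(spI_i.begin(), spI_i.end()),
    _["bap_time"] = NumericVector(bap_t.begin(), bap_t.end()),
    _["bap_id"] = IntegerVector(bap_i.begin(), bap_i.end()),
    _["kappa"] = kappa,
    _["W_soma"] = Ws, _["W_dend"] = Wd,
    _["bin_counts"] = NumericVector(bin_cnt.begin(),
                                    bin_cnt.begin() + bins_done),
    _["cum_abs_soma"] = cum_abs_s, _["cum_net_soma"] = cum_net_s,
    _["cum_abs_dend"] = cum_abs_d, _["cum_net_dend"] = cum_net_d,
    _["snapshots"] = List::create(
      _["t"] = NumericVector(snap_t.begin(), snap_t.end()),
      _["cum_abs_soma"] = NumericVector(snap_abs_s.begin(), snap_abs_s.end()),
      _["cum_net_soma"] = NumericVector(snap_net_s.begin(), snap_net_s.end()),
      _["cum_abs_dend"] = NumericVector(snap_abs_d.begin(), snap_abs_d.end()),
      _["cum_net_dend"] = NumericVector(snap_net_d.begin(), snap_net_d.end())),
    _["currents"] = currents,
    _["voltages"] = vrec,
    _["early_stopped"] = early,
    _["t_end_ms"] = t_end);
}
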