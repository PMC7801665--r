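// Fixed-step (forward Euler) simulation of two exponential integrate-and-fire
// populations (E, I) with conductance-based beta-function synapses, delayed
// spike delivery, and independent Poisson drive onto the excitatory sheet.
// Units: ms, mV, nS, pF (currents in pA).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct SynState {
  // one incoming synapse type onto a population: shared kinetics,
  // per-neuron rise/decay accumulators
  double tau_r, tau_d, erev, K;
  double dec_r, dec_d;
  std::vector<double> ar, ad;
  SynState(int n, double tr, double td, double er, double k, double dt)
      : tau_r(tr), tau_d(td), erev(er), K(k),
        dec_r(std::exp(-dt / tr)), dec_d(std::exp(-dt / td)),
        ar(n, 0.0), ad(n, 0.0) {}
  void decay() {
    for (size_t i = 0; i < ar.size(); ++i) {
      ar[i] *= dec_r;
      ad[i] *= dec_d;
    }
  }
  double g(int i) const { return K * (ad[i] - ar[i]); }
  void add(int i, double w) {
    ar[i] += w;
    ad[i] += w;
  }
};

// [[Rcpp::export]]
List simulate_eif_cpp(int nE, int nI,
                      NumericVector eifE, NumericVector eifI,
                      NumericVector synEI, NumericVector synIE,
                      NumericVector synExt,
                      IntegerVector ei_ptr, IntegerVector ei_idx, double gEI,
                      IntegerVector ie_ptr, IntegerVector ie_idx, double gIE,
                      double p_rate, double w_ext,
                      double dt, double duration, double record_from,
                      bool v_init_uniform,
                      double anneal_frac, double anneal_ms,
                      double i_const_E, double i_const_I) {
  // eif*: Cm, gL, EL, VT, DT, Vreset, Vpeak, tref
  // syn*: tau_r, tau_d, Erev, K, delay
  const double CmE = eifE[0], gLE = eifE[1], ELE = eifE[2], VTE = eifE[3],
               DTE = eifE[4], VrE = eifE[5], VpE = eifE[6], trefE = eifE[7];
  const double CmI = eifI[0], gLI = eifI[1], ELI = eifI[2], VTI = eifI[3],
               DTI = eifI[4], VrI = eifI[5], VpI = eifI[6], trefI = eifI[7];

  const int n_steps = (int)std::round(duration / dt);
  const int refE = (int)std::round(trefE / dt);
  const int refI = (int)std::round(trefI / dt);
  const int delayEI = std::max(1, (int)std::round(synEI[4] / dt));
  const int delayIE = std::max(1, (int)std::round(synIE[4] / dt));
  const int ring = std::max(delayEI, delayIE) + 1;

  SynState sEI(nI, synEI[0], synEI[1], synEI[2], synEI[3], dt); // E -> I
  SynState sIE(nE, synIE[0], synIE[1], synIE[2], synIE[3], dt); // I -> E
  SynState sExt(nE, synExt[0], synExt[1], synExt[2], synExt[3], dt);

  std::vector<double> VE(nE, ELE), VI(nI, ELI);
  if (v_init_uniform) {
    // desynchronized start: V0 ~ U(E_L, V_T)
    for (int i = 0; i < nE; ++i) VE[i] = ELE + R::unif_rand() * (VTE - ELE);
    for (int i = 0; i < nI; ++i) VI[i] = ELI + R::unif_rand() * (VTI - ELI);
  }
  std::vector<int> refcE(nE, 0), refcI(nI, 0);

  // ring buffers of pending conductance increments
  std::vector<std::vector<double>> bufI(ring, std::vector<double>(nI, 0.0));
  std::vector<std::vector<double>> bufE(ring, std::vector<double>(nE, 0.0));

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(1 << 20);
  spk_t.reserve(1 << 20);

  const double mu_ext = p_rate * dt / 1000.0; // p_rate in Hz, dt in ms

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // coupling ramp during settling: fraction anneal_frac -> 1
    double cf = 1.0;
    if (anneal_ms > 0.0 && t < anneal_ms)
      cf = anneal_frac + (1.0 - anneal_frac) * (t / anneal_ms);
    const double gEI_t = gEI * cf, gIE_t = gIE * cf;
    const int cur = step % ring;

    sEI.decay();
    sIE.decay();
    sExt.decay();

    // deliver delayed spikes scheduled for this step
    {
      std::vector<double>& di = bufI[cur];
      for (int i = 0; i < nI; ++i)
        if (di[i] != 0.0) { sEI.add(i, di[i]); di[i] = 0.0; }
      std::vector<double>& de = bufE[cur];
      for (int i = 0; i < nE; ++i)
        if (de[i] != 0.0) { sIE.add(i, de[i]); de[i] = 0.0; }
    }

    // external Poisson drive onto E
    if (mu_ext > 0.0 && w_ext > 0.0)
      for (int i = 0; i < nE; ++i) {
        int k = (int)R::rpois(mu_ext);
        if (k > 0) sExt.add(i, k * w_ext);
      }

    // integrate E
    for (int i = 0; i < nE; ++i) {
      if (refcE[i] > 0) { --refcE[i]; VE[i] = VrE; continue; }
      double V = VE[i];
      double isyn = i_const_E - sIE.g(i) * (V - sIE.erev)
                    - sExt.g(i) * (V - sExt.erev);
      double Vexp = V > VpE ? VpE : V; // clamp the exponential
      double dV = (-gLE * (V - ELE) + gLE * DTE * std::exp((Vexp - VTE) / DTE)
                   + isyn) * dt / CmE;
      V += dV;
      if (!std::isfinite(V))
        stop("numerical blow-up in excitatory unit %d at t = %.3f ms", i + 1, t);
      if (V >= VpE) {
        spk_id.push_back(i + 1);
        spk_t.push_back(t);
        V = VrE;
        refcE[i] = refE;
        // schedule E -> I deliveries
        std::vector<double>& slot = bufI[(step + delayEI) % ring];
        for (int p = ei_ptr[i]; p < ei_ptr[i + 1]; ++p)
          slot[ei_idx[p]] += gEI_t;
      }
      VE[i] = V;
    }

    // integrate I
    for (int i = 0; i < nI; ++i) {
      if (refcI[i] > 0) { --refcI[i]; VI[i] = VrI; continue; }
      double V = VI[i];
      double isyn = i_const_I - sEI.g(i) * (V - sEI.erev);
      double Vexp = V > VpI ? VpI : V;
      double dV = (-gLI * (V - ELI) + gLI * DTI * std::exp((Vexp - VTI) / DTI)
                   + isyn) * dt / CmI;
      V += dV;
      if (!std::isfinite(V))
        stop("numerical blow-up in inhibitory unit %d at t = %.3f ms", i + 1, t);
      if (V >= VpI) {
        spk_id.push_back(nE + i + 1);
        spk_t.push_back(t);
        V = VrI;
        refcI[i] = refI;
        std::vector<double>& slot = bufE[(step + delayIE) % ring];
        for (int p = ie_ptr[i]; p < ie_ptr[i + 1]; ++p)
          slot[ie_idx[p]] += gIE_t;
      }
      VI[i] = V;
    }
  }

  // counts over the full run and over the analysis window
  IntegerVector counts(nE + nI), counts_win(nE + nI);
  for (size_t k = 0; k < spk_id.size(); ++k) {
    counts[spk_id[k] - 1]++;
    if (spk_t[k] >= record_from) counts_win[spk_id[k] - 1]++;
  }
  return List::create(_["id"] = wrap(spk_id), _["t"] = wrap(spk_t),
                      _["counts"] = counts, _["counts_window"] = counts_win);
}

// Single-synapse conductance trace g(t) for a spike at t0 = 0 (oracle tests).
// [[Rcpp::export]]
NumericVector beta_conductance_cpp(double w, double tau_r, double tau_d,
                                   double K, double dt, double t_max) {
  int n = (int)std::round(t_max / dt) + 1;
  NumericVector g(n);
  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    g[i] = w * K * (std::exp(-t / tau_d) - std::exp(-t / tau_r));
  }
  return g;
}
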