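// Forward-Euler co-simulation of the dynamic-clamp half-center oscillator:
// two surrogate spiking neurons (Morris-Lecar-type two-variable membranes)
// coupled by virtual inhibitory synapses and hyperpolarization-activated
// currents, each driven by a pre-generated injected current trace.
// Every current component is recorded separately as ground truth.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct MLNeuron {
  double C, gL, EL, gCa, ECa, gK, EK, v1, v2, v3, v4, phi;
};

struct Clamp {
  double gsyn, Esyn, vsyn, gh, Eh, vh, taubar;
};

MLNeuron parse_ml(const List &p) {
  MLNeuron m;
  m.C = p["C"]; m.gL = p["gL"]; m.EL = p["EL"];
  m.gCa = p["gCa"]; m.ECa = p["ECa"]; m.gK = p["gK"]; m.EK = p["EK"];
  m.v1 = p["v1"]; m.v2 = p["v2"]; m.v3 = p["v3"]; m.v4 = p["v4"];
  m.phi = p["phi"];
  return m;
}

Clamp parse_clamp(const List &p) {
  Clamp c;
  c.gsyn = p["g_syn_max"]; c.Esyn = p["E_syn"]; c.vsyn = p["v_half_syn"];
  c.gh = p["g_h_max"]; c.Eh = p["E_h"]; c.vh = p["v_half_h"];
  c.taubar = p["tau_bar"];
  return c;
}

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

}  // namespace

// [[Rcpp::export]]
List hco_simulate_cpp(List neuron_params, List clamp_params, const arma::mat &u,
                      double delta, const arma::vec &v_init,
                      const arma::vec &n_init, const arma::vec &z_init,
                      const arma::vec &w_init, bool h_rate_alt) {
  const int N = u.n_rows;
  MLNeuron ml[2] = {parse_ml(neuron_params[0]), parse_ml(neuron_params[1])};
  Clamp cl[2] = {parse_clamp(clamp_params[0]), parse_clamp(clamp_params[1])};

  arma::mat V(N, 2), Isyn(N, 2), Ih(N, 2), Iapp(N, 2), Z(N, 2), W(N, 2);
  double v[2] = {v_init[0], v_init[1]};
  double ng[2] = {n_init[0], n_init[1]};
  double z[2] = {z_init[0], z_init[1]};
  double wg[2] = {w_init[0], w_init[1]};

  int diverged = 0;
  for (int t = 0; t < N; ++t) {
    if (!std::isfinite(v[0]) || !std::isfinite(v[1])) { diverged = t + 1; break; }
    double isyn[2], ih[2], iapp[2];
    for (int i = 0; i < 2; ++i) {
      isyn[i] = -cl[i].gsyn * z[i] * (v[i] - cl[i].Esyn);
      ih[i] = -cl[i].gh * wg[i] * (v[i] - cl[i].Eh);
      iapp[i] = ih[i] + isyn[i] + u(t, i);
      V(t, i) = v[i]; Isyn(t, i) = isyn[i]; Ih(t, i) = ih[i];
      Iapp(t, i) = iapp[i]; Z(t, i) = z[i]; W(t, i) = wg[i];
    }
    double vnext[2], nnext[2], znext[2], wnext[2];
    for (int i = 0; i < 2; ++i) {
      const int j = 1 - i;
      const MLNeuron &m = ml[i];
      const Clamp &c = cl[i];
      const double minf = 0.5 * (1.0 + std::tanh((v[i] - m.v1) / m.v2));
      const double ninf = 0.5 * (1.0 + std::tanh((v[i] - m.v3) / m.v4));
      const double lamn = m.phi * std::cosh((v[i] - m.v3) / (2.0 * m.v4));
      const double dv = (-m.gL * (v[i] - m.EL) - m.gCa * minf * (v[i] - m.ECa) -
                         m.gK * ng[i] * (v[i] - m.EK) + iapp[i]) / m.C;
      vnext[i] = v[i] + delta * dv;
      nnext[i] = ng[i] + delta * lamn * (ninf - ng[i]);
      const double ssyn = logistic((v[j] - c.vsyn) / 2.0);
      znext[i] = z[i] + delta / 50.0 * (1.1 - ssyn) * (-z[i] + ssyn);
      const double tauh = logistic((v[i] + 110.0) / 13.0);
      const double rate = h_rate_alt ? delta / (c.taubar * tauh + 0.1)
                                     : delta / (c.taubar * (tauh + 0.1));
      const double sh = logistic(-(v[i] - c.vh) / 7.0);
      wnext[i] = wg[i] + rate * (-wg[i] + sh);
    }
    for (int i = 0; i < 2; ++i) {
      v[i] = vnext[i]; ng[i] = nnext[i]; z[i] = znext[i]; wg[i] = wnext[i];
    }
  }

  return List::create(_["v"] = V, _["I_syn"] = Isyn, _["I_h"] = Ih,
                      _["I_app"] = Iapp, _["z"] = Z, _["w"] = W,
                      _["diverged"] = diverged,
                      _["state"] = NumericVector::create(v[0], v[1], ng[0],
                                                         ng[1], z[0], z[1],
                                                         wg[0], wg[1]));
}
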