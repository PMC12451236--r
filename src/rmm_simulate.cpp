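// Forward simulation of an RMM circuit: open loop (gamma = 0) or as a
// Luenberger observer correcting each step's voltage toward a measurement
// by a factor gamma before propagating.  This is the package's inner loop,
// so it lives in compiled code; parameters arrive pre-transformed (softplus
// already applied) in a plain list descriptor built on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Mlp {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
  arma::vec lo, hi;
  double eval(const arma::vec &x) const {
    arma::vec a = 2.0 * (x - lo) / (hi - lo) - 1.0;
    const size_t L = b.size();
    for (size_t l = 0; l < L; ++l) a = arma::tanh(W[l] * a + b[l]);
    return arma::as_scalar(W[L] * a);
  }
};

Mlp parse_mlp(const List &m) {
  Mlp out;
  List W = m["W"];
  List b = m["b"];
  for (R_xlen_t l = 0; l < W.size(); ++l)
    out.W.push_back(as<arma::mat>(W[l]));
  for (R_xlen_t l = 0; l < b.size(); ++l)
    out.b.push_back(as<arma::vec>(b[l]));
  out.lo = as<arma::vec>(m["lo"]);
  out.hi = as<arma::vec>(m["hi"]);
  return out;
}

struct Neuron {
  double c, leak_g, leak_b;
  int presyn;  // 0-based, -1 none
  bool has_int = false, has_syn_mlp = false, has_syn_cond = false;
  Mlp mlp_int, mlp_syn;
  arma::mat Aint, Asyn;
  arma::vec Bint, Bsyn;
  // conductance synapse
  double g = 0, sb = 0, Esyn = 0;
  arma::vec wpos, hlo, hhi;
};

}  // namespace

// [[Rcpp::export]]
List rmm_simulate_cpp(List desc, const arma::mat &u, const arma::vec &v0,
                      List w0, List z0, double gamma, const arma::mat &vdata,
                      bool return_states, bool return_currents) {
  const double delta = as<double>(desc["delta"]);
  List nl = desc["neurons"];
  const int n = nl.size();
  const int N = u.n_rows;
  const bool observe = gamma > 0.0;
  if (observe && ((int)vdata.n_rows != N || (int)vdata.n_cols != n))
    stop("observer mode requires measured voltages aligned with u");

  std::vector<Neuron> ne(n);
  std::vector<arma::vec> w(n), z(n);
  for (int i = 0; i < n; ++i) {
    List d = nl[i];
    Neuron &q = ne[i];
    q.c = as<double>(d["c"]);
    q.leak_g = as<double>(d["leak_g"]);
    q.leak_b = as<double>(d["leak_b"]);
    q.presyn = as<int>(d["presyn"]);
    if (d.containsElementNamed("intr") && !Rf_isNull(d["intr"])) {
      List it = d["intr"];
      q.has_int = true;
      q.mlp_int = parse_mlp(it["mlp"]);
      q.Aint = as<arma::mat>(it["A"]);
      q.Bint = as<arma::vec>(it["B"]);
    }
    if (d.containsElementNamed("syn") && !Rf_isNull(d["syn"])) {
      List sy = d["syn"];
      std::string type = as<std::string>(sy["type"]);
      q.Asyn = as<arma::mat>(sy["A"]);
      q.Bsyn = as<arma::vec>(sy["B"]);
      if (type == "mlp") {
        q.has_syn_mlp = true;
        q.mlp_syn = parse_mlp(sy["mlp"]);
      } else {
        q.has_syn_cond = true;
        q.g = as<double>(sy["g"]);
        q.sb = as<double>(sy["b"]);
        q.Esyn = as<double>(sy["E_syn"]);
        q.wpos = as<arma::vec>(sy["wpos"]);
        q.hlo = as<arma::vec>(sy["hlo"]);
        q.hhi = as<arma::vec>(sy["hhi"]);
      }
    }
    w[i] = q.has_int ? as<arma::vec>(w0[i]) : arma::vec();
    z[i] = (q.has_syn_mlp || q.has_syn_cond) ? as<arma::vec>(z0[i]) : arma::vec();
  }

  arma::mat vpred(N, n), vcorr(N, n);
  arma::mat Iint, Isyn, Ileak;
  if (return_currents) {
    Iint.zeros(N, n);
    Isyn.zeros(N, n);
    Ileak.zeros(N, n);
  }
  std::vector<arma::mat> wtraj(n), ztraj(n);
  if (return_states) {
    for (int i = 0; i < n; ++i) {
      wtraj[i].zeros(N, w[i].n_elem);
      ztraj[i].zeros(N, z[i].n_elem);
    }
  }

  arma::vec v = v0;
  int diverged = 0;  // 1-based index of first non-finite step, 0 = none
  arma::vec h(n), vc(n);
  for (int t = 0; t < N; ++t) {
    if (!v.is_finite()) { diverged = t + 1; break; }
    vpred.row(t) = v.t();
    vc = observe ? arma::vec(v + gamma * (vdata.row(t).t() - v)) : v;
    vcorr.row(t) = vc.t();
    if (return_states)
      for (int i = 0; i < n; ++i) {
        if (w[i].n_elem) wtraj[i].row(t) = w[i].t();
        if (z[i].n_elem) ztraj[i].row(t) = z[i].t();
      }
    for (int i = 0; i < n; ++i) {
      const Neuron &q = ne[i];
      double hi = q.leak_g * vc[i] - q.leak_b;
      double il = hi, ii = 0.0, is = 0.0;
      if (q.has_int) {
        arma::vec x(1 + w[i].n_elem);
        x[0] = vc[i];
        if (w[i].n_elem) x.subvec(1, w[i].n_elem) = w[i];
        ii = q.mlp_int.eval(x);
        hi += ii;
      }
      if (q.has_syn_mlp) {
        arma::vec x(1 + z[i].n_elem);
        x[0] = vc[i];
        x.subvec(1, z[i].n_elem) = z[i];
        is = q.mlp_syn.eval(x);
        hi += is;
      } else if (q.has_syn_cond) {
        arma::vec hz = (2.0 * z[i] - (q.hlo + q.hhi)) / (q.hhi - q.hlo);
        double gate = 1.0 / (1.0 + std::exp(-(arma::dot(q.wpos, hz) + q.sb)));
        is = q.g * gate * (vc[i] - q.Esyn);
        hi += is;
      }
      h[i] = hi;
      if (return_currents) {
        Iint(t, i) = ii;
        Isyn(t, i) = is;
        Ileak(t, i) = il;
      }
    }
    if (t < N - 1) {
      arma::vec vnext(n);
      for (int i = 0; i < n; ++i)
        vnext[i] = vc[i] + delta / ne[i].c * (-h[i] + u(t, i));
      for (int i = 0; i < n; ++i) {
        const Neuron &q = ne[i];
        if (q.has_int) w[i] = q.Aint * w[i] + q.Bint * vc[i];
        if (q.has_syn_mlp || q.has_syn_cond)
          z[i] = q.Asyn * z[i] + q.Bsyn * vc[q.presyn];
      }
      v = vnext;
    }
  }

  List out = List::create(
      _["v"] = vpred, _["v_corrected"] = vcorr, _["diverged"] = diverged);
  if (return_currents) {
    out["I_int"] = Iint;
    out["I_syn"] = Isyn;
    out["I_leak"] = Ileak;
  }
  if (return_states) {
    out["w"] = wrap(wtraj);
    out["z"] = wrap(ztraj);
  }
  return out;
}
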