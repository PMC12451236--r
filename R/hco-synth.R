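# Synthetic dynamic-clamp half-center oscillator.
#
# Two surrogate spiking neurons (Morris-Lecar-type, standing in for the
# biological gastric mill cells whose intrinsic dynamics are not modeled)
# are coupled by virtual inhibitory synapses and hyperpolarization-activated
# currents and driven by nonzero-mean Ornstein-Uhlenbeck currents.  Every
# current component is exported separately as ground truth.

#' Dynamic-clamp parameters
#'
#' Defaults are the dynamic-clamp parameter set that produces the
#' half-center rhythm: per neuron, maximal synaptic conductance 105/150 nS
#' with reversal -80 mV and half-activation -50/-44 mV (logistic slope
#' 2 mV), and H-current maximal conductance 225/120 nS with reversal
#' -10 mV, half-activation -45 mV (slope 7 mV) and time-constant scale
#' 1000/1500 ms.
#'
#' @param g_syn_max,E_syn,v_half_syn synaptic conductance (nS), reversal
#'   (mV), half-activation (mV); length-2 vectors (one entry per neuron).
#' @param g_h_max,E_h,v_half_h H-current conductance (nS), reversal (mV),
#'   half-activation (mV).
#' @param tau_bar H-current time-constant scale, ms.
#' @param h_rate_alt use the alternative parenthesization
#'   `tau_bar * tau_h(v) + 0.1` of the H-rate denominator instead of the
#'   default `tau_bar * (tau_h(v) + 0.1)`.
#' @return list of class `rmm_dynclamp_params`.
#' @export
dynclamp_params <- function(g_syn_max = c(105, 150), E_syn = c(-80, -80),
                            v_half_syn = c(-50, -44),
                            g_h_max = c(225, 120), E_h = c(-10, -10),
                            v_half_h = c(-45, -45),
                            tau_bar = c(1000, 1500), h_rate_alt = FALSE) {
  stopifnot(all(g_syn_max >= 0), all(g_h_max >= 0), all(tau_bar > 0))
  per <- function(x) if (length(x) == 1L) rep(x, 2L) else x
  structure(list(g_syn_max = per(g_syn_max), E_syn = per(E_syn),
                 v_half_syn = per(v_half_syn), g_h_max = per(g_h_max),
                 E_h = per(E_h), v_half_h = per(v_half_h),
                 tau_bar = per(tau_bar), h_rate_alt = isTRUE(h_rate_alt)),
            class = "rmm_dynclamp_params")
}

#' Ornstein-Uhlenbeck current parameters
#'
#' Discretized mean-reverting injected current
#' `u[t+1] = u[t] + delta*a*(mu - u[t]) + b*s(delta)*eps[t]` with standard
#' normal `eps`.  The default noise scaling is the literal `s(delta) =
#' delta`; `scaling = "sqrt_delta"` selects the Euler-Maruyama `sqrt(delta)`.
#'
#' @param mu process mean, nA.
#' @param a mean-reversion rate, 1/ms.
#' @param b noise scale.
#' @param delta sampling period, ms.
#' @param scaling `"literal_b_delta"` or `"sqrt_delta"`.
#' @return list of class `rmm_ou_params`.
#' @export
ou_params <- function(mu, a = 0.04, b = 0.1, delta = 0.1,
                      scaling = c("literal_b_delta", "sqrt_delta")) {
  scaling <- match.arg(scaling)
  if (a <= 0 || b < 0) stop_invalid("need a > 0 and b >= 0")
  structure(list(mu = mu, a = a, b = b, delta = delta, scaling = scaling),
            class = "rmm_ou_params")
}

ou_noise_scale <- function(p) {
  if (p$scaling == "literal_b_delta") p$delta else sqrt(p$delta)
}

#' One step of the discretized OU process
#'
#' @param state current value of the process.
#' @param p an [ou_params()].
#' @param eps standard-normal innovation (drawn from the session RNG when
#'   omitted).
#' @return next value.
#' @export
ou_step <- function(state, p, eps = stats::rnorm(1L)) {
  state + p$delta * p$a * (p$mu - state) + p$b * ou_noise_scale(p) * eps
}

#' Simulate an OU current series
#'
#' @param n number of samples.
#' @param p an [ou_params()].
#' @param u0 initial value (default the mean).
#' @return numeric series of length n (uses the session RNG; seed upstream).
#' @export
ou_series <- function(n, p, u0 = p$mu) {
  eps <- stats::rnorm(n - 1L)
  drive <- p$delta * p$a * p$mu + p$b * ou_noise_scale(p) * eps
  z <- stats::filter(drive, 1 - p$delta * p$a, method = "recursive",
                     init = u0)
  c(u0, as.numeric(z))
}

logistic_gate <- function(v, v_half, slope) {
  stats::plogis((v - v_half) / slope)
}

#' One step of the dynamic-clamp synapse
#'
#' Gate update `z <- z + delta/50 * (1.1 - sigma(v_pre)) * (-z + sigma(v_pre))`
#' with the logistic activation `sigma(v) = 1/(1+exp(-(v - v_half)/2))`;
#' current `I = -g_max * z * (v_post - E_syn)` (injected-current sign:
#' negative = hyperpolarizing for `v_post > E_syn`).
#'
#' @param z current gate value in \[0, 1.1\].
#' @param v_pre,v_post pre-/postsynaptic voltages, mV.
#' @param p a [dynclamp_params()].
#' @param i neuron index (selects the parameter column).
#' @param delta sampling period, ms.
#' @return list with `z` (next gate) and `I` (synaptic current, pA).
#' @export
dynclamp_synapse_step <- function(z, v_pre, v_post, p, i = 1L, delta = 0.1) {
  s <- logistic_gate(v_pre, p$v_half_syn[i], 2)
  I <- -p$g_syn_max[i] * z * (v_post - p$E_syn[i])
  z_next <- z + delta / 50 * (1.1 - s) * (-z + s)
  list(z = z_next, I = I)
}

#' One step of the dynamic-clamp H-current
#'
#' Gate relaxes toward the hyperpolarization-activated steady state
#' `sigma_h(v) = 1/(1+exp((v - v_half)/7))` with rate
#' `delta / (tau_bar * (tau_h(v) + 0.1))`,
#' `tau_h(v) = 1/(1+exp(-(v+110)/13))`; current
#' `I = -g_h_max * w * (v - E_h)` (depolarizing at hyperpolarized v).
#'
#' @param w gate in \[0, 1\].
#' @param v membrane voltage, mV.
#' @inheritParams dynclamp_synapse_step
#' @return list with `w` and `I`.
#' @export
dynclamp_h_step <- function(w, v, p, i = 1L, delta = 0.1) {
  tau_h <- stats::plogis((v + 110) / 13)
  rate <- if (p$h_rate_alt) delta / (p$tau_bar[i] * tau_h + 0.1)
          else delta / (p$tau_bar[i] * (tau_h + 0.1))
  sh <- stats::plogis(-(v - p$v_half_h[i]) / 7)
  I <- -p$g_h_max[i] * w * (v - p$E_h[i])
  list(w = w + rate * (-w + sh), I = I)
}

#' Surrogate spiking neuron parameters
#'
#' A two-variable Morris-Lecar-type conductance-based membrane (calcium,
#' potassium, leak) in pF/nS/mV/pA/ms units, configured to spike tonically
#' in the -45 to -30 mV range under depolarizing mean current and to be
#' silenced by nanoamp-scale inhibition.  It stands in for the biological
#' gastric mill cells, whose intrinsic dynamics the half-center experiment
#' does not model.
#'
#' @param C capacitance, pF.
#' @param gL,EL leak conductance (nS) and reversal (mV).
#' @param gCa,ECa instantaneous inward conductance and reversal.
#' @param gK,EK delayed-rectifier conductance and reversal.
#' @param v1,v2 half-activation and slope of the inward activation, mV.
#' @param v3,v4 half-activation and slope of the recovery variable, mV.
#' @param phi recovery rate scale, 1/ms.
#' @return list usable as one entry of `neuron_params` in
#'   [simulate_hco_dataset()].
#' @export
surrogate_neuron <- function(C = 250, gL = 40, EL = -70, gCa = 65,
                             ECa = 100, gK = 130, EK = -85, v1 = -30,
                             v2 = 10, v3 = -25, v4 = 12, phi = 0.1) {
  list(C = C, gL = gL, EL = EL, gCa = gCa, ECa = ECa, gK = gK, EK = EK,
       v1 = v1, v2 = v2, v3 = v3, v4 = v4, phi = phi)
}

#' Simulate a dynamic-clamp half-center oscillator dataset
#'
#' Forward-Euler co-simulation of two surrogate neurons, each receiving its
#' virtual synaptic and H currents plus an OU injected current.  The output
#' recording stores the voltages, the OU currents `u`, and every dynamic
#' clamp component separately (`Isyn12`, `Isyn21`, `Ih1`, `Ih2`, and the
#' total applied currents `Iapp1`, `Iapp2 = Ih + Isyn + u`).  An initial
#' transient is simulated and discarded so the stored series starts on the
#' established rhythm.  Deterministic given `seed`.
#'
#' @param duration_ms stored duration, ms.
#' @param delta sampling period, ms (native 0.1).
#' @param dynclamp a [dynclamp_params()].
#' @param ou list of two [ou_params()] (per neuron), or a single one reused.
#' @param neuron_params list of two [surrogate_neuron()] parameter sets.
#' @param seed integer seed for the OU innovations.
#' @param burn_in_ms discarded initial transient, ms.
#' @return an `rmm_recording` with ground-truth components.
#' @export
simulate_hco_dataset <- function(duration_ms, delta = 0.1,
                                 dynclamp = dynclamp_params(),
                                 ou = list(ou_params(mu = 0.03, delta = delta),
                                           ou_params(mu = 0.22, delta = delta)),
                                 neuron_params = list(surrogate_neuron(),
                                                      surrogate_neuron()),
                                 seed = 1L, burn_in_ms = 5000) {
  if (inherits(ou, "rmm_ou_params")) ou <- list(ou, ou)
  N_keep <- as.integer(round(duration_ms / delta))
  N_burn <- as.integer(round(burn_in_ms / delta))
  N <- N_keep + N_burn
  if (N_keep < 2L) stop_invalid("duration too short")
  u <- matrix(0, N, 2L)
  for (i in 1:2) {
    stopifnot(abs(ou[[i]]$delta - delta) < 1e-12)
    u[, i] <- with_seed(child_seed(seed, 100L + i), ou_series(N, ou[[i]]))
  }
  v0 <- c(-60, -50)
  n0 <- c(0.01, 0.05)
  z0 <- c(0.1, 0.1)
  w0 <- c(0.3, 0.3)
  res <- hco_simulate_cpp(lapply(neuron_params, scale_surrogate),
                          unclass_clamp(dynclamp), u, delta,
                          v0, n0, z0, w0, dynclamp$h_rate_alt)
  if (res$diverged > 0)
    stop_invalid("HCO simulation blew up at step ", res$diverged,
                 "; check parameters / sampling period")
  keep <- (N_burn + 1L):N
  comps <- list(Isyn12 = res$I_syn[keep, 1L], Isyn21 = res$I_syn[keep, 2L],
                Ih1 = res$I_h[keep, 1L], Ih2 = res$I_h[keep, 2L],
                Iapp1 = res$I_app[keep, 1L], Iapp2 = res$I_app[keep, 2L])
  rmm_recording(delta, res$v[keep, , drop = FALSE], u[keep, , drop = FALSE],
                comps,
                meta = list(generator = "dynamic-clamp HCO", seed = seed,
                            burn_in_ms = burn_in_ms,
                            ou = lapply(ou, unclass),
                            dynclamp = unclass(dynclamp)))
}

# per-neuron parameter lists for the compiled core; conductances arrive in
# nS (the dynamic-clamp table convention) and are converted to uS so that
# currents come out in nA
unclass_clamp <- function(p) {
  lapply(1:2, function(i) list(g_syn_max = p$g_syn_max[i] / 1000,
                               E_syn = p$E_syn[i],
                               v_half_syn = p$v_half_syn[i],
                               g_h_max = p$g_h_max[i] / 1000, E_h = p$E_h[i],
                               v_half_h = p$v_half_h[i],
                               tau_bar = p$tau_bar[i]))
}

# surrogate parameters arrive in pF / nS and are converted to nF / uS
scale_surrogate <- function(np) {
  np$C <- np$C / 1000
  for (g in c("gL", "gCa", "gK")) np[[g]] <- np[[g]] / 1000
  np
}
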