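# Shared fixtures: all synthetic, built in code at test time.

# smooth noisy voltage matrix covering a plausible membrane range
make_toy_voltages <- function(N = 60L, n = 2L, seed = 5L) {
  set.seed(seed)
  matrix(-55 + 10 * sin(seq(0, 6, length.out = n * N)) + rnorm(n * N), N, n)
}

# small two-neuron circuit with MLP intrinsic + MLP synapse
make_small_circuit <- function(v, seed = 3L, synapse = "mlp") {
  syn <- if (identical(synapse, "mlp")) {
    list(type = "mlp", taus = c(2, 20), hidden = c(3L))
  } else if (identical(synapse, "cond")) {
    list(type = "cond", taus = c(2, 20, 100), E_syn = -80, g0 = 0.05)
  } else NULL
  spec <- rmm_spec(2L, 0.1,
                   intrinsic = list(taus = c(1, 10, 100), hidden = c(4L, 4L)),
                   synapse = syn, c0 = 0.5)
  init_parameters(spec, v, seed = seed)
}

# passive single-pair circuit (leak only)
make_passive_circuit <- function(g = 0.01, E = -50, c0 = 0.5, delta = 0.1,
                                 n = 1L) {
  spec <- rmm_spec(n, delta, presyn = rep(NA_integer_, n), intrinsic = NULL,
                   synapse = NULL, c0 = c0, leak_g0 = g, leak_E0 = E)
  init_parameters(spec, NULL, seed = 1L)
}

# simulate a passive membrane exactly (scalar linear recursion)
passive_trajectory <- function(v0, u, g, E, c0, delta) {
  N <- length(u)
  v <- numeric(N)
  v[1L] <- v0
  for (t in seq_len(N - 1L))
    v[t + 1L] <- v[t] + delta / c0 * (-(g * v[t] - g * E) + u[t])
  v
}

# synthetic voltage trace with Gaussian-bump spikes at given sample indices
make_spike_trace <- function(at, N, baseline = -65, height = 45) {
  v <- rep(baseline, N)
  for (a in at) {
    idx <- a:(a + 20L)
    v[idx] <- baseline + height * exp(-((0:20) - 5)^2 / 8)
  }
  v
}

fd_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    e <- rep(0, length(x)); e[k] <- h
    g[k] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

ns <- asNamespace("rmmcircuit")
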