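# Open-loop and observer simulation of a trained circuit.

# Plain-list descriptor with parameters pre-transformed for the compiled core.
model_descriptor <- function(model) {
  neurons <- lapply(seq_along(model$neurons), function(i) {
    ne <- model$neurons[[i]]
    d <- list(c = capacitance(ne), leak_g = leak_g(ne), leak_b = leak_b(ne),
              presyn = if (is.na(model$presyn[i])) -1L else model$presyn[i] - 1L,
              intr = NULL, syn = NULL)
    if (!is.null(ne$intrinsic)) {
      m <- ne$intrinsic$mlp
      W <- m$W
      W[[length(W)]] <- I_SCALE * W[[length(W)]]
      d$intr <- list(mlp = list(W = W, b = m$b, lo = m$norm$lo, hi = m$norm$hi),
                     A = ne$intrinsic$bank$A, B = as.numeric(ne$intrinsic$bank$B))
    }
    if (!is.null(ne$synapse)) {
      sy <- ne$synapse
      if (sy$type == "mlp") {
        m <- sy$mlp
        W <- m$W
        W[[length(W)]] <- I_SCALE * W[[length(W)]]
        d$syn <- list(type = "mlp",
                      mlp = list(W = W, b = m$b, lo = m$norm$lo, hi = m$norm$hi),
                      A = sy$bank$A, B = as.numeric(sy$bank$B))
      } else {
        d$syn <- list(type = "cond", g = syn_gmax(sy), b = sy$b,
                      E_syn = sy$E_syn, wpos = softplus(sy$w_raw),
                      hlo = sy$hplus_lo, hhi = sy$hplus_hi,
                      A = sy$bank$A, B = as.numeric(sy$bank$B))
      }
    }
    d
  })
  list(delta = model$delta, neurons = neurons)
}

zero_states <- function(model) {
  list(w = lapply(model$neurons, function(ne) numeric(n_states(ne, "w"))),
       z = lapply(model$neurons, function(ne) numeric(n_states(ne, "z"))))
}

#' Warm-start circuit states on measured voltages
#'
#' Drives every internal bank with the measured voltages over a prefix (the
#' intrinsic bank with the neuron's own voltage, the synaptic bank with the
#' presynaptic voltage) and returns the states at the end of the prefix.
#' Under contraction the result is independent of the unknown initial state.
#'
#' @param model an `rmm_circuit`.
#' @param v measured voltage matrix (M x n) used as the warm-up prefix.
#' @return list with elements `w` and `z` (lists of state vectors per
#'   neuron), suitable as `x0` for [simulate_circuit()].
#' @export
warmup_circuit_states <- function(model, v) {
  v <- as.matrix(v)
  M <- nrow(v)
  w <- vector("list", length(model$neurons))
  z <- vector("list", length(model$neurons))
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    w[[i]] <- if (is.null(ne$intrinsic)) numeric(0) else {
      X <- bank_states(ne$intrinsic$bank, v[, i])
      # state after consuming the whole prefix
      as.numeric(ne$intrinsic$bank$A %*% X[M, ] + ne$intrinsic$bank$B * v[M, i])
    }
    z[[i]] <- if (is.null(ne$synapse)) numeric(0) else {
      j <- model$presyn[i]
      X <- bank_states(ne$synapse$bank, v[, j])
      as.numeric(ne$synapse$bank$A %*% X[M, ] + ne$synapse$bank$B * v[M, j])
    }
  }
  list(w = w, z = z)
}

#' Simulate a circuit open loop
#'
#' Forward simulation of the full model: internal banks are driven by the
#' *predicted* voltages, so errors compound exactly as they would in
#' deployment.  A non-finite state truncates the simulation and is reported
#' through the `diverged` field (1-based time index, 0 if none).
#'
#' @param model an `rmm_circuit`.
#' @param u injected current matrix (N x n), pA, sampled at the model delta.
#' @param v0 initial voltage vector (mV).
#' @param x0 initial internal states as returned by
#'   [warmup_circuit_states()] (default: zeros).
#' @param return_states also return internal state trajectories.
#' @param return_currents also return per-component current trajectories
#'   (`I_int`, `I_syn`, `I_leak`, outward-positive).
#' @return list with `v` (N x n predicted voltages), `diverged`, and
#'   optionally states/currents.
#' @export
simulate_circuit <- function(model, u, v0, x0 = NULL,
                             return_states = FALSE, return_currents = FALSE) {
  u <- as.matrix(u)
  stopifnot(ncol(u) == length(model$neurons), length(v0) == ncol(u))
  if (is.null(x0)) x0 <- zero_states(model)
  res <- rmm_simulate_cpp(model_descriptor(model), u, as.numeric(v0),
                          x0$w, x0$z, 0.0, matrix(0, 0L, 0L),
                          return_states, return_currents)
  if (res$diverged > 0)
    warning("simulation diverged at step ", res$diverged,
            "; trajectory truncated", call. = FALSE)
  res$v_corrected <- NULL
  res
}

#' Simulate the circuit as a voltage observer (nonlinear filter)
#'
#' Closed-loop simulation in which each step's voltage is corrected toward
#' the measurement by a factor `gamma` before driving the dynamics
#' (`v_corrected = v_pred + gamma * (v_measured - v_pred)`).  With
#' `gamma = 0` this reproduces [simulate_circuit()] exactly; with
#' `gamma = 1` the corrected output equals the measurements.  The filtered
#' voltage is the corrected series; the one-step predictions are returned
#' alongside.
#'
#' @inheritParams simulate_circuit
#' @param v_measured measured voltage matrix (N x n) aligned with `u`.
#' @param gamma correction factor in \[0, 1\].
#' @return list with `v` (one-step predictions), `v_corrected` (filtered
#'   voltages), `diverged`, and optional states/currents.
#' @export
observer_simulate <- function(model, v_measured, u, gamma, v0 = NULL,
                              x0 = NULL, return_states = FALSE,
                              return_currents = FALSE) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0 || gamma > 1)
    stop_invalid("`gamma` must be a single value in [0, 1]")
  u <- as.matrix(u)
  v_measured <- as.matrix(v_measured)
  stopifnot(nrow(u) == nrow(v_measured),
            ncol(u) == length(model$neurons))
  if (is.null(v0)) v0 <- v_measured[1L, ]
  if (is.null(x0)) x0 <- zero_states(model)
  if (gamma == 0) {
    res <- simulate_circuit(model, u, v0, x0, return_states, return_currents)
    res$v_corrected <- res$v
    return(res)
  }
  res <- rmm_simulate_cpp(model_descriptor(model), u, as.numeric(v0),
                          x0$w, x0$z, gamma, v_measured,
                          return_states, return_currents)
  if (res$diverged > 0)
    warning("observer simulation diverged at step ", res$diverged, call. = FALSE)
  res
}

# Pure-R reference simulator (short series only); used by the tests to
# cross-check the compiled core step by step.
simulate_circuit_r <- function(model, u, v0, x0 = NULL, gamma = 0,
                               v_measured = NULL) {
  u <- as.matrix(u)
  n <- length(model$neurons)
  N <- nrow(u)
  if (is.null(x0)) x0 <- zero_states(model)
  w <- x0$w; z <- x0$z
  delta <- model$delta
  v <- as.numeric(v0)
  V <- matrix(NA_real_, N, n)
  VC <- matrix(NA_real_, N, n)
  for (t in seq_len(N)) {
    V[t, ] <- v
    vc <- if (gamma > 0) v + gamma * (v_measured[t, ] - v) else v
    VC[t, ] <- vc
    h <- numeric(n)
    for (i in seq_len(n)) {
      ne <- model$neurons[[i]]
      h[i] <- neuron_current(ne, vc[i],
                             w = if (length(w[[i]])) matrix(w[[i]], ncol = 1L),
                             z = if (length(z[[i]])) matrix(z[[i]], ncol = 1L))$h
    }
    if (t < N) {
      vn <- vc + delta / vapply(model$neurons, capacitance, 0) * (-h + u[t, ])
      for (i in seq_len(n)) {
        ne <- model$neurons[[i]]
        if (length(w[[i]]))
          w[[i]] <- as.numeric(ne$intrinsic$bank$A %*% w[[i]] +
                                 ne$intrinsic$bank$B * vc[i])
        if (length(z[[i]]))
          z[[i]] <- as.numeric(ne$synapse$bank$A %*% z[[i]] +
                                 ne$synapse$bank$B * vc[model$presyn[i]])
      }
      v <- vn
    }
  }
  list(v = V, v_corrected = VC)
}
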