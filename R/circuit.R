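# RMM circuit model: per-neuron membrane current maps and their containers.
#
# Each neuron obeys the current balance
#   c * (v[t+1] - v[t]) / delta = -h(v, v_pre, w, z) + u
# where h is the total outward membrane current
#   h = I_int(v, w) + I_syn(., z) + leak_g * v - leak_b,
# I_int is a perceptron reading the neuron's own voltage and its intrinsic
# state bank w (driven by its own voltage), and I_syn is either a perceptron
# reading (v, z) with z driven by the presynaptic voltage, or a
# conductance-form synapse g * gate(z) * (v - E_syn).
# Capacitance, leak conductance and maximal conductances are kept positive
# through softplus reparameterization.

#' Describe an RMM circuit architecture
#'
#' Builds the architecture specification consumed by [init_parameters()].
#'
#' @param n_neurons number of neurons (the half-center oscillator uses 2).
#' @param delta sampling period, ms.
#' @param presyn integer vector: `presyn[i]` is the presynaptic partner of
#'   neuron i (`NA` for none).  Defaults to the reciprocal pair for 2
#'   neurons, none otherwise.
#' @param intrinsic `NULL` for a passive membrane, else a list with `taus`
#'   (continuous time constants, ms) and `hidden` (hidden-layer widths).
#' @param synapse `NULL`, or a list with `type = "mlp"` (`taus`, `hidden`)
#'   or `type = "cond"` (`taus`, `E_syn`, `g0`, `act_lo`, `act_hi`).
#' @param c0 initial capacitance, nF.
#' @param leak_g0 initial leak conductance, uS.
#' @param leak_E0 initial leak reversal, mV.
#' @param learn_c should the capacitance be learned (freeze with FALSE).
#' @return a list of class `rmm_spec`.
#' @export
rmm_spec <- function(n_neurons = 2L, delta = 0.1,
                     presyn = NULL,
                     intrinsic = list(taus = c(tau_fast_slow(), tau_ultraslow()),
                                      hidden = c(20L, 20L, 20L)),
                     synapse = list(type = "mlp", taus = tau_fast_slow(),
                                    hidden = c(10L, 10L, 10L)),
                     c0 = 1, leak_g0 = 0.01, leak_E0 = -50,
                     learn_c = TRUE) {
  if (is.null(presyn)) {
    presyn <- if (n_neurons == 2L) c(2L, 1L) else rep(NA_integer_, n_neurons)
  }
  stopifnot(length(presyn) == n_neurons)
  if (any(!is.na(presyn) & presyn == seq_len(n_neurons)))
    stop_invalid("self-loops are not allowed in `presyn`")
  if (!is.null(synapse) && any(is.na(presyn)))
    stop_invalid("a synapse model requires a presynaptic partner for every neuron")
  structure(list(n_neurons = as.integer(n_neurons), delta = delta,
                 presyn = as.integer(presyn), intrinsic = intrinsic,
                 synapse = synapse, c0 = c0, leak_g0 = leak_g0,
                 leak_E0 = leak_E0, learn_c = isTRUE(learn_c)),
            class = "rmm_spec")
}

#' Initialize an RMM circuit from an architecture spec and training data
#'
#' Builds the fixed state-space banks, warms them up on the training voltages
#' to fit the input normalizers (training min/max of v and of each internal
#' state map to -1/+1), and initializes all perceptrons with the
#' Nguyen-Widrow heuristic (biases uniform on \[-1, 1\]).  Deterministic given
#' `seed`.
#'
#' For the conductance synapse, the fixed range normalization `h+` is
#' calibrated from the bank's DC response so that at initialization the gate
#' is about 0 when the presynaptic voltage sits at `act_lo` (-60 mV) and
#' about 1 at `act_hi` (-40 mV).
#'
#' @param spec an [rmm_spec()].
#' @param v training voltage matrix (N x n_neurons), or `NULL` for models
#'   without perceptrons (passive membranes).
#' @param seed integer seed.
#' @return an object of class `rmm_circuit`.
#' @export
init_parameters <- function(spec, v = NULL, seed = 1L) {
  if (inherits(v, "rmm_recording")) v <- v$v
  n <- spec$n_neurons
  delta <- spec$delta
  needs_data <- !is.null(spec$intrinsic) ||
    (!is.null(spec$synapse) && spec$synapse$type == "mlp")
  if (needs_data && is.null(v))
    stop_invalid("training voltages are required to fit input normalizers")
  if (!is.null(v)) {
    v <- as.matrix(v)
    stopifnot(ncol(v) == n)
  }
  with_seed(child_seed(seed, 1L), {
    neurons <- vector("list", n)
    for (i in seq_len(n)) {
      neuron <- list(
        c_raw = softplus_inv(spec$c0 / C_SCALE),
        leak_g_raw = softplus_inv(spec$leak_g0 / G_SCALE),
        leak_b_raw = spec$leak_g0 * spec$leak_E0 / I_SCALE,
        intrinsic = NULL, synapse = NULL
      )
      if (!is.null(spec$intrinsic)) {
        bank <- build_ss_from_taus(spec$intrinsic$taus, delta, "orthogonal")
        W <- warmup_states(bank, v[, i],
                           warmup_plan(min(default_warmup_steps(bank),
                                           nrow(v) %/% 2L)))
        norm <- fit_normalizer(t(cbind(v[(nrow(v) - nrow(W) + 1L):nrow(v), i], W)))
        neuron$intrinsic <- list(
          mlp = mlp_init(1L + length(bank$lambdas), spec$intrinsic$hidden, norm),
          bank = bank)
      }
      if (!is.null(spec$synapse)) {
        j <- spec$presyn[i]
        if (spec$synapse$type == "mlp") {
          bank <- build_ss_from_taus(spec$synapse$taus, delta, "orthogonal")
          Z <- warmup_states(bank, v[, j],
                             warmup_plan(min(default_warmup_steps(bank),
                                             nrow(v) %/% 2L)))
          norm <- fit_normalizer(t(cbind(v[(nrow(v) - nrow(Z) + 1L):nrow(v), i], Z)))
          neuron$synapse <- list(
            type = "mlp",
            mlp = mlp_init(1L + length(bank$lambdas), spec$synapse$hidden, norm),
            bank = bank)
        } else if (spec$synapse$type == "cond") {
          bank <- build_ss_from_taus(spec$synapse$taus, delta, "diagonal")
          act_lo <- spec$synapse$act_lo %||% -60
          act_hi <- spec$synapse$act_hi %||% -40
          dcg <- dc_gain(bank)
          nz <- length(bank$lambdas)
          # softplus(w_raw) sums to 3 => gate = logistic(-3) ~ 0.047 at act_lo
          # and logistic(+3) ~ 0.95 at act_hi when every h+ channel sits at -/+1
          neuron$synapse <- list(
            type = "cond",
            g_raw = softplus_inv((spec$synapse$g0 %||% 0.1) / G_SCALE),
            w_raw = rep(softplus_inv(3 / nz), nz),
            b = 0,
            E_syn = spec$synapse$E_syn %||% -80,
            hplus_lo = act_lo * dcg, hplus_hi = act_hi * dcg,
            bank = bank)
        } else stop_invalid("unknown synapse type: ", spec$synapse$type)
      }
      neurons[[i]] <- neuron
    }
    structure(list(neurons = neurons, presyn = spec$presyn, delta = delta,
                   learn_c = spec$learn_c, spec = spec),
              class = "rmm_circuit")
  })
}

#' @export
print.rmm_circuit <- function(x, ...) {
  np <- length(pack_params(x))
  cat(sprintf("<rmm_circuit> %d neurons, delta = %g ms, %d learnable parameters\n",
              length(x$neurons), x$delta, np))
  for (i in seq_along(x$neurons)) {
    ne <- x$neurons[[i]]
    syn <- if (is.null(ne$synapse)) "none" else ne$synapse$type
    cat(sprintf("  neuron %d: c = %.4g nF, leak g = %.4g uS, intrinsic states = %d, synapse = %s (presyn %s)\n",
                i, softplus(ne$c_raw), softplus(ne$leak_g_raw),
                if (is.null(ne$intrinsic)) 0L else length(ne$intrinsic$bank$lambdas),
                syn, ifelse(is.na(x$presyn[i]), "-", x$presyn[i])))
  }
  invisible(x)
}

n_states <- function(neuron, which = c("w", "z")) {
  which <- match.arg(which)
  comp <- if (which == "w") neuron$intrinsic else neuron$synapse
  if (is.null(comp)) 0L else length(comp$bank$lambdas)
}

capacitance <- function(neuron) softplus(neuron$c_raw) * C_SCALE
leak_g <- function(neuron) softplus(neuron$leak_g_raw) * G_SCALE
leak_b <- function(neuron) neuron$leak_b_raw * I_SCALE
syn_gmax <- function(syn) softplus(syn$g_raw) * G_SCALE

# conductance-synapse gate; z is n_z x K
cond_gate <- function(syn, z) {
  hz <- (2 * z - (syn$hplus_lo + syn$hplus_hi)) / (syn$hplus_hi - syn$hplus_lo)
  pre <- crossprod(matrix(softplus(syn$w_raw), ncol = 1L), hz) + syn$b
  list(gate = logistic(pre), hz = hz, pre = pre)
}

#' Conductance-synapse current
#'
#' `I = g_max * gate(z) * (v_post - E_syn)` with `gate` a positive-weight
#' single-layer perceptron of the range-normalized low-passed presynaptic
#' voltage; the gate lies in (0, 1) and the current vanishes at the reversal
#' potential.
#'
#' @param syn the conductance-synapse component of an `rmm_circuit` neuron.
#' @param v_post postsynaptic voltage(s), mV.
#' @param z synaptic bank state (n_z vector or n_z x K matrix).
#' @return current(s), pA, outward-positive as entering `h`.
#' @export
conductance_synapse_current <- function(syn, v_post, z) {
  if (is.vector(z)) z <- matrix(z, ncol = 1L)
  as.numeric(syn_gmax(syn) * cond_gate(syn, z)$gate * (v_post - syn$E_syn))
}

# Total outward membrane current for one neuron, vectorized over K samples.
# v_self, v_pre: length-K vectors; w: n_w x K; z: n_z x K.
# Returns list(h, parts?, caches?) where caches hold what backprop needs.
neuron_current <- function(neuron, v_self, v_pre = NULL, w = NULL, z = NULL,
                           cache = FALSE, components = FALSE) {
  K <- length(v_self)
  h <- leak_g(neuron) * v_self - leak_b(neuron)
  I_leak <- h
  I_int <- numeric(K)
  I_syn <- numeric(K)
  int_cache <- NULL
  syn_cache <- NULL
  if (!is.null(neuron$intrinsic)) {
    X <- rbind(matrix(v_self, 1L), w)
    fw <- mlp_forward(neuron$intrinsic$mlp, X, cache = cache)
    if (cache) { int_cache <- fw$acts; I_int <- I_SCALE * as.numeric(fw$y) }
    else I_int <- I_SCALE * as.numeric(fw)
    h <- h + I_int
  }
  if (!is.null(neuron$synapse)) {
    syn <- neuron$synapse
    if (syn$type == "mlp") {
      X <- rbind(matrix(v_self, 1L), z)
      fw <- mlp_forward(syn$mlp, X, cache = cache)
      if (cache) { syn_cache <- fw$acts; I_syn <- I_SCALE * as.numeric(fw$y) }
      else I_syn <- I_SCALE * as.numeric(fw)
    } else {
      cg <- cond_gate(syn, z)
      I_syn <- as.numeric(syn_gmax(syn) * cg$gate * (v_self - syn$E_syn))
      if (cache) syn_cache <- cg
    }
    h <- h + I_syn
  }
  out <- list(h = h)
  if (components) out <- c(out, list(I_int = I_int, I_syn = I_syn, I_leak = I_leak))
  if (cache) out <- c(out, list(int_cache = int_cache, syn_cache = syn_cache))
  out
}

#' Total membrane current of one neuron
#'
#' The outward current `h = I_int + I_syn + I_leak` entering the voltage
#' update with a minus sign: `v[t+1] = v[t] + delta/c * (-h + u)`.
#'
#' @param neuron a neuron component of an `rmm_circuit`.
#' @param v_self own voltage(s), mV.
#' @param v_pre presynaptic voltage(s) (unused directly; the synaptic bank
#'   state `z` already encodes the presynaptic history), may be `NULL`.
#' @param w intrinsic bank state (n_w vector or n_w x K).
#' @param z synaptic bank state.
#' @param components if TRUE, also return `I_int`, `I_syn`, `I_leak`.
#' @return total current vector (pA), or a list when `components = TRUE`.
#' @export
total_membrane_current <- function(neuron, v_self, v_pre = NULL, w = NULL,
                                   z = NULL, components = FALSE) {
  if (!is.null(w) && is.vector(w)) w <- matrix(w, ncol = length(v_self))
  if (!is.null(z) && is.vector(z)) z <- matrix(z, ncol = length(v_self))
  res <- neuron_current(neuron, v_self, v_pre, w, z, components = components)
  if (components) res[c("h", "I_int", "I_syn", "I_leak")] else res$h
}

# ---- backward pass for one neuron's current -------------------------------
# ah: 1 x K (or length-K) adjoint of h.  Returns parameter gradients in
# traversal order pieces plus input adjoints (av_self, aw, az).
neuron_current_backprop <- function(neuron, v_self, w, z, fwd, ah) {
  ah <- matrix(ah, 1L)
  K <- ncol(ah)
  g_leak_g_raw <- sum(ah * v_self) * dsoftplus(neuron$leak_g_raw) * G_SCALE
  g_leak_b <- -sum(ah) * I_SCALE
  av <- as.numeric(ah) * leak_g(neuron)
  aw <- NULL; az <- NULL
  g_int <- NULL; g_syn <- NULL
  if (!is.null(neuron$intrinsic)) {
    bp <- mlp_backprop(neuron$intrinsic$mlp, fwd$int_cache, I_SCALE * ah)
    g_int <- mlp_grad_vec(bp, length(neuron$intrinsic$mlp$b))
    av <- av + as.numeric(bp$gX[1L, ])
    aw <- bp$gX[-1L, , drop = FALSE]
  }
  if (!is.null(neuron$synapse)) {
    syn <- neuron$synapse
    if (syn$type == "mlp") {
      bp <- mlp_backprop(syn$mlp, fwd$syn_cache, I_SCALE * ah)
      g_syn <- mlp_grad_vec(bp, length(syn$mlp$b))
      av <- av + as.numeric(bp$gX[1L, ])
      az <- bp$gX[-1L, , drop = FALSE]
    } else {
      cg <- fwd$syn_cache
      g <- syn_gmax(syn)
      drive <- v_self - syn$E_syn
      gate <- as.numeric(cg$gate)
      g_g_raw <- sum(ah * gate * drive) * dsoftplus(syn$g_raw) * G_SCALE
      agate <- as.numeric(ah) * g * drive
      apre <- agate * gate * (1 - gate)          # length K
      g_b <- sum(apre)
      g_w_raw <- as.numeric(cg$hz %*% apre) * dsoftplus(syn$w_raw)
      wpos <- softplus(syn$w_raw)
      az <- outer(wpos * (2 / (syn$hplus_hi - syn$hplus_lo)), apre)
      av <- av + as.numeric(ah) * g * gate
      g_syn <- c(g_g_raw, g_w_raw, g_b)
    }
  }
  list(g_leak_g_raw = g_leak_g_raw, g_leak_b = g_leak_b,
       g_int = g_int, g_syn = g_syn, av = av, aw = aw, az = az)
}

# ---- parameter packing ----------------------------------------------------
# Traversal order per neuron: [c_raw if learn_c], leak_g_raw, leak_b,
# intrinsic MLP (W1,b1,...,W_{L+1}), synapse (MLP params | g_raw, w_raw, b).

#' Flatten / restore the learnable parameters of a circuit
#'
#' The fixed quantities (state-space banks, normalizers, reversal potential,
#' gate range normalization) are not part of the vector.
#' @param model an `rmm_circuit`.
#' @return numeric parameter vector.
#' @export
pack_params <- function(model) {
  out <- lapply(model$neurons, function(ne) {
    v <- c(if (model$learn_c) ne$c_raw, ne$leak_g_raw, ne$leak_b_raw)
    if (!is.null(ne$intrinsic)) v <- c(v, mlp_param_vec(ne$intrinsic$mlp))
    if (!is.null(ne$synapse)) {
      v <- c(v, if (ne$synapse$type == "mlp") mlp_param_vec(ne$synapse$mlp)
             else c(ne$synapse$g_raw, ne$synapse$w_raw, ne$synapse$b))
    }
    v
  })
  unlist(out, use.names = FALSE)
}

#' @rdname pack_params
#' @param theta numeric vector as produced by [pack_params()].
#' @export
unpack_params <- function(model, theta) {
  pos <- 0L
  take <- function(k) {
    v <- theta[pos + seq_len(k)]
    pos <<- pos + k
    v
  }
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    if (model$learn_c) ne$c_raw <- take(1L)
    ne$leak_g_raw <- take(1L)
    ne$leak_b_raw <- take(1L)
    if (!is.null(ne$intrinsic)) {
      k <- mlp_n_params(ne$intrinsic$mlp)
      ne$intrinsic$mlp <- mlp_set_params(ne$intrinsic$mlp, take(k))
    }
    if (!is.null(ne$synapse)) {
      if (ne$synapse$type == "mlp") {
        k <- mlp_n_params(ne$synapse$mlp)
        ne$synapse$mlp <- mlp_set_params(ne$synapse$mlp, take(k))
      } else {
        ne$synapse$g_raw <- take(1L)
        nz <- length(ne$synapse$w_raw)
        ne$synapse$w_raw <- take(nz)
        ne$synapse$b <- take(1L)
      }
    }
    model$neurons[[i]] <- ne
  }
  stopifnot(pos == length(theta))
  model
}

# squared norm of the ANN parameters only (for r_rho); same traversal
ann_param_mask <- function(model) {
  unlist(lapply(model$neurons, function(ne) {
    m <- c(if (model$learn_c) FALSE, FALSE, FALSE)
    if (!is.null(ne$intrinsic)) m <- c(m, rep(TRUE, mlp_n_params(ne$intrinsic$mlp)))
    if (!is.null(ne$synapse)) {
      k <- if (ne$synapse$type == "mlp") mlp_n_params(ne$synapse$mlp)
           else 2L + length(ne$synapse$w_raw)
      m <- c(m, rep(TRUE, k))
    }
    m
  }), use.names = FALSE)
}
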