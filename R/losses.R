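# Training losses for the unified teacher-forcing / multiple-shooting /
# generalized-teacher-forcing formulation.  All gradients are hand-written
# reverse-mode passes (feed-forward backprop for TF; backpropagation through
# time *within shots only* for MS/GTF) and are verified against central
# finite differences in the test suite.

# index ranges of each neuron's parameter block inside pack_params()
param_layout <- function(model) {
  pos <- 0L
  lay <- vector("list", length(model$neurons))
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    li <- list()
    if (model$learn_c) { li$c <- pos + 1L; pos <- pos + 1L }
    li$leak_g <- pos + 1L; pos <- pos + 1L
    li$leak_b <- pos + 1L; pos <- pos + 1L
    if (!is.null(ne$intrinsic)) {
      k <- mlp_n_params(ne$intrinsic$mlp)
      li$int <- pos + seq_len(k); pos <- pos + k
    }
    if (!is.null(ne$synapse)) {
      k <- if (ne$synapse$type == "mlp") mlp_n_params(ne$synapse$mlp)
           else 2L + length(ne$synapse$w_raw)
      li$syn <- pos + seq_len(k); pos <- pos + k
    }
    lay[[i]] <- li
  }
  attr(lay, "n_params") <- pos
  lay
}

reg_term <- function(model, theta, rho, scale = 1) {
  if (rho == 0) return(list(loss = 0, grad = numeric(length(theta))))
  m <- ann_param_mask(model)
  list(loss = scale * rho * sum(theta[m]^2),
       grad = ifelse(m, 2 * scale * rho * theta, 0))
}

#' Precompute internal states under teacher forcing
#'
#' Drives every internal bank with the *measured* voltages (intrinsic banks
#' with the neuron's own voltage, synaptic banks with the presynaptic
#' voltage) over the whole training series, starting from zero at the first
#' sample.  The leading `burn_in` samples serve only to flush the unknown
#' initial condition; losses should be evaluated after them.  Refuses
#' non-contracting banks, for which the feed-forward problem is ill-posed.
#'
#' @param model an `rmm_circuit`.
#' @param v measured voltage matrix (N x n).
#' @param burn_in integer burn-in length, or `"auto"` (tolerance-derived,
#'   capped at a fifth of the data).
#' @return list with `w`, `z` (per-neuron N x n_states matrices aligned with
#'   the rows of `v`) and `burn_in`.
#' @export
precompute_internal_states <- function(model, v, burn_in = "auto") {
  v <- as.matrix(v)
  N <- nrow(v)
  Mreq <- 0L
  w <- vector("list", length(model$neurons))
  z <- vector("list", length(model$neurons))
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    if (!is.null(ne$intrinsic)) {
      chk <- check_contraction_linear(ne$intrinsic$bank)
      if (!chk$contracting)
        stop_invalid("intrinsic bank of neuron ", i, " is not contracting; ",
                     "teacher forcing is ill-posed")
      Mreq <- max(Mreq, default_warmup_steps(ne$intrinsic$bank))
      w[[i]] <- bank_states(ne$intrinsic$bank, v[, i])
    } else w[[i]] <- matrix(0, N, 0L)
    if (!is.null(ne$synapse)) {
      chk <- check_contraction_linear(ne$synapse$bank)
      if (!chk$contracting)
        stop_invalid("synaptic bank of neuron ", i, " is not contracting")
      Mreq <- max(Mreq, default_warmup_steps(ne$synapse$bank))
      z[[i]] <- bank_states(ne$synapse$bank, v[, model$presyn[i]])
    } else z[[i]] <- matrix(0, N, 0L)
  }
  M <- if (identical(burn_in, "auto")) min(Mreq, N %/% 5L) else as.integer(burn_in)
  if (M >= N) stop_invalid("burn-in (", M, ") consumes the whole series (", N, ")")
  list(w = w, z = z, burn_in = M)
}

tf_loss_grad <- function(model, v, u, states, rho, idx, want_grad = TRUE,
                         reg_scale = 1) {
  v <- as.matrix(v); u <- as.matrix(u)
  N <- nrow(v)
  if (length(idx) == 0L) stop_invalid("empty index set")
  if (any(idx < 1L) || any(idx >= N)) stop_invalid("indices out of range 1..N-1")
  lay <- param_layout(model)
  g <- numeric(attr(lay, "n_params"))
  loss <- 0
  K <- length(idx)
  delta <- model$delta
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    ci <- capacitance(ne)
    wm <- t(states$w[[i]][idx, , drop = FALSE])
    zm <- t(states$z[[i]][idx, , drop = FALSE])
    fw <- neuron_current(ne, v[idx, i], w = wm, z = zm, cache = want_grad)
    hu <- -fw$h + u[idx, i]
    r <- v[idx + 1L, i] - v[idx, i] - (delta / ci) * hu
    loss <- loss + sum(r^2) / K
    if (want_grad) {
      ar <- 2 * r / K
      ah <- ar * (delta / ci)          # dr/dh = +delta/c
      bp <- neuron_current_backprop(ne, v[idx, i], wm, zm, fw, ah)
      li <- lay[[i]]
      if (model$learn_c)
        g[li$c] <- g[li$c] + sum(ar * (delta / ci^2) * hu) * dsoftplus(ne$c_raw) * C_SCALE
      g[li$leak_g] <- g[li$leak_g] + bp$g_leak_g_raw
      g[li$leak_b] <- g[li$leak_b] + bp$g_leak_b
      if (!is.null(bp$g_int)) g[li$int] <- g[li$int] + bp$g_int
      if (!is.null(bp$g_syn)) g[li$syn] <- g[li$syn] + bp$g_syn
    }
  }
  theta <- pack_params(model)
  rg <- reg_term(model, theta, rho, reg_scale)
  list(loss = loss + rg$loss, grad = if (want_grad) g + rg$grad)
}

#' Teacher-forcing loss
#'
#' Mean squared one-step-ahead voltage prediction error over the given time
#' indices, with the internal states fixed to the precomputed
#' teacher-forced series, plus the ANN-parameter ridge penalty
#' `rho * ||theta||^2`.  No recurrence: gradients never propagate through
#' time.
#'
#' @param model an `rmm_circuit`.
#' @param v,u measured voltage / injected current matrices (N x n).
#' @param states output of [precompute_internal_states()].
#' @param rho parameter-regularization weight.
#' @param idx time indices (1-based, each < N) forming the batch.
#' @return scalar loss.
#' @export
tf_loss <- function(model, v, u, states, rho = 0, idx = NULL) {
  v <- as.matrix(v)
  if (is.null(idx)) idx <- (states$burn_in + 1L):(nrow(v) - 1L)
  tf_loss_grad(model, v, u, states, rho, idx, want_grad = FALSE)$loss
}

#' Multiple-shooting plan
#'
#' Tiles the training range with non-overlapping shots of `s` samples.  The
#' learnable per-shot initial voltages are initialized from the data and the
#' learnable initial internal states from the teacher-forced (warmed-up)
#' state series.  State-continuity errors are weighted per coordinate by the
#' squared reciprocal of the bank DC gain, i.e. measured in DC-normalized
#' state units.
#'
#' @param model an `rmm_circuit`.
#' @param v measured voltages (N x n).
#' @param states output of [precompute_internal_states()].
#' @param s shot length in samples (>= 1).
#' @param starts optional explicit shot start indices (each start must have
#'   `s` following samples; used to keep shots inside trial segments).
#' @return an object of class `rmm_shot_plan`.
#' @export
shot_plan <- function(model, v, states, s, starts = NULL) {
  v <- as.matrix(v)
  N <- nrow(v)
  s <- as.integer(s)
  if (s < 1L) stop_invalid("shot length must be >= 1")
  if (is.null(starts)) {
    first <- states$burn_in + 1L
    if (first + s > N) stop_invalid("shot length ", s, " exceeds usable data")
    starts <- seq.int(first, N - s, by = s)
  }
  if (any(starts + s > N)) stop_invalid("shot extends past the data")
  N_s <- length(starts)
  upsilon <- t(v[starts, , drop = FALSE])
  xi_w <- list(); xi_z <- list(); Dw <- list(); Dz <- list()
  for (i in seq_along(model$neurons)) {
    ne <- model$neurons[[i]]
    xi_w[[i]] <- t(states$w[[i]][starts, , drop = FALSE])
    xi_z[[i]] <- t(states$z[[i]][starts, , drop = FALSE])
    Dw[[i]] <- if (is.null(ne$intrinsic)) numeric(0)
               else 1 / dc_gain(ne$intrinsic$bank)^2
    Dz[[i]] <- if (is.null(ne$synapse)) numeric(0)
               else 1 / dc_gain(ne$synapse$bank)^2
  }
  # continuity only links shots that are temporally adjacent (shots never
  # bridge trial segments)
  has_next <- c(starts[-1L] == starts[-N_s] + s, FALSE)
  structure(list(s = s, starts = starts, n_shots = N_s, upsilon = upsilon,
                 xi_w = xi_w, xi_z = xi_z, Dw = Dw, Dz = Dz,
                 has_next = has_next),
            class = "rmm_shot_plan")
}

#' @export
print.rmm_shot_plan <- function(x, ...) {
  cat(sprintf("<rmm_shot_plan> %d shots of %d samples (first start %d)\n",
              x$n_shots, x$s, x$starts[1L]))
  invisible(x)
}

# Shared MS / GTF loss-and-gradient core.  `sel` indexes shots.  Data-fit
# terms run over the propagated predictions t = 1..s of each shot; with
# s = 1, pinned initial voltages and no continuity penalties this reduces
# exactly to the TF loss.  gamma = 0 gives plain multiple shooting.
msgtf_loss_grad <- function(model, v, u, plan, sel, gamma, rho, rho_v, rho_x,
                            pin_upsilon = FALSE, want_grad = TRUE,
                            reg_scale = 1) {
  v <- as.matrix(v); u <- as.matrix(u)
  n <- length(model$neurons)
  s <- plan$s
  K <- length(sel)
  if (K == 0L) stop_invalid("empty shot index set")
  if (gamma < 0 || gamma >= 1) stop_invalid("`gamma` must lie in [0, 1)")
  norm <- s * plan$n_shots
  delta <- model$delta
  lay <- param_layout(model)
  starts <- plan$starts[sel]
  cvec <- vapply(model$neurons, capacitance, 0)

  V <- if (pin_upsilon) t(v[starts, , drop = FALSE])
       else plan$upsilon[, sel, drop = FALSE]
  U0 <- V
  if (gamma > 0) V <- V + gamma * (t(v[starts, , drop = FALSE]) - V)
  W <- lapply(plan$xi_w, function(m) m[, sel, drop = FALSE])
  Z <- lapply(plan$xi_z, function(m) m[, sel, drop = FALSE])

  Vhist <- vector("list", s + 1L); Vhist[[1L]] <- V
  Whist <- vector("list", s + 1L); Whist[[1L]] <- W
  Zhist <- vector("list", s + 1L); Zhist[[1L]] <- Z
  caches <- vector("list", s)
  Phist <- vector("list", s)
  HUhist <- vector("list", s)
  loss <- 0
  for (t in seq_len(s)) {
    H <- matrix(0, n, K)
    HU <- matrix(0, n, K)
    cch <- vector("list", n)
    for (i in seq_len(n)) {
      fw <- neuron_current(model$neurons[[i]], V[i, ], w = W[[i]], z = Z[[i]],
                           cache = want_grad)
      H[i, ] <- fw$h
      cch[[i]] <- fw
    }
    Ut <- t(u[starts + t - 1L, , drop = FALSE])
    HU <- -H + Ut
    P <- V + (delta / cvec) * HU
    D <- t(v[starts + t, , drop = FALSE])
    loss <- loss + sum((P - D)^2) / norm
    # states propagate from the corrected voltage at t-1
    Wn <- W; Zn <- Z
    for (i in seq_len(n)) {
      ne <- model$neurons[[i]]
      if (ncol(plan$xi_w[[i]]) && nrow(plan$xi_w[[i]]))
        Wn[[i]] <- ne$intrinsic$bank$A %*% W[[i]] +
          ne$intrinsic$bank$B %*% V[i, , drop = FALSE]
      if (nrow(plan$xi_z[[i]]))
        Zn[[i]] <- ne$synapse$bank$A %*% Z[[i]] +
          ne$synapse$bank$B %*% V[model$presyn[i], , drop = FALSE]
    }
    V <- if (gamma > 0) P + gamma * (D - P) else P
    W <- Wn; Z <- Zn
    Vhist[[t + 1L]] <- V
    Whist[[t + 1L]] <- W
    Zhist[[t + 1L]] <- Z
    caches[[t]] <- cch
    Phist[[t]] <- P
    HUhist[[t]] <- HU
  }

  has_next <- plan$has_next[sel]
  if ((rho_v > 0 || rho_x > 0) && any(has_next)) {
    nx <- sel[has_next] + 1L
    cols <- which(has_next)
    if (rho_v > 0) {
      tgt <- if (pin_upsilon) t(v[plan$starts[nx], , drop = FALSE])
             else plan$upsilon[, nx, drop = FALSE]
      loss <- loss + rho_v * sum((V[, cols, drop = FALSE] - tgt)^2) / norm
    }
    if (rho_x > 0) {
      for (i in seq_len(n)) {
        if (nrow(plan$xi_w[[i]]))
          loss <- loss + rho_x * sum(plan$Dw[[i]] *
            (W[[i]][, cols, drop = FALSE] - plan$xi_w[[i]][, nx, drop = FALSE])^2) / norm
        if (nrow(plan$xi_z[[i]]))
          loss <- loss + rho_x * sum(plan$Dz[[i]] *
            (Z[[i]][, cols, drop = FALSE] - plan$xi_z[[i]][, nx, drop = FALSE])^2) / norm
      }
    }
  }

  theta <- pack_params(model)
  rg <- reg_term(model, theta, rho, reg_scale)
  loss <- loss + rg$loss
  if (!want_grad) return(list(loss = loss))

  # ---- reverse pass -------------------------------------------------------
  g <- numeric(attr(lay, "n_params"))
  g_ups <- matrix(0, n, plan$n_shots)
  g_xiw <- lapply(plan$xi_w, function(m) matrix(0, nrow(m), ncol(m)))
  g_xiz <- lapply(plan$xi_z, function(m) matrix(0, nrow(m), ncol(m)))

  aV <- matrix(0, n, K)
  aW <- lapply(W, function(m) matrix(0, nrow(m), ncol(m)))
  aZ <- lapply(Z, function(m) matrix(0, nrow(m), ncol(m)))
  if ((rho_v > 0 || rho_x > 0) && any(has_next)) {
    nx <- sel[has_next] + 1L
    cols <- which(has_next)
    if (rho_v > 0) {
      tgt <- if (pin_upsilon) t(v[plan$starts[nx], , drop = FALSE])
             else plan$upsilon[, nx, drop = FALSE]
      dd <- 2 * rho_v * (Vhist[[s + 1L]][, cols, drop = FALSE] - tgt) / norm
      aV[, cols] <- aV[, cols] + dd
      if (!pin_upsilon) g_ups[, nx] <- g_ups[, nx] - dd
    }
    if (rho_x > 0) {
      for (i in seq_len(n)) {
        if (nrow(plan$xi_w[[i]])) {
          dd <- 2 * rho_x * plan$Dw[[i]] *
            (Whist[[s + 1L]][[i]][, cols, drop = FALSE] -
               plan$xi_w[[i]][, nx, drop = FALSE]) / norm
          aW[[i]][, cols] <- aW[[i]][, cols] + dd
          g_xiw[[i]][, nx] <- g_xiw[[i]][, nx] - dd
        }
        if (nrow(plan$xi_z[[i]])) {
          dd <- 2 * rho_x * plan$Dz[[i]] *
            (Zhist[[s + 1L]][[i]][, cols, drop = FALSE] -
               plan$xi_z[[i]][, nx, drop = FALSE]) / norm
          aZ[[i]][, cols] <- aZ[[i]][, cols] + dd
          g_xiz[[i]][, nx] <- g_xiz[[i]][, nx] - dd
        }
      }
    }
  }

  for (t in s:1) {
    D <- t(v[starts + t, , drop = FALSE])
    aP <- (1 - gamma) * aV + 2 * (Phist[[t]] - D) / norm
    aVprev <- aP
    aWprev <- vector("list", n)
    aZprev <- vector("list", n)
    for (i in seq_len(n)) {
      ne <- model$neurons[[i]]
      ah <- -(delta / cvec[i]) * aP[i, ]
      bp <- neuron_current_backprop(ne, Vhist[[t]][i, ], Whist[[t]][[i]],
                                    Zhist[[t]][[i]], caches[[t]][[i]], ah)
      li <- lay[[i]]
      if (model$learn_c)
        g[li$c] <- g[li$c] +
          sum(aP[i, ] * (-delta / cvec[i]^2) * HUhist[[t]][i, ]) *
          dsoftplus(ne$c_raw) * C_SCALE
      g[li$leak_g] <- g[li$leak_g] + bp$g_leak_g_raw
      g[li$leak_b] <- g[li$leak_b] + bp$g_leak_b
      if (!is.null(bp$g_int)) g[li$int] <- g[li$int] + bp$g_int
      if (!is.null(bp$g_syn)) g[li$syn] <- g[li$syn] + bp$g_syn
      aVprev[i, ] <- aVprev[i, ] + bp$av
      aWprev[[i]] <- matrix(0, nrow(aW[[i]]), K)
      aZprev[[i]] <- matrix(0, nrow(aZ[[i]]), K)
      if (nrow(aW[[i]])) {
        Ab <- ne$intrinsic$bank
        aWprev[[i]] <- crossprod(Ab$A, aW[[i]])
        if (!is.null(bp$aw)) aWprev[[i]] <- aWprev[[i]] + bp$aw
        aVprev[i, ] <- aVprev[i, ] + as.numeric(crossprod(Ab$B, aW[[i]]))
      }
      if (nrow(aZ[[i]])) {
        Sb <- ne$synapse$bank
        aZprev[[i]] <- crossprod(Sb$A, aZ[[i]])
        if (!is.null(bp$az)) aZprev[[i]] <- aZprev[[i]] + bp$az
        j <- model$presyn[i]
        aVprev[j, ] <- aVprev[j, ] + as.numeric(crossprod(Sb$B, aZ[[i]]))
      }
    }
    aV <- aVprev
    aW <- aWprev
    aZ <- aZprev
  }
  if (!pin_upsilon) g_ups[, sel] <- g_ups[, sel] + (1 - gamma) * aV
  for (i in seq_len(n)) {
    if (nrow(aW[[i]])) g_xiw[[i]][, sel] <- g_xiw[[i]][, sel] + aW[[i]]
    if (nrow(aZ[[i]])) g_xiz[[i]][, sel] <- g_xiz[[i]][, sel] + aZ[[i]]
  }

  list(loss = loss, grad = g + rg$grad, g_upsilon = g_ups,
       g_xi_w = g_xiw, g_xi_z = g_xiz)
}

#' Multiple-shooting loss
#'
#' For each selected shot, simulates the full model for `s` steps from the
#' shot's (learnable) initial voltage and internal states, accumulates the
#' squared voltage error of the propagated predictions against the data,
#' and adds continuity penalties driving each shot's final states toward the
#' next shot's initial states (`rho_v` unweighted for voltage; `rho_x`
#' DC-gain weighted for internal states) plus the ANN ridge penalty.
#'
#' @inheritParams tf_loss
#' @param plan an [shot_plan()].
#' @param rho_v,rho_x voltage / internal-state continuity weights.
#' @param shots shot indices forming the batch (default all).
#' @param pin_upsilon fix the initial shot voltages to the data instead of
#'   treating them as learnable (the `s = 1` teacher-forcing reduction).
#' @return scalar loss.
#' @export
ms_loss <- function(model, v, u, plan, rho = 0, rho_v = 0, rho_x = 0,
                    shots = NULL, pin_upsilon = FALSE) {
  if (is.null(shots)) shots <- seq_len(plan$n_shots)
  msgtf_loss_grad(model, v, u, plan, shots, gamma = 0, rho = rho,
                  rho_v = rho_v, rho_x = rho_x, pin_upsilon = pin_upsilon,
                  want_grad = FALSE)$loss
}

#' Generalized-teacher-forcing rollout loss
#'
#' Identical to [ms_loss()] except that within each shot every propagated
#' voltage is corrected toward the measurement by the factor `gamma` before
#' driving the next step (the Luenberger-observer update).  `gamma = 0`
#' recovers multiple shooting exactly; as `gamma -> 1` every step is forced
#' by the data and the loss approaches the teacher-forcing structure.
#'
#' @inheritParams ms_loss
#' @param gamma measurement-correction factor in \[0, 1\).
#' @return scalar loss.
#' @export
gtf_rollout_loss <- function(model, v, u, plan, gamma, rho = 0, rho_v = 0,
                             rho_x = 0, shots = NULL, pin_upsilon = FALSE) {
  if (is.null(shots)) shots <- seq_len(plan$n_shots)
  msgtf_loss_grad(model, v, u, plan, shots, gamma = gamma, rho = rho,
                  rho_v = rho_v, rho_x = rho_x, pin_upsilon = pin_upsilon,
                  want_grad = FALSE)$loss
}

#' Partition items into mini-batches
#'
#' Teacher-forcing mode (`mode = "tf"`) optionally shuffles the samples
#' before the contiguous split (shuffling reorders samples *within*
#' batches).  Shot mode (`mode = "shots"`) permutes whole shots across
#' batches every epoch but never reorders samples within a shot.
#' Deterministic given `(seed, epoch)`.
#'
#' @param n_items number of samples or shots.
#' @param n_minibatches number of batches (<= n_items).
#' @param shuffle logical; in `"tf"` mode enables sample shuffling, in
#'   `"shots"` mode enables the across-batch shot permutation.
#' @param seed,epoch integers seeding the permutation.
#' @param mode `"tf"` or `"shots"`.
#' @return list of disjoint index vectors whose union is `1:n_items`.
#' @export
make_minibatches <- function(n_items, n_minibatches, shuffle = TRUE,
                             seed = 1L, epoch = 1L, mode = c("tf", "shots")) {
  mode <- match.arg(mode)
  if (n_minibatches > n_items)
    stop_invalid("more mini-batches (", n_minibatches, ") than items (",
                 n_items, ")")
  idx <- seq_len(n_items)
  if (shuffle)
    idx <- with_seed(child_seed(seed, 7L + epoch), sample.int(n_items))
  sizes <- rep(n_items %/% n_minibatches, n_minibatches)
  extra <- n_items %% n_minibatches
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep.int(seq_len(n_minibatches), sizes))
}
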