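#' Default continuous time-constant sets
#'
#' Time constants (ms) spanning the gating kinetics of stomatogastric
#' conductance-based neuron models: a fast+slow set of 24 values
#' (0.2--1.6 ms, 2--16 ms, 20--90 ms) and an ultraslow set of 8 values
#' (100--1500 ms).  Intrinsic-current state banks use the union of the two
#' sets (32 poles); synaptic banks use the fast+slow set only.
#'
#' @return numeric vector of time constants in ms.
#' @export
tau_fast_slow <- function() {
  c(0.2 * (1:8), 2.0 * (1:8), 10 + 10 * (1:8))
}

#' @rdname tau_fast_slow
#' @export
tau_ultraslow <- function() {
  200 * (1:8) - 100
}

#' Discretize a continuous time constant into a stable pole
#'
#' Maps a continuous time constant tau (ms) to the discrete-time pole
#' `exp(-delta/tau)`, which lies strictly inside (0, 1) for any positive tau
#' and sampling period, so stability is preserved by construction.
#'
#' @param tau continuous time constant, ms, > 0.  Vectorized.
#' @param delta sampling period, ms, > 0.
#' @return pole(s) in (0, 1).
#' @export
discretize_tau <- function(tau, delta) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop_invalid("`tau` must be finite and strictly positive (ms)")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop_invalid("`delta` must be a single positive sampling period (ms)")
  exp(-delta / tau)
}

new_ss <- function(A, B, lambdas, delta, kind, taus = NULL) {
  structure(
    list(A = A, B = B, lambdas = as.numeric(lambdas), delta = delta,
         kind = kind, taus = taus),
    class = "rmm_ss"
  )
}

#' @export
print.rmm_ss <- function(x, ...) {
  cat(sprintf("<rmm_ss> %s bank: %d states, delta = %g ms, poles in [%.6g, %.6g]\n",
              x$kind, length(x$lambdas), x$delta,
              min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

check_poles <- function(lambdas) {
  if (!is.numeric(lambdas) || length(lambdas) < 1L || any(!is.finite(lambdas)))
    stop_invalid("poles must be a non-empty finite numeric vector")
  if (any(lambdas <= 0) || any(lambdas >= 1))
    stop_invalid("poles must lie strictly inside (0, 1); got range [",
                 min(lambdas), ", ", max(lambdas), "]")
  if (anyDuplicated(lambdas))
    warning("duplicate poles in state-space bank; the construction remains well-defined",
            call. = FALSE)
  invisible(lambdas)
}

#' Build a linear state-space bank with orthonormal impulse responses
#'
#' Constructs a lower-triangular (A, B) pair from discrete poles so that the
#' state trajectories following a voltage impulse are mutually orthogonal
#' (the controllability Gramian is the identity).  This gives the model a
#' rich, non-redundant set of filtered voltage histories.  The recursion is
#' `A1 = lambda1`, `B1 = sqrt(1 - lambda1^2)`, and for each added pole the
#' new row couples to the running auxiliary vectors Gamma and Delta.
#'
#' @param lambdas discrete poles, each strictly in (0, 1).
#' @param delta sampling period in ms (stored for bookkeeping).
#' @param taus optional originating continuous time constants.
#' @return an object of class `rmm_ss` with fields `A`, `B`, `lambdas`,
#'   `delta`, `kind = "orthogonal"`.
#' @export
build_orthogonal_ss <- function(lambdas, delta, taus = NULL) {
  check_poles(lambdas)
  n <- length(lambdas)
  l1 <- lambdas[1L]
  A <- matrix(l1, 1L, 1L)
  B <- matrix(sqrt(1 - l1^2), 1L, 1L)
  Gam <- matrix(B[1L, 1L], 1L, 1L)  # row vector
  Del <- -l1
  if (n > 1L) {
    for (i in 2:n) {
      li <- lambdas[i]
      s <- sqrt(1 - li^2)
      A <- rbind(cbind(A, 0), cbind(s * Gam, li))
      B <- rbind(B, s * Del)
      Gam <- cbind(-li * Gam, s)
      Del <- -li * Del
    }
  }
  dimnames(A) <- NULL
  new_ss(A, B, lambdas, delta, "orthogonal", taus)
}

#' Build a diagonal first-order low-pass bank
#'
#' Each state is a unit-DC-gain first-order filter of the input voltage:
#' `A = diag(lambdas)`, `B = 1 - lambdas`.  Used for the biophysically
#' informed conductance synapse, whose gate reads low-passed presynaptic
#' voltage directly in mV.
#'
#' @inheritParams build_orthogonal_ss
#' @return an `rmm_ss` with `kind = "diagonal"`.
#' @export
build_diag_ss <- function(lambdas, delta, taus = NULL) {
  check_poles(lambdas)
  n <- length(lambdas)
  A <- diag(lambdas, n, n)
  B <- matrix(1 - lambdas, n, 1L)
  new_ss(A, B, lambdas, delta, "diagonal", taus)
}

#' Bank construction from time constants
#'
#' Convenience wrapper: discretizes `taus` at `delta` and builds the bank.
#' @param taus continuous time constants, ms.
#' @param delta sampling period, ms.
#' @param kind `"orthogonal"` or `"diagonal"`.
#' @return an `rmm_ss`.
#' @export
build_ss_from_taus <- function(taus, delta, kind = c("orthogonal", "diagonal")) {
  kind <- match.arg(kind)
  lam <- discretize_tau(taus, delta)
  if (kind == "orthogonal") build_orthogonal_ss(lam, delta, taus)
  else build_diag_ss(lam, delta, taus)
}

#' Contraction check for linear internal dynamics
#'
#' Linear internal dynamics contract exponentially iff the spectral radius of
#' A is below one.  Contraction underwrites warm-up, bounded teacher-forcing
#' gradients and the existence of a unique internal equilibrium at every
#' voltage.
#'
#' @param ss an `rmm_ss`, or any square matrix.
#' @return list with `contracting` (logical) and `spectral_radius`.
#' @export
check_contraction_linear <- function(ss) {
  A <- if (inherits(ss, "rmm_ss")) ss$A else as.matrix(ss)
  if (nrow(A) != ncol(A)) stop_invalid("A must be square")
  if (nrow(A) == 0L) return(list(contracting = TRUE, spectral_radius = 0))
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  list(contracting = sr < 1, spectral_radius = sr)
}

#' DC gain of a state bank
#'
#' Returns `(I - A)^{-1} B`, the steady-state value of each internal state
#' under a unit constant voltage.  The reciprocals of these entries weight
#' the multiple-shooting state-continuity norm.
#'
#' @param ss an `rmm_ss`.
#' @return numeric vector of length `n`.
#' @export
dc_gain <- function(ss) {
  n <- length(ss$lambdas)
  if (n == 0L) return(numeric(0))
  chk <- check_contraction_linear(ss)
  if (!chk$contracting)
    stop_invalid("dc_gain requires a contracting bank (spectral radius ",
                 signif(chk$spectral_radius, 6), " >= 1)")
  as.numeric(solve(diag(n) - ss$A, ss$B))
}

#' Simulate a linear state bank over a voltage series
#'
#' Computes the state sequence of `x[t+1] = A x[t] + B v[t]` aligned with the
#' input: row t of the result is the state at time t, driven by `v[1..t-1]`
#' (row 1 equals `x0`).  Exploits the (lower-)triangular structure of the
#' orthogonal construction: each state is a first-order recursive filter of
#' the lower states and the input, so the whole sequence is computed with n
#' calls to [stats::filter()].
#'
#' @param ss an `rmm_ss`.
#' @param v numeric voltage series.
#' @param x0 initial state (default zeros).
#' @return matrix `length(v) x n` of states.
#' @export
bank_states <- function(ss, v, x0 = NULL) {
  n <- length(ss$lambdas)
  N <- length(v)
  if (N < 1L) stop_invalid("empty voltage series")
  if (n == 0L) return(matrix(0, N, 0L))
  if (is.null(x0)) x0 <- numeric(n)
  stopifnot(length(x0) == n)
  X <- matrix(0, N, n)
  A <- ss$A
  B <- ss$B
  for (i in seq_len(n)) {
    drive <- B[i, 1L] * v
    if (i > 1L) {
      off <- A[i, seq_len(i - 1L), drop = FALSE]
      nz <- which(off != 0)
      if (length(nz))
        drive <- drive + X[, nz, drop = FALSE] %*% t(off[, nz, drop = FALSE])
    }
    lam <- A[i, i]
    # x[t+1] = lam x[t] + drive[t]; emit x[1..N] with x[1] = x0[i]
    z <- stats::filter(drive[seq_len(N)], filter = lam, method = "recursive",
                       init = x0[i])
    X[, i] <- c(x0[i], as.numeric(z)[seq_len(N - 1L)])
  }
  X
}

#' Default warm-up length
#'
#' Number of burn-in steps M such that the contraction factor
#' `max(lambda)^M` drops below `tol`, so the retained states are independent
#' of the unknown initial condition to that tolerance.
#'
#' @param ss an `rmm_ss`.
#' @param tol forgetting tolerance (default 1e-9).
#' @return integer M.
#' @export
default_warmup_steps <- function(ss, tol = 1e-9) {
  if (length(ss$lambdas) == 0L) return(0L)
  lmax <- max(ss$lambdas)
  as.integer(ceiling(log(tol) / log(lmax)))
}

#' Warm-up plan
#'
#' @param burn_in_steps integer M >= 0 of leading samples used only to flush
#'   the internal-state transient.
#' @param initial_state optional initial state vector (default zeros).
#' @return an object of class `rmm_warmup`.
#' @export
warmup_plan <- function(burn_in_steps, initial_state = NULL) {
  if (length(burn_in_steps) != 1L || burn_in_steps < 0)
    stop_invalid("`burn_in_steps` must be a single non-negative integer")
  structure(list(burn_in_steps = as.integer(burn_in_steps),
                 initial_state = initial_state),
            class = "rmm_warmup")
}

#' Warm up internal states over a data prefix
#'
#' Simulates the bank from `plan$initial_state` across the burn-in prefix of
#' `v` and returns the states aligned with the retained portion
#' `v[(M+1):N]`.  Under contraction the retained states are insensitive to
#' the initial state: two initial conditions differ after M steps by at most
#' `||dx0|| * max(lambda)^M`.
#'
#' @param ss an `rmm_ss`.
#' @param v voltage series, longer than the burn-in.
#' @param plan an `rmm_warmup` (default: tolerance-derived burn-in capped at
#'   half the data).
#' @return matrix `(N - M) x n` of retained states.
#' @export
warmup_states <- function(ss, v, plan = NULL) {
  N <- length(v)
  if (is.null(plan)) {
    M <- min(default_warmup_steps(ss), N %/% 2L)
    plan <- warmup_plan(M)
  }
  M <- plan$burn_in_steps
  if (N <= M)
    stop_invalid("insufficient data: series length ", N,
                 " not greater than burn-in ", M)
  X <- bank_states(ss, v, plan$initial_state)
  X[(M + 1L):N, , drop = FALSE]
}

#' Export / import a state-space bank as structured text
#'
#' Round-trips `taus`, `delta`, `A`, `B` through JSON at 17 significant
#' digits (lossless for doubles).
#' @param ss an `rmm_ss`.
#' @param path file path.
#' @export
write_ss <- function(ss, path) {
  obj <- list(kind = ss$kind, delta = ss$delta, lambdas = ss$lambdas,
              taus = ss$taus, A = as.numeric(ss$A), B = as.numeric(ss$B))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_ss
#' @export
read_ss <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$lambdas)
  A <- matrix(obj$A, n, n)  # stored column-major
  new_ss(A, matrix(obj$B, ncol = 1L), obj$lambdas, obj$delta, obj$kind,
         taus = obj$taus)
}
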