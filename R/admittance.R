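# Frequency-domain interpretation layer: steady-state IV/GV curves,
# admittance surfaces Y(v, omega), excitability regions and bifurcation
# candidates, for any membrane with contracting linear internal dynamics.
#
# The membrane interface is a small container holding the sampling period,
# the capacitance, the linear internal dynamics (A, B) and the total-current
# map h(v, x) with its exact partial derivatives.  The key simplification
# under linear internal dynamics: the resolvent vector
# r(omega) = (e^{j omega delta} I - A)^{-1} B does not depend on v, so
# Y(v, omega) = dh/dv(v) + dh/dx(v) . r(omega).

#' Construct a membrane for frequency-domain analysis
#'
#' @param h_fun function `(v, x) -> current` (total outward current).
#' @param dh_dv function `(v, x) -> scalar` exact partial.
#' @param dh_dx function `(v, x) -> length-m vector` exact partial (may be
#'   `NULL` when there are no internal states).
#' @param ss an `rmm_ss` bank (or `NULL` for a memoryless current).
#' @param C capacitance, pF.
#' @param delta sampling period, ms.
#' @param v_range voltage range over which the model is trusted (used for
#'   extrapolation warnings), or `NULL`.
#' @return object of class `rmm_membrane`.
#' @export
toy_membrane <- function(h_fun, dh_dv, dh_dx = NULL, ss = NULL, C = 1,
                         delta = 0.1, v_range = NULL) {
  m <- if (is.null(ss)) 0L else length(ss$lambdas)
  if (m > 0L) {
    chk <- check_contraction_linear(ss)
    if (!chk$contracting) stop_invalid("internal dynamics are not contracting")
  }
  structure(list(h_fun = h_fun, dh_dv = dh_dv, dh_dx = dh_dx, ss = ss,
                 m = m, C = C, delta = delta, v_range = v_range),
            class = "rmm_membrane")
}

#' Extract a per-neuron membrane from a trained circuit
#'
#' The analyzed current is the neuron's total *intrinsic* current
#' `h = I_int + I_leak` (the synaptic current is treated as an external
#' input), with the intrinsic bank as internal dynamics and exact partial
#' derivatives obtained by differentiating the perceptron.
#'
#' @param model an `rmm_circuit`.
#' @param neuron neuron index.
#' @return an `rmm_membrane`.
#' @export
neuron_membrane <- function(model, neuron = 1L) {
  ne <- model$neurons[[neuron]]
  lg <- leak_g(ne)
  lb <- leak_b(ne)
  if (is.null(ne$intrinsic)) {
    return(toy_membrane(
      h_fun = function(v, x) lg * v - lb,
      dh_dv = function(v, x) lg,
      dh_dx = NULL, ss = NULL, C = capacitance(ne), delta = model$delta))
  }
  mlp <- ne$intrinsic$mlp
  vr <- c(mlp$norm$lo[1L], mlp$norm$hi[1L])
  toy_membrane(
    h_fun = function(v, x) {
      I_SCALE * as.numeric(mlp_forward(mlp, c(v, x))) + lg * v - lb
    },
    dh_dv = function(v, x) {
      I_SCALE * mlp_input_grad(mlp, c(v, x))[1L, 1L] + lg
    },
    dh_dx = function(v, x) {
      I_SCALE * as.numeric(mlp_input_grad(mlp, c(v, x))[-1L, 1L])
    },
    ss = ne$intrinsic$bank, C = capacitance(ne), delta = model$delta,
    v_range = vr)
}

#' Internal equilibrium state
#'
#' Unique fixed point `x = f(v, x)` of the contracting internal dynamics at
#' a constant voltage; for the linear banks this is `(I - A)^{-1} B v` in
#' closed form.
#'
#' @param mem an `rmm_membrane`.
#' @param v voltage, mV (vectorized).
#' @return m x length(v) matrix of equilibrium states.
#' @export
internal_equilibrium <- function(mem, v) {
  if (mem$m == 0L) return(matrix(0, 0L, length(v)))
  dcg <- dc_gain(mem$ss)
  outer(dcg, v)
}

warn_extrapolation <- function(mem, v_grid) {
  if (!is.null(mem$v_range) &&
      (min(v_grid) < mem$v_range[1L] || max(v_grid) > mem$v_range[2L]))
    warning("voltage grid extends beyond the training range [",
            signif(mem$v_range[1L], 4), ", ", signif(mem$v_range[2L], 4),
            "] mV; extrapolated values are untrusted", call. = FALSE)
}

#' Steady-state IV and GV curves
#'
#' `u_inf(v) = h(v, x_inf(v))` and its exact derivative
#' `G_inf(v) = dh/dv + dh/dx (I - A)^{-1} B`, combining the partials of `h`
#' with the implicit-function sensitivity of the internal equilibrium.
#'
#' @param mem an `rmm_membrane`.
#' @param v_grid voltages, mV.
#' @return data.frame of class `rmm_equilibrium_curve` with columns `v`,
#'   `u_inf`, `G_inf`, and the equilibrium states as attribute `x_inf`.
#' @export
iv_gv_curves <- function(mem, v_grid) {
  warn_extrapolation(mem, v_grid)
  X <- internal_equilibrium(mem, v_grid)
  sens <- if (mem$m > 0L) dc_gain(mem$ss) else numeric(0)
  u_inf <- numeric(length(v_grid))
  G_inf <- numeric(length(v_grid))
  for (k in seq_along(v_grid)) {
    v <- v_grid[k]; x <- X[, k]
    u_inf[k] <- mem$h_fun(v, x)
    G_inf[k] <- mem$dh_dv(v, x) +
      if (mem$m > 0L) sum(mem$dh_dx(v, x) * sens) else 0
  }
  out <- data.frame(v = v_grid, u_inf = u_inf, G_inf = G_inf)
  attr(out, "x_inf") <- X
  class(out) <- c("rmm_equilibrium_curve", "data.frame")
  out
}

resolvent <- function(mem, omega) {
  # (e^{j omega delta} I - A)^{-1} B, per omega; m x length(omega) complex
  m <- mem$m
  out <- matrix(0i, m, length(omega))
  if (m == 0L) return(out)
  A <- mem$ss$A
  B <- mem$ss$B
  for (k in seq_along(omega)) {
    z <- exp(1i * omega[k] * mem$delta)
    out[, k] <- solve(diag(z, m) - A, B)
  }
  out
}

#' Admittance-voltage surface
#'
#' Complex admittance
#' `Y(v, omega) = dh/dv + dh/dx (e^{j omega delta} I - A)^{-1} B` evaluated
#' at the internal equilibrium of each grid voltage.  The real part is the
#' frequency-dependent conductance G and the imaginary part the susceptance
#' B; `G(v, 0)` equals the steady-state conductance `G_inf(v)`.
#'
#' @param mem an `rmm_membrane`.
#' @param v_grid voltages, mV.
#' @param omega_grid angular frequencies, rad/ms, within `[0, pi/delta]`
#'   (default: 0 plus a log-spaced grid up to the Nyquist frequency).
#' @return list of class `rmm_admittance_surface` with `v`, `omega`, complex
#'   matrix `Y` (v x omega), `G`, `B`, `delta`, `C`.
#' @export
admittance_surface <- function(mem, v_grid, omega_grid = NULL) {
  if (is.null(omega_grid))
    omega_grid <- c(0, 10^seq(-4, log10(pi / mem$delta), length.out = 60L))
  if (any(omega_grid < 0) || any(omega_grid > pi / mem$delta + 1e-12))
    stop_invalid("omega_grid must lie within [0, pi/delta]")
  warn_extrapolation(mem, v_grid)
  R <- resolvent(mem, omega_grid)
  X <- internal_equilibrium(mem, v_grid)
  Y <- matrix(0i, length(v_grid), length(omega_grid))
  for (k in seq_along(v_grid)) {
    v <- v_grid[k]; x <- X[, k]
    dv <- mem$dh_dv(v, x)
    if (mem$m > 0L) {
      dx <- mem$dh_dx(v, x)
      Y[k, ] <- dv + as.vector(crossprod(matrix(dx, ncol = 1L), R))
    } else Y[k, ] <- dv + 0i
  }
  structure(list(v = v_grid, omega = omega_grid, Y = Y,
                 G = Re(Y), B = Im(Y), delta = mem$delta, C = mem$C),
            class = "rmm_admittance_surface")
}

#' @export
print.rmm_admittance_surface <- function(x, ...) {
  cat(sprintf("<rmm_admittance_surface> %d voltages x %d frequencies, G in [%.4g, %.4g]\n",
              length(x$v), length(x$omega), min(x$G), max(x$G)))
  invisible(x)
}

#' Voltage-frequency excitability regions
#'
#' Marks the grid cells where the frequency-dependent conductance is
#' negative (the linearized total membrane current is locally active /
#' passivity-breaking) and labels 4-connected regions.
#'
#' @param surface an [admittance_surface()].
#' @return list with logical `mask` (v x omega), integer `labels`, and a
#'   `regions` data.frame (voltage and frequency extents, minimum G).
#' @export
excitability_map <- function(surface) {
  mask <- surface$G < 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cc > 1L) p - nr, if (cc < nc) p + nr)
      nb <- nb[lab[nb] == 0L & mask[nb]]
      queue <- c(queue, nb)
    }
  }
  regions <- NULL
  if (cur > 0L) {
    regions <- do.call(rbind, lapply(seq_len(cur), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      data.frame(region = k,
                 v_min = min(surface$v[idx[, 1L]]),
                 v_max = max(surface$v[idx[, 1L]]),
                 omega_min = min(surface$omega[idx[, 2L]]),
                 omega_max = max(surface$omega[idx[, 2L]]),
                 G_min = min(surface$G[idx]))
    }))
  } else {
    regions <- data.frame(region = integer(0), v_min = numeric(0),
                          v_max = numeric(0), omega_min = numeric(0),
                          omega_max = numeric(0), G_min = numeric(0))
  }
  list(mask = mask, labels = lab, regions = regions)
}

# complex bifurcation residual C (e^{j omega delta} - 1) + delta Y(v, omega)
bif_residual <- function(mem, v, omega) {
  x <- as.numeric(internal_equilibrium(mem, v))
  Yv <- mem$dh_dv(v, x) +
    if (mem$m > 0L) sum(mem$dh_dx(v, x) * resolvent(mem, omega)[, 1L])
    else 0
  mem$C * (exp(1i * omega * mem$delta) - 1) + mem$delta * Yv
}

#' Locate bifurcation candidates
#'
#' Solves `C (e^{j omega delta} - 1) + delta Y(v, omega) = 0` over the
#' voltage-frequency grid by sign-change bracketing and local refinement.
#' Roots with `omega = 0` are candidate fold (saddle-node) points --
#' equivalently zeros of the steady-state conductance `G_inf` -- and roots
#' with `omega > 0` are candidate Neimark-Sacker points.
#'
#' @param mem an `rmm_membrane`.
#' @param v_grid voltages scanned, mV.
#' @param omega_grid positive frequencies scanned, rad/ms (default
#'   log-spaced to Nyquist).
#' @param tol root tolerance passed to [stats::uniroot()].
#' @return data.frame with columns `v_bar`, `omega_bar`, `type`, `residual`.
#' @export
bifurcation_candidates <- function(mem, v_grid, omega_grid = NULL,
                                   tol = 1e-12) {
  if (is.null(omega_grid))
    omega_grid <- 10^seq(-4, log10(pi / mem$delta), length.out = 80L)
  out <- data.frame(v_bar = numeric(0), omega_bar = numeric(0),
                    type = character(0), residual = numeric(0))
  # fold candidates: zeros of G_inf (the residual at omega = 0 is purely real)
  crv <- suppressWarnings(iv_gv_curves(mem, v_grid))
  Gf <- function(v) suppressWarnings(iv_gv_curves(mem, v))$G_inf
  sg <- which(diff(sign(crv$G_inf)) != 0)
  for (k in sg) {
    r <- stats::uniroot(Gf, c(v_grid[k], v_grid[k + 1L]), tol = tol)
    out <- rbind(out, data.frame(v_bar = r$root, omega_bar = 0,
                                 type = "fold",
                                 residual = Mod(bif_residual(mem, r$root, 0))))
  }
  # Neimark-Sacker candidates: track omega roots of the imaginary part and
  # look for sign changes of the real part along the voltage axis
  if (mem$m > 0L) {
    im_f <- function(v, omega) Im(bif_residual(mem, v, omega))
    re_f <- function(v, omega) Re(bif_residual(mem, v, omega))
    omega_roots <- function(v) {
      vals <- vapply(omega_grid, function(om) im_f(v, om), 0)
      ix <- which(diff(sign(vals)) != 0)
      vapply(ix, function(k) {
        stats::uniroot(function(om) im_f(v, om),
                       c(omega_grid[k], omega_grid[k + 1L]), tol = tol)$root
      }, 0)
    }
    roots_prev <- omega_roots(v_grid[1L])
    for (k in seq_len(length(v_grid) - 1L)) {
      roots_next <- omega_roots(v_grid[k + 1L])
      for (om1 in roots_prev) {
        if (!length(roots_next)) next
        om2 <- roots_next[which.min(abs(log(roots_next) - log(om1)))]
        if (abs(log(om2) - log(om1)) > 1) next
        r1 <- re_f(v_grid[k], om1)
        r2 <- re_f(v_grid[k + 1L], om2)
        if (sign(r1) == sign(r2)) next
        g <- function(v) {
          omv <- tryCatch({
            lo <- min(om1, om2) / 2; hi <- max(om1, om2) * 2
            stats::uniroot(function(om) im_f(v, om), c(lo, hi), tol = tol)$root
          }, error = function(e) NA_real_)
          if (is.na(omv)) return(NA_real_)
          re_f(v, omv)
        }
        vr <- tryCatch(stats::uniroot(g, c(v_grid[k], v_grid[k + 1L]),
                                      tol = tol)$root,
                       error = function(e) NA_real_)
        if (is.na(vr)) next
        omr <- stats::uniroot(function(om) im_f(vr, om),
                              c(min(om1, om2) / 2, max(om1, om2) * 2),
                              tol = tol)$root
        out <- rbind(out, data.frame(v_bar = vr, omega_bar = omr,
                                     type = "neimark_sacker",
                                     residual = Mod(bif_residual(mem, vr, omr))))
      }
      roots_prev <- roots_next
    }
  }
  if (nrow(out) > 1L) {
    key <- paste(round(out$v_bar, 6), round(out$omega_bar, 6), out$type)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Small-signal sinusoid check of the admittance
#'
#' Simulates the total-current system `x[t+1] = A x[t] + B v[t]`,
#' `y[t] = h(v[t], x[t])` driven by `v[t] = v + eps sin(omega delta t)`,
#' extracts the steady-state output amplitude and phase by least squares
#' over whole periods, and compares them with the analytic prediction
#' (gain `|Y(v, omega)|`, phase `angle(Y)`).
#'
#' @param mem an `rmm_membrane`.
#' @param v set-point voltage, mV.
#' @param omega angular frequency, rad/ms (> 0).
#' @param eps sinusoid amplitude, mV.
#' @param periods number of steady-state periods fitted.
#' @return list with `simulated` (gain, phase, amplitude) and `predicted`
#'   (gain, phase from Y).
#' @export
sinusoid_gain_check <- function(mem, v, omega, eps, periods = 10L) {
  if (omega <= 0) stop_invalid("omega must be positive")
  delta <- mem$delta
  period <- max(2L, as.integer(ceiling(2 * pi / (omega * delta))))
  settle <- if (mem$m > 0L) {
    lmax <- max(Mod(eigen(mem$ss$A, only.values = TRUE)$values))
    as.integer(ceiling(log(1e-10) / log(max(lmax, 1e-6))))
  } else 0L
  settle <- max(settle, 2L * period)
  N <- settle + periods * period
  tt <- seq_len(N) - 1L
  vt <- v + eps * sin(omega * delta * tt)
  x <- as.numeric(internal_equilibrium(mem, v))
  y <- numeric(N)
  A <- if (mem$m > 0L) mem$ss$A
  B <- if (mem$m > 0L) as.numeric(mem$ss$B)
  for (t in seq_len(N)) {
    y[t] <- mem$h_fun(vt[t], x)
    if (mem$m > 0L) x <- as.numeric(A %*% x + B * vt[t])
  }
  keep <- (settle + 1L):N
  s <- sin(omega * delta * tt[keep])
  cc <- cos(omega * delta * tt[keep])
  fitc <- stats::lm.fit(cbind(s, cc, 1), y[keep])$coefficients
  amp <- unname(sqrt(fitc[1L]^2 + fitc[2L]^2))
  phase <- unname(atan2(fitc[2L], fitc[1L]))
  resfit <- y[keep] - cbind(s, cc, 1) %*% fitc
  if (sqrt(mean(resfit^2)) > 0.05 * max(amp, 1e-12))
    warning("sinusoid response has not settled to a clean steady state; ",
            "increase the horizon or reduce eps", call. = FALSE)
  x0 <- as.numeric(internal_equilibrium(mem, v))
  Yv <- mem$dh_dv(v, x0) +
    if (mem$m > 0L) sum(mem$dh_dx(v, x0) * resolvent(mem, omega)[, 1L])
    else 0
  list(simulated = list(gain = amp / eps, phase = phase, amplitude = amp),
       predicted = list(gain = Mod(Yv), phase = Arg(Yv)))
}
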