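make_trained_like_membrane <- function(seed = 9) {
  set.seed(1)
  v <- matrix(-55 + 12 * sin(seq(0, 20, length.out = 4000)) + rnorm(4000),
              2000, 2)
  spec <- rmm_spec(2, 0.1,
                   intrinsic = list(taus = c(1, 10, 100), hidden = c(6L, 6L)),
                   synapse = NULL, c0 = 0.8)
  mod <- init_parameters(spec, v, seed = seed)
  neuron_membrane(mod, 1)
}

test_that("internal equilibrium solves the fixed-point equation", {
  ssb <- ns$new_ss(matrix(0.5), matrix(0.5), 0.5, 0.1, "diagonal")
  mem <- toy_membrane(function(v, x) v + x, function(v, x) 1,
                      function(v, x) 1, ss = ssb)
  expect_equal(as.numeric(internal_equilibrium(mem, 3)), 3)
  expect_equal(as.numeric(internal_equilibrium(mem, 0)), 0)
  # diagonal banks have unit DC gain in every coordinate
  memd <- toy_membrane(function(v, x) v, function(v, x) 1,
                       function(v, x) c(0, 0), ss = build_diag_ss(c(0.3, 0.95), 0.1))
  expect_equal(as.numeric(internal_equilibrium(memd, -7)), c(-7, -7))
  # the fixed point satisfies x = A x + B v
  mem2 <- make_trained_like_membrane()
  x <- internal_equilibrium(mem2, -50)[, 1]
  expect_equal(as.numeric(mem2$ss$A %*% x + mem2$ss$B * -50), x,
               tolerance = 1e-10)
})

test_that("IV/GV curves reproduce closed forms and finite differences", {
  # passive: u = g(v - E), G = g
  mem <- toy_membrane(function(v, x) 5 * (v + 60), function(v, x) 5, C = 1)
  crv <- iv_gv_curves(mem, seq(-80, -40, 10))
  expect_equal(crv$u_inf, 5 * (crv$v + 60))
  expect_equal(crv$G_inf, rep(5, 5))
  # cubic toy: G = 3v^2 - 1 with zeros at +-1/sqrt(3)
  memc <- toy_membrane(function(v, x) v^3 - v, function(v, x) 3 * v^2 - 1)
  crc <- iv_gv_curves(memc, seq(-1, 1, 0.5))
  expect_equal(crc$G_inf, 3 * crc$v^2 - 1)
  # exact G_inf against centered finite differences of u_inf
  mem2 <- make_trained_like_membrane()
  vg <- seq(-58, -52, 1)
  crv2 <- iv_gv_curves(mem2, vg)
  fd <- (iv_gv_curves(mem2, vg + 1e-4)$u_inf -
           iv_gv_curves(mem2, vg - 1e-4)$u_inf) / 2e-4
  expect_lt(max(abs(fd - crv2$G_inf)), 1e-6)
  expect_warning(iv_gv_curves(mem2, c(-200, -50)), "training range")
})

test_that("admittance surface matches resolvent closed forms", {
  # passive membrane: Y == g at every frequency
  mem <- toy_membrane(function(v, x) 5 * (v + 60), function(v, x) 5, C = 1)
  surf <- admittance_surface(mem, seq(-80, -40, 5))
  expect_lt(max(Mod(surf$Y - 5)), 1e-12)
  # scalar toy h = v + x with bank A = B = 0.5
  ssb <- ns$new_ss(matrix(0.5), matrix(0.5), 0.5, 0.1, "diagonal")
  memt <- toy_membrane(function(v, x) v + x, function(v, x) 1,
                       function(v, x) 1, ss = ssb, delta = 0.1)
  s2 <- admittance_surface(memt, 0, c(0, pi / 0.1))
  expect_equal(Re(s2$Y[1, 1]), 2, tolerance = 1e-12)        # 1 + 0.5/(1-0.5)
  expect_equal(Re(s2$Y[1, 2]), 2 / 3, tolerance = 1e-12)    # 1 + 0.5/(-1.5)
  expect_error(admittance_surface(memt, 0, c(-1, 2)), "within")
})

test_that("zero-frequency conductance equals the steady-state GV curve", {
  mem <- make_trained_like_membrane()
  vg <- seq(-65, -45, 1)
  crv <- iv_gv_curves(mem, vg)
  surf <- admittance_surface(mem, vg)
  expect_lt(max(abs(surf$G[, 1] - crv$G_inf)), 1e-8)
})

test_that("admittance has conjugate symmetry in frequency", {
  mem <- make_trained_like_membrane()
  x <- internal_equilibrium(mem, -55)[, 1]
  dx <- mem$dh_dx(-55, x)
  Ypos <- mem$dh_dv(-55, x) + sum(dx * ns$resolvent(mem, 0.3)[, 1])
  Rneg <- solve(diag(exp(-0.3i * mem$delta), mem$m) - mem$ss$A, mem$ss$B)
  Yneg <- mem$dh_dv(-55, x) + sum(dx * Rneg)
  expect_equal(Yneg, Conj(Ypos), tolerance = 1e-12)
})

test_that("excitability regions capture negative-conductance cells", {
  # passive: empty mask
  mem <- toy_membrane(function(v, x) 5 * (v + 60), function(v, x) 5)
  em <- excitability_map(admittance_surface(mem, seq(-80, -40, 5)))
  expect_false(any(em$mask))
  expect_equal(nrow(em$regions), 0)
  # cubic toy: mask true exactly where |v| < 1/sqrt(3), at every omega
  memc <- toy_membrane(function(v, x) v^3 - v, function(v, x) 3 * v^2 - 1)
  vg <- seq(-1.5, 1.5, 0.05)
  em2 <- excitability_map(admittance_surface(memc, vg))
  inside <- abs(vg) < 1 / sqrt(3)
  expect_equal(rowSums(em2$mask) > 0, inside)
  expect_equal(nrow(em2$regions), 1)
  # a slow negative-conductance bank is excitable only at low frequencies:
  # h = g v - k x with x a slow low-pass of v gives Y(0) = g - k < 0 but
  # Y(high omega) ~ g > 0
  ssl <- build_diag_ss(discretize_tau(200, 0.1), 0.1)
  mems <- toy_membrane(function(v, x) 2 * v - 3 * x, function(v, x) 2,
                       function(v, x) -3, ss = ssl, delta = 0.1)
  surf <- admittance_surface(mems, 0, c(0, 1e-4, 0.01, 1))
  expect_lt(surf$G[1, 1], 0)
  expect_gt(surf$G[1, 4], 0)
  # closed form of the first-order resolvent
  lam <- ssl$lambdas
  om <- 0.01
  Yc <- 2 - 3 * (1 - lam) / (exp(1i * om * 0.1) - lam)
  expect_equal(surf$Y[1, 3], Yc, tolerance = 1e-12)
})

test_that("fold candidates sit at the zeros of the cubic GV curve", {
  memc <- toy_membrane(function(v, x) v^3 - v, function(v, x) 3 * v^2 - 1,
                       C = 1, delta = 0.1)
  cand <- bifurcation_candidates(memc, seq(-1.5, 1.5, 0.05))
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$type == "fold"))
  expect_lt(max(abs(sort(cand$v_bar) - c(-1, 1) / sqrt(3))), 1e-6)
  expect_true(all(cand$residual < 1e-8))
  # every omega = 0 candidate has |G_inf| below tolerance
  for (vb in cand$v_bar)
    expect_lt(abs(iv_gv_curves(memc, vb)$G_inf), 1e-8)
  # passive model yields no candidates
  memp <- toy_membrane(function(v, x) 5 * (v + 60), function(v, x) 5)
  expect_equal(nrow(bifurcation_candidates(memp, seq(-80, -40, 1))), 0)
})

test_that("small-signal sinusoid response matches the analytic admittance", {
  mem <- make_trained_like_membrane()
  for (om in c(0.05, 0.5, 5)) {
    chk <- sinusoid_gain_check(mem, -55, om, eps = 0.01)
    expect_lt(abs(chk$simulated$gain - chk$predicted$gain) /
                abs(chk$predicted$gain), 0.01)
    expect_lt(abs(chk$simulated$phase - chk$predicted$phase), 0.01)
  }
  # linearity: doubling eps doubles the output amplitude to first order
  a1 <- sinusoid_gain_check(mem, -55, 0.5, eps = 0.005)$simulated$amplitude
  a2 <- sinusoid_gain_check(mem, -55, 0.5, eps = 0.01)$simulated$amplitude
  expect_lt(abs(a2 / a1 - 2), 0.02)
  # passive membrane: exact gain g, zero phase
  memp <- toy_membrane(function(v, x) 5 * (v + 60), function(v, x) 5)
  chk <- sinusoid_gain_check(memp, -60, 0.5, eps = 0.1)
  expect_equal(chk$simulated$gain, 5, tolerance = 1e-8)
  expect_equal(chk$simulated$phase, 0, tolerance = 1e-8)
})
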