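test_that("discretize_tau maps time constants to stable poles", {
  expect_equal(discretize_tau(0.2, 0.1), exp(-0.5), tolerance = 1e-12)
  expect_equal(discretize_tau(7, 7), exp(-1), tolerance = 1e-12)
  # limits: slow taus approach 1 from below, fast taus approach 0
  expect_true(discretize_tau(1e9, 0.1) < 1)
  expect_true(discretize_tau(1e9, 0.1) > 1 - 1e-6)
  expect_true(discretize_tau(1e-9, 0.1) < 1e-6)
  expect_error(discretize_tau(-1, 0.1), "positive")
  expect_error(discretize_tau(1, 0), "positive")
})

test_that("orthogonal construction matches the hand-unrolled recursion", {
  expect_warning(ss <- build_orthogonal_ss(c(0.5, 0.5), 0.1), "duplicate")
  expect_equal(ss$A, rbind(c(0.5, 0), c(0.75, 0.5)), tolerance = 1e-12)
  expect_equal(as.numeric(ss$B), c(0.8660254, -0.4330127), tolerance = 1e-6)
  # n = 1 special cases
  s1 <- build_orthogonal_ss(0.3, 0.1)
  expect_equal(as.numeric(s1$A), 0.3)
  expect_equal(as.numeric(s1$B), sqrt(1 - 0.09))
  s0 <- build_orthogonal_ss(1e-12, 0.1)
  expect_equal(as.numeric(s0$B), 1, tolerance = 1e-9)
  expect_error(build_orthogonal_ss(c(0.5, 1.2), 0.1), "inside")
})

test_that("impulse-response state trajectories are orthonormal", {
  for (taus in list(tau_fast_slow(), tau_ultraslow(), c(0.7, 3.1, 45, 260))) {
    lam <- discretize_tau(taus, 0.1)
    ss <- build_orthogonal_ss(lam, 0.1)
    chk <- check_contraction_linear(ss)
    expect_true(chk$contracting)
    expect_equal(chk$spectral_radius, max(lam), tolerance = 1e-12)
    Tn <- ceiling(50 / (1 - max(lam)))
    X <- bank_states(ss, c(1, rep(0, Tn)))
    G <- crossprod(X)
    offd <- max(abs(G - diag(diag(G))))
    expect_lt(offd, 1e-6 * min(diag(G)))
    expect_equal(diag(G), rep(1, length(lam)), tolerance = 1e-8)
  }
})

test_that("diagonal banks are unit-DC first-order filters", {
  ss <- build_diag_ss(c(0.5, 0.9), 0.1)
  expect_equal(dc_gain(ss), c(1, 1), tolerance = 1e-12)
  # impulse responses: lambda^(t-1) * (1 - lambda) at t >= 1 after the impulse
  X <- bank_states(ss, c(1, rep(0, 10)))
  expect_equal(X[2:6, 1], 0.5^(0:4) * 0.5, tolerance = 1e-12)
  expect_equal(X[2:6, 2], 0.9^(0:4) * 0.1, tolerance = 1e-12)
  # constant input reaches the DC fixed point
  Xc <- bank_states(build_diag_ss(0.9, 0.1), rep(3, 2000))
  expect_equal(Xc[2000, 1], 3, tolerance = 1e-8)
  # lambda ~ 0 is a pure one-step delay
  Xd <- bank_states(build_diag_ss(1e-14, 0.1), c(5, 7, 9))
  expect_equal(Xd[, 1], c(0, 5, 7), tolerance = 1e-10)
})

test_that("contraction check flags unstable matrices", {
  expect_false(check_contraction_linear(diag(2))$contracting)
  expect_equal(check_contraction_linear(diag(2))$spectral_radius, 1)
  r <- check_contraction_linear(diag(c(0.5, 1.2)))
  expect_false(r$contracting)
  expect_equal(r$spectral_radius, 1.2)
})

test_that("dc_gain matches closed forms and refuses unstable banks", {
  ss <- ns$new_ss(matrix(0.5), matrix(0.5), 0.5, 0.1, "diagonal")
  expect_equal(dc_gain(ss), 1)
  ss0 <- ns$new_ss(matrix(0), matrix(4), 0.5, 0.1, "diagonal")
  expect_equal(dc_gain(ss0), 4)
  bad <- ns$new_ss(matrix(1.0), matrix(1), 1.0, 0.1, "diagonal")
  expect_error(dc_gain(bad), "contracting")
})

test_that("warm-up forgets the initial state at the contraction rate", {
  ss <- build_orthogonal_ss(c(0.5, 0.8, 0.9), 0.1)
  lmax <- max(ss$lambdas)
  M <- 200L
  set.seed(1)
  v <- rnorm(400, -55, 5)
  X1 <- warmup_states(ss, v, warmup_plan(M, initial_state = rep(0, 3)))
  X2 <- warmup_states(ss, v, warmup_plan(M, initial_state = rep(1, 3)))
  # non-normal transient growth allows a bounded constant over lmax^M
  expect_lt(max(abs(X1 - X2)), 10 * lmax^M * sqrt(3))
  expect_lt(max(abs(X1 - X2)), 1e-8)
  # constant input settles to dc_gain * c
  Xc <- warmup_states(ss, rep(2, 4000), warmup_plan(3000))
  expect_equal(Xc[nrow(Xc), ], dc_gain(ss) * 2, tolerance = 1e-6)
  expect_error(warmup_states(ss, rnorm(10), warmup_plan(20)), "insufficient")
  # log-linear decay envelope: the asymptotic slope of the discrepancy norm
  # equals log(lambda_max) (the construction is non-normal, so the envelope
  # holds asymptotically, not step by step)
  d <- abs(bank_states(ss, v, rep(0, 3)) - bank_states(ss, v, rep(1, 3)))
  dn <- sqrt(rowSums(d^2))
  tt <- 100:250
  slope <- stats::coef(stats::lm(log(dn[tt]) ~ tt))[2]
  expect_equal(unname(slope), log(lmax), tolerance = 1e-3)
})

test_that("default warm-up length reaches the tolerance", {
  ss <- build_ss_from_taus(c(1, 10), 0.1)
  M <- default_warmup_steps(ss, 1e-9)
  expect_lt(max(ss$lambdas)^M, 1e-9)
  expect_gte(max(ss$lambdas)^(M - 1L), 1e-9)
})

test_that("state-space banks round-trip through text export", {
  ss <- build_ss_from_taus(c(0.4, 3, 70), 0.1)
  f <- tempfile(fileext = ".json")
  write_ss(ss, f)
  ss2 <- read_ss(f)
  expect_equal(ss2$A, ss$A, tolerance = 1e-15)
  expect_equal(as.numeric(ss2$B), as.numeric(ss$B), tolerance = 1e-15)
  expect_equal(ss2$taus, ss$taus)
  expect_equal(ss2$delta, ss$delta)
  unlink(f)
})
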