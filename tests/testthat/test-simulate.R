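test_that("compiled simulator matches the R reference step by step", {
  v <- make_toy_voltages()
  u <- matrix(rnorm(120, 0, 0.05), 60, 2)
  for (syn in c("mlp", "cond")) {
    model <- make_small_circuit(v, synapse = syn)
    x0 <- warmup_circuit_states(model, v[1:10, ])
    simc <- simulate_circuit(model, u[11:40, ], v[11, ], x0)
    simr <- ns$simulate_circuit_r(model, u[11:40, ], v[11, ], x0)
    expect_lt(max(abs(simc$v - simr$v)), 1e-10)
    obs <- observer_simulate(model, v[11:40, ], u[11:40, ], 0.3, v[11, ], x0)
    obsr <- ns$simulate_circuit_r(model, u[11:40, ], v[11, ], x0, gamma = 0.3,
                                  v_measured = v[11:40, ])
    expect_lt(max(abs(obs$v_corrected - obsr$v_corrected)), 1e-10)
  }
})

test_that("observer with gamma = 0 equals open-loop simulation exactly", {
  v <- make_toy_voltages()
  u <- matrix(rnorm(120, 0, 0.05), 60, 2)
  model <- make_small_circuit(v)
  x0 <- warmup_circuit_states(model, v[1:10, ])
  sim <- simulate_circuit(model, u[11:50, ], v[11, ], x0)
  obs <- observer_simulate(model, v[11:50, ], u[11:50, ], 0, v[11, ], x0)
  expect_identical(obs$v, sim$v)
})

test_that("observer with gamma = 1 outputs the measurements", {
  v <- make_toy_voltages()
  u <- matrix(0, 60, 2)
  model <- make_small_circuit(v)
  obs <- observer_simulate(model, v, u, 1)
  expect_equal(obs$v_corrected, unname(v), tolerance = 1e-12)
  expect_error(observer_simulate(model, v, u, 1.5), "0, 1")
})

test_that("corrected voltage interpolates between prediction and measurement", {
  v <- make_toy_voltages()
  u <- matrix(rnorm(120, 0, 0.05), 60, 2)
  model <- make_small_circuit(v)
  for (gamma in c(0.25, 0.5, 0.9)) {
    obs <- observer_simulate(model, v, u, gamma)
    mix <- obs$v + gamma * (unname(v) - obs$v)
    expect_equal(obs$v_corrected, mix, tolerance = 1e-12)
    lo <- pmin(obs$v, unname(v)) - 1e-12
    hi <- pmax(obs$v, unname(v)) + 1e-12
    expect_true(all(obs$v_corrected >= lo & obs$v_corrected <= hi))
  }
})

test_that("passive membrane follows the scalar closed forms", {
  g <- 0.012; E <- -52; c0 <- 0.4; delta <- 0.1
  model <- make_passive_circuit(g, E, c0)
  # zero input from v0, E = 0 equivalent: v decays to E geometrically
  sim <- simulate_circuit(model, matrix(0, 400, 1), -80)
  expect_equal(sim$v[, 1], E + (-80 - E) * (1 - delta * g / c0)^(0:399),
               tolerance = 1e-9)
  # constant input settles at E + u/g
  simc <- simulate_circuit(model, matrix(0.06, 20000, 1), -52)
  expect_equal(simc$v[20000, 1], E + 0.06 / g, tolerance = 1e-6)
})

test_that("uncoupled passive neurons simulate independently", {
  spec <- rmm_spec(2L, 0.1, presyn = c(NA_integer_, NA_integer_),
                   intrinsic = NULL, synapse = NULL, c0 = 0.5,
                   leak_g0 = 0.01, leak_E0 = -50)
  model <- init_parameters(spec, NULL, seed = 1)
  u <- cbind(rnorm(200, 0, 0.02), rnorm(200, 0.05, 0.02))
  sim <- simulate_circuit(model, u, c(-60, -40))
  one <- make_passive_circuit(0.01, -50, 0.5)
  s1 <- simulate_circuit(one, u[, 1, drop = FALSE], -60)
  s2 <- simulate_circuit(one, u[, 2, drop = FALSE], -40)
  expect_equal(sim$v[, 1], s1$v[, 1], tolerance = 1e-12)
  expect_equal(sim$v[, 2], s2$v[, 1], tolerance = 1e-12)
})

test_that("divergence is reported with a time index and truncation", {
  model <- make_passive_circuit(0.01, -50, 1e-5)  # absurd capacitance
  expect_warning(sim <- simulate_circuit(model, matrix(1, 200, 1), -60),
                 "diverged")
  expect_gt(sim$diverged, 0)
})

test_that("open-loop equilibrium is consistent with the steady-state IV curve", {
  v <- make_toy_voltages(seed = 13)
  spec <- rmm_spec(1L, 0.1, presyn = NA_integer_,
                   intrinsic = list(taus = c(1, 10), hidden = c(4L)),
                   synapse = NULL, c0 = 0.5)
  model <- init_parameters(spec, v[, 1, drop = FALSE], seed = 21)
  u0 <- 0.04
  sim <- simulate_circuit(model, matrix(u0, 60000, 1), -55)
  expect_equal(sim$diverged, 0)
  v_end <- sim$v[60000, 1]
  mem <- neuron_membrane(model, 1)
  crv <- suppressWarnings(iv_gv_curves(mem, v_end))
  expect_equal(crv$u_inf, u0, tolerance = 1e-5)
})
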