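make_loss_fixture <- function(synapse = "mlp") {
  v <- make_toy_voltages()
  u <- matrix(rnorm(120, 0, 0.05), 60, 2)
  model <- make_small_circuit(v, synapse = synapse)
  states <- precompute_internal_states(model, v, burn_in = 5)
  list(v = v, u = u, model = model, states = states)
}

test_that("teacher-forcing gradient matches finite differences", {
  fx <- make_loss_fixture()
  idx <- 6:59
  res <- ns$tf_loss_grad(fx$model, fx$v, fx$u, fx$states, 1e-4, idx)
  th <- pack_params(fx$model)
  f <- function(t) ns$tf_loss_grad(unpack_params(fx$model, t), fx$v, fx$u,
                                   fx$states, 1e-4, idx,
                                   want_grad = FALSE)$loss
  gn <- fd_gradient(f, th)
  expect_lt(max(abs(gn - res$grad) / pmax(abs(gn), 1e-4)), 1e-5)
})

test_that("shooting and GTF gradients match finite differences", {
  for (synapse in c("mlp", "cond")) {
    fx <- make_loss_fixture(synapse)
    plan <- shot_plan(fx$model, fx$v, fx$states, s = 5)
    sel <- c(2L, 4L, 7L)
    th <- pack_params(fx$model)
    for (gamma in c(0, 0.3)) {
      res <- ns$msgtf_loss_grad(fx$model, fx$v, fx$u, plan, sel, gamma,
                                rho = 1e-4, rho_v = 2, rho_x = 1.5)
      f <- function(t) ns$msgtf_loss_grad(unpack_params(fx$model, t), fx$v,
                                          fx$u, plan, sel, gamma, 1e-4, 2,
                                          1.5, want_grad = FALSE)$loss
      gn <- fd_gradient(f, th)
      expect_lt(max(abs(gn - res$grad) / pmax(abs(gn), 1e-4)), 1e-5)
      # shot-state gradients (initial voltages and internal states)
      fu <- function(uv) {
        p2 <- plan; p2$upsilon[] <- uv
        ns$msgtf_loss_grad(fx$model, fx$v, fx$u, p2, sel, gamma, 1e-4, 2,
                           1.5, want_grad = FALSE)$loss
      }
      gU <- fd_gradient(fu, as.numeric(plan$upsilon))
      expect_lt(max(abs(gU - as.numeric(res$g_upsilon))), 1e-5)
      fxw <- function(xv) {
        p2 <- plan; p2$xi_w[[1]][] <- xv
        ns$msgtf_loss_grad(fx$model, fx$v, fx$u, p2, sel, gamma, 1e-4, 2,
                           1.5, want_grad = FALSE)$loss
      }
      gX <- fd_gradient(fxw, as.numeric(plan$xi_w[[1]]))
      expect_lt(max(abs(gX - as.numeric(res$g_xi_w[[1]]))), 1e-5)
    }
  }
})

test_that("reduction chain: s = 1 pinned shooting equals teacher forcing", {
  fx <- make_loss_fixture()
  plan1 <- shot_plan(fx$model, fx$v, fx$states, s = 1)
  l_ms <- ms_loss(fx$model, fx$v, fx$u, plan1, rho = 1e-4, rho_v = 0,
                  rho_x = 0, pin_upsilon = TRUE)
  l_tf <- tf_loss(fx$model, fx$v, fx$u, fx$states, rho = 1e-4,
                  idx = plan1$starts)
  expect_lt(abs(l_ms - l_tf), 1e-10)
})

test_that("reduction chain: GTF with gamma = 0 equals multiple shooting", {
  fx <- make_loss_fixture()
  plan <- shot_plan(fx$model, fx$v, fx$states, s = 6)
  expect_identical(
    gtf_rollout_loss(fx$model, fx$v, fx$u, plan, 0, 1e-4, 2, 1.5),
    ms_loss(fx$model, fx$v, fx$u, plan, 1e-4, 2, 1.5))
})

test_that("perfect one-step model attains only the regularization floor", {
  # passive model generating its own data: TF residuals are exactly zero
  g <- 0.01; E <- -50; c0 <- 0.5
  model <- make_passive_circuit(g, E, c0)
  set.seed(3)
  u <- matrix(rnorm(200, 0.05, 0.02), 200, 1)
  v <- matrix(passive_trajectory(-60, u[, 1], g, E, c0, 0.1), 200, 1)
  states <- precompute_internal_states(model, v, burn_in = 0)
  expect_lt(tf_loss(model, v, u, states, rho = 0), 1e-22)
  # hand-computed single-sample residual
  idx <- 17L
  r_hand <- (v[18] - v[17] - 0.1 / c0 * (-(g * v[17] - g * E) + u[17]))^2
  expect_equal(tf_loss(model, v, u, states, rho = 0, idx = idx), r_hand,
               tolerance = 1e-15)
})

test_that("two-shot rollout of a passive model reproduces a hand unroll", {
  g <- 0.01; E <- -50; c0 <- 0.5; delta <- 0.1
  model <- make_passive_circuit(g, E, c0)
  set.seed(4)
  u <- matrix(rnorm(9, 0.05, 0.03), 9, 1)
  v <- matrix(rnorm(9, -55, 3), 9, 1)
  states <- precompute_internal_states(model, v, burn_in = 0)
  plan <- shot_plan(model, v, states, s = 2)
  # hand unroll: shots start at 1, 3, 5, 7 with upsilon = v[start]
  hand <- 0
  for (st in c(1, 3, 5, 7)) {
    vv <- v[st]
    for (t in 1:2) {
      vv <- vv + delta / c0 * (-(g * vv - g * E) + u[st + t - 1])
      hand <- hand + (vv - v[st + t])^2
    }
  }
  hand <- hand / (2 * 4)
  expect_equal(ms_loss(model, v, u, plan, 0, 0, 0), hand, tolerance = 1e-12)
})

test_that("precomputed states settle to closed-form fixed points", {
  v <- make_toy_voltages()
  model <- make_small_circuit(v)
  # constant voltage: states approach dc_gain * c
  vc <- matrix(-48, 12000, 2)
  st <- precompute_internal_states(model, vc, burn_in = 0)
  bank <- model$neurons[[1]]$intrinsic$bank
  expect_equal(st$w[[1]][12000, ], dc_gain(bank) * -48, tolerance = 1e-4)
  # zero voltage: states stay zero
  st0 <- precompute_internal_states(model, matrix(0, 50, 2), burn_in = 0)
  expect_true(all(abs(st0$w[[1]]) < 1e-12))
  # recomputation with a different burn-in start state is forgotten
  ss <- model$neurons[[1]]$intrinsic$bank
  X1 <- bank_states(ss, v[, 1], rep(0, 3))
  X2 <- bank_states(ss, v[, 1], rep(5, 3))
  M <- 50L
  lmax <- max(ss$lambdas)
  expect_lt(max(abs(X1[M, ] - X2[M, ])), 5 * sqrt(3) * lmax^(M - 1))
})

test_that("TF is refused when a bank is not contracting", {
  v <- make_toy_voltages()
  model <- make_small_circuit(v)
  model$neurons[[1]]$intrinsic$bank$A[1, 1] <- 1.5
  model$neurons[[1]]$intrinsic$bank$lambdas[1] <- 1.5
  expect_error(precompute_internal_states(model, v), "contracting")
})

test_that("mini-batches partition the items deterministically", {
  b1 <- make_minibatches(100, 7, shuffle = TRUE, seed = 3, epoch = 2)
  b2 <- make_minibatches(100, 7, shuffle = TRUE, seed = 3, epoch = 2)
  expect_identical(b1, b2)
  b3 <- make_minibatches(100, 7, shuffle = TRUE, seed = 3, epoch = 3)
  expect_false(identical(b1, b3))
  expect_equal(sort(unname(unlist(b1))), 1:100)
  expect_length(b1, 7)
  # no shuffle: identity contiguous split
  b0 <- make_minibatches(10, 2, shuffle = FALSE)
  expect_identical(unname(b0), list(1:5, 6:10))
  expect_error(make_minibatches(3, 5), "more mini-batches")
})

test_that("TF gradient norm does not grow with the dataset length", {
  set.seed(9)
  g <- 0.01; E <- -50; c0 <- 0.5
  model <- make_passive_circuit(g * 1.3, E + 4, c0)  # deliberately wrong params
  mk <- function(N) {
    u <- matrix(rnorm(N, 0.05, 0.02), N, 1)
    v <- matrix(passive_trajectory(-60, u[, 1], g, E, c0, 0.1), N, 1)
    states <- precompute_internal_states(model, v, burn_in = 0)
    res <- ns$tf_loss_grad(model, v, u, states, 0, 1:(N - 1))
    sqrt(sum(res$grad^2))
  }
  n1 <- mk(500); n2 <- mk(1000); n4 <- mk(2000)
  expect_lt(n4 / n1, 1.5)
  expect_lt(n2 / n1, 1.5)
})
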