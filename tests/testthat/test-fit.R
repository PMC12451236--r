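make_passive_data <- function(g = 0.012, E = -52, c0 = 0.6, N = 4000L,
                              seed = 11L, disturbance = NULL) {
  delta <- 0.1
  u <- matrix(ns$with_seed(seed, ou_series(N, ou_params(mu = 0.05, a = 0.04,
                                                        b = 0.5))), N, 1)
  d <- if (is.null(disturbance)) numeric(N) else disturbance
  v <- matrix(0, N, 1)
  v[1] <- -60
  for (t in 1:(N - 1))
    v[t + 1] <- v[t] + delta / c0 * (-(g * v[t] - g * E) + u[t] + d[t])
  list(v = v, u = u, g = g, E = E, c0 = c0)
}

test_that("zero epochs return the initial model unchanged", {
  dat <- make_passive_data()
  model0 <- make_passive_circuit()
  cfg <- train_config("tf", epochs = 0, burn_in = 0)
  fit <- fit_rmm(model0, dat, cfg)
  expect_identical(pack_params(fit$model), pack_params(model0))
  expect_equal(nrow(fit$trace), 0)
})

test_that("training is deterministic given seed and config", {
  dat <- make_passive_data()
  model0 <- make_passive_circuit()
  cfg <- train_config("tf", epochs = 20, n_minibatches = 4, seed = 7,
                      burn_in = 0, snapshot_every = 1e9)
  f1 <- fit_rmm(model0, dat, cfg)
  f2 <- fit_rmm(model0, dat, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(pack_params(f1$model), pack_params(f2$model))
})

test_that("teacher forcing recovers passive-membrane parameters within 5%", {
  dat <- make_passive_data()
  model0 <- make_passive_circuit(g = 0.02, E = -60, c0 = 1)
  cfg <- train_config("tf", epochs = 2000, n_minibatches = 4, seed = 3,
                      burn_in = 0, snapshot_every = 1e9)
  fit <- fit_rmm(model0, dat, cfg)
  ne <- fit$model$neurons[[1]]
  expect_lt(abs(ns$leak_g(ne) / dat$g - 1), 0.05)
  expect_lt(abs(ns$leak_b(ne) / ns$leak_g(ne) / dat$E - 1), 0.05)
  expect_lt(abs(ns$capacitance(ne) / dat$c0 - 1), 0.05)
  # loss decreased over training
  expect_lt(utils::tail(fit$trace$loss, 1), fit$trace$loss[1])
})

test_that("multiple shooting recovers passive-membrane parameters within 5%", {
  dat <- make_passive_data()
  model0 <- make_passive_circuit(g = 0.02, E = -60, c0 = 1)
  cfg <- train_config("ms", epochs = 500, shot_len = 10, n_minibatches = 4,
                      seed = 3, burn_in = 0, snapshot_every = 1e9,
                      lr_schedule = list(c(1, 0.01)))
  fit <- fit_rmm(model0, dat, cfg)
  ne <- fit$model$neurons[[1]]
  expect_lt(abs(ns$leak_g(ne) / dat$g - 1), 0.05)
  expect_lt(abs(ns$leak_b(ne) / ns$leak_g(ne) / dat$E - 1), 0.05)
  expect_lt(abs(ns$capacitance(ne) / dat$c0 - 1), 0.05)
  expect_lt(utils::tail(fit$trace$loss, 1), fit$trace$loss[1])
})

test_that("snapshot selection returns the best recorded validation metric", {
  rec <- simulate_hco_dataset(6000, seed = 21)
  sp <- make_train_val_split(rec)
  spec <- rmm_spec(2, 0.1,
                   intrinsic = list(taus = c(1, 10, 100), hidden = c(4L)),
                   synapse = list(type = "mlp", taus = c(2, 20), hidden = c(4L)),
                   c0 = 0.25)
  model0 <- init_parameters(spec, sp$train$v, seed = 4)
  cfg <- train_config("tf", epochs = 10, n_minibatches = 8,
                      snapshot_every = 2, seed = 4, burn_in = 1000)
  fit <- fit_rmm(model0, sp$train, cfg, validation = sp$validation)
  recorded <- fit$trace$val_metric[!is.na(fit$trace$val_metric)]
  expect_equal(fit$best_metric, max(recorded))
  re_eval <- validate_model(fit$model, sp$validation)
  expect_equal(re_eval$mean, fit$best_metric, tolerance = 1e-12)
})

test_that("the exploding-gradient guard aborts with a diagnostic", {
  dat <- make_passive_data()
  model0 <- make_passive_circuit()
  cfg <- train_config("tf", epochs = 5, burn_in = 0, n_minibatches = 2,
                      snapshot_every = 1e9, max_grad = 1e-9)
  expect_error(fit_rmm(model0, dat, cfg), "exploding|aborted")
})

test_that("an observer with small gamma filters unmeasured disturbances", {
  N <- 6000L
  d <- 0.3 * sin(2 * pi * (1:N) / 4000) + 0.2 * sin(2 * pi * (1:N) / 900)
  dat <- make_passive_data(N = N, disturbance = d)
  model0 <- make_passive_circuit(g = 0.02, E = -60, c0 = 1)
  cfg <- train_config("tf", epochs = 1200, n_minibatches = 4, seed = 3,
                      burn_in = 0, snapshot_every = 1e9)
  fit <- fit_rmm(model0, dat, cfg)
  open <- observer_simulate(fit$model, dat$v, dat$u, 0)
  filt <- observer_simulate(fit$model, dat$v, dat$u, 0.05)
  mse_open <- mean((open$v - dat$v)^2)
  mse_filt <- mean((filt$v_corrected - dat$v)^2)
  expect_lt(mse_filt, mse_open)
})
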