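test_that("OU process fixed point and geometric mean reversion", {
  p <- ou_params(mu = 0.5, a = 0.04, b = 0, delta = 0.1)
  expect_equal(ou_step(0.5, p, eps = 1.23), 0.5)
  # geometric approach with factor 1 - delta*a = 0.996
  u <- 1
  u2 <- ou_step(u, p, eps = 0)
  expect_equal((u2 - 0.5) / (u - 0.5), 0.996, tolerance = 1e-12)
  s <- ou_series(1000, p, u0 = 1)
  expect_equal(s[1000] - 0.5, 0.5 * 0.996^999, tolerance = 1e-9)
})

test_that("OU sample mean converges to mu within Monte-Carlo error", {
  p <- ou_params(mu = 0.3, a = 0.04, b = 0.1, delta = 0.1)
  set.seed(10)
  s <- ou_series(300000, p)
  sd_stat <- p$b * p$delta / sqrt(1 - (1 - p$delta * p$a)^2)
  n_eff <- 300000 * p$delta * p$a   # roughly one independent sample per 1/(a delta)
  expect_lt(abs(mean(s) - 0.3), 3 * sd_stat / sqrt(n_eff))
  # sqrt-delta scaling increases the innovation size accordingly
  p2 <- ou_params(mu = 0, a = 0.04, b = 0.1, delta = 0.1, scaling = "sqrt_delta")
  expect_equal(ou_step(0, p2, eps = 1), 0.1 * sqrt(0.1))
  # literal scaling uses b * delta
  expect_equal(ou_step(0, ou_params(0, 0.04, 0.1, 0.1), eps = 1), 0.1 * 0.1)
})

test_that("dynamic-clamp synapse gate settles at its logistic target", {
  p <- dynclamp_params()
  # constant presyn at half-activation: sigma = 0.5, z -> 0.5
  z <- 0.2
  for (k in 1:20000) z <- dynclamp_synapse_step(z, -50, -60, p, i = 1)$z
  expect_equal(z, 0.5, tolerance = 1e-6)
  st <- dynclamp_synapse_step(0.5, -50, -60, p, i = 1)
  expect_equal(st$I, -105 * 0.5 * (-60 + 80), tolerance = 1e-9)  # -1050
  # reversal potential nulls the current
  expect_equal(dynclamp_synapse_step(0.7, -40, -80, p, i = 1)$I, 0)
  # hyperpolarized presyn closes the gate
  z <- 0.6
  for (k in 1:60000) z <- dynclamp_synapse_step(z, -100, -60, p, i = 1)$z
  expect_lt(z, 1e-6)
})

test_that("dynamic-clamp H gate activates with hyperpolarization", {
  p <- dynclamp_params()
  # constant v at half-activation: w -> 0.5
  w <- 0.1
  for (k in 1:300000) w <- dynclamp_h_step(w, -45, p, i = 1)$w
  expect_equal(w, 0.5, tolerance = 1e-5)
  st <- dynclamp_h_step(0.5, -45, p, i = 1)
  expect_equal(st$I, -225 * 0.5 * (-45 + 10), tolerance = 1e-9)  # 3937.5
  # depolarization deactivates
  w <- 0.5
  for (k in 1:500000) w <- dynclamp_h_step(w, 0, p, i = 1)$w
  expect_lt(w, 2e-3)   # sigma_h(0) = 1/(1+exp(45/7)) ~ 1.6e-3
  # step-response time constant matches the configured rate
  wseq <- numeric(20000)
  w <- 0
  for (k in 1:20000) { w <- dynclamp_h_step(w, -45, p, i = 1)$w; wseq[k] <- w }
  tau_h <- stats::plogis((-45 + 110) / 13)
  rate <- 0.1 / (1000 * (tau_h + 0.1))
  fit <- stats::lm(log(0.5 - wseq[1:10000]) ~ I(1:10000))
  expect_equal(unname(stats::coef(fit)[2]), log(1 - rate), tolerance = 1e-6)
})

test_that("the generated dataset keeps exact current bookkeeping", {
  rec <- simulate_hco_dataset(3000, seed = 3)
  expect_s3_class(rec, "rmm_recording")
  for (nm in names(rec$components))
    expect_length(rec$components[[nm]], nrow(rec$v))
  expect_identical(rec$components$Iapp1,
                   rec$components$Ih1 + rec$components$Isyn12 + rec$u[, 1])
  expect_identical(rec$components$Iapp2,
                   rec$components$Ih2 + rec$components$Isyn21 + rec$u[, 2])
})

test_that("generation is deterministic given the seed", {
  r1 <- simulate_hco_dataset(2000, seed = 9)
  r2 <- simulate_hco_dataset(2000, seed = 9)
  expect_identical(r1$v, r2$v)
  expect_identical(r1$u, r2$u)
  r3 <- simulate_hco_dataset(2000, seed = 10)
  expect_false(identical(r1$v, r3$v))
})

test_that("gates remain inside their invariant boxes over long runs", {
  rec_raw <- ns$hco_simulate_cpp(
    lapply(list(surrogate_neuron(), surrogate_neuron()), ns$scale_surrogate),
    ns$unclass_clamp(dynclamp_params()),
    cbind(ns$with_seed(1, ou_series(100000, ou_params(0.03))),
          ns$with_seed(2, ou_series(100000, ou_params(0.22)))),
    0.1, c(-60, -50), c(0.01, 0.05), c(0.1, 0.1), c(0.3, 0.3), FALSE)
  expect_true(all(rec_raw$z >= 0 & rec_raw$z <= 1.1))
  expect_true(all(rec_raw$w >= 0 & rec_raw$w <= 1))
})

test_that("the circuit bursts in anti-phase and alternation needs the synapses", {
  rec <- simulate_hco_dataset(20000, seed = 2)
  cfg <- metric_config(delta = rec$delta)
  s1 <- extract_smoothed_spike_train(rec$v[, 1], cfg)
  s2 <- extract_smoothed_spike_train(rec$v[, 2], cfg)
  expect_gt(length(s1$spike_indices), 20)
  expect_gt(length(s2$spike_indices), 20)
  expect_lt(stats::cor(s1$values, s2$values), -0.1)
  # both neurons keep spiking in the second half (persistent rhythm)
  half <- nrow(rec$v) / 2
  expect_gt(sum(s1$spike_indices > half), 10)
  expect_gt(sum(s2$spike_indices > half), 10)
  # with the dynamic clamp switched off the cells are quiescent: no rhythm
  rec0 <- simulate_hco_dataset(20000, seed = 2,
                               dynclamp = dynclamp_params(g_syn_max = c(0, 0),
                                                          g_h_max = c(0, 0)))
  s10 <- extract_smoothed_spike_train(rec0$v[, 1], cfg)
  s20 <- extract_smoothed_spike_train(rec0$v[, 2], cfg)
  expect_lt(length(s10$spike_indices) + length(s20$spike_indices), 5)
})

test_that("train/validation split is contiguous and recorded", {
  rec <- simulate_hco_dataset(1000, seed = 1)
  N <- nrow(rec$v)
  sp <- make_train_val_split(rec, 0.75)
  expect_equal(nrow(sp$train$v), floor(0.75 * N))
  expect_equal(nrow(sp$validation$v), N - floor(0.75 * N))
  expect_identical(rbind(sp$train$v, sp$validation$v), rec$v)
  expect_equal(sp$train$meta$split$boundary, floor(0.75 * N))
  expect_error(make_train_val_split(rec, 1.0), "empty")
})
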