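# Step-by-step scalar oracle for constant-drive integrate-and-fire counting.
oracle_if_count <- function(drive, v_th, t_steps) {
  v <- 0
  n <- 0L
  for (t in seq_len(t_steps)) {
    v <- v + drive
    if (v >= v_th) {
      v <- v - v_th
      n <- n + 1L
    }
  }
  n
}

test_that("if_step integrates, fires and soft-resets as specified", {
  st <- if_neuron(v_th = 1)
  r <- if_step(st, 0.5 * 1 + 0.25 * 1)
  expect_equal(r$state$v_m, 0.75)
  expect_false(r$spiked)

  st2 <- if_neuron(v_th = 1, v_m = 0.9)
  r2 <- if_step(st2, 0.2)
  expect_true(r2$spiked)
  expect_equal(r2$state$v_m, 0.1)           # subtraction reset
  expect_equal(r2$state$spike_count, 1L)

  # no leak: zero input leaves the potential unchanged
  st3 <- if_neuron(v_th = 2, v_m = 0.4)
  expect_equal(if_step(st3, 0)$state$v_m, 0.4)

  # reset-to-zero variant
  st4 <- if_neuron(v_th = 1, v_m = 0.9, reset = "zero")
  expect_equal(if_step(st4, 0.3)$state$v_m, 0)

  expect_error(if_neuron(v_th = 0), "positive")
})

test_that("constant drive produces floor(c T / V_th) spikes within one", {
  for (case in list(c(0.3, 1, 1000), c(0.07, 1, 500), c(0.3, 2.5, 400),
                    c(0.949, 1, 200))) {
    drive <- case[1]; v_th <- case[2]; t_steps <- case[3]
    st <- if_neuron(v_th = v_th)
    for (t in seq_len(t_steps)) st <- if_step(st, drive)$state
    expect_equal(st$spike_count, oracle_if_count(drive, v_th, t_steps))
    expect_lte(abs(st$spike_count - floor(drive * t_steps / v_th)), 1)
  }
  # the spiking-network simulator agrees with the scalar oracle:
  # a single input always spiking through weight 0.3 into one IF neuron
  net <- structure(list(
    chain = list(list(W = matrix(0.3, 1, 1), bias_current = 0)),
    v_th = 1, r_max = 1, t_steps = 1000L,
    encoder = list(xmin = 0, range = 1),
    lambda = 1, fan_out = list(1, 0), calib_X = matrix(1, 1, 1),
    n_neurons = c(1, 1)), class = "spiking_network")
  sim <- neorespire:::snn_simulate(net, matrix(1, 1, 1), 1000L,
                                   deterministic = TRUE)
  expect_equal(sum(sim$counts[[1]]), oracle_if_count(0.3, 1, 1000))
  expect_lte(abs(sum(sim$counts[[1]]) - 300), 1)
})

test_that("membrane potential integrates spike trains through the kernel", {
  dyn <- membrane_dynamics(u0 = 0.2, spike_times = numeric(0))
  expect_equal(membrane_potential(dyn, w = 3, t = 10), 0.2)

  dyn2 <- membrane_dynamics(u0 = 0, a = 1, spike_times = c(1, 2, 3))
  expect_equal(membrane_potential(dyn2, w = 0.5, t = 5), 1.5)
  # linearity in the weight
  expect_equal(membrane_potential(dyn2, w = 1.0, t = 5), 3.0)
  # only spikes up to t contribute
  expect_equal(membrane_potential(dyn2, w = 0.5, t = 1.5), 0.5)
  # exponential kernel decays
  dyn3 <- membrane_dynamics(kernel = "exp", tau = 1, spike_times = 0)
  expect_equal(membrane_potential(dyn3, w = 1, t = 2), exp(-2))
})

test_that("rate encoding matches binomial moments and has a deterministic mode", {
  expect_equal(sum(rate_encode(0, 1000, xmin = 0, range = 1)), 0)

  counts <- vapply(1:60, function(s) {
    sum(rate_encode(0.5, 1000, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 500), 3 * 15.8 / sqrt(60))
  expect_lt(abs(stats::sd(counts) - 15.8), 6)

  # deterministic mode: exact evenly spaced count, seed-independent
  d1 <- rate_encode(0.5, 1000, seed = 1, deterministic = TRUE)
  d2 <- rate_encode(0.5, 1000, seed = 99, deterministic = TRUE)
  expect_identical(d1, d2)
  expect_equal(sum(d1), 500)
  expect_equal(sum(rate_encode(0.25, 1000, deterministic = TRUE)), 250)

  # affine calibration clips outside the calibrated range
  expect_equal(sum(rate_encode(-3, 100, xmin = -1, range = 2)), 0)
  expect_equal(sum(rate_encode(5, 100, xmin = -1, range = 2,
                               deterministic = TRUE)), 100)
  expect_error(rate_encode(0.5, 0), ">= 1")
  expect_error(isi_encode(1), "not implemented")
})

test_that("conversion preserves topology and zero-weight nets stay silent", {
  m <- build_mlp(c(2, 7, 3, 1), seed = 2)
  set.seed(3)
  calib <- matrix(rnorm(100), ncol = 2)
  net <- convert_to_snn(m, calib, t_steps = 50)
  expect_equal(net$n_neurons, c(2, 7, 3, 1))
  chain <- as_dense_chain(m)
  for (i in seq_along(chain)) {
    expect_equal(dim(net$chain[[i]]$W), dim(chain[[i]]$W))
  }

  # dead (all-zero) model: conversion refuses
  m0 <- m
  for (i in seq_along(m0$layers)) {
    m0$layers[[i]]$W <- m0$layers[[i]]$W * 0
    m0$layers[[i]]$b <- m0$layers[[i]]$b * 0
  }
  expect_error(convert_to_snn(m0, calib), "dead layer")

  # zero weights but live biases: no synaptic spikes from the input
  m$layers[[1]]$W <- m$layers[[1]]$W * 0
  m$layers[[1]]$b <- abs(m$layers[[1]]$b) + 0.1
  net2 <- convert_to_snn(m, calib, t_steps = 50)
  res_a <- snn_infer(net2, calib[1:5, ], t_steps = 50, seed = 1)
  res_b <- snn_infer(net2, calib[6:10, ], t_steps = 50, seed = 2)
  # input-independent: identical hidden rates for different inputs
  expect_equal(res_a$hidden_rates[[1]][1, ], res_b$hidden_rates[[1]][1, ])
})

test_that("hidden firing rates track normalized ReLU activations", {
  m <- build_mlp(c(2, 16, 1), seed = 7)
  set.seed(42)
  X <- matrix(rnorm(120), ncol = 2)
  net <- convert_to_snn(m, X, t_steps = 2000)
  res <- snn_infer(net, X, t_steps = 2000, seed = 9)
  ann <- neorespire:::chain_forward(as_dense_chain(m), X)
  target <- ann$activations[[1]] / net$lambda[1]
  expect_gt(stats::cor(as.vector(target), as.vector(res$hidden_rates[[1]])),
            0.99)
})

test_that("deterministic encoding gives bit-identical records and conserved routing", {
  m <- build_mlp(c(2, 5, 1), seed = 4)
  set.seed(5)
  X <- matrix(rnorm(40), ncol = 2)
  net <- convert_to_snn(m, X, t_steps = 100)
  r1 <- snn_infer(net, X, t_steps = 100, seed = 3, deterministic = TRUE)
  r2 <- snn_infer(net, X, t_steps = 100, seed = 8, deterministic = TRUE)
  expect_identical(r1$spike_record$per_neuron, r2$spike_record$per_neuron)

  rec <- r1$spike_record
  expect_equal(rec$routing_events,
               sum(mapply(function(cnt, fo) sum(cnt * fo),
                          rec$per_neuron, rec$fan_out)))
  expect_equal(rec$total_spikes, sum(unlist(rec$per_neuron)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_record_csv(rec, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("neuron_id", "spike_count"))
  expect_equal(sum(back$spike_count), rec$total_spikes)
})

test_that("threshold sweep shapes its matrix and degrades to the majority class", {
  sp <- make_split(duration = 240, sim_seed = 21, split_seed = 22)
  fit <- train_network(build_1dcnn(seed = 2), sp$train, NULL,
                       train_config(max_epochs = 25, seed = 23))
  net <- convert_to_snn(fit$model, sp$train$X, t_steps = 60)

  sets <- list("30" = as_windowed(sp$test$X[1:30, ], sp$test$y[1:30]),
               "60" = as_windowed(sp$test$X[1:60, ], sp$test$y[1:60]))
  sw <- threshold_sweep(net, sets, v_th_grid = c(1, 2, 40), t_steps = 60,
                        seed = 31)
  expect_equal(dim(sw$accuracy), c(3L, 2L))
  expect_equal(dim(sw$spikes), c(3L, 2L))

  # V_th -> infinity: no spikes anywhere, prediction collapses to one class,
  # accuracy equals that class's prevalence in the evaluation set
  big <- snn_infer(net, sp$test$X, t_steps = 60, seed = 5, v_th = 1e6)
  expect_equal(big$spike_record$total_spikes,
               sum(big$spike_record$per_neuron[[1]]) +
                 sum(big$spike_record$per_neuron[[length(big$spike_record$per_neuron)]]))
  expect_equal(mean(big$labels == sp$test$y), mean(sp$test$y == 1))
})
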