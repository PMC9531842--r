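#' Dense-chain view of a network
#'
#' Collapses the computational graph to an equivalent chain of dense layers:
#' the kernel-1 convolution becomes a structured (weight-tied) matrix over
#' the flattened feature map, identity pooling/flatten/dropout disappear.
#' Used by the spiking conversion, which stores per-synapse weights.
#'
#' @param model A `network_model`.
#' @return List of layers, each `list(W, b, activation)`.
#' @export
as_dense_chain <- function(model) {
  stopifnot(inherits(model, "network_model"))
  chain <- list()
  for (l in model$layers) {
    if (l$kind == "conv1d") {
      Fn <- length(l$w)
      W <- matrix(0, l$positions, l$positions * Fn)
      for (p in seq_len(l$positions)) {
        W[p, ((p - 1L) * Fn + 1L):(p * Fn)] <- l$w
      }
      chain[[length(chain) + 1L]] <- list(W = W, b = rep(l$b, l$positions),
                                          activation = l$activation)
    } else if (l$kind == "dense") {
      chain[[length(chain) + 1L]] <- list(W = l$W, b = l$b,
                                          activation = l$activation)
    }
  }
  chain
}

# ANN forward over a dense chain; returns post-activation outputs per layer
# plus the final pre-activation (used for output-layer calibration).
chain_forward <- function(chain, X) {
  A <- as.matrix(X)
  acts <- vector("list", length(chain))
  z_last <- NULL
  for (i in seq_along(chain)) {
    Z <- sweep(A %*% chain[[i]]$W, 2, chain[[i]]$b, "+")
    z_last <- Z
    A <- apply_activation(Z, chain[[i]]$activation)
    acts[[i]] <- A
  }
  list(activations = acts, z_out = z_last)
}

#' Convert a trained network to a rate-coded spiking network
#'
#' Every hidden ReLU unit becomes an integrate-and-fire (IF) neuron with
#' soft (subtract) reset; each layer's biases arrive as weighted spikes from
#' an always-on auxiliary neuron chain (rate `1/v_th^l` at level `l`), so
#' bias and synaptic drive attenuate identically when the threshold is swept;
#' weights are rescaled by data-based normalization so that, at threshold 1,
#' each neuron's firing rate approximates its normalized ReLU activation.
#' The per-layer normalizer `lambda` is the maximum activation observed on
#' the calibration batch. Standardized inputs are rate-encoded through an
#' affine map of the calibrated input range onto `[0, 1]`, with the offset
#' absorbed into the first layer's bias currents; the signed output
#' pre-activation is treated the same way (calibrated range mapped onto
#' `[0, 1]` via the output bias current), which centres the half-maximum-rate
#' decision rule on the midpoint of the calibrated score range.
#'
#' @param model A trained `network_model` with ReLU hidden layers.
#' @param calib_X Calibration input matrix (standardized features, e.g. the
#'   training partition).
#' @param v_th Firing threshold (dimensionless; applied to every IF neuron).
#' @param r_max Maximum input spike probability per step.
#' @param t_steps Default simulation horizon in steps.
#' @param max_calib Rows of `calib_X` retained for decision-threshold
#'   calibration at inference time.
#' @return A `spiking_network`.
#' @export
convert_to_snn <- function(model, calib_X, v_th = 1, r_max = 1,
                           t_steps = 1000L, max_calib = 100L) {
  stopifnot(inherits(model, "network_model"))
  if (v_th <= 0) stop("`v_th` must be positive", call. = FALSE)
  calib_X <- as.matrix(calib_X)
  chain <- as_dense_chain(model)
  cf <- chain_forward(chain, calib_X)
  L <- length(chain)

  lambda <- numeric(L)
  for (i in seq_len(L - 1L)) lambda[i] <- max(cf$activations[[i]])
  # the signed output pre-activation is mapped affinely onto [0, 1] via the
  # symmetric calibrated range [-max|z|, +max|z|], mirroring the input
  # encoder; the ANN decision boundary z = 0 then sits at rate 1/2, which is
  # what the half-maximum-rate decoding compares against
  z_min <- -max(abs(cf$z_out))
  lambda[L] <- 2 * max(abs(cf$z_out))
  if (any(lambda <= 0)) {
    stop("dead layer: zero maximum calibration activation in layer ",
         paste(which(lambda <= 0), collapse = ", "), call. = FALSE)
  }

  xmin <- apply(calib_X, 2, min)
  xmax <- apply(calib_X, 2, max)
  range <- xmax - xmin
  if (any(range <= 0)) stop("degenerate calibration input range", call. = FALSE)

  snn_chain <- vector("list", L)
  for (i in seq_len(L)) {
    W <- chain[[i]]$W
    b <- chain[[i]]$b
    if (i == 1L) {
      Ws <- W * (range / r_max) / lambda[1]
      bs <- (b + drop(xmin %*% W)) / lambda[1]
    } else if (i == L) {
      Ws <- W * lambda[i - 1L] / lambda[i]
      bs <- (b - z_min) / lambda[i]
    } else {
      Ws <- W * lambda[i - 1L] / lambda[i]
      bs <- b / lambda[i]
    }
    snn_chain[[i]] <- list(W = Ws, bias_current = bs)
  }

  fan_out <- vector("list", L + 1L)
  fan_out[[1]] <- rowSums(chain[[1]]$W != 0)            # input encoder neurons
  for (i in seq_len(L - 1L)) fan_out[[i + 1L]] <- rowSums(chain[[i + 1L]]$W != 0)
  fan_out[[L + 1L]] <- rep(0, ncol(chain[[L]]$W))       # output neurons

  keep <- seq_len(min(nrow(calib_X), max_calib))
  structure(
    list(chain = snn_chain, v_th = v_th, r_max = r_max, t_steps = as.integer(t_steps),
         encoder = list(xmin = xmin, range = range),
         lambda = lambda, fan_out = fan_out,
         calib_X = calib_X[keep, , drop = FALSE],
         n_neurons = c(ncol(calib_X), vapply(snn_chain, function(l) ncol(l$W), numeric(1)))),
    class = "spiking_network"
  )
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("spiking_network: IF neurons per layer [",
      paste(x$n_neurons, collapse = ", "), "], v_th =", x$v_th,
      ", T =", x$t_steps, "\n")
  invisible(x)
}

#' Integrate-and-fire neuron state and one synchronous step
#'
#' `if_neuron()` creates the state; `if_step()` adds the weighted synaptic
#' input and bias current to the membrane potential and, if it reaches the
#' threshold, emits a spike and applies the configured reset (soft reset
#' subtracts the threshold; `"zero"` resets to 0). A pure IF neuron has no
#' leak: with zero input the potential is unchanged.
#'
#' @param v_th Firing threshold (> 0).
#' @param bias_current Constant per-step input current.
#' @param v_m Initial membrane potential.
#' @param reset `"subtract"` (soft reset, default) or `"zero"`.
#' @return `if_neuron()`: an `if_neuron` state list; `if_step()`: list with
#'   the updated `state` and logical `spiked`.
#' @examples
#' st <- if_neuron(v_th = 1)
#' if_step(st, weighted_input = 0.75)
#' @export
if_neuron <- function(v_th = 1, bias_current = 0, v_m = 0,
                      reset = c("subtract", "zero")) {
  if (v_th <= 0) stop("`v_th` must be positive", call. = FALSE)
  structure(list(v_m = v_m, v_th = v_th, bias_current = bias_current,
                 spike_count = 0L, reset = match.arg(reset)),
            class = "if_neuron")
}

#' @rdname if_neuron
#' @param state An `if_neuron` state.
#' @param weighted_input Sum of weighted presynaptic activations this step.
#' @export
if_step <- function(state, weighted_input = 0) {
  stopifnot(inherits(state, "if_neuron"))
  state$v_m <- state$v_m + weighted_input + state$bias_current
  spiked <- state$v_m >= state$v_th
  if (spiked) {
    state$v_m <- if (state$reset == "subtract") state$v_m - state$v_th else 0
    state$spike_count <- state$spike_count + 1L
  }
  list(state = state, spiked = spiked)
}

#' Membrane potential driven by a spike train through a linear filter
#'
#' `u(t) = u0 + a * sum_i D(t - t_i) * w` over spikes `t_i <= t`, where the
#' spike train is a sum of Dirac deltas. The default delta kernel models the
#' no-leak IF neuron (each spike deposits `a * w`); an exponential kernel
#' `exp(-s / tau)` adds leak.
#'
#' @param u0 Initial potential.
#' @param a Positive gain constant.
#' @param kernel `"delta"` or `"exp"`.
#' @param tau Time constant of the exponential kernel.
#' @param spike_times Numeric vector of input spike times.
#' @return `membrane_dynamics()`: a configuration list;
#'   `membrane_potential()`: the potential at time `t`.
#' @examples
#' dyn <- membrane_dynamics(spike_times = c(1, 2, 3))
#' membrane_potential(dyn, w = 0.5, t = 5)  # 1.5
#' @export
membrane_dynamics <- function(u0 = 0, a = 1, kernel = c("delta", "exp"),
                              tau = 1, spike_times = numeric(0)) {
  structure(list(u0 = u0, a = a, kernel = match.arg(kernel), tau = tau,
                 spike_times = sort(spike_times)),
            class = "membrane_dynamics")
}

#' @rdname membrane_dynamics
#' @param dyn A `membrane_dynamics` object.
#' @param w Synaptic weight.
#' @param t Evaluation time.
#' @export
membrane_potential <- function(dyn, w, t) {
  stopifnot(inherits(dyn, "membrane_dynamics"))
  ti <- dyn$spike_times[dyn$spike_times <= t]
  if (length(ti) == 0) return(dyn$u0)
  contrib <- switch(dyn$kernel,
                    delta = rep(1, length(ti)),
                    exp = exp(-(t - ti) / dyn$tau))
  dyn$u0 + dyn$a * w * sum(contrib)
}

#' Rate-encode an input vector into spike trains
#'
#' Maps each input through the affine calibration `g(x) = (x - xmin)/range`,
#' clips to `[0, 1]`, scales by `r_max`, and emits either Bernoulli spike
#' trains at that per-step probability or (deterministic mode) evenly spaced
#' spikes at the same rate.
#'
#' @param x Numeric input vector.
#' @param t_steps Number of simulation steps (>= 1).
#' @param r_max Maximum per-step spike probability.
#' @param seed Seed for the Bernoulli draws.
#' @param xmin,range Affine calibration of the input range.
#' @param deterministic Evenly spaced, seed-independent spikes.
#' @return Binary matrix `t_steps` x `length(x)`.
#' @export
rate_encode <- function(x, t_steps, r_max = 1, seed = 1L, xmin = 0, range = 1,
                        deterministic = FALSE) {
  if (t_steps < 1) stop("`t_steps` must be >= 1", call. = FALSE)
  p <- pmin(pmax((x - xmin) / range, 0), 1) * r_max
  if (deterministic) {
    steps <- seq_len(t_steps)
    S <- vapply(p, function(pi) {
      diff(floor(c(0, steps * pi)))
    }, numeric(t_steps))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    S <- matrix(stats::runif(t_steps * length(p)), t_steps) <
      matrix(p, t_steps, length(p), byrow = TRUE)
  }
  matrix(as.numeric(S), t_steps, length(p))
}

#' Inter-spike-interval encoder (not implemented)
#'
#' ISI encoding represents an activation by the gap between consecutive
#' spikes rather than their count. Only rate coding is supported; this stub
#' documents the interface and always errors.
#'
#' @param ... Ignored.
#' @export
isi_encode <- function(...) {
  stop("ISI encoding is not implemented; use rate_encode()", call. = FALSE)
}

# Deterministic spike trains of the bias (auxiliary) neuron chain: aux_0
# fires every step; aux_l is an IF neuron driven by aux_{l-1} with unit
# weight, so its rate is 1/v_th^l. Layer l draws its bias spikes from
# aux_{l-1}, which keeps bias and synaptic drive attenuating identically as
# the threshold grows.
aux_spike_trains <- function(t_steps, n_levels, v_th) {
  A <- matrix(0, t_steps, n_levels)
  A[, 1] <- 1
  if (n_levels > 1) {
    v <- numeric(n_levels - 1)
    for (t in seq_len(t_steps)) {
      for (l in seq_len(n_levels - 1)) {
        v[l] <- v[l] + A[t, l]
        if (v[l] >= v_th) {
          A[t, l + 1] <- 1
          v[l] <- v[l] - v_th
        }
      }
    }
  }
  A
}

# Core synchronous simulation, vectorized over samples.
# Returns per-layer spike-count matrices (n x m), input and bias-neuron
# spike counts and output rates.
snn_simulate <- function(net, X, t_steps, seed = 1L, v_th = net$v_th,
                         deterministic = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  L <- length(net$chain)
  P <- pmin(pmax(sweep(sweep(X, 2, net$encoder$xmin), 2, net$encoder$range, "/"),
                 0), 1) * net$r_max

  V <- lapply(net$chain, function(l) matrix(0, n, ncol(l$W)))
  counts <- lapply(net$chain, function(l) matrix(0, n, ncol(l$W)))
  in_counts <- matrix(0, n, ncol(X))
  aux <- aux_spike_trains(t_steps, L, v_th)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  for (t in seq_len(t_steps)) {
    if (deterministic) {
      S <- floor(t * P) - floor((t - 1) * P)
    } else {
      S <- (matrix(stats::runif(n * ncol(P)), n) < P) * 1
    }
    in_counts <- in_counts + S
    for (i in seq_len(L)) {
      drive <- S %*% net$chain[[i]]$W
      if (aux[t, i] > 0) {
        drive <- sweep(drive, 2, net$chain[[i]]$bias_current, "+")
      }
      V[[i]] <- V[[i]] + drive
      S <- (V[[i]] >= v_th) * 1
      V[[i]] <- V[[i]] - v_th * S
      counts[[i]] <- counts[[i]] + S
    }
  }
  list(counts = counts, in_counts = in_counts, aux_counts = colSums(aux),
       out_rates = drop(counts[[L]]) / t_steps)
}

#' Spiking-network inference by spike-count decoding
#'
#' Simulates `t_steps` synchronous steps of the converted network for every
#' input row. Hidden-layer firing rates approximate the normalized ReLU
#' activations of the source network. The binary label is decoded from the
#' output spike rate: 1 (breathing) when the rate reaches half the maximum
#' output rate observed on the stored calibration batch simulated under the
#' same threshold and horizon.
#'
#' @param net A `spiking_network`.
#' @param X Input matrix (standardized features).
#' @param t_steps Simulation horizon (defaults to the network's setting).
#' @param seed Seed for the stochastic input encoder.
#' @param v_th Firing threshold override (the sweep uses this).
#' @param deterministic Use the deterministic evenly spaced encoder.
#' @return List with `labels`, `output_rates`, `decision_rate`,
#'   `hidden_rates` (per-layer n x m matrices) and a `spike_record`.
#' @export
snn_infer <- function(net, X, t_steps = net$t_steps, seed = 1L,
                      v_th = net$v_th, deterministic = FALSE) {
  stopifnot(inherits(net, "spiking_network"))
  if (t_steps < 1) stop("`t_steps` must be >= 1", call. = FALSE)

  calib <- snn_simulate(net, net$calib_X, t_steps,
                        seed = (seed + 999983L) %% .Machine$integer.max,
                        v_th = v_th, deterministic = deterministic)
  decision_rate <- 0.5 * max(calib$out_rates)

  sim <- snn_simulate(net, X, t_steps, seed = seed, v_th = v_th,
                      deterministic = deterministic)
  L <- length(net$chain)
  rates <- lapply(sim$counts, function(cc) cc / t_steps)

  # bias (aux) neurons: level i feeds the biases of layer i (n_i synapses)
  # and, below the last level, the next aux neuron; their trains are shared
  # across the batch, so counts scale with the number of samples
  n_batch <- nrow(as.matrix(X))
  aux_fan <- vapply(seq_len(L), function(i) {
    net$n_neurons[i + 1L] + as.numeric(i < L)
  }, numeric(1))
  per_neuron <- c(list(colSums(sim$in_counts)),
                  lapply(sim$counts, colSums),
                  list(sim$aux_counts * n_batch))
  record <- new_spike_record(per_neuron, c(net$fan_out, list(aux_fan)),
                             n_batch, t_steps)

  list(labels = as.integer(sim$out_rates >= decision_rate),
       output_rates = sim$out_rates,
       decision_rate = decision_rate,
       hidden_rates = rates[-L],
       spike_record = record)
}

new_spike_record <- function(per_neuron, fan_out, n_samples, t_steps) {
  routing <- sum(mapply(function(cnt, fo) sum(cnt * fo), per_neuron, fan_out))
  structure(list(per_neuron = per_neuron, fan_out = fan_out,
                 total_spikes = sum(unlist(per_neuron)),
                 routing_events = routing,
                 n_samples = n_samples, t_steps = t_steps),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike_record: %d samples x %d steps; %s spikes, %s routing events\n",
              x$n_samples, x$t_steps, format(x$total_spikes, big.mark = ","),
              format(x$routing_events, big.mark = ",")))
  invisible(x)
}

#' Export per-neuron spike counts as CSV
#'
#' @param record A `spike_record`.
#' @param path Output path; header `neuron_id,spike_count`.
#' @return `path`, invisibly.
#' @export
write_spike_record_csv <- function(record, path) {
  stopifnot(inherits(record, "spike_record"))
  counts <- unlist(record$per_neuron)
  utils::write.csv(data.frame(neuron_id = seq_along(counts) - 1L,
                              spike_count = as.integer(round(counts))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Accuracy/energy design-space sweep over the firing threshold
#'
#' Evaluates top-1 accuracy and total spike counts for every combination of
#' firing threshold and evaluation set. The decision rate is recalibrated at
#' each threshold, so very large thresholds (where no calibration spikes
#' survive) degrade predictions toward a single class.
#'
#' @param net A `spiking_network`.
#' @param eval_sets Named list of `windowed_dataset`s (names typically the
#'   sample sizes).
#' @param v_th_grid Numeric vector of thresholds (default 1..10).
#' @param t_steps Simulation horizon per window.
#' @param seed Base seed; each cell uses a derived seed.
#' @return A `threshold_sweep` result: `accuracy` and `spikes` matrices
#'   (thresholds x sets).
#' @export
threshold_sweep <- function(net, eval_sets, v_th_grid = 1:10, t_steps = 100L,
                            seed = 1L) {
  stopifnot(inherits(net, "spiking_network"))
  if (length(v_th_grid) == 0) stop("`v_th_grid` must be non-empty", call. = FALSE)
  if (is.null(names(eval_sets))) {
    names(eval_sets) <- vapply(eval_sets, function(d) as.character(nrow(d$X)), "")
  }
  acc <- matrix(NA_real_, length(v_th_grid), length(eval_sets),
                dimnames = list(v_th = v_th_grid, set = names(eval_sets)))
  spikes <- acc
  for (i in seq_along(v_th_grid)) {
    for (j in seq_along(eval_sets)) {
      ds <- eval_sets[[j]]
      res <- snn_infer(net, ds$X, t_steps = t_steps,
                       seed = (seed + 7919L * i + j) %% .Machine$integer.max,
                       v_th = v_th_grid[i])
      acc[i, j] <- mean(res$labels == ds$y)
      spikes[i, j] <- res$spike_record$total_spikes
    }
  }
  structure(list(accuracy = acc, spikes = spikes, v_th_grid = v_th_grid,
                 t_steps = t_steps),
            class = "threshold_sweep")
}

#' Accuracy/energy design-space exploration with fresh evaluation draws
#'
#' Convenience wrapper over [threshold_sweep()] that, for every
#' (threshold, sample size) cell, draws a fresh evaluation batch of the
#' requested size from `source` (with replacement) under a derived seed —
#' so small-sample cells carry the sampling variability a small test batch
#' really has — and evaluates the spiking network on it.
#'
#' @param net A `spiking_network`.
#' @param source A `windowed_dataset` to draw evaluation batches from
#'   (typically the test partition).
#' @param sizes Integer vector of evaluation sample sizes.
#' @param v_th_grid Thresholds to sweep.
#' @param t_steps Simulation horizon per window.
#' @param seed Base seed.
#' @return A `threshold_sweep` result.
#' @export
sweep_design_space <- function(net, source, sizes, v_th_grid = 1:10,
                               t_steps = 100L, seed = 1L) {
  stopifnot(inherits(net, "spiking_network"), inherits(source, "windowed_dataset"))
  acc <- matrix(NA_real_, length(v_th_grid), length(sizes),
                dimnames = list(v_th = v_th_grid, set = sizes))
  spikes <- acc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_along(v_th_grid)) {
    for (j in seq_along(sizes)) {
      cell_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      set.seed(cell_seed)
      idx <- sample.int(nrow(source$X), sizes[j], replace = TRUE)
      res <- snn_infer(net, source$X[idx, , drop = FALSE], t_steps = t_steps,
                       seed = cell_seed, v_th = v_th_grid[i])
      acc[i, j] <- mean(res$labels == source$y[idx])
      spikes[i, j] <- res$spike_record$total_spikes
    }
  }
  structure(list(accuracy = acc, spikes = spikes, v_th_grid = v_th_grid,
                 t_steps = t_steps),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Threshold sweep (T =", x$t_steps, "steps): accuracy\n")
  print(round(x$accuracy, 4))
  invisible(x)
}
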