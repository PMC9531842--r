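# Shared fixtures, built in code at test time.

# Small labelled dataset from the full simulate -> featurize path.
make_split <- function(duration = 300, sim_seed = 1L, split_seed = 2L,
                       cfg = rfid_config()) {
  tl <- generate_protocol(breathing_protocol(total_duration = duration))
  st <- simulate_interrogations(tl, cfg, seed = sim_seed)
  f <- compute_features(st)
  w <- suppressWarnings(build_windows(f, tl))
  c(clean_and_split(w, seed = split_seed), list(timeline = tl, windows = w))
}

# Linearly separable two-feature dataset (no simulation involved).
make_separable <- function(n = 120, seed = 5L, margin = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(2 * n, sd = 0.3), ncol = 2)
  X[, 1] <- X[, 1] + ifelse(y == 1, margin, -margin) / 2
  neorespire:::new_windowed_dataset(X, y, seq_len(n) - 1, 1)
}

as_windowed <- function(X, y) {
  neorespire:::new_windowed_dataset(as.matrix(X), y, seq_len(length(y)) - 1, 1)
}
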