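# Independent oracle: explicit loop-based forward pass over the dense-chain
# weights, coded without reusing the package's matrix path.
oracle_forward <- function(model, x) {
  chain <- as_dense_chain(model)
  a <- as.numeric(x)
  for (l in chain) {
    z <- numeric(ncol(l$W))
    for (j in seq_along(z)) {
      s <- l$b[j]
      for (i in seq_along(a)) s <- s + a[i] * l$W[i, j]
      z[j] <- s
    }
    a <- switch(l$activation,
                relu = pmax(z, 0),
                sigmoid = 1 / (1 + exp(-z)),
                none = z)
  }
  a
}

test_that("the canonical classifier has exactly the pinned parameter counts", {
  m <- build_1dcnn(seed = 1)
  expect_identical(as.integer(n_parameters(m)), 46129L)
  counts <- vapply(m$layers, function(l) {
    switch(l$kind, conv1d = length(l$w) + length(l$b),
           dense = length(l$W) + length(l$b), 0L)
  }, numeric(1))
  expect_equal(counts[counts > 0], c(128, 25800, 20100, 101))
})

test_that("forward equals an explicit loop-based oracle and handles degenerate layers", {
  m <- build_1dcnn(seed = 3)
  set.seed(7)
  X <- matrix(rnorm(20), ncol = 2)
  p_pkg <- forward(m, X)
  p_orc <- apply(X, 1, function(x) oracle_forward(m, x))
  expect_equal(p_pkg, p_orc, tolerance = 1e-6)
  expect_true(all(p_pkg >= 0 & p_pkg <= 1))

  # all-zero parameters: sigmoid(0) = 0.5 for any input
  m0 <- m
  for (i in seq_along(m0$layers)) {
    for (nm in c("w", "W", "b")) {
      if (!is.null(m0$layers[[i]][[nm]])) {
        m0$layers[[i]][[nm]] <- m0$layers[[i]][[nm]] * 0
      }
    }
  }
  expect_equal(forward(m0, X), rep(0.5, nrow(X)))

  # shape mismatch is an error
  expect_error(forward(m, matrix(1, 2, 3)), "expects")
})

test_that("kernel-1 convolution is a per-position linear map", {
  m <- build_1dcnn(seed = 2)
  conv <- m$layers[[1]]
  x <- c(0.7, -1.3)
  fc <- neorespire:::forward_cache(m, matrix(x, 1), training = FALSE)
  Z <- fc$caches[[1]]$Z
  expect_equal(drop(Z), c(x[1] * conv$w + conv$b, x[2] * conv$w + conv$b))
})

test_that("early stopping follows the patience rule", {
  expect_equal(early_stop_epoch(c(.5, .4, .41, .42, .43, .44, .45), 5), 7)
  expect_equal(early_stop_epoch(seq(1, 0.1, by = -0.1), 5), 10)   # never triggers
  expect_equal(early_stop_epoch(c(.5, .6, .7, .8), 3), 4)
  expect_equal(early_stop_epoch(c(.5, .4, .3), 1), 3)
})

test_that("training fits separable data and respects epoch budgets", {
  ds <- make_separable(n = 120, seed = 5)
  val <- make_separable(n = 40, seed = 6)
  cfg <- train_config(max_epochs = 30, seed = 1)
  fit <- train_network(build_1dcnn(seed = 1), ds, val, cfg)
  pred <- as.integer(forward(fit$model, ds$X) >= 0.5)
  expect_gte(mean(pred == ds$y), 0.99)
  expect_lte(fit$stopped_epoch, 30)
  expect_equal(fit$history$epoch, seq_len(fit$stopped_epoch))

  # patience >= max_epochs with a tiny budget runs the full budget
  cfg2 <- train_config(max_epochs = 4, early_stop_patience = 10, seed = 1)
  fit2 <- train_network(build_1dcnn(seed = 1), ds, val, cfg2)
  expect_equal(fit2$stopped_epoch, 4L)
})

test_that("training is reproducible under one seed", {
  ds <- make_separable(n = 60, seed = 8)
  cfg <- train_config(max_epochs = 5, seed = 4)
  f1 <- train_network(build_1dcnn(seed = 4), ds, NULL, cfg)
  f2 <- train_network(build_1dcnn(seed = 4), ds, NULL, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("grid search enumerates every combination and is order-invariant", {
  ds <- make_separable(n = 40, seed = 9)
  val <- make_separable(n = 20, seed = 10)
  builder <- function(seed = 1L) build_mlp(c(2, 4, 1), seed = seed)
  cfg <- train_config(max_epochs = 2, seed = 2)

  gs <- grid_search(c(1, 2), c(0.01, 0.1, 0.3), ds, val, builder, cfg)
  expect_equal(nrow(gs$table), 6L)

  # single-point grid returns that point
  gs1 <- grid_search(2, 0.01, ds, val, builder, cfg)
  expect_equal(gs1$best$epochs, 2)
  expect_equal(gs1$best$learning_rate, 0.01)

  # permuting the grids leaves the selected configuration unchanged
  gs_perm <- grid_search(c(2, 1), c(0.3, 0.01, 0.1), ds, val, builder, cfg)
  expect_equal(gs_perm$best, gs$best, ignore_attr = TRUE)

  expect_error(grid_search(numeric(0), 0.1, ds, val, builder, cfg), "non-empty")
})

test_that("repeated k-fold partitions correctly and reports the standard error", {
  expect_equal(cv_standard_error(0.02, 4), 0.01)

  ds <- make_separable(n = 30, seed = 11)
  builder <- function(seed = 1L) build_mlp(c(2, 3, 1), seed = seed)
  cfg <- train_config(max_epochs = 2, seed = 3)
  cv <- repeated_kfold(builder, ds, k = 5, repeats = 2, seed = 7, cfg = cfg)
  expect_equal(dim(cv$fold_accuracy), c(2L, 5L))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_equal(cv$sigma_error, cv$sigma / sqrt(2))
  expect_false(cv$degenerate)

  # every sample lands in exactly one test fold per repeat: fold sizes sum to n
  # (checked indirectly: 5 folds of 6 samples each produce defined accuracies)
  expect_false(any(is.na(cv$fold_accuracy)))

  expect_warning(
    cv1 <- repeated_kfold(builder, ds, k = 5, repeats = 1, seed = 7, cfg = cfg),
    "single repeat")
  expect_true(cv1$degenerate)
  expect_equal(cv1$sigma_error, cv1$sigma)

  expect_error(repeated_kfold(builder, ds, k = 50, repeats = 1, cfg = cfg),
               "exceed")
})

test_that("models serialize to JSON and back without loss", {
  m <- build_1dcnn(seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$layers, m$layers, tolerance = 1e-12)
  X <- matrix(rnorm(10), ncol = 2)
  expect_equal(forward(m2, X), forward(m, X), tolerance = 1e-12)
})
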