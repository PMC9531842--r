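#' Construct the canonical 1-D convolutional respiratory classifier
#'
#' The network takes the two standardized window features as a length-2,
#' single-channel sequence and applies: Conv1D (64 filters, kernel size 1,
#' ReLU) -> MaxPool1D (pool 1, stride 1; identity) -> Flatten -> Dropout
#' (rate 0.01) -> Dense 200 (ReLU) -> Dense 100 (ReLU) -> Dense 1 (sigmoid),
#' for 46,129 trainable parameters in total. The single sigmoid output unit
#' is thresholded at 0.5 to predict breathing (1) versus apnea (0).
#'
#' Weights are initialized Glorot-uniform under `seed`.
#'
#' @param seed Integer seed for weight initialization.
#' @param input_len Input sequence length (2 window features).
#' @param n_filters Convolution filters.
#' @param hidden Sizes of the two fully connected hidden layers.
#' @param dropout_rate Dropout rate applied to the flattened feature map
#'   during training.
#' @return An object of class `network_model`.
#' @examples
#' m <- build_1dcnn(seed = 1)
#' n_parameters(m)  # 46129
#' @export
build_1dcnn <- function(seed = 1L, input_len = 2L, n_filters = 64L,
                        hidden = c(200L, 100L), dropout_rate = 0.01) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  flat <- input_len * n_filters
  layers <- list(
    list(kind = "conv1d", w = glorot(1L, n_filters, n = n_filters),
         b = numeric(n_filters), positions = input_len, activation = "relu"),
    list(kind = "maxpool1d", pool = 1L, stride = 1L),
    list(kind = "flatten"),
    list(kind = "dropout", rate = dropout_rate),
    list(kind = "dense", W = glorot(flat, hidden[1]), b = numeric(hidden[1]),
         activation = "relu"),
    list(kind = "dense", W = glorot(hidden[1], hidden[2]),
         b = numeric(hidden[2]), activation = "relu"),
    list(kind = "dense", W = glorot(hidden[2], 1L), b = numeric(1),
         activation = "sigmoid")
  )
  new_network_model(layers, input_len)
}

# Glorot-uniform init; for conv1d `n` overrides the matrix layout.
glorot <- function(fan_in, fan_out, n = NULL) {
  limit <- sqrt(6 / (fan_in + fan_out))
  if (is.null(n)) {
    matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
  } else {
    stats::runif(n, -limit, limit)
  }
}

new_network_model <- function(layers, input_len) {
  structure(list(layers = layers, input_len = as.integer(input_len)),
            class = "network_model")
}

#' Construct a plain multilayer perceptron
#'
#' Dense ReLU chain used for conversion experiments and property checks; the
#' final layer activation is configurable.
#'
#' @param sizes Integer vector of layer widths, input first, output last.
#' @param seed Seed for Glorot-uniform initialization.
#' @param out_activation Activation of the output layer.
#' @return A `network_model`.
#' @export
build_mlp <- function(sizes, seed = 1L,
                      out_activation = c("sigmoid", "relu", "none")) {
  out_activation <- match.arg(out_activation)
  stopifnot(length(sizes) >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
    act <- if (i == length(sizes) - 1L) out_activation else "relu"
    list(kind = "dense", W = glorot(sizes[i], sizes[i + 1]),
         b = numeric(sizes[i + 1]), activation = act)
  })
  new_network_model(layers, sizes[1])
}

#' Trainable parameter count of a network
#' @param model A `network_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "network_model"))
  sum(vapply(model$layers, function(l) {
    switch(l$kind,
           conv1d = length(l$w) + length(l$b),
           dense = length(l$W) + length(l$b),
           0L)
  }, numeric(1)))
}

#' @export
print.network_model <- function(x, ...) {
  cat("network_model (", n_parameters(x), " parameters)\n", sep = "")
  for (l in x$layers) {
    desc <- switch(l$kind,
      conv1d = sprintf("conv1d(filters=%d, kernel=1, %s)", length(l$w), l$activation),
      maxpool1d = sprintf("maxpool1d(pool=%d, stride=%d)", l$pool, l$stride),
      flatten = "flatten",
      dropout = sprintf("dropout(rate=%g)", l$rate),
      dense = sprintf("dense(%d -> %d, %s)", nrow(l$W), ncol(l$W), l$activation))
    cat("  -", desc, "\n")
  }
  invisible(x)
}

apply_activation <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         sigmoid = 1 / (1 + exp(-Z)),
         none = Z,
         stop("unknown activation: ", activation))
}

# Forward pass keeping per-layer caches for backprop / calibration.
# Returns list(out, caches); caches[[i]] holds the layer input A, the
# pre-activation Z (parameterized layers) and the dropout mask if training.
forward_cache <- function(model, X, training = FALSE) {
  A <- as.matrix(X)
  if (ncol(A) != model$input_len) {
    stop("input has ", ncol(A), " columns; model expects ", model$input_len,
         call. = FALSE)
  }
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "conv1d") {
      # kernel size 1 on one channel: per-position linear map sharing w, b
      Z <- do.call(cbind, lapply(seq_len(l$positions), function(p) outer(A[, p], l$w)))
      Z <- sweep(Z, 2, rep(l$b, l$positions), "+")
      caches[[i]] <- list(A = A, Z = Z)
      A <- apply_activation(Z, l$activation)
    } else if (l$kind == "maxpool1d") {
      if (l$pool != 1L || l$stride != 1L) {
        stop("only pool = stride = 1 (identity) pooling is supported", call. = FALSE)
      }
      caches[[i]] <- list()
    } else if (l$kind == "flatten") {
      caches[[i]] <- list()
    } else if (l$kind == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(stats::rbinom(length(A), 1L, 1 - l$rate), nrow(A)) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        A <- A * mask
      } else {
        caches[[i]] <- list()
      }
    } else if (l$kind == "dense") {
      Z <- A %*% l$W
      Z <- sweep(Z, 2, l$b, "+")
      caches[[i]] <- list(A = A, Z = Z)
      A <- apply_activation(Z, l$activation)
    }
  }
  list(out = A, caches = caches)
}

#' Forward pass: probability of breathing
#'
#' Runs the network at inference (dropout inactive) and returns the sigmoid
#' output for each input row.
#'
#' @param model A `network_model`.
#' @param X Numeric matrix (n x input_len) of standardized features.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
forward <- function(model, X) {
  stopifnot(inherits(model, "network_model"))
  drop(forward_cache(model, X, training = FALSE)$out)
}

#' @export
predict.network_model <- function(object, newdata, type = c("prob", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- forward(object, newdata)
  if (type == "prob") p else as.integer(p >= threshold)
}

# Per-layer hidden activations (post-activation), used for data-based
# weight normalization when converting to a spiking network.
hidden_activations <- function(model, X) {
  fc <- forward_cache(model, X, training = FALSE)
  acts <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind %in% c("conv1d", "dense")) {
      acts[[length(acts) + 1L]] <- apply_activation(fc$caches[[i]]$Z, l$activation)
    }
  }
  acts
}

binary_cross_entropy <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backward pass: gradients of mean binary cross-entropy w.r.t. every
# parameter tensor. Returns a list parallel to model$layers.
backward_pass <- function(model, fc, y) {
  n <- length(y)
  grads <- vector("list", length(model$layers))
  # sigmoid + BCE: dL/dZ_out = (p - y) / n
  dA <- NULL
  dZ <- (fc$out - matrix(y, ncol = 1)) / n
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$kind == "dense") {
      if (is.null(dZ)) dZ <- dA * (fc$caches[[i]]$Z > 0)  # relu layers
      grads[[i]] <- list(W = crossprod(fc$caches[[i]]$A, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
      dZ <- NULL
    } else if (l$kind == "dropout") {
      if (!is.null(fc$caches[[i]]$mask)) dA <- dA * fc$caches[[i]]$mask
    } else if (l$kind %in% c("flatten", "maxpool1d")) {
      # identity
    } else if (l$kind == "conv1d") {
      dZc <- dA * (fc$caches[[i]]$Z > 0)
      Fn <- length(l$w)
      A_in <- fc$caches[[i]]$A
      dw <- numeric(Fn)
      db <- numeric(Fn)
      dA_in <- matrix(0, nrow(A_in), ncol(A_in))
      for (p in seq_len(l$positions)) {
        cols <- ((p - 1L) * Fn + 1L):(p * Fn)
        dw <- dw + drop(crossprod(dZc[, cols, drop = FALSE], A_in[, p]))
        db <- db + colSums(dZc[, cols, drop = FALSE])
        dA_in[, p] <- dZc[, cols, drop = FALSE] %*% l$w
      }
      grads[[i]] <- list(w = dw, b = db)
      dA <- dA_in
    }
  }
  grads
}

#' Training configuration
#'
#' Hyperparameters for Adam training with per-epoch shuffling and
#' patience-based early stopping on validation loss.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Consecutive epochs without validation-loss
#'   improvement before training stops; `Inf` disables early stopping.
#' @param val_fraction Fraction of the training set held out for early
#'   stopping when no validation set is supplied.
#' @param seed Single seed driving initial shuffling, dropout and the
#'   internal validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 5L,
                         max_epochs = 100L, early_stop_patience = 5L,
                         val_fraction = 0.1, seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (early_stop_patience < 1) stop("`early_stop_patience` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Epoch at which patience-based early stopping halts training
#'
#' Given a sequence of per-epoch validation losses, returns the epoch after
#' which training stops: the first epoch completing `patience` consecutive
#' epochs with no improvement over the best loss so far, or the final epoch.
#'
#' @param val_losses Numeric vector of validation losses per epoch.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return The stopping epoch (1-based).
#' @examples
#' early_stop_epoch(c(.5, .4, .41, .42, .43, .44, .45), patience = 5)  # 7
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  length(val_losses)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$kind,
           conv1d = list(m = list(w = 0 * l$w, b = 0 * l$b),
                         v = list(w = 0 * l$w, b = 0 * l$b)),
           dense = list(m = list(W = 0 * l$W, b = 0 * l$b),
                        v = list(W = 0 * l$W, b = 0 * l$b)),
           NULL)
  })
}

#' Train a network with Adam, minibatches and early stopping
#'
#' Minimizes binary cross-entropy with the Adam optimizer (beta1 0.9, beta2
#' 0.999), shuffling the training set each epoch. After every epoch the
#' validation loss is evaluated; training stops once it has not improved for
#' `early_stop_patience` consecutive epochs (or at `max_epochs`), and the
#' weights of the best-validation-loss epoch are restored. If `val` is
#' `NULL`, a `val_fraction` slice of `train` is held out internally.
#'
#' @param model A `network_model` (weights are the starting point).
#' @param train,val `windowed_dataset`s (standardized); `val` may be `NULL`.
#' @param cfg A [train_config()].
#' @return List with the trained `model`, a `history` data frame (epoch,
#'   train_loss, val_loss) and `stopped_epoch`.
#' @export
train_network <- function(model, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "network_model"), inherits(cfg, "train_config"))
  X <- train$X
  y <- train$y
  if (length(unique(y)) < 1 || nrow(X) == 0) stop("empty training set", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  if (is.null(val)) {
    n_val <- max(1L, floor(cfg$val_fraction * nrow(X)))
    vi <- sample.int(nrow(X), n_val)
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    X <- X[-vi, , drop = FALSE]; y <- y[-vi]
  } else {
    Xv <- val$X; yv <- val$y
  }

  lr <- cfg$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  opt <- adam_init(model$layers)
  step <- 0L
  best_loss <- Inf
  best_layers <- model$layers
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(X))
    batch_losses <- numeric(0)
    for (start in seq(1, nrow(X), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, nrow(X))]
      fc <- forward_cache(model, X[idx, , drop = FALSE], training = TRUE)
      loss <- binary_cross_entropy(drop(fc$out), y[idx])
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (loss = %s)", epoch, loss),
             call. = FALSE)
      }
      batch_losses <- c(batch_losses, loss)
      grads <- backward_pass(model, fc, y[idx])
      step <- step + 1L
      for (i in seq_along(model$layers)) {
        if (is.null(grads[[i]])) next
        for (nm in names(grads[[i]])) {
          g <- grads[[i]][[nm]]
          opt[[i]]$m[[nm]] <- beta1 * opt[[i]]$m[[nm]] + (1 - beta1) * g
          opt[[i]]$v[[nm]] <- beta2 * opt[[i]]$v[[nm]] + (1 - beta2) * g^2
          mhat <- opt[[i]]$m[[nm]] / (1 - beta1^step)
          vhat <- opt[[i]]$v[[nm]] / (1 - beta2^step)
          model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    val_loss <- binary_cross_entropy(forward(model, Xv), yv)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_layers <- model$layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$layers <- best_layers
  list(model = model, history = history, stopped_epoch = max(history$epoch))
}

#' Exhaustive grid search over epochs and learning rate
#'
#' Trains one model per (epochs, learning rate) combination and scores each
#' by misclassification rate on the validation set, returning the full score
#' table and the argmin configuration (ties broken by fewer epochs, then
#' smaller learning rate, so the result is invariant to grid ordering).
#'
#' @param epochs_grid Integer vector of epoch budgets.
#' @param lr_grid Numeric vector of learning rates.
#' @param train,val `windowed_dataset`s.
#' @param builder Zero/one-argument function returning a fresh
#'   `network_model` (passed `seed`).
#' @param cfg_base Base [train_config()]; epochs/learning rate are overridden
#'   per combination. Early stopping is disabled during the search so each
#'   budget is honoured.
#' @return List with `best` (epochs, learning_rate, misclassification) and
#'   `table` (one row per combination).
#' @export
grid_search <- function(epochs_grid, lr_grid, train, val,
                        builder = build_1dcnn, cfg_base = train_config()) {
  if (length(epochs_grid) == 0 || length(lr_grid) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  combos <- expand.grid(epochs = epochs_grid, learning_rate = lr_grid)
  f_d <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- cfg_base
    cfg$max_epochs <- as.integer(combos$epochs[i])
    cfg$learning_rate <- combos$learning_rate[i]
    cfg$early_stop_patience <- Inf
    fit <- train_network(builder(seed = cfg$seed), train, val, cfg)
    pred <- as.integer(forward(fit$model, val$X) >= 0.5)
    mean(pred != val$y)
  }, numeric(1))
  tab <- cbind(combos, misclassification = f_d)
  ord <- order(tab$misclassification, tab$epochs, tab$learning_rate)
  tab_sorted <- tab[ord, ]
  list(best = tab_sorted[1, ], table = tab)
}

#' Standard error of a cross-validation estimate
#'
#' `sigma / sqrt(n)` for sample standard deviation `sigma` over `n` repeats.
#'
#' @param sigma Sample standard deviation of the repeat means.
#' @param n Number of repeats.
#' @return The standard error.
#' @export
cv_standard_error <- function(sigma, n) sigma / sqrt(n)

#' Repeated k-fold cross-validation
#'
#' Partitions the data into `k` folds per repeat (fresh random partition each
#' repeat), trains on k-1 folds, scores accuracy on the held-out fold, and
#' summarizes: mean accuracy over all folds and repeats, the sample standard
#' deviation of the per-repeat means, and its standard error `sigma/sqrt(n)`.
#' With a single repeat the standard deviation over repeats is undefined; the
#' fold-level standard deviation is reported instead with `degenerate = TRUE`
#' and a warning.
#'
#' @param builder Function (`seed` argument) returning a fresh model.
#' @param dataset A standardized `windowed_dataset`.
#' @param k Number of folds (>= 2, <= n).
#' @param repeats Number of repeats (>= 1).
#' @param seed Integer seed for fold assignment.
#' @param cfg [train_config()] used for every fold.
#' @return A `cv_result`: list with `fold_accuracy` (repeats x k matrix),
#'   `mean`, `sigma`, `sigma_error`, `n_repeats`, `degenerate`.
#' @export
repeated_kfold <- function(builder, dataset, k = 10L, repeats = 3L, seed = 1L,
                           cfg = train_config()) {
  n <- nrow(dataset$X)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the number of samples", call. = FALSE)
  if (repeats < 1) stop("`repeats` must be >= 1", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  acc <- matrix(NA_real_, repeats, k)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    folds <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      test_i <- which(folds == f)
      tr <- new_windowed_dataset(dataset$X[-test_i, , drop = FALSE],
                                 dataset$y[-test_i], dataset$t0[-test_i],
                                 dataset$window_s)
      te <- new_windowed_dataset(dataset$X[test_i, , drop = FALSE],
                                 dataset$y[test_i], dataset$t0[test_i],
                                 dataset$window_s)
      fit <- train_network(builder(seed = cfg$seed), tr, NULL, cfg)
      pred <- as.integer(forward(fit$model, te$X) >= 0.5)
      acc[r, f] <- mean(pred == te$y)
    }
  }
  repeat_means <- rowMeans(acc)
  degenerate <- repeats == 1L
  if (degenerate) {
    sigma <- stats::sd(acc[1, ])
    warning("single repeat: sigma reported over folds; standard error equals sigma",
            call. = FALSE)
    sigma_error <- sigma
  } else {
    sigma <- stats::sd(repeat_means)
    sigma_error <- cv_standard_error(sigma, repeats)
  }
  structure(list(fold_accuracy = acc, mean = mean(acc), sigma = sigma,
                 sigma_error = sigma_error, n_repeats = repeats,
                 degenerate = degenerate),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV (%d repeat%s): accuracy %.4f +/- %.4f (SE)\n",
              ncol(x$fold_accuracy), x$n_repeats,
              if (x$n_repeats > 1) "s" else "", x$mean, x$sigma_error))
  invisible(x)
}

#' Serialize / load a network as JSON
#'
#' Stores the architecture manifest and all weight tensors as portable JSON
#' text (full double precision).
#'
#' @param model A `network_model`.
#' @param path Output path.
#' @return `write_model_json()`: `path` invisibly; `read_model_json()`: the
#'   `network_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  payload <- list(
    input_len = model$input_len,
    layers = lapply(model$layers, function(l) {
      if (!is.null(l$W)) l$W <- list(dim = dim(l$W), data = as.numeric(l$W))
      l
    })
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  layers <- lapply(payload$layers, function(l) {
    if (!is.null(l$W)) {
      l$W <- matrix(unlist(l$W$data), unlist(l$W$dim)[1], unlist(l$W$dim)[2])
    }
    for (nm in c("w", "b")) if (!is.null(l[[nm]])) l[[nm]] <- as.numeric(unlist(l[[nm]]))
    for (nm in c("positions", "pool", "stride")) {
      if (!is.null(l[[nm]])) l[[nm]] <- as.integer(l[[nm]])
    }
    l
  })
  new_network_model(layers, as.integer(payload$input_len))
}
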