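#' Round half away from zero
#'
#' Deterministic tie-breaking used by every quantizer in the package
#' (`round()` in base R rounds half to even, which changes lattice values at
#' exact midpoints).
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' k-bit quantization on the unit interval
#'
#' Maps `z` in `[0, 1]` onto the `2^k`-point lattice `{i / (2^k - 1)}`:
#' `Q(z) = round((2^k - 1) z) / (2^k - 1)`, rounding half away from zero.
#' Idempotent; both endpoints are fixed points.
#'
#' @param z_r Numeric vector in `[0, 1]`.
#' @param k Total bits (>= 1).
#' @return Quantized values in `[0, 1]`.
#' @examples
#' quantize_unit(0.6, k = 2)  # 2/3
#' @export
quantize_unit <- function(z_r, k) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (any(z_r < 0 | z_r > 1)) {
    stop("`z_r` must lie in [0, 1]; clip activations first", call. = FALSE)
  }
  levels <- 2^k - 1
  round_half_away(levels * z_r) / levels
}

#' k-bit quantization of a weight tensor
#'
#' Squashes weights through tanh, rescales to `[0, 1]` by the tensor's
#' maximum tanh magnitude, quantizes on the unit lattice and (for
#' `dequantize = TRUE`) inverts the affine-plus-tanh map back to the signed
#' weight scale. The largest-magnitude weight always lands on an exact
#' lattice endpoint.
#'
#' @param w_r Numeric weight tensor (vector/matrix).
#' @param k Total bits.
#' @param dequantize Return signed weights (default) rather than the raw
#'   unit-lattice values.
#' @return Tensor of the same shape; attribute `max_tanh` stores the
#'   per-tensor normalizer.
#' @export
quantize_weights <- function(w_r, k, dequantize = TRUE) {
  m <- max(abs(tanh(w_r)))
  if (m == 0) stop("cannot quantize an all-zero weight tensor", call. = FALSE)
  arg <- tanh(w_r) / (2 * m) + 0.5
  q <- quantize_unit(arg, k)
  out <- if (dequantize) atanh(pmin(pmax((q - 0.5) * 2 * m, -1 + 1e-15), 1 - 1e-15)) else q
  if (is.matrix(w_r)) out <- matrix(out, nrow(w_r), ncol(w_r))
  attr(out, "max_tanh") <- m
  out
}

#' k-bit quantization of activations
#'
#' Clips to `[0, 1]` then quantizes on the unit lattice.
#'
#' @param x_r Numeric activations.
#' @param k Total bits.
#' @return Quantized activations in `[0, 1]`.
#' @export
quantize_activations <- function(x_r, k) {
  quantize_unit(pmin(pmax(x_r, 0), 1), k)
}

#' Fixed-point mantissa quantization
#'
#' `2^(b-k+1) * clip(round(x * 2^(k-b-1)), -2^(k-1), 2^(k-1) - 1)` with `b`
#' integer bits left of the binary point out of `k` total bits; saturates at
#' the representable range.
#'
#' @param x Numeric input.
#' @param k Total bits.
#' @param b Bits left of the binary point (`0 <= b < k`).
#' @return Quantized values.
#' @examples
#' mantissa_quantize(0.3, k = 8, b = 0)  # 0.296875
#' @export
mantissa_quantize <- function(x, k, b = 0) {
  if (b >= k || b < 0) stop("require 0 <= b < k", call. = FALSE)
  scaled <- round_half_away(x * 2^(k - b - 1))
  clipped <- pmin(pmax(scaled, -2^(k - 1)), 2^(k - 1) - 1)
  2^(b - k + 1) * clipped
}

#' Model storage size under k-bit parameters
#'
#' Parameter count times bits per parameter. For the canonical classifier
#' (46,129 parameters) this gives 92,258 bits at k = 2 up to 2,952,256 bits
#' at full 64-bit precision.
#'
#' @param model A `network_model`.
#' @param k Bits per parameter.
#' @return Size in bits.
#' @export
model_size_bits <- function(model, k) {
  n_parameters(model) * k
}

#' Quantize a trained network to k bits
#'
#' Applies the tanh-normalized weight quantizer to every parameterized
#' tensor (weights and biases alike) and records the activation bit width.
#' The final sigmoid output stays in full precision; hidden activations are
#' clipped to `[0, 1]` and quantized during [quantized_forward()].
#'
#' @param model A trained `network_model`.
#' @param k Bits for weights and activations.
#' @return A `quantized_model`.
#' @export
quantize_model <- function(model, k) {
  stopifnot(inherits(model, "network_model"))
  qlayers <- lapply(model$layers, function(l) {
    if (l$kind == "conv1d") {
      l$w <- strip_attr(quantize_weights(l$w, k))
      if (any(l$b != 0)) l$b <- strip_attr(quantize_weights(l$b, k))
    } else if (l$kind == "dense") {
      l$W <- strip_attr(quantize_weights(l$W, k))
      if (any(l$b != 0)) l$b <- strip_attr(quantize_weights(l$b, k))
    }
    l
  })
  structure(list(layers = qlayers, input_len = model$input_len, k = k),
            class = c("quantized_model", "network_model"))
}

strip_attr <- function(x) {
  attr(x, "max_tanh") <- NULL
  x
}

#' Forward pass of a quantized network
#'
#' Identical to [forward()] except every hidden (ReLU) activation is clipped
#' to `[0, 1]` and quantized to the model's bit width before feeding the
#' next layer; the output sigmoid is kept in full precision.
#'
#' @param qmodel A `quantized_model` from [quantize_model()].
#' @param X Input matrix.
#' @return Probability vector.
#' @export
quantized_forward <- function(qmodel, X) {
  stopifnot(inherits(qmodel, "quantized_model"))
  A <- as.matrix(X)
  k <- qmodel$k
  for (l in qmodel$layers) {
    if (l$kind == "conv1d") {
      Z <- do.call(cbind, lapply(seq_len(l$positions), function(p) outer(A[, p], l$w)))
      Z <- sweep(Z, 2, rep(l$b, l$positions), "+")
      A <- quantize_activations(apply_activation(Z, l$activation), k)
    } else if (l$kind == "dense") {
      Z <- sweep(A %*% l$W, 2, l$b, "+")
      A <- apply_activation(Z, l$activation)
      if (l$activation == "relu") A <- quantize_activations(A, k)
    }
    # pooling (identity), flatten, dropout: no-ops at inference
  }
  drop(A)
}

#' @export
print.quantized_model <- function(x, ...) {
  cat(sprintf("quantized_model: k = %d bits, %d parameters, %s bits total\n",
              x$k, n_parameters(x), format(model_size_bits(x, x$k), big.mark = ",")))
  invisible(x)
}
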