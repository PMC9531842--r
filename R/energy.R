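#' Per-operation energy coefficient table
#'
#' Energy constants for the spike-count model (per spike and per synaptic
#' routing event, neuromorphic-hardware figures) and a parametric model for
#' conventional inference: `e_mac(k)` pJ per multiply-accumulate and
#' `e_mem(k)` pJ per parameter access at bit width `k`. By default
#' `e_mac(k) = e_mac_coef * k^2` (multiplier area/energy scales roughly
#' quadratically in operand width) and `e_mem(k) = e_mem_coef * k` (access
#' energy scales with word length). Explicit per-k tables override the
#' coefficients; with an explicit table, asking for a missing `k` is an
#' error. The coefficients are illustrative defaults for ordering and ratio
#' comparisons, not calibrated silicon numbers.
#'
#' @param e_spike_pj Energy per neuron spike, pJ (23.6 pJ at a 30 Hz spike
#'   frequency calibration condition).
#' @param e_route_pj Energy per synaptic routing event, pJ.
#' @param e_mac_coef,e_mem_coef Coefficients of the parametric MAC/memory
#'   models.
#' @param e_mac_pj,e_mem_pj Optional named numeric vectors (names = k) of
#'   explicit per-k energies, pJ.
#' @return An `energy_table`.
#' @export
energy_table <- function(e_spike_pj = 23.6, e_route_pj = 3,
                         e_mac_coef = 2, e_mem_coef = 1,
                         e_mac_pj = NULL, e_mem_pj = NULL) {
  if (any(c(e_spike_pj, e_route_pj, e_mac_coef, e_mem_coef) < 0)) {
    stop("energy entries must be non-negative", call. = FALSE)
  }
  structure(list(e_spike_pj = e_spike_pj, e_route_pj = e_route_pj,
                 e_mac_coef = e_mac_coef, e_mem_coef = e_mem_coef,
                 e_mac_pj = e_mac_pj, e_mem_pj = e_mem_pj),
            class = "energy_table")
}

#' Energy per MAC / per parameter access at bit width k
#' @param table An [energy_table()].
#' @param k Bit width.
#' @return Energy in pJ.
#' @export
e_mac <- function(table, k) {
  stopifnot(inherits(table, "energy_table"))
  lookup_or_scale(table$e_mac_pj, table$e_mac_coef, k, power = 2)
}

#' @rdname e_mac
#' @export
e_mem <- function(table, k) {
  stopifnot(inherits(table, "energy_table"))
  lookup_or_scale(table$e_mem_pj, table$e_mem_coef, k, power = 1)
}

lookup_or_scale <- function(tab, coef, k, power) {
  if (!is.null(tab)) {
    hit <- match(as.character(k), names(tab))
    if (any(is.na(hit))) {
      stop("no energy entry for k = ", paste(k[is.na(hit)], collapse = ", "),
           call. = FALSE)
    }
    unname(tab[hit])
  } else {
    coef * k^power
  }
}

new_energy_report <- function(breakdown, model_id) {
  structure(list(total_pj = sum(breakdown$energy_pj), breakdown = breakdown,
                 model = model_id),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("energy_report [%s]: %.1f pJ\n", x$model, x$total_pj))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Spike-count energy of a spiking-network inference
#'
#' `total = n_spikes * e_spike + n_routing * e_route`, broken down by layer
#' and by category (spike vs routing).
#'
#' @param record A `spike_record` from [snn_infer()].
#' @param table An [energy_table()].
#' @param model_id Label used in the report.
#' @return An `energy_report`.
#' @export
snn_energy <- function(record, table = energy_table(), model_id = "snn") {
  stopifnot(inherits(record, "spike_record"), inherits(table, "energy_table"))
  rows <- do.call(rbind, lapply(seq_along(record$per_neuron), function(i) {
    cnt <- record$per_neuron[[i]]
    fo <- record$fan_out[[i]]
    data.frame(layer = i - 1L,  # layer 0 = input encoders
               category = c("spike", "routing"),
               energy_pj = c(sum(cnt) * table$e_spike_pj,
                             sum(cnt * fo) * table$e_route_pj))
  }))
  new_energy_report(rows, model_id)
}

#' Parametric energy of a conventional (quantized) network inference
#'
#' `total = sum over layers of macs * e_mac(k) + params * e_mem(k)`, with MAC
#' counts derived from layer shapes (one inference).
#'
#' @param model A `network_model` (or `quantized_model`).
#' @param k_bits Bit width of parameters and arithmetic.
#' @param table An [energy_table()].
#' @param model_id Label used in the report.
#' @return An `energy_report`.
#' @export
ann_energy <- function(model, k_bits, table = energy_table(),
                       model_id = sprintf("ann_k%d", k_bits)) {
  stopifnot(inherits(model, "network_model"))
  rows <- list()
  li <- 0L
  for (l in model$layers) {
    macs <- params <- NULL
    if (l$kind == "conv1d") {
      macs <- l$positions * length(l$w)
      params <- length(l$w) + length(l$b)
    } else if (l$kind == "dense") {
      macs <- nrow(l$W) * ncol(l$W)
      params <- length(l$W) + length(l$b)
    }
    if (!is.null(macs)) {
      li <- li + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(layer = li, category = c("mac", "memory"),
                   energy_pj = c(macs * e_mac(table, k_bits),
                                 params * e_mem(table, k_bits)))
    }
  }
  new_energy_report(do.call(rbind, rows), model_id)
}

#' MAC count of one inference
#' @param model A `network_model`.
#' @return Total multiply-accumulate operations per inference.
#' @export
mac_count <- function(model) {
  stopifnot(inherits(model, "network_model"))
  sum(vapply(model$layers, function(l) {
    switch(l$kind,
           conv1d = l$positions * length(l$w),
           dense = nrow(l$W) * ncol(l$W),
           0)
  }, numeric(1)))
}

#' Accuracy/energy tradeoff table
#'
#' Combines energy reports with their accuracies into a table sorted by
#' energy, with each model's energy ratio to the cheapest.
#'
#' @param reports List of `energy_report`s.
#' @param accuracies Numeric vector of matching top-1 accuracies.
#' @return Data frame `model`, `accuracy`, `energy_pj`, `energy_ratio`.
#' @export
compare_energy <- function(reports, accuracies) {
  stopifnot(length(reports) == length(accuracies))
  df <- data.frame(
    model = vapply(reports, function(r) r$model, ""),
    accuracy = accuracies,
    energy_pj = vapply(reports, function(r) r$total_pj, numeric(1))
  )
  df <- df[order(df$energy_pj), ]
  df$energy_ratio <- df$energy_pj / min(df$energy_pj)
  rownames(df) <- NULL
  df
}
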