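#' Configuration of the seven-stage pipeline
#'
#' Bundles every stage's settings: simulation protocol and RFID link, window
#' featurization, training, quantization grid, spiking conversion, threshold
#' sweep and the energy table. One master seed deterministically derives all
#' stage seeds.
#'
#' @param out_dir Run directory for artifacts.
#' @param seed Master seed.
#' @param protocol A [breathing_protocol()].
#' @param rfid An [rfid_config()].
#' @param train_cfg A [train_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param window_n Trailing window for the RSSI-from-minimum feature.
#' @param test_fraction Held-out test fraction.
#' @param k_grid Quantization bit widths evaluated.
#' @param k_report Bit width of the quantized model kept for comparison.
#' @param snn_t_steps Simulation horizon per window for spiking inference
#'   (the pipeline's selected low-energy design point).
#' @param sweep_t_steps Simulation horizon per window during the threshold
#'   sweep.
#' @param snn_v_th Firing threshold used for spiking inference.
#' @param sweep_v_th_grid Thresholds swept in the design-space exploration.
#' @param sweep_sizes Evaluation sample sizes for the sweep (windows are
#'   resampled with replacement from the test partition).
#' @param energy An [energy_table()].
#' @param raw_csv Optional path to a pre-simulated interrogation CSV; when
#'   given, the simulate stage loads it instead of simulating.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("neorespire_run_"),
                            seed = 1L,
                            protocol = breathing_protocol(total_duration = 600),
                            rfid = rfid_config(),
                            train_cfg = train_config(),
                            window_n = 28L,
                            test_fraction = 0.25,
                            k_grid = c(2L, 4L, 8L, 16L, 32L, 64L),
                            k_report = 8L,
                            snn_t_steps = 200L,
                            sweep_t_steps = 100L,
                            snn_v_th = 1,
                            sweep_v_th_grid = 1:10,
                            sweep_sizes = c(100L, 200L, 500L, 1000L, 2000L),
                            energy = energy_table(),
                            raw_csv = NULL) {
  stopifnot(inherits(protocol, "breathing_protocol"), inherits(rfid, "rfid_config"),
            inherits(train_cfg, "train_config"), inherits(energy, "energy_table"))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), protocol = protocol,
         rfid = rfid, train_cfg = train_cfg, window_n = as.integer(window_n),
         test_fraction = test_fraction, k_grid = as.integer(k_grid),
         k_report = as.integer(k_report), snn_t_steps = as.integer(snn_t_steps),
         sweep_t_steps = as.integer(sweep_t_steps), snn_v_th = snn_v_th, sweep_v_th_grid = sweep_v_th_grid,
         sweep_sizes = as.integer(sweep_sizes), energy = energy,
         raw_csv = raw_csv),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Every numeric default of [pipeline_config()] and its sub-configurations
#' can be overridden from a YAML file with top-level keys matching the
#' argument names (`protocol`, `rfid`, `train`, `energy` as nested maps).
#'
#' @param path YAML file path.
#' @param out_dir Output directory (overrides any value in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$protocol)) args$protocol <- do.call(breathing_protocol, y$protocol)
  if (!is.null(y$rfid)) args$rfid <- do.call(rfid_config, y$rfid)
  if (!is.null(y$train)) args$train_cfg <- do.call(train_config, y$train)
  if (!is.null(y$energy)) args$energy <- do.call(energy_table, y$energy)
  for (nm in c("seed", "window_n", "test_fraction", "k_grid", "k_report",
               "snn_t_steps", "sweep_t_steps", "snn_v_th", "sweep_v_th_grid", "sweep_sizes",
               "raw_csv", "out_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full seven-stage pipeline
#'
#' Executes simulate -> featurize -> train -> quantize -> convert -> sweep ->
#' evaluate, persisting every artifact into the run directory together with
#' a manifest recording the configuration hash and derived stage seeds. All
#' stochastic stages are seeded from the master seed, so a repeated run with
#' the same configuration reproduces every artifact.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory results (`stream`, `split`,
#'   `fit`, `qmodels`, `snn`, `sweep`, `metrics`, `energy`, paths).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # 1. simulate -------------------------------------------------------------
  timeline <- generate_protocol(cfg$protocol)
  stream <- with_stage("simulate", {
    if (!is.null(cfg$raw_csv)) {
      if (!file.exists(cfg$raw_csv)) {
        stop("missing input path: ", cfg$raw_csv)
      }
      read_interrogations_csv(cfg$raw_csv)
    } else {
      simulate_interrogations(timeline, cfg$rfid, seed = stage_seed(cfg, 11L))
    }
  })
  write_interrogations_csv(stream, file.path(cfg$out_dir, "raw.csv"))
  writeLines(jsonlite::toJSON(as.data.frame(timeline), digits = NA),
             file.path(cfg$out_dir, "timeline.json"))
  say("simulate: %d interrogations over %g s", nrow(stream), max(timeline$end_s))

  # 2. featurize ------------------------------------------------------------
  split <- with_stage("featurize", {
    feats <- compute_features(stream, window_n = cfg$window_n)
    write_feature_csvs(
      feats,
      data.frame(timestamp_s = feats$timestamp_s,
                 state = timeline_state(timeline, feats$timestamp_s)),
      cfg$out_dir
    )
    windows <- build_windows(feats, timeline)
    clean_and_split(windows, test_fraction = cfg$test_fraction,
                    seed = stage_seed(cfg, 23L))
  })
  say("featurize: %d train / %d test windows",
      nrow(split$train$X), nrow(split$test$X))

  # 3. train ----------------------------------------------------------------
  fit <- with_stage("train", {
    tc <- cfg$train_cfg
    tc$seed <- stage_seed(cfg, 37L)
    train_network(build_1dcnn(seed = tc$seed), split$train, NULL, tc)
  })
  write_model_json(fit$model, file.path(cfg$out_dir, "model.json"))
  utils::write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  say("train: stopped at epoch %d (val loss %.4f)", fit$stopped_epoch,
      min(fit$history$val_loss))

  cnn_prob <- forward(fit$model, split$test$X)
  cnn_pred <- as.integer(cnn_prob >= 0.5)
  cnn_metrics <- all_metrics(confusion(split$test$y, cnn_pred),
                             scores = cnn_prob, y_true = split$test$y)

  # 4. quantize -------------------------------------------------------------
  quant <- with_stage("quantize", {
    rows <- lapply(cfg$k_grid, function(k) {
      qm <- quantize_model(fit$model, k)
      qpred <- as.integer(quantized_forward(qm, split$test$X) >= 0.5)
      data.frame(k = k, top1 = mean(qpred == split$test$y),
                 model_size_bits = model_size_bits(fit$model, k),
                 energy_pj = ann_energy(fit$model, k, cfg$energy)$total_pj)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(quant, file.path(cfg$out_dir, "quantization.csv"),
                   row.names = FALSE)
  qmodel <- quantize_model(fit$model, cfg$k_report)
  write_model_json(qmodel, file.path(cfg$out_dir,
                                     sprintf("model_q%d.json", cfg$k_report)))
  say("quantize: evaluated k = %s", paste(cfg$k_grid, collapse = ", "))

  # 5. convert --------------------------------------------------------------
  snn <- with_stage("convert", {
    convert_to_snn(fit$model, split$train$X, v_th = cfg$snn_v_th,
                   t_steps = cfg$snn_t_steps)
  })
  writeLines(jsonlite::toJSON(list(lambda = snn$lambda, v_th = snn$v_th,
                                   t_steps = snn$t_steps,
                                   n_neurons = snn$n_neurons),
                              digits = NA, auto_unbox = TRUE),
             file.path(cfg$out_dir, "snn_manifest.json"))
  snn_res <- snn_infer(snn, split$test$X, t_steps = cfg$snn_t_steps,
                       seed = stage_seed(cfg, 53L))
  snn_metrics <- all_metrics(confusion(split$test$y, snn_res$labels),
                             scores = snn_res$output_rates,
                             y_true = split$test$y)
  write_spike_record_csv(snn_res$spike_record,
                         file.path(cfg$out_dir, "spikes.csv"))
  say("convert: SNN test accuracy %.4f (CNN %.4f)", snn_metrics$top1,
      cnn_metrics$top1)

  # 6. sweep ----------------------------------------------------------------
  sweep_res <- with_stage("sweep", {
    sweep_design_space(snn, split$test, sizes = cfg$sweep_sizes,
                       v_th_grid = cfg$sweep_v_th_grid,
                       t_steps = cfg$sweep_t_steps, seed = stage_seed(cfg, 67L))
  })
  sweep_df <- data.frame(
    v_th = rep(sweep_res$v_th_grid, times = ncol(sweep_res$accuracy)),
    size = rep(colnames(sweep_res$accuracy), each = nrow(sweep_res$accuracy)),
    accuracy = as.vector(sweep_res$accuracy),
    total_spikes = as.vector(sweep_res$spikes)
  )
  utils::write.csv(sweep_df, file.path(cfg$out_dir, "sweep.csv"),
                   row.names = FALSE)
  say("sweep: %d thresholds x %d sizes", length(cfg$sweep_v_th_grid),
      length(cfg$sweep_sizes))

  # 7. evaluate -------------------------------------------------------------
  energy <- with_stage("evaluate", {
    n_test <- nrow(split$test$X)
    reports <- list(
      snn_energy(snn_res$spike_record, cfg$energy, model_id = "snn"),
      scale_report(ann_energy(fit$model, cfg$k_report, cfg$energy,
                              model_id = sprintf("ann_k%d", cfg$k_report)), n_test),
      scale_report(ann_energy(fit$model, 2L, cfg$energy, model_id = "ann_k2"), n_test),
      scale_report(ann_energy(fit$model, 64L, cfg$energy, model_id = "ann_k64"), n_test)
    )
    accs <- c(snn_metrics$top1,
              quant$top1[match(cfg$k_report, quant$k)],
              quant$top1[match(2L, quant$k)],
              quant$top1[match(64L, quant$k)])
    compare_energy(reports, accs)
  })
  utils::write.csv(energy, file.path(cfg$out_dir, "energy.csv"),
                   row.names = FALSE)

  metrics <- list(
    n_windows = nrow(split$train$X) + nrow(split$test$X),
    n_test = nrow(split$test$X),
    cnn = unclass(cnn_metrics)[c("top1", "precision", "recall", "f1",
                                 "sensitivity", "specificity", "auc")],
    snn = unclass(snn_metrics)[c("top1", "precision", "recall", "f1",
                                 "sensitivity", "specificity", "auc")],
    quantization = quant,
    parameter_count = n_parameters(fit$model),
    stopped_epoch = fit$stopped_epoch
  )
  writeLines(jsonlite::toJSON(metrics, digits = NA, auto_unbox = TRUE),
             file.path(cfg$out_dir, "metrics.json"))

  manifest <- list(
    config_hash = config_hash(cfg),
    master_seed = cfg$seed,
    stage_seeds = list(simulate = stage_seed(cfg, 11L),
                       split = stage_seed(cfg, 23L),
                       train = stage_seed(cfg, 37L),
                       snn = stage_seed(cfg, 53L),
                       sweep = stage_seed(cfg, 67L)),
    artifacts = list.files(cfg$out_dir)
  )
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE),
             file.path(cfg$out_dir, "manifest.json"))
  say("evaluate: artifacts in %s", cfg$out_dir)

  invisible(list(timeline = timeline, stream = stream, split = split,
                 fit = fit, cnn_metrics = cnn_metrics, quant = quant,
                 qmodel = qmodel, snn = snn, snn_res = snn_res,
                 snn_metrics = snn_metrics, sweep = sweep_res,
                 energy = energy, metrics = metrics, out_dir = cfg$out_dir))
}

# Per-batch ANN energy: one inference per test window.
scale_report <- function(report, n) {
  report$breakdown$energy_pj <- report$breakdown$energy_pj * n
  report$total_pj <- report$total_pj * n
  report
}
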