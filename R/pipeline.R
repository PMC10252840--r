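# End-to-end pipeline: simulate/ingest -> denoise -> window -> split ->
# train -> evaluate, with every artifact written to a run directory.

#' Pipeline run configuration
#'
#' One `seed` fans out deterministically to the simulation, splitting and
#' training sub-seeds, so a run is reproducible from a single knob.
#' `max_windows` caps the dataset by stratified subsampling (window counts
#' grow as subjects x channels x windows and the full geometry is far more
#' than a desk-scale training run needs; `NULL` keeps everything).
#'
#' @param out_dir Run directory to create.
#' @param data_dir Existing STEW-dialect directory to ingest; `NULL`
#'   simulates into `out_dir/data` instead.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param wavelet A [wavelet_config()], or `NULL` to skip denoising.
#' @param window_length,mode,label_policy Windowing options, see
#'   [make_windows()].
#' @param model Model name, see [model_spec()].
#' @param train A [train_config()] (its seed is overridden by `seed`).
#' @param seed Master seed.
#' @param max_windows Optional cap on total windows.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, data_dir = NULL, sim = sim_config(),
                       wavelet = wavelet_config(), window_length = 128L,
                       mode = "wideband", label_policy = "by_condition",
                       model = "CBGG", train = train_config(), seed = 1L,
                       max_windows = NULL) {
  seed <- as.integer(seed)
  sim$seed <- seed
  train$seed <- seed + 202L
  structure(
    list(out_dir = out_dir, data_dir = data_dir, sim = sim,
         wavelet = wavelet, window_length = as.integer(window_length),
         mode = mode, label_policy = label_policy, model = model,
         train = train, seed = seed, split_seed = seed + 101L,
         max_windows = max_windows),
    class = "run_config")
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))
  res
}

# stratified subsample keeping class balance; deterministic given seed
.subsample_windows <- function(ds, max_windows, seed) {
  n <- nrow(ds$values)
  if (is.null(max_windows) || n <= max_windows) return(ds)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  keep <- .stratified_take(ds$meta$label, seq_len(n), max_windows / n)
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$meta <- ds$meta[keep, , drop = FALSE]
  rownames(ds$meta) <- NULL
  ds
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest), wavelet denoising, windowing, the
#' 70/30-70/30 stratified split, training with convergence tracing, and
#' test-set evaluation (metric table + ROC), writing all artifacts under
#' `config$out_dir`. Fails with the offending stage named.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `model`, test `metrics`,
#'   `roc`, `trace`, the `split` plan, and the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # validate the model name before paying for data stages
  spec <- .stage("build", model_spec(config$model))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- config$data_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(config$out_dir, "data")
    .stage("simulate", generate_dataset(config$sim, data_dir))
  }
  recs <- .stage("ingest", read_stew_dir(
    data_dir, fs = config$sim$fs,
    expected_channels = config$sim$n_channels))
  ds <- .stage("windows", {
    d <- make_windows(recs, config$wavelet, config$window_length,
                      mode = config$mode, label_policy = config$label_policy)
    .subsample_windows(d, config$max_windows, config$split_seed)
  })
  split <- .stage("split", make_split(ds, seed = config$split_seed))

  sub <- function(idx) list(x = ds$values[idx, , drop = FALSE],
                            y = ds$meta$label[idx])
  model <- .stage("train", {
    m <- build_model(spec, config$window_length)
    train_model(m, sub(split$train_idx), sub(split$val_idx), config$train)
  })
  result <- .stage("evaluate", {
    test <- sub(split$test_idx)
    pred <- predict(model, test$x,
                    threshold = config$train$classification_threshold)
    list(metrics = compute_metrics(confusion_matrix(test$y, pred$labels)),
         roc = roc_curve(test$y, pred$probabilities))
  })
  .stage("export", {
    write_manifest(ds, file.path(config$out_dir, "windows.tsv"), split = split)
    export_report(
      list(metrics = result$metrics, roc = result$roc, trace = model$trace,
           config = .config_as_list(config)),
      config$out_dir)
  })
  invisible(list(model = model, metrics = result$metrics, roc = result$roc,
                 trace = model$trace, split = split,
                 out_dir = config$out_dir))
}

# flatten the config for the JSON manifest (round-trips unchanged)
.config_as_list <- function(config) {
  sim <- unclass(config$sim)
  # named vectors lose names through JSON arrays; objects keep them
  sim$band_amplitudes <- lapply(sim$band_amplitudes, as.list)
  list(model = config$model, seed = config$seed,
       split_seed = config$split_seed,
       window_length = config$window_length, mode = config$mode,
       label_policy = config$label_policy,
       max_windows = config$max_windows,
       sim = sim,
       wavelet = if (is.null(config$wavelet)) NULL else unclass(config$wavelet),
       train = unclass(config$train))
}

#' Read a pipeline configuration from JSON
#'
#' The on-disk format is the JSON written to each run manifest; every
#' stage's options round-trip unchanged.
#'
#' @param path JSON file.
#' @param out_dir Run directory for the resulting config.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- j$sim
  sim_args$band_amplitudes <- lapply(sim_args$band_amplitudes,
                                     function(v) unlist(v))
  sim <- do.call(sim_config, sim_args)
  wav <- if (is.null(j$wavelet)) NULL else
    do.call(wavelet_config, j$wavelet)
  tr <- do.call(train_config, j$train[c("epochs", "batch_size", "seed",
                                        "learning_rate",
                                        "classification_threshold")])
  run_config(out_dir = out_dir, sim = sim, wavelet = wav,
             window_length = j$window_length, mode = j$mode,
             label_policy = j$label_policy, model = j$model, train = tr,
             seed = j$seed, max_windows = j$max_windows)
}
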