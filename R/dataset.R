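# Labeled univariate windows and split/fold plans.
#
# The classifier's sample unit is a single-channel (optionally single-band)
# non-overlapping window: the convolutional front end sees one feature per
# time step, which is the only reading under which the published parameter
# totals of the two-layer hybrids are exact.

#' Cut recordings into labeled univariate windows
#'
#' Each channel is denoised by the wavelet stage (unless `wavelet_config`
#' is `NULL`) and, in `per_band` mode, split into its five band
#' reconstructions. Every resulting series is cut into
#' `floor(length / window_length)` non-overlapping windows, each inheriting
#' the recording's binary label.
#'
#' @param recordings List of `eeg_recording` objects.
#' @param wavelet_config A [wavelet_config()] driving denoising (and band
#'   splitting in `per_band` mode), or `NULL` to window the raw signal.
#' @param window_length Window length in samples (default 128 = 1 s at
#'   128 Hz).
#' @param mode `"wideband"` (one denoised series per channel) or
#'   `"per_band"` (five band series per channel).
#' @param label_policy Passed to [to_binary_label()].
#' @return A `window_dataset`: list with `values` (matrix, one window per
#'   row) and `meta` (data frame: subject, condition, channel, band,
#'   window_index, label).
#' @export
make_windows <- function(recordings, wavelet_config = wavelet_config(),
                         window_length = 128L,
                         mode = c("wideband", "per_band"),
                         label_policy = "by_condition") {
  mode <- match.arg(mode)
  window_length <- as.integer(window_length)
  if (window_length < 1L) stop("window_length must be >= 1", call. = FALSE)
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)

  chunks <- list()
  meta <- list()
  for (rec in recordings) {
    stopifnot(inherits(rec, "eeg_recording"))
    n <- ncol(rec$data)
    if (window_length > n)
      stop("window_length (", window_length,
           ") exceeds recording length (", n, ")", call. = FALSE)
    label <- to_binary_label(rec, policy = label_policy)
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, ]
      if (is.null(wavelet_config)) {
        series <- list(wideband = x)
      } else {
        dec <- dwt_decompose(x, wavelet_config, fs = rec$fs)
        den <- fdr_denoise(dec)
        if (mode == "wideband") {
          series <- list(wideband = dwt_reconstruct(den))
        } else {
          series <- den$band_signals
        }
      }
      if (is.null(wavelet_config) && mode == "per_band")
        stop("per_band mode requires a wavelet_config", call. = FALSE)
      n_win <- n %/% window_length
      for (band in names(series)) {
        s <- series[[band]]
        w <- matrix(s[seq_len(n_win * window_length)],
                    nrow = n_win, ncol = window_length, byrow = TRUE)
        chunks[[length(chunks) + 1L]] <- w
        meta[[length(meta) + 1L]] <- data.frame(
          subject = rec$subject_id, condition = rec$condition,
          channel = rec$channel_names[ch], band = band,
          window_index = seq_len(n_win), label = label,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(values = do.call(rbind, chunks), meta = do.call(rbind, meta),
         window_length = window_length, mode = mode),
    class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat("<window_dataset> ", nrow(x$values), " windows x ", x$window_length,
      " samples (", x$mode, "); labels: ",
      paste(sprintf("%d:%d", sort(unique(x$meta$label)),
                    as.integer(table(x$meta$label))), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

.dataset_labels <- function(samples) {
  if (inherits(samples, "window_dataset")) samples$meta$label
  else as.integer(samples)
}

# stratified pick of ~frac of each class; total matched to round(frac * n)
# by largest-remainder allocation across classes
.stratified_take <- function(labels, pool, frac) {
  n_target <- round(frac * length(pool))
  cls <- sort(unique(labels[pool]))
  n_c <- vapply(cls, function(c) sum(labels[pool] == c), integer(1))
  want <- frac * n_c
  take <- floor(want)
  rem <- n_target - sum(take)
  if (rem > 0) {
    extra <- order(want - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  } else if (rem < 0) {
    drop <- order(want - take)[seq_len(-rem)]
    take[drop] <- take[drop] - 1L
  }
  picked <- integer(0)
  for (i in seq_along(cls)) {
    members <- pool[labels[pool] == cls[i]]
    picked <- c(picked, sample(members, take[i]))
  }
  sort(picked)
}

#' Train/validation/test split plan
#'
#' Outer 70/30 train+val/test split, then an inner 70/30 split of the
#' retained portion into train/validation; both stratified by class
#' (within one sample per partition) and deterministic given `seed`.
#' With `group_by_subject = TRUE`, whole subjects are assigned to
#' partitions instead of individual windows (leakage-free variant;
#' partition sizes then only approximate the target fractions).
#'
#' @param samples A `window_dataset` or an integer label vector.
#' @param seed Integer seed.
#' @param stratified Stratify by class (requires both classes present).
#' @param test_frac,val_frac Outer test fraction and inner validation
#'   fraction.
#' @param group_by_subject Assign whole subjects, not windows.
#' @return A `split_plan`: disjoint, exhaustive `train_idx`, `val_idx`,
#'   `test_idx`.
#' @export
make_split <- function(samples, seed = 1L, stratified = TRUE,
                       test_frac = 0.3, val_frac = 0.3,
                       group_by_subject = FALSE) {
  labels <- .dataset_labels(samples)
  n <- length(labels)
  if (n < 10L) stop("need at least 10 samples to split", call. = FALSE)
  if (stratified && length(unique(labels)) < 2L)
    stop("stratified split requires both classes", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  if (group_by_subject) {
    if (!inherits(samples, "window_dataset"))
      stop("group_by_subject requires a window_dataset", call. = FALSE)
    subj <- samples$meta$subject
    us <- sort(unique(subj))
    ns <- length(us)
    perm <- sample(us)
    n_test <- max(1L, round(test_frac * ns))
    n_val <- max(1L, round(val_frac * (ns - n_test)))
    test_s <- perm[seq_len(n_test)]
    val_s <- perm[n_test + seq_len(n_val)]
    test_idx <- which(subj %in% test_s)
    val_idx <- which(subj %in% val_s)
    train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  } else if (stratified) {
    test_idx <- .stratified_take(labels, seq_len(n), test_frac)
    rest <- setdiff(seq_len(n), test_idx)
    val_idx <- .stratified_take(labels, rest, val_frac)
    train_idx <- setdiff(rest, val_idx)
  } else {
    perm <- sample.int(n)
    n_test <- round(test_frac * n)
    n_val <- round(val_frac * (n - n_test))
    test_idx <- sort(perm[seq_len(n_test)])
    val_idx <- sort(perm[n_test + seq_len(n_val)])
    train_idx <- sort(perm[-seq_len(n_test + n_val)])
  }
  structure(
    list(train_idx = train_idx, val_idx = val_idx, test_idx = test_idx,
         seed = as.integer(seed), stratified = stratified,
         group_by_subject = group_by_subject),
    class = "split_plan")
}

#' Stratified k-fold plan
#'
#' Shuffles each class and deals it round-robin across folds, so per-fold
#' class counts differ from exact proportionality by at most one.
#'
#' @param samples A `window_dataset` or an integer label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class (each class must have >= k members).
#' @return A `fold_plan`: `k`, integer `fold` assignment per sample,
#'   `seed`, `stratified`.
#' @export
make_folds <- function(samples, k = 10L, seed = 1L, stratified = TRUE) {
  labels <- .dataset_labels(samples)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  fold <- integer(n)
  if (stratified) {
    # per class: floor(n_c / k) everywhere, extras to the currently
    # smallest folds, so overall fold sizes also differ by at most one
    sizes <- integer(k)
    for (cls in sort(unique(labels))) {
      members <- which(labels == cls)
      if (length(members) < k)
        stop("class ", cls, " has fewer than k = ", k, " samples", call. = FALSE)
      base <- length(members) %/% k
      extra <- length(members) %% k
      counts <- rep(base, k)
      if (extra > 0) {
        bump <- order(sizes, seq_len(k))[seq_len(extra)]
        counts[bump] <- counts[bump] + 1L
      }
      fold[sample(members)] <- rep(seq_len(k), counts)
      sizes <- sizes + counts
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  structure(list(k = k, fold = fold, stratified = stratified,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Serialize a window dataset's metadata and plan assignments
#'
#' Writes a columnar text manifest (tab-separated) with one row per
#' window: sample id, subject, condition, channel, band, window index,
#' label, and, when plans are supplied, partition and fold columns.
#'
#' @param dataset A `window_dataset`.
#' @param path Output file.
#' @param split Optional `split_plan`.
#' @param folds Optional `fold_plan`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path, split = NULL, folds = NULL) {
  stopifnot(inherits(dataset, "window_dataset"))
  df <- cbind(sample_id = seq_len(nrow(dataset$meta)), dataset$meta)
  if (!is.null(split)) {
    part <- rep("train", nrow(df))
    part[split$val_idx] <- "val"
    part[split$test_idx] <- "test"
    df$partition <- part
  }
  if (!is.null(folds)) df$fold <- folds$fold
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
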