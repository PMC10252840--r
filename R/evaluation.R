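# Confusion-matrix metrics, ROC/AUC, cross-validation, report export.

#' Confusion matrix from labels and predictions
#'
#' Class 1 is "stress" (positive), class 0 "relax" (negative).
#'
#' @param truth,predicted Integer 0/1 vectors of equal length.
#' @return An object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length", call. = FALSE)
  if (length(truth) == 0L) stop("empty confusion matrix", call. = FALSE)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  structure(
    list(TP = sum(truth == 1L & predicted == 1L),
         FP = sum(truth == 0L & predicted == 1L),
         TN = sum(truth == 0L & predicted == 0L),
         FN = sum(truth == 1L & predicted == 0L)),
    class = "confusion_matrix")
}

# likelihood ratios from percent-scale sensitivity/specificity; division by
# zero yields a flagged Inf rather than an error
.likelihood_ratios <- function(sensitivity, specificity) {
  plr <- if (specificity >= 100) Inf else sensitivity / (100 - specificity)
  nlr <- if (specificity <= 0) Inf else (100 - sensitivity) / specificity
  list(plr = plr, nlr = nlr)
}

#' Likelihood ratios from percent-scale rates
#'
#' `+LR = sensitivity / (100 - specificity)` and
#' `-LR = (100 - sensitivity) / specificity`, both on the percent scale of
#' the published metric table. Undefined ratios return `Inf`.
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`.
#' @return List with `plr` and `nlr`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(is.numeric(sensitivity), is.numeric(specificity))
  .likelihood_ratios(sensitivity, specificity)
}

#' Full metric report from a confusion matrix
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1 on the
#' percent scale, plus positive/negative likelihood ratios (unitless).
#' Degenerate denominators yield flagged `Inf`/`NaN` values, never an
#' error.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) Inf * sign(num + 0.5) else num / den
  accuracy <- (cm$TP + cm$TN) / total * 100
  precision <- div(cm$TP, cm$TP + cm$FP) * 100
  sensitivity <- div(cm$TP, cm$TP + cm$FN) * 100
  specificity <- div(cm$TN, cm$FP + cm$TN) * 100
  f1 <- if (is.finite(precision) && is.finite(sensitivity) &&
            precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NaN
  lr <- .likelihood_ratios(sensitivity, specificity)
  structure(
    list(accuracy = accuracy, precision = precision,
         sensitivity = sensitivity, specificity = specificity, f1 = f1,
         plr = lr$plr, nlr = lr$nlr, confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf(
    "accuracy %.*f%%  precision %.*f%%  sensitivity %.*f%%  specificity %.*f%%  F1 %.*f%%\n",
    digits, x$accuracy, digits, x$precision, digits, x$sensitivity,
    digits, x$specificity, digits, x$f1))
  cat(sprintf("+LR %.4g  -LR %.4g  (TP %d FP %d TN %d FN %d)\n",
              x$plr, x$nlr, x$confusion$TP, x$confusion$FP,
              x$confusion$TN, x$confusion$FN))
  invisible(x)
}

#' ROC curve with tie grouping and trapezoidal AUC
#'
#' One operating point per distinct score (identical scores enter or leave
#' the positive set together), plus the (0,0) and (1,1) endpoints. The
#' area under the curve is computed by the trapezoidal rule, making it
#' invariant under strictly monotone transformations of the scores.
#'
#' @param labels Integer 0/1 truth vector, both classes present.
#' @param probabilities Finite numeric scores, higher = more stress-like.
#' @return An object of class `roc_curve`: `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_curve <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length", call. = FALSE)
  if (any(!is.finite(probabilities)))
    stop("probabilities must be finite", call. = FALSE)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC requires both classes present", call. = FALSE)

  ord <- order(probabilities, decreasing = TRUE)
  s <- probabilities[ord]; y <- labels[ord]
  grp_last <- cumsum(rle(s)$lengths)         # last index of each tie group
  tp <- cumsum(y == 1L)[grp_last]
  fp <- cumsum(y == 0L)[grp_last]
  tpr <- c(0, tp / P, 1)
  fpr <- c(0, fp / N, 1)
  thresholds <- c(Inf, s[grp_last], -Inf)
  keep <- !duplicated(cbind(fpr, tpr))       # collapse repeated endpoints
  fpr <- fpr[keep]; tpr <- tpr[keep]; thresholds <- thresholds[keep]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", length(x$fpr), " points, AUC = ",
      sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Stratified cross-validated training and evaluation
#'
#' For each fold: train on the remaining folds, evaluate on the held-out
#' fold. Fold training seeds derive deterministically from
#' `config$seed + fold`.
#'
#' @param spec A [model_spec()].
#' @param samples A `window_dataset` (or `list(x =, y =)`).
#' @param fold_plan A [make_folds()] plan.
#' @param config A [train_config()].
#' @param window_length Window length; defaults to the dataset's.
#' @return List with `fold_metrics` (list of `metrics_report`),
#'   `fold_accuracy` (numeric vector) and `mean_accuracy`.
#' @export
cross_validate <- function(spec, samples, fold_plan, config = train_config(),
                           window_length = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(fold_plan, "fold_plan"))
  xy <- .as_xy(samples)
  if (is.null(window_length)) window_length <- ncol(xy$x)
  fold_metrics <- vector("list", fold_plan$k)
  for (f in seq_len(fold_plan$k)) {
    hold <- which(fold_plan$fold == f)
    keep <- which(fold_plan$fold != f)
    if (length(unique(xy$y[keep])) < 2L)
      stop("fold ", f, ": training portion contains a single class",
           call. = FALSE)
    cfg <- config
    cfg$seed <- as.integer(config$seed + f)
    model <- build_model(spec, window_length)
    model <- train_model(model,
                         list(x = xy$x[keep, , drop = FALSE], y = xy$y[keep]),
                         config = cfg)
    pred <- predict(model, xy$x[hold, , drop = FALSE],
                    threshold = cfg$classification_threshold)
    fold_metrics[[f]] <- compute_metrics(
      confusion_matrix(xy$y[hold], pred$labels))
  }
  acc <- vapply(fold_metrics, function(m) m$accuracy, numeric(1))
  list(fold_metrics = fold_metrics, fold_accuracy = acc,
       mean_accuracy = mean(acc))
}

#' Export run artifacts as columnar text
#'
#' Writes `metrics.tsv`, `confusion.tsv`, `roc.tsv`, `trace.tsv` and a
#' JSON `manifest.json` (configuration echo; no timestamps, so re-export
#' is byte-identical).
#'
#' @param run A list with any of: `metrics` (a `metrics_report`), `roc`
#'   (a `roc_curve`), `trace` (convergence data frame), `config` (named
#'   list echoed into the manifest).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(run, out_dir) {
  if (!is.list(run)) stop("run must be a list of artifacts", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  written <- character(0)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(run$metrics)) {
    m <- run$metrics
    wt(data.frame(metric = c("accuracy", "precision", "sensitivity",
                             "specificity", "f1", "plr", "nlr"),
                  value = c(m$accuracy, m$precision, m$sensitivity,
                            m$specificity, m$f1, m$plr, m$nlr)),
       "metrics.tsv")
    cm <- m$confusion
    wt(data.frame(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN),
       "confusion.tsv")
  }
  if (!is.null(run$roc))
    wt(data.frame(threshold = run$roc$thresholds, fpr = run$roc$fpr,
                  tpr = run$roc$tpr, auc = run$roc$auc), "roc.tsv")
  if (!is.null(run$trace)) wt(run$trace, "trace.tsv")
  manifest <- run$config
  if (is.null(manifest)) manifest <- list()
  manifest$package_version <- as.character(utils::packageVersion("stresswave"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  written <- c(written, path)
  invisible(written)
}
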