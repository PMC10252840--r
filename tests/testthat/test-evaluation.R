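test_that("metric formulas agree with hand arithmetic", {
  cm <- structure(list(TP = 90L, FN = 10L, TN = 80L, FP = 20L),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)
  expect_equal(m$precision, 90 / 110 * 100)
  expect_equal(m$plr, 4.5)
  expect_equal(m$nlr, 0.125)
  expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))
})

test_that("published sensitivity/specificity reproduce the printed ratios", {
  lr <- likelihood_ratios(98.08, 97.76)
  expect_equal(round(lr$plr), 44)
  expect_equal(round(lr$nlr, 2), 0.02)
})

test_that("degenerate matrices yield flagged values, never errors", {
  perfect <- confusion_matrix(c(0, 0, 1, 1), c(0, 0, 1, 1))
  m <- compute_metrics(perfect)
  expect_equal(m$accuracy, 100)
  expect_equal(m$nlr, 0)
  expect_true(is.infinite(m$plr))
  expect_error(compute_metrics(confusion_matrix(integer(0), integer(0))))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(40)
  for (i in 1:20) {
    truth <- rbinom(60, 1, 0.5)
    pred <- rbinom(60, 1, 0.5)
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(confusion_matrix(truth, pred))
    miss_rate <- m$confusion$FN / (m$confusion$TP + m$confusion$FN) * 100
    fp_rate <- m$confusion$FP / (m$confusion$FP + m$confusion$TN) * 100
    expect_equal(m$sensitivity + miss_rate, 100)
    expect_equal(m$specificity + fp_rate, 100)
    # accuracy = prevalence-weighted mean of sensitivity and specificity
    npos <- m$confusion$TP + m$confusion$FN
    nneg <- m$confusion$FP + m$confusion$TN
    expect_equal(m$accuracy,
                 (m$sensitivity * npos + m$specificity * nneg) / (npos + nneg))
  }
})

test_that("ROC endpoints, ties and AUC behave canonically", {
  # perfect separation
  r <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1.0)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
  # all-tied scores collapse to the chance diagonal
  r2 <- roc_curve(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(r2$auc, 0.5)
  expect_equal(length(r2$fpr), 2L)   # tie group collapses onto the endpoint
  # label-independent scores give AUC ~ 0.5 (permutation null)
  set.seed(123)
  n <- 10000
  labels <- rbinom(n, 1, 0.5)
  scores <- runif(n)
  r3 <- roc_curve(labels, scores)
  expect_gt(r3$auc, 0.48); expect_lt(r3$auc, 0.52)
  expect_error(roc_curve(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  labels <- rbinom(300, 1, 0.4)
  scores <- rnorm(300) + labels
  a1 <- roc_curve(labels, scores)$auc
  a2 <- roc_curve(labels, exp(scores))$auc
  a3 <- roc_curve(labels, stats::plogis(scores))$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("AUC equals the Wilcoxon rank statistic (independent oracle)", {
  set.seed(55)
  labels <- rbinom(200, 1, 0.5)
  scores <- rnorm(200) + 0.8 * labels
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wilcox_auc <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(roc_curve(labels, scores)$auc, wilcox_auc)
})

test_that("the ROC operating point at a cut matches direct thresholding", {
  set.seed(17)
  labels <- rbinom(500, 1, 0.5)
  probs <- stats::plogis(rnorm(500) + labels)
  r <- roc_curve(labels, probs)
  cut <- 0.5
  # curve point: last tie group whose threshold is >= the cut
  idx <- max(which(r$thresholds >= cut))
  cm <- confusion_matrix(labels, as.integer(probs >= cut))
  m <- compute_metrics(cm)
  expect_equal(r$tpr[idx], m$sensitivity / 100)
  expect_equal(r$fpr[idx], 1 - m$specificity / 100)
})

test_that("export_report writes byte-stable columnar artifacts", {
  truth <- rep(0:1, each = 10)
  pred <- c(rep(0, 8), rep(1, 2), rep(1, 9), 0)
  run <- list(
    metrics = compute_metrics(confusion_matrix(truth, pred)),
    roc = roc_curve(truth, seq(0, 1, length.out = 20)),
    trace = data.frame(epoch = 1:3, train_loss = c(0.6, 0.5, 0.4),
                       train_acc = c(0.6, 0.7, 0.8),
                       val_loss = NA_real_, val_acc = NA_real_),
    config = list(model = "CBGG", seed = 7L))
  dir <- withr::local_tempdir()
  files <- export_report(run, dir)
  expect_true(all(file.exists(files)))
  metrics <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(metrics$value[metrics$metric == "accuracy"], 85)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$model, "CBGG")
  expect_equal(manifest$seed, 7L)
  # re-export is byte-identical (no timestamps in the artifacts)
  before <- lapply(files, readLines)
  export_report(run, dir)
  expect_identical(lapply(files, readLines), before)
})
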