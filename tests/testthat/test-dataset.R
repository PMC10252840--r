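make_recs <- function(n_subjects = 1L, duration = 10, seed = 1) {
  cfg <- tiny_sim(seed = seed, n_subjects = n_subjects, duration = duration)
  recs <- list()
  for (s in seq_len(n_subjects)) for (cond in c("lo", "hi"))
    recs[[length(recs) + 1L]] <- generate_recording(cfg, s, cond)
  recs
}

test_that("window counts follow floor(len / window_length) x channels x bands", {
  recs <- make_recs(duration = 10)            # 1280 samples per channel
  ds <- make_windows(recs, wavelet_config(), 128)
  expect_equal(nrow(ds$values), 2 * 14 * 10)  # 2 recordings
  expect_equal(ncol(ds$values), 128L)
  per_band <- make_windows(recs[1], wavelet_config(), 128, mode = "per_band")
  expect_equal(nrow(per_band$values), 5 * 14 * 10)
  expect_setequal(unique(per_band$meta$band),
                  c("Delta", "Theta", "Alpha", "Beta", "Gamma"))
  # full-length windows: one per channel
  whole <- make_windows(recs[1], NULL, ncol(recs[[1]]$data))
  expect_equal(nrow(whole$values), 14L)
  expect_error(make_windows(recs[1], NULL, 10 * 128 + 1), "exceeds")
})

test_that("windows inherit the recording's binary label", {
  recs <- make_recs(duration = 5)
  ds <- make_windows(recs, NULL, 128)
  expect_setequal(unique(ds$meta$label[ds$meta$condition == "hi"]), 1L)
  expect_setequal(unique(ds$meta$label[ds$meta$condition == "lo"]), 0L)
})

test_that("split plan: 70/30 outer, 70/30 inner, stratified, deterministic", {
  labels <- rep(0:1, each = 50)
  sp <- make_split(labels, seed = 11)
  expect_length(sp$test_idx, 30L)
  expect_length(sp$val_idx, 21L)
  expect_length(sp$train_idx, 49L)
  all_idx <- c(sp$train_idx, sp$val_idx, sp$test_idx)
  expect_setequal(all_idx, seq_along(labels))
  expect_equal(length(all_idx), length(unique(all_idx)))
  sp2 <- make_split(labels, seed = 11)
  expect_identical(sp, sp2)
  expect_false(identical(sp, make_split(labels, seed = 12)))
})

test_that("stratification preserves an unbalanced class ratio within 1", {
  labels <- rep(0:1, times = c(600, 400))
  sp <- make_split(labels, seed = 3)
  for (part in list(sp$train_idx, sp$val_idx, sp$test_idx)) {
    frac1 <- sum(labels[part] == 1)
    expect_lt(abs(frac1 - 0.4 * length(part)), 1 + 1e-9)
  }
})

test_that("split input validation", {
  expect_error(make_split(rep(0:1, 4)), "at least 10")
  expect_error(make_split(rep(1L, 50)), "both classes")
})

test_that("fold plans are disjoint, exhaustive and balanced", {
  labels <- rep(0:1, each = 50)
  fp <- make_folds(labels, k = 10, seed = 5)
  expect_equal(sort(unique(fp$fold)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(fp$fold == f & labels == 0), 5L)
    expect_equal(sum(fp$fold == f & labels == 1), 5L)
  }
  # 95 samples, k = 10: fold sizes 9 or 10
  labels2 <- rep(0:1, length.out = 95)
  fp2 <- make_folds(labels2, k = 10, seed = 5)
  expect_true(all(table(fp2$fold) %in% c(9L, 10L)))
  # proportionality within 1 per class
  for (cls in 0:1) {
    per_fold <- table(fp2$fold[labels2 == cls])
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_identical(fp, make_folds(labels, k = 10, seed = 5))
  expect_error(make_folds(rep(0:1, 3), k = 10), "exceeds")
  expect_error(make_folds(rep(c(0, 1, 1, 1), 10), k = 15), "fewer than k")
})

test_that("subject-grouped splits never leak a subject across partitions", {
  recs <- make_recs(n_subjects = 6L, duration = 4, seed = 9)
  ds <- make_windows(recs, NULL, 128)
  sp <- make_split(ds, seed = 2, group_by_subject = TRUE)
  subj_of <- function(idx) unique(ds$meta$subject[idx])
  expect_length(intersect(subj_of(sp$train_idx), subj_of(sp$test_idx)), 0L)
  expect_length(intersect(subj_of(sp$train_idx), subj_of(sp$val_idx)), 0L)
  expect_length(intersect(subj_of(sp$val_idx), subj_of(sp$test_idx)), 0L)
})

test_that("manifests serialize all metadata columns", {
  recs <- make_recs(duration = 4)
  ds <- make_windows(recs, NULL, 128)
  sp <- make_split(ds, seed = 1)
  fp <- make_folds(ds, k = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(ds, path, split = sp, folds = fp)
  df <- read.delim(path)
  expect_equal(nrow(df), nrow(ds$values))
  expect_true(all(c("sample_id", "subject", "channel", "band", "label",
                    "partition", "fold") %in% names(df)))
  expect_setequal(unique(df$partition), c("train", "val", "test"))
})
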