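# mean-shifted, linearly separable toy task: fast to learn, oracle-checked
shift_toy <- function(n = 200, T = 16, seed = 1, delta = 1.5) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * T, mean = ifelse(y == 1, delta, -delta), sd = 1), n, T)
  list(x = X, y = y)
}

test_that("closed-form parameter counts match the published two-layer totals", {
  expect_identical(count_parameters(model_spec("CNN-RNN")), 12673L)
  expect_identical(count_parameters(model_spec("CNN-LSTM")), 49729L)
  expect_identical(count_parameters(model_spec("CNN-GRU")), 37569L)
  # single-bias GRU accounting differs by exactly 3u per GRU layer
  expect_identical(
    count_parameters(model_spec("CNN-GRU", gru_variant = "single_bias")),
    37569L - 3L * 64L)
  # layer-level sanity: dense on 16 inputs
  spec <- model_spec("CBGG")
  dense <- spec$layers[[length(spec$layers)]]
  expect_identical(dense$input_dim, 16L)
  expect_identical(stresswave:::.layer_params(dense), 17L)
})

test_that("CBGG stack has the specified layer sequence", {
  spec <- model_spec("CBGG")
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(kinds, c("conv1d", "maxpool1d", "bilstm", "gru2", "gru2",
                        "dropout", "dense"))
  units <- vapply(spec$layers[3:5], function(l) l$units, integer(1))
  expect_equal(units, c(64L, 32L, 16L))
  expect_true(spec$layers[[3]]$return_sequences)
  expect_true(spec$layers[[4]]$return_sequences)
  expect_false(spec$layers[[5]]$return_sequences)
  expect_error(model_spec("CNN-TRANSFORMER"), "unknown model name")
})

test_that("counts equal actual weight sizes for every spec and window length", {
  for (nm in MODEL_NAMES) {
    spec <- model_spec(nm)
    counts <- integer(0)
    for (L in c(64L, 128L, 256L)) {
      set.seed(1)
      w <- stresswave:::.init_weights(spec, L)
      counts <- c(counts, sum(vapply(w, length, integer(1))))
    }
    expect_true(all(counts == count_parameters(spec)), info = nm)
  }
})

test_that("analytic gradients match finite differences on every stack", {
  set.seed(9)
  T <- 8L; n <- 6L
  y <- rep(0:1, 3)
  X <- matrix(rnorm(n * T), n, T)
  for (nm in MODEL_NAMES) {
    m <- build_model(model_spec(nm), T)
    set.seed(2)
    w <- stresswave:::.init_weights(m$spec, T)
    w <- lapply(w, function(m0) m0 + matrix(rnorm(length(m0), sd = 0.05),
                                            nrow(m0)))
    out <- stresswave:::nn_loss_grad_cpp(w, m$arch, X, y)
    worst <- 0
    for (wi in seq_along(w)) {
      nel <- length(w[[wi]])
      for (j in unique(pmin(nel, c(1L, max(1L, nel %/% 3L), nel)))) {
        eps <- 1e-5
        wp <- w; wp[[wi]][j] <- wp[[wi]][j] + eps
        wm <- w; wm[[wi]][j] <- wm[[wi]][j] - eps
        num <- (stresswave:::nn_loss_grad_cpp(wp, m$arch, X, y)$loss -
                  stresswave:::nn_loss_grad_cpp(wm, m$arch, X, y)$loss) /
          (2 * eps)
        ana <- out$grads[[wi]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("a separable toy task is learned to >= 90% (oracle-verified)", {
  toy <- shift_toy()
  # independent check that the task is easy: logistic regression on the
  # window mean reaches >= 90%
  fit <- suppressWarnings(
    stats::glm(toy$y ~ rowMeans(toy$x), family = stats::binomial()))
  expect_gte(mean((stats::fitted(fit) >= 0.5) == (toy$y == 1)), 0.9)

  m <- build_model(model_spec("CNN-RNN"), ncol(toy$x))
  m <- train_model(m, toy, config = train_config(epochs = 20, batch_size = 25,
                                                 seed = 7))
  expect_gte(utils::tail(m$trace$train_acc, 1), 0.9)
})

test_that("training loss is non-increasing in >= 80% of epoch transitions", {
  # full-batch training isolates optimizer behavior from minibatch noise;
  # val set = train set, so val_loss is the end-of-epoch training-set loss
  toy <- shift_toy()
  cfg <- train_config(epochs = 40, batch_size = nrow(toy$x), seed = 7,
                      learning_rate = 5e-4)
  m <- train_model(build_model(model_spec("CNN-RNN"), ncol(toy$x)), toy,
                   val_samples = toy, config = cfg)
  expect_gte(mean(diff(m$trace$val_loss) <= 0), 0.8)
  expect_lt(utils::tail(m$trace$val_loss, 1), m$trace$val_loss[1])
})

test_that("training is deterministic given the seed", {
  toy <- shift_toy(n = 60)
  cfg <- train_config(epochs = 3, batch_size = 20, seed = 5)
  m1 <- train_model(build_model(model_spec("CNN-GRU"), 16), toy, config = cfg)
  m2 <- train_model(build_model(model_spec("CNN-GRU"), 16), toy, config = cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$weights, m2$weights)
  cfg2 <- cfg; cfg2$seed <- 6L
  m3 <- train_model(build_model(model_spec("CNN-GRU"), 16), toy, config = cfg2)
  expect_false(identical(m1$trace, m3$trace))
})

test_that("training rejects degenerate inputs", {
  toy <- shift_toy(n = 40)
  one_class <- list(x = toy$x[toy$y == 1, ], y = toy$y[toy$y == 1])
  m <- build_model(model_spec("CNN-RNN"), 16)
  expect_error(train_model(m, one_class), "single class")
  expect_error(train_model(m, list(x = toy$x[0, , drop = FALSE], y = integer(0))),
               "empty")
  expect_error(train_model(m, list(x = matrix(0, 10, 8),
                                   y = rep(0:1, 5))), "mismatch")
  expect_error(predict(m, toy$x), "not fitted")
})

test_that("prediction respects thresholds, ties and permutation invariance", {
  toy <- shift_toy(n = 60)
  m <- train_model(build_model(model_spec("CNN-RNN"), 16), toy,
                   config = train_config(epochs = 5, batch_size = 20, seed = 2))
  p <- predict(m, toy$x)
  expect_true(all(p$probabilities > 0 & p$probabilities < 1))
  # tie rule: p >= threshold maps to stress
  expect_identical(predict(m, toy$x, threshold = min(p$probabilities))$labels,
                   rep(1L, nrow(toy$x)))
  expect_true(all(predict(m, toy$x,
                          threshold = max(p$probabilities) + 1e-9)$labels == 0L))
  # order permutation leaves probabilities attached to their windows
  set.seed(3)
  perm <- sample(nrow(toy$x))
  p2 <- predict(m, toy$x[perm, ])
  expect_equal(p2$probabilities, p$probabilities[perm], tolerance = 1e-12)
  # constant-zero input still yields a probability strictly inside (0,1)
  p0 <- predict(m, matrix(0, 1, 16))
  expect_gt(p0$probabilities, 0); expect_lt(p0$probabilities, 1)
})

test_that("cross-validation trains per fold and averages accuracies", {
  toy <- shift_toy(n = 80)
  fp <- make_folds(toy$y, k = 2, seed = 4)
  cv <- cross_validate(model_spec("CNN-RNN"), toy, fp,
                       train_config(epochs = 10, batch_size = 20, seed = 11))
  expect_length(cv$fold_accuracy, 2L)
  expect_gte(min(cv$fold_accuracy), 90)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  cv2 <- cross_validate(model_spec("CNN-RNN"), toy, fp,
                        train_config(epochs = 10, batch_size = 20, seed = 11))
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
})
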