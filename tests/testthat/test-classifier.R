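test_that("builds are deterministic in the seed and head starts symmetric", {
  a <- tiny_arch()
  c1 <- build_classifier(a, train_config(seed = 5L))
  c2 <- build_classifier(a, train_config(seed = 5L))
  expect_identical(c1$weights, c2$weights)
  c3 <- build_classifier(a, train_config(seed = 6L))
  expect_false(identical(c1$weights, c3$weights))
  # zero-initialized head: exactly 0.5/0.5 on any input
  x <- array(runif(16 * 16 * 3), dim = c(16L, 16L, 3L))
  p <- predict_proba(c1, list(x))
  expect_identical(as.numeric(p), 0.5)
})

test_that("train_config defaults pin the training protocol", {
  cfg <- train_config()
  expect_identical(cfg$batch_size, 32L)
  expect_identical(cfg$max_epochs, 30L)
  expect_identical(cfg$optimizer, "adagrad")
  expect_identical(cfg$learning_rate, 0.001)
  expect_identical(cfg$loss, "categorical_cross_entropy")
  expect_identical(cfg$activation, "relu")
})

test_that("input size mismatch is a configuration error", {
  clf <- build_classifier(tiny_arch(), train_config(seed = 1L))
  bad <- array(0, dim = c(8L, 8L, 3L))
  expect_error(predict_proba(clf, list(bad)), "configuration error")
  expect_error(arch_config(input_size = c(30L, 30L, 3L)), "divisible")
})

test_that("training precondition errors", {
  clf <- build_classifier(tiny_arch(), train_config(seed = 1L))
  d <- generate_domain(tiny_spec(n_train = 3L))
  one_class <- Filter(function(s) s$label == 0L, d$train)
  expect_error(train_classifier(clf, one_class), "each class")
  expect_error(train_classifier(clf, list()), "samples")
  unl <- d$train
  unl[[1]]$label <- NA_integer_
  expect_error(train_classifier(clf, unl), "labeled")
})

test_that("zero epochs is the identity; training moves weights", {
  clf <- build_classifier(tiny_arch(), train_config(seed = 2L))
  d <- generate_domain(tiny_spec(n_train = 4L, seed = 2L))
  same <- train_classifier(clf, d$train, epochs = 0L)
  expect_identical(same$weights, clf$weights)
  moved <- train_classifier(clf, d$train, epochs = 2L)
  expect_false(identical(moved$weights, clf$weights))
  expect_identical(nrow(moved$train_history), 2L)
})

test_that("separable toy set is learned and loss decreases (3 seeds)", {
  # zero-shift blob geometry at full amplitude and no noise, 50 per class
  for (s in 1:3) {
    spec <- domain_shift_spec("T", image_size = c(32L, 32L, 3L),
                              n_train_per_class = 50L, n_test_per_class = 10L,
                              seed = s, class_signal_amplitude = 1,
                              texture_noise_sd = 0, background_level = 0.2)
    d <- generate_domain(spec)
    clf <- build_classifier(arch_config(input_size = c(32L, 32L, 3L)),
                            train_config(seed = s + 10L))
    clf <- train_classifier(clf, d$train)
    h <- clf$train_history
    expect_gte(h$accuracy[nrow(h)], 0.95)
    expect_lte(h$loss[nrow(h)], h$loss[1])
  }
})

test_that("predict_proba is a pure batch-order-preserving function", {
  d <- generate_domain(tiny_spec(n_train = 4L, seed = 7L))
  clf <- build_classifier(tiny_arch(), train_config(seed = 7L))
  clf <- train_classifier(clf, d$train, epochs = 3L)
  p <- predict_proba(clf, d$test)
  # duplicates in a batch get identical scores
  pdup <- predict_proba(clf, c(d$test[1], d$test[1], d$test[2]))
  expect_identical(pdup[1], pdup[2])
  expect_identical(pdup[3], p[2])
  # two-class probabilities sum to 1
  pm <- attr(p, "probs")
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-6)
  expect_identical(predict_proba(clf, d$test), p)
})

test_that("snapshot/restore round-trips predictions bit-for-bit", {
  d <- generate_domain(tiny_spec(n_train = 5L, seed = 4L))
  clf <- build_classifier(tiny_arch(), train_config(seed = 4L))
  clf <- train_classifier(clf, d$train, epochs = 2L)
  snap <- snapshot_weights(clf, "w1")
  p_before <- predict_proba(clf, d$test)
  clf2 <- train_classifier(clf, d$train, epochs = 2L, seed = 99L)
  expect_false(identical(predict_proba(clf2, d$test), p_before))
  clf3 <- restore_weights(clf2, snap)
  expect_identical(predict_proba(clf3, d$test), p_before)
  expect_identical(clf3$weights_tag, "w1")
})

test_that("weight files embed the architecture and reload exactly", {
  clf <- build_classifier(tiny_arch(), train_config(seed = 12L))
  d <- generate_domain(tiny_spec(n_train = 3L, seed = 12L))
  clf <- train_classifier(clf, d$train, epochs = 1L)
  snap <- snapshot_weights(clf, "w1")
  path <- withr::local_tempfile(fileext = ".json")
  save_weights(snap, path)
  back <- load_weights(path)
  expect_identical(back$tag, "w1")
  expect_identical(unclass(back$arch), unclass(snap$arch))
  expect_identical(back$weights$dense$W, snap$weights$dense$W)
  for (l in seq_along(snap$weights$conv))
    expect_identical(back$weights$conv[[l]]$W, snap$weights$conv[[l]]$W)
  clf_back <- restore_weights(clf, back)
  expect_identical(predict_proba(clf_back, d$test), predict_proba(clf, d$test))
})

test_that("grad_cam satisfies its contract on real classifiers", {
  d <- generate_domain(tiny_spec(n_train = 5L, seed = 6L))
  clf <- build_classifier(tiny_arch(), train_config(seed = 6L))
  # all-zero head: zero gradient, all-zero heatmap
  hm0 <- grad_cam(clf, d$test[[1]])
  expect_true(all(hm0 == 0))
  clf <- train_classifier(clf, d$train, epochs = 3L)
  hm <- grad_cam(clf, d$test[[1]])
  expect_identical(dim(hm), c(16L, 16L))
  expect_gte(min(hm), 0)
  expect_lte(max(hm), 1)
})

test_that("grad_cam matches the analytic toy-network computation", {
  # one conv block, one filter, single-channel 8x8 input, gain 1
  arch <- arch_config(input_size = c(8L, 8L, 1L), conv_filters = 1L,
                      logit_gain = 1)
  clf <- build_classifier(arch, train_config(seed = 1L))
  W <- array(0, dim = c(3L, 3L, 1L, 1L))
  W[2, 2, 1, 1] <- 1; W[1, 2, 1, 1] <- 0.5; W[3, 2, 1, 1] <- -0.25
  clf$weights$conv[[1]]$W <- W
  clf$weights$conv[[1]]$b <- 0.01
  clf$weights$dense$W <- matrix(c(-0.3, 0.8), 1L, 2L)
  clf$weights$dense$b <- c(0, 0)
  x <- array(0, dim = c(8L, 8L, 1L))
  x[3, 5, 1] <- 1  # one-hot input
  hm <- grad_cam(clf, x, target_class = 1L)

  # oracle: manual chain rule on the toy network
  Z <- pmax(conv2d_ref(x[, , 1], W[, , 1, 1]) + 0.01, 0)
  # max-pool 2x2 gradient routing
  dZ <- matrix(0, 8, 8)
  dgap <- clf$weights$dense$W[1, 2]     # d logit_1 / d gap
  for (i in 1:4) for (j in 1:4) {
    blk <- Z[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    am <- which(blk == max(blk), arr.ind = TRUE)[1, ]
    dZ[2 * i - 2 + am[1], 2 * j - 2 + am[2]] <-
      dZ[2 * i - 2 + am[1], 2 * j - 2 + am[2]] + dgap / 16
  }
  alpha <- mean(dZ)
  cam <- pmax(alpha * Z, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  expect_equal(hm, cam, tolerance = 1e-12)
  expect_identical(which.max(hm), which.max(cam))
})

test_that("warm-started fine-tuning changes weights", {
  src <- generate_domain(tiny_spec("S", n_train = 6L, seed = 1L))
  tgt <- generate_domain(tiny_spec("G", n_train = 6L, seed = 2L,
                                   intensity_mean_shift = 0.2))
  clf <- build_classifier(tiny_arch(), train_config(seed = 3L))
  clf <- train_classifier(clf, src$train, epochs = 2L)
  w1 <- clf$weights
  clf <- train_classifier(clf, tgt$train, epochs = 2L, seed = 4L)
  expect_false(identical(clf$weights, w1))
})
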