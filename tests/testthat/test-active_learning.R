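test_that("least_confidence scores binary posteriors", {
  expect_identical(least_confidence(0.5), 0.5)
  expect_identical(least_confidence(1), 0)
  expect_equal(least_confidence(0.8), 0.2)
  p <- runif(50)
  expect_equal(least_confidence(p), least_confidence(1 - p))
  expect_true(all(least_confidence(p) >= 0 & least_confidence(p) <= 0.5))
  expect_error(least_confidence(1.2), "\\[0, 1\\]")
  expect_error(least_confidence(-0.1), "\\[0, 1\\]")
})

test_that("select_queries picks the most uncertain, ties by id", {
  expect_identical(select_queries(c(a = 0.05, b = 0.49, c = 0.30), 1), "b")
  expect_identical(select_queries(c(b = 0.30, a = 0.30), 1), "a")
  expect_identical(select_queries(c(a = 0.1, b = 0.4, c = 0.2), 10),
                   c("b", "c", "a"))
  expect_error(select_queries(numeric(0), 1), "pool exhausted")
  expect_error(select_queries(c(0.1, 0.2), 1), "named")
})

test_that("select_queries equals an exhaustive sort oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:500, 1)
    scores <- round(runif(n, 0, 0.5), 2)  # coarse grid forces ties
    names(scores) <- replicate(n, paste(sample(letters, 6, TRUE),
                                        collapse = ""))
    scores <- scores[!duplicated(names(scores))]
    k <- sample(seq_along(scores), 1)
    oracle <- names(scores)[order(-scores, names(scores))][seq_len(k)]
    expect_identical(select_queries(scores, k), oracle)
  }
})

test_that("random baseline is seeded, uniform, exhaustive at n = pool", {
  expect_identical(random_query_baseline("a", 1, 1L), "a")
  ids <- sprintf("s%02d", 1:20)
  d1 <- random_query_baseline(ids, 5, 42L)
  expect_identical(random_query_baseline(ids, 5, 42L), d1)
  expect_false(identical(random_query_baseline(ids, 5, 43L), d1))
  full <- random_query_baseline(ids, 20, 7L)
  expect_setequal(full, ids)
  expect_error(random_query_baseline(character(0), 1, 1L), "pool exhausted")
})

test_that("al_config derives the per-iteration batch per the loop arithmetic", {
  cfg <- al_config(N = 100, l = 20, m = 4)
  expect_identical(cfg$n, 20L)
  expect_error(al_config(N = 10, l = 10, m = 2), "0 < l < N")
  expect_error(al_config(N = 10, l = 9, m = 5), "< 1")
})

test_that("AL loop: budget arithmetic, partition, remainder, no leakage", {
  d <- generate_domain(tiny_spec(n_train = 50L, n_test = 10L, seed = 21L))
  clf <- build_classifier(tiny_arch(), train_config(seed = 21L))
  # N = 100, l = 20, m = 3 -> n = 26 with remainder absorbed at the end
  cfg <- al_config(N = 100, l = 20, m = 3, seed = 5L)
  res <- run_active_learning(clf, d, d$test, config = cfg,
                             epochs_per_iter = 1L)
  h <- res$state$history
  expect_identical(h$n_labeled, c(20L, 46L, 72L, 100L))
  expect_identical(h$fraction_labeled[4], 1)
  expect_identical(res$state$iteration, 3L)
  expect_length(res$state$unlabeled_ids, 0L)
  pool_ids <- vapply(d$train, `[[`, character(1), "sample_id")
  expect_setequal(res$state$labeled_ids, pool_ids)
  test_ids <- vapply(d$test, `[[`, character(1), "sample_id")
  expect_length(intersect(res$state$labeled_ids, test_ids), 0L)
  expect_identical(res$classifier$weights_tag, "w12")
})

test_that("AL loop is deterministic under a fixed seed (both strategies)", {
  d <- generate_domain(tiny_spec(n_train = 20L, n_test = 5L, seed = 31L))
  for (strat in c("least_confidence", "random")) {
    cfg <- al_config(N = 40, l = 10, m = 2, strategy = strat, seed = 9L)
    r1 <- run_active_learning(build_classifier(tiny_arch(),
                                               train_config(seed = 2L)),
                              d, d$test, config = cfg, epochs_per_iter = 1L)
    r2 <- run_active_learning(build_classifier(tiny_arch(),
                                               train_config(seed = 2L)),
                              d, d$test, config = cfg, epochs_per_iter = 1L)
    expect_identical(r1$state$labeled_ids, r2$state$labeled_ids)
    expect_identical(r1$state$history, r2$state$history)
    expect_identical(r1$classifier$weights, r2$classifier$weights)
  }
})

test_that("config/pool mismatch and oracle failure are errors", {
  d <- generate_domain(tiny_spec(n_train = 10L, n_test = 2L, seed = 41L))
  clf <- build_classifier(tiny_arch(), train_config(seed = 1L))
  expect_error(run_active_learning(clf, d, d$test,
                                   config = al_config(50, 10, 2)),
               "config\\$N")
  bad_oracle <- function(ids) rep(NA_integer_, length(ids))
  expect_error(run_active_learning(clf, d, d$test,
                                   config = al_config(20, 4, 2, seed = 1L),
                                   oracle = bad_oracle, epochs_per_iter = 0L),
               "oracle failed")
})

test_that("uncertainty querying prefers ambiguous samples", {
  # classifier probabilities fixed by construction: scores near 0.5 win
  scores <- c(x1 = 0.49, x2 = 0.01, x3 = 0.25, x4 = 0.45)
  picked <- select_queries(scores, 2)
  expect_identical(picked, c("x1", "x4"))
})
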