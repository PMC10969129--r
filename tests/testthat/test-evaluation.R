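test_that("confusion counts partition the samples", {
  cc <- confusion_counts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_identical(unclass(cc)[c("Tp", "Tn", "Fp", "Fn")],
                   list(Tp = 5L, Tn = 5L, Fp = 0L, Fn = 0L))
  cc2 <- confusion_counts(rep(c(1, 0), each = 5), rep(1, 10))
  expect_identical(cc2$Tp, 5L)
  expect_identical(cc2$Fp, 5L)
  expect_identical(cc2$Tn + cc2$Fn, 0L)
  expect_error(confusion_counts(c(0, 1), c(1)), "length")
  expect_error(confusion_counts(c(0, 2), c(1, 1)), "0 or 1")
})

test_that("confusion counts match a brute-force tally on random labels", {
  set.seed(7)
  for (rep in 1:20) {
    truth <- sample(0:1, 200, TRUE)
    pred <- sample(0:1, 200, TRUE)
    cc <- confusion_counts(truth, pred)
    tally <- c(Tp = 0L, Tn = 0L, Fp = 0L, Fn = 0L)
    for (i in 1:200) {
      key <- if (truth[i] == 1L && pred[i] == 1L) "Tp"
        else if (truth[i] == 0L && pred[i] == 0L) "Tn"
        else if (truth[i] == 0L && pred[i] == 1L) "Fp" else "Fn"
      tally[key] <- tally[key] + 1L
    }
    expect_identical(unlist(unclass(cc)[names(tally)]), tally)
  }
})

test_that("metric formulas match direct substitution", {
  m <- compute_metrics(structure(list(Tp = 40L, Tn = 30L, Fp = 20L, Fn = 10L),
                                 class = "confusion_counts"))
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$precision, 40 / 60)
  expect_equal(m$recall, 0.80)
  expect_equal(m$f1, 2 * (40 / 60) * 0.8 / ((40 / 60) + 0.8))
  perfect <- compute_metrics(confusion_counts(rep(c(1, 0), 50),
                                              rep(c(1, 0), 50)))
  expect_identical(c(perfect$accuracy, perfect$precision, perfect$recall,
                     perfect$f1), rep(1, 4))
})

test_that("degenerate denominators yield flagged zeros", {
  m <- compute_metrics(confusion_counts(c(0, 0, 0), c(0, 0, 0)))
  expect_identical(m$precision, 0)
  expect_identical(m$recall, 0)
  expect_true(all(c("precision", "recall") %in% m$degenerate))
})

test_that("AUC limit cases and invariances", {
  truth <- rep(c(1, 0), each = 5)
  m_perf <- compute_metrics(confusion_counts(truth, truth),
                            scores = c(seq(0.9, 0.5, -0.1),
                                       seq(0.4, 0, -0.1)), truth = truth)
  expect_identical(m_perf$auc, 1)
  m_const <- compute_metrics(confusion_counts(truth, truth),
                             scores = rep(0.5, 10), truth = truth)
  expect_identical(m_const$auc, 0.5)
  # invariance under strictly monotone score transformations
  set.seed(3)
  sc <- runif(40)
  tr <- sample(0:1, 40, TRUE)
  cc <- confusion_counts(tr, as.integer(sc > 0.5))
  a1 <- compute_metrics(cc, scores = sc, truth = tr)$auc
  a2 <- compute_metrics(cc, scores = qlogis(sc * 0.98 + 0.01),
                        truth = tr)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC agrees with brute-force pairwise concordance", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    truth <- sample(0:1, n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0L, 1L)
    scores <- round(runif(n), 2)  # ties likely
    m <- compute_metrics(confusion_counts(truth, as.integer(scores > 0.5)),
                         scores = scores, truth = truth)
    pos <- scores[truth == 1L]; neg <- scores[truth == 0L]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(m$auc, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("combined test sets pool counts without reweighting", {
  d <- generate_domain(tiny_spec(n_train = 2L, n_test = 5L, seed = 51L))
  e <- generate_domain(tiny_spec("U", n_train = 2L, n_test = 3L, seed = 52L))
  comb <- build_combined_test(d$test, e$test)
  expect_length(comb, 16L)
  expect_identical(attr(comb, "test_set_tag"), "T1+T2")
  # combining a set with itself doubles every confusion count
  clf <- build_classifier(tiny_arch(), train_config(seed = 1L))
  clf <- train_classifier(clf, d$train, epochs = 1L)
  twice <- build_combined_test(d$test, d$test)
  m1 <- evaluate_classifier(clf, d$test)
  m2 <- evaluate_classifier(clf, twice)
  for (f in c("Tp", "Tn", "Fp", "Fn"))
    expect_identical(m2$counts[[f]], 2L * m1$counts[[f]])
  # pooled accuracy equals (correct_A + correct_B) / (n_A + n_B)
  mA <- evaluate_classifier(clf, d$test)
  mB <- evaluate_classifier(clf, e$test)
  mAB <- evaluate_classifier(clf, comb)
  correct <- mA$accuracy * mA$n_samples + mB$accuracy * mB$n_samples
  expect_equal(mAB$accuracy, correct / (mA$n_samples + mB$n_samples),
               tolerance = 1e-12)
  unl <- d$test
  unl[[1]]$label <- NA_integer_
  expect_error(build_combined_test(unl, e$test), "labeled")
})

test_that("evaluation matrix is the snapshot x test-set cross product", {
  d <- generate_domain(tiny_spec(n_train = 3L, n_test = 3L, seed = 61L))
  e <- generate_domain(tiny_spec("U", n_train = 3L, n_test = 3L, seed = 62L))
  mk <- function(s) train_classifier(
    build_classifier(tiny_arch(), train_config(seed = s)), d$train,
    epochs = 1L)
  clfs <- list(w1 = mk(1L), w2 = mk(2L), w12 = mk(3L))
  tests <- list(T1 = d$test, `T1+T2` = build_combined_test(d$test, e$test))
  tab <- evaluate_matrix(clfs, tests)
  expect_identical(nrow(tab), 6L)
  expect_setequal(unique(tab$weights_tag), names(clfs))
  expect_setequal(unique(tab$test_set_tag), names(tests))
  expect_identical(evaluate_matrix(clfs, tests), tab)
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})
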