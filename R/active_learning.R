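#' Least-confidence uncertainty score
#'
#' For a binary posterior `P = P(class 1 | x)` the score is
#' `min(P, 1 - P)`: 0 for a fully confident prediction, 0.5 at maximal
#' uncertainty, symmetric under `P -> 1 - P`. The active-learning loop
#' queries the samples with the *largest* score.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Scores in `[0, 0.5]`, same length and names as `p`.
#' @export
least_confidence <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_param("p", "probabilities must lie in [0, 1]")
  pmin(p, 1 - p)
}

#' Select the most uncertain samples from a scored pool
#'
#' Returns the ids with the largest least-confidence scores (predicted
#' probability closest to 0.5). Ties are broken by ascending sample id;
#' the output is ordered by (descending score, ascending id). Asking for
#' more than the pool holds returns the whole pool in that order.
#'
#' @param scores Named numeric vector: `sample_id -> score`.
#' @param n_query Number of samples to select, >= 1.
#' @return Character vector of selected sample ids.
#' @export
select_queries <- function(scores, n_query) {
  if (length(scores) == 0L)
    stop("state error: pool exhausted (no scores to query)", call. = FALSE)
  ids <- names(scores)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop_param("scores", "must be a named vector of sample scores")
  if (!is_count(n_query)) stop_param("n_query", "must be a positive count")
  ord <- order(-as.numeric(scores), ids, method = "radix")
  ids[ord][seq_len(min(n_query, length(scores)))]
}

#' Random query baseline
#'
#' Uniform draw without replacement from the unlabeled pool; the control
#' condition against which uncertainty sampling's label efficiency is
#' measured.
#'
#' @param unlabeled_ids Character vector of pool ids.
#' @param n_query Number to draw (capped at the pool size).
#' @param seed Integer seed; same seed, same draw.
#' @return Character vector of selected ids.
#' @export
random_query_baseline <- function(unlabeled_ids, n_query, seed) {
  if (length(unlabeled_ids) == 0L)
    stop("state error: pool exhausted", call. = FALSE)
  if (!is_count(n_query)) stop_param("n_query", "must be a positive count")
  # sort first so the draw is independent of the caller's id order
  ids <- sort(unlabeled_ids)
  with_seed(seed, sample(ids, min(n_query, length(ids))))
}

#' Active-learning budget configuration
#'
#' `N` is the target pool size, `l` the initially labeled count, `m` the
#' number of query-and-retrain iterations; each iteration adds
#' `n = floor((N - l) / m)` oracle-labeled samples, with the final
#' iteration absorbing any remainder so labeling ends at exactly `N`.
#'
#' @param N Total pool size.
#' @param l Initially labeled count, `0 < l < N`.
#' @param m Iteration count, >= 1.
#' @param strategy `"least_confidence"` or `"random"`.
#' @param seed Integer seed for the initial stratified draw and the
#'   random strategy.
#' @return An object of class `al_config` with the derived `n`.
#' @export
al_config <- function(N, l, m, strategy = c("least_confidence", "random"),
                      seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is_count(N)) stop_param("N", "must be a positive count")
  if (!is_count(l) || l >= N)
    stop_param("l", "must satisfy 0 < l < N")
  if (!is_count(m)) stop_param("m", "must be a positive count")
  n <- (N - l) %/% m
  if (n < 1L)
    stop_param("m", sprintf("per-iteration batch floor((N-l)/m) = %d < 1", n))
  structure(list(N = as.integer(N), l = as.integer(l), m = as.integer(m),
                 n = as.integer(n), strategy = strategy,
                 seed = as.integer(seed)),
            class = "al_config")
}

# Class-stratified initial labeled draw (true labels known to the oracle).
initial_labeled_ids <- function(pool_ids, pool_labels, l, seed) {
  ids0 <- sort(pool_ids[pool_labels == 0L])
  ids1 <- sort(pool_ids[pool_labels == 1L])
  n0 <- ceiling(l / 2); n1 <- l - n0
  if (n0 > length(ids0) || n1 > length(ids1))
    stop("configuration error: pool too small for stratified initial draw",
         call. = FALSE)
  with_seed(derive_seed(seed, "al", "init"),
            c(sample(ids0, n0), sample(ids1, n1)))
}

#' Run the iterative label-and-retrain loop
#'
#' Starting from a classifier carrying source-domain weights, the loop
#' (i) trains on the `l` initially labeled target samples (warm start,
#' recorded as iteration 0), then for each of `m` iterations (ii) scores
#' the unlabeled pool with [least_confidence()] over [predict_proba()],
#' (iii) moves the top-`n` most uncertain samples (or a random batch
#' under the `"random"` strategy) into the labeled set with their oracle
#' labels, (iv) retrains from the current weights, and (v) records
#' metrics on the target test set (and optionally a combined test set).
#' After the final iteration the labeled set is the whole pool and the
#' resulting weights are tagged `"w12"`.
#'
#' True pool labels are masked from the learner: only ids the oracle has
#' been asked about contribute labels to training. Test samples are
#' never eligible for querying.
#'
#' @param classifier An `al_classifier` (typically carrying `"w1"`).
#' @param pool A `domain_dataset` whose `train` split is the query pool.
#' @param test_target List of labeled target-test `image_sample`s.
#' @param test_combined Optional combined (source + target) test list.
#' @param config An [al_config()]; `config$N` must equal the pool size.
#' @param oracle Function `ids -> integer labels`; defaults to the pool's
#'   own true labels (a simulated expert annotator).
#' @param epochs_per_iter Optional override of epochs per retraining.
#' @return `list(classifier =, state =)` where `state` is an `al_state`
#'   with the final partition, the last scores and a `history` data
#'   frame (one row per iteration 0..m: `iteration`, `n_labeled`,
#'   `fraction_labeled`, `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   and `accuracy_combined` when a combined test set is supplied).
#' @export
run_active_learning <- function(classifier, pool, test_target,
                                test_combined = NULL, config,
                                oracle = NULL, epochs_per_iter = NULL) {
  stopifnot(inherits(classifier, "al_classifier"),
            inherits(pool, "domain_dataset"),
            inherits(config, "al_config"))
  pool_samples <- pool$train
  pool_ids <- vapply(pool_samples, `[[`, character(1), "sample_id")
  names(pool_samples) <- pool_ids
  true_labels <- sample_labels(pool_samples)
  names(true_labels) <- pool_ids
  if (length(pool_ids) != config$N)
    stop("configuration error: config$N does not match the pool size",
         call. = FALSE)
  if (anyNA(true_labels) && is.null(oracle))
    stop("configuration error: pool labels unavailable and no oracle given",
         call. = FALSE)
  oracle <- oracle %||% function(ids) unname(true_labels[ids])
  test_ids <- c(vapply(test_target, `[[`, character(1), "sample_id"),
                if (!is.null(test_combined))
                  vapply(test_combined, `[[`, character(1), "sample_id"))

  labeled_ids <- initial_labeled_ids(pool_ids, true_labels, config$l,
                                     config$seed)
  unlabeled_ids <- setdiff(pool_ids, labeled_ids)
  oracle_labels <- fetch_oracle_labels(oracle, labeled_ids)

  history <- list()
  scores <- numeric(0)
  for (iter in 0:config$m) {
    if (iter > 0L) {
      # batch size: final iteration absorbs the remainder so we end at N
      n_i <- if (iter == config$m) length(unlabeled_ids) else config$n
      batch <- if (config$strategy == "least_confidence") {
        p_un <- predict_proba(classifier, pool_samples[unlabeled_ids])
        scores <- least_confidence(p_un)
        names(scores) <- unlabeled_ids
        select_queries(scores, n_i)
      } else {
        random_query_baseline(unlabeled_ids, n_i,
                              derive_seed(config$seed, "al", "rand", iter))
      }
      if (any(batch %in% test_ids))
        stop("state error: query selected a test sample", call. = FALSE)
      oracle_labels <- c(oracle_labels, fetch_oracle_labels(oracle, batch))
      labeled_ids <- c(labeled_ids, batch)
      unlabeled_ids <- setdiff(unlabeled_ids, batch)
    }
    stopifnot(length(intersect(labeled_ids, unlabeled_ids)) == 0L,
              setequal(c(labeled_ids, unlabeled_ids), pool_ids))

    train_set <- pool_samples[labeled_ids]
    for (k in seq_along(train_set)) train_set[[k]]$label <-
      oracle_labels[[labeled_ids[k]]]
    classifier <- train_classifier(classifier, train_set,
                                   epochs = epochs_per_iter,
                                   seed = derive_seed(config$seed, "al",
                                                      "train", iter))
    rec <- evaluate_classifier(classifier, test_target,
                               weights_tag = "al",
                               test_set_tag = "T2")
    row <- data.frame(iteration = iter, n_labeled = length(labeled_ids),
                      fraction_labeled = length(labeled_ids) / config$N,
                      accuracy = rec$accuracy, precision = rec$precision,
                      recall = rec$recall, f1 = rec$f1, auc = rec$auc)
    if (!is.null(test_combined)) {
      recc <- evaluate_classifier(classifier, test_combined,
                                  weights_tag = "al", test_set_tag = "T1+T2")
      row$accuracy_combined <- recc$accuracy
    }
    history[[iter + 1L]] <- row
  }
  classifier$weights_tag <- "w12"
  state <- structure(list(iteration = config$m,
                          labeled_ids = labeled_ids,
                          unlabeled_ids = unlabeled_ids,
                          scores = scores,
                          config = config,
                          history = do.call(rbind, history)),
                     class = "al_state")
  list(classifier = classifier, state = state)
}

fetch_oracle_labels <- function(oracle, ids) {
  lab <- oracle(ids)
  if (length(lab) != length(ids) || anyNA(lab))
    stop(sprintf("state error: oracle failed on requested ids (%s)",
                 paste(head(ids, 3L), collapse = ", ")), call. = FALSE)
  stats::setNames(as.integer(lab), ids)
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<al_state> %d iterations, %d labeled / %d pool (%s)\n",
              x$iteration, length(x$labeled_ids),
              length(x$labeled_ids) + length(x$unlabeled_ids),
              x$config$strategy))
  print(x$history, row.names = FALSE)
  invisible(x)
}
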