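#' Configuration for the three-phase experiment
#'
#' Phase 1 trains on the source domain and measures the cross-domain
#' loss; Phase 2 runs active learning on the target pool starting from
#' the source weights (`w1 -> w12`); Phase 3 trains on the target domain
#' alone from fresh initialization (`w2`) as the reference. All
#' randomness flows from `seed` through named substreams (data,
#' initialization, active learning, baseline), so a run is a pure
#' function of its configuration.
#'
#' @param source_spec,target_spec [domain_shift_spec()]s; their `seed`
#'   fields are overridden per run from the experiment seed.
#' @param arch An [arch_config()].
#' @param train An [train_config()].
#' @param al_l,al_m Initial labeled count and iteration count for the
#'   active-learning phase (defaults: one sixth of the pool, 5
#'   iterations).
#' @param al_strategy Query strategy for Phase 2.
#' @param epochs_per_iter Optional epoch override per AL retraining.
#' @param n_seeds Number of independent replicate runs.
#' @param seed Root seed.
#' @param gradcam_k Explanation panels per condition (most and least
#'   uncertain target test samples).
#' @param output_dir Optional directory for CSV/JSON/PNG artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(source_spec, target_spec,
                              arch = arch_config(),
                              train = train_config(),
                              al_l = NULL, al_m = 5L,
                              al_strategy = "least_confidence",
                              epochs_per_iter = NULL,
                              n_seeds = 1L, seed = 1L,
                              gradcam_k = 2L, output_dir = NULL) {
  stopifnot(inherits(source_spec, "domain_shift_spec"),
            inherits(target_spec, "domain_shift_spec"),
            inherits(arch, "arch_config"), inherits(train, "train_config"))
  if (!is_count(n_seeds)) stop_param("n_seeds", "must be a positive count")
  N <- 2L * target_spec$n_train_per_class
  al_l <- as.integer(al_l %||% max(2L, N %/% 6L))
  structure(list(source_spec = source_spec, target_spec = target_spec,
                 arch = arch, train = train,
                 al_l = al_l, al_m = as.integer(al_m),
                 al_strategy = al_strategy,
                 epochs_per_iter = epochs_per_iter,
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 gradcam_k = as.integer(gradcam_k),
                 output_dir = output_dir),
            class = "experiment_config")
}

respec_seed <- function(spec, seed) {
  spec$seed <- seed
  spec
}

# Compact content digest of a weight set (FNV-1a over the IEEE bytes);
# used by the manifest to assert snapshot identity across reruns.
weight_digest <- function(weights) {
  v <- c(unlist(lapply(weights$conv, function(l) c(l$W, l$b))),
         weights$dense$W, weights$dense$b)
  bytes <- as.integer(writeBin(as.numeric(v), raw()))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Phase 1: source-domain pretraining
#'
#' Trains a fresh classifier on the source train split and evaluates it
#' on the source test set (`M1`) and the combined test set (`Mav1`);
#' the weights are tagged `"w1"`.
#'
#' @param source A source `domain_dataset`.
#' @param test_combined Combined test set from [build_combined_test()].
#' @param arch,train [arch_config()] / [train_config()].
#' @return `list(classifier =, M1 =, Mav1 =)`.
#' @export
run_phase1 <- function(source, test_combined, arch = arch_config(),
                       train = train_config()) {
  clf <- build_classifier(arch, train)
  clf <- train_classifier(clf, source$train)
  clf$weights_tag <- "w1"
  list(classifier = clf,
       M1 = evaluate_classifier(clf, source$test, "w1", "T1"),
       Mav1 = evaluate_classifier(clf, test_combined, "w1", "T1+T2"))
}

#' Phase 2: active learning on the target pool
#'
#' Starts from the `"w1"` classifier and runs the label-and-retrain loop
#' over the target train split; returns the `"w12"` classifier, the loop
#' state (whose history is the labeled-budget curve), and evaluations on
#' the target test set (`M12`) and the combined set (`Mav12`).
#'
#' @param classifier_w1 Classifier from [run_phase1()].
#' @param target Target `domain_dataset` (train split = query pool).
#' @param test_combined Combined test set.
#' @param config An [al_config()].
#' @param epochs_per_iter Optional epoch override per retraining.
#' @return `list(classifier =, state =, M12 =, Mav12 =)`.
#' @export
run_phase2 <- function(classifier_w1, target, test_combined, config,
                       epochs_per_iter = NULL) {
  res <- run_active_learning(classifier_w1, target, target$test,
                             test_combined, config,
                             epochs_per_iter = epochs_per_iter)
  list(classifier = res$classifier, state = res$state,
       M12 = evaluate_classifier(res$classifier, target$test, "w12", "T2"),
       Mav12 = evaluate_classifier(res$classifier, test_combined, "w12",
                                   "T1+T2"))
}

#' Phase 3: target-only training
#'
#' Trains a fresh classifier on the fully labeled target train split
#' (the reference the adapted model is compared against) and evaluates
#' on the target test set (`M2`) and the combined set (`Mav2`); weights
#' tagged `"w2"`.
#'
#' @param target Target `domain_dataset`.
#' @param test_combined Combined test set.
#' @param arch,train [arch_config()] / [train_config()].
#' @return `list(classifier =, M2 =, Mav2 =)`.
#' @export
run_phase3 <- function(target, test_combined, arch = arch_config(),
                       train = train_config()) {
  clf <- build_classifier(arch, train)
  clf <- train_classifier(clf, target$train)
  clf$weights_tag <- "w2"
  list(classifier = clf,
       M2 = evaluate_classifier(clf, target$test, "w2", "T2"),
       Mav2 = evaluate_classifier(clf, test_combined, "w2", "T1+T2"))
}

#' Run the full three-phase protocol
#'
#' For each replicate seed: generate the two-domain benchmark, run
#' Phases 1-3, assemble the evaluation matrix (`w1`, `w2`, `w12` by
#' `T1`, `T2`, `T1+T2`), the labeled-budget curve, and optional Grad-CAM
#' panels for the most and least uncertain target test samples under
#' each weight snapshot. Artifacts (metrics.csv, budget_curve.csv,
#' manifest.json, gradcam/*.png) are written when `output_dir` is set.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_result`: per-seed results,
#'   the pooled `metrics` table, `budget_curves`, the aggregate
#'   mean/sd `summary`, and the run `manifest`.
#' @export
run_full_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  runs <- list()
  metrics <- list()
  curves <- list()
  for (i in seq_len(config$n_seeds)) {
    run_seed <- derive_seed(config$seed, "run", i)
    src_spec <- respec_seed(config$source_spec,
                            derive_seed(run_seed, "data", "source"))
    tgt_spec <- respec_seed(config$target_spec,
                            derive_seed(run_seed, "data", "target"))
    bench <- generate_two_domain_benchmark(src_spec, tgt_spec)
    combined <- build_combined_test(bench$source$test, bench$target$test)

    train_cfg <- config$train
    train_cfg$seed <- derive_seed(run_seed, "init", "w1")
    p1 <- run_phase1(bench$source, combined, config$arch, train_cfg)

    alcfg <- al_config(N = length(bench$target$train), l = config$al_l,
                       m = config$al_m, strategy = config$al_strategy,
                       seed = derive_seed(run_seed, "al"))
    p2 <- run_phase2(p1$classifier, bench$target, combined, alcfg,
                     epochs_per_iter = config$epochs_per_iter)

    train_cfg3 <- config$train
    train_cfg3$seed <- derive_seed(run_seed, "init", "w2")
    p3 <- run_phase3(bench$target, combined, config$arch, train_cfg3)

    clfs <- list(w1 = p1$classifier, w2 = p3$classifier,
                 w12 = p2$classifier)
    tests <- list(T1 = bench$source$test, T2 = bench$target$test,
                  `T1+T2` = combined)
    mt <- evaluate_matrix(clfs, tests)
    mt$seed_index <- i
    metrics[[i]] <- mt
    curve <- p2$state$history
    curve$seed_index <- i
    curves[[i]] <- curve

    if (!is.null(out_dir) && config$gradcam_k > 0L)
      write_gradcam_panels(clfs, bench$target$test, config$gradcam_k,
                           file.path(out_dir, "gradcam", paste0("seed", i)))
    runs[[i]] <- list(seed = run_seed, phase1 = p1, phase2 = p2, phase3 = p3,
                      digests = lapply(clfs,
                                       function(cc) weight_digest(cc$weights)))
  }
  metrics <- do.call(rbind, metrics)
  curves <- do.call(rbind, curves)
  summary <- aggregate(cbind(accuracy, f1, auc) ~ weights_tag + test_set_tag,
                       data = metrics,
                       FUN = function(v) c(mean = mean(v), sd = sd(v)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("alshift")),
    r_version = R.version.string,
    root_seed = config$seed,
    run_seeds = vapply(runs, `[[`, integer(1), "seed"),
    source_spec = unclass(config$source_spec),
    target_spec = unclass(config$target_spec),
    arch = unclass(config$arch), train = unclass(config$train),
    al = list(l = config$al_l, m = config$al_m,
              strategy = config$al_strategy,
              epochs_per_iter = config$epochs_per_iter),
    weight_digests = lapply(runs, `[[`, "digests"),
    artifacts = if (is.null(out_dir)) list() else
      list(metrics = "metrics.csv", budget_curve = "budget_curve.csv"))
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(curves, file.path(out_dir, "budget_curve.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(runs = runs, metrics = metrics, budget_curves = curves,
                 summary = summary, manifest = manifest),
            class = "experiment_result")
}

# Grad-CAM overlays for the k most and k least uncertain target test
# samples under each snapshot.
write_gradcam_panels <- function(classifiers, test_samples, k, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (wt in names(classifiers)) {
    clf <- classifiers[[wt]]
    p <- predict_proba(clf, test_samples)
    unc <- least_confidence(p)
    ord <- order(-unc)
    pick <- c(head(ord, k), head(rev(ord), k))
    kind <- c(rep("uncertain", min(k, length(ord))),
              rep("confident", min(k, length(ord))))
    for (j in seq_along(pick)) {
      s <- test_samples[[pick[j]]]
      hm <- grad_cam(clf, s)
      write_gradcam_overlay(s$pixels, hm,
                            file.path(dir, sprintf("%s_%s_%s.png", wt,
                                                   kind[j], s$sample_id)))
    }
  }
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d seed(s)\n",
              length(x$runs)))
  print(x$summary)
  invisible(x)
}
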