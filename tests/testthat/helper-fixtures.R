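# Shared fixtures: everything is generated in code at test time.

# Small, fast spec: 16x16 images suit the two-block test architecture.
tiny_spec <- function(domain_id = "T", n_train = 10L, n_test = 4L,
                      seed = 1L, ...) {
  domain_shift_spec(domain_id, image_size = c(16L, 16L, 3L),
                    n_train_per_class = n_train, n_test_per_class = n_test,
                    seed = seed, ...)
}

tiny_arch <- function(...) {
  arch_config(input_size = c(16L, 16L, 3L), conv_filters = c(4L, 8L), ...)
}

# Plain image_sample builder for hand-made pixel content.
make_sample <- function(id, pixels, label = 0L, domain_id = "X",
                        split = "train") {
  structure(list(sample_id = id, pixels = pixels, label = label,
                 domain_id = domain_id, split = split),
            class = "image_sample")
}

# Dataset wrapper around a list of samples (train only unless test given).
make_dataset <- function(train, test = list(), domain_id = "X",
                         class_names = c("NC", "ASD")) {
  structure(list(domain_id = domain_id, train = train, test = test,
                 class_names = class_names),
            class = "domain_dataset")
}

# The acceptance suite shares one set of expensive runs (criteria 4-7).
# Cached per session so several test_that blocks can reuse it. The one
# scale-down choice (32x32 images) is documented in the methods
# vignette; pool and test sizes are the stated 300/100 per domain and
# every (re)training uses the full 30-epoch protocol.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_runs <- function(seeds = 1:5, root_seed = 20260910L) {
  key <- paste0("runs_", root_seed, "_", paste(seeds, collapse = "-"))
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  arch <- arch_config(input_size = c(32L, 32L, 3L))
  out <- lapply(seeds, function(s) {
    run_benchmark_protocol(derive_seed_public(root_seed, s), arch)
  })
  .acceptance_cache[[key]] <- out
  out
}

derive_seed_public <- function(root, i) {
  # keep derived seeds below 2^31
  as.integer((as.double(root) * 97L + i * 1009L) %% 2147483647)
}

# One full protocol replicate on the strong-shift benchmark: phases 1-3
# plus an active-learning run under each query strategy (shared by the
# degradation, recovery, label-efficiency and budget-curve criteria).
run_benchmark_protocol <- function(seed, arch,
                                   n_train_per_class = 150L,
                                   n_test_per_class = 50L,
                                   al_l = 50L, al_m = 5L,
                                   epochs_per_iter = 30L) {
  specs <- strong_shift_specs(seed = seed,
                              n_train_per_class = n_train_per_class,
                              n_test_per_class = n_test_per_class,
                              image_size = arch$input_size)
  bench <- generate_two_domain_benchmark(specs$source, specs$target)
  combined <- build_combined_test(bench$source$test, bench$target$test)
  p1 <- run_phase1(bench$source, combined, arch,
                   train_config(seed = seed + 1L))
  p3 <- run_phase3(bench$target, combined, arch,
                   train_config(seed = seed + 2L))
  N <- length(bench$target$train)
  al_lc <- run_phase2(p1$classifier, bench$target, combined,
                      al_config(N, al_l, al_m, "least_confidence",
                                seed = seed + 3L),
                      epochs_per_iter = epochs_per_iter)
  al_rand <- run_phase2(p1$classifier, bench$target, combined,
                        al_config(N, al_l, al_m, "random",
                                  seed = seed + 3L),
                        epochs_per_iter = epochs_per_iter)
  list(seed = seed, bench = bench, combined = combined,
       p1 = p1, p3 = p3, al_lc = al_lc, al_rand = al_rand)
}

# Reference conv (cross-correlation, zero padding) used as the Grad-CAM
# and classifier oracle on toy networks; deliberately independent of the
# package's compiled path.
conv2d_ref <- function(A, W) {
  h <- nrow(A); w <- ncol(A); k <- dim(W)[1]; pad <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      si <- i + di - 1 - pad; sj <- j + dj - 1 - pad
      if (si >= 1 && si <= h && sj >= 1 && sj <= w)
        acc <- acc + A[si, sj] * W[di, dj]
    }
    out[i, j] <- acc
  }
  out
}
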