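#' Normalized pixel-intensity histogram of a dataset
#'
#' Pools every pixel of every sample (train and test, all channels) and
#' bins on fixed equal-width bins over \[0, 1\]; the density sums to 1.
#' The discrepancy between two domains' profiles is the observable form
#' of domain shift this package studies.
#'
#' @param dataset A `domain_dataset` (or plain list of `image_sample`s).
#' @param n_bins Number of bins, >= 2 (default 50).
#' @return An object of class `intensity_profile` with `domain_id`,
#'   `bin_edges` (length `n_bins + 1`), `density` and `n_pixels`.
#' @export
intensity_histogram <- function(dataset, n_bins = 50L) {
  if (!is_count(n_bins, min = 2L)) stop_param("n_bins", "must be >= 2")
  samples <- dataset_samples(dataset)
  if (length(samples) == 0L) stop_param("dataset", "dataset is empty")
  v <- pooled_intensities(samples)
  profile_from_values(v, n_bins,
                      if (inherits(dataset, "domain_dataset"))
                        dataset$domain_id else "")
}

dataset_samples <- function(dataset) {
  if (inherits(dataset, "domain_dataset")) c(dataset$train, dataset$test)
  else dataset
}

pooled_intensities <- function(samples, subsample_per_image = NULL,
                               seed = NULL) {
  vals <- lapply(samples, function(s) {
    v <- as.numeric(s$pixels)
    if (!is.null(subsample_per_image) && length(v) > subsample_per_image)
      v <- v[sample.int(length(v), subsample_per_image)]
    v
  })
  unlist(vals, use.names = FALSE)
}

profile_from_values <- function(v, n_bins, domain_id) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(domain_id = domain_id, bin_edges = edges,
                 density = counts / length(v), n_pixels = length(v)),
            class = "intensity_profile")
}

#' Two-sample t statistic on pooled values
#'
#' Direct implementation of the two-sample t test for a difference in
#' means: `"student_pooled"` uses the pooled-variance formula with
#' `df = nA + nB - 2`; `"welch"` (the default, since equal variances
#' cannot be assumed between image corpora) uses the unequal-variance
#' statistic with Welch-Satterthwaite degrees of freedom. The p value is
#' two-sided. If both groups have zero variance and equal means the
#' result is `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant `"welch"` or `"student_pooled"`.
#' @return An object of class `ttest_result` with `t_value`, `p_value`,
#'   `df` and `variant`.
#' @export
two_sample_tstat <- function(a, b, variant = c("welch", "student_pooled")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_param("a/b", "each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (dm == 0)
      return(structure(list(t_value = 0, p_value = 1,
                            df = if (variant == "welch") NA_real_ else na + nb - 2,
                            variant = variant), class = "ttest_result"))
    stop_param("a/b", "both groups are constant with different means (t undefined)")
  }
  if (variant == "student_pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- dm / se
  structure(list(t_value = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
                 variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<two-sample t (%s)> t = %.4f, df = %.2f, p = %.4g\n",
              x$variant, x$t_value, x$df, x$p_value))
  invisible(x)
}

#' Quantify the shift between two domains
#'
#' Emits pooled and per-class intensity profiles for both datasets plus
#' the two-sample t test on the pooled pixel populations. Because every
#' pixel counts as an observation, p values become degenerate at scale;
#' `subsample_per_image` (seeded) bounds the population while leaving
#' the t statistic's sign and order of magnitude interpretable, and the
#' subsample size used is recorded in the report.
#'
#' @param dataset_A,dataset_B `domain_dataset`s sharing `class_names`.
#' @param n_bins Histogram bins (default 50).
#' @param subsample_per_image Optional cap on pixels drawn per image.
#' @param variant t-test variant, see [two_sample_tstat()].
#' @param seed Seed for the per-image subsample.
#' @return An object of class `domain_comparison`: `profile_A`,
#'   `profile_B`, per-class profiles, `ttest`, and bookkeeping fields.
#' @export
compare_domains <- function(dataset_A, dataset_B, n_bins = 50L,
                            subsample_per_image = NULL,
                            variant = c("welch", "student_pooled"),
                            seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset_A, "domain_dataset"),
            inherits(dataset_B, "domain_dataset"))
  if (!identical(dataset_A$class_names, dataset_B$class_names))
    stop("configuration error: datasets disagree on class_names",
         call. = FALSE)
  get_vals <- function(ds, cls = NULL) {
    ss <- dataset_samples(ds)
    if (!is.null(cls)) ss <- Filter(function(s) identical(s$label, cls), ss)
    ss
  }
  vals <- with_seed(seed, list(
    A = pooled_intensities(get_vals(dataset_A), subsample_per_image),
    B = pooled_intensities(get_vals(dataset_B), subsample_per_image)))
  per_class <- list()
  for (cl in 0:1) {
    cname <- dataset_A$class_names[cl + 1L]
    per_class[[cname]] <- list(
      A = profile_from_values(pooled_intensities(get_vals(dataset_A, cl)),
                              n_bins, dataset_A$domain_id),
      B = profile_from_values(pooled_intensities(get_vals(dataset_B, cl)),
                              n_bins, dataset_B$domain_id))
  }
  structure(list(
    profile_A = profile_from_values(vals$A, n_bins, dataset_A$domain_id),
    profile_B = profile_from_values(vals$B, n_bins, dataset_B$domain_id),
    per_class = per_class,
    ttest = two_sample_tstat(vals$A, vals$B, variant),
    n_bins = n_bins, subsample_per_image = subsample_per_image,
    seed = seed), class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat(sprintf("<domain_comparison '%s' vs '%s'>\n",
              x$profile_A$domain_id, x$profile_B$domain_id))
  cat(sprintf("  pooled pixels: %d vs %d (%s per image)\n",
              x$profile_A$n_pixels, x$profile_B$n_pixels,
              if (is.null(x$subsample_per_image)) "all"
              else as.character(x$subsample_per_image)))
  print(x$ttest)
  invisible(x)
}
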