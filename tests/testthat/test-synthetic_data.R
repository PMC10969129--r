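test_that("spec validation names the offending field", {
  expect_error(tiny_spec(class_signal_amplitude = 1.5),
               "class_signal_amplitude")
  expect_error(tiny_spec(intensity_mean_shift = 0.7), "intensity_mean_shift")
  expect_error(tiny_spec(intensity_scale = 0), "intensity_scale")
  expect_error(tiny_spec(texture_noise_sd = -0.1), "texture_noise_sd")
  expect_error(tiny_spec(background_level = 2), "background_level")
  expect_error(tiny_spec(n_train_per_class = 0), "n_train_per_class")
  expect_error(domain_shift_spec(""), "domain_id")
})

test_that("zero-signal, zero-noise spec degenerates to a flat background", {
  spec <- tiny_spec(class_signal_amplitude = 0, texture_noise_sd = 0,
                    intensity_mean_shift = 0, intensity_scale = 1,
                    background_level = 0.4)
  d <- generate_domain(spec)
  for (s in c(d$train, d$test))
    expect_true(all(s$pixels == 0.4))
})

test_that("generation is deterministic and conserves per-cell counts", {
  spec <- tiny_spec(n_train = 7L, n_test = 3L, seed = 42L)
  d1 <- generate_domain(spec)
  d2 <- generate_domain(spec)
  expect_identical(d1, d2)
  for (split in c("train", "test")) {
    lab <- vapply(d1[[split]], `[[`, integer(1), "label")
    n_expect <- if (split == "train") 7L else 3L
    expect_identical(sum(lab == 0L), n_expect)
    expect_identical(sum(lab == 1L), n_expect)
  }
  ids <- c(vapply(d1$train, `[[`, character(1), "sample_id"),
           vapply(d1$test, `[[`, character(1), "sample_id"))
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(vapply(d1$train, function(s) s$domain_id, character(1)) == "T"))
})

test_that("pixels are clipped to [0, 1]", {
  d <- generate_domain(tiny_spec(intensity_mean_shift = 0.5,
                                 texture_noise_sd = 0.3, seed = 9L))
  for (s in d$train) {
    expect_gte(min(s$pixels), 0)
    expect_lte(max(s$pixels), 1)
  }
})

test_that("intensity_mean_shift moves the mean intensity by its value", {
  # settings chosen so no pixel clips: the contrast is checked before
  # clipping effects can bite
  base <- list(n_train = 50L, n_test = 50L, class_signal_amplitude = 0.3,
               background_level = 0.3, texture_noise_sd = 0.02)
  a <- generate_domain(do.call(tiny_spec, c(list(domain_id = "A", seed = 5L,
                                                 intensity_mean_shift = 0), base)))
  b <- generate_domain(do.call(tiny_spec, c(list(domain_id = "B", seed = 5L,
                                                 intensity_mean_shift = 0.2), base)))
  mean_of <- function(d) mean(vapply(c(d$train, d$test),
                                     function(s) mean(s$pixels), numeric(1)))
  expect_equal(mean_of(b) - mean_of(a), 0.2, tolerance = 0.01)
})

test_that("two-domain benchmark enforces shared geometry and size", {
  s1 <- tiny_spec("A")
  s2 <- tiny_spec("B", signal_geometry = "oriented_bar")
  expect_error(generate_two_domain_benchmark(s1, s2), "signal_geometry")
  s3 <- domain_shift_spec("B", image_size = c(32L, 32L, 3L))
  expect_error(generate_two_domain_benchmark(s1, s3), "image_size")
})

test_that("swapping source and target exchanges roles exactly", {
  sa <- tiny_spec("A", seed = 1L)
  sb <- tiny_spec("B", seed = 2L, intensity_mean_shift = 0.1)
  ab <- generate_two_domain_benchmark(sa, sb)
  ba <- generate_two_domain_benchmark(sb, sa)
  expect_identical(ab$source, ba$target)
  expect_identical(ab$target, ba$source)
})

test_that("detectable shift: t statistic monotone in mean shift", {
  # shift-controllability property, averaged over 3 seeds
  shifts <- c(0, 0.05, 0.1, 0.2)
  mean_abs_t <- vapply(shifts, function(sh) {
    ts <- vapply(1:3, function(sd0) {
      a <- generate_domain(tiny_spec("A", n_train = 15L, seed = sd0))
      b <- generate_domain(tiny_spec("B", n_train = 15L, seed = sd0 + 50L,
                                     intensity_mean_shift = sh))
      va <- unlist(lapply(c(a$train, a$test), function(s) as.numeric(s$pixels)))
      vb <- unlist(lapply(c(b$train, b$test), function(s) as.numeric(s$pixels)))
      abs(two_sample_tstat(va, vb)$t_value)
    }, numeric(1))
    mean(ts)
  }, numeric(1))
  expect_true(all(diff(mean_abs_t) >= 0))
})

test_that("specs round-trip through JSON", {
  spec <- tiny_spec(signal_geometry = "oriented_bar",
                    intensity_mean_shift = -0.12, seed = 77L)
  path <- withr::local_tempfile(fileext = ".json")
  write_domain_shift_spec(spec, path)
  expect_identical(read_domain_shift_spec(path), spec)
})

test_that("strong-shift specs encode the stated target nuisance", {
  sp <- strong_shift_specs(seed = 3L)
  expect_identical(sp$target$intensity_mean_shift, 0.2)
  expect_identical(sp$target$texture_noise_sd, 2 * sp$source$texture_noise_sd)
  expect_identical(sp$source$intensity_mean_shift, 0)
  expect_identical(sp$source$signal_geometry, sp$target$signal_geometry)
})
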