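#' Read or write an 8-bit PNG image
#'
#' The package carries its own compact PNG codec (zlib-backed) so that
#' datasets round-trip through the standard class-per-subdirectory layout
#' without external imaging dependencies. `write_png()` quantizes to
#' 8-bit RGB; `read_png()` accepts 8-bit grayscale/RGB/RGBA (alpha is
#' dropped) and returns intensities in \[0, 1\].
#'
#' @param path PNG file path.
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @return `read_png()` returns an `H x W x C` array (`C` 1 or 3).
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop_param("path", sprintf("no such file: %s", path))
  png_read_cpp(path.expand(path))
}

#' @rdname read_png
#' @export
write_png <- function(pixels, path) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop_param("pixels", "must be an H x W x 3 array")
  png_write_rgb8(path.expand(path), pixels)
  invisible(path)
}

# Bilinear resize of one channel (matrix), pixel-centre alignment.
resize_channel <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  sy <- if (h == 1L) rep(1, out_h) else pmin(pmax((seq_len(out_h) - 0.5) * h / out_h + 0.5, 1), h)
  sx <- if (w == 1L) rep(1, out_w) else pmin(pmax((seq_len(out_w) - 0.5) * w / out_w + 0.5, 1), w)
  y0 <- pmin(floor(sy), h - 1L); y0[y0 < 1] <- 1
  x0 <- pmin(floor(sx), w - 1L); x0[x0 < 1] <- 1
  fy <- sy - y0; fx <- sx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
  c_ <- m[y0, x0 + 1, drop = FALSE]; d_ <- m[y0 + 1, x0 + 1, drop = FALSE]
  Fy <- matrix(fy, out_h, out_w); Fx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - Fy) * (1 - Fx) + b * Fy * (1 - Fx) + c_ * (1 - Fy) * Fx + d_ * Fy * Fx
}

#' Deterministic image preprocessing
#'
#' Replicates grayscale input to 3 channels, resizes with a fixed
#' bilinear kernel and clamps intensities to \[0, 1\]. The operation is
#' idempotent: input already at `target_size` with 3 channels and values
#' in range is returned bitwise-unchanged.
#'
#' @param pixels `H x W x C` array (or `H x W` matrix, treated as one
#'   channel) with finite intensities.
#' @param target_size Integer `(height, width)`.
#' @return `target_height x target_width x 3` array in `[0, 1]`.
#' @export
preprocess <- function(pixels, target_size) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L)
    stop_param("pixels", "must be an H x W x C array")
  if (d[1] < 1L || d[2] < 1L) stop_param("pixels", "zero-area image")
  if (any(!is.finite(pixels))) stop_param("pixels", "non-finite intensities")
  target_size <- as.integer(target_size[1:2])
  if (d[3] == 3L && d[1] == target_size[1] && d[2] == target_size[2] &&
      min(pixels) >= 0 && max(pixels) <= 1)
    return(pixels)
  if (d[3] == 1L) pixels <- array(pixels, dim = c(d[1], d[2], 3L))
  else if (d[3] == 2L) pixels <- array(pixels[, , 1L], dim = c(d[1], d[2], 3L))
  else if (d[3] > 3L) pixels <- pixels[, , 1:3, drop = FALSE]
  out <- array(0, dim = c(target_size, 3L))
  for (c in 1:3)
    out[, , c] <- resize_channel(pixels[, , c], target_size[1], target_size[2])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Write a dataset as a class-per-subdirectory image tree
#'
#' Layout: `<root>/<split>/<class_name>/<sample_id>.png`, plus a
#' `classes.txt` (class0 name first) recording class order so a
#' round-trip read restores the same integer labels.
#'
#' @param dataset A `domain_dataset`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @seealso [read_image_directory()]
#' @export
write_image_directory <- function(dataset, root) {
  stopifnot(inherits(dataset, "domain_dataset"))
  for (split in c("train", "test")) {
    for (cls in dataset$class_names)
      dir.create(file.path(root, split, cls), recursive = TRUE,
                 showWarnings = FALSE)
    for (s in dataset[[split]]) {
      if (is.na(s$label))
        stop("cannot write unlabeled sample to a class directory",
             call. = FALSE)
      cls <- dataset$class_names[s$label + 1L]
      write_png(s$pixels, file.path(root, split, cls,
                                    paste0(s$sample_id, ".png")))
    }
  }
  writeLines(dataset$class_names, file.path(root, "classes.txt"))
  invisible(root)
}

#' Read a class-per-subdirectory image dataset
#'
#' Expects `<root>/{train,test}/<class_name>/*.png` with exactly two
#' class subdirectories per split. Files are read in lexicographic path
#' order (explicit sort, not filesystem order) so sample order is
#' platform-independent. Undecodable files are skipped with a warning.
#' Class order (which directory is class 0) is taken from `classes.txt`
#' when present (as written by [write_image_directory()]), else from the
#' sorted directory names.
#'
#' @param root Dataset root directory.
#' @param domain_id Domain tag for the returned dataset.
#' @param target_size Integer `(height, width)` passed to [preprocess()].
#' @return A `domain_dataset`.
#' @export
read_image_directory <- function(root, domain_id, target_size = c(64L, 64L)) {
  if (!dir.exists(root)) stop_param("root", sprintf("no such directory: %s", root))
  cls_file <- file.path(root, "classes.txt")
  class_names <- NULL
  if (file.exists(cls_file)) class_names <- readLines(cls_file, warn = FALSE)
  splits <- list()
  for (split in c("train", "test")) {
    sdir <- file.path(root, split)
    if (!dir.exists(sdir))
      stop(sprintf("structure error: missing split directory '%s'", split),
           call. = FALSE)
    dirs <- sort(list.dirs(sdir, recursive = FALSE, full.names = FALSE))
    if (length(dirs) != 2L)
      stop(sprintf("structure error: split '%s' has %d class subdirectories, expected 2",
                   split, length(dirs)), call. = FALSE)
    if (is.null(class_names)) class_names <- dirs
    if (!setequal(dirs, class_names))
      stop(sprintf("structure error: split '%s' classes (%s) do not match (%s)",
                   split, paste(dirs, collapse = ", "),
                   paste(class_names, collapse = ", ")), call. = FALSE)
    samples <- list()
    n_skipped <- 0L
    for (cls in class_names) {
      files <- sort(list.files(file.path(sdir, cls),
                               pattern = "\\.png$", ignore.case = TRUE,
                               full.names = TRUE))
      if (length(files) == 0L)
        warning(sprintf("split '%s' class '%s' has no images", split, cls),
                call. = FALSE)
      label <- match(cls, class_names) - 1L
      for (fp in files) {
        px <- tryCatch(read_png(fp), error = function(e) NULL)
        if (is.null(px)) { n_skipped <- n_skipped + 1L; next }
        sid <- sub("\\.png$", "", basename(fp), ignore.case = TRUE)
        samples[[length(samples) + 1L]] <-
          new_image_sample(sid, preprocess(px, target_size), label,
                           domain_id, split)
      }
    }
    if (n_skipped > 0L)
      warning(sprintf("skipped %d undecodable file(s) in split '%s'",
                      n_skipped, split), call. = FALSE)
    splits[[split]] <- samples
  }
  new_domain_dataset(domain_id, splits$train, splits$test,
                     class_names = class_names)
}

#' Summarize a dataset directory or object
#'
#' Prints per-split per-class sample counts and an intensity summary;
#' the programmatic counterpart of the `dataset inspect` command line.
#'
#' @param x A dataset root path or a `domain_dataset`.
#' @param ... Passed to [read_image_directory()] when `x` is a path.
#' @return Invisibly, a data frame of counts and mean intensities.
#' @export
inspect_dataset <- function(x, ...) {
  ds <- if (is.character(x)) read_image_directory(x, domain_id = basename(x), ...)
        else x
  stopifnot(inherits(ds, "domain_dataset"))
  rows <- list()
  for (split in c("train", "test")) {
    for (cl in 0:1) {
      sel <- Filter(function(s) identical(s$label, cl), ds[[split]])
      mi <- if (length(sel)) mean(vapply(sel, function(s) mean(s$pixels),
                                         numeric(1))) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        split = split, class = ds$class_names[cl + 1L], n = length(sel),
        mean_intensity = mi)
    }
  }
  out <- do.call(rbind, rows)
  cat(sprintf("dataset '%s' (%s / %s)\n", ds$domain_id,
              ds$class_names[1], ds$class_names[2]))
  print(out, row.names = FALSE)
  invisible(out)
}
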