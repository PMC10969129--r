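# Internal helpers: seeded evaluation and seed-substream derivation.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a root seed and string tags.
# A small multiplicative hash keeps distinct (seed, tag) pairs apart; this
# is stream separation, not cryptography.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(tags)) {
    h <- (h * 31 + code) %% 2147483563
  }
  as.integer(h %% 2147483562) + 1L
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}
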