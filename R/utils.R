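#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Each simulated output file/component gets its own RNG stream so that
#' components are independently reproducible. The sub-seed is a deterministic
#' hash of the master seed and a short character tag, kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the component (e.g. `"genome"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## 1-based inclusive display label for a window, e.g. "chr8:111250001-111255000"
window_label <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

## midpoint of a 1-based inclusive interval, defined as the centre of the
## equivalent 0-based half-open interval: floor((start-1 + end)/2), returned
## as a 1-based position. For [4001, 6000] this is 5001, the first base of
## the second half, so even-width fragments fall in the downstream window.
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) - 1 + as.numeric(end)) / 2) + 1)
}

## named chromosome lengths from a toy_genome or a named numeric vector
chrom_lengths_of <- function(x) {
  if (inherits(x, "toy_genome")) {
    stats::setNames(x$chrom_lengths, x$chrom_names)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a 'toy_genome' or a named numeric vector of chromosome lengths")
  }
}
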