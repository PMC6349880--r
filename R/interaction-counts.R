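#' Interaction count container
#'
#' Holds the window x bait x library read-count tensor of a multi-bait
#' 4C experiment together with its library design and processing state.
#' The state machine is `raw -> filtered -> merged -> normalized`; the bait
#' axis disappears at the merge and normalization can only be applied once.
#'
#' @param counts 3-d array `[window, bait, library]` (or matrix
#'   `[window, library]` for an already-merged object).
#' @param windows `GRanges` of windows (length = first dimension).
#' @param libs data.frame with columns `condition` and `replicate`, one row
#'   per library.
#' @param state One of `"raw"`, `"filtered"`, `"merged"`, `"normalized"`.
#' @return An object of class `interaction_counts`.
#' @export
interaction_counts <- function(counts, windows, libs, state = "raw") {
  stopifnot(length(dim(counts)) %in% c(2L, 3L))
  nd <- length(dim(counts))
  stopifnot(dim(counts)[1] == length(windows),
            dim(counts)[nd] == nrow(libs),
            all(c("condition", "replicate") %in% names(libs)),
            state %in% c("raw", "filtered", "merged", "normalized"))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nd == 2L && state %in% c("raw", "filtered"))
    state <- "merged"
  libs$library_id <- paste(libs$condition, libs$replicate, sep = ".")
  dimnames(counts)[[1]] <- windows$label
  dimnames(counts)[[nd]] <- libs$library_id
  if (nd == 3L && is.null(dimnames(counts)[[2]]))
    dimnames(counts)[[2]] <- paste0("bait", sprintf("%02d", seq_len(dim(counts)[2])))
  structure(list(counts = counts, windows = windows, libs = libs,
                 state = state, observed = NULL, size_factors = NULL,
                 log = character(0)),
            class = "interaction_counts")
}

#' @export
print.interaction_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("interaction_counts [%s]: %d windows x %s%d libraries (%s)\n",
              x$state, d[1],
              if (length(d) == 3L) sprintf("%d baits x ", d[2]) else "",
              d[length(d)],
              paste(unique(x$libs$condition), collapse = "/")))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

## subset an interaction_counts to a logical/integer window index
subset_windows <- function(x, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (length(dim(x$counts)) == 3L) {
    x$counts <- x$counts[keep, , , drop = FALSE]
  } else {
    x$counts <- x$counts[keep, , drop = FALSE]
  }
  x$windows <- x$windows[keep]
  if (!is.null(x$observed)) x$observed <- x$observed[keep, , drop = FALSE]
  if (x$state == "raw") x$state <- "filtered"
  x
}

#' Merge the bait axis of an interaction-count tensor
#'
#' The per-window interaction frequency is the average read count across all
#' baits (zero baits included), decoupling bait support from magnitude.
#'
#' @param x An `interaction_counts` with a bait axis.
#' @return A merged `interaction_counts` (matrix `[window, library]`).
#' @export
merge_baits <- function(x) {
  stopifnot(inherits(x, "interaction_counts"))
  if (length(dim(x$counts)) != 3L) stop("bait axis already merged")
  n_baits <- dim(x$counts)[2]
  x$counts <- apply(x$counts, c(1, 3), mean)
  x$state <- "merged"
  x$log <- c(x$log, sprintf("merge_baits: mean over %d baits", n_baits))
  x
}

#' Export merged counts as the long TSV schema
#'
#' @param x An `interaction_counts`.
#' @param path Output TSV path (`window`, `bait`, `condition`, `replicate`,
#'   `count`; `bait` is `"merged"` after the merge).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "interaction_counts"))
  if (length(dim(x$counts)) == 3L) {
    d <- dim(x$counts)
    df <- expand.grid(window = x$windows$label,
                      bait = dimnames(x$counts)[[2]],
                      lib = seq_len(d[3]), stringsAsFactors = FALSE)
    df$count <- as.vector(x$counts)
  } else {
    df <- expand.grid(window = x$windows$label, bait = "merged",
                      lib = seq_len(ncol(x$counts)), stringsAsFactors = FALSE)
    df$count <- as.vector(x$counts)
  }
  df$condition <- x$libs$condition[df$lib]
  df$replicate <- x$libs$replicate[df$lib]
  utils::write.table(df[, c("window", "bait", "condition", "replicate", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format count TSV into an interaction_counts object
#'
#' @param path TSV with header `window  bait  condition  replicate  count`.
#' @param windows Optional `GRanges` of windows; by default window labels are
#'   parsed back into coordinates.
#' @param state Processing state of the stored counts.
#' @return An `interaction_counts`.
#' @export
read_counts_tsv <- function(path, windows = NULL, state = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("window", "bait", "condition", "replicate", "count") %in% names(df)))
  wl <- unique(df$window)
  baits <- unique(df$bait)
  df$lib <- paste(df$condition, df$replicate, sep = ".")
  libs_id <- unique(df$lib)
  libs <- unique(df[, c("condition", "replicate", "lib")])
  libs <- libs[match(libs_id, libs$lib), c("condition", "replicate")]
  arr <- array(0, dim = c(length(wl), length(baits), length(libs_id)),
               dimnames = list(wl, baits, libs_id))
  arr[cbind(match(df$window, wl), match(df$bait, baits), match(df$lib, libs_id))] <- df$count
  if (is.null(windows)) {
    m <- regmatches(wl, regexec("^(.+):(\\d+)-(\\d+)$", wl))
    windows <- GenomicRanges::GRanges(
      vapply(m, `[`, "", 2),
      IRanges::IRanges(as.integer(vapply(m, `[`, "", 3)),
                       as.integer(vapply(m, `[`, "", 4))))
    windows$label <- wl
  }
  if (length(baits) == 1L && baits == "merged") {
    m2 <- matrix(arr[, 1, ], nrow = length(wl),
                 dimnames = list(wl, libs_id))
    return(interaction_counts(m2, windows, libs, state = "merged"))
  }
  interaction_counts(arr, windows, libs, state = state)
}
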