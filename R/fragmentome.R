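## Genome geometry: in-silico restriction digestion, 5-kb window tiling,
## fragment -> window aggregation, and the pre-statistical count filters.

#' In-silico restriction digestion of a genome
#'
#' Cuts each chromosome immediately before every occurrence of the
#' restriction motif (DpnII `GATC` by default), producing fragments that
#' tile each chromosome exactly. A chromosome with no motif occurrence
#' yields a single whole-chromosome fragment (logged, not an error).
#'
#' @param genome A `toy_genome` (sequences are scanned), or a
#'   [Biostrings::DNAStringSet].
#' @param motif 4-mer restriction motif; defaults to the genome's motif.
#' @return A [GenomicRanges::GRanges] of fragments (1-based inclusive),
#'   sorted, with metadata column `fragment_id`.
#' @examples
#' g <- make_genome(2, 100000, seed = 1)
#' fr <- digest_genome(g)
#' sum(GenomicRanges::width(fr)) == sum(g$chrom_lengths)
#' @export
digest_genome <- function(genome, motif = NULL) {
  if (inherits(genome, "toy_genome")) {
    seqs <- genome$seqs
    if (is.null(motif)) motif <- genome$motif
  } else if (inherits(genome, "DNAStringSet")) {
    seqs <- genome
    if (is.null(motif)) motif <- "GATC"
  } else stop("genome must be a toy_genome or DNAStringSet")
  stopifnot(nchar(motif) == 4L)

  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  per_chrom <- lapply(seq_along(seqs), function(i) {
    hits <- Biostrings::start(Biostrings::matchPattern(motif, seqs[[i]]))
    L <- lens[i]
    if (length(hits) == 0L) {
      message(sprintf("digest_genome: no %s site on %s; whole chromosome kept as one fragment",
                      motif, names(seqs)[i]))
      return(data.frame(chrom = names(seqs)[i], start = 1L, end = L))
    }
    cuts <- hits[hits > 1L]          # a motif at position 1 cuts before base 1: no-op
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, L)
    data.frame(chrom = names(seqs)[i], start = starts, end = ends)
  })
  df <- do.call(rbind, per_chrom)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               seqlengths = lens)
  gr$fragment_id <- seq_along(gr)
  gr
}

#' Tile a genome into non-overlapping 5-kb windows
#'
#' Windows are the unit of interaction analysis. Each chromosome is cut into
#' `ceiling(L / width)` windows; the terminal window may be shorter. Labels
#' are rendered 1-based inclusive as `"chrom:start-end"`.
#'
#' @param x A `toy_genome`, or a named numeric vector of chromosome lengths.
#' @param width Window width in bp (default 5000).
#' @return A [GenomicRanges::GRanges] with metadata column `label`; names are
#'   the labels.
#' @examples
#' w <- tile_windows(c(chrA = 12000))
#' w$label  # "chrA:1-5000" "chrA:5001-10000" "chrA:10001-12000"
#' @export
tile_windows <- function(x, width = 5000) {
  lens <- chrom_lengths_of(x)
  per_chrom <- lapply(names(lens), function(ch) {
    L <- as.integer(lens[[ch]])
    n <- ceiling(L / width)
    starts <- as.integer((seq_len(n) - 1L) * width + 1L)
    ends <- pmin(as.integer(seq_len(n) * width), L)
    data.frame(chrom = ch, start = starts, end = ends)
  })
  df <- do.call(rbind, per_chrom)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               seqlengths = lens)
  gr$label <- window_label(df$chrom, df$start, df$end)
  names(gr) <- gr$label
  gr
}

#' Aggregate fragment-level counts to windows
#'
#' Each fragment is assigned to the single window containing its midpoint,
#' so fragments spanning a window boundary are never double counted; window
#' counts are sums over assigned fragments. Total counts are conserved.
#'
#' @param fragments `GRanges` of fragments.
#' @param fragment_counts Numeric matrix/array whose first dimension matches
#'   `fragments` (columns are libraries, or a 3-d array fragment x bait x
#'   library), or a numeric vector.
#' @param windows `GRanges` of windows from [tile_windows()].
#' @return Counts with the first dimension replaced by windows (named by
#'   window label).
#' @export
aggregate_to_windows <- function(fragments, fragment_counts, windows) {
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(fragments),
    IRanges::IRanges(interval_midpoint(GenomicRanges::start(fragments),
                                       GenomicRanges::end(fragments)),
                     width = 1L))
  hit <- GenomicRanges::findOverlaps(mids, windows, select = "first")
  if (anyNA(hit))
    stop("fragment midpoint outside every window: fragment coordinates must lie within the genome")
  idx <- factor(hit, levels = seq_along(windows))
  if (is.null(dim(fragment_counts))) fragment_counts <- cbind(count = fragment_counts)
  dm <- dim(fragment_counts)
  stopifnot(dm[1] == length(fragments))
  flat <- matrix(fragment_counts, nrow = dm[1])
  out <- matrix(0, nrow = length(windows), ncol = ncol(flat))
  for (j in seq_len(ncol(flat)))
    out[, j] <- as.numeric(tapply(flat[, j], idx, sum, default = 0))
  dim(out) <- c(length(windows), dm[-1])
  dn <- dimnames(fragment_counts)
  dimnames(out) <- c(list(windows$label), if (length(dm) > 1) dn[-1] else list(NULL))
  out
}

#' Zero out bait-adjacent (self/undigested) products
#'
#' Emulates the combined effect of PCR blockers and computational removal of
#' undigested or self-ligated reads: counts on each bait's own fragment and
#' its two flanking fragments are set to zero.
#'
#' @param fragment_counts Counts whose first dimension matches `fragments`.
#' @param fragments `GRanges` of fragments from [digest_genome()].
#' @param genome `toy_genome` providing bait positions.
#' @return List with `counts` (same shape, suppressed rows zeroed) and
#'   `suppressed` (integer indices of zeroed fragments).
#' @export
suppress_bait_products <- function(fragment_counts, fragments, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  baits <- GenomicRanges::GRanges(genome$rdna$chrom,
                                  IRanges::IRanges(genome$rdna$bait_pos, width = 1L))
  bait_frag <- GenomicRanges::findOverlaps(baits, fragments, select = "first")
  if (anyNA(bait_frag)) stop("bait position outside fragment map")
  same_chrom <- as.character(GenomicRanges::seqnames(fragments))
  sup <- integer(0)
  for (i in bait_frag) {
    nb <- c(i - 1L, i, i + 1L)
    nb <- nb[nb >= 1L & nb <= length(fragments)]
    nb <- nb[same_chrom[nb] == same_chrom[i]]
    sup <- c(sup, nb)
  }
  sup <- sort(unique(sup))
  if (is.null(dim(fragment_counts))) {
    fragment_counts[sup] <- 0
  } else {
    flat <- matrix(fragment_counts, nrow = dim(fragment_counts)[1])
    flat[sup, ] <- 0
    fragment_counts[] <- flat
  }
  list(counts = fragment_counts, suppressed = sup)
}

## ---- count filters on interaction_counts objects ---------------------------

#' Bait-support filter and bait merge
#'
#' Removes windows whose counts (summed over libraries) are nonzero in fewer
#' than `min_baits` of the 11 baits, then (optionally) merges the bait axis
#' by taking the mean read count across all baits, the semi-quantitative
#' interaction frequency.
#'
#' @param x An `interaction_counts` in a per-bait state.
#' @param min_baits Minimum number of supporting baits (default 4).
#' @param merge Merge the bait axis after filtering (default `TRUE`).
#' @return The filtered (and possibly merged) `interaction_counts`.
#' @export
apply_bait_support_filter <- function(x, min_baits = 4, merge = TRUE) {
  stopifnot(inherits(x, "interaction_counts"))
  if (x$state %in% c("merged", "normalized"))
    stop("per-bait counts required: counts are already merged")
  n_baits <- dim(x$counts)[2]
  if (min_baits > n_baits)
    stop(sprintf("min_baits = %d exceeds the %d baits present", min_baits, n_baits))
  support <- bait_support(x)
  keep <- support >= min_baits
  x <- subset_windows(x, keep)
  x$log <- c(x$log, sprintf("bait_support_filter: removed %d windows with < %d supporting baits",
                            sum(!keep), min_baits))
  if (merge) x <- merge_baits(x)
  x
}

## number of baits with a nonzero total count per window
bait_support <- function(x) {
  tot <- apply(x$counts, c(1, 2), sum)
  rowSums(tot > 0)
}

#' Single-bait outlier filter
#'
#' Removes windows whose interaction signal is concentrated in one bait:
#' a window is dropped when its maximum per-bait count (summed over
#' libraries) exceeds `ratio` times the summed counts of all other baits.
#'
#' @param x An `interaction_counts` in a per-bait state.
#' @param ratio Outlier ratio threshold (> 1; default 10).
#' @return The filtered `interaction_counts`.
#' @export
apply_single_bait_outlier_filter <- function(x, ratio = 10) {
  stopifnot(inherits(x, "interaction_counts"))
  if (x$state %in% c("merged", "normalized"))
    stop("per-bait counts required: counts are already merged")
  if (ratio <= 1) stop("ratio must be > 1")
  tot <- apply(x$counts, c(1, 2), sum)          # window x bait
  mx <- apply(tot, 1, max)
  rest <- rowSums(tot) - mx
  drop <- mx > ratio * rest
  x <- subset_windows(x, !drop)
  x$log <- c(x$log, sprintf("single_bait_outlier_filter: removed %d windows (ratio > %g)",
                            sum(drop), ratio))
  x
}

#' Replicate-observation filter
#'
#' Within each condition, a window is "observed" only if it has a nonzero
#' count (summed over baits) in every replicate of that condition. Windows
#' observed in no condition are removed; the per-condition observation flags
#' are retained for downstream testing (a window untested in a condition
#' yields `NA` p-values there).
#'
#' @param x An `interaction_counts` (per-bait or merged).
#' @return The filtered `interaction_counts` with an `observed`
#'   window-by-condition logical matrix.
#' @export
apply_replicate_filter <- function(x) {
  stopifnot(inherits(x, "interaction_counts"))
  conds <- unique(x$libs$condition)
  tab <- table(x$libs$condition)
  if (any(tab < 2))
    stop("every condition needs >= 2 replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  lib_tot <- library_totals(x)                   # window x library
  obs <- sapply(conds, function(cc) {
    j <- which(x$libs$condition == cc)
    rowSums(lib_tot[, j, drop = FALSE] > 0) == length(j)
  })
  colnames(obs) <- conds
  keep <- rowSums(obs) >= 1
  x <- subset_windows(x, keep)
  x$observed <- obs[keep, , drop = FALSE]
  x$log <- c(x$log, sprintf("replicate_filter: removed %d windows observed in no condition",
                            sum(!keep)))
  x
}

## per-window, per-library count totals (summing over baits if present)
library_totals <- function(x) {
  if (length(dim(x$counts)) == 3L) apply(x$counts, c(1, 3), sum) else x$counts
}

#' Expected TSS-distance distribution from the digestion null
#'
#' The null model for interaction position relative to genes: every
#' restriction fragment, weighted equally, is assigned the distance from its
#' midpoint to the nearest TSS. Comparing the observed interaction set
#' against this histogram shows whether interactions sit closer to (or
#' farther from) promoters than the fragment map alone predicts.
#'
#' @param fragments `GRanges` from [digest_genome()].
#' @param annotation `GRanges` with `tss` and `gene_id` metadata.
#' @param breaks Histogram breaks for the signed distances (bp); default
#'   spans +/- 100 kb in 5-kb bins.
#' @return List with `distances` (signed, per fragment), `histogram`
#'   (counts per bin), `breaks`, and `mean_abs_distance`.
#' @export
expected_tss_distance_null <- function(fragments, annotation,
                                       breaks = seq(-1e5, 1e5, by = 5000)) {
  if (length(annotation) == 0) stop("annotation is empty")
  ann <- annotate_nearest_tss(fragments, annotation)
  d <- ann$signed_distance
  h <- graphics::hist(pmax(pmin(d, max(breaks)), min(breaks)),
                      breaks = breaks, plot = FALSE)
  list(distances = d, histogram = h$counts, breaks = breaks,
       mean_abs_distance = mean(abs(d), na.rm = TRUE))
}
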