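# Shared fixtures, built once per test run.

# small genome + derived geometry, memoised
.fix <- new.env()

tiny_genome <- function() {
  if (is.null(.fix$genome)) {
    .fix$genome <- make_genome(n_chroms = 2, chrom_length = 1e5, seed = 42)
  }
  .fix$genome
}

tiny_annotation <- function() {
  if (is.null(.fix$annotation)) {
    .fix$annotation <- make_annotation(tiny_genome(), n_genes = 20, seed = 42,
                                       gene_length_range = c(1000, 3000))
  }
  .fix$annotation
}

# construct an interaction_counts from an explicit window x bait x library
# array, with 2 conditions x 2 replicates by default
make_ic <- function(arr, conditions = c("a", "b"), n_reps = 2) {
  n_w <- dim(arr)[1]
  w <- GenomicRanges::GRanges("chrT",
                              IRanges::IRanges((seq_len(n_w) - 1L) * 5000L + 1L,
                                               width = 5000L))
  w$label <- sprintf("%s:%d-%d", "chrT", GenomicRanges::start(w), GenomicRanges::end(w))
  names(w) <- w$label
  libs <- data.frame(condition = rep(conditions, each = n_reps),
                     replicate = rep(seq_len(n_reps), length(conditions)))
  interaction_counts(arr, w, libs, state = if (length(dim(arr)) == 3) "raw" else "merged")
}

# GRanges of n contiguous 5-kb windows on one chromosome
toy_windows <- function(n, chrom = "chrT", width = 5000L) {
  w <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges((seq_len(n) - 1L) * width + 1L,
                                               width = width))
  w$label <- sprintf("%s:%d-%d", chrom, GenomicRanges::start(w), GenomicRanges::end(w))
  names(w) <- w$label
  w
}

# minimal annotation GRanges from explicit TSS positions
toy_genes <- function(chrom, tss, strand = "+", gene_id = NULL, span = 1000L) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(n))
  start <- ifelse(strand == "+", tss, pmax(1L, tss - span))
  end <- ifelse(strand == "+", tss + span, tss)
  gr <- GenomicRanges::GRanges(rep_len(chrom, n), IRanges::IRanges(start, end),
                               strand = strand)
  gr$gene_id <- gene_id
  gr$tss <- as.integer(tss)
  gr
}

# build a minimal fourc_diff table for classification tests
fake_diff <- function(windows, log2FC, fdr, comparison = "a_vs_b") {
  res <- data.frame(window = windows, comparison = comparison,
                    baseMeanA = 100, baseMeanB = 100 * 2^log2FC,
                    log2FC = log2FC, pval = fdr, fdr = fdr,
                    stringsAsFactors = FALSE)
  class(res) <- c("fourc_diff", "data.frame")
  res
}
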