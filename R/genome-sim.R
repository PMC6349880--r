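#' Simulate a toy genome with a designated rDNA unit
#'
#' Builds a small multi-chromosome genome in which the restriction motif
#' (DpnII site `GATC` by default) occurs at a controlled density, and places
#' a single rDNA repeat unit carrying 11 bait positions in its transcribed
#' (18S/28S-like) regions on the first chromosome. Inter-site filler sequence
#' is drawn from {A, C, T} so the motif occurs exactly where planted; this is
#' a deliberate toy simplification that makes the fragment map exact.
#'
#' @param n_chroms Number of chromosomes (>= 2).
#' @param chrom_length Length of each chromosome in bp (>= 50000).
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @param site_spacing Mean spacing between restriction sites in bp.
#' @param motif Restriction motif (4-mer, default `"GATC"`).
#' @param rdna_length Length of the rDNA unit in bp.
#' @return An object of class `toy_genome`: a list with `chrom_names`,
#'   `chrom_lengths`, `seqs` (a [Biostrings::DNAStringSet]), `motif`, and
#'   `rdna` (list with `chrom`, `start`, `end`, `bait_pos` — 11 absolute bp
#'   positions inside the unit).
#' @examples
#' g <- make_genome(2, 100000, seed = 1)
#' length(g$rdna$bait_pos)  # 11
#' @export
make_genome <- function(n_chroms = 4, chrom_length = 2e6, seed = 1,
                        site_spacing = 500, motif = "GATC",
                        rdna_length = 45000) {
  stopifnot(n_chroms >= 2, nchar(motif) == 4L, site_spacing > nchar(motif))
  if (chrom_length < 5e4)
    stop("chrom_length must be >= 50000 bp")
  rdna_start <- 20001L
  if (rdna_start + rdna_length - 1L > chrom_length)
    stop("chrom_length too small to host the rDNA unit")

  rdna_length <- as.integer(rdna_length)
  chrom_names <- paste0("chr", seq_len(n_chroms))
  # filler lacking G cannot contain GATC, nor can a junction with the planted
  # motif create a stray occurrence: the fragment map is exact by construction
  filler_alphabet <- c("A", "C", "T")

  seqs <- with_seed(derive_seed(seed, "genome"), {
    lapply(seq_len(n_chroms), function(i) {
      gap_mean <- site_spacing - nchar(motif)
      n_gaps <- ceiling(chrom_length / site_spacing * 1.6) + 10L
      gaps <- pmax(1L, as.integer(round(stats::rexp(n_gaps, 1 / gap_mean))))
      pieces <- character(2L * n_gaps)
      total <- 0L
      k <- 0L
      for (g in gaps) {
        fill <- paste(sample(filler_alphabet, g, replace = TRUE), collapse = "")
        pieces[k + 1L] <- fill
        pieces[k + 2L] <- motif
        k <- k + 2L
        total <- total + g + nchar(motif)
        if (total >= chrom_length) break
      }
      s <- paste(pieces[seq_len(k)], collapse = "")
      substr(s, 1L, chrom_length)
    })
  })
  seqs <- Biostrings::DNAStringSet(unlist(seqs))
  names(seqs) <- chrom_names

  # rDNA unit on chromosome 1: an 18S-like and a 28S-like transcribed block,
  # with 4 + 7 = 11 bait positions spread across them (fixed fractional
  # offsets within the unit, so the layout is stable across seeds)
  frac18 <- c(0.05, 0.10, 0.15, 0.20)
  frac28 <- c(0.45, 0.52, 0.59, 0.66, 0.73, 0.80, 0.87)
  bait_pos <- rdna_start + as.integer(round(c(frac18, frac28) * (rdna_length - 1L)))
  rdna <- list(chrom = chrom_names[1L], start = rdna_start,
               end = rdna_start + rdna_length - 1L, bait_pos = bait_pos)

  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(rep(as.integer(chrom_length), n_chroms),
                                         chrom_names),
         seqs = seqs, motif = motif, rdna = rdna),
    class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosomes, %s bp total, motif %s\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), x$motif))
  cat(sprintf("rDNA unit %s:%d-%d with %d baits\n", x$rdna$chrom,
              x$rdna$start, x$rdna$end, length(x$rdna$bait_pos)))
  invisible(x)
}

#' Write a toy genome to FASTA
#'
#' @param genome A `toy_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "toy_genome"))
  Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
  invisible(path)
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` non-overlapping genes across the genome (skipping the
#' rDNA unit), with both strands represented. The transcription start site
#' (TSS) is the interval start for `+` genes and the interval end for `-`
#' genes.
#'
#' @param genome A `toy_genome`.
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param gene_length_range Min/max gene length in bp.
#' @param min_gap Minimum intergenic gap in bp.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `tss` (bp), strand set, sorted by position.
#' @export
make_annotation <- function(genome, n_genes = 400, seed = 1,
                            gene_length_range = c(2000, 8000), min_gap = 500) {
  stopifnot(inherits(genome, "toy_genome"), n_genes >= 1)
  lens <- genome$chrom_lengths
  # usable space excludes the rDNA unit on its chromosome
  usable <- as.numeric(lens)
  i_r <- match(genome$rdna$chrom, genome$chrom_names)
  usable[i_r] <- usable[i_r] - (genome$rdna$end - genome$rdna$start + 1)
  need_per_gene <- max(gene_length_range) + min_gap
  capacity <- floor(sum(usable) / need_per_gene)
  if (n_genes > capacity)
    stop(sprintf("n_genes = %d exceeds genome capacity (~%d)", n_genes, capacity))

  # allocate genes to chromosomes proportional to usable length
  alloc <- floor(n_genes * usable / sum(usable))
  rem <- n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L

  res <- with_seed(derive_seed(seed, "annotation"), {
    out <- list()
    gid <- 0L
    for (i in seq_along(genome$chrom_names)) {
      k <- alloc[i]
      if (k == 0) next
      glens <- as.integer(round(stats::runif(k, gene_length_range[1], gene_length_range[2])))
      # stick-breaking: distribute the free space into k+1 gaps
      free <- usable[i] - sum(glens) - (k + 1L) * min_gap
      if (free < 0) stop("internal: chromosome over-allocated")
      w <- stats::runif(k + 1L)
      gaps <- min_gap + floor(free * w / sum(w))
      starts <- as.integer(cumsum(gaps[seq_len(k)]) + c(0, cumsum(glens[-k])) + 1)
      ends <- starts + glens - 1L
      # shift genes past the rDNA unit on its chromosome
      if (i == i_r) {
        shift <- ifelse(ends >= genome$rdna$start,
                        genome$rdna$end - genome$rdna$start + 1L, 0L)
        starts <- starts + shift; ends <- ends + shift
      }
      strand <- sample(c("+", "-"), k, replace = TRUE)
      out[[i]] <- data.frame(chrom = genome$chrom_names[i], start = starts,
                             end = ends, strand = strand,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  # guarantee both strands represented
  if (length(unique(res$strand)) == 1L)
    res$strand[nrow(res)] <- setdiff(c("+", "-"), res$strand[1L])
  stopifnot(all(res$end <= lens[res$chrom]))

  gr <- GenomicRanges::GRanges(
    seqnames = res$chrom,
    ranges = IRanges::IRanges(res$start, res$end),
    strand = res$strand,
    seqlengths = lens)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr$gene_id <- sprintf("gene%04d", seq_along(gr))
  gr$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr
}

#' Write a gene annotation (or peak set) to BED6
#'
#' @param gr A `GRanges`; `gene_id` metadata used as the name column if present.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$gene_id)) gr$gene_id else
    if (!is.null(gr$name)) gr$name else paste0("feat", seq_along(gr))
  out <- gr
  out$name <- nm
  out$score <- 0L
  out$gene_id <- NULL
  out$tss <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
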