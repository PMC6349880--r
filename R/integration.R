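## Biological integration: nearest-TSS annotation, the reciprocal
## (UBTF-dependent) class-switch workflow, expression coupling statistics,
## TSS-distance bands, peak/gene overlaps, and the SPRITE-style bootstrap.

#' Annotate windows (or fragments) with the nearest TSS
#'
#' Distance is measured from the interval midpoint to the nearest gene TSS
#' on the same chromosome; ties are broken by lexicographically smallest
#' `gene_id`. The signed distance is negative when the TSS lies upstream of
#' the midpoint in the gene's reading direction (i.e. the midpoint is
#' downstream of the promoter).
#'
#' @param windows `GRanges` of query intervals.
#' @param annotation `GRanges` with `gene_id` and `tss` metadata.
#' @return data.frame with one row per query: `window` (label or index),
#'   `gene_id`, `distance` (bp, non-negative), `signed_distance`.
#' @export
annotate_nearest_tss <- function(windows, annotation) {
  if (length(annotation) == 0) stop("annotation is empty")
  stopifnot(!is.null(annotation$gene_id), !is.null(annotation$tss))
  q_chr <- as.character(GenomicRanges::seqnames(windows))
  mid <- interval_midpoint(GenomicRanges::start(windows), GenomicRanges::end(windows))
  a_chr <- as.character(GenomicRanges::seqnames(annotation))
  tss <- as.integer(annotation$tss)
  strand <- as.character(GenomicRanges::strand(annotation))
  gid <- annotation$gene_id

  n <- length(windows)
  out_gene <- rep(NA_character_, n)
  out_sd <- rep(NA_real_, n)
  for (ch in unique(q_chr)) {
    ai <- which(a_chr == ch)
    qi <- which(q_chr == ch)
    if (length(ai) == 0) next
    # sort TSS; for each midpoint check flanking candidates via findInterval
    ord <- ai[order(tss[ai], gid[ai])]
    ts <- tss[ord]
    pos <- findInterval(mid[qi], ts)
    for (k in seq_along(qi)) {
      cand <- unique(pmin(pmax(c(pos[k], pos[k] + 1L), 1L), length(ts)))
      d <- abs(ts[cand] - mid[qi[k]])
      best_d <- min(d)
      # all genes at the winning distance (either flank may tie), tie-break by id
      hits <- ord[which(abs(ts - mid[qi[k]]) == best_d)]
      best <- hits[order(gid[hits])][1L]
      out_gene[qi[k]] <- gid[best]
      out_sd[qi[k]] <- if (strand[best] == "-") mid[qi[k]] - tss[best]
                       else tss[best] - mid[qi[k]]
    }
  }
  lab <- if (!is.null(windows$label)) windows$label else as.character(seq_len(n))
  data.frame(window = lab, gene_id = out_gene,
             distance = abs(out_sd), signed_distance = out_sd,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of windows in a TSS-distance band
#'
#' @param tss_map data.frame from [annotate_nearest_tss()].
#' @param band Two-element numeric, inclusive bounds on `|distance|` in bp
#'   (default 5-20 kb).
#' @return The fraction of mapped windows with distance in the band.
#' @export
tss_distance_band_fraction <- function(tss_map, band = c(5000, 20000)) {
  d <- tss_map$distance[!is.na(tss_map$distance)]
  if (length(d) == 0) stop("empty TSS-distance map")
  mean(d >= band[1] & d <= band[2])
}

#' Reciprocal (UBTF-dependent) class-switch classification
#'
#' Implements the reciprocal filtering workflow: keep only windows that are
#' significant in both the premalignant-to-malignant comparison and the
#' control-vs-knockdown comparison, with opposite fold-change signs.
#' Category `incMal_decUbtf` holds windows that gain rDNA interaction in
#' malignancy and lose it without UBTF; `decMal_incUbtf` is the mirror
#' image. All other windows are removed.
#'
#' @param diff_prem_mal `fourc_diff` for the stage comparison (logFC = mal
#'   vs prem).
#' @param diff_lmp_shUbtf `fourc_diff` for the knockdown comparison (logFC =
#'   shUbtf vs LMP).
#' @param fdr_cutoff Significance cutoff in both comparisons (default 0.1,
#'   inclusive).
#' @param annotation Optional `GRanges`; when given together with `windows`,
#'   nearest genes are attached.
#' @param windows Optional `GRanges` matching the window universe.
#' @return A `class_switch_set`: data.frame `window`, `category`,
#'   `logFC_interaction` (stage), `logFC_knockdown`, and `gene_id` when
#'   annotated.
#' @export
classify_class_switch <- function(diff_prem_mal, diff_lmp_shUbtf,
                                  fdr_cutoff = 0.1,
                                  annotation = NULL, windows = NULL) {
  shared <- intersect(diff_prem_mal$window, diff_lmp_shUbtf$window)
  if (length(shared) == 0) stop("the two comparisons share no windows")
  a <- diff_prem_mal[match(shared, diff_prem_mal$window), ]
  b <- diff_lmp_shUbtf[match(shared, diff_lmp_shUbtf$window), ]
  sig <- !is.na(a$fdr) & !is.na(b$fdr) &
    a$fdr <= fdr_cutoff & b$fdr <= fdr_cutoff
  inc <- sig & a$log2FC > 0 & b$log2FC < 0
  dec <- sig & a$log2FC < 0 & b$log2FC > 0
  keep <- inc | dec
  out <- data.frame(window = shared[keep],
                    category = ifelse(inc[keep], "incMal_decUbtf", "decMal_incUbtf"),
                    logFC_interaction = a$log2FC[keep],
                    logFC_knockdown = b$log2FC[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation) && !is.null(windows) && nrow(out) > 0) {
    wsub <- windows[match(out$window, windows$label)]
    out$gene_id <- annotate_nearest_tss(wsub, annotation)$gene_id
  }
  class(out) <- c("class_switch_set", "data.frame")
  out
}

#' @export
print.class_switch_set <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("incMal_decUbtf", "decMal_incUbtf")))
  cat(sprintf("class_switch_set: %d reciprocal windows (%d incMal_decUbtf, %d decMal_incUbtf)\n",
              nrow(x), tab[1], tab[2]))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x)), digits = 4)
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (length_bp * total_mapped)`.
#'
#' @param counts Gene x library count matrix (or vector).
#' @param lengths Gene lengths in bp (> 0), recycled along rows.
#' @param totals Per-library totals; defaults to column sums.
#' @return RPKM values, same shape as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, totals = NULL) {
  if (is.null(dim(counts))) counts <- cbind(counts)
  stopifnot(all(lengths > 0))
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(counts * 1e9 / lengths, 2, totals, "/")
}

#' Differential expression with the interaction-test machinery
#'
#' Runs the same normalization + conditional NB exact test + BH pipeline on
#' gene counts and applies the expression thresholds: a gene is
#' differentially expressed (DE) when `fdr <= fdr_cutoff` and
#' `|logFC| >= lfc_cutoff`.
#'
#' @param counts Gene x library count matrix.
#' @param libs data.frame with `condition`, `replicate` per library.
#' @param comparison `c(condA, condB)`; logFC is B vs A.
#' @param fdr_cutoff FDR threshold (default 0.1).
#' @param lfc_cutoff |logFC| threshold (default 0.5).
#' @return A `fourc_diff`-style data.frame with an extra logical column
#'   `de`.
#' @export
call_de_genes <- function(counts, libs, comparison,
                          fdr_cutoff = 0.1, lfc_cutoff = 0.5) {
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, unclass(sf), "/")
  disp <- estimate_dispersions(norm, libs = libs)
  res <- nb_test_pairwise(norm, comparison, dispersions = disp, libs = libs)
  res$de <- !is.na(res$fdr) & res$fdr <= fdr_cutoff & abs(res$log2FC) >= lfc_cutoff
  res
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The K-S statistic `D = sup |F_A - F_B|` with the asymptotic p-value
#' (Kolmogorov distribution at effective sample size
#' `n_A n_B / (n_A + n_B)`), as used for density comparisons of expression
#' distributions.
#'
#' @param a,b Numeric samples (each length >= 5 for the asymptotic p to be
#'   meaningful; smaller samples are rejected).
#' @param alternative Passed to [stats::ks.test()] (`"two.sided"` default;
#'   `"greater"` tests that `a` is stochastically smaller than `b`).
#' @return List with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_density_compare <- function(a, b, alternative = "two.sided") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5 || length(b) < 5)
    stop("both samples must have >= 5 finite values")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = alternative,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Expression-by-interaction integration report
#'
#' Two density comparisons: (i) expression level (RPKM) of genes associated
#' with rDNA-interacting windows vs all other genes; (ii) expression log
#' fold change of genes associated with significantly increased vs
#' significantly decreased interactions. Both are compared with the K-S
#' test; the second is the inverse-coupling readout (increased interaction
#' is expected to shift expression down).
#'
#' @param rpkm Named numeric vector of mean RPKM per gene (one condition or
#'   an average).
#' @param expr_lfc Named numeric vector of expression log2FC per gene.
#' @param tss_map data.frame from [annotate_nearest_tss()] over the
#'   interacting window set.
#' @param classes data.frame from [classify_windows()] (columns `window`,
#'   `class`).
#' @param one_sided Use the one-sided K-S test for the logFC comparison
#'   (increased-interaction genes stochastically smaller), default `FALSE`.
#' @return List `rpkm_ks` (interacting vs non-interacting),
#'   `lfc_ks` (increased vs decreased), group sizes and medians; empty
#'   groups yield `NA` entries with a warning.
#' @export
expression_by_interaction_report <- function(rpkm, expr_lfc, tss_map, classes,
                                             one_sided = FALSE) {
  interacting <- unique(tss_map$gene_id[!is.na(tss_map$gene_id)])
  all_genes <- names(rpkm)
  non <- setdiff(all_genes, interacting)
  rpkm_ks <- if (length(intersect(interacting, all_genes)) >= 5 && length(non) >= 5) {
    ks_density_compare(rpkm[intersect(interacting, all_genes)], rpkm[non])
  } else { warning("RPKM comparison group empty or too small"); NA }

  cls <- classes[match(tss_map$window, classes$window), "class"]
  inc_genes <- unique(tss_map$gene_id[cls %in% "increased"])
  dec_genes <- unique(tss_map$gene_id[cls %in% "decreased"])
  inc_lfc <- expr_lfc[intersect(inc_genes, names(expr_lfc))]
  dec_lfc <- expr_lfc[intersect(dec_genes, names(expr_lfc))]
  lfc_ks <- if (length(inc_lfc) >= 5 && length(dec_lfc) >= 5) {
    ks_density_compare(inc_lfc, dec_lfc,
                       alternative = if (one_sided) "greater" else "two.sided")
  } else { warning("logFC comparison group empty or too small"); NA }

  list(rpkm_ks = rpkm_ks,
       lfc_ks = lfc_ks,
       n_interacting = length(interacting), n_non_interacting = length(non),
       n_increased_genes = length(inc_lfc), n_decreased_genes = length(dec_lfc),
       median_lfc_increased = if (length(inc_lfc)) stats::median(inc_lfc) else NA_real_,
       median_lfc_decreased = if (length(dec_lfc)) stats::median(dec_lfc) else NA_real_)
}

#' Fraction of windows overlapping a peak set
#'
#' A window overlaps a peak when the intersection is at least `min_overlap`
#' bp (default 1).
#'
#' @param windows `GRanges` of windows.
#' @param peaks `GRanges` of peaks.
#' @param min_overlap Minimum intersection width in bp.
#' @return List with `fraction`, `overlapping` (labels or indices), and the
#'   logical vector `hit`.
#' @export
peak_overlap_fraction <- function(windows, peaks, min_overlap = 1L) {
  if (any(GenomicRanges::start(peaks) > GenomicRanges::end(peaks)))
    stop("malformed peak intervals")
  if (length(windows) == 0) stop("no windows supplied")
  hit <- GenomicRanges::countOverlaps(windows, peaks,
                                      minoverlap = as.integer(min_overlap)) > 0
  lab <- if (!is.null(windows$label)) windows$label else as.character(seq_along(windows))
  list(fraction = mean(hit), overlapping = lab[hit], hit = hit)
}

#' Overlap between two gene sets
#'
#' @param genes_a,genes_b Character vectors of gene ids (de-duplicated).
#' @return List with `intersection`, `fraction_of_a`, `fraction_of_b`,
#'   `n_a`, `n_b`.
#' @export
gene_set_overlap <- function(genes_a, genes_b) {
  a <- unique(genes_a[!is.na(genes_a)])
  b <- unique(genes_b[!is.na(genes_b)])
  i <- intersect(a, b)
  list(intersection = i,
       fraction_of_a = if (length(a)) length(i) / length(a) else NA_real_,
       fraction_of_b = if (length(b)) length(i) / length(b) else NA_real_,
       n_a = length(a), n_b = length(b))
}

#' Average 4C occupancy profile around SPRITE regions, with a bootstrap null
#'
#' For every SPRITE region the span of +/-`flank` bp around its centre is
#' binned at `bin` bp and each bin scored 1 when it overlaps any 4C window.
#' The profile is the mean score per bin over regions; the observed central
#' enrichment (central-bin mean) is compared against `n_boot` placements of
#' equally many, equally sized regions dropped uniformly on the genome
#' (chromosome chosen proportional to length), giving the empirical p-value
#' `(1 + #{boot >= obs}) / (n_boot + 1)`.
#'
#' @param windows_4c `GRanges` of 4C interaction windows.
#' @param sprite_regions `GRanges` of SPRITE-derived regions.
#' @param chrom_lengths Named chromosome lengths (or a `toy_genome`).
#' @param flank Half-span in bp (default 100 kb).
#' @param bin Bin width in bp (default 5 kb).
#' @param n_boot Bootstrap placements (default 1000).
#' @param seed Integer seed.
#' @return List `profile` (mean occupancy per bin), `offsets` (bin centre
#'   offsets, bp), `observed` (central enrichment), `boot` (bootstrap
#'   central enrichments), `p`, `n_regions_used`.
#' @export
sprite_profile_and_bootstrap <- function(windows_4c, sprite_regions,
                                         chrom_lengths, flank = 1e5,
                                         bin = 5000, n_boot = 1000, seed = 1) {
  lens <- chrom_lengths_of(chrom_lengths)
  half_bins <- floor(flank / bin)
  offsets <- (-half_bins:half_bins) * bin
  central <- half_bins + 1L

  # per-chromosome interval index: sorted window starts + running max of ends,
  # so "bin [lo, hi] overlaps any window" is two findInterval lookups
  win_idx <- local({
    wch <- as.character(GenomicRanges::seqnames(windows_4c))
    lapply(stats::setNames(nm = names(lens)), function(cc) {
      i <- which(wch == cc)
      if (length(i) == 0) return(NULL)
      o <- i[order(GenomicRanges::start(windows_4c)[i])]
      list(ss = GenomicRanges::start(windows_4c)[o],
           ce = cummax(GenomicRanges::end(windows_4c)[o]))
    })
  })
  any_overlap <- function(cc, lo, hi) {
    ix <- win_idx[[cc]]
    if (is.null(ix)) return(rep(FALSE, length(lo)))
    k <- findInterval(hi, ix$ss)
    k >= 1 & ix$ce[pmax(k, 1)] >= lo
  }

  profile_of <- function(ch, ctr) {
    ok <- ctr - flank - bin / 2 >= 1 & ctr + flank + bin / 2 <= lens[ch]
    ch <- ch[ok]; ctr <- ctr[ok]
    if (length(ctr) == 0) return(NULL)
    n_bin <- length(offsets)
    lo <- rep(ctr, each = n_bin) + rep(offsets, length(ctr)) - floor(bin / 2) + 1L
    hi <- lo + bin - 1L
    chb <- rep(ch, each = n_bin)
    hit <- logical(length(lo))
    for (cc in unique(chb)) {
      j <- chb == cc
      hit[j] <- any_overlap(cc, lo[j], hi[j])
    }
    list(profile = rowMeans(matrix(hit, nrow = n_bin)), n = length(ctr))
  }

  obs_prof <- profile_of(as.character(GenomicRanges::seqnames(sprite_regions)),
                         interval_midpoint(GenomicRanges::start(sprite_regions),
                                           GenomicRanges::end(sprite_regions)))
  if (is.null(obs_prof))
    stop("no SPRITE region fits inside a chromosome with the requested flank")
  if (obs_prof$n < length(sprite_regions))
    warning(sprintf("%d region(s) skipped: flank exceeds chromosome bounds",
                    length(sprite_regions) - obs_prof$n))
  obs <- obs_prof$profile[central]
  widths <- GenomicRanges::width(sprite_regions)[seq_len(obs_prof$n)]

  boot <- with_seed(derive_seed(seed, "sprite_boot"), {
    vapply(seq_len(n_boot), function(i) {
      ch <- sample(names(lens), obs_prof$n, replace = TRUE, prob = as.numeric(lens))
      lo <- flank + bin
      hi <- lens[ch] - widths - flank - bin
      st <- floor(stats::runif(obs_prof$n, lo, pmax(lo + 1, hi)))
      ctr <- interval_midpoint(st, st + widths - 1L)
      p <- profile_of(ch, ctr)
      if (is.null(p)) 0 else p$profile[central]
    }, 0)
  })
  p <- (1 + sum(boot >= obs)) / (n_boot + 1)
  list(profile = obs_prof$profile, offsets = offsets, observed = obs,
       boot = boot, p = p, n_regions_used = obs_prof$n)
}
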