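#' Run the full synthetic 4C-seq analysis pipeline
#'
#' Generates the default synthetic dataset (toy genome with an rDNA unit and
#' 11 baits, gene annotation, two-series 4C counts with planted
#' constitutive/differential/reciprocal interactions, inversely coupled
#' expression, peak sets), then runs every analysis stage: bait-level
#' filters, bait merge, median-of-ratios normalization, conditional NB
#' exact tests over all stage pairs and the knockdown pair,
#' constitutive/differential classification, reciprocal class-switch
#' detection, nearest-TSS annotation, expression integration, peak
#' overlaps, and the SPRITE bootstrap. Planted-truth recovery is summarized
#' against the ledger.
#'
#' @param seed Master seed for every stochastic component.
#' @param n_chroms,chrom_length Toy genome dimensions.
#' @param n_genes Annotation size.
#' @param n_boot SPRITE bootstrap placements.
#' @param fdr_cutoff Significance cutoff used throughout (default 0.1).
#' @param quiet Suppress progress messages.
#' @return A `nad4c_pipeline` list with every intermediate and a `summary`
#'   data.frame of the headline numbers.
#' @export
run_pipeline <- function(seed = 1, n_chroms = 4, chrom_length = 2e6,
                         n_genes = 400, n_boot = 200, fdr_cutoff = 0.1,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating genome + annotation")
  genome <- make_genome(n_chroms, chrom_length, seed = seed)
  annotation <- make_annotation(genome, n_genes = n_genes, seed = seed)
  windows <- tile_windows(genome)

  say("simulating 4C counts")
  sim <- simulate_fourc_counts(genome, seed = seed)
  counts <- sim$counts
  truth <- sim$truth

  say("filtering")
  flt <- apply_replicate_filter(counts)
  flt <- apply_single_bait_outlier_filter(flt)
  merged <- apply_bait_support_filter(flt, min_baits = 4, merge = TRUE)

  say("normalizing + testing")
  sf <- size_factors(merged)
  norm <- normalize_counts(merged, sf)
  disp <- estimate_dispersions(norm)
  comparisons <- list(wt_vs_prem = c("wt", "prem"),
                      prem_vs_mal = c("prem", "mal"),
                      wt_vs_mal = c("wt", "mal"),
                      LMP_vs_shUbtf = c("LMP", "shUbtf"))
  diffs <- lapply(comparisons, function(cmp)
    nb_test_pairwise(norm, cmp, dispersions = disp))

  stage_diffs <- diffs[c("wt_vs_prem", "prem_vs_mal", "wt_vs_mal")]
  classes <- classify_windows(stage_diffs, direction_from = "prem_vs_mal",
                              fdr_cutoff = fdr_cutoff)
  cs <- classify_class_switch(diffs$prem_vs_mal, diffs$LMP_vs_shUbtf,
                              fdr_cutoff = fdr_cutoff,
                              annotation = annotation, windows = windows)

  say("expression integration")
  expr <- simulate_expression_counts(annotation, windows, truth, seed = seed)
  truth <- expr$truth
  de <- call_de_genes(expr$counts, expr$libs, c("prem", "mal"))
  rpkm <- compute_rpkm(expr$counts, expr$gene_lengths[rownames(expr$counts)])
  rpkm_mean <- rowMeans(rpkm)
  # on the dense toy tiling every gene is nearest to some surviving window,
  # so the interacting/non-interacting RPKM contrast is drawn on the
  # differential window set, where association is informative
  diff_windows <- classes$window[classes$class %in% c("increased", "decreased")]
  tss_map <- annotate_nearest_tss(
    norm$windows[match(diff_windows, norm$windows$label)], annotation)
  expr_lfc <- stats::setNames(de$log2FC, de$window)
  report <- expression_by_interaction_report(rpkm_mean, expr_lfc, tss_map, classes)

  say("overlap statistics")
  switch_windows <- windows[match(cs$window, windows$label)]
  designated <- if (length(switch_windows) >= 10) switch_windows else
    norm$windows[seq_len(min(50, length(norm$windows)))]
  peaks <- simulate_peak_sets(genome, designated, seed = seed)
  me1 <- peak_overlap_fraction(designated, peaks$H3K4me1)
  me3_in_me1 <- if (length(me1$overlapping) > 0)
    peak_overlap_fraction(designated[me1$hit], peaks$H3K4me3) else NULL
  band <- tss_distance_band_fraction(
    annotate_nearest_tss(designated, annotation))

  say("SPRITE bootstrap")
  sprite <- sprite_profile_and_bootstrap(
    designated, peaks$SPRITE, genome, n_boot = n_boot, seed = seed)

  # recovery vs the planted truth
  tested <- diffs$prem_vs_mal$window[!is.na(diffs$prem_vs_mal$pval)]
  planted_diff <- truth$differential_windows$window
  called_diff <- classes$window[classes$class %in% c("increased", "decreased")]
  sens <- mean(intersect(planted_diff, tested) %in% called_diff)
  fdp <- if (length(called_diff) > 0)
    mean(!(called_diff %in% planted_diff)) else 0
  planted_rec <- truth$reciprocal_windows$window
  rec_sens <- if (length(planted_rec) > 0)
    mean(intersect(planted_rec, tested) %in% cs$window) else NA_real_

  summary_df <- data.frame(
    quantity = c("windows_total", "windows_after_filters", "n_differential",
                 "n_constitutive", "n_class_switch", "diff_sensitivity",
                 "diff_fdp", "switch_sensitivity", "h3k4me1_overlap_fraction",
                 "tss_band_fraction_5_20kb", "sprite_p", "n_de_genes"),
    value = c(length(windows), length(norm$windows), length(called_diff),
              sum(classes$class %in% "constitutive"), nrow(cs), sens, fdp,
              rec_sens, me1$fraction, band, sprite$p, sum(de$de)),
    stringsAsFactors = FALSE)

  structure(list(genome = genome, annotation = annotation, windows = windows,
                 counts_raw = counts, counts_norm = norm, size_factors = sf,
                 dispersions = disp, diffs = diffs, classes = classes,
                 class_switch = cs, expression = expr, de = de,
                 report = report, peaks = peaks,
                 overlaps = list(H3K4me1 = me1, H3K4me3_in_me1 = me3_in_me1),
                 tss_band_fraction = band, sprite = sprite, truth = truth,
                 summary = summary_df),
            class = "nad4c_pipeline")
}

#' @export
print.nad4c_pipeline <- function(x, ...) {
  cat("nad4c pipeline run\n")
  df <- x$summary
  df$value <- signif(df$value, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
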