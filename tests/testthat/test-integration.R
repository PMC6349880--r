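# Nearest-TSS annotation, class-switch workflow, RPKM/DE, K-S comparisons,
# interval overlaps and the SPRITE bootstrap.

test_that("nearest-TSS annotation: named-gene case, ties, signs, idempotence", {
  # a window whose nearest TSS belongs to Ebf1 maps to Ebf1
  w <- GenomicRanges::GRanges("chr11", IRanges::IRanges(44660001, 44665000))
  w$label <- "chr11:44660001-44665000"
  genes <- toy_genes("chr11", tss = c(44661000, 44800000),
                     strand = c("-", "+"), gene_id = c("Ebf1", "Other"))
  out <- annotate_nearest_tss(w, genes)
  expect_equal(out$gene_id, "Ebf1")

  # midpoint exactly at a TSS: distance 0
  g0 <- toy_genes("chr11", tss = 44662501, gene_id = "AtMid")
  expect_equal(annotate_nearest_tss(w, g0)$distance, 0)

  # equidistant genes: lexicographically smallest id wins
  gt <- toy_genes("chr11", tss = c(44662501 - 100, 44662501 + 100),
                  gene_id = c("zzz", "aaa"))
  expect_equal(annotate_nearest_tss(w, gt)$gene_id, "aaa")

  # sign convention: negative iff the TSS is upstream of the midpoint in the
  # gene's reading direction
  gp <- toy_genes("chr11", tss = 44660000, strand = "+", gene_id = "plus")
  expect_lt(annotate_nearest_tss(w, gp)$signed_distance, 0)
  gm <- toy_genes("chr11", tss = 44670000, strand = "-", gene_id = "minus")
  expect_lt(annotate_nearest_tss(w, gm)$signed_distance, 0)
  gp2 <- toy_genes("chr11", tss = 44670000, strand = "+", gene_id = "plus2")
  expect_gt(annotate_nearest_tss(w, gp2)$signed_distance, 0)

  # idempotence: the map is a pure function of its inputs
  expect_identical(annotate_nearest_tss(w, genes), annotate_nearest_tss(w, genes))
  expect_error(annotate_nearest_tss(w, genes[0]), "empty")
})

test_that("nearest-TSS map equals the all-pairs brute force on 20 x 50", {
  set.seed(10)
  w <- toy_windows(20, chrom = "chr1")
  tss <- sort(sample.int(110000, 50))
  genes <- toy_genes("chr1", tss = tss,
                     strand = sample(c("+", "-"), 50, replace = TRUE))
  out <- annotate_nearest_tss(w, genes)
  mids <- floor((GenomicRanges::start(w) - 1 + GenomicRanges::end(w)) / 2) + 1
  for (i in 1:20) {
    d <- abs(tss - mids[i])
    best <- min(d)
    cand <- genes$gene_id[d == best]
    expect_equal(out$gene_id[i], sort(cand)[1])
    expect_equal(out$distance[i], best)
  }
  # a window on a chromosome without genes maps to NA
  w2 <- suppressWarnings(c(w, toy_windows(1, chrom = "chrEmpty")))
  out2 <- annotate_nearest_tss(w2, genes)
  expect_true(is.na(out2$gene_id[21]))
})

test_that("TSS-distance band fraction matches a brute-force count", {
  m <- data.frame(window = paste0("w", 1:4), gene_id = "g",
                  distance = c(10000, 0, 5000, 20001),
                  signed_distance = c(10000, 0, -5000, 20001))
  expect_equal(tss_distance_band_fraction(m), 2 / 4)  # 10000 and 5000 in [5k,20k]
  m$distance <- rep(10000, 4)
  expect_equal(tss_distance_band_fraction(m), 1)
  m$distance <- rep(0, 4)
  expect_equal(tss_distance_band_fraction(m), 0)
  set.seed(11)
  d <- sample.int(40000, 50)
  m50 <- data.frame(window = paste0("w", 1:50), gene_id = "g",
                    distance = d, signed_distance = d)
  expect_equal(tss_distance_band_fraction(m50), mean(d >= 5000 & d <= 20000))
  expect_error(tss_distance_band_fraction(m50[0, ]), "empty")
})

test_that("class-switch classification keeps only significant reciprocal windows", {
  w <- paste0("w", 1:6)
  pm <- fake_diff(w, log2FC = c(0.909, -1.2, 2.0, 1.5, -0.8, 0.5),
                  fdr = c(0.01, 0.02, 0.5, 0.03, 0.04, 0.2),
                  comparison = "prem_vs_mal")
  kd <- fake_diff(w, log2FC = c(-1.925, 1.0, -2.0, 1.0, -1.0, -0.5),
                  fdr = c(0.02, 0.01, 0.01, 0.02, 0.03, 0.01),
                  comparison = "LMP_vs_shUbtf")
  cs <- classify_class_switch(pm, kd)
  # w1: up in malignant, down without UBTF, significant in both
  expect_true("w1" %in% cs$window)
  expect_equal(cs$category[cs$window == "w1"], "incMal_decUbtf")
  # w2: down in malignant, up without UBTF
  expect_equal(cs$category[cs$window == "w2"], "decMal_incUbtf")
  # w3 significant in only one comparison: removed
  expect_false("w3" %in% cs$window)
  # w4: significant both but same sign: removed
  expect_false("w4" %in% cs$window)
  # categories disjoint by construction
  expect_false(any(duplicated(cs$window)))
  expect_error(classify_class_switch(pm, fake_diff(paste0("x", 1:3), 0, 1)),
               "share no windows")
})

test_that("RPKM formula, zeros, and the conservation identity", {
  expect_equal(unname(compute_rpkm(10, 2000, 1e6)[1, 1]), 5)
  expect_equal(unname(compute_rpkm(0, 2000, 1e6)[1, 1]), 0)
  set.seed(12)
  cnt <- matrix(rpois(40, 500), 10, 4)
  len <- sample(500:5000, 10)
  r <- compute_rpkm(cnt, len)
  # sum_g RPKM_g * length_g/1e3 = 1e6 when totals are the in-table sums
  expect_equal(unname(colSums(r * len / 1e3)), rep(1e6, 4))
  expect_error(compute_rpkm(cnt, len, totals = rep(0, 4)), "positive")
})

test_that("DE calling applies both the FDR and magnitude thresholds", {
  libs <- data.frame(condition = rep(c("prem", "mal"), each = 3),
                     replicate = rep(1:3, 2))
  set.seed(13)
  base <- rpois(60, 300)
  m <- cbind(matrix(rpois(180, base), 60, 3),
             matrix(rpois(180, base), 60, 3))
  # plant two genes: strong fold change and sub-threshold fold change
  m[1, 4:6] <- rpois(3, base[1] * 8)
  m[2, 4:6] <- rpois(3, base[2] * 2^0.3)
  rownames(m) <- paste0("g", 1:60)
  de <- call_de_genes(m, libs, c("prem", "mal"))
  expect_true(de$de[1])
  expect_false(de$de[2])    # |logFC| < 0.5 even if significant
  expect_true(all(abs(de$log2FC[de$de]) >= 0.5))
  expect_true(all(de$fdr[de$de] <= 0.1))
})

test_that("K-S comparison: identity, separation, and the ECDF-sweep oracle", {
  x <- c(1.2, 3.4, 2.2, 5.5, 0.1, 9.9, 4.4, 3.3, 2.1, 7.7)
  same <- ks_density_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  set.seed(14)
  a <- runif(500); b <- runif(500, 0.5, 1.5)
  sep <- ks_density_compare(a, b)
  expect_lt(abs(sep$D - 0.5), 0.06)
  expect_lt(sep$p, 1e-10)

  # brute-force ECDF sweep on two 10-point samples
  y <- c(0.5, 1.5, 2.5, 3.0, 3.1, 6.0, 6.5, 8.0, 8.5, 9.0)
  grid <- sort(c(x, y))
  D_bf <- max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t), 0)))
  expect_equal(ks_density_compare(x, y)$D, D_bf)
  expect_error(ks_density_compare(1:3, x), ">= 5")
})

test_that("inverse expression coupling is detected in the integration report", {
  g <- make_genome(2, 5e5, seed = 20)
  ann <- make_annotation(g, n_genes = 120, seed = 20,
                         gene_length_range = c(1000, 2500))
  w <- tile_windows(g)
  sim <- simulate_fourc_counts(w, seed = 20, frac_differential = 0.5,
                               frac_reciprocal = 0, n_lowbait = 0, spike = FALSE)
  e <- simulate_expression_counts(ann, w, sim$truth, coupling = 1, effect = 2,
                                  seed = 20)
  de <- call_de_genes(e$counts, e$libs, c("prem", "mal"))
  lfc <- stats::setNames(de$log2FC, de$window)

  # group genes by the planted interaction direction (prem->mal windows)
  tr <- sim$truth$differential_windows
  tr <- tr[tr$comparison == "prem_vs_mal", ]
  tmap <- annotate_nearest_tss(w[match(tr$window, w$label)], ann)
  classes <- data.frame(window = tr$window,
                        class = ifelse(tr$logfc > 0, "increased", "decreased"))
  rpkm <- rowMeans(compute_rpkm(e$counts, e$gene_lengths[rownames(e$counts)]))
  rep <- expression_by_interaction_report(rpkm, lfc, tmap, classes,
                                          one_sided = TRUE)
  # increased-interaction genes are shifted down in expression
  expect_lt(rep$median_lfc_increased, rep$median_lfc_decreased)
  expect_lt(rep$lfc_ks$p, 0.05)
})

test_that("peak overlap fraction equals brute-force interval intersection", {
  set.seed(15)
  w <- toy_windows(100, chrom = "chrO")
  ps <- sort(sample.int(490000, 60))
  peaks <- GenomicRanges::GRanges("chrO", IRanges::IRanges(ps, width = 800))
  out <- peak_overlap_fraction(w, peaks)
  hit_bf <- vapply(seq_along(w), function(i)
    any(ps <= GenomicRanges::end(w)[i] & ps + 799 >= GenomicRanges::start(w)[i]),
    TRUE)
  expect_equal(unname(out$hit), unname(hit_bf))
  expect_equal(out$fraction, mean(hit_bf))

  cover <- GenomicRanges::GRanges("chrO", IRanges::IRanges(1, 500000))
  expect_equal(peak_overlap_fraction(w, cover)$fraction, 1)
  far <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 100))
  expect_equal(suppressWarnings(peak_overlap_fraction(w, far)$fraction), 0)
  # minimum-overlap criterion: a 1-bp touch fails a 100-bp requirement
  touch <- GenomicRanges::GRanges("chrO", IRanges::IRanges(5000, 5000))
  expect_equal(peak_overlap_fraction(w[1], touch)$fraction, 1)
  expect_equal(peak_overlap_fraction(w[1], touch, min_overlap = 100)$fraction, 0)
})

test_that("gene-set overlap fractions and Venn partition identity", {
  a <- c("g1", "g2", "g3", "g4"); b <- c("g3", "g4", "g5")
  o <- gene_set_overlap(a, b)
  expect_setequal(o$intersection, c("g3", "g4"))
  expect_equal(o$fraction_of_a, 0.5)
  expect_equal(o$fraction_of_b, 2 / 3)
  expect_equal(o$n_a, length(o$intersection) + length(setdiff(a, b)))
  expect_equal(gene_set_overlap(a, a)$fraction_of_a, 1)
  expect_equal(gene_set_overlap(a, "zz")$fraction_of_a, 0)
})

test_that("SPRITE profile: perfect concordance and a brute-force 5-region tally", {
  lens <- c(chrS = 2e6)
  w <- toy_windows(40, chrom = "chrS")
  w <- GenomicRanges::shift(w, 500000)   # keep away from chromosome edges

  # regions = the windows themselves: central occupancy 1, p = 1/(n_boot+1)
  res <- sprite_profile_and_bootstrap(w, w[1:10], lens, n_boot = 99, seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 100)

  # brute-force per-region tally on 5 regions
  regions <- GenomicRanges::GRanges("chrS",
                                    IRanges::IRanges(c(400000, 600000, 800000,
                                                       1000000, 1500000),
                                                     width = 2000))
  res5 <- sprite_profile_and_bootstrap(w, regions, lens, n_boot = 9, seed = 2)
  ws <- GenomicRanges::start(w); we <- GenomicRanges::end(w)
  ctr <- floor((GenomicRanges::start(regions) - 1 + GenomicRanges::end(regions)) / 2) + 1
  offs <- res5$offsets
  prof_bf <- sapply(offs, function(o) {
    mean(vapply(ctr, function(cc) {
      lo <- cc + o - 2500 + 1; hi <- cc + o - 2500 + 5000
      any(ws <= hi & we >= lo)
    }, TRUE))
  })
  expect_equal(res5$profile, prof_bf)

  # flank larger than the chromosome: region skipped with a warning
  edge <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1000, 3000))
  expect_warning(sprite_profile_and_bootstrap(w, c(regions, edge), lens,
                                              n_boot = 9, seed = 3),
                 "skipped")
})
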