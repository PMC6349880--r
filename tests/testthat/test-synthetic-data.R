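# Synthetic genome, annotation, count and peak generators: constructor
# contracts, determinism, and planted-effect marginals.

test_that("make_genome honours its contract and is byte-deterministic", {
  g <- make_genome(2, 1e5, seed = 1)
  expect_s3_class(g, "toy_genome")
  expect_length(g$chrom_names, 2)
  expect_length(g$rdna$bait_pos, 11)
  expect_true(all(g$rdna$bait_pos >= g$rdna$start & g$rdna$bait_pos <= g$rdna$end))
  expect_equal(unname(Biostrings::width(g$seqs)), rep(1e5L, 2))

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f1)
  write_genome_fasta(make_genome(2, 1e5, seed = 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the sequence
  g3 <- make_genome(2, 1e5, seed = 2)
  expect_false(identical(as.character(g$seqs[[1]]), as.character(g3$seqs[[1]])))

  expect_error(make_genome(2, 3e4), "50000")
  expect_error(make_genome(2, 6e4, rdna_length = 5e4), "rDNA")
})

test_that("restriction motif occurs at controlled density, verified by string scan", {
  g <- tiny_genome()
  for (i in seq_along(g$seqs)) {
    s <- as.character(g$seqs[[i]])
    hits <- gregexpr(g$motif, s, fixed = TRUE)[[1]]
    n_sites <- sum(hits > 0)
    expect_gt(n_sites, 0)
    # mean spacing ~500 bp (within a factor accounting for truncation noise)
    spacing <- nchar(s) / n_sites
    expect_gt(spacing, 300); expect_lt(spacing, 800)
  }
})

test_that("make_annotation emits valid, in-bounds, non-overlapping BED6 genes", {
  g <- tiny_genome()
  ann <- make_annotation(g, n_genes = 50, seed = 1,
                         gene_length_range = c(500, 1500))
  expect_length(ann, 50)
  expect_setequal(unique(as.character(GenomicRanges::strand(ann))), c("+", "-"))
  # TSS convention: start for "+", end for "-"
  plus <- as.character(GenomicRanges::strand(ann)) == "+"
  expect_equal(ann$tss[plus], GenomicRanges::start(ann)[plus])
  expect_equal(ann$tss[!plus], GenomicRanges::end(ann)[!plus])
  # full-scan bounds check
  lens <- g$chrom_lengths[as.character(GenomicRanges::seqnames(ann))]
  expect_true(all(ann$tss >= 1 & ann$tss <= lens))
  expect_true(all(GenomicRanges::start(ann) >= 1 &
                    GenomicRanges::end(ann) <= lens))
  # non-overlapping
  expect_equal(sum(GenomicRanges::countOverlaps(ann, ann) != 1), 0)
  # BED round trip
  bed <- tempfile(fileext = ".bed")
  write_bed(ann, bed)
  back <- rtracklayer::import(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann))
  expect_equal(back$name, ann$gene_id)
  # capacity guard
  expect_error(make_annotation(g, n_genes = 1e5), "capacity")
})

test_that("4C counts reproduce NB/Poisson marginals and planted fold changes", {
  w <- toy_windows(40)
  # Poisson limit: dispersion 0 gives variance/mean ~ 1
  sim0 <- simulate_fourc_counts(w, conditions = list(stage = c("a", "b")),
                                n_reps = 30, mean_count = 200, dispersion = 0,
                                frac_differential = 0, frac_background = 0,
                                n_lowbait = 0, spike = FALSE, seed = 3)
  # per (window, library) cell the 11 bait counts are iid Poisson draws:
  # variance/mean ratio ~ 1 in the dispersion -> 0 limit
  arr0 <- sim0$counts$counts
  m0 <- apply(arr0, c(1, 3), mean)
  v0 <- apply(arr0, c(1, 3), stats::var)
  ratio <- mean(v0) / mean(m0)
  expect_lt(ratio, 1.1)
  expect_gt(ratio, 0.9)

  # NB: variance/mean ~ 1 + alpha*mu at alpha = 0.1, mu = 100
  simnb <- simulate_fourc_counts(w, conditions = list(stage = c("a", "b")),
                                 n_reps = 200, mean_count = 100, dispersion = 0.1,
                                 frac_differential = 0, frac_background = 0,
                                 n_lowbait = 0, spike = FALSE, seed = 4)
  arr <- simnb$counts$counts
  sf <- simnb$truth$size_factors_true
  # per (window, library) cell the 11 baits are iid NB draws; pool over baits
  m <- apply(arr, c(1, 3), mean)
  v <- apply(arr, c(1, 3), stats::var)
  ratio <- colMeans(v) / colMeans(m)     # per library
  # V = mu + alpha mu^2 averaged over windows: 1 + alpha E[mu^2]/E[mu]
  expected <- 1 + 0.1 * colMeans(m^2) / colMeans(m)
  expect_true(all(abs(ratio / expected - 1) < 0.35))

  # planted logFC = 1: ratio of condition means ~ 2 over many replicates
  simfc <- simulate_fourc_counts(w, conditions = list(stage = c("a", "b")),
                                 n_reps = 500, mean_count = 100,
                                 dispersion = 0.05, logfc = 1,
                                 frac_differential = 0.3, frac_reciprocal = 0,
                                 frac_background = 0, n_lowbait = 0,
                                 spike = FALSE, seed = 5)
  tr <- simfc$truth$differential_windows
  expect_gt(nrow(tr), 0)   # effects are planted even without background windows
  tot <- nad4c:::library_totals(simfc$counts)
  tot <- sweep(tot, 2, simfc$truth$size_factors_true, "/")
  a_mean <- rowMeans(tot[, simfc$counts$libs$condition == "a"])
  b_mean <- rowMeans(tot[, simfc$counts$libs$condition == "b"])
  obs <- log2(b_mean / a_mean)[match(tr$window, simfc$counts$windows$label)]
  expect_true(all(abs(obs - tr$logfc) < 0.2))
})

test_that("generator marginals pass a chi-square variance check (100 windows)", {
  # self-normalized z per window of the squared standardized residuals,
  # combined across windows as chi-square(100): rejects if the NB
  # mean-variance relationship (with the true size factors) is wrong
  w <- toy_windows(100)
  alpha <- 0.1
  sim <- simulate_fourc_counts(w, conditions = list(stage = c("a", "b")),
                               n_reps = 30, mean_count = 80, dispersion = alpha,
                               frac_differential = 0, frac_background = 0,
                               n_lowbait = 0, spike = FALSE, seed = 6)
  arr <- sim$counts$counts
  sf <- sim$truth$size_factors_true
  z <- vapply(seq_len(dim(arr)[1]), function(wi) {
    x <- arr[wi, , ]                                 # bait x library
    mu_w <- mean(sweep(x, 2, sf, "/"))
    mu <- matrix(rep(sf * mu_w, each = nrow(x)), nrow = nrow(x))
    V <- mu + alpha * mu^2
    d <- (x - mu)^2 / V
    (mean(d) - 1) / (stats::sd(d) / sqrt(length(d)))
  }, 0)
  stat <- sum(z^2)
  p <- stats::pchisq(stat, df = 100, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("truth ledger categories are disjoint and self-consistent", {
  sim <- simulate_fourc_counts(toy_windows(200), seed = 9)
  tr <- sim$truth
  expect_s3_class(tr, "truth_ledger")
  expect_length(intersect(tr$constitutive_windows, tr$differential_windows$window), 0)
  expect_length(intersect(tr$constitutive_windows, tr$background_windows), 0)
  expect_length(intersect(tr$differential_windows$window, tr$background_windows), 0)
  expect_true(all(tr$reciprocal_windows$window %in% tr$differential_windows$window))
  expect_true(all(abs(tr$differential_windows$logfc) > 0))
  expect_false(any(duplicated(tr$reciprocal_windows$window)))
  # ledger consistent with the emitted table dimensions
  expect_true(all(tr$differential_windows$window %in% sim$counts$windows$label))
  # determinism of the whole draw
  sim2 <- simulate_fourc_counts(toy_windows(200), seed = 9)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$truth$differential_windows, sim2$truth$differential_windows)
  # errors
  expect_error(simulate_fourc_counts(toy_windows(10), dispersion = -1), "dispersion")
  expect_error(simulate_fourc_counts(toy_windows(10), n_reps = 1), "replicates")
})

test_that("expression coupling follows the inverse sign rule and is recoverable", {
  g <- tiny_genome()
  ann <- tiny_annotation()
  w <- tile_windows(g)
  sim <- simulate_fourc_counts(w, seed = 2, n_lowbait = 0, spike = FALSE)

  # coupling = 0: no coupled genes
  e0 <- simulate_expression_counts(ann, w, sim$truth, coupling = 0, seed = 2)
  expect_null(e0$truth$coupled_genes)

  e1 <- simulate_expression_counts(ann, w, sim$truth, coupling = 1,
                                   effect = 2, seed = 2)
  cg <- e1$truth$coupled_genes
  expect_gt(nrow(cg), 0)
  # sign rule: expression effect opposes the interaction effect
  expect_true(all(sign(cg$logfc_expression) == -sign(cg$logfc_interaction)))
  expect_error(simulate_expression_counts(ann, w, sim$truth, coupling = 1.2),
               "coupling")
})

test_that("planted expression logFC is recovered within +/-0.2 on a large panel", {
  g <- make_genome(4, 2e6, seed = 12)
  ann <- make_annotation(g, n_genes = 1000, seed = 12,
                         gene_length_range = c(1000, 2500))
  w <- tile_windows(g)
  sim <- simulate_fourc_counts(w, seed = 12, frac_differential = 0.5,
                               n_lowbait = 0, spike = FALSE)
  e <- simulate_expression_counts(ann, w, sim$truth, coupling = 1, effect = 2,
                                  n_reps = 6, seed = 12)
  cg <- e$truth$coupled_genes
  cg <- cg[grepl("prem_vs_mal", cg$comparison), ]
  m_prem <- rowMeans(e$counts[cg$gene_id, e$libs$condition == "prem", drop = FALSE])
  m_mal <- rowMeans(e$counts[cg$gene_id, e$libs$condition == "mal", drop = FALSE])
  est <- log2((m_mal + 0.5) / (m_prem + 0.5))
  expect_gt(length(est), 50)
  expect_lt(abs(mean(est - cg$logfc_expression)), 0.2)
})

test_that("peak sets realize their target overlap, measured independently", {
  g <- tiny_genome()
  w <- tile_windows(g)
  designated <- w[seq(1, length(w), by = 3)]

  brute_overlap <- function(windows, peaks) {
    ws <- GenomicRanges::start(windows); we <- GenomicRanges::end(windows)
    wc <- as.character(GenomicRanges::seqnames(windows))
    ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
    pc <- as.character(GenomicRanges::seqnames(peaks))
    hit <- vapply(seq_along(windows), function(i)
      any(pc == wc[i] & ps <= we[i] & pe >= ws[i]), TRUE)
    mean(hit)
  }

  sets <- simulate_peak_sets(g, designated,
                             target_overlap = c(H3K4me1 = 0.27, full = 1, none = 0),
                             n_background = 20, seed = 3)
  expect_named(sets, c("H3K4me1", "full", "none"))
  expect_lt(abs(brute_overlap(designated, sets$H3K4me1) - 0.27), 0.05)
  expect_equal(brute_overlap(designated, sets$full), 1)
  # target 0: no peak touches a designated window
  expect_equal(brute_overlap(designated, sets$none), 0)
  expect_error(simulate_peak_sets(g, designated, target_overlap = c(x = 1.5)),
               "\\[0, 1\\]")
})

test_that("count tables and the truth ledger round-trip through TSV/JSON", {
  sim <- simulate_fourc_counts(toy_windows(15), seed = 8, n_lowbait = 2)
  tsv <- tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, tsv)
  back <- read_counts_tsv(tsv)
  expect_equal(unname(back$counts), unname(sim$counts$counts))
  expect_equal(back$windows$label, sim$counts$windows$label)

  js <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(sort(parsed$constitutive_windows),
               sort(sim$truth$constitutive_windows))
})
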