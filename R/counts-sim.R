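## Synthetic 4C / RNA count generators with a ground-truth ledger.
## The defaults are the study conditions the package is validated under:
## 11 rDNA baits, 2 replicates per condition, the malignant-progression
## series {wt, prem, mal} plus the knockdown series {LMP, shUbtf}, NB counts
## at mean ~100 reads/window/bait with dispersion 0.05, planted fold changes
## of 2^2, and library size factors log-uniform on [0.5, 2].

#' Simulate multi-bait 4C window counts with planted structure
#'
#' Generates the window x bait x library count tensor of a two-series 4C
#' experiment. A configurable fraction of windows carries a planted
#' differential interaction (a log2 fold change in one stage transition);
#' half of the prem->mal differential windows are additionally reciprocal
#' ("class switch"): their change is reversed in the shUbtf vs LMP series.
#' Background windows with near-zero means exercise the replicate filter; a
#' configurable subset of windows receives counts in fewer than four baits
#' (bait-support filter) and one window gets a single-bait spike (outlier
#' filter).
#'
#' @param genome A `toy_genome` (windows are its 5-kb tiling), or a
#'   `GRanges` of windows.
#' @param conditions Named list of condition series; comparisons are planted
#'   between consecutive members of a series.
#' @param n_reps Replicates per condition (>= 2).
#' @param mean_count Median per-bait NB mean of interacting windows.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param logfc Planted |log2 fold change| of differential windows.
#' @param frac_differential Fraction of interacting windows that are
#'   differential.
#' @param frac_reciprocal Fraction of prem->mal differential windows that
#'   are reciprocal in the knockdown series.
#' @param frac_background Fraction of windows given near-zero means.
#' @param n_lowbait Number of windows restricted to 3 supporting baits.
#' @param spike Plant one single-bait spike window (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `counts` (`interaction_counts`, state `"raw"`) and
#'   `truth` (a `truth_ledger`).
#' @export
simulate_fourc_counts <- function(genome,
                                  conditions = list(stage = c("wt", "prem", "mal"),
                                                    knockdown = c("LMP", "shUbtf")),
                                  n_reps = 2,
                                  mean_count = 100,
                                  dispersion = 0.05,
                                  logfc = 2,
                                  frac_differential = 0.25,
                                  frac_reciprocal = 0.5,
                                  frac_background = 0.10,
                                  n_lowbait = 25,
                                  spike = TRUE,
                                  seed = 1) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_reps < 2) stop("at least 2 replicates per condition are required")
  stopifnot(frac_differential >= 0, frac_differential <= 1,
            frac_reciprocal >= 0, frac_reciprocal <= 1)
  windows <- if (inherits(genome, "toy_genome")) tile_windows(genome) else genome
  n_w <- length(windows)
  cond_all <- unlist(conditions, use.names = FALSE)
  libs <- data.frame(condition = rep(cond_all, each = n_reps),
                     replicate = rep(seq_len(n_reps), length(cond_all)),
                     stringsAsFactors = FALSE)
  n_lib <- nrow(libs)
  n_baits <- 11L

  out <- with_seed(derive_seed(seed, "fourc"), {
    sf_true <- exp(stats::runif(n_lib, log(0.5), log(2)))

    idx <- sample.int(n_w)                       # random window roles
    n_bg <- round(frac_background * n_w)
    bg <- idx[seq_len(n_bg)]
    interacting <- if (n_bg > 0) idx[-seq_len(n_bg)] else idx
    n_diff <- round(frac_differential * length(interacting))
    diff_w <- interacting[seq_len(n_diff)]
    const_w <- interacting[-seq_len(n_diff)]

    # each differential window gets one stage transition and a sign
    stage <- conditions[[1]]
    transitions <- paste(stage[-length(stage)], stage[-1], sep = "_vs_")
    tr <- sample(transitions, n_diff, replace = TRUE)
    sgn <- sample(c(-1, 1), n_diff, replace = TRUE)
    # reciprocal subset: prem->mal windows whose change reverses under knockdown
    pm <- which(tr == paste(stage[length(stage) - 1L], stage[length(stage)], sep = "_vs_"))
    n_rec <- round(frac_reciprocal * length(pm))
    rec <- if (n_rec > 0) sample(pm, n_rec) else integer(0)

    mu_w <- stats::rlnorm(n_w, log(mean_count), 0.3)
    mu_w[bg] <- stats::rlnorm(length(bg), log(0.4), 0.3)

    # per-condition mean multiplier: effects persist from their transition on
    fold <- matrix(1, n_w, length(cond_all), dimnames = list(NULL, cond_all))
    for (k in seq_len(n_diff)) {
      w <- diff_w[k]
      to <- sub(".*_vs_", "", tr[k])
      from_i <- match(to, stage)
      fold[w, stage[from_i:length(stage)]] <- 2^(sgn[k] * logfc)
    }
    if (length(conditions) >= 2 && length(rec) > 0) {
      kd <- conditions[[2]]                      # c(control, knockdown)
      for (k in rec)
        fold[diff_w[k], kd[2]] <- 2^(-sgn[k] * logfc)
    }

    low <- integer(0)
    if (n_lowbait > 0) low <- sample(const_w, min(n_lowbait, length(const_w)))
    spike_w <- if (spike) sample(setdiff(const_w, low), 1L) else integer(0)

    counts <- array(0L, dim = c(n_w, n_baits, n_lib))
    size <- if (dispersion > 0) 1 / dispersion else Inf
    for (j in seq_len(n_lib)) {
      mu_j <- sf_true[j] * mu_w * fold[, libs$condition[j]] / 1
      for (b in seq_len(n_baits)) {
        mu_b <- mu_j
        counts[, b, j] <- if (is.finite(size))
          stats::rnbinom(n_w, size = size, mu = mu_b)
        else stats::rpois(n_w, mu_b)
      }
    }
    # low-bait windows: signal restricted to baits 1..3
    if (length(low) > 0) counts[low, 4:n_baits, ] <- 0L
    # single-bait spike: near-background window whose signal sits in bait 1 only
    if (length(spike_w) == 1L) {
      counts[spike_w, , ] <- stats::rpois(n_baits * n_lib, 1)
      counts[spike_w, 1, ] <- as.integer(round(50 * mean_count))
    }

    categories <- c("up-mal/down-shUbtf", "down-mal/up-shUbtf")
    rec_cat <- if (length(rec) > 0)
      ifelse(sgn[rec] > 0, categories[1], categories[2]) else character(0)

    list(counts = counts, sf_true = sf_true,
         constitutive = windows$label[sort(setdiff(const_w, c(low, spike_w)))],
         differential = data.frame(window = windows$label[diff_w],
                                   comparison = tr, logfc = sgn * logfc,
                                   stringsAsFactors = FALSE),
         reciprocal = data.frame(window = windows$label[diff_w[rec]],
                                 category = rec_cat,
                                 logfc_interaction = sgn[rec] * logfc,
                                 stringsAsFactors = FALSE),
         background = windows$label[sort(bg)],
         lowbait = windows$label[sort(low)],
         spike = windows$label[spike_w])
  })

  bait_names <- paste0("bait", sprintf("%02d", seq_len(n_baits)))
  dimnames(out$counts)[[2]] <- bait_names
  ic <- interaction_counts(out$counts, windows, libs, state = "raw")
  truth <- structure(
    list(constitutive_windows = out$constitutive,
         differential_windows = out$differential,
         reciprocal_windows = out$reciprocal,
         coupled_genes = NULL,
         size_factors_true = stats::setNames(out$sf_true, ic$libs$library_id),
         background_windows = out$background,
         lowbait_windows = out$lowbait,
         spike_window = out$spike,
         params = list(mean_count = mean_count, dispersion = dispersion,
                       logfc = logfc, n_reps = n_reps)),
    class = "truth_ledger")
  list(counts = ic, truth = truth)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf(paste0("truth_ledger: %d constitutive, %d differential ",
                     "(%d reciprocal), %d background windows\n"),
              length(x$constitutive_windows), nrow(x$differential_windows),
              nrow(x$reciprocal_windows), length(x$background_windows)))
  if (!is.null(x$coupled_genes))
    cat(sprintf("%d coupled genes (inverse expression coupling)\n",
                nrow(x$coupled_genes)))
  invisible(x)
}

#' Write a truth ledger to JSON
#'
#' @param truth A `truth_ledger`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_ledger"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate gene expression counts inversely coupled to interaction changes
#'
#' Gene-level NB counts for the stage series. A `coupling` fraction of the
#' planted differential windows passes its change to the nearest gene with
#' the opposite sign: increased rDNA interaction is planted as decreased
#' expression of the associated gene, the inverse relationship the
#' interaction/expression integration is designed to detect.
#'
#' @param annotation `GRanges` from [make_annotation()].
#' @param windows `GRanges` of windows (universe of the truth ledger).
#' @param truth `truth_ledger` from [simulate_fourc_counts()]; updated and
#'   returned.
#' @param coupling Fraction in `[0, 1]` of differential windows whose
#'   nearest gene is coupled.
#' @param effect Planted |log2 fold change| of coupled genes' expression.
#' @param conditions Stage conditions (expression is simulated for these).
#' @param n_reps Replicates per condition.
#' @param mean_count Median NB mean per gene.
#' @param dispersion NB dispersion.
#' @param seed Integer seed.
#' @return List with `counts` (gene x library matrix), `libs`,
#'   `gene_lengths` (bp, named), and the updated `truth`.
#' @export
simulate_expression_counts <- function(annotation, windows, truth,
                                       coupling = 0.8, effect = 2,
                                       conditions = c("wt", "prem", "mal"),
                                       n_reps = 2, mean_count = 200,
                                       dispersion = 0.1, seed = 1) {
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  stopifnot(inherits(truth, "truth_ledger"))
  genes <- annotation$gene_id
  n_g <- length(genes)
  libs <- data.frame(condition = rep(conditions, each = n_reps),
                     replicate = rep(seq_len(n_reps), length(conditions)),
                     stringsAsFactors = FALSE)
  n_lib <- nrow(libs)

  # nearest gene of every differential window (coupling precondition)
  cand <- NULL
  if (coupling > 0 && nrow(truth$differential_windows) > 0) {
    dw <- truth$differential_windows
    wsub <- windows[match(dw$window, windows$label)]
    ann_map <- annotate_nearest_tss(wsub, annotation)
    cand <- data.frame(gene_id = ann_map$gene_id, comparison = dw$comparison,
                       logfc_interaction = dw$logfc, stringsAsFactors = FALSE)
    cand <- cand[!is.na(cand$gene_id), , drop = FALSE]
    cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  }

  out <- with_seed(derive_seed(seed, "expression"), {
    coupled <- NULL
    if (!is.null(cand) && nrow(cand) > 0) {
      take <- sort(sample.int(nrow(cand), round(coupling * nrow(cand))))
      coupled <- cand[take, , drop = FALSE]
      coupled$logfc_expression <- -sign(coupled$logfc_interaction) * effect
    }
    base <- stats::rlnorm(n_g, log(mean_count), 0.5)
    fold <- matrix(1, n_g, length(conditions), dimnames = list(genes, conditions))
    if (!is.null(coupled) && nrow(coupled) > 0) {
      for (k in seq_len(nrow(coupled))) {
        gi <- match(coupled$gene_id[k], genes)
        to <- sub(".*_vs_", "", coupled$comparison[k])
        from_i <- match(to, conditions)
        if (is.na(from_i)) next
        fold[gi, conditions[from_i:length(conditions)]] <-
          2^coupled$logfc_expression[k]
      }
    }
    size <- if (dispersion > 0) 1 / dispersion else Inf
    counts <- matrix(0L, n_g, n_lib,
                     dimnames = list(genes, paste(libs$condition, libs$replicate, sep = ".")))
    for (j in seq_len(n_lib)) {
      mu <- base * fold[, libs$condition[j]]
      counts[, j] <- if (is.finite(size)) stats::rnbinom(n_g, size = size, mu = mu)
        else stats::rpois(n_g, mu)
    }
    list(counts = counts, coupled = coupled)
  })

  truth$coupled_genes <- out$coupled
  list(counts = out$counts, libs = libs,
       gene_lengths = stats::setNames(GenomicRanges::width(annotation), genes),
       truth = truth)
}

#' Simulate peak sets with a target overlap against designated windows
#'
#' Emits H3K4me1, H3K4me3, UBTF and SPRITE region sets. For each set, a
#' fraction `target_overlap` of the designated windows receives a peak
#' inside it; remaining peaks are placed away from all designated windows,
#' so the realized overlap fraction of the designated set matches the target
#' up to rounding.
#'
#' @param genome A `toy_genome` (for chromosome lengths).
#' @param target_windows `GRanges` of designated windows the overlap is
#'   measured against.
#' @param target_overlap Named numeric vector of target overlap fractions in
#'   `[0, 1]` (names become the peak sets).
#' @param peak_width Peak width in bp (SPRITE regions are 4x wider).
#' @param n_background Background peaks per set placed off the designated
#'   windows.
#' @param seed Integer seed.
#' @return Named list of `GRanges` peak sets.
#' @export
simulate_peak_sets <- function(genome, target_windows,
                               target_overlap = c(H3K4me1 = 0.27, H3K4me3 = 0.10,
                                                  UBTF = 0.01, SPRITE = 0.50),
                               peak_width = 1000, n_background = 100, seed = 1) {
  stopifnot(inherits(genome, "toy_genome"))
  if (any(target_overlap < 0 | target_overlap > 1))
    stop("target_overlap fractions must be in [0, 1]")
  if (length(target_windows) == 0) stop("no designated windows supplied")
  lens <- genome$chrom_lengths

  with_seed(derive_seed(seed, "peaks"), {
    sets <- lapply(names(target_overlap), function(nm) {
      tgt <- target_overlap[[nm]]
      wd <- if (nm == "SPRITE") peak_width * 4L else peak_width
      k <- round(tgt * length(target_windows))
      hit_idx <- if (k > 0) sort(sample.int(length(target_windows), k)) else integer(0)
      hits <- target_windows[hit_idx]
      in_peaks <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(hits)),
        IRanges::IRanges(start = pmax(
          GenomicRanges::start(hits),
          interval_midpoint(GenomicRanges::start(hits), GenomicRanges::end(hits)) -
            as.integer(wd / 2)),
          width = wd),
        seqlengths = lens)
      # background peaks rejected until off every designated window
      bg_ch <- character(0); bg_st <- integer(0); tries <- 0L
      while (length(bg_ch) < n_background && tries < 50L * n_background) {
        tries <- tries + 1L
        ch <- sample(names(lens), 1, prob = as.numeric(lens))
        st <- sample.int(max(1L, lens[[ch]] - wd), 1)
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = wd))
        if (length(GenomicRanges::findOverlaps(cand, target_windows)) == 0) {
          bg_ch <- c(bg_ch, ch); bg_st <- c(bg_st, st)
        }
      }
      if (length(bg_ch) < n_background && tgt < 1)
        stop(sprintf("cannot place background peaks for %s: genome too densely covered by designated windows", nm))
      bg <- GenomicRanges::GRanges(bg_ch, IRanges::IRanges(bg_st, width = wd),
                                   seqlengths = lens)
      gr <- c(in_peaks, bg)
      gr <- GenomicRanges::sort(gr)
      gr$name <- sprintf("%s_peak%04d", nm, seq_along(gr))
      gr
    })
    names(sets) <- names(target_overlap)
    sets
  })
}
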