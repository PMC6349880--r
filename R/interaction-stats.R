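## Normalization and differential statistics on merged window counts:
## median-of-ratios size factors, NB dispersion estimation, the conditional
## NB exact test, BH false-discovery control, and window classification.

#' Median-of-ratios size factors (effective library size)
#'
#' For each library j the scaling factor is the median, over windows with
#' nonzero counts in every library, of the ratio of the library's count to
#' the geometric mean of the window's counts across libraries.
#'
#' @param x An `interaction_counts` in the merged state, or a numeric matrix
#'   `[feature, library]`.
#' @return Named numeric vector of positive size factors, class
#'   `size_factors`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)  # library 2 = 2x library 1
#' size_factors(m)
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "interaction_counts")) {
    if (x$state == "normalized") stop("size factors must be computed on unnormalized counts")
    if (length(dim(x$counts)) == 3L) stop("merge baits before computing size factors")
    x$counts
  } else as.matrix(x)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok))
    stop("no window has nonzero counts in all libraries; size factors undefined")
  lg <- log(m[ok, , drop = FALSE])
  geo <- rowMeans(lg)                      # log geometric mean per window
  # median taken on the ratio scale (for an even window count this differs
  # from the log-scale median by the interpolation rule)
  sf <- apply(exp(lg - geo), 2, stats::median)
  names(sf) <- colnames(m)
  structure(sf, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors (median-of-ratios):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Normalize counts to the effective library size
#'
#' Divides each library's counts by its size factor. Refuses to normalize
#' twice.
#'
#' @param x An `interaction_counts` in the merged state.
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @return The normalized `interaction_counts` (state `"normalized"`).
#' @export
normalize_counts <- function(x, sf = NULL) {
  stopifnot(inherits(x, "interaction_counts"))
  if (x$state == "normalized") stop("counts are already normalized")
  if (length(dim(x$counts)) == 3L) stop("merge baits before normalizing")
  if (is.null(sf)) sf <- size_factors(x)
  stopifnot(length(sf) == ncol(x$counts), all(is.finite(sf)), all(sf > 0))
  x$counts <- sweep(x$counts, 2, unclass(sf), "/")
  x$size_factors <- unclass(sf)
  x$state <- "normalized"
  x$log <- c(x$log, "normalize: counts divided by median-of-ratios size factors")
  x
}

#' Estimate NB dispersions with a 1/mu trend
#'
#' Per-window raw dispersion by the method of moments,
#' `alpha = max(0, (V - mu) / mu^2)` with `V` the pooled within-condition
#' variance and `mu` the grand mean of normalized counts; a trend
#' `alpha(mu) = a0 + a1/mu` is fitted by least squares over windows with
#' positive raw dispersion, and the working dispersion is the conservative
#' `max(raw, trend, floor)`.
#'
#' @param x Normalized `interaction_counts`, or a numeric matrix with `libs`
#'   supplied.
#' @param libs data.frame with `condition` (needed only for a bare matrix).
#' @param alpha_floor Lower bound on the working dispersion (default 1e-8).
#' @return A `dispersion_model` list: `raw`, `trend_coef` (a0, a1), `fitted`,
#'   `final`, `mu`.
#' @export
estimate_dispersions <- function(x, libs = NULL, alpha_floor = 1e-8) {
  if (inherits(x, "interaction_counts")) {
    m <- x$counts; libs <- x$libs
  } else m <- as.matrix(x)
  stopifnot(!is.null(libs))
  cond <- as.character(libs$condition)
  tab <- table(cond)
  if (any(tab < 2)) stop("dispersion estimation needs >= 2 replicates per condition")

  mu <- rowMeans(m)
  ssq <- 0; df <- 0
  for (cc in names(tab)) {
    j <- which(cond == cc)
    mc <- rowMeans(m[, j, drop = FALSE])
    ssq <- ssq + rowSums((m[, j, drop = FALSE] - mc)^2)
    df <- df + (length(j) - 1L)
  }
  V <- ssq / df
  raw <- pmax(0, (V - mu) / mu^2)
  raw[!is.finite(raw)] <- 0

  use <- raw > 0 & mu > 0
  if (sum(use) >= 3 && stats::sd(1 / mu[use]) > 1e-12) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])
    a <- fit$coefficients
    a[is.na(a)] <- 0
  } else if (sum(use) >= 1) {
    a <- c(mean(raw[use]), 0)       # degenerate trend: intercept only
  } else a <- c(0, 0)
  fitted <- pmax(a[1] + a[2] / mu, 0)
  fitted[!is.finite(fitted)] <- 0
  final <- pmax(raw, fitted, alpha_floor)
  structure(list(raw = raw, trend_coef = stats::setNames(as.numeric(a), c("a0", "a1")),
                 fitted = fitted, final = final, mu = mu),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("dispersion_model: %d features, median working alpha = %.4g\n",
              length(x$final), stats::median(x$final)))
  cat(sprintf("trend alpha(mu) = %.4g + %.4g/mu\n",
              x$trend_coef[1], x$trend_coef[2]))
  invisible(x)
}

## Conditional NB exact test for one feature.
## kA, kB: integer condition totals; nA, nB: replicate numbers; alpha: NB
## dispersion (per replicate). Returns the two-sided p-value of the observed
## split of kA + kB, conditioning on the total.
nb_exact_p <- function(kA, kB, nA, nB, alpha) {
  s <- kA + kB
  if (s == 0) return(1)
  a <- 0:s
  mu0 <- s / (nA + nB)                      # per-replicate null mean
  if (alpha < 1e-12) {
    # Poisson boundary of the NB family
    la <- stats::dpois(a, nA * mu0, log = TRUE)
    lb <- stats::dpois(s - a, nB * mu0, log = TRUE)
  } else {
    la <- stats::dnbinom(a, size = nA / alpha, mu = nA * mu0, log = TRUE)
    lb <- stats::dnbinom(s - a, size = nB / alpha, mu = nB * mu0, log = TRUE)
  }
  lf <- la + lb
  lf <- lf - max(lf)
  f <- exp(lf)
  obs <- f[kA + 1L]
  # two-sided: sum of outcomes no more probable than the observed one
  min(1, sum(f[f <= obs * (1 + 1e-10)]) / sum(f))
}

#' Pairwise conditional NB exact test on normalized counts
#'
#' For each window the replicate-summed normalized counts of the two
#' conditions are rounded to integers and the observed split of their total
#' is tested against the conditional distribution implied by NB sampling
#' with the working dispersion (Robinson-Smyth style exact test). The log2
#' fold change uses condition means of normalized counts, with a 0.5
#' pseudocount applied only when a mean is zero; p-values never use
#' pseudocounts. Windows not observed in either condition (per the replicate
#' filter) get `NA` p-values and are excluded from FDR adjustment.
#'
#' @param x Normalized `interaction_counts` (or matrix plus `libs`).
#' @param comparison Character vector `c(condA, condB)`; logFC is B vs A.
#' @param dispersions A `dispersion_model`, or numeric vector of per-window
#'   dispersions (recycled if length 1). Estimated if missing.
#' @param libs data.frame with `condition` when `x` is a bare matrix.
#' @param observed Optional logical matrix `[window, condition]` of
#'   observation flags; taken from `x` if present.
#' @return A `fourc_diff` data.frame: `window`, `comparison`, `baseMeanA`,
#'   `baseMeanB`, `log2FC`, `pval`, `fdr`.
#' @export
nb_test_pairwise <- function(x, comparison, dispersions = NULL, libs = NULL,
                             observed = NULL) {
  if (inherits(x, "interaction_counts")) {
    if (x$state != "normalized") stop("normalize counts before testing")
    m <- x$counts; libs <- x$libs
    if (is.null(observed)) observed <- x$observed
    labels <- x$windows$label
  } else {
    m <- as.matrix(x)
    labels <- rownames(m)
    if (is.null(labels)) labels <- paste0("feature", seq_len(nrow(m)))
  }
  stopifnot(!is.null(libs), length(comparison) == 2L)
  cond <- as.character(libs$condition)
  if (!all(comparison %in% cond))
    stop("comparison conditions not present in the library design")
  jA <- which(cond == comparison[1]); jB <- which(cond == comparison[2])
  if (length(jA) < 2 || length(jB) < 2)
    stop("both conditions need >= 2 replicates")

  if (is.null(dispersions)) {
    sub <- m[, c(jA, jB), drop = FALSE]
    dispersions <- estimate_dispersions(sub, libs = libs[c(jA, jB), , drop = FALSE])
  }
  alpha <- if (inherits(dispersions, "dispersion_model")) dispersions$final else dispersions
  alpha <- rep_len(alpha, nrow(m))

  meanA <- rowMeans(m[, jA, drop = FALSE])
  meanB <- rowMeans(m[, jB, drop = FALSE])
  kA <- as.integer(round(rowSums(m[, jA, drop = FALSE])))
  kB <- as.integer(round(rowSums(m[, jB, drop = FALSE])))

  testable <- rep(TRUE, nrow(m))
  if (!is.null(observed) && all(comparison %in% colnames(observed)))
    testable <- observed[, comparison[1]] & observed[, comparison[2]]

  p <- rep(NA_real_, nrow(m))
  idx <- which(testable)
  p[idx] <- vapply(idx, function(i)
    nb_exact_p(kA[i], kB[i], length(jA), length(jB), alpha[i]), 0)

  c0 <- ifelse(meanA == 0 | meanB == 0, 0.5, 0)
  lfc <- log2((meanB + c0) / (meanA + c0))

  res <- data.frame(window = labels,
                    comparison = paste(comparison, collapse = "_vs_"),
                    baseMeanA = meanA, baseMeanB = meanB,
                    log2FC = lfc, pval = p,
                    fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("fourc_diff", "data.frame")
  res
}

#' @export
print.fourc_diff <- function(x, n = 6, ...) {
  cat(sprintf("fourc_diff: %s, %d windows, %d significant at FDR <= 0.1\n",
              x$comparison[1], nrow(x), sum(x$fdr <= 0.1, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @export
summary.fourc_diff <- function(object, fdr_cutoff = 0.1, ...) {
  sig <- !is.na(object$fdr) & object$fdr <= fdr_cutoff
  out <- list(comparison = object$comparison[1],
              n = nrow(object), n_tested = sum(!is.na(object$pval)),
              n_significant = sum(sig),
              n_increased = sum(sig & object$log2FC > 0),
              n_decreased = sum(sig & object$log2FC < 0),
              fdr_cutoff = fdr_cutoff)
  class(out) <- "summary.fourc_diff"
  out
}

#' @export
print.summary.fourc_diff <- function(x, ...) {
  cat(sprintf("%s: %d/%d windows tested; %d significant at FDR <= %g (%d up, %d down)\n",
              x$comparison, x$n_tested, x$n, x$n_significant, x$fdr_cutoff,
              x$n_increased, x$n_decreased))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment; `NA` values are preserved and excluded from
#' the adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify windows as constitutive or differential
#'
#' A window is constitutive when FDR > `fdr_cutoff` in every pairwise
#' cell-stage comparison; otherwise it is differential, with the direction
#' (increased/decreased) read off the sign of the log fold change of the
#' comparison named by `direction_from`.
#'
#' @param results Named list of `fourc_diff` results, one per pairwise
#'   comparison (all three stage pairs for the standard design).
#' @param direction_from Name of the comparison providing the direction
#'   (default: last element of `results`).
#' @param fdr_cutoff Significance cutoff (default 0.1; FDR equal to the
#'   cutoff counts as differential).
#' @return data.frame `window`, `class` in
#'   `{constitutive, increased, decreased}` (NA when untested in some
#'   comparison), plus per-comparison `fdr_*` columns.
#' @export
classify_windows <- function(results, direction_from = NULL, fdr_cutoff = 0.1) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(results, function(r) r$comparison[1], "")
  w <- results[[1]]$window
  for (r in results)
    if (!identical(r$window, w)) stop("all comparisons must share the window universe")
  if (is.null(direction_from)) direction_from <- names(results)[length(results)]
  if (!direction_from %in% names(results)) stop("unknown direction_from comparison")

  fdr_mat <- sapply(results, function(r) r$fdr)
  any_na <- apply(fdr_mat, 1, anyNA)
  sig_any <- apply(fdr_mat <= fdr_cutoff, 1, any)
  dir_lfc <- results[[direction_from]]$log2FC

  cls <- rep(NA_character_, length(w))
  cls[!any_na & !sig_any] <- "constitutive"
  diff_idx <- which(sig_any %in% TRUE)
  cls[diff_idx] <- ifelse(dir_lfc[diff_idx] >= 0, "increased", "decreased")

  out <- data.frame(window = w, class = cls, stringsAsFactors = FALSE)
  for (nm in names(results)) out[[paste0("fdr_", nm)]] <- results[[nm]]$fdr
  out
}

#' Select the top interactions for a representative bait
#'
#' Windows with raw counts strictly greater than `min_count` in both
#' replicates of the representative bait within one condition are eligible;
#' they are ranked by merged interaction frequency (mean over baits,
#' averaged across the condition's replicates) and the top
#' `ceiling(frac * n)` are returned.
#'
#' @param x Per-bait `interaction_counts` (raw or filtered).
#' @param representative_bait Bait name or index.
#' @param condition Condition to rank within.
#' @param frac Fraction to keep (default 0.10).
#' @param min_count Eligibility threshold, strict (default 10).
#' @return data.frame of selected windows with their merged frequency,
#'   ranked.
#' @export
select_top_interactions <- function(x, representative_bait, condition,
                                    frac = 0.10, min_count = 10) {
  stopifnot(inherits(x, "interaction_counts"))
  if (length(dim(x$counts)) != 3L)
    stop("per-bait counts required (run before the bait merge)")
  baits <- dimnames(x$counts)[[2]]
  if (is.character(representative_bait)) {
    bi <- match(representative_bait, baits)
    if (is.na(bi)) stop("unknown representative bait: ", representative_bait)
  } else bi <- as.integer(representative_bait)
  if (is.na(bi) || bi < 1 || bi > length(baits)) stop("unknown representative bait")
  j <- which(x$libs$condition == condition)
  if (length(j) < 2) stop("condition needs >= 2 replicates")

  rep_counts <- x$counts[, bi, j, drop = FALSE]
  eligible <- apply(rep_counts > min_count, 1, all)
  n_el <- sum(eligible)
  if (n_el == 0)
    return(data.frame(window = character(0), frequency = numeric(0)))
  freq <- apply(x$counts[, , j, drop = FALSE], 1, mean)
  ord <- order(-freq, x$windows$label)
  ord <- ord[eligible[ord]]
  k <- ceiling(frac * n_el)
  sel <- ord[seq_len(k)]
  data.frame(window = x$windows$label[sel], frequency = freq[sel],
             stringsAsFactors = FALSE, row.names = NULL)
}
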