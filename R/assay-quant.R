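## Closed-form arithmetic for the bench quantifications: qPCR relative
## expression, ChIP percent-input with serum subtraction, HpaII/MeDIP
## methylation percentages, 3C-qPCR relative interaction frequency, and the
## psoralen active-rDNA fraction. All functions are vectorized over their
## Ct (or intensity) arguments; amplification efficiency is 2.0 per cycle
## unless configured.

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = E^-[(ct_target - ct_norm) - (ct_target_ref - ct_norm_ref)]`,
#' i.e. target expression normalized to a housekeeping amplicon and
#' expressed relative to a reference sample.
#'
#' @param ct_target,ct_norm Ct of the target and normalizer amplicons in the
#'   sample of interest.
#' @param ct_target_ref,ct_norm_ref The same Cts in the reference sample.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Fold change relative to the reference (1 for the reference
#'   itself).
#' @examples
#' qpcr_relative_expression(20, 18, 21, 18)  # one cycle earlier: 2-fold
#' @export
qpcr_relative_expression <- function(ct_target, ct_norm, ct_target_ref,
                                     ct_norm_ref, efficiency = 2) {
  if (anyNA(c(ct_target, ct_norm, ct_target_ref, ct_norm_ref)))
    stop("all four Ct values are required")
  ddct <- (ct_target - ct_norm) - (ct_target_ref - ct_norm_ref)
  efficiency^(-ddct)
}

#' ChIP enrichment as percent of input, with serum-control subtraction
#'
#' `%IP = 100 * input_fraction * E^(ct_input - ct_ip)`; the percentage
#' recovered with the non-immune serum control is computed the same way and
#' subtracted. A negative result after subtraction is floored at 0 with a
#' warning.
#'
#' @param ct_ip Ct of the immunoprecipitated DNA.
#' @param ct_input Ct of the (diluted) input DNA.
#' @param input_fraction Fraction of chromatin the input lane represents
#'   (in `(0, 1]`).
#' @param ct_serum,ct_input_serum Cts for the serum control IP and its
#'   input; when `ct_serum` is `NA` the unsubtracted value is returned with
#'   attribute `subtracted = FALSE`.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Percent of input (serum-subtracted when possible), attribute
#'   `subtracted` flags whether subtraction happened.
#' @export
chip_percent_input <- function(ct_ip, ct_input, input_fraction = 1,
                               ct_serum = NA, ct_input_serum = ct_input,
                               efficiency = 2) {
  if (any(input_fraction <= 0 | input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  pct_ip <- 100 * input_fraction * efficiency^(ct_input - ct_ip)
  if (all(is.na(ct_serum))) {
    attr(pct_ip, "subtracted") <- FALSE
    return(pct_ip)
  }
  pct_rs <- 100 * input_fraction * efficiency^(ct_input_serum - ct_serum)
  out <- pct_ip - pct_rs
  if (any(out < 0, na.rm = TRUE)) {
    warning("negative percent-input after serum subtraction floored at 0")
    out <- pmax(out, 0)
  }
  attr(out, "subtracted") <- TRUE
  out
}

#' Percent methylation from HpaII-resistance qPCR
#'
#' DNA resistant to the methylation-sensitive HpaII digestion (= methylated
#' at the site) relative to mock-digested DNA:
#' `% methylated = 100 * E^(ct_mock - ct_digested)`, capped at 100 with a
#' warning.
#'
#' @param ct_digested Ct after HpaII digestion.
#' @param ct_mock Ct of the mock-digested control.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return List with `percent_methylated` and `percent_unmethylated`
#'   (complement to 100).
#' @export
hpaii_resistance <- function(ct_digested, ct_mock, efficiency = 2) {
  pct <- 100 * efficiency^(ct_mock - ct_digested)
  if (any(pct > 100, na.rm = TRUE)) {
    warning("HpaII resistance above 100% capped")
    pct <- pmin(pct, 100)
  }
  list(percent_methylated = pct, percent_unmethylated = 100 - pct)
}

#' MeDIP recovery as percent of total input DNA
#'
#' Same arithmetic as [chip_percent_input()], with the input scaled to a
#' stated DNA mass (the assay normalizes to 20 ng of input): the input Ct is
#' taken to represent `input_ng` of DNA, and recovery is expressed relative
#' to that mass. The serum (non-immune) control is subtracted when present.
#'
#' @param ct_ip Ct of the immunoprecipitated DNA.
#' @param ct_input Ct of the input aliquot representing `input_ng` of DNA.
#' @param input_ng Input DNA mass in ng the percentage is normalized to
#'   (> 0; default 20); retained as an explicit unit declaration.
#' @param ct_serum Ct of the serum control (NA to skip subtraction).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Percent of total DNA bound, attribute `subtracted` as in
#'   [chip_percent_input()].
#' @export
medip_percent_total <- function(ct_ip, ct_input, input_ng = 20, ct_serum = NA,
                                efficiency = 2) {
  if (any(input_ng <= 0)) stop("input_ng must be positive")
  chip_percent_input(ct_ip, ct_input, input_fraction = 1,
                     ct_serum = ct_serum, ct_input_serum = ct_input,
                     efficiency = efficiency)
}

#' 3C-qPCR interaction frequency relative to a reference sample
#'
#' Crosslinking frequency is double-normalized to a single-copy locus and a
#' multi-copy locus; the two normalizers are combined as a geometric mean
#' (configurable), and the result expressed as percent of the reference
#' sample: `raw = E^-ct_3c / g(E^-ct_single, E^-ct_multi)`,
#' `result = 100 * raw / raw_ref`.
#'
#' @param ct_3c,ct_single_copy,ct_multi_copy Cts for the ligation product
#'   and the two normalizer amplicons (vectors over samples).
#' @param reference Index or name of the reference sample within the
#'   vectors.
#' @param combine How the two normalizers are combined: `"geometric"`
#'   (default), `"arithmetic"`, or `"sequential"` (divide by both in turn).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Percent interaction frequency relative to the reference (100 for
#'   the reference itself).
#' @export
c3_relative_frequency <- function(ct_3c, ct_single_copy, ct_multi_copy,
                                  reference = 1, combine = "geometric",
                                  efficiency = 2) {
  n <- length(ct_3c)
  stopifnot(length(ct_single_copy) == n, length(ct_multi_copy) == n)
  ri <- if (is.character(reference)) match(reference, names(ct_3c)) else reference
  if (is.na(ri) || ri < 1 || ri > n) stop("reference sample missing")
  q <- function(ct) efficiency^(-ct)
  norm <- switch(combine,
    geometric = sqrt(q(ct_single_copy) * q(ct_multi_copy)),
    arithmetic = (q(ct_single_copy) + q(ct_multi_copy)) / 2,
    sequential = q(ct_single_copy) * q(ct_multi_copy),
    stop("combine must be geometric, arithmetic or sequential"))
  raw <- q(ct_3c) / norm
  100 * raw / raw[ri]
}

#' Active rDNA fraction from psoralen band intensities
#'
#' The psoralen crosslinking gel separates open (active) from closed
#' (inactive) rDNA chromatin; the active fraction is
#' `100 * active / (active + inactive)`.
#'
#' @param active,inactive Band intensities (arbitrary units, >= 0; not both
#'   zero).
#' @return Percent active rDNA.
#' @examples
#' psoralen_active_fraction(38.2, 61.8)  # 38.2
#' @export
psoralen_active_fraction <- function(active, inactive) {
  if (any(active < 0 | inactive < 0)) stop("band intensities must be >= 0")
  if (any(active + inactive == 0)) stop("active + inactive must be > 0")
  100 * active / (active + inactive)
}
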