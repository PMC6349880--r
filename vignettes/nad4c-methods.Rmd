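---
title: "Methods: multi-bait 4C-seq analysis of rDNA-genome interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-bait 4C-seq analysis of rDNA-genome interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nad4c)
```

## The problem

Ribosomal DNA (rDNA) repeats nucleate the nucleolus, and non-rDNA genomic
regions that associate with it (nucleolar-associated domains, NADs) are
placed in a repressive nuclear compartment. In a 4C-seq experiment with
baits inside the rDNA repeat, every locus contacting the rDNA is captured
and sequenced, so per-window read counts measure rDNA-genome interaction
frequency. `nad4c` implements the count-level analysis of such an
experiment across a malignant-progression series (wild type, premalignant,
malignant B cells) plus a UBTF-knockdown series (control vs shUbtf), from
raw per-bait window counts to reciprocal "class switch" interactions and
their expression consequences. Read alignment and peak calling are upstream
of the package; it consumes count tables and BED interval sets.

## The processing model

The unit of analysis is the non-overlapping 5-kb genomic window; a window
label renders its 1-based inclusive coordinates (`chr8:111250001-111255000`).
Counts enter as a `window x bait x library` tensor with 11 baits (4 in the
18S-like and 7 in the 28S-like transcribed regions) and 2 replicates per
condition, and pass through a fixed state machine:

1. **Replicate observation** — within each condition a window counts as
   observed only if its bait-summed count is nonzero in *every* replicate;
   windows observed in no condition are dropped, and per-condition flags
   propagate so an untested condition yields `NA` p-values. The published
   workflow states the two-replicate requirement without a count threshold;
   we read "observed" as nonzero in all replicates.
2. **Single-bait outlier filter** — a window is dropped when its largest
   per-bait count exceeds `ratio` times the sum of all other baits. The
   threshold is not stated in the source workflow; the default 10 is
   configurable and logged.
3. **Bait-support filter and merge** — windows with nonzero counts in fewer
   than 4 of the 11 baits are dropped; survivors are merged by the *mean
   count over all 11 baits*. Averaging over all baits (zeros included),
   rather than contributing baits only, decouples support from magnitude and
   keeps merged values comparable across windows; the original description
   ("the average read number") does not disambiguate, and we document our
   choice rather than assert equivalence.
4. **Normalization** — median-of-ratios size factors: for library $j$,
   $s_j = \mathrm{median}_w \, k_{wj} / (\prod_j k_{wj})^{1/m}$ over windows
   with nonzero counts in all $m$ libraries. The median is taken on the
   ratio scale, exactly as the formula reads; for an even window count this
   differs from a log-scale median only in the interpolation rule.
   Normalization divides by $s_j$ and refuses to run twice.

Fragment-level entry is also supported: in-silico digestion cuts before
every occurrence of the DpnII motif `GATC`, fragments map to the window
containing their midpoint (computed on 0-based half-open coordinates, so a
fragment spanning a boundary is never double-counted), and bait-adjacent
products (the bait fragment and its two flanking fragments, the self-ligated
and undigested material suppressed by PCR blockers experimentally) are
zeroed before aggregation.

## The differential test

Differential interaction between two conditions is assessed per window with
a conditional negative-binomial exact test in the Robinson-Smyth style:
replicate-summed normalized counts $k_A, k_B$ (rounded to integers, logged)
are compared against the conditional distribution of the split of
$k_A + k_B$ under a shared NB mean, using per-window dispersion $\alpha_w$.
The two-sided p-value sums all splits no more probable than the observed
one. When the supplied dispersion is below $10^{-12}$ the Poisson boundary
of the NB family is used directly; in that limit the test reduces exactly
to a conditional binomial test, which is how it is validated.

Dispersions are estimated by method of moments
($\hat\alpha_w = \max(0, (V_w - \mu_w)/\mu_w^2)$ with pooled
within-condition variance), a least-squares trend $\alpha(\mu) = a_0 +
a_1/\mu$ over windows with positive raw estimates, and the conservative
working value $\max(\text{raw}, \text{trend}, 10^{-8})$. With only two
replicates per condition the raw estimates are noisy; taking the max biases
dispersion upward, which keeps the realized false-discovery proportion low
at a small cost in power (the recovery tests quantify both).

Fold changes are $\log_2$ ratios of condition means of normalized counts; a
0.5 pseudocount enters only when a mean is zero, and never touches
p-values. Multiple testing uses Benjamini-Hochberg adjustment (the FDR
procedure is unnamed in the source; BH is the delegated package's default),
with `NA` p-values excluded. A window is **constitutive** when FDR > 0.1 in
every pairwise stage comparison and **differential** otherwise; because the
inclusion cutoff is printed as "FDR <= 0.1", a window at exactly 0.1 counts
as differential, and the same inclusive boundary is used in the class-switch
step for consistency.

**Class switching.** The reciprocal workflow intersects the
premalignant-to-malignant comparison with the control-vs-knockdown
comparison: a window is kept only when significant in both with opposite
fold-change signs, yielding the two categories *increased in malignancy /
decreased without UBTF* and its mirror image. Everything else is removed.

## Integration

Windows are annotated with the nearest transcription start site measured
from the window midpoint (ties broken by lexicographically smallest gene
id; the anchor point is unstated in the source and the midpoint is the
natural choice for 5-kb windows). The signed distance is negative when the
TSS lies upstream of the midpoint in the gene's reading direction. Derived
statistics: the fraction of windows within 5-20 kb of their gene's TSS;
RPKM ($10^9 \cdot \text{count}/(\text{length} \cdot \text{total})$);
differential expression re-using the same NB machinery with thresholds
FDR <= 0.1 and $|\log_2 FC| \ge 0.5$; two-sample Kolmogorov-Smirnov
comparisons with asymptotic p-values at effective size $n_A n_B/(n_A+n_B)$;
interval overlaps at a configurable minimum intersection (default 1 bp,
unstated in the source); and gene-set intersections reported relative to
both inputs.

The SPRITE concordance statistic bins the span of $\pm$100 kb around each
SPRITE-region centre at 5 kb, scores each bin for overlap with any 4C
window, and compares the observed central-bin occupancy against `n_boot`
placements of equally many, equally sized regions dropped uniformly on the
genome (chromosome chosen proportional to length, placements clipped so the
full span fits). The empirical p-value $(1 + \#\{boot \ge obs\})/(n_{boot}
+ 1)$ is exact-valid by construction: under the null
$P(p \le x) \le x + 1/(n_{boot}+1)$.

## The synthetic-data generator

The generator exists so every stage runs at desk scale against known truth.
Its defaults are the study conditions the pipeline is validated under: 11
baits, two replicates per condition, the five conditions of the two series,
NB counts with per-bait window means log-normal around 100 and dispersion
0.05, planted $|\log_2 FC| = 2$ on 25% of interacting windows (half of the
premalignant-to-malignant subset reciprocal in the knockdown series),
library size factors log-uniform on $[0.5, 2]$ so normalization recovery is
non-trivial, 10% near-zero background windows to exercise the replicate
filter, 25 windows confined to three baits (bait-support filter) and one
single-bait spike window (outlier filter). Real library depths and 4C
dispersions are not published for this design, so these are chosen values,
not inferred ones. Every component draws from its own RNG stream derived
from the master seed and a component tag, so outputs are independently
reproducible; identical seeds give byte-identical files.

The toy genome plants the `GATC` motif at mean spacing ~500 bp and fills
between sites with bases drawn from {A, C, T}; lacking G, the filler can
create no stray motif, making the fragment map exact by construction. This
and the uniform window occupancy are deliberate departures from real
genomes: passing tests demonstrate correctness of the arithmetic and
calibration of the statistics under the stated model, not robustness to
mappability artefacts, copy-number variation, GC bias, or the heavy spatial
clustering of real NADs. One consequence surfaces in the expression
integration: on a densely tiled toy genome every gene is nearest to *some*
surviving window, so the interacting/non-interacting expression contrast is
drawn on the differential window set, where association is informative.

Expression coupling is planted inversely: a coupled gene receives an
expression fold change of opposite sign to its window's interaction change
(effect 2 by default), emulating the repressive effect of nucleolar
association; peak sets are placed to realize a target overlap fraction with
a designated window set up to rounding.

## Numerical choices and degenerate inputs

* Exact-test splits enumerate $0..s$; identical profiles give $p = 1$, an
  all-zero window gives $p = 1$, $\log_2 FC = 0$.
* A chromosome without a restriction site digests to one whole-chromosome
  fragment (logged, not an error); terminal short windows are retained.
* Dispersion trend fitting falls back to an intercept-only fit when all
  window means coincide, and to 0 when fewer than three windows inform it.
* ChIP/MeDIP percentages floor at 0 after serum subtraction, HpaII
  resistance caps at 100; both warn. The two 3C normalizers combine as a
  geometric mean by default (the combination rule is unstated in the
  source; arithmetic and sequential modes are provided).
* qPCR amplification efficiency is fixed at 2.0 per cycle and configurable
  per amplicon.

## Problem sizes

The default pipeline (`run_pipeline()`) uses 4 chromosomes x 2 Mb (1600
windows), 400 genes, 200 bootstrap placements; it completes in well under a
minute and the full validation suite in a few minutes. These sizes were
chosen so that planted-recovery statistics are stable across seeds while
the whole analysis remains interactive.

## Known limitations

An external spike-in control (e.g. an E. coli fragment) is not modelled; counts enter as genomic windows only, and normalization never uses a spike-in. Bait demultiplexing, exact-match bait filtering (which excludes 18S/28S
pseudogene products upstream of the counts), mapq filtering, peak calling
and GO enrichment are out of scope. The exact-test variant and
dispersion-sharing mode of the original delegated package are not fully
specified in the source; ours are documented above and validated against
closed-form oracles rather than asserted identical. The size-factor
estimator is equivariant in ratio only: rescaling library $j$ by $c$ also
moves every window's geometric mean by $c^{1/m}$, so all size factors pick
up that common factor and normalized counts its inverse — a property shared
by the reference implementation.
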