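---
title: "Comparing maternal and zygotic gene regulatory architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing maternal and zygotic gene regulatory architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

During early animal development, control of the embryo passes from mRNAs
deposited by the mother to transcripts made by the zygote itself (the
maternal-to-zygotic transition, MZT). mztarch asks whether genes expressed on
the two sides of this transition carry systematically different *amounts of
regulatory sequence*, using region lengths as a proxy for regulatory
complexity when base-level annotation of regulatory elements is unavailable:

* **transcriptional** regulation is proxied by the 5' intergenic region
  (IGR) — the span available for promoters and enhancers upstream of the
  coding sequence — with the first intron and the 3' IGR as robustness
  variants;
* **post-transcriptional** regulation is proxied by the 3' UTR (plus the 5'
  UTR as a variant).

Because absolute lengths are incomparable across genomes spanning a 30-fold
size range, all cross-species statements are made through within-genome
comparisons (class vs. genome-wide distribution), within-genome percentile
ranks (for orthologs), and maternal-to-genome ratios.

## Length definitions

All internal coordinates are 0-based half-open; GFF3/GTF 1-based inclusive
coordinates are converted at the parser boundary. This removes off-by-one
ambiguity from every distance computation.

* A gene's **coding intervals** are the union, over its transcripts, of exon
  segments overlapped by the transcript's CDS span. Genes with no CDS are
  excluded from all analyses (and recorded as skipped).
* **5' IGR**: the number of bases strictly between the gene's 5'-most coding
  base and the nearest coding base of a *different* gene in the gene's 5'
  direction, on either strand. Overlapping or abutting coding sequence gives
  0. The **3' IGR** mirrors this from the 3'-most coding base. A gene with no
  coding neighbour in the required direction is *censored* (`NA` plus a
  reason), not assigned a distance to the chromosome end — assembly edges
  would otherwise contaminate the distributions.
* **First intron**: per transcript, the intron closest 3' of the translation
  start; the gene value is the maximum across isoforms
  (`intron1_max`), with `intron1_noncoding` the largest run inside that
  intron not covered by any gene's coding interval (nested genes shorten
  it). Intronless genes get 0.
* **UTRs**: per-gene values are maxima of per-transcript totals. 3' UTRs
  under 5 bp and 5' UTRs under 3 bp are treated as annotation artifacts and
  reported absent; these thresholds are exposed (`utr3_min`, `utr5_min`) and
  lowering them can only increase the number of genes with a present UTR.
  3' UTRs spanning more than one exon (a likely nonsense-mediated-decay
  signature) are excluded from the maximum unless `allow_multiexon_utr3` is
  set; when every isoform is multi-exon the gene's 3' UTR is absent.
* **Operons**: in trans-spliced genomes only the 5'-most operon member has
  an interpretable 5' IGR; downstream members are flagged out of every 5'
  IGR analysis. Trans-splicing also makes the summed-UTR variant
  meaningless, so "worm mode" omits `utr5_plus_utr3`.
* The 3' IGR is measured from the 3'-most coding base; a UTR-inclusive
  alternative would shorten it by the 3' UTR's genomic extent.

## Gene classes

**Origin of synthesis.** Three classifiers cover the kinds of data available
across species:

* `classify_origin_decoupled()` consumes separately quantified maternal and
  zygotic abundance components plus a time course. A significant decrease is
  fold change ≥ 3 (the `p ≤ 0.001` criterion is applied only when a
  per-gene p column is supplied — without replicate-level data no p-value
  can be computed, so the fold-change rule alone decides). Zero zygotic
  component → strict-maternal; a minority (< 33%) zygotic fraction →
  mostly-maternal; a stable profile → maternal-zygotic, which is left as
  "whatever the stability test leaves" — it is known to absorb slowly
  decaying maternal transcripts, and no sharper rule is invented.
* `classify_origin_timecourse()` uses profiles only: present before the
  transition and reduced ≥ 3-fold at *every* later point → strict-maternal;
  absent before, present after → strict-zygotic.
* `classify_origin_rank()` selects the top fraction of expressed genes by
  abundance (0.50 for a laid-egg stage, 0.25 for gastrulation-stage zygotic
  calls); ties at the cutoff are all kept, and the selected sets are nested
  as the fraction grows.

Precomputed label tables are accepted verbatim (`read_origin_labels()`),
since published class tables are the common case. Presence is a simple
abundance threshold (`presence_call`); platform-specific detection calls are
out of scope.

**Conservation.** From a presence/absence profile over a panel with ≥ 1
unicellular, ≥ 1 plant and ≥ 2 animal taxa: present in any unicellular
taxon → *core*; else present in ≥ 2 animals and no plant → *metazoan*; else
*other*. The classes are exhaustive and mutually exclusive.

## The percentile KS sweep

Class-vs-reference length comparisons use a one-sided two-sample
Kolmogorov-Smirnov test whose statistic is
`D = sup_x [F_ref(x) − F_class(x)]`; a significant result means the class
has *fewer short lengths* than the reference. The asymptotic p-value is
`exp(−2 D² n_a n_b / (n_a + n_b))`. Region lengths are integers with many
ties, so the empirical-CDF supremum is taken over observed points and a
permutation p-value is available as the exact alternative; it enumerates
all splits when `choose(n_a + n_b, n_a)` is small (≤ 50,000) and otherwise
uses Monte Carlo with the add-one correction. Under a continuous null the
asymptotic rejection rate at α = 0.05 sits near 0.05 (measured ≤ 0.07 over
2,000 replicates at n = 500 in the acceptance checks).

To localise *where* distributions differ, `percentile_sweep()` truncates
both samples at increasing percentile cutoffs (15th, then +5% up to 100%,
which reproduces the plain test exactly) and reports, besides the full
grid, the minimum p-value with its percentile and the top-most percentile
with p < α. Grid p-values are reported raw, as is conventional for this
procedure; a Bonferroni column is emitted for information only.

**Truncation anchoring.** The cutoff can be the percentile of the reference
sample (`subset_anchor = "reference"`, the default: subsets are comparable
across gene classes), of the pooled sample (`"pooled"`), or of each sample
separately (`"each"`). The choice matters for where the minimum lands: for
a sample missing everything below the reference's 20th percentile,
reference anchoring gives `D(q) ≈ 20/q` against an effective sample size
growing with `q`, and the product is maximised at the *35th* percentile —
deterministically, independent of n. Pooled and per-sample anchoring
localise the minimum at or below the 30th percentile. The recovery
benchmarks therefore use pooled anchoring; analyses of real contrasts
should pick one anchor a priori and report it.

**Percentile convention:** linear interpolation between order statistics
(R's default type 7) everywhere, fixed for reproducibility.

## Ortholog rank fold changes

Within each genome, genes are rank-normalised by 5' IGR length:
`rank = (average rank)/n`, so ranks lie in (0, 1], tied lengths share a
rank, censored genes are excluded, and any strictly monotone transform of
the lengths is irrelevant. For each 1:1 ortholog pair the statistic is
`log2(rank_a / rank_b)`; zero means the gene ranks identically in both
genomes. Ranks are ascending (short = low); the antisymmetry of fold
changes under species swap and all planted-effect checks are unaffected by
that convention, but the sign of reported fold changes depends on it. The
1:1:1 restriction is enforced by intersecting two pairwise tables on the
anchor species. The maternal subset is defined as pairs maternal in *both*
species, and its fold changes are compared against all pairs with the same
one-sided KS test (direction: maternal shifted towards larger fold
changes).

## Ratio summaries

Maternal regulatory specificity per species is the ratio of a location
measure of maternal metazoan 5' IGR lengths to the same measure over all
metazoan genes (the metazoan stratum is the one most reflective of
regulatory complexity; ratios are invariant to genome-wide rescaling).
Three measures guard against outliers: median, 75th percentile, and a 5%
trimmed mean. "5% trimmed" is ambiguous in common usage; the default trims
5% from *each* tail (base R's convention for `mean(trim =)`), and
`trim_per_tail = 0.025` gives the 5%-total alternative. At zero trim the
trimmed mean is the arithmetic mean and with growing trim it approaches
the median.

## The synthetic-data generator

`simulate_genome()` lays genes sequentially along chromosomes with
log-normal intergenic gaps and builds real exon/intron/UTR coordinates
(emitted as GFF3), so the parser and the interval engine are exercised end
to end rather than feeding bare length vectors to the statistics. Length
distributions are log-normal — positive, heavy right tails, the standard
first approximation for genomic length data. Defaults: 500 genes on 2
chromosomes, gaps LN(log 1000, 0.8), 1–4 exons, per-class UTR scales with
core genes shorter than metazoan ones, and fly-like origin-class
proportions (11% strict-maternal, 30% maternal-zygotic, 4% strict-zygotic,
45% unclassified).

Planted, recoverable effects are expressed per class: `igr5_scale`
multiplies the gap facing a gene's 5' end (both flanks if both genes face
it), `utr3_left_truncation_percentile` re-draws a 3' UTR conditional on
exceeding that percentile of its base distribution (under-representation of
short 3' UTRs), and `conservation_igr5_scale` plants the core/metazoan
contrast. With all effects at their null values, class and genome
distributions are indistinguishable and downstream rejection rates sit at
α. Everything is deterministic given the seed, byte for byte.

`simulate_expression()` produces decoupled components and a 4-point time
course (1 pre-MZT point): maternal genes decay 8-fold after the transition
(comfortably past the 3-fold calling threshold under the default 0.2-log2
multiplicative noise), strict-zygotic genes are absent before and high
after, maternal-zygotic genes are flat. `simulate_phylo_profiles()` emits a
26-taxon panel (4 unicellular, 2 plant, 20 animal) consistent with the true
conservation classes. `simulate_orthologs()` builds partner genomes whose
5' IGR ranks equal the anchor's perturbed by Gaussian noise; at zero noise
the partner lengths are an exact monotone transform of the anchor's, so
every fold change is exactly zero (average-rank ties included).
`simulate_rnai()` assigns phenotype calls with a configurable association
to 5' IGR rank.

**What the generator does not emulate:** real expression platforms'
detection calls and replicate structure, alternative-splicing graphs beyond
a second shorter-3'-UTR isoform, sequence content of any kind, assembly
gaps, and annotation error modes other than short/missing UTRs. Passing
recovery tests therefore demonstrate that the pipeline detects the stated
effect classes at the stated sizes — not that real annotations are free of
biases the generator does not model.

## The packaged six-species panel

`synthetic_panel()` instantiates the comparative design at 1,000 genes per
species: three high-nutrition species (fly/worm/fish-like, maternal
`igr5_scale` 0.5, zygotic 2.0), one medium (chick-like, 0.9) and two low
(mouse/human-like, 1.6; mouse zygotic 0.7), so the maternal-to-genome ratio
falls as maternal nutritional contribution rises — the egg-laying vs.
live-bearing dichotomy. The fish-like species adds the maternal 3' UTR
truncation; the worm-like species has operons (15% of genes),
trans-splicing and an RNAi table with an `igr5`-linked phenotype (3' UTR
untouched); the human-like species anchors the ortholog analysis, with a
planted maternal rank shift in the chick-like pair only. Labels are
produced by the package's own classifiers on simulated expression; the
chick/human-like species use rank-based maternal calls and run only the
all-maternal and metazoan-vs-core comparisons, since no zygotic class
exists for them.

Problem sizes throughout (1,000-gene panels, 500-sample KS benchmarks with
200–2,000 replicates, 50 oracle genomes of 40–120 genes) were chosen so
each planted effect is recovered with high power while a complete run of
the test suite and the reproduction script stays in the minutes range on a
single core.

## Numerical and degenerate-input choices

* Empty samples, all-empty truncations, empty maternal pair subsets, and
  genomes with < 2 usable ranks are errors, not silent NAs.
* `p` values are clipped into (0, 1]; `d = 0` gives `p = 1` exactly.
* Sweep grid points whose truncation empties either sample are skipped;
  `q_top_significant` is `NA` when no grid point is significant.
* Ties: average ranks for percentile ranks; all-inclusive ties at the rank
  classifier cutoff; ECDF supremum over observed points for the KS
  statistic.
* When a comparison's class or reference is empty after filtering, the
  pipeline warns and skips it; a failing species is recorded while the
  remaining species proceed.

## Limitations

* The asymptotic one-sided p-value ignores discreteness; for small samples
  or extreme tie loads use the permutation option.
* Censoring at chromosome ends deletes genes from IGR distributions; on
  highly fragmented assemblies this loses many genes (real pipelines should
  use chromosome-level assemblies).
* The maternal-zygotic class is heterogeneous by construction; results for
  it should be read as "stable maternal presence", not as a mechanistic
  claim.
* Rank-based maternal calls (laid-egg stages) misclassify genuinely
  expressed genes just under the rank threshold; the threshold's effect
  should be checked by varying `top_fraction` (the selected sets are
  nested, which makes such scans cheap).
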