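---
title: "Methods: gene body methylation dynamics from bisulfite count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene body methylation dynamics from bisulfite count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemethyl)
```

This vignette documents the statistical model behind `beemethyl`, the
parameters that matter, the synthetic-data generator used to validate
it, and the numerical and design choices made where several readings
were defensible. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

The unit of observation is a strand-resolved cytosine with a
dinucleotide context (CG, CA, CT or CC — the reference base downstream
of the C on its own strand) and two read counts: `n_meth` (bisulfite
protected, read as C) and `n_unmeth` (converted, read as T). The
methylation level of any feature — a site, an exon, a gene, a
metaprofile bin — is always the *weighted* level
`sum(n_meth) / sum(n_meth + n_unmeth)` over the contributing
cytosines. Count-weighting matters: a mean of per-site fractions gives
shallow sites the same vote as deep ones and is biased at low
coverage. A feature with zero informative cytosines has a *missing*
level, never zero.

Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
closed) is converted on ingest and BED12 is taken as-is, so a GFF3 and
BED12 description of the same exon yield identical internal intervals.
CG sites on opposite strands of one dyad are kept as separate records;
`pool_cg_strands()` pools them on request (pooling is recoverable,
splitting is not). Duplicate site rows are an error, not silently
summed, because duplicates almost always indicate an upstream merge
bug.

## Differential methylation

For a pair of samples, each biological replicate contributes a
two-sided Fisher exact test on its 2x2 count table; a feature is
differential only when `p < alpha` in **both** replicates. The
replicate-concordance rule (rather than pooled testing or multiple
testing correction) is the primary error control: two independent
replicates each tested at `alpha` give a concordant false-positive
rate far below `alpha` under the null. A Benjamini–Hochberg switch
exists but is off by default.

The two-sided p-value sums all tables with the observed margins whose
point probability does not exceed the observed one (the standard
definition, with a `1 + 1e-7` relative tie tolerance). The test is
implemented in-package, vectorised over features; the test suite
verifies it against `stats::fisher.test` on random tables and against
an exact integer enumeration oracle on *every* 2x2 table with both row
margins up to 30.

Significance levels differ by resolution, reflecting the different
scales of the three analyses: sites use `alpha = 0.001`, exons and
genes use `alpha = 0.05` with a minimum level of 0.1. Eligibility for
change statistics follows the kernel-density rules: at least 10
(sites) or 20 (exons/genes) informative sequenced cytosines in each
sample, and a level of at least 0.1 in at least one sample.
"Informative cytosines" is implemented as summed read coverage, not
distinct covered positions — the natural reading of *sequenced*
cytosines; the alternative (distinct positions) would make the
site-level threshold of 10 unreachable at typical depth.

## Percent-methylation-change and the partial/full split

The change statistic divides the level difference by the *larger* of
the two levels, as a signed percent, so it is antisymmetric, bounded
in [-100, 100], and equals ±100 exactly when one sample has lost all
methylation. Numerically, the ratio is formed before scaling by 100 so
the full-loss boundary is exact in floating point. `pmc(0, 0)` is
defined as 0 — the formula is 0/0 there, and "no change" is the only
consistent reading. Differential features split at `|pmc| >= 90` into
*full* versus *partial* changes.

Exon methylation states (for the single/double/triple-CG exon
analyses) bin eligible exons — at least 34% methylated with at least 4
informative reads in one of the samples — into unmethylated /
intermediate / fully methylated. The printed bin edges in the source
figure legend are internally inconsistent ("0 ≥ and < 0.1", "0.9 > and
≤ 1"); we adopt the closest consistent partition `[0, 0.1)`,
`[0.1, 0.9]`, `(0.9, 1]`. At realistic coverage the probability mass
exactly on a boundary is negligible, so the choice does not affect any
reported proportion meaningfully.

## Metaprofiles

Gene-aligned profiles anchor bins at the 5' or 3' end of each gene
(strand-aware), extend a configurable span — default 3000 bp, a
conventional span for ~3 kb honey bee genes; the source analyses do
not state theirs — and average methylation count-weighted within each
bin. Genes shorter than the span contribute only over their own
length; partial terminal bins keep their true width; intron-restricted
profiles exclude exon-overlapping sites entirely. Two invariants pin
the implementation down: the coverage-weighted mean of bin values
equals the overall weighted methylation of the profiled sites
(conservation), and mirroring the genome while flipping every strand
leaves profiles bit-identical (strand symmetry).

Splice-event profiles count events overlapping each bin, normalised by
the number of genes spanning the bin; site-class profiles do the same
for highly (>= 0.8) and lowly (0.05–0.8, exclusive) methylated sites.

## Expression and splicing integration

Gene responsiveness is the row sum of differential-expression
indicators over all pairwise stage comparisons (DE: `q < 0.05` and
fold change > 2, consumed as calls). Set overlaps report the
representation factor (observed / expected under independence) with
exact hypergeometric tails, under both the all-genes and the
methylated-genes-only universe — the contrast between those two
universes is the analysis's central control.

Differential splicing compares replicate PSI values per event with a
two-sample t-test, BH correction across events, and the rule
`|dPSI| >= 0.1` and `q < 0.05`. The test defaults to the
pooled-variance Student t rather than Welch: with two replicates per
side, Welch's degrees of freedom collapse toward 1 and the test has
essentially no power even for enormous effects, which would make the
procedure vacuous at the study's own design size. Welch and an exact
permutation test remain available (`method=`). Missing PSI values
(emitted upstream for zero-expression events) drop the event from
testing; they are never imputed as 0.

Sample-structure summaries use Pearson correlation, PCA on centred
columns, and average-linkage hierarchical clustering of the Euclidean
distance matrix, over complete-case features only (the dropped count
is reported).

## Non-CG analysis

Context annotation reads the downstream reference base on the
cytosine's own strand; CH (= CA, CT, CC) is assessed per strand with
no symmetric pooling, since CH is inherently asymmetric. The CH error
rate — apparent CH methylation explained by genetic CG polymorphism —
is the percentage of reads overlapping reference CH sites whose base
pattern supports a CG dinucleotide; the per-read flag is taken as
input (a converter from alignments is upstream of this package's
scope). Motif matrices anchor the methylated C at offset 0 (A at +1
for CA sites), reverse-complement minus-strand windows, and report
per-position information content `2 - H` bits; the ±5 bp window is a
display convention.

## The synthetic-data generator

The generator emulates the germline/soma methylome structure the
analyses were built for, and its defaults are the study conditions the
recovery tests run under:

* **Geometry**: genes with `1 + Poisson(4)` exons (~250 bp) separated
  by ~400 bp introns; random sequence whose base composition is chosen
  so the expected CG dinucleotide density equals `cg_density` (default
  0.02/bp, AT-rich as in the honey bee genome). The cytosine context
  map is derived from that sequence, so context annotation and
  simulation cannot disagree.
* **Site states**: 40% of genes form the methylated class; within
  them, 90% of exonic (20% of intronic) CG dyads are methylated —
  gene body methylation is exon-enriched. Methylated dyads draw embryo
  levels from Beta(38, 2) (mean 0.95) and sperm levels from
  Beta(18, 2), whose heavy mass near 1 reproduces a ~0.9 sperm median
  at site level; everything else sits below 0.01. Both cytosines of a
  dyad share one true level.
* **Somatic drop**: each exon draws a per-tissue multiplicative drop
  factor from a Beta with mean `soma_drop` (larva 0.25, pupa/head
  0.10) and concentration 20, correlated across somatic tissues at
  0.8 via a Gaussian copula — methylation changes travel together
  across post-embryonic samples.
* **Noise**: counts are beta-binomial at Poisson(20) coverage with
  intra-class correlation 0.08, plus a per-exon, per-experiment logit
  shift (sd 0.35) shared across all tissues of an experiment. The
  split matters: the experiment-level shift lowers cross-experiment
  replicate correlation of methylated-exon levels into the observed
  0.65–0.8 range and creates experiment-specific methylation patterns,
  while leaving the within-experiment Fisher null intact (both tissues
  of one experiment share the shift). Germline replicate correlations
  stay higher because levels saturate near 1.
* **Reads**: per-read CG states over 1–3-CG exons use an exchangeable
  within-read correlation (0.8 germline, 0.3 soma) — with probability
  rho the read's sites share one latent uniform, otherwise they are
  independent. No data constrain the real magnitude of within-read
  correlation; these values are assumptions, chosen so germline reads
  are coherent and somatic reads mosaic.
* **Expression / splicing**: DE truth is assigned per gene pair with
  probability `de_fraction` (0.3), multiplied by 0.3 for
  methylated-class genes — encoding their low responsiveness; DSE
  truth gives |dPSI| in [0.1, 0.3] to 20% of events. FPKM values are
  loosely consistent with the calls; downstream analyses consume the
  calls, not the FPKM, matching the pipeline's scope.
* **Head CH**: CA sites inside CG-methylated genes methylate at 0.004
  (CT at 0.002, CC at 0) in head samples only, zero elsewhere. Genic
  CH sites are thinned to 25% for tractability; thinning does not
  change any per-site rate.

Every emitted feature appears exactly once in the truth ledger
(gene classes, per-exon drop factors, per-dyad tissue probabilities),
and identical configuration plus seed gives byte-identical output.

What the generator does *not* emulate: repeat-element methylation,
bisulfite conversion error as a separate channel (it is folded into
the beta-binomial noise), chromosome-scale methylation domains,
read-length effects, or the absolute genome-wide methylation averages
of real honey bee data (the methylated-class share is calibrated to
the exon-level structure, not to whole-genome percentages). Passing
recovery tests therefore demonstrates that the estimators recover the
generative structure they target — drops, concordance, orderings,
overlaps — not that they would be unbiased under every artefact of
real libraries.

## Problem sizes and tolerances

The test suite validates at sizes chosen for statistical resolution:
the drop-recovery and null-rate checks use 1000 genes (~2000
methylated exons) at 20x coverage with 2 replicates, asserting the
median exon change within ±3 points of the generative 25%, a full-DME
fraction below 5%, and a concordant null DMC rate at or below
`alpha = 0.001`; the Fisher implementation is checked against exact
rational enumeration over all ~246,000 tables with margins up to 30;
overlap tails are checked exhaustively for universes up to 50; profile
conservation holds to 1e-12 and strand reflection exactly. The
decoupled-overlap null uses 50 seeds at 80 genes and asserts the mean
representation factor within two standard deviations of 1.

## Known limitations

* The Fisher test is anticonservative under overdispersion beyond the
  binomial; replicate concordance absorbs this in practice, but
  single-replicate designs should not rely on the nominal `alpha`.
* With two replicates the PSI t-test (any flavour) has minimal degrees
  of freedom; the BH-corrected calls are best treated as a screen.
* The percent-methylation-change statistic is unstable when both
  levels are near zero; the 0.1-level eligibility filter exists
  precisely to keep such features out of density summaries.
* `aggregate_methylation()` assigns a site to every overlapping gene;
  overlapping gene models (rare in the simulated annotation) would
  count such sites once per gene.
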