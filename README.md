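# beemethyl

Analysis of gene body CG methylation dynamics across honey bee
development from whole-genome bisulfite sequencing (WGBS) count data.

In honey bees, DNA methylation is concentrated in the exons of a
subset of genes ("gene body methylation"). Its global level fluctuates
across development — high in sperm and embryo, dropping by roughly a
quarter in larvae, partially recovering in pupae and adult heads — yet
individual sites rarely lose methylation completely, and methylation
changes are largely uncoupled from developmentally regulated
transcription and splicing. Adult heads additionally carry a faint
non-CG (CA > CT) methylation signal restricted to CG-methylated genes.
`beemethyl` implements the statistical machinery to quantify all of
this from per-cytosine count tables, and ships a seeded synthetic
methylome generator with a ground-truth ledger, so that every analysis
step can be validated by parameter recovery.

The package is aimed at researchers analysing invertebrate WGBS data
at site, exon and gene resolution with small numbers of biological
replicates.

## The statistics at its core

* **Weighted methylation level** of a feature:
  `m = sum(n_meth) / sum(n_meth + n_unmeth)` over contributing
  cytosines (count-weighted, never a mean of per-site fractions).
* **Differential methylation**: a two-sided Fisher exact test on the
  2x2 table (methylated, unmethylated) x (sample A, sample B), run
  separately per biological replicate; a feature is differential only
  when `p < alpha` in *every* replicate (replicate concordance), with
  eligibility filters on informative coverage and minimum level.
* **Percent-methylation-change (pmc)**: the signed difference between
  two levels divided by the larger one,

  ```
  pmc(a, b) =  100 (a - b) / a   if a > b
              -100 (b - a) / b   if b > a
                0                otherwise
  ```

  Differential features with `|pmc| >= 90` are *full* changes; the
  rest are *partial*.
* **Gene responsiveness**: the number of pairwise stage comparisons in
  which a gene is differentially expressed (0..21 for seven stages).
* **Representation factor**: observed overlap of two gene sets divided
  by the overlap expected under independence in a stated universe,
  with exact hypergeometric tail probabilities.
* **Read-level epialleles**: classification of single bisulfite reads
  over 1-3-CG exons as fully / partially / unmethylated.
* **Non-CG analysis**: sequence-context annotation (CG/CA/CT/CC),
  CH/CW summaries, error-rate estimation from reads supporting CG at
  reference CH sites, and position frequency matrices around
  methylated CA sites.

## Worked example

Simulate a germline/soma study (sperm, embryo, larva; two replicate
experiments), then call differential exon methylation between embryo
and larva:

```r
library(beemethyl)

cfg <- sim_config(seed = 7, n_genes = 150,
                  tissues = c("sperm", "embryo", "larva"))
sim <- simulate_dataset(cfg, reads_per_exon = 30)
cg  <- dplyr::filter(sim$methylome$sites, context == "CG")

exon_counts <- aggregate_counts(cg, sim$annotation$genes,
                                feature = "exon")
dme <- call_differential_methylation(exon_counts, c("embryo", "larva"),
                                     alpha = 0.05, min_informative = 20)
glance(dme)
#> # A tibble: 1 × 7
#>   n_features n_eligible  n_dm n_partial n_full median_abs_pmc_dm alpha
#>        <int>      <int> <int>     <int>  <int>             <dbl> <dbl>
#> 1        766        257   214       214      0              28.2  0.05
```

Of 766 exons with CG coverage, 257 pass the eligibility filters and
214 are differentially methylated in both replicates — every one of
them a *partial* change (`n_full = 0`): larval hypomethylation shaves
levels down rather than erasing them. The median change among eligible
exons recovers the simulated 25% drop:

```r
changes <- change_density_inputs(exon_counts, c("embryo", "larva"),
                                 resolution = "exon")
median(changes$pmc)
#> [1] 25.4
```

Single-read epialleles show the germline fidelity ordering — sperm and
embryo reads are fully methylated more often than larval reads
(here, 2-CG exons):

```r
classify_reads(sim$reads) |>
  dplyr::filter(read_class == "fully", cg_count == 2)
#> # A tibble: 3 × 5
#>   tissue cg_count read_class     n proportion
#> 1 embryo        2 fully        444      0.235
#> 2 larva         2 fully        277      0.147
#> 3 sperm         2 fully        398      0.211
```

`run_pipeline(cfg, out_dir)` chains all stages (aggregation,
differential calling, metaprofiles, expression/splicing integration,
non-CG analysis) into a run directory with TSV outputs, a
`summary.json` and a regenerable plain-text report
(`make_report(out_dir)`).

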