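# secondhit

Finding the missing second allele in inherited retinal dystrophy (IRD)
patients who carry one heterozygous pathogenic variant in a recessive gene.

Exon-focused genetic testing leaves many autosomal-recessive IRD patients
*monoallelic*: one pathogenic allele in *USH2A*, *ABCA4* or *CEP290* and no
second hit. When the entire genomic sequence of those genes is captured,
the second allele can be searched for among copy-number variants,
deep-intronic splice-activating variants and synonymous variants —
`secondhit` implements that analysis as a tested R pipeline:

* **Read-depth CNV calling.** Per-interval counts are library-size
  normalized (rescaled to the batch mean total) and divided by the
  leave-one-out median of the other samples in the run:
  ratio ≈ 1 diploid, < 0.6 deletion, > 1.40 duplication (strict
  thresholds), with zygosity banded on the run mean (≤ 0.10 homozygous,
  [0.35, 0.60) heterozygous loss, (1.40, 1.65] three-copy gain).
* **Breakpoint refinement.** Over whole-gene per-base coverage, the
  smoothed (running-median, 50 bp) sample/reference ratio is scanned for a
  threshold crossing sustained ≥ 50 bp, giving base-resolution breakpoints.
* **Allele-balance corroboration.** Heterozygous SNPs inside a three-copy
  span shift from ~50:50 to ~67:33 (major-haplotype reads ~
  Binomial(d, 2/3)); `allele_balance_shift()` turns that into a verdict.
* **Variant screening.** Discard DP < 20 or FS > 60.0; retain only
  MAF < 0.015 in every population database where the variant is observed.
* **Splice rules.** Decision thresholds over MaxEntScan (score ≥ 2,
  variation > 15%), HSF (≥ 70, > 10%) and NNSPLICE (> 0.4, > 10%) scores,
  combined by a configurable majority policy.
* **Prioritization.** Stepwise second-hit search (known gene first, other
  loci second) with explicit causality criteria, segregation handling,
  compound-heterozygote completion and a deep-intronic candidate cap.
* **Cohort reporting.** Diagnostic yield, mutation-type spectrum,
  recurrent alleles, per-phenotype genes, second-hit rates by prior gene.

A transcribed 29-family cohort fixture (`load_cohort_fixture()`) and
synthetic-data generators make the whole workflow runnable and testable
offline; see `vignettes/second-hit-workflow.Rmd` for the methods and
design notes and `inst/extdata/cohort_schema.md` for the fixture schema.

## Worked example

```r
library(secondhit)

# CNV route: synthetic whole-gene profiles carrying the two published
# USH2A structural alleles
fx <- family_cnv_profiles("R")                 # homozygous deletion family
calls <- call_cnv_intervals(normalize_counts(fx$coverage))
calls <- calls[calls$sample == "carrier", ]
refine_breakpoints(calls, fx$sample, fx$reference)[
  , c("direction", "zygosity", "refined_left", "refined_right")]
#> # A tibble: 1 × 4
#>   direction zygosity   refined_left refined_right
#>   <chr>     <chr>             <int>         <int>
#> 1 deletion  homozygous    215949321     216272841

# cohort route: screen -> splice rules -> prioritize -> report
pipe <- run_cohort_pipeline()
pipe$summary
#> Cohort of 29 families: 17 solved (diagnostic yield 58.62%)
#> Causal mutation occurrences: 31 (8 novel)
#>
#> Mutation-type spectrum:
#>       class count percent
#>    missense    18    58.1
#>    splicing     4    12.9
#>  frameshift     4    12.9
#>    nonsense     3     9.7
#>         CNV     2     6.5
#> ...
#> Second-hit rate by prior gene:
#>  prior_gene n_prior solved_same_gene rate_percent
#>       ABCA4       8                0          0.0
#>      CEP290       2                0          0.0
#>       USH2A      15               13         86.7
```

The refined span is the deletion's first and last affected base (1-based,
hg19). In the cohort summary, 17 of 29 families receive a molecular
diagnosis (yield 58.62%); 13 of the 15 families with a prior *USH2A*
allele are completed in *USH2A* itself, and the recurrent p.Cys759Phe
allele appears in 9 solved families, always compound-heterozygous.

## Analysis workflow

The `analysis/` scripts run the study as a narrative sequence, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_batch.R     # synthetic capture batch
Rscript analysis/02_call_cnvs.R          # CNV calls + breakpoint refinement
Rscript analysis/03_screen_variants.R    # QC + MAF screens
Rscript analysis/04_prioritize_cohort.R  # splice rules + second-hit search
Rscript analysis/05_report.R             # cohort summary
```

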