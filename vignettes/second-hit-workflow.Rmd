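---
title: "Finding the second hit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the second hit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondhit)
```

## The problem

Inherited retinal dystrophies (IRDs) are Mendelian photoreceptor
degenerations — retinitis pigmentosa (RP), Stargardt disease (STGD), Leber
congenital amaurosis (LCA), cone dystrophy (COD) and Usher syndrome (USH) —
with overwhelmingly autosomal-recessive inheritance in the genes this
package deals with. A recurrent diagnostic dead end is the *monoallelic*
patient: one clearly pathogenic heterozygous allele in a recessive gene
(most often *USH2A*, *ABCA4* or *CEP290*) and no second allele found by
exon-focused testing. The missing "second hit" may be a deep-intronic
splice-activating variant, a synonymous variant with a splicing effect, or
a copy-number variant (CNV) — all invisible unless the *whole* gene,
introns included, is captured and the analysis looks for them specifically.

`secondhit` reimplements such an analysis as a tested, reusable pipeline:

1. a cross-sample read-depth CNV caller for targeted panels, with
   base-resolution breakpoint refinement and allele-balance corroboration
   (`normalize_counts()`, `call_cnv_intervals()`, `refine_breakpoints()`,
   `allele_balance_shift()`);
2. record-level variant screening (`qc_filter()`, `maf_filter()`);
3. decision-threshold rules over external splice-predictor scores
   (`evaluate_splice_tool()`, `evaluate_splice_variant()`);
4. a stepwise prioritization and causality engine
   (`prioritize_family()`, `assess_causality()`, `check_genotype_model()`);
5. cohort-level diagnostic reporting (`summarize_cohort()`).

Because no sequencing data accompany the source cohort, the package ships
(a) generators that synthesise inputs with the statistical structure the
method assumes, and (b) a fixture transcribing the published 29-family
cohort so the downstream stages run end to end offline.

## The read-depth CNV model

For a batch of $n \ge 3$ samples captured together, let $c_{ij}$ be the
read count of sample $i$ on panel interval $j$. Counts are first rescaled
so every sample's total equals the batch mean total (library-size
normalization by the average number of reads per sample):
$\tilde c_{ij} = c_{ij}\,\bar T / T_i$. Each rescaled count is then
compared with the other samples in the batch through the dosage ratio

$$ r_{ij} = \frac{\tilde c_{ij}}{\operatorname{median}_{k \ne i}\,\tilde c_{kj}}, $$

which is $\approx 1$ for normal dosage, $\approx 0.5$ for a heterozygous
deletion, $\approx 0$ for a homozygous deletion and $\approx 1.5$ for a
three-copy duplication. An interval is flagged as deleted when
$r < \theta_{del} = 0.6$ and duplicated when $r > \theta_{dup} = 1.40$ —
strict inequalities; a ratio exactly at a threshold is not a call.

Design choices the thresholds alone do not fix:

* **Reference statistic.** The per-interval reference is the *leave-one-out
  median* of the other samples' rescaled counts. The median keeps a
  CNV-carrying neighbour from contaminating the reference; the
  leave-one-out form keeps the tested sample out of its own denominator.
* **Uncallable intervals.** Intervals whose reference falls below
  `min_reference_count` (default 50 rescaled reads) are flagged uncallable
  and never divided — a zero or near-zero denominator is a capture
  failure, not evidence.
* **Merging.** Runs of same-direction flagged intervals merge, tolerating
  `max_gap` (default 1) interior unflagged intervals as capture-efficiency
  dropouts; runs with fewer than `min_intervals` (default 2) flagged
  intervals are dropped as single-interval noise. Both are configurable;
  the per-interval rule is applied first and run means are summarized
  afterwards.
* **Zygosity bands** follow the expected dosages 0, 0.5 and 1.5 with slack
  for noise: a deletion run with mean ratio $\le 0.10$ is homozygous and
  within $[0.35, 0.60)$ heterozygous; a duplication within $(1.40, 1.65]$
  is a heterozygous three-copy gain; anything else is undetermined.
* **Normalization caveat.** Because each sample's own total is the
  library-size estimate, an event spanning a large fraction of the panel
  biases all of that sample's ratios away from 1 by the event's share of
  the total. On a realistic panel (hundreds to thousands of intervals) the
  bias is negligible; the simulators embed events small relative to the
  panel for the same reason.

### Breakpoint refinement

Whole-gene (intronic) capture yields contiguous per-base coverage, so CNV
boundaries can be read off the depth profile at base resolution. The
per-base sample/reference ratio is smoothed with a running median (span
`refine_window` = 50 bases, odd-rounded) and scanned: the left breakpoint
is the first base, moving rightward from the flank preceding the
interval-level call, where the smoothed ratio crosses the call's direction
threshold and *stays* crossed for at least `refine_window` bases; the right
breakpoint is symmetric. A running median preserves a clean step edge
exactly, so on noise-free profiles the refined coordinates equal the true
first and last affected base; under Poisson noise at depth 100 the median
absolute error stays within half the scan window (the test suite checks
$\le 25$ bp over 100 replicates). If no sustained crossing exists the call
is returned unrefined with an explicit note rather than a guessed
coordinate. Reported coordinates are 1-based inclusive (first to last
affected base, the HGVS genomic convention); panel intervals are BED
0-based half-open internally.

### Allele-balance corroboration

A tandem duplication places two of three copies on one haplotype, so every
heterozygous SNP inside the span shifts from ~50:50 towards ~67:33. With
per-SNP major-haplotype read counts $X \sim \mathrm{Bin}(d, 2/3)$,
`allele_balance_shift()` reports the mean major-allele fraction over SNPs
with depth $\ge 20$ and issues a verdict: *supports three copies* when the
mean lies in $[0.60, 0.75]$ and $\ge 80\%$ of SNPs individually exceed
0.58; *supports two copies* when the mean lies in $[0.45, 0.55]$;
otherwise *inconclusive*. When only ref/alt depths are available the
better-supported allele is taken as major per SNP; this folding inflates
the statistic at balanced sites by roughly
$\sqrt{2/\pi}\,\sigma_d$ (about 1.8 percentage points at depth 500), which
is why the generator labels the multi-copy haplotype directly and the
two-copy check is performed on the labelled counts.

```{r allele-balance}
snps <- simulate_allele_depths(region_copy_number = 3, n_snps = 100,
                               total_depth = 500, seed = 1)
shift <- allele_balance_shift(snps)
round(100 * shift$mean_major_fraction, 1)
shift$verdict
```

## Variant screening

Two record-level screens, both with strict boundaries as stated in the
protocol they encode:

* **QC:** discard coverage $< 20\times$ or FisherStrand $> 60.0$
  (DP = 20 and FS = 60.0 are retained). Records with missing DP/FS are
  rejected with reason `missing-qc`, never silently passed.
* **Frequency:** retain only variants with MAF $< 0.015$ in *every*
  database where they are observed (1000G, EVS, ExAC, GnomAD, dbSNP, and
  the Spanish CSVS when populated); absence from a database passes. The
  conjunction reads the screen as: one high-frequency observation anywhere
  disqualifies a rare-disease allele. A MAF exactly at 0.015 is rejected —
  the retain rule is $<$, and the boundary is configurable.

The filters are idempotent, commute, and are checked against brute-force
set-comprehension oracles in the tests.

## Splice-predictor decision rules

The predictors themselves (MaxEntScan, HSF, NNSPLICE) are upstream tools;
their scores are inputs. The rules encoded here:

| tool | active-site score | variation |
|---|---|---|
| MaxEnt | $\ge 2$ | $> 15\%$ |
| HSF | $\ge 70$ | $> 10\%$ |
| NNSPLICE | $> 0.4$ | $> 10\%$ |

"Active site" resolves an ambiguity in the stated thresholds: for a
native-site **loss** the biologically active site is the wild-type one, so
the minimum score applies to the wild-type score and variation is
$|mut - wt|/wt$; for a cryptic-site **gain** both apply to the new
(mutant) site, so a site arising from nothing scores a 100% change rather
than a division by zero. The per-variant combination policy is not fixed
by the protocol; the default is majority-style — at least two of the tools
that were run must pass (degenerating to the single tool's verdict when
only one was run, which keeps the `any` $\supseteq$ `majority`
$\supseteq$ `all` containment exact) — matching the practice of citing
multiple concordant predictors. `any` and `all` are available.

## Prioritization and causality

The stepwise search per family: **(1)** try to complete the genotype in
the gene already carrying the known monoallelic variant — SNVs/indels,
splice-flagged intronic/synonymous variants, and CNV alleles all count;
**(2)** only if that fails, assess recessive two-allele (or
segregation-confirmed dominant one-allele) explanations at other loci.

The causality criteria are stated in the source protocol as a list —
segregation, database pathogenicity or novelty, phenotype consistency —
whose conjunction is ambiguous as printed. The engine implements the
reading that matches how the cohort's alleles were actually accepted:

> causal ⇔ (database-pathogenic OR novel-with-damaging-evidence) AND
> phenotype-consistent AND segregation ∈ {consistent, not performed}

with three sharpenings:

* **Failed segregation excludes.** An allele in *cis* with the known
  variant can never complete a recessive genotype, whatever its
  predictions.
* **Presumption rule.** Where relatives were unavailable, a
  phenotype-consistent allele meeting the pathogenicity criteria is
  *presumed* causal — except deep-intronic alleles, which are capped at
  *candidate* without segregation; prediction-only evidence for
  pseudo-exon activation is treated as insufficient for a diagnosis.
* **Conflicting database records** (ClinVar "conflicting interpretations")
  are resolved by strict majority of the recorded votes:
  pathogenic-leaning majority counts as database-pathogenic,
  benign-leaning majority excludes, ties stay VUS. This reproduces the
  cohort's acceptances (e.g. a 13:0:2 pathogenic:benign:VUS record is
  accepted; a 4:5 record is not) without a per-allele fiat.

Genotype models: a recessive gene completes with one homozygous or two
heterozygous causal alleles; unphased double heterozygotes are assumed in
trans and flagged `phase unconfirmed` (parental phasing was unavailable in
a minority of the solved families, and assuming trans is the only reading
under which those families are diagnosable). A dominant gene completes at
causal level only with confirmatory segregation — a novel dominant-gene
heterozygote with failed predictions and no relatives stays a *candidate*,
which is exactly the status of the one such family in the cohort. Two
distinct homozygous causal alleles in one gene raise a zygosity
contradiction (status capped at candidate with an explicit note).

Phenotype consistency is a strict lookup in a packaged gene-to-phenotype
map (RP/arRP/sRP are one class); no fuzzy matching.

## Reporting conventions

* **Allele counting:** per family, a homozygous genotype contributes one
  counted mutation; a recurrent allele counts once per family carrying it.
  This is the only convention under which the fixture cohort yields its
  published totals (31 causal occurrences; verified by enumeration in the
  tests).
* **Spectrum classes:** intronic-splicing and synonymous-splice pool into
  "splicing"; both CNV directions pool into "CNV".
* **Rounding:** percentages are rounded half-up (yield to 2 dp, spectrum
  to 1 dp). The published spectrum percentages are not reproducible by any
  single rounding rule (58.1 and 6.5 require rounding up while 9.6
  requires truncation of the same 1/31 grid); the reporter uses standard
  half-up throughout, which reproduces four of the five printed values and
  gives 9.7 for 3/31. The acceptance tests therefore compare percentages
  at one unit in the last printed digit.
* The reporter also emits the count of solved families explained by
  *USH2A* with its own computed percentage, rather than echoing any
  printed one.

## The synthetic-data generators

`simulate_coverage()` draws interval counts as Poisson around
$\text{library}_i \times \text{efficiency}_j \times \text{length}_j \times
\text{CN}/2$ — the standard capture model. It emulates: Poisson count
noise, log-normal per-sample library sizes (`library_size_sd`, default
0.2), shared interval capture efficiencies, and embedded events with copy
number 0, 1 or 3. It does **not** emulate GC bias, mapping artifacts,
batch-correlated capture failures, mosaicism, or copy numbers above 3 —
so a passing recovery test shows the caller is correct *under the stated
noise model*, not that it is robust to real-world capture pathologies.
Defaults reflect the study conditions the package reproduces: batches of 6
samples (multiplexed capture pools), mean depths of several hundred fold
(the source design averaged ~800×), and a miniature panel standing in for
the unpublished full interval list.

`simulate_allele_depths()` draws binomial allele counts at het SNPs
(p = 1/2 at CN2, 2/3 at CN3, the tandem-duplication haplotype model).
`simulate_variant_table()` draws an annotated variant list whose MAF
spectrum is dominated by common polymorphisms with a configurable rare
fraction — the generator/filter round trip at a realistic load (2,349
variants, rare fraction 314/2349) is a test invariant. All generators are
byte-identical under a fixed seed (`withr::with_seed`, so the caller's RNG
state is untouched).

`family_cnv_profiles()` reconstructs, as clean synthetic dosage profiles,
the base-resolution evidence for the two published *USH2A* structural
alleles (homozygous deletion chr1:g.215,949,321_216,272,841, heterozygous
duplication chr1:g.216,005,789_216,019,066, hg19), embedded in a batch
with diploid ballast intervals so library-size normalization is not
confounded by the event itself. No read data underlie these profiles; they
are step functions (optionally Poisson-dispersed) carrying the published
breakpoints, and exist so the caller → refiner path can be exercised and
checked for exact recovery.

## The cohort fixture

`load_cohort_fixture()` returns the transcribed 29-family cohort: 25
families with a prior monoallelic variant (15 *USH2A*, 8 *ABCA4*, 2
*CEP290*), every published candidate variant with its annotations, and the
gene-phenotype map. Transcription choices that required judgement are
flagged in the data itself and in `inst/extdata/cohort_schema.md`:

* HGVS strings are kept verbatim, including printed idiosyncrasies.
* The source marks only six causal variants as novel in its table but
  counts eight; the fixture pins the two extra flags (M13, M12) and marks
  them `novel_inferred`.
* The label "m33" is reused in the source for two different variants; the
  fixture renames the second `m33b`.
* One family's hearing loss is attributed in the source to a different
  cause; the fixture records the phenotype as printed (arRP, with the
  hearing loss in the free-text features) and the phenotype class used for
  analysis is non-syndromic RP.
* DP, FS, most MAFs and the numeric splice scores behind qualitative
  predictor calls are synthetic, chosen once so that reported variants
  pass the screens they passed in the source analysis; the few printed
  frequencies (0.019, 0.029, the GnomAD carrier counts) are used directly.

Problem sizes throughout the tests (batch sizes 3–10, panels of 40–200
intervals at depths 100–600, 200-seed recovery sweeps, 10,000-record
filter oracles) were chosen as the smallest scales at which the checked
statistics are stable; they are the package's own choices.

## Known limitations

* The caller is a threshold method; it has no explicit noise model, no
  GC correction, and no split-read/discordant-pair evidence, so it cannot
  see balanced events (inversions) and its power near the thresholds
  degrades with shallow panels exactly as the normalization-bias note
  above describes.
* CNV population-frequency annotation (DGV/DECIPHER) is out of scope and
  carried only as annotation fields.
* The splice rules classify predictions; they do not validate splicing.
  Functional confirmation is explicitly outside the package.
* The engine's causality rule is a faithful encoding of one published
  protocol, not a general ACMG/AMP classifier.
* Whether interval counts are duplicate-filtered upstream is the caller's
  caller's responsibility: the package takes whatever counts are supplied.

## Reproducing the headline numbers

```{r pipeline}
pipe <- run_cohort_pipeline()
pipe$summary
```

The `analysis/` scripts run the same stages as a narrative workflow
(simulate → call → screen → prioritize → report), writing their tables
under `results/`; `scripts/acceptance.R` recomputes the allele-balance
quantity from scratch for an arbitrary seed.
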