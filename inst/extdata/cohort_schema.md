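# Cohort fixture schema

The fixture transcribes the published 29-family IRD cohort (families A-AC)
into two linked TSVs plus a gene-to-phenotype map. Every row carries a
`provenance` column naming the table cell it was transcribed from.

## cohort_families.tsv (one row per family)

| column | meaning |
|---|---|
| family_id | family label A..AC |
| index_id | index patient pedigree position |
| clin_diagnosis | clinical diagnosis as printed: STGD, COD, sRP, arRP, LCA, USH |
| features | free-text clinical notes (annotation only) |
| inheritance | autosomal-recessive or simplex (presumed mode) |
| segregation_available | TRUE for the 10 families where relatives were genotyped |
| prior_gene / prior_variant | previously known monoallelic variant (NA for the 4 unscreened families); family T carries a second prior variant in `prior_gene2` / `prior_variant2` |
| table2_status | final "solved with this panel" column: Yes / No / Unknown (provenance; the engine never reads it) |
| table2_gene | causative or candidate gene as printed (provenance) |

Marginals: 29 families; 25 with a prior variant (15 USH2A, 8 ABCA4,
2 CEP290); statuses 17 Yes / 2 Unknown / 10 No.

## cohort_variants.tsv (one row per variant per family)

Identity and annotation: `variant_id` (M# = reported causal, m# = other, as
printed; the source reuses "m33" for two different variants — the family-B
deep-intronic duplication is stored as `m33b`), `gene`, `hgvs_c`, `hgvs_p`
(verbatim, including printed idiosyncrasies), `consequence` (missense |
nonsense | frameshift | intronic-splicing | synonymous-splice |
deep-intronic | cnv-deletion | cnv-duplication | other), `zygosity`
(het | hom), `chrom`, and for the two CNVs the published hg19 breakpoints in
`pos`/`end` (1-based inclusive).

QC and frequency: `dp`, `fs` and most `maf_*` values are **synthetic**
(chosen so that every reported variant passes the published screens); the
source prints only the 1000G frequencies of m4 (0.019) and m6 (0.029) and
the GnomAD carrier counts behind m33/m39/m40. CNV rows carry placeholder
dp = 999, fs = 0 (read-depth alleles have no per-site QC).

Database labels: `db_label` (pathogenic | likely-pathogenic | conflicting |
VUS | benign | absent) with `db_source`; for ClinVar
conflicting-interpretation entries the printed vote tallies are kept in
`db_votes_path` (pathogenic + likely pathogenic), `db_votes_benign`
(benign + likely benign) and `db_votes_vus`.

Novelty: `novel` marks alleles absent from public databases. The source
text counts 8 novel causal alleles but marks only 6 causal variants "This
study" (M2, M7, M8, M16, M21, M23); `novel_inferred = TRUE` flags the two
assignments made to reconcile the count (M13, which carries no literature
citation, and M12) — see the package vignette.

Predictions: `missense_pred` (damaging | mixed | benign) summarises the
printed MutationTaster/SIFT/PolyPhen calls; numeric splice scores
(`maxent_*`, `hsf_*`, `nns_*`, with `splice_event` donor|acceptor and
`splice_site` native-site-loss|cryptic-site-gain) are **synthetic** values
consistent with the printed qualitative predictor outcomes (e.g. "NNS: New
donor", "HSF: No impact").

Segregation: `segregation` = consistent (tested, co-segregates) |
inconsistent (tested, in cis with the known variant: m33b, m36, m37) |
unavailable.

## gene_phenotypes.tsv

Strict gene-to-phenotype lookup (`phenotypes` semicolon-separated;
RP/arRP/sRP are one class) with inheritance `mode`, transcribed for the
genes named in the source for this cohort.
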