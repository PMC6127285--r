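#!/usr/bin/env Rscript
# Aggregate the per-family results into the cohort diagnostic summary:
# yield, mutation-type spectrum, recurrent alleles, per-phenotype genes and
# second-hit rates by prior gene.

suppressPackageStartupMessages(library(secondhit))
dir.create("results", showWarnings = FALSE)

cohort <- load_cohort_fixture()
results <- readr::read_tsv("results/family_results.tsv",
                           show_col_types = FALSE)
results$causal_alleles[is.na(results$causal_alleles)] <- ""
summary <- summarize_cohort(results, cohort)
print(summary)

write_summary_json(summary, "results/cohort_summary.json")
readr::write_tsv(summary$recurrent_alleles, "results/recurrent_alleles.tsv")
cat("\nWrote results/cohort_summary.json and results/recurrent_alleles.tsv\n")
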