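#' Aggregate per-family prioritization results into a cohort summary
#'
#' Applies the cohort's allele-counting convention: per family, a homozygous
#' genotype contributes one counted mutation, and a recurrent allele is
#' counted once per family carrying it. The mutation-type spectrum pools
#' intronic-splicing with synonymous-splice variants into a "splicing" class
#' and both CNV directions into "CNV"; percentages use the causal-occurrence
#' denominator and are rounded half-up to one decimal. Diagnostic yield is
#' `100 * solved / families`, rounded half-up to two decimals.
#'
#' @param results tibble from [prioritize_cohort()] (one row per family).
#' @param cohort the `cohort_fixture` the results were computed from (for
#'   variant annotations and phenotype labels).
#' @return A `cohort_summary` list: `n_families`, `n_solved`,
#'   `yield_percent`, `spectrum` (class/count/percent tibble),
#'   `n_causal_occurrences`, `n_novel`, `recurrent_alleles`,
#'   `per_phenotype` (solved/total and genes per clinical diagnosis),
#'   `second_hit_by_prior_gene`, `solved_by_gene`, `statuses`, `notes`.
#' @export
summarize_cohort <- function(results, cohort) {
  abort_if(anyDuplicated(results$family_id) > 0L,
           "duplicate family_id in results")
  fam <- cohort$families
  var <- cohort$variants
  results <- results[match(fam$family_id, results$family_id), ]
  abort_if(anyNA(results$family_id), "results must cover every family")
  n <- nrow(fam)
  solved <- results[results$status == "solved", ]
  n_solved <- nrow(solved)
  yield <- round_half_up(100 * n_solved / max(n, 1L), 2)

  # causal allele occurrences (one per allele per family; hom already single)
  occ <- tidyr::separate_rows(
    solved[, c("family_id", "causal_gene", "causal_alleles")],
    "causal_alleles", sep = ";")
  occ <- occ[nzchar(occ$causal_alleles), , drop = FALSE]
  occ <- dplyr::left_join(occ,
    var[, c("family_id", "variant_id", "consequence", "zygosity", "novel")],
    by = c("family_id", "causal_alleles" = "variant_id"))

  spectrum_class <- function(consequence) {
    dplyr::case_match(consequence,
      "missense" ~ "missense",
      c("intronic-splicing", "synonymous-splice") ~ "splicing",
      "frameshift" ~ "frameshift",
      "nonsense" ~ "nonsense",
      c("cnv-deletion", "cnv-duplication") ~ "CNV",
      .default = "other")
  }
  classes <- c("missense", "splicing", "frameshift", "nonsense", "CNV",
               "other")
  tab <- table(factor(spectrum_class(occ$consequence), levels = classes))
  spectrum <- tibble::tibble(
    class = classes, count = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / max(sum(tab), 1L), 1))
  spectrum <- spectrum[spectrum$count > 0 | spectrum$class != "other", ]

  recurrent <- dplyr::count(occ, .data$causal_alleles, name = "n_families")
  recurrent <- dplyr::arrange(recurrent, dplyr::desc(.data$n_families),
                              .data$causal_alleles)

  per_phenotype <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(fam, results, by = "family_id"),
                    .data$clin_diagnosis),
    total = dplyr::n(),
    solved = sum(.data$status == "solved"),
    genes = paste(sort(unique(stats::na.omit(
      .data$causal_gene[.data$status == "solved"]))), collapse = ";"),
    .groups = "drop")

  prior <- fam[!is.na(fam$prior_gene), ]
  prior_res <- dplyr::left_join(prior, results, by = "family_id")
  second_hit <- dplyr::summarise(
    dplyr::group_by(prior_res, .data$prior_gene),
    n_prior = dplyr::n(),
    solved_same_gene = sum(.data$status == "solved" &
                             .data$causal_gene == .data$prior_gene,
                           na.rm = TRUE),
    rate_percent = round_half_up(100 * .data$solved_same_gene /
                                   .data$n_prior, 1),
    .groups = "drop")

  solved_by_gene <- dplyr::count(solved, .data$causal_gene,
                                 name = "n_families")
  statuses <- c(solved = n_solved,
                candidate = sum(results$status == "candidate"),
                unsolved = sum(results$status == "unsolved"))

  notes <- character(0)
  ush <- solved_by_gene$n_families[solved_by_gene$causal_gene == "USH2A"]
  if (length(ush) == 1L && n_solved > 0L) {
    notes <- c(notes, sprintf(
      "%d of %d solved families are explained by USH2A (%.1f%%)",
      ush, n_solved, 100 * ush / n_solved))
  }
  structure(list(
    n_families = n, n_solved = n_solved, yield_percent = yield,
    n_causal_occurrences = sum(spectrum$count),
    n_novel = sum(occ$novel, na.rm = TRUE),
    spectrum = spectrum, recurrent_alleles = recurrent,
    per_phenotype = per_phenotype,
    second_hit_by_prior_gene = second_hit,
    solved_by_gene = solved_by_gene, statuses = statuses,
    occurrences = occ, notes = notes), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d families: %d solved (diagnostic yield %.2f%%)\n",
              x$n_families, x$n_solved, x$yield_percent))
  cat(sprintf("Causal mutation occurrences: %d (%d novel)\n",
              x$n_causal_occurrences, x$n_novel))
  cat("\nMutation-type spectrum:\n")
  print(as.data.frame(x$spectrum), row.names = FALSE)
  cat("\nSolved cases by clinical diagnosis:\n")
  print(as.data.frame(x$per_phenotype), row.names = FALSE)
  cat("\nSecond-hit rate by prior gene:\n")
  print(as.data.frame(x$second_hit_by_prior_gene), row.names = FALSE)
  for (nn in x$notes) cat("\nNote:", nn, "\n")
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary a `cohort_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- summary[c("n_families", "n_solved", "yield_percent",
                   "n_causal_occurrences", "n_novel", "spectrum",
                   "recurrent_alleles", "per_phenotype",
                   "second_hit_by_prior_gene", "solved_by_gene", "statuses",
                   "notes")]
  out$statuses <- as.list(out$statuses)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
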