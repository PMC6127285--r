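#' Decide whether a gene fits a family's phenotype
#'
#' A strict lookup in the packaged gene-to-phenotype map; the three
#' non-syndromic retinitis pigmentosa labels (RP, arRP, sRP) are treated as
#' one phenotype class. No fuzzy matching.
#'
#' @param gene gene symbol.
#' @param diagnosis clinical diagnosis label (RP | arRP | sRP | USH | STGD |
#'   LCA | COD).
#' @param gene_map tibble with `gene`, `mode`, `phenotypes`
#'   (semicolon-separated).
#' @return `TRUE`/`FALSE`; unknown genes are inconsistent.
#' @export
phenotype_consistent <- function(gene, diagnosis, gene_map) {
  row <- gene_map[gene_map$gene == gene, ]
  if (nrow(row) == 0L) return(FALSE)
  ph <- strsplit(row$phenotypes[1], ";", fixed = TRUE)[[1]]
  norm <- function(d) ifelse(d %in% c("RP", "arRP", "sRP"), "RP", d)
  norm(diagnosis) %in% norm(ph)
}

gene_inheritance <- function(gene, gene_map) {
  row <- gene_map[gene_map$gene == gene, ]
  if (nrow(row) == 0L) "autosomal-recessive" else row$mode[1]
}

db_majority_pathogenic <- function(label, votes_path, votes_benign,
                                   votes_vus) {
  if (is.na(label)) return(FALSE)
  if (label %in% c("pathogenic", "likely-pathogenic")) return(TRUE)
  if (label == "conflicting") {
    vp <- votes_path %||% NA
    if (is.na(vp)) return(FALSE)
    return(vp > (votes_benign %||% 0) + (votes_vus %||% 0))
  }
  FALSE
}

db_majority_benign <- function(label, votes_path, votes_benign) {
  if (is.na(label)) return(FALSE)
  if (label == "benign") return(TRUE)
  if (label == "conflicting") {
    vb <- votes_benign %||% NA
    if (is.na(vb)) return(FALSE)
    return(vb > (votes_path %||% 0))
  }
  FALSE
}

#' Assess one screened variant against the causality criteria
#'
#' A variant is classified `causal` when it is either described as pathogenic
#' or likely pathogenic in databases (conflicting database records are
#' resolved by strict majority of the recorded interpretation votes) or is a
#' novel variant with a damaging consequence or prediction (nonsense,
#' frameshift, CNV, predicted splice-altering by the combined splice rule, or
#' a damaging missense prediction), and its gene fits the family phenotype,
#' and segregation, where performed, is consistent. A failed segregation
#' (the allele lies in cis with the known variant) excludes it outright, as
#' does a majority-benign database record or a phenotype-inconsistent gene.
#' Deep-intronic alleles whose segregation could not be tested are capped at
#' `candidate` regardless of predictions. Everything else that survives the
#' screen in a phenotype-consistent gene remains a `candidate`.
#'
#' @param variant one-row tibble of a screened variant (with `splice_flag`).
#' @param family one-row tibble of the family.
#' @param gene_map gene-to-phenotype map.
#' @return List of criteria flags plus `classification` (`causal` /
#'   `candidate` / `excluded`) and a `rationale` string.
#' @export
assess_causality <- function(variant, family, gene_map) {
  v <- as.list(variant)
  segregates <- switch(v$segregation, consistent = "yes",
                       inconsistent = "no", "NA")
  pheno_ok <- phenotype_consistent(v$gene, family$clin_diagnosis, gene_map)
  db_path <- db_majority_pathogenic(v$db_label, v$db_votes_path,
                                    v$db_votes_benign, v$db_votes_vus)
  db_benign <- db_majority_benign(v$db_label, v$db_votes_path,
                                  v$db_votes_benign)
  damaging <- switch(v$consequence,
    nonsense = TRUE, frameshift = TRUE,
    `cnv-deletion` = TRUE, `cnv-duplication` = TRUE,
    `intronic-splicing` = isTRUE(v$splice_flag),
    `synonymous-splice` = isTRUE(v$splice_flag),
    `deep-intronic` = isTRUE(v$splice_flag),
    missense = identical(v$missense_pred, "damaging"),
    FALSE)
  novel_damaging <- isTRUE(v$novel) && damaging
  classification <- if (segregates == "no") {
    "excluded"
  } else if (db_benign || !pheno_ok) {
    "excluded"
  } else if ((db_path || novel_damaging) &&
             !(v$consequence == "deep-intronic" && segregates == "NA")) {
    "causal"
  } else {
    "candidate"
  }
  rationale <- if (classification == "excluded") {
    if (segregates == "no") "fails segregation (in cis with known variant)"
    else if (db_benign) "database majority benign"
    else "gene-phenotype mismatch"
  } else if (classification == "causal") {
    paste0(if (db_path) "database pathogenic" else "novel with damaging consequence/prediction",
           if (segregates == "yes") "; segregation consistent"
           else "; presumed causal (phenotype-matched, segregation unavailable)")
  } else if (v$consequence == "deep-intronic" && segregates == "NA" &&
             (db_path || novel_damaging)) {
    "deep-intronic without segregation: capped at candidate"
  } else {
    "plausible but pathogenicity criteria incomplete"
  }
  list(variant_id = v$variant_id %||% paste0(v$gene, ":", v$hgvs_c),
       gene = v$gene, zygosity = v$zygosity,
       segregates = segregates, database_pathogenic = db_path,
       novel_with_damaging_prediction = novel_damaging,
       phenotype_consistent = pheno_ok,
       classification = classification, rationale = rationale)
}

#' Check whether a set of assessed alleles completes a genotype model
#'
#' Recessive genes complete with one homozygous allele or two (or more)
#' heterozygous alleles; unphased double heterozygotes are assumed in trans
#' and flagged `"phase unconfirmed"`. Dominant genes complete with a single
#' heterozygous allele, but only a segregation-confirmed causal allele
#' completes the model at causal level; without segregation the model is
#' candidate at best. Two distinct homozygous causal alleles in one gene are
#' a zygosity contradiction.
#'
#' @param alleles tibble of assessments for one gene (columns
#'   `classification`, `zygosity`, `segregates`, `variant_id`).
#' @param inheritance_mode `"autosomal-recessive"` or `"autosomal-dominant"`.
#' @return List with `status` (`completed-causal`, `completed-candidate`,
#'   `incomplete`, `inconsistent`), the supporting `alleles`, `model`
#'   (`homozygous`/`compound-het`/`dominant-het`) and `notes`.
#' @export
check_genotype_model <- function(alleles, inheritance_mode =
                                   "autosomal-recessive") {
  empty <- list(status = "incomplete", alleles = character(0),
                model = NA_character_, notes = NA_character_)
  if (nrow(alleles) == 0L) return(empty)
  alleles <- dplyr::arrange(alleles, variant_id)
  ok <- alleles[alleles$classification != "excluded", , drop = FALSE]
  if (nrow(ok) == 0L) return(empty)
  causal <- ok[ok$classification == "causal", , drop = FALSE]
  if (sum(causal$zygosity == "hom") >= 2L) {
    return(list(status = "inconsistent", alleles = causal$variant_id,
                model = NA_character_,
                notes = "zygosity contradiction: two homozygous causal alleles in one gene"))
  }
  if (inheritance_mode == "autosomal-dominant") {
    confirmed <- causal[causal$segregates == "yes", , drop = FALSE]
    if (nrow(confirmed) >= 1L) {
      return(list(status = "completed-causal",
                  alleles = confirmed$variant_id[1], model = "dominant-het",
                  notes = NA_character_))
    }
    return(list(status = "completed-candidate", alleles = ok$variant_id[1],
                model = "dominant-het",
                notes = "dominant single heterozygote without confirmatory segregation"))
  }
  hom_causal <- causal[causal$zygosity == "hom", , drop = FALSE]
  if (nrow(hom_causal) == 1L) {
    return(list(status = "completed-causal", alleles = hom_causal$variant_id,
                model = "homozygous", notes = NA_character_))
  }
  het_causal <- causal[causal$zygosity == "het", , drop = FALSE]
  if (nrow(het_causal) >= 2L) {
    phased <- all(het_causal$segregates == "yes")
    return(list(status = "completed-causal", alleles = het_causal$variant_id,
                model = "compound-het",
                notes = if (phased) NA_character_ else
                  "phase unconfirmed: double heterozygote assumed in trans"))
  }
  if (any(ok$zygosity == "hom") || nrow(ok) >= 2L) {
    picked <- if (any(ok$zygosity == "hom")) {
      ok$variant_id[ok$zygosity == "hom"][1]
    } else ok$variant_id
    return(list(status = "completed-candidate", alleles = picked,
                model = if (any(ok$zygosity == "hom")) "homozygous"
                        else "compound-het",
                notes = "genotype completed by candidate alleles only"))
  }
  empty
}

#' Prioritize one family: find and classify the second hit
#'
#' Implements the stepwise search: (1) complete the genotype in the gene
#' carrying the previously known monoallelic variant, considering SNVs and
#' indels, predicted splice-altering intronic and synonymous variants, and
#' CNV alleles; (2) if no complete explanation exists there, assess recessive
#' two-allele (or segregation-confirmed dominant one-allele) explanations in
#' any other panel gene. The family is `solved` when a genotype model is
#' completed entirely by causal alleles, `candidate` when only a
#' candidate-level completion exists (for example an unsegregated
#' deep-intronic pair, or a dominant heterozygote without segregation), and
#' `unsolved` otherwise — the defining monoallelic state, a single
#' heterozygous allele in a recessive gene, never completes a model.
#'
#' @param family one-row tibble from the cohort `families` table.
#' @param candidates screened, splice-flagged variant tibble for this family.
#' @param gene_map gene-to-phenotype map.
#' @param cnv_calls optional CNV call tibble (from [call_cnv_intervals()])
#'   for this family's index sample; converted to CNV alleles and appended.
#' @return One-row tibble: `family_id`, `status`, `causal_gene`,
#'   `causal_alleles` (";"-separated), `model`, `notes`.
#' @export
prioritize_family <- function(family, candidates, gene_map,
                              cnv_calls = NULL) {
  stopifnot(nrow(family) == 1L)
  candidates <- tibble::as_tibble(candidates)
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0L) {
    candidates <- dplyr::bind_rows(candidates, cnv_as_alleles(cnv_calls))
  }
  result <- function(status, gene = NA_character_, alleles = character(0),
                     model = NA_character_, notes = NA_character_) {
    tibble::tibble(family_id = family$family_id, status = status,
                   causal_gene = gene,
                   causal_alleles = paste(alleles, collapse = ";"),
                   model = model, notes = notes)
  }
  if (nrow(candidates) == 0L) {
    return(result("unsolved", notes = "no candidate variants survive screening"))
  }
  assessed <- dplyr::bind_rows(purrr::map(seq_len(nrow(candidates)),
    function(i) tibble::as_tibble(assess_causality(candidates[i, ], family,
                                                   gene_map))))
  prior_genes <- stats::na.omit(c(family$prior_gene,
                                  family$prior_gene2 %||% NA_character_))
  genes <- unique(c(prior_genes[prior_genes %in% assessed$gene],
                    sort(unique(assessed$gene))))
  models <- lapply(genes, function(g)
    check_genotype_model(assessed[assessed$gene == g, , drop = FALSE],
                         gene_inheritance(g, gene_map)))
  names(models) <- genes
  for (g in genes) {
    m <- models[[g]]
    if (m$status == "completed-causal") {
      note <- m$notes
      if (length(prior_genes) > 0L && !g %in% prior_genes) {
        note <- paste(stats::na.omit(c(note,
          "different locus than the prior monoallelic variant")),
          collapse = "; ")
      }
      return(result("solved", g, m$alleles, m$model,
                    if (length(note) && nzchar(note)) note else NA_character_))
    }
  }
  for (g in genes) {
    m <- models[[g]]
    if (m$status %in% c("completed-candidate", "inconsistent")) {
      return(result("candidate", g, character(0), m$model,
                    paste(stats::na.omit(c(m$notes, paste0("candidate alleles: ",
                      paste(m$alleles, collapse = ";")))), collapse = "; ")))
    }
  }
  result("unsolved",
         notes = "no gene completes a recessive or confirmed dominant genotype")
}

#' Convert CNV calls into allele records for prioritization
#'
#' @param calls tibble from [call_cnv_intervals()] with a `gene` column (or
#'   spanning a single-gene panel region).
#' @return Variant-record rows with consequence `cnv-deletion` /
#'   `cnv-duplication`.
#' @export
cnv_as_alleles <- function(calls) {
  tibble::tibble(
    variant_id = sprintf("cnv_%s_%d_%d", calls$chrom, calls$start, calls$end),
    gene = calls$gene %||% NA_character_,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = ifelse(calls$direction == "deletion", "cnv-deletion",
                         "cnv-duplication"),
    zygosity = ifelse(calls$zygosity == "homozygous", "hom", "het"),
    dp = NA_integer_, fs = NA_real_,
    db_label = "absent", db_votes_path = NA_real_,
    db_votes_benign = NA_real_, db_votes_vus = NA_real_,
    novel = TRUE, missense_pred = NA_character_,
    splice_flag = FALSE, segregation = "unavailable"
  )
}

#' Prioritize every family of a cohort
#'
#' @param cohort a `cohort_fixture`.
#' @param candidates screened, splice-flagged variant tibble (all families).
#' @return Tibble with one [prioritize_family()] row per family, in the
#'   cohort's family order.
#' @export
prioritize_cohort <- function(cohort, candidates) {
  fam <- cohort$families
  dplyr::bind_rows(purrr::map(seq_len(nrow(fam)), function(i) {
    prioritize_family(fam[i, ],
                      candidates[candidates$family_id == fam$family_id[i], ,
                                 drop = FALSE],
                      cohort$gene_phenotypes)
  }))
}
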