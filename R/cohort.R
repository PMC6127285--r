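#' Load the packaged 29-family cohort fixture
#'
#' The fixture transcribes the study cohort: 29 unrelated families with
#' inherited retinal dystrophies, 25 of them carrying a previously detected
#' monoallelic variant in USH2A (15), ABCA4 (8) or CEP290 (2), together with
#' every published candidate variant (annotations, zygosity, database labels,
#' splice-predictor outcomes, segregation) and a gene-to-phenotype map for
#' the relevant panel genes. Values the source tables do not print (DP, FS,
#' most MAFs, numeric splice scores behind qualitative predictor calls) are
#' synthetic and documented in `inst/extdata/cohort_schema.md`.
#'
#' @param dir directory holding the fixture TSVs; defaults to the installed
#'   package copies.
#' @return A `cohort_fixture` list: `families` (29 rows), `variants` (one
#'   row per variant per family) and `gene_phenotypes`.
#' @export
load_cohort_fixture <- function(dir = system.file("extdata",
                                                  package = "secondhit")) {
  fam <- readr::read_tsv(file.path(dir, "cohort_families.tsv"),
                         show_col_types = FALSE)
  var <- readr::read_tsv(file.path(dir, "cohort_variants.tsv"),
                         show_col_types = FALSE)
  map <- readr::read_tsv(file.path(dir, "gene_phenotypes.tsv"),
                         show_col_types = FALSE)
  x <- structure(list(families = fam, variants = var, gene_phenotypes = map),
                 class = "cohort_fixture")
  validate_cohort_fixture(x)
  x
}

#' Validate a cohort fixture against its schema
#'
#' Checks the structural invariants of the transcription (family count,
#' prior-variant marginals, closed vocabularies, per-family variant linkage)
#' and names the offending family in every error.
#'
#' @param x a `cohort_fixture`.
#' @return `x`, invisibly, or an error.
#' @export
validate_cohort_fixture <- function(x) {
  fam <- x$families
  var <- x$variants
  abort_if(nrow(fam) != 29L,
           sprintf("cohort fixture must hold exactly 29 families, found %d",
                   nrow(fam)))
  abort_if(anyDuplicated(fam$family_id) > 0L, "duplicate family_id in fixture")
  prior <- fam[!is.na(fam$prior_gene), ]
  abort_if(nrow(prior) != 25L,
           "exactly 25 families must carry a prior monoallelic variant")
  abort_if(!all(prior$prior_gene %in% c("USH2A", "ABCA4", "CEP290")),
           paste("prior variant outside USH2A/ABCA4/CEP290 in family",
                 prior$family_id[!prior$prior_gene %in%
                                   c("USH2A", "ABCA4", "CEP290")][1]))
  abort_if(!all(fam$table2_status %in% c("Yes", "No", "Unknown")),
           "table2_status must be Yes/No/Unknown")
  cons_ok <- c("missense", "nonsense", "frameshift", "intronic-splicing",
               "synonymous-splice", "deep-intronic", "cnv-deletion",
               "cnv-duplication", "other")
  for (i in seq_len(nrow(var))) {
    fid <- var$family_id[i]
    abort_if(!fid %in% fam$family_id,
             sprintf("variant row %d references unknown family %s", i, fid))
    abort_if(!var$consequence[i] %in% cons_ok,
             sprintf("family %s: invalid consequence '%s'", fid,
                     var$consequence[i]))
    abort_if(!var$zygosity[i] %in% c("het", "hom"),
             sprintf("family %s: invalid zygosity '%s'", fid,
                     var$zygosity[i]))
    abort_if(!var$segregation[i] %in% c("consistent", "inconsistent",
                                        "unavailable"),
             sprintf("family %s: invalid segregation '%s'", fid,
                     var$segregation[i]))
  }
  mafs <- as.matrix(var[, maf_columns(var)])
  bad <- which(rowSums(!is.na(mafs) & (mafs < 0 | mafs > 1)) > 0)
  abort_if(length(bad) > 0,
           sprintf("family %s: MAF outside [0, 1]", var$family_id[bad[1]]))
  invisible(x)
}
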