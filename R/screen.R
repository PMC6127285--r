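#' Configuration for record-level variant screening
#'
#' Thresholds of the quality-control and population-frequency screens applied
#' to every annotated small variant before prioritization: records with read
#' depth below `min_dp` (coverage < 20X) or strand bias above `max_fs`
#' (FisherStrand > 60.0) are discarded, and only variants with MAF below
#' `maf_threshold` in every database where they are observed remain. All
#' boundaries are strict as stated: DP = 20, FS = 60.0 are retained, a MAF
#' exactly at the threshold is rejected (the retain rule is `MAF <
#' threshold`).
#'
#' @param min_dp minimum read depth retained.
#' @param max_fs maximum Phred-scaled strand bias retained.
#' @param maf_threshold population-frequency cut; the conjunction runs over
#'   every database with an observation (absence passes).
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_dp = 20, max_fs = 60.0, maf_threshold = 0.015) {
  abort_if(min_dp <= 0 || max_fs <= 0 || maf_threshold <= 0,
           "screen thresholds must all be positive")
  structure(list(min_dp = min_dp, max_fs = max_fs,
                 maf_threshold = maf_threshold),
            class = "screen_config")
}

maf_columns <- function(x) grep("^maf_", names(x), value = TRUE)

#' Quality-control filter on depth and strand bias
#'
#' Retains records with `dp >= min_dp` and `fs <= max_fs`. A record with a
#' missing DP or FS is rejected with reason `"missing-qc"`, never silently
#' passed.
#'
#' @param records variant tibble with `dp` and `fs` columns.
#' @param config a [screen_config()].
#' @return List with `retained` and `rejected` tibbles; `rejected` carries a
#'   machine-readable `reason` column (`low-depth`, `strand-bias`,
#'   `missing-qc`).
#' @export
qc_filter <- function(records, config = screen_config()) {
  records <- tibble::as_tibble(records)
  abort_if(!all(c("dp", "fs") %in% names(records)),
           "records need dp and fs columns")
  missing_qc <- is.na(records$dp) | is.na(records$fs)
  low <- !missing_qc & records$dp < config$min_dp
  sb <- !missing_qc & !low & records$fs > config$max_fs
  reason <- rep(NA_character_, nrow(records))
  reason[missing_qc] <- "missing-qc"
  reason[low] <- "low-depth"
  reason[sb] <- "strand-bias"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Population minor-allele-frequency filter
#'
#' Retains a record iff its MAF is below the threshold in every database
#' where the variant is present (`maf_*` columns; `NA` means not observed and
#' passes). One high-frequency observation in any database disqualifies a
#' rare-disease allele.
#'
#' @param records variant tibble with `maf_*` columns.
#' @param config a [screen_config()].
#' @return List with `retained` and `rejected`; `rejected` gains `reason`
#'   (`common-allele`) and `offending_db`.
#' @export
maf_filter <- function(records, config = screen_config()) {
  records <- tibble::as_tibble(records)
  cols <- maf_columns(records)
  abort_if(length(cols) == 0L, "records carry no maf_* columns")
  m <- as.matrix(records[, cols])
  abort_if(any(m < 0 | m > 1, na.rm = TRUE),
           "MAF values must lie in [0, 1]")
  high <- !is.na(m) & m >= config$maf_threshold
  keep <- rowSums(high) == 0L
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "common-allele"
    rejected$offending_db <- apply(high[!keep, , drop = FALSE], 1, function(h)
      paste(sub("^maf_", "", cols[h]), collapse = ","))
  } else {
    rejected$reason <- character(0)
    rejected$offending_db <- character(0)
  }
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Run the full record-level screen (QC then MAF)
#'
#' The two filters are idempotent and order-independent; this helper applies
#' both and keeps every rejection with its reason.
#'
#' @param records variant tibble.
#' @param config a [screen_config()].
#' @return List with `retained` and `rejected`.
#' @export
screen_variants <- function(records, config = screen_config()) {
  qc <- qc_filter(records, config)
  mf <- maf_filter(qc$retained, config)
  rejected <- dplyr::bind_rows(qc$rejected, mf$rejected)
  list(retained = mf$retained, rejected = rejected)
}

#' Read/write annotated variant tables (VCF-lite TSV)
#'
#' Column layout: `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `hgvs_c`,
#' `hgvs_p`, `consequence`, `zygosity`, `dp`, `fs`, one `maf_*` column per
#' database (empty = not observed), optional splice-score columns, `db_label`,
#' `novel`, `segregation`.
#'
#' @param path TSV path.
#' @param x variant tibble (write).
#' @return Tibble (read) or `path` invisibly (write).
#' @export
read_variants_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_variants_tsv
#' @export
write_variants_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
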