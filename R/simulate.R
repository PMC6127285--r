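#' Simulation settings for one synthetic sequencing batch
#'
#' Captures the batch structure the cross-sample CNV method assumes: several
#' samples captured and sequenced together, with per-sample library-size
#' variation, interval-specific capture efficiency, and optional embedded
#' copy-number events.
#'
#' @param n_samples samples per batch; the ratio method needs at least 3.
#' @param mean_depth expected mean per-base depth in a diploid region.
#' @param library_size_sd relative (log-normal) spread of per-sample totals.
#' @param cnv_events tibble with columns `sample` (index), `first_interval`,
#'   `last_interval` (panel row indices) and `copy_number` (0, 1 or 3);
#'   `NULL` for none.
#' @param snp_density heterozygous SNPs per kb (used by allele-depth
#'   simulation helpers).
#' @param read_length nominal read length relating depth to interval read
#'   counts (`count ~ depth * length / read_length`).
#' @param seed integer seed; a fixed seed makes every simulated output
#'   byte-identical across runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 6L, mean_depth = 200, library_size_sd = 0.2,
                       cnv_events = NULL, snp_density = 1, read_length = 100,
                       seed = 1L) {
  abort_if(n_samples < 3L, "n_samples must be >= 3: the ratio method compares each sample against the rest of its batch")
  abort_if(mean_depth <= 0, "mean_depth must be positive")
  abort_if(library_size_sd < 0, "library_size_sd must be >= 0")
  if (!is.null(cnv_events)) {
    cnv_events <- tibble::as_tibble(cnv_events)
    need <- c("sample", "first_interval", "last_interval", "copy_number")
    abort_if(!all(need %in% names(cnv_events)),
             "cnv_events needs columns sample, first_interval, last_interval, copy_number")
    abort_if(!all(cnv_events$copy_number %in% c(0L, 1L, 3L)),
             "copy_number must be 0, 1 or 3")
    abort_if(any(cnv_events$sample < 1L | cnv_events$sample > n_samples),
             "cnv_event sample index outside the batch")
  }
  structure(list(n_samples = as.integer(n_samples), mean_depth = mean_depth,
                 library_size_sd = library_size_sd, cnv_events = cnv_events,
                 snp_density = snp_density, read_length = read_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an interval read-count matrix for one batch
#'
#' Counts are Poisson draws around `library_size_i * efficiency_j * length_j *
#' copy_number/2` (scaled by the nominal read length), the standard capture
#' model for threshold-based read-depth calling: expectation scales linearly
#' with copy number, per-sample totals vary log-normally, and interval capture
#' efficiency is shared across samples.
#'
#' @param design a [panel_design()].
#' @param config a [sim_config()]; `cnv_events` spans must lie inside the
#'   panel.
#' @return A `coverage_matrix`: list with `intervals` (the design), `counts`
#'   (integer matrix, intervals x samples), `truth` (the event table) and
#'   `batch_id`.
#' @export
simulate_coverage <- function(design, config = sim_config()) {
  stopifnot(inherits(design, "panel_design"), inherits(config, "sim_config"))
  n_int <- nrow(design)
  ev <- config$cnv_events
  if (!is.null(ev)) {
    abort_if(any(ev$first_interval < 1L | ev$last_interval > n_int |
                   ev$first_interval > ev$last_interval),
             "cnv_event span lies outside the panel intervals")
  }
  withr::with_seed(config$seed, {
    lib <- exp(stats::rnorm(config$n_samples, 0, config$library_size_sd))
    lib <- lib / mean(lib)
    base <- config$mean_depth * design$efficiency *
      (design$end - design$start) / config$read_length
    lambda <- outer(base, lib) # intervals x samples
    cn <- matrix(2, n_int, config$n_samples)
    if (!is.null(ev)) {
      for (k in seq_len(nrow(ev))) {
        cn[ev$first_interval[k]:ev$last_interval[k], ev$sample[k]] <-
          ev$copy_number[k]
      }
    }
    counts <- matrix(stats::rpois(length(lambda), lambda * cn / 2),
                     n_int, config$n_samples)
  })
  colnames(counts) <- sprintf("S%02d", seq_len(config$n_samples))
  structure(list(intervals = design, counts = counts,
                 truth = ev, expected_totals = colSums(lambda),
                 batch_id = sprintf("batch-seed%d", config$seed)),
            class = "coverage_matrix")
}

#' Simulate per-SNP allele depths inside a region of known copy number
#'
#' At copy number 2 the two haplotypes are balanced, so reads from the
#' designated (major) haplotype follow Binomial(depth, 1/2). In a tandem
#' three-copy duplication one haplotype carries two of the three copies, so
#' its reads follow Binomial(depth, 2/3) — the ~67:33 allele-ratio shift that
#' unmasks a heterozygous duplication at the SNPs it contains.
#'
#' @param region_copy_number 2 or 3.
#' @param n_snps number of heterozygous SNPs in the span.
#' @param total_depth total read depth per SNP.
#' @param seed integer seed.
#' @return Tibble with columns `snp`, `total_dp`, `major_dp`, `minor_dp`,
#'   `major_fraction`. `major_dp` counts reads from the multi-copy haplotype
#'   (an arbitrary designated haplotype at copy number 2).
#' @export
simulate_allele_depths <- function(region_copy_number, n_snps, total_depth,
                                   seed = 1L) {
  abort_if(!region_copy_number %in% c(2L, 3L),
           "region_copy_number must be 2 or 3 (no allele-ratio shift is defined for other states)")
  abort_if(total_depth <= 0, "total_depth must be positive")
  p <- if (region_copy_number == 3L) 2 / 3 else 1 / 2
  withr::with_seed(seed, {
    major <- stats::rbinom(n_snps, total_depth, p)
  })
  tibble::tibble(
    snp = seq_len(n_snps),
    total_dp = as.integer(total_depth),
    major_dp = major,
    minor_dp = as.integer(total_depth) - major,
    major_fraction = major / total_depth
  )
}

#' Simulate an annotated variant table
#'
#' Emulates the post-calling annotated variant list of one panel-sequenced
#' sample: a MAF spectrum dominated by common polymorphisms with a configurable
#' rare fraction, plus depth (DP) and strand-bias (FS) fields. Approximately
#' `rare_fraction` of the records have maximum database MAF < `maf_threshold`
#' (or are absent from every database, as novel variants are).
#'
#' @param n_variants number of records.
#' @param rare_fraction proportion in `[0, 1]` of records below the screening
#'   threshold in every database.
#' @param seed integer seed.
#' @param maf_threshold the screening threshold the spectrum is built around.
#' @return Tibble in the VCF-lite layout used across the package (see
#'   [read_variants_tsv()]).
#' @export
simulate_variant_table <- function(n_variants, rare_fraction, seed = 1L,
                                   maf_threshold = 0.015) {
  abort_if(rare_fraction < 0 || rare_fraction > 1,
           "rare_fraction must lie in [0, 1]")
  dbs <- c("maf_1000g", "maf_evs", "maf_exac", "maf_gnomad", "maf_dbsnp",
           "maf_csvs")
  if (n_variants == 0L) {
    return(empty_variant_table())
  }
  withr::with_seed(seed, {
    rare <- stats::runif(n_variants) < rare_fraction
    maf <- matrix(NA_real_, n_variants, length(dbs),
                  dimnames = list(NULL, dbs))
    for (j in seq_along(dbs)) {
      seen <- stats::runif(n_variants) < 0.8
      common_maf <- maf_threshold +
        (0.5 - maf_threshold) * stats::rbeta(n_variants, 0.8, 3)
      rare_maf <- maf_threshold * stats::rbeta(n_variants, 0.5, 5)
      maf[, j] <- ifelse(rare, rare_maf, common_maf)
      maf[!seen, j] <- NA_real_
    }
    # a slice of rare variants is fully novel: absent everywhere
    novel <- rare & stats::runif(n_variants) < 0.2
    maf[novel, ] <- NA_real_
    # common variants must be observed in at least one database
    unseen <- !rare & rowSums(!is.na(maf)) == 0L
    if (any(unseen)) {
      maf[unseen, 1] <- maf_threshold +
        (0.5 - maf_threshold) * stats::rbeta(sum(unseen), 0.8, 3)
    }
    cons <- sample(c("missense", "synonymous-splice", "intronic-splicing",
                     "deep-intronic", "nonsense", "frameshift", "other"),
                   n_variants, replace = TRUE,
                   prob = c(0.25, 0.05, 0.05, 0.35, 0.02, 0.03, 0.25))
    out <- tibble::tibble(
      chrom = sample(c("chr1", "chr2", "chr12"), n_variants, replace = TRUE),
      pos = sample.int(2e8, n_variants, replace = TRUE),
      ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      gene = sample(c("USH2A", "ABCA4", "CEP290", "EYS", "CRB1"),
                    n_variants, replace = TRUE),
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      consequence = cons,
      zygosity = sample(c("het", "hom"), n_variants, replace = TRUE,
                        prob = c(0.9, 0.1)),
      dp = stats::rpois(n_variants, 180) + 1L,
      fs = round(stats::rexp(n_variants, 1 / 8), 3)
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(maf))
    out$db_label <- ifelse(novel, "absent", "VUS")
    out$novel <- novel
    out$segregation <- "unavailable"
  })
  out
}

empty_variant_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), hgvs_c = character(), hgvs_p = character(),
    consequence = character(), zygosity = character(),
    dp = integer(), fs = numeric(),
    maf_1000g = numeric(), maf_evs = numeric(), maf_exac = numeric(),
    maf_gnomad = numeric(), maf_dbsnp = numeric(), maf_csvs = numeric(),
    db_label = character(), novel = logical(), segregation = character()
  )
}
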