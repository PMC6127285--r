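#' Configuration for the read-depth CNV caller
#'
#' Dosage-ratio thresholds: an interval ratio around 1 implies normal (diploid)
#' dosage, a ratio below `theta_del` flags a deletion and above `theta_dup` a
#' duplication (both strict inequalities — a ratio exactly equal to a
#' threshold is not a call). Zygosity is banded on the run mean ratio around
#' the expected dosages 0, 0.5 and 1.5.
#'
#' @param theta_del deletion threshold (ratio strictly below calls).
#' @param theta_dup duplication threshold (ratio strictly above calls).
#' @param hom_del_max upper bound of the homozygous-deletion band.
#' @param het_del_band heterozygous-deletion band `[lo, hi)` on the mean ratio.
#' @param het_dup_band heterozygous-duplication (three-copy) band `(lo, hi]`.
#' @param min_intervals minimum flagged intervals per call; shorter runs are
#'   dropped as single-interval capture noise.
#' @param max_gap unflagged intervals tolerated inside a run
#'   (capture-efficiency dropouts).
#' @param min_reference_count intervals whose cross-sample reference falls
#'   below this count are flagged uncallable rather than divided.
#' @param refine_window `w`: bases a breakpoint-refinement threshold crossing
#'   must be sustained for (also the running-median smoothing span).
#' @return A `cnv_config` list.
#' @export
cnv_config <- function(theta_del = 0.6, theta_dup = 1.40,
                       hom_del_max = 0.10, het_del_band = c(0.35, 0.60),
                       het_dup_band = c(1.40, 1.65),
                       min_intervals = 2L, max_gap = 1L,
                       min_reference_count = 50, refine_window = 50L) {
  abort_if(!(theta_del > 0 && theta_del < 1 && theta_dup > 1),
           "need 0 < theta_del < 1 < theta_dup")
  abort_if(min_intervals < 1L, "min_intervals must be >= 1")
  structure(list(theta_del = theta_del, theta_dup = theta_dup,
                 hom_del_max = hom_del_max, het_del_band = het_del_band,
                 het_dup_band = het_dup_band,
                 min_intervals = as.integer(min_intervals),
                 max_gap = as.integer(max_gap),
                 min_reference_count = min_reference_count,
                 refine_window = as.integer(refine_window)),
            class = "cnv_config")
}

#' Normalize a coverage matrix into cross-sample dosage ratios
#'
#' Each sample's counts are rescaled so its total equals the batch mean total
#' (library-size normalization by the average number of reads per sample);
#' each rescaled count is then divided by a per-interval reference: the
#' leave-one-out median of the other samples' rescaled counts. The median
#' resists a CNV-carrying neighbour contaminating the reference. Intervals
#' whose reference falls below `min_reference_count` are flagged uncallable
#' (ratio `NA`), never divided.
#'
#' @param cov a `coverage_matrix` (see [simulate_coverage()] or
#'   [read_counts_tsv()]).
#' @param config a [cnv_config()].
#' @return A `ratio_matrix`: list with `intervals`, `ratios` (matrix, `NA`
#'   where uncallable), `reference` (leave-one-out medians), `callable`
#'   (logical matrix) and `normalization_factors`.
#' @export
normalize_counts <- function(cov, config = cnv_config()) {
  stopifnot(inherits(cov, "coverage_matrix"))
  counts <- cov$counts
  n_samples <- ncol(counts)
  abort_if(n_samples < 3L,
           "cross-sample normalization needs a batch of at least 3 samples")
  totals <- colSums(counts)
  abort_if(any(totals == 0),
           paste0("degenerate sample with zero total reads: ",
                  paste(colnames(counts)[totals == 0], collapse = ", ")))
  factors <- mean(totals) / totals
  rescaled <- sweep(counts, 2, factors, `*`)
  reference <- matrix(NA_real_, nrow(counts), n_samples,
                      dimnames = dimnames(counts))
  for (s in seq_len(n_samples)) {
    reference[, s] <- apply(rescaled[, -s, drop = FALSE], 1, stats::median)
  }
  callable <- reference >= config$min_reference_count
  ratios <- ifelse(callable, rescaled / reference, NA_real_)
  structure(list(intervals = cov$intervals, ratios = ratios,
                 reference = reference, callable = callable,
                 normalization_factors = factors, batch_id = cov$batch_id),
            class = "ratio_matrix")
}

#' Classify one ratio against the calling thresholds
#'
#' The per-interval rule applied before any merging: strictly below
#' `theta_del` is a deletion, strictly above `theta_dup` a duplication,
#' anything else (including uncallable `NA`) normal.
#'
#' @param ratio numeric vector of dosage ratios.
#' @param config a [cnv_config()].
#' @return Character vector `"del"`, `"dup"` or `"normal"`.
#' @export
classify_ratio <- function(ratio, config = cnv_config()) {
  out <- rep("normal", length(ratio))
  out[!is.na(ratio) & ratio < config$theta_del] <- "del"
  out[!is.na(ratio) & ratio > config$theta_dup] <- "dup"
  out
}

cnv_zygosity <- function(direction, mean_ratio, config) {
  if (direction == "del") {
    if (mean_ratio <= config$hom_del_max) return("homozygous")
    if (mean_ratio >= config$het_del_band[1] &&
        mean_ratio < config$het_del_band[2]) return("heterozygous")
    return("undetermined")
  }
  if (mean_ratio > config$het_dup_band[1] &&
      mean_ratio <= config$het_dup_band[2]) return("heterozygous")
  "undetermined"
}

#' Call copy-number variants from a ratio matrix
#'
#' Per sample, callable intervals are classified with [classify_ratio()];
#' runs of same-direction flagged intervals on one chromosome are merged,
#' tolerating up to `max_gap` unflagged intervals inside a run; runs with
#' fewer than `min_intervals` flagged intervals are dropped. Zygosity is
#' banded on the mean ratio over the flagged intervals: deletions at or below
#' `hom_del_max` are homozygous, within the heterozygous band a single-copy
#' loss; duplications inside `het_dup_band` are heterozygous three-copy
#' gains; anything else is undetermined. An empty call set is a valid result.
#'
#' @param rm a `ratio_matrix` from [normalize_counts()].
#' @param config a [cnv_config()].
#' @return Tibble of calls: `sample`, `chrom`, `start`, `end` (1-based
#'   inclusive genomic span of the flagged intervals), `first_interval`,
#'   `last_interval`, `direction` (`"deletion"`/`"duplication"`),
#'   `mean_ratio`, `zygosity`, `n_intervals`, `refined`,
#'   `refined_left`, `refined_right`, `note`. Calls within a sample are
#'   sorted and pairwise non-overlapping.
#' @export
call_cnv_intervals <- function(rm, config = cnv_config()) {
  stopifnot(inherits(rm, "ratio_matrix"))
  iv <- rm$intervals
  out <- list()
  for (s in colnames(rm$ratios)) {
    cls <- classify_ratio(rm$ratios[, s], config)
    for (dir in c("del", "dup")) {
      idx <- which(cls == dir)
      if (length(idx) == 0L) next
      same_chr <- iv$chrom[idx]
      run_id <- cumsum(c(1L, (diff(idx) - 1L > config$max_gap) |
                           (same_chr[-1] != same_chr[-length(same_chr)])))
      for (r in split(idx, run_id)) {
        if (length(r) < config$min_intervals) next
        mr <- mean(rm$ratios[r, s])
        out[[length(out) + 1L]] <- tibble::tibble(
          sample = s, chrom = iv$chrom[r[1]],
          start = iv$start[r[1]] + 1L, end = iv$end[r[length(r)]],
          first_interval = r[1], last_interval = r[length(r)],
          direction = if (dir == "del") "deletion" else "duplication",
          mean_ratio = mr,
          zygosity = cnv_zygosity(dir, mr, config),
          n_intervals = length(r), refined = FALSE,
          refined_left = NA_integer_, refined_right = NA_integer_,
          note = NA_character_
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      sample = character(), chrom = character(), start = integer(),
      end = integer(), first_interval = integer(), last_interval = integer(),
      direction = character(), mean_ratio = numeric(), zygosity = character(),
      n_intervals = integer(), refined = logical(),
      refined_left = integer(), refined_right = integer(), note = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), sample, chrom, start)
}

#' Write and read interval count matrices as TSV
#'
#' Layout: interval key columns (`chrom`, `start`, `end`, `gene`, `class`,
#' `efficiency`) followed by one integer column per sample.
#'
#' @param cov a `coverage_matrix`.
#' @param path file path.
#' @return `path` (write) or a `coverage_matrix` (read).
#' @export
write_counts_tsv <- function(cov, path) {
  x <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(cov$intervals)),
                        tibble::as_tibble(cov$counts))
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param batch_id batch label for the read matrix.
#' @export
read_counts_tsv <- function(path, batch_id = basename(path)) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  key <- c("chrom", "start", "end", "gene", "class", "efficiency")
  design <- panel_design(x$chrom, x$start, x$end, x$gene, x$class,
                         x$efficiency)
  counts <- as.matrix(x[, setdiff(names(x), key), drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(intervals = design, counts = counts, truth = NULL,
                 batch_id = batch_id),
            class = "coverage_matrix")
}
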