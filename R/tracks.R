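#' Synthetic per-base coverage profiles for the two USH2A CNV worked examples
#'
#' Reconstructs, as clean synthetic dosage profiles, the base-resolution
#' evidence behind the two USH2A structural alleles of the cohort: the
#' homozygous deletion of exons 22-55 in family R
#' (chr1:g.215,949,321_216,272,841del, hg19) and the heterozygous tandem
#' duplication of exons 46-47 in family P
#' (chr1:g.216,005,789_216,019,066dup, hg19). The carrier track is the
#' diploid reference profile scaled by copy number / 2 over the event span
#' (0 for the homozygous deletion, 1.5 for the heterozygous duplication),
#' optionally with Poisson sampling noise. No sequencing data underlie these
#' tracks; they are synthetic reconstructions of the published breakpoints
#' used to exercise the caller and refiner end to end.
#'
#' @param family `"R"` (homozygous deletion) or `"P"` (heterozygous
#'   duplication).
#' @param depth diploid per-base depth of the reference profile.
#' @param noise if `TRUE`, Poisson-disperse both tracks (seeded); if `FALSE`
#'   (default) the tracks are noise-free step functions.
#' @param seed seed used when `noise = TRUE`.
#' @param n_ballast diploid 1 kb intervals added outside the USH2A window so
#'   that, as in the full capture design, the event is a small fraction of
#'   the panel and library-size normalization is not confounded by the event
#'   itself.
#' @return List with `sample` and `reference` [coverage_track()]s, the
#'   1 kb tiling `panel` over the window (plus ballast), a batch
#'   `coverage_matrix` (carrier plus five diploid samples), and the true
#'   `span` (1-based inclusive).
#' @export
family_cnv_profiles <- function(family = c("R", "P"), depth = 100,
                                noise = FALSE, seed = 1L,
                                n_ballast = 3300L) {
  family <- match.arg(family)
  win_lo <- 215945001L
  win_hi <- 216277000L
  span <- if (family == "R") c(215949321L, 216272841L)
          else c(216005789L, 216019066L)
  cn <- if (family == "R") 0 else 3
  n <- win_hi - win_lo + 1L
  pos <- seq(win_lo, win_hi)
  ref <- rep(depth, n)
  sam <- ref * ifelse(pos >= span[1] & pos <= span[2], cn / 2, 1)
  if (noise) {
    withr::with_seed(seed, {
      sam <- stats::rpois(n, sam)
      ref <- stats::rpois(n, ref)
    })
  }
  # 1 kb panel tiles over the window, for the interval-level call, plus
  # diploid ballast elsewhere on the panel
  tile <- 1000L
  starts <- seq(win_lo - 1L, win_hi - tile, by = tile)
  bstarts <- seq(10000000L, by = tile, length.out = n_ballast)
  panel <- panel_design(c(rep("chr1", length(starts)),
                          rep("chr2", n_ballast)),
                        c(starts, bstarts), c(starts, bstarts) + tile,
                        c(rep("USH2A", length(starts)),
                          rep("BALLAST", n_ballast)),
                        "whole-gene-tile")
  cum <- c(0, cumsum(sam))
  cum_ref <- c(0, cumsum(ref))
  win_tiles <- panel$gene == "USH2A"
  idx_lo <- panel$start[win_tiles] - win_lo + 2L  # 1-based offset, first base
  idx_hi <- panel$end[win_tiles] - win_lo + 1L
  carrier_counts <- (cum[idx_hi + 1L] - cum[idx_lo]) / 100
  diploid_counts <- (cum_ref[idx_hi + 1L] - cum_ref[idx_lo]) / 100
  ballast_count <- depth * tile / 100
  counts <- cbind(c(round(carrier_counts), rep(ballast_count, n_ballast)),
                  matrix(c(round(diploid_counts),
                           rep(ballast_count, n_ballast)), nrow(panel), 5))
  storage.mode(counts) <- "integer"
  colnames(counts) <- c("carrier", paste0("ctrl", 1:5))
  cov <- structure(list(intervals = panel, counts = counts, truth = NULL,
                        batch_id = paste0("family-", family)),
                   class = "coverage_matrix")
  list(sample = coverage_track("chr1", win_lo, sam),
       reference = coverage_track("chr1", win_lo, ref),
       panel = panel, coverage = cov, span = span,
       expected_zygosity = if (family == "R") "homozygous" else "heterozygous")
}
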