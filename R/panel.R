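#' Construct a capture-panel design
#'
#' A panel design is the ordered set of targeted genomic intervals of a
#' capture experiment, each tagged with the gene it belongs to, a region
#' class, and a relative capture efficiency. Intervals use BED conventions
#' internally: 0-based, half-open `[start, end)`.
#'
#' @param chrom character chromosome per interval.
#' @param start,end integer BED coordinates (0-based half-open); `end > start`.
#' @param gene gene symbol per interval.
#' @param class region class, `"coding-exon"` or `"whole-gene-tile"`.
#' @param efficiency positive relative capture efficiency per interval
#'   (defaults to 1; rescaled to mean 1).
#' @param build reference build label (annotation only).
#' @return A `panel_design`: a tibble with columns `chrom`, `start`, `end`,
#'   `gene`, `class`, `efficiency` sorted within chromosome, plus a `build`
#'   attribute.
#' @export
panel_design <- function(chrom, start, end, gene, class = "coding-exon",
                         efficiency = 1, build = "hg19") {
  n <- length(chrom)
  abort_if(n == 0L, "panel design needs at least one interval")
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    gene = as.character(rep_len(gene, n)),
    class = as.character(rep_len(class, n)),
    efficiency = as.numeric(rep_len(efficiency, n))
  )
  abort_if(any(x$end <= x$start), "every interval must satisfy end > start")
  abort_if(any(x$efficiency <= 0), "capture efficiencies must all be > 0")
  abort_if(!all(x$class %in% c("coding-exon", "whole-gene-tile")),
           "region class must be 'coding-exon' or 'whole-gene-tile'")
  x <- dplyr::arrange(x, chrom, start)
  # non-overlap within chromosome
  by_chr <- split(x, x$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1L && any(ch$start[-1] < ch$end[-nrow(ch)])) {
      stop("panel intervals overlap on chromosome ", ch$chrom[1], call. = FALSE)
    }
  }
  x$efficiency <- x$efficiency / mean(x$efficiency)
  structure(x, class = c("panel_design", class(x)), build = build)
}

#' Read a panel design from an extended BED file
#'
#' Expects the standard three BED columns followed by `gene`, `class` and
#' optionally `efficiency`.
#'
#' @param path path to a tab-separated BED file (no header).
#' @param build reference build label.
#' @return A [panel_design()].
#' @export
read_panel_bed <- function(path, build = "hg19") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "gene",
                                       "class", "efficiency")[1:min(6,
                           ncol(utils::read.table(path, sep = "\t", nrows = 1)))],
                         stringsAsFactors = FALSE)
  if (is.null(x$efficiency)) x$efficiency <- 1
  panel_design(x$chrom, x$start, x$end, x$gene, x$class, x$efficiency,
               build = build)
}

#' Write a panel design as an extended BED file
#'
#' @param design a [panel_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Miniature IRD panel used by the examples and simulations
#'
#' A scaled-down stand-in for a targeted IRD capture design: whole-gene tiles
#' (100 bp) across a window of the USH2A locus plus a handful of coding-exon
#' intervals for other IRD genes. The full published-panel interval list is
#' not public, so this miniature carries the same structure (whole-gene tiling
#' of a large recessive gene, scattered exons elsewhere) at a testable size.
#'
#' @param tile_bp tile width for the whole-gene region.
#' @param gene_start,gene_end BED bounds of the tiled USH2A window (hg19-like
#'   coordinates).
#' @return A [panel_design()].
#' @export
example_panel <- function(tile_bp = 100L,
                          gene_start = 215960000L, gene_end = 215966000L) {
  starts <- seq(gene_start, gene_end - tile_bp, by = tile_bp)
  tiles <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + tile_bp, gene = "USH2A",
                          class = "whole-gene-tile")
  exons <- tibble::tibble(
    chrom = c(rep("chr1", 4), rep("chr12", 3), rep("chr8", 2), "chr4"),
    start = c(94458000L, 94466000L, 94473000L, 94484000L,
              88442000L, 88471000L, 88502000L,
              87600000L, 87655000L, 155665000L),
    end = c(94458240L, 94466180L, 94473150L, 94484220L,
            88442210L, 88471160L, 88502190L,
            87600200L, 87655180L, 155665210L),
    gene = c(rep("ABCA4", 4), rep("CEP290", 3), rep("CNGB3", 2), "LRAT"),
    class = "coding-exon"
  )
  x <- dplyr::bind_rows(tiles, exons)
  panel_design(x$chrom, x$start, x$end, x$gene, x$class)
}
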