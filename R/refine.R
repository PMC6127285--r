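#' Per-base coverage track
#'
#' A dense depth profile over one contiguous genomic window, the
#' base-resolution evidence that whole-gene capture provides for breakpoint
#' determination.
#'
#' @param chrom chromosome.
#' @param start 1-based genomic position of the first value.
#' @param depth numeric vector of per-base depths.
#' @return A `coverage_track` list.
#' @export
coverage_track <- function(chrom, start, depth) {
  abort_if(length(depth) == 0L, "empty coverage track")
  structure(list(chrom = chrom, start = as.integer(start),
                 depth = as.numeric(depth)),
            class = "coverage_track")
}

track_positions <- function(track) {
  seq(track$start, length.out = length(track$depth))
}

#' Read/write a coverage track as bedGraph
#'
#' Uses rtracklayer for the format itself; the track must cover one
#' contiguous window of a single chromosome (uncovered bases load as depth 0).
#'
#' @param path bedGraph path.
#' @param track a [coverage_track()].
#' @return A `coverage_track` (read) or `path` invisibly (write).
#' @export
read_bedgraph_track <- function(path) {
  abort_if(!requireNamespace("rtracklayer", quietly = TRUE),
           "reading bedGraph requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "bedGraph"))
  abort_if(nrow(gr) == 0L, "empty bedGraph")
  lo <- min(gr$start)
  hi <- max(gr$end)
  depth <- numeric(hi - lo + 1L)
  for (i in seq_len(nrow(gr))) {
    depth[(gr$start[i]:gr$end[i]) - lo + 1L] <- gr$score[i]
  }
  coverage_track(as.character(gr$seqnames[1]), lo, depth)
}

#' @rdname read_bedgraph_track
#' @export
write_bedgraph_track <- function(track, path) {
  abort_if(!requireNamespace("rtracklayer", quietly = TRUE) ||
             !requireNamespace("GenomicRanges", quietly = TRUE),
           "writing bedGraph requires the rtracklayer package")
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + starts - 1L,
                                                track$start + ends - 1L),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Refine CNV breakpoints to base resolution
#'
#' Whole-gene (intronic) capture yields contiguous per-base coverage, so the
#' boundaries of a dosage change can be read off the depth profile directly.
#' The sample/reference per-base depth ratio is smoothed with a running median
#' (span `refine_window`, odd-rounded) and scanned over the call span plus a
#' flank: the refined left breakpoint is the first base, scanning rightward,
#' where the smoothed ratio crosses the call's direction threshold and stays
#' crossed for at least `refine_window` bases; the right breakpoint is
#' symmetric. Coordinates are reported 1-based inclusive, first to last
#' affected base. If no sustained crossing exists the call is returned
#' unrefined with a warning note.
#'
#' @param call one-row tibble from [call_cnv_intervals()].
#' @param sample_track [coverage_track()] for the carrier over the call
#'   region.
#' @param reference_track matched diploid-reference track (same window).
#' @param config a [cnv_config()].
#' @param flank bases searched beyond the interval-level span on each side.
#' @return The call row with `refined`, `refined_left`, `refined_right`
#'   updated.
#' @export
refine_breakpoints <- function(call, sample_track, reference_track,
                               config = cnv_config(), flank = 5000L) {
  stopifnot(nrow(call) == 1L, inherits(sample_track, "coverage_track"),
            inherits(reference_track, "coverage_track"))
  abort_if(sample_track$chrom != call$chrom,
           "coverage track chromosome does not match the call")
  abort_if(sample_track$start != reference_track$start ||
             length(sample_track$depth) != length(reference_track$depth),
           "sample and reference tracks must cover the same window")
  pos <- track_positions(sample_track)
  ratio <- ifelse(reference_track$depth > 0,
                  sample_track$depth / reference_track$depth, NA_real_)
  k <- 2L * (config$refine_window %/% 2L) + 1L
  smooth <- ratio
  ok <- !is.na(ratio)
  if (sum(ok) >= k) smooth[ok] <- stats::runmed(ratio[ok], k)
  crossed <- if (call$direction == "deletion") {
    !is.na(smooth) & smooth < config$theta_del
  } else {
    !is.na(smooth) & smooth > config$theta_dup
  }
  lo <- max(min(pos), call$start - flank)
  hi <- min(max(pos), call$end + flank)
  in_win <- pos >= lo & pos <= hi
  r <- rle(crossed & in_win)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  sustained <- which(r$values & r$lengths >= config$refine_window)
  if (length(sustained) == 0L) {
    call$note <- "no sustained threshold crossing; breakpoints unrefined"
    return(call)
  }
  call$refined_left <- pos[run_start[sustained[1]]]
  call$refined_right <- pos[run_end[sustained[length(sustained)]]]
  call$refined <- TRUE
  call
}
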