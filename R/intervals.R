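# Internal interval helpers. Coordinates are 0-based half-open throughout;
# GRanges conversion shifts start by +1 and back.

#' Convert a 0-based half-open interval data frame to GRanges
#' @param x data.frame with columns chrom, start, end (0-based half-open) and
#'   optionally strand
#' @return a `GRanges` (1-based closed, as GRanges requires)
#' @keywords internal
#' @noRd
intervals_to_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Convert GRanges back to a 0-based half-open data frame
#' @keywords internal
#' @noRd
gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  if (any(!nzchar(x$chrom))) stop("empty chromosome name")
  invisible(x)
}

interval_midpoints <- function(x) {
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}
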