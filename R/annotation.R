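# Region-gene annotation: nearest-TSS assignment within a 50 kb window,
# context classification relative to gene boundaries, top-N selection, and
# permutation enrichment of regions in labelled annotation classes
# (e.g. repeat families).

#' Annotate regions to the nearest TSS within a window
#'
#' Each region is assigned to the gene whose TSS is nearest to the region
#' midpoint, provided the distance is at most `tss_window_bp` (a window of
#' twice that, centered on the TSS). One gene per region; regions with no TSS
#' in range get `gene_id = NA`. Equidistant TSSs are broken by ascending
#' (chrom, gene start, gene_id).
#'
#' @param regions data.frame with `chrom`, `start`, `end` (and any further
#'   columns, e.g. a `differential_regions` table)
#' @param genes gene model table from [gene_models()]
#' @param tss_window_bp maximum midpoint-to-TSS distance (default 50000)
#' @return `regions` with `gene_id`, `distance_to_tss` (signed bp on the gene
#'   strand; negative = upstream of the TSS) appended
#' @export
annotate_to_tss <- function(regions, genes, tss_window_bp = 50000L) {
  stopifnot(is.data.frame(regions), is.data.frame(genes))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be distinct")
  out <- as.data.frame(regions)
  out$gene_id <- rep(NA_character_, nrow(out))
  out$distance_to_tss <- rep(NA_real_, nrow(out))
  if (!nrow(out) || !nrow(genes)) return(out)
  mid <- interval_midpoints(out)
  # deterministic candidate order for tie-breaks
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  for (ch in unique(out$chrom)) {
    ri <- which(out$chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    tss <- g$tss[gi]
    o <- order(tss)
    tss_s <- tss[o]
    # nearest sorted TSS: candidate below and above the midpoint
    pos <- findInterval(mid[ri], tss_s)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tss_s))
    d_lo <- abs(mid[ri] - tss_s[lo]); d_hi <- abs(mid[ri] - tss_s[hi])
    d_lo[pos < 1] <- Inf
    pick <- ifelse(d_hi < d_lo, hi, lo)  # ties -> lower TSS coordinate
    # genes sharing the winning TSS coordinate: first in (start, gene_id)
    # candidate order wins (order() is stable)
    pick <- match(tss_s[pick], tss_s)
    best <- gi[o][pick]
    dist <- abs(mid[ri] - g$tss[best])
    ok <- dist <= tss_window_bp
    signed <- ifelse(g$strand[best] == "+", mid[ri] - g$tss[best],
                     g$tss[best] - mid[ri])
    out$gene_id[ri[ok]] <- g$gene_id[best[ok]]
    out$distance_to_tss[ri[ok]] <- signed[ok]
  }
  out
}

#' Annotate regions to the gene body containing their midpoint
#'
#' Companion to [annotate_to_tss()] for intragenic analyses (gene-body DHR
#' density, bidirectional detection), where relevant regions can lie far
#' beyond any TSS window inside long genes. Gene bodies are non-overlapping
#' by construction of the simulator; with overlapping real gene models the
#' (chrom, start, gene_id) earliest gene wins.
#'
#' @inheritParams annotate_to_tss
#' @return `regions` with `gene_id` (NA when the midpoint is in no gene body)
#' @export
annotate_intragenic <- function(regions, genes) {
  out <- as.data.frame(regions)
  out$gene_id <- rep(NA_character_, nrow(out))
  if (!nrow(out) || !nrow(genes)) return(out)
  mid <- interval_midpoints(out)
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  mg <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  gg <- intervals_to_gr(g)
  GenomicRanges::strand(gg) <- "*"
  hit <- GenomicRanges::findOverlaps(mg, gg, select = "first")
  ok <- !is.na(hit)
  out$gene_id[ok] <- g$gene_id[hit[ok]]
  out
}

#' Classify regions relative to gene boundaries
#'
#' Exclusive label with precedence `tss_proximal` > `intragenic` > `boundary`
#' > `intergenic`: a region is TSS-proximal if its midpoint lies within
#' `proximity_bp` of any TSS; else intragenic if its midpoint falls inside a
#' gene body; else boundary if the region overlaps a gene edge (a gene start
#' or end falls inside the region); else intergenic. Boolean flags for each
#' class are returned alongside, since the classes genuinely overlap.
#'
#' @inheritParams annotate_to_tss
#' @param proximity_bp TSS proximity radius (default 25000)
#' @return `regions` with `context` plus logical `is_tss_proximal`,
#'   `is_intragenic`, `is_boundary` columns
#' @export
classify_context <- function(regions, genes, proximity_bp = 25000L) {
  out <- as.data.frame(regions)
  n <- nrow(out)
  if (!n) {
    out$context <- character(0)
    out$is_tss_proximal <- out$is_intragenic <- out$is_boundary <- logical(0)
    return(out)
  }
  mid <- interval_midpoints(out)
  is_prox <- logical(n); is_intra <- logical(n); is_bound <- logical(n)
  for (ch in unique(out$chrom)) {
    ri <- which(out$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    tss <- sort(genes$tss[gi])
    pos <- findInterval(mid[ri], tss)
    d_lo <- ifelse(pos >= 1, mid[ri] - tss[pmax(pos, 1L)], Inf)
    d_hi <- ifelse(pos < length(tss), tss[pmin(pos + 1L, length(tss))] - mid[ri], Inf)
    is_prox[ri] <- pmin(d_lo, d_hi) <= proximity_bp
    mg <- GenomicRanges::GRanges(ch, IRanges::IRanges(mid[ri] + 1L, width = 1L))
    gg <- intervals_to_gr(genes[gi, ])
    GenomicRanges::strand(gg) <- "*"
    is_intra[ri] <- GenomicRanges::countOverlaps(mg, gg) > 0
    edges <- c(genes$start[gi], genes$end[gi] - 1L)
    cnt <- vapply(seq_along(ri), function(k) {
      any(edges >= out$start[ri[k]] & edges < out$end[ri[k]])
    }, logical(1))
    is_bound[ri] <- cnt
  }
  out$context <- ifelse(is_prox, "tss_proximal",
                 ifelse(is_intra, "intragenic",
                 ifelse(is_bound, "boundary", "intergenic")))
  out$is_tss_proximal <- is_prox
  out$is_intragenic <- is_intra
  out$is_boundary <- is_bound
  out
}

#' Select the top differential regions
#'
#' Filter to `q < q_threshold`, rank by ascending p, truncate to `n`. Rank
#' ties are broken by ascending (chrom, start) so the selection is
#' deterministic.
#'
#' @param regions `differential_regions` data.frame with `p` and `q`
#' @param n maximum regions to keep (default 2000)
#' @param q_threshold FDR threshold (default 0.01)
#' @export
select_top_regions <- function(regions, n = 2000L, q_threshold = 0.01) {
  stopifnot(all(c("p", "q") %in% names(regions)))
  keep <- regions[regions$q < q_threshold, , drop = FALSE]
  keep <- keep[order(keep$p, keep$chrom, keep$start), , drop = FALSE]
  head(keep, n)
}

#' Permutation enrichment of regions in annotation classes
#'
#' For each labelled class of intervals (e.g. a repeat family), the observed
#' fraction of region base pairs overlapping the class is compared against a
#' null in which each region is re-placed uniformly on its own chromosome
#' with its length preserved. Fold = observed / mean(null); the p-value is
#' the two-sided empirical tail with add-one correction.
#'
#' @param regions data.frame of regions (non-empty)
#' @param classes named list of interval data.frames (`chrom`, `start`, `end`)
#' @param genome named vector of chromosome lengths
#' @param n_permutations number of random placements (default 200)
#' @param seed RNG seed
#' @return data.frame with one row per class: `class`, `observed_fraction`,
#'   `expected_fraction`, `fold`, `p`
#' @export
class_enrichment <- function(regions, classes, genome, n_permutations = 200L,
                             seed = 1L) {
  if (!nrow(regions)) stop("empty region list: enrichment undefined")
  stopifnot(length(classes) >= 1, !is.null(names(classes)))
  widths <- vapply(classes, function(cl) sum(cl$end - cl$start), numeric(1))
  if (any(widths <= 0)) stop("zero-length annotation class")
  # per class and chromosome: merged intervals with cumulative coverage, so
  # region/class overlap reduces to two findInterval lookups per region
  cls_idx <- lapply(classes, function(cl) {
    gr <- intervals_to_gr(cl); GenomicRanges::strand(gr) <- "*"
    m <- gr_to_intervals(GenomicRanges::reduce(gr))
    lapply(split(m, m$chrom), function(d) {
      d <- d[order(d$start), ]
      list(start = d$start, end = d$end, cum = cumsum(d$end - d$start))
    })
  })
  # covered bp of the class below coordinate x
  cov_below <- function(idx, x) {
    i <- findInterval(x, idx$start)
    out <- numeric(length(x))
    pos <- i > 0
    out[pos] <- idx$cum[i[pos]] - pmax(idx$end[i[pos]] - x[pos], 0)
    out
  }
  overlap_frac <- function(reg_df) {
    tot <- sum(reg_df$end - reg_df$start)
    vapply(cls_idx, function(by_chrom) {
      ov <- 0
      for (ch in unique(reg_df$chrom)) {
        idx <- by_chrom[[ch]]
        if (is.null(idx)) next
        sel <- reg_df$chrom == ch
        ov <- ov + sum(cov_below(idx, reg_df$end[sel]) -
                       cov_below(idx, reg_df$start[sel]))
      }
      ov / tot
    }, numeric(1))
  }
  obs <- overlap_frac(regions)
  set.seed(as.integer(seed))
  lens <- regions$end - regions$start
  chrom_len <- genome[regions$chrom]
  null <- matrix(NA_real_, n_permutations, length(classes))
  for (b in seq_len(n_permutations)) {
    st <- floor(runif(nrow(regions), 0, pmax(chrom_len - lens, 1)))
    null[b, ] <- overlap_frac(data.frame(chrom = regions$chrom, start = st,
                                         end = st + lens))
  }
  p_up <- (1 + colSums(null >= matrix(obs, n_permutations, length(obs),
                                      byrow = TRUE))) / (n_permutations + 1)
  p_dn <- (1 + colSums(null <= matrix(obs, n_permutations, length(obs),
                                      byrow = TRUE))) / (n_permutations + 1)
  expected <- colMeans(null)
  data.frame(
    class = names(classes),
    observed_fraction = unname(obs),
    expected_fraction = unname(expected),
    fold = unname(obs / pmax(expected, .Machine$double.eps)),
    p = unname(pmin(1, 2 * pmin(p_up, p_dn))),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
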