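# Sliding-window segmentation of DIP-Seq enrichment with a Monte-Carlo
# permutation background model.
#
# Windows tile each chromosome at a fixed step (default: 1000 bp windows,
# 500 bp step). The null distribution of window tag counts is built by
# redrawing tag positions uniformly within each chromosome (tag count per
# chromosome preserved); windows whose observed count has a small empirical
# upper-tail probability under that null are merged into enriched regions.

window_starts <- function(chrom_len, window_bp, step_bp) {
  if (window_bp >= chrom_len) return(0)
  seq(0, chrom_len - 1, by = step_bp)
}

#' Count tags in sliding windows
#'
#' A tag at position `p` contributes to every window whose half-open interval
#' contains `p`. Trailing windows truncated by the chromosome end are kept and
#' flagged `partial`. A window larger than the chromosome degrades to a single
#' whole-chromosome window with a warning.
#'
#' @param tags a [tag_set()]
#' @param window_bp window width in bp (default 1000)
#' @param step_bp step between window starts in bp; must satisfy
#'   `1 <= step_bp <= window_bp`
#' @return object of class `window_counts`: list with `windows` (data.frame
#'   `chrom`, `start`, `end`, `count`, `partial`), `window_bp`, `step_bp`,
#'   `n_tags`
#' @export
count_windows <- function(tags, window_bp = 1000L, step_bp = window_bp %/% 2L) {
  stopifnot(inherits(tags, "tag_set"))
  if (!(step_bp >= 1 && window_bp >= step_bp)) {
    stop("need window_bp >= step_bp >= 1")
  }
  chroms <- names(tags$genome)
  per <- lapply(chroms, function(ch) {
    len <- tags$genome[[ch]]
    wb <- window_bp
    if (wb >= len) {
      warning(sprintf("window (%d bp) >= chromosome %s (%d bp); using one whole-chromosome window",
                      as.integer(window_bp), ch, as.integer(len)))
    }
    starts <- window_starts(len, wb, step_bp)
    ends <- pmin(starts + wb, len)
    pos <- sort(tags$tags$pos[tags$tags$chrom == ch])
    # count = #tags with start <= pos < end, via ECDF on sorted positions
    cnt <- findInterval(ends - 0.5, pos) - findInterval(starts - 0.5, pos)
    data.frame(chrom = ch, start = starts, end = ends, count = cnt,
               partial = (ends - starts) < wb, stringsAsFactors = FALSE)
  })
  structure(
    list(windows = do.call(rbind, per), window_bp = as.integer(window_bp),
         step_bp = as.integer(step_bp), n_tags = nrow(tags$tags),
         genome = tags$genome),
    class = "window_counts"
  )
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d windows (%d bp, step %d bp), %d tags\n",
              nrow(x$windows), x$window_bp, x$step_bp, x$n_tags))
  invisible(x)
}

# One permutation draw of full-window counts for one chromosome.
# When step divides window, tag positions only matter through their step-bin
# membership, so uniform redraws are generated directly as multinomial bin
# counts and windows are rolling sums of bins; otherwise positions are drawn
# uniformly and counted per window.
perm_window_counts <- function(n_tags, chrom_len, window_bp, step_bp) {
  if (n_tags == 0) {
    starts <- window_starts(chrom_len, window_bp, step_bp)
    full <- (pmin(starts + window_bp, chrom_len) - starts) == window_bp
    return(integer(sum(full)))
  }
  if (window_bp %% step_bp == 0) {
    nbins <- ceiling(chrom_len / step_bp)
    widths <- rep(step_bp, nbins)
    widths[nbins] <- chrom_len - (nbins - 1) * step_bp
    bins <- as.vector(rmultinom(1, n_tags, widths / chrom_len))
    k <- window_bp %/% step_bp
    cs <- c(0, cumsum(bins))
    # windows entirely inside the chromosome only
    n_full <- floor((chrom_len - window_bp) / step_bp) + 1
    if (n_full < 1) return(integer(0))
    cs[(k + 1):(n_full + k)] - cs[1:n_full]
  } else {
    pos <- sort(floor(runif(n_tags, 0, chrom_len)))
    starts <- window_starts(chrom_len, window_bp, step_bp)
    ends <- pmin(starts + window_bp, chrom_len)
    full <- (ends - starts) == window_bp
    (findInterval(ends - 0.5, pos) - findInterval(starts - 0.5, pos))[full]
  }
}

#' Monte-Carlo null distribution of window counts
#'
#' For each permutation, tag positions are redrawn uniformly within each
#' chromosome, preserving the per-chromosome tag count, and windows are
#' re-counted. The pooled counts over all permutations and full-width windows
#' give the empirical null; upper-tail probabilities use the add-one estimator
#' `P(N >= c) = (1 + #draws >= c) / (n_draws + 1)`, so p-values are in (0, 1].
#'
#' @param tags a [tag_set()]; must contain at least one tag
#' @param window_bp,step_bp window geometry, matching the observed counts
#' @param n_permutations number of Monte-Carlo permutations (>= 1)
#' @param seed integer seed for the permutation stream
#' @return object of class `mc_null`: `tail_p[c + 1] = P(N >= c)` for
#'   `c = 0..max_count`, plus `n_draws`, `window_bp`, `step_bp`
#' @export
monte_carlo_null <- function(tags, window_bp = 1000L,
                             step_bp = window_bp %/% 2L,
                             n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(tags, "tag_set"), n_permutations >= 1)
  if (nrow(tags$tags) == 0) stop("no tags: null distribution undefined")
  per_chrom <- table(factor(tags$tags$chrom, levels = names(tags$genome)))
  set.seed(as.integer(seed))
  max_seen <- 0L
  tab <- numeric(0)  # tab[c+1] = #draws with count == c
  for (b in seq_len(n_permutations)) {
    for (ch in names(tags$genome)) {
      cnt <- perm_window_counts(as.integer(per_chrom[[ch]]),
                                tags$genome[[ch]], window_bp, step_bp)
      if (!length(cnt)) next
      mx <- max(cnt)
      if (mx + 1 > length(tab)) tab <- c(tab, numeric(mx + 1 - length(tab)))
      t2 <- tabulate(cnt + 1L, nbins = length(tab))
      tab <- tab + t2
    }
  }
  n_draws <- sum(tab)
  # upper tail with add-one correction (p in (0,1])
  tail_counts <- rev(cumsum(rev(tab)))
  tail_p <- (1 + tail_counts) / (n_draws + 1)
  structure(
    list(tail_p = tail_p, n_draws = n_draws,
         window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
         n_permutations = as.integer(n_permutations), seed = as.integer(seed)),
    class = "mc_null"
  )
}

#' @export
print.mc_null <- function(x, ...) {
  cat(sprintf("mc_null: %d permutations, %.3g pooled window draws, min attainable p = %.3g\n",
              x$n_permutations, x$n_draws, 1 / (x$n_draws + 1)))
  invisible(x)
}

#' Empirical upper-tail probability of window counts under the null
#'
#' @param null an `mc_null`
#' @param count observed window count(s); non-integer values (width-rescaled
#'   partial windows) use the tail at `ceiling(count)`
#' @return `P(N >= count)` per element, in (0, 1]
#' @export
null_tail_p <- function(null, count) {
  stopifnot(inherits(null, "mc_null"))
  c_int <- as.integer(ceiling(count))
  idx <- pmin(c_int + 1L, length(null$tail_p))
  p <- null$tail_p[idx]
  # counts beyond anything seen in the null get the minimum attainable p
  p[c_int + 1L > length(null$tail_p)] <- 1 / (null$n_draws + 1)
  p[c_int <= 0] <- 1
  p
}

#' Segment enriched regions from windowed counts
#'
#' Windows with empirical p <= `alpha` are retained; retained windows that
#' overlap or lie within `merge_gap_bp` of each other are merged. A region's
#' empirical p is the minimum window p and its extent the union of its
#' windows. Partial terminal windows are rescaled to full-window width before
#' the tail lookup.
#'
#' @param obs a `window_counts` from [count_windows()]
#' @param null an `mc_null` from [monte_carlo_null()] with the same geometry
#' @param alpha window retention level (default 0.001)
#' @param merge_gap_bp maximum gap between merged windows (default: window
#'   width)
#' @param min_region_bp minimum width of a reported region. With overlapping
#'   windows (step < window) the default `window_bp + step_bp` demands
#'   support from at least two windows, which suppresses isolated
#'   single-window noise calls; with non-overlapping windows the default is
#'   0 (every significant window can stand alone)
#' @param mark,library_id labels carried into the result
#' @return object of class `enriched_regions`: data.frame `chrom`, `start`,
#'   `end`, `max_count`, `p` (sorted, non-overlapping), with attributes
#'   `mark`, `library_id`, `alpha`
#' @export
segment_enriched_regions <- function(obs, null, alpha = 0.001,
                                     merge_gap_bp = obs$window_bp,
                                     min_region_bp = if (obs$step_bp <
                                       obs$window_bp)
                                       obs$window_bp + obs$step_bp else 0L,
                                     mark = "5mC", library_id = "lib") {
  stopifnot(inherits(obs, "window_counts"), inherits(null, "mc_null"))
  if (obs$window_bp != null$window_bp || obs$step_bp != null$step_bp) {
    stop("null was built with different window/step settings")
  }
  w <- obs$windows
  eff <- w$count * ifelse(w$partial, obs$window_bp / (w$end - w$start), 1)
  p <- null_tail_p(null, eff)
  keep <- which(p <= alpha)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      max_count = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) {
    return(structure(empty, class = c("enriched_regions", "data.frame"),
                     mark = mark, library_id = library_id, alpha = alpha))
  }
  sig <- w[keep, ]
  sig$p <- p[keep]
  gr <- intervals_to_gr(sig)
  GenomicRanges::strand(gr) <- "*"
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap_bp + 1L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  reg <- gr_to_intervals(merged)
  reg$max_count <- as.integer(tapply(sig$count[S4Vectors::queryHits(hit)],
                                     S4Vectors::subjectHits(hit), max))
  reg$p <- as.numeric(tapply(sig$p[S4Vectors::queryHits(hit)],
                             S4Vectors::subjectHits(hit), min))
  reg$strand <- NULL
  reg <- reg[reg$end - reg$start >= min_region_bp, , drop = FALSE]
  reg <- reg[order(reg$chrom, reg$start), ]
  rownames(reg) <- NULL
  structure(reg, class = c("enriched_regions", "data.frame"),
            mark = mark, library_id = library_id, alpha = alpha)
}

#' @export
print.enriched_regions <- function(x, ...) {
  cat(sprintf("enriched_regions: %d regions (%s, %s), alpha = %g\n",
              nrow(x), attr(x, "mark"), attr(x, "library_id"),
              attr(x, "alpha")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' One-call segmentation of a tag set
#'
#' Convenience wrapper: [count_windows()], [monte_carlo_null()],
#' [segment_enriched_regions()] with settings from a [dip_config()].
#'
#' @param tags a [tag_set()]
#' @param cfg a [dip_config()]
#' @param alpha window retention level (default `cfg$enrichment_alpha`)
#' @export
segment_tags <- function(tags, cfg = dip_config(), alpha = cfg$enrichment_alpha) {
  obs <- count_windows(tags, cfg$window_bp, cfg$window_step_bp)
  null <- monte_carlo_null(tags, cfg$window_bp, cfg$window_step_bp,
                           cfg$n_permutations, seed = cfg$seed)
  segment_enriched_regions(obs, null, alpha = alpha,
                           mark = tags$mark, library_id = tags$library_id)
}
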