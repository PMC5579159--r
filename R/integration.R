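# Cross-dataset integration: direction-stratified Fisher overlap tests of
# gene sets, in-silico replicate pooling with a per-region Fisher test
# (the pooled-sample comparison used for cross-time-point analyses), K-means
# clustering of gene-level methylation profiles, and metagene / heatmap
# visualization of tag density.

#' Fisher exact test of gene-set overlap
#'
#' Builds the 2x2 table from the universe and applies a two-sided Fisher
#' exact test. The odds ratio is the sample (cross-product) odds ratio, with
#' a Haldane correction of 0.5 per cell when any cell is zero. The test is
#' symmetric in its two sets.
#'
#' @param genes_a,genes_b character vectors (subsets of `universe`)
#' @param universe character vector of all eligible genes
#' @param label_a,label_b optional labels carried into the result
#' @return one-row data.frame: labels, `n_a`, `n_b`, `n_overlap`,
#'   `universe_size`, `odds_ratio`, `p`
#' @export
overlap_test <- function(genes_a, genes_b, universe,
                         label_a = "set_a", label_b = "set_b") {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  a <- unique(as.character(genes_a)); b <- unique(as.character(genes_b))
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  k <- length(intersect(a, b))
  n11 <- k
  n12 <- length(a) - k
  n21 <- length(b) - k
  n22 <- length(universe) - length(a) - length(b) + k
  tab <- matrix(c(n11, n21, n12, n22), 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (any(tab == 0)) {
    ((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5))
  } else (n11 * n22) / (n12 * n21)
  data.frame(set_a = label_a, set_b = label_b,
             n_a = length(a), n_b = length(b), n_overlap = k,
             universe_size = length(universe), odds_ratio = or, p = p,
             stringsAsFactors = FALSE)
}

#' Family of overlap tests with BH adjustment
#'
#' @param pairs named list; each element a list with `a`, `b` (gene id
#'   vectors) and optional `label_a`, `label_b`
#' @param universe common gene universe
#' @return data.frame with one row per pair and a BH-adjusted `q` column
#' @export
overlap_tests <- function(pairs, universe) {
  rows <- lapply(names(pairs), function(nm) {
    pr <- pairs[[nm]]
    overlap_test(pr$a, pr$b, universe,
                 label_a = pr$label_a %||% paste0(nm, "_a"),
                 label_b = pr$label_b %||% paste0(nm, "_b"))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Pool replicate tag sets in silico
#'
#' @param tagsets list of [tag_set()]s of the same mark, condition and genome
#' @return a single [tag_set()] with the tag multiset union;
#'   `library_id` is the concatenation of the inputs'
#' @export
pool_in_silico <- function(tagsets) {
  stopifnot(length(tagsets) >= 1)
  g1 <- tagsets[[1]]$genome
  for (ts in tagsets[-1]) {
    if (!identical(ts$genome, g1)) stop("mismatched genomes")
    if (ts$mark != tagsets[[1]]$mark ||
        ts$condition != tagsets[[1]]$condition) {
      stop("pool only replicates of one mark and condition")
    }
  }
  tags <- do.call(rbind, lapply(tagsets, function(ts) ts$tags))
  tag_set(tags, g1,
          library_id = paste(vapply(tagsets, `[[`, "", "library_id"),
                             collapse = "+"),
          mark = tagsets[[1]]$mark, condition = tagsets[[1]]$condition)
}

#' Per-region Fisher test between two pooled libraries
#'
#' For each region, the 2x2 table (tags in region vs tags elsewhere, per
#' library) is tested with a two-sided Fisher exact test; p-values are
#' BH-adjusted. Direction is the sign of the normalized proportion
#' difference, treatment (second library) minus reference (first).
#'
#' @param pooled_ref,pooled_trt pooled [tag_set()]s (reference, e.g. sham,
#'   and treatment, e.g. irradiated)
#' @param regions data.frame of non-overlapping intervals
#' @return data.frame: regions with `count_ref`, `count_trt`, `p`, `q`,
#'   `direction`
#' @export
pooled_region_test <- function(pooled_ref, pooled_trt, regions) {
  n_ref <- nrow(pooled_ref$tags); n_trt <- nrow(pooled_trt$tags)
  if (n_ref == 0 || n_trt == 0) stop("a pooled library has zero tags")
  rc <- count_tags_in_regions(list(pooled_ref, pooled_trt), regions)
  k_ref <- rc$counts[, 1]; k_trt <- rc$counts[, 2]
  p <- vapply(seq_len(nrow(regions)), function(i) {
    fisher.test(matrix(c(k_trt[i], n_trt - k_trt[i],
                         k_ref[i], n_ref - k_ref[i]), 2))$p.value
  }, numeric(1))
  prop_diff <- k_trt / n_trt - k_ref / n_ref
  out <- data.frame(regions, count_ref = k_ref, count_trt = k_trt,
                    p = p, q = bh_adjust(p),
                    direction = ifelse(prop_diff >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-level methylation-change profiles
#'
#' The feature vector per gene: signed -log10 best q for each mark (sign =
#' direction of the most significant associated region) and the mean
#' normalized tag density per mark, the summaries fed to
#' [kmeans_profiles()].
#'
#' @param annot_by_mark named list (one element per mark) of annotated
#'   `differential_regions` tables with `gene_id`, `q`, `direction`,
#'   `base_mean`
#' @return data.frame: `gene_id` plus `signed_score_<mark>` and
#'   `level_<mark>` columns; genes with no region for a mark get 0 score
#'   and 0 level
#' @export
gene_methylation_profiles <- function(annot_by_mark) {
  stopifnot(length(annot_by_mark) >= 1, !is.null(names(annot_by_mark)))
  ids <- sort(unique(unlist(lapply(annot_by_mark, function(a) {
    a$gene_id[!is.na(a$gene_id)]
  }))))
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (mk in names(annot_by_mark)) {
    a <- annot_by_mark[[mk]]
    a <- a[!is.na(a$gene_id), , drop = FALSE]
    best <- a[order(a$gene_id, a$q), ]
    best <- best[!duplicated(best$gene_id), ]
    i <- match(ids, best$gene_id)
    score <- ifelse(is.na(i), 0,
                    -log10(pmax(best$q[i], .Machine$double.xmin)) *
                      ifelse(best$direction[i] == "up", 1, -1))
    lev <- vapply(ids, function(g) {
      m <- a$base_mean[a$gene_id == g]
      if (length(m)) mean(m) else 0
    }, numeric(1))
    out[[paste0("signed_score_", mk)]] <- score
    out[[paste0("level_", mk)]] <- unname(lev)
  }
  out
}

#' K-means clustering of gene methylation profiles
#'
#' Features are standardized per dimension (zero-variance dimensions
#' dropped); the best of `n_starts` random initializations by total
#' within-cluster sum of squares is kept, and cluster labels are
#' canonicalized by descending cluster size. Also reports the mean
#' silhouette width for a range of k to guide the choice.
#'
#' @param profiles data.frame from [gene_methylation_profiles()] (first
#'   column `gene_id`, the rest numeric features)
#' @param k number of clusters (default 4)
#' @param n_starts random restarts (default 25)
#' @param seed RNG seed
#' @param silhouette_k integer vector of k values for the silhouette report
#'   (NULL to skip)
#' @return list with `cluster` (named integer vector), `centers`,
#'   `tot_withinss`, `silhouette` (data.frame k / mean width, or NULL)
#' @export
kmeans_profiles <- function(profiles, k = 4L, n_starts = 25L, seed = 1L,
                            silhouette_k = NULL) {
  x <- as.matrix(profiles[, setdiff(names(profiles), "gene_id"), drop = FALSE])
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (k > nrow(x)) stop("k exceeds the number of genes")
  sdv <- apply(x, 2, sd)
  x <- scale(x[, sdv > 0, drop = FALSE])
  set.seed(as.integer(seed))
  fit <- kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  # canonical labels: descending cluster size, ties by first occurrence
  sizes <- tabulate(fit$cluster, k)
  relab <- order(-sizes, seq_len(k))
  newlab <- match(fit$cluster, relab)
  cl <- setNames(newlab, profiles$gene_id)
  sil <- NULL
  if (!is.null(silhouette_k)) {
    dm <- as.matrix(dist(x))
    sil <- data.frame(k = silhouette_k, mean_silhouette = vapply(
      silhouette_k, function(kk) {
        if (kk < 2 || kk >= nrow(x)) return(NA_real_)
        f <- kmeans(x, centers = kk, nstart = n_starts, iter.max = 100L)
        mean_silhouette(dm, f$cluster)
      }, numeric(1)))
  }
  list(cluster = cl, centers = fit$centers[relab, , drop = FALSE],
       tot_withinss = fit$tot.withinss, silhouette = sil)
}

# mean silhouette width from a distance matrix and hard labels
mean_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  ks <- sort(unique(labels))
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- if (any(same)) mean(dm[i, same]) else 0
    b <- min(vapply(ks[ks != labels[i]], function(g) {
      mean(dm[i, labels == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Metagene tag-density matrix
#'
#' Per gene: `n_flank_bins` fixed-width bins over each `flank_bp` flank and
#' `n_body_bins` bins over the body rescaled to unit length, oriented 5'->3'
#' (minus-strand genes are flipped). Bin tag counts are divided by bin width
#' and then by the genome-wide median window density ("median-normalized"),
#' so a uniform library gives values near 1. Rows are ordered by descending
#' `expression`. Genes shorter than `n_body_bins` bp are skipped with a
#' warning.
#'
#' @param tags a [tag_set()]
#' @param genes gene model table
#' @param flank_bp flank width (default 10000)
#' @param n_body_bins bins across the gene body (default 100)
#' @param n_flank_bins bins per flank (default 50)
#' @param expression named numeric vector (gene_id -> expression); genes
#'   missing from it get -Inf and sort last
#' @return matrix genes x (2 * n_flank_bins + n_body_bins), rownames =
#'   gene ids in plotted (descending-expression) order; attribute
#'   `median_density` holds the normalizer (tags/bp)
#' @export
metagene_matrix <- function(tags, genes, flank_bp = 10000L,
                            n_body_bins = 100L, n_flank_bins = 50L,
                            expression = NULL) {
  stopifnot(inherits(tags, "tag_set"), nrow(genes) >= 1)
  short <- genes$length < n_body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than n_body_bins bp skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  wc <- count_windows(tags, 1000L, 1000L)
  med <- median(wc$windows$count[!wc$windows$partial]) / 1000
  if (med <= 0) stop("median window density is zero; library too sparse")
  pos_by_chrom <- split(tags$tags$pos, tags$tags$chrom)
  pos_by_chrom <- lapply(pos_by_chrom, sort)
  nb <- 2L * n_flank_bins + n_body_bins
  mat <- matrix(0, nrow(genes), nb)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up_edges <- seq(g$start - flank_bp, g$start, length.out = n_flank_bins + 1)
    body_edges <- seq(g$start, g$end, length.out = n_body_bins + 1)
    dn_edges <- seq(g$end, g$end + flank_bp, length.out = n_flank_bins + 1)
    edges <- c(up_edges, body_edges[-1], dn_edges[-1])
    pos <- pos_by_chrom[[g$chrom]] %||% numeric(0)
    cum <- findInterval(edges - 0.5, pos)
    cnt <- diff(cum)
    dens <- cnt / diff(edges) / med
    if (g$strand == "-") dens <- rev(dens)
    mat[i, ] <- dens
  }
  rownames(mat) <- genes$gene_id
  colnames(mat) <- c(paste0("up", seq_len(n_flank_bins)),
                     paste0("body", seq_len(n_body_bins)),
                     paste0("down", seq_len(n_flank_bins)))
  expr <- if (is.null(expression)) {
    setNames(genes$expr_level %||% rep(0, nrow(genes)), genes$gene_id)
  } else expression
  ev <- expr[rownames(mat)]
  ev[is.na(ev)] <- -Inf
  mat <- mat[order(-ev), , drop = FALSE]
  attr(mat, "median_density") <- med
  mat
}

#' Row-scale a matrix and render it as a capped heatmap
#'
#' Each row is centered and scaled to unit (population) variance;
#' zero-variance rows become 0. For rendering, values are capped at the
#' `cap_quantile` quantile of the scaled matrix (the published convention:
#' color maps scaled to the 80% quantile).
#'
#' @param m numeric matrix (non-empty)
#' @param cap_quantile rendering cap (default 0.80)
#' @param plot draw the heatmap with [graphics::image()]?
#' @return list with `scaled` (row-scaled matrix), `capped` (scaled matrix
#'   truncated at the cap), `cap_value`
#' @export
row_scaled_heatmap <- function(m, cap_quantile = 0.80, plot = FALSE) {
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))  # population SD
  scaled <- (m - mu) / ifelse(sdp > 0, sdp, 1)
  scaled[sdp == 0, ] <- 0
  cap <- quantile(scaled, cap_quantile, names = FALSE)
  capped <- pmin(scaled, cap)
  if (plot) {
    image(t(capped[rev(seq_len(nrow(capped))), , drop = FALSE]),
          col = hcl.colors(64, "RdYlGn", rev = TRUE), axes = FALSE,
          xlab = "bins", ylab = "regions")
  }
  list(scaled = scaled, capped = capped, cap_value = cap)
}

#' Plot a metagene heatmap or average profile
#'
#' @param mat matrix from [metagene_matrix()]
#' @param cap_quantile color cap (default 0.80 quantile of the matrix)
#' @param type `"heatmap"` (genes x bins) or `"profile"` (column means)
#' @return invisibly, the capped matrix or the profile vector
#' @export
plot_metagene <- function(mat, cap_quantile = 0.80,
                          type = c("heatmap", "profile")) {
  type <- match.arg(type)
  if (type == "profile") {
    prof <- colMeans(mat)
    graphics::plot(seq_along(prof), prof, type = "l",
                   xlab = "bin (5' flank | body | 3' flank)",
                   ylab = "median-normalized density")
    return(invisible(prof))
  }
  cap <- quantile(mat, cap_quantile, names = FALSE)
  capped <- pmin(mat, cap)
  image(t(capped[rev(seq_len(nrow(capped))), , drop = FALSE]),
        col = hcl.colors(64, "Spectral", rev = TRUE), axes = FALSE,
        xlab = "bins", ylab = "genes (by expression)")
  invisible(capped)
}
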