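test_that("bidirectional overlap p equals exhaustive enumeration on a toy universe", {
  universe <- sprintf("g%02d", 1:20)
  up <- universe[1:5]
  down <- universe[c(1, 2, 3, 10)]   # overlap 3
  res <- find_bidirectional_genes(up, down, universe)
  expect_equal(res$bidirectional_genes, c("g01", "g02", "g03"))

  # oracle: enumerate all C(20,4) possible down-sets, count those sharing
  # >= 3 genes with the up-set
  combos <- combn(20, 4)
  share <- colSums(matrix(combos %in% 1:5, nrow = 4))
  p_enum <- mean(share >= 3)
  expect_equal(res$overlap_p, p_enum, tolerance = 1e-12)

  # disjoint sets: empty intersection, upper tail includes 0 -> p = 1
  res0 <- find_bidirectional_genes(universe[1:5], universe[6:9], universe)
  expect_length(res0$bidirectional_genes, 0)
  expect_equal(res0$overlap_p, 1)

  expect_error(find_bidirectional_genes(universe, down, universe[1:3]),
               "universe")
})

test_that("set algebra is identical from annotations and from id vectors", {
  ann_up <- data.frame(gene_id = c("a", "a", "b", NA), p = c(1, 1, 1, 1) / 10)
  ann_dn <- data.frame(gene_id = c("b", "c", NA), p = c(0.01, 0.02, 0.5))
  uni <- c("a", "b", "c", "d")
  r1 <- find_bidirectional_genes(ann_up, ann_dn, uni)
  r2 <- find_bidirectional_genes(c("a", "b"), c("b", "c"), uni)
  expect_identical(r1[c("up_genes", "down_genes", "bidirectional_genes",
                        "overlap_p")],
                   r2[c("up_genes", "down_genes", "bidirectional_genes",
                        "overlap_p")])
})

test_that("density bins follow the transcription direction and the length filter", {
  genes <- mk_genes(chrom = c("chr1", "chr1", "chr1"),
                    start = c(0, 300000, 700000),
                    end = c(220000, 520000, 750000),
                    strand = c("+", "-", "+"),
                    gene_id = c("plus", "minus", "short"))
  # plus-strand gene, DHR midpoints at TSS + 10k, 60k, 110k, 160k
  mk_dhr <- function(mids, gid) {
    data.frame(chrom = "chr1", start = mids - 500L, end = mids + 500L,
               gene_id = gid, stringsAsFactors = FALSE)
  }
  d_plus <- mk_dhr(c(10000L, 60000L, 110000L, 160000L), "plus")
  # minus-strand mirror: TSS = 519999, offsets 10k/60k/110k/160k go leftward
  d_minus <- mk_dhr(519999L - c(10000L, 60000L, 110000L, 160000L), "minus")
  tab <- dhr_density_bins(genes, rbind(d_plus, d_minus))
  expect_equal(rownames(tab), c("plus", "minus"))  # 'short' filtered out
  expect_equal(unname(tab["plus", ]), c(1L, 1L, 1L, 1L))
  expect_equal(unname(tab["minus", ]), c(1L, 1L, 1L, 1L))

  # gene with no DHR: row of zeros
  tab0 <- dhr_density_bins(genes, d_plus)
  expect_equal(unname(tab0["minus", ]), rep(0L, 4))

  # offsets beyond the binned span are not counted
  far <- mk_dhr(210000L, "plus")
  expect_equal(sum(dhr_density_bins(genes, far)["plus", ]), 0)

  expect_error(dhr_density_bins(genes, d_plus, min_gene_length_bp = 150000),
               "exceeds")
})

test_that("strand symmetry: mirroring the genome leaves the density table invariant", {
  L <- 1e6
  genes <- mk_genes("chr1", c(100000, 500000), c(350000, 800000),
                    c("+", "-"), c("gA", "gB"))
  set.seed(4)
  mids <- c(sample(100000:349999, 6), sample(500000:799999, 5))
  dhr <- data.frame(chrom = "chr1", start = mids - 100L, end = mids + 100L,
                    gene_id = c(rep("gA", 6), rep("gB", 5)))
  tab <- dhr_density_bins(genes, dhr)
  # mirror: x -> L - x, strands flipped
  genes_m <- mk_genes("chr1", L - c(350000, 800000), L - c(100000, 500000),
                      c("-", "+"), c("gA", "gB"))
  dhr_m <- data.frame(chrom = "chr1", start = L - (mids + 100L),
                      end = L - (mids - 100L),
                      gene_id = dhr$gene_id)
  tab_m <- dhr_density_bins(genes_m, dhr_m)
  expect_equal(tab_m[rownames(tab), ], tab[rownames(tab), ])
})

test_that("permutation density test matches exhaustive enumeration on tiny contrasts", {
  x <- matrix(c(5, 1, 4, 2, 3, 1, 0, 1, 1, 0,
                1, 0, 2, 1, 0, 0, 1, 0, 0, 1), nrow = 5)
  labels <- c("bidirectional", "bidirectional", "bidirectional",
              "up_only", "up_only")
  # B >= C(5,3) = 10 triggers exact enumeration over all splits
  res <- permutation_density_test(x, labels,
                                  c("bidirectional", "up_only"),
                                  n_permutations = 1000, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_splits, 10)
  # hand enumeration of the global statistic
  splits <- combn(5, 3)
  g_all <- apply(splits, 2, function(i) {
    sum(colMeans(x[i, , drop = FALSE]) - colMeans(x[-i, , drop = FALSE]))
  })
  g_obs <- sum(colMeans(x[1:3, ]) - colMeans(x[4:5, ]))
  expect_equal(res$global_p, mean(abs(g_all) >= abs(g_obs) - 1e-12))

  # identical rows in both classes: T = 0, p = 1
  xx <- matrix(1, nrow = 4, ncol = 3)
  res0 <- permutation_density_test(xx, c("a", "a", "b", "b"), c("a", "b"),
                                   n_permutations = 50, seed = 1)
  expect_equal(unname(res0$observed), rep(0, 3))
  expect_equal(res0$global_p, 1)

  expect_error(permutation_density_test(x, labels, c("bidirectional", "none"),
                                        100, 1), "non-empty")
})

test_that("permutation density test is calibrated under label exchange", {
  set.seed(12)
  rej <- vapply(1:200, function(b) {
    x <- matrix(rpois(20 * 4, 2), nrow = 20)
    lab <- rep(c("a", "b"), each = 10)
    permutation_density_test(x, lab, c("a", "b"),
                             n_permutations = 99, seed = b)$global_p <= 0.05
  }, logical(1))
  # rejection rate near nominal (binomial 99% band around 0.05 for 200 runs)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("density-significance correlation behaves on constructed inputs", {
  genes <- mk_genes("chr1", seq(0, 4) * 3e5, seq(0, 4) * 3e5 + 250000,
                    rep("+", 5), sprintf("g%d", 1:5))
  # density strictly increasing with significance score
  dhr <- do.call(rbind, lapply(1:5, function(i) {
    k <- i  # i DHRs for gene i
    data.frame(chrom = "chr1", start = genes$start[i] + seq_len(k) * 10000L,
               end = genes$start[i] + seq_len(k) * 10000L + 1000L,
               gene_id = genes$gene_id[i], p = 10^(-i),
               stringsAsFactors = FALSE)
  }))
  tab <- dhr_density_bins(genes, dhr, min_gene_length_bp = 200000,
                          bin_bp = 50000, n_bins = 4)
  res <- density_vs_significance(genes, dhr, tab)
  expect_equal(res$rho, 1)

  # constant density: rho 0 by convention, with a warning
  dhr2 <- dhr[!duplicated(dhr$gene_id), ]
  dhr2$p <- 0.5
  tab2 <- dhr_density_bins(genes, dhr2)
  expect_warning(res2 <- density_vs_significance(genes, dhr2, tab2),
                 "zero variance")
  expect_equal(res2$rho, 0)

  expect_error(density_vs_significance(genes, dhr[1, ], tab[1, , drop = FALSE]),
               ">= 3 genes")
})

test_that("recovery report handles perfect, empty, and partial detection", {
  truth <- list(bidirectional_genes = c("a", "b", "c"))
  perfect <- structure(list(bidirectional_genes = c("a", "b", "c")),
                       class = "bidirectional_result")
  r <- bidirectional_recovery_report(perfect, truth)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)

  none <- structure(list(bidirectional_genes = character(0)),
                    class = "bidirectional_result")
  r0 <- bidirectional_recovery_report(none, truth)
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  part <- structure(list(bidirectional_genes = c("a", "z")),
                    class = "bidirectional_result")
  rp <- bidirectional_recovery_report(part, truth)
  expect_equal(rp$recall, 1 / 3)
  expect_equal(rp$precision, 1 / 2)
})
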