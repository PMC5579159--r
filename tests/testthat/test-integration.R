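test_that("overlap test equals hypergeometric enumeration and is symmetric", {
  universe <- sprintf("g%02d", 1:20)
  a <- universe[1:4]                 # table (1,3,2,14): overlap 1
  b <- universe[c(1, 5, 6)]
  res <- overlap_test(a, b, universe)
  # oracle: full enumeration of the two-sided Fisher p over the support
  k <- 0:3
  probs <- dhyper(k, 4, 16, 3)
  p_enum <- sum(probs[probs <= dhyper(1, 4, 16, 3) + 1e-12])
  expect_equal(res$p, p_enum, tolerance = 1e-10)
  expect_equal(res$n_overlap, 1)

  # symmetry
  res_ba <- overlap_test(b, a, universe)
  expect_equal(res_ba$p, res$p)
  expect_equal(res_ba$n_overlap, res$n_overlap)

  # independence expectation -> odds ratio ~ 1: 10x10 overlap 5 in 20
  res1 <- overlap_test(universe[1:10], universe[c(1:5, 11:15)], universe)
  expect_equal(res1$odds_ratio, 1, tolerance = 1e-12)

  expect_error(overlap_test(a, b, character(0)), "empty universe")

  # family version adjusts with BH
  fam <- overlap_tests(list(one = list(a = a, b = b),
                            two = list(a = universe[1:10],
                                       b = universe[1:10])), universe)
  expect_equal(fam$q, bh_adjust(fam$p))
})

test_that("in-silico pooling is a tag multiset union and counts add", {
  genome <- c(chr1 = 50000)
  t1 <- mk_tags(c(10, 500, 2500), chrom_len = 50000, library_id = "r1")
  t2 <- mk_tags(c(500, 900), chrom_len = 50000, library_id = "r2")
  pooled <- pool_in_silico(list(t1, t2))
  expect_equal(nrow(pooled$tags), 5)
  expect_equal(pooled$library_id, "r1+r2")
  # single replicate: identity
  expect_equal(pool_in_silico(list(t1))$tags, t1$tags)

  # pooled window counts equal the sum of per-replicate window counts
  wp <- count_windows(pooled, 1000, 500)
  w1 <- count_windows(t1, 1000, 500)
  w2 <- count_windows(t2, 1000, 500)
  expect_identical(wp$windows$count, w1$windows$count + w2$windows$count)

  t3 <- mk_tags(5, chrom_len = 99, library_id = "other")
  expect_error(pool_in_silico(list(t1, t3)), "mismatched genomes")
  t4 <- tag_set(t2$tags, genome, mark = "5hmC")
  expect_error(pool_in_silico(list(t1, t4)), "one mark")
})

test_that("pooled region test matches the hypergeometric tail and reports direction", {
  genome <- c(chr1 = 1e6)
  set.seed(6)
  # construct libraries with known per-region counts: 30/1000 vs 10/1000
  reg <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  mk_lib <- function(k, n, id, cond) {
    pos <- c(sample(0:9999, k, replace = TRUE),
             sample(20000:999999, n - k, replace = TRUE))
    mk_tags(pos, chrom_len = 1e6, library_id = id, condition = cond)
  }
  ref <- mk_lib(10, 1000, "sham_pool", "sham")
  trt <- mk_lib(30, 1000, "irr_pool", "irradiated")
  out <- pooled_region_test(ref, trt, reg)
  expect_equal(out$count_ref, 10L)
  expect_equal(out$count_trt, 30L)
  expect_equal(out$direction, "up")
  # oracle: two-sided Fisher p enumerated from the hypergeometric support
  support <- 0:40
  probs <- dhyper(support, 1000, 1000, 40)
  p_enum <- sum(probs[probs <= dhyper(30, 1000, 1000, 40) + 1e-12])
  expect_equal(out$p, p_enum, tolerance = 1e-10)

  # symmetric table: p = 1
  sym <- pooled_region_test(mk_lib(15, 500, "a", "sham"),
                            mk_lib(15, 500, "b", "irradiated"), reg)
  expect_equal(sym$p, 1)

  expect_error(pooled_region_test(mk_tags(integer(0), 1e6), trt, reg),
               "zero tags")
})

test_that("k-means profiling recovers planted structure deterministically", {
  set.seed(3)
  blob <- function(n, cx, cy) {
    data.frame(x = rnorm(n, cx, 0.1), y = rnorm(n, cy, 0.1))
  }
  prof <- cbind(data.frame(gene_id = sprintf("g%02d", 1:40)),
                rbind(blob(25, 5, 5), blob(15, -5, -5)))
  fit <- kmeans_profiles(prof, k = 2, seed = 7)
  # cluster 1 is the larger planted blob, exactly
  expect_equal(unname(fit$cluster[1:25]), rep(1L, 25))
  expect_equal(unname(fit$cluster[26:40]), rep(2L, 15))
  # determinism
  fit2 <- kmeans_profiles(prof, k = 2, seed = 7)
  expect_identical(fit$cluster, fit2$cluster)
  # k = 1: total variance
  fit1 <- kmeans_profiles(prof, k = 1, seed = 7)
  expect_length(unique(fit1$cluster), 1)
  x <- scale(as.matrix(prof[, c("x", "y")]))
  expect_equal(fit1$tot_withinss, sum(scale(x, scale = FALSE)^2))

  expect_error(kmeans_profiles(prof, k = 100), "exceeds")

  sil <- kmeans_profiles(prof, k = 2, seed = 7, silhouette_k = 2:4)
  expect_true(which.max(sil$silhouette$mean_silhouette) == 1)
})

test_that("gene profiles summarize direction, significance, and level per mark", {
  ann <- list(
    `5mC` = data.frame(gene_id = c("a", "a", "b"), q = c(1e-4, 0.5, 0.2),
                       direction = c("down", "up", "up"),
                       base_mean = c(10, 30, 5)),
    `5hmC` = data.frame(gene_id = c("a", NA), q = c(1e-2, 1e-8),
                        direction = c("up", "down"), base_mean = c(8, 99))
  )
  prof <- gene_methylation_profiles(ann)
  expect_equal(prof$gene_id, c("a", "b"))
  expect_equal(prof$signed_score_5mC[1], -4)  # down, q = 1e-4 -> -(-log10 q)
  expect_equal(prof$level_5mC[1], 20)   # mean of 10 and 30
  expect_equal(prof$signed_score_5hmC[2], 0)  # no 5hmC region for b
})

test_that("metagene matrix is flat for uniform tags and median-normalized", {
  set.seed(10)
  L <- 5e6
  ts <- mk_tags(sample.int(L, 150000, replace = TRUE) - 1L, chrom_len = L)
  genes <- mk_genes(chrom = rep("chr1", 20),
                    start = seq(100000, by = 240000, length.out = 20),
                    end = seq(100000, by = 240000, length.out = 20) + 60000,
                    strand = rep(c("+", "-"), 10))
  mm <- metagene_matrix(ts, genes, flank_bp = 10000, n_body_bins = 50,
                        n_flank_bins = 20,
                        expression = setNames(runif(20), genes$gene_id))
  prof <- colMeans(mm)
  expect_equal(mean(prof), 1, tolerance = 0.05)
  expect_lt(sd(prof) / mean(prof), 0.1)   # flat profile

  # genes shorter than the body bin count are skipped with a warning
  tiny <- mk_genes("chr1", 0, 30, "+", "tiny")
  expect_warning(metagene_matrix(ts, rbind(genes, tiny), n_body_bins = 50),
                 "skipped")
})

test_that("row scaling matches hand z-scores and capping uses the quantile", {
  m <- rbind(c(1, 2, 3), c(4, 4, 4))
  hs <- row_scaled_heatmap(m, cap_quantile = 0.80)
  expect_equal(hs$scaled[1, ], c(-1.225, 0, 1.225), tolerance = 1e-3)
  expect_equal(hs$scaled[2, ], c(0, 0, 0))   # constant row -> zeros
  expect_equal(hs$cap_value, quantile(hs$scaled, 0.8, names = FALSE))
  expect_true(all(hs$capped <= hs$cap_value + 1e-12))
})

test_that("two synthetic experiments with shared truth show concordant overlap", {
  # gene universes with a planted shared up-set reproduce the cross-dataset
  # overlap logic: concordant pairs significant, independent pairs not
  set.seed(15)
  universe <- sprintf("g%03d", 1:300)
  shared <- sample(universe, 40)
  up1 <- union(shared, sample(setdiff(universe, shared), 20))
  up2 <- union(shared, sample(setdiff(universe, shared), 20))
  ind1 <- sample(universe, 60)
  ind2 <- sample(universe, 60)
  conc <- overlap_test(up1, up2, universe)
  expect_lt(conc$p, 0.01)
  indep <- overlap_test(ind1, ind2, universe)
  expect_gt(indep$p, 0.01)
})
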